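#' Build the complete knee soft-tissue model for one case
#'
#' Executes the prediction pipeline in dependency order — cartilage layers,
#' menisci, ligaments and patellar tendon, ACL, then PCL — with every stage's
#' output added to the obstacle set of the later stages. All stages are
#' deterministic given their inputs.
#'
#' @param bones named list with `femur`, `tibia_fibula`, `patella`
#'   [knee_mesh()]s of the target case.
#' @param landmarks a [landmark_set()] valid for the bones.
#' @param mean_maps named list of (sealed) mean [thickness_map()]s:
#'   `femoral`, `medial_plateau`, `lateral_plateau`, `patellar`.
#' @param profiles named list of `polynomial_profile`s: `MM_height`,
#'   `MM_width`, `LM_height`, `LM_width`, `ACL_radius`, `PCL_radius`.
#' @param target_length femoral length of the case (mm); computed from the
#'   length landmarks when `NULL`.
#' @param params a [wrap_params()] list shared by all wrapping stages.
#' @param meniscus_nodes,ligament_grid meniscal centerline resolution and
#'   ligament membrane grid `c(n_cols, n_rows)`.
#' @return a `knee_model` list: `cartilage` (named meshes), `menisci`,
#'   `ligaments` (incl. the patellar tendon), `cruciates`, `obstacles`
#'   (final [obstacle_set()]), `target_length`, and a `manifest` data frame
#'   of all produced structures.
#' @export
build_knee_model <- function(bones, landmarks, mean_maps, profiles,
                             target_length = NULL, params = wrap_params(),
                             meniscus_nodes = 60L,
                             ligament_grid = c(20L, 30L)) {
  femur <- bones$femur
  tibia <- bones$tibia_fibula
  patella <- bones$patella
  if (is.null(target_length)) {
    target_length <- femoral_length(femur, landmarks)
  }
  ## stage 1: cartilage by thickness-map projection
  fem_cart <- predict_cartilage(femur, seal_edges(mean_maps$femoral), target_length)
  tib_cart <- predict_cartilage(tibia, seal_edges(mean_maps$medial_plateau), target_length)
  tib_cart <- predict_cartilage(tib_cart, seal_edges(mean_maps$lateral_plateau), target_length)
  pat_cart <- predict_cartilage(patella, seal_edges(mean_maps$patellar), target_length)
  cartilage <- list(femur = fem_cart, tibia_fibula = tib_cart, patella = pat_cart)
  obstacles <- obstacle_set(list(fem_cart, tib_cart, pat_cart))

  ## stage 2: menisci between the tibial and femoral cartilage
  ## (roots are annotated on the bone; lift them onto the cartilage surface)
  root <- function(nm) project_out(landmark_point(landmarks, tibia, nm), obstacles)
  menisci <- list(
    medial = build_meniscus(obstacles, root("MM_anterior_root"),
                            root("MM_posterior_root"),
                            profiles$MM_height, profiles$MM_width,
                            side = "medial", n_nodes = meniscus_nodes,
                            params = params),
    lateral = build_meniscus(obstacles, root("LM_anterior_root"),
                             root("LM_posterior_root"),
                             profiles$LM_height, profiles$LM_width,
                             side = "lateral", n_nodes = meniscus_nodes,
                             params = params))
  for (m in menisci) obstacles <- add_obstacle(obstacles, m$surface)

  ## stage 3: ligament bands and the patellar tendon
  tab <- default_ligament_table()
  mesh_of <- function(bone) switch(bone, femur = femur, tibia_fibula = tibia,
                                   patella = patella)
  att <- function(nm) {
    e <- landmarks$entries[[nm]]
    if (is.null(e)) stop("missing landmark '", nm, "' for ligament prediction")
    transfer_landmarks(landmarks, mesh_of(e$bone), nm)[[1L]]
  }
  ligaments <- list()
  for (i in seq_len(nrow(tab))) {
    ligaments[[tab$name[i]]] <- predict_ligament(
      tab$name[i], att(tab$origin[i]), att(tab$insertion[i]), obstacles,
      thickness = tab$thickness[i],
      n_cols = ligament_grid[1L], n_rows = ligament_grid[2L], params = params)
  }
  ligaments$PT <- predict_patellar_tendon(att("PT_origin"), att("PT_insertion"),
                                          obstacles, params = params)
  for (lg in ligaments) {
    if (is_watertight(lg$solid)) obstacles <- add_obstacle(obstacles, lg$solid)
  }

  ## stage 4/5: cruciates; the ACL tube constrains the PCL course
  cr_pt <- function(mesh, nm) {
    # cruciate attachments are annotated on the bone, which lies inside the
    # cartilage composite; lift them onto the composite surface
    project_out(landmark_point(landmarks, mesh, nm), obstacles)
  }
  acl <- predict_cruciate("ACL", cr_pt(femur, "ACL_origin"),
                          cr_pt(tibia, "ACL_insertion"),
                          obstacles, profiles$ACL_radius, params = params)
  pcl <- predict_cruciate("PCL", cr_pt(femur, "PCL_origin"),
                          cr_pt(tibia, "PCL_insertion"),
                          obstacles, profiles$PCL_radius, acl = acl,
                          params = params)
  obstacles <- add_obstacle(obstacles, acl$tube$surface,
                            inflation = tube_chordal_inflation(acl$tube))
  obstacles <- add_obstacle(obstacles, pcl$tube$surface,
                            inflation = tube_chordal_inflation(pcl$tube))

  structures <- c(
    list(femur = femur, tibia_fibula = tibia, patella = patella),
    stats::setNames(cartilage, paste0(names(cartilage), "_cartilage")),
    stats::setNames(lapply(menisci, `[[`, "surface"),
                    paste0(names(menisci), "_meniscus")),
    stats::setNames(lapply(ligaments, `[[`, "solid"), names(ligaments)),
    list(ACL = acl$tube$surface, PCL = pcl$tube$surface))
  manifest <- data.frame(
    structure = names(structures),
    kind = c(rep("bone", 3L), rep("cartilage", 3L), rep("meniscus", 2L),
             rep("ligament", length(ligaments)), rep("cruciate", 2L)),
    n_vertices = vapply(structures, n_vertices, integer(1)),
    n_faces = vapply(structures, n_faces, integer(1)),
    watertight = vapply(structures, is_watertight, logical(1)),
    row.names = NULL)
  structure(list(cartilage = cartilage, menisci = menisci,
                 ligaments = ligaments, cruciates = list(ACL = acl, PCL = pcl),
                 structures = structures, obstacles = obstacles,
                 target_length = target_length, manifest = manifest),
            class = "knee_model")
}

#' @export
print.knee_model <- function(x, ...) {
  cat(sprintf("<knee_model> %d structures (femoral length %.1f mm)\n",
              nrow(x$manifest), x$target_length))
  print(x$manifest)
  invisible(x)
}

#' Write a knee model bundle to disk
#'
#' Emits one ASCII PLY per structure plus a JSON manifest carrying structure
#' metadata and MD5 content hashes (the determinism fingerprint of a build).
#'
#' @param model a `knee_model`.
#' @param out_dir output directory (created if missing).
#' @return path of the manifest JSON, invisibly.
#' @export
write_knee_model <- function(model, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(model$structures)) {
    p <- file.path(out_dir, paste0(nm, ".ply"))
    write_mesh(model$structures[[nm]], p)
    files[nm] <- p
  }
  manifest <- model$manifest
  manifest$file <- basename(files[manifest$structure])
  manifest$md5 <- unname(tools::md5sum(files[manifest$structure]))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Mean maps and pooled profiles from a training cohort
#'
#' The model-building half of a leave-one-out experiment: average the
#' femoral-length-normalized thickness maps per region and fit the default-
#' degree polynomial profiles on the pooled profile samples of the training
#' cases.
#'
#' @param cases list of cohort cases (see [generate_cohort()]).
#' @return list with `mean_maps` and `profiles`.
#' @export
build_population_model <- function(cases) {
  region_names <- names(cases[[1L]]$maps)
  mean_maps <- lapply(region_names, function(rn) {
    seal_edges(mean_map(lapply(cases, function(cs) cs$maps[[rn]])))
  })
  names(mean_maps) <- region_names
  degs <- c(default_profile_degrees(), default_radius_degrees())
  prof_names <- names(cases[[1L]]$profile_samples)
  profiles <- lapply(prof_names, function(pn) {
    pooled_s <- unlist(lapply(cases, function(cs) cs$profile_samples[[pn]]$s))
    pooled_v <- unlist(lapply(cases, function(cs) cs$profile_samples[[pn]]$values))
    deg <- degs[[sub("_radius$", "", pn)]]
    if (is.null(deg) || is.na(deg)) deg <- degs[[pn]]
    fit_polynomial(profile_samples(pooled_s, pooled_v, structure_label = pn), deg)
  })
  names(profiles) <- prof_names
  list(mean_maps = mean_maps, profiles = profiles)
}

#' Build the full model for a synthetic case from a configuration
#'
#' Configuration-driven entry point: generates (or reuses) a synthetic
#' cohort, builds the population model from all cases except the target,
#' predicts the target case's complete soft-tissue anatomy and optionally
#' writes the bundle to disk.
#'
#' @param config a named list or path to a YAML file with fields
#'   `n_cases`, `seed`, `case` (index of the target case), optional
#'   `output_dir`, `thickness_noise_sd`, `profile_noise_sd`, `subdiv`.
#' @return a `knee_model` (with attribute `"manifest_path"` when written).
#' @export
build_full_model <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("n_cases", "seed", "case", "output_dir", "thickness_noise_sd",
             "profile_noise_sd", "subdiv")
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  n_cases <- config$n_cases %||% 6L
  seed <- config$seed %||% 1L
  target <- config$case %||% 1L
  cohort <- generate_cohort(n_cases, seed = seed,
                            thickness_noise_sd = config$thickness_noise_sd %||% 0.1,
                            profile_noise_sd = config$profile_noise_sd %||% 0.15,
                            subdiv = config$subdiv %||% 3L)
  tpl <- attr(cohort, "template")
  pop <- build_population_model(cohort[-target])
  case <- cohort[[target]]
  model <- build_knee_model(case$bones, tpl$landmarks, pop$mean_maps,
                            pop$profiles)
  if (!is.null(config$output_dir)) {
    mp <- write_knee_model(model, config$output_dir)
    attr(model, "manifest_path") <- mp
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out validation of cartilage maps and profile predictions
#'
#' Runs the leave-one-out driver over a cohort for every cartilage region
#' (value-space thickness comparison of the scaled mean map against the
#' case's measured map) and every profile (default-degree fit on pooled
#' training samples compared against the case's measured samples), and
#' returns pooled median/range tables.
#'
#' @param cohort list of cases from [generate_cohort()].
#' @param out_dir optional directory for per-table CSV output.
#' @return named list of tables (data frames with metric, median, min, max).
#' @export
run_validation <- function(cohort, out_dir = NULL) {
  if (length(cohort) < 2L) stop("cohort must contain at least 2 cases")
  region_names <- names(cohort[[1L]]$maps)
  tables <- list()
  for (rn in region_names) {
    res <- leave_one_out(
      cohort,
      builder = function(train) mean_map(lapply(train, function(cs) cs$maps[[rn]])),
      predictor = function(model, case) {
        m <- model
        scale <- case$femoral_length / m$reference_length
        thickness_map(m$bone_label, m$region, m$values * scale,
                      edge_indices = m$edge_indices,
                      reference_length = case$femoral_length,
                      region_name = m$region_name)
      },
      comparator = function(pred, case) compare_thickness_maps(pred, case$maps[[rn]]))
    tables[[paste0("cartilage_", rn)]] <- res$pooled
  }
  degs <- c(default_profile_degrees(), default_radius_degrees())
  for (pn in names(cohort[[1L]]$profile_samples)) {
    deg <- degs[[pn]]
    res <- leave_one_out(
      cohort,
      builder = function(train) {
        s <- unlist(lapply(train, function(cs) cs$profile_samples[[pn]]$s))
        v <- unlist(lapply(train, function(cs) cs$profile_samples[[pn]]$values))
        fit_polynomial(profile_samples(s, v, structure_label = pn), deg)
      },
      predictor = function(model, case) eval_profile(model, case$profile_samples[[pn]]$s),
      comparator = function(pred, case) {
        distance_report(abs(pred - case$profile_samples[[pn]]$values))
      })
    tables[[paste0("profile_", pn)]] <- res$pooled
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  tables
}
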