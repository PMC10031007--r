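#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto the unit sphere; the deterministic
#' template all synthetic bones derive from.
#'
#' @param subdiv subdivision level (0 = icosahedron, 3 = 642 vertices).
#' @param radius sphere radius in mm.
#' @return a watertight [knee_mesh()].
#' @export
icosphere <- function(subdiv = 3L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    mid_cache <- new.env(hash = TRUE)
    nv <- nrow(v)
    newv <- list()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      hit <- mid_cache[[key]]
      if (!is.null(hit)) return(hit)
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      newv[[length(newv) + 1L]] <<- p
      id <- nv + length(newv)
      mid_cache[[key]] <- id
      id
    }
    newf <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c_ <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4L * i - 3L, ] <- c(a, ab, ca)
      newf[4L * i - 2L, ] <- c(b, bc, ab)
      newf[4L * i - 1L, ] <- c(c_, ca, bc)
      newf[4L * i, ] <- c(ab, bc, ca)
    }
    v <- rbind(v, do.call(rbind, newv))
    f <- newf
  }
  knee_mesh(radius * v, f, bone_label = "sphere")
}

# smoothstep on [0,1]
sstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# gaussian-like bump of direction alignment: 1 at v.d = 1, ~0 away
dir_bump <- function(dirs, d, w) {
  d <- d / sqrt(sum(d^2))
  c_ <- dirs %*% d
  exp(-(1 - c_) / w)
}

#' Synthetic knee template geometry
#'
#' Deterministic analogs of the three bones, all derived from one icosphere
#' template so vertex correspondence across cases is exact by construction.
#' Axes: +x lateral, +y anterior, +z proximal; units mm. The distal femur is
#' a sphere with two blended condylar lobes; the proximal tibia a flattened
#' plate with two shallow concave plateau patches; the patella a small lens
#' anterior to the femur. Articular regions, smooth ground-truth thickness
#' fields (vanishing at the region edges), landmark vertex indices for all
#' attachments and roots, and meniscal / cruciate profile truth polynomials
#' are all defined on the template.
#'
#' @param subdiv icosphere subdivision level per bone.
#' @return list with `femur`, `tibia`, `patella` ([knee_mesh()]s), `regions`
#'   (named list of `bone` + `indices`), `truth_fields` (per-region vertex
#'   thickness in mm), `landmarks` (a [landmark_set()]), `profiles` (named
#'   list of truth `polynomial_profile`s), `femoral_length` (mm).
#' @export
synthetic_knee_template <- function(subdiv = 3L) {
  sph <- icosphere(subdiv)
  u <- sph$vertices  # unit directions
  n <- nrow(u)

  ## femur: radius field with two distal condylar lobes, stretched proximally
  lobe1 <- dir_bump(u, c(0.55, 0.0, -0.84), 0.10)
  lobe2 <- dir_bump(u, c(-0.55, 0.0, -0.84), 0.10)
  rf <- 24 * (1 + 0.33 * lobe1 + 0.33 * lobe2)
  fv <- u * as.numeric(rf)
  fv[, 3] <- fv[, 3] * (1 + 0.35 * sstep(fv[, 3] / 15))  # proximal stretch
  femur <- knee_mesh(fv, sph$faces, bone_label = "femur")

  ## tibia(+fibula analog): flattened plate with two concave plateau dimples
  tv <- cbind(29 * u[, 1], 26 * u[, 2], 10.5 * u[, 3])
  topw <- pmax(u[, 3], 0)
  dimple <- function(x0) exp(-((tv[, 1] - x0)^2 + tv[, 2]^2) / 70)
  tv[, 3] <- tv[, 3] - 1.6 * topw * (dimple(12) + dimple(-12))
  tv[, 3] <- tv[, 3] - 47.5
  tibia <- knee_mesh(tv, sph$faces, bone_label = "tibia_fibula")

  ## patella: lens anterior to the femoral groove
  pv <- cbind(11 * u[, 1], 5.5 * u[, 2], 9 * u[, 3])
  pv[, 2] <- pv[, 2] + 33
  pv[, 3] <- pv[, 3] - 10
  patella <- knee_mesh(pv, sph$faces, bone_label = "patella")

  ## articular regions + smooth truth thickness fields (0 at region edge)
  cdist <- u[, 3] * -1  # distal alignment on femur template directions
  fem_reg <- which(cdist > 0.45)
  fem_field <- 2.2 * sstep((cdist[fem_reg] - 0.45) / 0.4)

  top <- u[, 3]
  med_reg <- which(top > 0.55 & tv[, 1] < -3)
  lat_reg <- which(top > 0.55 & tv[, 1] > 3)
  plateau_field <- function(reg, x0) {
    r2 <- (tv[reg, 1] - x0)^2 + tv[reg, 2]^2
    2.6 * sstep((top[reg] - 0.55) / 0.35) * exp(-r2 / 160)
  }
  med_field <- plateau_field(med_reg, -12)
  lat_field <- plateau_field(lat_reg, 12)

  pat_reg <- which(u[, 2] < -0.45)  # posterior patellar facet faces the femur
  pat_field <- 2.8 * sstep((-u[, 2][pat_reg] - 0.45) / 0.4)

  regions <- list(
    femoral = list(bone = "femur", indices = fem_reg),
    medial_plateau = list(bone = "tibia_fibula", indices = med_reg),
    lateral_plateau = list(bone = "tibia_fibula", indices = lat_reg),
    patellar = list(bone = "patella", indices = pat_reg))
  truth_fields <- list(femoral = fem_field, medial_plateau = med_field,
                       lateral_plateau = lat_field, patellar = pat_field)

  ## landmarks: anchored at deterministic template vertices
  nn_f <- function(p) anchor_points(femur, p)
  nn_t <- function(p) anchor_points(tibia, p)
  nn_p <- function(p) anchor_points(patella, p)
  patch <- function(mesh, p, k = 9L) {
    d2 <- rowSums(sweep(mesh$vertices, 2L, p)^2)
    sort(order(d2)[seq_len(k)])
  }
  top_z <- -37
  lm <- list(
    femur_length_proximal = list(bone = "femur", indices = nn_f(c(0, 0, 60))),
    femur_length_distal = list(bone = "femur", indices = nn_f(c(0, 0, -40))),
    MPFL_origin = list(bone = "femur", indices = patch(femur, c(-26, 2, -8))),
    MPFL_insertion = list(bone = "patella", indices = patch(patella, c(-11, 33, -10))),
    LPFL_origin = list(bone = "femur", indices = patch(femur, c(26, 2, -8))),
    LPFL_insertion = list(bone = "patella", indices = patch(patella, c(11, 33, -10))),
    sMCL_origin = list(bone = "femur", indices = patch(femur, c(-27, 0, -12))),
    sMCL_ant_insertion = list(bone = "tibia_fibula", indices = patch(tibia, c(-28, 8, -44))),
    sMCL_post_insertion = list(bone = "tibia_fibula", indices = patch(tibia, c(-28, -8, -44))),
    LCL_origin = list(bone = "femur", indices = patch(femur, c(27, 0, -12))),
    LCL_insertion = list(bone = "tibia_fibula", indices = patch(tibia, c(28, -4, -44))),
    ALL_origin = list(bone = "femur", indices = patch(femur, c(26, 6, -14))),
    ALL_insertion = list(bone = "tibia_fibula", indices = patch(tibia, c(24, 14, -42))),
    POL_origin = list(bone = "femur", indices = patch(femur, c(-24, -10, -14))),
    POL_insertion = list(bone = "tibia_fibula", indices = patch(tibia, c(-24, -14, -42))),
    OPL_origin = list(bone = "femur", indices = patch(femur, c(12, -22, -16))),
    OPL_insertion = list(bone = "tibia_fibula", indices = patch(tibia, c(-16, -20, -42))),
    PT_origin = list(bone = "patella",
                     indices = patch(patella, c(0, 34, -18), k = 12L)),
    PT_insertion = list(bone = "tibia_fibula",
                        indices = patch(tibia, c(0, 26, -40), k = 12L)),
    ACL_origin = list(bone = "femur", indices = nn_f(c(5, -6, -26))),
    ACL_insertion = list(bone = "tibia_fibula", indices = nn_t(c(-1, 8, top_z))),
    PCL_origin = list(bone = "femur", indices = nn_f(c(-5, 6, -26))),
    PCL_insertion = list(bone = "tibia_fibula", indices = nn_t(c(1, -8, top_z))),
    MM_anterior_root = list(bone = "tibia_fibula", indices = nn_t(c(-13, 14, top_z))),
    MM_posterior_root = list(bone = "tibia_fibula", indices = nn_t(c(-13, -14, top_z))),
    LM_anterior_root = list(bone = "tibia_fibula", indices = nn_t(c(13, 14, top_z))),
    LM_posterior_root = list(bone = "tibia_fibula", indices = nn_t(c(13, -14, top_z))))
  landmarks <- landmark_set(lm, provenance = "averaged")

  ## truth profiles (power basis on [0,1]); anatomical magnitudes in mm
  profiles <- list(
    MM_height = synthetic_profile_truth(6L, base = 4.6, amp = 0.8),
    MM_width = synthetic_profile_truth(4L, base = 7.5, amp = 1.2),
    LM_height = synthetic_profile_truth(4L, base = 4.2, amp = 0.7),
    LM_width = synthetic_profile_truth(4L, base = 7.2, amp = 1.1),
    ACL_radius = synthetic_profile_truth(2L, base = 2.2, amp = 0.45),
    PCL_radius = synthetic_profile_truth(4L, base = 2.4, amp = 0.45))
  for (nm in names(profiles)) profiles[[nm]]$structure_label <- nm

  fl <- {
    p1 <- colMeans(femur$vertices[lm$femur_length_proximal$indices, , drop = FALSE])
    p2 <- colMeans(femur$vertices[lm$femur_length_distal$indices, , drop = FALSE])
    sqrt(sum((p1 - p2)^2))
  }
  list(femur = femur, tibia = tibia, patella = patella, regions = regions,
       truth_fields = truth_fields, landmarks = landmarks,
       profiles = profiles, femoral_length = fl)
}

#' Standard truth polynomial of a given degree
#'
#' A fixed Chebyshev-flavoured polynomial on `[0, 1]` whose every degree
#' contributes a sizeable share of the variation, re-scaled to `base + amp *
#' shape`. Used as generating ground truth for profile fitting and degree
#' selection.
#'
#' @param degree generating degree (0 to 8).
#' @param base,amp offset and amplitude in mm.
#' @return a `polynomial_profile`.
#' @export
synthetic_profile_truth <- function(degree, base = 5, amp = 1) {
  if (degree < 0L || degree > 8L) stop("degree must be in 0..8")
  # shifted Chebyshev polynomials T*_k on [0,1], power-basis coefficients
  cheb <- list(
    c(1),
    c(-1, 2),
    c(1, -8, 8),
    c(-1, 18, -48, 32),
    c(1, -32, 160, -256, 128),
    c(-1, 50, -400, 1120, -1280, 512),
    c(1, -72, 840, -3584, 6912, -6144, 2048),
    c(-1, 112, -1568, 9408, -26880, 39424, -28672, 8192),
    c(1, -128, 2688, -21504, 84480, -180224, 212992, -131072, 32768))
  # geometric mix: every order up to `degree` contributes a sizeable share,
  # so degree selection sees a clear elbow exactly at `degree`
  coef <- numeric(degree + 1L)
  coef[1L] <- base
  if (degree >= 1L) {
    for (k in seq_len(degree)) {
      ck <- amp * 0.8^k
      coef[seq_len(k + 1L)] <- coef[seq_len(k + 1L)] + ck * cheb[[k + 1L]]
    }
  }
  polynomial_profile(coef)
}

#' Noisy profile samples from a truth polynomial
#'
#' @param truth a `polynomial_profile`.
#' @param n number of samples at equidistant positions.
#' @param noise_sd absolute noise standard deviation (mm); use
#'   `relative_noise` to scale with the profile's value range instead.
#' @param relative_noise optional fraction of the truth value range.
#' @param seed RNG seed.
#' @return a [profile_samples()].
#' @export
synthetic_profile_samples <- function(truth, n = 50L, noise_sd = 0,
                                      relative_noise = NULL, seed = 1L) {
  s <- seq(0, 1, length.out = n)
  y <- eval_profile(truth, s)
  if (!is.null(relative_noise)) {
    noise_sd <- relative_noise * (max(y) - min(y))
  }
  set.seed(seed)
  yy <- pmax(y + stats::rnorm(n, sd = noise_sd), 0)
  profile_samples(s, yy, structure_label = truth$structure_label)
}

case_seed <- function(seed, i) (as.integer(seed) * 10007L + i * 127L) %% 2147483647L

#' Generate a corresponded synthetic knee cohort
#'
#' Every case is the template scaled by a uniform per-case factor (emulating
#' femoral-length variation), with cartilage meshes equal to bone plus the
#' scaled ground-truth thickness field displaced along vertex normals, and
#' measured thickness maps equal to the scaled truth plus i.i.d. Gaussian
#' vertex noise (clamped at zero). Profile measurements are the truth
#' polynomials sampled with additive noise. Landmarks are the template's
#' vertex indices, valid for every case by correspondence. Reproducible for
#' a fixed seed; each case draws from its own stream derived from (seed,
#' case index), so extending the cohort never perturbs earlier cases.
#'
#' @param n_cases cohort size.
#' @param seed integer RNG seed.
#' @param scale_range per-case uniform scale factor interval.
#' @param thickness_noise_sd i.i.d. vertex noise on measured maps (mm).
#' @param profile_noise_sd additive noise on profile samples (mm).
#' @param profile_n samples per profile measurement.
#' @param subdiv template mesh resolution.
#' @param template optional pre-built [synthetic_knee_template()] to reuse.
#' @return list of cases; each case is a list with `case_id`, `scale`,
#'   `femoral_length`, `bones` (list of three [knee_mesh()]s), `cartilage`
#'   (named per-bone combined bone+cartilage meshes), `maps` (named measured
#'   [thickness_map()]s per region), `profile_samples` (named list), and
#'   `truth` (scaled noise-free fields). The template is attached as
#'   attribute `"template"`.
#' @export
generate_cohort <- function(n_cases, seed = 1L, scale_range = c(0.92, 1.08),
                            thickness_noise_sd = 0.1, profile_noise_sd = 0.15,
                            profile_n = 40L, subdiv = 3L, template = NULL) {
  if (n_cases < 1L) stop("n_cases must be >= 1")
  tpl <- if (is.null(template)) synthetic_knee_template(subdiv) else template
  vnorms <- list(femur = vertex_normals(tpl$femur),
                 tibia_fibula = vertex_normals(tpl$tibia),
                 patella = vertex_normals(tpl$patella))
  bone_of <- function(lbl) switch(lbl, femur = tpl$femur,
                                  tibia_fibula = tpl$tibia, patella = tpl$patella)
  cases <- lapply(seq_len(n_cases), function(i) {
    set.seed(case_seed(seed, i))
    scl <- stats::runif(1L, scale_range[1L], scale_range[2L])
    bones <- lapply(list(femur = tpl$femur, tibia_fibula = tpl$tibia,
                         patella = tpl$patella), function(m) {
      m$vertices <- m$vertices * scl
      m$case_id <- sprintf("case%03d", i)
      m
    })
    # cartilage meshes: bone + scaled truth field along vertex normals
    cart <- bones
    for (rn in names(tpl$regions)) {
      reg <- tpl$regions[[rn]]
      fld <- tpl$truth_fields[[rn]] * scl
      m <- cart[[reg$bone]]
      m$vertices[reg$indices, ] <- m$vertices[reg$indices, , drop = FALSE] +
        fld * vnorms[[reg$bone]][reg$indices, , drop = FALSE]
      cart[[reg$bone]] <- m
    }
    for (b in names(cart)) cart[[b]]$bone_label <- paste0(b, "_cartilage")
    # measured maps: scaled truth + vertex noise
    maps <- lapply(names(tpl$regions), function(rn) {
      reg <- tpl$regions[[rn]]
      truth <- tpl$truth_fields[[rn]] * scl
      vals <- pmax(truth + stats::rnorm(length(truth), sd = thickness_noise_sd), 0)
      thickness_map(reg$bone, reg$indices, vals,
                    edge_indices = region_edges(bone_of(reg$bone), reg$indices),
                    reference_length = tpl$femoral_length * scl,
                    region_name = rn)
    })
    names(maps) <- names(tpl$regions)
    profs <- lapply(tpl$profiles, function(tr) {
      s <- seq(0, 1, length.out = profile_n)
      y <- pmax(eval_profile(tr, s) + stats::rnorm(profile_n, sd = profile_noise_sd), 0)
      profile_samples(s, y, structure_label = tr$structure_label)
    })
    list(case_id = sprintf("case%03d", i), scale = scl,
         femoral_length = tpl$femoral_length * scl,
         bones = bones, cartilage = cart, maps = maps,
         profile_samples = profs,
         truth = lapply(tpl$truth_fields, function(f) f * scl))
  })
  attr(cases, "template") <- tpl
  cases
}

#' Benchmark obstacle/anchor suites for the wrap engine
#'
#' Deterministic geometric benchmarks with independent reference path
#' lengths: free space (reference = anchor distance), spheres with anchors
#' separated by a central angle (reference = great-circle arc R*theta), and
#' a condyle-analog obstacle whose reference is meant to be computed by a
#' dense graph shortest-path oracle in the test harness.
#'
#' @param subdiv obstacle mesh resolution.
#' @return named list of cases, each with `obstacles`, `start`, `end`,
#'   `reference_length` (NA where oracle-computed) and `description`.
#' @export
generate_wrap_benchmarks <- function(subdiv = 3L) {
  sph <- function(R) icosphere(subdiv, radius = R)
  quarter <- list(
    obstacles = obstacle_set(list(sph(10))),
    start = c(10, 0, 0), end = c(0, 10, 0),
    reference_length = 10 * pi / 2,
    description = "sphere R=10, anchors at central angle pi/2")
  half <- list(
    obstacles = obstacle_set(list(sph(10))),
    start = c(10, 0, 0), end = c(-10 * cos(0.2), 10 * sin(0.2), 0),
    reference_length = 10 * (pi - 0.2),
    description = "sphere R=10, central angle pi-0.2")
  free <- list(
    obstacles = obstacle_set(),
    start = c(-7, 2, 1), end = c(5, -3, 4),
    reference_length = sqrt(sum((c(-7, 2, 1) - c(5, -3, 4))^2)),
    description = "free space, straight segment")
  condyle <- local({
    tpl <- synthetic_knee_template(subdiv)
    list(obstacles = obstacle_set(list(tpl$femur)),
         start = c(-26, 2, -8), end = c(26, 2, -8),
         reference_length = NA_real_,
         description = "condyle analog, reference via graph shortest path")
  })
  list(sphere_quarter = quarter, sphere_near_half = half,
       free_space = free, condyle = condyle)
}
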