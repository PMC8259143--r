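## ---- synthetic cohort + phantom generator -------------------------------

#' Configuration for the synthetic tabular cohort
#'
#' Defaults are the reference-cohort calibration returned by
#' [cohort_reference()]: class sizes 74 ccRCC / 31 AML.wovf, per-class
#' means/SDs for every quantitative parameter, and the categorical
#' frequencies for gender, location, growth pattern, pseudocapsule sign,
#' cystic degeneration and angular interface.
#'
#' @param n_ccrcc,n_aml positive integer class sizes.
#' @param quantitative data.frame as in `cohort_reference()$quantitative`;
#'   SDs must be >= 0 (0 gives degenerate, exactly-mean draws).
#' @param categorical data.frame as in `cohort_reference()$categorical`;
#'   frequencies must lie in `[0, 1]`.
#' @param correlation common pairwise correlation between quantitative
#'   features within a class, in `[0, 1)`.  The reference values are
#'   marginal summaries, so the default is 0; real CT parameters co-vary, so
#'   it is configurable.
#' @param seed integer seed governing all draws.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_ccrcc = 74L, n_aml = 31L,
                          quantitative = cohort_reference()$quantitative,
                          categorical = cohort_reference()$categorical,
                          correlation = 0, seed = 1L) {
  if (n_ccrcc < 1 || n_aml < 1)
    stop("class sizes must be positive integers", call. = FALSE)
  if (any(quantitative$sd_ccrcc < 0) || any(quantitative$sd_aml < 0))
    stop("feature SDs must be non-negative", call. = FALSE)
  if (any(categorical$freq_ccrcc < 0 | categorical$freq_ccrcc > 1) ||
      any(categorical$freq_aml < 0 | categorical$freq_aml > 1))
    stop("categorical frequencies must lie in [0, 1]", call. = FALSE)
  if (correlation < 0 || correlation >= 1)
    stop("correlation must lie in [0, 1)", call. = FALSE)
  structure(list(n_ccrcc = as.integer(n_ccrcc), n_aml = as.integer(n_aml),
                 quantitative = quantitative, categorical = categorical,
                 correlation = correlation, seed = as.integer(seed)),
            class = "cohort_config")
}

## deterministic per-lesion sub-seed from the global seed (kept < 2^31)
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(i)) %% 2147483647)
}

#' Simulate a tabular lesion cohort
#'
#' Draws one row per lesion: class label, categorical variables with the
#' configured per-class frequencies, and quantitative parameters from
#' (optionally equicorrelated) normal distributions with the configured
#' per-class means/SDs.  Deterministic under a fixed seed.
#'
#' @param config a [cohort_config()].
#' @return A `data.frame` lesion table with columns `lesion_id`, `class`,
#'   `gender`, `location`, `growth`, `pseudocapsule`, `cystic`, `angular`
#'   (flags coded 0/1), `age`, `size_cm` and all quantitative parameters.
#' @export
#' @examples
#' tab <- simulate_cohort(cohort_config(n_ccrcc = 20, n_aml = 10, seed = 7))
#' table(tab$class)
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  q <- config$quantitative
  feats <- setdiff(q$feature, c("age", "size_cm"))
  draw_class <- function(n, mean_col, sd_col, freq_col, label) {
    p <- nrow(q)
    rho <- config$correlation
    z <- matrix(rnorm(n * p), n, p)
    if (rho > 0) {
      R <- matrix(rho, p, p); diag(R) <- 1
      z <- z %*% chol(R)
    }
    x <- sweep(sweep(z, 2, q[[sd_col]], `*`), 2, q[[mean_col]], `+`)
    colnames(x) <- q$feature
    cc <- config$categorical
    flags <- vapply(seq_len(nrow(cc)),
                    function(i) rbinom(n, 1L, cc[[freq_col]][i]),
                    integer(n))
    if (n == 1L) flags <- matrix(flags, nrow = 1L)
    colnames(flags) <- cc$variable
    data.frame(class = rep(label, n),
               gender = ifelse(flags[, "gender"] == 1, "male", "female"),
               location = ifelse(flags[, "location"] == 1, "left", "right"),
               growth = ifelse(flags[, "growth"] == 1,
                               "endophytic", "exophytic"),
               pseudocapsule = flags[, "pseudocapsule"],
               cystic = flags[, "cystic"],
               angular = flags[, "angular"],
               age = x[, "age"], size_cm = x[, "size_cm"],
               x[, feats, drop = FALSE],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    draw_class(config$n_ccrcc, "mean_ccrcc", "sd_ccrcc", "freq_ccrcc",
               .classes[1]),
    draw_class(config$n_aml, "mean_aml", "sd_aml", "freq_aml", .classes[2]))
  out <- cbind(lesion_id = sprintf("L%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Specification of one synthetic lesion phantom
#'
#' Parameterizes the voxel-level generator: a spherical tumor with
#' margin-adjacent enhancement patches (compact blobs of elevated HU), thin
#' arc-shaped vessels, non-enhancing cysts, an optional pseudocapsule rim,
#' plus homogeneous renal-cortex and psoas reference regions, all corrupted
#' by i.i.d. Gaussian HU noise.
#'
#' @param class `"ccRCC"` or `"AML.wovf"` (label only; the geometry is set by
#'   the other arguments).
#' @param diameter_mm tumor diameter, at most 40 mm (the small-renal-tumor
#'   inclusion rule).
#' @param base_hu named length-4 vector (PCP, CMP, NP, EP): bulk tumor HU.
#' @param patch_hu named length-4 vector: HU inside enhancement patches.
#' @param cortex_hu,psoas_hu named length-4 vectors for the reference
#'   tissues.
#' @param n_patches,patch_radius_mm number and radius of enhancement
#'   patches.
#' @param n_vessels number of thin curvilinear intratumoral vessels.
#' @param cyst_fraction fraction of tumor volume occupied by non-enhancing
#'   cysts, in `[0, 1)`.
#' @param cyst_hu constant attenuation of cystic/necrotic fluid, identical
#'   in every phase (non-enhancing by construction).
#' @param pseudocapsule logical; add a hypodense rim just inside the tumor
#'   boundary.
#' @param noise_sd global HU noise SD (>= 0).
#' @param spacing in-plane voxel spacing in mm.
#' @param thickness slice thickness in mm.
#' @return A list of class `lesion_spec`.
#' @export
lesion_spec <- function(class = "ccRCC", diameter_mm = 28,
                        base_hu = c(PCP = 30.3, CMP = 128, NP = 92.9,
                                    EP = 80.5),
                        patch_hu = c(PCP = 34.7, CMP = 216.9, NP = 129.1,
                                     EP = 101.5),
                        cortex_hu = c(PCP = 33, CMP = 186.7, NP = 147.8,
                                      EP = 137.2),
                        psoas_hu = c(PCP = 55, CMP = 55, NP = 55, EP = 55),
                        n_patches = 3L, patch_radius_mm = 2.5,
                        n_vessels = 1L, cyst_fraction = 0.12,
                        cyst_hu = 35,
                        pseudocapsule = TRUE, noise_sd = 9.6,
                        spacing = 0.7, thickness = 1) {
  class <- match.arg(class, .classes)
  if (diameter_mm <= 0 || diameter_mm > 40)
    stop("tumor diameter must be in (0, 40] mm", call. = FALSE)
  if (cyst_fraction < 0 || cyst_fraction >= 1)
    stop("cyst_fraction must lie in [0, 1)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  for (v in list(base_hu, patch_hu, cortex_hu, psoas_hu))
    stopifnot(length(v) == 4L)
  structure(list(class = class, diameter_mm = diameter_mm,
                 base_hu = setNames(as.numeric(base_hu), .phases),
                 patch_hu = setNames(as.numeric(patch_hu), .phases),
                 cortex_hu = setNames(as.numeric(cortex_hu), .phases),
                 psoas_hu = setNames(as.numeric(psoas_hu), .phases),
                 n_patches = as.integer(n_patches),
                 patch_radius_mm = patch_radius_mm,
                 n_vessels = as.integer(n_vessels),
                 cyst_fraction = cyst_fraction, cyst_hu = cyst_hu,
                 pseudocapsule = isTRUE(pseudocapsule),
                 noise_sd = noise_sd, spacing = spacing,
                 thickness = thickness),
            class = "lesion_spec")
}

#' Class-calibrated lesion spec with between-lesion variation
#'
#' Draws per-lesion patch and bulk HU from the per-class reference
#' distributions (patch HU from the smaller-ROI attenuation, bulk HU from
#' the whole-tumor attenuation) so that a cohort of phantoms reproduces the
#' configured class means on average.  AML phantoms get fewer, lower-contrast
#' patches, no cysts and no pseudocapsule.
#'
#' @param class `"ccRCC"` or `"AML.wovf"`.
#' @param seed integer seed for the per-lesion draws.
#' @param reference calibration list as from [cohort_reference()].
#' @return A [lesion_spec()].
#' @export
lesion_spec_from_class <- function(class = "ccRCC", seed = 1L,
                                   reference = cohort_reference()) {
  class <- match.arg(class, .classes)
  q <- reference$quantitative
  pick <- function(feature, col) q[q$feature == feature, col]
  cols <- if (class == "ccRCC") c("mean_ccrcc", "sd_ccrcc")
          else c("mean_aml", "sd_aml")
  set.seed(derive_seed(seed, 1L))
  hu <- function(roi) {
    v <- vapply(.phases, function(ph) {
      f <- paste0("AVT_", ph, "_", roi)
      rnorm(1, pick(f, cols[1]), pick(f, cols[2]))
    }, numeric(1))
    setNames(v, .phases)
  }
  patch <- hu("2")          # smaller-ROI attenuation = patch level
  base  <- hu("3")          # whole-tumor attenuation = bulk level
  size <- max(1.2, min(4, rnorm(1, pick("size_cm", cols[1]),
                                pick("size_cm", cols[2]))))
  if (class == "ccRCC")
    lesion_spec(class, diameter_mm = size * 10, base_hu = base,
                patch_hu = patch, n_patches = 3L, n_vessels = 1L,
                cyst_fraction = 0.12, pseudocapsule = TRUE)
  else
    lesion_spec(class, diameter_mm = size * 10, base_hu = base,
                patch_hu = patch, n_patches = 2L, n_vessels = 0L,
                cyst_fraction = 0, pseudocapsule = FALSE)
}

## voxels of a sphere, in index space; dim = c(nz, ny, nx)
sphere_mask <- function(dim, center, radius_mm, spacing, thickness) {
  z <- (seq_len(dim[1]) - center[1]) * thickness
  y <- (seq_len(dim[2]) - center[2]) * spacing
  x <- (seq_len(dim[3]) - center[3]) * spacing
  outer(outer(z^2, y^2, `+`), x^2, `+`) <= radius_mm^2
}

#' Simulate a four-phase lesion volume
#'
#' Builds co-registered PCP/CMP/NP/EP voxel grids containing the tumor, its
#' internal structures and the reference tissues described by a
#' [lesion_spec()], plus ground-truth masks for every structure.
#'
#' @param spec a [lesion_spec()].
#' @param seed integer seed (patch/vessel/cyst placement and HU noise).
#' @return A list of class `four_phase_volume` with elements `phases` (named
#'   list of 3-D HU arrays, dimension slice x row x col), `spacing`,
#'   `thickness`, and `masks` (logical arrays: `tumor`, `patches`,
#'   `vessels`, `cysts`, `pseudocapsule`, `cortex`, `psoas`).
#' @export
#' @examples
#' vol <- simulate_lesion_volume(lesion_spec(diameter_mm = 20), seed = 3)
#' sapply(vol$masks, sum)
simulate_lesion_volume <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "lesion_spec"))
  set.seed(derive_seed(seed, 2L))
  d <- spec$diameter_mm; R <- d / 2
  sp <- spec$spacing; th <- spec$thickness
  nx <- ceiling((d + 50) / sp)
  ny <- ceiling((d + 20) / sp)
  nz <- ceiling((d + 12) / th)
  dim <- c(nz, ny, nx)
  ctr <- c(nz / 2, ny / 2, (R + 8) / sp)
  if (ctr[3] * sp + R > nx * sp)
    stop("tumor diameter exceeds volume extent", call. = FALSE)

  tumor <- sphere_mask(dim, ctr, R, sp, th)
  patches <- array(FALSE, dim); vessels <- array(FALSE, dim)
  cysts <- array(FALSE, dim); pseudo <- array(FALSE, dim)

  ## enhancement patches: compact blobs near the tumor margin
  if (spec$n_patches > 0) {
    ang0 <- stats::runif(1, 0, 2 * pi)
    for (k in seq_len(spec$n_patches)) {
      a <- ang0 + (k - 1) * 2 * pi / spec$n_patches
      c_k <- ctr + c(0, 0.6 * R * sin(a) / sp, 0.6 * R * cos(a) / sp)
      patches <- patches | sphere_mask(dim, c_k, spec$patch_radius_mm, sp, th)
    }
  }
  ## vessels: thin arc-shaped curvilinear structures, offset in z from the
  ## patch plane so the two structure families stay disjoint
  if (spec$n_vessels > 0) {
    for (k in seq_len(spec$n_vessels)) {
      t <- seq(0, pi / 2, length.out = 80)
      zc <- ctr[1] + 0.35 * R / th
      pts <- cbind(zc, ctr[2] + 0.5 * R * sin(t + k) / sp,
                   ctr[3] + 0.5 * R * cos(t + k) / sp)
      for (i in seq_len(nrow(pts))) {
        vessels <- vessels | sphere_mask(dim, pts[i, ], 0.8, sp, th)
      }
    }
  }
  ## cysts: central non-enhancing spheres covering cyst_fraction of volume
  if (spec$cyst_fraction > 0) {
    vol_target <- spec$cyst_fraction * 4 / 3 * pi * R^3
    r_c <- (vol_target * 3 / (4 * pi * 2))^(1 / 3)   # two cysts
    for (k in 1:2) {
      a <- stats::runif(1, 0, 2 * pi)
      c_k <- ctr + c(0, 0.3 * R * sin(a) / sp, 0.3 * R * cos(a) / sp) *
        (k - 1)
      cysts <- cysts | sphere_mask(dim, c_k, r_c, sp, th)
    }
    cysts <- cysts & tumor
  }
  if (spec$pseudocapsule)
    pseudo <- tumor & !sphere_mask(dim, ctr, R - 1.5, sp, th)
  vessels <- vessels & tumor
  patches <- patches & tumor & !cysts & !vessels

  ## reference tissues, outside the tumor
  cortex <- array(FALSE, dim)
  c0 <- ceiling((d + 20) / sp); c1 <- ceiling((d + 27) / sp)
  cortex[, seq(round(0.3 * ny), round(0.7 * ny)), c0:c1] <- TRUE
  psoas_ctr <- c(nz / 2, ny / 2, (d + 38) / sp)
  psoas <- array(FALSE, dim)
  pz <- (seq_len(ny) - psoas_ctr[2]) * sp
  px <- (seq_len(nx) - psoas_ctr[3]) * sp
  disc <- outer(pz^2, px^2, `+`) <= 6^2
  for (s in seq_len(nz)) psoas[s, , ][disc] <- TRUE

  phases <- lapply(.phases, function(ph) {
    g <- array(-50, dim)                       # retroperitoneal background
    g[tumor] <- spec$base_hu[ph]
    if (spec$pseudocapsule && ph != "PCP") g[pseudo] <- spec$base_hu[ph] - 20
    g[patches] <- spec$patch_hu[ph]
    g[vessels] <- spec$patch_hu[ph] + 20
    g[cysts] <- spec$cyst_hu                   # fluid, never enhances
    g[cortex] <- spec$cortex_hu[ph]
    g[psoas] <- spec$psoas_hu[ph]
    if (spec$noise_sd > 0)
      g <- g + array(rnorm(length(g), 0, spec$noise_sd), dim)
    g
  })
  names(phases) <- .phases
  structure(list(phases = phases, spacing = sp, thickness = th,
                 masks = list(tumor = tumor, patches = patches,
                              vessels = vessels, cysts = cysts,
                              pseudocapsule = pseudo, cortex = cortex,
                              psoas = psoas),
                 spec = spec),
            class = "four_phase_volume")
}

#' Simulate replicate observer measurements
#'
#' Perturbs a table of true quantitative values with independent Gaussian
#' measurement noise per observer and repeat, for inter-observer agreement
#' (ICC) studies.
#'
#' @param truth data.frame of per-lesion true values; a `lesion_id` column is
#'   carried through, all other numeric columns are perturbed.
#' @param noise_sd measurement noise SD (>= 0), same units as the features.
#' @param n_observers number of observers (>= 2 for agreement studies).
#' @param n_repeats repeats per observer.
#' @param seed integer seed.
#' @return Long-format data.frame with columns `lesion_id`, `observer`,
#'   `repeat_` and the perturbed feature columns.
#' @export
simulate_observer_measurements <- function(truth, noise_sd = 15,
                                           n_observers = 2L, n_repeats = 1L,
                                           seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_observers < 2)
    stop("agreement studies require at least 2 observers", call. = FALSE)
  set.seed(derive_seed(seed, 3L))
  num <- vapply(truth, is.numeric, logical(1))
  num["lesion_id" == names(truth)] <- FALSE
  id <- if ("lesion_id" %in% names(truth)) truth$lesion_id
        else sprintf("L%03d", seq_len(nrow(truth)))
  out <- do.call(rbind, lapply(seq_len(n_observers), function(o) {
    do.call(rbind, lapply(seq_len(n_repeats), function(r) {
      x <- truth[, num, drop = FALSE]
      x[] <- lapply(x, function(col) col + rnorm(length(col), 0, noise_sd))
      cbind(data.frame(lesion_id = id, observer = o, repeat_ = r,
                       stringsAsFactors = FALSE), x)
    }))
  }))
  rownames(out) <- NULL
  out
}
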