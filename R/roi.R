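## ---- ROI placement protocols and measurement ----------------------------

#' Planar circular ROI geometry
#'
#' @param slice,row,col center in voxel index space (row/col may be
#'   fractional; slice is rounded when measuring).
#' @param radius_mm in-plane radius in mm.
#' @param spacing in-plane pixel spacing in mm.
#' @param phase optional phase label.
#' @param shape `"circle"` (quasi-circular ROIs are discretized circles).
#' @return A list of class `roi_geometry` with the derived `area_mm2`.
#' @export
roi_geometry <- function(slice, row, col, radius_mm, spacing = 0.7,
                         phase = NA_character_, shape = "circle") {
  if (radius_mm <= 0) stop("ROI radius must be positive", call. = FALSE)
  structure(list(shape = shape, slice = slice, row = row, col = col,
                 radius_mm = radius_mm, spacing = spacing,
                 area_mm2 = pi * radius_mm^2, phase = phase),
            class = "roi_geometry")
}

## pixel (row, col) indices of a disc on one slice
disc_pixels <- function(dim_rc, row, col, radius_mm, spacing) {
  rr <- seq_len(dim_rc[1]); cc <- seq_len(dim_rc[2])
  hit <- outer((rr - row)^2, (cc - col)^2, `+`) * spacing^2 <= radius_mm^2
  which(hit, arr.ind = TRUE)
}

## 3-D connected components, 6-connectivity; returns integer label array
label_components_3d <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nz <- dm[1]; ny <- dm[2]
  stride <- c(1L, nz, nz * ny)
  inmask <- logical(prod(dm)); inmask[idx] <- TRUE
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start; lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      ai <- arrayInd(v, dm)
      for (d in 1:3) for (s in c(-1L, 1L)) {
        pos <- ai[d] + s
        if (pos < 1L || pos > dm[d]) next
        nb <- v + s * stride[d]
        if (inmask[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

## elongation of a voxel set: sqrt of ratio of the two largest principal
## variances of the (mm-scaled) voxel coordinates
region_elongation <- function(coords_mm) {
  if (nrow(coords_mm) < 4) return(1)
  ev <- sort(eigen(stats::cov(coords_mm), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  ev <- pmax(ev, 1e-9)
  sqrt(ev[1] / ev[2])
}

#' Detect enhancement regions inside a tumor
#'
#' Finds connected high-intensity regions in the corticomedullary grid
#' within the tumor: candidate voxels are those above a within-tumor
#' intensity quantile; thin curvilinear (vessel-like) components, components
#' below a minimum volume, and voxels in supplied exclusion masks (cysts,
#' calcification, vessels) are removed.  An empty result is valid (a
#' homogeneous tumor has no preferred enhancement region).
#'
#' @param volume_cmp 3-D HU array of the corticomedullary phase.
#' @param tumor_mask logical array, same dimension, non-empty.
#' @param spacing,thickness voxel spacing in mm.
#' @param exclude optional list of logical arrays to exclude.
#' @param threshold_quantile within-tumor intensity quantile defining
#'   "obviously enhanced" voxels (default 0.9).
#' @param elongation_max components with principal-axis elongation above
#'   this are classed as vessels and dropped (default 3).
#' @param min_volume_mm3 minimum component volume (default 10 mm^3), removing
#'   isolated noise voxels.
#' @param mean_excess_sd a region's mean must exceed the detection threshold
#'   by at least this many noise SDs (noise estimated from the sub-threshold
#'   tumor voxels); clusters of noise voxels barely past the threshold are
#'   rejected while genuinely enhanced patches sit far above it.
#' @return A list of logical region masks (possibly empty).
#' @export
detect_enhancement_regions <- function(volume_cmp, tumor_mask,
                                       spacing = 0.7, thickness = 1,
                                       exclude = NULL,
                                       threshold_quantile = 0.9,
                                       elongation_max = 3,
                                       min_volume_mm3 = 10,
                                       mean_excess_sd = 2) {
  if (!any(tumor_mask)) stop("tumor mask is empty", call. = FALSE)
  thr <- quantile(volume_cmp[tumor_mask], threshold_quantile, names = FALSE)
  cand <- tumor_mask & (volume_cmp > thr)
  bulk <- tumor_mask & volume_cmp <= thr
  for (m in exclude) {
    cand <- cand & !m
    bulk <- bulk & !m
  }
  lab <- label_components_3d(cand)
  n <- max(lab)
  if (n == 0L) return(list())
  noise_sd <- sd(volume_cmp[bulk])
  vox_mm3 <- spacing^2 * thickness
  out <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    if (length(idx) * vox_mm3 < min_volume_mm3) next
    if (is.finite(noise_sd) && noise_sd > 0 &&
        mean(volume_cmp[idx]) < thr + mean_excess_sd * noise_sd) next
    ai <- arrayInd(idx, dim(lab))
    coords <- cbind(ai[, 1] * thickness, ai[, 2] * spacing,
                    ai[, 3] * spacing)
    if (region_elongation(coords) > elongation_max) next
    m <- array(FALSE, dim(lab)); m[idx] <- TRUE
    out[[length(out) + 1L]] <- m
  }
  out
}

#' Place a fixed-area circular ROI on a region
#'
#' Places a circular ROI centered on the region's (optionally
#' intensity-weighted) centroid, on the region's best slice, with area inside
#' the requested range and every pixel inside the constraint mask.  The
#' radius starts at the top of the range and is shrunk until the ROI fits;
#' if the achievable area falls below the lower bound the condition
#' `"region-too-small"` is signalled (unless `fallback = TRUE`, in which case
#' the largest inscribed circle is returned).
#'
#' @param region_mask logical 3-D array defining the target region.
#' @param area_range_mm2 length-2 numeric, e.g. `c(10, 20)` for the smaller
#'   ROI and `c(50, 100)` for the small ROI.
#' @param spacing in-plane pixel spacing in mm.
#' @param intensity optional HU array for intensity-weighted centroiding.
#' @param within logical array the ROI must stay inside (defaults to the
#'   region itself; pass the tumor mask to allow the ROI to spill into
#'   surrounding tumor parenchyma).
#' @param phase optional phase label stored in the geometry.
#' @param fallback return the largest inscribed circle instead of erroring
#'   when the region cannot host the minimum area.
#' @return A [roi_geometry()].
#' @export
place_fixed_area_roi <- function(region_mask, area_range_mm2, spacing = 0.7,
                                 intensity = NULL, within = region_mask,
                                 phase = NA_character_, fallback = FALSE) {
  stopifnot(length(area_range_mm2) == 2L, area_range_mm2[1] > 0,
            diff(area_range_mm2) >= 0)
  if (!any(region_mask)) stop("region mask is empty", call. = FALSE)
  dm <- dim(region_mask)
  counts <- vapply(seq_len(dm[1]), function(s) sum(region_mask[s, , ]),
                   numeric(1))
  slice <- which.max(counts)
  sl <- region_mask[slice, , ]
  ai <- which(sl, arr.ind = TRUE)
  w <- if (is.null(intensity)) rep(1, nrow(ai))
       else pmax(intensity[slice, , ][sl], 0)
  if (sum(w) == 0) w <- rep(1, nrow(ai))
  ctr <- colSums(ai * w) / sum(w)
  within_sl <- within[slice, , ]
  pa <- spacing^2
  fit <- function(r) {
    px <- disc_pixels(dm[2:3], ctr[1], ctr[2], r, spacing)
    if (!nrow(px) || !all(within_sl[px])) return(NULL)
    px
  }
  r <- sqrt(area_range_mm2[2] / pi)
  px <- NULL
  while (r > spacing / 4) {
    px <- fit(r)
    if (!is.null(px) && nrow(px) * pa <= area_range_mm2[2]) break
    px <- NULL
    r <- r - spacing / 20
  }
  if (is.null(px) || nrow(px) * pa < area_range_mm2[1]) {
    if (!fallback || is.null(px)) {
      cond <- structure(
        class = c("region-too-small", "error", "condition"),
        list(message = sprintf(
          "region cannot host a %.0f mm^2 ROI (largest fit: %.1f mm^2)",
          area_range_mm2[1], if (is.null(px)) 0 else nrow(px) * pa),
          call = sys.call(-1)))
      stop(cond)
    }
  }
  roi_geometry(slice, ctr[1], ctr[2], r, spacing, phase)
}

#' Place a whole-tumor ROI
#'
#' On the largest cross-sectional slice of the tumor, returns the largest
#' circular ROI whose every pixel stays at least `margin_mm` inside the
#' tumor boundary (the whole-tumor heterogeneity ROI: cover as much of the
#' tumor as possible while keeping the rim clear of surrounding tissue).
#'
#' @param tumor_mask logical 3-D array, non-empty.
#' @param margin_mm required in-plane distance from the tumor edge (>= 0).
#' @param spacing in-plane pixel spacing in mm.
#' @param phase optional phase label.
#' @return A [roi_geometry()].
#' @export
place_whole_tumor_roi <- function(tumor_mask, margin_mm = 2.5,
                                  spacing = 0.7, phase = NA_character_) {
  if (!any(tumor_mask)) stop("tumor mask is empty", call. = FALSE)
  if (margin_mm < 0) stop("margin must be >= 0", call. = FALSE)
  dm <- dim(tumor_mask)
  counts <- vapply(seq_len(dm[1]), function(s) sum(tumor_mask[s, , ]),
                   numeric(1))
  slice <- which.max(counts)
  sl <- tumor_mask[slice, , ]
  ## work in a 1-pixel padded frame so the grid border bounds the mask too
  pad <- matrix(FALSE, nrow(sl) + 2, ncol(sl) + 2)
  pad[2:(nrow(sl) + 1), 2:(ncol(sl) + 1)] <- sl
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- seq_len(nrow(m)) + dr; cs <- seq_len(ncol(m)) + dc
    ok_r <- rs >= 1 & rs <= nrow(m); ok_c <- cs >= 1 & cs <= ncol(m)
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  adj <- shift(pad, 1, 0) | shift(pad, -1, 0) | shift(pad, 0, 1) |
    shift(pad, 0, -1)
  bnd <- which(!pad & adj, arr.ind = TRUE)          # padded coordinates
  inside <- which(pad, arr.ind = TRUE)
  d2 <- outer(inside[, 1], bnd[, 1], `-`)^2 +
    outer(inside[, 2], bnd[, 2], `-`)^2
  dist_mm <- sqrt(apply(d2, 1, min)) * spacing
  best <- which.max(dist_mm)
  radius <- dist_mm[best] - margin_mm
  if (radius < spacing)
    stop("tumor too small for the requested margin", call. = FALSE)
  roi_geometry(slice, inside[best, 1] - 1, inside[best, 2] - 1, radius,
               spacing, phase)
}

#' Measure mean and SD attenuation inside an ROI
#'
#' @param phase_grid 3-D HU array.
#' @param roi a [roi_geometry()].
#' @param slice optional slice overriding the geometry's slice (used when
#'   averaging over adjacent section-images).
#' @param sd_type `"population"` (divisor n, the workstation convention used
#'   for the heterogeneity SD) or `"sample"` (divisor n - 1).
#' @return A list of class `roi_measurement`: `mean`, `sd`, `n_pixels`,
#'   `area_mm2`.
#' @export
measure_roi <- function(phase_grid, roi, slice = NULL,
                        sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(roi, "roi_geometry"))
  s <- round(if (is.null(slice)) roi$slice else slice)
  dm <- dim(phase_grid)
  if (s < 1 || s > dm[1]) stop("ROI slice outside grid", call. = FALSE)
  px <- disc_pixels(dm[2:3], roi$row, roi$col, roi$radius_mm, roi$spacing)
  if (!nrow(px)) stop("ROI contains no pixels", call. = FALSE)
  vals <- phase_grid[s, , ][px]
  m <- mean(vals)
  v <- if (sd_type == "population") mean((vals - m)^2)
       else stats::var(vals)
  structure(list(mean = m, sd = sqrt(v), n_pixels = nrow(px),
                 area_mm2 = nrow(px) * roi$spacing^2),
            class = "roi_measurement")
}

#' Protocol parameters for per-lesion measurement
#'
#' @param roi1_range_mm2,roi2_range_mm2 target area ranges of the small and
#'   smaller enhancement ROIs.
#' @param roi3_margin_mm whole-tumor ROI margin (midpoint of the 2--3 mm
#'   placement rule).
#' @param threshold_quantile,elongation_max,min_volume_mm3 passed to
#'   [detect_enhancement_regions()].
#' @param n_repeats measurements per section-image for the enhancement ROIs
#'   (at least two per the protocol); the whole-tumor ROI uses
#'   `roi3_repeats`.
#' @param roi3_repeats repeats for the whole-tumor ROI (three per protocol).
#' @param n_observers number of simulated independent observers.
#' @param observer_sd SD (HU) of the zero-mean measurement perturbation
#'   applied per observer/repeat; 0 makes repeats exact copies.
#' @param adjacent half-width of the adjacent-slice window (1 gives the
#'   three adjacent section-images).
#' @param sd_type SD convention, see [measure_roi()].
#' @return A list of class `protocol_config`.
#' @export
protocol_config <- function(roi1_range_mm2 = c(50, 100),
                            roi2_range_mm2 = c(10, 20),
                            roi3_margin_mm = 2.5,
                            threshold_quantile = 0.9, elongation_max = 3,
                            min_volume_mm3 = 10, n_repeats = 2L,
                            roi3_repeats = 3L, n_observers = 2L,
                            observer_sd = 0, adjacent = 1L,
                            sd_type = "population") {
  structure(as.list(environment()), class = "protocol_config")
}

#' Measure one lesion under the full three-ROI protocol
#'
#' Applies the complete measurement protocol to a four-phase volume:
#'
#' * enhancement regions are detected on the corticomedullary grid and, per
#'   region, the smaller ROI is placed inside the region and the small ROI
#'   is placed over it inside the tumor; geometries are then propagated
#'   unchanged to the other phases and averaged over regions, three adjacent
#'   section-images, repeats and observers (a flat grand mean);
#' * the whole-tumor ROI is fixed on the excretory phase (clearest tumor
#'   boundary) and propagated to the other phases; its SD is the tumor
#'   heterogeneity HDT and its mean the whole-tumor attenuation;
#' * cortex attenuation (AVC) is read from a homogeneous cortex ROI and the
#'   psoas SD (HDP) from a psoas ROI at the whole-tumor ROI's level.
#'
#' @param volume a `four_phase_volume` (see [simulate_lesion_volume()]); all
#'   four phases must be present, otherwise an `"incomplete-four-phase"`
#'   condition is signalled.
#' @param config a [protocol_config()].
#' @param seed seed for the simulated observer perturbations.
#' @return One-row data.frame with columns `AVT_<phase>_<1|2|3>`,
#'   `AVC_<phase>`, `HDT_<phase>`, `HDP_<phase>`; the placement log is
#'   attached as attribute `"log"`.
#' @export
measure_lesion_protocol <- function(volume, config = protocol_config(),
                                    seed = 1L) {
  stopifnot(inherits(volume, "four_phase_volume"))
  if (!all(.phases %in% names(volume$phases)))
    stop(structure(class = c("incomplete-four-phase", "error", "condition"),
                   list(message = paste(
                     "incomplete-four-phase: need PCP, CMP, NP and EP;",
                     "got", paste(names(volume$phases), collapse = ", ")),
                     call = sys.call(-1))))
  sp <- volume$spacing; th <- volume$thickness
  masks <- volume$masks
  set.seed(derive_seed(seed, 4L))
  log <- character()
  perturb <- function() if (config$observer_sd > 0)
    rnorm(1, 0, config$observer_sd) else 0

  ## --- enhancement regions on CMP --------------------------------------
  regions <- detect_enhancement_regions(
    volume$phases$CMP, masks$tumor, sp, th,
    exclude = masks[intersect(c("cysts", "vessels"), names(masks))],
    threshold_quantile = config$threshold_quantile,
    elongation_max = config$elongation_max,
    min_volume_mm3 = config$min_volume_mm3)
  if (!length(regions)) {
    regions <- list(masks$tumor)
    log <- c(log, "no enhancement region detected; using whole tumor")
  } else {
    log <- c(log, sprintf("detected %d enhancement region(s)",
                          length(regions)))
  }
  place2 <- function(region) {
    tryCatch(place_fixed_area_roi(region, config$roi2_range_mm2, sp,
                                  intensity = volume$phases$CMP,
                                  within = region & masks$tumor,
                                  phase = "CMP", fallback = TRUE),
             error = function(e) NULL)
  }
  avoid <- masks$tumor
  for (nm in intersect(c("cysts", "vessels"), names(masks)))
    avoid <- avoid & !masks[[nm]]
  place1 <- function(region) {
    tryCatch(place_fixed_area_roi(region, config$roi1_range_mm2, sp,
                                  intensity = volume$phases$CMP,
                                  within = avoid,
                                  phase = "CMP", fallback = TRUE),
             error = function(e) NULL)
  }
  rois1 <- Filter(Negate(is.null), lapply(regions, place1))
  rois2 <- Filter(Negate(is.null), lapply(regions, place2))
  if (!length(rois1) || !length(rois2))
    stop("could not place enhancement ROIs inside the tumor",
         call. = FALSE)

  grand_mean_avt <- function(rois, grid) {
    vals <- c()
    for (roi in rois) {
      for (ds in -config$adjacent:config$adjacent) {
        s <- min(max(round(roi$slice) + ds, 1), dim(grid)[1])
        base <- measure_roi(grid, roi, slice = s, sd_type = config$sd_type)
        for (obs in seq_len(config$n_observers))
          for (rep_ in seq_len(config$n_repeats))
            vals <- c(vals, base$mean + perturb())
      }
    }
    mean(vals)
  }

  ## --- whole-tumor ROI fixed on EP, propagated -------------------------
  roi3 <- place_whole_tumor_roi(masks$tumor, config$roi3_margin_mm, sp,
                                phase = "EP")
  log <- c(log, sprintf(
    "whole-tumor ROI: slice %d, radius %.1f mm (margin %.1f mm)",
    round(roi3$slice), roi3$radius_mm, config$roi3_margin_mm))

  roi3_stats <- function(grid) {
    ms <- replicate(config$roi3_repeats, {
      b <- measure_roi(grid, roi3, sd_type = config$sd_type)
      c(b$mean + perturb(), b$sd + perturb())
    })
    rowMeans(ms)
  }

  ## --- reference tissues ------------------------------------------------
  roi_cortex <- place_fixed_area_roi(masks$cortex, c(50, 100), sp,
                                     fallback = TRUE)
  roi_psoas <- tryCatch(
    place_fixed_area_roi(masks$psoas, c(50, 100), sp, fallback = TRUE),
    error = function(e) stop("psoas mask cannot host a reference ROI",
                             call. = FALSE))
  roi_psoas$slice <- roi3$slice      # psoas read at the whole-tumor level

  out <- list()
  for (ph in .phases) {
    g <- volume$phases[[ph]]
    out[[paste0("AVT_", ph, "_1")]] <- grand_mean_avt(rois1, g)
    out[[paste0("AVT_", ph, "_2")]] <- grand_mean_avt(rois2, g)
    s3 <- roi3_stats(g)
    out[[paste0("AVT_", ph, "_3")]] <- s3[1]
    out[[paste0("HDT_", ph)]] <- s3[2]
    out[[paste0("AVC_", ph)]] <-
      measure_roi(g, roi_cortex, sd_type = config$sd_type)$mean
    out[[paste0("HDP_", ph)]] <-
      measure_roi(g, roi_psoas, sd_type = config$sd_type)$sd
  }
  res <- as.data.frame(out)
  attr(res, "log") <- log
  res
}
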