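## ---- file round-tripping: CSV lesion tables, NIfTI volumes, JSON config --

#' Write a lesion table to CSV
#'
#' UTF-8, comma-separated, header row, "." decimal.  Ratio columns
#' (`RER_*`, `SHR_*`) are rounded to two decimals to match reporting
#' precision; all other numeric columns are written at full precision.
#'
#' @param table lesion table data.frame.
#' @param path output CSV path.
#' @export
write_lesion_table <- function(table, path) {
  ratio <- grep("^(RER|SHR)_", names(table))
  for (j in ratio) table[[j]] <- round(table[[j]], 2)
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a lesion table CSV
#'
#' @param path CSV path.
#' @param require_class require a valid `class` column (ccRCC / AML.wovf).
#' @return data.frame.
#' @export
read_lesion_table <- function(path, require_class = TRUE) {
  if (!file.exists(path))
    stop(sprintf("lesion table not found: %s", path), call. = FALSE)
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"lesion_id" %in% names(tab))
    stop("schema error: missing 'lesion_id' column", call. = FALSE)
  if (anyDuplicated(tab$lesion_id))
    stop("schema error: duplicate lesion ids", call. = FALSE)
  if (require_class) {
    if (!"class" %in% names(tab))
      stop("schema error: missing 'class' column", call. = FALSE)
    bad <- setdiff(unique(tab$class), .classes)
    if (length(bad))
      stop(sprintf("schema error: unknown class label(s): %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  for (fl in intersect(c("pseudocapsule", "cystic", "angular"), names(tab)))
    if (!all(tab[[fl]] %in% c(0, 1, NA)))
      stop(sprintf("schema error: flag '%s' must be 0/1", fl),
           call. = FALSE)
  tab
}

## integer label codes for the companion mask volume; overlaps resolved by
## assignment order (later wins), so cysts/vessels take precedence over
## patches, and everything tumor-internal stays in 1..5
.mask_labels <- c(tumor = 1L, pseudocapsule = 5L, patches = 2L,
                  vessels = 3L, cysts = 4L, cortex = 6L, psoas = 7L)

#' Write a four-phase volume as NIfTI
#'
#' One NIfTI per phase (`<prefix>_PCP.nii.gz`, ...) plus an integer-labeled
#' companion volume `<prefix>_labels.nii.gz` (1 tumor, 2 enhancement patch,
#' 3 vessel, 4 cyst, 5 pseudocapsule, 6 cortex, 7 psoas; tumor is the union
#' of labels 1-5).
#'
#' @param volume a `four_phase_volume`.
#' @param dir output directory (created).
#' @param prefix file prefix.
#' @export
write_four_phase_volume <- function(volume, dir, prefix = "lesion") {
  stopifnot(inherits(volume, "four_phase_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- c(volume$thickness, volume$spacing, volume$spacing)
  for (ph in .phases) {
    im <- RNifti::asNifti(volume$phases[[ph]])
    RNifti::pixdim(im) <- pd
    RNifti::writeNifti(im, file.path(dir, sprintf("%s_%s.nii.gz",
                                                  prefix, ph)))
  }
  lab <- array(0L, dim(volume$masks$tumor))
  for (nm in names(.mask_labels))
    if (!is.null(volume$masks[[nm]])) lab[volume$masks[[nm]]] <-
      .mask_labels[[nm]]
  im <- RNifti::asNifti(lab)
  RNifti::pixdim(im) <- pd
  RNifti::writeNifti(im, file.path(dir, sprintf("%s_labels.nii.gz", prefix)))
  invisible(dir)
}

#' Read a four-phase volume written by [write_four_phase_volume()]
#'
#' @param dir directory holding the NIfTI files.
#' @param prefix file prefix.
#' @return A `four_phase_volume`.
#' @export
read_four_phase_volume <- function(dir, prefix = "lesion") {
  phases <- lapply(.phases, function(ph) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, ph))
    if (!file.exists(f))
      stop(structure(class = c("incomplete-four-phase", "error",
                               "condition"),
                     list(message = sprintf(
                       "incomplete-four-phase: missing %s", f),
                       call = sys.call(-1))))
    im <- RNifti::readNifti(f)
    array(as.numeric(im), dim(im))
  })
  names(phases) <- .phases
  imf <- file.path(dir, sprintf("%s_labels.nii.gz", prefix))
  im <- RNifti::readNifti(imf)
  lab <- array(as.integer(im), dim(im))
  pd <- RNifti::pixdim(im)
  masks <- list(tumor = lab >= 1L & lab <= 5L,
                patches = lab == 2L, vessels = lab == 3L,
                cysts = lab == 4L, pseudocapsule = lab == 5L,
                cortex = lab == 6L, psoas = lab == 7L)
  structure(list(phases = phases, spacing = pd[2], thickness = pd[1],
                 masks = masks, spec = NULL),
            class = "four_phase_volume")
}

#' Read or write a run configuration as JSON
#'
#' @param config named list (seeds, phantom parameters, protocol
#'   parameters, statistical alpha, phases, output directory).
#' @param path JSON path.
#' @export
write_run_config <- function(config, path) {
  if (!is.null(config$alpha) && (config$alpha <= 0 || config$alpha >= 1))
    stop("alpha must lie in (0, 1)", call. = FALSE)
  jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config not found: %s", path), call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
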