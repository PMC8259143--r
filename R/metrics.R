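## ---- derived quantitative parameters ------------------------------------

#' Net enhancement value (NEV)
#'
#' Attenuation gain of the tumor in an enhanced phase over the pre-contrast
#' phase, `AVT_enhanced - AVT_PCP`, in HU.  Negative values are allowed and
#' signal de-enhancement.
#'
#' @param avt_enhanced,avt_pcp tumor attenuation (HU) in the enhanced and
#'   pre-contrast phase.
#' @return HU difference.
#' @export
#' @examples
#' compute_nev(216.91, 34.73)
compute_nev <- function(avt_enhanced, avt_pcp) avt_enhanced - avt_pcp

#' Relative enhancement ratio (RER)
#'
#' Tumor attenuation normalized by the attenuation of homogeneous adjacent
#' renal cortex in the same phase, `AVT / AVC * 100`, in percent.
#'
#' @param avt tumor attenuation (HU).
#' @param avc cortex attenuation (HU), non-zero.
#' @return Percentage.
#' @export
#' @examples
#' compute_rer(188.93, 204.51)
compute_rer <- function(avt, avc) {
  if (any(avc == 0)) stop("cortex attenuation must be non-zero",
                          call. = FALSE)
  avt / avc * 100
}

#' Standardized heterogeneous ratio (SHR)
#'
#' Tumor heterogeneity (SD within the whole-tumor ROI) normalized by the
#' psoas SD at the same level, `HDT / HDP * 100`, in percent; the psoas term
#' absorbs scanner noise that would otherwise inflate the raw SD.
#'
#' @param hdt tumor SD (HU).
#' @param hdp psoas SD (HU), non-zero.
#' @return Percentage.
#' @export
#' @examples
#' compute_shr(43.62, 11.81)
compute_shr <- function(hdt, hdp) {
  if (any(hdp == 0)) stop("psoas SD must be non-zero", call. = FALSE)
  hdt / hdp * 100
}

#' Assemble the quantitative lesion table
#'
#' Takes raw per-lesion protocol measurements (`AVT_<phase>_<roi>`,
#' `AVC_<phase>`, `HDT_<phase>`, `HDP_<phase>`) and derives the full set of
#' quantitative columns: NEV and RER for every enhanced phase and ROI
#' variant, and SHR for every phase.  Lesions with any missing phase are
#' kept but flagged `incomplete`.
#'
#' @param records data.frame of raw measurements, one row per lesion, with a
#'   `lesion_id` column (created if absent).  Duplicate ids are an error.
#' @return data.frame with all derived columns and a logical `incomplete`
#'   flag.
#' @export
assemble_quant_table <- function(records) {
  records <- as.data.frame(records)
  if (!"lesion_id" %in% names(records))
    records$lesion_id <- sprintf("L%03d", seq_len(nrow(records)))
  if (anyDuplicated(records$lesion_id))
    stop("duplicate lesion identifiers", call. = FALSE)
  need <- function(ph) c(paste0("AVT_", ph, "_", 1:3), paste0("AVC_", ph),
                         paste0("HDT_", ph), paste0("HDP_", ph))
  for (col in unlist(lapply(.phases, need)))
    if (!col %in% names(records)) records[[col]] <- NA_real_
  out <- records
  for (ph in c("CMP", "NP", "EP")) {
    for (roi in 1:3) {
      avt <- out[[paste0("AVT_", ph, "_", roi)]]
      out[[paste0("NEV_", ph, "_", roi)]] <-
        compute_nev(avt, out[[paste0("AVT_PCP_", roi)]])
      out[[paste0("RER_", ph, "_", roi)]] <-
        ifelse(out[[paste0("AVC_", ph)]] == 0, NA_real_,
               avt / out[[paste0("AVC_", ph)]] * 100)
    }
  }
  for (ph in .phases)
    out[[paste0("SHR_", ph)]] <-
      ifelse(out[[paste0("HDP_", ph)]] == 0, NA_real_,
             out[[paste0("HDT_", ph)]] / out[[paste0("HDP_", ph)]] * 100)
  phase_cols <- lapply(.phases, need)
  out$incomplete <- Reduce(`|`, lapply(phase_cols, function(cols)
    apply(is.na(records[, cols, drop = FALSE]), 1, any)))
  out
}
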