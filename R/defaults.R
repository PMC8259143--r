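#' Reference cohort calibration values
#'
#' Per-class means and standard deviations of every quantitative CT parameter,
#' and per-class frequencies of the categorical variables, for a reference
#' surgical cohort of 74 small ccRCC and 31 fat-poor AML.  These are the
#' default generative targets of [cohort_config()] and the calibration source
#' for the lesion phantoms.
#'
#' Quantitative columns follow the naming scheme `<PARAM>_<PHASE>[_<ROI>]`
#' with phases `PCP` (pre-contrast), `CMP` (corticomedullary), `NP`
#' (nephrographic), `EP` (excretory) and ROI variants `1` (small, 50--100
#' mm^2), `2` (smaller, 10--20 mm^2), `3` (whole tumor).  AVT/NEV/HDT are in
#' Hounsfield units; RER/SHR are percentages.
#'
#' @return A list with elements `quantitative` (data.frame: feature,
#'   mean_ccrcc, sd_ccrcc, mean_aml, sd_aml), `categorical` (data.frame:
#'   variable, level coded 1, freq_ccrcc, freq_aml) and `n` (named vector of
#'   reference class sizes).
#' @export
#' @examples
#' head(cohort_reference()$quantitative)
cohort_reference <- function() {
  q <- read.csv(text = "feature,mean_ccrcc,sd_ccrcc,mean_aml,sd_aml
AVT_PCP_1,32.78,6.50,38.33,5.47
AVT_PCP_2,34.73,6.08,40.17,6.43
AVT_PCP_3,30.28,5.78,32.72,9.18
HDT_PCP,11.60,2.42,12.78,4.91
SHR_PCP,150.12,38.98,166.87,60.86
AVT_CMP_1,166.15,40.61,147.58,27.16
NEV_CMP_1,133.37,40.30,108.94,28.39
RER_CMP_1,88.22,19.03,76.23,14.59
AVT_CMP_2,216.91,43.87,181.18,32.67
NEV_CMP_2,182.31,45.15,140.68,33.75
RER_CMP_2,116.21,17.48,89.39,14.48
AVT_CMP_3,127.99,41.55,115.54,31.79
NEV_CMP_3,95.47,34.12,85.40,29.43
RER_CMP_3,66.85,19.44,60.75,14.96
HDT_CMP,39.58,8.38,29.04,6.92
SHR_CMP,412.11,116.92,290.53,85.78
AVT_NP_1,108.05,22.28,108.77,21.26
NEV_NP_1,75.27,22.51,70.13,21.61
RER_NP_1,72.84,12.38,67.16,7.94
AVT_NP_2,129.11,24.69,116.90,21.80
NEV_NP_2,94.25,25.98,78.02,26.48
RER_NP_2,87.36,12.75,71.83,8.49
AVT_NP_3,92.89,27.15,93.20,23.71
NEV_NP_3,62.67,25.87,60.48,21.26
RER_NP_3,62.52,17.48,57.28,10.16
HDT_NP,25.03,5.86,20.19,5.21
SHR_NP,304.39,80.20,259.94,64.79
AVT_EP_1,87.56,16.61,87.72,12.03
NEV_EP_1,54.77,17.10,49.07,13.18
RER_EP_1,63.73,9.27,60.52,10.64
AVT_EP_2,101.46,18.53,97.05,14.63
NEV_EP_2,66.86,19.54,56.56,18.08
RER_EP_2,73.95,10.30,65.74,11.32
AVT_EP_3,80.49,17.99,78.64,19.51
NEV_EP_3,50.67,17.70,45.92,16.21
RER_EP_3,57.88,11.35,53.85,11.32
HDT_EP,19.79,4.72,16.00,4.40
SHR_EP,247.34,66.58,204.87,54.68
age,54.61,11.44,51.00,10.71
size_cm,2.80,0.71,2.70,0.62",
    stringsAsFactors = FALSE)
  cat <- data.frame(
    variable = c("gender", "location", "growth", "pseudocapsule",
                 "cystic", "angular"),
    level1   = c("male", "left", "endophytic", "present", "present",
                 "present"),
    freq_ccrcc = c(48, 37, 42, 25, 36, 9) / 74,
    freq_aml   = c(7, 17, 12, 2, 6, 13) / 31,
    stringsAsFactors = FALSE
  )
  list(quantitative = q, categorical = cat,
       n = c(ccRCC = 74L, AML.wovf = 31L))
}

## canonical phase / class labels used throughout
.phases <- c("PCP", "CMP", "NP", "EP")
.classes <- c("ccRCC", "AML.wovf")

quant_feature_names <- function() cohort_reference()$quantitative$feature
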