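# Shared fixtures, built once per test run.

# structured ccRCC-like phantom (patches, vessel, cysts, pseudocapsule)
fixture_ccrcc_vol <- simulate_lesion_volume(lesion_spec(), seed = 11)

# noise-free, structure-free homogeneous phantom
fixture_flat_spec <- lesion_spec(noise_sd = 0, n_patches = 0L,
                                 n_vessels = 0L, cyst_fraction = 0,
                                 pseudocapsule = FALSE)
fixture_flat_vol <- simulate_lesion_volume(fixture_flat_spec, seed = 11)

# single-patch phantom (connected ground-truth patch mask)
fixture_onepatch_vol <- simulate_lesion_volume(
  lesion_spec(n_patches = 1L, cyst_fraction = 0), seed = 13)

# protocol measurement of the structured phantom, shared across tests
fixture_ccrcc_meas <- measure_lesion_protocol(fixture_ccrcc_vol, seed = 2)

# small reference cohort table
fixture_cohort <- simulate_cohort(cohort_config(seed = 101))

# published variable sets per phase (coding: male = 1, flag present = 1)
published_vars <- list(
  PCP = c("gender", "pseudocapsule", "angular", "AVT_PCP_1"),
  CMP = c("gender", "cystic", "RER_CMP_2", "SHR_CMP"),
  NP  = c("gender", "pseudocapsule", "RER_NP_2", "HDT_NP"),
  EP  = c("gender", "angular", "RER_EP_2", "SHR_EP"))

# translate a four-phase volume by whole voxels (background fill -50)
translate_volume <- function(vol, dr = 0L, dc = 0L) {
  shift_arr <- function(a, fill) {
    out <- array(fill, dim(a))
    dm <- dim(a)
    rs <- seq_len(dm[2] - abs(dr)); cs <- seq_len(dm[3] - abs(dc))
    out[, rs + max(dr, 0), cs + max(dc, 0)] <-
      a[, rs + max(-dr, 0), cs + max(-dc, 0)]
    out
  }
  vol$phases <- lapply(vol$phases, shift_arr, fill = -50)
  vol$masks <- lapply(vol$masks, shift_arr, fill = FALSE)
  vol
}
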