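# Published summary statistics from the Tieguanyin tea survey (91 samples,
# Fujian) that this package ships as its default study conditions. Only
# summaries were published -- the raw per-sample data and the consumption
# survey are not available -- which is why the synthetic module exists.

#' Published made-tea concentration summaries
#'
#' Per-element range, mean and SD of the five metals in made tea (mg/kg dry
#' mass) from the 91-sample survey. The Cd minimum was reported only as
#' "below detection"; it is carried here as 0 with the censoring handled by
#' the generator's `nd_fraction`.
#'
#' @return Tibble with columns `element`, `mean_mg_kg`, `sd_mg_kg`,
#'   `min_mg_kg`, `max_mg_kg`.
#' @export
reference_concentrations <- function() {
  tibble::tibble(
    element = c("Cu", "Pb", "Cr", "Cd", "Ni"),
    mean_mg_kg = c(8.18, 0.84, 0.51, 0.04, 1.90),
    sd_mg_kg = c(2.10, 0.40, 0.28, 0.02, 0.70),
    min_mg_kg = c(2.65, 0.21, 0.08, 0, 1.02),
    max_mg_kg = c(11.61, 2.00, 1.38, 0.11, 2.93)
  )
}

#' Published mean brewing transfer rates
#'
#' Mean fraction of each element's mass in the brewed leaves that ends up in
#' the infusion under the 7 g / 150 mL / 10 min protocol.
#'
#' @return Named numeric vector of fractions.
#' @export
reference_transfer_rates <- function() {
  c(Cu = 0.102, Pb = 0.315, Cr = 0.423, Cd = 0.536, Ni = 0.704)
}

#' Published hazard quotients by subpopulation
#'
#' The survey's reported HQ and bioavailability-adjusted HQ, on the percent
#' scale and rounded to 2 significant figures as published, for six
#' subpopulations. These printed cells are the only trace of the (unpublished)
#' consumption survey, so [default_profiles()] back-solves the consumption
#' ratios from the Cu column of this table.
#'
#' @return Tibble with columns `element`, `profile`, `hq_pct`,
#'   `adjusted_hq_pct`.
#' @export
reference_hq <- function() {
  profiles <- c("male", "female", "urban", "rural", "age_18_40", "age_ge_41")
  hq <- rbind(
    Cu = c(4.7e-3, 3.1e-3, 4.0e-3, 3.7e-3, 3.7e-3, 5.0e-3),
    Pb = c(1.7e-2, 1.1e-2, 1.4e-2, 1.3e-2, 1.3e-2, 1.8e-2),
    Cr = c(1.6e-2, 1.1e-2, 1.4e-2, 1.3e-2, 1.3e-2, 1.7e-2),
    Cd = c(4.9e-3, 3.2e-3, 4.2e-3, 3.8e-3, 3.8e-3, 5.1e-3),
    Ni = c(1.5e-2, 1.0e-2, 1.3e-2, 1.2e-2, 1.2e-2, 1.6e-2)
  )
  adj <- rbind(
    Cu = c(2.0e-3, 1.2e-3, 1.6e-3, 1.5e-3, 1.5e-3, 2.0e-3),
    Pb = c(1.0e-2, 6.7e-3, 8.6e-3, 8.0e-3, 8.0e-3, 1.0e-2),
    Cr = c(1.6e-4, 1.1e-4, 1.4e-4, 1.3e-4, 1.3e-4, 1.7e-4),
    Cd = c(2.4e-3, 1.6e-3, 2.1e-3, 1.9e-3, 1.9e-3, 2.5e-3),
    Ni = c(1.5e-3, 1.0e-3, 1.3e-3, 1.2e-3, 1.2e-3, 1.6e-3)
  )
  tibble::tibble(
    element = rep(rownames(hq), times = length(profiles)),
    profile = rep(profiles, each = nrow(hq)),
    hq_pct = as.vector(hq),
    adjusted_hq_pct = as.vector(adj)
  )
}

#' Published hazard index row by subpopulation
#'
#' @return Tibble with columns `profile`, `hi_pct`, `adjusted_hi_pct`
#'   (percent scale, 2 significant figures as published).
#' @export
reference_hi <- function() {
  tibble::tibble(
    profile = c("male", "female", "urban", "rural", "age_18_40", "age_ge_41"),
    hi_pct = c(5.8e-2, 3.8e-2, 4.9e-2, 4.6e-2, 4.6e-2, 6.1e-2),
    adjusted_hi_pct = c(1.6e-2, 1.1e-2, 1.4e-2, 1.3e-2, 1.3e-2, 1.7e-2)
  )
}

#' Published analytical quality-control reference
#'
#' Per-element certified reference material (green tea CRM) values, infusion
#' spike recoveries at 10/50/100 ug/L, and blank-derived detection limits
#' (LOD = 3 x SD of 10 reagent blanks, LOQ = 10 x SD), as reported for the
#' survey's ICP-MS method. [gen_qc_batch()] uses these as its targets.
#'
#' @return Tibble with columns `element`, `certified_mean`, `certified_sd`,
#'   `detected_mean`, `detected_sd` (CRM scale), `recovery_10`, `recovery_50`,
#'   `recovery_100` (percent), `lod_ug_l`, `loq_ug_l`.
#' @export
default_qc_reference <- function() {
  tibble::tibble(
    element = c("Cu", "Ni", "Pb", "Cd", "Cr"),
    certified_mean = c(24, 5.4, 1.6, 0.076, 0.92),
    certified_sd = c(1, 0.4, 0.2, 0.004, 0.20),
    detected_mean = c(24.4, 5.4, 1.7, 0.077, 0.92),
    detected_sd = c(0.5, 0.2, 0.1, 0.001, 0.01),
    recovery_10 = c(110.6, 103.6, 90.1, 85.3, 100.4),
    recovery_50 = c(110.7, 96.8, 85.9, 87.3, 94.7),
    recovery_100 = c(114.2, 98.8, 87.2, 84.3, 96.8),
    lod_ug_l = c(0.09, 0.02, 0.01, 0.003, 0.009),
    loq_ug_l = c(0.3, 0.06, 0.03, 0.01, 0.03)
  )
}
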