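#' Brewing transfer rate
#'
#' Fraction of an element's mass in the brewed tea leaves that ends up in the
#' infusion: `T = (C_i * V_i) / (C_t * M_t)`, with the made-tea concentration
#' in mg/kg read as ug/g so the units cancel. Values above 1 are possible
#' under measurement noise and are permitted (callers may flag them);
#' negative inputs are rejected.
#'
#' @param c_infusion_ug_l Infusion concentration C_i, ug/L.
#' @param c_tea_mg_kg Made-tea concentration C_t, mg/kg (= ug/g). Must be > 0.
#' @param brewing A [brewing_spec()].
#' @return Dimensionless transfer fraction (vectorised).
#' @export
#' @examples
#' transfer_rate(46.667, 1) # ~1: all mass brewed out of 1 mg/kg tea
transfer_rate <- function(c_infusion_ug_l, c_tea_mg_kg,
                          brewing = default_brewing()) {
  if (any(c_infusion_ug_l < 0, na.rm = TRUE)) {
    abort_validation("infusion concentration must be >= 0")
  }
  if (any(c_tea_mg_kg <= 0, na.rm = TRUE)) {
    abort_validation(
      "transfer rate undefined for made-tea concentration <= 0")
  }
  (c_infusion_ug_l * brewing$water_volume_l) /
    (c_tea_mg_kg * brewing$tea_mass_g)
}

#' Infusion concentration implied by a transfer rate
#'
#' Exact inverse of [transfer_rate()]: `C_i = T * C_t * M_t / V_i` in ug/L.
#'
#' @param c_tea_mg_kg Made-tea concentration, mg/kg. Must be >= 0.
#' @param transfer Transfer fraction, >= 0.
#' @param brewing A [brewing_spec()].
#' @return Infusion concentration in ug/L (vectorised).
#' @export
#' @examples
#' infusion_concentration(0.84, 0.315) # ~12.35 ug/L Pb
infusion_concentration <- function(c_tea_mg_kg, transfer,
                                   brewing = default_brewing()) {
  if (any(transfer < 0, na.rm = TRUE)) {
    abort_validation("transfer must be >= 0")
  }
  if (any(c_tea_mg_kg < 0, na.rm = TRUE)) {
    abort_validation("made-tea concentration must be >= 0")
  }
  transfer * c_tea_mg_kg * brewing$tea_mass_g / brewing$water_volume_l
}

#' Per-element mean transfer rates from a paired dataset
#'
#' Computes the per-sample transfer rate for every sample carrying both a
#' made-tea and an infusion measurement of an element, then summarises with
#' the arithmetic mean of those per-sample ratios (treating samples as the
#' replication unit, not a ratio of element totals). Samples lacking either
#' matrix are skipped and counted; elements with no pairs at all are omitted
#' with a warning. Censored values must be substituted first (see
#' [substitute_censored()]); which policy produced a summary is recorded in
#' the `censoring_policy` attribute carried over from the input.
#'
#' @param dataset A `conc_dataset` containing both `made_tea` (mg/kg) and
#'   `infusion` (ug/L) measurements.
#' @param brewing Brewing spec; defaults to the one attached to `dataset`.
#' @return Tibble with columns `element`, `mean_t`, `sd_t` (`NA` when n = 1),
#'   `n`, `n_skipped`, `n_flagged` (pairs with T > 1).
#' @export
mean_transfer_rates <- function(dataset, brewing = NULL) {
  brewing <- brewing %||% attr(dataset, "brewing") %||% default_brewing()
  if (any(is.na(dataset$value))) {
    abort_validation(
      "dataset contains unsubstituted censored values; run substitute_censored() first")
  }
  made <- dataset[dataset$matrix == "made_tea", c("sample_id", "element", "value")]
  inf <- dataset[dataset$matrix == "infusion", c("sample_id", "element", "value")]
  names(made)[3] <- "c_tea"
  names(inf)[3] <- "c_inf"
  paired <- dplyr::inner_join(made, inf, by = c("sample_id", "element"))
  elements <- unique(c(made$element, inf$element))
  out <- lapply(elements, function(el) {
    p <- paired[paired$element == el & paired$c_tea > 0, ]
    n_all <- length(unique(c(made$sample_id[made$element == el],
                             inf$sample_id[inf$element == el])))
    if (nrow(p) == 0) {
      warn(sprintf("No paired made-tea/infusion samples for %s; omitted", el))
      return(NULL)
    }
    t_i <- transfer_rate(p$c_inf, p$c_tea, brewing)
    tibble::tibble(
      element = el,
      mean_t = mean(t_i),
      sd_t = if (length(t_i) > 1) stats::sd(t_i) else NA_real_,
      n = length(t_i),
      n_skipped = n_all - nrow(p),
      n_flagged = sum(t_i > 1)
    )
  })
  res <- dplyr::bind_rows(out)
  skipped <- sum(res$n_skipped)
  if (!is.na(skipped) && skipped > 0) {
    inform(sprintf("%d sample/element pairs lacked one matrix and were skipped",
                   skipped))
  }
  attr(res, "censoring_policy") <- attr(dataset, "censoring_policy")
  res
}
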