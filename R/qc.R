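#' Blank-based detection limits
#'
#' LOD = 3 x SD of the reagent blanks, LOQ = 10 x SD, computed per element
#' with the sample SD (n - 1 denominator). At least two uncensored blank
#' measurements per element are required.
#'
#' @param blanks A `conc_dataset` of blank measurements (ug/L), or any data
#'   frame with columns `element` and `value`.
#' @param elements Optional subset of elements; defaults to every element in
#'   `blanks`.
#' @return Tibble with columns `element`, `lod`, `loq`, `n_blanks` (ug/L).
#' @export
#' @examples
#' blanks <- data.frame(element = "Cu", value = c(0, 0.01, 0.02))
#' detection_limits(blanks) # lod 0.03, loq 0.1
detection_limits <- function(blanks, elements = NULL) {
  df <- tibble::as_tibble(blanks)
  if (!all(c("element", "value") %in% names(df))) {
    abort_format("blanks need `element` and `value` columns")
  }
  df <- df[!is.na(df$value), c("element", "value")]
  elements <- elements %||% unique(df$element)
  out <- lapply(elements, function(el) {
    v <- df$value[df$element == el]
    if (length(v) < 2) {
      abort_validation(sprintf(
        "Need >= 2 uncensored blank measurements for %s (got %d)",
        el, length(v)))
    }
    s <- stats::sd(v)
    tibble::tibble(element = el, lod = 3 * s, loq = 10 * s,
                   n_blanks = length(v))
  })
  dplyr::bind_rows(out)
}

#' Substitute censored (below-detection) values
#'
#' Replaces the absent values of censored measurements according to a
#' policy: the study's own rule assigns the LOQ (`"loq"`, the conservative
#' default); `"half_loq"` and `"zero"` are offered as sensitivity
#' alternatives. Censored flags are preserved for provenance and the policy
#' is recorded as an attribute. Limits must be expressed in the unit of the
#' dataset's matrix.
#'
#' @param dataset A `conc_dataset`.
#' @param limits Tibble with columns `element` and `loq` (e.g. from
#'   [detection_limits()]), or a named numeric vector of LOQs.
#' @param policy One of `"loq"`, `"half_loq"`, `"zero"`.
#' @return The dataset with all values present; attribute
#'   `censoring_policy` records the policy used.
#' @export
substitute_censored <- function(dataset, limits,
                                policy = c("loq", "half_loq", "zero")) {
  policy <- match.arg(policy)
  if (is.numeric(limits) && !is.null(names(limits))) {
    limits <- tibble::tibble(element = names(limits), loq = unname(limits))
  }
  if (!all(c("element", "loq") %in% names(limits))) {
    abort_format("limits need `element` and `loq`")
  }
  cens <- dataset$censored
  if (any(cens)) {
    need <- unique(dataset$element[cens])
    missing_el <- setdiff(need, limits$element)
    if (length(missing_el) > 0) {
      abort_validation(sprintf(
        "No detection limits supplied for censored element(s): %s",
        paste(missing_el, collapse = ", ")))
    }
    loq <- limits$loq[match(dataset$element[cens], limits$element)]
    dataset$value[cens] <- switch(policy,
      loq = loq,
      half_loq = loq / 2,
      zero = 0
    )
  }
  attr(dataset, "censoring_policy") <- policy
  dataset
}

#' Spike recovery
#'
#' Recovery (%) of a known spike: `(measured - base) / spiked * 100`. The
#' survey's spikes were 10, 50 and 100 ug/L added to infusion with
#' negligible base signal.
#'
#' @param measured Measured concentration of the spiked sample (ug/L).
#' @param spiked Nominal spike concentration (ug/L), > 0.
#' @param base Unspiked base concentration (ug/L), default 0.
#' @return Recovery in percent (vectorised).
#' @export
#' @examples
#' spike_recovery(11.06, 10) # 110.6 %
spike_recovery <- function(measured, spiked, base = 0) {
  if (any(spiked <= 0)) abort_validation("`spiked` must be > 0")
  (measured - base) / spiked * 100
}

#' Certified reference material check
#'
#' Compares a detected mean against the certified value of a reference
#' material: pass when `|detected - certified| <= k * sqrt(certified_sd^2 +
#' detected_sd^2)` (default coverage k = 2). The z-like score is the
#' difference in units of the combined SD (0 when both difference and SDs
#' are zero).
#'
#' @param detected_mean,detected_sd Detected mean and SD.
#' @param certified_mean,certified_sd Certified mean and SD.
#' @param k Coverage multiplier.
#' @return List with `pass` (logical), `score`, `tolerance`.
#' @export
#' @examples
#' crm_check(24.4, 0.5, 24, 1) # pass: |0.4| <= 2 * sqrt(1.25)
crm_check <- function(detected_mean, detected_sd, certified_mean,
                      certified_sd, k = 2) {
  if (detected_sd < 0 || certified_sd < 0) {
    abort_validation("SDs must be >= 0")
  }
  diff <- detected_mean - certified_mean
  combined <- sqrt(certified_sd^2 + detected_sd^2)
  score <- if (combined == 0) {
    if (diff == 0) 0 else Inf * sign(diff)
  } else {
    diff / combined
  }
  list(pass = abs(diff) <= k * combined, score = score,
       tolerance = k * combined)
}

#' Assemble a QC report for a batch
#'
#' Composes [detection_limits()], [spike_recovery()] and [crm_check()] over a
#' QC batch: one row per element with LOD/LOQ, recovery per spike level,
#' recovery pass (within `recovery_limits`) and CRM pass.
#'
#' @param blanks Blank measurements (see [detection_limits()]).
#' @param spikes Tibble with columns `element`, `spike_level`, `measured`
#'   and optionally `base` (ug/L).
#' @param crm Tibble with columns `element`, `certified_mean`,
#'   `certified_sd`, `detected_mean`, `detected_sd`, or `NULL` to skip the
#'   CRM check.
#' @param recovery_limits Acceptable recovery band in percent.
#' @param k CRM coverage multiplier.
#' @return Tibble, one row per element per spike level, with columns
#'   `element`, `lod`, `loq`, `n_blanks`, `spike_level`, `recovery`,
#'   `recovery_ok`, `crm_pass`.
#' @export
qc_report <- function(blanks, spikes, crm = NULL,
                      recovery_limits = c(70, 120), k = 2) {
  lims <- detection_limits(blanks)
  spikes <- tibble::as_tibble(spikes)
  if (!"base" %in% names(spikes)) spikes$base <- 0
  spikes$recovery <- spike_recovery(spikes$measured, spikes$spike_level,
                                    spikes$base)
  spikes$recovery_ok <- spikes$recovery >= recovery_limits[1] &
    spikes$recovery <= recovery_limits[2]
  out <- dplyr::left_join(
    spikes[, c("element", "spike_level", "recovery", "recovery_ok")],
    lims, by = "element")
  if (!is.null(crm)) {
    crm_pass <- vapply(seq_len(nrow(crm)), function(i) {
      crm_check(crm$detected_mean[i], crm$detected_sd[i],
                crm$certified_mean[i], crm$certified_sd[i], k = k)$pass
    }, logical(1))
    out <- dplyr::left_join(
      out, tibble::tibble(element = crm$element, crm_pass = crm_pass),
      by = "element")
  } else {
    out$crm_pass <- NA
  }
  out[, c("element", "lod", "loq", "n_blanks", "spike_level", "recovery",
          "recovery_ok", "crm_pass")]
}
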