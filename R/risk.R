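#' Estimated daily intake
#'
#' `EDI = C_t * T * D / Bw` in ug per kg body weight per day, where C_t is
#' the made-tea concentration (mg/kg, read as ug/g), T the brewing transfer
#' fraction, D the daily mass of tea brewed (g/day) and Bw the body weight
#' (kg). Equivalent to `C_t * T * r` with the canonical consumption ratio
#' `r = D / Bw` (g per kg bw per day). The infusion concentration never
#' enters directly: transfer applied to the made-tea level is what reaches
#' the drinker.
#'
#' @param c_tea_mg_kg Made-tea concentration, mg/kg, >= 0.
#' @param transfer Transfer fraction, >= 0.
#' @param ratio Consumption ratio r = D/Bw, g/kg bw/day; alternatively give
#'   `daily_tea_mass_g` and `body_weight_kg`.
#' @param daily_tea_mass_g,body_weight_kg Optional D and Bw pair.
#' @return EDI in ug/kg bw/day (vectorised).
#' @export
#' @examples
#' edi(0.84, 0.315, ratio = 2.25e-3) # Pb for a heavy-consuming profile
edi <- function(c_tea_mg_kg, transfer, ratio = NULL,
                daily_tea_mass_g = NULL, body_weight_kg = NULL) {
  if (is.null(ratio)) {
    if (is.null(daily_tea_mass_g) || is.null(body_weight_kg)) {
      abort_validation("give `ratio` or both `daily_tea_mass_g` and `body_weight_kg`")
    }
    if (any(body_weight_kg <= 0)) abort_validation("body weight must be > 0")
    if (any(daily_tea_mass_g < 0)) abort_validation("daily tea mass must be >= 0")
    ratio <- daily_tea_mass_g / body_weight_kg
  }
  if (any(c_tea_mg_kg < 0) || any(transfer < 0) || any(ratio < 0)) {
    abort_validation("edi inputs must be nonnegative")
  }
  c_tea_mg_kg * transfer * ratio
}

#' Hazard quotient
#'
#' `HQ = EDI / RfD`, dimensionless; both in ug/kg bw/day. HQ < 1 is
#' conventionally deemed acceptable (see [hq_acceptable()]).
#'
#' @param edi Estimated daily intake, ug/kg bw/day.
#' @param rfd Oral reference dose, ug/kg bw/day, > 0.
#' @return Dimensionless HQ (vectorised).
#' @export
hq <- function(edi, rfd) {
  if (any(rfd <= 0)) abort_validation("rfd must be > 0")
  edi / rfd
}

#' @rdname hq
#' @param x Hazard quotient(s).
#' @export
hq_acceptable <- function(x) x < 1

#' Bioavailability-adjusted hazard quotient
#'
#' `HQ * bioavailability`, using the element's oral absorption fraction.
#'
#' @param hq Dimensionless hazard quotient(s).
#' @param bioavailability Fraction in (0, 1].
#' @return Adjusted HQ (vectorised).
#' @export
adjusted_hq <- function(hq, bioavailability) {
  if (any(bioavailability <= 0 | bioavailability > 1)) {
    abort_validation("bioavailability must lie in (0, 1]")
  }
  hq * bioavailability
}

#' Hazard index
#'
#' Sum of the per-element hazard quotients for one subpopulation. (Some
#' typeset renderings of the index divide by the number of elements; the
#' quantity used and reported throughout this field, and reproduced by the
#' published HI rows this package's tests check, is the plain sum.) The same
#' operation applied to adjusted HQs yields the adjusted HI.
#'
#' @param hqs Numeric vector of HQs, length >= 1.
#' @return Dimensionless HI.
#' @export
hi <- function(hqs) {
  if (length(hqs) < 1) abort_validation("hi needs at least one HQ")
  sum(hqs)
}

#' Carcinogenic target risk
#'
#' `TR = EDI * Sf` with the EDI converted from ug/kg bw/day to mg/kg bw/day
#' before multiplying the slope factor (Sf in per mg/kg bw/day). The
#' microgram-to-milligram conversion is the single place the two
#' concentration scales meet, and is tested explicitly.
#'
#' @param edi Estimated daily intake, ug/kg bw/day.
#' @param sf Oral carcinogenic slope factor, per mg/kg bw/day; `NA` marks a
#'   non-carcinogen and is an error here.
#' @return Dimensionless lifetime cancer risk (vectorised).
#' @export
tr <- function(edi, sf) {
  if (any(is.na(sf))) {
    abort_validation("slope factor absent: element is not a registered carcinogen")
  }
  if (any(sf < 0)) abort_validation("sf must be >= 0")
  (edi * 1e-3) * sf
}

#' Total carcinogenic risk and contributions
#'
#' Sums per-element target risks, reports each element's contribution
#' fraction, and flags exceedance of the conventional 1e-4 acceptability
#' threshold.
#'
#' @param trs Named or unnamed numeric vector of per-element TRs, length >= 1.
#' @param threshold Acceptability threshold (default 1e-4).
#' @return List with `total`, `contribution` (fractions summing to 1 when
#'   the total is positive, `NA` otherwise), `exceeds`.
#' @export
tr_total <- function(trs, threshold = 1e-4) {
  if (length(trs) < 1) abort_validation("tr_total needs at least one TR")
  total <- sum(trs)
  contribution <- if (total > 0) trs / total else rep(NA_real_, length(trs))
  list(total = total, contribution = contribution,
       exceeds = total > threshold)
}

#' Back-solve a consumption ratio from a reported hazard quotient
#'
#' Algebraic inversion of the EDI/HQ chain: `r = HQ * RfD / (C_t * T)`,
#' giving the daily-tea-mass to body-weight ratio (g/kg bw/day) that would
#' produce a given HQ. Used to reconstruct unpublished survey ratios from
#' published HQ tables (see [default_profiles()]).
#'
#' @param hq Dimensionless hazard quotient (not percent).
#' @param rfd Oral reference dose, ug/kg bw/day, > 0.
#' @param c_tea_mg_kg Made-tea concentration, mg/kg, > 0.
#' @param transfer Transfer fraction, > 0.
#' @return Ratio r in g/kg bw/day (vectorised).
#' @export
invert_consumption_ratio <- function(hq, rfd, c_tea_mg_kg, transfer) {
  if (any(rfd <= 0)) abort_validation("rfd must be > 0")
  if (any(c_tea_mg_kg <= 0) || any(transfer <= 0)) {
    abort_validation("c_tea_mg_kg and transfer must be > 0 to invert")
  }
  hq * rfd / (c_tea_mg_kg * transfer)
}

#' Full deterministic risk assessment
#'
#' Composes EDI -> HQ -> adjusted HQ -> HI and TR -> TR_total for every
#' consumption profile. Inputs may be summary-level (named vectors of mean
#' concentrations and mean transfer rates) or sample-level (`conc_dataset`s,
#' from which means are computed; censored values must be substituted
#' first). All arithmetic is full double precision; rounding happens only in
#' the report layer.
#'
#' @param concentrations Named numeric vector of made-tea means (mg/kg), or
#'   a `conc_dataset` with `made_tea` rows.
#' @param transfers Named numeric vector of transfer fractions, a tibble from
#'   [mean_transfer_rates()], or `NULL` to derive rates from `concentrations`
#'   when it is a paired dataset.
#' @param toxref Toxicological reference table; see [default_toxref()].
#' @param profiles Consumption profiles; see [default_profiles()].
#' @param tr_threshold Carcinogenic acceptability threshold.
#' @return Object of class `risk_assessment`: a list of tibbles
#'   `exposure` (profile, element, edi, hq, hq_ok, adjusted_hq),
#'   `hazard` (profile, hi, adjusted_hi),
#'   `cancer` (profile, element, tr, tr_adjusted, contribution) and
#'   `cancer_total` (profile, tr_total, exceeds_threshold). `tr_adjusted`
#'   is TR scaled by oral bioavailability, the package's interpretation of
#'   a bioavailability-aware cancer risk.
#' @export
#' @examples
#' a <- assess(c(Pb = 0.84), c(Pb = 0.315),
#'             profiles = data.frame(name = "male",
#'                                   ratio_g_per_kg_day = 2.25e-3))
#' a$exposure
assess <- function(concentrations, transfers = NULL,
                   toxref = default_toxref(), profiles = default_profiles(),
                   tr_threshold = 1e-4) {
  if (inherits(concentrations, "conc_dataset")) {
    if (is.null(transfers)) {
      transfers <- mean_transfer_rates(concentrations)
    }
    made <- concentrations[concentrations$matrix == "made_tea", ]
    if (any(is.na(made$value))) {
      abort_validation(
        "dataset contains unsubstituted censored values; run substitute_censored() first")
    }
    conc <- tapply(made$value, made$element, mean)
    concentrations <- setNames(as.numeric(conc), names(conc))
  }
  if (is.data.frame(transfers)) {
    transfers <- setNames(transfers$mean_t, transfers$element)
  }
  if (is.null(names(concentrations)) || is.null(names(transfers))) {
    abort_validation("concentrations and transfers must be named by element")
  }
  elements <- names(concentrations)
  missing_t <- setdiff(elements, names(transfers))
  if (length(missing_t) > 0) {
    abort_validation(sprintf("No transfer rate for element(s): %s",
                             paste(missing_t, collapse = ", ")))
  }
  missing_tox <- setdiff(elements, toxref$element)
  if (length(missing_tox) > 0) {
    abort_validation(sprintf("No toxicological reference for element(s): %s",
                             paste(missing_tox, collapse = ", ")))
  }
  profiles <- consumption_profiles(profiles)
  tox <- toxref[match(elements, toxref$element), ]

  empty <- function(...) tibble::tibble(...)
  exposure <- empty(profile = character(), element = character(),
                    edi = double(), hq = double(), hq_ok = logical(),
                    adjusted_hq = double())
  hazard <- empty(profile = character(), hi = double(),
                  adjusted_hi = double())
  cancer <- empty(profile = character(), element = character(),
                  tr = double(), tr_adjusted = double(),
                  contribution = double())
  cancer_total <- empty(profile = character(), tr_total = double(),
                        exceeds_threshold = logical())

  for (i in seq_len(nrow(profiles))) {
    p <- profiles[i, ]
    e <- edi(concentrations[elements], transfers[elements],
             ratio = p$ratio_g_per_kg_day)
    q <- hq(e, tox$rfd)
    aq <- adjusted_hq(q, tox$bioavailability)
    exposure <- dplyr::bind_rows(exposure, tibble::tibble(
      profile = p$name, element = elements, edi = unname(e),
      hq = unname(q), hq_ok = hq_acceptable(unname(q)),
      adjusted_hq = unname(aq)))
    hazard <- dplyr::bind_rows(hazard, tibble::tibble(
      profile = p$name, hi = hi(q), adjusted_hi = hi(aq)))
    carc <- which(!is.na(tox$sf))
    if (length(carc) > 0) {
      trs <- tr(e[carc], tox$sf[carc])
      tot <- tr_total(trs, threshold = tr_threshold)
      cancer <- dplyr::bind_rows(cancer, tibble::tibble(
        profile = p$name, element = elements[carc], tr = unname(trs),
        tr_adjusted = unname(trs * tox$bioavailability[carc]),
        contribution = unname(tot$contribution)))
      cancer_total <- dplyr::bind_rows(cancer_total, tibble::tibble(
        profile = p$name, tr_total = tot$total,
        exceeds_threshold = tot$exceeds))
    }
  }

  structure(
    list(exposure = exposure, hazard = hazard, cancer = cancer,
         cancer_total = cancer_total),
    class = "risk_assessment",
    elements = elements, tr_threshold = tr_threshold
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  cat(sprintf("<risk_assessment> %d profile(s) x %d element(s)\n",
              nrow(x$hazard), length(attr(x, "elements"))))
  if (nrow(x$hazard) > 0) {
    cat("Hazard index (dimensionless; < 1 acceptable):\n")
    print(x$hazard, n = Inf)
    if (nrow(x$cancer_total) > 0) {
      cat(sprintf("Total carcinogenic risk (threshold %g):\n",
                  attr(x, "tr_threshold")))
      print(x$cancer_total, n = Inf)
    }
  }
  invisible(x)
}
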