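# Synthetic data generation. Only summary statistics of the survey were
# published; these generators produce datasets with that summary structure
# (moment-matched truncated lognormal concentrations, logit-normal transfer
# rates, blank/spike QC batches) so every pipeline stage is testable.

#' Default per-element simulation specification
#'
#' One row per element: made-tea mean/SD/range (mg/kg) from the published
#' survey summaries, mean transfer rate from the published brewing results,
#' transfer SD defaulting to 0.3 x mean (no dispersion was published), and
#' the fraction of made-tea values emitted as censored (nonzero only for Cd,
#' whose published minimum was "below detection").
#'
#' @return Tibble with columns `element`, `mean_mg_kg`, `sd_mg_kg`,
#'   `min_mg_kg`, `max_mg_kg`, `transfer_mean`, `transfer_sd`, `nd_fraction`.
#' @export
default_sim_spec <- function() {
  conc <- reference_concentrations()
  tm <- reference_transfer_rates()
  spec <- tibble::tibble(
    element = conc$element,
    mean_mg_kg = conc$mean_mg_kg,
    sd_mg_kg = conc$sd_mg_kg,
    min_mg_kg = conc$min_mg_kg,
    max_mg_kg = conc$max_mg_kg,
    transfer_mean = unname(tm[conc$element]),
    transfer_sd = 0.3 * unname(tm[conc$element]),
    nd_fraction = ifelse(conc$element == "Cd", 0.05, 0)
  )
  validate_sim_spec(spec)
}

validate_sim_spec <- function(spec) {
  spec <- tibble::as_tibble(spec)
  required <- c("element", "mean_mg_kg", "sd_mg_kg", "min_mg_kg",
                "max_mg_kg", "transfer_mean", "transfer_sd", "nd_fraction")
  missing_cols <- setdiff(required, names(spec))
  if (length(missing_cols) > 0) {
    abort_format(sprintf("sim spec lacks column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  }
  bad <- spec$min_mg_kg > spec$mean_mg_kg | spec$mean_mg_kg > spec$max_mg_kg
  if (any(bad)) {
    abort_validation(sprintf(
      "Infeasible sim spec for %s: range excludes the mean",
      paste(spec$element[bad], collapse = ", ")))
  }
  if (any(spec$sd_mg_kg <= 0)) abort_validation("sim spec sd must be > 0")
  if (any(spec$transfer_mean <= 0 | spec$transfer_mean >= 1)) {
    abort_validation("transfer_mean must lie strictly in (0, 1)")
  }
  if (any(spec$transfer_sd < 0)) abort_validation("transfer_sd must be >= 0")
  if (any(spec$nd_fraction < 0 | spec$nd_fraction >= 1)) {
    abort_validation("nd_fraction must lie in [0, 1)")
  }
  spec
}

#' Read a simulation specification from YAML
#'
#' The YAML holds a list of per-element mappings with the columns of
#' [default_sim_spec()] as keys (`transfer_sd` and `nd_fraction` optional).
#'
#' @param path YAML file path.
#' @return Validated sim-spec tibble.
#' @export
read_sim_spec <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("File not found: %s", path))
  rows <- yaml::read_yaml(path)
  spec <- dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      element = r$element,
      mean_mg_kg = as.numeric(r$mean_mg_kg),
      sd_mg_kg = as.numeric(r$sd_mg_kg),
      min_mg_kg = as.numeric(r$min_mg_kg),
      max_mg_kg = as.numeric(r$max_mg_kg),
      transfer_mean = as.numeric(r$transfer_mean),
      transfer_sd = as.numeric(r$transfer_sd %||% (0.3 * r$transfer_mean)),
      nd_fraction = as.numeric(r$nd_fraction %||% 0)
    )
  }))
  validate_sim_spec(spec)
}

# --- distribution fitting --------------------------------------------------

# k-th moment of a lognormal(meanlog, sdlog) truncated to [a, b] (closed form)
trunc_lnorm_moment <- function(meanlog, sdlog, a, b, k = 1) {
  za <- if (a <= 0) -Inf else (log(a) - meanlog) / sdlog
  zb <- (log(b) - meanlog) / sdlog
  p <- pnorm(zb) - pnorm(za)
  if (!is.finite(p) || p < 1e-12) return(NA_real_)
  exp(k * meanlog + k^2 * sdlog^2 / 2) *
    (pnorm(zb - k * sdlog) - pnorm(za - k * sdlog)) / p
}

# Fit (meanlog, sdlog) so the TRUNCATED moments match (mean, sd) as closely
# as the family allows, with the mean weighted heavily so it is matched
# exactly whenever feasible. sdlog is kept inside [0.02, 2.5]: beyond that
# the truncated family degenerates to power laws and the tail-probability
# arithmetic loses all precision.
match_trunc_lnorm <- function(mean, sd, a, b, mean_weight = 200) {
  cv2 <- (sd / mean)^2
  sl0 <- min(max(sqrt(log(1 + cv2)), 0.05), 2)
  ml0 <- log(mean) - sl0^2 / 2
  clamp <- function(p) {
    c(min(max(p[1], log(b) - 12), log(b) + 6),
      min(max(p[2], log(0.02)), log(2.5)))
  }
  obj <- function(p) {
    p <- clamp(p)
    m1 <- trunc_lnorm_moment(p[1], exp(p[2]), a, b, 1)
    m2 <- trunc_lnorm_moment(p[1], exp(p[2]), a, b, 2)
    if (is.na(m1) || is.na(m2)) return(1e6)
    s <- sqrt(max(m2 - m1^2, 0))
    mean_weight * (m1 / mean - 1)^2 + (s / sd - 1)^2
  }
  fit <- stats::optim(c(ml0, log(sl0)), obj,
                      control = list(maxit = 4000, reltol = 1e-14))
  par <- clamp(fit$par)
  m1 <- trunc_lnorm_moment(par[1], exp(par[2]), a, b, 1)
  m2 <- trunc_lnorm_moment(par[1], exp(par[2]), a, b, 2)
  list(meanlog = par[1], sdlog = exp(par[2]),
       mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# inverse-CDF sampling from the truncated lognormal
rtrunc_lnorm <- function(n, meanlog, sdlog, a, b) {
  pa <- if (a <= 0) 0 else plnorm(a, meanlog, sdlog)
  pb <- plnorm(b, meanlog, sdlog)
  qlnorm(runif(n, pa, pb), meanlog, sdlog)
}

# k-th moment of plogis(N(mu, sigma)) by quadrature
logitnorm_moment <- function(mu, sigma, k = 1) {
  integrate(function(z) plogis(mu + sigma * z)^k * stats::dnorm(z),
            -Inf, Inf, rel.tol = 1e-10)$value
}

# Fit (mu, sigma) of a logit-normal to a target (mean, sd) on (0, 1)
match_logitnorm <- function(mean, sd, mean_weight = 200) {
  s0 <- max(sd / (mean * (1 - mean)), 1e-3)  # delta-method start
  obj <- function(p) {
    sig <- min(max(exp(p[2]), 1e-4), 8)
    m1 <- logitnorm_moment(p[1], sig, 1)
    m2 <- logitnorm_moment(p[1], sig, 2)
    s <- sqrt(max(m2 - m1^2, 0))
    mean_weight * (m1 / mean - 1)^2 + (s / sd - 1)^2
  }
  fit <- stats::optim(c(qlogis(mean), log(s0)), obj,
                      control = list(maxit = 4000, reltol = 1e-14))
  sig <- min(max(exp(fit$par[2]), 1e-4), 8)
  m1 <- logitnorm_moment(fit$par[1], sig, 1)
  m2 <- logitnorm_moment(fit$par[1], sig, 2)
  list(mu = fit$par[1], sigma = sig, mean = m1,
       sd = sqrt(max(m2 - m1^2, 0)))
}

# one master seed, deterministic per-element substreams
substream_seed <- function(seed, index, salt = 0L) {
  (as.integer(seed) %% 1000003L) * 2011L + index * 7919L + salt * 104729L
}

# --- generators ------------------------------------------------------------

#' Generate a made-tea concentration dataset
#'
#' Per element, draws `n` concentrations from a lognormal truncated to the
#' spec's range, with parameters fitted so the truncated mean (and, where
#' the family allows, the SD) matches the spec. For elements with a nonzero
#' `nd_fraction`, the corresponding lower quantile of the fitted distribution
#' acts as the reporting limit: draws below it are emitted censored
#' (value absent, flag set). Deterministic given `seed`.
#'
#' @param spec Sim spec tibble; see [default_sim_spec()].
#' @param n Samples per element, >= 1.
#' @param seed Master seed; per-element substreams are derived from it.
#' @param brewing Brewing spec attached to the dataset.
#' @return A `conc_dataset` with matrix `made_tea`, sample ids `S001..`.
#' @export
gen_made_tea <- function(spec = default_sim_spec(), n = 91, seed = 1,
                         brewing = default_brewing()) {
  spec <- validate_sim_spec(spec)
  if (n < 1) abort_validation("n must be >= 1")
  ids <- sprintf("S%03d", seq_len(n))
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    fit <- match_trunc_lnorm(s$mean_mg_kg, s$sd_mg_kg, s$min_mg_kg,
                             s$max_mg_kg)
    set.seed(substream_seed(seed, i, salt = 1L))
    x <- rtrunc_lnorm(n, fit$meanlog, fit$sdlog, s$min_mg_kg, s$max_mg_kg)
    censored <- rep(FALSE, n)
    if (s$nd_fraction > 0) {
      pa <- if (s$min_mg_kg <= 0) 0 else
        plnorm(s$min_mg_kg, fit$meanlog, fit$sdlog)
      pb <- plnorm(s$max_mg_kg, fit$meanlog, fit$sdlog)
      nd_limit <- qlnorm(pa + s$nd_fraction * (pb - pa), fit$meanlog,
                         fit$sdlog)
      censored <- x < nd_limit
      x[censored] <- NA_real_
    }
    tibble::tibble(sample_id = ids, element = s$element,
                   matrix = "made_tea", value = x, censored = censored)
  })
  out <- concentration_dataset(dplyr::bind_rows(rows), brewing = brewing,
                               elements = unique(spec$element))
  attr(out, "seed") <- seed
  out
}

#' Generate infusion concentrations from a made-tea dataset
#'
#' Per sample, draws a transfer rate from a logit-normal fitted to the
#' spec's (mean, SD) -- guaranteeing T strictly inside (0, 1) -- and converts
#' it to an infusion concentration with [infusion_concentration()]. A
#' transfer SD of (numerically) zero degenerates to the constant mean rate.
#' Censored made-tea values must be substituted first.
#'
#' @param made_tea A `conc_dataset` of made-tea measurements, all values
#'   present.
#' @param spec Sim spec tibble.
#' @param brewing Brewing spec; defaults to the one attached to `made_tea`.
#' @param seed Master seed.
#' @return A `conc_dataset` with matrix `infusion` (ug/L), same sample ids.
#' @export
gen_infusions <- function(made_tea, spec = default_sim_spec(),
                          brewing = NULL, seed = 1) {
  spec <- validate_sim_spec(spec)
  brewing <- brewing %||% attr(made_tea, "brewing") %||% default_brewing()
  if (any(is.na(made_tea$value))) {
    abort_validation(
      "made_tea contains unsubstituted censored values; run substitute_censored() first")
  }
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    s <- spec[i, ]
    m <- made_tea[made_tea$element == s$element &
                    made_tea$matrix == "made_tea", ]
    if (nrow(m) == 0) return(NULL)
    if (s$transfer_sd < 1e-12) {
      t_i <- rep(s$transfer_mean, nrow(m))
    } else {
      fit <- match_logitnorm(s$transfer_mean, s$transfer_sd)
      set.seed(substream_seed(seed, i, salt = 2L))
      t_i <- plogis(rnorm(nrow(m), fit$mu, fit$sigma))
    }
    tibble::tibble(
      sample_id = m$sample_id, element = s$element, matrix = "infusion",
      value = infusion_concentration(m$value, t_i, brewing),
      censored = FALSE)
  })
  out <- concentration_dataset(dplyr::bind_rows(rows), brewing = brewing,
                               elements = unique(spec$element))
  attr(out, "seed") <- seed
  out
}

#' Generate a QC batch of blanks and spikes
#'
#' Ten reagent blanks per element, drawn and then affinely standardised so
#' the sample SD equals exactly LOD/3 (so [detection_limits()] reproduces
#' the reference LOD/LOQ) with the blank mean at 3 x SD (standardised
#' deviates of n = 10 are bounded by 3, keeping all blanks nonnegative).
#' Spiked samples at 10/50/100 ug/L with recoveries drawn near the reference
#' values. Deterministic given `seed`.
#'
#' @param qc_ref Reference table; see [default_qc_reference()].
#' @param seed Master seed.
#' @param n_blanks Blanks per element.
#' @param spike_levels Nominal spike concentrations, ug/L.
#' @param recovery_noise_sd SD (percentage points) of the recovery draw.
#' @return List with `blanks` (a `conc_dataset`, matrix `blank`) and
#'   `spikes` (tibble: `element`, `spike_level`, `base`, `measured`).
#' @export
gen_qc_batch <- function(qc_ref = default_qc_reference(), seed = 1,
                         n_blanks = 10, spike_levels = c(10, 50, 100),
                         recovery_noise_sd = 1.5) {
  blanks <- lapply(seq_len(nrow(qc_ref)), function(i) {
    s_target <- qc_ref$lod_ug_l[i] / 3
    set.seed(substream_seed(seed, i, salt = 3L))
    z <- rnorm(n_blanks)
    z <- (z - mean(z)) / stats::sd(z)      # exact sample mean 0, SD 1
    v <- 3 * s_target + s_target * z       # sample SD exactly lod/3
    tibble::tibble(sample_id = sprintf("blank_%02d", seq_len(n_blanks)),
                   element = qc_ref$element[i], matrix = "blank",
                   value = pmax(v, 0), censored = FALSE)
  })
  blanks <- concentration_dataset(dplyr::bind_rows(blanks),
                                  elements = unique(qc_ref$element))
  rec_cols <- c(`10` = "recovery_10", `50` = "recovery_50",
                `100` = "recovery_100")
  spikes <- lapply(seq_len(nrow(qc_ref)), function(i) {
    set.seed(substream_seed(seed, i, salt = 4L))
    lev <- spike_levels
    rec_ref <- vapply(as.character(lev), function(l) {
      col <- rec_cols[l]
      if (is.na(col)) 100 else qc_ref[[col]][i]
    }, numeric(1))
    rec <- rnorm(length(lev), rec_ref, recovery_noise_sd)
    tibble::tibble(element = qc_ref$element[i], spike_level = lev,
                   base = 0, measured = lev * rec / 100)
  })
  list(blanks = blanks, spikes = dplyr::bind_rows(spikes))
}

#' Default consumption profiles for six subpopulations
#'
#' The survey assessed males/females, urban/rural residents and two age
#' bands, but never published their daily tea mass or body weight. The
#' ratios here are back-derived: for each subpopulation,
#' [invert_consumption_ratio()] is applied to its published Cu hazard
#' quotient together with the published Cu mean concentration and mean
#' transfer rate. (Back-solving from any of the five elements agrees within
#' a few percent; Cu anchors the convention.)
#'
#' @return Profile tibble with columns `name`, `ratio_g_per_kg_day`.
#' @export
#' @examples
#' default_profiles()
default_profiles <- function() {
  ref <- reference_hq()
  cu <- ref[ref$element == "Cu", ]
  conc <- reference_concentrations()
  cu_mean <- conc$mean_mg_kg[conc$element == "Cu"]
  cu_t <- reference_transfer_rates()[["Cu"]]
  cu_rfd <- default_toxref()$rfd[default_toxref()$element == "Cu"]
  consumption_profiles(tibble::tibble(
    name = cu$profile,
    ratio_g_per_kg_day = invert_consumption_ratio(
      cu$hq_pct / 100, cu_rfd, cu_mean, cu_t)
  ))
}
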