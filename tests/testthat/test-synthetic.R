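test_that("generators are deterministic in the master seed", {
  a <- gen_made_tea(seed = 17, n = 20)
  b <- gen_made_tea(seed = 17, n = 20)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a),
                         as.data.frame(gen_made_tea(seed = 18, n = 20))))

  lims <- made_tea_nd_limits()
  inf_a <- gen_infusions(substitute_censored(a, lims), seed = 17)
  inf_b <- gen_infusions(substitute_censored(b, lims), seed = 17)
  expect_identical(as.data.frame(inf_a), as.data.frame(inf_b))

  qa <- gen_qc_batch(seed = 9)
  qb <- gen_qc_batch(seed = 9)
  expect_identical(as.data.frame(qa$blanks), as.data.frame(qb$blanks))
  expect_identical(qa$spikes, qb$spikes)
})

test_that("generated concentrations respect the spec ranges and censoring", {
  spec <- default_sim_spec()
  one <- gen_made_tea(spec, n = 1, seed = 3)
  expect_equal(nrow(one), nrow(spec))
  ds <- gen_made_tea(spec, n = 200, seed = 3)
  for (i in seq_len(nrow(spec))) {
    v <- ds$value[ds$element == spec$element[i] & !ds$censored]
    expect_true(all(v >= spec$min_mg_kg[i] & v <= spec$max_mg_kg[i]))
  }
  # only Cd is censored under the default spec, at about nd_fraction
  expect_equal(unique(ds$element[ds$censored]), "Cd")
  frac <- mean(ds$censored[ds$element == "Cd"])
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 200))

  bad <- spec; bad$mean_mg_kg[1] <- bad$max_mg_kg[1] + 1
  expect_error(gen_made_tea(bad), class = "brewrisk_validation_error")
})

test_that("generated transfer rates stay strictly inside (0, 1)", {
  spec <- default_sim_spec()
  made <- substitute_censored(gen_made_tea(spec, n = 200, seed = 8),
                              made_tea_nd_limits(spec))
  inf <- gen_infusions(made, spec, seed = 8)
  for (el in spec$element) {
    ci <- inf$value[inf$element == el]
    ct <- made$value[made$element == el]
    tt <- transfer_rate(ci, ct)
    expect_true(all(tt > 0 & tt < 1))
  }
  # degenerate transfer SD: every implied rate equals the configured mean
  spec0 <- spec; spec0$transfer_sd <- 0
  inf0 <- gen_infusions(made, spec0, seed = 8)
  t_cu <- transfer_rate(inf0$value[inf0$element == "Cu"],
                        made$value[made$element == "Cu"])
  expect_equal(t_cu, rep(spec$transfer_mean[spec$element == "Cu"], 200))

  cens <- concentration_dataset(tibble::tibble(
    sample_id = "s1", element = "Cd", matrix = "made_tea",
    value = NA_real_, censored = TRUE))
  expect_error(gen_infusions(cens, spec),
               class = "brewrisk_validation_error")  # unsubstituted
})

test_that("a survey-sized batch recovers the published summary means", {
  spec <- default_sim_spec()
  made <- substitute_censored(gen_made_tea(spec, n = 91, seed = 1),
                              made_tea_nd_limits(spec))
  inf <- gen_infusions(made, spec, seed = 1)
  ds <- concentration_dataset(rbind(as.data.frame(made),
                                    as.data.frame(inf)))
  mt <- suppressMessages(mean_transfer_rates(ds))
  for (i in seq_len(nrow(spec))) {
    el <- spec$element[i]
    se_c <- spec$sd_mg_kg[i] / sqrt(91)
    expect_lt(abs(mean(made$value[made$element == el]) -
                    spec$mean_mg_kg[i]), 3 * se_c)
    se_t <- spec$transfer_sd[i] / sqrt(91)
    expect_lt(abs(mt$mean_t[mt$element == el] - spec$transfer_mean[i]),
              3 * se_t)
  }
})

test_that("samplers reproduce their analytic truncated moments at scale", {
  spec <- default_sim_spec()
  n <- 2e5
  for (i in seq_len(nrow(spec))) {
    s <- spec[i, ]
    fit <- brewrisk:::match_trunc_lnorm(s$mean_mg_kg, s$sd_mg_kg,
                                        s$min_mg_kg, s$max_mg_kg)
    set.seed(2024)
    x <- brewrisk:::rtrunc_lnorm(n, fit$meanlog, fit$sdlog,
                                 s$min_mg_kg, s$max_mg_kg)
    expect_lt(abs(mean(x) / fit$mean - 1), 0.01)
    expect_lt(abs(sd(x) / fit$sd - 1), 0.01)
    # the fit matches the requested mean for every element
    expect_lt(abs(fit$mean / s$mean_mg_kg - 1), 1e-3)

    tfit <- brewrisk:::match_logitnorm(s$transfer_mean, s$transfer_sd)
    set.seed(2024)
    tt <- plogis(rnorm(n, tfit$mu, tfit$sigma))
    expect_lt(abs(mean(tt) / s$transfer_mean - 1), 0.01)
    expect_lt(abs(sd(tt) / s$transfer_sd - 1), 0.01)
  }
})

test_that("QC batches reproduce the reference detection limits exactly", {
  batch <- gen_qc_batch(seed = 2)
  dl <- detection_limits(batch$blanks)
  ref <- default_qc_reference()
  expect_equal(dl$lod[dl$element == "Cu"], 0.09)
  expect_equal(dl$loq[dl$element == "Cu"], 0.3)
  expect_equal(dl$lod[dl$element == "Pb"], 0.01)
  expect_equal(setNames(dl$lod, dl$element)[ref$element],
               setNames(ref$lod_ug_l, ref$element))
  expect_true(all(batch$blanks$value >= 0))
  # recoveries land near the reference values
  rec <- spike_recovery(batch$spikes$measured, batch$spikes$spike_level)
  ref_rec <- c(t(as.matrix(ref[, c("recovery_10", "recovery_50",
                                   "recovery_100")])))
  expect_lt(max(abs(rec - ref_rec)), 6)  # 4 sigma of the 1.5-point noise
})

test_that("default profiles are the back-derived survey ratios", {
  p <- default_profiles()
  expect_equal(nrow(p), 6)
  expect_setequal(p$name, c("male", "female", "urban", "rural",
                            "age_18_40", "age_ge_41"))
  r <- setNames(p$ratio_g_per_kg_day, p$name)
  expect_lt(r[["female"]], r[["male"]])  # males consume more per kg
  expect_gt(r[["age_ge_41"]], r[["age_18_40"]])
  expect_equal(unname(r[["male"]]),
               invert_consumption_ratio(4.7e-5, 40, 8.18, 0.102))
})

test_that("sim specs round trip through YAML with defaults filled in", {
  path <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(list(element = "Cu", mean_mg_kg = 8, sd_mg_kg = 2,
                             min_mg_kg = 3, max_mg_kg = 12,
                             transfer_mean = 0.1)), path)
  spec <- read_sim_spec(path)
  expect_equal(spec$transfer_sd, 0.03)
  expect_equal(spec$nd_fraction, 0)
  expect_error(brewrisk:::validate_sim_spec(transform(spec,
                                                      transfer_mean = 1.2)),
               class = "brewrisk_validation_error")
})
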