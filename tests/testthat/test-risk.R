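ref_conc <- setNames(reference_concentrations()$mean_mg_kg,
                     reference_concentrations()$element)
ref_t <- reference_transfer_rates()
tox <- default_toxref()

test_that("EDI follows the intake chain and its algebraic identities", {
  expect_equal(edi(8.18, 0.102, ratio = 0), 0)
  expect_equal(edi(8.18, 0.102, daily_tea_mass_g = 0, body_weight_kg = 60), 0)
  # ratio and (D, Bw) representations agree
  expect_equal(edi(0.84, 0.315, ratio = 9 / 55),
               edi(0.84, 0.315, daily_tea_mass_g = 9, body_weight_kg = 55))
  # constructed boundary: C_t = RfD * Bw / (T * D) gives EDI = RfD exactly
  rfd <- 3.57; bw <- 62; d <- 8.5; tt <- 0.315
  expect_equal(edi(rfd * bw / (tt * d), tt, daily_tea_mass_g = d,
                   body_weight_kg = bw), rfd)
  # Pb intake for the male profile ratio back-solved from the published Cu HQ
  r_male <- invert_consumption_ratio(4.7e-5, 40, 8.18, 0.102)
  expect_equal(edi(0.84, 0.315, ratio = r_male), 5.962e-4, tolerance = 1e-3)
  expect_error(edi(-1, 0.5, ratio = 1), class = "brewrisk_validation_error")
})

test_that("HQ, adjusted HQ and the acceptability flag behave", {
  expect_equal(hq(3.57, 3.57), 1)
  expect_false(hq_acceptable(hq(3.57, 3.57)))  # borderline is not acceptable
  expect_equal(hq(0, 5), 0)
  expect_error(hq(1, 0), class = "brewrisk_validation_error")

  expect_equal(adjusted_hq(1.6e-4, 0.01), 1.6e-6)  # published Cr male cell
  expect_equal(adjusted_hq(0.42, 1), 0.42)
  expect_equal(adjusted_hq(1.7e-4, 0.6), 1.02e-4)  # published Pb male cell
  expect_error(adjusted_hq(1, 0), class = "brewrisk_validation_error")
  expect_error(adjusted_hq(1, 1.2), class = "brewrisk_validation_error")
})

test_that("HI is the plain sum of hazard quotients", {
  expect_equal(hi(0.3), 0.3)
  # published male and female HQ columns sum to the published HI row
  expect_equal(hi(c(4.7, 17, 16, 4.9, 15) * 1e-5), 5.76e-4)
  expect_equal(hi(c(3.1, 11, 11, 3.2, 10) * 1e-5), 3.83e-4)
  expect_2sf(hi(c(4.7, 17, 16, 4.9, 15) * 1e-5) * 100, 5.8e-2)
  expect_2sf(hi(c(3.1, 11, 11, 3.2, 10) * 1e-5) * 100, 3.8e-2)
  expect_error(hi(numeric(0)), class = "brewrisk_validation_error")
})

test_that("TR converts micrograms to milligrams before the slope factor", {
  expect_equal(tr(0, 0.5), 0)
  expect_equal(tr(1000, 1), 1)  # 1000 ug = 1 mg: unit-conversion pivot
  # dimension bookkeeping: sf = 1000/rfd makes TR collapse onto HQ
  for (rfd in c(1, 3.57, 40)) {
    e <- 0.37
    expect_equal(tr(e, 1000 / rfd), hq(e, rfd))
  }
  # Cr for females: the published minimum TR
  r_female <- invert_consumption_ratio(3.1e-5, 40, 8.18, 0.102)
  tr_cr_f <- tr(edi(0.51, 0.423, ratio = r_female), 0.5)
  expect_equal(tr_cr_f, 1.603e-7, tolerance = 1e-3)
  expect_equal(tr_cr_f, 1.62e-7, tolerance = 0.02)  # printed, 2-sf inputs
  expect_error(tr(1, NA), class = "brewrisk_validation_error")
})

test_that("total carcinogenic risk sums and apportions", {
  one <- tr_total(0.5e-7)
  expect_equal(one$contribution, 1)
  expect_false(one$exceeds)

  # hand sum of the male Pb/Cd/Cr TRs implied by the published HQs
  trs <- c(Pb = 5.2e-9, Cd = 3.1e-7, Cr = 2.4e-7)
  tot <- tr_total(trs)
  expect_equal(tot$total, 5.552e-7)
  expect_false(tot$exceeds)
  expect_equal(sum(tot$contribution), 1)

  # homogeneity: scaling the TRs scales the total, not the contributions
  tot10 <- tr_total(10 * trs)
  expect_equal(tot10$total, 10 * tot$total)
  expect_equal(tot10$contribution, tot$contribution)
  expect_true(tr_total(c(9e-5, 2e-5))$exceeds)
  expect_error(tr_total(numeric(0)), class = "brewrisk_validation_error")
})

test_that("consumption-ratio inversion reconstructs the survey ratios", {
  expect_equal(invert_consumption_ratio(4.7e-5, 40, 8.18, 0.102),
               2.2533e-3, tolerance = 1e-4)
  expect_equal(invert_consumption_ratio(3.1e-5, 40, 8.18, 0.102),
               1.4862e-3, tolerance = 1e-4)
  expect_equal(invert_consumption_ratio(0, 40, 8.18, 0.102), 0)
  expect_error(invert_consumption_ratio(1, 1, 0, 0.5),
               class = "brewrisk_validation_error")
})

test_that("back-solving the ratio from any element of a column agrees", {
  ref <- reference_hq()
  for (col in c("male", "female")) {
    cells <- ref[ref$profile == col, ]
    rfd <- tox$rfd[match(cells$element, tox$element)]
    rs <- invert_consumption_ratio(cells$hq_pct / 100, rfd,
                                   ref_conc[cells$element],
                                   ref_t[cells$element])
    expect_lt(sd(rs) / mean(rs), 0.03)  # CV below 3 %
  }
})

test_that("assess composes the full chain deterministically", {
  profs <- default_profiles()
  a <- assess(ref_conc, ref_t, profiles = profs)
  expect_s3_class(a, "risk_assessment")
  expect_equal(nrow(a$exposure), 30)
  expect_equal(nrow(a$cancer), 18)  # Pb, Cr, Cd per profile

  # adjusted HI never exceeds HI; equality only at bioavailability 1
  expect_true(all(a$hazard$adjusted_hi <= a$hazard$hi))
  tox1 <- tox; tox1$bioavailability <- 1
  a1 <- assess(ref_conc, ref_t, toxref = tox1, profiles = profs)
  expect_equal(a1$hazard$adjusted_hi, a1$hazard$hi)

  # linearity: doubling every consumption ratio doubles EDI, HQ, HI, TR
  profs2 <- profs; profs2$ratio_g_per_kg_day <- 2 * profs2$ratio_g_per_kg_day
  a2 <- assess(ref_conc, ref_t, profiles = profs2)
  expect_equal(a2$exposure$edi, 2 * a$exposure$edi)
  expect_equal(a2$hazard$hi, 2 * a$hazard$hi)
  expect_equal(a2$cancer_total$tr_total, 2 * a$cancer_total$tr_total)
  # and doubling concentrations does the same
  a3 <- assess(2 * ref_conc, ref_t, profiles = profs)
  expect_equal(a3$hazard$hi, 2 * a$hazard$hi)

  # contributions sum to one per profile
  by_prof <- tapply(a$cancer$contribution, a$cancer$profile, sum)
  expect_equal(unname(as.numeric(by_prof)), rep(1, 6))

  # empty profile list: empty outputs, no error
  a0 <- assess(ref_conc, ref_t,
               profiles = data.frame(name = character(),
                                     ratio_g_per_kg_day = double()))
  expect_equal(nrow(a0$exposure), 0)
  expect_equal(nrow(a0$hazard), 0)

  expect_error(assess(c(Zn = 1), c(Zn = 0.5)),
               class = "brewrisk_validation_error")
  expect_error(assess(ref_conc, ref_t[1:3]),
               class = "brewrisk_validation_error")
})

test_that("assess accepts sample-level datasets and matches the summary path", {
  ds <- toy_paired_dataset()
  a_ds <- assess(ds, profiles = data.frame(name = "p",
                                           ratio_g_per_kg_day = 2e-3))
  conc <- c(Cu = 9, Pb = 0.9)
  mt <- mean_transfer_rates(ds)
  a_sum <- assess(conc, mt, profiles = data.frame(name = "p",
                                                  ratio_g_per_kg_day = 2e-3))
  expect_equal(a_ds$exposure$edi, a_sum$exposure$edi)
  expect_equal(a_ds$hazard$hi, a_sum$hazard$hi)
})
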