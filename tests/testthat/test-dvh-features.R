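test_that("dvh_curve validates its invariants", {
  expect_s3_class(dvh_curve("P1", "esophagus", c(0, 10, 20), c(1, 0.5, 0)),
                  "dvh_curve")
  expect_error(dvh_curve("P1", "s", c(1, 10), c(1, 0)), "start at 0")
  expect_error(dvh_curve("P1", "s", c(0, 10, 5), c(1, 0.5, 0)),
               "strictly increasing")
  expect_error(dvh_curve("P1", "s", c(0, 10), c(1, 1.2)), "\\[0, 1\\]")
  expect_error(dvh_curve("P1", "s", c(0, 10, 20), c(1, 0.2, 0.5)),
               "non-increasing")
  expect_error(dvh_curve("P1", "s", c(0, 10), c(0.9, 0.5)), "must be 1")
})

test_that("EQD2 transform matches the linear-quadratic formula", {
  # 2 Gy/fraction is a fixed point for any alpha/beta
  cv <- dvh_curve("P1", "esophagus", c(0, 25, 50), c(1, 0.5, 0))
  for (ab in c(3, 10)) {
    eq <- eqd2_transform(cv, ab, fraction_number = 25)
    expect_equal(eq$dose_bins[3], 50)  # d = 2 Gy exactly
    expect_equal(eq$dose_bins[1], 0)
    expect_identical(eq$volume_fractions, cv$volume_fractions)
    expect_identical(eq$dose_kind, "EQD2")
  }
  # hand-evaluated: 50 Gy in 5 fx, alpha/beta 3: 50*(10+3)/(2+3) = 130
  eq5 <- eqd2_transform(cv, 3, fraction_number = 5)
  expect_equal(eq5$dose_bins[3], 130)
  # state and parameter errors
  expect_error(eqd2_transform(eq5, 3, 5), "already EQD2")
  expect_error(eqd2_transform(cv, 3, 0), "fraction_number")
  expect_error(eqd2_transform(cv, -1, 5), "alpha_beta")
})

test_that("EQD2 transform preserves Dx ranking across patients", {
  set.seed(11)
  curves <- lapply(1:25, function(i) random_dvh(paste0("P", i)))
  d30_phys <- vapply(curves, dose_at_volume, numeric(1), x = 30)
  d30_eq <- vapply(curves, function(cv)
    dose_at_volume(eqd2_transform(cv, 10, 30), 30), numeric(1))
  expect_identical(order(d30_phys), order(d30_eq))
})

test_that("dose_at_volume inverts the cumulative curve", {
  # uniform dose: whole structure at 10 Gy
  uni <- dvh_curve("P1", "s", c(0, 5, 10), c(1, 1, 1))
  for (x in c(5, 20, 50, 100)) expect_equal(dose_at_volume(uni, x), 10)
  # linear curve V(D) = 1 - D/20 on [0, 20]
  lin <- dvh_curve("P1", "s", c(0, 20), c(1, 0))
  expect_equal(dose_at_volume(lin, 50), 10)
  expect_equal(dose_at_volume(lin, 5), 19)
  expect_error(dose_at_volume(lin, 0), "\\(0, 100\\]")
  expect_error(dose_at_volume(lin, 101), "\\(0, 100\\]")
  # plateau below 1 resolves to its lowest dose
  plat <- dvh_curve("P1", "s", c(0, 5, 10, 15), c(1, 0.4, 0.4, 0))
  expect_equal(dose_at_volume(plat, 40), 5)
  # D100 is the minimum structure dose (end of the V = 1 plateau)
  shelf <- dvh_curve("P1", "s", c(0, 8, 16), c(1, 1, 0))
  expect_equal(dose_at_volume(shelf, 100), 8)
})

test_that("Dx is non-increasing in x and matches a brute-force scan", {
  set.seed(21)
  xs <- seq(5, 100, by = 5)
  for (i in 1:200) {
    cv <- random_dvh()
    dx <- dose_at_volume(cv, xs)
    expect_true(all(diff(dx) <= 1e-9))
    for (x in c(10, 50, 90))
      expect_lt(abs(dose_at_volume(cv, x) - brute_force_dx(cv, x)), 0.011)
  }
})

test_that("mean dose equals the differential-DVH weighted mean", {
  lin <- dvh_curve("P1", "s", c(0, 20), c(1, 0))
  expect_equal(mean_dose(lin), 10)
  set.seed(31)
  for (i in 1:50) {
    cv <- random_dvh()
    cv$volume_fractions[length(cv$volume_fractions)] <- 0
    d <- cv$dose_bins; v <- cv$volume_fractions; n <- length(d)
    mass <- v[-n] - v[-1]
    diff_mean <- sum(mass * (d[-n] + d[-1]) / 2)
    expect_equal(mean_dose(cv), diff_mean, tolerance = 1e-6)
  }
})

test_that("fractional metrics divide by treatment days", {
  m <- c(D40 = 40, D80 = 12, mean = 20, max = 60)
  expect_equal(unname(fractional_metrics(m, 1)), unname(m))
  expect_equal(fractional_metrics(m, 40)[["fD40"]], 1)
  expect_equal(unname(fractional_metrics(m, 20)),
               unname(2 * fractional_metrics(m, 40)))
  expect_named(fractional_metrics(m, 2), c("fD40", "fD80", "fmean", "fmax"))
  expect_error(fractional_metrics(m, 0), "treatment_days")
})

test_that("summarize_structure assembles the full metric set", {
  # uniform 10 Gy at 2 Gy/fraction: EQD2 identity, mean = max = Dx = 10
  uni <- dvh_curve("P1", "esophagus", c(0, 5, 10), c(1, 1, 1))
  sm <- summarize_structure(uni, alpha_beta = 10, fraction_number = 5,
                            treatment_days = 10)
  expect_equal(unname(sm$Dx), rep(10, 20), tolerance = 1e-9)
  expect_equal(sm$mean_dose, 10, tolerance = 1e-3)
  expect_equal(sm$max_dose, 10, tolerance = 1e-9)
  # fDx from the physical curve: 10 Gy / 10 days = 1 Gy/day
  expect_equal(unname(sm$fDx["fD50"]), 1, tolerance = 1e-9)
  # linear curve V = 1 - D/20, 10 fx, alpha/beta 3: EQD2 warps each bin to
  # E(D) = D(D/10 + 3)/5, so the mean is
  # int_0^20 (1 - D/20) E'(D) dD = 26/3 (analytic)
  lin <- dvh_curve("P1", "heart", c(0, 20), c(1, 0))
  sm2 <- summarize_structure(lin, alpha_beta = 3, fraction_number = 10,
                             fractional = FALSE)
  expect_equal(sm2$mean_dose, 26 / 3, tolerance = 5e-3)
  expect_null(sm2$fDx)
  # Dx non-increasing over the grid
  expect_true(all(diff(sm2$Dx) <= 1e-9))
})
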