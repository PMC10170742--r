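test_that("age inversion recovers the curve age and clamps ghost roots", {
  fit <- paper_fit()
  # inverting the unrounded critical area lands exactly on the boundary age
  sch <- derive_scheme(fit)
  est <- estimate_age(data.frame(wound_area = sch$crit_area,
                                 wound_perimeter = sch$crit_perimeter), fit)
  expect_equal(est$age_from_area, 12, tolerance = 1e-9)
  expect_equal(est$age_from_perimeter, 24, tolerance = 1e-9)
  # the rounded report value 0.016 inverts a touch above 12 d
  est2 <- estimate_age(data.frame(wound_area = 0.016,
                                  wound_perimeter = 0.5), fit)
  expect_equal(est2$age_from_area, ((0.311 - sqrt(0.016)) / 0.053)^2,
               tolerance = 1e-12)
  expect_equal(round(est2$age_from_area, 2), 12.12)
  # intercept perimeter is age 0
  est3 <- estimate_age(data.frame(wound_area = 0.05, wound_perimeter = 1.299),
                       fit)
  expect_equal(est3$age_from_perimeter, 0, tolerance = 1e-12)
  # a wound larger than the age-0 intercept clamps to 0, not a ghost age
  est4 <- estimate_age(data.frame(wound_area = 0.12, wound_perimeter = 1.4),
                       fit)
  expect_identical(est4$age_from_area, 0)
  expect_identical(est4$age_from_perimeter, 0)
})

test_that("closed and half-closed wounds give censored estimates", {
  est <- estimate_age(data.frame(wound_area = 0, wound_perimeter = 0),
                      paper_fit())
  expect_true(est$censored)
  expect_true(is.na(est$age_from_area))
  expect_true(is.na(est$age_from_perimeter))
  expect_true(is.na(est$age_combined))
  # zero area with a still-open perimeter only bounds age from below
  half <- estimate_age(data.frame(wound_area = 0, wound_perimeter = 0.02),
                       paper_fit())
  expect_true(half$censored)
  expect_true(is.na(half$age_combined))
})

test_that("estimated age is monotone non-increasing in wound size", {
  fit <- paper_fit()
  areas <- seq(1e-6, 0.15, length.out = 80)
  est_a <- estimate_age(data.frame(wound_area = areas,
                                   wound_perimeter = 0.5), fit)
  expect_true(all(diff(est_a$age_from_area) <= 1e-12))
  perims <- seq(1e-6, 1.6, length.out = 80)
  est_p <- estimate_age(data.frame(wound_area = 0.05,
                                   wound_perimeter = perims), fit)
  expect_true(all(diff(est_p$age_from_perimeter) <= 1e-12))
})

test_that("pTAL is the difference of combined age estimates", {
  fit <- paper_fit()
  h <- make_events("V1", c(5, 15))
  res <- predict_tal(h, fit)
  expect_equal(res$status, "ok")
  expect_equal(res$record$ptal, 10, tolerance = 1e-9)
  expect_equal(res$record$tal, 10)

  # the same event twice gives a zero pTAL
  same <- make_events("V2", c(7, 7))
  same$date <- same$date[1]  # predict_tal itself does not re-sort
  expect_equal(predict_tal(same, fit)$record$ptal, 0, tolerance = 1e-12)

  # swapping the two events negates tal and ptal alike
  swapped <- h[2:1, ]
  r2 <- predict_tal(swapped, fit)
  expect_equal(r2$record$tal, -res$record$tal)
  expect_equal(r2$record$ptal, -res$record$ptal, tolerance = 1e-9)
  expect_equal(r2$record$abs_diff, res$record$abs_diff, tolerance = 1e-9)
})

test_that("training and closed-wound sharks are excluded with reasons", {
  fit <- paper_fit()
  h <- make_events("T1", c(0, 14), cord_remnants = c(TRUE, FALSE))
  res <- predict_tal(h, fit, training_ids = "T1")
  expect_equal(res$status, "excluded")
  expect_match(res$reason, "construct the regression")

  closed <- make_events("C1", c(10, 40))
  res2 <- predict_tal(closed, fit)
  expect_equal(res2$status, "excluded")
  expect_match(res2$reason, "closed umbilicus")

  expect_error(predict_tal(make_events("X", 5), fit), ">= 2 events")
})

test_that("validate_cohort splits records and exclusions", {
  fit <- paper_fit()
  ev <- rbind(
    make_events("A", c(5, 15)),
    make_events("B", c(10, 40)),            # closed at recapture
    make_events("T", c(0, 12), cord_remnants = c(TRUE, FALSE)),
    make_events("S", 8)                     # never recaptured
  )
  val <- validate_cohort(build_histories(ev), fit, training_ids = "T")
  expect_equal(val$records$shark_id, "A")
  expect_setequal(val$exclusions$shark_id, c("B", "T"))
})

test_that("on noise-free cohorts pTAL equals TAL", {
  coh <- generate_cohort(noise_free_config(n_sharks = 200, n_training = 30,
                                           seed = 37))
  h <- build_histories(coh$events)
  pairs <- assemble_training_pairs(h)
  fit <- fit_wound_models(pairs)
  val <- validate_cohort(h, fit, training_ids = attr(pairs, "anchor_ids"))
  expect_gt(nrow(val$records), 0)
  expect_equal(val$records$ptal, as.numeric(val$records$tal),
               tolerance = 1e-9)
})

test_that("validation summary reproduces the published 5 +/- 3 days", {
  tb <- validation_reference()
  s <- summarize_validation(tb)
  expect_equal(s$mean_abs_diff, mean(tb$abs_diff), tolerance = 1e-12)
  expect_equal(round(s$mean_abs_diff, 2), 4.88)
  expect_equal(round(s$sd_abs_diff, 2), 3.08)
  expect_identical(s$mean_days, 5)
  expect_identical(s$sd_days, 3)
  expect_identical(s$n, 17L)

  expect_equal(summarize_validation(rep(0, 5))$sd_abs_diff, 0)
  expect_error(summarize_validation(3), "at least 2")
})
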