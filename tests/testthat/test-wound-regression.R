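test_that("training pairs use days-old anchors and elapsed-day ages", {
  # 16 anchored sharks: 13 recaptured once, 3 twice -> 35 observations
  ages_once <- lapply(1:13, function(i) c(0, 7 + i))
  ages_twice <- lapply(1:3, function(i) c(0, 10 + i, 20 + i))
  ev <- do.call(rbind, c(
    lapply(seq_along(ages_once), function(i)
      make_events(sprintf("T%02d", i), ages_once[[i]],
                  cord_remnants = c(TRUE, FALSE))),
    lapply(seq_along(ages_twice), function(i)
      make_events(sprintf("W%02d", i), ages_twice[[i]],
                  cord_remnants = c(TRUE, FALSE, FALSE)))
  ))
  pairs <- assemble_training_pairs(build_histories(ev))
  expect_equal(nrow(pairs), 35)
  expect_equal(length(attr(pairs, "anchor_ids")), 16)
  expect_true(all(pairs$age[!duplicated(pairs$shark_id)] == 0))
  # ages are elapsed days from the anchor
  expect_setequal(pairs$age[pairs$shark_id == "T01"], c(0, 8))
})

test_that("non-anchored and never-recaptured histories contribute nothing", {
  ev <- rbind(
    make_events("noanchor", c(5, 15), cord_remnants = c(FALSE, FALSE)),
    make_events("single", 0, cord_remnants = TRUE)
  )
  pairs <- assemble_training_pairs(build_histories(ev))
  expect_equal(nrow(pairs), 0)
})

test_that("a late cord-remnant flag is an inconsistent anchor", {
  ev <- make_events("X", c(0, 10), cord_remnants = c(FALSE, TRUE))
  expect_error(assemble_training_pairs(build_histories(ev)),
               "inconsistent aging anchor")
})

test_that("closed-wound observations are excluded from the response", {
  ev <- make_events("X", c(0, 10, 40), cord_remnants = c(TRUE, FALSE, FALSE))
  pairs <- assemble_training_pairs(build_histories(ev))
  expect_equal(nrow(pairs), 2)
  expect_equal(attr(pairs, "n_closed_excluded"), 1L)
})

test_that("noise-free data are fitted exactly, for any positive coefficients", {
  set.seed(42)
  for (rep in 1:5) {
    a0 <- runif(1, 0.2, 0.6); a1 <- runif(1, 0.03, 0.08)
    b0 <- runif(1, 0.8, 2.0); b1 <- runif(1, 0.02, 0.06)
    coh <- generate_cohort(noise_free_config(a0 = a0, a1 = a1, b0 = b0,
                                             b1 = b1, n_sharks = 0,
                                             n_training = 25),
                           seed = 100 + rep)
    fit <- fit_wound_models(assemble_training_pairs(build_histories(coh$events)))
    expect_equal(fit$a0, a0, tolerance = 1e-6)
    expect_equal(fit$a1, a1, tolerance = 1e-6)
    expect_equal(fit$b0, b0, tolerance = 1e-6)
    expect_equal(fit$b1, b1, tolerance = 1e-6)
    expect_lt(fit$var_eps_area, 1e-10)
    expect_lt(fit$var_eps_perim, 1e-10)
  }
})

test_that("fits are invariant to id relabelling and row order", {
  coh <- generate_cohort(training_config(40, seed = 17))
  pairs <- assemble_training_pairs(build_histories(coh$events))
  fit1 <- fit_wound_models(pairs)

  shuffled <- pairs[sample(nrow(pairs)), ]
  relabel <- setNames(sprintf("Z%03d", seq_along(unique(pairs$shark_id))),
                      unique(pairs$shark_id))
  shuffled$shark_id <- unname(relabel[shuffled$shark_id])
  fit2 <- fit_wound_models(shuffled)
  expect_equal(fit1$a0, fit2$a0, tolerance = 1e-8)
  expect_equal(fit1$a1, fit2$a1, tolerance = 1e-8)
  expect_equal(fit1$b0, fit2$b0, tolerance = 1e-8)
  expect_equal(fit1$b1, fit2$b1, tolerance = 1e-8)
})

test_that("underdetermined training data are rejected", {
  one_shark <- make_events("X", c(0, 10), cord_remnants = c(TRUE, FALSE))
  expect_error(
    fit_wound_models(assemble_training_pairs(build_histories(one_shark))),
    "insufficient training data")
})

test_that("parameter recovery improves with cohort size", {
  # RMSE shrinks with n; |bias| settles at a small floor (a few percent)
  # induced by the zero-truncation of measurements and the exclusion of
  # closed wounds, both of which select against low healing trajectories
  # near closure.
  ns <- c(25, 100, 400)
  nrep <- 20
  sd_a1 <- bias_a1 <- numeric(length(ns))
  for (j in seq_along(ns)) {
    est <- vapply(seq_len(nrep), function(r) {
      coh <- generate_cohort(training_config(ns[j]), seed = 5000 + j * 100 + r)
      fit_wound_models(assemble_training_pairs(build_histories(coh$events)))$a1
    }, numeric(1))
    sd_a1[j] <- sd(est)
    bias_a1[j] <- mean(est) - PAPER_A1
  }
  expect_true(all(diff(sd_a1) < 0))
  expect_lt(abs(bias_a1[length(ns)]), 0.05 * PAPER_A1)
})

test_that("closure age is the larger x-intercept, with its ceiling day", {
  cl <- closure_age(paper_fit())
  expect_equal(cl$area_days, (PAPER_A0 / PAPER_A1)^2, tolerance = 1e-12)
  expect_equal(cl$perimeter_days, PAPER_B0 / PAPER_B1, tolerance = 1e-12)
  expect_equal(round(cl$area_days, 2), 34.43)
  expect_equal(round(cl$perimeter_days, 2), 35.11)
  expect_identical(cl$day, 36L)

  # degenerate curves close at age 0; doubling b0 doubles the intercept
  zero <- closure_age(wound_model_fit(1e-12, 1, 1e-12, 1))
  expect_equal(zero$days, 0, tolerance = 1e-10)
  f1 <- wound_model_fit(PAPER_A0, PAPER_A1, PAPER_B0, PAPER_B1)
  f2 <- wound_model_fit(PAPER_A0, PAPER_A1, 2 * PAPER_B0, PAPER_B1)
  expect_equal(closure_age(f2)$perimeter_days,
               2 * closure_age(f1)$perimeter_days, tolerance = 1e-12)
})
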