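two_step_features <- function(vals1, vals2, K = 1) {
  dplyr::bind_rows(
    tibble::tibble(person = "A", foot = "l", speed = "normal", cycle = 1L,
                   mode_rank = seq_len(K), alpha = vals1[1],
                   freq = vals1[2], s0 = vals1[3]),
    tibble::tibble(person = "A", foot = "l", speed = "normal", cycle = 2L,
                   mode_rank = seq_len(K), alpha = vals2[1],
                   freq = vals2[2], s0 = vals2[3]))
}

test_that("baselines average steps and invert the sample deviation", {
  f <- two_step_features(c(1, 1, 1), c(3, 3, 3))
  b <- compute_baseline(f)
  expect_equal(c(b$centroid_alpha, b$centroid_freq, b$centroid_s0),
               c(2, 2, 2))
  # sample variance (1/(C-1)) sum (F - <F>)^2 = 2, spread = 2^{-1/2}
  expect_equal(c(b$spread_alpha, b$spread_freq, b$spread_s0),
               rep(2^(-1 / 2), 3))
  expect_equal(b$n_steps, 2)

  # identical steps: centroid equals the step, spread capped, warning
  f0 <- two_step_features(c(1, 2, 3), c(1, 2, 3))
  expect_warning(b0 <- compute_baseline(f0), "zero within-person variance")
  expect_equal(b0$centroid_freq, 2)
  expect_equal(b0$spread_alpha, 1e6)

  expect_error(compute_baseline(f[f$cycle == 1, ]), "at least 2 steps")
  f_mixed <- f
  f_mixed$person <- c("A", "B")
  expect_error(compute_baseline(f_mixed), "person")
})

test_that("centroids converge to the generator means", {
  co <- make_cohort(n_persons = 2, seed = 6)
  prof <- person_profile(co, "P01")
  steps <- simulate_cohort_steps(co, steps_per_person = 30, feet = "l",
                                 seed = 8)
  f <- featurize_steps(steps[steps$person == "P01", ])
  b <- compute_baseline(f)
  # within 3 standard errors per component (sd/sqrt(C) via the spread),
  # plus a small allowance for the noise-induced estimator bias that the
  # weakest modes carry (see the methods vignette)
  se <- 3 / (b$spread_freq * sqrt(b$n_steps))
  expect_true(all(abs(b$centroid_freq - prof$freq) < pmax(se, 0.15)))
})

test_that("identification cost is zero at the centroid and literal elsewhere", {
  f <- two_step_features(c(1, 1, 1), c(3, 3, 3))
  b <- compute_baseline(f)
  probe <- f
  probe$alpha <- probe$freq <- probe$s0 <- 2  # exactly the centroid
  expect_equal(identification_cost(probe, b), 0)

  # one probe step, deviation d per component, spread s per component:
  # cost = 3 * s * d^2
  probe1 <- probe[probe$cycle == 1, ]
  d <- 0.7
  probe1$alpha <- probe1$freq <- probe1$s0 <- 2 + d
  expect_equal(identification_cost(probe1, b), 3 * 2^(-1 / 2) * d^2)

  bad <- probe1
  bad$mode_rank <- 2L
  expect_error(identification_cost(bad, b), "mode-rank")
})

test_that("vectorized cost equals the naive triple-loop reference", {
  set.seed(99)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    gal_steps <- random_features(n_steps = sample(3:8, 1), K = K)
    probe <- random_features(n_steps = sample(1:4, 1), K = K)
    b <- compute_baseline(gal_steps)
    std <- i %% 2 == 0
    expect_equal(identification_cost(probe, b, standardized = std),
                 naive_cost(probe, b, standardized = std),
                 tolerance = 1e-12)
  }
})

test_that("argmin identification picks the zero-cost candidate", {
  f <- two_step_features(c(1, 1, 1), c(3, 3, 3))
  bA <- compute_baseline(f)
  bB <- bA
  bB$person <- "B"
  bB$centroid_alpha <- bB$centroid_alpha + 5
  gallery <- dplyr::bind_rows(bA, bB)

  probe <- f[f$cycle == 1, ]
  probe$alpha <- probe$freq <- probe$s0 <- 2
  res <- identify_person(probe, gallery)
  expect_equal(res$person, "A")
  expect_equal(res$costs$cost[res$costs$person == "A"], 0)

  # gallery of one: trivially that person
  expect_equal(identify_person(probe, bA)$person, "A")
  expect_error(identify_person(probe, gallery[0, ]), "empty gallery")
})

test_that("well-separated cohorts identify every full probe set correctly", {
  co <- make_cohort(n_persons = 5, separation = 2, steps_per_person = 6,
                    seed = 13)
  steps <- simulate_cohort_steps(co, feet = "l", seed = 14)
  f <- featurize_steps(steps)
  gallery <- build_gallery(f)
  for (p in unique(f$person)) {
    probe <- f[f$person == p, ]
    expect_equal(identify_person(probe, gallery)$person, p)
  }
})

test_that("probe cost against own baseline beats a displaced baseline", {
  co <- make_cohort(n_persons = 2, seed = 17)
  steps <- simulate_cohort_steps(co, steps_per_person = 20, feet = "l",
                                 seed = 18)
  f <- featurize_steps(steps[steps$person == "P01", ])
  b <- compute_baseline(f)
  shifted <- b
  for (comp in c("alpha", "freq", "s0")) {
    shifted[[paste0("centroid_", comp)]] <-
      shifted[[paste0("centroid_", comp)]] +
      3 / shifted[[paste0("spread_", comp)]]  # +3 within-person sd
  }
  own <- identification_cost(f, b)
  disp <- identification_cost(f, shifted)
  expect_lt(own, disp)
})

test_that("Monte-Carlo evaluation is reproducible and self-consistent", {
  co <- make_cohort(n_persons = 4, steps_per_person = 8, seed = 19)
  steps <- simulate_cohort_steps(co, feet = "l", seed = 20)
  f <- featurize_steps(steps)
  e1 <- evaluate_identification(f, n_repeats = 100, seed = 5)
  e2 <- evaluate_identification(f, n_repeats = 100, seed = 5)
  expect_identical(e1$summary, e2$summary)
  expect_identical(e1$confusion, e2$confusion)
  expect_equal(sum(e1$confusion$n), 100)
  expect_true(all(e1$summary$accuracy >= 0 & e1$summary$accuracy <= 1))

  # fraction 1 probes are the person's full step set: the repeat outcome
  # must agree with a direct identify_person call
  ef <- evaluate_identification(f, fraction = 1, n_repeats = 20, seed = 6)
  gallery <- build_gallery(f)
  manual <- vapply(unique(f$person), function(p) {
    identify_person(f[f$person == p, ], gallery)$person == p
  }, logical(1))
  conf <- ef$confusion
  for (i in seq_len(nrow(conf))) {
    expect_equal(conf$true[i] == conf$predicted[i],
                 unname(manual[conf$true[i]]))
  }

  expect_error(evaluate_identification(f, fraction = 0.05),
               "not enough steps")
})

test_that("identification accuracy is monotone in cohort separation", {
  acc_at <- function(sep) {
    co <- make_cohort(n_persons = 6, separation = sep,
                      steps_per_person = 10, seed = 23)
    steps <- simulate_cohort_steps(co, feet = "l", seed = 24)
    f <- featurize_steps(steps)
    evaluate_identification(f, n_repeats = 300, seed = 25,
                            holdout = TRUE)$summary$accuracy
  }
  accs <- vapply(c(0, 0.4, 1.2), acc_at, numeric(1))
  expect_true(all(diff(accs) >= -0.05))  # allow Monte-Carlo wiggle
  expect_gt(accs[3], accs[1])
})
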