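# Fits in this file are deliberately small; sampler seeds are fixed so the
# suite is deterministic.

dyads_from <- function(roster, y, n, feature = "shape") {
  data.frame(roster[, c("child_id", "group_id", "community", "condition",
                        "position", "age_years", "sex")],
             feature = feature, y_matches = y, n_max = n,
             stringsAsFactors = FALSE)
}

test_that("the design matrix centers covariates and partitions records", {
  ros <- flat_roster(2)
  ros$age_years <- c(8, 10)
  d <- dyads_from(ros, c(3, 4), c(5, 5))
  des <- build_design(d, "shape")
  expect_equal(des$age, c(-1, 1))
  expect_equal(des$centers$age, 9)

  dy <- simulate_dyads(simulate_roster(study_config(2, 3), 1), true_params(), 2)
  des2 <- build_design(dy, "color")
  n_rec <- sum(dy$feature == "color")
  expect_equal(sum(tabulate(des2$child)), n_rec)
  expect_equal(sum(tabulate(des2$grp)), n_rec)
  expect_equal(sum(tabulate(des2$comm)), n_rec)

  bad <- dyads_from(flat_roster(1), 7, 5)
  expect_error(build_design(bad, "shape"), "y_matches")
  ok <- dyads_from(flat_roster(1), 5, 5)   # boundary y = n is legal
  expect_silent(build_design(ok, "shape"))
})

test_that("a balanced half-successes fit concentrates near one half", {
  ros <- flat_roster(10)
  d <- dyads_from(ros, rep(50, 10), rep(100, 10))
  fit <- suppressWarnings(
    fit_full_model(build_design(d, "shape"), sampler_settings(2, 300, 300, seed = 301)))
  p <- mean(predict_probability(fit, "unobserved"))
  expect_gt(p, 0.47)
  expect_lt(p, 0.53)
})

test_that("saturated counts push the posterior to the boundary", {
  ros <- flat_roster(15)
  d <- dyads_from(ros, rep(12, 15), rep(12, 15))
  fit <- suppressWarnings(
    fit_full_model(build_design(d, "shape"), sampler_settings(2, 300, 300, seed = 302)))
  expect_gte(mean(predict_probability(fit, "unobserved")), 0.95)
})

test_that("predictions invert the linear predictor exactly", {
  cols <- c("a[1]", "u_comm[1]", "b_cond", "bc[1]", "b_pos", "b_sex",
            "b_sexcond", "b_age", "ba[1]", "b_agecond", "bac[1]",
            "sd_comm", "sd_g", "sd_ch")
  draws <- matrix(0, nrow = 3, ncol = length(cols),
                  dimnames = list(NULL, cols))
  draws[, "a[1]"] <- c(0.2, -0.1, 0.4)
  draws[, "u_comm[1]"] <- c(0.05, 0, -0.05)
  draws[, "b_cond"] <- c(0.5, 0.3, 0.1)
  draws[, "b_age"] <- c(0.1, 0.2, 0.3)
  draws[, "b_sex"] <- c(-0.2, 0.1, 0)
  draws[, "b_pos"] <- c(0.02, 0.03, 0.04)
  fit <- posterior_draws(draws, chain = rep(1L, 3), model = "individual_full",
                         meta = list(centers = list(age = 9, position = 3),
                                     levels = list(community = "A")))
  p <- predict_probability(fit, condition = "observed", community = "A",
                           age = 10, position = 2, sex = "male")
  eta <- draws[, "a[1]"] + draws[, "u_comm[1]"] + draws[, "b_cond"] +
    draws[, "b_pos"] * (-1) + draws[, "b_sex"] + draws[, "b_age"] * 1
  expect_equal(p, plogis(eta))

  zero <- posterior_draws(matrix(0, 2, length(cols),
                                 dimnames = list(NULL, cols)),
                          chain = rep(1L, 2), model = "individual_full",
                          meta = fit$meta)
  expect_identical(predict_probability(zero, "unobserved"), c(0.5, 0.5))
  expect_error(predict_probability(fit, "observed", community = "Z"),
               "unknown community")
  expect_error(predict_probability(fit, "sideways"), "unknown condition")
})

test_that("contrasts vanish for identical settings and negate under exchange", {
  set.seed(303)
  cols <- c("a[1]", "u_comm[1]", "b_cond", "bc[1]", "b_pos", "b_sex",
            "b_sexcond", "b_age", "ba[1]", "b_agecond", "bac[1]")
  draws <- matrix(rnorm(50 * length(cols), 0, 0.3), nrow = 50,
                  dimnames = list(NULL, cols))
  fit <- posterior_draws(draws, chain = rep(1L, 50), model = "individual_full",
                         meta = list(centers = list(age = 9, position = 3),
                                     levels = list(community = "A")))
  same <- contrast(fit, list(condition = "observed"), list(condition = "observed"))
  expect_equal(same$mean, 0)
  expect_equal(same$hpdi, c(0, 0))
  ab <- contrast(fit, list(condition = "observed"), list(condition = "unobserved"))
  ba <- contrast(fit, list(condition = "unobserved"), list(condition = "observed"))
  expect_equal(ab$draws, -ba$draws)
  expect_equal(ab$mean, -ba$mean)
})

test_that("aggregated binomial rows and split Bernoulli rows agree", {
  set.seed(304)
  ros <- flat_roster(20)
  n <- rep(8L, 20)
  y <- rbinom(20, n, 0.7)
  agg <- dyads_from(ros, y, n)
  split_rows <- do.call(rbind, lapply(seq_len(20), function(i) {
    d <- dyads_from(ros[rep(i, n[i]), ], 0L, 1L)
    d$y_matches <- as.integer(seq_len(n[i]) <= y[i])
    d
  }))
  f1 <- suppressWarnings(
    fit_full_model(build_design(agg, "shape"), sampler_settings(2, 400, 400, seed = 305)))
  f2 <- suppressWarnings(
    fit_full_model(build_design(split_rows, "shape"), sampler_settings(2, 400, 400, seed = 306)))
  p1 <- mean(predict_probability(f1, "unobserved"))
  p2 <- mean(predict_probability(f2, "unobserved"))
  expect_lt(abs(p1 - p2), 0.03)
})

test_that("the posterior mean tracks the generative baseline monotonically", {
  cfg <- study_config(n_communities = 2, groups_per_community = 3)
  ros <- simulate_roster(cfg, 307)
  est <- sapply(c(0.3, 0.5, 0.7), function(p0) {
    pars <- true_params(baseline = c(shape = qlogis(p0), color = 0),
                       b_position = 0, b_age = 0,
                       sd_community = 0, sd_group = 0, sd_child = 0)
    dy <- simulate_dyads(ros, pars, 308)
    fit <- suppressWarnings(
      fit_full_model(build_design(dy, "shape"),
                     sampler_settings(2, 300, 300, seed = 309)))
    mean(predict_probability(fit, "unobserved"))
  })
  expect_true(all(diff(est) > 0))
})

test_that("community-varying age slopes are recovered by the age model", {
  cfg <- study_config(groups_per_community = 22)   # ~600 children
  ros <- simulate_roster(cfg, 310)
  slopes <- c(0.3, 0, -0.3, 0, 0.3)
  pars <- true_params(b_age = 0, b_age_community = slopes, b_position = 0,
                      sd_community = 0.1, sd_group = 0.2, sd_child = 0.3)
  dy <- simulate_dyads(ros, pars, 311)
  fit <- suppressWarnings(
    fit_age_model(build_design(dy, "shape"), sampler_settings(4, 500, 500, seed = 312)))
  rec <- sapply(1:5, function(k)
    mean(param_draws(fit, "b_age") + param_draws(fit, sprintf("ba[%d]", k))))
  expect_true(all(rec[slopes > 0] > 0))
  expect_true(all(rec[slopes < 0] < 0))
  expect_true(all(abs(rec[slopes == 0]) < 0.2))
})

test_that("zero-effect data leave the age-slope intervals covering zero", {
  cfg <- study_config(groups_per_community = 8)
  ros <- simulate_roster(cfg, 313)
  pars <- true_params(b_age = 0, b_position = 0,
                      sd_community = 0.1, sd_group = 0.2, sd_child = 0.3)
  dy <- simulate_dyads(ros, pars, 314)
  fit <- suppressWarnings(
    fit_age_model(build_design(dy, "shape"), sampler_settings(2, 400, 400, seed = 315)))
  covered <- sapply(1:5, function(k) {
    s <- param_draws(fit, "b_age") + param_draws(fit, sprintf("ba[%d]", k))
    pi <- percentile_interval(s, 0.89)
    pi[1] <= 0 && 0 <= pi[2]
  })
  expect_gte(sum(covered), 4L)
})

test_that("a single-community study degenerates gracefully", {
  cfg <- study_config(n_communities = 1, groups_per_community = 4)
  ros <- simulate_roster(cfg, 316)
  dy <- simulate_dyads(ros, true_params(), 317)
  fit <- suppressWarnings(
    fit_age_model(build_design(dy, "color"), sampler_settings(2, 200, 200, seed = 318)))
  expect_s3_class(fit, "posterior_draws")
  expect_equal(length(fit$meta$levels$community), 1L)
  p <- predict_probability(fit, "unobserved")
  expect_true(all(p > 0 & p < 1))
})

test_that("null condition effects are covered by the contrast HPDI across replicates", {
  cfg <- study_config(groups_per_community = 2)   # ~55 children per replicate
  pars <- true_params(b_position = 0, b_age = 0,
                      sd_community = 0.1, sd_group = 0.2, sd_child = 0.3)
  covered <- logical(10)
  for (r in 1:10) {
    ros <- simulate_roster(cfg, 400 + r)
    dy <- simulate_dyads(ros, pars, 500 + r)
    fit <- suppressWarnings(
      fit_full_model(build_design(dy, "shape"),
                     sampler_settings(2, 300, 300, seed = 600 + r)))
    ct <- contrast(fit, list(condition = "observed"),
                   list(condition = "unobserved"))
    covered[r] <- ct$hpdi[1] <= 0 && 0 <= ct$hpdi[2]
  }
  expect_gte(sum(covered), ceiling(0.85 * 10))
})

test_that("predicted probabilities and contrasts stay inside their ranges", {
  cfg <- study_config(n_communities = 2, groups_per_community = 2)
  ros <- simulate_roster(cfg, 319)
  dy <- simulate_dyads(ros, true_params(), 320)
  fit <- suppressWarnings(
    fit_full_model(build_design(dy, "shape"), sampler_settings(2, 200, 200, seed = 321)))
  for (setting in list(list(condition = "observed"),
                       list(condition = "unobserved", age = 12),
                       list(condition = 0.5, marginal = TRUE))) {
    p <- do.call(predict_probability, c(list(fit = fit), setting))
    expect_true(all(p > 0 & p < 1))
  }
  ct <- contrast(fit, list(condition = "observed"), list(condition = "unobserved"))
  expect_true(all(ct$draws > -1 & ct$draws < 1))
})
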