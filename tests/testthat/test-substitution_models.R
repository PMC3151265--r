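# substitution models: generators, transition probabilities, discrete gamma,
# average ts/tv ratio

test_that("generators satisfy calibration, detailed balance and nesting", {
  set.seed(101)
  models <- c(list(jc_model(), hky_model(c(.3, .2, .2, .3), 2.5)),
              lapply(1:6, function(i) random_model("REV")))
  for (m in models) {
    Q <- build_generator(m)
    expect_equal(rowSums(Q), rep(0, 4), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(-sum(m$frequencies * diag(Q)), 1, tolerance = 1e-12)
    db <- outer(m$frequencies, rep(1, 4)) * Q
    expect_lt(max(abs(db - t(db))), 1e-12)
  }
  # JC: symmetry forces every off-diagonal rate to 1/3
  Qjc <- build_generator(jc_model())
  expect_equal(unname(Qjc[1, 2:4]), rep(1 / 3, 3), tolerance = 1e-12)
  # model collapse: HKY(kappa=1, equal pi) and REV(all r equal) reproduce JC
  expect_equal(build_generator(hky_model(rep(.25, 4), 1)), Qjc)
  expect_equal(build_generator(rev_model(rep(.25, 4), rep(2, 6))), Qjc)
})

test_that("REV generator entries match direct arithmetic", {
  # oracle: q_ij = scale * r_ij * pi_j with scale from -sum pi_i q_ii = 1
  pi <- c(0.3, 0.2, 0.3, 0.2)
  r <- c(1, 2, 1, 1, 2, 1)  # AC AG AT CG CT GT
  R <- matrix(0, 4, 4)
  R[lower.tri(R)] <- R[upper.tri(R)] <- 0  # filled below
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  Qraw <- matrix(0, 4, 4)
  for (k in 1:6) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    Qraw[i, j] <- r[k] * pi[j]
    Qraw[j, i] <- r[k] * pi[i]
  }
  diag(Qraw) <- -rowSums(Qraw)
  scale <- 1 / -sum(pi * diag(Qraw))
  expect_equal(build_generator(rev_model(pi, r)), Qraw * scale,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("invalid models are rejected", {
  expect_error(rev_model(c(.5, .5, 0, 0)), "1e-8|frequencies")
  expect_error(rev_model(c(.3, .3, .3, .2)), "sum to 1")
  expect_error(build_generator(rev_model(rep(.25, 4), rep(0, 6))),
               "degenerate")
  expect_error(hky_model(kappa = -1), "positive")
})

test_that("transition probabilities are stochastic and consistent", {
  set.seed(102)
  for (kind in c("JC", "HKY", "REV")) {
    m <- random_model(kind)
    Q <- build_generator(m)
    expect_equal(transition_probabilities(Q, 0, m$frequencies), diag(4),
                 tolerance = 1e-12, ignore_attr = TRUE)
    for (rep in 1:4) {
      a <- runif(1, 0, 5); b <- runif(1, 0, 5)
      Pa <- transition_probabilities(Q, a, m$frequencies)
      Pb <- transition_probabilities(Q, b, m$frequencies)
      Pab <- transition_probabilities(Q, a + b, m$frequencies)
      expect_equal(rowSums(Pa), rep(1, 4), tolerance = 1e-10,
                   ignore_attr = TRUE)
      expect_true(all(Pa >= 0 & Pa <= 1))
      # Chapman-Kolmogorov
      expect_equal(Pa %*% Pb, Pab, tolerance = 1e-8, ignore_attr = TRUE)
    }
    # stationarity at large t
    Pinf <- transition_probabilities(Q, 500, m$frequencies)
    for (i in 1:4)
      expect_equal(unname(Pinf[i, ]), unname(m$frequencies),
                   tolerance = 1e-8)
  }
  # JC closed form at t = 0.75
  Pjc <- transition_probabilities(build_generator(jc_model()), 0.75)
  expect_equal(unname(diag(Pjc)), rep(0.25 + 0.75 * exp(-1), 4),
               tolerance = 1e-10)
  expect_error(transition_probabilities(build_generator(jc_model()), -0.1),
               "nonnegative")
})

test_that("discrete gamma matches the quadrature oracle and its contracts", {
  g1 <- discretize_gamma(0.7, 1)
  expect_equal(g1$category_rates, 1)
  for (alpha in c(0.2, 0.5, 1, 3, 20)) {
    for (K in c(2, 4, 6)) {
      g <- discretize_gamma(alpha, K)
      expect_equal(sum(g$category_probs), 1, tolerance = 1e-12)
      expect_equal(sum(g$category_probs * g$category_rates), 1,
                   tolerance = 1e-10)
      expect_true(all(diff(g$category_rates) >= 0))
    }
  }
  # quadrature oracle at alpha = 0.5, K = 6
  g <- discretize_gamma(0.5, 6)
  oracle <- gamma_bin_means_quadrature(0.5, 6)
  oracle <- oracle / sum(oracle / 6)  # same exact renormalization
  expect_equal(g$category_rates, oracle, tolerance = 1e-6)
  # all rates approach 1 as alpha grows; the extreme-bin deviation of the
  # conditional-mean discretization scales as 1/sqrt(alpha), so 1e-2 needs
  # alpha in the tens of thousands
  dev <- vapply(c(2, 20, 200, 2e5), function(a)
    max(abs(discretize_gamma(a, 6)$category_rates - 1)), 0)
  expect_true(all(diff(dev) < 0))
  expect_lt(dev[4], 1e-2)
  expect_error(discretize_gamma(-1, 6), "positive")
  expect_error(discretize_gamma(1, 0), "positive")
})

test_that("average ts/tv ratio R follows its closed forms", {
  expect_equal(average_ts_tv_ratio(jc_model()), 0.5, tolerance = 1e-12)
  # equal-frequency HKY: R = kappa/2
  for (kappa in c(0.5, 2, 7))
    expect_equal(average_ts_tv_ratio(hky_model(rep(.25, 4), kappa)),
                 kappa / 2, tolerance = 1e-12)
  # general HKY oracle: kappa (piA piG + piC piT) / ((piA+piG)(piC+piT))
  f <- c(.4, .1, .2, .3)
  expect_equal(average_ts_tv_ratio(hky_model(f, 3)),
               3 * (f[1] * f[3] + f[2] * f[4]) /
                 ((f[1] + f[3]) * (f[2] + f[4])), tolerance = 1e-12)
  # scale invariance
  m <- random_model("REV")
  m7 <- rev_model(m$frequencies, m$exchangeabilities * 7)
  expect_equal(average_ts_tv_ratio(m), average_ts_tv_ratio(m7),
               tolerance = 1e-12)
  # no transversion flux
  expect_error(
    average_ts_tv_ratio(rev_model(rep(.25, 4), c(0, 1, 0, 0, 1, 0))),
    "transversion")
})

test_that("model configs round-trip", {
  m <- hky_model(c(.3, .2, .2, .3), 2.5)
  g <- discretize_gamma(0.6, 6)
  cfg <- model_config(m, g)
  back <- parse_model_config(cfg)
  expect_equal(back$model$frequencies, m$frequencies, tolerance = 1e-10)
  expect_equal(back$model$kappa, m$kappa, tolerance = 1e-10)
  expect_equal(back$gamma$alpha, g$alpha, tolerance = 1e-10)
})
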