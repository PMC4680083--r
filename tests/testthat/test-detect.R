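# Bayesian deflection detector: likelihood, sampler, Hellinger decision

test_that("log-likelihood matches a hand-computed Poisson sum", {
  # 5 bins, counts (0,3,3,0,0), response interval over the 2nd and 3rd
  r <- spike_raster(
    tibble::tibble(trial = rep(1:3, each = 2),
                   time = rep(c(0.0015, 0.0025), 3)),
    cycle_duration = 0.005, n_trials = 3)
  h <- bin_raster(r, 0.001)
  expect_equal(h$count, c(0L, 3L, 3L, 0L, 0L))
  lam1 <- 0.3; lam2 <- 2.5
  theta <- response_model(lam1, lam2, tau1 = 0.001, tau2 = 0.002, cycle = 0.005)
  # independent per-bin oracle: k log(lam) - lam - log(k!)
  manual <- 2 * (3 * log(lam2) - lam2 - log(6)) + 3 * (0 * log(lam1) - lam1)
  expect_equal(log_likelihood(theta, h), manual, tolerance = 1e-12)
})

test_that("log-likelihood handles zero rates by convention", {
  r <- spike_raster(NULL, cycle_duration = 0.01, n_trials = 2)
  h <- bin_raster(r, 0.001)
  expect_equal(log_likelihood(response_model(0, 0, 0.002, 0.003, 0.01), h), 0)
  r2 <- spike_raster(tibble::tibble(trial = 1, time = 0.0005),
                     cycle_duration = 0.01, n_trials = 2)
  h2 <- bin_raster(r2, 0.001)
  expect_equal(log_likelihood(response_model(0, 1, 0.002, 0.003, 0.01), h2),
               -Inf)
})

test_that("with equal rates the interval is irrelevant", {
  set.seed(2)
  r <- generate_raster(40, 40, seed = 17)
  h <- bin_raster(r)
  lam <- mean(h$count)
  l1 <- log_likelihood(response_model(lam, lam, 0.05, 0.05), h)
  l2 <- log_likelihood(response_model(lam, lam, 0.2, 0.1), h)
  single <- sum(stats::dpois(h$count, lam, log = TRUE))
  expect_equal(l1, single, tolerance = 1e-10)
  expect_equal(l2, single, tolerance = 1e-10)
})

test_that("invalid response models are rejected", {
  expect_error(response_model(-1, 1, 0.01, 0.01), "invalid")
  expect_error(response_model(1, 1, 0.3, 0.1, cycle = 1 / 3), "invalid")
  expect_error(response_model(1, 1, 0.01, 0), "invalid")
})

test_that("hellinger agrees with brute-force evaluation on 1000 random pairs", {
  set.seed(33)
  brute <- function(p, q) {
    # independent elementwise evaluation of the sqrt form
    acc <- 0
    for (i in seq_along(p)) acc <- acc + (sqrt(p[i]) - sqrt(q[i]))^2
    sqrt(acc / 2)
  }
  for (rep in 1:1000) {
    n <- sample(5:200, 1)
    p <- runif(n); p <- p / sum(p)
    q <- runif(n); q <- q / sum(q)
    br <- seq(0, 1, length.out = n + 1)
    got <- hellinger(prob_hist(br, p), prob_hist(br, q))
    expect_equal(got, brute(p, q), tolerance = 1e-12)
  }
})

test_that("hellinger limiting cases: identical gives 0, disjoint gives 1", {
  br <- seq(0, 1, length.out = 11)
  p <- rep(0.1, 10)
  expect_equal(hellinger(prob_hist(br, p), prob_hist(br, p)), 0)
  a <- c(rep(0.2, 5), rep(0, 5))
  b <- c(rep(0, 5), rep(0.2, 5))
  expect_equal(hellinger(prob_hist(br, a), prob_hist(br, b)), 1)
  # worked example: (0.5, 0.5, 0) vs (0, 0.5, 0.5)
  br3 <- c(0, 1, 2, 3)
  expect_equal(hellinger(prob_hist(br3, c(0.5, 0.5, 0)),
                         prob_hist(br3, c(0, 0.5, 0.5))),
               sqrt(0.5), tolerance = 1e-12)
})

test_that("hellinger rejects mismatched grids and unnormalized inputs", {
  expect_error(hellinger(prob_hist(0:5, rep(0.2, 5)),
                         prob_hist(seq(0, 10, 2), rep(0.2, 5))),
               "grid")
  expect_error(hellinger(prob_hist(0:5, rep(0.3, 5)),
                         prob_hist(0:5, rep(0.2, 5))),
               "sum to 1")
})

test_that("identical seeds give bit-identical chains and decisions", {
  r <- generate_raster(30, 90, 0.03, 0.03, seed = 21)
  h <- bin_raster(r)
  ps1 <- metropolis_hastings(h, 3000, 500, seed = 99)
  ps2 <- metropolis_hastings(h, 3000, 500, seed = 99)
  expect_identical(ps1$lambda1, ps2$lambda1)
  expect_identical(ps1$tau2, ps2$tau2)
  d1 <- detect_response(r, n_iter = 3000, burn_in = 500, seed = 42)
  d2 <- detect_response(r, n_iter = 3000, burn_in = 500, seed = 42)
  expect_identical(glance(d1), glance(d2))
})

test_that("posterior recovers known parameters within 3 posterior sd", {
  # lambda1 = 0.5, lambda2 = 2.0 spikes/bin (trial-summed), 30 ms onset,
  # 20 ms duration, 333 ms cycle: rates 25 / 100 spikes/s over 20 trials
  r <- generate_raster(25, 100, 0.03, 0.02, n_trials = 20, cycle = 1 / 3,
                       seed = 42)
  ps <- metropolis_hastings(bin_raster(r), 12000, 2000, seed = 7)
  est <- tidy(ps)
  truth <- c(lambda1 = 0.5, lambda2 = 2.0, tau1 = 0.03, tau2 = 0.02)
  for (k in seq_len(4)) {
    expect_lt(abs(est$estimate[k] - truth[k]), 3 * est$std.error[k],
              label = sprintf("|%s - truth|", est$term[k]))
  }
  # acceptance rate in the random-walk regime
  expect_gt(attr(ps, "acceptance_rate"), 0.05)
  expect_lt(attr(ps, "acceptance_rate"), 0.7)
})

test_that("marginal histograms share one grid and sum to 1", {
  r <- generate_raster(30, 90, 0.05, 0.03, seed = 13)
  ps <- metropolis_hastings(bin_raster(r), 3000, 500, seed = 3)
  m <- marginal_histograms(ps)
  expect_equal(sum(m$p_lambda1$prob), 1, tolerance = 1e-12)
  expect_equal(sum(m$p_lambda2$prob), 1, tolerance = 1e-12)
  expect_identical(m$p_lambda1$breaks, m$p_lambda2$breaks)
  expect_length(m$p_lambda1$prob, 100)
})

test_that("strong responses are detected with probability 1", {
  r <- generate_raster(20, 100, 0.03, 0.02, seed = 31)
  d <- detect_response(r, n_iter = 5000, burn_in = 1000, seed = 32)
  expect_true(d$significant)
  expect_equal(d$probability, 1, tolerance = 1e-9)
  expect_gt(d$magnitude_mean, 0)
  expect_lt(abs(d$latency_mean_ms - 30), 10)
})

test_that("suppression is detected as a response (two-sided)", {
  r <- generate_raster(60, 0, 0.05, 0.04, seed = 3)
  d <- detect_response(r, n_iter = 5000, burn_in = 1000, seed = 9)
  expect_true(d$significant)
  expect_lt(d$magnitude_mean, 0)
})

test_that("all-zero histogram still yields a valid run", {
  r <- spike_raster(NULL, cycle_duration = 1 / 3, n_trials = 20)
  d <- detect_response(r, n_iter = 2000, burn_in = 500, seed = 1)
  expect_false(d$significant)
  expect_lt(mean(d$posterior$lambda1), 0.5)
})

test_that("magnitude converts to a per-trial rate", {
  expect_equal(magnitude_to_rate(1.44, 0.001, 20), 72)
})
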