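#' Four-parameter spike-response model
#'
#' Piecewise-constant Poisson model of a trial-summed peristimulus time
#' histogram: spikes per bin have mean `lambda1` outside a single
#' response interval `[tau1, tau1 + tau2)` and `lambda2` inside it.
#' Rates are in spikes per bin summed across trials; latencies in
#' seconds. A "response" is any deflection -- `lambda2` above or below
#' `lambda1` -- so suppression counts as a response too. If a response is
#' multi-phasic only one phase is captured.
#'
#' @param lambda1 Rate outside the response interval (spikes/bin,
#'   trial-summed), >= 0.
#' @param lambda2 Rate inside the interval, >= 0.
#' @param tau1 Response onset latency in seconds, >= 0.
#' @param tau2 Response duration in seconds, > 0; `tau1 + tau2` must not
#'   exceed `cycle`.
#' @param cycle Stimulus cycle duration in seconds.
#' @return A `response_model` list.
#' @export
response_model <- function(lambda1, lambda2, tau1, tau2, cycle = 1 / 3) {
  if (lambda1 < 0 || lambda2 < 0 || tau1 < 0 || tau2 <= 0 ||
      tau1 + tau2 > cycle + 1e-12) {
    stop("invalid response model parameters", call. = FALSE)
  }
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 tau1 = tau1, tau2 = tau2, cycle = cycle),
            class = "response_model")
}

# map a (tau1, tau2) interval to bin indices: bins (b1+1)..b2 are inside;
# edges rounded to the nearest bin boundary
interval_bins <- function(tau1, tau2, bin_width, n_bins) {
  b1 <- round(tau1 / bin_width)
  b2 <- round((tau1 + tau2) / bin_width)
  c(max(0L, min(b1, n_bins)), max(0L, min(b2, n_bins)))
}

#' Log-likelihood of a binned histogram under the response model
#'
#' Independent Poisson bins: mean `lambda2` inside the response interval
#' (edges rounded to bin boundaries), `lambda1` outside. Zero rates are
#' allowed: a zero-count bin contributes 0 under a zero rate, and a
#' nonzero count under a zero rate gives `-Inf`.
#'
#' @param theta A [response_model()].
#' @param h A `binned_histogram` from [bin_raster()].
#' @return The log-likelihood (may be `-Inf`).
#' @export
log_likelihood <- function(theta, h) {
  stopifnot(inherits(theta, "response_model"), inherits(h, "binned_histogram"))
  bw <- attr(h, "bin_width")
  nb <- nrow(h)
  b <- interval_bins(theta$tau1, theta$tau2, bw, nb)
  inside <- seq_len(nb) > b[1] & seq_len(nb) <= b[2]
  lam <- ifelse(inside, theta$lambda2, theta$lambda1)
  sum(stats::dpois(h$count, lam, log = TRUE))
}

# O(1) profile log-likelihood kernel used inside the sampler (constant
# log(c!) terms dropped; they cancel in the acceptance ratio)
ll_kernel <- function(lam1, lam2, b1, b2, csum, n_bins) {
  s_tot <- csum[n_bins + 1]
  s_in <- csum[b2 + 1] - csum[b1 + 1]
  n_in <- b2 - b1
  s_out <- s_tot - s_in
  n_out <- n_bins - n_in
  term <- function(s, n, lam) {
    if (lam == 0) {
      if (s > 0) -Inf else 0
    } else {
      s * log(lam) - n * lam
    }
  }
  term(s_in, n_in, lam2) + term(s_out, n_out, lam1)
}

#' Metropolis-Hastings posterior sampling of the response model
#'
#' Random-walk Metropolis-Hastings over `theta = (lambda1, lambda2, tau1,
#' tau2)` given a trial-summed histogram. Priors are uniform: rates on
#' `[0, 2 * max(count, 1)]`, `tau1` on `[0, cycle]`, `tau2` on
#' `(0, cycle - tau1]`. Proposals are independent Gaussian perturbations
#' of all four parameters with standard deviation 5% of each prior range;
#' proposals outside the support (or whose rounded response interval
#' contains no whole bin) are rejected. The chain is initialized at the
#' empirical mean rate with the latency placed at the peak of a lightly
#' smoothed histogram.
#'
#' @param h A `binned_histogram` from [bin_raster()].
#' @param n_iter Total iterations (default 12000).
#' @param burn_in Burn-in iterations discarded from the front (default
#'   2000).
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards. Identical seeds give identical chains.
#' @return A `posterior_samples` tibble with columns `lambda1`,
#'   `lambda2`, `tau1`, `tau2` (one row per kept iteration) and
#'   attributes `acceptance_rate`, `n_kept`, `burn_in`, `bin_width`,
#'   `cycle_duration`, `n_trials`.
#' @export
metropolis_hastings <- function(h, n_iter = 12000, burn_in = 2000, seed = NULL) {
  stopifnot(inherits(h, "binned_histogram"), n_iter > burn_in, burn_in >= 0)
  local_seed(seed)

  bw <- attr(h, "bin_width")
  cyc <- attr(h, "cycle_duration")
  nb <- nrow(h)
  counts <- h$count
  csum <- c(0, cumsum(counts))

  lam_max <- 2 * max(max(counts), 1)
  sd_lam <- 0.05 * lam_max
  sd_tau <- 0.05 * cyc

  # data-driven start, washed out by burn-in: candidate intervals sit over
  # the contiguous regions of largest smoothed excursion above and below
  # the mean count (a response may be an increase or a suppression); the
  # candidate with the higher posterior wins
  sm <- stats::filter(counts, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- mean(counts)
  region_around <- function(dev, pk) {
    ok <- dev >= 0.5 * dev[pk]
    lo <- pk
    while (lo > 1 && ok[lo - 1]) lo <- lo - 1
    hi <- pk
    while (hi < nb && ok[hi + 1]) hi <- hi + 1
    c(lo, hi)
  }
  start_from <- function(reg) {
    inside <- seq(reg[1], reg[2])
    outside_mean <- if (length(inside) >= nb) mean(counts) else mean(counts[-inside])
    th <- c(lambda1 = max(outside_mean, 1e-3),
            lambda2 = max(mean(counts[inside]), 1e-3),
            tau1 = min((reg[1] - 1) * bw, 0.9 * cyc),
            tau2 = max((reg[2] - reg[1] + 1) * bw, 2 * bw))
    th[4] <- min(th[4], cyc - th[3])
    th
  }

  log_post <- function(th) {
    if (th[1] < 0 || th[1] > lam_max || th[2] < 0 || th[2] > lam_max ||
        th[3] < 0 || th[3] > cyc || th[4] <= 0 || th[3] + th[4] > cyc) {
      return(-Inf)
    }
    b <- interval_bins(th[3], th[4], bw, nb)
    if (b[2] <= b[1]) return(-Inf)  # interval must contain a whole bin
    # conditional-uniform prior on tau2 given tau1 has density 1/(cyc-tau1)
    ll_kernel(th[1], th[2], b[1], b[2], csum, nb) - log(cyc - th[3])
  }

  cand <- list(
    start_from(region_around(pmax(sm - mean(counts), 0), which.max(sm))),
    start_from(region_around(pmax(mean(counts) - sm, 0), which.min(sm)))
  )
  lps <- vapply(cand, log_post, numeric(1))
  cur <- cand[[which.max(lps)]]
  lp_cur <- max(lps)
  if (!is.finite(lp_cur)) {
    cur <- c(lambda1 = max(mean(counts), 1e-3),
             lambda2 = max(mean(counts), 1e-3),
             tau1 = 0.25 * cyc, tau2 = 0.25 * cyc)
    lp_cur <- log_post(cur)
  }
  n_kept <- n_iter - burn_in
  chain <- matrix(NA_real_, n_kept, 4,
                  dimnames = list(NULL, c("lambda1", "lambda2", "tau1", "tau2")))
  sds <- c(sd_lam, sd_lam, sd_tau, sd_tau)
  n_acc <- 0L
  # systematic-scan random walk: one Gaussian proposal per parameter per
  # iteration, each accepted or rejected on its own Metropolis ratio.
  # Every 10th iteration additionally attempts a mode-jumping move that
  # redraws (tau1, tau2) uniformly over their triangular support (the
  # density is constant, so the proposal is symmetric and the plain
  # Metropolis ratio applies); this lets the interval hop between
  # competing explanations of the histogram instead of diffusing.
  for (i in seq_len(n_iter)) {
    steps <- stats::rnorm(4) * sds
    lu <- log(stats::runif(4))
    for (k in 1:4) {
      prop <- cur
      prop[k] <- prop[k] + steps[k]
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && lu[k] < lp_prop - lp_cur) {
        cur <- prop
        lp_cur <- lp_prop
        n_acc <- n_acc + 1L
      }
    }
    if (i %% 10L == 0L) {
      repeat {
        t1 <- stats::runif(1, 0, cyc)
        t2 <- stats::runif(1, 0, cyc)
        if (t1 + t2 < cyc) break
      }
      prop <- cur
      prop[3] <- t1
      prop[4] <- t2
      lp_prop <- log_post(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp_cur) {
        cur <- prop
        lp_cur <- lp_prop
      }
    }
    if (i > burn_in) chain[i - burn_in, ] <- cur
  }
  n_acc <- n_acc / 4

  out <- tibble::as_tibble(chain)
  attr(out, "acceptance_rate") <- n_acc / n_iter
  attr(out, "n_kept") <- n_kept
  attr(out, "burn_in") <- burn_in
  attr(out, "bin_width") <- bw
  attr(out, "cycle_duration") <- cyc
  attr(out, "n_trials") <- attr(h, "n_trials")
  class(out) <- c("posterior_samples", class(out))
  out
}

# run the calling function under a temporary seed, restoring the caller's
# RNG state on exit
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  withr::local_seed(seed, .local_envir = env)
  invisible()
}

#' Marginal rate posteriors on a shared support
#'
#' Histograms the posterior samples of `lambda1` and `lambda2` on one
#' common grid of `n_bins` equal bins spanning the pooled sample range,
#' each normalized to sum to 1.
#'
#' @param ps A `posterior_samples` object.
#' @param n_bins Number of shared bins (default 100).
#' @return A list with elements `p_lambda1` and `p_lambda2`, each a
#'   `prob_hist` (list of `breaks` and `prob`).
#' @export
marginal_histograms <- function(ps, n_bins = 100) {
  stopifnot(inherits(ps, "posterior_samples"), n_bins >= 2)
  pooled <- range(c(ps$lambda1, ps$lambda2))
  if (diff(pooled) == 0) pooled <- pooled + c(-0.5, 0.5) * max(pooled[1], 1) * 1e-6
  breaks <- seq(pooled[1], pooled[2], length.out = n_bins + 1)
  hist_of <- function(x) {
    idx <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), n_bins)
    prob_hist(breaks, tabulate(idx, n_bins) / length(x))
  }
  list(p_lambda1 = hist_of(ps$lambda1), p_lambda2 = hist_of(ps$lambda2))
}

#' @rdname marginal_histograms
#' @param breaks Bin edges (length `n_bins + 1`).
#' @param prob Bin probabilities summing to 1.
#' @export
prob_hist <- function(breaks, prob) {
  stopifnot(length(breaks) == length(prob) + 1, all(diff(breaks) > 0),
            all(prob >= 0))
  structure(list(breaks = breaks, prob = prob), class = "prob_hist")
}

#' Hellinger distance between two binned distributions
#'
#' `HD = sqrt(0.5 * sum((sqrt(P_i) - sqrt(Q_i))^2))` over a shared bin
#' grid. Ranges from 0 (identical) to 1 (disjoint supports). Used as the
#' response-probability statistic: the distance between the posterior
#' marginals of the inside- and outside-interval rates.
#'
#' @param P,Q `prob_hist` objects on identical bin grids (each summing
#'   to 1).
#' @return The Hellinger distance in \[0, 1\].
#' @export
hellinger <- function(P, Q) {
  stopifnot(inherits(P, "prob_hist"), inherits(Q, "prob_hist"))
  if (length(P$breaks) != length(Q$breaks) ||
      max(abs(P$breaks - Q$breaks)) > 1e-9 * max(abs(P$breaks), 1)) {
    stop("P and Q must share one bin grid", call. = FALSE)
  }
  for (x in list(P$prob, Q$prob)) {
    if (abs(sum(x) - 1) > 1e-6) stop("probabilities must sum to 1", call. = FALSE)
  }
  min(1, sqrt(0.5 * sum((sqrt(P$prob) - sqrt(Q$prob))^2)))
}

#' Detect a stimulus-evoked deflection in a spike raster
#'
#' The full Bayesian response test: bin the raster, sample the
#' four-parameter response model posterior by Metropolis-Hastings, build
#' shared-support marginals of the two rates, and report the Hellinger
#' distance between them as the response probability. A response is
#' significant when the probability reaches `threshold`; deflections in
#' either direction (rate increases or suppression) are detected.
#'
#' @param r A [spike_raster()].
#' @param bin_width Histogram bin width in seconds (default 1 ms).
#' @param n_iter,burn_in Sampler iterations / burn-in (defaults 12000 /
#'   2000).
#' @param threshold Significance level on the Hellinger distance
#'   (default 0.95).
#' @param n_marginal_bins Shared marginal bins (default 100).
#' @param seed Optional integer seed.
#' @param keep_posterior Keep the posterior samples in the result
#'   (default TRUE; set FALSE to save memory in large sweeps).
#' @return A `response_decision` object with fields `probability`,
#'   `significant`, `magnitude_mean`/`magnitude_sd` (posterior of
#'   `lambda2 - lambda1`, spikes/bin trial-summed), `latency_mean_ms`/
#'   `latency_sd_ms` (posterior of `tau1`), `duration_mean_ms`,
#'   `acceptance_rate`, `n_kept`, `threshold`.
#' @export
detect_response <- function(r, bin_width = 0.001, n_iter = 12000,
                            burn_in = 2000, threshold = 0.95,
                            n_marginal_bins = 100, seed = NULL,
                            keep_posterior = TRUE) {
  stopifnot(inherits(r, "spike_raster"), n_trials(r) >= 1)
  h <- bin_raster(r, bin_width)
  ps <- metropolis_hastings(h, n_iter = n_iter, burn_in = burn_in, seed = seed)
  m <- marginal_histograms(ps, n_marginal_bins)
  hd <- hellinger(m$p_lambda1, m$p_lambda2)
  dmag <- ps$lambda2 - ps$lambda1
  out <- list(
    probability = hd,
    significant = hd >= threshold,
    magnitude_mean = mean(dmag),
    magnitude_sd = stats::sd(dmag),
    latency_mean_ms = mean(ps$tau1) * 1000,
    latency_sd_ms = stats::sd(ps$tau1) * 1000,
    duration_mean_ms = mean(ps$tau2) * 1000,
    acceptance_rate = attr(ps, "acceptance_rate"),
    n_kept = attr(ps, "n_kept"),
    threshold = threshold,
    marginals = m,
    posterior = if (keep_posterior) ps else NULL
  )
  class(out) <- "response_decision"
  out
}

#' Convert a trial-summed magnitude to spikes per second per trial
#'
#' The detector's magnitude is in spikes per bin summed across trials;
#' this converts to a per-trial firing-rate change.
#'
#' @param magnitude Spikes/bin summed over trials.
#' @param bin_width Bin width in seconds.
#' @param n_trials Number of trials.
#' @return Rate change in spikes/s per trial.
#' @export
magnitude_to_rate <- function(magnitude, bin_width = 0.001, n_trials = 20) {
  magnitude / (bin_width * n_trials)
}

#' @export
print.response_decision <- function(x, ...) {
  cat(sprintf(
    "Response probability = %.2f (%ssignificant at %.2f)\nMagnitude = %.2f +/- %.2f spikes/bin, Latency = %.2f +/- %.2f ms\n",
    x$probability, if (x$significant) "" else "not ", x$threshold,
    x$magnitude_mean, x$magnitude_sd, x$latency_mean_ms, x$latency_sd_ms))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.response_decision <- function(x, ...) {
  tibble::tibble(
    term = c("probability", "magnitude", "latency_ms", "duration_ms"),
    estimate = c(x$probability, x$magnitude_mean, x$latency_mean_ms,
                 x$duration_mean_ms),
    std.error = c(NA, x$magnitude_sd, x$latency_sd_ms, NA)
  )
}

#' @exportS3Method generics::glance
glance.response_decision <- function(x, ...) {
  tibble::tibble(
    probability = x$probability, significant = x$significant,
    magnitude_mean = x$magnitude_mean, magnitude_sd = x$magnitude_sd,
    latency_mean_ms = x$latency_mean_ms, latency_sd_ms = x$latency_sd_ms,
    acceptance_rate = x$acceptance_rate, n_kept = x$n_kept
  )
}

#' @exportS3Method generics::tidy
tidy.posterior_samples <- function(x, ...) {
  tibble::tibble(
    term = c("lambda1", "lambda2", "tau1", "tau2"),
    estimate = c(mean(x$lambda1), mean(x$lambda2), mean(x$tau1), mean(x$tau2)),
    std.error = c(stats::sd(x$lambda1), stats::sd(x$lambda2),
                  stats::sd(x$tau1), stats::sd(x$tau2))
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.response_decision <- function(object, ...) {
  m <- object$marginals
  mid <- function(ph) (head(ph$breaks, -1) + tail(ph$breaks, -1)) / 2
  df <- dplyr::bind_rows(
    tibble::tibble(rate = mid(m$p_lambda1), prob = m$p_lambda1$prob,
                   parameter = "lambda1 (background)"),
    tibble::tibble(rate = mid(m$p_lambda2), prob = m$p_lambda2$prob,
                   parameter = "lambda2 (response)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate, y = .data$prob,
                                   fill = .data$parameter)) +
    ggplot2::geom_col(position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "rate (spikes/bin, trial-summed)", y = "posterior probability",
                  subtitle = sprintf("Response probability = %.2f", object$probability))
}
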