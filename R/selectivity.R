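#' Selectivity index
#'
#' `SI = (Ct - Ce) / Ct`, where `Ct` is the number of stimuli presented
#' and `Ce` the number that evoked a significant response. 0 means the
#' cell responded to everything; values near 1 mean high selectivity.
#' Defined for cells that responded to at least one stimulus.
#'
#' @param c_total Number of stimuli presented (> 0).
#' @param c_evoked Number evoking a significant response
#'   (`0 <= c_evoked <= c_total`). Vectorized.
#' @return SI in \[0, 1\] (NA where `c_evoked == 0`: non-responders are
#'   excluded from the SI population, not an error).
#' @export
selectivity_index <- function(c_total, c_evoked) {
  if (any(c_total <= 0)) stop("c_total must be positive", call. = FALSE)
  if (any(c_evoked < 0 | c_evoked > c_total)) {
    stop("c_evoked must lie in [0, c_total]", call. = FALSE)
  }
  ifelse(c_evoked == 0, NA_real_, (c_total - c_evoked) / c_total)
}

#' Population selectivity summary
#'
#' Summarises a decision table over a cell population: per-cell SI
#' (responders only), the spread of responders across stimuli, whether
#' response counts relate to CF or to thresholds (least-squares r^2,
#' i.e. squared Pearson correlation), and a Welch two-sample t-test
#' comparing CF and broadband-noise thresholds between responders and
#' non-responders.
#'
#' @param decisions A tibble with columns `cell_id`, `stimulus_id`,
#'   `significant` (logical), e.g. from [run_experiment()] or built from
#'   [detect_response()] results.
#' @param cells A tibble with columns `cell_id`, `cf_khz`,
#'   `cf_threshold_db`, `bbn_threshold_db`.
#' @return A `selectivity_summary` object; see [tidy.selectivity_summary()]
#'   (per-cell table) and [glance.selectivity_summary()] (one-row
#'   population summary).
#' @export
population_summary <- function(decisions, cells) {
  need <- c("cell_id", "stimulus_id", "significant")
  stopifnot(all(need %in% names(decisions)))
  per_cell <- decisions |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(ct = dplyr::n(), ce = sum(.data$significant),
                     .groups = "drop") |>
    dplyr::mutate(si = selectivity_index(.data$ct, .data$ce),
                  responder = .data$ce > 0) |>
    dplyr::left_join(cells, by = "cell_id")

  per_stimulus <- decisions |>
    dplyr::group_by(.data$stimulus_id) |>
    dplyr::summarise(n_responders = sum(.data$significant), .groups = "drop")

  responders <- dplyr::filter(per_cell, .data$responder)
  r2 <- function(x, y) {
    if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
    stats::cor(x, y)^2
  }
  welch <- function(var) {
    a <- per_cell[[var]][per_cell$responder]
    b <- per_cell[[var]][!per_cell$responder]
    if (length(a) < 2 || length(b) < 2) {
      return(list(mean_responders = mean(a), sd_responders = stats::sd(a),
                  mean_nonresponders = mean(b), sd_nonresponders = stats::sd(b),
                  p_value = NA_real_))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    list(mean_responders = mean(a), sd_responders = stats::sd(a),
         mean_nonresponders = mean(b), sd_nonresponders = stats::sd(b),
         p_value = tt$p.value)
  }

  structure(list(
    per_cell = per_cell,
    per_stimulus = per_stimulus,
    median_si = if (nrow(responders) > 0) stats::median(responders$si) else NA_real_,
    responders_per_stimulus_mean = mean(per_stimulus$n_responders),
    responders_per_stimulus_sd = stats::sd(per_stimulus$n_responders),
    r2_cf_vs_nresponses = r2(responders$cf_khz, responders$ce),
    r2_cfthr_vs_nresponses = r2(responders$cf_threshold_db, responders$ce),
    r2_bbnthr_vs_nresponses = r2(responders$bbn_threshold_db, responders$ce),
    cf_threshold_comparison = welch("cf_threshold_db"),
    bbn_threshold_comparison = welch("bbn_threshold_db")
  ), class = "selectivity_summary")
}

#' @export
print.selectivity_summary <- function(x, ...) {
  cat(sprintf(
    "Selectivity summary: %d cells (%d responders)\nmedian SI = %.2f; responders per stimulus = %.2f +/- %.2f\nr2 (CF, CF thr, BBN thr vs #responses) = %.2f, %.2f, %.2f\n",
    nrow(x$per_cell), sum(x$per_cell$responder), x$median_si,
    x$responders_per_stimulus_mean, x$responders_per_stimulus_sd,
    x$r2_cf_vs_nresponses, x$r2_cfthr_vs_nresponses,
    x$r2_bbnthr_vs_nresponses))
  invisible(x)
}

#' Per-cell selectivity table
#'
#' @param x A `selectivity_summary`.
#' @param ... Unused.
#' @return Tibble with one row per cell: `cell_id`, `ct`, `ce`, `si`,
#'   `responder` plus the cell metadata columns.
#' @exportS3Method generics::tidy
tidy.selectivity_summary <- function(x, ...) x$per_cell

#' One-row population summary
#'
#' @param x A `selectivity_summary`.
#' @param ... Unused.
#' @return One-row tibble of the population statistics.
#' @exportS3Method generics::glance
glance.selectivity_summary <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$per_cell),
    n_responders = sum(x$per_cell$responder),
    median_si = x$median_si,
    responders_per_stimulus_mean = x$responders_per_stimulus_mean,
    responders_per_stimulus_sd = x$responders_per_stimulus_sd,
    r2_cf_vs_nresponses = x$r2_cf_vs_nresponses,
    r2_cfthr_vs_nresponses = x$r2_cfthr_vs_nresponses,
    r2_bbnthr_vs_nresponses = x$r2_bbnthr_vs_nresponses,
    cf_thr_p = x$cf_threshold_comparison$p_value,
    bbn_thr_p = x$bbn_threshold_comparison$p_value
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.selectivity_summary <- function(object, ...) {
  df <- dplyr::filter(object$per_cell, .data$responder)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$si)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 1) +
    ggplot2::geom_vline(xintercept = object$median_si, linetype = 2) +
    ggplot2::labs(x = "selectivity index", y = "cells",
                  subtitle = sprintf("median SI = %.2f", object$median_si))
}
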