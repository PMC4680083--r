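#' Rate-independent spike-train similarity
#'
#' Temporal similarity between two rasters: each trial's spike train is
#' smoothed with a Gaussian kernel, normalized to unit L2 norm (making
#' the measure insensitive to uniform rate scaling), and the score is the
#' mean inner product over all cross-raster trial pairs. When `a` and `b`
#' are the same raster, same-index trial pairs (a trial against itself)
#' are excluded, so the self-similarity of a noisy response is below 1
#' and directly comparable to the cross-similarity of two responses.
#'
#' Identical, perfectly repeated spike trains score 1; rasters with no
#' common temporal structure score near the chance overlap set by the
#' kernel width; a raster with no spikes at all scores 0.
#'
#' @param a,b [spike_raster()]s with equal cycle durations.
#' @param kernel_width Gaussian kernel standard deviation in seconds
#'   (default 5 ms).
#' @param dt Evaluation grid step in seconds (default 0.5 ms).
#' @param exclude_diagonal Exclude same-index trial pairs? Default: auto
#'   (`TRUE` when `a` and `b` are identical objects).
#' @return Similarity score in \[0, 1\].
#' @export
spike_similarity <- function(a, b, kernel_width = 0.005, dt = 5e-4,
                             exclude_diagonal = NULL) {
  stopifnot(inherits(a, "spike_raster"), inherits(b, "spike_raster"))
  if (abs(cycle_duration(a) - cycle_duration(b)) > 1e-9) {
    stop("rasters must share one cycle duration", call. = FALSE)
  }
  if (is.null(exclude_diagonal)) exclude_diagonal <- identical(a, b)
  grid <- seq(0, cycle_duration(a), by = dt)
  smooth_unit <- function(spikes) {
    if (length(spikes) == 0) return(numeric(length(grid)))
    f <- rowSums(vapply(spikes, function(s) stats::dnorm(grid, s, kernel_width),
                        numeric(length(grid))))
    nrm <- sqrt(sum(f^2))
    if (nrm == 0) numeric(length(grid)) else f / nrm
  }
  fa <- vapply(raster_trials(a), smooth_unit, numeric(length(grid)))
  fb <- vapply(raster_trials(b), smooth_unit, numeric(length(grid)))
  gram <- crossprod(fa, fb)                     # n_trials(a) x n_trials(b)
  keep <- matrix(TRUE, nrow(gram), ncol(gram))
  if (exclude_diagonal) {
    k <- min(dim(gram))
    keep[cbind(seq_len(k), seq_len(k))] <- FALSE
  }
  if (!any(keep)) return(0)
  mean(gram[keep])
}
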