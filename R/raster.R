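#' Trial-stamped spike raster
#'
#' Spike times from repeated presentations of one stimulus, expressed in
#' seconds from the onset of each stimulus cycle. Stored as a tibble with
#' columns `trial` and `time` plus attributes `cycle_duration` and
#' `n_trials`; trials with no spikes are represented implicitly (the
#' trial index simply does not appear).
#'
#' @param spikes A data frame with columns `trial` (integer, 1-based) and
#'   `time` (seconds), or NULL/empty for a silent raster.
#' @param cycle_duration Stimulus cycle duration in seconds (default
#'   1/3 s, a 3 Hz repetition rate).
#' @param n_trials Number of stimulus repetitions (default 20).
#' @return A `spike_raster` tibble.
#' @export
spike_raster <- function(spikes = NULL, cycle_duration = 1 / 3, n_trials = 20) {
  stopifnot(cycle_duration > 0, n_trials >= 1)
  if (is.null(spikes) || nrow(spikes) == 0) {
    spikes <- tibble::tibble(trial = integer(), time = numeric())
  }
  spikes <- tibble::as_tibble(spikes)[c("trial", "time")]
  spikes$trial <- as.integer(spikes$trial)
  if (nrow(spikes) > 0) {
    if (any(spikes$time < 0)) stop("negative spike time", call. = FALSE)
    if (any(spikes$time >= cycle_duration)) {
      stop("spike time at or beyond cycle_duration", call. = FALSE)
    }
    if (any(spikes$trial < 1 | spikes$trial > n_trials)) {
      stop("trial index outside 1..n_trials", call. = FALSE)
    }
    spikes <- dplyr::arrange(spikes, .data$trial, .data$time)
    dup <- unlist(tapply(spikes$time, spikes$trial,
                         function(x) duplicated(x)), use.names = FALSE)
    if (any(dup)) stop("duplicate spike times within a trial", call. = FALSE)
  }
  attr(spikes, "cycle_duration") <- cycle_duration
  attr(spikes, "n_trials") <- as.integer(n_trials)
  class(spikes) <- c("spike_raster", class(spikes))
  spikes
}

#' @rdname spike_raster
#' @param r A `spike_raster`.
#' @export
cycle_duration <- function(r) attr(r, "cycle_duration")

#' @rdname spike_raster
#' @export
n_trials <- function(r) attr(r, "n_trials")

# spike times per trial (list of length n_trials; empty trials included)
raster_trials <- function(r) {
  out <- vector("list", n_trials(r))
  for (i in seq_len(n_trials(r))) out[[i]] <- numeric()
  if (nrow(r) > 0) {
    sp <- split(r$time, factor(r$trial, levels = seq_len(n_trials(r))))
    for (i in seq_along(sp)) out[[i]] <- sp[[i]]
  }
  out
}

#' Bin a raster into a trial-summed peristimulus time histogram
#'
#' Counts spikes from all trials in half-open bins `[i*bw, (i+1)*bw)`.
#' The number of bins is `ceiling(cycle_duration / bin_width)`, so the
#' last bin may be partial when the bin width does not divide the cycle
#' exactly.
#'
#' @param r A [spike_raster()].
#' @param bin_width Bin width in seconds (default 1 ms).
#' @return A `binned_histogram` tibble with columns `time` (left bin
#'   edge, s) and `count`, plus attributes `bin_width`, `n_trials`,
#'   `cycle_duration`.
#' @export
bin_raster <- function(r, bin_width = 0.001) {
  stopifnot(inherits(r, "spike_raster"), bin_width > 0)
  cyc <- cycle_duration(r)
  nb <- as.integer(ceiling(cyc / bin_width - 1e-9))
  counts <- integer(nb)
  if (nrow(r) > 0) {
    idx <- pmin(floor(r$time / bin_width) + 1L, nb)
    tb <- tabulate(idx, nbins = nb)
    counts <- as.integer(tb)
  }
  out <- tibble::tibble(time = (seq_len(nb) - 1) * bin_width, count = counts)
  attr(out, "bin_width") <- bin_width
  attr(out, "n_trials") <- n_trials(r)
  attr(out, "cycle_duration") <- cyc
  class(out) <- c("binned_histogram", class(out))
  out
}

#' Read / write raster CSVs
#'
#' The raster interchange format is one row per spike with columns
#' `cell_id`, `stimulus_id`, `trial_index`, `spike_time_s` (header
#' required).
#'
#' @param path CSV path.
#' @param cycle_duration,n_trials Raster geometry applied to every
#'   (cell, stimulus) group.
#' @return `read_raster_csv()`: a tibble with one row per (cell,
#'   stimulus) and a list-column `raster` of [spike_raster()]s.
#' @export
read_raster_csv <- function(path, cycle_duration = 1 / 3, n_trials = 20) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("cell_id", "stimulus_id", "trial_index", "spike_time_s")
  if (!all(need %in% names(df))) {
    stop("raster CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  # data.frame (not tibble) inside summarise: tibble() would install its
  # own data mask and capture the .data pronoun
  df |>
    dplyr::group_by(.data$cell_id, .data$stimulus_id) |>
    dplyr::summarise(raster = list(spike_raster(
      data.frame(trial = .data$trial_index, time = .data$spike_time_s),
      cycle_duration = cycle_duration, n_trials = n_trials)),
      .groups = "drop")
}

#' @rdname read_raster_csv
#' @param rasters A tibble with columns `cell_id`, `stimulus_id` and a
#'   list-column `raster` of [spike_raster()]s.
#' @export
write_raster_csv <- function(rasters, path) {
  rows <- purrr::pmap(rasters[c("cell_id", "stimulus_id", "raster")],
    function(cell_id, stimulus_id, raster) {
      if (nrow(raster) == 0) return(NULL)
      tibble::tibble(cell_id = cell_id, stimulus_id = stimulus_id,
                     trial_index = raster$trial, spike_time_s = raster$time)
    })
  utils::write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.spike_raster <- function(object, bin_width = 0.005, ...) {
  h <- bin_raster(object, bin_width)
  p_raster <- ggplot2::ggplot(object,
    ggplot2::aes(x = .data$time * 1000, y = .data$trial)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::labs(x = NULL, y = "trial")
  p_psth <- ggplot2::ggplot(h,
    ggplot2::aes(x = .data$time * 1000, y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 1000) +
    ggplot2::labs(x = "time (ms)", y = "spikes/bin")
  if (requireNamespace("patchwork", quietly = TRUE)) {
    patchwork::wrap_plots(p_raster, p_psth, ncol = 1)
  } else {
    p_psth
  }
}
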