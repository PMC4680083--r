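#' PSD heat map of a stimulus set
#'
#' One row per stimulus, rows ordered by the frequency of peak power,
#' color giving power in dB relative to the loudest stimulus in the set
#' -- the standard at-a-glance view of where a suite's spectral energy
#' lies before and after cochlear distortion.
#'
#' @param waves List of [waveform()]s.
#' @param ids Character stimulus ids (same length).
#' @param resolution PSD resolution in Hz (default 1000).
#' @param floor_db Display floor in dB (default -80).
#' @param f_max Highest frequency shown, Hz (default 120 kHz).
#' @return A ggplot object.
#' @export
plot_psd_heatmap <- function(waves, ids, resolution = 1000, floor_db = -80,
                             f_max = 120000) {
  stopifnot(length(waves) == length(ids))
  psds <- purrr::map(waves, psd, resolution = resolution)
  ref <- max(purrr::map_dbl(psds, ~ max(.x$power)))
  df <- purrr::map2(psds, ids, function(p, id) {
    tibble::tibble(stimulus_id = id, frequency = p$frequency,
                   power_db = 10 * log10(pmax(p$power, .Machine$double.xmin) / ref),
                   peak_f = p$frequency[which.max(p$power)])
  }) |> dplyr::bind_rows() |>
    dplyr::filter(.data$frequency <= f_max)
  ord <- df |> dplyr::distinct(.data$stimulus_id, .data$peak_f) |>
    dplyr::arrange(.data$peak_f)
  df$stimulus_id <- factor(df$stimulus_id, levels = ord$stimulus_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency / 1000,
                                   y = .data$stimulus_id,
                                   fill = pmax(.data$power_db, floor_db))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "dB re max") +
    ggplot2::labs(x = "frequency (kHz)", y = NULL)
}

#' Tone-battery response of a model cell
#'
#' Presents a series of pure tones and collects the model cell's raster
#' for each: the raw material of a spectral-temporal histogram, which
#' exposes excitatory and inhibitory frequency regions together with
#' their timing.
#'
#' @param cell A `model_cell`.
#' @param freqs Tone frequencies in Hz (default 11 tones, 10--50 kHz).
#' @param duration Tone duration in seconds (default 50 ms).
#' @param n_trials,cycle Raster geometry.
#' @param sample_rate Hz.
#' @param seed Optional integer seed.
#' @return Tibble with columns `frequency` and list-column `raster`.
#' @export
tone_battery_response <- function(cell, freqs = seq(10e3, 50e3, length.out = 11),
                                  duration = 0.05, n_trials = 20,
                                  cycle = 1 / 3, sample_rate = 400000,
                                  seed = NULL) {
  seeds <- derive_seeds(seed %||% 1, length(freqs), "tones")
  tibble::tibble(
    frequency = freqs,
    raster = purrr::map2(freqs, seeds, function(f, s) {
      tone <- generate_usv(syllable_spec("flat", f, duration = duration),
                           sample_rate)
      model_cell_response(cell, tone, n_trials = n_trials, cycle = cycle,
                          seed = s)
    })
  )
}

#' Spectral-temporal histogram
#'
#' Stacks the peristimulus time histograms of a tone battery: one row
#' per tone frequency, time on the x axis, spike count as color.
#' Excitatory bands appear as bright rows during the stimulus;
#' inhibitory sidebands as dark rows that can outlast it.
#'
#' @param battery Output of [tone_battery_response()].
#' @param bin_width PSTH bin width in seconds (default 5 ms).
#' @return A ggplot object.
#' @export
plot_spectral_temporal <- function(battery, bin_width = 0.005) {
  df <- purrr::map2(battery$raster, battery$frequency, function(r, f) {
    h <- bin_raster(r, bin_width)
    tibble::tibble(frequency = f, time = h$time, count = h$count)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time * 1000,
                                   y = factor(.data$frequency / 1000),
                                   fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "spikes/bin") +
    ggplot2::labs(x = "time (ms)", y = "tone frequency (kHz)")
}

#' Export the figure bundle for an experiment
#'
#' Writes the stimulus-set PSD heat maps (original and distorted), the
#' per-pair PSTH comparison grid, and per-stimulus PSD CSVs. Missing
#' components are skipped with a warning rather than failing the whole
#' export; an empty results object produces an empty bundle.
#'
#' @param results A `dcnvoc_results` from [run_experiment()].
#' @param outdir Output directory (created if needed).
#' @param width,height Device size in inches.
#' @return Character vector of files written, invisibly.
#' @export
export_figures <- function(results, outdir, width = 7, height = 6) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  save_fig <- function(name, expr) {
    path <- file.path(outdir, name)
    ok <- tryCatch({
      p <- expr()
      ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
      TRUE
    }, error = function(e) {
      warning("skipping figure ", name, ": ", conditionMessage(e),
              call. = FALSE)
      FALSE
    })
    if (ok) written <<- c(written, path)
  }
  if (nrow(results$stimuli) > 0) {
    save_fig("psd_original.png", function() {
      plot_psd_heatmap(results$stimuli$wave, results$stimuli$stimulus_id)
    })
    save_fig("psd_distorted.png", function() {
      plot_psd_heatmap(results$stimuli$distorted, results$stimuli$stimulus_id)
    })
  }
  if (nrow(results$rasters) > 0) {
    save_fig("psth_pairs.png", function() {
      df <- purrr::pmap(results$rasters[c("cell_id", "stimulus_id", "variant",
                                          "raster")],
        function(cell_id, stimulus_id, variant, raster) {
          h <- bin_raster(raster, 0.005)
          tibble::tibble(cell_id = cell_id, stimulus_id = stimulus_id,
                         variant = variant, time = h$time, count = h$count)
        }) |> dplyr::bind_rows()
      ggplot2::ggplot(df, ggplot2::aes(x = .data$time * 1000, y = .data$count,
                                       fill = .data$variant)) +
        ggplot2::geom_col(position = "identity", alpha = 0.5) +
        ggplot2::facet_grid(cell_id ~ stimulus_id) +
        ggplot2::labs(x = "time (ms)", y = "spikes/bin")
    })
  }
  for (i in seq_len(nrow(results$stimuli))) {
    path <- file.path(outdir, paste0("psd_", results$stimuli$stimulus_id[i], ".csv"))
    write_psd_csv(psd(results$stimuli$distorted[[i]]), path)
    written <- c(written, path)
  }
  invisible(written)
}
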