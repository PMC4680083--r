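#' Configuration for an end-to-end simulated experiment
#'
#' Bundles every tunable of the pipeline. Defaults reproduce the study
#' conditions: a 35-syllable ultrasonic suite presented for 20
#' repetitions at a 3 Hz cycle, a nonlinear cochlea with 1 ms / 2 ms
#' reverberation and the default Boltzmann stage, 40 kHz band-splitting,
#' 1 ms histogram bins and a 0.95 Hellinger significance level.
#'
#' @param suite Tibble of syllable specs (default [usv_suite_default35()]).
#' @param sample_rate Stimulus sample rate, Hz.
#' @param reverb,boltz Cochlea stage parameters.
#' @param level Drive level into the nonlinearity (see
#'   [apply_cochlea_filter()]).
#' @param distortion_enabled If FALSE the ear is linear (reverberation
#'   only) -- the control condition in which high-pass-filtered
#'   ultrasonic stimuli reach low-CF cells unchanged and should evoke
#'   nothing.
#' @param cells Model-cell population tibble (default
#'   [model_cell_population()] with 8 cells, built from `seed`).
#' @param n_trials,cycle Raster geometry (defaults 20, 1/3 s).
#' @param bin_width,n_iter,burn_in,threshold,n_marginal_bins Detection
#'   parameters (see [detect_response()]).
#' @param seed Master integer seed; every stochastic stage derives its
#'   own stream from it.
#' @return A `run_config` list.
#' @export
run_config <- function(suite = usv_suite_default35(),
                       sample_rate = 400000,
                       reverb = reverb_params(),
                       boltz = boltzmann_params(),
                       level = 1,
                       distortion_enabled = TRUE,
                       cells = NULL,
                       n_trials = 20,
                       cycle = 1 / 3,
                       bin_width = 0.001,
                       n_iter = 12000,
                       burn_in = 2000,
                       threshold = 0.95,
                       n_marginal_bins = 100,
                       seed = 1) {
  if (is.null(cells)) cells <- model_cell_population(seed = seed)
  structure(list(
    suite = suite, sample_rate = sample_rate, reverb = reverb, boltz = boltz,
    level = level, distortion_enabled = distortion_enabled, cells = cells,
    n_trials = n_trials, cycle = cycle, bin_width = bin_width,
    n_iter = n_iter, burn_in = burn_in, threshold = threshold,
    n_marginal_bins = n_marginal_bins, seed = as.integer(seed)
  ), class = "run_config")
}

# deterministic per-(stage, index) seed stream derived from the master seed
derive_seeds <- function(seed, n, stage) {
  offset <- sum(utf8ToInt(stage)) * 10007L
  (as.integer(seed) + offset + 911L * seq_len(n)) %% .Machine$integer.max
}

#' Run the end-to-end simulated experiment
#'
#' Pipeline stages, mirroring the experimental logic:
#' 1. Synthesize the stimulus suite (all spectral energy at/above 50 kHz).
#' 2. Build the two presentation variants per stimulus: the original
#'    high-passed at 40 kHz (`original_hp`) and the cochlea-distorted
#'    version low-passed at 40 kHz so only distortion products remain
#'    (`distorted_lp`).
#' 3. Pass each presented variant through the ear model (the nonlinear
#'    cochlea filter, or reverberation only when
#'    `distortion_enabled = FALSE`).
#' 4. Simulate each model cell's spike raster for each variant and run
#'    the Bayesian response detector on it.
#' 5. Compare decisions within each (cell, stimulus) pair and compute
#'    within-pair vs cross-cell spike-train similarity.
#' 6. Summarise selectivity across the population (on the `original_hp`
#'    condition).
#'
#' Fully deterministic given `config$seed`.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory; when given, writes
#'   `decisions.csv`, `pairs.csv`, `rasters.csv`, `summary.json` and a
#'   provenance `manifest.json`.
#' @param verbose Print stage progress? Default FALSE.
#' @return A `dcnvoc_results` list: `decisions` (tibble: one row per
#'   cell x stimulus x variant), `pairs` (tibble: per cell x stimulus
#'   agreement and similarity), `selectivity` (a `selectivity_summary`),
#'   `rasters` (tibble with list-column), `stimuli` (tibble with
#'   waveform list-columns), `config`.
#' @export
run_experiment <- function(config, outdir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("stage 1/6: synthesizing %d stimuli", nrow(config$suite))
  stimuli <- config$suite |>
    dplyr::mutate(wave = purrr::map(seq_len(dplyr::n()), function(i) {
      generate_usv(config$suite[i, ], config$sample_rate)
    }))

  say("stage 2/6: cochlea filtering and band splitting")
  stimuli <- stimuli |>
    dplyr::mutate(
      original_hp = purrr::map(.data$wave, highpass_40k),
      distorted = purrr::map(.data$wave, apply_cochlea_filter,
                             reverb = config$reverb, boltz = config$boltz,
                             level = config$level),
      distorted_lp = purrr::map(.data$distorted, lowpass_40k)
    )

  say("stage 3/6: ear processing")
  # the ear receives stimuli at their native levels (normalize_input =
  # FALSE): the band-limited distortion-product stimulus is quieter than
  # the full original, exactly as presented
  ear <- function(w) {
    if (config$distortion_enabled) {
      apply_cochlea_filter(w, config$reverb, config$boltz, config$level,
                           normalize_input = FALSE)
    } else {
      reverberate(w, config$reverb)
    }
  }
  stimuli <- stimuli |>
    dplyr::mutate(ear_original = purrr::map(.data$original_hp, ear),
                  ear_distorted = purrr::map(.data$distorted_lp, ear))

  say("stage 4/6: %d cells x %d stimuli x 2 variants: rasters + detection",
      nrow(config$cells), nrow(stimuli))
  grid <- tidyr::expand_grid(
    cell_idx = seq_len(nrow(config$cells)),
    stim_idx = seq_len(nrow(stimuli)),
    variant = c("original_hp", "distorted_lp")
  )
  seeds_r <- derive_seeds(config$seed, nrow(grid), "raster")
  seeds_d <- derive_seeds(config$seed, nrow(grid), "detect")
  res <- purrr::pmap(list(grid$cell_idx, grid$stim_idx, grid$variant,
                          seeds_r, seeds_d),
    function(ci, si, variant, sr, sd_) {
      cell <- config$cells$cell[[ci]]
      w <- if (variant == "original_hp") stimuli$ear_original[[si]] else
        stimuli$ear_distorted[[si]]
      raster <- model_cell_response(cell, w, n_trials = config$n_trials,
                                    cycle = config$cycle, seed = sr)
      dec <- detect_response(raster, bin_width = config$bin_width,
                             n_iter = config$n_iter, burn_in = config$burn_in,
                             threshold = config$threshold,
                             n_marginal_bins = config$n_marginal_bins,
                             seed = sd_, keep_posterior = FALSE)
      list(raster = raster, decision = glance(dec))
    })
  decisions <- dplyr::bind_rows(purrr::map(res, "decision")) |>
    dplyr::mutate(cell_id = config$cells$cell_id[grid$cell_idx],
                  stimulus_id = stimuli$stimulus_id[grid$stim_idx],
                  variant = grid$variant, .before = 1)
  rasters <- tibble::tibble(
    cell_id = config$cells$cell_id[grid$cell_idx],
    stimulus_id = stimuli$stimulus_id[grid$stim_idx],
    variant = grid$variant,
    raster = purrr::map(res, "raster"))

  say("stage 5/6: paired comparison and similarity")
  pairs <- pair_comparison(decisions, rasters)

  say("stage 6/6: selectivity summary")
  natural <- dplyr::filter(decisions, .data$variant == "original_hp")
  selectivity <- population_summary(
    dplyr::select(natural, "cell_id", "stimulus_id", "significant"),
    dplyr::select(config$cells, "cell_id", "cf_khz", "cf_threshold_db",
                  "bbn_threshold_db"))

  out <- structure(list(decisions = decisions, pairs = pairs,
                        selectivity = selectivity, rasters = rasters,
                        stimuli = stimuli, config = config,
                        elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                   class = "dcnvoc_results")
  if (!is.null(outdir)) write_results(out, outdir)
  out
}

# per (cell, stimulus): do the original-band and distortion-band decisions
# agree, and is the within-pair response similarity above cross-cell level?
pair_comparison <- function(decisions, rasters) {
  wide <- decisions |>
    dplyr::select("cell_id", "stimulus_id", "variant", "significant") |>
    tidyr::pivot_wider(names_from = "variant", values_from = "significant")
  sim_within <- purrr::pmap_dbl(wide[c("cell_id", "stimulus_id")],
    function(cell_id, stimulus_id) {
      ra <- raster_lookup(rasters, cell_id, stimulus_id, "original_hp")
      rb <- raster_lookup(rasters, cell_id, stimulus_id, "distorted_lp")
      spike_similarity(ra, rb)
    })
  # cross-cell reference: original response of this cell vs distortion
  # response of the "next" cell to the same stimulus
  cells <- unique(wide$cell_id)
  sim_cross <- purrr::pmap_dbl(wide[c("cell_id", "stimulus_id")],
    function(cell_id, stimulus_id) {
      if (length(cells) < 2) return(NA_real_)
      other <- cells[(match(cell_id, cells) %% length(cells)) + 1]
      ra <- raster_lookup(rasters, cell_id, stimulus_id, "original_hp")
      rb <- raster_lookup(rasters, other, stimulus_id, "distorted_lp")
      spike_similarity(ra, rb)
    })
  wide |>
    dplyr::mutate(
      responding = .data$original_hp | .data$distorted_lp,
      agree = .data$original_hp == .data$distorted_lp,
      similarity_within = sim_within,
      similarity_cross = sim_cross)
}

raster_lookup <- function(rasters, cell, stim, variant) {
  i <- which(rasters$cell_id == cell & rasters$stimulus_id == stim &
               rasters$variant == variant)
  rasters$raster[[i[1]]]
}

#' @export
print.dcnvoc_results <- function(x, ...) {
  resp <- dplyr::filter(x$pairs, .data$responding)
  cat(sprintf(
    "<dcnvoc_results: %d cells x %d stimuli>\n%d significant decisions; %d responding pairs, %.0f%% agreement\nmedian SI = %.2f; elapsed %.1f s\n",
    nrow(x$config$cells), nrow(x$stimuli),
    sum(x$decisions$significant), nrow(resp),
    if (nrow(resp) > 0) 100 * mean(resp$agree) else NA,
    x$selectivity$median_si, x$elapsed_s))
  invisible(x)
}

write_results <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$decisions, file.path(outdir, "decisions.csv"),
                   row.names = FALSE)
  utils::write.csv(results$pairs, file.path(outdir, "pairs.csv"),
                   row.names = FALSE)
  write_raster_csv(results$rasters |>
                     dplyr::mutate(stimulus_id = paste(.data$stimulus_id,
                                                       .data$variant, sep = ":")),
                   file.path(outdir, "rasters.csv"))
  summary_json <- list(
    selectivity = as.list(glance(results$selectivity)),
    pairs = list(
      n_responding = sum(results$pairs$responding),
      agreement = mean(results$pairs$agree[results$pairs$responding]),
      similarity_within_mean = mean(results$pairs$similarity_within),
      similarity_cross_mean = mean(results$pairs$similarity_cross)
    )
  )
  jsonlite::write_json(summary_json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cfg <- results$config
  manifest <- list(
    seed = cfg$seed,
    n_stimuli = nrow(cfg$suite),
    n_cells = nrow(cfg$cells),
    n_trials = cfg$n_trials,
    cycle_s = cfg$cycle,
    distortion_enabled = cfg$distortion_enabled,
    detection = list(bin_width = cfg$bin_width, n_iter = cfg$n_iter,
                     burn_in = cfg$burn_in, threshold = cfg$threshold),
    package_version = as.character(utils::packageVersion("dcnvoc"))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Load a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()] (nested `reverb:` and
#' `boltzmann:` blocks mirror [reverb_params()] / [boltzmann_params()]).
#' Unknown keys are an error, so typos in scientific parameters fail
#' loudly instead of silently running defaults.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("sample_rate", "level", "distortion_enabled", "n_trials",
             "cycle", "bin_width", "n_iter", "burn_in", "threshold",
             "n_marginal_bins", "seed", "n_cells", "cf_range_hz",
             "reverb", "boltzmann")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  rv <- do.call(reverb_params, as.list(y$reverb %||% list()))
  bz <- do.call(boltzmann_params, as.list(y$boltzmann %||% list()))
  args <- y[setdiff(names(y), c("reverb", "boltzmann", "n_cells", "cf_range_hz"))]
  cells <- NULL
  if (!is.null(y$n_cells)) {
    cells <- model_cell_population(
      n = y$n_cells,
      cf_range = y$cf_range_hz %||% c(10e3, 35e3),
      seed = y$seed %||% 1)
  }
  do.call(run_config, c(args, list(reverb = rv, boltz = bz, cells = cells)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
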