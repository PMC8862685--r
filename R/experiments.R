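# Experiment orchestration: named presets, config parsing, output tables.

#' Write / read spike trains as one-column spike-time text
#'
#' @param spike_times Spike times (ms).
#' @param path File path.
#' @return `read_spike_times` returns a numeric vector of times (ms).
#' @export
write_spike_times <- function(spike_times, path) {
  utils::write.table(data.frame(time_ms = spike_times), path,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spike_times
#' @export
read_spike_times <- function(path) {
  utils::read.table(path, header = TRUE)$time_ms
}

#' Parse a plain-text key/value experiment config
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers where possible, otherwise kept as strings.
#'
#' @param path Config file path.
#' @return Named list of settings.
#' @export
read_experiment_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

default_sweep <- function(f_max = 1000, n = 20) {
  unique(c(5, round(exp(seq(log(5), log(f_max), length.out = n)), 1)))
}

experiment_registry <- function() {
  list(
    fig1 = function(cfg) {
      freqs <- default_sweep(cfg$f_max %||% 600, cfg$n_freqs %||% 16)
      list(
        ffei = transmission_sweep(
          triad_runner("ffei", seed = cfg$seed, duration = cfg$duration,
                       tau_fall_i = cfg$tau_fall_i %||% 20),
          freqs, n_trials = cfg$n_trials),
        ffe = transmission_sweep(
          triad_runner("ffe", seed = cfg$seed, duration = cfg$duration),
          freqs, n_trials = cfg$n_trials))
    },
    fig2 = function(cfg) {
      freqs <- default_sweep(cfg$f_max %||% 200, cfg$n_freqs %||% 12)
      amp <- cfg$amplitude %||%
        model_parameters()$current_injection$amplitude_na
      inj_runner <- function(F, trial) {
        run_current_injection(F, amp, n_trials = 1,
                              duration = cfg$duration)$trials[[1]]
      }
      list(injection = transmission_sweep(inj_runner, freqs, n_trials = 1),
           ffei = transmission_sweep(
             triad_runner("ffei", seed = cfg$seed, duration = cfg$duration),
             freqs, n_trials = cfg$n_trials))
    },
    fig4 = function(cfg) {
      freqs <- default_sweep(cfg$f_max %||% 600, cfg$n_freqs %||% 14)
      rows <- model_parameters()$triad_delay_rows
      rows <- rbind(data.frame(delta_ms = 1, P_max_ei_us = 1.21), rows)
      out <- lapply(seq_len(nrow(rows)), function(i) {
        transmission_sweep(
          triad_runner("ffei", seed = cfg$seed, duration = cfg$duration,
                       P_max_e = rows$P_max_ei_us[i],
                       P_max_i = rows$P_max_ei_us[i],
                       delay = rows$delta_ms[i]),
          freqs, n_trials = cfg$n_trials)
      })
      names(out) <- paste0("delta_", rows$delta_ms, "ms")
      out
    },
    fig5 = function(cfg) {
      freqs <- default_sweep(cfg$f_max %||% 500, cfg$n_freqs %||% 12)
      lapply(stats::setNames(c("ffei", "ffe", "nc"),
                             c("ffei", "ffe", "nc")), function(mode) {
        transmission_sweep(
          multilevel_runner(mode, seed = cfg$seed, duration = cfg$duration),
          freqs, n_trials = cfg$n_trials)
      })
    },
    fig6 = function(cfg) {
      freqs <- default_sweep(cfg$f_max %||% 100, cfg$n_freqs %||% 8)
      lapply(stats::setNames(c("mixed", "single"), c("mixed", "single")),
             function(mode) {
        transmission_sweep(
          xor_runner(mode, seed = cfg$seed, duration = cfg$duration),
          freqs, n_trials = cfg$n_trials,
          measure_freq = function(F) 2 * F)
      })
    },
    fig9 = function(cfg) {
      freqs <- default_sweep(cfg$f_max %||% 200, cfg$n_freqs %||% 12)
      list(
        ffei = transmission_sweep(
          cortical_runner("ffei", seed = cfg$seed, duration = cfg$duration,
                          tau_m_I = cfg$tau_m_I %||% 10),
          freqs, n_trials = cfg$n_trials),
        ffe = transmission_sweep(
          cortical_runner("ffe", seed = cfg$seed, duration = cfg$duration),
          freqs, n_trials = cfg$n_trials))
    },
    t3 = function(cfg) {
      res <- run_triad(F = 5, n_trials = cfg$n_trials, seed = cfg$seed,
                       duration = cfg$duration)
      fc <- vapply(res$trials, function(tr) {
        fourier_coefficient(tr$grid, tr$spike_times, 5)
      }, numeric(1))
      list(fc_f_5hz = mean(fc))
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a named experiment preset
#'
#' Executes one of the shipped experiment presets (`fig1`, `fig2`, `fig4`,
#' `fig5`, `fig6`, `fig9`, `t3`) deterministically from a seed, writing
#' per-condition transmission-curve CSVs and a JSON manifest (parameters,
#' seed, runtime) to `out_dir`.
#'
#' @param experiment Preset name, or a config-file path (see
#'   [read_experiment_config()]) containing an `experiment` key plus
#'   overrides (`seed`, `n_trials`, `duration`, `f_max`, `n_freqs`, ...).
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @param n_trials Trials per frequency point.
#' @param duration Trial length (ms).
#' @param ... Additional overrides merged into the config.
#' @return Invisibly, the list of per-condition results.
#' @export
run_experiment <- function(experiment, out_dir = ".", seed = 1,
                           n_trials = 10, duration = 5000, ...) {
  cfg <- list(seed = seed, n_trials = n_trials, duration = duration, ...)
  if (file.exists(experiment) && !experiment %in%
        names(experiment_registry())) {
    file_cfg <- read_experiment_config(experiment)
    experiment <- file_cfg$experiment
    file_cfg$experiment <- NULL
    cfg[names(file_cfg)] <- file_cfg
  }
  reg <- experiment_registry()
  if (!experiment %in% names(reg)) {
    stop("unknown experiment preset: ", experiment, call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  results <- reg[[experiment]](cfg)
  elapsed <- proc.time()[["elapsed"]] - t0
  for (nm in names(results)) {
    r <- results[[nm]]
    if (inherits(r, "transmission_curve")) {
      write_transmission_csv(
        r, file.path(out_dir, sprintf("%s_%s.csv", experiment, nm)))
    }
  }
  manifest <- list(
    experiment = experiment, seed = cfg$seed, n_trials = cfg$n_trials,
    duration_ms = cfg$duration, runtime_s = round(elapsed, 2),
    package_version = as.character(utils::packageVersion("ffeisim")),
    half_cutoffs = lapply(results, function(r) {
      if (inherits(r, "transmission_curve")) attr(r, "half_cutoff") else NULL
    }),
    scalars = Filter(is.numeric, results))
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(experiment, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(results)
}

#' Generate small deterministic fixture spike trains
#'
#' Writes the fixture files used by the test suite: a periodic 100 Hz
#' train, a single spike at 100 ms, and a seeded anti-phase 5 Hz Poisson
#' pair.
#'
#' @param dir Output directory.
#' @param seed Seed for the Poisson pair.
#' @return Invisibly, the written file paths.
#' @export
generate_fixtures <- function(dir = ".", seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    periodic_100hz = file.path(dir, "periodic_100hz.txt"),
    single_spike = file.path(dir, "single_spike.txt"),
    xor_pair_i1 = file.path(dir, "xor_pair_i1.txt"),
    xor_pair_i2 = file.path(dir, "xor_pair_i2.txt"))
  write_spike_times(seq(10, 1000, by = 10), paths["periodic_100hz"])
  write_spike_times(100, paths["single_spike"])
  g <- sim_grid(dt = 0.1, duration = 1000)
  set.seed(seed)
  write_spike_times(poisson_spikes(g, rate_profile(PR = 100, F = 5)),
                    paths["xor_pair_i1"])
  write_spike_times(poisson_spikes(g, rate_profile(PR = 100, F = 5,
                                                   phase = pi)),
                    paths["xor_pair_i2"])
  invisible(paths)
}
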