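# Trial container: a directory with a JSON manifest (cells + trial
# records) and one CSV per trial (columns time_s, value). Plain-text,
# lossless to 12 significant digits.

CONTAINER_SCHEMA_VERSION <- "1.0"

#' Write a trial container
#'
#' @param datasets List with `cells` (list of records: `cell_id`,
#'   `condition`, `access_resistance_mohm`, `depth_um`,
#'   `sampling_rate_hz`) and `trials` (list of `list(meta, samples)` where
#'   `meta` holds `cell_id`, `trial_id`, `kind` ("vm" or "epsc"),
#'   `direction_deg`, `stim_onset_s`, `stim_dur_s`, `ttl_time_s`).
#'   [vm_trial()] and [epsc_trial()] objects are also accepted in
#'   `trials`.
#' @param path Directory to create.
#' @return `path`, invisibly.
#' @export
write_trial_container <- function(datasets, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  trials <- lapply(datasets$trials, as_container_trial)
  meta <- lapply(trials, `[[`, "meta")
  cell_ids <- vapply(datasets$cells, `[[`, "", "cell_id")
  for (m in meta) {
    if (!m$cell_id %in% cell_ids) {
      stop(sprintf("write_trial_container: trial references unknown cell '%s'",
                   m$cell_id))
    }
  }
  manifest <- list(schema_version = CONTAINER_SCHEMA_VERSION,
                   cells = datasets$cells, trials = meta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    fs <- cell_rate(datasets$cells, tr$meta$cell_id)
    tcol <- (seq_along(tr$samples) - 1L) / fs
    fn <- file.path(path, sprintf("%s_%s.csv", tr$meta$cell_id,
                                  tr$meta$trial_id))
    lines <- c("time_s,value",
               sprintf("%.12g,%.12g", tcol, tr$samples))
    writeLines(lines, fn)
  }
  invisible(path)
}

#' @noRd
cell_rate <- function(cells, cell_id) {
  for (cl in cells) if (cl$cell_id == cell_id) return(cl$sampling_rate_hz)
  stop(sprintf("unknown cell '%s'", cell_id))
}

#' @noRd
as_container_trial <- function(x) {
  if (inherits(x, "vm_trial")) {
    list(meta = list(cell_id = x$cell_id, trial_id = x$trial_id,
                     kind = "vm", direction_deg = x$direction,
                     stim_onset_s = x$stim_onset, stim_dur_s = x$stim_dur,
                     ttl_time_s = NA),
         samples = x$samples)
  } else if (inherits(x, "epsc_trial")) {
    list(meta = list(cell_id = x$cell_id, trial_id = 1L, kind = "epsc",
                     direction_deg = NA, stim_onset_s = NA, stim_dur_s = NA,
                     ttl_time_s = x$ttl_time),
         samples = x$current)
  } else x
}

#' Read a trial container
#'
#' Validates the manifest (schema version, every trial referencing a known
#' cell) and reconstructs [vm_trial()] / [epsc_trial()] objects.
#'
#' @param path Container directory written by [write_trial_container()].
#' @return List with `cells` and `trials` (reconstructed objects).
#' @export
read_trial_container <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stop(sprintf("read_trial_container: no manifest.json in '%s'", path))
  }
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$schema_version, CONTAINER_SCHEMA_VERSION)) {
    stop("read_trial_container: unsupported schema version")
  }
  cells <- manifest$cells
  cell_ids <- vapply(cells, `[[`, "", "cell_id")
  cond_of <- function(id) {
    cells[[match(id, cell_ids)]]$condition %||% NA_character_
  }
  trials <- lapply(manifest$trials, function(m) {
    if (!m$cell_id %in% cell_ids) {
      stop(sprintf("read_trial_container: trial references unknown cell '%s'",
                   m$cell_id))
    }
    fn <- file.path(path, sprintf("%s_%s.csv", m$cell_id, m$trial_id))
    dat <- utils::read.csv(fn)
    fs <- cell_rate(cells, m$cell_id)
    if (abs(nrow(dat) - round(nrow(dat) / fs * fs)) > 1) {
      stop("read_trial_container: array length inconsistent with rate")
    }
    if (identical(m$kind, "epsc")) {
      cl <- cells[[match(m$cell_id, cell_ids)]]
      epsc_trial(dat$value, fs, ttl_time = m$ttl_time_s,
                 cell_id = m$cell_id,
                 access_resistance = cl$access_resistance_mohm %||% NA_real_,
                 depth = cl$depth_um %||% NA_real_,
                 group = cond_of(m$cell_id))
    } else {
      vm_trial(dat$value, fs, m$stim_onset_s, m$stim_dur_s,
               direction = m$direction_deg %||% NA_real_,
               cell_id = m$cell_id, trial_id = m$trial_id,
               condition = cond_of(m$cell_id))
    }
  })
  list(cells = cells, trials = trials)
}

#' Analysis configuration
#'
#' All tunables of the familiarity/tuning pipelines in one validated
#' object; unknown names are rejected.
#'
#' @param ... Overrides of the defaults: `spike_removal_ms`,
#'   `spike_thresh_mV`, `fine_ms`, `coarse_ms`, `bin_ms`, `gauss_win_ms`,
#'   `gauss_sigma_ms`, `bands`, `osc_criterion`, `familiarity_windows`,
#'   `tuning_windows`, `n_reps`, `seed`, `filter_order`.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    spike_removal_ms = 12.5,
    spike_thresh_mV = 15,
    fine_ms = 0.5,
    coarse_ms = 500,
    bin_ms = 10,
    gauss_win_ms = 200,
    gauss_sigma_ms = 40,
    bands = default_bands(),
    osc_criterion = oscillation_criterion(),
    familiarity_windows = window_spec(response = c(0.05, 0.25),
                                      baseline = c(2.5, 4.7)),
    tuning_windows = window_spec(response = c(0.05, 0.55),
                                 baseline = c(2.5, 3.5)),
    n_reps = 2000,
    seed = 1L,
    filter_order = 4)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop(sprintf("analysis_config: unknown option(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "analysis_config")
}

# group trials by cell id
#' @noRd
split_by_cell <- function(trials) {
  ids <- vapply(trials, `[[`, "", "cell_id")
  split(trials, factor(ids, levels = unique(ids)))
}

#' Familiarity (single-direction) analysis pipeline
#'
#' For each cell: spike detection, spike removal, oscillation-trial
#' probability, band magnitudes (4--7, 8--12, 13--30 Hz) in the response
#' window, delta-Vm peaks in windows I--III, and the baseline-subtracted
#' firing rate. The group summary compares naive vs experienced cells per
#' measure with two-sided Mann-Whitney (Wilcoxon rank-sum) tests and
#' Benjamini-Hochberg correction across the table.
#'
#' @param container A list from [read_trial_container()], or a list of
#'   [vm_trial()]s in its `trials` field.
#' @param config An [analysis_config()].
#' @return List with `per_cell` (data.frame) and `group_summary`
#'   (data.frame); empty input gives empty tables with a warning.
#' @export
run_familiarity_pipeline <- function(container, config = analysis_config()) {
  trials <- container$trials %||% container
  trials <- Filter(function(x) inherits(x, "vm_trial"), trials)
  if (!length(trials)) {
    warning("run_familiarity_pipeline: no vm trials in container")
    return(list(per_cell = data.frame(), group_summary = data.frame()))
  }
  by_cell <- split_by_cell(trials)
  rows <- lapply(by_cell, function(trs) {
    cond <- trs[[1L]]$condition
    spikes <- lapply(trs, detect_spikes, fine_ms = config$fine_ms,
                     coarse_ms = config$coarse_ms,
                     thresh_mV = config$spike_thresh_mV)
    clean <- lapply(trs, remove_spikes, window_ms = config$spike_removal_ms)
    oscil <- detect_oscillation_trials(clean, config$osc_criterion)
    respw <- config$osc_criterion$response
    mags <- vapply(config$bands, function(b) {
      mean(vapply(clean, band_magnitude, numeric(1), band = b,
                  window = respw))
    }, numeric(1))
    dvm <- rowMeans(vapply(clean, delta_vm_peaks, numeric(3),
                           baseline = config$familiarity_windows$baseline))
    data.frame(
      cell_id = trs[[1L]]$cell_id, condition = cond,
      n_trials = length(trs),
      osc_probability = oscil$probability,
      mag_4_7 = mags[["theta"]], mag_8_12 = mags[["alpha"]],
      mag_13_30 = mags[["beta"]],
      dvm_I = dvm[["I"]], dvm_II = dvm[["II"]], dvm_III = dvm[["III"]],
      rate_bs = baseline_subtracted_rate(
        spikes, config$familiarity_windows, trs[[1L]]$stim_onset),
      stringsAsFactors = FALSE)
  })
  per_cell <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  list(per_cell = per_cell,
       group_summary = group_compare(per_cell,
                                     setdiff(names(per_cell),
                                             c("cell_id", "condition",
                                               "n_trials"))))
}

# two-sided rank-sum tests naive vs experienced with BH correction
#' @noRd
group_compare <- function(per_cell, measures) {
  conds <- unique(per_cell$condition)
  if (length(conds) != 2L) {
    return(data.frame(measure = measures,
                      mean_a = NA_real_, mean_b = NA_real_,
                      U = NA_real_, p = NA_real_, p_adj = NA_real_))
  }
  res <- lapply(measures, function(m) {
    a <- per_cell[[m]][per_cell$condition == conds[1L]]
    b <- per_cell[[m]][per_cell$condition == conds[2L]]
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(measure = m, mean_a = mean(a), mean_b = mean(b),
               U = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[2:3] <- paste0("mean_", conds)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Tuning (12-direction) analysis pipeline
#'
#' For each [tuning_dataset()]: per-direction baseline-subtracted rates,
#' split-half OSI/DSI, response-class rates, band magnitudes and ITPC for
#' the preferred/opposite/orthogonal directions, and pooled spike-phase
#' samples on the 4--7 Hz oscillation (phases only where membrane traces
#' are present).
#'
#' @param datasets List of [tuning_dataset()]s.
#' @param config An [analysis_config()].
#' @return List with `per_cell` (data.frame), `rates_by_direction`
#'   (data.frame), `phases` (data.frame, possibly empty), and
#'   `group_summary`.
#' @export
run_tuning_pipeline <- function(datasets, config = analysis_config()) {
  if (inherits(datasets, "tuning_dataset")) datasets <- list(datasets)
  if (!length(datasets)) {
    warning("run_tuning_pipeline: no datasets")
    return(list(per_cell = data.frame(), rates_by_direction = data.frame(),
                phases = data.frame(), group_summary = data.frame()))
  }
  per_cell <- list()
  rate_rows <- list()
  phase_rows <- list()
  for (ds in datasets) {
    sel <- split_half_selectivity(ds, n_reps = config$n_reps,
                                  seed = config$seed)
    cls <- response_rates_by_class(ds)
    band_cols <- c(rep(NA_real_, 3))
    itpc_theta <- NA_real_
    has_vm <- !is.null(ds$trials[[1L]][[1L]]$vm)
    if (has_vm) {
      class_dirs <- c(preferred = cls$pref_direction,
                      opposite = (cls$pref_direction + 180) %% 360,
                      orthogonal = (cls$pref_direction + 90) %% 360)
      respw <- ds$windows$response
      vm_of <- function(dir) {
        lapply(ds$trials[[as.character(dir)]], `[[`, "vm")
      }
      mags <- vapply(names(class_dirs), function(cl) {
        clean <- lapply(vm_of(class_dirs[[cl]]), remove_spikes,
                        window_ms = config$spike_removal_ms)
        mean(vapply(clean, band_magnitude, numeric(1),
                    band = config$bands$theta, window = respw))
      }, numeric(1))
      band_cols <- mags
      clean_pref <- lapply(vm_of(class_dirs[["preferred"]]), remove_spikes,
                           window_ms = config$spike_removal_ms)
      Wp <- wavelet_transform(clean_pref,
                              freqs = wavelet_freqs()[
                                wavelet_freqs() >= 4 & wavelet_freqs() <= 7])
      it <- itpc(Wp)
      fs <- clean_pref[[1L]]$sampling_rate
      on <- clean_pref[[1L]]$stim_onset
      idx <- window_indices(on + respw[1], on + respw[2], fs, dim(Wp)[3])
      itpc_theta <- mean(it[, idx])
      for (cl in names(class_dirs)) {
        dtrs <- ds$trials[[as.character(class_dirs[[cl]])]]
        for (tr in dtrs) {
          if (is.null(tr$vm)) next
          clean <- remove_spikes(tr$vm, window_ms = config$spike_removal_ms)
          ph <- spike_phases(clean, tr$spikes, band = config$bands$theta,
                             window = respw, direction_class = cl)
          if (length(ph$phases)) {
            phase_rows[[length(phase_rows) + 1L]] <- data.frame(
              cell_id = ds$cell_id, trial_id = tr$vm$trial_id,
              direction_class = cl, phase_rad = ph$phases,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    per_cell[[length(per_cell) + 1L]] <- data.frame(
      cell_id = ds$cell_id, condition = ds$condition,
      osi = sel$osi, dsi = sel$dsi, pref_direction = sel$pref_direction,
      r_pref = cls$r_pref, r_opp = cls$r_opp, r_orth = cls$r_orth,
      mag_pref = band_cols[[1L]], mag_opp = band_cols[[2L]],
      mag_orth = band_cols[[3L]], itpc_4_7_pref = itpc_theta,
      stringsAsFactors = FALSE)
    rate_rows[[length(rate_rows) + 1L]] <- data.frame(
      cell_id = ds$cell_id, condition = ds$condition,
      direction = ds$directions,
      rate_bs = unname(vapply(trial_rates_by_direction(ds), mean,
                              numeric(1))),
      stringsAsFactors = FALSE)
  }
  per_cell <- do.call(rbind, c(per_cell, list(make.row.names = FALSE)))
  measures <- c("osi", "dsi", "r_pref", "r_opp", "r_orth")
  list(per_cell = per_cell,
       rates_by_direction = do.call(rbind, c(rate_rows,
                                             list(make.row.names = FALSE))),
       phases = if (length(phase_rows)) {
         do.call(rbind, c(phase_rows, list(make.row.names = FALSE)))
       } else data.frame(),
       group_summary = group_compare(per_cell, measures))
}
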