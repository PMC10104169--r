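# Orchestration of the three experiment types (rest, NOR, auditory) into
# summary tables, plus the command-line dispatcher. Every value in a summary
# table is reproducible by calling the owning module directly with the same
# inputs.

#' Session configuration
#'
#' Collects the tunable analysis parameters with their defaults; values are
#' validated against the module preconditions here, at load time.
#'
#' @param ... overrides of the defaults (see the returned list for names).
#' @return a named list of class `session_config`.
#' @export
session_config <- function(...) {
  cfg <- list(
    notch_hz = 50, lfp_fs = 1000, mua_sigma = 3,
    rest_threshold_percentile = 20, rest_window_s = 3,
    bands = band_scheme(),
    pac_phase_range = c(6, 10), pac_amp_range = c(40, 60),
    psi_bands = c("theta", "high_gamma"),
    psi_epleng_s = 60, psi_segleng_s = 1, psi_n_shuffles = 1000,
    ppc_epoch_s = 25, ppc_min_spikes = 250,
    nor_target_s = 5, nor_di_min = 0.2,
    aep_window_ms = c(10, 350), aep_k = 3,
    mmn_window_ms = c(40, 200),
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  stopifnot(cfg$lfp_fs > 0, cfg$mua_sigma > 0, cfg$psi_segleng_s > 0,
            cfg$psi_epleng_s >= cfg$psi_segleng_s,
            cfg$ppc_min_spikes >= 2, cfg$nor_target_s > 0)
  structure(cfg, class = c("session_config", "list"))
}

row_metric <- function(session, analysis, region, metric, value) {
  data.frame(session = session, analysis = analysis, region = region,
             metric = metric, value = value, stringsAsFactors = FALSE)
}

#' Rest (quiet-alertness) analysis
#'
#' Band powers per region, theta-gamma PAC (local dHPC and inter-regional
#' mPFC-phase to dHPC-amplitude), and surrogate-corrected PSI per configured
#' band, over 3-s rest windows (or the whole recording when no accelerometer
#' is present).
#'
#' @param lfp an `lfp_signal` with both regions (already preprocessed).
#' @param cfg a `session_config`.
#' @param rec optional raw `recording` supplying the accelerometer for rest
#'   detection.
#' @param spikes optional `spike_train` for PPC.
#' @param session session identifier for the table.
#' @return data frame with one row per (region/pair, metric).
#' @export
run_rest_analysis <- function(lfp, cfg = session_config(), rec = NULL,
                              spikes = NULL, session = "session1") {
  rest <- if (!is.null(rec) && !is.null(rec$accel)) {
    detect_rest_epochs(rec, threshold_percentile = cfg$rest_threshold_percentile)
  } else {
    epoch_set(0, duration_s(lfp), "rest")
  }
  windows <- tile_epochs(rest, cfg$rest_window_s)
  out <- list()
  for (region in unique(lfp$regions)) {
    ch <- which(lfp$regions == region)[1]
    ps <- multitaper_psd(lfp, windows, channel = ch)
    for (bn in setdiff(names(cfg$bands), "theta_wide")) {
      out[[length(out) + 1L]] <- row_metric(
        session, "rest", region, paste0("power_", bn),
        band_power(ps, cfg$bands, bn))
    }
  }
  hpc <- which(lfp$regions == "dHPC")[1]
  cm_local <- comodulogram(lfp, phase_channel = hpc,
                           amp_centers = seq(10, 100, by = 5))
  out[[length(out) + 1L]] <- row_metric(
    session, "rest", "dHPC", "pac_local",
    pac_quantify(cm_local, cfg$pac_phase_range, cfg$pac_amp_range))
  cm_ir <- interregional_pac(lfp, amp_centers = seq(10, 100, by = 5))
  out[[length(out) + 1L]] <- row_metric(
    session, "rest", "mPFC_phase-dHPC_amp", "pac_interregional",
    pac_quantify(cm_ir, cfg$pac_phase_range, cfg$pac_amp_range))
  for (bn in cfg$psi_bands) {
    pr <- psi_analysis(lfp, cfg$bands[[bn]],
                       epleng_s = min(cfg$psi_epleng_s, duration_s(lfp)),
                       segleng_s = cfg$psi_segleng_s,
                       n_shuffles = cfg$psi_n_shuffles, seed = cfg$seed)
    out[[length(out) + 1L]] <- row_metric(
      session, "rest", "mPFC->dHPC", paste0("psi_corrected_", bn),
      pr$psi_corrected)
    out[[length(out) + 1L]] <- row_metric(
      session, "rest", "mPFC->dHPC", paste0("psi_p_", bn), pr$p_value)
  }
  if (!is.null(spikes)) {
    pp <- ppc_by_epochs(spikes, lfp, cfg$bands$theta,
                        epoch_s = cfg$ppc_epoch_s,
                        min_spikes = cfg$ppc_min_spikes, channel = hpc)
    out[[length(out) + 1L]] <- row_metric(
      session, "rest", "dHPC", "ppc_theta",
      mean(pp$ppc, na.rm = TRUE))
  }
  do.call(rbind, out)
}

#' Novel-object-recognition analysis
#'
#' Discrimination index, per-object visit statistics, and the
#' visit-epoch PSI (concatenated 5-s epochs per object class).
#'
#' @param lfp an `lfp_signal` with both regions.
#' @param visits a `visit_record` for the memory test.
#' @param cfg a `session_config`.
#' @param phase `"STM"` or `"LTM"`.
#' @param session session identifier.
#' @return data frame with one row per metric.
#' @export
run_nor_analysis <- function(lfp, visits, cfg = session_config(),
                             phase = "STM", session = "session1") {
  score <- discrimination_index(visits)
  out <- list(
    row_metric(session, phase, "behavior", "di", score$di),
    row_metric(session, phase, "behavior", "total_exploration_s",
               score$total_exploration_s),
    row_metric(session, phase, "behavior", "n_visits_novel",
               unname(score$n_visits["novel"])),
    row_metric(session, phase, "behavior", "n_visits_familiar",
               unname(score$n_visits["familiar"])))
  eps <- label_visit_epochs(visits, phase, target_s = cfg$nor_target_s)
  for (obj in names(eps)) {
    for (bn in cfg$psi_bands) {
      pr <- psi_analysis(lfp, cfg$bands[[bn]], epochs = eps[[obj]],
                         segleng_s = cfg$psi_segleng_s,
                         n_shuffles = cfg$psi_n_shuffles, seed = cfg$seed)
      out[[length(out) + 1L]] <- row_metric(
        session, phase, paste0("mPFC->dHPC_", obj),
        paste0("psi_corrected_", bn), pr$psi_corrected)
    }
  }
  do.call(rbind, out)
}

#' Auditory analysis (AEP and/or MMN)
#'
#' Response ratio and P2/P3 metrics from a click-train session; per-frequency
#' difference-wave AUC from an oddball session.
#'
#' @param lfp an `lfp_signal` (mPFC).
#' @param events event table; click trains need `onset_s`, oddball needs
#'   `onset_s`, `freq_hz`, `role`, `block`.
#' @param cfg a `session_config`.
#' @param spikes optional `spike_train`.
#' @param session session identifier.
#' @return data frame with one row per metric.
#' @export
run_auditory_analysis <- function(lfp, events, cfg = session_config(),
                                  spikes = NULL, session = "session1") {
  out <- list()
  if (all(c("freq_hz", "role", "block") %in% names(events))) {
    mm <- mmn_analysis(lfp, events, mmn_window_ms = cfg$mmn_window_ms)
    for (nm in names(mm$combinations)) {
      out[[length(out) + 1L]] <- row_metric(
        session, "mmn", "mPFC", paste0("auc_", nm),
        mm$combinations[[nm]]$auc)
    }
  } else {
    trials <- epoch_trials(lfp, events)
    det <- detect_aep(trials, window_ms = cfg$aep_window_ms, k = cfg$aep_k)
    out[[length(out) + 1L]] <- row_metric(
      session, "aep", "mPFC", "response_ratio", det$response_ratio)
    for (comp in c("P2", "P3")) {
      met <- component_metrics(trials, comp, spikes = spikes)
      out[[length(out) + 1L]] <- row_metric(
        session, "aep", "mPFC", paste0(tolower(comp), "_amplitude_uv"),
        met$amplitude)
      out[[length(out) + 1L]] <- row_metric(
        session, "aep", "mPFC", paste0(tolower(comp), "_firing_rate_hz"),
        met$firing_rate)
    }
  }
  do.call(rbind, out)
}

#' Command-line dispatcher
#'
#' Thin shell over the pipeline: `cli_main(c("simulate", ...))` etc. The
#' installed script `inst/cli/circuit-sync.R` forwards `commandArgs(TRUE)`
#' here. Commands: `simulate` (write a synthetic rest session),
#' `rest`, `nor`, `aep`, `mmn` (run the corresponding analysis on a session
#' prefix written by `simulate` or [write_recording()]). Common flags:
#' `--seed N`, `--out DIR`, `--config cfg.yaml`, `--prefix PATH`,
#' `--duration S`.
#'
#' @param argv character vector of arguments.
#' @return invisibly, the result table (analyses) or output prefix
#'   (simulate).
#' @export
cli_main <- function(argv) {
  if (length(argv) < 1L) {
    stop("usage: circuit-sync {simulate|rest|nor|aep|mmn} [--seed N] ",
         "[--out DIR] [--config cfg.yaml] [--prefix PATH] [--duration S]")
  }
  cmd <- argv[1]
  opts <- list(seed = 1L, out = ".", config = NULL, prefix = NULL,
               duration = 120)
  args <- argv[-1]
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts)) stop("unknown option --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts$seed <- as.integer(opts$seed)
  opts$duration <- as.numeric(opts$duration)
  cfg <- session_config(seed = opts$seed)
  if (!is.null(opts$config)) {
    y <- yaml::read_yaml(opts$config)
    cfg <- do.call(session_config, c(y, list(seed = opts$seed)))
  }
  dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
  if (cmd == "simulate") {
    gt <- ground_truth(seed = opts$seed)
    rec <- gen_coupled_lfp(gt, duration_s = opts$duration, fs_hz = 1000)
    prefix <- file.path(opts$out, sprintf("session_seed%d", opts$seed))
    write_recording(rec, prefix)
    write_ground_truth(gt, paste0(prefix, "_truth.json"))
    message("wrote ", prefix, ".bin/.json")
    return(invisible(prefix))
  }
  if (is.null(opts$prefix)) stop("--prefix is required for analysis commands")
  rec <- read_recording(opts$prefix)
  lfp <- if (rec$fs > cfg$lfp_fs) extract_lfp(rec, cfg$notch_hz, cfg$lfp_fs)
         else lfp_signal(rec$signals, rec$fs, rec$regions)
  tab <- switch(cmd,
    rest = run_rest_analysis(lfp, cfg, rec = rec),
    nor = {
      ev <- rec$events
      vis <- visit_record(ev$label, ev$onset_s, ev$offset_s)
      run_nor_analysis(lfp, vis, cfg)
    },
    aep = run_auditory_analysis(lfp, rec$events, cfg),
    mmn = run_auditory_analysis(lfp, rec$events, cfg),
    stop("unknown command: ", cmd))
  out_path <- file.path(opts$out, paste0(cmd, "_summary.csv"))
  utils::write.csv(tab, out_path, row.names = FALSE)
  message("wrote ", out_path)
  invisible(tab)
}
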