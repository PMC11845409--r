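write_matrix_tsv <- function(m, path, row_name = "row") {
  df <- data.table::data.table(row = rownames(m) %||% seq_len(nrow(m)))
  data.table::setnames(df, "row", row_name)
  for (j in seq_len(ncol(m)))
    df[[colnames(m)[j] %||% paste0("c", j)]] <- m[, j]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Analyse one session bundle
#'
#' Saccade detection, gait extraction, trial exclusion and stride-phase
#' assignment for one participant x condition recording.
#'
#' @param bundle A [recording_bundle()].
#' @param cfg An [analysis_config()].
#' @return List: `saccades` (with stride percentile), `gait`, `strides`,
#'   `exclusions`, `percentiles` (assigned stride percentiles of retained
#'   saccades), `tracking`.
#' @export
analyse_session <- function(bundle, cfg = analysis_config()) {
  rec <- read_tracking(bundle$tracking_path, bundle$tracking_rate)
  sacc <- detect_saccades_recording(rec, cfg$saccade)
  gait <- extract_gait(rec, cfg$gait)
  events <- read_events(bundle$events_path)
  tw <- data.frame(trial_id = events$trial_id %||% seq_len(nrow(events)),
                   start_s = events$onset,
                   end_s = events$onset + events$duration)
  excl <- exclude_bad_trials(gait, attr(rec, "dropouts"), cfg$gait, tw)
  good_trials <- excl$trial_id[!excl$excluded]
  strides <- build_strides(gait, cfg$gait$stride_convention)
  strides_good <- strides[strides$trial_id %in% good_trials, , drop = FALSE]
  phases <- assign_phase(sacc$onset_s[sacc$trial_id %in% good_trials],
                         strides_good)
  sacc$stride_pct <- NA_real_
  if (nrow(phases)) {
    first <- phases[!duplicated(phases$event_time), ]
    sacc$stride_pct <- first$pct[match(sacc$onset_s, first$event_time)]
    sacc$step_pct <- first$step_pct[match(sacc$onset_s, first$event_time)]
  } else sacc$step_pct <- NA_real_
  list(saccades = sacc, gait = gait, strides = strides_good,
       exclusions = excl, percentiles = phases$pct,
       trial_windows = tw, tracking = rec)
}

#' Run the full pipeline over a set of bundles
#'
#' Per participant: saccade detection, gait extraction and phase assignment
#' (tables written as TSV). Per condition: group cyclic-entrainment
#' statistics with permutation null, prevalence and phase clustering (JSON).
#' Optionally ("eeg" stage) gait-locked time-frequency per participant
#' (TSV matrices) and the group-level cluster test (JSON). A log file
#' records every parameter and seed. Outputs are byte-reproducible for a
#' fixed config.
#'
#' @param bundles List of [recording_bundle()]s.
#' @param cfg An [analysis_config()].
#' @param out_dir Output directory.
#' @param stages Subset of c("saccades", "cyclic", "eeg", "cluster").
#' @return Invisible list of per-condition results.
#' @export
run_pipeline <- function(bundles, cfg = analysis_config(), out_dir,
                         stages = c("saccades", "cyclic")) {
  validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline_log.json")
  jsonlite::write_json(list(config = unclass(cfg),
                            participants = vapply(bundles, `[[`, "",
                                                  "participant_id"),
                            stages = stages),
                       log_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = 12)
  sessions <- list()
  for (b in bundles) {
    key <- paste0(b$participant_id, "_", b$condition)
    res <- tryCatch(analyse_session(b, cfg), error = function(e)
      stop("stage 'saccades/gait' failed for ", key, ": ",
           conditionMessage(e)))
    sessions[[key]] <- c(res, list(bundle = b))
    data.table::fwrite(
      cbind(participant = b$participant_id, condition = b$condition,
            res$saccades),
      file.path(out_dir, paste0(key, "_saccades.tsv")), sep = "\t")
    data.table::fwrite(
      cbind(participant = b$participant_id, condition = b$condition,
            res$gait$steps),
      file.path(out_dir, paste0(key, "_strides.tsv")), sep = "\t")
  }
  out <- list()
  conds <- unique(vapply(bundles, `[[`, "", "condition"))
  if ("cyclic" %in% stages) {
    for (cond in setdiff(conds, "static")) {
      keys <- names(sessions)[vapply(sessions, function(s)
        s$bundle$condition == cond, logical(1))]
      percs <- lapply(sessions[keys], `[[`, "percentiles")
      percs <- percs[lengths(percs) > 0]
      if (length(percs) < 2L) next
      ent <- tryCatch(
        group_entrainment(percs, cfg$cyclic, seed = cfg$seed),
        error = function(e) stop("stage 'cyclic' failed for condition ",
                                 cond, ": ", conditionMessage(e)))
      out[[cond]]$entrainment <- ent
      jsonlite::write_json(
        list(condition = cond, grid = ent$scan$grid, r2 = ent$scan$r2,
             null_bound = ent$null$bound, best_freq = ent$scan$best_freq,
             best_fit = unclass(ent$scan$best_fit)[c("a0", "a1", "b1", "A",
                                                     "phi", "r2")],
             band_sig = ent$group_sig$band_sig, k = ent$k, n = ent$n,
             prevalence = list(map = ent$prevalence$map,
                               hpdi = as.list(ent$prevalence$hpdi),
                               alpha = ent$prevalence$alpha),
             rayleigh = if (!is.null(ent$rayleigh))
               unclass(ent$rayleigh) else NULL),
        file.path(out_dir, paste0("entrainment_", cond, ".json")),
        auto_unbox = TRUE, digits = 12, pretty = TRUE)
    }
  }
  if ("eeg" %in% stages) {
    for (key in names(sessions)) {
      s <- sessions[[key]]
      if (s$bundle$condition == "static") next
      eeg <- tryCatch({
        rec <- read_eeg(s$bundle$eeg_path)
        rec <- preprocess_eeg(rec, cfg$eeg)
        good <- s$exclusions$trial_id[!s$exclusions$excluded]
        st <- s$gait$steps[s$gait$steps$trial_id %in% good & s$gait$steps$ok, ]
        gait_tf(rec, st, cfg$eeg)
      }, error = function(e) stop("stage 'eeg' failed for ", key, ": ",
                                  conditionMessage(e)))
      sessions[[key]]$gait_tf <- eeg
      chan_avg <- apply(eeg$power, c(2, 3), mean)
      rownames(chan_avg) <- sprintf("%.2f", eeg$freqs)
      colnames(chan_avg) <- sprintf("%g", eeg$grid_pct)
      write_matrix_tsv(chan_avg,
                       file.path(out_dir, paste0(key, "_gait_tf.tsv")),
                       row_name = "freq_hz")
    }
    if ("cluster" %in% stages) {
      for (cond in setdiff(conds, "static")) {
        keys <- names(sessions)[vapply(sessions, function(s)
          s$bundle$condition == cond && !is.null(s$gait_tf), logical(1))]
        if (length(keys) < 3L) next
        maps <- t(vapply(sessions[keys], function(s)
          as.vector(apply(s$gait_tf$power, c(2, 3), mean)),
          numeric(length(sessions[[keys[1]]]$gait_tf$freqs) *
                    length(sessions[[keys[1]]]$gait_tf$grid_pct))))
        gt <- sessions[[keys[1]]]$gait_tf
        ct <- cluster_test_2d(maps, dims = c(length(gt$freqs),
                                             length(gt$grid_pct)),
                              p_thresh = cfg$cluster$p_thresh,
                              n_perm = cfg$cluster$n_perm,
                              seed = split_seed(cfg$seed, 2L)[2])
        rep <- cluster_report(ct, gt$freqs, gt$grid_pct, alpha = 0.05)
        out[[cond]]$cluster <- ct
        jsonlite::write_json(rep,
                             file.path(out_dir,
                                       paste0("clusters_", cond, ".json")),
                             auto_unbox = TRUE, digits = 12, pretty = TRUE,
                             dataframe = "rows")
      }
    }
  }
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic session), `run-all` (full
#' pipeline over simulated or listed sessions), `detect-saccades`,
#' `extract-gait`, `cyclic-fit` (single-session stages). Flags:
#' `--out-dir`, `--seed`, `--config` (JSON), `--condition`, `--n-trials`,
#' `--participants`, `--stages` (comma-separated).
#'
#' @param args Character vector of CLI arguments (default: the command
#'   line).
#' @return Invisibly, the subcommand's result.
#' @export
stridesync_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: stridesync <subcommand> [--flag value ...]")
  cmd <- args[1]
  flags <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    if (startsWith(rest[i], "--")) {
      flags[[sub("^--", "", rest[i])]] <- rest[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  seed <- as.integer(flags$seed %||% 1L)
  out_dir <- flags[["out-dir"]] %||% "."
  cfg <- if (!is.null(flags$config)) read_config(flags$config) else
    analysis_config(seed = seed)
  cfg$seed <- seed
  cond <- flags$condition %||% "natural"
  n_trials <- as.integer(flags[["n-trials"]] %||% 100L)
  result <- switch(
    cmd,
    "simulate" = simulate_session(
      out_dir, participant_id = flags$participant %||% "sim01",
      walk = walk_params(cond, n_trials = n_trials),
      sacc = saccade_params(
        modulation_depth = as.numeric(flags$depth %||% 0.3)),
      eeg = eeg_params(), seed = seed),
    "detect-saccades" = {
      rec <- read_tracking(flags$tracking)
      sacc <- detect_saccades_recording(rec, cfg$saccade)
      data.table::fwrite(sacc, file.path(out_dir, "saccades.tsv"), sep = "\t")
      sacc
    },
    "extract-gait" = {
      rec <- read_tracking(flags$tracking)
      g <- extract_gait(rec, cfg$gait)
      data.table::fwrite(g$steps, file.path(out_dir, "strides.tsv"),
                         sep = "\t")
      g
    },
    "run-all" = {
      n_part <- as.integer(flags$participants %||% 3L)
      bundles <- lapply(seq_len(n_part), function(p)
        simulate_session(file.path(out_dir, "sessions"),
                         participant_id = sprintf("sim%02d", p),
                         walk = walk_params(cond, n_trials = n_trials),
                         sacc = saccade_params(
                           modulation_depth = as.numeric(flags$depth %||% 0.3)),
                         eeg = eeg_params(),
                         seed = split_seed(seed, n_part)[p]))
      stages <- strsplit(flags$stages %||% "saccades,cyclic", ",")[[1]]
      run_pipeline(bundles, cfg, out_dir, stages = stages)
    },
    stop("unknown subcommand: ", cmd))
  invisible(result)
}
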