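#' Reproducible pipeline commands
#'
#' File-based stages that compose into the full study shape on synthetic
#' data: generate -> train -> decode -> evaluate (plus benchmark and
#' simulate-assist). Every artifact embeds the hash of the configuration
#' that produced it, and `run_evaluate()` refuses decode files whose model
#' hash does not match the supplied model. Logging goes to stderr; machine
#' artifacts are pure JSON/CSV.
#'
#' @name pipeline
NULL

config_hash <- function(obj) {
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10, force = TRUE)
  # tiny polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_msg <- function(...) message("[synid] ", ...)

#' Generate a synthetic session on disk
#'
#' Writes one CSV per trial, a session manifest and a `truth.json` sidecar
#' (true onsets, W_true, seed) for test oracles.
#'
#' @param out_dir output directory (created if missing).
#' @param cfg a [generator_config()].
#' @return the manifest path, invisibly.
#' @export
run_generate <- function(out_dir, cfg = generator_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ses <- generate_session(cfg)
  rows <- list(); onsets <- integer(0)
  write_set <- function(set, mode_name, offset) {
    for (i in seq_along(set)) {
      f <- sprintf("trial_%s_%03d.csv", mode_name, i)
      write_trial(set[[i]], file.path(out_dir, f))
      rows[[length(rows) + 1]] <<- data.frame(
        file = f, direction = set[[i]]$direction,
        mode = if (mode_name == "train") "transparent" else "assistive")
      onsets <<- c(onsets, set[[i]]$onset_index)
    }
  }
  write_set(ses$train, "train", 0)
  write_set(ses$test, "test", length(ses$train))
  trials <- do.call(rbind, rows)
  write_manifest(trials, file.path(out_dir, "session.json"),
                 fs_raw = cfg$raw_hz, muscle_names = rownames(cfg$W_true),
                 mvc = ses$mvc)
  jsonlite::write_json(
    list(seed = cfg$seed, W_true = unclass(cfg$W_true),
         true_onsets = onsets, config_hash = config_hash(unclass(cfg)[setdiff(names(cfg), "layout")])),
    file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("generated ", nrow(trials), " trials in ", out_dir)
  invisible(file.path(out_dir, "session.json"))
}

manifest_envelopes <- function(manifest_path, subset_mode = NULL) {
  m <- read_manifest(manifest_path)
  dirn <- dirname(manifest_path)
  tr <- m$trials
  if (!is.null(subset_mode)) tr <- tr[tr$mode == subset_mode, , drop = FALSE]
  envs <- lapply(file.path(dirn, tr$file), read_trial, muscle_names = m$muscle_names)
  list(manifest = m, trials = tr,
       envelopes = lapply(envs, `[[`, "envelope"),
       trajectories = lapply(envs, `[[`, "trajectory"))
}

#' Train a decoder from a session manifest
#'
#' Uses the transparent-mode trials: detects onsets, extracts synergies and
#' fits the per-direction mixtures, then writes the model JSON.
#'
#' @param manifest_path session manifest (JSON).
#' @param out_path model output path.
#' @param n_syn synergy count.
#' @param seed training seed.
#' @param gain_h onset gain.
#' @return the trained `decoder_model`, invisibly.
#' @export
run_train <- function(manifest_path, out_path, n_syn = 4, seed = 1,
                      gain_h = default_config()$onset$gain_h) {
  d <- manifest_envelopes(manifest_path, "transparent")
  onsets <- lapply(d$envelopes, detect_onset, gain_h = gain_h)
  model <- train_decoder(d$envelopes, d$trials$direction, onsets,
                         n_syn = n_syn, seed = seed)
  write_decoder_model(model, out_path)
  log_msg("trained decoder on ", length(d$envelopes), " trials -> ", out_path)
  invisible(model)
}

#' Decode a session's assistive trials with a stored model
#'
#' @param manifest_path session manifest.
#' @param model_path decoder model JSON.
#' @param out_path decode-summary JSON output.
#' @param gain_h onset gain.
#' @return decode summary list, invisibly.
#' @export
run_decode <- function(manifest_path, model_path, out_path,
                       gain_h = default_config()$onset$gain_h) {
  model <- read_decoder_model(model_path)
  d <- manifest_envelopes(manifest_path, "assistive")
  n <- length(d$envelopes)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    on_i <- detect_onset(d$envelopes[[i]], gain_h = gain_h)
    n_it <- round(model$t_acc_s * model$control_fs)
    if (is.null(on_i) || on_i$index + n_it > ncol(d$envelopes[[i]]$values)) {
      out[[i]] <- list(file = d$trials$file[i], direction = d$trials$direction[i],
                       excluded = TRUE, reason = "onset not timely detected")
      next
    }
    tr <- decode_trial(d$envelopes[[i]], on_i, model)
    out[[i]] <- list(file = d$trials$file[i], direction = d$trials$direction[i],
                     excluded = FALSE, onset_index = on_i$index,
                     final_estimate = tr$final_estimate, estimates = tr$estimates,
                     final_p_cum = tr$p_cum[tr$n_iterations, ])
  }
  res <- list(model_hash = config_hash(jsonlite::read_json(model_path)),
              control_fs = model$control_fs, t_acc_s = model$t_acc_s,
              decodes = out)
  jsonlite::write_json(res, out_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("decoded ", n, " trials -> ", out_path)
  invisible(res)
}

#' Evaluate decode results into session metrics
#'
#' @param decodes_path decode-summary JSON from [run_decode()].
#' @param model_path the model used (hash checked against the decode file).
#' @param out_path metrics JSON output; a per-trial CSV is written next to
#'   it with suffix `_trials.csv`.
#' @return `session_metrics`, invisibly.
#' @export
run_evaluate <- function(decodes_path, model_path, out_path) {
  res <- jsonlite::read_json(decodes_path, simplifyVector = FALSE)
  if (!identical(res$model_hash, config_hash(jsonlite::read_json(model_path))))
    stop("dependency error: decode file was produced with a different model")
  dec <- res$decodes
  true_dirs <- vapply(dec, `[[`, character(1), "direction")
  excluded <- vapply(dec, `[[`, logical(1), "excluded")
  est_dirs <- vapply(dec, function(d) if (d$excluded) NA_character_ else d$final_estimate,
                     character(1))
  sm <- session_metrics(true_dirs[!excluded], est_dirs[!excluded])
  sm$n_excluded <- sum(excluded)
  est_steps <- lapply(dec[!excluded], function(d) unlist(d$estimates))
  curve <- accuracy_vs_time(est_steps, true_dirs[!excluded])
  obj <- list(confusion = unclass(sm$confusion),
              accuracy_pct = sm$accuracy_pct,
              type1_pct = sm$type1_pct, type2_pct = sm$type2_pct,
              type3_pct = sm$type3_pct, type4_pct = sm$type4_pct,
              modified_accuracy_pct = sm$modified_accuracy_pct,
              chance_level_pct = sm$chance_level_pct,
              n_trials = sm$n_trials, n_excluded = sm$n_excluded,
              modified_accuracy_vs_time = curve)
  jsonlite::write_json(obj, out_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(trial_table(true_dirs[!excluded], est_dirs[!excluded]),
                   sub("\\.json$", "_trials.csv", out_path), row.names = FALSE)
  log_msg("metrics -> ", out_path)
  invisible(sm)
}

#' Run the kinematics-based benchmark over a session's trajectories
#'
#' @param manifest_path session manifest whose trial files carry trajectories.
#' @param out_path JSON output of per-trial final benchmark estimates.
#' @param min_disp displacement gate in meters.
#' @return benchmark summary, invisibly.
#' @export
run_benchmark <- function(manifest_path, out_path, min_disp = 0.01) {
  d <- manifest_envelopes(manifest_path, "assistive")
  out <- lapply(seq_along(d$trajectories), function(i) {
    traj <- d$trajectories[[i]]
    if (is.null(traj)) return(list(file = d$trials$file[i], excluded = TRUE))
    est <- kinematic_benchmark(traj, min_disp = min_disp)
    list(file = d$trials$file[i], direction = d$trials$direction[i],
         excluded = FALSE, final_estimate = est[length(est)])
  })
  jsonlite::write_json(list(benchmark = out), out_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("benchmark -> ", out_path)
  invisible(out)
}

#' Simulate assisted reaches toward each decoded target
#'
#' @param model_path decoder model JSON (for the control rate).
#' @param out_path CSV of simulated hand trajectories.
#' @param layout a [target_layout()].
#' @param gains,admittance,gain_multiplier assistance parameters.
#' @return data.frame of trajectories, invisibly.
#' @export
run_simulate_assist <- function(model_path, out_path, layout = target_layout(),
                                gains = c(0.01, 0.03, 0.01), admittance = 1,
                                gain_multiplier = 1000) {
  model <- read_decoder_model(model_path)
  arm <- arm_model()
  dt <- 1 / model$control_fs
  n <- round(1.2 / dt)
  rows <- lapply(DIRECTIONS, function(d) {
    tgt <- layout$targets[d, ]
    mj <- min_jerk(layout$home, tgt, 1.2, model$control_fs)
    X <- simulate_assisted_reach(mj$velocity[-1, , drop = FALSE], layout$home, tgt,
                                 gains, admittance, arm, dt, gain_multiplier)
    data.frame(direction = d, step = seq_len(nrow(X)) - 1,
               x_m = X[, 1], y_m = X[, 2], z_m = X[, 3])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, out_path, row.names = FALSE)
  log_msg("simulated assisted reaches -> ", out_path)
  invisible(df)
}
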