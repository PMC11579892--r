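#' Write and read the plain-text trial file format
#'
#' One CSV per trial: header `time_s,<muscle_1>,...,<muscle_6>` with
#' optional trailing `x_m,y_m,z_m` trajectory columns; UTF-8, decimal point.
#'
#' @param trial a `synthetic_trial`, `emg_trial`, or `envelope_series`.
#' @param path output file.
#' @param trajectory optional samples x 3 matrix when `trial` carries none.
#' @export
write_trial <- function(trial, path, trajectory = NULL) {
  if (inherits(trial, "synthetic_trial")) {
    vals <- trial$envelope$values; fs <- trial$envelope$fs
    trajectory <- trial$trajectory
  } else if (inherits(trial, "emg_trial")) {
    vals <- trial$samples; fs <- trial$fs_raw
  } else {
    vals <- trial$values; fs <- trial$fs
  }
  df <- data.frame(time_s = (seq_len(ncol(vals)) - 1) / fs, t(vals))
  names(df) <- c("time_s", rownames(vals))
  if (!is.null(trajectory)) {
    df$x_m <- trajectory[, 1]; df$y_m <- trajectory[, 2]; df$z_m <- trajectory[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @param muscle_names expected muscle columns; inferred from the header by
#'   default (all non-time, non-trajectory columns).
#' @return `read_trial()`: list with `envelope` (an `envelope_series`),
#'   `trajectory` (samples x 3 or NULL) and `fs`.
#' @export
read_trial <- function(path, muscle_names = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  traj_cols <- intersect(c("x_m", "y_m", "z_m"), names(df))
  if (is.null(muscle_names))
    muscle_names <- setdiff(names(df), c("time_s", traj_cols))
  fs <- 1 / stats::median(diff(df$time_s))
  vals <- t(as.matrix(df[, muscle_names, drop = FALSE]))
  traj <- if (length(traj_cols) == 3) as.matrix(df[, c("x_m", "y_m", "z_m")]) else NULL
  list(envelope = envelope_series(pmax(vals, 0), round(fs), muscle_names),
       trajectory = traj, fs = round(fs))
}

#' Write and read a session manifest
#'
#' JSON with `fs_raw`, `muscle_names`, `mvc` (muscle to value map) and
#' `trials`, a list of `{file, direction, mode}` records.
#'
#' @param trials data.frame with columns `file`, `direction`, `mode`.
#' @param path manifest path.
#' @param fs_raw raw sampling rate recorded in the manifest.
#' @param muscle_names ordered muscle labels.
#' @param mvc named per-muscle MVC values.
#' @export
write_manifest <- function(trials, path, fs_raw = 1000,
                           muscle_names = default_muscles(), mvc = NULL) {
  obj <- list(fs_raw = fs_raw, muscle_names = muscle_names,
              mvc = as.list(mvc), trials = trials)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(m$trials) || NROW(m$trials) == 0) stop("manifest has no trials")
  m$mvc <- unlist(m$mvc)
  m
}

#' Save and load a synergy model as JSON
#'
#' Values are written with 17 significant digits so the stored decimal
#' representation round-trips bit-exactly.
#'
#' @param model a `synergy_model`.
#' @param path file path.
#' @export
write_synergy_model <- function(model, path) {
  obj <- list(W = unclass(model$W), n_syn = model$n_syn,
              muscle_names = model$muscle_names,
              extraction_meta = model$extraction_meta[c("iterations", "final_rmse",
                                                        "restarts", "seed")])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_synergy_model
#' @export
read_synergy_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- matrix(unlist(o$W), nrow = length(o$muscle_names),
              dimnames = list(o$muscle_names, NULL))
  structure(list(W = W, n_syn = o$n_syn, muscle_names = o$muscle_names,
                 extraction_meta = o$extraction_meta),
            class = "synergy_model")
}

#' Save and load a full decoder model as JSON
#'
#' @param model a `decoder_model`.
#' @param path file path.
#' @export
write_decoder_model <- function(model, path) {
  gm <- lapply(model$gmms, function(g)
    list(weights = g$weights, means = g$means,
         covariances = lapply(g$covariances, unclass)))
  obj <- list(synergy = list(W = unclass(model$synergy$W),
                             n_syn = model$synergy$n_syn,
                             muscle_names = model$synergy$muscle_names),
              gmms = gm, t_acc_s = model$t_acc_s, control_fs = model$control_fs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname write_decoder_model
#' @export
read_decoder_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- o$synergy$n_syn
  W <- matrix(unlist(o$synergy$W), nrow = length(o$synergy$muscle_names),
              dimnames = list(o$synergy$muscle_names, NULL))
  syn <- structure(list(W = W, n_syn = d, muscle_names = o$synergy$muscle_names,
                        extraction_meta = list()), class = "synergy_model")
  gmms <- lapply(o$gmms, function(g) {
    means <- if (is.matrix(g$means)) lapply(seq_len(nrow(g$means)), function(i) g$means[i, ]) else g$means
    covs <- if (is.array(g$covariances) && length(dim(g$covariances)) == 3)
      lapply(seq_len(dim(g$covariances)[1]), function(i) g$covariances[i, , ])
    else lapply(g$covariances, function(S) matrix(unlist(S), d, d))
    structure(list(weights = g$weights, means = means, covariances = covs),
              class = "direction_gmm")
  })
  gmms <- gmms[DIRECTIONS]
  decoder_model(syn, gmms, t_acc_s = o$t_acc_s, control_fs = o$control_fs)
}

#' Read a YAML run configuration
#'
#' Validates keys against the package's known configuration schema; unknown
#' keys are rejected so typos fail loudly.
#'
#' @param path YAML file.
#' @return configuration list merged over [default_config()].
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  known <- c(names(base), "arm", "assist", "manipulability", "generator",
             "seed", "n_syn", "t_acc_s")
  bad <- setdiff(names(user), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  for (k in intersect(names(user), names(base)))
    base[[k]] <- utils::modifyList(base[[k]], user[[k]])
  c(base, user[setdiff(names(user), names(base))])
}
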