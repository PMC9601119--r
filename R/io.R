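#' Read a delimited trial matrix
#'
#' Reads a CSV with one row per sample and one column per channel, as
#' written by [write_trial_matrix()]. Rows must be rectangular and fully
#' numeric; violations are reported with the offending line number.
#'
#' @param path File path.
#' @param fs Sampling rate the file is declared to have (stored as an
#'   attribute, used for consistency checks downstream).
#' @return Numeric samples x channels matrix with attribute `fs`.
#' @export
read_trial_matrix <- function(path, fs) {
  if (!file.exists(path)) {
    stop_fbewt(sprintf("file not found: %s", path), "fbewt_io_error")
  }
  nf <- tryCatch(utils::count.fields(path, sep = ","),
                 warning = function(w) NULL, error = function(e) NULL)
  if (is.null(nf) || length(nf) == 0) {
    stop_fbewt(sprintf("%s: empty or unreadable file.", path),
               "fbewt_format_error")
  }
  if (length(unique(nf)) != 1) {
    bad <- which(nf != nf[1])[1]
    stop_fbewt(sprintf("%s: ragged row at line %d (%d fields, expected %d).",
                       path, bad, nf[bad], nf[1]), "fbewt_format_error")
  }
  dat <- utils::read.csv(path, header = FALSE, colClasses = "character")
  m <- suppressWarnings(matrix(as.numeric(as.matrix(dat)), nrow = nrow(dat)))
  if (any(is.na(m))) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop_fbewt(sprintf("%s: non-numeric value at line %d.", path, bad),
               "fbewt_format_error")
  }
  attr(m, "fs") <- fs
  m
}

#' Write a trial matrix as delimited text
#'
#' @param m Numeric samples x channels matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_matrix <- function(m, path) {
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.trial_file <- function(dir, subject, trial, modality) {
  file.path(dir, sprintf("sub%02d_trial%02d_%s.csv", subject, trial, modality))
}

#' Write a trial dataset to a directory
#'
#' Lays out one CSV per trial and modality
#' (`sub{ss}_trial{tt}_{eeg|ecg}.csv`, one row per sample, one column per
#' channel) plus a `ratings.csv` table with columns subject, trial, arousal,
#' valence, dominance. This is the pipeline's canonical on-disk input
#' layout.
#'
#' @param trials Trial tibble as from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in seq_len(nrow(trials))) {
    for (mod in intersect(c("eeg", "ecg"), names(trials))) {
      write_trial_matrix(trials[[mod]][[r]],
                         .trial_file(dir, trials$subject[r], trials$trial[r], mod))
    }
  }
  utils::write.csv(
    trials[, c("subject", "trial", "arousal", "valence", "dominance")],
    file.path(dir, "ratings.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' Read a trial dataset from a directory
#'
#' Inverse of [write_dataset()].
#'
#' @param dir Dataset directory.
#' @param fs_eeg,fs_ecg Sampling rates in Hz.
#' @param modality `"both"` (default), `"eeg"` or `"ecg"`.
#' @return Trial tibble (see [generate_dataset()]).
#' @export
read_dataset <- function(dir, fs_eeg = 128, fs_ecg = 256,
                         modality = c("both", "eeg", "ecg")) {
  modality <- match.arg(modality)
  rf <- file.path(dir, "ratings.csv")
  if (!dir.exists(dir) || !file.exists(rf)) {
    stop_fbewt(sprintf("dataset directory or ratings.csv missing under %s", dir),
               "fbewt_io_error")
  }
  ratings <- utils::read.csv(rf)
  mods <- if (modality == "both") c("eeg", "ecg") else modality
  fs_of <- c(eeg = fs_eeg, ecg = fs_ecg)
  out <- tibble::as_tibble(ratings)
  for (mod in mods) {
    out[[mod]] <- lapply(seq_len(nrow(ratings)), function(r) {
      read_trial_matrix(
        .trial_file(dir, ratings$subject[r], ratings$trial[r], mod),
        fs_of[[mod]]
      )
    })
  }
  out
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline in one flat list, with the
#' study's printed settings as defaults: 4 modes, smoothing window 3,
#' 5-fold cross-validation, KNN with k = 1 and Euclidean distance, 128/256
#' Hz sampling, scale-space parameters q0 = 0.5 and W = 5, adaptive tau,
#' log-energy probability floor 1e-12.
#'
#' @return Named list of settings.
#' @export
default_config <- function() {
  list(
    fs_eeg = 128, fs_ecg = 256,
    analysis_window_s = 60, epoch_s = 1,
    n_modes = 4,
    q0 = 0.5, eps_max = NA, W = 5,
    tau = NA,
    entropy_floor = 1e-12,
    smoothing_window = 3,
    classifier = "knn", k = 1, metric = "euclidean",
    k_folds = 5,
    seed = 1
  )
}

#' Read / write a run configuration
#'
#' YAML key-value files that round-trip through [read_run_config()] and
#' [write_run_config()] without loss; missing keys fall back to
#' [default_config()].
#'
#' @param path YAML file path.
#' @return `read_run_config()`: the configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_fbewt(sprintf("config file not found: %s", path), "fbewt_io_error")
  }
  cfg <- yaml::read_yaml(path)
  out <- default_config()
  for (k in names(cfg)) out[[k]] <- cfg[[k]]
  out
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write an evaluation report as structured text
#'
#' JSON with the confusion counts, metric percentages, per-fold accuracies,
#' classifier settings and seed, so the metrics can be recomputed from the
#' stored counts.
#'
#' @param eval A `fbewt_eval` from [crossval_evaluate()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(eval, path) {
  stopifnot(inherits(eval, "fbewt_eval"))
  jsonlite::write_json(
    list(
      dimension = eval$dimension,
      confusion = as.list(eval$confusion),
      metrics = as.list(round(eval$metrics, 4)),
      per_fold_accuracy = eval$per_fold$accuracy,
      classifier = eval$classifier[c("classifier", "k", "metric")],
      k_folds = eval$k_folds,
      seed = eval$seed,
      n = eval$n
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
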