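#' Preprocess trials into mean-subtracted 1-s epochs
#'
#' Keeps only the final `analysis_window_s` seconds of every trial, cuts
#' each channel into non-overlapping `epoch_s`-second epochs, and subtracts
#' each epoch's mean. With the defaults every trial yields 60 epochs per
#' channel: 128 samples for EEG, 256 for ECG.
#'
#' @param trials Tibble with one row per trial: columns `subject`, `trial`,
#'   `arousal`, `valence`, `dominance` and list columns `eeg` and/or `ecg`
#'   holding samples x channels matrices (as from [generate_dataset()] or
#'   [read_dataset()]).
#' @param fs_eeg,fs_ecg Sampling rates of the two modalities in Hz.
#' @param analysis_window_s Length of the analysed tail in seconds
#'   (default 60).
#' @param epoch_s Epoch length in seconds (default 1).
#' @return A tibble with one row per (trial, modality, channel, epoch):
#'   columns `subject`, `trial`, `arousal`, `valence`, `dominance`,
#'   `modality`, `channel`, `epoch`, `fs` and the list column `samples`
#'   (zero-mean numeric vector of length `fs * epoch_s`).
#' @export
preprocess_trials <- function(trials, fs_eeg = 128, fs_ecg = 256,
                              analysis_window_s = 60, epoch_s = 1) {
  mods <- intersect(c("eeg", "ecg"), names(trials))
  if (length(mods) == 0) {
    stop_fbewt("`trials` must contain an `eeg` and/or `ecg` list column.",
               "fbewt_invalid_argument")
  }
  fs_of <- c(eeg = fs_eeg, ecg = fs_ecg)
  out <- vector("list", nrow(trials) * length(mods))
  k <- 0L
  for (r in seq_len(nrow(trials))) {
    for (mod in mods) {
      X <- trials[[mod]][[r]]
      fs <- fs_of[[mod]]
      need <- analysis_window_s * fs
      if (nrow(X) < need) {
        stop_fbewt(sprintf(
          "trial (subject %s, trial %s, %s) is shorter than the %gs analysis window.",
          trials$subject[r], trials$trial[r], mod, analysis_window_s),
          "fbewt_invalid_input")
      }
      tail_x <- X[(nrow(X) - need + 1):nrow(X), , drop = FALSE]
      n_ep <- analysis_window_s / epoch_s
      len <- fs * epoch_s
      k <- k + 1L
      out[[k]] <- tibble::tibble(
        subject = trials$subject[r], trial = trials$trial[r],
        arousal = trials$arousal[r], valence = trials$valence[r],
        dominance = trials$dominance[r],
        modality = mod,
        channel = rep(seq_len(ncol(tail_x)), each = n_ep),
        epoch = rep(seq_len(n_ep), ncol(tail_x)),
        fs = fs,
        samples = lapply(seq_len(ncol(tail_x) * n_ep) - 1L, function(i) {
          ch <- i %/% n_ep + 1L
          e <- i %% n_ep
          v <- tail_x[(e * len + 1):((e + 1) * len), ch]
          v - mean(v)
        })
      )
    }
  }
  dplyr::bind_rows(out[seq_len(k)])
}

# Entropy features for one channel of one trial: E is an S x n_epochs
# matrix of zero-mean epochs. Returns an n_epochs x (n_modes * 3) matrix.
.channel_features <- function(E, fs, n_modes, q0, eps_max, W, tau, floor,
                              method) {
  S <- nrow(E)
  n_ep <- ncol(E)
  bs <- .fbse_basis(S)
  K <- if (method == "collocation") bs$Binv %*% E else bs$Wq %*% E
  X <- stats::mvfft(E)
  gains <- vector("list", n_modes)
  for (c_i in seq_len(n_modes)) gains[[c_i]] <- matrix(0, S, n_ep)
  bnd <- .boundaries_for_matrix(abs(K), n_modes, q0, eps_max, W)
  for (j in seq_len(n_ep)) {
    omegas <- pi * bnd[[j]] / S
    tau_j <- if (is.null(tau)) 0.9 * .tau_bound(omegas) else tau
    g <- .bank_gains_fft(omegas, tau_j, S)
    for (c_i in seq_len(n_modes)) gains[[c_i]][, j] <- g[, c_i]
  }
  feats <- matrix(NA_real_, n_ep, n_modes * 3)
  for (c_i in seq_len(n_modes)) {
    R <- Re(stats::mvfft(X * gains[[c_i]], inverse = TRUE)) / S
    Kc <- if (method == "collocation") bs$Binv %*% R else bs$Wq %*% R
    Ec <- Kc^2 * (S^2 / 2) * bs$j1sq
    tot <- colSums(Ec)
    ok <- tot > 0
    P <- sweep(Ec, 2, ifelse(ok, tot, 1), "/")
    Plog <- P * log2(P)
    Plog[P == 0] <- 0
    sse <- -colSums(Plog)
    we <- ifelse(colSums(Ec < 1e-300) > 0, 0,
                 exp(colMeans(log(pmax(Ec, 1e-300)))) / colMeans(Ec))
    lee <- -colSums(log2(pmax(P, floor)))
    sse[!ok] <- NA_real_; we[!ok] <- NA_real_; lee[!ok] <- NA_real_
    feats[, (c_i - 1) * 3 + 1:3] <- cbind(sse, we, lee)
  }
  feats
}

#' Extract Fourier-Bessel entropy features from preprocessed epochs
#'
#' For every channel of every epoch: compute the FBSE magnitude spectrum,
#' detect band boundaries on it, build the Meyer-type filter bank, extract
#' the `n_modes` narrow-band modes, re-expand each mode in the FB domain and
#' evaluate its Shannon spectral entropy, Wiener entropy and log energy
#' entropy. Features are laid out channel-major, then mode, then entropy
#' (SSE, WE, LEE), named `ch{c}_m{m}_{sse|we|lee}` with channels numbered
#' EEG first: 14 EEG channels give 168 columns, 2 ECG channels give 24, and
#' the combined modalities give 192.
#'
#' @param epochs Epoch tibble from [preprocess_trials()]; may be filtered to
#'   a single modality beforehand.
#' @param n_modes Number of narrow-band components per epoch (default 4,
#'   i.e. 3 detected boundaries).
#' @param q0,eps_max,W Scale-space parameters ([gaussian_scale_space()]).
#' @param tau Filter transition half-width; `NULL` (default) adapts it per
#'   epoch to 0.9 of the frame bound.
#' @param floor Probability floor of the log energy entropy.
#' @param method FBSE analysis rule, see [fbse_transform()].
#' @param degenerate How to fill feature values of an all-zero epoch:
#'   `"zero"` (default) or `"drop"` the row.
#' @return A tibble with one row per epoch: `subject`, `trial`, `epoch`,
#'   the three ratings, and one numeric column per feature.
#' @export
extract_features <- function(epochs, n_modes = 4, q0 = 0.5, eps_max = NULL,
                             W = 5, tau = NULL, floor = 1e-12,
                             method = c("collocation", "quadrature"),
                             degenerate = c("zero", "drop")) {
  method <- match.arg(method)
  degenerate <- match.arg(degenerate)
  chans <- dplyr::arrange(
    dplyr::distinct(epochs, .data$modality, .data$channel),
    factor(.data$modality, levels = c("eeg", "ecg")), .data$channel
  )
  blocks <- vector("list", nrow(chans))
  base <- NULL
  for (ci in seq_len(nrow(chans))) {
    sub <- dplyr::arrange(
      dplyr::filter(epochs, .data$modality == chans$modality[ci],
                    .data$channel == chans$channel[ci]),
      .data$subject, .data$trial, .data$epoch
    )
    if (ci == 1L) {
      base <- dplyr::select(sub, "subject", "trial", "epoch",
                            "arousal", "valence", "dominance")
    }
    key <- paste(sub$subject, sub$trial)
    feats <- matrix(NA_real_, nrow(sub), n_modes * 3)
    for (k in unique(key)) {
      rows <- which(key == k)
      E <- matrix(unlist(sub$samples[rows]), ncol = length(rows))
      feats[rows, ] <- .channel_features(E, sub$fs[rows[1]], n_modes, q0,
                                         eps_max, W, tau, floor, method)
    }
    colnames(feats) <- paste0(
      "ch", ci, "_m", rep(seq_len(n_modes), each = 3), "_",
      rep(c("sse", "we", "lee"), n_modes)
    )
    blocks[[ci]] <- feats
  }
  fm <- dplyr::bind_cols(base, tibble::as_tibble(do.call(cbind, blocks)))
  bad <- !stats::complete.cases(fm)
  if (any(bad)) {
    if (degenerate == "drop") {
      fm <- fm[!bad, ]
    } else {
      fm[bad, ] <- lapply(fm[bad, ], function(col) {
        if (is.numeric(col)) tidyr::replace_na(col, 0) else col
      })
    }
  }
  fm
}

.feature_cols <- function(fm) grep("^ch\\d+_m\\d+_", names(fm), value = TRUE)

# Centred moving average with shrunken edge windows.
.moving_avg <- function(x, w) {
  h <- (w - 1L) / 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - h)
  hi <- pmin(n, seq_len(n) + h)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Smooth feature trajectories within each trial
#'
#' Replaces every feature column by its centred moving average over
#' consecutive epochs of the same trial (default window 3). Edge epochs use
#' the shrunken window that fits; `window = 1` is the identity. Emotion
#' evolves slowly relative to 1-s epochs, so temporal smoothing suppresses
#' epoch-level feature noise.
#'
#' @param fm Feature tibble from [extract_features()].
#' @param window Odd positive window length in epochs (default 3).
#' @return `fm` with smoothed feature columns, rows ordered by
#'   subject/trial/epoch.
#' @export
smooth_features <- function(fm, window = 3) {
  if (length(window) != 1L || window < 1 || window %% 2 == 0) {
    stop_fbewt("`window` must be an odd positive integer.",
               "fbewt_invalid_argument")
  }
  if (window == 1) return(fm)
  cols <- .feature_cols(fm)
  fm <- dplyr::arrange(fm, .data$subject, .data$trial, .data$epoch)
  dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(fm, .data$subject, .data$trial),
    dplyr::across(dplyr::all_of(cols), ~ .moving_avg(.x, window))
  ))
}

#' Binarise a 1-5 emotion rating
#'
#' Ratings up to 3 are "low" (0); 4 and 5 are "high" (1).
#'
#' @param rating Integer vector with values in 1..5.
#' @return Integer vector of 0/1 labels.
#' @examples
#' labelize(1:5)
#' @export
labelize <- function(rating) {
  if (any(!rating %in% 1:5)) {
    stop_fbewt("ratings must lie in 1..5.", "fbewt_invalid_argument")
  }
  as.integer(rating > 3)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity \eqn{TP/(TP+FN)}, specificity \eqn{TN/(FP+TN)},
#' precision \eqn{TP/(TP+FP)} and F1 score \eqn{2TP/(2TP+FP+FN)}, all as
#' percentages.
#'
#' @param tp,tn,fp,fn Confusion counts (class "high" = positive).
#' @return Named numeric vector of the five percentages.
#' @examples
#' confusion_metrics(tp = 8, tn = 7, fp = 3, fn = 2)
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  100 * c(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (fp + tn),
    precision = tp / (tp + fp),
    f1 = 2 * tp / (2 * tp + fp + fn)
  )
}

#' Cross-validated evaluation of one emotion dimension
#'
#' Binarises the chosen dimension's ratings, randomly assigns epochs to
#' `k_folds` folds independent of subject (fold sizes differ by at most 1),
#' fits the classifier on each training split, predicts the held-out fold,
#' pools the confusion counts over folds and reports the five metrics of
#' [confusion_metrics()]. Deterministic for a fixed `seed`.
#'
#' @param fm Feature tibble from [extract_features()] (optionally smoothed).
#' @param dimension `"arousal"`, `"valence"` or `"dominance"`.
#' @param classifier A [classifier_spec()] (default KNN, k = 1, Euclidean).
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `fbewt_eval`: confusion counts, metric
#'   percentages, per-fold accuracies, fold assignment vector, the
#'   classifier spec, `k_folds` and `seed`. See [tidy.fbewt_eval()] and
#'   [glance.fbewt_eval()].
#' @export
crossval_evaluate <- function(fm,
                              dimension = c("arousal", "valence", "dominance"),
                              classifier = classifier_spec(),
                              k_folds = 5, seed = 1) {
  dimension <- match.arg(dimension)
  y <- labelize(fm[[dimension]])
  if (length(unique(y)) < 2) {
    stop_fbewt("labels are single-class; nothing to discriminate.",
               "fbewt_degenerate_input")
  }
  if (min(table(y)) < k_folds) {
    stop_fbewt("need at least `k_folds` observations in each class.",
               "fbewt_degenerate_input")
  }
  x <- as.matrix(fm[, .feature_cols(fm)])
  n <- nrow(x)
  set.seed(seed)
  folds <- sample(rep(seq_len(k_folds), length.out = n))
  tp <- tn <- fp <- fn <- 0L
  per_fold <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    te <- folds == f
    fit <- fit_classifier(classifier, x[!te, , drop = FALSE], y[!te])
    pred <- predict(fit, x[te, , drop = FALSE])
    truth <- y[te]
    tp <- tp + sum(pred == 1 & truth == 1)
    tn <- tn + sum(pred == 0 & truth == 0)
    fp <- fp + sum(pred == 1 & truth == 0)
    fn <- fn + sum(pred == 0 & truth == 1)
    per_fold[f] <- 100 * mean(pred == truth)
  }
  structure(
    list(
      dimension = dimension,
      confusion = c(tp = tp, tn = tn, fp = fp, fn = fn),
      metrics = confusion_metrics(tp, tn, fp, fn),
      per_fold = tibble::tibble(fold = seq_len(k_folds),
                                n_test = as.integer(table(folds)),
                                accuracy = per_fold),
      folds = folds,
      classifier = classifier,
      k_folds = k_folds,
      seed = seed,
      n = n
    ),
    class = "fbewt_eval"
  )
}

#' @export
print.fbewt_eval <- function(x, ...) {
  cat(sprintf("<fbewt_eval> %s, %d-fold CV, %s classifier, n = %d\n",
              x$dimension, x$k_folds, x$classifier$classifier, x$n))
  cat(sprintf("  confusion: TP %d  TN %d  FP %d  FN %d\n",
              x$confusion["tp"], x$confusion["tn"],
              x$confusion["fp"], x$confusion["fn"]))
  m <- x$metrics
  cat(sprintf(
    "  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  precision %.2f%%  F1 %.2f%%\n",
    m["accuracy"], m["sensitivity"], m["specificity"], m["precision"], m["f1"]))
  invisible(x)
}
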