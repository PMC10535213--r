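#' Subject-level split plan
#'
#' Shuffles the subject ids with the seed and assigns `floor(n * ratio)`
#' subjects to the training, test and cross-subject sets in that order. With
#' 32 subjects and the default 0.6/0.2/0.2 ratios this gives 19/6/6 with one
#' subject left over; the default policy leaves the extra subject unassigned
#' (matching those printed counts), `leftover = "train"` adds it to the
#' training set.
#'
#' @param subject_ids vector of ids (at least 3).
#' @param ratios train/test/cross fractions, summing to at most 1.
#' @param seed shuffle seed.
#' @param leftover policy for subjects not covered by the floor counts.
#' @return object of class `split_plan` with `train`, `test`, `cross`,
#'   `unassigned`.
#' @export
split_subjects <- function(subject_ids, ratios = c(0.6, 0.2, 0.2), seed = 1,
                           leftover = c("unassigned", "train")) {
  leftover <- match.arg(leftover)
  n <- length(subject_ids)
  if (n < 3) stop("need at least 3 subjects")
  if (length(ratios) != 3 || any(ratios < 0) || sum(ratios) > 1 + 1e-9)
    stop("ratios must be three nonnegative fractions summing to <= 1")
  sizes <- floor(n * ratios)
  ids <- with_seed(seed, sample(subject_ids))
  train <- ids[seq_len(sizes[1])]
  test <- ids[sizes[1] + seq_len(sizes[2])]
  cross <- ids[sizes[1] + sizes[2] + seq_len(sizes[3])]
  rest <- setdiff(ids, c(train, test, cross))
  if (leftover == "train" && length(rest)) {
    train <- c(train, rest); rest <- rest[0]
  }
  structure(list(train = train, test = test, cross = cross,
                 unassigned = rest, ratios = ratios, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan (%s): train %d, test %d, cross %d, unassigned %d\n",
              paste(x$ratios, collapse = "/"), length(x$train),
              length(x$test), length(x$cross), length(x$unassigned)))
  invisible(x)
}

#' Generate and featurise a synthetic cohort
#'
#' Experiment driver that maps each synthetic subject through baseline
#' removal, differential-entropy featurisation and sequence construction
#' without retaining the raw recordings, so full cohorts stay cheap in
#' memory. Sequences can be subsampled per subject (stratified, seeded) to
#' scale an experiment down.
#'
#' @param n_subjects cohort size.
#' @param cfg a [synth_config()].
#' @param distortion_strength passed to the cohort profile draws.
#' @param dimension emotion dimension for the labels.
#' @param seq_len segments per sequence.
#' @param n_per_subject optional cap on sequences per subject.
#' @param window_s segment window in seconds.
#' @return list of per-subject entries `list(batch, profile, subject_id)`.
#' @export
cohort_features <- function(n_subjects, cfg, distortion_strength = 0,
                            dimension = "valence", seq_len = 10,
                            n_per_subject = NULL, window_s = 0.5) {
  profiles <- draw_profiles(n_subjects, cfg, distortion_strength)
  lapply(profiles, function(pr) {
    sub <- generate_subject(pr, cfg)
    rec <- strip_baseline(sub$recording, cfg$baseline_s)
    ft <- featurize(rec, sub$ratings, window_s = window_s)
    batch <- make_sequences(ft, dimension, seq_len)
    if (!is.null(n_per_subject))
      batch <- subsample_sequences(batch, n_per_subject,
                                   seed = derive_seed(cfg$seed, pr$subject_id + 5000))
    list(batch = batch, profile = pr, subject_id = pr$subject_id)
  })
}

#' Ten-fold cross-validation of the classifier
#'
#' Assigns sequences to `folds` seeded folds (sizes differing by at most
#' one), trains on the remainder and scores the held-out fold.
#'
#' @param batch training `sequence_batch`.
#' @param config a [net_config()].
#' @param folds number of folds (>= 2, at most the number of sequences).
#' @param epochs,lr training parameters per fold.
#' @param seed seed governing fold assignment and every fold's training.
#' @param verbose print per-fold accuracy.
#' @return object of class `cv_result`: `fold_accuracy`, `mean_accuracy`,
#'   `fold` assignment.
#' @export
run_cv <- function(batch, config = net_config(), folds = 10, epochs = 100,
                   lr = 0.001, seed = 1, verbose = FALSE) {
  n <- length(batch$label)
  if (folds < 2 || folds > n) stop("folds must lie in [2, n_sequences]")
  fold <- with_seed(derive_seed(seed, 31), sample(rep(seq_len(folds),
                                                      length.out = n)))
  acc <- numeric(folds)
  for (k in seq_len(folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    net <- emotion_net(subset_sequences(batch, tr), config, epochs = epochs,
                       lr = lr, seed = derive_seed(seed, 100 + k))
    cls <- predict(net, subset_sequences(batch, te), type = "class")
    acc[k] <- mean(cls == batch$label[te])
    if (verbose) cat(sprintf("fold %2d  accuracy %.4f\n", k, acc[k]))
  }
  structure(list(fold_accuracy = acc, mean_accuracy = mean(acc), fold = fold),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds, mean accuracy %.4f\n",
              length(x$fold_accuracy), x$mean_accuracy))
  cat("  folds:", paste(sprintf("%.3f", x$fold_accuracy), collapse = " "), "\n")
  invisible(x)
}

#' Train the final model on all training sequences
#'
#' Thin wrapper over [emotion_net()] that optionally writes a checkpoint
#' (RDS plus JSON config sidecar). Training aborts with a diagnostic on a
#' non-finite loss; the per-epoch loss curve is kept in the fit's `history`.
#'
#' @inheritParams run_cv
#' @param checkpoint optional path for [save_model()].
#' @return the fitted `emotion_net`.
#' @export
train_full <- function(batch, config = net_config(), epochs = 100, lr = 0.001,
                       seed = 1, checkpoint = NULL, verbose = FALSE) {
  net <- emotion_net(batch, config, epochs = epochs, lr = lr, seed = seed,
                     verbose = verbose)
  if (!is.null(checkpoint)) save_model(net, checkpoint)
  net
}

#' 2x2 confusion matrix
#'
#' Rows are predicted classes, columns true classes.
#'
#' @param predicted,truth 0/1 vectors of equal length.
#' @return 2x2 integer matrix with dimnames `pred_0/1` x `true_0/1`.
#' @export
confusion_matrix <- function(predicted, truth) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  m <- matrix(0L, 2, 2, dimnames = list(c("pred_0", "pred_1"),
                                        c("true_0", "true_1")))
  for (p in 0:1) for (t in 0:1)
    m[p + 1, t + 1] <- sum(predicted == p & truth == t)
  m
}

#' Apply a subject's score distortion to model outputs
#'
#' Emulates the individual response mapping: the two-unit scores are
#' normalised to a positive-class probability `p`, the subject's monotone
#' distortion is applied, and the pair `(1 - d(p), d(p))` is returned (a
#' single-unit score is distorted directly). A common monotone map applied to
#' both raw units would leave the argmax decision unchanged, so the
#' distortion acts on the class probability, which shifts the effective
#' decision threshold away from 0.5 - exactly the miscalibration the
#' isotonic observer is meant to undo.
#'
#' @param scores n x 2 (or n x 1) score matrix.
#' @param profile a [subject_profile()] carrying the distortion.
#' @return distorted score matrix of the same shape.
#' @export
apply_score_distortion <- function(scores, profile) {
  s <- as.matrix(scores)
  d <- profile$distortion
  if (ncol(s) == 1) return(matrix(d(pmin(pmax(s[, 1], 0), 1)), ncol = 1))
  p <- s[, 2] / pmax(s[, 1] + s[, 2], 1e-12)
  pd <- d(pmin(pmax(p, 0), 1))
  cbind(1 - pd, pd)
}

#' Cross-subject evaluation with and without calibration
#'
#' Scores each held-out subject with the trained network, optionally applies
#' the subject's score distortion (when a profile is present), and reports
#' per-subject accuracy and confusion matrices. With `with_calibration = TRUE` the
#' subject's sequences are split into calibration and evaluation halves, an
#' isotonic map is fitted per output unit on the calibration half, and the
#' paired raw/calibrated accuracies are reported on the evaluation half only
#' (no leakage), giving the paired with/without-calibration table.
#'
#' @param net a fitted [emotion_net()].
#' @param subjects list of per-subject entries as from [cohort_features()]
#'   (`batch`, optional `profile`, `subject_id`).
#' @param with_calibration also fit and apply per-subject isotonic calibration.
#' @param calib_fraction fraction of each subject's sequences used for
#'   calibration when `with_calibration`.
#' @param seed seed for the calibration splits.
#' @param distort apply each subject's score distortion before evaluation.
#' @return object of class `evaluation_report`: per-subject table
#'   (`subject`, `n_eval`, `accuracy_raw`, `accuracy_calibrated`,
#'   `delta`), confusion matrices, mean accuracies and the config echo.
#' @export
evaluate_cohort <- function(net, subjects, with_calibration = FALSE,
                            calib_fraction = 0.5, seed = 1, distort = TRUE) {
  stopifnot(inherits(net, "emotion_net"))
  rows <- list(); confusion <- list(); residuals <- list()
  for (s in subjects) {
    sid <- s$subject_id %||% s$profile$subject_id
    scores <- predict(net, s$batch)
    if (distort && !is.null(s$profile))
      scores <- apply_score_distortion(scores, s$profile)
    truth <- s$batch$label
    if (with_calibration) {
      cal <- calibrate_subject(scores, s$batch$labels,
                               calib_fraction = calib_fraction,
                               seed = derive_seed(seed, sid))
      truth_eval <- truth[cal$idx_eval]
      cm_raw <- confusion_matrix(cal$class_raw, truth_eval)
      cm_cal <- confusion_matrix(cal$class_calibrated, truth_eval)
      rows[[length(rows) + 1]] <- data.frame(
        subject = sid, n_eval = length(cal$idx_eval),
        accuracy_raw = cal$accuracy_raw,
        accuracy_calibrated = cal$accuracy_calibrated,
        delta = cal$accuracy_calibrated - cal$accuracy_raw)
      confusion[[as.character(sid)]] <- list(raw = cm_raw, calibrated = cm_cal)
      residuals[[length(residuals) + 1]] <- cbind(
        observer_residuals(cal$scores_eval, cal$calibrated_eval,
                           cal$labels_eval)[, -1, drop = FALSE],
        subject = sid)
    } else {
      cls <- predict_class(scores)
      cm <- confusion_matrix(cls, truth)
      rows[[length(rows) + 1]] <- data.frame(
        subject = sid, n_eval = length(truth),
        accuracy_raw = mean(cls == truth),
        accuracy_calibrated = NA_real_, delta = NA_real_)
      confusion[[as.character(sid)]] <- list(raw = cm)
    }
  }
  tab <- do.call(rbind, rows)
  structure(list(
    subjects = tab, confusion = confusion,
    residuals = if (length(residuals)) do.call(rbind, residuals) else NULL,
    mean_accuracy_raw = mean(tab$accuracy_raw),
    mean_accuracy_calibrated = if (with_calibration) mean(tab$accuracy_calibrated) else NA_real_,
    with_calibration = with_calibration, calib_fraction = calib_fraction, seed = seed,
    dimension = net$dimension
  ), class = "evaluation_report")
}

#' Multi-seed with/without-calibration study
#'
#' Repeats the cross-subject experiment over `n_seeds` fresh draws: each seed
#' generates a new cohort of held-out subjects (with score distortions drawn
#' at the given strength), scores them with the trained network, and compares
#' mean accuracy with and without per-subject isotonic calibration on the
#' evaluation halves.
#'
#' @param net a fitted [emotion_net()].
#' @param base_cfg the [synth_config()] the study derives its per-seed
#'   generator configurations from.
#' @param n_seeds number of independent repetitions.
#' @param n_cross held-out subjects per seed.
#' @param distortion_strength spread of the per-subject score distortions.
#' @param n_per_subject sequences kept per subject.
#' @param calib_fraction fraction of each subject's sequences used for
#'   calibration.
#' @return data frame with one row per seed: `seed`,
#'   `accuracy_raw`, `accuracy_calibrated`, `delta`, `win`
#'   (calibrated at least as accurate).
#' @export
calibration_seed_study <- function(net, base_cfg, n_seeds = 10, n_cross = 2,
                           distortion_strength = 1, n_per_subject = 120,
                           calib_fraction = 0.5) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    cfg_s <- base_cfg
    cfg_s$seed <- derive_seed(base_cfg$seed, 9000 + s)
    subs <- cohort_features(n_cross, cfg_s, distortion_strength,
                            dimension = net$dimension %||% "valence",
                            n_per_subject = n_per_subject)
    rep <- evaluate_cohort(net, subs, with_calibration = TRUE,
                           calib_fraction = calib_fraction,
                           seed = derive_seed(base_cfg$seed, 9100 + s))
    data.frame(seed = s,
               accuracy_raw = rep$mean_accuracy_raw,
               accuracy_calibrated = rep$mean_accuracy_calibrated,
               delta = rep$mean_accuracy_calibrated -
                 rep$mean_accuracy_raw,
               win = rep$mean_accuracy_calibrated >=
                 rep$mean_accuracy_raw)
  })
  do.call(rbind, rows)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s)%s\n", x$dimension %||% "?",
              if (x$with_calibration) ", paired with/without calibration" else ""))
  print(x$subjects, row.names = FALSE, digits = 4)
  cat(sprintf("mean accuracy without calibration: %.4f\n",
              x$mean_accuracy_raw))
  if (x$with_calibration)
    cat(sprintf("mean accuracy with calibration:    %.4f\n",
                x$mean_accuracy_calibrated))
  invisible(x)
}

#' Serialise an evaluation report deterministically
#'
#' @param report an `evaluation_report`.
#' @param path optional file to write the JSON to.
#' @return the JSON string, invisibly when `path` is given.
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(
    dimension = report$dimension, with_calibration = report$with_calibration,
    calib_fraction = report$calib_fraction, seed = report$seed,
    subjects = report$subjects,
    mean_accuracy_raw = report$mean_accuracy_raw,
    mean_accuracy_calibrated = report$mean_accuracy_calibrated,
    confusion = lapply(report$confusion, function(cl)
      lapply(cl, function(m) unname(as.matrix(m))))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
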