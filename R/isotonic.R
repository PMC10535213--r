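#' Weighted isotonic regression by pair-adjacent violators
#'
#' Fits the monotone step function minimising
#' `sum(w * (y - yhat)^2)` subject to `yhat` nondecreasing in the score `f`,
#' the calibration map used to absorb per-subject differences between raw
#' classifier scores and observed labels. Adjacent violators are pooled to
#' their weighted mean, cascading left while any violation remains, which
#' yields the unique constrained least-squares solution. Exact ties in `f`
#' are pre-pooled by weighted mean so the fit is well defined.
#'
#' @param f numeric vector of raw scores (the regressor).
#' @param y numeric vector of observations (0/1 labels for calibration).
#' @param w positive case weights (default all 1).
#' @return an object of class `isotonic_fit`: `x` (ascending pooled scores),
#'   `fit` (fitted values, nondecreasing), `thresholds` (score breakpoints,
#'   strictly ascending, one per block), `block_values` (fitted value per
#'   block), `fitted` and `residuals` aligned with the input order, `M` the
#'   number of items.
#' @seealso [predict.isotonic_fit()], [calibrate_subject()]
#' @export
pav_fit <- function(f, y, w = NULL) {
  M <- length(y)
  if (M < 1) stop("empty calibration set")
  if (length(f) != M) stop("f and y must have equal length")
  w <- w %||% rep(1, M)
  if (length(w) != M) stop("w must match y in length")
  if (any(w <= 0)) stop("weights must be positive")

  ord <- order(f)
  fs <- f[ord]; ys <- y[ord]; ws <- w[ord]
  # pre-pool exact score ties by weighted mean
  grp <- cumsum(c(TRUE, diff(fs) > 0))
  xs <- tapply(fs, grp, `[`, 1)
  wg <- as.numeric(tapply(ws, grp, sum))
  yg <- as.numeric(tapply(ws * ys, grp, sum)) / wg
  m <- length(xs)

  # stack-based PAV: pool while the previous block mean exceeds the next
  val <- numeric(m); wt <- numeric(m); cnt <- integer(m)
  top <- 0L
  for (i in seq_len(m)) {
    top <- top + 1L
    val[top] <- yg[i]; wt[top] <- wg[i]; cnt[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      wsum <- wt[top - 1L] + wt[top]
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) / wsum
      wt[top - 1L] <- wsum
      cnt[top - 1L] <- cnt[top - 1L] + cnt[top]
      top <- top - 1L
    }
  }
  fit_g <- rep(val[seq_len(top)], cnt[seq_len(top)])

  fitted_sorted <- fit_g[grp]
  fitted <- numeric(M)
  fitted[ord] <- fitted_sorted
  blocks <- c(TRUE, diff(fit_g) != 0)
  structure(list(
    x = as.numeric(xs), fit = fit_g,
    thresholds = as.numeric(xs)[blocks], block_values = fit_g[blocks],
    fitted = fitted, residuals = y - fitted, M = M
  ), class = "isotonic_fit")
}

#' Evaluate the calibration step function
#'
#' Right-continuous stepwise-constant evaluation: a score falling in a block's
#' interval returns that block's value; scores below the first breakpoint and
#' above the last clamp to the outer block values. The fit only pins the
#' function at the observed scores, so between two adjacent observed scores
#' the jump is placed at their midpoint - a new score is assigned the value
#' of the nearest observed neighbourhood rather than being pulled to the
#' lower block across the whole gap.
#'
#' @param object an [pav_fit()] result.
#' @param newdata numeric vector of raw scores.
#' @param ... unused.
#' @return calibrated values.
#' @export
predict.isotonic_fit <- function(object, newdata, ...) {
  x <- object$x
  if (length(x) == 1) return(rep(object$fit, length(newdata)))
  cuts <- (x[-1] + x[-length(x)]) / 2
  object$fit[findInterval(newdata, cuts) + 1]
}

#' @export
fitted.isotonic_fit <- function(object, ...) object$fitted

#' @export
residuals.isotonic_fit <- function(object, ...) object$residuals

#' @export
print.isotonic_fit <- function(x, ...) {
  cat(sprintf("isotonic_fit: %d items pooled into %d block(s)\n",
              x$M, length(x$block_values)))
  cat("  block values:", paste(sprintf("%.4f", x$block_values), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
plot.isotonic_fit <- function(x, ...) {
  graphics::plot(x$x, x$fit, type = "s", xlab = "raw score",
                 ylab = "calibrated value", main = "isotonic calibration", ...)
  invisible(x)
}

#' Per-subject score calibration
#'
#' Splits one held-out subject's scored sequences into a calibration part and
#' an evaluation part (stratified by true class), fits one isotonic map per
#' output unit on the calibration part, and applies it to the evaluation
#' part. If the calibration part contains a single class, the calibration
#' falls back to the identity with a warning rather than producing a constant
#' classifier.
#'
#' @param scores n x 2 (or n x 1) matrix of raw model scores for the subject.
#' @param labels matching one-hot (or single-column 0/1) label matrix.
#' @param calib_fraction fraction of sequences used to fit the calibration.
#' @param seed seed for the stratified split.
#' @param min_sequences minimum sequences the subject must have.
#' @return list with `models` (per-unit `isotonic_fit` or `NULL` on
#'   fallback), `idx_calib`, `idx_eval`, `scores_eval` (raw),
#'   `calibrated_eval`, `labels_eval`, `class_raw`, `class_calibrated`,
#'   `accuracy_raw`, `accuracy_calibrated`, `fallback`.
#' @export
calibrate_subject <- function(scores, labels, calib_fraction = 0.5, seed = 1,
                              min_sequences = 10) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  n <- nrow(scores)
  if (n < min_sequences) stop("subject has fewer than ", min_sequences,
                              " sequences")
  if (calib_fraction <= 0 || calib_fraction >= 1)
    stop("calib_fraction must lie in (0, 1)")
  truth <- if (ncol(labels) == 2) labels[, 2] else labels[, 1]
  idx_calib <- with_seed(seed, {
    unlist(lapply(0:1, function(cl) {
      pool <- which(truth == cl)
      sample(pool, floor(length(pool) * calib_fraction))
    }))
  })
  idx_calib <- sort(idx_calib)
  idx_eval <- setdiff(seq_len(n), idx_calib)
  fallback <- length(unique(truth[idx_calib])) < 2
  if (fallback) {
    warning("single-class calibration split; falling back to identity calibration")
    models <- NULL
    calibrated <- scores[idx_eval, , drop = FALSE]
  } else {
    models <- lapply(seq_len(ncol(scores)), function(u)
      pav_fit(scores[idx_calib, u], labels[idx_calib, u]))
    calibrated <- vapply(seq_len(ncol(scores)), function(u)
      predict(models[[u]], scores[idx_eval, u]), numeric(length(idx_eval)))
    calibrated <- matrix(calibrated, nrow = length(idx_eval))
  }
  cls_raw <- predict_class(scores[idx_eval, , drop = FALSE])
  cls_cal <- predict_class(calibrated)
  list(
    models = models, idx_calib = idx_calib, idx_eval = idx_eval,
    scores_eval = scores[idx_eval, , drop = FALSE],
    calibrated_eval = calibrated,
    labels_eval = labels[idx_eval, , drop = FALSE],
    class_raw = cls_raw, class_calibrated = cls_cal,
    accuracy_raw = mean(cls_raw == truth[idx_eval]),
    accuracy_calibrated = mean(cls_cal == truth[idx_eval]),
    fallback = fallback
  )
}

#' Observer residual summary
#'
#' The observer's error signal is the difference between observed labels and
#' predicted scores. This summarises the mean residual per subject before and
#' after calibration; effective calibration shrinks its magnitude.
#'
#' @param scores_before,scores_after score matrices aligned with `labels`.
#' @param labels one-hot (or single-column) label matrix.
#' @param subject subject id per row (default: one subject).
#' @return data frame with one row per subject: `subject`, `n`,
#'   `mean_residual_before`, `mean_residual_after`.
#' @export
observer_residuals <- function(scores_before, scores_after, labels,
                               subject = NULL) {
  sb <- as.matrix(scores_before); sa <- as.matrix(scores_after)
  lb <- as.matrix(labels)
  if (!identical(dim(sb), dim(lb)) || !identical(dim(sa), dim(lb)))
    stop("scores and labels are misaligned")
  subject <- subject %||% rep(1L, nrow(lb))
  if (length(subject) != nrow(lb)) stop("subject vector is misaligned")
  ids <- unique(subject)
  out <- do.call(rbind, lapply(ids, function(id) {
    r <- subject == id
    data.frame(subject = id, n = sum(r),
               mean_residual_before = mean(lb[r, ] - sb[r, ]),
               mean_residual_after = mean(lb[r, ] - sa[r, ]))
  }))
  rownames(out) <- NULL
  out
}
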