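#' Build consecutive-segment sequences for the recurrent classifier
#'
#' Groups consecutive feature-map segments within each trial into
#' non-overlapping runs of `seq_len` (default 10, i.e. 5 s of context at 0.5-s
#' windows). Sequences never span trial boundaries; each inherits the binary
#' label of its trial on the requested emotion dimension as a one-hot pair
#' (negative, positive).
#'
#' @param ft a [featurize()] result carrying labels.
#' @param dimension `"valence"` or `"arousal"`.
#' @param seq_len segments per sequence (`>= 1`).
#' @return object of class `sequence_batch`: `inputs` array
#'   n x seq_len x bands x 9 x 9, `labels` n x 2 one-hot matrix, `label`
#'   integer 0/1 vector, provenance `subject`, `trial`.
#' @export
make_sequences <- function(ft, dimension = c("valence", "arousal"),
                           seq_len = 10) {
  stopifnot(inherits(ft, "feature_tensor"), seq_len >= 1)
  dimension <- match.arg(dimension)
  lab_all <- switch(dimension, valence = ft$labels_valence,
                    arousal = ft$labels_arousal)
  if (is.null(lab_all)) stop("feature tensor carries no ", dimension, " labels")
  d <- dim(ft$values)
  k <- ft$segs_per_trial
  runs <- k %/% seq_len
  if (runs < 1) stop("seq_len exceeds the segments available per trial")
  trials <- unique(ft$trial)
  n <- length(trials) * runs
  inputs <- array(0, dim = c(n, seq_len, d[2], d[3], d[4]))
  label <- integer(n); trial_of <- integer(n)
  i <- 0L
  for (tr in trials) {
    segs <- which(ft$trial == tr)
    for (r in seq_len(runs)) {
      i <- i + 1L
      take <- segs[(r - 1) * seq_len + seq_len(seq_len)]
      inputs[i, , , , ] <- ft$values[take, , , , drop = FALSE]
      label[i] <- lab_all[segs[1]]
      trial_of[i] <- tr
    }
  }
  structure(list(
    inputs = inputs, labels = cbind(1 - label, label), label = label,
    subject = rep(ft$subject_id %||% NA_integer_, n), trial = trial_of,
    dimension = dimension
  ), class = "sequence_batch")
}

#' Subset a sequence batch
#'
#' @param batch a `sequence_batch`.
#' @param idx integer indices of the sequences to keep.
#' @return the subsetted `sequence_batch`.
#' @export
subset_sequences <- function(batch, idx) {
  stopifnot(inherits(batch, "sequence_batch"))
  structure(list(
    inputs = batch$inputs[idx, , , , , drop = FALSE],
    labels = batch$labels[idx, , drop = FALSE], label = batch$label[idx],
    subject = batch$subject[idx], trial = batch$trial[idx],
    dimension = batch$dimension
  ), class = "sequence_batch")
}

#' Stratified subsample of a sequence batch
#'
#' Draws `n` sequences balanced across the two classes (seeded), the
#' package's standard way of scaling an experiment down.
#'
#' @param batch a `sequence_batch`.
#' @param n number of sequences to keep.
#' @param seed RNG seed for the draw.
#' @return a `sequence_batch` of `n` sequences.
#' @export
subsample_sequences <- function(batch, n, seed = 1) {
  stopifnot(inherits(batch, "sequence_batch"))
  n_tot <- length(batch$label)
  if (n >= n_tot) return(batch)
  with_seed(seed, {
    idx <- unlist(lapply(0:1, function(cl) {
      pool <- which(batch$label == cl)
      take <- min(length(pool), ceiling(n * length(pool) / n_tot))
      sample(pool, take)
    }))
    idx <- sort(sample(idx, min(n, length(idx))))
    subset_sequences(batch, idx)
  })
}

#' Concatenate sequence batches
#'
#' @param ... `sequence_batch` objects with matching shapes and dimension.
#' @return the combined `sequence_batch`.
#' @export
bind_sequences <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "sequence_batch")) parts <- parts[[1]]
  stopifnot(all(vapply(parts, inherits, TRUE, "sequence_batch")))
  d <- dim(parts[[1]]$inputs)
  n <- sum(vapply(parts, function(p) dim(p$inputs)[1], 1L))
  inputs <- array(0, dim = c(n, d[-1]))
  at <- 0L
  for (p in parts) {
    np <- dim(p$inputs)[1]
    if (np) inputs[at + seq_len(np), , , , ] <- p$inputs
    at <- at + np
  }
  structure(list(
    inputs = inputs,
    labels = do.call(rbind, lapply(parts, `[[`, "labels")),
    label = unlist(lapply(parts, `[[`, "label")),
    subject = unlist(lapply(parts, `[[`, "subject")),
    trial = unlist(lapply(parts, `[[`, "trial")),
    dimension = parts[[1]]$dimension
  ), class = "sequence_batch")
}

#' @export
print.sequence_batch <- function(x, ...) {
  d <- dim(x$inputs)
  cat(sprintf("sequence_batch: %d sequences x %d steps x %dx%dx%d (%s; %d/%d neg/pos)\n",
              d[1], d[2], d[3], d[4], d[5], x$dimension,
              sum(x$label == 0), sum(x$label == 1)))
  invisible(x)
}
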