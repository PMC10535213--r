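#' Differential entropy of a signal segment
#'
#' Under the Gaussian assumption the differential entropy of a band-filtered
#' segment reduces to `0.5 * log(2 * pi * e * var(x))` in nats, with the
#' variance estimated as the unbiased sample variance. A variance floor
#' (default 1e-12) guards the logarithm against pathological constant
#' segments; hitting the floor raises a warning.
#'
#' @param x numeric vector, length >= 2, finite.
#' @param var_floor lower bound on the variance estimate.
#' @return differential entropy in nats.
#' @export
differential_entropy <- function(x, var_floor = 1e-12) {
  if (length(x) < 2 || any(!is.finite(x))) stop("x must be >= 2 finite values")
  v <- var(x)
  if (v < var_floor) {
    warning("variance below floor; returning floored differential entropy")
    v <- var_floor
  }
  0.5 * log(2 * pi * exp(1) * v)
}

# spec-registry placements of the 32-channel montage on the 9x9 scalp grid
GRID_PLACEMENT <- data.frame(
  channel = c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
              "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
              "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
              "PO3", "PO4", "O1", "Oz", "O2"),
  row = c(0, 0, 1, 1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 4,
          5, 5, 5, 5, 6, 6, 6, 6, 6, 7, 7, 8, 8, 8),
  col = c(3, 5, 3, 5, 0, 2, 4, 6, 8, 1, 3, 5, 7, 0, 2, 4, 6, 8,
          1, 3, 5, 7, 0, 2, 4, 6, 8, 3, 5, 3, 4, 5)
)

#' 9x9 scalp grid of the 32-channel 10-20 montage
#'
#' Maps each electrode name to a cell of a 9 x 9 grid preserving the scalp
#' topography: row 0 is frontal (the Fp line), column 0 the left side. The
#' registry is the standard 2-D layout used for DEAP-style spatial feature
#' maps; alternative layouts can be supplied as a replacement registry.
#'
#' @param layout optional replacement registry: data frame with columns
#'   `channel`, `row`, `col` (0-based, within the 9x9 grid, unique cells).
#' @return an `electrode_grid` data frame (`channel`, `row`, `col`).
#' @export
electrode_grid <- function(layout = NULL) {
  g <- layout %||% GRID_PLACEMENT
  stopifnot(is.data.frame(g), all(c("channel", "row", "col") %in% names(g)))
  if (anyDuplicated(g$channel)) stop("duplicate channel in grid layout")
  if (anyDuplicated(g$row * 9 + g$col)) stop("duplicate grid cell in layout")
  if (any(g$row < 0 | g$row > 8 | g$col < 0 | g$col > 8))
    stop("grid coordinates must lie within the 9x9 grid")
  structure(g, class = c("electrode_grid", "data.frame"))
}

#' Place per-channel values on the scalp grid
#'
#' @param values named numeric vector, one value per channel name.
#' @param grid an [electrode_grid()].
#' @return 9 x 9 numeric matrix; cells without an electrode are exactly 0.
#' @export
map_to_grid <- function(values, grid = electrode_grid()) {
  if (is.null(names(values))) stop("values must be named by channel")
  idx <- match(names(values), grid$channel)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(names(values)[is.na(idx)], collapse = ", "))
  m <- matrix(0, 9, 9)
  m[cbind(grid$row[idx] + 1, grid$col[idx] + 1)] <- values
  m
}

#' Differential entropy feature tensor of one recording
#'
#' Composes the full feature pipeline: each trial is zero-phase band-pass
#' filtered in the four canonical bands, cut into non-overlapping `window_s`
#' segments, the per-channel differential entropy of each band-filtered
#' segment is computed, and the values are placed on the 9 x 9 scalp grid.
#' A default DEAP-geometry subject (40 x 32 x 7680 after baseline removal)
#' yields a 4800 x 4 x 9 x 9 tensor. Filtering happens once per whole trial,
#' before segmentation, so 0.5-s windows carry no per-window filter
#' transients.
#'
#' @param rec an `eeg_recording` with the baseline already stripped.
#' @param ratings optional ratings data frame; when given, per-segment binary
#'   labels are attached using [binarize_rating()] (threshold 5).
#' @param bands band definitions, see [eeg_bands()].
#' @param grid an [electrode_grid()] covering all channels of `rec`.
#' @param window_s segment length in seconds.
#' @param var_floor variance floor passed to the entropy estimator.
#' @return object of class `feature_tensor`: `values` array
#'   n_segments x n_bands x 9 x 9, provenance vectors `trial`, `segment`,
#'   `subject_id`, and (with ratings) `labels_valence`, `labels_arousal`.
#' @export
featurize <- function(rec, ratings = NULL, bands = eeg_bands(),
                      grid = electrode_grid(), window_s = 0.5,
                      var_floor = 1e-12) {
  stopifnot(inherits(rec, "eeg_recording"))
  idx <- match(rec$channel_names, grid$channel)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(rec$channel_names[is.na(idx)], collapse = ", "))
  rows <- grid$row[idx] + 1; cols <- grid$col[idx] + 1
  bank <- butter_bank(bands, rec$sample_rate_hz)
  d <- dim(rec$data)
  wn <- as.integer(round(window_s * rec$sample_rate_hz))
  if (wn < 2 || abs(window_s * rec$sample_rate_hz - wn) > 1e-9)
    stop("window_s must give an integer number of >= 2 samples")
  if (d[3] %% wn != 0) stop("trial length is not divisible by the window")
  k <- d[3] %/% wn
  nb <- length(bank)
  values <- array(0, dim = c(d[1] * k, nb, 9, 9))
  floored <- 0L
  for (tr in seq_len(d[1])) {
    x <- rec$data[tr, , , drop = FALSE]
    dim(x) <- c(d[2], d[3])
    xt <- t(x)                                   # samples x channels
    seg_ids <- (tr - 1) * k + seq_len(k)
    for (bi in seq_len(nb)) {
      xf <- filtfilt_mat(bank[[bi]]$b, bank[[bi]]$a, xt)
      dim(xf) <- c(wn, k, d[2])
      m <- colMeans(xf)                          # k x channels
      v <- (colSums(xf^2) - wn * m^2) / (wn - 1)
      floored <- floored + sum(v < var_floor)
      v[v < var_floor] <- var_floor
      de <- 0.5 * log(2 * pi * exp(1) * v)
      at <- cbind(rep(seg_ids, times = d[2]), bi,
                  rep(rows, each = k), rep(cols, each = k))
      values[at] <- de
    }
  }
  if (floored > 0)
    warning(floored, " segment variance(s) hit the floor; entropies clamped")
  ft <- structure(list(
    values = values, trial = rep(seq_len(d[1]), each = k),
    segment = rep(seq_len(k), times = d[1]), subject_id = rec$subject_id,
    band_names = bands$name, segs_per_trial = k
  ), class = "feature_tensor")
  if (!is.null(ratings)) {
    ord <- ratings[order(ratings$trial), ]
    ft$labels_valence <- binarize_rating(ord$valence)[ft$trial]
    ft$labels_arousal <- binarize_rating(ord$arousal)[ft$trial]
  }
  ft
}

#' @export
print.feature_tensor <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("feature_tensor: subject %s, %d segments x %d bands x %dx%d grid\n",
              x$subject_id %||% "?", d[1], d[2], d[3], d[4]))
  invisible(x)
}
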