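# Sensor-fusion feature extraction and binary conversion.
#
# Nine IMU channels are fused per time step into five features: M1-M3 are
# products of (|axis|+1) within each sensor (so each is >= 1 and grows with
# overall motion intensity of that sensor), M4 and M5 are signed cross-channel
# products sensitive to coordinated rotation/acceleration. Each feature is
# compared against its own threshold and the result coded as a bipolar +/-1
# matrix, from which the most active contiguous 5x5 window is cut as the
# activity template.

DEFAULT_THRESHOLDS <- c(16, 24, 32, 40, 48)

#' Fuse the nine IMU axes into five activity features
#'
#' Per time step `n`:
#' \deqn{M1 = (|Gx|+1)(|Gy|+1)(|Gz|+1)}
#' \deqn{M2 = (|Ax|+1)(|Ay|+1)(|Az|+1)}
#' \deqn{M3 = (|Mx|+1)(|My|+1)(|Mz|+1)}
#' \deqn{M4 = \tfrac12 (Ax\,My\,Gz - Gx\,My\,Az)}
#' \deqn{M5 = \tfrac12 (Gx\,Ay + Ax\,My + Mx\,Gy - Gx\,My - Ax\,Gy - Mx\,Ay)}
#' The computation is pointwise: each output row depends only on the same
#' input row.
#'
#' @param rec an `imu_recording`, or any numeric matrix/data frame with the
#'   nine columns `Gx,Gy,Gz,Ax,Ay,Az,Mx,My,Mz`.
#' @return a `fused_features` numeric matrix, N x 5, columns `M1..M5`.
#' @export
fuse_axes <- function(rec) {
  ch <- if (inherits(rec, "imu_recording")) rec$channels else as.matrix(rec)
  missing <- setdiff(CHANNEL_NAMES, colnames(ch))
  if (length(missing)) {
    stop("input is missing channel(s): ", paste(missing, collapse = ", "))
  }
  ch <- ch[, CHANNEL_NAMES, drop = FALSE]
  if (anyNA(ch)) stop("input channels contain missing values")
  g <- abs(ch[, c("Gx", "Gy", "Gz")]) + 1
  a <- abs(ch[, c("Ax", "Ay", "Az")]) + 1
  m <- abs(ch[, c("Mx", "My", "Mz")]) + 1
  M <- cbind(
    M1 = g[, 1] * g[, 2] * g[, 3],
    M2 = a[, 1] * a[, 2] * a[, 3],
    M3 = m[, 1] * m[, 2] * m[, 3],
    M4 = 0.5 * (ch[, "Ax"] * ch[, "My"] * ch[, "Gz"] -
                  ch[, "Gx"] * ch[, "My"] * ch[, "Az"]),
    M5 = 0.5 * (ch[, "Gx"] * ch[, "Ay"] + ch[, "Ax"] * ch[, "My"] +
                  ch[, "Mx"] * ch[, "Gy"] - ch[, "Gx"] * ch[, "My"] -
                  ch[, "Ax"] * ch[, "Gy"] - ch[, "Mx"] * ch[, "Ay"])
  )
  structure(M, class = c("fused_features", class(M)))
}

#' Threshold fused features into a bipolar 5 x N matrix
#'
#' Row `i` of the output is `+1` where the paired feature value strictly
#' exceeds `thresholds[i]`, else `-1` (a value exactly equal to the threshold
#' maps to `-1`). Two pairings are supported: `"per-feature"` (row `i`
#' thresholds feature `Mi` with its own threshold, the default) and
#' `"thermometer"` (all five rows threshold one selected feature at the five
#' levels, a thermometer code).
#'
#' @param feat a `fused_features` matrix from [fuse_axes()].
#' @param thresholds strictly increasing numeric vector of length 5.
#' @param pairing `"per-feature"` or `"thermometer"`.
#' @param thermometer_feature which feature the thermometer code reads
#'   (column index 1-5), used only for `pairing = "thermometer"`.
#' @return a `binary_features` matrix, 5 x N over \{+1, -1\}, with the
#'   thresholds and pairing stored as attributes.
#' @export
binarize <- function(feat, thresholds = DEFAULT_THRESHOLDS,
                     pairing = c("per-feature", "thermometer"),
                     thermometer_feature = 1L) {
  if (inherits(feat, "binary_features")) {
    stop("input is already a binary feature matrix; re-thresholding +/-1 values is not meaningful")
  }
  pairing <- match.arg(pairing)
  if (length(thresholds) != 5L) {
    stop("`thresholds` must have length 5, got ", length(thresholds))
  }
  if (any(diff(thresholds) <= 0)) stop("`thresholds` must be strictly increasing")
  feat <- unclass(as.matrix(feat))
  if (ncol(feat) != 5L) stop("fused feature matrix must have 5 columns M1..M5")
  n <- nrow(feat)
  out <- matrix(-1, nrow = 5L, ncol = n)
  for (i in 1:5) {
    src <- if (pairing == "per-feature") feat[, i] else feat[, thermometer_feature]
    out[i, src > thresholds[i]] <- 1          # strict inequality
  }
  rownames(out) <- paste0("M", 1:5)
  structure(out, class = c("binary_features", class(out)),
            thresholds = thresholds, pairing = pairing)
}

#' Extract the most active 5 x 5 window as a pattern template
#'
#' Scans all contiguous 5-column windows (stride 1) of the bipolar feature
#' matrix and returns the one with the largest count of `+1` entries; ties go
#' to the earliest start. This is the sliding-window step that cuts the
#' activity's feature map out of the full recording.
#'
#' @param bin a `binary_features` matrix (5 x N, N >= 5).
#' @param class_label optional activity label carried on the template.
#' @param flip if `TRUE`, reverse the window left-right (column reversal)
#'   before storing. Off by default; Hebbian storage of a pattern and of its
#'   column-reversal are equally valid templates.
#' @return a `pattern_template`: list with `grid` (5 x 5 bipolar matrix),
#'   `vector` (its row-major flattening, length 25), `window_start` (1-based
#'   index of the first column of the chosen window), `label`.
#' @export
extract_template <- function(bin, class_label = NULL, flip = FALSE) {
  if (!is.matrix(bin) || nrow(bin) != 5L) stop("`bin` must be a 5 x N matrix")
  assert_bipolar(as.vector(bin), "binary feature matrix")
  n <- ncol(bin)
  if (n < 5L) stop("need at least 5 columns for a 5 x 5 window, got ", n)
  pos_per_col <- colSums(bin == 1)
  window_sums <- stats::filter(pos_per_col, rep(1, 5), sides = 1)[5:n]
  start <- which.max(window_sums)             # which.max takes the earliest tie
  grid <- unclass(bin)[, start:(start + 4L), drop = FALSE]
  attributes(grid) <- list(dim = dim(grid))
  if (flip) grid <- grid[, 5:1]
  template(grid, label = class_label, window_start = start, flipped = flip)
}

#' Construct a pattern template from a 5 x 5 bipolar grid
#'
#' @param grid 5 x 5 matrix over \{+1, -1\}, or a length-25 bipolar vector
#'   interpreted row-major.
#' @param label optional class label.
#' @param window_start,flipped provenance fields filled by
#'   [extract_template()].
#' @return a `pattern_template`.
#' @export
template <- function(grid, label = NULL, window_start = NA_integer_,
                     flipped = FALSE) {
  if (is.vector(grid) && length(grid) == 25L) {
    grid <- matrix(grid, nrow = 5L, byrow = TRUE)
  }
  if (!is.matrix(grid) || !all(dim(grid) == c(5L, 5L))) {
    stop("template grid must be 5 x 5 (or a length-25 vector)")
  }
  assert_bipolar(as.vector(grid), "template grid")
  structure(list(grid = grid,
                 vector = as.vector(t(grid)),   # row-major: neuron k = grid[row, col]
                 label = label,
                 window_start = window_start,
                 flipped = flipped),
            class = "pattern_template")
}

#' @export
print.pattern_template <- function(x, ...) {
  cat(sprintf("<pattern_template>%s%s\n",
              if (!is.null(x$label)) paste0(" class=", x$label) else "",
              if (!is.na(x$window_start)) paste0(" window_start=", x$window_start) else ""))
  for (i in 1:5) cat(" ", paste(ifelse(x$grid[i, ] > 0, "#", "."), collapse = " "), "\n")
  invisible(x)
}

## Coerce templates / vectors / matrices to a q x 25 matrix of bipolar rows.
as_pattern_matrix <- function(patterns) {
  if (inherits(patterns, "pattern_template")) patterns <- list(patterns)
  if (is.list(patterns)) {
    rows <- lapply(patterns, function(p) {
      if (inherits(p, "pattern_template")) p$vector else as.numeric(p)
    })
    lens <- vapply(rows, length, 1L)
    if (length(unique(lens)) != 1L) {
      stop("patterns have unequal lengths: ", paste(unique(lens), collapse = ", "))
    }
    patterns <- do.call(rbind, rows)
  } else if (is.vector(patterns)) {
    patterns <- matrix(patterns, nrow = 1L)
  }
  assert_bipolar(as.vector(patterns), "pattern matrix")
  patterns
}
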