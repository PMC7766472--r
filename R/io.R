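# CSV / JSON interchange for recordings, templates and weights.
#
# Recordings travel as CSV (`t,Gx,...,Mz`, one row per sample) with a JSON
# sidecar holding label/seed/sample-rate; templates and weight matrices as
# JSON. All readers validate strictly and name the offending column or row.

IMU_HEADER <- c("t", CHANNEL_NAMES)

#' Write an IMU recording to CSV (with JSON sidecar)
#'
#' @param rec an `imu_recording`.
#' @param path output CSV path; metadata goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  df <- data.frame(t = rec$time, rec$channels, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(label = rec$label, seed = rec$seed, sample_rate = rec$sample_rate,
               n_samples = nrow(rec$channels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an IMU recording from CSV
#'
#' Validates the exact header `t,Gx,Gy,Gz,Ax,Ay,Az,Mx,My,Mz` and rejects
#' malformed rows with their line numbers. The JSON sidecar, when present,
#' restores label/seed/sample-rate; otherwise the sample rate is inferred
#' from the time column.
#'
#' @param path CSV path written by [write_imu_csv()].
#' @return an `imu_recording`.
#' @export
read_imu_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(IMU_HEADER, names(df))
  if (length(missing)) {
    stop("malformed IMU CSV '", path, "': missing column(s) ",
         paste(missing, collapse = ", "))
  }
  numeric_cols <- vapply(df[IMU_HEADER], is.numeric, logical(1))
  if (any(!numeric_cols)) {
    stop("malformed IMU CSV '", path, "': non-numeric column(s) ",
         paste(IMU_HEADER[!numeric_cols], collapse = ", "))
  }
  bad <- which(!stats::complete.cases(df[IMU_HEADER]))
  if (length(bad)) {
    stop("malformed IMU CSV '", path, "': incomplete row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "))  # +1 for the header line
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  sample_rate <- meta$sample_rate %||%
    (if (nrow(df) > 1) 1 / stats::median(diff(df$t)) else 50)
  structure(list(time = df$t,
                 channels = as.matrix(df[CHANNEL_NAMES]),
                 sample_rate = sample_rate,
                 label = meta$label %||% NA_character_,
                 seed = as.integer(meta$seed %||% NA_integer_)),
            class = "imu_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a pattern template as JSON
#'
#' Layout: `{"grid": [[...5x5 of +/-1...]], "class": ..., "window_start": ...}`.
#'
#' @param tpl a [template()].
#' @param path JSON path.
#' @return `path` (write) / a `pattern_template` (read).
#' @export
write_template_json <- function(tpl, path) {
  stopifnot(inherits(tpl, "pattern_template"))
  jsonlite::write_json(list(grid = tpl$grid, class = tpl$label,
                            window_start = tpl$window_start,
                            flipped = tpl$flipped),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_template_json
#' @export
read_template_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$grid)) stop("template JSON '", path, "' has no 'grid' field")
  template(as.matrix(obj$grid), label = obj$class,
           window_start = obj$window_start %||% NA_integer_,
           flipped = isTRUE(obj$flipped))
}

#' Write / read a trained network's weights as JSON
#'
#' Layout: `{"n": 25, "eta": 1.0, "w": [[...]]}`. Reading validates symmetry
#' and the zero diagonal.
#'
#' @param net a `hopfield` fit (write) or JSON path (read).
#' @param path JSON path.
#' @return `path` (write) / a `hopfield` object without stored patterns
#'   (read).
#' @export
write_weights_json <- function(net, path) {
  W <- as_weights(net)
  eta <- if (inherits(net, "hopfield")) net$eta else 1
  jsonlite::write_json(list(n = nrow(W), eta = eta, w = W),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_weights_json
#' @export
read_weights_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(obj$w)
  if (!is.numeric(W) || nrow(W) != ncol(W)) {
    stop("weights JSON '", path, "': 'w' is not a square numeric matrix")
  }
  W <- as_weights(W)  # rejects asymmetric / self-feedback matrices
  structure(list(weights = W, eta = obj$eta %||% 1, n = nrow(W),
                 patterns = matrix(numeric(0), 0, nrow(W))),
            class = "hopfield")
}
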