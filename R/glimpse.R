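#' Multi-scale glimpse sensor
#'
#' The glimpse sensor ("retina encoding") extracts `k` patches centred on a
#' focal location. The innermost patch reads the signal at full resolution;
#' each outer scale covers a window `scale_factor` times larger per axis and
#' is reduced back to the base patch size by non-overlapping block mean
#' pooling, so the sensor sees a small region sharply and its surroundings
#' coarsely. Locations are continuous coordinates in \[-1, +1\]^2 with
#' (-1, -1) the top-left (first-channel, first-sample) corner and (0, 0) the
#' centre of the array.
#'
#' @name glimpse-sensor
NULL

#' Glimpse sensor configuration
#'
#' @param k Number of scales (>= 1).
#' @param base_rows,base_cols Innermost patch size in source cells. All
#'   scales are resampled to this size.
#' @param scale_factor Integer >= 2; linear growth factor between successive
#'   scales (scale `s` spans `base * scale_factor^(s-1)` cells per axis).
#' @param pad_value Value read for out-of-bounds cells. Inputs are expected
#'   to be standardized per epoch, so the default 0 is neutral.
#' @return An object of class `glimpse_config`.
#' @export
#' @examples
#' glimpse_config(k = 3, base_rows = 2, base_cols = 7)
glimpse_config <- function(k = 3L, base_rows = 2L, base_cols = 7L,
                           scale_factor = 2L, pad_value = 0) {
  k <- as.integer(k); base_rows <- as.integer(base_rows)
  base_cols <- as.integer(base_cols); scale_factor <- as.integer(scale_factor)
  if (is.na(k) || k < 1L) stop("glimpse_config: k must be a positive integer")
  if (is.na(base_rows) || base_rows < 1L || is.na(base_cols) || base_cols < 1L)
    stop("glimpse_config: base_rows and base_cols must be >= 1")
  if (is.na(scale_factor) || scale_factor < 2L)
    stop("glimpse_config: scale_factor must be an integer >= 2")
  if (!is.numeric(pad_value) || length(pad_value) != 1L || !is.finite(pad_value))
    stop("glimpse_config: pad_value must be a finite scalar")
  structure(list(k = k, base_rows = base_rows, base_cols = base_cols,
                 scale_factor = scale_factor, pad_value = pad_value),
            class = "glimpse_config")
}

#' @export
print.glimpse_config <- function(x, ...) {
  cat(sprintf("<glimpse_config> k = %d scales, base %d x %d, scale factor %d, pad %g\n",
              x$k, x$base_rows, x$base_cols, x$scale_factor, x$pad_value))
  invisible(x)
}

#' Clip a location into the valid coordinate box
#'
#' @param coords Numeric length-2 vector (row axis, column axis).
#' @return Coordinates clipped elementwise into \[-1, +1\].
#' @export
clip_location <- function(coords) {
  if (!is.numeric(coords) || length(coords) != 2L || any(!is.finite(coords)))
    stop("location coordinates must be two finite numbers")
  pmin(pmax(as.numeric(coords), -1), 1)
}

#' Convert grid indices to normalized coordinates
#'
#' Maps 1-based grid indices affinely to cell centres in \[-1, +1\]:
#' cell `i` of an axis with extent `e` has centre `(2 i - 1) / e - 1`, so the
#' centre cell of an odd-extent axis maps to 0 exactly and cell 1 maps to
#' -1 plus half a cell width.
#'
#' @param index Integer length-2 vector of 1-based (row, col) indices.
#' @param grid_shape Integer length-2 vector of axis extents.
#' @return Numeric length-2 coordinates in \[-1, +1\].
#' @seealso [denormalize_location()]
#' @export
normalize_location <- function(index, grid_shape) {
  index <- as.numeric(index); grid_shape <- as.numeric(grid_shape)
  if (length(index) != 2L || length(grid_shape) != 2L)
    stop("index and grid_shape must have length 2")
  if (any(!is.finite(index)) || any(index < 1) || any(index > grid_shape))
    stop("invalid coordinates: index outside grid")
  (2 * index - 1) / grid_shape - 1
}

#' Convert normalized coordinates to the nearest grid cell index
#'
#' Inverse of [normalize_location()]: returns the 1-based index of the cell
#' whose centre is nearest to `coords`. Exact ties between two cell centres
#' are resolved toward the coordinate origin (the grid centre), and
#' coordinates are clipped into \[-1, +1\] first.
#'
#' @inheritParams normalize_location
#' @param coords Numeric length-2 vector in \[-1, +1\].
#' @return Integer length-2 vector of (row, col) indices.
#' @export
denormalize_location <- function(coords, grid_shape) {
  coords <- clip_location(coords)
  grid_shape <- as.numeric(grid_shape)
  out <- integer(2L)
  for (a in 1:2) {
    e <- grid_shape[a]
    x <- ((coords[a] + 1) * e + 1) / 2      # real-valued index; centres at integers
    lo <- floor(x); frac <- x - lo
    if (abs(frac - 0.5) < 1e-9) {
      centre <- (e + 1) / 2
      out[a] <- if (x > centre) as.integer(lo) else as.integer(lo + 1)
    } else {
      out[a] <- as.integer(round(x))
    }
    out[a] <- min(max(out[a], 1L), as.integer(e))
  }
  out
}

# Window start index for a width-w window "centred" at idx; even widths put
# the extra cell toward the index origin.
window_start <- function(idx, w) as.integer(idx - w %/% 2L)

# Extract a rows x cols window with pad_value outside bounds.
padded_window <- function(signal, r0, r1, c0, c1, pad_value) {
  nr <- nrow(signal); nc <- ncol(signal)
  out <- matrix(pad_value, r1 - r0 + 1L, c1 - c0 + 1L)
  rr <- max(r0, 1L):min(r1, nr); cc <- max(c0, 1L):min(c1, nc)
  if (r0 <= nr && r1 >= 1L && c0 <= nc && c1 >= 1L && length(rr) && length(cc))
    out[rr - r0 + 1L, cc - c0 + 1L] <- signal[rr, cc, drop = FALSE]
  out
}

# Mean-pool a matrix down to target_rows x target_cols using contiguous,
# as-equal-as-possible blocks (exact non-overlapping blocks when divisible).
block_mean_pool <- function(m, target_rows, target_cols) {
  rb <- floor((seq_len(nrow(m)) - 1L) * target_rows / nrow(m)) + 1L
  cb <- floor((seq_len(ncol(m)) - 1L) * target_cols / ncol(m)) + 1L
  sums <- rowsum(m, rb)                     # collapse rows into row blocks
  sums <- t(rowsum(t(sums), cb))            # then columns
  cnt <- outer(tabulate(rb, target_rows), tabulate(cb, target_cols))
  sums / cnt
}

extract_glimpse_impl <- function(signal, loc, config, clamp_rows) {
  if (!inherits(config, "glimpse_config")) stop("config must be a glimpse_config")
  if (!is.matrix(signal) || !is.numeric(signal) || length(signal) == 0L)
    stop("signal must be a non-empty numeric matrix")
  coords <- clip_location(loc)
  idx <- denormalize_location(coords, dim(signal))
  k <- config$k; br <- config$base_rows; bc <- config$base_cols
  out <- array(NA_real_, dim = c(k, br, bc))
  for (s in seq_len(k)) {
    f <- config$scale_factor^(s - 1L)
    wr <- br * f; wc <- bc * f
    if (clamp_rows && wr > nrow(signal)) {
      r0 <- 1L; r1 <- nrow(signal)
    } else {
      r0 <- window_start(idx[1L], wr); r1 <- r0 + wr - 1L
    }
    c0 <- window_start(idx[2L], wc); c1 <- c0 + wc - 1L
    win <- padded_window(signal, r0, r1, c0, c1, config$pad_value)
    out[s, , ] <- if (s == 1L && nrow(win) == br && ncol(win) == bc) win
                  else block_mean_pool(win, br, bc)
  }
  structure(out, class = "glimpse_stack", location = coords, config = config)
}

#' Extract a multi-scale glimpse from a 2-D signal
#'
#' The scale-1 patch is the raw `base_rows x base_cols` window centred (even
#' widths extend one extra cell toward the origin) at the grid cell nearest
#' the focal location; scale `s > 1` covers a window `scale_factor^(s-1)`
#' times larger per axis, reduced to base size by non-overlapping block mean
#' pooling. Cells outside the signal read `pad_value`.
#'
#' @param signal Numeric matrix (rows x cols); for images, rows = image rows.
#' @param loc Numeric length-2 location in \[-1, +1\]^2 (clipped if outside).
#' @param config A [glimpse_config()].
#' @return A `glimpse_stack`: a `k x base_rows x base_cols` array with
#'   attributes `location` and `config`.
#' @export
#' @examples
#' x <- matrix(seq(0, 63), 8, 8, byrow = TRUE)
#' g <- extract_glimpse(x, c(0, 0), glimpse_config(k = 2, base_rows = 2, base_cols = 2))
#' dim(g)
extract_glimpse <- function(signal, loc, config) {
  extract_glimpse_impl(signal, loc, config, clamp_rows = FALSE)
}

#' Extract a multi-scale glimpse from a channels x time signal
#'
#' Identical contract to [extract_glimpse()] with axis 1 = channels and
#' axis 2 = time, except that scale windows which would exceed the channel
#' extent are clamped to the full channel range before pooling (a 2 x 7 base
#' patch on 22 channels would otherwise overflow the channel axis at high
#' scales while the time axis still has room).
#'
#' @inheritParams extract_glimpse
#' @param signal Numeric channels x time matrix.
#' @return A `glimpse_stack`.
#' @export
extract_glimpse_multichannel <- function(signal, loc, config) {
  if (inherits(config, "glimpse_config") && config$base_rows > nrow(signal))
    stop("base_rows exceeds the number of channels")
  extract_glimpse_impl(signal, loc, config, clamp_rows = TRUE)
}

#' @export
print.glimpse_stack <- function(x, ...) {
  d <- dim(x)
  loc <- attr(x, "location")
  cat(sprintf("<glimpse_stack> %d scale(s) of %d x %d at location (%.3f, %.3f)\n",
              d[1], d[2], d[3], loc[1], loc[2]))
  invisible(x)
}

# Flatten a glimpse stack to the network input vector (column-major over the
# k x rows x cols array; fixed, documented order).
flatten_stack <- function(stack) as.numeric(stack)

#' Write a glimpse stack to CSV for inspection
#'
#' One block of `base_rows` rows per scale, preceded by a `scale` column.
#'
#' @param stack A `glimpse_stack`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_glimpse_csv <- function(stack, path) {
  d <- dim(stack)
  rows <- do.call(rbind, lapply(seq_len(d[1]), function(s) {
    cbind(scale = s, row = seq_len(d[2]), matrix(stack[s, , ], d[2], d[3]))
  }))
  colnames(rows) <- c("scale", "row", paste0("c", seq_len(d[3])))
  utils::write.csv(as.data.frame(rows), path, row.names = FALSE)
  invisible(path)
}
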