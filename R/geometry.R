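# Vectorized 3D helpers: points and vectors are n x 3 matrices (lab frame, mm).

as_mat3 <- function(p) {
  if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
}

vnorm <- function(m) sqrt(rowSums(m^2))

vnormalize <- function(m, what = "vector") {
  n <- vnorm(m)
  if (any(n < 1e-9, na.rm = TRUE))
    stop("degenerate geometry: zero-length ", what, call. = FALSE)
  m / n
}

vcross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vdot <- function(a, b) rowSums(a * b)

# remove from v its component along unit vector u (both n x 3)
vreject <- function(v, u) v - vdot(v, u) * u

#' Anatomical segment frame
#'
#' Origin plus right-handed orthonormal axes of a body segment, expressed in
#' the laboratory frame.  Convention for every segment built by this
#' package: `x` points anteriorly (roughly along the direction of
#' progression), `y` is the mediolateral flexion axis (pointing to the
#' subject's left for gait along +X), `z` completes the right-handed triad
#' (`x` cross `y` = `z`), pointing proximally/upward.
#'
#' @param origin 3-vector (mm, lab frame).
#' @param x_axis,y_axis,z_axis unit 3-vectors; must be mutually orthogonal
#'   and right-handed within 1e-9.
#' @return a `SegmentFrame` object.
#' @export
segment_frame <- function(origin, x_axis, y_axis, z_axis) {
  ax <- rbind(x_axis, y_axis, z_axis)
  if (any(abs(vnorm(ax) - 1) > 1e-9))
    stop("segment axes must be unit vectors", call. = FALSE)
  g <- tcrossprod(ax)
  if (max(abs(g - diag(3))) > 1e-9)
    stop("segment axes must be mutually orthogonal", call. = FALSE)
  if (max(abs(vcross(ax[1, , drop = FALSE], ax[2, , drop = FALSE]) - z_axis)) > 1e-9)
    stop("segment axes must be right-handed (x cross y = z)", call. = FALSE)
  structure(list(origin = as.numeric(origin), x_axis = as.numeric(x_axis),
                 y_axis = as.numeric(y_axis), z_axis = as.numeric(z_axis)),
            class = "SegmentFrame")
}

#' @export
print.SegmentFrame <- function(x, ...) {
  cat("SegmentFrame\n")
  cat(sprintf("  origin: (%.2f, %.2f, %.2f) mm\n", x$origin[1], x$origin[2],
              x$origin[3]))
  for (ax in c("x_axis", "y_axis", "z_axis"))
    cat(sprintf("  %s: (%.4f, %.4f, %.4f)\n", ax, x[[ax]][1], x[[ax]][2],
                x[[ax]][3]))
  invisible(x)
}

# A frame series: list(origin, x, y, z), each n x 3. Row i is the segment
# frame at marker frame i; NA rows mark frames where construction failed.
frame_series <- function(origin, x, y, z) {
  list(origin = origin, x = x, y = y, z = z)
}

frame_series_row <- function(fs, i) {
  segment_frame(fs$origin[i, ], fs$x[i, ], fs$y[i, ], fs$z[i, ])
}

single_frame <- function(fs) frame_series_row(fs, 1L)
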