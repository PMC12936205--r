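# Internal helpers shared across modules.
#
# Coordinate convention used throughout the package: images are numeric
# matrices indexed [row, col] = [y, x]; continuous positions are given as
# (x, y) in pixel units, 1-based, with the centre of pixel (i, j) at
# x = j, y = i.  All lengths in profiles are nanometres, times in seconds;
# pixel coordinates are converted at module boundaries via `pixel_size`.

# Evaluate `expr` with a private RNG stream; the caller's .Random.seed is
# untouched.  `seed` must be a single finite integer-valued number.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Construct an image stack
#'
#' A lightweight container for a single-channel movie: a numeric
#' \code{H x W x T} array plus the physical metadata every downstream stage
#' needs (pixel size and frame interval).
#'
#' @param frames numeric array, \code{H x W x T} (rows = y, cols = x).
#' @param pixel_size pixel size in nm/px.
#' @param frame_interval frame interval in seconds.
#' @param channel label, e.g. \code{"tcr"} or \code{"actin"}.
#' @return an object of class \code{ImageStack}.
#' @export
image_stack <- function(frames, pixel_size, frame_interval, channel = "tcr") {
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L, pixel_size > 0, frame_interval > 0)
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel),
            class = "ImageStack")
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ImageStack [%s]: %d x %d px, %d frames, %.1f nm/px, %.2f s/frame\n",
              x$channel, d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' @export
dim.ImageStack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3]

stack_frame <- function(stack, t) stack$frames[, , t]

#' Construct a cell geometry
#'
#' Describes the analyzable region of one synapse: the cell footprint minus
#' the central actin-depleted cSMAC.
#'
#' @param center numeric (x, y) centre in px.
#' @param cell_radius cell radius in px.
#' @param csmac_radius cSMAC radius in px.
#' @param mask logical H x W matrix, TRUE inside the analyzable annulus; if
#'   NULL an annular mask is built from the radii (requires \code{dim}).
#' @param dim image dimensions c(H, W), used when \code{mask} is NULL.
#' @return an object of class \code{CellGeometry}.
#' @export
cell_geometry <- function(center, cell_radius, csmac_radius, mask = NULL,
                          dim = NULL) {
  stopifnot(length(center) == 2L, cell_radius > 0,
            csmac_radius >= 0, csmac_radius < cell_radius)
  if (is.null(mask)) {
    stopifnot(!is.null(dim))
    r <- pixel_radii(dim[1], dim[2], center)
    mask <- r <= cell_radius & r > csmac_radius
  }
  structure(list(center = as.numeric(center), cell_radius = cell_radius,
                 csmac_radius = csmac_radius, mask = mask),
            class = "CellGeometry")
}

#' @export
print.CellGeometry <- function(x, ...) {
  cat(sprintf("CellGeometry: centre (%.1f, %.1f) px, R = %.1f px, cSMAC = %.1f px\n",
              x$center[1], x$center[2], x$cell_radius, x$csmac_radius))
  invisible(x)
}

# Matrix of radial distances (px) of every pixel centre from `center` (x, y).
pixel_radii <- function(H, W, center) {
  dx <- matrix(seq_len(W), H, W, byrow = TRUE) - center[1]
  dy <- matrix(seq_len(H), H, W) - center[2]
  sqrt(dx * dx + dy * dy)
}

# Matrix of polar angles of every pixel centre.
pixel_angles <- function(H, W, center) {
  dx <- matrix(seq_len(W), H, W, byrow = TRUE) - center[1]
  dy <- matrix(seq_len(H), H, W) - center[2]
  atan2(dy, dx)
}

# Signed smallest angular difference a - b, in (-pi, pi].
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

radial_dist <- function(x, y, center) {
  sqrt((x - center[1])^2 + (y - center[2])^2)
}
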