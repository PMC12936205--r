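# Particle image velocimetry of the actin channel: windowed FFT
# cross-correlation between consecutive frames with three-point Gaussian
# sub-pixel peak interpolation, plus the directional flow summary and the
# particle-based cross-validation route.

#' Particle image velocimetry of an image stack
#'
#' For every consecutive frame pair, the displacement maximizing the
#' mean-subtracted circular cross-correlation is found in each interrogation
#' window (search limited to a quarter window) and refined to sub-pixel
#' precision by a three-point Gaussian fit.  Displacements are converted to
#' nm/s via the stack metadata.
#'
#' @param stack an \code{ImageStack} (usually the actin channel).
#' @param window interrogation window size in px (default 32, minimum 16).
#' @param overlap window overlap in px (default 16).
#' @param geometry optional \code{CellGeometry}; vectors whose window centre
#'   lies outside the mask are discarded.
#' @param subtract_background if TRUE (default) and the stack has at least
#'   10 frames, the per-pixel temporal mean is subtracted before
#'   correlation, removing static structure (cell outline, cSMAC dip) that
#'   otherwise locks windows to zero displacement.
#' @return data.frame with columns \code{t} (first frame of the pair),
#'   \code{x}, \code{y} (window centre, px), \code{u}, \code{v} (nm/s).
#' @export
piv <- function(stack, window = 32, overlap = 16, geometry = NULL,
                subtract_background = TRUE) {
  if (n_frames(stack) < 2) stop("need at least 2 frames")
  if (window < 16) stop("window must be at least 16 px")
  H <- dim(stack)[1]; W <- dim(stack)[2]
  if (window > min(H, W)) stop("window larger than image")
  step <- window - overlap
  if (step < 1) stop("overlap must be smaller than window")
  x0 <- seq(1L, W - window + 1L, by = step)
  y0 <- seq(1L, H - window + 1L, by = step)
  ctr_off <- (window - 1) / 2
  scale <- stack$pixel_size / stack$frame_interval
  keep_center <- function(cx, cy) {
    if (is.null(geometry)) return(TRUE)
    geometry$mask[round(cy), round(cx)]
  }
  frames <- stack$frames
  if (subtract_background && n_frames(stack) >= 10) {
    bg <- apply(frames, c(1, 2), mean)
    frames <- sweep(frames, c(1, 2), bg)
  }
  out <- vector("list", (n_frames(stack) - 1L) * length(x0) * length(y0))
  k <- 0L
  for (t in seq_len(n_frames(stack) - 1L)) {
    A <- frames[, , t]
    B <- frames[, , t + 1L]
    for (iy in y0) for (ix in x0) {
      cx <- ix + ctr_off; cy <- iy + ctr_off
      if (!keep_center(cx, cy)) next
      wa <- A[iy:(iy + window - 1L), ix:(ix + window - 1L)]
      wb <- B[iy:(iy + window - 1L), ix:(ix + window - 1L)]
      d <- corr_displacement(wa, wb, window %/% 4L)
      k <- k + 1L
      out[[k]] <- c(t, cx, cy, d[1] * scale, d[2] * scale)
    }
  }
  if (!k) stop("no PIV vectors inside the mask")
  m <- do.call(rbind, out[seq_len(k)])
  data.frame(t = m[, 1], x = m[, 2], y = m[, 3], u = m[, 4], v = m[, 5])
}

# Displacement (dx, dy) of window b relative to a, in px, by circular FFT
# cross-correlation with mean subtraction and Gaussian 3-point sub-pixel
# interpolation.  Search restricted to |d| <= maxdisp.
corr_displacement <- function(a, b, maxdisp) {
  n <- nrow(a)
  a <- a - mean(a); b <- b - mean(b)
  if (all(a == 0) || all(b == 0)) return(c(0, 0))
  cc <- Re(fft(Conj(fft(a)) * fft(b), inverse = TRUE))
  # normalize by the overlap envelope: without it the triangular loss of
  # overlap biases the peak toward zero displacement by ~sigma^2/n px
  sh0 <- ((0:(n - 1L) + n / 2) %% n) - n / 2
  env <- (1 - abs(sh0) / n)
  cc <- cc / outer(env, env)
  # cc[dy+1, dx+1] (0-based circular lags): shift so lag 0 is centred
  sh <- function(i, n) ((i + n / 2) %% n) - n / 2     # lag of index i (0-based)
  lags <- sh(0:(n - 1L), n)
  ok <- abs(lags) <= maxdisp
  sub <- cc[ok, ok, drop = FALSE]
  li <- lags[ok]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  dy <- li[pk[1]]; dx <- li[pk[2]]
  # 3-point Gaussian interpolation per axis (fallback: parabolic)
  refine <- function(cm, c0, cp) {
    r <- 0
    if (cm > 0 && c0 > 0 && cp > 0 && c0 >= cm && c0 >= cp) {
      den <- log(cm) - 2 * log(c0) + log(cp)
      if (den < 0) r <- (log(cm) - log(cp)) / (2 * den)
    } else {
      den <- cm - 2 * c0 + cp
      if (den < 0) r <- (cm - cp) / (2 * den)
    }
    max(-1, min(1, r))
  }
  at <- function(ddy, ddx) {
    iy <- (ddy %% n) + 1L; ix <- (ddx %% n) + 1L
    cc[iy, ix]
  }
  ry <- refine(at(dy - 1, dx), at(dy, dx), at(dy + 1, dx))
  rx <- refine(at(dy, dx - 1), at(dy, dx), at(dy, dx + 1))
  c(dx + rx, dy + ry)
}

#' Directional summary of PIV flow fields
#'
#' A vector is anterograde if its radial component (projection on the
#' outward unit vector at its position) is positive.  Only vectors with
#' speed above \code{noise_floor} enter the fraction and the speed
#' statistics.
#'
#' @param fields data.frame from [piv()].
#' @param geometry a \code{CellGeometry}.
#' @param noise_floor minimum speed in nm/s (default 10).
#' @return list with \code{n_vectors}, \code{anterograde_fraction},
#'   \code{mean_speed} (nm/s) and \code{mean_speed_by_direction}.
#' @export
flow_summary <- function(fields, geometry, noise_floor = 10) {
  if (!nrow(fields)) stop("no flow vectors")
  sp <- sqrt(fields$u^2 + fields$v^2)
  keep <- sp > noise_floor
  if (!any(keep)) stop("all vectors below the noise floor")
  f <- fields[keep, ]
  sp <- sp[keep]
  dx <- f$x - geometry$center[1]; dy <- f$y - geometry$center[2]
  rn <- pmax(sqrt(dx^2 + dy^2), 1e-9)
  radial <- (f$u * dx + f$v * dy) / rn
  dir <- ifelse(radial > 0, "anterograde", "retrograde")
  list(n_vectors = nrow(f),
       anterograde_fraction = mean(radial > 0),
       mean_speed = mean(sp),
       mean_speed_by_direction = tapply(sp, dir, mean))
}

#' Particle-based actin flow summary
#'
#' Cross-validates PIV by re-using the microcluster detection and tracking
#' modules on the actin channel: the brightest actin features are detected,
#' linked, motility-filtered and classified, giving the same summary shape
#' as [flow_summary()].
#'
#' @param actin an actin-channel \code{ImageStack}.
#' @param geometry a \code{CellGeometry}.
#' @param percentile detection percentile (default 0.99: only the
#'   brightest actin features).  The per-pixel temporal mean is subtracted
#'   before thresholding so the selection picks moving features rather than
#'   static structure.
#' @param search_range,memory linking parameters, see [link()].
#' @return list as returned by [directional_fraction()].
#' @export
actin_particle_tracking <- function(actin, geometry, percentile = 0.99,
                                    search_range = 5, memory = 2) {
  # subtract the per-pixel temporal mean so only moving structures are
  # detected: static features (cell outline, cSMAC rim, cortical profile)
  # otherwise dominate the brightest-pixel threshold
  flat <- actin
  bg <- apply(actin$frames, c(1, 2), mean)
  flat$frames <- pmax(sweep(actin$frames, c(1, 2), bg), 0)
  feats <- detect_features(flat, percentile = percentile,
                           geometry = geometry)
  tracks <- link(feats, search_range = search_range, memory = memory)
  # direction calls need several steps; short fragments are mostly relinked
  # texture fluctuations, not persistent features
  motile <- filter_motile(tracks, min_length = 6)
  summ <- summarize_tracks(motile, geometry, actin$pixel_size,
                           actin$frame_interval)
  directional_fraction(summ)
}
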