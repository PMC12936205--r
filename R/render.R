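# Rendering of ground truth into noisy two-channel movies.  The TCR channel
# is a sum of diffraction-limited Gaussian spots at the cluster positions;
# the actin channel is a cortical base level (dimmed inside the cSMAC) plus
# a flow-advected speckle texture and bright expanding wavefront bands.
# Photon shot noise is Poisson, camera noise additive Gaussian.

#' Render a ground-truth scenario into a two-channel movie
#'
#' @param gt a \code{GroundTruth} from [simulate_ground_truth()].
#' @param profile the matching \code{GeneratorProfile}.
#' @param noise if \code{FALSE}, return the expected-intensity images with
#'   no Poisson or read noise (useful for oracle tests).
#' @return list with \code{tcr} and \code{actin}, both \code{ImageStack}s
#'   carrying pixel-size and frame-interval metadata.
#' @export
render_movie <- function(gt, profile = gt$profile, noise = TRUE) {
  profile <- validate_profile(profile)
  px <- profile_px(profile)
  H <- W <- px$img
  if (!all(dim(gt$geometry$mask) == c(H, W)))
    stop("image too small to contain cell disc (profile/ground-truth mismatch)")
  TT <- profile$n_frames
  ctr <- gt$geometry$center
  rmat <- pixel_radii(H, W, ctr)
  tmat <- pixel_angles(H, W, ctr)

  # cortical base profile: 1 in the lamella, csmac_dim inside the cSMAC,
  # 0 outside the cell, with ~1 px soft transitions
  soft <- function(d, w = 1) pmin(1, pmax(0, d / w + 0.5))
  cortex <- soft(px$R - rmat) *
    (profile$csmac_dim + (1 - profile$csmac_dim) * soft(rmat - px$rc))

  tcr <- array(0, c(H, W, TT))
  actin <- array(0, c(H, W, TT))

  with_local_seed(profile$seed + 424243, {
    # --- TCR channel ------------------------------------------------------
    cl <- gt$clusters
    for (t in seq_len(TT)) {
      fr <- matrix(profile$background_rate, H, W)
      rows <- which(cl$frame == t)
      if (length(rows))
        fr <- add_gaussian_spots(fr, cl$x[rows], cl$y[rows],
                                 rep(profile$cluster_photon_rate,
                                     length(rows)), px$psf)
      tcr[, , t] <- fr
    }

    # --- actin channel ----------------------------------------------------
    ns <- profile$n_speckles
    if (ns > 0) {
      sp <- spawn_positions(ns, gt$geometry, 0)
      sx <- sp[, 1]; sy <- sp[, 2]
      samp <- profile$speckle_photon_rate * exp(rnorm(ns, 0, 0.35) - 0.061)
      # a small population of bright actin foci: the discrete trackable
      # features used by the particle-based flow cross-validation
      bright <- runif(ns) < 0.03
      samp[bright] <- samp[bright] * 10
    } else sx <- sy <- samp <- numeric(0)
    kern <- gaussian_kernel(px$speckle_sigma)
    dt <- profile$frame_interval
    for (t in seq_len(TT)) {
      if (t > 1L && ns > 0) {
        v <- gt$flow(sx, sy, t - 1L)          # nm/s
        sx <- sx + v[, 1] * dt / profile$pixel_size + rnorm(ns, 0, 0.05)
        sy <- sy + v[, 2] * dt / profile$pixel_size + rnorm(ns, 0, 0.05)
        rr <- radial_dist(sx, sy, ctr)
        # turnover: speckles leaving the annulus or exceeding their
        # lifetime (actin turnover) respawn uniformly over the annulus,
        # keeping the texture density stationary
        dead <- rr <= px$rc + 1 | rr >= px$R - 0.5 |
          runif(ns) < dt / profile$speckle_lifetime
        nd <- sum(dead)
        if (nd) {
          r <- sqrt(runif(nd, (px$rc + 1.5)^2, (px$R - 1)^2))
          a <- runif(nd, -pi, pi)
          sx[dead] <- ctr[1] + r * cos(a)
          sy[dead] <- ctr[2] + r * sin(a)
        }
      }
      fr <- profile$cortex_rate * cortex
      if (ns > 0) {
        spl <- bilinear_splat(H, W, sx, sy, samp)
        fr <- fr + fft_convolve(spl, kern)
      }
      fa <- gt$fronts[gt$fronts$frame == t, , drop = FALSE]
      if (nrow(fa))
        fr <- fr + wave_ridge(rmat, tmat, fa, profile, px)
      actin[, , t] <- fr
    }

    if (noise) {
      tcr <- array(rpois(length(tcr), pmax(tcr, 0)), dim(tcr))
      actin <- array(rpois(length(actin), pmax(actin, 0)), dim(actin))
      if (profile$read_noise_sd > 0) {
        tcr <- tcr + array(rnorm(length(tcr), 0, profile$read_noise_sd),
                           dim(tcr))
        actin <- actin + array(rnorm(length(actin), 0, profile$read_noise_sd),
                               dim(actin))
        tcr[tcr < 0] <- 0
        actin[actin < 0] <- 0
      }
    }
  })

  list(tcr = image_stack(tcr, profile$pixel_size, profile$frame_interval,
                         "tcr"),
       actin = image_stack(actin, profile$pixel_size, profile$frame_interval,
                           "actin"))
}

# Add exact (sub-pixel) Gaussian spots to a frame.  `photons` is the total
# photon count of each spot; sigma in px.
add_gaussian_spots <- function(frame, x, y, photons, sigma) {
  H <- nrow(frame); W <- ncol(frame)
  hw <- ceiling(3 * sigma)
  for (i in seq_along(x)) {
    xlo <- floor(x[i]) - hw; xhi <- floor(x[i]) + hw + 1L
    ylo <- floor(y[i]) - hw; yhi <- floor(y[i]) + hw + 1L
    if (xhi < 1L || xlo > W || yhi < 1L || ylo > H) next
    jx <- max(1L, xlo):min(W, xhi)
    jy <- max(1L, ylo):min(H, yhi)
    gx <- dnorm(jx, x[i], sigma)
    gy <- dnorm(jy, y[i], sigma)
    frame[jy, jx] <- frame[jy, jx] + photons[i] * outer(gy, gx)
  }
  frame
}

# Distribute point masses onto the four neighbouring pixels (bilinear).
bilinear_splat <- function(H, W, x, y, w) {
  out <- matrix(0, H, W)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  for (k in 0:3) {
    xi <- x0 + k %% 2; yi <- y0 + k %/% 2
    wk <- w * (if (k %% 2) fx else 1 - fx) * (if (k %/% 2) fy else 1 - fy)
    ok <- xi >= 1 & xi <= W & yi >= 1 & yi <= H
    if (any(ok)) {
      idx <- (xi[ok] - 1L) * H + yi[ok]
      acc <- tapply(wk[ok], idx, sum)
      out[as.integer(names(acc))] <- out[as.integer(names(acc))] + acc
    }
  }
  out
}

# Normalized 2-D Gaussian kernel truncated at 3 sigma (odd size).
gaussian_kernel <- function(sigma, truncate = 3) {
  hw <- max(1L, ceiling(truncate * sigma))
  g <- dnorm(-hw:hw, 0, sigma)
  k <- outer(g, g)
  k / sum(k)
}

# FFT convolution with zero padding (linear, same size).
fft_convolve <- function(img, kern) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kern); kw <- ncol(kern)
  PH <- H + kh - 1L; PW <- W + kw - 1L
  a <- matrix(0, PH, PW); a[1:H, 1:W] <- img
  b <- matrix(0, PH, PW); b[1:kh, 1:kw] <- kern
  cc <- Re(fft(fft(a) * fft(b), inverse = TRUE)) / (PH * PW)
  oy <- (kh - 1L) %/% 2; ox <- (kw - 1L) %/% 2
  cc[(1 + oy):(H + oy), (1 + ox):(W + ox)]
}

# Additive intensity of the wavefront bands in one frame: a step-like
# front (sigmoid rise of width wave_front_sigma centred on the leading
# edge, so the intensity gradient is maximal exactly at the front line), a
# plateau of length wave_band behind it, and a Gaussian trailing decay,
# within the front's angular arc (soft angular shoulders).
wave_ridge <- function(rmat, tmat, fronts, profile, px) {
  out <- matrix(0, nrow(rmat), ncol(rmat))
  for (j in seq_len(nrow(fronts))) {
    re <- fronts$r_edge[j]
    dr <- rmat - re
    sel <- which(dr > -(px$band + 4 * px$back_sigma) & dr < 4 * px$front_sigma)
    if (!length(sel)) next
    da <- abs(ang_diff(tmat[sel], fronts$theta[j]))
    wang <- pmin(1, pmax(0, (fronts$arc[j] / 2 - da) / 0.15))
    d <- dr[sel]
    prof <- stats::plogis(-d / px$front_sigma)
    behind <- pmax(0, -d - px$band)
    prof <- prof * exp(-behind^2 / (2 * px$back_sigma^2))
    out[sel] <- out[sel] + profile$wave_amplitude * prof * wang
  }
  out
}
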