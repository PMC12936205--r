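# Phenomenological tracer model of TCR transport.  Tracers default to
# retrograde motion (50 nm/s toward the synapse centre) and couple either to
# detected actin wavefronts (mode 1) or to the local PIV flow when its
# magnitude exceeds a speed threshold (mode 2).  Outward/inward run-time
# distributions of the resulting trajectories are compared by KDE-smoothed
# mean squared error.

#' Initialize tracer particles
#'
#' Uniform random positions in the analyzable annulus.
#'
#' @param n number of tracers (default 100).
#' @param geometry a \code{CellGeometry}.
#' @param seed RNG seed.
#' @return data.frame with \code{tracer}, \code{x}, \code{y}, \code{state}.
#' @export
init_tracers <- function(n = 100, geometry, seed = 1) {
  if (n < 1) stop("n must be at least 1")
  if (geometry$cell_radius - geometry$csmac_radius <= 2)
    stop("degenerate geometry")
  with_local_seed(seed, {
    p <- spawn_positions(n, geometry, 0)
    data.frame(tracer = seq_len(n), x = p[, 1], y = p[, 2], state = "free")
  })
}

# Move a set of radii by a signed radial step (px), clamped to the annulus.
.radial_move <- function(r, step, geometry) {
  pmin(pmax(r + step, geometry$csmac_radius), geometry$cell_radius - 0.5)
}

#' Advance tracers one step against a wavefront set (mode 1)
#'
#' A tracer with at least one edge coordinate inside its scan disc couples
#' to the wavefront and moves radially outward at the wavefront expansion
#' speed; otherwise it moves radially inward at its default speed.  Inward
#' motion stops at the cSMAC boundary.
#'
#' @param tracers data.frame from [init_tracers()].
#' @param edges data.frame of edge coordinates (\code{x}, \code{y}) for the
#'   current frame (e.g. \code{WavefrontSet$edges} or
#'   [gt_wavefront_edges()]); may be empty.
#' @param geometry a \code{CellGeometry}.
#' @param dt step duration in s.
#' @param pixel_size nm/px.
#' @param default_speed default retrograde speed in nm/s (default 50).
#' @param scan_radius scan radius in nm (default 300).
#' @param wave_speed outward speed while coupled, nm/s (default 40).
#' @return the advanced tracers data.frame.
#' @export
step_mode1 <- function(tracers, edges, geometry, dt, pixel_size,
                       default_speed = 50, scan_radius = 300,
                       wave_speed = 40) {
  scan_px <- scan_radius / pixel_size
  coupled <- rep(FALSE, nrow(tracers))
  if (!is.null(edges) && nrow(edges)) {
    for (i in seq_len(nrow(tracers))) {
      d2 <- (edges$x - tracers$x[i])^2 + (edges$y - tracers$y[i])^2
      coupled[i] <- any(d2 <= scan_px^2)
    }
  }
  ctr <- geometry$center
  r <- radial_dist(tracers$x, tracers$y, ctr)
  th <- atan2(tracers$y - ctr[2], tracers$x - ctr[1])
  step_px <- ifelse(coupled, wave_speed, -default_speed) * dt / pixel_size
  r2 <- .radial_move(r, step_px, geometry)
  tracers$x <- ctr[1] + r2 * cos(th)
  tracers$y <- ctr[2] + r2 * sin(th)
  tracers$state <- ifelse(coupled, "wave_coupled", "free")
  tracers
}

#' Advance tracers one step against a PIV flow field (mode 2)
#'
#' The mean of the PIV vectors whose grid points fall inside the tracer's
#' scan disc is computed (if none fall inside, the nearest grid vector is
#' used).  If its magnitude exceeds \code{speed_threshold} the tracer moves
#' with that velocity; otherwise it moves radially inward at the default
#' speed.
#'
#' @inheritParams step_mode1
#' @param field data.frame with \code{x}, \code{y} (px) and \code{u},
#'   \code{v} (nm/s) for the current frame pair.
#' @param speed_threshold minimum flow magnitude in nm/s for coupling.
#' @return the advanced tracers data.frame.
#' @export
step_mode2 <- function(tracers, field, geometry, dt, pixel_size,
                       speed_threshold, default_speed = 50,
                       scan_radius = 300) {
  scan_px <- scan_radius / pixel_size
  ctr <- geometry$center
  n <- nrow(tracers)
  r <- radial_dist(tracers$x, tracers$y, ctr)
  th <- atan2(tracers$y - ctr[2], tracers$x - ctr[1])
  newx <- tracers$x; newy <- tracers$y
  state <- rep("free", n)
  have_field <- !is.null(field) && nrow(field) > 0
  for (i in seq_len(n)) {
    uv <- c(0, 0); ok <- FALSE
    if (have_field) {
      d2 <- (field$x - tracers$x[i])^2 + (field$y - tracers$y[i])^2
      inside <- d2 <= scan_px^2
      if (any(inside)) uv <- c(mean(field$u[inside]), mean(field$v[inside]))
      else { j <- which.min(d2); uv <- c(field$u[j], field$v[j]) }
      ok <- sqrt(sum(uv^2)) > speed_threshold
    }
    if (ok) {
      state[i] <- "flow_coupled"
      px <- tracers$x[i] + uv[1] * dt / pixel_size
      py <- tracers$y[i] + uv[2] * dt / pixel_size
      rr <- radial_dist(px, py, ctr)
      rr2 <- .radial_move(rr, 0, geometry)
      if (rr > 1e-9 && rr2 != rr) { px <- ctr[1] + (px - ctr[1]) * rr2 / rr
                                    py <- ctr[2] + (py - ctr[2]) * rr2 / rr }
      newx[i] <- px; newy[i] <- py
    } else {
      r2 <- .radial_move(r[i], -default_speed * dt / pixel_size, geometry)
      newx[i] <- ctr[1] + r2 * cos(th[i])
      newy[i] <- ctr[2] + r2 * sin(th[i])
    }
  }
  tracers$x <- newx; tracers$y <- newy; tracers$state <- state
  tracers
}

#' Run a tracer simulation
#'
#' @param mode 1 (wavefront-coupled) or 2 (flow-coupled).
#' @param inputs for mode 1, a list of per-frame edge data.frames (or
#'   \code{WavefrontSet}s); for mode 2, a list of per-frame-pair flow
#'   data.frames or a single data.frame with a \code{t} column.
#' @param geometry a \code{CellGeometry}.
#' @param n_steps number of steps.
#' @param dt step duration in s.
#' @param pixel_size nm/px.
#' @param n number of tracers (default 100).
#' @param seed RNG seed (tracer initialization and jitter).
#' @param speed_threshold mode-2 coupling threshold in nm/s.
#' @param default_speed default retrograde speed, nm/s (default 50).
#' @param scan_radius scan radius, nm (default 300).
#' @param wave_speed mode-1 outward speed, nm/s (default 40).
#' @param jitter_sd optional positional noise, nm per axis per step
#'   (default 0: fully deterministic given the initial positions).
#' @return data.frame with \code{tracer}, \code{step} (0-based), \code{x},
#'   \code{y}, \code{state}.
#' @export
run_simulation <- function(mode, inputs, geometry, n_steps, dt, pixel_size,
                           n = 100, seed = 1, speed_threshold = 13,
                           default_speed = 50, scan_radius = 300,
                           wave_speed = 40, jitter_sd = 0) {
  stopifnot(mode %in% c(1, 2))
  get_input <- function(t) {
    if (is.data.frame(inputs)) {
      if (!is.null(inputs$t)) return(inputs[inputs$t == t, , drop = FALSE])
      return(inputs)
    }
    if (t > length(inputs)) stop("inputs shorter than n_steps")
    el <- inputs[[t]]
    if (inherits(el, "WavefrontSet")) el$edges else el
  }
  tracers <- init_tracers(n, geometry, seed)
  rec <- vector("list", n_steps + 1L)
  rec[[1]] <- cbind(tracers[, c("tracer", "x", "y", "state")], step = 0L)
  with_local_seed(seed + 9901, {
    for (s in seq_len(n_steps)) {
      inp <- get_input(s)
      tracers <- if (mode == 1)
        step_mode1(tracers, inp, geometry, dt, pixel_size, default_speed,
                   scan_radius, wave_speed)
      else
        step_mode2(tracers, inp, geometry, dt, pixel_size, speed_threshold,
                   default_speed, scan_radius)
      if (jitter_sd > 0) {
        jp <- jitter_sd * sqrt(dt) / pixel_size
        tracers$x <- tracers$x + rnorm(n, 0, jp)
        tracers$y <- tracers$y + rnorm(n, 0, jp)
      }
      rec[[s + 1L]] <- cbind(tracers[, c("tracer", "x", "y", "state")],
                             step = s)
    }
  })
  out <- do.call(rbind, rec)
  out <- out[order(out$tracer, out$step), c("tracer", "step", "x", "y",
                                            "state")]
  rownames(out) <- NULL
  out
}

#' Outward and inward run-time distributions of trajectories
#'
#' For each trajectory, maximal runs of consecutive steps with positive
#' (outward) or negative (inward) radial increments are extracted; zero
#' increments break runs without starting one.  Run lengths (in seconds)
#' are pooled and summarized as a probability-density histogram plus a
#' Gaussian-KDE smoothed curve sampled at the bin centres.
#'
#' @param trajectories data.frame with \code{tracer} (or \code{cluster}),
#'   \code{step} (or \code{frame}), \code{x}, \code{y}.
#' @param geometry a \code{CellGeometry}.
#' @param dt step duration in s.
#' @return list with \code{outward} and \code{inward}, each a
#'   \code{DurationDistribution} (or NULL when that direction has no runs).
#' @export
outward_time_distribution <- function(trajectories, geometry, dt = 1) {
  idc <- if (!is.null(trajectories$tracer)) "tracer" else "cluster"
  stc <- if (!is.null(trajectories$step)) "step" else "frame"
  sp <- split(trajectories, trajectories[[idc]])
  outd <- numeric(0); ind <- numeric(0)
  for (d in sp) {
    d <- d[order(d[[stc]]), ]
    if (nrow(d) < 2) next
    r <- radial_dist(d$x, d$y, geometry$center)
    s <- sign(diff(r))
    runs <- rle(s)
    outd <- c(outd, runs$lengths[runs$values > 0] * dt)
    ind <- c(ind, runs$lengths[runs$values < 0] * dt)
  }
  if (!length(outd) && !length(ind)) stop("no runs found")
  list(outward = duration_distribution(outd, dt),
       inward = duration_distribution(ind, dt))
}

#' Build a duration distribution
#'
#' Histogram bin width is set from the Gaussian-KDE bandwidth (Scott's
#' rule); densities are normalized so that the histogram integrates to one.
#' The KDE curve is evaluated at the bin centres and linearly interpolated
#' in between.
#'
#' @param durations numeric vector of run durations in s.
#' @param dt native time resolution in s (lower bound on the bin width).
#' @return a \code{DurationDistribution}: list with \code{durations},
#'   \code{bin_edges}, \code{density}, \code{grid}, \code{kde}.
#' @export
duration_distribution <- function(durations, dt = 1) {
  if (!length(durations)) return(NULL)
  bw <- if (length(durations) > 1 && stats::sd(durations) > 0)
    stats::bw.nrd(durations) else dt / 2
  width <- max(dt, bw)
  lo <- min(durations) - width / 2
  nb <- max(1L, ceiling((max(durations) - lo) / width))
  edges <- lo + width * (0:nb)
  h <- graphics::hist(durations, breaks = edges, plot = FALSE)
  dens <- h$counts / (sum(h$counts) * width)
  centers <- h$mids
  kd <- stats::density(durations, bw = max(bw, dt / 4), from = min(centers),
                       to = max(max(centers), min(centers) + 1e-9), n = 256)
  kde_at <- stats::approx(kd$x, pmax(kd$y, 0), xout = centers, rule = 2)$y
  structure(list(durations = durations, bin_edges = edges, density = dens,
                 grid = centers, kde = kde_at), class = "DurationDistribution")
}

#' Mean squared error between two duration distributions
#'
#' Both KDE curves are evaluated on the common grid (the union of the two
#' sets of bin centres; density is taken as zero outside a distribution's
#' own support) and the mean of squared pointwise differences is returned.
#'
#' @param d1,d2 \code{DurationDistribution}s.
#' @return mean squared error (density^2 units).
#' @export
distribution_mse <- function(d1, d2) {
  if (is.null(d1) || is.null(d2)) stop("both distributions must be non-empty")
  grid <- sort(unique(c(d1$grid, d2$grid)))
  if (!length(grid)) stop("no common duration grid")
  ev <- function(d) {
    if (length(d$grid) == 1L) return(ifelse(grid == d$grid, d$kde, 0))
    y <- stats::approx(d$grid, d$kde, xout = grid, rule = 1)$y
    y[is.na(y)] <- 0
    y
  }
  mean((ev(d1) - ev(d2))^2)
}

#' Estimate wavefront expansion speed from consecutive edge sets
#'
#' Each edge pixel at frame t+1 is matched to its nearest edge pixel at
#' frame t (within \code{max_step} px); the mean radial displacement of
#' matched pixels, over all frame pairs, estimates the outward expansion
#' speed.
#'
#' @param wavefronts list of \code{WavefrontSet} (or edge data.frames).
#' @param geometry a \code{CellGeometry}.
#' @param dt frame interval, s.
#' @param pixel_size nm/px.
#' @param max_step maximum matching distance in px (default 3).
#' @return speed in nm/s.
#' @export
estimate_wave_speed <- function(wavefronts, geometry, dt, pixel_size,
                                max_step = 3) {
  getd <- function(w) if (inherits(w, "WavefrontSet")) w$edges else w
  steps <- numeric(0)
  for (t in seq_len(length(wavefronts) - 1L)) {
    a <- getd(wavefronts[[t]]); b <- getd(wavefronts[[t + 1L]])
    if (!nrow(a) || !nrow(b)) next
    nb <- min(nrow(b), 400L)
    bi <- b[seq(1L, nrow(b), length.out = nb), , drop = FALSE]
    ra <- radial_dist(a$x, a$y, geometry$center)
    for (i in seq_len(nrow(bi))) {
      d2 <- (a$x - bi$x[i])^2 + (a$y - bi$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= max_step^2)
        steps <- c(steps,
                   radial_dist(bi$x[i], bi$y[i], geometry$center) - ra[j])
    }
  }
  if (!length(steps)) stop("no matchable edges")
  mean(steps) * pixel_size / dt
}
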