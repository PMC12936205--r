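# Ground-truth simulation of one synapse scenario: cluster trajectories with
# retrograde drift, a diffusive subpopulation, outward-expanding actin
# wavefront arcs, and stochastic cluster-wave coupling.  The rendered movies
# (render_movie) are generated from this ground truth, so every pipeline
# stage can be scored against known answers.

#' Simulate the ground truth of one synthetic synapse
#'
#' Clusters advect toward the synapse centre at the profile's retrograde
#' speed (plus Brownian jitter); a configurable fraction is purely diffusive.
#' Wavefront arcs nucleate at random radii and angles and expand outward at
#' the wave speed until they reach the cell edge.  A drifting cluster that
#' lies inside a front's band, or within \code{capture_radius} ahead of its
#' leading edge (inside the front's angular arc), couples to it with
#' probability \code{coupling_prob} (one Bernoulli trial per cluster-front
#' encounter) and then advects outward at the wave speed until the front
#' dies.  Clusters absorbed at the cSMAC boundary or
#' unbinding (exponential lifetime) are replaced so the concurrent cluster
#' count stays constant.
#'
#' @param profile a \code{GeneratorProfile} from [make_profile()].
#' @return a \code{GroundTruth} list with elements \code{geometry}
#'   (\code{CellGeometry}), \code{clusters} (data.frame: cluster, frame, x,
#'   y, coupled, mode), \code{fronts} (data.frame: front, frame, r_edge,
#'   theta, arc), \code{labels} (per-cluster realized direction), and
#'   \code{flow} (function(x, y, t) returning the true actin velocity in
#'   nm/s).
#' @export
simulate_ground_truth <- function(profile) {
  profile <- validate_profile(profile)
  px <- profile_px(profile)
  TT <- profile$n_frames
  dt <- profile$frame_interval
  center <- c(px$img / 2 + 0.5, px$img / 2 + 0.5)
  geometry <- cell_geometry(center, px$R, px$rc, dim = c(px$img, px$img))

  with_local_seed(profile$seed, {
    n <- profile$n_clusters
    # --- initial cluster population ---------------------------------------
    pos <- spawn_positions(n, geometry, px$min_sep)
    x <- pos[, 1]; y <- pos[, 2]
    diffusive <- runif(n) < profile$diffusive_fraction
    speed <- pmax(0.1 * px$retro_step,
                  rnorm(n, px$retro_step, px$retro_step_sd))
    coupled_to <- integer(n)            # 0 = free
    ids <- seq_len(n)
    next_id <- n + 1L
    tried <- vector("list", n)          # front ids already trialled

    # --- front state ------------------------------------------------------
    fr_id <- integer(0); fr_t0 <- numeric(0)
    fr_r0 <- numeric(0); fr_theta <- numeric(0)
    next_front <- 1L

    cl_rec <- vector("list", TT)
    fr_rec <- vector("list", TT)

    # warm-up: run the dynamics for a burn-in period before frame 1 so the
    # front population and cluster coupling states start at steady state
    warm <- 80L
    for (t in seq.int(1L - warm, TT)) {
      # advance / kill / nucleate fronts
      r_edge <- fr_r0 + px$wave_step * (t - fr_t0)
      alive <- r_edge < px$R
      fr_id <- fr_id[alive]; fr_t0 <- fr_t0[alive]
      fr_r0 <- fr_r0[alive]; fr_theta <- fr_theta[alive]
      r_edge <- r_edge[alive]
      n_new <- rpois(1, profile$wave_nucleation_rate * dt)
      if (n_new > 0) {
        fr_id <- c(fr_id, seq.int(next_front, next_front + n_new - 1L))
        next_front <- next_front + n_new
        fr_t0 <- c(fr_t0, rep(t, n_new))
        r0_new <- runif(n_new, px$rc + 2, 0.9 * px$R)
        fr_r0 <- c(fr_r0, r0_new)
        fr_theta <- c(fr_theta, runif(n_new, -pi, pi))
        r_edge <- c(r_edge, r0_new)
      }
      if (t >= 1L && length(fr_id))
        fr_rec[[t]] <- data.frame(front = fr_id, frame = t, r_edge = r_edge,
                                  theta = fr_theta, arc = profile$wave_arc)

      if (t > 1L - warm) {
        # --- move clusters ------------------------------------------------
        rr <- radial_dist(x, y, center)
        th <- atan2(y - center[2], x - center[1])
        # coupled clusters advect outward with the wave and converge onto
        # the polymerizing front line over a few frames
        ci <- which(coupled_to > 0L)
        for (k in ci) {
          j <- match(coupled_to[k], fr_id)
          if (is.na(j)) { coupled_to[k] <- 0L; next }
          approach <- pmin(1.5, pmax(-0.6, 0.6 * (r_edge[j] - rr[k])))
          rk <- min(rr[k] + px$wave_step + approach, px$R - 0.5)
          x[k] <- center[1] + rk * cos(th[k]) + rnorm(1, 0, px$jitter)
          y[k] <- center[2] + rk * sin(th[k]) + rnorm(1, 0, px$jitter)
        }
        fi <- which(coupled_to == 0L & !diffusive)
        if (length(fi)) {
          x[fi] <- x[fi] - speed[fi] * cos(th[fi]) +
            rnorm(length(fi), 0, px$jitter)
          y[fi] <- y[fi] - speed[fi] * sin(th[fi]) +
            rnorm(length(fi), 0, px$jitter)
        }
        di <- which(diffusive)
        if (length(di)) {
          x[di] <- x[di] + rnorm(length(di), 0, px$diff_jitter)
          y[di] <- y[di] + rnorm(length(di), 0, px$diff_jitter)
        }
        # keep inside the annulus (reflect diffusive, clip others at R)
        rr <- radial_dist(x, y, center)
        over <- rr > px$R - 0.5
        if (any(over)) {
          sc <- (px$R - 0.5) / rr[over]
          x[over] <- center[1] + (x[over] - center[1]) * sc
          y[over] <- center[2] + (y[over] - center[2]) * sc
        }
        rr <- radial_dist(x, y, center)
        under <- diffusive & rr < px$rc + 0.5
        if (any(under)) {
          sc <- (px$rc + 0.5) / rr[under]
          x[under] <- center[1] + (x[under] - center[1]) * sc
          y[under] <- center[2] + (y[under] - center[2]) * sc
        }
        # steric exclusion: microclusters are extended (~250 nm) objects
        # that do not interpenetrate; push overlapping pairs apart
        ex <- 0.65 * px$min_sep
        for (sweep in 1:3) {
          dm <- as.matrix(stats::dist(cbind(x, y)))
          dm[upper.tri(dm, diag = TRUE)] <- Inf
          ov <- which(dm < ex, arr.ind = TRUE)
          if (!nrow(ov)) break
          for (q in seq_len(nrow(ov))) {
            i <- ov[q, 1]; j <- ov[q, 2]
            dx <- x[i] - x[j]; dy <- y[i] - y[j]
            dd <- sqrt(dx * dx + dy * dy)
            if (dd < 1e-6) { dx <- 1; dy <- 0; dd <- 1 }
            push <- (ex - dd) / 2
            x[i] <- x[i] + push * dx / dd; y[i] <- y[i] + push * dy / dd
            x[j] <- x[j] - push * dx / dd; y[j] <- y[j] - push * dy / dd
          }
        }

        # --- deaths and respawns -----------------------------------------
        rr <- radial_dist(x, y, center)
        absorbed <- !diffusive & coupled_to == 0L & rr <= px$rc + 0.6
        unbound <- runif(n) < dt / profile$cluster_lifetime
        dead <- which(absorbed | unbound)
        for (k in dead) {
          p <- spawn_positions(1, geometry, px$min_sep, cbind(x[-k], y[-k]))
          x[k] <- p[1]; y[k] <- p[2]
          diffusive[k] <- runif(1) < profile$diffusive_fraction
          speed[k] <- max(0.1 * px$retro_step,
                          rnorm(1, px$retro_step, px$retro_step_sd))
          coupled_to[k] <- 0L
          ids[k] <- next_id; next_id <- next_id + 1L
          tried[k] <- list(NULL)
        }

        # --- coupling trials ---------------------------------------------
        if (length(fr_id) && profile$coupling_prob > 0) {
          rr <- radial_dist(x, y, center)
          th <- atan2(y - center[2], x - center[1])
          for (k in which(coupled_to == 0L)) {
            # capture anywhere inside the band, or within capture_radius
            # ahead of the leading edge
            near <- rr[k] >= r_edge - px$band & rr[k] <= r_edge + px$capture &
              abs(ang_diff(th[k], fr_theta)) <= profile$wave_arc / 2
            cand <- fr_id[near]
            cand <- setdiff(cand, tried[[k]])
            if (!length(cand)) next
            hit <- cand[runif(length(cand)) < profile$coupling_prob]
            tried[[k]] <- c(tried[[k]], cand)
            if (length(hit)) coupled_to[k] <- hit[1]
          }
        }
      }

      if (t >= 1L && n > 0L)
        cl_rec[[t]] <- data.frame(cluster = ids, frame = rep(t, n), x = x,
                                  y = y, coupled = coupled_to > 0L,
                                  mode = ifelse(diffusive, "diffusive",
                                                "drift"))
    }

    clusters <- if (n > 0L) do.call(rbind, cl_rec)
      else data.frame(cluster = integer(0), frame = integer(0),
                      x = numeric(0), y = numeric(0), coupled = logical(0),
                      mode = character(0))
    fronts <- if (all(vapply(fr_rec, is.null, logical(1))))
      data.frame(front = integer(0), frame = integer(0), r_edge = numeric(0),
                 theta = numeric(0), arc = numeric(0))
    else do.call(rbind, fr_rec[!vapply(fr_rec, is.null, logical(1))])
    rownames(clusters) <- rownames(fronts) <- NULL

    gt <- list(profile = profile, geometry = geometry, clusters = clusters,
               fronts = fronts,
               labels = ground_truth_labels(clusters, geometry),
               flow = make_true_flow(profile, fronts, center))
    class(gt) <- "GroundTruth"
    gt
  })
}

# Direction labels from realized start/end radii of every cluster instance.
ground_truth_labels <- function(clusters, geometry) {
  if (!nrow(clusters))
    return(data.frame(cluster = integer(0), n_frames = integer(0),
                      r_start = numeric(0), r_end = numeric(0),
                      end_to_end = numeric(0), ever_coupled = logical(0),
                      mode = character(0), direction = character(0)))
  sp <- split(clusters, clusters$cluster)
  out <- lapply(sp, function(d) {
    d <- d[order(d$frame), ]
    n <- nrow(d)
    r0 <- radial_dist(d$x[1], d$y[1], geometry$center)
    r1 <- radial_dist(d$x[n], d$y[n], geometry$center)
    data.frame(cluster = d$cluster[1], n_frames = n, r_start = r0, r_end = r1,
               end_to_end = sqrt((d$x[n] - d$x[1])^2 + (d$y[n] - d$y[1])^2),
               ever_coupled = any(d$coupled),
               mode = d$mode[1],
               direction = if (r1 > r0) "anterograde"
                           else if (r1 < r0) "retrograde" else "tie")
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Analytic actin velocity field (nm/s): inward cortical flow everywhere,
# outward at wave_speed inside the band trailing each active front edge.
make_true_flow <- function(profile, fronts, center) {
  px <- profile_px(profile)
  band <- px$band
  force(fronts)
  function(x, y, t) {
    dx <- x - center[1]; dy <- y - center[2]
    r <- sqrt(dx * dx + dy * dy)
    r[r < 1e-9] <- 1e-9
    ux <- dx / r; uy <- dy / r
    sp <- rep(-profile$actin_flow_speed, length(x))
    fa <- fronts[fronts$frame == t, , drop = FALSE]
    if (nrow(fa)) {
      th <- atan2(dy, dx)
      for (j in seq_len(nrow(fa))) {
        inband <- r >= fa$r_edge[j] - band & r <= fa$r_edge[j] + band / 2 &
          abs(ang_diff(th, fa$theta[j])) <= fa$arc[j] / 2
        sp[inband] <- profile$wave_speed
      }
    }
    cbind(u = sp * ux, v = sp * uy)
  }
}

# Sample edge-pixel coordinates along every front arc present in `frame`.
# Returns a data.frame(front, x, y) with ~1 px spacing along each arc.
#' Ground-truth wavefront edge coordinates for one frame
#'
#' @param gt a \code{GroundTruth}.
#' @param frame frame index.
#' @return data.frame with columns \code{front}, \code{x}, \code{y} (px).
#' @export
gt_wavefront_edges <- function(gt, frame) {
  fa <- gt$fronts[gt$fronts$frame == frame, , drop = FALSE]
  ctr <- gt$geometry$center
  if (!nrow(fa))
    return(data.frame(front = integer(0), x = numeric(0), y = numeric(0)))
  out <- lapply(seq_len(nrow(fa)), function(j) {
    r <- fa$r_edge[j]
    nth <- max(3L, ceiling(fa$arc[j] * r))
    th <- fa$theta[j] + seq(-fa$arc[j] / 2, fa$arc[j] / 2, length.out = nth)
    data.frame(front = fa$front[j], x = ctr[1] + r * cos(th),
               y = ctr[2] + r * sin(th))
  })
  do.call(rbind, out)
}

# Uniform positions in the analyzable annulus with a minimum pairwise
# separation (best effort: rejection sampling with a capped retry count).
spawn_positions <- function(n, geometry, min_sep, existing = NULL) {
  ctr <- geometry$center
  R <- geometry$cell_radius - 1
  rc <- geometry$csmac_radius + 1
  pts <- if (is.null(existing)) matrix(numeric(0), 0, 2) else existing
  out <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    for (try in 1:30) {
      r <- sqrt(runif(1, rc^2, R^2))
      a <- runif(1, -pi, pi)
      p <- c(ctr[1] + r * cos(a), ctr[2] + r * sin(a))
      if (!nrow(pts) ||
          min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep)
        break
    }
    out[i, ] <- p
    pts <- rbind(pts, p)
  }
  out
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("GroundTruth '%s': %d frames, %d cluster instances, %d fronts\n",
              x$profile$name, x$profile$n_frames,
              length(unique(x$clusters$cluster)),
              length(unique(x$fronts$front))))
  invisible(x)
}
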