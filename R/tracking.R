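# Trajectory linking with velocity-predictive assignment, motility
# filtering, direction classification and per-track statistics.
#
# The linker predicts each track's next position from its instantaneous
# velocity, v(t0) = (x(t0) - x(t-1)) / (t0 - t-1), as
# P(t1) = x(t0) + v(t0) (t1 - t0), and assigns features to tracks by
# minimizing the distance to the predicted position (greedy over candidate
# pairs in increasing distance, ties broken by smaller feature index).

#' Link per-frame features into trajectories
#'
#' @param features data.frame with columns \code{frame}, \code{x}, \code{y}
#'   and optionally \code{intensity}.
#' @param search_range maximum assignment distance in px (default 5).
#' @param memory number of consecutive frames a track may go undetected and
#'   still be continued (default 2).
#' @param predictive if \code{FALSE}, predict with zero velocity (plain
#'   nearest-neighbour linking); used as a contrast oracle in tests.
#' @return data.frame with columns \code{track}, \code{frame}, \code{x},
#'   \code{y}, \code{intensity}.
#' @export
link <- function(features, search_range = 5, memory = 2, predictive = TRUE) {
  if (search_range <= 0) stop("search_range must be positive")
  if (!nrow(features)) stop("no features to link")
  if (is.null(features$intensity)) features$intensity <- NA_real_
  frames <- sort(unique(features$frame))

  # active track state
  tr_id <- integer(0); tr_x <- tr_y <- tr_px <- tr_py <- numeric(0)
  tr_vx <- tr_vy <- numeric(0); tr_last <- integer(0)
  next_id <- 1L
  rec <- vector("list", length(frames))

  for (fi in seq_along(frames)) {
    t <- frames[fi]
    ff <- features[features$frame == t, , drop = FALSE]
    nf <- nrow(ff)
    assigned_f <- logical(nf)
    assigned_t <- logical(length(tr_id))
    if (length(tr_id) && nf) {
      gap <- t - tr_last
      ok <- gap <= memory + 1L
      # predicted positions at time t
      px <- tr_x + if (predictive) tr_vx * gap else 0
      py <- tr_y + if (predictive) tr_vy * gap else 0
      d2 <- outer(px, ff$x, "-")^2 + outer(py, ff$y, "-")^2
      d2[!ok, ] <- Inf
      cand <- which(d2 <= search_range^2, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d2[cand], cand[, 1], cand[, 2])
        cand <- cand[ord, , drop = FALSE]
        for (k in seq_len(nrow(cand))) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (!assigned_t[i] && !assigned_f[j]) {
            assigned_t[i] <- TRUE; assigned_f[j] <- TRUE
            gp <- t - tr_last[i]
            tr_vx[i] <- (ff$x[j] - tr_x[i]) / gp
            tr_vy[i] <- (ff$y[j] - tr_y[i]) / gp
            tr_x[i] <- ff$x[j]; tr_y[i] <- ff$y[j]; tr_last[i] <- t
          }
        }
      }
    }
    # new tracks for unassigned features
    new_j <- which(!assigned_f)
    if (length(new_j)) {
      nn <- length(new_j)
      tr_id <- c(tr_id, seq.int(next_id, next_id + nn - 1L))
      next_id <- next_id + nn
      tr_x <- c(tr_x, ff$x[new_j]); tr_y <- c(tr_y, ff$y[new_j])
      tr_vx <- c(tr_vx, rep(0, nn)); tr_vy <- c(tr_vy, rep(0, nn))
      tr_last <- c(tr_last, rep(t, nn))
      assigned_t <- c(assigned_t, rep(TRUE, nn))
    }
    # record assignments for this frame
    owner <- integer(nf)
    live <- which(tr_last == t)
    # map each feature to its track id: features assigned above or new
    # (both have tr_last == t and matching coordinates)
    for (j in seq_len(nf)) {
      hit <- live[tr_x[live] == ff$x[j] & tr_y[live] == ff$y[j]]
      owner[j] <- tr_id[hit[1]]
      live <- setdiff(live, hit[1])
    }
    rec[[fi]] <- data.frame(track = owner, frame = t, x = ff$x, y = ff$y,
                            intensity = ff$intensity)
    # drop tracks lost for longer than `memory`
    keep <- (t - tr_last) <= memory
    tr_id <- tr_id[keep]; tr_x <- tr_x[keep]; tr_y <- tr_y[keep]
    tr_vx <- tr_vx[keep]; tr_vy <- tr_vy[keep]; tr_last <- tr_last[keep]
  }
  out <- do.call(rbind, rec)
  out <- out[order(out$track, out$frame), ]
  rownames(out) <- NULL
  out
}

#' Filter out non-motile tracks
#'
#' Keeps tracks whose end-to-end displacement (first to last point) is at
#' least \code{min_displacement} pixels; the default 3.5 px corresponds to
#' 146 nm at 41.6 nm/px, about 5\% of the cell radius.  A displacement of
#' exactly 3.5 px is kept.
#'
#' @param tracks data.frame as returned by [link()].
#' @param min_displacement threshold in px.
#' @param min_length minimum number of points per track (default 2).
#' @return the filtered tracks data.frame.
#' @export
filter_motile <- function(tracks, min_displacement = 3.5, min_length = 2) {
  sp <- split(seq_len(nrow(tracks)), tracks$track)
  keep <- unlist(lapply(sp, function(ix) {
    if (length(ix) < min_length) return(integer(0))
    d <- tracks[ix, ]
    d <- d[order(d$frame), ]
    e2e <- sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2)
    if (e2e >= min_displacement) ix else integer(0)
  }), use.names = FALSE)
  out <- tracks[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify track direction
#'
#' Compares the radial distance of the first and last track points from the
#' synapse centre: larger final radius is anterograde, smaller retrograde,
#' equal is a tie.
#'
#' @param track data.frame of one track's points (\code{frame}, \code{x},
#'   \code{y}).
#' @param geometry a \code{CellGeometry}.
#' @return \code{"anterograde"}, \code{"retrograde"} or \code{"tie"}.
#' @export
classify_direction <- function(track, geometry) {
  d <- track[order(track$frame), ]
  r0 <- radial_dist(d$x[1], d$y[1], geometry$center)
  r1 <- radial_dist(d$x[nrow(d)], d$y[nrow(d)], geometry$center)
  if (r1 > r0) "anterograde" else if (r1 < r0) "retrograde" else "tie"
}

#' Mean track speed in nm/s
#'
#' Mean of frame-to-frame step lengths divided by the elapsed time per step,
#' converted to nm via the pixel size.
#'
#' @param track data.frame of one track's points.
#' @param pixel_size nm/px.
#' @param frame_interval seconds per frame.
#' @return speed in nm/s.
#' @export
track_speed <- function(track, pixel_size, frame_interval) {
  d <- track[order(track$frame), ]
  if (nrow(d) < 2) stop("track needs at least 2 points")
  step <- sqrt(diff(d$x)^2 + diff(d$y)^2)
  dtf <- diff(d$frame)
  mean(step / dtf) * pixel_size / frame_interval
}

#' Normalized radial coordinate
#'
#' Maps a position to \[0, 1\] between the cSMAC boundary (0) and the cell
#' periphery (1); values are clipped to the interval.
#'
#' @param x,y position in px.
#' @param geometry a \code{CellGeometry}.
#' @return normalized radius in \[0, 1\].
#' @export
radial_normalize <- function(x, y, geometry) {
  den <- geometry$cell_radius - geometry$csmac_radius
  if (den <= 0) stop("degenerate geometry: cell_radius <= csmac_radius")
  r <- radial_dist(x, y, geometry$center)
  pmin(1, pmax(0, (r - geometry$csmac_radius) / den))
}

#' Per-track summary table
#'
#' @param tracks data.frame as returned by [link()] (usually after
#'   [filter_motile()]).
#' @param geometry a \code{CellGeometry}.
#' @param pixel_size nm/px.
#' @param frame_interval seconds per frame.
#' @return data.frame with one row per track: \code{track}, \code{n},
#'   \code{direction}, \code{speed} (nm/s), \code{end_to_end} (px),
#'   \code{r_start_norm}, \code{mean_intensity}.
#' @export
summarize_tracks <- function(tracks, geometry, pixel_size, frame_interval) {
  sp <- split(tracks, tracks$track)
  out <- lapply(sp, function(d) {
    d <- d[order(d$frame), ]
    n <- nrow(d)
    data.frame(track = d$track[1], n = n,
               direction = classify_direction(d, geometry),
               speed = if (n >= 2)
                 track_speed(d, pixel_size, frame_interval) else NA_real_,
               end_to_end = sqrt((d$x[n] - d$x[1])^2 + (d$y[n] - d$y[1])^2),
               r_start_norm = radial_normalize(d$x[1], d$y[1], geometry),
               mean_intensity = mean(d$intensity))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Directional summary of a set of tracks
#'
#' The anterograde fraction counts anterograde over anterograde plus
#' retrograde tracks; ties are excluded from the fraction but reported.
#'
#' @param track_summary data.frame from [summarize_tracks()], or a tracks
#'   data.frame together with \code{geometry} and metadata.
#' @return list with \code{n_tracks}, \code{n_anterograde},
#'   \code{n_retrograde}, \code{n_tie}, \code{anterograde_fraction},
#'   \code{mean_speed} (nm/s) and \code{mean_speed_by_direction}.
#' @export
directional_fraction <- function(track_summary) {
  if (!nrow(track_summary)) stop("no motile tracks")
  na <- sum(track_summary$direction == "anterograde")
  nr <- sum(track_summary$direction == "retrograde")
  nt <- sum(track_summary$direction == "tie")
  if (na + nr == 0) stop("no non-tie motile tracks")
  list(n_tracks = nrow(track_summary), n_anterograde = na,
       n_retrograde = nr, n_tie = nt,
       anterograde_fraction = na / (na + nr),
       mean_speed = mean(track_summary$speed, na.rm = TRUE),
       mean_speed_by_direction = tapply(track_summary$speed,
                                        track_summary$direction, mean,
                                        na.rm = TRUE))
}

#' Probability density histogram of feature intensities per direction
#'
#' Density in each bin is frequency / (total frequency x bin width), so the
#' histogram integrates to one within each direction group.
#'
#' @param track_summary data.frame from [summarize_tracks()].
#' @param bins number of equal-width bins over the pooled intensity range
#'   (default 20).
#' @return list per direction with \code{bin_edges} and \code{density}.
#' @export
intensity_density <- function(track_summary, bins = 20) {
  v <- track_summary$mean_intensity
  v <- v[is.finite(v)]
  if (!length(v)) stop("no intensities available")
  edges <- seq(min(v), max(v), length.out = bins + 1L)
  if (edges[1] == edges[bins + 1L]) edges <- edges[1] + c(-0.5, 0.5)
  out <- list()
  for (dir in c("anterograde", "retrograde")) {
    vi <- track_summary$mean_intensity[track_summary$direction == dir]
    vi <- vi[is.finite(vi)]
    if (!length(vi)) next
    h <- graphics::hist(vi, breaks = edges, plot = FALSE)
    w <- diff(h$breaks)
    out[[dir]] <- list(bin_edges = h$breaks,
                       density = h$counts / (sum(h$counts) * w))
  }
  out
}
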