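# Microcluster detection: 8-bit conversion, Gaussian filtering, percentile
# thresholding with connected-component feature extraction, and the
# actin-derived positive mask restricting analysis to the dSMAC/pSMAC
# annulus.

#' Convert a stack to 8-bit
#'
#' Linear min-max rescale over the whole stack to \[0, 255\] with
#' round-half-up quantization; a constant stack maps to 0.
#'
#' @param stack an \code{ImageStack} (or plain array/matrix).
#' @return the rescaled stack, same class as the input.
#' @export
to_8bit <- function(stack) {
  frames <- if (inherits(stack, "ImageStack")) stack$frames else stack
  lo <- min(frames); hi <- max(frames)
  out <- if (hi > lo) floor((frames - lo) / (hi - lo) * 255 + 0.5)
         else array(0, dim(frames))
  if (inherits(stack, "ImageStack")) { stack$frames <- out; stack }
  else out
}

#' Gaussian filter of a frame
#'
#' Convolution with a normalized Gaussian kernel of standard deviation
#' \code{radius / 2}, truncated at two standard deviations, replicated
#' borders.
#'
#' @param frame numeric matrix.
#' @param radius filter radius in px (default 3).
#' @return filtered matrix of the same size.
#' @export
gaussian_filter <- function(frame, radius = 3) {
  stopifnot(radius >= 1)
  sigma <- radius / 2
  k <- gaussian_kernel(sigma, truncate = 2)
  conv_replicate(frame, k)
}

# Linear convolution with replicate-padded borders.
conv_replicate <- function(img, kern) {
  hh <- (nrow(kern) - 1L) %/% 2
  hw <- (ncol(kern) - 1L) %/% 2
  H <- nrow(img); W <- ncol(img)
  pad <- img[c(rep(1L, hh), 1:H, rep(H, hh)),
             c(rep(1L, hw), 1:W, rep(W, hw)), drop = FALSE]
  full <- fft_convolve(pad, kern)
  full[(hh + 1L):(hh + H), (hw + 1L):(hw + W)]
}

#' Detect microcluster features in one frame
#'
#' Pixels at or above the stated intensity percentile form 8-connected
#' components; components of at least \code{min_size} pixels become features
#' with intensity-weighted (sub-pixel) centroids.
#'
#' @param frame numeric matrix (a filtered 8-bit frame in the standard
#'   pipeline).
#' @param percentile intensity percentile in (0, 1) defining the threshold
#'   (default 0.97).
#' @param min_size minimum component size in px (default 4).
#' @param geometry optional \code{CellGeometry}; when given, only features
#'   whose centroid falls inside the mask are returned.
#' @return data.frame with columns \code{x}, \code{y}, \code{intensity}
#'   (summed), \code{size} (px).
#' @export
threshold_detect <- function(frame, percentile = 0.97, min_size = 4,
                             geometry = NULL) {
  if (percentile <= 0 || percentile >= 1)
    stop("percentile must be in (0, 1)")
  th <- stats::quantile(frame, percentile, names = FALSE)
  fg <- which(frame >= th & frame > min(frame))
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      intensity = numeric(0), size = integer(0))
  if (!length(fg)) return(empty)
  lab <- label_components(fg, nrow(frame))
  int <- frame[fg]
  y <- (fg - 1L) %% nrow(frame) + 1L
  x <- (fg - 1L) %/% nrow(frame) + 1L
  sz <- tapply(rep(1L, length(fg)), lab, sum)
  keep <- names(sz)[sz >= min_size]
  if (!length(keep)) return(empty)
  sel <- lab %in% keep
  lf <- factor(lab[sel])
  wsum <- tapply(int[sel], lf, sum)
  cx <- tapply(int[sel] * x[sel], lf, sum) / wsum
  cy <- tapply(int[sel] * y[sel], lf, sum) / wsum
  out <- data.frame(x = as.numeric(cx), y = as.numeric(cy),
                    intensity = as.numeric(wsum),
                    size = as.integer(sz[levels(lf)]))
  if (!is.null(geometry)) {
    ix <- pmin(pmax(round(out$x), 1), ncol(geometry$mask))
    iy <- pmin(pmax(round(out$y), 1), nrow(geometry$mask))
    out <- out[geometry$mask[cbind(iy, ix)], , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# 8-connected component labelling of foreground linear indices (column-major
# with H rows).  Union-find; returns an integer label per index.
label_components <- function(idx, H) {
  n <- length(idx)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pos <- integer(0)
  lut <- new.env(hash = TRUE, size = 2L * n)
  for (i in seq_len(n)) assign(as.character(idx[i]), i, envir = lut)
  y <- (idx - 1L) %% H
  x <- (idx - 1L) %/% H
  offs <- list(c(-1L, -1L), c(0L, -1L), c(1L, -1L), c(-1L, 0L))
  for (o in offs) {
    nb <- (x + o[2]) * H + (y + o[1]) + 1L
    valid <- (y + o[1]) >= 0L & (y + o[1]) < H
    for (i in which(valid)) {
      j <- lut[[as.character(nb[i])]]
      if (!is.null(j)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Build the actin positive mask
#'
#' Thresholds the time-averaged actin image (Otsu) to obtain the cell
#' footprint, takes its filled largest connected component as the cell, and
#' identifies the cSMAC as the low-intensity hole nearest the footprint
#' centroid.  The returned mask is the footprint minus the cSMAC: the
#' dSMAC/pSMAC annulus in which TCR transport is analyzed.
#'
#' @param actin an actin-channel \code{ImageStack}.
#' @return a \code{CellGeometry} with \code{center}, \code{cell_radius},
#'   \code{csmac_radius} (equivalent-disc radii, px) and the boolean mask.
#' @export
actin_positive_mask <- function(actin) {
  avg <- apply(actin$frames, c(1, 2), mean)
  if (max(avg) <= min(avg)) stop("no cell footprint found (constant image)")
  sm <- conv_replicate(avg, gaussian_kernel(2))
  rng <- range(sm)
  u <- (sm - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(t(u)), range = c(0, 1))
  fp <- u > th
  lab <- EBImage::bwlabel(EBImage::Image(t(fp)))
  labm <- t(EBImage::imageData(lab))
  if (max(labm) == 0) stop("no cell footprint found")
  big <- which.max(tabulate(labm[labm > 0]))
  fp <- labm == big
  filled <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(fp)))))
  filled <- filled > 0
  idx <- which(filled)
  cy <- (idx - 1L) %% nrow(filled) + 1L
  cx <- (idx - 1L) %/% nrow(filled) + 1L
  center <- c(mean(cx), mean(cy))
  cell_radius <- sqrt(sum(filled) / pi)
  holes <- filled & !fp
  csmac <- holes
  if (any(holes)) {
    hl <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(holes)))))
    nh <- max(hl)
    # hole nearest the centroid (by its own centroid distance)
    dbest <- Inf; best <- 0L
    for (h in seq_len(nh)) {
      hi <- which(hl == h)
      hy <- mean((hi - 1L) %% nrow(hl) + 1L)
      hx <- mean((hi - 1L) %/% nrow(hl) + 1L)
      d <- sqrt((hx - center[1])^2 + (hy - center[2])^2)
      if (d < dbest) { dbest <- d; best <- h }
    }
    csmac <- hl == best
  }
  csmac_radius <- sqrt(max(sum(csmac), 0) / pi)
  cell_geometry(center, cell_radius, csmac_radius, mask = fp & !csmac)
}

#' Detection accuracy against ground truth
#'
#' Fraction of true cluster positions matched by a detected feature within
#' \code{match_radius}, matching greedily by distance with each feature used
#' at most once per frame.
#'
#' @param features data.frame with columns \code{frame}, \code{x}, \code{y}
#'   (detections pooled over frames).
#' @param gt a \code{GroundTruth} (its \code{clusters} table provides the
#'   true positions), or a data.frame with \code{frame}, \code{x}, \code{y}.
#' @param match_radius maximum match distance in px (default 3).
#' @return matched fraction in \[0, 1\].
#' @export
detection_accuracy <- function(features, gt, match_radius = 3) {
  truth <- if (inherits(gt, "GroundTruth")) gt$clusters else gt
  if (!nrow(truth)) stop("empty ground truth")
  matched <- 0L
  for (t in unique(truth$frame)) {
    tt <- truth[truth$frame == t, , drop = FALSE]
    ff <- features[features$frame == t, , drop = FALSE]
    if (!nrow(ff)) next
    matched <- matched + greedy_match_count(tt$x, tt$y, ff$x, ff$y,
                                            match_radius)
  }
  matched / nrow(truth)
}

# Greedy one-to-one matching by increasing distance; returns match count.
greedy_match_count <- function(tx, ty, fx, fy, radius) {
  d <- outer(tx, fx, "-")^2 + outer(ty, fy, "-")^2
  cand <- which(d <= radius^2, arr.ind = TRUE)
  if (!nrow(cand)) return(0L)
  ord <- order(d[cand])
  cand <- cand[ord, , drop = FALSE]
  tu <- logical(length(tx)); fu <- logical(length(fx))
  m <- 0L
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!tu[i] && !fu[j]) { tu[i] <- TRUE; fu[j] <- TRUE; m <- m + 1L }
  }
  m
}

#' Detect features in every frame of a stack
#'
#' Standard per-frame pipeline: whole-stack 8-bit conversion, per-frame
#' Gaussian filter, percentile threshold detection.
#'
#' @inheritParams threshold_detect
#' @param stack an \code{ImageStack}.
#' @param radius Gaussian filter radius in px.
#' @return data.frame of features with a \code{frame} column.
#' @export
detect_features <- function(stack, percentile = 0.97, min_size = 4,
                            radius = 3, geometry = NULL) {
  s8 <- to_8bit(stack)
  out <- vector("list", n_frames(s8))
  for (t in seq_len(n_frames(s8))) {
    f <- gaussian_filter(stack_frame(s8, t), radius)
    ft <- threshold_detect(f, percentile, min_size, geometry)
    if (nrow(ft)) ft$frame <- t
    out[[t]] <- ft
  }
  out <- do.call(rbind, out[vapply(out, nrow, integer(1)) > 0])
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0), intensity = numeric(0),
                      size = integer(0), frame = integer(0))
  rownames(out) <- NULL
  out
}
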