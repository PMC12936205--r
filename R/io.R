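# Reading and writing of the standard interchange formats: multi-page
# 16-bit TIFF movies with ImageJ-style metadata, CSV tables, JSON summaries
# and YAML run configurations.

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Pixel size and frame interval are stored in an ImageJ-style description
#' tag where the TIFF writer supports it, and always in a JSON sidecar file
#' (\code{<path>.meta.json}) so the stack round-trips through
#' [read_stack_tiff()].  Intensities are stored as integer counts (clipped
#' at 65535).
#'
#' @param stack an \code{ImageStack}.
#' @param path output file path.
#' @export
write_stack_tiff <- function(stack, path) {
  TT <- n_frames(stack)
  desc <- sprintf(
    "ImageJ=1.53t\nimages=%d\nframes=%d\nunit=um\npixelwidth=%.6f\nfinterval=%.6f\nchannel=%s",
    TT, TT, stack$pixel_size / 1000, stack$frame_interval, stack$channel)
  pages <- lapply(seq_len(TT), function(t) {
    m <- pmin(pmax(round(stack$frames[, , t]), 0), 65535) / 65535
    attr(m, "description") <- desc
    m
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(pixel_size_nm = stack$pixel_size,
                            frame_interval_s = stack$frame_interval,
                            channel = stack$channel, n_frames = TT),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF written by [write_stack_tiff()]
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval fallbacks (nm/px, s) when the file
#'   carries no metadata.
#' @return an \code{ImageStack} with intensities as integer counts.
#' @export
read_stack_tiff <- function(path, pixel_size = NA, frame_interval = NA) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  desc <- attr(pages[[1]], "description")
  channel <- "unknown"
  if (!is.null(desc)) {
    grab <- function(key) {
      m <- regmatches(desc, regexec(paste0(key, "=([0-9eE.+-]+)"), desc))[[1]]
      if (length(m) == 2) as.numeric(m[2]) else NA
    }
    pw <- grab("pixelwidth")
    if (is.finite(pw)) pixel_size <- pw * 1000
    fi <- grab("finterval")
    if (is.finite(fi)) frame_interval <- fi
    mc <- regmatches(desc, regexec("channel=([a-zA-Z0-9_]+)", desc))[[1]]
    if (length(mc) == 2) channel <- mc[2]
  }
  sidecar <- paste0(path, ".meta.json")
  if ((!is.finite(pixel_size) || !is.finite(frame_interval)) &&
      file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    pixel_size <- as.numeric(meta$pixel_size_nm)
    frame_interval <- as.numeric(meta$frame_interval_s)
    if (!is.null(meta$channel)) channel <- meta$channel
  }
  if (!is.finite(pixel_size) || !is.finite(frame_interval))
    stop("pixel_size / frame_interval not in file metadata; pass explicitly")
  frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- round(pages[[t]] * 65535)
  image_stack(frames, pixel_size, frame_interval, channel)
}

#' Write tracks (or any table) as CSV
#' @param x data.frame.
#' @param path output path.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file.
#' @return validated config list, see [run_pipeline()].
#' @export
read_run_config <- function(path) {
  validate_run_config(yaml::read_yaml(path))
}
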