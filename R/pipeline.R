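# End-to-end orchestration: generate (or load) movies, run detection,
# tracking, PIV, wavefront detection and colocalization per cell, aggregate
# per-cell statistics as mean +/- SEM and compare groups with the
# Mann-Whitney test.

#' Analyze one two-channel movie
#'
#' The full analysis chain on a single cell: actin positive mask, TCR
#' detection and predictive linking, motility filter, direction
#' classification, PIV flow summary, Sobel wavefront detection and
#' TCR-wavefront colocalization.
#'
#' @param tcr,actin \code{ImageStack}s of the two channels (\code{actin}
#'   may be NULL: flow and wave stages are then skipped and the geometry
#'   must be supplied).
#' @param params named list of stage parameters; missing entries take the
#'   package defaults (see [default_params()]).
#' @param geometry optional \code{CellGeometry}; when NULL it is recovered
#'   from the actin channel.
#' @return list with \code{geometry}, \code{features}, \code{tracks},
#'   \code{motile}, \code{track_summary}, \code{tcr} (directional summary),
#'   \code{flow} (PIV summary or "skipped"), \code{actin_particles},
#'   \code{colocalization} (fraction or "skipped").
#' @export
analyze_movie <- function(tcr, actin = NULL, params = list(),
                          geometry = NULL) {
  p <- utils::modifyList(default_params(), params)
  if (is.null(geometry)) {
    if (is.null(actin))
      stop("need either an actin channel or an explicit geometry")
    geometry <- actin_positive_mask(actin)
  }
  features <- detect_features(tcr, percentile = p$percentile,
                              min_size = p$min_size, radius = p$radius,
                              geometry = geometry)
  tracks <- link(features, search_range = p$search_range, memory = p$memory)
  motile <- filter_motile(tracks, min_displacement = p$min_displacement)
  tsum <- summarize_tracks(motile, geometry, tcr$pixel_size,
                           tcr$frame_interval)
  res <- list(geometry = geometry, features = features, tracks = tracks,
              motile = motile, track_summary = tsum,
              tcr = directional_fraction(tsum))
  if (is.null(actin)) {
    res$flow <- res$actin_particles <- res$colocalization <- "skipped"
    return(res)
  }
  fields <- piv(actin, window = p$piv_window, overlap = p$piv_overlap,
                geometry = geometry)
  res$flow <- flow_summary(fields, geometry, noise_floor = p$noise_floor)
  res$fields <- fields
  res$actin_particles <- tryCatch(
    actin_particle_tracking(actin, geometry,
                            percentile = p$actin_percentile,
                            search_range = p$search_range,
                            memory = p$memory),
    error = function(e) "skipped")
  wf <- detect_wavefronts(actin, gmin = p$gmin, gmax = p$gmax,
                          geometry = geometry)
  res$wavefronts <- wf
  res$colocalization <- tcr_wave_colocalization(motile, wf)
  res
}

#' Default stage parameters
#'
#' @return named list: detection (\code{percentile} 0.97, \code{min_size} 4,
#'   \code{radius} 3), actin feature detection (\code{actin_percentile}
#'   0.99), tracking (\code{search_range} 5 px, \code{memory} 2,
#'   \code{min_displacement} 3.5 px), PIV (\code{piv_window} 32,
#'   \code{piv_overlap} 16, \code{noise_floor} 10 nm/s), wavefront gradient
#'   bounds (\code{gmin} 10, \code{gmax} 40 AU).
#' @export
default_params <- function() {
  list(percentile = 0.97, min_size = 4, radius = 3, actin_percentile = 0.99,
       search_range = 5, memory = 2, min_displacement = 3.5,
       piv_window = 32, piv_overlap = 16, noise_floor = 10,
       gmin = 10, gmax = 40)
}

#' Validate a run configuration
#'
#' @param config list with \code{profiles} (character vector of profile
#'   names, or list of lists with \code{name} and \code{overrides}),
#'   \code{n_cells}, \code{seed}, optional \code{params}, \code{outdir},
#'   \code{stages}.
#' @return the normalized config.
#' @export
validate_run_config <- function(config) {
  if (is.null(config$profiles) || !length(config$profiles))
    stop("config must name at least one profile")
  profs <- lapply(config$profiles, function(p) {
    if (is.character(p)) p <- list(name = p, overrides = list())
    if (is.null(p$overrides)) p$overrides <- list()
    # raises on unknown names / bad overrides before any stage runs
    make_profile(p$name, p$overrides)
    p
  })
  config$profiles <- profs
  if (is.null(config$n_cells)) config$n_cells <- 1L
  if (config$n_cells < 1) stop("n_cells must be at least 1")
  if (is.null(config$seed)) config$seed <- 1L
  if (is.null(config$params)) config$params <- list()
  utils::modifyList(default_params(), config$params)  # validates names exist
  config
}

#' Run the full pipeline over simulated cells
#'
#' For every profile and cell, generates ground truth and movies with a
#' per-cell seed (base seed + cell index), runs [analyze_movie()], scores
#' detection accuracy against the ground truth, and aggregates per-cell
#' metrics.  When two or more profiles are configured, consecutive profile
#' pairs are compared with the Mann-Whitney test on the TCR anterograde
#' fraction.
#'
#' @param config a run configuration (see [validate_run_config()]), or a
#'   path to a YAML file.
#' @param write if TRUE and \code{config$outdir} is set, per-cell artifacts
#'   (tracks CSV, flow CSV, summary JSON) are written there.
#' @return a \code{Report} list: \code{cells} (per-cell data.frame),
#'   \code{aggregates} (per-profile mean +/- SEM), \code{comparisons},
#'   \code{config}.
#' @export
run_pipeline <- function(config, write = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  rows <- list()
  for (pr in config$profiles) {
    for (cell in seq_len(config$n_cells)) {
      seed <- config$seed + cell - 1L
      prof <- make_profile(pr$name,
                           utils::modifyList(pr$overrides,
                                             list(seed = seed)))
      gt <- simulate_ground_truth(prof)
      mov <- render_movie(gt, prof)
      res <- analyze_movie(mov$tcr, mov$actin, config$params)
      # detector recall scored within the analyzed (masked) region
      tr <- gt$clusters
      g <- res$geometry
      inm <- g$mask[cbind(pmin(pmax(round(tr$y), 1), nrow(g$mask)),
                          pmin(pmax(round(tr$x), 1), ncol(g$mask)))]
      acc <- detection_accuracy(res$features, tr[inm, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        profile = pr$name, cell = cell, seed = seed,
        n_motile = res$tcr$n_tracks,
        tcr_anterograde = res$tcr$anterograde_fraction,
        tcr_speed = res$tcr$mean_speed,
        actin_anterograde = if (is.list(res$flow))
          res$flow$anterograde_fraction else NA_real_,
        actin_speed = if (is.list(res$flow)) res$flow$mean_speed
          else NA_real_,
        colocalization = if (is.numeric(res$colocalization))
          res$colocalization else NA_real_,
        detection_accuracy = acc)
      if (write && !is.null(config$outdir)) {
        d <- file.path(config$outdir, pr$name, sprintf("cell_%02d", cell))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_table_csv(res$motile, file.path(d, "tracks.csv"))
        if (is.data.frame(res$fields))
          write_table_csv(res$fields, file.path(d, "flow.csv"))
        jsonlite::write_json(rows[[length(rows)]],
                             file.path(d, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }
  cells <- do.call(rbind, rows)
  metrics <- c("tcr_anterograde", "tcr_speed", "actin_anterograde",
               "actin_speed", "colocalization", "detection_accuracy")
  aggregates <- do.call(rbind, lapply(split(cells, cells$profile), function(d)
    do.call(rbind, lapply(metrics, function(m) {
      v <- d[[m]][is.finite(d[[m]])]
      data.frame(profile = d$profile[1], metric = m,
                 mean = if (length(v)) mean(v) else NA_real_,
                 sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v))
                 else NA_real_,
                 n = length(v))
    }))))
  rownames(aggregates) <- NULL
  comparisons <- NULL
  prof_names <- vapply(config$profiles, `[[`, "", "name")
  if (length(prof_names) >= 2 && config$n_cells >= 3) {
    comparisons <- do.call(rbind, lapply(seq_len(length(prof_names) - 1L),
      function(i) {
        a <- cells$tcr_anterograde[cells$profile == prof_names[i]]
        b <- cells$tcr_anterograde[cells$profile == prof_names[i + 1L]]
        data.frame(group_a = prof_names[i], group_b = prof_names[i + 1L],
                   metric = "tcr_anterograde",
                   p_value = mann_whitney(a, b))
      }))
  }
  structure(list(cells = cells, aggregates = aggregates,
                 comparisons = comparisons, config = config),
            class = "Report")
}

#' @export
print.Report <- function(x, ...) {
  cat("Pipeline report:", nrow(x$cells), "cells\n")
  print(x$aggregates)
  if (!is.null(x$comparisons)) print(x$comparisons)
  invisible(x)
}

#' Mann-Whitney (Wilcoxon rank-sum) two-sided test
#'
#' Exact p-value when both groups have at most 8 values and there are no
#' ties; otherwise the normal approximation with tie correction.
#'
#' @param a,b numeric vectors (per-cell values of two groups).
#' @return two-sided p-value.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  ties <- any(duplicated(c(a, b)))
  exact <- length(a) <= 8 && length(b) <= 8 && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = !exact)$p.value)
}

#' Mean and standard error of the mean
#'
#' @param values numeric vector, length at least 2.
#' @return list with \code{mean} and \code{sem} (sample sd / sqrt(n)).
#' @export
aggregate_mean_sem <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(length(values)))
}
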