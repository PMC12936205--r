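# Shared fixtures.  Small-scale profiles keep unit tests fast; the heavier
# movie fixtures are generated once per session and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A reduced-scale scenario: 1.5 um cell, 40 frames, 12 clusters.
tiny_profile <- function(name = "primary", ...) {
  make_profile(name, utils::modifyList(
    list(cell_radius = 1500, csmac_radius = 400, n_frames = 40,
         n_clusters = 12, n_speckles = 250, min_separation = 450,
         seed = 11),
    list(...)))
}

tiny_gt <- function(name = "primary", ...) {
  simulate_ground_truth(tiny_profile(name, ...))
}

tiny_movie <- function(name = "primary", ...) {
  key <- paste0("movie_", name, "_", paste(c(...), collapse = "_"))
  cached(key, {
    gt <- tiny_gt(name, ...)
    list(gt = gt, movie = render_movie(gt, gt$profile))
  })
}

# Flat test geometry for synthetic constructions.
flat_geometry <- function(H = 96, W = 96, cell_radius = 44,
                          csmac_radius = 10) {
  cell_geometry(c(W / 2 + 0.5, H / 2 + 0.5), cell_radius, csmac_radius,
                dim = c(H, W))
}

# Random-speckle texture frame used by PIV oracles.
speckle_frame <- function(H, pts, amp = 300, sigma = 1.3) {
  synaptrack:::add_gaussian_spots(matrix(0, H, H), pts[, 1], pts[, 2],
                                  rep(amp, nrow(pts)), sigma)
}
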