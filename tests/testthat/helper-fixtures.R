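# Shared tiny-scanner fixtures, built once per test run.

tiny_geom <- function() scanner_geometry(6, 6, n_layers = 1)
tiny_grid <- function(geom = tiny_geom()) voxel_grid(geom, n_planes = 3, dz = 8, m = 1)

.fixture_env <- new.env()

# memoised unpruned seed pool on the tiny scanner
tiny_store <- function() {
  if (is.null(.fixture_env$store))
    .fixture_env$store <- build_seed_pool(tiny_geom(), tiny_grid(),
                                          drf_model(prune_rel = 0))
  .fixture_env$store
}

tiny_schedule <- function() {
  if (is.null(.fixture_env$sched))
    .fixture_env$sched <- make_schedule(tiny_geom(), tiny_grid())
  .fixture_env$sched
}

random_lors <- function(geom, n) {
  data.frame(ur = sample.int(geom$n_rows, n, TRUE) - 1,
             uc = sample.int(geom$n_cols, n, TRUE) - 1,
             lr = sample.int(geom$n_rows, n, TRUE) - 1,
             lc = sample.int(geom$n_cols, n, TRUE) - 1)
}

random_voxels <- function(grid, n) {
  half <- (grid$n_planes - 1) / 2
  data.frame(slice = sample.int(grid$n_planes, n, TRUE) - 1 - half,
             vrow = sample.int(grid$n_vrows, n, TRUE) - 1,
             vcol = sample.int(grid$n_vcols, n, TRUE) - 1)
}

# relative difference against the magnitude of the reference
rel_err <- function(got, ref) {
  scale <- max(abs(ref))
  if (scale == 0) return(max(abs(got)))
  max(abs(got - ref)) / scale
}
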