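test_that("schedules partition the LOR set with the expected family sizes", {
  geom <- tiny_geom(); grid <- tiny_grid()
  sched <- tiny_schedule()
  sl <- schedule_lors(sched)
  expect_equal(nrow(sl), lor_count(geom, layers = FALSE))
  expect_false(anyDuplicated(sl$linear) > 0)
  expect_setequal(sl$linear, seq_len(nrow(sl)) - 1)

  geom8 <- scanner_geometry(8, 8, n_layers = 1)
  grid8 <- voxel_grid(geom8, n_planes = 3, dz = 8, m = 1)
  # one generic oblique orientation: symmetric families of 4
  s1 <- make_schedule(geom8, grid8, data.frame(dr = 2, dc = 3))
  expect_equal(nrow(s1$families[[1]]), 4)
  l1 <- schedule_lors(s1)
  expect_setequal(paste(l1$lr - l1$ur, l1$lc - l1$uc),
                  c("2 3", "-2 3", "2 -3", "-2 -3"))
  expect_false(anyDuplicated(l1$linear) > 0)
  # one-sided orientations: families of 2; axial orientation: families of 1
  expect_equal(nrow(make_schedule(geom8, grid8,
                                  data.frame(dr = 0, dc = 3))$families[[1]]), 2)
  expect_equal(nrow(make_schedule(geom8, grid8,
                                  data.frame(dr = 0, dc = 0))$families[[1]]), 1)
  expect_error(make_schedule(geom8, grid8, data.frame(dr = 99, dc = 0)),
               "unknown orientation")
})

test_that("forward projection reproduces DRF columns and the sum identity", {
  store <- tiny_store(); sched <- tiny_schedule()
  geom <- tiny_geom(); grid <- tiny_grid()
  expect_equal(sum(forward_project(image_volume(0, grid), store, sched)$values), 0)
  # point source at a seed voxel projects to that voxel's expanded DRF column
  vox <- data.frame(slice = 0, vrow = 2, vcol = 2)
  y <- forward_project(point_source(grid, vox), store, sched)
  lors <- planarpet:::lor_from_linear(geom, seq_len(lor_count(geom, FALSE)) - 1)
  ref <- srm_element(store, lors, vox[rep(1, nrow(lors)), ])
  expect_equal(y$values, ref)
  # sum over LORs of Hx equals the sensitivity-weighted voxel sum
  set.seed(11)
  x <- runif(voxel_count(grid))
  lhs <- sum(forward_project(image_volume(x, grid), store, sched)$values)
  rhs <- sum(as.vector(sensitivity_image(store, sched)) * x)
  expect_lt(abs(lhs - rhs) / abs(rhs), 1e-10)
  expect_error(forward_project(image_volume(-1, grid), store, sched),
               "negative")
})

test_that("forward and back projection are adjoint and linear", {
  store <- tiny_store(); sched <- tiny_schedule()
  grid <- tiny_grid(); geom <- tiny_geom()
  n_lor <- lor_count(geom, layers = FALSE)
  set.seed(23)
  for (rep in 1:20) {
    x <- runif(voxel_count(grid))
    y <- runif(n_lor)
    hx <- forward_project(image_volume(x, grid), store, sched)$values
    hty <- as.vector(back_project(lor_histogram(y, geom), store, sched))
    lhs <- sum(hx * y); rhs <- sum(x * hty)
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-10)
  }
  # linearity
  a <- 2.5; b <- 0.3
  x1 <- runif(voxel_count(grid)); x2 <- runif(voxel_count(grid))
  f <- function(x) forward_project(image_volume(x, grid), store, sched)$values
  expect_lt(rel_err(f(a * x1 + b * x2), a * f(x1) + b * f(x2)), 1e-10)
  # nonnegativity preservation
  expect_true(all(f(x1) >= 0))
  expect_true(all(as.vector(back_project(lor_histogram(abs(rnorm(n_lor)), geom),
                                         store, sched)) >= 0))
})

test_that("back projection of ones is the sensitivity image, with symmetry", {
  store <- tiny_store(); sched <- tiny_schedule()
  geom <- tiny_geom(); grid <- tiny_grid()
  ones <- lor_histogram(1, geom)
  sens <- sensitivity_image(store, sched)
  expect_equal(as.vector(back_project(ones, store, sched)), as.vector(sens))
  # empty schedule gives a zero sensitivity image
  empty <- make_schedule(geom, grid, data.frame(dr = numeric(0), dc = numeric(0)))
  expect_equal(sum(sensitivity_image(store, empty)), 0)
  expect_equal(sum(back_project(lor_histogram(0, geom), store, sched)), 0)
  # in-plane reflection symmetry of the full-scanner sensitivity
  s <- as.array(sens)
  expect_lt(rel_err(s[rev(seq_len(dim(s)[1])), , ], s), 1e-12)
  expect_lt(rel_err(s[, rev(seq_len(dim(s)[2])), ], s), 1e-12)
  # every voxel in the common acceptance has positive sensitivity
  expect_true(all(as.vector(sens) > 0))
})

test_that("zero-value skipping is a semantic no-op", {
  store <- tiny_store(); sched <- tiny_schedule()
  geom <- tiny_geom(); grid <- tiny_grid()
  set.seed(4)
  # sparse image (99% zeros)
  x <- numeric(voxel_count(grid))
  x[sample(length(x), ceiling(length(x) / 100))] <- runif(ceiling(length(x) / 100))
  expect_identical(forward_project(image_volume(x, grid), store, sched,
                                   zero_skip = TRUE)$values,
                   forward_project(image_volume(x, grid), store, sched)$values)
  y <- numeric(lor_count(geom, FALSE))
  y[sample(length(y), 50)] <- rpois(50, 5)
  expect_identical(as.vector(back_project(lor_histogram(y, geom), store, sched,
                                          zero_skip = TRUE)),
                   as.vector(back_project(lor_histogram(y, geom), store, sched)))
  # all-zero histogram returns immediately with a zero image
  expect_equal(sum(back_project(lor_histogram(0, geom), store, sched,
                                zero_skip = TRUE)), 0)
  # dense inputs are also unchanged
  yd <- runif(length(y))
  expect_identical(as.vector(back_project(lor_histogram(yd, geom), store, sched,
                                          zero_skip = TRUE)),
                   as.vector(back_project(lor_histogram(yd, geom), store, sched)))
})

test_that("scheduled and naive per-LOR execution paths agree", {
  store <- tiny_store(); sched <- tiny_schedule()
  grid <- tiny_grid()
  set.seed(8)
  x <- runif(voxel_count(grid))
  fast <- forward_project(image_volume(x, grid), store, sched)$values
  slow <- forward_project_naive(image_volume(x, grid), store, sched)$values
  expect_lt(rel_err(slow, fast), 1e-10)
  # and on a strict sub-schedule
  sub <- make_schedule(tiny_geom(), grid, data.frame(dr = c(0, 1), dc = c(0, 2)))
  fast2 <- forward_project(image_volume(x, grid), store, sub)$values
  slow2 <- forward_project_naive(image_volume(x, grid), store, sub)$values
  expect_lt(rel_err(slow2, fast2), 1e-10)
})

test_that("fingerprint mismatches are fatal before compute", {
  store <- tiny_store()
  other_geom <- scanner_geometry(6, 6, n_layers = 1, head_separation = 50)
  other_grid <- voxel_grid(other_geom, n_planes = 3, dz = 8, m = 1)
  sched_other <- make_schedule(other_geom, other_grid)
  expect_error(srm_matrix(store, sched_other), "fingerprint")
  vol_other <- image_volume(1, other_grid)
  expect_error(forward_project(vol_other, store, tiny_schedule()),
               "fingerprint|length")
  y_other <- lor_histogram(1, other_geom)
  expect_error(back_project(y_other, store, tiny_schedule()), "fingerprint")
})
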