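test_that("seed pool layout counts plane and offset classes", {
  # default grid: 60 plane classes x 3 in-plane classes
  skel <- build_seed_pool(default_geometry(), default_grid(), compute = FALSE)
  expect_equal(skel$n_seeds, 180)
  expect_equal(nrow(seed_pool_layout(tiny_geom(), tiny_grid())), 2)
  g1 <- scanner_geometry(4, 4, n_layers = 1)
  expect_equal(nrow(seed_pool_layout(g1, voxel_grid(g1, 5, dz = 6, m = 1))), 3)
  expect_equal(nrow(seed_pool_layout(g1, voxel_grid(g1, 1, dz = 6, m = 1))), 1)
  expect_error(compute_seed_drf(tiny_geom(), tiny_grid(),
                                list(slice = -1, vrow = 2, vcol = 2)),
               "representative")
})

test_that("the geometric detection model behaves physically", {
  geom <- tiny_geom(); grid <- tiny_grid()
  store <- tiny_store()
  # voxel far outside both crystals' acceptance cone: zero probability
  off <- srm_element(store,
                     data.frame(ur = 0, uc = 0, lr = 0, lc = 0),
                     data.frame(slice = 0, vrow = 5, vcol = 5))
  expect_equal(off, 0)
  # perpendicular LOR directly over a seed voxel dominates its orientation
  # family: compare against every same-orientation LOR for that voxel
  vox <- data.frame(slice = 0, vrow = 2, vcol = 2)
  perp <- expand.grid(ur = 0:5, uc = 0:5)
  lor0 <- data.frame(ur = perp$ur, uc = perp$uc, lr = perp$ur, lc = perp$uc)
  vals <- srm_element(store, lor0, vox[rep(1, nrow(lor0)), ])
  expect_equal(which.max(vals), which(perp$ur == 2 & perp$uc == 2))
  # halving crystal thickness strictly decreases every nonzero entry
  thin <- scanner_geometry(6, 6, n_layers = 1, crystal_thickness = 10)
  store_thin <- build_seed_pool(thin, voxel_grid(thin, 3, dz = 8, m = 1),
                                drf_model(prune_rel = 0))
  set.seed(7)
  lor <- random_lors(geom, 400)
  voxs <- random_voxels(grid, 400)
  v_thick <- srm_element(store, lor, voxs)
  v_thin <- srm_element(store_thin, lor, voxs)
  nz <- v_thick > 0
  expect_gt(sum(nz), 20)
  expect_true(all(v_thin[nz] < v_thick[nz]))
})

test_that("the model itself honours the symmetry group", {
  geom <- tiny_geom(); grid <- tiny_grid()
  model <- drf_model(prune_rel = 0)
  set.seed(19)
  lor <- random_lors(geom, 300)
  vox <- random_voxels(grid, 300)
  T <- planarpet:::lv_tuple(geom, grid, lor, vox)
  base <- planarpet:::drf_prob(geom, grid, T, model)
  flips <- expand.grid(fx = c(FALSE, TRUE), fy = c(FALSE, TRUE),
                       fz = c(FALSE, TRUE), ix = c(FALSE, TRUE))
  for (i in seq_len(nrow(flips))) {
    Tg <- planarpet:::tuple_op(T, flips$fx[i], flips$fy[i], flips$fz[i],
                               flips$ix[i])
    got <- planarpet:::drf_prob(geom, grid, Tg, model)
    expect_lt(rel_err(got, base), 1e-12)
    # zero/nonzero pattern is exactly invariant
    expect_identical(got > 0, base > 0)
  }
  # shift invariance is exact: same tuple, bitwise-equal value
  shifted <- apply_transform(geom, grid,
                             data.frame(fx = FALSE, fy = FALSE, fz = FALSE,
                                        ix = FALSE, shift_row = 1,
                                        shift_col = -2), lor, vox)
  T2 <- planarpet:::lv_tuple(geom, grid, shifted$lor, shifted$vox)
  expect_identical(planarpet:::drf_prob(geom, grid, T2, model), base)
})

test_that("symmetry-expanded SRM equals the brute-force oracle elementwise", {
  geoms <- list(
    list(geom = tiny_geom(), grid = tiny_grid()),
    list(geom = scanner_geometry(5, 7, n_layers = 1, pitch = 3),
         grid = NULL),
    list(geom = scanner_geometry(4, 4, n_layers = 1),
         grid = NULL))
  geoms[[2]]$grid <- voxel_grid(geoms[[2]]$geom, n_planes = 5, dz = 5, m = 1)
  geoms[[3]]$grid <- voxel_grid(geoms[[3]]$geom, n_planes = 3, dz = 10, m = 2)
  for (gg in geoms) {
    model <- drf_model(prune_rel = 0)
    store <- if (identical(gg$geom, tiny_geom())) tiny_store()
             else build_seed_pool(gg$geom, gg$grid, model)
    B <- brute_force_srm(gg$geom, gg$grid, model)
    H <- srm_matrix(store, make_schedule(gg$geom, gg$grid))
    expect_true(all(B@x >= 0))
    expect_true(all(Matrix::colSums(B) <= 1))
    expect_lt(max(abs(H - B)) / max(B), 1e-12)
    expect_identical(as.logical(as.matrix(H != 0)), as.logical(as.matrix(B != 0)))
  }
})

test_that("element lookups agree with shift-invariance and with brute force", {
  geom <- tiny_geom(); grid <- tiny_grid()
  store <- tiny_store()
  # Eq-(6)-style shifted image pairs have identical values
  lor <- data.frame(ur = 1, uc = 1, lr = 2, lc = 1)
  vox <- data.frame(slice = 0, vrow = 1, vcol = 1)
  shifted_lor <- data.frame(ur = 3, uc = 4, lr = 4, lc = 4)
  shifted_vox <- data.frame(slice = 0, vrow = 3, vcol = 4)
  expect_identical(srm_element(store, lor, vox),
                   srm_element(store, shifted_lor, shifted_vox))
  expect_gt(srm_element(store, lor, vox), 0)
  # out-of-acceptance pair is zero
  expect_equal(srm_element(store, data.frame(ur = 0, uc = 0, lr = 5, lc = 5),
                           data.frame(slice = 0, vrow = 0, vcol = 0)), 0)
  # full elementwise agreement with the brute-force oracle
  B <- brute_force_srm(geom, grid, drf_model(prune_rel = 0))
  set.seed(3)
  lors <- random_lors(geom, 500)
  voxs <- random_voxels(grid, 500)
  i <- planarpet:::lor_linear_index(geom, lors$ur, lors$uc, lors$lr, lors$lc) + 1
  j <- planarpet:::voxel_linear_index(grid, voxs$slice, voxs$vrow, voxs$vcol) + 1
  got <- srm_element(store, lors, voxs)
  ref <- B[cbind(i, j)]
  expect_lt(rel_err(got, ref), 1e-12)
})

test_that("pool construction is deterministic and pruning is recorded", {
  geom <- scanner_geometry(4, 4, n_layers = 1)
  grid <- voxel_grid(geom, n_planes = 3, dz = 8, m = 1)
  s1 <- build_seed_pool(geom, grid, drf_model())
  s2 <- build_seed_pool(geom, grid, drf_model())
  expect_identical(s1$values, s2$values)
  expect_identical(s1$keys, s2$keys)
  # pruned store drops the smallest entries but keeps the large ones
  sp <- build_seed_pool(geom, grid, drf_model(prune_rel = 0.5))
  s0 <- build_seed_pool(geom, grid, drf_model(prune_rel = 0))
  expect_lt(length(sp$values), length(s0$values))
  expect_gte(min(sp$seeds[[1]]$entries$value),
             0.5 * max(sp$seeds[[1]]$entries$value))
  expect_equal(sp$model$prune_rel, 0.5)
})
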