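test_that("plane classes group signed slices by reflection about the central plane", {
  expect_equal(nrow(plane_classes(119)), 60)
  expect_equal(plane_classes(119)$representative, 0:59)
  expect_equal(nrow(plane_classes(1)), 1)
  # independent brute-force grouping of {-3..3} by |slice|
  expect_equal(nrow(plane_classes(7)), length(unique(abs(-3:3))))
  for (n in c(3, 9, 45, 201))
    expect_equal(nrow(plane_classes(n)), (n + 1) / 2)
  expect_error(plane_classes(4), "odd")
})

test_that("in-plane offset classes match independent orbit enumeration", {
  expect_equal(inplane_seed_classes(1)$n_classes, 1)
  expect_equal(inplane_seed_classes(4)$n_classes, 3)
  expect_equal(inplane_seed_classes(6)$n_classes, 6)
  # closed-form oracle: k = ceiling(m/2) 1D reflection classes, then
  # unordered pairs (with repetition) under axis interchange
  for (m in 1:8) {
    k <- ceiling(m / 2)
    expect_equal(inplane_seed_classes(m)$n_classes, k * (k + 1) / 2)
  }
  # orbits partition the m*m offsets
  ic <- inplane_seed_classes(4)
  expect_equal(sum(ic$representatives$orbit_size), 16)
  expect_false(anyNA(ic$class_of))
})

test_that("canonicalization round-trips and its transform is a group element", {
  geom <- tiny_geom(); grid <- tiny_grid()
  set.seed(101)
  lor <- random_lors(geom, 1000)
  vox <- random_voxels(grid, 1000)
  can <- canonicalize(geom, grid, lor, vox)
  expect_true(all(can$seed_vox$slice >= 0))
  back <- apply_transform(geom, grid, can$transform, can$seed_lor, can$seed_vox)
  expect_identical(back$lor, lor)
  expect_identical(back$vox, vox)
  # already-canonical pairs map to themselves with the identity transform
  can2 <- canonicalize(geom, grid, can$seed_lor, can$seed_vox)
  expect_identical(can2$key, can$key)
  expect_identical(can2$seed_lor, can$seed_lor)
  expect_false(any(can2$transform$fx | can2$transform$fy |
                   can2$transform$fz | can2$transform$ix))
  expect_true(all(can2$transform$shift_row == 0 & can2$transform$shift_col == 0))
})

test_that("canonical images enumerate the same orbit partition as brute force", {
  # independent oracle: partition all (LOR, voxel) pairs of a mini scanner
  # into orbits by breadth-first closure over the index-level generators
  geom <- scanner_geometry(3, 3, n_layers = 1, head_separation = 30)
  grid <- voxel_grid(geom, n_planes = 3, dz = 4, m = 1)
  lors <- expand.grid(ur = 0:2, uc = 0:2, lr = 0:2, lc = 0:2,
                      KEEP.OUT.ATTRS = FALSE)
  voxs <- expand.grid(slice = -1:1, vrow = 0:2, vcol = 0:2,
                      KEEP.OUT.ATTRS = FALSE)
  pair_id <- function(l, v) paste(l$ur, l$uc, l$lr, l$lc, v$slice, v$vrow, v$vcol)
  all_pairs <- expand.grid(li = seq_len(nrow(lors)), vi = seq_len(nrow(voxs)))
  ids <- pair_id(lors[all_pairs$li, ], voxs[all_pairs$vi, ])
  # physical-lattice generators: reflections, head swap, interchange, and
  # the +-1-pitch shifts where they stay on the lattice
  neighbors <- function(l, v) {
    out <- list()
    flips <- expand.grid(fx = c(FALSE, TRUE), fy = c(FALSE, TRUE),
                         fz = c(FALSE, TRUE), ix = c(FALSE, TRUE))
    for (i in seq_len(nrow(flips))) {
      tr <- data.frame(flips[i, ], shift_row = 0, shift_col = 0)
      r <- apply_transform(geom, grid, tr, l, v)
      out[[length(out) + 1]] <- r
    }
    for (dr in -1:1) for (dc in -1:1) {
      tr <- data.frame(fx = FALSE, fy = FALSE, fz = FALSE, ix = FALSE,
                       shift_row = dr, shift_col = dc)
      r <- apply_transform(geom, grid, tr, l, v)
      ok <- all(r$lor >= 0) && all(r$lor[, c("ur", "lr")] <= 2) &&
        all(r$lor[, c("uc", "lc")] <= 2) &&
        r$vox$vrow >= 0 && r$vox$vrow <= 2 && r$vox$vcol >= 0 && r$vox$vcol <= 2
      if (ok) out[[length(out) + 1]] <- r
    }
    out
  }
  orbit_of <- rep(NA_integer_, length(ids))
  names(orbit_of) <- ids
  n_orbits <- 0
  for (k in seq_along(ids)) {
    if (!is.na(orbit_of[k])) next
    n_orbits <- n_orbits + 1
    queue <- list(list(lor = lors[all_pairs$li[k], ], vox = voxs[all_pairs$vi[k], ]))
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      id <- pair_id(cur$lor, cur$vox)
      if (!is.na(orbit_of[id])) next
      orbit_of[id] <- n_orbits
      queue <- c(queue, neighbors(cur$lor, cur$vox))
    }
  }
  can <- canonicalize(geom, grid,
                      lors[all_pairs$li, ], voxs[all_pairs$vi, ])
  expect_equal(length(unique(can$key)), n_orbits)
  # canonical key constant on each brute-force orbit
  expect_true(all(tapply(can$key, orbit_of, function(k) length(unique(k))) == 1))
})

test_that("symmetric families have the right sizes and are symmetric relations", {
  geom <- tiny_geom()
  fam <- symmetric_family(geom, data.frame(ur = 0, uc = 1, lr = 2, lc = 4))
  expect_equal(nrow(fam), 4)
  # a LOR through the exact detector center of an odd-sized head is fixed
  godd <- scanner_geometry(5, 5, n_layers = 1)
  fam1 <- symmetric_family(godd, data.frame(ur = 2, uc = 2, lr = 2, lc = 2))
  expect_equal(nrow(fam1), 1)
  # membership symmetry, exhaustively on the tiny scanner
  lors <- expand.grid(ur = 0:5, uc = 0:5, lr = 0:5, lc = 0:5)
  key <- function(l) paste(l$ur, l$uc, l$lr, l$lc)
  fam_keys <- lapply(seq_len(nrow(lors)), function(i)
    key(symmetric_family(geom, lors[i, ])))
  all_keys <- key(lors)
  symmetric <- vapply(seq_len(nrow(lors)), function(i)
    all(vapply(fam_keys[[i]], function(kk)
      all_keys[i] %in% fam_keys[[match(kk, all_keys)]], logical(1))),
    logical(1))
  expect_true(all(symmetric))
})

test_that("orientations partition the LOR set", {
  geom8 <- scanner_geometry(8, 8, n_layers = 1)
  expect_equal(nrow(enumerate_orientations(geom8)), 225)
  expect_equal(nrow(enumerate_orientations(scanner_geometry(1, 1, n_layers = 1))), 1)
  geom <- tiny_geom()
  ors <- enumerate_orientations(geom)
  lors <- expand.grid(ur = 0:5, uc = 0:5, lr = 0:5, lc = 0:5)
  okey <- paste(lors$lr - lors$ur, lors$lc - lors$uc)
  expect_true(all(okey %in% paste(ors$dr, ors$dc)))
  counts <- table(factor(okey, levels = paste(ors$dr, ors$dc)))
  # every LOR in exactly one orientation bucket
  expect_equal(sum(counts), nrow(lors))
})

test_that("group elements compose with their inverses to the identity", {
  geom <- tiny_geom(); grid <- tiny_grid()
  set.seed(33)
  lor <- random_lors(geom, 1000)
  vox <- random_voxels(grid, 1000)
  flips <- expand.grid(fx = c(FALSE, TRUE), fy = c(FALSE, TRUE),
                       fz = c(FALSE, TRUE), ix = c(FALSE, TRUE))
  for (i in seq_len(nrow(flips))) {
    tr <- data.frame(flips[i, ], shift_row = 2, shift_col = -1)
    fwd <- apply_transform(geom, grid, tr, lor, vox)
    # inverse: undo the shift, then undo the flips (opposite application order)
    mid_lor <- fwd$lor; mid_vox <- fwd$vox
    mid_lor$ur <- mid_lor$ur - 2; mid_lor$lr <- mid_lor$lr - 2
    mid_lor$uc <- mid_lor$uc + 1; mid_lor$lc <- mid_lor$lc + 1
    mid_vox$vrow <- mid_vox$vrow - grid$m * 2
    mid_vox$vcol <- mid_vox$vcol + grid$m * 1
    undone <- planarpet:::apply_flags(geom, grid, mid_lor, mid_vox,
                                      flips$fx[i], flips$fy[i], flips$fz[i],
                                      flips$ix[i], inverse = FALSE)
    expect_identical(undone$lor, lor)
    expect_identical(undone$vox, vox)
    # shifts never change the invariant tuple
    tr_shift <- data.frame(fx = FALSE, fy = FALSE, fz = FALSE, ix = FALSE,
                           shift_row = 3, shift_col = -2)
    shifted <- apply_transform(geom, grid, tr_shift, lor, vox)
    expect_identical(planarpet:::lv_tuple(geom, grid, shifted$lor, shifted$vox),
                     planarpet:::lv_tuple(geom, grid, lor, vox))
  }
})
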