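#' @title Symmetry group of the dual-head planar scanner
#' @description
#' The system response of a dual-head planar scanner is invariant under
#' (i) in-plane shifts of a crystal pair and voxel by whole crystal pitches,
#' (ii) reflections about the x-, y- and z- coordinate planes, and
#' (iii) interchanging the roles of the x- and y-axes. These operations
#' generate a group of order 16 acting on (LOR, voxel) pairs (8 when axis
#' interchange is unavailable, see Details). Quotienting the full system
#' response matrix by this group leaves one seed detector response function
#' (DRF) per z-plane reflection class and in-plane voxel offset class.
#'
#' Internally every (LOR, voxel) pair is reduced to an integer invariant
#' tuple `(s, gux, glx, guy, gly)`: the signed voxel slice plus the four
#' crystal-minus-voxel in-plane offsets in half in-plane-voxel units. The
#' tuple is constant under shifts, reflections negate or swap its components,
#' and canonicalization picks the lexicographically greatest tuple over the
#' group orbit (which in particular has a nonnegative seed slice).
#'
#' @details Axis interchange maps the crystal lattice onto itself only when
#' the row and column lattices are congruent modulo one pitch, i.e. when
#' `n_vrows - m*n_rows` and `n_vcols - m*n_cols` have equal parity (always
#' true for detector-face grids with `n_rows - n_cols` even). Otherwise the
#' interchange generator is dropped and the group has order 8.
#' @name symmetry
NULL

## ---- invariant tuples (internal) ----

# Integer parity offsets of the voxel lattice relative to the crystal lattice.
lattice_offsets <- function(geom, grid) {
  list(kr = (grid$n_vrows - 1) - grid$m * (geom$n_rows - 1),
       kc = (grid$n_vcols - 1) - grid$m * (geom$n_cols - 1))
}

use_interchange <- function(geom, grid) {
  k <- lattice_offsets(geom, grid)
  (k$kr - k$kc) %% 2 == 0
}

# (LOR, voxel) -> invariant integer tuple matrix with columns
# s, gux, glx, guy, gly. Exact integer arithmetic throughout.
lv_tuple <- function(geom, grid, lor, vox) {
  m <- grid$m
  k <- lattice_offsets(geom, grid)
  cbind(s = vox$slice,
        gux = 2 * m * lor$ur - 2 * vox$vrow + k$kr,
        glx = 2 * m * lor$lr - 2 * vox$vrow + k$kr,
        guy = 2 * m * lor$uc - 2 * vox$vcol + k$kc,
        gly = 2 * m * lor$lc - 2 * vox$vcol + k$kc)
}

# Apply one group element to tuple rows, in the fixed normal-form order
# flip_x, flip_y, flip_z, interchange.
tuple_op <- function(T, fx, fy, fz, ix) {
  s <- T[, 1]; gux <- T[, 2]; glx <- T[, 3]; guy <- T[, 4]; gly <- T[, 5]
  if (fx) { gux <- -gux; glx <- -glx }
  if (fy) { guy <- -guy; gly <- -gly }
  if (fz) { tmp <- gux; gux <- glx; glx <- tmp
            tmp <- guy; guy <- gly; gly <- tmp
            s <- -s }
  if (ix) { tx <- gux; ty <- glx
            gux <- guy; glx <- gly; guy <- tx; gly <- ty }
  cbind(s = s, gux = gux, glx = glx, guy = guy, gly = gly)
}

# The group element table (data.frame of logical flags).
group_elements <- function(interchange = TRUE) {
  g <- expand.grid(fx = c(FALSE, TRUE), fy = c(FALSE, TRUE),
                   fz = c(FALSE, TRUE), ix = if (interchange) c(FALSE, TRUE) else FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  g
}

# Canonicalize tuple rows: lexicographically greatest image over the group.
# Returns list(tuple = matrix, op = row index into group_elements()).
canonical_tuple <- function(T, interchange = TRUE) {
  ops <- group_elements(interchange)
  best <- tuple_op(T, ops$fx[1], ops$fy[1], ops$fz[1], ops$ix[1])
  op <- rep.int(1L, nrow(T))
  for (e in seq_len(nrow(ops))[-1]) {
    cand <- tuple_op(T, ops$fx[e], ops$fy[e], ops$fz[e], ops$ix[e])
    gt <- (cand[, 1] > best[, 1]) |
      (cand[, 1] == best[, 1] & (cand[, 2] > best[, 2] |
        (cand[, 2] == best[, 2] & (cand[, 3] > best[, 3] |
          (cand[, 3] == best[, 3] & (cand[, 4] > best[, 4] |
            (cand[, 4] == best[, 4] & cand[, 5] > best[, 5])))))))
    if (any(gt)) {
      best[gt, ] <- cand[gt, , drop = FALSE]
      op[gt] <- e
    }
  }
  list(tuple = best, op = op)
}

tuple_key <- function(T) {
  paste(T[, 1], T[, 2], T[, 3], T[, 4], T[, 5], sep = ":")
}

## ---- class enumeration ----

#' Z-plane reflection classes
#'
#' Signed slices `-(n-1)/2 ... (n-1)/2` are grouped by reflection about the
#' central plane, i.e. by `|slice|`, leaving `(n+1)/2` classes with
#' nonnegative representatives. For the default 119-plane grid this yields 60
#' classes with representatives 0..59.
#'
#' @param n_planes odd number of z-planes.
#' @return A data.frame with columns `class`, `representative`, `orbit_size`.
#' @export
plane_classes <- function(n_planes) {
  if (length(n_planes) != 1 || n_planes < 1 || n_planes != round(n_planes))
    stop("'n_planes' must be a positive integer")
  if (n_planes %% 2 == 0)
    stop("'n_planes' must be odd: the central plane must lie midway between the heads")
  half <- (n_planes - 1) / 2
  data.frame(class = 0:half, representative = 0:half,
             orbit_size = c(1, rep(2, half)))
}

#' In-plane seed voxel offset classes
#'
#' The `m*m` in-plane voxel offsets within one crystal pitch are grouped
#' under in-plane reflections and axis interchange by explicit orbit
#' enumeration. For quarter-pitch voxels (`m = 4`) this yields 3 classes, so
#' together with the plane classes the default grid needs only `60 * 3 = 180`
#' seed DRFs.
#'
#' @param m in-plane subdivision (voxels per crystal pitch).
#' @return A list with `representatives` (data.frame `a`, `b`, `class`,
#'   `orbit_size`), `class_of` (an `m x m` integer matrix mapping offset
#'   `(a, b)`, 0-based, to its class), and `n_classes`.
#' @export
inplane_seed_classes <- function(m) {
  if (length(m) != 1 || m < 1 || m != round(m))
    stop("'m' must be a positive integer")
  m <- as.integer(m)
  offs <- expand.grid(a = 0:(m - 1), b = 0:(m - 1), KEEP.OUT.ATTRS = FALSE)
  id <- function(a, b) a + m * b + 1L
  class_of <- rep(NA_integer_, m * m)
  n_classes <- 0L
  reps <- list()
  for (i in seq_len(m * m)) {
    if (!is.na(class_of[i])) next
    n_classes <- n_classes + 1L
    # breadth-first closure under {reflect a, reflect b, swap}
    queue <- i
    orbit <- integer(0)
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (!is.na(class_of[j])) next
      class_of[j] <- n_classes - 1L
      orbit <- c(orbit, j)
      a <- offs$a[j]; b <- offs$b[j]
      queue <- c(queue,
                 id(m - 1L - a, b), id(a, m - 1L - b), id(b, a))
    }
    reps[[n_classes]] <- data.frame(a = offs$a[i], b = offs$b[i],
                                    class = n_classes - 1L,
                                    orbit_size = length(orbit))
  }
  list(representatives = do.call(rbind, reps),
       class_of = matrix(class_of, nrow = m, ncol = m),
       n_classes = as.integer(n_classes))
}

## ---- index-level group action ----

# Apply index-level reflection/interchange ops to (lor, vox) data frames on
# the extended lattice. Order of application: ix, fz, fy, fx when
# inverse = TRUE (the inverse of the canonicalization normal form);
# fx, fy, fz, ix when inverse = FALSE.
apply_flags <- function(geom, grid, lor, vox, fx, fy, fz, ix, inverse = FALSE) {
  do_fx <- function() {
    lor$ur <<- geom$n_rows - 1 - lor$ur
    lor$lr <<- geom$n_rows - 1 - lor$lr
    vox$vrow <<- grid$n_vrows - 1 - vox$vrow
  }
  do_fy <- function() {
    lor$uc <<- geom$n_cols - 1 - lor$uc
    lor$lc <<- geom$n_cols - 1 - lor$lc
    vox$vcol <<- grid$n_vcols - 1 - vox$vcol
  }
  do_fz <- function() {
    tmp <- lor$ur; lor$ur <<- lor$lr; lor$lr <<- tmp
    tmp <- lor$uc; lor$uc <<- lor$lc; lor$lc <<- tmp
    vox$slice <<- -vox$slice
  }
  do_ix <- function() {
    if (!use_interchange(geom, grid))
      stop("axis interchange is not an index-level symmetry of this geometry/grid")
    dR <- (geom$n_rows - geom$n_cols) / 2
    vdR <- (grid$n_vrows - grid$n_vcols) / 2
    ur <- lor$uc + dR; uc <- lor$ur - dR
    lr <- lor$lc + dR; lc <- lor$lr - dR
    lor$ur <<- ur; lor$uc <<- uc; lor$lr <<- lr; lor$lc <<- lc
    vr <- vox$vcol + vdR; vc <- vox$vrow - vdR
    vox$vrow <<- vr; vox$vcol <<- vc
  }
  steps <- if (inverse) list(c("ix", ix), c("fz", fz), c("fy", fy), c("fx", fx))
           else list(c("fx", fx), c("fy", fy), c("fz", fz), c("ix", ix))
  for (st in steps) {
    if (as.logical(st[2]))
      switch(st[1], fx = do_fx(), fy = do_fy(), fz = do_fz(), ix = do_ix())
  }
  list(lor = lor, vox = vox)
}

#' Apply a symmetry transform to (LOR, voxel) pairs
#'
#' Transforms are the objects returned by [canonicalize()]: a data.frame with
#' logical columns `fx`, `fy`, `fz`, `ix` and integer columns `shift_row`,
#' `shift_col`. Application order is interchange, z-flip, y-flip, x-flip,
#' then the crystal-pitch shift (voxels shift by `m` voxels per pitch).
#'
#' @param geom a [scanner_geometry()]; @param grid a [voxel_grid()].
#' @param transform one-row or `n`-row transform data.frame.
#' @param lor data.frame with columns `ur`, `uc`, `lr`, `lc`.
#' @param vox data.frame with columns `slice`, `vrow`, `vcol`.
#' @return `list(lor = , vox = )` transformed pairs.
#' @export
apply_transform <- function(geom, grid, transform, lor, vox) {
  n <- nrow(lor)
  stopifnot(nrow(vox) == n)
  tr <- transform[rep_len(seq_len(nrow(transform)), n), , drop = FALSE]
  out_lor <- lor; out_vox <- vox
  # group rows by flag pattern so each pattern is applied vectorized
  pat <- paste(tr$fx, tr$fy, tr$fz, tr$ix)
  for (p in unique(pat)) {
    idx <- which(pat == p)
    r <- apply_flags(geom, grid, lor[idx, , drop = FALSE], vox[idx, , drop = FALSE],
                     tr$fx[idx[1]], tr$fy[idx[1]], tr$fz[idx[1]], tr$ix[idx[1]],
                     inverse = TRUE)
    out_lor[idx, ] <- r$lor
    out_vox[idx, ] <- r$vox
  }
  m <- grid$m
  out_lor$ur <- out_lor$ur + tr$shift_row
  out_lor$lr <- out_lor$lr + tr$shift_row
  out_lor$uc <- out_lor$uc + tr$shift_col
  out_lor$lc <- out_lor$lc + tr$shift_col
  out_vox$vrow <- out_vox$vrow + m * tr$shift_row
  out_vox$vcol <- out_vox$vcol + m * tr$shift_col
  list(lor = out_lor, vox = out_vox)
}

#' Canonicalize (LOR, voxel) pairs onto their seed representatives
#'
#' Maps every (LOR, voxel) pair on the extended lattice to the unique seed
#' pair of its symmetry orbit plus the transform that recovers the input:
#' `apply_transform(geom, grid, transform, seed_lor, seed_vox)` reproduces
#' `(lor, vox)` exactly. The seed voxel has nonnegative slice and sits under
#' the central crystal; the system-matrix value at the input pair equals the
#' value at the seed pair.
#'
#' @inheritParams apply_transform
#' @return A list with `seed_lor`, `seed_vox`, `transform` (all data.frames
#'   with one row per input pair) and `key` (the canonical tuple key used by
#'   seed stores).
#' @export
canonicalize <- function(geom, grid, lor, vox) {
  stopifnot(inherits(geom, "scanner_geometry"), inherits(grid, "voxel_grid"))
  inter <- use_interchange(geom, grid)
  T <- lv_tuple(geom, grid, lor, vox)
  can <- canonical_tuple(T, interchange = inter)
  ops <- group_elements(inter)
  C <- can$tuple
  m <- grid$m
  k <- lattice_offsets(geom, grid)
  r0 <- (geom$n_rows - 1) %/% 2
  c0 <- (geom$n_cols - 1) %/% 2
  # seed voxel: phase of the canonical tuple placed under the central crystal
  rho_r <- ((k$kr - C[, "gux"]) / 2) %% m
  rho_c <- ((k$kc - C[, "guy"]) / 2) %% m
  vr <- m * r0 + rho_r
  vc <- m * c0 + rho_c
  seed_vox <- data.frame(slice = C[, "s"], vrow = vr, vcol = vc)
  seed_lor <- data.frame(
    ur = (C[, "gux"] - k$kr + 2 * vr) / (2 * m),
    uc = (C[, "guy"] - k$kc + 2 * vc) / (2 * m),
    lr = (C[, "glx"] - k$kr + 2 * vr) / (2 * m),
    lc = (C[, "gly"] - k$kc + 2 * vc) / (2 * m))
  # transform: inverse flags of the canonicalizing op, then the shift that
  # carries the un-flipped seed onto the input
  fl <- ops[can$op, , drop = FALSE]
  tr0 <- data.frame(fx = fl$fx, fy = fl$fy, fz = fl$fz, ix = fl$ix,
                    shift_row = 0, shift_col = 0)
  back <- apply_transform(geom, grid, tr0, seed_lor, seed_vox)
  tr0$shift_row <- (vox$vrow - back$vox$vrow) / m
  tr0$shift_col <- (vox$vcol - back$vox$vcol) / m
  if (any(tr0$shift_row != round(tr0$shift_row)) ||
      any(tr0$shift_col != round(tr0$shift_col)))
    stop("internal error: non-integral symmetry shift")
  list(seed_lor = seed_lor, seed_vox = seed_vox, transform = tr0,
       key = tuple_key(C))
}

## ---- LOR families and orientations ----

#' Symmetric family of a LOR
#'
#' The orbit of a LOR under the in-plane reflections `{identity, x-flip,
#' y-flip, x- and y-flip}` — the up-to-4 LORs that share one seed DRF column
#' within a shift-invariant group and are processed together by the
#' projectors. Fixed points are deduplicated.
#'
#' @param geom a [scanner_geometry()].
#' @param lor one-row data.frame with columns `ur`, `uc`, `lr`, `lc`.
#' @return A data.frame of distinct LORs (first row = input).
#' @export
symmetric_family <- function(geom, lor) {
  stopifnot(nrow(lor) == 1)
  R <- geom$n_rows - 1; C <- geom$n_cols - 1
  fam <- rbind(
    lor[, c("ur", "uc", "lr", "lc")],
    data.frame(ur = R - lor$ur, uc = lor$uc, lr = R - lor$lr, lc = lor$lc),
    data.frame(ur = lor$ur, uc = C - lor$uc, lr = lor$lr, lc = C - lor$lc),
    data.frame(ur = R - lor$ur, uc = C - lor$uc, lr = R - lor$lr, lc = C - lor$lc))
  fam[!duplicated(fam), , drop = FALSE]
}

#' Enumerate LOR orientations
#'
#' An orientation is the integer crystal displacement
#' `(dr, dc) = (lr - ur, lc - uc)` between the two endpoints of a LOR. A
#' scanner with `n_rows x n_cols` heads has
#' `(2 n_rows - 1) * (2 n_cols - 1)` orientations and every LOR belongs to
#' exactly one.
#'
#' @param geom a [scanner_geometry()].
#' @param max_tilt optionally restrict to `|dr|, |dc| <= max_tilt`.
#' @return A data.frame with columns `dr`, `dc`.
#' @export
enumerate_orientations <- function(geom, max_tilt = Inf) {
  stopifnot(inherits(geom, "scanner_geometry"))
  rmax <- min(geom$n_rows - 1, max_tilt)
  cmax <- min(geom$n_cols - 1, max_tilt)
  expand.grid(dr = seq(-rmax, rmax), dc = seq(-cmax, cmax),
              KEEP.OUT.ATTRS = FALSE)
}

# Group orientations into reflection classes (dr, dc) ~ (+-dr, +-dc).
# Returns a data.frame of canonical orientations (dr, dc >= 0) with the
# class size, plus the class id of every input row.
orientation_classes <- function(orientations) {
  adr <- abs(orientations$dr); adc <- abs(orientations$dc)
  key <- paste(adr, adc)
  ukey <- !duplicated(key)
  classes <- data.frame(dr = adr[ukey], dc = adc[ukey])
  classes$size <- (1 + (classes$dr > 0)) * (1 + (classes$dc > 0))
  list(classes = classes, class_id = match(key, key[ukey]))
}

# All member orientations of a canonical class (dr, dc >= 0).
class_members <- function(dr, dc) {
  drs <- unique(c(dr, -dr)); dcs <- unique(c(dc, -dc))
  expand.grid(dr = drs, dc = dcs, KEEP.OUT.ATTRS = FALSE)
}
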