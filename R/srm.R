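#' Geometric detector-response model parameters
#'
#' The system response matrix is built from a deterministic geometric
#' detection model: annihilation photon pairs are emitted back-to-back and
#' isotropically from sub-voxel points; the pair is detected on a LOR when
#' one photon enters the upper crystal face and the collinear partner enters
#' the lower crystal face, each with probability `1 - exp(-mu * L)` for the
#' slant path `L` through the crystal. The per-LOR probability is a
#' solid-angle quadrature over `n_sub^3` sub-voxel emission points and
#' `n_face^2` crystal-face patches, symmetrized between the two heads so the
#' head-swap symmetry holds to rounding error.
#'
#' @param mu linear attenuation coefficient of the crystal at 511 keV, in
#'   1/mm (default 0.087, LSO).
#' @param n_sub sub-voxel emission points per axis.
#' @param n_face face quadrature points per axis.
#' @param prune_rel entries below `prune_rel` times the per-seed maximum are
#'   dropped from the stored DRF (0 disables pruning).
#' @param scale overall probability scale (the absolute efficiency is not
#'   fixed by the geometric model; reconstruction is scale-invariant).
#' @param max_tilt maximum stored |crystal row/col displacement| between the
#'   two LOR endpoints, in pitches (Inf = full angular acceptance).
#' @return An object of class `drf_model`.
#' @export
drf_model <- function(mu = 0.087, n_sub = 2, n_face = 4, prune_rel = 1e-9,
                      scale = 1, max_tilt = Inf) {
  stopifnot(mu > 0, n_sub >= 1, n_face >= 1, prune_rel >= 0, scale > 0,
            max_tilt >= 0)
  structure(list(mu = mu, n_sub = as.integer(n_sub),
                 n_face = as.integer(n_face), prune_rel = prune_rel,
                 scale = scale, max_tilt = max_tilt),
            class = "drf_model")
}

# centered quadrature offsets spanning `size`
quad_offsets <- function(n, size) {
  ((2 * seq_len(n) - n - 1) / (2 * n)) * size
}

# One-sided fan quadrature: photon #1 sampled on the upper crystal face,
# partner projected onto the lower face. Vectorized over tuple rows.
drf_prob_fan <- function(geom, grid, T, model) {
  m <- grid$m; p <- geom$pitch
  dz <- grid$dz; sep <- geom$head_separation
  th <- geom$crystal_thickness
  u <- p / (2 * m)                       # half in-plane voxel / tuple unit
  Xu <- T[, "gux"] * u; Yu <- T[, "guy"] * u
  Xl <- T[, "glx"] * u; Yl <- T[, "gly"] * u
  zu <- sep / 2 - T[, "s"] * dz          # upper face, voxel-centered frame
  zl <- -sep / 2 - T[, "s"] * dz         # lower face
  se <- quad_offsets(model$n_sub, p / m) # emission offsets, x/y
  sz <- quad_offsets(model$n_sub, dz)    # emission offsets, z
  fq <- quad_offsets(model$n_face, p)    # face patch centers
  dA <- (p / model$n_face)^2
  half <- p / 2
  acc <- numeric(nrow(T))
  for (ez in sz) {
    dzz <- zu - ez
    f <- (ez - zl) / dzz                 # opposite-ray scaling to lower face
    for (ex in se) for (ey in se) {
      for (qx in fq) {
        dx <- Xu + qx - ex
        ox <- ex - dx * f
        hx <- abs(ox - Xl) <= half
        if (!any(hx)) next
        for (qy in fq) {
          dy <- Yu + qy - ey
          oy <- ey - dy * f
          hit <- which(hx & (abs(oy - Yl) <= half))
          if (!length(hit)) next
          dzh <- dzz[hit]
          r2 <- dx[hit]^2 + dy[hit]^2 + dzh^2
          r <- sqrt(r2)
          pdet <- 1 - exp(-model$mu * th * r / dzh)
          acc[hit] <- acc[hit] + dA * dzh / (2 * pi * r2 * r) * pdet * pdet
        }
      }
    }
  }
  model$scale * acc / model$n_sub^3
}

# Symmetrized detector response probability for invariant tuples.
# Averaging the upper-face and lower-face fans makes the model exactly
# head-swap symmetric (up to addition rounding); reflection and interchange
# symmetry hold because all coordinates enter through signed products.
drf_prob <- function(geom, grid, T, model) {
  colnames(T) <- c("s", "gux", "glx", "guy", "gly")
  Tz <- tuple_op(T, FALSE, FALSE, TRUE, FALSE)
  0.5 * (drf_prob_fan(geom, grid, T, model) +
         drf_prob_fan(geom, grid, Tz, model))
}

## ---- seed enumeration ----

#' Seed pool layout
#'
#' Enumerates the seed voxels of the compressed system matrix: one per
#' (z-plane reflection class, in-plane offset class). The representative
#' voxel of a class sits under the central crystal at the class's in-plane
#' phase, on the class's nonnegative slice.
#'
#' @param geom a [scanner_geometry()]; @param grid a [voxel_grid()] covering
#'   the detector face (`n_vrows = m * n_rows`, `n_vcols = m * n_cols`).
#' @return A data.frame with one row per seed: `seed_id`, `plane_class`,
#'   `inplane_class`, `slice`, `phase_a`, `phase_b`, `vrow`, `vcol`.
#' @export
seed_pool_layout <- function(geom, grid) {
  stopifnot(inherits(geom, "scanner_geometry"), inherits(grid, "voxel_grid"))
  if (grid$n_vrows != grid$m * geom$n_rows ||
      grid$n_vcols != grid$m * geom$n_cols)
    stop("seed pool requires a detector-face grid (n_vrows = m * n_rows, n_vcols = m * n_cols)")
  pc <- plane_classes(grid$n_planes)
  ic <- inplane_seed_classes(grid$m)
  r0 <- (geom$n_rows - 1) %/% 2
  c0 <- (geom$n_cols - 1) %/% 2
  grid_df <- expand.grid(plane_class = pc$class,
                         inplane_class = ic$representatives$class,
                         KEEP.OUT.ATTRS = FALSE)
  grid_df <- grid_df[order(grid_df$plane_class, grid_df$inplane_class), ]
  ia <- ic$representatives$a[grid_df$inplane_class + 1]
  ib <- ic$representatives$b[grid_df$inplane_class + 1]
  data.frame(seed_id = seq_len(nrow(grid_df)) - 1L,
             plane_class = grid_df$plane_class,
             inplane_class = grid_df$inplane_class,
             slice = pc$representative[grid_df$plane_class + 1],
             phase_a = ia, phase_b = ib,
             vrow = grid$m * r0 + ia, vcol = grid$m * c0 + ib,
             row.names = NULL)
}

#' Compute the detector response function of one seed voxel
#'
#' Enumerates every crystal pair on the extended lattice whose geometric
#' acceptance can contain the seed voxel, evaluates the geometric detection
#' model for each, and prunes entries below the relative threshold.
#'
#' @inheritParams seed_pool_layout
#' @param seed_voxel a one-row data.frame (or list) with `slice`, `vrow`,
#'   `vcol`; must be a class representative as produced by
#'   [seed_pool_layout()].
#' @param model a [drf_model()].
#' @return A list with the seed description and `entries`: a data.frame of
#'   invariant offsets `gux`, `glx`, `guy`, `gly` and probabilities `value`.
#' @export
compute_seed_drf <- function(geom, grid, seed_voxel, model = drf_model()) {
  layout <- seed_pool_layout(geom, grid)
  hit <- which(layout$slice == seed_voxel$slice &
               layout$vrow == seed_voxel$vrow &
               layout$vcol == seed_voxel$vcol)
  if (length(hit) != 1)
    stop("seed_voxel is not a class representative of this grid")
  m <- grid$m; p <- geom$pitch
  k <- lattice_offsets(geom, grid)
  vr <- seed_voxel$vrow; vc <- seed_voxel$vcol; s <- seed_voxel$slice
  mar <- geom$extension_margin
  urs <- seq(-mar, geom$n_rows - 1 + mar)
  ucs <- seq(-mar, geom$n_cols - 1 + mar)
  up <- expand.grid(ur = urs, uc = ucs, KEEP.OUT.ATTRS = FALSE)

  # voxel-centered coordinates and opposite-ray projection bounds
  xv <- (vr - (grid$n_vrows - 1) / 2) * grid$pitch_in
  yv <- (vc - (grid$n_vcols - 1) / 2) * grid$pitch_in
  Xu <- (up$ur - (geom$n_rows - 1) / 2) * p - xv
  Yu <- (up$uc - (geom$n_cols - 1) / 2) * p - yv
  hz <- grid$dz / 2; hxy <- grid$pitch_in / 2
  zu <- geom$head_separation / 2 - s * grid$dz
  zl <- -geom$head_separation / 2 - s * grid$dz
  fr <- c((-hz - zl) / (zu + hz), (hz - zl) / (zu - hz))  # f at ez = -hz, +hz
  proj_range <- function(Xc) {
    lo <- rep(Inf, length(Xc)); hi <- rep(-Inf, length(Xc))
    for (f in fr) for (e in c(-hxy, hxy)) for (q in c(-p / 2, p / 2)) {
      o <- e * (1 + f) - (Xc + q) * f
      lo <- pmin(lo, o); hi <- pmax(hi, o)
    }
    list(lo = lo, hi = hi)
  }
  prx <- proj_range(Xu); pry <- proj_range(Yu)
  # candidate lower-crystal index windows (extended lattice, tilt-limited)
  win <- function(pr, uu, n, xy) {
    lo <- ceiling((pr$lo + xy - p / 2) / p + (n - 1) / 2 - 1e-9)
    hi <- floor((pr$hi + xy + p / 2) / p + (n - 1) / 2 + 1e-9)
    lo <- pmax(lo, -mar, uu - model$max_tilt)
    hi <- pmin(hi, n - 1 + mar, uu + model$max_tilt)
    list(lo = lo, hi = hi, n = pmax(0, hi - lo + 1))
  }
  wr <- win(prx, up$ur, geom$n_rows, xv)
  wc <- win(pry, up$uc, geom$n_cols, yv)
  nper <- wr$n * wc$n
  keep <- nper > 0
  if (!any(keep)) {
    entries <- data.frame(gux = integer(0), glx = integer(0),
                          guy = integer(0), gly = integer(0),
                          value = numeric(0))
  } else {
    idx <- rep(which(keep), nper[keep])
    # within-upper cartesian enumeration of (lr, lc)
    offs <- sequence(nper[keep]) - 1
    lr <- wr$lo[idx] + offs %/% wc$n[idx]
    lc <- wc$lo[idx] + offs %% wc$n[idx]
    T <- cbind(s = rep(s, length(idx)),
               gux = 2 * m * up$ur[idx] - 2 * vr + k$kr,
               glx = 2 * m * lr - 2 * vr + k$kr,
               guy = 2 * m * up$uc[idx] - 2 * vc + k$kc,
               gly = 2 * m * lc - 2 * vc + k$kc)
    val <- drf_prob(geom, grid, T, model)
    nz <- val > 0
    entries <- data.frame(gux = T[nz, "gux"], glx = T[nz, "glx"],
                          guy = T[nz, "guy"], gly = T[nz, "gly"],
                          value = val[nz])
  }
  if (nrow(entries) && model$prune_rel > 0) {
    thr <- model$prune_rel * max(entries$value)
    entries <- entries[entries$value >= thr, , drop = FALSE]
  }
  list(slice = s, vrow = vr, vcol = vc,
       plane_class = layout$plane_class[hit],
       inplane_class = layout$inplane_class[hit],
       entries = entries)
}

#' Build the seed-DRF pool (compressed system response matrix)
#'
#' Computes one detector response function per (plane class, in-plane class)
#' seed voxel and indexes all entries by their canonical symmetry key, from
#' which any system-matrix element can be recovered via [srm_element()] or
#' expanded into projector matrices.
#'
#' @inheritParams compute_seed_drf
#' @param compute if `FALSE`, return the store skeleton (layout, counts,
#'   fingerprint) without computing DRFs; useful for dimensioning.
#' @param verbose print per-seed progress.
#' @return An object of class `seed_drf_store`.
#' @export
build_seed_pool <- function(geom, grid, model = drf_model(), compute = TRUE,
                            verbose = FALSE) {
  layout <- seed_pool_layout(geom, grid)
  store <- structure(
    list(geom = geom, grid = grid, model = model, layout = layout,
         n_seeds = nrow(layout),
         fingerprint = geometry_fingerprint(geom, grid),
         seeds = NULL, tuples = NULL, values = NULL, keys = NULL,
         computed = FALSE, cache = new.env(parent = emptyenv())),
    class = "seed_drf_store")
  if (!compute) return(store)
  seeds <- vector("list", nrow(layout))
  tup_list <- vector("list", nrow(layout))
  val_list <- vector("list", nrow(layout))
  for (i in seq_len(nrow(layout))) {
    sd <- compute_seed_drf(geom, grid, layout[i, ], model)
    seeds[[i]] <- sd
    if (nrow(sd$entries)) {
      T <- cbind(s = rep(sd$slice, nrow(sd$entries)),
                 gux = sd$entries$gux, glx = sd$entries$glx,
                 guy = sd$entries$guy, gly = sd$entries$gly)
      can <- canonical_tuple(T, interchange = use_interchange(geom, grid))
      tup_list[[i]] <- can$tuple
      val_list[[i]] <- sd$entries$value
    }
    if (verbose)
      message(sprintf("seed %d/%d (slice %d, phase %d,%d): %d entries",
                      i, nrow(layout), sd$slice, layout$phase_a[i],
                      layout$phase_b[i], nrow(sd$entries)))
  }
  tuples <- do.call(rbind, tup_list)
  values <- unlist(val_list, use.names = FALSE)
  if (is.null(tuples)) {
    tuples <- matrix(numeric(0), 0, 5,
                     dimnames = list(NULL, c("s", "gux", "glx", "guy", "gly")))
    values <- numeric(0)
  }
  keys <- tuple_key(tuples)
  first <- !duplicated(keys)
  store$seeds <- seeds
  store$tuples <- tuples[first, , drop = FALSE]
  store$values <- values[first]
  store$keys <- keys[first]
  store$computed <- TRUE
  store
}

#' @export
print.seed_drf_store <- function(x, ...) {
  cat(sprintf("Seed-DRF store: %d seeds (%d plane classes x %d in-plane classes)\n",
              x$n_seeds, length(unique(x$layout$plane_class)),
              length(unique(x$layout$inplane_class))))
  if (x$computed)
    cat(sprintf("  %d canonical entries, prune threshold %.3g (relative)\n",
                length(x$values), x$model$prune_rel))
  else cat("  layout only (DRFs not computed)\n")
  invisible(x)
}

#' Look up system response matrix elements
#'
#' Canonicalizes each (LOR, voxel) pair and returns the stored seed-DRF
#' probability (0 for pruned or geometrically impossible pairs). Equals the
#' directly computed detector response up to floating-point reordering.
#'
#' @param store a computed [build_seed_pool()] store.
#' @param lor data.frame with 0-based columns `ur`, `uc`, `lr`, `lc`
#'   (physical front-layer crystals).
#' @param vox data.frame with columns `slice`, `vrow`, `vcol`.
#' @return Numeric vector of probabilities.
#' @export
srm_element <- function(store, lor, vox) {
  stopifnot(inherits(store, "seed_drf_store"))
  if (!store$computed) stop("seed pool was built with compute = FALSE")
  geom <- store$geom; grid <- store$grid
  if (any(lor$ur < 0 | lor$ur >= geom$n_rows | lor$lr < 0 | lor$lr >= geom$n_rows |
          lor$uc < 0 | lor$uc >= geom$n_cols | lor$lc < 0 | lor$lc >= geom$n_cols))
    stop("index error: LOR crystal out of physical range")
  half <- (grid$n_planes - 1) / 2
  if (any(abs(vox$slice) > half | vox$vrow < 0 | vox$vrow >= grid$n_vrows |
          vox$vcol < 0 | vox$vcol >= grid$n_vcols))
    stop("index error: voxel out of range")
  T <- lv_tuple(geom, grid, lor, vox)
  can <- canonical_tuple(T, interchange = use_interchange(geom, grid))
  i <- match(tuple_key(can$tuple), store$keys)
  out <- store$values[i]
  out[is.na(i)] <- 0
  out
}

#' Brute-force system response matrix (test oracle)
#'
#' Computes every front-layer system-matrix element directly from the
#' geometric detection model, voxel by voxel, with no symmetry reuse. Only
#' intended for tiny scanners; refuses problems with more than `1e7`
#' (LOR, voxel) pairs.
#'
#' @inheritParams compute_seed_drf
#' @return A sparse [Matrix::sparseMatrix()] of dimension
#'   `lor_count(geom, layers = FALSE)` x `voxel_count(grid)`, unpruned.
#' @export
brute_force_srm <- function(geom, grid, model = drf_model()) {
  n_lor <- lor_count(geom, layers = FALSE)
  n_vox <- voxel_count(grid)
  if (n_lor * n_vox > 1e7)
    stop("brute_force_srm refuses problems with more than 1e7 (LOR, voxel) pairs")
  lors <- lor_from_linear(geom, seq_len(n_lor) - 1)
  voxs <- all_voxels(grid)
  chunk <- max(1, floor(2e6 / n_lor))
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j0 in seq(1, n_vox, by = chunk)) {
    js <- j0:min(n_vox, j0 + chunk - 1)
    nl <- length(js) * n_lor
    lor_rep <- lors[rep(seq_len(n_lor), times = length(js)), ]
    vox_rep <- voxs[rep(js, each = n_lor), ]
    T <- lv_tuple(geom, grid, lor_rep, vox_rep)
    val <- drf_prob(geom, grid, T, model)
    nz <- which(val > 0)
    if (length(nz)) {
      ii <- c(ii, rep(seq_len(n_lor), times = length(js))[nz])
      jj <- c(jj, rep(js, each = n_lor)[nz])
      xx <- c(xx, val[nz])
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n_lor, n_vox))
}
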