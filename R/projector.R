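#' Image volumes and LOR histograms
#'
#' An `image_volume` is a nonnegative 3D array over the voxel grid, indexed
#' `[vrow + 1, vcol + 1, plane]` with plane 1 the most negative slice. A
#' `lor_histogram` is a dense nonnegative vector over the front-layer LOR
#' space in row-major `(ur, uc, lr, lc)` order.
#'
#' @param data array or vector of voxel values (recycled scalar allowed).
#' @param grid a [voxel_grid()].
#' @return An `image_volume` object.
#' @export
image_volume <- function(data, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  dims <- c(grid$n_vrows, grid$n_vcols, grid$n_planes)
  if (length(data) == 1) data <- rep(as.numeric(data), prod(dims))
  if (length(data) != prod(dims))
    stop("volume data length does not match the grid (", prod(dims), " voxels)")
  vol <- array(as.numeric(data), dim = dims)
  attr(vol, "grid") <- grid
  attr(vol, "fingerprint") <- geometry_fingerprint_grid(grid)
  class(vol) <- c("image_volume", class(vol))
  vol
}

# grid-only fingerprint (volumes do not depend on the crystal layout)
geometry_fingerprint_grid <- function(grid) {
  f <- tempfile(); on.exit(unlink(f))
  writeLines(paste("grid", grid$n_planes, format(grid$dz, digits = 15), grid$m,
                   grid$n_vrows, grid$n_vcols,
                   format(grid$pitch, digits = 15),
                   format(grid$head_separation, digits = 15), sep = ":"), f)
  unname(tools::md5sum(f))
}

#' @param values dense numeric vector of per-LOR values.
#' @param geom a [scanner_geometry()].
#' @rdname image_volume
#' @export
lor_histogram <- function(values, geom) {
  stopifnot(inherits(geom, "scanner_geometry"))
  n <- lor_count(geom, layers = FALSE)
  if (length(values) == 1) values <- rep(as.numeric(values), n)
  if (length(values) != n)
    stop("histogram length ", length(values), " does not match the front-layer LOR count ", n)
  structure(list(values = as.numeric(values),
                 n_rows = geom$n_rows, n_cols = geom$n_cols,
                 fingerprint = geometry_fingerprint(geom)),
            class = "lor_histogram")
}

#' @export
print.lor_histogram <- function(x, ...) {
  cat(sprintf("LOR histogram: %s bins, %s nonzero, total %.6g\n",
              format(length(x$values), big.mark = ","),
              format(sum(x$values != 0), big.mark = ","), sum(x$values)))
  invisible(x)
}

#' Build a projection schedule over a subset of LOR orientations
#'
#' A schedule organizes the LORs of the given orientations the way the
#' symmetry-compressed projectors consume them: orientations are grouped into
#' reflection classes `(+-dr, +-dc)`, each class is covered by the
#' shift-invariant LORs of its canonical orientation expanded through a
#' symmetric family of up to 4 reflections. The scheduled LORs partition the
#' class's physical LORs exactly once. Listing any member of a class
#' schedules the whole class.
#'
#' @param geom a [scanner_geometry()]; @param grid a [voxel_grid()].
#' @param orientations data.frame with columns `dr`, `dc`; default all
#'   orientations of the scanner.
#' @return An object of class `projection_schedule`.
#' @export
make_schedule <- function(geom, grid, orientations = NULL) {
  stopifnot(inherits(geom, "scanner_geometry"), inherits(grid, "voxel_grid"))
  if (is.null(orientations)) orientations <- enumerate_orientations(geom)
  if (!all(c("dr", "dc") %in% names(orientations)))
    stop("orientations must have columns 'dr' and 'dc'")
  if (any(abs(orientations$dr) > geom$n_rows - 1 |
          abs(orientations$dc) > geom$n_cols - 1))
    stop("unknown orientation: displacement exceeds the detector array")
  oc <- orientation_classes(orientations)
  classes <- oc$classes
  # family operators per class: reflections that change the orientation sign
  fam <- lapply(seq_len(nrow(classes)), function(i) {
    dr <- classes$dr[i]; dc <- classes$dc[i]
    f <- data.frame(fx = FALSE, fy = FALSE)
    if (dr > 0) f <- rbind(f, data.frame(fx = TRUE, fy = FALSE))
    if (dc > 0) f <- rbind(f, data.frame(fx = FALSE, fy = TRUE))
    if (dr > 0 && dc > 0) f <- rbind(f, data.frame(fx = TRUE, fy = TRUE))
    f
  })
  id <- paste(classes$dr, classes$dc, collapse = ";")
  structure(list(geom = geom, grid = grid, classes = classes, families = fam,
                 id = id,
                 fingerprint = geometry_fingerprint(geom, grid),
                 cache = new.env(parent = emptyenv())),
            class = "projection_schedule")
}

#' @export
print.projection_schedule <- function(x, ...) {
  cat(sprintf("Projection schedule: %d orientation classes (%d orientations), %s LORs\n",
              nrow(x$classes), sum(x$classes$size),
              format(nrow(schedule_lors(x)), big.mark = ",")))
  invisible(x)
}

#' Enumerate the LORs of a schedule
#'
#' Expands every class into its shift-invariant base LORs and symmetric
#' family members; together these cover each scheduled physical LOR exactly
#' once.
#'
#' @param sched a [make_schedule()] object.
#' @return A data.frame with columns `ur`, `uc`, `lr`, `lc`, `linear`
#'   (0-based row-major linear LOR index), `class` and `member`.
#' @export
schedule_lors <- function(sched) {
  if (!is.null(sched$cache$lors)) return(sched$cache$lors)
  geom <- sched$geom
  if (nrow(sched$classes) == 0) {
    empty <- data.frame(ur = integer(0), uc = integer(0), lr = integer(0),
                        lc = integer(0), class = integer(0), member = integer(0),
                        linear = numeric(0))
    sched$cache$lors <- empty
    return(empty)
  }
  out <- vector("list", nrow(sched$classes))
  for (i in seq_len(nrow(sched$classes))) {
    dr <- sched$classes$dr[i]; dc <- sched$classes$dc[i]
    base <- expand.grid(ur = 0:(geom$n_rows - 1 - dr),
                        uc = 0:(geom$n_cols - 1 - dc),
                        KEEP.OUT.ATTRS = FALSE)
    fam <- sched$families[[i]]
    pieces <- vector("list", nrow(fam))
    for (f in seq_len(nrow(fam))) {
      ur <- base$ur; lr <- base$ur + dr
      uc <- base$uc; lc <- base$uc + dc
      if (fam$fx[f]) { ur <- geom$n_rows - 1 - ur; lr <- geom$n_rows - 1 - lr }
      if (fam$fy[f]) { uc <- geom$n_cols - 1 - uc; lc <- geom$n_cols - 1 - lc }
      pieces[[f]] <- data.frame(ur = ur, uc = uc, lr = lr, lc = lc,
                                class = i - 1L, member = f - 1L)
    }
    out[[i]] <- do.call(rbind, pieces)
  }
  lors <- do.call(rbind, out)
  lors$linear <- lor_linear_index(geom, lors$ur, lors$uc, lors$lr, lors$lc)
  sched$cache$lors <- lors
  lors
}

#' Expand the seed pool into the sparse system matrix of a schedule
#'
#' Every canonical seed entry is carried through the symmetry group, kept
#' when its image orientation belongs to the schedule, and expanded over all
#' in-range crystal-pitch shifts. The result is the sparse system matrix
#' block `H` (front-layer LOR space x voxels) whose rows outside the
#' schedule are zero. Cached on the store per schedule.
#'
#' @param store a computed [build_seed_pool()] store.
#' @param sched a [make_schedule()] object on the same geometry and grid.
#' @return A [Matrix::sparseMatrix()] of dimension
#'   `lor_count(geom, layers = FALSE)` x `voxel_count(grid)`.
#' @export
srm_matrix <- function(store, sched) {
  stopifnot(inherits(store, "seed_drf_store"),
            inherits(sched, "projection_schedule"))
  if (!store$computed) stop("seed pool was built with compute = FALSE")
  if (!identical(store$fingerprint, sched$fingerprint))
    stop("geometry fingerprint mismatch between seed pool and schedule")
  key <- paste0("H:", sched$id)
  cached <- get0(key, envir = store$cache)
  if (!is.null(cached)) return(cached)
  geom <- store$geom; grid <- store$grid; m <- grid$m
  k <- lattice_offsets(geom, grid)
  n_lor <- lor_count(geom, layers = FALSE)
  n_vox <- voxel_count(grid)
  if (n_lor >= 2^31 - 1) stop("scanner too large for in-memory expansion")
  class_key <- paste(sched$classes$dr, sched$classes$dc)

  E <- store$tuples
  ops <- group_elements(use_interchange(geom, grid))
  kept <- vector("list", nrow(ops))
  for (e in seq_len(nrow(ops))) {
    Tg <- tuple_op(E, ops$fx[e], ops$fy[e], ops$fz[e], ops$ix[e])
    dr <- (Tg[, "glx"] - Tg[, "gux"]) / (2 * m)
    dc <- (Tg[, "gly"] - Tg[, "guy"]) / (2 * m)
    sel <- which(!is.na(match(paste(abs(dr), abs(dc)), class_key)))
    if (length(sel))
      kept[[e]] <- cbind(Tg[sel, , drop = FALSE], entry = sel,
                         val = store$values[sel], dr = dr[sel], dc = dc[sel])
  }
  A <- do.call(rbind, kept)
  if (is.null(A) || nrow(A) == 0) {
    H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n_lor, n_vox))
    assign(key, H, envir = store$cache)
    return(H)
  }
  # drop duplicate group images of the same entry (orbit fixed points)
  dup <- duplicated(paste(A[, "entry"], tuple_key(A)))
  A <- A[!dup, , drop = FALSE]

  # shift expansion: vr = m*ur + br with br = (kr - gux)/2
  br <- (k$kr - A[, "gux"]) / 2
  bc <- (k$kc - A[, "guy"]) / 2
  dr <- A[, "dr"]; dc <- A[, "dc"]
  ur_lo <- pmax(0, -dr, ceiling(-br / m))
  ur_hi <- pmin(geom$n_rows - 1, geom$n_rows - 1 - dr,
                floor((grid$n_vrows - 1 - br) / m))
  uc_lo <- pmax(0, -dc, ceiling(-bc / m))
  uc_hi <- pmin(geom$n_cols - 1, geom$n_cols - 1 - dc,
                floor((grid$n_vcols - 1 - bc) / m))
  nr <- pmax(0, ur_hi - ur_lo + 1)
  nc <- pmax(0, uc_hi - uc_lo + 1)
  nper <- nr * nc
  rows <- which(nper > 0)
  if (!length(rows)) {
    H <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n_lor, n_vox))
    assign(key, H, envir = store$cache)
    return(H)
  }
  idx <- rep(rows, nper[rows])
  offs <- sequence(nper[rows]) - 1
  ur <- ur_lo[idx] + offs %/% nc[idx]
  uc <- uc_lo[idx] + offs %% nc[idx]
  lr <- ur + dr[idx]; lc <- uc + dc[idx]
  vr <- m * ur + br[idx]; vc <- m * uc + bc[idx]
  i <- lor_linear_index(geom, ur, uc, lr, lc) + 1
  j <- voxel_linear_index(grid, A[idx, "s"], vr, vc) + 1
  H <- Matrix::sparseMatrix(i = i, j = j, x = A[idx, "val"],
                            dims = c(n_lor, n_vox))
  assign(key, H, envir = store$cache)
  H
}

check_volume <- function(x, grid) {
  if (inherits(x, "image_volume")) {
    if (!identical(attr(x, "fingerprint"), geometry_fingerprint_grid(grid)))
      stop("geometry fingerprint mismatch: volume grid differs from the store grid")
    as.vector(x)
  } else if (length(x) == voxel_count(grid)) {
    as.numeric(x)
  } else stop("image length does not match the voxel grid")
}

check_histogram <- function(y, geom) {
  if (inherits(y, "lor_histogram")) {
    if (!identical(y$fingerprint, geometry_fingerprint(geom)))
      stop("geometry fingerprint mismatch: histogram geometry differs from the store")
    y$values
  } else if (length(y) == lor_count(geom, layers = FALSE)) {
    as.numeric(y)
  } else stop("histogram length mismatch: expected the front-layer LOR count")
}

#' Forward projection H x
#'
#' Projects an image through the scheduled part of the system matrix. LORs
#' outside the schedule are zero. The accumulation order is fixed by the
#' schedule, so repeated runs are bit-identical.
#'
#' @param x an [image_volume()] (nonnegative).
#' @param store a computed seed pool; @param sched a schedule.
#' @param zero_skip skip zero voxels (identical result, less work).
#' @return A [lor_histogram()].
#' @export
forward_project <- function(x, store, sched, zero_skip = FALSE) {
  xv <- check_volume(x, store$grid)
  if (any(xv < 0)) stop("negative input voxel in forward projection")
  H <- srm_matrix(store, sched)
  if (zero_skip) {
    nz <- which(xv != 0)
    y <- numeric(nrow(H))
    if (length(nz))
      y <- as.vector(H[, nz, drop = FALSE] %*% xv[nz])
  } else {
    y <- as.vector(H %*% xv)
  }
  lor_histogram(y, store$geom)
}

#' Back projection H^T y
#'
#' Accumulates histogram values into image space over the scheduled LORs;
#' accumulation into shared voxels is deterministic.
#'
#' @param y a [lor_histogram()] or dense vector.
#' @inheritParams forward_project
#' @return An [image_volume()].
#' @export
back_project <- function(y, store, sched, zero_skip = FALSE) {
  yv <- check_histogram(y, store$geom)
  H <- srm_matrix(store, sched)
  if (zero_skip) {
    nz <- which(yv != 0)
    if (!length(nz)) return(image_volume(0, store$grid))
    b <- as.vector(Matrix::crossprod(H[nz, , drop = FALSE], yv[nz]))
  } else {
    b <- as.vector(Matrix::crossprod(H, yv))
  }
  image_volume(b, store$grid)
}

#' Sensitivity image of a schedule
#'
#' Per-voxel sum of system-matrix elements over the scheduled LORs — the
#' back projection of an all-ones histogram and the OSEM normalization
#' denominator. Cached per schedule.
#'
#' @inheritParams forward_project
#' @return An [image_volume()].
#' @export
sensitivity_image <- function(store, sched) {
  key <- paste0("sens:", sched$id)
  cached <- get0(key, envir = store$cache)
  if (!is.null(cached)) return(cached)
  H <- srm_matrix(store, sched)
  sens <- image_volume(Matrix::colSums(H), store$grid)
  assign(key, sens, envir = store$cache)
  sens
}

#' Naive per-LOR forward projection (reference execution path)
#'
#' Computes the same projections as [forward_project()] by looking up each
#' scheduled (LOR, voxel) element individually through [srm_element()] with
#' no grouping into shift-invariant families. Used to verify that the
#' scheduled execution path is algebraically equivalent to a plain per-LOR
#' loop. Tiny scanners only.
#'
#' @inheritParams forward_project
#' @return A [lor_histogram()].
#' @export
forward_project_naive <- function(x, store, sched) {
  xv <- check_volume(x, store$grid)
  geom <- store$geom; grid <- store$grid
  lors <- schedule_lors(sched)
  n_vox <- voxel_count(grid)
  if (nrow(lors) * n_vox > 2e7)
    stop("naive projection is a test oracle for tiny scanners only")
  voxs <- all_voxels(grid)
  y <- numeric(lor_count(geom, layers = FALSE))
  chunk <- max(1, floor(2e6 / n_vox))
  for (i0 in seq(1, nrow(lors), by = chunk)) {
    is <- i0:min(nrow(lors), i0 + chunk - 1)
    lrep <- lors[rep(is, each = n_vox), c("ur", "uc", "lr", "lc")]
    vrep <- voxs[rep(seq_len(n_vox), times = length(is)), ]
    h <- srm_element(store, lrep, vrep)
    sums <- rowsum(h * xv[rep(seq_len(n_vox), times = length(is))],
                   group = rep(is, each = n_vox), reorder = FALSE)
    y[lors$linear[is] + 1] <- as.vector(sums)
  }
  lor_histogram(y, geom)
}
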