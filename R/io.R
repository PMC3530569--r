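#' Histogram file input/output
#'
#' Dense storage is a little-endian binary file of `float64`, `float32` or
#' `uint32` values in row-major `(ur, uc, lr, lc)` order with a JSON sidecar
#' header `<path>.json` (format version, dtype, bin count, head dimensions,
#' geometry fingerprint). Sparse storage is a tab-separated file with header
#' `ur uc lr lc value` listing nonzero bins, with the same sidecar. Both
#' round-trip losslessly for their dtype.
#'
#' @param h a [lor_histogram()].
#' @param path output file.
#' @param storage `"dense"` or `"sparse"`.
#' @param dtype dense element type; `uint32` requires nonnegative integer
#'   counts below 2^31.
#' @return `path`, invisibly.
#' @export
write_histogram <- function(h, path, storage = c("dense", "sparse"),
                            dtype = c("float64", "float32", "uint32")) {
  stopifnot(inherits(h, "lor_histogram"))
  storage <- match.arg(storage)
  dtype <- match.arg(dtype)
  header <- list(format = "planarpet-histogram", version = 1L,
                 storage = storage, dtype = dtype,
                 n = length(h$values), n_rows = h$n_rows, n_cols = h$n_cols,
                 ordering = "row-major (upper.row, upper.col, lower.row, lower.col), 0-based",
                 fingerprint = h$fingerprint)
  if (storage == "dense") {
    con <- file(path, "wb"); on.exit(close(con))
    if (dtype == "float64") {
      writeBin(h$values, con, size = 8, endian = "little")
    } else if (dtype == "float32") {
      writeBin(h$values, con, size = 4, endian = "little")
    } else {
      v <- h$values
      if (any(v < 0 | v != round(v) | v >= 2^31))
        stop("uint32 storage requires nonnegative integer counts below 2^31")
      writeBin(as.integer(v), con, size = 4, endian = "little")
    }
  } else {
    geom_dims <- list(n_rows = h$n_rows, n_cols = h$n_cols)
    nz <- which(h$values != 0)
    fake_geom <- list(n_rows = h$n_rows, n_cols = h$n_cols)
    lor <- lor_from_linear(fake_geom, nz - 1)
    df <- data.frame(ur = lor$ur, uc = lor$uc, lr = lor$lr, lc = lor$lc,
                     value = sprintf("%.17g", h$values[nz]))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @param path histogram file written by [write_histogram()].
#' @rdname write_histogram
#' @return `read_histogram` returns a [lor_histogram()].
#' @export
read_histogram <- function(path) {
  hpath <- paste0(path, ".json")
  if (!file.exists(hpath)) stop("format error: missing histogram header ", hpath)
  header <- jsonlite::read_json(hpath)
  if (!identical(header$format, "planarpet-histogram"))
    stop("format error: not a planarpet histogram header")
  n <- header$n
  if (header$storage == "dense") {
    size <- switch(header$dtype, float64 = 8, float32 = 4, uint32 = 4,
                   stop("format error: unknown dtype ", header$dtype))
    if (file.info(path)$size != n * size)
      stop("format error: truncated histogram file (expected ", n * size,
           " bytes, found ", file.info(path)$size, ")")
    con <- file(path, "rb"); on.exit(close(con))
    values <- if (header$dtype == "uint32")
      as.numeric(readBin(con, "integer", n = n, size = 4, endian = "little"))
    else readBin(con, "double", n = n,
                 size = if (header$dtype == "float32") 4 else 8,
                 endian = "little")
    if (length(values) != n) stop("format error: truncated histogram file")
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c(rep("numeric", 4), "character"))
    values <- numeric(n)
    fake_geom <- list(n_rows = header$n_rows, n_cols = header$n_cols)
    lin <- lor_linear_index(fake_geom, df$ur, df$uc, df$lr, df$lc)
    values[lin + 1] <- as.numeric(df$value)
  }
  structure(list(values = values, n_rows = header$n_rows,
                 n_cols = header$n_cols, fingerprint = header$fingerprint),
            class = "lor_histogram")
}

#' Volume file input/output
#'
#' Volumes are written as NIfTI-1 (`.nii` / `.nii.gz` extensions, voxel
#' spacing `(pitch/m, pitch/m, dz)` mm) or as raw little-endian float64 with
#' a JSON sidecar (any other extension).
#'
#' @param vol an [image_volume()].
#' @param path output file; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  grid <- attr(vol, "grid")
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- array(as.vector(vol), dim = dim(vol))
    attr(arr, "pixdim") <- c(grid$pitch_in, grid$pitch_in, grid$dz)
    img <- RNifti::asNifti(arr, datatype = "double", internal = FALSE)
    RNifti::writeNifti(img, path)
  } else {
    con <- file(path, "wb")
    writeBin(as.vector(vol), con, size = 8, endian = "little")
    close(con)
    header <- list(format = "planarpet-volume", version = 1L,
                   dims = dim(vol),
                   spacing_mm = c(grid$pitch_in, grid$pitch_in, grid$dz),
                   fingerprint = attr(vol, "fingerprint"))
    jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' @param path volume file; @param grid the [voxel_grid()] the volume must
#'   match.
#' @rdname write_volume
#' @return `read_volume` returns an [image_volume()].
#' @export
read_volume <- function(path, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  dims <- c(grid$n_vrows, grid$n_vcols, grid$n_planes)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (!identical(as.integer(dim(arr)), as.integer(dims)))
      stop("volume dimensions ", paste(dim(arr), collapse = "x"),
           " do not match the grid ", paste(dims, collapse = "x"))
    sp <- RNifti::pixdim(img)
    if (max(abs(sp[1:3] - c(grid$pitch_in, grid$pitch_in, grid$dz))) > 1e-6)
      stop("volume voxel spacing does not match the grid")
    image_volume(arr, grid)
  } else {
    hpath <- paste0(path, ".json")
    if (!file.exists(hpath)) stop("format error: missing volume header ", hpath)
    header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
    if (!identical(header$format, "planarpet-volume"))
      stop("format error: not a planarpet volume header")
    if (!identical(as.integer(header$dims), as.integer(dims)))
      stop("volume dimensions ", paste(header$dims, collapse = "x"),
           " do not match the grid ", paste(dims, collapse = "x"))
    n <- prod(dims)
    if (file.info(path)$size != n * 8)
      stop("format error: truncated volume file")
    con <- file(path, "rb"); on.exit(close(con))
    image_volume(readBin(con, "double", n = n, size = 8, endian = "little"),
                 grid)
  }
}

## ---- seed pool serialization ----

# write one sparse seed DRF as a Matrix Market coordinate file; indices are
# a 2D factorization of the 4D offset box (x-pair rows, y-pair columns)
write_seed_mm <- function(entries, box, path) {
  nr <- (box$gux[2] - box$gux[1] + 1) * (box$glx[2] - box$glx[1] + 1)
  nc <- (box$guy[2] - box$guy[1] + 1) * (box$gly[2] - box$gly[1] + 1)
  i <- (entries$gux - box$gux[1]) * (box$glx[2] - box$glx[1] + 1) +
    (entries$glx - box$glx[1]) + 1
  j <- (entries$guy - box$guy[1]) * (box$gly[2] - box$gly[1] + 1) +
    (entries$gly - box$gly[1]) + 1
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate real general",
               sprintf("%d %d %d", nr, nc, nrow(entries))), con)
  if (nrow(entries))
    writeLines(sprintf("%d %d %.17g", i, j, entries$value), con)
  invisible(path)
}

read_seed_mm <- function(path, box) {
  M <- Matrix::readMM(path)
  T <- methods::as(M, "TsparseMatrix")
  glx_n <- box$glx[2] - box$glx[1] + 1
  gly_n <- box$gly[2] - box$gly[1] + 1
  data.frame(gux = box$gux[1] + T@i %/% glx_n,
             glx = box$glx[1] + T@i %% glx_n,
             guy = box$guy[1] + T@j %/% gly_n,
             gly = box$gly[1] + T@j %% gly_n,
             value = T@x)
}

#' Save / load a seed-DRF pool
#'
#' The pool directory holds one Matrix Market coordinate file per seed plus
#' `manifest.json` recording the geometry and grid, the detection-model
#' parameters, the class layout and each seed's offset bounding box. Loading
#' reconstructs the store (including the canonical lookup index) and refuses
#' geometry mismatches.
#'
#' @param store a computed [build_seed_pool()] store.
#' @param dir pool directory (created if missing).
#' @return `dir` (save) or a `seed_drf_store` (load).
#' @export
save_seed_pool <- function(store, dir) {
  stopifnot(inherits(store, "seed_drf_store"))
  if (!store$computed) stop("seed pool was built with compute = FALSE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geom <- store$geom; grid <- store$grid
  seeds_meta <- vector("list", store$n_seeds)
  for (i in seq_len(store$n_seeds)) {
    sd <- store$seeds[[i]]
    e <- sd$entries
    box <- if (nrow(e)) list(gux = range(e$gux), glx = range(e$glx),
                             guy = range(e$guy), gly = range(e$gly))
           else list(gux = c(0, 0), glx = c(0, 0), guy = c(0, 0), gly = c(0, 0))
    fname <- sprintf("seed_%03d.mtx", i - 1)
    write_seed_mm(e, box, file.path(dir, fname))
    seeds_meta[[i]] <- list(file = fname, slice = sd$slice, vrow = sd$vrow,
                            vcol = sd$vcol, n_entries = nrow(e), box = box)
  }
  manifest <- list(
    format = "planarpet-seed-pool", version = 1L,
    fingerprint = store$fingerprint,
    geometry = list(rows = geom$n_rows, cols = geom$n_cols,
                    pitch_mm = geom$pitch, thickness_mm = geom$crystal_thickness,
                    layers = geom$n_layers, separation_mm = geom$head_separation,
                    extension_margin = geom$extension_margin),
    grid = list(n_planes = grid$n_planes, dz_mm = grid$dz, m = grid$m,
                n_vrows = grid$n_vrows, n_vcols = grid$n_vcols),
    model = unclass(store$model),
    index_layout = "MM row-1 = (gux-gux_min)*n_glx + (glx-glx_min); col-1 likewise for (guy, gly)",
    seeds = seeds_meta)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @param dir pool directory written by [save_seed_pool()].
#' @rdname save_seed_pool
#' @export
load_seed_pool <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stop("format error: missing pool manifest ", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  if (!identical(man$format, "planarpet-seed-pool"))
    stop("format error: not a planarpet seed pool")
  geom <- build_geometry(man$geometry)
  grid <- voxel_grid(geom, n_planes = man$grid$n_planes, dz = man$grid$dz_mm,
                     m = man$grid$m, n_vrows = man$grid$n_vrows,
                     n_vcols = man$grid$n_vcols)
  fp <- geometry_fingerprint(geom, grid)
  if (!identical(fp, man$fingerprint))
    stop("geometry fingerprint mismatch: pool manifest does not match its geometry")
  model <- do.call(drf_model, as.list(man$model))
  store <- build_seed_pool(geom, grid, model, compute = FALSE)
  layout <- store$layout
  seeds <- vector("list", nrow(layout))
  tup_list <- vector("list", nrow(layout))
  val_list <- vector("list", nrow(layout))
  nseeds <- if (is.data.frame(man$seeds)) nrow(man$seeds) else length(man$seeds)
  if (nseeds != nrow(layout))
    stop("format error: pool manifest seed count does not match the grid layout")
  for (i in seq_len(nrow(layout))) {
    meta <- if (is.data.frame(man$seeds)) man$seeds[i, ] else man$seeds[[i]]
    box <- if (is.data.frame(man$seeds)) {
      list(gux = unlist(meta$box$gux), glx = unlist(meta$box$glx),
           guy = unlist(meta$box$guy), gly = unlist(meta$box$gly))
    } else lapply(meta$box, unlist)
    e <- read_seed_mm(file.path(dir, meta$file), box)
    seeds[[i]] <- list(slice = layout$slice[i], vrow = layout$vrow[i],
                       vcol = layout$vcol[i],
                       plane_class = layout$plane_class[i],
                       inplane_class = layout$inplane_class[i], entries = e)
    if (nrow(e)) {
      T <- cbind(s = rep(layout$slice[i], nrow(e)), gux = e$gux, glx = e$glx,
                 guy = e$guy, gly = e$gly)
      can <- canonical_tuple(T, interchange = use_interchange(geom, grid))
      tup_list[[i]] <- can$tuple
      val_list[[i]] <- e$value
    }
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
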