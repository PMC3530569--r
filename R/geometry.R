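#' Dual-head planar scanner geometry
#'
#' Describes two opposed rectangular crystal-array detector heads. The
#' coordinate system is right-handed with the origin at the center of the
#' active imaging volume: the z-axis is perpendicular to the heads, the x-axis
#' runs along the crystal rows and the y-axis along the crystal columns. The
#' upper head front face sits at z = +`head_separation`/2, the lower head at
#' z = -`head_separation`/2.
#'
#' Every ordered pair of crystals, one per head, defines one line of response
#' (LOR). Depth-of-interaction (DOI) layers are counted in the LOR index space
#' but detector response functions are computed for single-layer crystal
#' endpoints (front face plus full crystal thickness).
#'
#' @param n_rows,n_cols crystals per head along x and y.
#' @param pitch crystal pitch in mm.
#' @param crystal_thickness crystal thickness along z in mm.
#' @param n_layers DOI layers per head (affects LOR counting only).
#' @param head_separation face-to-face gap between the heads in mm.
#' @param extension_margin extra crystal index range per side of the extended
#'   lattice used by the symmetry machinery. Defaults to
#'   `ceiling(max(n_rows, n_cols)/2) + 1`, which is enough for every
#'   physically realizable crystal/voxel offset to have an in-range seed
#'   representative.
#' @return An object of class `scanner_geometry`.
#' @examples
#' g <- scanner_geometry(n_rows = 8, n_cols = 8, n_layers = 1)
#' lor_count(g)
#' @export
scanner_geometry <- function(n_rows, n_cols, pitch = 2.4, crystal_thickness = 20,
                             n_layers = 2, head_separation = 60,
                             extension_margin = NULL) {
  chk_num <- function(x, name, integer = FALSE, min = NULL) {
    if (length(x) != 1 || !is.numeric(x) || !is.finite(x))
      stop("configuration error: '", name, "' must be a single finite number",
           call. = FALSE)
    if (integer && x != round(x))
      stop("configuration error: '", name, "' must be an integer", call. = FALSE)
    if (!is.null(min) && x < min)
      stop("configuration error: '", name, "' must be >= ", min, call. = FALSE)
    as.numeric(x)
  }
  n_rows <- chk_num(n_rows, "n_rows", integer = TRUE, min = 1)
  n_cols <- chk_num(n_cols, "n_cols", integer = TRUE, min = 1)
  n_layers <- chk_num(n_layers, "n_layers", integer = TRUE, min = 1)
  pitch <- chk_num(pitch, "pitch", min = .Machine$double.eps)
  crystal_thickness <- chk_num(crystal_thickness, "crystal_thickness",
                               min = .Machine$double.eps)
  head_separation <- chk_num(head_separation, "head_separation",
                             min = .Machine$double.eps)
  if (is.null(extension_margin))
    extension_margin <- ceiling(max(n_rows, n_cols) / 2) + 1
  extension_margin <- chk_num(extension_margin, "extension_margin",
                              integer = TRUE, min = 0)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
         crystal_thickness = crystal_thickness, n_layers = n_layers,
         head_separation = head_separation, extension_margin = extension_margin),
    class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat(sprintf("Dual-head planar PET geometry: %d x %d crystals/head, %d layer(s)\n",
              x$n_rows, x$n_cols, x$n_layers))
  cat(sprintf("  pitch %.3g mm, thickness %.3g mm, head separation %.3g mm\n",
              x$pitch, x$crystal_thickness, x$head_separation))
  cat(sprintf("  LORs: %s (all layers), %s (front layer)\n",
              format(lor_count(x), big.mark = ","),
              format(lor_count(x, layers = FALSE), big.mark = ",")))
  invisible(x)
}

#' Build a scanner geometry from a plain key-value configuration
#'
#' Accepts the flat key set used in YAML scanner configs: `rows`, `cols`,
#' `pitch_mm`, `thickness_mm`, `separation_mm`, `layers`, `extension_margin`.
#' Missing optional keys fall back to the full-scale defaults (2.4 mm pitch,
#' 20 mm thickness, 60 mm separation, 2 layers).
#'
#' @param config named list (for example from [yaml::read_yaml()]).
#' @return A [scanner_geometry()] object.
#' @export
build_geometry <- function(config) {
  if (!is.list(config)) stop("configuration error: config must be a named list")
  need <- function(key) {
    if (is.null(config[[key]]))
      stop("configuration error: missing required key '", key, "'", call. = FALSE)
    config[[key]]
  }
  opt <- function(key, default) if (is.null(config[[key]])) default else config[[key]]
  scanner_geometry(
    n_rows = need("rows"), n_cols = need("cols"),
    pitch = opt("pitch_mm", 2.4),
    crystal_thickness = opt("thickness_mm", 20),
    n_layers = opt("layers", 2),
    head_separation = opt("separation_mm", 60),
    extension_margin = config[["extension_margin"]])
}

#' Voxel grid of the active imaging volume
#'
#' The grid has an odd number of z-planes with the central plane exactly
#' midway between the heads (slice index 0, signed slices around it), and an
#' in-plane voxel pitch of one `m`-th of the crystal pitch. The in-plane
#' extent defaults to the detector face (`m * n_rows` by `m * n_cols` voxels).
#'
#' @param geom a [scanner_geometry()].
#' @param n_planes odd number of z-planes.
#' @param dz plane spacing in mm.
#' @param m in-plane subdivision: voxels per crystal pitch (positive integer).
#' @param n_vrows,n_vcols in-plane voxel counts; default `m * n_rows`,
#'   `m * n_cols`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(geom, n_planes, dz, m = 1,
                       n_vrows = NULL, n_vcols = NULL) {
  stopifnot(inherits(geom, "scanner_geometry"))
  if (length(n_planes) != 1 || n_planes < 1 || n_planes != round(n_planes))
    stop("configuration error: 'n_planes' must be a positive integer")
  if (n_planes %% 2 == 0)
    stop("configuration error: 'n_planes' must be odd (central plane midway between the heads)")
  if (length(m) != 1 || m < 1 || m != round(m))
    stop("configuration error: 'm' must be a positive integer")
  if (!is.numeric(dz) || dz <= 0) stop("configuration error: 'dz' must be > 0")
  if (is.null(n_vrows)) n_vrows <- m * geom$n_rows
  if (is.null(n_vcols)) n_vcols <- m * geom$n_cols
  half <- (n_planes - 1) / 2
  if (half * dz + dz / 2 > geom$head_separation / 2 + 1e-12)
    stop("configuration error: voxel z-extent reaches beyond the detector faces")
  structure(
    list(n_planes = as.numeric(n_planes), dz = as.numeric(dz), m = as.numeric(m),
         n_vrows = as.numeric(n_vrows), n_vcols = as.numeric(n_vcols),
         pitch = geom$pitch, pitch_in = geom$pitch / m,
         head_separation = geom$head_separation),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("Voxel grid: %d planes (dz %.3g mm) x %d x %d in-plane (%.3g mm)\n",
              x$n_planes, x$dz, x$n_vrows, x$n_vcols, x$pitch_in))
  cat(sprintf("  %s voxels, slices %+d..%+d\n",
              format(prod(x$n_planes, x$n_vrows, x$n_vcols), big.mark = ","),
              -(x$n_planes - 1) / 2, (x$n_planes - 1) / 2))
  invisible(x)
}

#' Build a voxel grid from a plain key-value configuration
#'
#' Keys: `n_planes`, `dz_mm`, `m`, optional `n_vrows`, `n_vcols`.
#'
#' @inheritParams build_geometry
#' @param geom a [scanner_geometry()].
#' @return A [voxel_grid()] object.
#' @export
build_grid <- function(config, geom) {
  if (!is.list(config)) stop("configuration error: config must be a named list")
  need <- function(key) {
    if (is.null(config[[key]]))
      stop("configuration error: missing required key '", key, "'", call. = FALSE)
    config[[key]]
  }
  voxel_grid(geom, n_planes = need("n_planes"), dz = need("dz_mm"),
             m = if (is.null(config[["m"]])) 1 else config[["m"]],
             n_vrows = config[["n_vrows"]], n_vcols = config[["n_vcols"]])
}

#' Read a scanner + grid configuration from a YAML file
#'
#' @param path YAML file with the keys documented in [build_geometry()] and
#'   [build_grid()].
#' @return `list(geometry = , grid = )`.
#' @export
read_scanner_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  geom <- build_geometry(cfg)
  grid <- build_grid(cfg, geom)
  list(geometry = geom, grid = grid, config = cfg)
}

#' Default full-scale dual-head geometry and grid
#'
#' Two 104 x 72 double-layered heads, 2.4 mm pitch, 20 mm thick crystals,
#' 60 mm apart; 119 z-planes at 0.5 mm with quarter-pitch (0.6 mm) in-plane
#' voxels over the detector face.
#'
#' @return [scanner_geometry()] / [voxel_grid()] objects.
#' @export
default_geometry <- function() {
  scanner_geometry(n_rows = 104, n_cols = 72, pitch = 2.4,
                   crystal_thickness = 20, n_layers = 2, head_separation = 60)
}

#' @rdname default_geometry
#' @export
default_grid <- function() {
  voxel_grid(default_geometry(), n_planes = 119, dz = 0.5, m = 4)
}

#' Number of lines of response of a scanner
#'
#' One LOR per ordered pair of crystals, one from each head:
#' `(n_rows * n_cols * n_layers)^2`. With `layers = FALSE` the front-layer
#' LOR space used by the reconstruction is counted instead.
#'
#' @param geom a [scanner_geometry()].
#' @param layers count DOI layers (default) or only the front layer.
#' @return The LOR count as a double.
#' @export
lor_count <- function(geom, layers = TRUE) {
  stopifnot(inherits(geom, "scanner_geometry"))
  n <- geom$n_rows * geom$n_cols * (if (layers) geom$n_layers else 1)
  n * n
}

#' Number of voxels of a grid
#' @param grid a [voxel_grid()].
#' @return The voxel count as a double.
#' @export
voxel_count <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  grid$n_planes * grid$n_vrows * grid$n_vcols
}

#' Physical center of crystals
#'
#' @param geom a [scanner_geometry()].
#' @param head `"upper"` or `"lower"` (recycled).
#' @param row,col 0-based crystal indices (vectors).
#' @param layer 0-based DOI layer, 0 = front (facing the imaging volume).
#' @param extended allow indices on the extended lattice.
#' @return A matrix with columns `x`, `y`, `z` in mm.
#' @export
crystal_center <- function(geom, head, row, col, layer = 0, extended = FALSE) {
  stopifnot(inherits(geom, "scanner_geometry"))
  n <- max(length(row), length(col), length(head), length(layer))
  head <- rep_len(head, n); row <- rep_len(row, n)
  col <- rep_len(col, n); layer <- rep_len(layer, n)
  lo <- if (extended) -geom$extension_margin else 0
  if (any(row < lo | row > geom$n_rows - 1 + (if (extended) geom$extension_margin else 0)) ||
      any(col < lo | col > geom$n_cols - 1 + (if (extended) geom$extension_margin else 0)))
    stop("index error: crystal row/col out of range")
  if (any(layer < 0 | layer > geom$n_layers - 1))
    stop("index error: crystal layer out of range")
  if (!all(head %in% c("upper", "lower")))
    stop("index error: head must be 'upper' or 'lower'")
  x <- (row - (geom$n_rows - 1) / 2) * geom$pitch
  y <- (col - (geom$n_cols - 1) / 2) * geom$pitch
  depth <- geom$head_separation / 2 +
    (layer + 0.5) * geom$crystal_thickness / geom$n_layers
  z <- ifelse(head == "upper", depth, -depth)
  cbind(x = x, y = y, z = z)
}

#' Physical center of voxels
#'
#' @param grid a [voxel_grid()].
#' @param slice signed plane index (0 = central plane).
#' @param vrow,vcol 0-based in-plane voxel indices.
#' @return A matrix with columns `x`, `y`, `z` in mm.
#' @export
voxel_center <- function(grid, slice, vrow, vcol) {
  stopifnot(inherits(grid, "voxel_grid"))
  half <- (grid$n_planes - 1) / 2
  if (any(abs(slice) > half)) stop("index error: voxel slice out of range")
  if (any(vrow < 0 | vrow >= grid$n_vrows | vcol < 0 | vcol >= grid$n_vcols))
    stop("index error: voxel row/col out of range")
  cbind(x = (vrow - (grid$n_vrows - 1) / 2) * grid$pitch_in,
        y = (vcol - (grid$n_vcols - 1) / 2) * grid$pitch_in,
        z = slice * grid$dz)
}

## ---- index helpers (internal) ----

# 0-based row-major LOR linear index over (ur, uc, lr, lc), front layer.
lor_linear_index <- function(geom, ur, uc, lr, lc) {
  ((ur * geom$n_cols + uc) * geom$n_rows + lr) * geom$n_cols + lc
}

# Inverse of lor_linear_index.
lor_from_linear <- function(geom, i) {
  lc <- i %% geom$n_cols; i <- (i - lc) / geom$n_cols
  lr <- i %% geom$n_rows; i <- (i - lr) / geom$n_rows
  uc <- i %% geom$n_cols; i <- (i - uc) / geom$n_cols
  data.frame(ur = i, uc = uc, lr = lr, lc = lc)
}

# 0-based voxel linear index matching R's column-major array layout
# [vrow + 1, vcol + 1, plane]; plane = slice + (n_planes-1)/2 + 1.
voxel_linear_index <- function(grid, slice, vrow, vcol) {
  plane0 <- slice + (grid$n_planes - 1) / 2
  vrow + grid$n_vrows * (vcol + grid$n_vcols * plane0)
}

voxel_from_linear <- function(grid, j) {
  vrow <- j %% grid$n_vrows; j <- (j - vrow) / grid$n_vrows
  vcol <- j %% grid$n_vcols; j <- (j - vcol) / grid$n_vcols
  data.frame(slice = j - (grid$n_planes - 1) / 2, vrow = vrow, vcol = vcol)
}

# All voxels of a grid in linear-index order.
all_voxels <- function(grid) {
  voxel_from_linear(grid, seq_len(voxel_count(grid)) - 1)
}

#' Geometry + grid fingerprint
#'
#' A short hash of the physically relevant geometry and grid parameters, used
#' to refuse combining data generated under different configurations.
#'
#' @param geom a [scanner_geometry()].
#' @param grid a [voxel_grid()] (optional).
#' @return A character scalar.
#' @export
geometry_fingerprint <- function(geom, grid = NULL) {
  stopifnot(inherits(geom, "scanner_geometry"))
  desc <- paste(
    "geom", geom$n_rows, geom$n_cols, format(geom$pitch, digits = 15),
    format(geom$crystal_thickness, digits = 15), geom$n_layers,
    format(geom$head_separation, digits = 15), sep = ":")
  if (!is.null(grid)) {
    stopifnot(inherits(grid, "voxel_grid"))
    desc <- paste(desc, "grid", grid$n_planes, format(grid$dz, digits = 15),
                  grid$m, grid$n_vrows, grid$n_vcols, sep = ":")
  }
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(desc, f)
  unname(tools::md5sum(f))
}
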