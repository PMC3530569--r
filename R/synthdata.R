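#' Derenzo resolution phantom specification
#'
#' A micro Deluxe Derenzo-style phantom: a cylinder of parallel rods along z,
#' split into one angular sector per rod-diameter group. Within a group the
#' center-to-center rod spacing is twice the rod diameter, in the classic
#' triangular arrangement growing outward from the phantom center.
#'
#' @param diameters rod diameters in mm, strictly decreasing; one sector per
#'   diameter. Default: the six micro Deluxe groups.
#' @param radius phantom radius in mm (`NULL`: fit the grid).
#' @param activity rod activity value.
#' @param rod_length rod length along z in mm (`Inf`: full grid extent).
#' @return An object of class `derenzo_spec`.
#' @export
derenzo_spec <- function(diameters = c(2.4, 2.0, 1.7, 1.35, 1.0, 0.75),
                         radius = NULL, activity = 1, rod_length = Inf) {
  if (!length(diameters) || any(diameters <= 0))
    stop("rod diameters must be positive")
  if (length(diameters) > 1 && any(diff(diameters) >= 0))
    stop("rod diameters must be strictly decreasing across groups")
  if (activity < 0) stop("activity must be nonnegative")
  if (rod_length <= 0) stop("rod_length must be positive")
  structure(list(diameters = diameters, radius = radius, activity = activity,
                 rod_length = rod_length),
            class = "derenzo_spec")
}

# rod centers of one sector: triangular lattice at spacing 2d growing from
# the center along the sector bisector, clipped to the sector and radius
derenzo_rods <- function(spec, radius) {
  n_groups <- length(spec$diameters)
  sector <- 2 * pi / n_groups
  rods <- list()
  for (gidx in seq_len(n_groups)) {
    d <- spec$diameters[gidx]
    spacing <- 2 * d
    bisector <- (gidx - 1) * sector + sector / 2
    ub <- c(cos(bisector), sin(bisector))
    wb <- c(-sin(bisector), cos(bisector))
    r0 <- 2 * d
    max_rows <- ceiling((radius - r0) / (spacing * sqrt(3) / 2)) + 1
    pts <- list()
    for (i in 0:max(0, max_rows)) {
      dist <- r0 + i * spacing * sqrt(3) / 2
      off <- (seq_len(i + 1) - 1 - i / 2) * spacing
      px <- dist * ub[1] + off * wb[1]
      py <- dist * ub[2] + off * wb[2]
      pts[[i + 1]] <- cbind(px, py)
    }
    P <- do.call(rbind, pts)
    keep <- sqrt(P[, 1]^2 + P[, 2]^2) <= radius - d
    # perpendicular distance to the two sector edge lines must exceed d
    for (edge in c(bisector - sector / 2, bisector + sector / 2)) {
      dist_edge <- abs(P[, 1] * sin(edge) - P[, 2] * cos(edge))
      along <- P[, 1] * cos(edge) + P[, 2] * sin(edge)
      keep <- keep & (dist_edge >= d | along <= 0)
    }
    if (any(keep))
      rods[[gidx]] <- data.frame(group = gidx - 1L, diameter = d,
                                 x = P[keep, 1], y = P[keep, 2])
  }
  do.call(rbind, rods)
}

#' Voxelize a Derenzo phantom onto a grid
#'
#' A voxel is active (value `spec$activity`) iff its center lies inside a rod
#' cylinder and within the rod length around the central plane. Deterministic
#' (no randomness). The rod table is attached as attribute `"rods"`.
#'
#' @param grid a [voxel_grid()].
#' @param spec a [derenzo_spec()].
#' @return An [image_volume()] with attributes `"rods"` (data.frame of rod
#'   centers and diameters) and `"spec"`.
#' @export
derenzo_phantom <- function(grid, spec = derenzo_spec()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(spec, "derenzo_spec"))
  half_x <- grid$n_vrows / 2 * grid$pitch_in
  half_y <- grid$n_vcols / 2 * grid$pitch_in
  radius <- spec$radius
  if (is.null(radius)) radius <- 0.95 * min(half_x, half_y)
  if (radius > min(half_x, half_y) + 1e-9)
    stop("phantom radius ", radius, " mm exceeds the voxel grid extent")
  rods <- derenzo_rods(spec, radius)
  if (is.null(rods) || nrow(rods) == 0)
    stop("no rods fit inside the phantom; enlarge the radius")
  vx <- (seq_len(grid$n_vrows) - 1 - (grid$n_vrows - 1) / 2) * grid$pitch_in
  vy <- (seq_len(grid$n_vcols) - 1 - (grid$n_vcols - 1) / 2) * grid$pitch_in
  X <- matrix(vx, grid$n_vrows, grid$n_vcols)
  Y <- matrix(vy, grid$n_vrows, grid$n_vcols, byrow = TRUE)
  inplane <- matrix(FALSE, grid$n_vrows, grid$n_vcols)
  for (r in seq_len(nrow(rods))) {
    inplane <- inplane |
      ((X - rods$x[r])^2 + (Y - rods$y[r])^2 <= (rods$diameter[r] / 2)^2)
  }
  if (!any(inplane) && spec$activity > 0)
    stop("no voxel center falls inside any rod; use a finer grid (larger m) or larger rods")
  half <- (grid$n_planes - 1) / 2
  zs <- (-half:half) * grid$dz
  zmask <- abs(zs) <= spec$rod_length / 2
  vol <- array(0, dim = c(grid$n_vrows, grid$n_vcols, grid$n_planes))
  for (p in which(zmask)) vol[, , p] <- inplane * spec$activity
  out <- image_volume(vol, grid)
  attr(out, "rods") <- rods
  attr(out, "spec") <- spec
  out
}

#' Point source volume
#'
#' Unit activity at one voxel, zero elsewhere.
#'
#' @param grid a [voxel_grid()].
#' @param vox one-row data.frame (or list) with `slice`, `vrow`, `vcol`.
#' @return An [image_volume()].
#' @export
point_source <- function(grid, vox) {
  half <- (grid$n_planes - 1) / 2
  if (abs(vox$slice) > half || vox$vrow < 0 || vox$vrow >= grid$n_vrows ||
      vox$vcol < 0 || vox$vcol >= grid$n_vcols)
    stop("index error: voxel out of range")
  x <- numeric(voxel_count(grid))
  x[voxel_linear_index(grid, vox$slice, vox$vrow, vox$vcol) + 1] <- 1
  image_volume(x, grid)
}

#' Simulate a Poisson measurement
#'
#' Forward-projects a true activity image through the system matrix, scales
#' the projection to the requested expected total count, and draws
#' independent Poisson counts per LOR with a seeded generator.
#'
#' @param x_true nonnegative [image_volume()].
#' @param store a computed seed pool; @param sched a projection schedule.
#' @param total_counts requested expected total number of coincidences.
#' @param seed integer seed for the Poisson draw.
#' @return A list with `counts` (the noisy [lor_histogram()]), `mean` (the
#'   noise-free scaled projection) and `scale`.
#' @export
simulate_measurement <- function(x_true, store, sched, total_counts = 1e6,
                                 seed = 1) {
  stopifnot(total_counts > 0)
  fp <- forward_project(x_true, store, sched)
  tot <- sum(fp$values)
  if (tot == 0)
    stop("all-zero forward projection: nothing to scale to the requested counts")
  scale <- total_counts / tot
  mu <- fp$values * scale
  counts <- with_seed(seed, stats::rpois(length(mu), mu))
  list(counts = lor_histogram(as.numeric(counts), store$geom),
       mean = lor_histogram(mu, store$geom),
       scale = scale)
}

#' Peak-to-valley contrast along a rod row
#'
#' Measures resolution recovery on a reconstructed Derenzo volume: peaks are
#' the reconstructed values at the rod centers of one group (central plane),
#' valleys the values at midpoints between adjacent rods of that group
#' (center-to-center distance twice the diameter). Returns
#' `mean(peaks) / mean(valleys)`.
#'
#' @param vol reconstructed [image_volume()].
#' @param rods rod table (attribute `"rods"` of [derenzo_phantom()]).
#' @param group 0-based group index to profile.
#' @return A single contrast ratio (may be `Inf` when valleys are zero).
#' @export
rod_contrast <- function(vol, rods, group = 0) {
  grid <- attr(vol, "grid")
  g <- rods[rods$group == group, , drop = FALSE]
  if (nrow(g) < 2) stop("group must contain at least two rods")
  d <- g$diameter[1]
  nearest <- function(x, y) {
    vr <- round(x / grid$pitch_in + (grid$n_vrows - 1) / 2)
    vc <- round(y / grid$pitch_in + (grid$n_vcols - 1) / 2)
    cbind(pmin(pmax(vr, 0), grid$n_vrows - 1),
          pmin(pmax(vc, 0), grid$n_vcols - 1))
  }
  plane <- (grid$n_planes - 1) / 2 + 1
  pk <- nearest(g$x, g$y)
  peaks <- vol[cbind(pk[, 1] + 1, pk[, 2] + 1, plane)]
  # adjacent rod pairs at the nominal spacing 2d
  valleys <- c()
  for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
    dist <- sqrt((g$x[i] - g$x[j])^2 + (g$y[i] - g$y[j])^2)
    if (abs(dist - 2 * d) < 0.25 * d) {
      mv <- nearest((g$x[i] + g$x[j]) / 2, (g$y[i] + g$y[j]) / 2)
      valleys <- c(valleys, vol[cbind(mv[, 1] + 1, mv[, 2] + 1, plane)])
    }
  }
  if (!length(valleys)) stop("no adjacent rod pairs found in group ", group)
  mean(peaks) / mean(valleys)
}
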