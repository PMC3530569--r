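#' Partition LOR orientations into ordered subsets
#'
#' Orientation reflection classes are shuffled with a seeded generator and
#' dealt round-robin over `S` subsets. Classes are kept atomic so that the
#' symmetric LOR families of a schedule never straddle two subsets; subset
#' sizes in classes differ by at most one.
#'
#' @param orientations data.frame with columns `dr`, `dc` (for example from
#'   [enumerate_orientations()]).
#' @param S number of subsets.
#' @param seed integer seed for the shuffle.
#' @return An object of class `subset_plan`: a list with `S`, `seed` and
#'   `subsets`, a list of orientation data.frames.
#' @export
partition_subsets <- function(orientations, S, seed = 1) {
  oc <- orientation_classes(orientations)
  n_cl <- nrow(oc$classes)
  if (S < 1 || S != round(S)) stop("'S' must be a positive integer")
  if (S > n_cl)
    stop("more subsets (", S, ") than orientation classes (", n_cl, ")")
  perm <- with_seed(seed, sample.int(n_cl))
  assign_id <- integer(n_cl)
  assign_id[perm] <- (seq_len(n_cl) - 1L) %% S
  subsets <- lapply(seq_len(S) - 1L, function(s) {
    cls <- oc$classes[assign_id == s, , drop = FALSE]
    do.call(rbind, lapply(seq_len(nrow(cls)), function(i)
      class_members(cls$dr[i], cls$dc[i])))
  })
  structure(list(S = as.integer(S), seed = as.integer(seed),
                 classes = cbind(oc$classes, subset = assign_id),
                 subsets = subsets),
            class = "subset_plan")
}

#' @export
print.subset_plan <- function(x, ...) {
  cat(sprintf("Subset plan: %d subsets over %d orientation classes (seed %d)\n",
              x$S, nrow(x$classes), x$seed))
  invisible(x)
}

#' Reconstruction configuration
#'
#' @param n_iterations full passes over all subsets.
#' @param init initial voxel value on reconstructable voxels (default 1).
#' @param normalization optional per-LOR multiplicative factors applied to
#'   the measured histogram before reconstruction (identity by default).
#' @param background optional additive mean background per LOR (defaults to
#'   zero: randoms and scatter are ignored).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_iterations = 10, init = 1, normalization = NULL,
                         background = NULL) {
  stopifnot(n_iterations >= 1, init > 0)
  structure(list(n_iterations = as.integer(n_iterations), init = init,
                 normalization = normalization, background = background),
            class = "recon_config")
}

#' One OSEM subset update
#'
#' The multiplicative expectation-maximization update restricted to one
#' subset schedule:
#' `x'_j = x_j / sens_j * sum_i h_ij g_i / (H x)_i` over the scheduled LORs.
#' Bins with zero projected mean and zero counts contribute nothing; bins
#' with zero projected mean but positive counts are skipped with a warning
#' (this convention preserves the EM fixed point). Voxels with zero subset
#' sensitivity are left unchanged.
#'
#' @param x current image ([image_volume()] or vector).
#' @param g measured counts ([lor_histogram()] or dense vector), nonnegative.
#' @param store a computed seed pool.
#' @param sched the subset schedule.
#' @param warn_inconsistent warn on zero-mean/positive-count bins.
#' @return The updated [image_volume()].
#' @export
osem_subset_update <- function(x, g, store, sched, warn_inconsistent = TRUE) {
  xv <- check_volume(x, store$grid)
  gv <- check_histogram(g, store$geom)
  if (any(gv < 0)) stop("negative counts in measured histogram")
  H <- srm_matrix(store, sched)
  sens <- as.vector(sensitivity_image(store, sched))
  fp <- as.vector(H %*% xv)
  ratio <- numeric(length(fp))
  pos <- fp > 0
  ratio[pos] <- gv[pos] / fp[pos]
  if (warn_inconsistent) {
    sched_rows <- schedule_lors(sched)$linear + 1
    bad <- sum(!pos[sched_rows] & gv[sched_rows] > 0)
    if (bad > 0)
      warning(bad, " bin(s) with positive counts but zero projected mean were skipped")
  }
  bp <- as.vector(Matrix::crossprod(H, ratio))
  out <- xv
  sj <- sens > 0
  out[sj] <- xv[sj] * bp[sj] / sens[sj]
  image_volume(out, store$grid)
}

#' OSEM / MLEM reconstruction
#'
#' Applies [osem_subset_update()] cyclically over the subsets of `plan` for
#' `config$n_iterations` full passes, starting from a constant image (value
#' `config$init` on every voxel seen by at least one subset, 0 elsewhere).
#' With a single subset this is plain MLEM, whose Poisson log-likelihood
#' `sum_i [g_i log (Hx)_i - (Hx)_i]` is non-decreasing and whose total
#' projected counts match the measured counts after every pass.
#'
#' @param g measured counts ([lor_histogram()] or dense vector).
#' @param store a computed seed pool.
#' @param plan a [partition_subsets()] plan.
#' @param config a [recon_config()].
#' @param verbose print per-iteration log-likelihood.
#' @return The reconstructed [image_volume()] with attribute `"log"`, a
#'   data.frame with one row per full iteration (`iteration`, `loglik`,
#'   `min_voxel`, `max_voxel`, `flagged_bins`).
#' @export
reconstruct <- function(g, store, plan, config = recon_config(),
                        verbose = FALSE) {
  stopifnot(inherits(plan, "subset_plan"), inherits(config, "recon_config"))
  gv <- check_histogram(g, store$geom)
  if (!is.null(config$normalization)) gv <- gv * config$normalization
  scheds <- lapply(plan$subsets, function(o) make_schedule(store$geom, store$grid, o))
  sens_total <- Reduce(`+`, lapply(scheds, function(s)
    as.vector(sensitivity_image(store, s))))
  if (all(sens_total == 0)) stop("all-zero sensitivity: no reconstructable voxels")
  x <- numeric(voxel_count(store$grid))
  x[sens_total > 0] <- config$init
  sched_rows <- lapply(scheds, function(s) schedule_lors(s)$linear + 1)
  log <- vector("list", config$n_iterations)
  flagged_total <- 0L
  for (it in seq_len(config$n_iterations)) {
    for (s in seq_along(scheds)) {
      wh <- withCallingHandlers(
        x <- as.vector(osem_subset_update(x, gv, store, scheds[[s]],
                                          warn_inconsistent = FALSE)),
        warning = function(w) invokeRestart("muffleWarning"))
    }
    # Poisson log-likelihood over all scheduled bins, by disjoint subsets
    ll <- 0; flagged <- 0L
    for (s in seq_along(scheds)) {
      fp <- as.vector(srm_matrix(store, scheds[[s]]) %*% x)[sched_rows[[s]]]
      gs <- gv[sched_rows[[s]]]
      pos <- fp > 0
      ll <- ll + sum(gs[pos] * log(fp[pos]) - fp[pos])
      flagged <- flagged + sum(!pos & gs > 0)
    }
    log[[it]] <- data.frame(iteration = it, loglik = ll,
                            min_voxel = min(x), max_voxel = max(x),
                            flagged_bins = flagged)
    if (verbose)
      message(sprintf("iteration %d: loglik %.6f", it, ll))
  }
  vol <- image_volume(x, store$grid)
  attr(vol, "log") <- do.call(rbind, log)
  attr(vol, "plan") <- list(S = plan$S, seed = plan$seed)
  vol
}

#' MLEM reconstruction (single subset)
#'
#' @inheritParams reconstruct
#' @param n_iterations number of MLEM iterations.
#' @return See [reconstruct()].
#' @export
mlem_reconstruct <- function(g, store, n_iterations = 10) {
  plan <- partition_subsets(enumerate_orientations(store$geom), S = 1, seed = 1)
  reconstruct(g, store, plan, recon_config(n_iterations = n_iterations))
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
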