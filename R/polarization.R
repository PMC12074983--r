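#' Convex hull of a 3D point set
#'
#' Facet-enumeration hull for the small point sets that occur in
#' chromatin traces (at most a few dozen points): every plane through a
#' triple of points with all remaining points on one side is a hull
#' facet plane. Coplanar facets are merged by plane, and facet polygons
#' are taken as the 2D convex hull of the points on each plane, so
#' volumes are exact up to floating point. The hull is returned in
#' half-space form, which also gives a fast point-membership test.
#'
#' @param pts `n x 3` numeric matrix (no `NA`).
#' @return list: `planes` (`m x 4`; columns are the outward unit normal
#'   and offset, a point `x` is inside iff `planes[,1:3] %*% x <=
#'   planes[,4]` for all rows), `volume`, `centroid`, `degenerate`
#'   (`TRUE` when the points span fewer than 3 dimensions, in which
#'   case `volume = 0` and `planes` is empty).
#' @export
convex_hull_3d <- function(pts) {
  pts <- unique(as.matrix(pts))
  storage.mode(pts) <- "double"
  if (anyNA(pts)) stop("hull points must be finite")
  n <- nrow(pts)
  degen <- list(planes = matrix(0, 0, 4), volume = 0,
                centroid = colMeans(pts), degenerate = TRUE)
  if (n < 4) return(degen)
  scale <- max(apply(pts, 2, function(x) diff(range(x))), 0)
  if (scale == 0) return(degen)
  tol <- 1e-9 * scale
  ctr <- colMeans(pts)
  combs <- utils::combn(n, 3)
  planes <- matrix(0, 0, 4)
  keys <- character(0)
  for (t in seq_len(ncol(combs))) {
    p1 <- pts[combs[1, t], ]; p2 <- pts[combs[2, t], ]; p3 <- pts[combs[3, t], ]
    u <- p2 - p1; v <- p3 - p1
    nrm <- c(u[2] * v[3] - u[3] * v[2],
             u[3] * v[1] - u[1] * v[3],
             u[1] * v[2] - u[2] * v[1])
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12 * scale^2) next
    nrm <- nrm / nn
    off <- sum(nrm * p1)
    s <- drop(pts %*% nrm) - off
    if (all(s <= tol)) {
      # outward already
    } else if (all(s >= -tol)) {
      nrm <- -nrm; off <- -off
    } else next
    key <- paste(round(c(nrm, off / scale), 7), collapse = "/")
    if (key %in% keys) next
    keys <- c(keys, key)
    planes <- rbind(planes, c(nrm, off))
  }
  if (nrow(planes) == 0) return(degen)
  # facet areas -> volume via pyramids from the interior centroid
  vol <- 0
  for (f in seq_len(nrow(planes))) {
    nrm <- planes[f, 1:3]; off <- planes[f, 4]
    s <- abs(drop(pts %*% nrm) - off)
    on_plane <- pts[s <= 10 * tol, , drop = FALSE]
    if (nrow(on_plane) < 3) next
    # orthonormal in-plane basis
    a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    xy <- cbind(drop(on_plane %*% e1), drop(on_plane %*% e2))
    h <- grDevices::chull(xy)
    poly <- xy[h, , drop = FALSE]
    k <- nrow(poly)
    if (k < 3) next
    area <- abs(sum(poly[, 1] * poly[c(2:k, 1), 2] -
                    poly[c(2:k, 1), 1] * poly[, 2])) / 2
    height <- off - sum(nrm * ctr)
    vol <- vol + area * height / 3
  }
  if (vol <= tol^3) return(degen)
  list(planes = unname(planes), volume = as.numeric(unname(vol)),
       centroid = ctr, degenerate = FALSE)
}

# logical vector: which rows of `pts` lie inside the hull
points_in_hull <- function(pts, hull, tol = 1e-9) {
  if (hull$degenerate) return(rep(FALSE, nrow(pts)))
  scale <- max(abs(hull$planes[, 4]), 1)
  s <- pts %*% t(hull$planes[, 1:3, drop = FALSE])
  apply(sweep(s, 2, hull$planes[, 4]) <= tol * scale, 1, all)
}

#' A/B compartment polarization index of a trace
#'
#' Quantifies spatial segregation of the A- and B-compartment targets
#' as `PI = sqrt((1 - Vs/Va) (1 - Vs/Vb))`, where `Va` and `Vb` are the
#' convex-hull volumes of the observed A and B positions and `Vs` is
#' the volume of their intersection: 1 for fully segregated hulls, 0
#' when one hull coincides with (or contains) the other. The three
#' volumes are evaluated as voxel counts on one shared grid spanning
#' both hulls so that discretization bias cancels in the ratios.
#'
#' @inheritParams compartment_contact_frequencies
#' @param grid_n grid resolution along the longest box edge
#'   (default 48).
#' @param min_per_compartment minimum observed targets per compartment
#'   (hull construction needs >= 4 non-coplanar points).
#' @return PI in \[0,1\], or `NA` when either compartment has too few
#'   or degenerate (coplanar) positions.
#' @export
polarization_index <- function(trace, profile, grid_n = 48L,
                               min_per_compartment = 4L) {
  pos <- as_positions(trace)
  if (nrow(pos) != nrow(profile))
    stop("profile length does not match trace")
  obs <- stats::complete.cases(pos)
  a_pts <- pos[obs & profile$label == "A", , drop = FALSE]
  b_pts <- pos[obs & profile$label == "B", , drop = FALSE]
  if (nrow(a_pts) < min_per_compartment ||
      nrow(b_pts) < min_per_compartment) return(NA_real_)
  ha <- convex_hull_3d(a_pts)
  hb <- convex_hull_3d(b_pts)
  if (ha$degenerate || hb$degenerate) return(NA_real_)
  all_pts <- rbind(a_pts, b_pts)
  lo <- apply(all_pts, 2, min); hi <- apply(all_pts, 2, max)
  pad <- 0.01 * max(hi - lo)
  lo <- lo - pad; hi <- hi + pad
  step <- max(hi - lo) / grid_n
  gx <- seq(lo[1] + step / 2, hi[1], by = step)
  gy <- seq(lo[2] + step / 2, hi[2], by = step)
  gz <- seq(lo[3] + step / 2, hi[3], by = step)
  grid <- as.matrix(expand.grid(gx, gy, gz))
  in_a <- points_in_hull(grid, ha)
  in_b <- points_in_hull(grid, hb)
  na <- sum(in_a); nb <- sum(in_b); ns <- sum(in_a & in_b)
  if (na == 0 || nb == 0) return(NA_real_)
  sqrt(max(0, 1 - ns / na) * max(0, 1 - ns / nb))
}

#' Scrambled-label control distribution for the polarization index
#'
#' Shuffles the compartment identities across targets (preserving the
#' A:B count) and recomputes the polarization index, yielding the
#' randomized-control distribution against which observed polarization
#' is judged.
#'
#' @param traces list of position matrices, or a trace array from
#'   [trace_array()].
#' @param profile a [compartment_profile()].
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param permutations optional list of explicit label-index
#'   permutations (overrides random draws; an identity permutation
#'   reproduces the observed values).
#' @inheritParams polarization_index
#' @return `n_perm x n_traces` matrix of control PI values.
#' @export
scrambled_polarization_control <- function(traces, profile, n_perm = 10L,
                                           seed = 1L, permutations = NULL,
                                           grid_n = 48L) {
  if (is.array(traces) && length(dim(traces)) == 3)
    traces <- lapply(seq_len(dim(traces)[1]), function(i) traces[i, , ])
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  if (is.null(permutations)) {
    set.seed(seed)
    permutations <- replicate(n_perm, sample(nrow(profile)),
                              simplify = FALSE)
  }
  out <- matrix(NA_real_, length(permutations), length(traces))
  for (p in seq_along(permutations)) {
    prof_p <- profile
    prof_p$label <- profile$label[permutations[[p]]]
    prof_p$score <- profile$score[permutations[[p]]]
    out[p, ] <- vapply(traces, polarization_index, numeric(1),
                       profile = prof_p, grid_n = grid_n)
  }
  out
}
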