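#' Nuclear morphology from voxelized nuclei
#'
#' Nuclei arrive as a 3D voxel intensity array plus a binary nuclear
#' mask and the (possibly anisotropic) voxel size in nm; the screen's
#' imaging used 108-nm pixels and 200-nm z steps. Two per-cell
#' features are computed: the coefficient of variation (COV) of
#' in-mask voxel intensities (intensity unevenness) and the 3D
#' sphericity of the mask.
#'
#' @name nuclear-morphology
NULL

# shift a 3D array by `by` voxels along `axis`, zero-filling
shift_3d <- function(arr, axis, by) {
  d <- dim(arr)
  out <- array(0, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- seq_len(n - abs(by)) + max(0, -by)
  dst <- seq_len(n - abs(by)) + max(0, by)
  ix <- function(k, idx) switch(k, list(idx, TRUE, TRUE),
                                list(TRUE, idx, TRUE),
                                list(TRUE, TRUE, idx))
  out <- do.call(`[<-`, c(list(out), ix(axis, dst),
                          list(do.call(`[`, c(list(arr), ix(axis, src),
                                              list(drop = FALSE))))))
  out
}

# separable Gaussian smoothing of a 3D array (zero boundary)
gaussian_smooth_3d <- function(arr, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) {
    acc <- array(0, dim(arr))
    for (j in seq_along(k))
      acc <- acc + k[j] * shift_3d(arr, axis, j - r - 1L)
    arr <- acc
  }
  arr
}

# resample a 3D array along z to the target spacing;
# method "nearest" (masks) or "linear" (intensities)
resample_z <- function(arr, voxel_nm, target_nm,
                       method = c("nearest", "linear")) {
  method <- match.arg(method)
  dz <- voxel_nm[3]
  if (abs(dz - target_nm) < 1e-9) return(arr)
  nz <- dim(arr)[3]
  new_nz <- max(2L, round(nz * dz / target_nm))
  # voxel-center coordinates, old vs new grid
  zc_new <- (seq_len(new_nz) - 0.5) * (nz * dz / new_nz)
  z_frac <- zc_new / dz + 0.5            # position on old slice index scale
  out <- array(0, c(dim(arr)[1:2], new_nz))
  for (k in seq_len(new_nz)) {
    if (method == "nearest") {
      out[, , k] <- arr[, , min(nz, max(1L, round(z_frac[k])))]
    } else {
      z0 <- floor(z_frac[k])
      w <- z_frac[k] - z0
      z0 <- min(nz, max(1L, z0))
      z1 <- min(nz, z0 + 1L)
      out[, , k] <- (1 - w) * arr[, , z0] + w * arr[, , z1]
    }
  }
  out
}

# TRUE when the mask has a single 6-connected foreground component
single_component <- function(mask) {
  tot <- sum(mask)
  if (tot == 0) return(FALSE)
  seed <- array(FALSE, dim(mask))
  seed[which(mask)[1]] <- TRUE
  repeat {
    grown <- seed
    for (axis in 1:3) for (by in c(-1L, 1L))
      grown <- grown | (shift_3d(seed * 1, axis, by) > 0)
    grown <- grown & mask
    if (sum(grown) == sum(seed)) break
    seed <- grown
  }
  sum(seed) == tot
}

#' Coefficient of variation of in-mask voxel intensities
#'
#' COV = population SD / mean of the intensities inside the nuclear
#' mask; the standard measure of nuclear intensity unevenness.
#' Invariant under positive rescaling of the intensities.
#'
#' @param intensity 3D numeric array of voxel intensities.
#' @param mask congruent logical (or 0/1) array.
#' @return non-negative number.
#' @export
intensity_cov <- function(intensity, mask) {
  if (!all(dim(intensity) == dim(mask)))
    stop("intensity and mask shapes differ")
  v <- intensity[mask > 0]
  if (length(v) == 0) stop("empty mask")
  m <- mean(v)
  if (m <= 0) stop("undefined COV: mean in-mask intensity is not positive")
  sqrt(mean((v - m)^2)) / m
}

#' 3D sphericity of a voxel mask
#'
#' `psi = pi^(1/3) (6 V)^(2/3) / A`, 1 for a perfect sphere and lower
#' for elongated or multi-lobed shapes. The mask is first resampled to
#' isotropic voxels (nearest neighbor, at the lateral spacing). The
#' volume is the voxel count; the surface area is estimated by the
#' coarea formula, integrating the gradient magnitude of a
#' Gaussian-smoothed copy of the mask, which avoids the systematic
#' overestimate of voxel-face counting.
#'
#' @param mask 3D logical (or 0/1) array, single connected component.
#' @param voxel_nm numeric length-3 voxel size (x, y, z) in nm; x and y
#'   must agree.
#' @param sigma smoothing bandwidth in (isotropic) voxels.
#' @param check_connected verify the mask is one 6-connected
#'   component (default TRUE; callers producing guaranteed
#'   single-nucleus masks may disable it).
#' @return list: `sphericity`, `volume_um3`, `area_um2`.
#' @export
sphericity <- function(mask, voxel_nm = c(108, 108, 200), sigma = 0.8,
                       check_connected = TRUE) {
  mask <- (mask > 0) * 1
  if (sum(mask) == 0) stop("empty mask")
  if (abs(voxel_nm[1] - voxel_nm[2]) > 1e-6)
    stop("x and y voxel sizes must agree")
  if (check_connected && !single_component(mask > 0))
    stop("mask has multiple connected components; split nuclei first")
  iso <- voxel_nm[1]
  m <- resample_z(mask, voxel_nm, iso, method = "nearest")
  # zero-pad so masks touching the array edge keep their full surface
  pad <- ceiling(3 * sigma) + 1L
  mp <- array(0, dim(m) + 2L * pad)
  mp[pad + seq_len(dim(m)[1]), pad + seq_len(dim(m)[2]),
     pad + seq_len(dim(m)[3])] <- m
  m <- mp
  vox_um <- iso / 1000
  V <- sum(m) * vox_um^3
  f <- gaussian_smooth_3d(m, sigma)
  gx <- (shift_3d(f, 1, -1L) - shift_3d(f, 1, 1L)) / 2
  gy <- (shift_3d(f, 2, -1L) - shift_3d(f, 2, 1L)) / 2
  gz <- (shift_3d(f, 3, -1L) - shift_3d(f, 3, 1L)) / 2
  A <- sum(sqrt(gx^2 + gy^2 + gz^2)) * vox_um^2
  psi <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  list(sphericity = psi, volume_um3 = V, area_um2 = A)
}

#' Per-cell nuclear features
#'
#' @inheritParams sphericity
#' @param intensity 3D intensity array congruent with `mask`.
#' @return one-row data.frame: `cov`, `sphericity`, `volume_um3`,
#'   `area_um2`.
#' @export
nuclear_features <- function(intensity, mask,
                             voxel_nm = c(108, 108, 200),
                             check_connected = TRUE) {
  sp <- sphericity(mask, voxel_nm, check_connected = check_connected)
  data.frame(cov = intensity_cov(intensity, mask),
             sphericity = sp$sphericity,
             volume_um3 = sp$volume_um3, area_um2 = sp$area_um2)
}

#' Perturbation tests on per-cell nuclear features
#'
#' For each perturbation and feature, a two-sided Wilcoxon rank-sum
#' test of its per-cell values against the pooled non-targeting
#' controls; log2fc of group means; BH FDR across perturbations, one
#' family per feature. Groups below `min_cells` are flagged
#' insufficient.
#'
#' @param cells data.frame: `sgrna`, logical `is_control`, plus one
#'   numeric column per feature (default features `cov` and
#'   `sphericity`).
#' @param features feature column names to test.
#' @param min_cells minimum cells per perturbation (default 10).
#' @return data.frame: `sgrna`, `phenotype`, `n`, `log2fc`, `p`,
#'   `fdr`, `z`, `is_control`, `insufficient`.
#' @export
nuclear_tests <- function(cells, features = c("cov", "sphericity"),
                          min_cells = 10L) {
  stopifnot(all(c("sgrna", "is_control") %in% names(cells)),
            all(features %in% names(cells)))
  ctrl <- cells[cells$is_control, , drop = FALSE]
  if (nrow(ctrl) == 0) stop("no control cells")
  sgrnas <- setdiff(unique(cells$sgrna), NA)
  out <- list()
  for (feat in features) {
    y <- ctrl[[feat]]
    y <- y[!is.na(y)]
    rows <- lapply(sgrnas, function(sg) {
      x <- cells[[feat]][cells$sgrna == sg]
      x <- x[!is.na(x)]
      insuff <- length(x) < min_cells
      lfc <- log2(mean(x) / mean(y))
      p <- if (insuff) NA_real_ else
        stats::wilcox.test(x, y, exact = FALSE)$p.value
      z <- (mean(x) - mean(y)) / stats::sd(y)
      data.frame(sgrna = sg, phenotype = feat, n = length(x),
                 log2fc = lfc, p = p, z = z,
                 is_control = cells$is_control[match(sg, cells$sgrna)],
                 insufficient = insuff, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$fdr <- fdr_correct(df$p)
    out[[feat]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("sgrna", "phenotype", "n", "log2fc", "p", "fdr", "z",
          "is_control", "insufficient")]
}
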