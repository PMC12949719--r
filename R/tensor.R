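#' Fit diffusion tensors by log-linear least squares
#'
#' Per masked voxel, solves `ln S(g, b) = ln S0 - b g' D g` by ordinary least
#' squares over all volumes; b = 0 volumes enter as zero-weighting rows and
#' estimate `ln S0`. The design matrix is shared across voxels, so the whole
#' field is solved with one QR factorisation. Signals are floored at
#' `floor_frac * S0` (S0 taken as the voxel's mean b = 0 signal) before the
#' log to avoid `-Inf`; voxels whose signal is entirely zero, or whose fit is
#' non-finite, are flagged out of `valid_mask`.
#'
#' @param dwi a `dwi_dataset` (see [generate_dwi_phantom()] or [read_dwi()]).
#' @param floor_frac signal floor as a fraction of the voxel's b = 0 signal.
#' @param weighted logical; if `TRUE` uses weighted least squares with
#'   weights `S^2` (the first-order variance correction for log-transformed
#'   Rician-corrupted magnitudes). Default is the unweighted fit.
#' @return A `tensor_field`: list with `tensors`, an (x,y,z,6) array ordered
#'   `Dxx, Dyy, Dzz, Dxy, Dxz, Dyz` in mm^2/s, `valid_mask`, and `log_s0`.
#' @export
fit_tensor_loglinear <- function(dwi, floor_frac = 1e-6, weighted = FALSE) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  validate_dwi(dwi)
  dims <- dim(dwi$signals)[1:3]
  nvol <- dim(dwi$signals)[4]
  if (nvol < 7L) abort("tensor fit needs at least 7 volumes, got %d", nvol)

  b <- dwi$bvals
  g <- dwi$bvecs
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])

  vox <- which(dwi$mask)
  S <- matrix(dwi$signals, nrow = prod(dims))[vox, , drop = FALSE]  # nvox x nvol
  s0 <- rowMeans(S[, b == 0, drop = FALSE])
  dead <- rowSums(S) <= 0 | !is.finite(s0) | s0 <= 0
  floorv <- pmax(s0, .Machine$double.eps) * floor_frac
  Sf <- pmax(S, matrix(floorv, nrow(S), ncol(S)))
  Y <- t(log(Sf))                # nvol x nvox

  # column equilibration: b-value columns are O(b) while the intercept is
  # O(1); normalising columns keeps the QR solve near machine precision
  cs <- sqrt(colSums(X^2))
  Xs <- sweep(X, 2L, cs, "/")
  if (!weighted) {
    beta <- qr.coef(qr(Xs), Y) / cs    # 7 x nvox
  } else {
    beta <- matrix(NA_real_, 7L, ncol(Y))
    for (j in seq_len(ncol(Y))) {
      w <- S[j, ]^2
      beta[, j] <- stats::lm.wfit(Xs, Y[, j], w)$coefficients / cs
    }
  }

  ok <- apply(is.finite(beta), 2L, all) & !dead
  tens <- array(0, dim = c(dims, 6L))
  tm <- matrix(0, prod(dims), 6L)
  tm[vox, ] <- t(beta[2:7, , drop = FALSE])
  tm[vox[!ok], ] <- NA_real_
  tens[] <- tm
  valid <- array(FALSE, dims)
  valid[vox[ok]] <- TRUE
  log_s0 <- array(NA_real_, dims)
  log_s0[vox] <- beta[1L, ]
  structure(list(tensors = tens, valid_mask = valid, log_s0 = log_s0),
            class = "tensor_field")
}

# Internal validation of the dataset invariants.
validate_dwi <- function(dwi) {
  d <- dim(dwi$signals)
  if (length(d) != 4L) abort("'signals' must be a 4-D array")
  if (d[4] != length(dwi$bvals) || d[4] != nrow(dwi$bvecs))
    abort("volume count mismatch: %d signals vs %d bvals vs %d bvecs",
          d[4], length(dwi$bvals), nrow(dwi$bvecs))
  nz <- dwi$bvals > 0
  if (!any(!nz)) abort("no b = 0 volume present")
  nrm <- sqrt(rowSums(dwi$bvecs[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    abort("non-unit gradient directions on the b > 0 shell")
  if (nrow(unique(round(dwi$bvecs[nz, , drop = FALSE], 6))) < 6L)
    abort("fewer than 6 distinct diffusion-encoding directions")
  invisible(dwi)
}

#' Eigendecomposition of a tensor field
#'
#' Symmetric eigendecomposition per valid voxel. Eigenvalues are sorted
#' descending; the principal eigenvector's sign is normalised to nonnegative
#' z (ties broken by nonnegative y, then nonnegative x) so repeated runs give
#' identical direction maps.
#'
#' @param field a `tensor_field`.
#' @return A list of class `scalar_maps_eigen` with `eigenvalues` (x,y,z,3),
#'   `principal_direction` (x,y,z,3) and `valid_mask`.
#' @export
tensor_eigensystem <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  dims <- dim(field$tensors)[1:3]
  tm <- matrix(field$tensors, nrow = prod(dims))
  vox <- which(field$valid_mask)
  if (any(!is.finite(tm[vox, ])))
    abort("non-finite tensor entries inside valid_mask")
  ev <- matrix(NA_real_, prod(dims), 3L)
  pd <- matrix(NA_real_, prod(dims), 3L)
  for (v in vox) {
    D <- matrix(c(tm[v, 1], tm[v, 4], tm[v, 5],
                  tm[v, 4], tm[v, 2], tm[v, 6],
                  tm[v, 5], tm[v, 6], tm[v, 3]), 3L, 3L)
    e <- eigen(D, symmetric = TRUE)     # descending for symmetric input
    ev[v, ] <- e$values
    v1 <- e$vectors[, 1L]
    s <- sign(v1[3])
    if (s == 0) s <- sign(v1[2])
    if (s == 0) s <- sign(v1[1])
    if (s == 0) s <- 1
    pd[v, ] <- v1 * s
  }
  eva <- array(ev, dim = c(dims, 3L))
  pda <- array(pd, dim = c(dims, 3L))
  structure(list(eigenvalues = eva, principal_direction = pda,
                 valid_mask = field$valid_mask),
            class = "scalar_maps_eigen")
}

#' Fractional anisotropy and mean diffusivity from eigenvalues
#'
#' `md` is the raw eigenvalue mean (trace/3), preserving any negative fitted
#' eigenvalues so apparent diffusivities stay untouched for ALPS use. Inside
#' the FA formula eigenvalues are clamped at zero (FA requires a positive
#' semidefinite tensor); clamped voxels are reported via the `clamped`
#' attribute. FA of the zero tensor is defined as 0, and FA is guaranteed to
#' lie in [0, 1].
#'
#' @param eigenvalues an n x 3 matrix, a length-3 vector, or an (x,y,z,3)
#'   array of eigenvalues (mm^2/s).
#' @return A list with `fa` and `md`, shaped like the input minus the
#'   eigenvalue axis; `fa` carries a logical `clamped` attribute.
#' @export
compute_fa_md <- function(eigenvalues) {
  dm <- dim(eigenvalues)
  if (is.null(dm)) {
    if (length(eigenvalues) != 3L) abort("need three eigenvalues per voxel")
    ev <- matrix(eigenvalues, 1L, 3L); out_dim <- NULL
  } else if (length(dm) == 2L && dm[2] == 3L) {
    ev <- eigenvalues; out_dim <- NULL
  } else if (dm[length(dm)] == 3L) {
    ev <- matrix(eigenvalues, ncol = 3L); out_dim <- dm[-length(dm)]
  } else abort("last axis of 'eigenvalues' must have length 3")

  md <- rowMeans(ev)
  lp <- pmax(ev, 0)
  clamped <- rowSums(ev < 0) > 0
  mp <- rowMeans(lp)
  num <- (lp[, 1] - mp)^2 + (lp[, 2] - mp)^2 + (lp[, 3] - mp)^2
  den <- lp[, 1]^2 + lp[, 2]^2 + lp[, 3]^2
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa <- pmin(pmax(fa, 0), 1)
  if (!is.null(out_dim) && length(out_dim) > 1L) {
    dim(fa) <- out_dim; dim(md) <- out_dim; dim(clamped) <- out_dim
  } else if (is.null(dm)) {
    fa <- fa[[1L]]; md <- md[[1L]]; clamped <- clamped[[1L]]
  }
  attr(fa, "clamped") <- clamped
  list(fa = fa, md = md)
}

#' Directionally encoded colour (DEC) FA map
#'
#' Standard RGB convention: red = left-right (x), green = anterior-posterior
#' (y), blue = superior-inferior (z); each channel is the FA-scaled absolute
#' component of the principal eigenvector, clipped to [0, 1].
#'
#' @param fa FA values (vector or array).
#' @param principal_direction matching unit directions, last axis length 3.
#' @return An array with a trailing length-3 RGB axis, values in [0, 1].
#' @export
dec_fa_map <- function(fa, principal_direction) {
  dm <- dim(principal_direction)
  pd <- if (is.null(dm)) matrix(principal_direction, 1L, 3L)
        else matrix(principal_direction, ncol = 3L)
  fav <- as.vector(fa)
  if (length(fav) != nrow(pd)) abort("'fa' and 'principal_direction' disagree in size")
  rgb <- abs(pd) * fav
  rgb <- pmin(pmax(rgb, 0), 1)
  if (!is.null(dm)) dim(rgb) <- dm else rgb <- drop(rgb)
  rgb
}

#' All scalar maps from a tensor field
#'
#' Convenience wrapper chaining [tensor_eigensystem()], [compute_fa_md()] and
#' [dec_fa_map()].
#'
#' @param field a `tensor_field`.
#' @return A list of class `scalar_maps` with `eigenvalues`,
#'   `principal_direction`, `fa`, `md`, `dec_rgb`, `valid_mask`.
#' @export
scalar_maps <- function(field) {
  eig <- tensor_eigensystem(field)
  fm <- compute_fa_md(eig$eigenvalues)
  dec <- dec_fa_map(fm$fa, eig$principal_direction)
  structure(list(eigenvalues = eig$eigenvalues,
                 principal_direction = eig$principal_direction,
                 fa = fm$fa, md = fm$md, dec_rgb = dec,
                 valid_mask = eig$valid_mask),
            class = "scalar_maps")
}
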