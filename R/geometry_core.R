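## Rigid-body superposition (Kabsch), RMSD/RMSF machinery and the medoid
## "representative structure" rule.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile` and `reference` point sets of equal size. The reflection case
#' (negative determinant) is corrected by flipping the smallest singular
#' vector, so the returned rotation always has determinant +1.
#'
#' The transform acts on row-vector coordinates:
#' `fitted = mobile %*% rotation + translation` (row-wise).
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3, not all
#'   collinear.
#' @return list with `rotation` (3 x 3), `translation` (length 3) and
#'   `rmsd` (Angstrom), class `superposition`.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("point sets must be N x 3 matrices")
  if (nrow(mobile) != nrow(reference))
    stop("point-count mismatch: ", nrow(mobile), " vs ", nrow(reference))
  if (nrow(mobile) < 3L)
    stop("superposition needs at least 3 points")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  M <- sweep(mobile, 2, mc); R0 <- sweep(reference, 2, rc)
  if (svd(M, nu = 0, nv = 0)$d[2] < 1e-8 * max(1, svd(M, nu = 0, nv = 0)$d[1]))
    stop("degenerate point set: all points (nearly) collinear")
  H <- crossprod(M, R0)
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- M %*% rot
  rmsd <- sqrt(sum((fitted - R0)^2) / nrow(M))
  structure(list(rotation = rot,
                 translation = as.numeric(rc - drop(mc %*% rot)),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd = %.4f A\n", x$rmsd))
  invisible(x)
}

#' Apply a superposition transform to coordinates
#' @param xyz N x 3 matrix.
#' @param sp a `superposition` from [superpose()].
#' @return transformed N x 3 matrix.
#' @export
apply_transform <- function(xyz, sp) {
  sweep(as.matrix(xyz) %*% sp$rotation, 2, sp$translation, "+")
}

## Minimum RMSD between two centered N x 3 sets, given their squared norms.
## Uses sum of signed singular values of the 3x3 cross-covariance.
.pair_rmsd <- function(Mc, Rc, gM, gR) {
  sv <- svd(crossprod(Mc, Rc))
  d <- sign(det(sv$u) * det(sv$v))
  tr <- sv$d[1] + sv$d[2] + d * sv$d[3]
  sqrt(max(0, (gM + gR - 2 * tr) / nrow(Mc)))
}

## Rows of a frame block (n x 3k) -> list of k x 3 matrices is avoided;
## reshape one frame row into k x 3.
.row_xyz <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Per-frame RMSD time series
#'
#' Each frame's selected atoms are superposed onto the same selection in a
#' reference frame; the minimized RMSD is reported against the time axis.
#'
#' @param t a `groove_trajectory`.
#' @param selection atom indices or a [select_calpha()] result; non-empty.
#' @param reference_frame index of the reference frame (default 1).
#' @return a [metric_series] labelled "rmsd" (Angstrom vs ns).
#' @export
rmsd_series <- function(t, selection, reference_frame = 1L) {
  stopifnot(inherits(t, "groove_trajectory"))
  idx <- sel_indices(selection)
  if (!length(idx)) stop("empty selection")
  if (reference_frame < 1L || reference_frame > n_frames(t))
    stop("reference frame index out of range")
  block <- traj_sel_xyz(t, idx)
  ref <- .row_xyz(block[reference_frame, ])
  Rc <- sweep(ref, 2, colMeans(ref)); gR <- sum(Rc^2)
  vals <- vapply(seq_len(nrow(block)), function(i) {
    M <- .row_xyz(block[i, ])
    Mc <- sweep(M, 2, colMeans(M))
    .pair_rmsd(Mc, Rc, sum(Mc^2), gR)
  }, numeric(1))
  metric_series(frame_times(t), vals, label = "rmsd")
}

#' Per-residue RMSF profile
#'
#' Root-mean-square fluctuation of each selected atom about its mean
#' position. By default all frames are iteratively superposed onto their
#' mean structure (superpose, re-average, repeat until the mean shifts by
#' less than `tol`), which removes the dependence on an arbitrary reference
#' frame; `reference = "frame"` fits onto `ref_frame` instead. Atoms sharing
#' a residue number are combined by root-mean-square.
#'
#' @param t a `groove_trajectory` with >= 2 frames.
#' @param selection atom indices or a [select_calpha()] result.
#' @param reference `"mean"` (default) or `"frame"`.
#' @param ref_frame reference frame index when `reference = "frame"`.
#' @param tol convergence threshold on the mean-structure shift (Angstrom).
#' @param max_iter iteration cap for the mean-structure fit.
#' @return list with `resids` and `values` (Angstrom), class `rmsf_profile`.
#' @export
rmsf_profile <- function(t, selection, reference = c("mean", "frame"),
                         ref_frame = 1L, tol = 1e-6, max_iter = 50L) {
  stopifnot(inherits(t, "groove_trajectory"))
  reference <- match.arg(reference)
  if (n_frames(t) < 2L) stop("RMSF needs at least 2 frames")
  idx <- sel_indices(selection)
  if (!length(idx)) stop("empty selection")
  block <- traj_sel_xyz(t, idx)
  nf <- nrow(block); k <- length(idx)
  frames <- lapply(seq_len(nf), function(i) .row_xyz(block[i, ]))

  fit_all <- function(ref) lapply(frames, function(M)
    apply_transform(M, superpose(M, ref)))

  if (reference == "frame") {
    if (ref_frame < 1L || ref_frame > nf) stop("reference frame out of range")
    fitted <- fit_all(frames[[ref_frame]])
    mean_xyz <- Reduce(`+`, fitted) / nf
  } else {
    ref <- frames[[1L]]
    for (it in seq_len(max_iter)) {
      fitted <- fit_all(ref)
      mean_xyz <- Reduce(`+`, fitted) / nf
      shift <- sqrt(mean(rowSums((mean_xyz - ref)^2)))
      ref <- mean_xyz
      if (shift < tol) break
    }
    fitted <- fit_all(ref)
    mean_xyz <- Reduce(`+`, fitted) / nf
  }
  msf <- Reduce(`+`, lapply(fitted, function(M)
    rowSums((M - mean_xyz)^2))) / nf
  resid_of <- t$topology$atom$resid[idx]
  per_res <- tapply(msf, resid_of, mean)
  resids <- as.integer(names(per_res))
  ord <- order(match(resids, resid_of))  # preserve selection order
  structure(list(resids = resids[ord],
                 values = sqrt(as.numeric(per_res)[ord])),
            class = "rmsf_profile")
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("rmsf_profile: %d residues, mean %.3f A (range %.3f-%.3f)\n",
              length(x$resids), mean(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.data.frame.rmsf_profile <- function(x, ...) {
  data.frame(resid = x$resids, value = x$values)
}

#' Medoid representative frame of a trajectory window
#'
#' Operationalizes the "most representative conformation over the final K
#' frames" rule as the medoid under pairwise superposed RMSD: the in-window
#' frame minimizing its mean RMSD to every other in-window frame. Ties go
#' to the lowest frame index.
#'
#' @param t a `groove_trajectory`.
#' @param selection atom indices or a [select_calpha()] result.
#' @param window number of trailing frames to consider (default 1000,
#'   capped at the trajectory length); must be >= 2.
#' @return absolute (1-based) index of the representative frame.
#' @export
representative_frame <- function(t, selection, window = 1000L) {
  stopifnot(inherits(t, "groove_trajectory"))
  nf <- n_frames(t)
  window <- min(as.integer(window), nf)
  if (window < 2L) stop("window must contain at least 2 frames")
  first <- nf - window + 1L
  block <- traj_sel_xyz(t, selection)[first:nf, , drop = FALSE]
  centered <- vector("list", window); g <- numeric(window)
  for (i in seq_len(window)) {
    M <- .row_xyz(block[i, ])
    Mc <- sweep(M, 2, colMeans(M))
    centered[[i]] <- Mc; g[i] <- sum(Mc^2)
  }
  tot <- numeric(window)
  for (i in seq_len(window - 1L)) for (j in (i + 1L):window) {
    d <- .pair_rmsd(centered[[i]], centered[[j]], g[i], g[j])
    tot[i] <- tot[i] + d; tot[j] <- tot[j] + d
  }
  first + which.min(tot / (window - 1L)) - 1L
}
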