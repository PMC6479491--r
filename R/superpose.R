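#' Optimal rigid-body superposition
#'
#' Least-squares fit of `mobile` onto `reference` over a selection, using the
#' SVD-based optimal rotation with a reflection guard (proper rotation only,
#' `det(R) = +1`). The returned transform maps mobile coordinates as
#' `sweep(mobile, 2, mobile_center) %*% rotation + reference_center`.
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices (angstroms).
#' @param selection Atom indices (or expression resolved against `model`) the
#'   fit is computed over; the transform applies to all atoms. Defaults to
#'   all rows.
#' @param model Optional atom tibble used to resolve a selection expression.
#' @return A list with `rotation` (3x3), `mobile_center`, `reference_center`
#'   (length-3), `rmsd` (post-fit RMSD over the selection, angstroms) and
#'   `coords` (all mobile atoms, transformed).
#' @export
superpose <- function(mobile, reference, selection = NULL, model = NULL) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference))) {
    abort("`mobile` and `reference` must have identical dimensions.")
  }
  idx <- if (is.null(selection)) {
    seq_len(nrow(mobile))
  } else if (is.null(model)) {
    as.integer(selection)
  } else {
    .resolve_selection(model, selection)
  }
  if (length(idx) < 3) abort("Superposition needs at least 3 selected atoms.")
  P <- mobile[idx, , drop = FALSE]
  Q <- reference[idx, , drop = FALSE]
  cm <- colMeans(P)
  cr <- colMeans(Q)
  Pc <- sweep(P, 2, cm)
  Qc <- sweep(Q, 2, cr)
  if (qr(Pc)$rank < 2) abort("Selected atoms are collinear; fit is degenerate.")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted_sel <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((fitted_sel - Qc)^2)))
  coords <- sweep(sweep(mobile, 2, cm) %*% R, 2, cr, `+`)
  list(
    rotation = R, mobile_center = cm, reference_center = cr,
    rmsd = rmsd, coords = coords
  )
}

# Superpose every frame onto fixed reference coordinates (over `idx`),
# returning a new coordinate array.
.superpose_frames <- function(coords, reference, idx) {
  nf <- dim(coords)[1]
  out <- coords
  for (i in seq_len(nf)) {
    m <- coords[i, , , drop = FALSE]
    dim(m) <- dim(m)[2:3]
    out[i, , ] <- superpose(m, reference, selection = idx)$coords
  }
  out
}

#' Superpose an ensemble onto its mean structure
#'
#' Iterative mean-structure fitting: fit all frames to an initial reference
#' (frame 1 by default), recompute the mean, refit, for `iterations` rounds.
#' This is the reference treatment used before RMSF and covariance analysis.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param selection Selection (expression, `atom_selection` or indices) the
#'   fit is computed over.
#' @param reference `"mean"` (iterated mean-structure fit) or `"first"`.
#' @param iterations Maximum mean-fit refinement rounds (default 3).
#' @param tol Stop refining once the mean structure shifts by less than this
#'   RMS amount (angstroms) between rounds; `NULL` runs all `iterations`.
#' @return The ensemble with all frames rigid-body aligned; the (selection)
#'   mean coordinates are stored in attribute `"mean_coords"`.
#' @export
superpose_ensemble <- function(ensemble, selection = "backbone",
                               reference = c("mean", "first"), iterations = 3,
                               tol = NULL) {
  reference <- match.arg(reference)
  idx <- .resolve_selection(ensemble$topology, selection)
  coords <- .superpose_frames(ensemble$coords, frame_coords(ensemble, 1), idx)
  if (reference == "mean" && n_frames(ensemble) > 1) {
    prev <- NULL
    for (it in seq_len(iterations)) {
      ref <- apply(coords, c(2, 3), mean)
      if (!is.null(tol) && !is.null(prev) &&
        sqrt(mean((ref - prev)^2)) < tol) {
        break
      }
      coords <- .superpose_frames(coords, ref, idx)
      prev <- ref
    }
  }
  out <- trajectory_ensemble(ensemble$topology, coords, times = ensemble$times)
  attr(out, "mean_coords") <- apply(coords, c(2, 3), mean)
  out
}
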