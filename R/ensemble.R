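#' Trajectory ensembles
#'
#' A `trajectory_ensemble` bundles a topology (an atom tibble as returned by
#' [read_pdb()]) with an ordered stack of coordinate frames and their
#' timestamps. Coordinates are in angstroms, times in picoseconds.
#'
#' @param topology Atom tibble (one row per atom; see [read_pdb()]).
#' @param coords Numeric array `n_frames x n_atoms x 3`, or a list of
#'   `n_atoms x 3` matrices.
#' @param times Numeric vector of frame times (ps), strictly increasing.
#'   Defaults to `0, stride, 2 * stride, ...`.
#' @param stride Frame spacing in ps used when `times` is not given.
#'
#' @return An object of class `trajectory_ensemble`: a list with elements
#'   `topology`, `coords` (array) and `times`.
#' @export
trajectory_ensemble <- function(topology, coords, times = NULL, stride = 1) {
  if (is.list(coords) && !is.array(coords)) {
    n_frames <- length(coords)
    coords <- array(
      unlist(lapply(coords, function(m) as.numeric(m))),
      dim = c(nrow(coords[[1]]), 3, n_frames)
    )
    coords <- aperm(coords, c(3, 1, 2))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (n_atoms != nrow(topology)) {
    abort(sprintf(
      "Frame atom count (%d) does not match topology (%d atoms).",
      n_atoms, nrow(topology)
    ))
  }
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * stride
  if (length(times) != n_frames) abort("`times` must have one entry per frame.")
  if (n_frames > 1 && any(diff(times) <= 0)) {
    abort("Frame times must be strictly increasing.")
  }
  if (!all(is.finite(coords))) abort("Frame coordinates must be finite.")
  structure(
    list(topology = as_tibble(topology), coords = coords, times = as.numeric(times)),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf(
    "<trajectory_ensemble> %d frames x %d atoms (%d residues), t = %g..%g ps\n",
    n_frames(x), n_atoms(x), length(unique(x$topology$residue_index)),
    min(x$times), max(x$times)
  ))
  invisible(x)
}

#' Ensemble dimensions
#'
#' @param ensemble A [trajectory_ensemble()].
#' @return Integer count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) dim(ensemble$coords)[2]

#' Extract one frame's coordinates
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` numeric matrix (angstroms).
#' @export
frame_coords <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  m <- ensemble$coords[i, , , drop = FALSE]
  dim(m) <- dim(m)[2:3]
  m
}

#' Single-frame ensemble view of a structure
#'
#' Wraps a static structure as a one-frame ensemble so frame-wise analyses
#' apply uniformly.
#'
#' @param model Atom tibble.
#' @return A [trajectory_ensemble()] with one frame at t = 0.
#' @export
as_ensemble <- function(model) {
  trajectory_ensemble(model, array(as.matrix(model[, c("x", "y", "z")]),
    dim = c(1, nrow(model), 3)
  ))
}
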