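#' Minimum-energy representative structure selection
#'
#' Ranks frames by a supplied total-conformational-energy series, clusters
#' the `k` lowest-energy frames by pairwise superposed RMSD (single linkage
#' at `rmsd_cutoff`), and selects the lowest-energy member of the largest
#' cluster as the representative. Ties on cluster size go to the cluster
#' containing the global energy minimum; ties on energy to the earliest
#' frame.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param profile Energy profile tibble (`time`, `energy`) aligned to the
#'   ensemble frames (see [read_energy_profile()]).
#' @param selection Selection for the RMSD fit (default `"backbone"`).
#' @param k Number of lowest-energy frames to cluster (default 20, capped at
#'   the frame count).
#' @param rmsd_cutoff Single-linkage cut height, angstroms (default 2.0).
#' @return An object of class `representative_set`: `lowest_energy_frame`,
#'   `representative_frame`, and a `top_k` tibble (`frame`, `time`, `energy`,
#'   `cluster`), sorted ascending by energy.
#' @export
select_representative <- function(ensemble, profile, selection = "backbone",
                                  k = 20, rmsd_cutoff = 2.0) {
  nf <- n_frames(ensemble)
  if (nrow(profile) != nf) {
    abort(sprintf(
      "Energy profile has %d rows but the ensemble has %d frames.",
      nrow(profile), nf
    ))
  }
  if (!all(is.finite(profile$energy))) abort("Energies must be finite.")
  k <- min(k, nf)
  idx <- .resolve_selection(ensemble$topology, selection)
  ord <- order(profile$energy, ensemble$times)
  top <- ord[seq_len(k)]
  if (k == 1) {
    cl <- 1L
  } else {
    D <- matrix(0, k, k)
    for (i in seq_len(k - 1)) {
      ref <- frame_coords(ensemble, top[i])
      for (j in seq(i + 1, k)) {
        D[i, j] <- D[j, i] <-
          superpose(frame_coords(ensemble, top[j]), ref, selection = idx)$rmsd
      }
    }
    cl <- cutree(hclust(as.dist(D), method = "single"), h = rmsd_cutoff)
  }
  sizes <- table(cl)
  best_size <- max(sizes)
  cand <- as.integer(names(sizes)[sizes == best_size])
  if (length(cand) > 1) {
    with_min <- cl[1] # top[1] is the global minimum-energy frame
    cand <- if (with_min %in% cand) with_min else min(cand)
  }
  members <- top[cl == cand]
  # members inherit energy order from `top`; first is lowest energy,
  # earliest-time on ties (order() is stable on the time key)
  structure(
    list(
      lowest_energy_frame = top[1],
      representative_frame = members[1],
      rmsd_cutoff = rmsd_cutoff,
      top_k = tibble(
        frame = top, time = ensemble$times[top],
        energy = profile$energy[top], cluster = as.integer(cl)
      )
    ),
    class = "representative_set"
  )
}

#' @export
print.representative_set <- function(x, ...) {
  cat(sprintf(
    "<representative_set> %d low-energy frames, %d cluster(s) at %.2f A\n  lowest-energy frame %d; representative frame %d (t = %g ps)\n",
    nrow(x$top_k), length(unique(x$top_k$cluster)), x$rmsd_cutoff,
    x$lowest_energy_frame, x$representative_frame,
    x$top_k$time[x$top_k$frame == x$representative_frame]
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.representative_set <- function(x, ...) x$top_k

#' @exportS3Method generics::glance
glance.representative_set <- function(x, ...) {
  tibble(
    lowest_energy_frame = x$lowest_energy_frame,
    representative_frame = x$representative_frame,
    n_clusters = length(unique(x$top_k$cluster)),
    largest_cluster = max(table(x$top_k$cluster))
  )
}

#' Energy versus RMSD table
#'
#' Per-frame superposed RMSD against a reference frame (default: the
#' lowest-energy frame) paired with the supplied energy, for the standard
#' energy-vs-RMSD scatter.
#'
#' @inheritParams select_representative
#' @param reference_frame Reference frame index; default the lowest-energy
#'   frame of `profile`.
#' @return A tibble with `frame`, `time`, `rmsd` (angstroms) and `energy`.
#' @export
energy_rmsd_scatter <- function(ensemble, profile, selection = "backbone",
                                reference_frame = NULL) {
  nf <- n_frames(ensemble)
  if (nrow(profile) != nf) abort("Energy profile length mismatch.")
  if (is.null(reference_frame)) {
    reference_frame <- order(profile$energy, ensemble$times)[1]
  }
  rs <- rmsd_series(ensemble, selection, reference_frame = reference_frame)
  tibble(
    frame = seq_len(nf), time = ensemble$times,
    rmsd = rs$rmsd, energy = profile$energy
  )
}
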