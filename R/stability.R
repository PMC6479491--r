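#' RMSD time series against a reference frame
#'
#' Per-frame superposed root-mean-square deviation over a selection, relative
#' to a reference frame of the same ensemble (the "equilibrated structure" of
#' a simulation workflow; frame 1 by default).
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param selection Selection expression, `atom_selection` or indices
#'   (default `"backbone"`).
#' @param reference_frame Index of the reference frame (1-based, default 1).
#' @return A tibble (`rin_rmsd`) with columns `time` (ps) and `rmsd`
#'   (angstroms); the value at the reference frame is 0.
#' @export
rmsd_series <- function(ensemble, selection = "backbone", reference_frame = 1) {
  idx <- .resolve_selection(ensemble$topology, selection)
  if (length(idx) == 0) abort("Selection is empty.")
  if (reference_frame < 1 || reference_frame > n_frames(ensemble)) {
    abort("`reference_frame` is out of range.")
  }
  ref <- frame_coords(ensemble, reference_frame)
  vals <- vapply(seq_len(n_frames(ensemble)), function(i) {
    superpose(frame_coords(ensemble, i), ref, selection = idx)$rmsd
  }, numeric(1))
  vals[reference_frame] <- 0
  out <- tibble(time = ensemble$times, rmsd = vals)
  class(out) <- c("rin_rmsd", class(out))
  attr(out, "selection_label") <- attr(idx, "label")
  attr(out, "reference_label") <- sprintf("frame %d", reference_frame)
  out
}

#' Per-residue RMSF
#'
#' Root-mean-square fluctuation about the time-average position after
#' iterative mean-structure superposition, reported per residue at its
#' C-alpha atom.
#'
#' @inheritParams rmsd_series
#' @param selection Selection the fluctuations are computed for; residues
#'   without a C-alpha in the selection are omitted with a warning. Default
#'   `"calpha"`.
#' @param fit_selection Selection used for the superposition fit (defaults to
#'   `selection`).
#' @param reference `"mean"` or `"first"`, see [superpose_ensemble()].
#' @return A tibble (`rin_rmsf`) with `residue_index`, `label` (author
#'   numbering), and `rmsf` (angstroms).
#' @export
rmsf_table <- function(ensemble, selection = "calpha", fit_selection = selection,
                       reference = c("mean", "first")) {
  if (n_frames(ensemble) < 2) abort("RMSF needs at least 2 frames.")
  reference <- match.arg(reference)
  topo <- ensemble$topology
  idx <- .resolve_selection(topo, selection)
  if (length(idx) == 0) abort("Selection is empty.")
  fit_idx <- .resolve_selection(topo, fit_selection)
  fitted <- superpose_ensemble(ensemble, fit_idx, reference = reference)
  mean_xyz <- attr(fitted, "mean_coords")
  dev2 <- matrix(0, n_frames(ensemble), length(idx))
  for (i in seq_len(n_frames(ensemble))) {
    d <- frame_coords(fitted, i)[idx, , drop = FALSE] - mean_xyz[idx, , drop = FALSE]
    dev2[i, ] <- rowSums(d^2)
  }
  atom_rmsf <- sqrt(colMeans(dev2))
  sel_topo <- topo[idx, ]
  is_ca <- sel_topo$name == "CA"
  res_all <- unique(sel_topo$residue_index)
  res_ca <- unique(sel_topo$residue_index[is_ca])
  missing <- setdiff(res_all, res_ca)
  if (length(missing) > 0) {
    warn(sprintf(
      "%d residue(s) lack a C-alpha in the selection and were omitted.",
      length(missing)
    ))
  }
  keep <- which(is_ca)
  out <- tibble(
    residue_index = sel_topo$residue_index[keep],
    label = residue_labels(sel_topo[keep, ]),
    rmsf = atom_rmsf[keep]
  )
  out <- out[!duplicated(out$residue_index), ]
  class(out) <- c("rin_rmsf", class(out))
  out
}

#' Solvent-accessible surface area time series
#'
#' Shrake-Rupley sphere-sampling SASA of the selected atoms, per frame.
#' Sphere points are placed on a deterministic golden-spiral lattice; the
#' area is reported in nm^2 (the unit simulation packages print).
#'
#' @inheritParams rmsd_series
#' @param probe_radius Solvent probe radius in nm (default 0.14, water).
#' @param n_points Quadrature points per atom sphere (default 960, >= 100).
#' @param radii Named vdW radii in nm per element; defaults cover C, N, O, S, H.
#' @return A tibble (`rin_sasa`) with `time` (ps) and `sasa` (nm^2).
#' @export
sasa_series <- function(ensemble, selection = "backbone", probe_radius = 0.14,
                        n_points = 960, radii = .vdw_radii_nm) {
  if (n_points < 100) abort("`n_points` must be at least 100.")
  idx <- .resolve_selection(ensemble$topology, selection)
  if (length(idx) == 0) abort("Selection is empty.")
  elements <- ensemble$topology$element[idx]
  unknown <- setdiff(unique(elements), names(radii))
  if (length(unknown) > 0) {
    abort(sprintf(
      "No van der Waals radius for element(s): %s.",
      paste(unknown, collapse = ", ")
    ))
  }
  r_ang <- radii[elements] * 10 + probe_radius * 10 # expanded radii, angstrom
  pts <- .sphere_points(n_points)
  vals <- vapply(seq_len(n_frames(ensemble)), function(i) {
    xyz <- frame_coords(ensemble, i)[idx, , drop = FALSE]
    .shrake_rupley(xyz, r_ang, pts) / 100 # A^2 -> nm^2
  }, numeric(1))
  out <- tibble(time = ensemble$times, sasa = vals)
  class(out) <- c("rin_sasa", class(out))
  attr(out, "probe_radius") <- probe_radius
  out
}

# Deterministic golden-spiral unit-sphere lattice.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Total accessible area (squared input units) of spheres with expanded radii
# `r` centred at `xyz`, by point counting.
.shrake_rupley <- function(xyz, r, pts) {
  n <- nrow(xyz)
  total <- 0
  if (n > 1) d2 <- as.matrix(dist(xyz))^2
  for (i in seq_len(n)) {
    surf <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, nrow(pts))
    if (n > 1) {
      nb <- which(d2[i, ] < (r[i] + r)^2)
      nb <- setdiff(nb, i)
      for (j in nb) {
        dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
          (surf[, 3] - xyz[j, 3])^2
        # strictly-inside points are buried; points exactly on a coincident
        # sphere are assigned to the lower-indexed atom (degenerate overlap)
        buried <- dj2 < r[j]^2 - 1e-9 | (abs(dj2 - r[j]^2) <= 1e-9 & j < i)
        acc <- acc & !buried
        if (!any(acc)) break
      }
    }
    total <- total + 4 * pi * r[i]^2 * mean(acc)
  }
  total
}
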