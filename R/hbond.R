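#' Geometric hydrogen-bond criterion
#'
#' Donor-acceptor distance and angular cutoffs, boundary inclusive. The
#' default angle convention (`"hda"`) measures the angle at the donor between
#' the D->H and D->A vectors, the convention the 3.5 A / 30 degree cutoffs
#' originate from; `"dha"` instead bounds the deviation from linearity of the
#' D-H...A angle.
#'
#' @param max_distance Donor-acceptor distance cutoff, angstroms (default 3.5).
#' @param max_angle Angular cutoff, degrees, in (0, 90) (default 30).
#' @param angle_def `"hda"` (angle at donor) or `"dha"` (deviation from
#'   linearity at the hydrogen).
#' @return A list of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_distance = 3.5, max_angle = 30,
                            angle_def = c("hda", "dha")) {
  if (max_distance <= 0) abort("`max_distance` must be positive.")
  if (max_angle <= 0 || max_angle >= 90) abort("`max_angle` must be in (0, 90).")
  structure(
    list(
      max_distance = max_distance, max_angle = max_angle,
      angle_def = match.arg(angle_def)
    ),
    class = "hbond_criterion"
  )
}

.hbond_elements <- c("N", "O", "S")
.dh_covalent_max <- 1.25 # angstrom; H attachment threshold

# Donor-hydrogen pairs present in `coords`: heavy N/O/S atoms of `cand` with
# a same-residue H within covalent range.
.find_donors <- function(model, coords, cand) {
  h_idx <- which(model$element == "H")
  heavy <- cand[model$element[cand] %in% .hbond_elements]
  pairs <- list()
  skipped <- 0L
  for (d in heavy) {
    hs <- h_idx[model$residue_index[h_idx] == model$residue_index[d]]
    if (length(hs) > 0) {
      dd <- sqrt(colSums((t(coords[hs, , drop = FALSE]) - coords[d, ])^2))
      hs <- hs[dd < .dh_covalent_max]
    }
    if (length(hs) == 0) {
      skipped <- skipped + 1L
      next
    }
    pairs[[length(pairs) + 1L]] <- cbind(d, hs)
  }
  list(
    pairs = if (length(pairs)) do.call(rbind, pairs) else matrix(0L, 0, 2),
    skipped = skipped
  )
}

#' Detect hydrogen bonds in one frame
#'
#' A bond is recorded iff the donor-acceptor distance is `<= max_distance`
#' and the criterion angle is `<= max_angle` (ties count). Donors are N/O/S
#' atoms with a covalently attached hydrogen (same residue, D-H < 1.25 A);
#' acceptors are N/O/S atoms. Intra-residue pairs are excluded unless
#' `intra_residue = TRUE`.
#'
#' @param model Atom tibble.
#' @param coords `n_atoms x 3` coordinate matrix; defaults to the model's own
#'   coordinates.
#' @param donors_from,acceptors_from Selections restricting donor and
#'   acceptor atoms (default `"all"`).
#' @param criterion An [hbond_criterion()].
#' @param intra_residue Allow donor and acceptor in the same residue?
#' @return A tibble with one row per (donor, hydrogen, acceptor) triple:
#'   atom indices and serials, residue labels, `da_distance` (A) and `angle`
#'   (degrees).
#' @export
detect_hbonds <- function(model, coords = NULL, donors_from = "all",
                          acceptors_from = "all",
                          criterion = hbond_criterion(),
                          intra_residue = FALSE) {
  if (is.null(coords)) coords <- as.matrix(model[, c("x", "y", "z")])
  if (!any(model$element == "H")) {
    abort("No explicit hydrogens in the model; protonate before H-bond analysis.")
  }
  don_sel <- .resolve_selection(model, donors_from)
  acc_sel <- .resolve_selection(model, acceptors_from)
  acc <- acc_sel[model$element[acc_sel] %in% .hbond_elements]
  fd <- .find_donors(model, coords, don_sel)
  if (fd$skipped > 0 && isTRUE(getOption("rinflow.warn_skipped_donors", FALSE))) {
    warn(sprintf("%d donor candidate(s) had no attached hydrogen; skipped.", fd$skipped))
  }
  rows <- list()
  for (r in seq_len(nrow(fd$pairs))) {
    d <- fd$pairs[r, 1]
    h <- fd$pairs[r, 2]
    a_ok <- acc[acc != d]
    if (!intra_residue) {
      a_ok <- a_ok[model$residue_index[a_ok] != model$residue_index[d]]
    }
    if (length(a_ok) == 0) next
    da <- t(coords[a_ok, , drop = FALSE]) - coords[d, ]
    dist_da <- sqrt(colSums(da^2))
    near <- dist_da <= criterion$max_distance + 1e-9
    if (!any(near)) next
    a_ok <- a_ok[near]
    da <- da[, near, drop = FALSE]
    dist_da <- dist_da[near]
    dh <- coords[h, ] - coords[d, ]
    if (criterion$angle_def == "hda") {
      cosang <- colSums(da * dh) / (dist_da * sqrt(sum(dh^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    } else {
      hd <- coords[d, ] - coords[h, ]
      ha <- t(coords[a_ok, , drop = FALSE]) - coords[h, ]
      cosang <- colSums(ha * hd) / (sqrt(colSums(ha^2)) * sqrt(sum(hd^2)))
      ang <- 180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    }
    pass <- ang <= criterion$max_angle + 1e-9
    if (!any(pass)) next
    a_ok <- a_ok[pass]
    rows[[length(rows) + 1L]] <- tibble(
      donor = d, hydrogen = h, acceptor = a_ok,
      da_distance = dist_da[pass], angle = ang[pass]
    )
  }
  if (length(rows) == 0) {
    out <- tibble(
      donor = integer(), hydrogen = integer(), acceptor = integer(),
      da_distance = numeric(), angle = numeric()
    )
  } else {
    out <- dplyr::bind_rows(rows)
  }
  out$donor_label <- residue_labels(model[out$donor, ])
  out$acceptor_label <- residue_labels(model[out$acceptor, ])
  attr(out, "n_donors_skipped") <- fd$skipped
  out
}

.check_disjoint <- function(a, b) {
  if (length(intersect(a, b)) > 0) {
    abort("Atom groups overlap; H-bond groups must be disjoint.")
  }
}

# Cross-group H-bond records of one frame (donor in either group, acceptor
# in the other).
.cross_hbonds <- function(model, coords, idx_a, idx_b, criterion) {
  ab <- detect_hbonds(model, coords,
    donors_from = idx_a, acceptors_from = idx_b, criterion = criterion
  )
  ba <- detect_hbonds(model, coords,
    donors_from = idx_b, acceptors_from = idx_a, criterion = criterion
  )
  dplyr::distinct(
    dplyr::bind_rows(ab, ba), .data$donor, .data$hydrogen, .data$acceptor,
    .keep_all = TRUE
  )
}

#' Per-frame hydrogen-bond counts between two groups
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param group_a,group_b Disjoint selections (e.g. `"ligand"` and
#'   `"protein"`); bonds are counted in both donor/acceptor directions.
#' @inheritParams detect_hbonds
#' @return A tibble with `time` (ps) and `n_hbonds`.
#' @export
hbond_count_series <- function(ensemble, group_a, group_b,
                               criterion = hbond_criterion()) {
  topo <- ensemble$topology
  idx_a <- .resolve_selection(topo, group_a)
  idx_b <- .resolve_selection(topo, group_b)
  .check_disjoint(idx_a, idx_b)
  counts <- vapply(seq_len(n_frames(ensemble)), function(i) {
    nrow(.cross_hbonds(topo, frame_coords(ensemble, i), idx_a, idx_b, criterion))
  }, numeric(1))
  out <- tibble(time = ensemble$times, n_hbonds = as.integer(counts))
  class(out) <- c("rin_hbond_series", class(out))
  out
}

#' Per-residue hydrogen-bond occupancy
#'
#' For each residue contributing atoms to `group_a`, the fraction of frames
#' in which that residue forms at least one H-bond with `group_b` (either
#' donor/acceptor direction). Residues with zero occupancy are omitted; rows
#' are sorted by descending occupancy.
#'
#' @inheritParams hbond_count_series
#' @return A tibble (`rin_occupancy`) with `residue_index`, `label`,
#'   `occupancy` and `n_frames`.
#' @export
occupancy_table <- function(ensemble, group_a, group_b,
                            criterion = hbond_criterion()) {
  nf <- n_frames(ensemble)
  if (nf == 0) abort("Ensemble has zero frames.")
  topo <- ensemble$topology
  idx_a <- .resolve_selection(topo, group_a)
  idx_b <- .resolve_selection(topo, group_b)
  .check_disjoint(idx_a, idx_b)
  hits <- new.env(parent = emptyenv())
  for (i in seq_len(nf)) {
    hb <- .cross_hbonds(topo, frame_coords(ensemble, i), idx_a, idx_b, criterion)
    if (nrow(hb) == 0) next
    # residue on the group_a side of each bond
    res_a <- ifelse(hb$donor %in% idx_a,
      topo$residue_index[hb$donor], topo$residue_index[hb$acceptor]
    )
    for (rr in unique(res_a)) {
      k <- as.character(rr)
      prev <- if (is.null(hits[[k]])) integer() else hits[[k]]
      hits[[k]] <- union(prev, i)
    }
  }
  res_idx <- as.integer(ls(hits))
  occ <- vapply(as.character(res_idx), function(k) length(hits[[k]]) / nf, numeric(1))
  lab <- vapply(res_idx, function(rr) {
    residue_labels(topo[match(rr, topo$residue_index), ])
  }, character(1))
  out <- tibble(
    residue_index = res_idx, label = lab,
    occupancy = unname(occ), n_frames = nf
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$occupancy), .data$residue_index)
  class(out) <- c("rin_occupancy", class(out))
  out
}
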