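#' Essential dynamics: covariance eigen-decomposition of an ensemble
#'
#' Frames are iteratively superposed onto their mean structure over the
#' selection (removing rigid-body translation and rotation); the sample
#' covariance of the 3M-dimensional coordinate vector is then diagonalised.
#' Eigenvalues are reported in nm^2 (coordinates are converted from
#' angstroms), sorted descending.
#'
#' @param ensemble A [trajectory_ensemble()] with at least 2 frames.
#' @param selection Selection expression, `atom_selection` or indices
#'   (default `"backbone"`).
#' @param fit Superpose frames onto the mean first (default `TRUE`); set
#'   `FALSE` for ensembles that are already aligned (the covariance is then
#'   taken over the raw coordinates).
#' @details The covariance divisor is the frame count (population
#'   convention, as trajectory-analysis tools use), so the projection
#'   variance `sum(p^2)/n` along mode i equals eigenvalue i exactly.
#' @return An object of class `essential_dynamics`: `eigenvalues` (nm^2),
#'   `eigenvectors` (3M x 3M orthonormal, columns), `mean_coordinates`
#'   (M x 3, angstroms), `trace` (nm^2), `selection`, `selection_label`,
#'   `n_frames`.
#' @export
fit_essential_dynamics <- function(ensemble, selection = "backbone", fit = TRUE) {
  if (n_frames(ensemble) < 2) abort("Essential dynamics needs at least 2 frames.")
  idx <- .resolve_selection(ensemble$topology, selection)
  if (length(idx) > n_atoms(ensemble)) abort("Selection exceeds frame atom count.")
  nf <- n_frames(ensemble)
  if (fit) {
    fitted <- superpose_ensemble(ensemble, idx,
      reference = "mean", iterations = 50, tol = 1e-10
    )
    target <- attr(fitted, "mean_coords")[idx, , drop = FALSE]
  } else {
    target <- NULL
  }
  X <- .project_frames_nm(ensemble, idx, target)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / nf
  eig <- eigen(C, symmetric = TRUE)
  structure(
    list(
      eigenvalues = eig$values,
      eigenvectors = eig$vectors,
      mean_coordinates = matrix(mu * 10, ncol = 3, byrow = TRUE),
      fit_target = target,
      center = mu,
      trace = sum(diag(C)),
      selection = idx,
      selection_label = attr(idx, "label") %||% "indices",
      n_frames = nf
    ),
    class = "essential_dynamics"
  )
}

# Flatten each frame's selected atoms to nm, superposing onto `target`
# (angstrom) first when one is given.
.project_frames_nm <- function(ensemble, idx, target) {
  nf <- n_frames(ensemble)
  X <- matrix(NA_real_, nf, 3 * length(idx))
  for (i in seq_len(nf)) {
    fc <- frame_coords(ensemble, i)[idx, , drop = FALSE]
    if (!is.null(target)) {
      fc <- superpose(fc, target, selection = seq_len(nrow(target)))$coords
    }
    X[i, ] <- as.numeric(t(fc)) / 10
  }
  X
}

#' @export
print.essential_dynamics <- function(x, ...) {
  ev <- pmax(x$eigenvalues, 0)
  cat(sprintf(
    "<essential_dynamics> %d modes from %d frames ('%s')\n  total variance %.4g nm^2; PC1 %.1f%%, PC1-2 %.1f%%\n",
    length(ev), x$n_frames, x$selection_label, sum(ev),
    100 * ev[1] / sum(ev), 100 * sum(ev[1:2]) / sum(ev)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.essential_dynamics <- function(x, ...) {
  ev <- x$eigenvalues
  tibble(
    component = seq_along(ev),
    eigenvalue = ev,
    variance_fraction = ev / sum(pmax(ev, 0)),
    cumulative_fraction = cumsum(ev / sum(pmax(ev, 0)))
  )
}

#' @exportS3Method generics::glance
glance.essential_dynamics <- function(x, ...) {
  tibble(
    n_modes = length(x$eigenvalues), n_frames = x$n_frames,
    total_variance = x$trace,
    pc1_fraction = x$eigenvalues[1] / sum(pmax(x$eigenvalues, 0))
  )
}

#' Project an ensemble onto principal modes
#'
#' Frames are superposed onto the model's mean structure, mean-centred and
#' projected onto the first `k` eigenvectors. Projections are in nm; their
#' per-column variance equals the corresponding eigenvalue.
#'
#' @param ensemble A [trajectory_ensemble()] (typically the one the model was
#'   fitted on).
#' @param model An [fit_essential_dynamics()] object.
#' @param k Number of leading modes (default 2).
#' @return A tibble (`projection_series`) with `time` (ps) and columns
#'   `pc1 ... pck` (nm).
#' @export
project_ensemble <- function(ensemble, model, k = 2) {
  if (k < 1) abort("`k` must be at least 1.")
  if (k > ncol(model$eigenvectors)) abort("`k` exceeds the number of modes.")
  idx <- model$selection
  X <- .project_frames_nm(ensemble, idx, model$fit_target)
  P <- sweep(X, 2, model$center) %*% model$eigenvectors[, seq_len(k), drop = FALSE]
  out <- as_tibble(setNames(as.data.frame(P), paste0("pc", seq_len(k))))
  out <- dplyr::bind_cols(tibble(time = ensemble$times), out)
  class(out) <- c("projection_series", class(out))
  attr(out, "eigenvalues") <- model$eigenvalues[seq_len(k)]
  out
}

#' Cosine content of a principal-component projection
#'
#' Overlap of the projection time series with a half-cosine,
#' `c_i = (2/T) (integral cos(i pi t / T) p(t) dt)^2 / integral p(t)^2 dt`,
#' evaluated by trapezoidal quadrature on the frame time grid. Values near 1
#' indicate random-diffusion-like sampling; only components with low cosine
#' content define a meaningful free-energy landscape.
#'
#' @param series A [project_ensemble()] result with at least 4 frames.
#' @param i Component index (the cosine frequency is `i pi / T`).
#' @return A fraction in `[0, 1]`.
#' @export
cosine_content <- function(series, i = 1) {
  col <- paste0("pc", i)
  if (!col %in% names(series)) abort(sprintf("Series has no column '%s'.", col))
  if (nrow(series) < 4) abort("Cosine content needs at least 4 frames.")
  p <- series[[col]]
  t <- series$time - series$time[1]
  T_ <- t[length(t)]
  denom <- pracma::trapz(t, p^2)
  if (denom <= 0) {
    warn("All-zero projection; cosine content defined as 0.")
    return(0)
  }
  num <- pracma::trapz(t, cos(i * pi * t / T_) * p)
  max(0, min(1, (2 / T_) * num^2 / denom))
}

#' Free-energy landscape over two principal components
#'
#' 2-D histogram of the projections on a principal-component pair, converted
#' to relative free energies by Boltzmann inversion:
#' `deltaG(bin) = -kB T ln(count / count_max)` (kJ/mol, kB = 0.0083145
#' kJ/mol/K), so the most populated bin sits at deltaG = 0 and empty bins
#' are masked (`NA`). Both components must have cosine content below
#' `cosine_threshold` unless `force = TRUE`.
#'
#' @param series A [project_ensemble()] result.
#' @param pc_pair Indices of the two components (default `c(1, 2)`).
#' @param n_bins Bins per axis (default 32, minimum 4).
#' @param temperature Kelvin (default 300).
#' @param cosine_threshold Admissibility bound on cosine content (default 0.2).
#' @param force Skip the admissibility check?
#' @return An object of class `free_energy_surface`: bin edges per axis,
#'   `counts` and `delta_g` matrices, `pc_pair`, `temperature`, `n_frames`.
#' @export
free_energy_surface <- function(series, pc_pair = c(1, 2), n_bins = 32,
                                temperature = 300, cosine_threshold = 0.2,
                                force = FALSE) {
  if (n_bins < 4) abort("`n_bins` must be at least 4.")
  stopifnot(length(pc_pair) == 2)
  cols <- paste0("pc", pc_pair)
  if (!all(cols %in% names(series))) {
    abort(sprintf("Series lacks columns %s.", paste(cols, collapse = ", ")))
  }
  if (!force) {
    cc <- vapply(pc_pair, function(i) cosine_content(series, i), numeric(1))
    if (any(cc > cosine_threshold)) {
      abort(sprintf(
        "Cosine content (%.3f, %.3f) exceeds %.2f; the landscape is not converged. Use `force = TRUE` to override.",
        cc[1], cc[2], cosine_threshold
      ))
    }
  }
  x <- series[[cols[1]]]
  y <- series[[cols[2]]]
  ex <- .fel_edges(x, n_bins)
  ey <- .fel_edges(y, n_bins)
  ix <- findInterval(x, ex, rightmost.closed = TRUE)
  iy <- findInterval(y, ey, rightmost.closed = TRUE)
  counts <- matrix(0L, n_bins, n_bins)
  for (f in seq_along(ix)) counts[ix[f], iy[f]] <- counts[ix[f], iy[f]] + 1L
  dg <- -.kB * temperature * log(counts / max(counts))
  dg[counts == 0L] <- NA_real_
  structure(
    list(
      pc_pair = pc_pair, edges_x = ex, edges_y = ey,
      counts = counts, delta_g = dg,
      temperature = temperature, n_frames = length(ix)
    ),
    class = "free_energy_surface"
  )
}

.fel_edges <- function(v, n_bins) {
  lo <- min(v)
  hi <- max(v)
  w <- if (hi > lo) (hi - lo) / (n_bins - 1) else 1
  seq(lo - w / 2, hi + w / 2, length.out = n_bins + 1)
}

#' @export
print.free_energy_surface <- function(x, ...) {
  cat(sprintf(
    "<free_energy_surface> PC%d x PC%d, %d x %d bins, %d frames, T = %g K\n  deltaG range 0..%.3f kJ/mol over %d populated bins\n",
    x$pc_pair[1], x$pc_pair[2], nrow(x$counts), ncol(x$counts), x$n_frames,
    x$temperature, max(x$delta_g, na.rm = TRUE), sum(x$counts > 0)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.free_energy_surface <- function(x, ...) {
  cx <- (head(x$edges_x, -1) + tail(x$edges_x, -1)) / 2
  cy <- (head(x$edges_y, -1) + tail(x$edges_y, -1)) / 2
  grid <- tidyr::expand_grid(ix = seq_along(cx), iy = seq_along(cy))
  tibble(
    pc_a = cx[grid$ix], pc_b = cy[grid$iy],
    count = x$counts[cbind(grid$ix, grid$iy)],
    delta_g = x$delta_g[cbind(grid$ix, grid$iy)]
  )
}

#' @exportS3Method generics::glance
glance.free_energy_surface <- function(x, ...) {
  tibble(
    n_frames = x$n_frames, n_bins = nrow(x$counts),
    populated_bins = sum(x$counts > 0), temperature = x$temperature,
    max_delta_g = max(x$delta_g, na.rm = TRUE)
  )
}

#' Frames in the free-energy minimum basin
#'
#' Indices of the frames falling in the deltaG = 0 bin (the most populated
#' bin; ties resolved to the first bin in column-major order), ordered by
#' time.
#'
#' @param surface A [free_energy_surface()].
#' @param series The [project_ensemble()] result the surface was built from.
#' @return Integer frame indices.
#' @export
locate_minimum_frames <- function(surface, series) {
  cols <- paste0("pc", surface$pc_pair)
  x <- series[[cols[1]]]
  y <- series[[cols[2]]]
  if (length(x) != surface$n_frames) {
    abort("Surface and series are not from the same ensemble.")
  }
  ix <- findInterval(x, surface$edges_x, rightmost.closed = TRUE)
  iy <- findInterval(y, surface$edges_y, rightmost.closed = TRUE)
  best <- which(surface$counts == max(surface$counts))[1]
  bi <- (best - 1) %% nrow(surface$counts) + 1
  bj <- (best - 1) %/% nrow(surface$counts) + 1
  frames <- which(ix == bi & iy == bj)
  frames[order(series$time[frames])]
}
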