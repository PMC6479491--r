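#' Specification for a synthetic peptide ensemble
#'
#' Describes a generated ensemble with known, parameterised properties: an
#' idealised extended backbone (bond lengths N-CA 1.46, CA-C 1.52, C-O 1.23,
#' C-N 1.33 angstroms) decorated with an amide hydrogen and a C-beta per
#' residue, plus (a) per-residue isotropic Gaussian positional noise, (b)
#' designed hydrogen-bond pairs hitting an exact target occupancy, and (c) an
#' optional dominant collective mode so one covariance eigenvector carries a
#' controlled fraction of the variance.
#'
#' @param n_residues Number of residues (>= 2).
#' @param n_frames Number of frames (>= 2).
#' @param fluctuation Per-residue Gaussian noise standard deviation per
#'   coordinate, angstroms; scalar or length-`n_residues` vector. A residue
#'   with noise sigma has expected RMSF `sigma * sqrt(3)`.
#' @param hbond_pairs List of `list(donor =, acceptor =, occupancy =)`
#'   entries (residue numbers, occupancy in `[0, 1]`). Donor/H/acceptor atoms
#'   are placed on-axis inside the 3.5 A / 30 degree criterion in exactly
#'   `round(occupancy * n_frames)` frames and beyond 4.5 A otherwise, so
#'   occupancy recovery is exact.
#' @param collective_mode `NULL`, or a list with `amplitude` (angstroms) or
#'   `variance_fraction` (target fraction of total positional variance) and
#'   optionally `direction` (an `n_atoms x 3` matrix; default: a
#'   Gaussian-enveloped z-displacement centred mid-chain, zero net
#'   translation). Per-frame mode coefficients are drawn i.i.d. Gaussian
#'   (not sinusoidal), keeping the cosine content of the leading projection
#'   low.
#' @param seed Integer RNG seed; generation is deterministic given the seed.
#' @return A list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_residues, n_frames, fluctuation = 0,
                          hbond_pairs = list(), collective_mode = NULL,
                          seed = 1) {
  stopifnot(n_residues >= 2, n_frames >= 2)
  if (length(fluctuation) == 1) fluctuation <- rep(fluctuation, n_residues)
  if (length(fluctuation) != n_residues || any(fluctuation < 0)) {
    abort("`fluctuation` must be a non-negative scalar or per-residue vector.")
  }
  for (p in hbond_pairs) {
    if (!all(c("donor", "acceptor", "occupancy") %in% names(p))) {
      abort("Each hbond pair needs `donor`, `acceptor`, `occupancy`.")
    }
    if (p$occupancy < 0 || p$occupancy > 1) abort("Occupancy must be in [0, 1].")
    if (p$donor == p$acceptor) abort("Donor and acceptor residues must differ.")
    if (p$donor > n_residues || p$acceptor > n_residues) {
      abort("hbond pair residue out of range.")
    }
  }
  structure(
    list(
      n_residues = n_residues, n_frames = n_frames,
      fluctuation = fluctuation, hbond_pairs = hbond_pairs,
      collective_mode = collective_mode, seed = as.integer(seed)
    ),
    class = "ensemble_spec"
  )
}

# Idealised extended-chain topology: per residue N, H, CA, CB, C, O. The
# chain zig-zags in z so that C-alpha atoms are never collinear (rigid-body
# fits over the C-alpha selection stay well-posed).
.chain_topology <- function(n_residues) {
  pitch <- 1.46 + 1.52 + 1.33
  per <- lapply(seq_len(n_residues) - 1L, function(i) {
    x0 <- i * pitch
    tibble(
      name = c("N", "H", "CA", "CB", "C", "O"),
      element = c("N", "H", "C", "C", "C", "O"),
      residue_index = i,
      residue_name = "ALA",
      chain = "A",
      resseq = i + 1L,
      het = FALSE,
      x = x0 + c(0, 0, 1.46, 1.46, 2.98, 2.98),
      y = c(0, -1.0, 0, -1.5, 0, 1.23),
      z = 0.7 * (i %% 2)
    )
  })
  out <- dplyr::bind_rows(per)
  out$serial <- seq_len(nrow(out))
  .atom_tibble(out)
}

# Default collective-mode direction: Gaussian-enveloped z-displacement over
# the chain, zero net translation, unit 3N-norm.
.default_mode_direction <- function(topo) {
  n_res <- max(topo$residue_index) + 1
  w <- exp(-0.5 * ((topo$residue_index - (n_res - 1) / 2) / (n_res / 4))^2)
  D <- cbind(0, 0, w - mean(w))
  D / sqrt(sum(D^2))
}

#' Generate a synthetic peptide ensemble
#'
#' @param spec An [ensemble_spec()].
#' @return A [trajectory_ensemble()] (frames 1 ps apart). The realised
#'   per-frame mode coefficients, mode direction, and the bonded-frame set of
#'   each designed H-bond pair are attached as attribute `"design"`.
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  topo <- .chain_topology(spec$n_residues)
  base <- as.matrix(topo[, c("x", "y", "z")])
  if (min(dist(base)) < 0.5) {
    abort("Infeasible base geometry: atoms overlap by < 0.5 angstroms.")
  }
  na <- nrow(topo)
  nf <- spec$n_frames
  set.seed(spec$seed)
  sigma <- spec$fluctuation[topo$residue_index + 1]
  coords <- array(NA_real_, dim = c(nf, na, 3))
  noise <- array(rnorm(nf * na * 3), dim = c(nf, na, 3)) *
    array(rep(sigma, each = nf), dim = c(nf, na, 3))
  design <- list()
  mode_coef <- NULL
  D <- NULL
  if (!is.null(spec$collective_mode)) {
    cm <- spec$collective_mode
    D <- cm$direction %||% .default_mode_direction(topo)
    D <- D / sqrt(sum(D^2))
    A <- cm$amplitude
    if (is.null(A)) {
      f <- cm$variance_fraction
      if (is.null(f) || f <= 0 || f >= 1) {
        abort("collective_mode needs `amplitude` or `variance_fraction` in (0,1).")
      }
      A <- sqrt(f / (1 - f) * sum(3 * sigma^2))
    }
    mode_coef <- rnorm(nf, 0, A)
  }
  for (i in seq_len(nf)) {
    fc <- base + noise[i, , ]
    if (!is.null(D)) fc <- fc + mode_coef[i] * D
    coords[i, , ] <- fc
  }
  # designed hydrogen-bond pairs: absolute anchor placement overrides noise
  # and mode for the three atoms involved, guaranteeing exact occupancy
  bonded_sets <- list()
  for (j in seq_along(spec$hbond_pairs)) {
    p <- spec$hbond_pairs[[j]]
    anchor <- c(10 * (j - 1), -15, 0)
    don_n <- which(topo$resseq == p$donor & topo$name == "N")
    don_h <- which(topo$resseq == p$donor & topo$name == "H")
    acc_o <- which(topo$resseq == p$acceptor & topo$name == "O")
    m <- round(p$occupancy * nf)
    bonded <- sort(sample(nf, m))
    for (i in seq_len(nf)) {
      coords[i, don_n, ] <- anchor
      coords[i, don_h, ] <- anchor + c(1.0, 0, 0)
      coords[i, acc_o, ] <- anchor +
        if (i %in% bonded) c(2.9, 0, 0) else c(5.5, 0, 0)
    }
    bonded_sets[[j]] <- bonded
  }
  out <- trajectory_ensemble(topo, coords, times = seq_len(nf) - 1)
  attr(out, "design") <- list(
    mode_direction = D, mode_coefficients = mode_coef,
    bonded_frames = bonded_sets
  )
  out
}

#' Generate a two-cluster structure bridged by a single hub residue
#'
#' Two spatially compact residue clusters whose members are all within
#' contact range (< 7 angstroms, pairwise) of each other but beyond contact
#' range of the other cluster, joined only through one central hub residue.
#' In the residue interaction network built at the 7 A cutoff the hub is the
#' unique articulation node and attains the maximal betweenness centrality.
#'
#' @param n_per_cluster Residues per cluster (>= 3).
#' @param seed Integer RNG seed.
#' @return An atom tibble (glycine residues: N, CA, C, O). The hub is the
#'   first residue (`resseq 1`); cluster members follow. The hub/cluster
#'   residue indices are attached as attribute `"design"`.
#' @export
generate_hub_structure <- function(n_per_cluster, seed = 1) {
  if (n_per_cluster < 3) abort("`n_per_cluster` must be at least 3.")
  set.seed(seed)
  centers <- list(a = c(-8.5, 0, 0), b = c(8.5, 0, 0))
  # two bridge members per cluster face the hub, so only the hub (never a
  # single bridge residue) is a cut vertex of the contact graph
  place <- function(center, toward_hub) {
    pos <- list(
      center + toward_hub * 3.3 + rnorm(3, 0, 0.1),
      center + toward_hub * 3.3 + c(0, 1.2, 0) + rnorm(3, 0, 0.1)
    )
    for (i in seq_len(n_per_cluster - 2)) {
      v <- rnorm(3)
      pos[[i + 2]] <- center + v / sqrt(sum(v^2)) * runif(1, 0, 1.8)
    }
    pos
  }
  ca <- c(
    list(c(0, 0, 0)), # hub
    place(centers$a, c(1, 0, 0)),
    place(centers$b, c(-1, 0, 0))
  )
  n_res <- length(ca)
  per <- lapply(seq_len(n_res), function(i) {
    p <- ca[[i]]
    tibble(
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      residue_index = i - 1L, residue_name = "GLY", chain = "A",
      resseq = i, het = FALSE,
      x = p[1] + c(-0.8, 0, 0.8, 0.8),
      y = p[2] + c(0, 0, 0, 0.9),
      z = p[3]
    )
  })
  out <- dplyr::bind_rows(per)
  out$serial <- seq_len(nrow(out))
  out <- .atom_tibble(out)
  attr(out, "design") <- list(
    hub = 1L,
    cluster_a = 1L + seq_len(n_per_cluster),
    cluster_b = 1L + n_per_cluster + seq_len(n_per_cluster)
  )
  out
}

#' Generate a noisy per-frame energy series with a designed minimum
#'
#' @param n_frames Number of frames.
#' @param minimum_at 1-based frame index of the unique global minimum, which
#'   is at least 1 energy unit below every other frame.
#' @param seed Integer RNG seed.
#' @param stride Frame spacing, ps.
#' @return A tibble (`energy_profile`) with `time` (ps) and `energy` (kJ/mol).
#' @export
generate_energy_series <- function(n_frames, minimum_at, seed = 1, stride = 1) {
  if (minimum_at < 1 || minimum_at > n_frames) {
    abort("`minimum_at` must be a valid frame index.")
  }
  set.seed(seed)
  e <- rnorm(n_frames, mean = 100, sd = 5)
  e[minimum_at] <- min(e[-minimum_at]) - runif(1, 1, 2)
  out <- tibble(time = (seq_len(n_frames) - 1) * stride, energy = e)
  class(out) <- c("energy_profile", class(out))
  out
}

#' Read a per-frame energy series from two-column text
#'
#' Whitespace-separated `time energy` rows; `#` and `@` comment lines are
#' tolerated (xvg-compatible).
#'
#' @param path Input file path.
#' @return A tibble (`energy_profile`) with `time` and `energy`.
#' @export
read_energy_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*[#@]", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("No data rows in '%s'.", path))
  mat <- do.call(rbind, lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(v) < 2 || anyNA(v[1:2])) {
      abort(sprintf("Malformed energy row at data line %d of '%s'.", i, path))
    }
    v[1:2]
  }))
  out <- tibble(time = mat[, 1], energy = mat[, 2])
  class(out) <- c("energy_profile", class(out))
  out
}

#' Write a per-frame energy series as two-column text
#'
#' @param profile A tibble with `time` and `energy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_energy_profile <- function(profile, path) {
  writeLines(c(
    "# time_ps energy_kJ_mol",
    sprintf("%.6g %.10g", profile$time, profile$energy)
  ), path)
  invisible(path)
}
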