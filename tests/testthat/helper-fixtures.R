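# Fixture builders and independent oracles shared across the suite.

# ---- atom tibble / PDB fixtures -------------------------------------------

make_atoms <- function(name, element, resseq, x, y, z,
                       residue_name = "ALA", chain = "A", het = FALSE) {
  n <- length(name)
  residue_name <- rep_len(residue_name, n)
  het <- rep_len(het, n)
  tibble::tibble(
    serial = seq_len(n), name = name, element = element,
    residue_index = as.integer(factor(resseq, levels = unique(resseq))) - 1L,
    residue_name = residue_name, chain = rep_len(chain, n),
    resseq = as.integer(resseq), het = het,
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
}

pdb_line <- function(serial, name, resname, chain, resseq, x, y, z,
                     type = "ATOM", occ = 1.0, alt = "", element = NULL) {
  if (is.null(element)) element <- substr(gsub("[^A-Za-z]", "", name), 1, 1)
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    type, serial, name4, alt, resname, chain, resseq, x, y, z, occ, 0, element
  )
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# A glycine-only tripeptide with explicit backbone atoms (N, CA, C, O).
gly_tripeptide <- function() {
  rows <- list()
  for (i in 0:2) {
    x0 <- i * 4
    rows[[i + 1]] <- tibble::tibble(
      name = c("N", "CA", "C", "O"), element = c("N", "C", "C", "O"),
      resseq = i + 1L,
      x = x0 + c(0, 1.4, 2.9, 2.9), y = c(0, 0, 0, 1.2), z = 0
    )
  }
  df <- dplyr::bind_rows(rows)
  make_atoms(df$name, df$element, df$resseq, df$x, df$y, df$z,
    residue_name = "GLY"
  )
}

# Ensemble from an explicit list of coordinate matrices over a topology.
ens_from_frames <- function(topology, frames, times = NULL) {
  trajectory_ensemble(topology, frames, times = times)
}

# ---- graph fixtures and shortest-path oracles -----------------------------

# A `rin` object from an abstract edge list (for centrality tests).
rin_from_edges <- function(n, edges, hbond_count = NULL) {
  nodes <- tibble::tibble(
    node = seq_len(n), label = paste0("G", seq_len(n)), chain = "A",
    residue_index = seq_len(n) - 1L,
    bb_x = seq_len(n), bb_y = 0, bb_z = 0,
    sc_x = NA_real_, sc_y = NA_real_, sc_z = NA_real_
  )
  ed <- if (is.null(edges) || nrow(edges) == 0) {
    tibble::tibble(
      from = integer(), to = integer(), distance = numeric(),
      contact_types = character(), hbond_count = integer()
    )
  } else {
    tibble::tibble(
      from = as.integer(pmin(edges[, 1], edges[, 2])),
      to = as.integer(pmax(edges[, 1], edges[, 2])),
      distance = 1, contact_types = "bb-bb",
      hbond_count = if (is.null(hbond_count)) 0L else as.integer(hbond_count)
    )
  }
  structure(list(nodes = nodes, edges = ed, n_nodes = n), class = "rin")
}

random_graph_edges <- function(n, p) {
  pairs <- t(utils::combn(n, 2))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

adj_matrix <- function(n, edges) {
  A <- matrix(FALSE, n, n)
  if (nrow(edges) > 0) {
    A[edges] <- TRUE
    A[edges[, 2:1, drop = FALSE]] <- TRUE
  }
  A
}

# BFS distances and shortest-path counts from one source (path-counting DP,
# independent of the Brandes accumulation being tested).
bfs_sigma <- function(A, s) {
  n <- nrow(A)
  d <- rep(Inf, n)
  sigma <- numeric(n)
  d[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(A[v, ])) {
        if (is.infinite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- union(nxt, w)
        }
        if (d[w] == d[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- nxt
  }
  list(d = d, sigma = sigma)
}

# Brute-force normalised betweenness: enumerate every (s, t) pair and count
# shortest paths through k via the sigma product identity.
brute_betweenness <- function(A) {
  n <- nrow(A)
  bs <- lapply(seq_len(n), function(s) bfs_sigma(A, s))
  cb <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (is.infinite(bs[[s]]$d[t])) next
      for (k in seq_len(n)) {
        if (k == s || k == t) next
        if (bs[[s]]$d[k] + bs[[k]]$d[t] == bs[[s]]$d[t]) {
          cb[k] <- cb[k] +
            bs[[s]]$sigma[k] * bs[[k]]$sigma[t] / bs[[s]]$sigma[t]
        }
      }
    }
  }
  cb * 2 / ((n - 1) * (n - 2))
}

# Brute-force closeness with the same component-scaled convention.
brute_closeness <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(k) {
    d <- bfs_sigma(A, k)$d
    reach <- which(is.finite(d) & seq_len(n) != k)
    if (length(reach) == 0) {
      return(0)
    }
    r <- length(reach) + 1
    (sum(d[reach]) / (r - 1))^-1 * (r - 1) / (n - 1)
  }, numeric(1))
}

# Articulation nodes by brute force: removing the node increases the number
# of connected components among the remainder.
brute_articulation <- function(A) {
  n <- nrow(A)
  n_comp <- function(M) {
    m <- nrow(M)
    if (m == 0) {
      return(0)
    }
    seen <- rep(FALSE, m)
    comps <- 0
    for (s in seq_len(m)) {
      if (seen[s]) next
      comps <- comps + 1
      frontier <- s
      seen[s] <- TRUE
      while (length(frontier) > 0) {
        nxt <- integer(0)
        for (v in frontier) {
          for (w in which(M[v, ])) {
            if (!seen[w]) {
              seen[w] <- TRUE
              nxt <- c(nxt, w)
            }
          }
        }
        frontier <- nxt
      }
    }
    comps
  }
  base <- n_comp(A)
  which(vapply(seq_len(n), function(k) {
    n_comp(A[-k, -k, drop = FALSE]) > base
  }, logical(1)))
}

# Numerical rigid-fit RMSD oracle: direct minimisation over rotations
# (Euler angles) and translations, independent of the SVD solution.
oracle_fit_rmsd <- function(mobile, reference) {
  rot <- function(a) {
    Rx <- matrix(c(1, 0, 0, 0, cos(a[1]), sin(a[1]), 0, -sin(a[1]), cos(a[1])), 3)
    Ry <- matrix(c(cos(a[2]), 0, -sin(a[2]), 0, 1, 0, sin(a[2]), 0, cos(a[2])), 3)
    Rz <- matrix(c(cos(a[3]), sin(a[3]), 0, -sin(a[3]), cos(a[3]), 0, 0, 0, 1), 3)
    Rz %*% Ry %*% Rx
  }
  obj <- function(par) {
    R <- rot(par[1:3])
    moved <- sweep(mobile %*% t(R), 2, par[4:6], `+`)
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(0.5, -0.3, 0.2, 0, 0, 0), c(2, 1, -1, 1, -1, 0))) {
    o <- stats::optim(start, obj, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}
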