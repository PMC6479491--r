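#' Build a weighted residue interaction network
#'
#' Nodes are amino-acid residues, each carrying two coarse-grained centers:
#' the C-alpha position (backbone) and the side-chain heavy atom farthest
#' from the C-alpha (absent for glycine; C-beta for alanine). An edge is
#' placed between two residues iff any of the (up to four) center-pair
#' distances is strictly below `cutoff`; its weight is the number of distinct
#' hydrogen bonds between the two residues in this structure (0 allowed, and
#' 0 throughout when the model carries no explicit hydrogens).
#'
#' @param model Atom tibble (typically the minimum-energy representative).
#' @param cutoff Contact distance cutoff, angstroms (default 7, strict `<`).
#' @param criterion [hbond_criterion()] used for the edge weights.
#' @param exclude_neighbors Drop edges between residues within this sequence
#'   separation on the same chain (default 0 = keep all).
#' @param include_ligand Add each non-water HETATM group as one extra node
#'   (centers: heavy-atom centroid and the heavy atom farthest from it)?
#' @return An object of class `rin`: `nodes` tibble (`node`, `label`,
#'   `chain`, `residue_index`, centers), `edges` tibble (`from`, `to`,
#'   `distance`, `contact_types`, `hbond_count`) and `n_nodes`.
#' @export
build_rin <- function(model, cutoff = 7.0, criterion = hbond_criterion(),
                      exclude_neighbors = 0, include_ligand = FALSE) {
  if (cutoff <= 0) abort("`cutoff` must be positive.")
  prot <- model[model$residue_name %in% .standard_aa & !model$het, ]
  res_ids <- unique(prot$residue_index)
  bb_names <- .default_backbone
  nodes <- list()
  for (rr in res_ids) {
    atoms <- prot[prot$residue_index == rr, ]
    ca <- atoms[atoms$name == "CA", ]
    if (nrow(ca) == 0) {
      warn(sprintf(
        "Residue %s lacks a C-alpha; excluded from the network.",
        residue_labels(atoms[1, ])
      ))
      next
    }
    ca_xyz <- as.numeric(ca[1, c("x", "y", "z")])
    sc <- atoms[!(atoms$name %in% bb_names) & atoms$element != "H", ]
    sc_xyz <- if (nrow(sc) == 0) {
      c(NA_real_, NA_real_, NA_real_)
    } else {
      d <- (sc$x - ca_xyz[1])^2 + (sc$y - ca_xyz[2])^2 + (sc$z - ca_xyz[3])^2
      as.numeric(sc[which.max(d), c("x", "y", "z")])
    }
    nodes[[length(nodes) + 1L]] <- tibble(
      residue_index = rr, label = residue_labels(ca[1, ]),
      chain = ca$chain[1],
      bb_x = ca_xyz[1], bb_y = ca_xyz[2], bb_z = ca_xyz[3],
      sc_x = sc_xyz[1], sc_y = sc_xyz[2], sc_z = sc_xyz[3]
    )
  }
  nodes <- dplyr::bind_rows(nodes)
  if (include_ligand) {
    lig <- model[model$het & !(model$residue_name %in% .water_res), ]
    for (rr in unique(lig$residue_index)) {
      atoms <- lig[lig$residue_index == rr & lig$element != "H", ]
      if (nrow(atoms) == 0) next
      cen <- colMeans(as.matrix(atoms[, c("x", "y", "z")]))
      d <- (atoms$x - cen[1])^2 + (atoms$y - cen[2])^2 + (atoms$z - cen[3])^2
      far <- as.numeric(atoms[which.max(d), c("x", "y", "z")])
      nodes <- dplyr::bind_rows(nodes, tibble(
        residue_index = rr,
        label = paste0(atoms$residue_name[1], atoms$resseq[1]),
        chain = atoms$chain[1],
        bb_x = cen[1], bb_y = cen[2], bb_z = cen[3],
        sc_x = far[1], sc_y = far[2], sc_z = far[3]
      ))
    }
  }
  n <- nrow(nodes)
  if (n < 3) abort("Network needs at least 3 residue nodes.")
  nodes$node <- seq_len(n)
  nodes <- nodes[, c(
    "node", "label", "chain", "residue_index",
    "bb_x", "bb_y", "bb_z", "sc_x", "sc_y", "sc_z"
  )]

  hb_counts <- .residue_hbond_counts(model, criterion)
  BB <- as.matrix(nodes[, c("bb_x", "bb_y", "bb_z")])
  SC <- as.matrix(nodes[, c("sc_x", "sc_y", "sc_z")])
  pair_d <- function(A, B) {
    out <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
    sqrt(pmax(out, 0))
  }
  d_bb <- pair_d(BB, BB)
  d_bs <- pair_d(BB, SC)
  d_ss <- pair_d(SC, SC)
  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (exclude_neighbors > 0 &&
        nodes$chain[i] == nodes$chain[j] &&
        abs(nodes$residue_index[i] - nodes$residue_index[j]) <= exclude_neighbors) {
        next
      }
      dists <- c(
        "bb-bb" = d_bb[i, j], "bb-sc" = d_bs[i, j],
        "sc-bb" = d_bs[j, i], "sc-sc" = d_ss[i, j]
      )
      hit <- !is.na(dists) & dists < cutoff
      if (!any(hit)) next
      types <- unique(sub("sc-bb", "bb-sc", names(dists)[hit]))
      key <- paste(
        sort(c(nodes$residue_index[i], nodes$residue_index[j])),
        collapse = "_"
      )
      edges[[length(edges) + 1L]] <- tibble(
        from = i, to = j,
        distance = min(dists[hit]),
        contact_types = paste(sort(types), collapse = ","),
        hbond_count = hb_counts[[key]] %||% 0L
      )
    }
  }
  edges <- if (length(edges)) dplyr::bind_rows(edges) else tibble(
    from = integer(), to = integer(), distance = numeric(),
    contact_types = character(), hbond_count = integer()
  )
  structure(list(nodes = nodes, edges = edges, n_nodes = n), class = "rin")
}

# Distinct H-bond count per unordered residue pair, keyed "i_j" by sorted
# residue_index.
.residue_hbond_counts <- function(model, criterion) {
  out <- list()
  if (!any(model$element == "H")) return(out)
  hb <- detect_hbonds(model, criterion = criterion)
  if (nrow(hb) == 0) return(out)
  ri <- model$residue_index
  for (r in seq_len(nrow(hb))) {
    key <- paste(sort(c(ri[hb$donor[r]], ri[hb$acceptor[r]])), collapse = "_")
    out[[key]] <- (out[[key]] %||% 0L) + 1L
  }
  out
}

#' @export
print.rin <- function(x, ...) {
  cat(sprintf(
    "<rin> %d residue nodes, %d contact edges (%d with H-bond weight > 0)\n",
    x$n_nodes, nrow(x$edges), sum(x$edges$hbond_count > 0)
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rin <- function(x, ...) {
  dplyr::mutate(x$edges,
    label_from = x$nodes$label[.data$from],
    label_to = x$nodes$label[.data$to]
  )
}

# Adjacency list with edge lengths. Unit lengths by default; the
# "inverse-hbond" mode uses 1 / (1 + hbond_count) so H-bond-rich contacts
# are shorter.
.rin_adjacency <- function(net, weights = c("unit", "inverse-hbond")) {
  weights <- match.arg(weights)
  n <- net$n_nodes
  adj <- vector("list", n)
  wts <- vector("list", n)
  len <- if (weights == "unit") {
    rep(1, nrow(net$edges))
  } else {
    1 / (1 + net$edges$hbond_count)
  }
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$from[r]
    j <- net$edges$to[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
    wts[[i]] <- c(wts[[i]], len[r])
    wts[[j]] <- c(wts[[j]], len[r])
  }
  list(adj = adj, wts = wts, n = n)
}

# Single-source shortest-path distances (Dijkstra; equals BFS on unit
# lengths). O(V^2), fine at residue-network size.
.dijkstra <- function(g, s) {
  d <- rep(Inf, g$n)
  d[s] <- 0
  done <- rep(FALSE, g$n)
  repeat {
    u <- which(!done & is.finite(d))
    if (length(u) == 0) break
    u <- u[which.min(d[u])]
    done[u] <- TRUE
    nb <- g$adj[[u]]
    if (length(nb) > 0) {
      nd <- d[u] + g$wts[[u]]
      upd <- nd < d[nb]
      d[nb[upd]] <- nd[upd]
    }
  }
  d
}

#' Degree centrality
#'
#' Raw degree (contact count) per node plus the `degree / (N - 1)`
#' normalised variant.
#'
#' @param net A [build_rin()] network (or any `rin` object).
#' @return A tibble with `node`, `label`, `degree`, `degree_norm`.
#' @export
degree_centrality <- function(net) {
  deg <- tabulate(c(net$edges$from, net$edges$to), nbins = net$n_nodes)
  tibble(
    node = net$nodes$node, label = net$nodes$label,
    degree = as.integer(deg), degree_norm = deg / (net$n_nodes - 1)
  )
}

#' Closeness centrality
#'
#' `C_C(k) = ((sum_i d(i, k)) / (N - 1))^-1` with shortest-path distances
#' `d` computed by Dijkstra's algorithm (unit edge lengths by default, so
#' `d` is the minimum number of edges). On disconnected graphs the sum runs
#' over the node's component and the value is scaled by
#' `(reachable - 1) / (N - 1)`; isolated nodes get 0 with a warning. On a
#' connected graph this is exactly the textbook definition.
#'
#' @inheritParams degree_centrality
#' @param weights `"unit"` (default) or `"inverse-hbond"` (edge length
#'   `1 / (1 + hbond_count)`), a sensitivity mode.
#' @return A tibble with `node`, `label`, `closeness`.
#' @export
closeness_centrality <- function(net, weights = c("unit", "inverse-hbond")) {
  g <- .rin_adjacency(net, weights)
  n <- g$n
  if (n < 2) abort("Closeness needs at least 2 nodes.")
  vals <- numeric(n)
  singleton <- FALSE
  for (k in seq_len(n)) {
    d <- .dijkstra(g, k)
    reach <- which(is.finite(d) & seq_len(n) != k)
    if (length(reach) == 0) {
      singleton <- TRUE
      vals[k] <- 0
      next
    }
    r <- length(reach) + 1
    vals[k] <- ((sum(d[reach])) / (r - 1))^-1 * (r - 1) / (n - 1)
  }
  if (singleton) warn("Isolated node(s): closeness reported as 0.")
  tibble(node = net$nodes$node, label = net$nodes$label, closeness = vals)
}

#' Betweenness centrality (Brandes' algorithm)
#'
#' `C_B(k) = [2 / ((N - 1)(N - 2))] * sum_{s < t, s != k != t}
#' sigma_st(k) / sigma_st`, where `sigma_st` counts shortest paths between
#' `s` and `t` and `sigma_st(k)` those passing through `k` (endpoints
#' excluded). Computed by Brandes' single-source dependency accumulation;
#' values lie in `[0, 1]`.
#'
#' @inheritParams closeness_centrality
#' @return A tibble with `node`, `label`, `betweenness`.
#' @export
betweenness_centrality <- function(net, weights = c("unit", "inverse-hbond")) {
  weights <- match.arg(weights)
  g <- .rin_adjacency(net, weights)
  n <- g$n
  if (n < 3) abort("Betweenness needs at least 3 nodes.")
  cb <- numeric(n)
  for (s in seq_len(n)) {
    if (weights == "unit") {
      res <- .brandes_bfs(g, s)
    } else {
      res <- .brandes_dijkstra(g, s)
    }
    sigma <- res$sigma
    delta <- numeric(n)
    for (w in res$order) { # non-increasing distance from s
      for (v in res$pred[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  # each unordered pair accumulated from both endpoints
  cb <- cb / 2 * 2 / ((n - 1) * (n - 2))
  tibble(node = net$nodes$node, label = net$nodes$label, betweenness = cb)
}

.brandes_bfs <- function(g, s) {
  n <- g$n
  d <- rep(-1L, n)
  sigma <- numeric(n)
  pred <- vector("list", n)
  d[s] <- 0L
  sigma[s] <- 1
  queue <- c(s)
  order <- integer(0)
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    order <- c(order, v)
    for (w in g$adj[[v]]) {
      if (d[w] < 0) {
        d[w] <- d[v] + 1L
        queue <- c(queue, w)
      }
      if (d[w] == d[v] + 1L) {
        sigma[w] <- sigma[w] + sigma[v]
        pred[[w]] <- c(pred[[w]], v)
      }
    }
  }
  list(sigma = sigma, pred = pred, order = rev(order))
}

.brandes_dijkstra <- function(g, s) {
  n <- g$n
  d <- rep(Inf, n)
  sigma <- numeric(n)
  pred <- vector("list", n)
  done <- rep(FALSE, n)
  d[s] <- 0
  sigma[s] <- 1
  order <- integer(0)
  eps <- 1e-12
  repeat {
    cand <- which(!done & is.finite(d))
    if (length(cand) == 0) break
    u <- cand[which.min(d[cand])]
    done[u] <- TRUE
    order <- c(order, u)
    nbs <- g$adj[[u]]
    for (t in seq_along(nbs)) {
      w <- nbs[t]
      nd <- d[u] + g$wts[[u]][t]
      if (nd < d[w] - eps) {
        d[w] <- nd
        sigma[w] <- sigma[u]
        pred[[w]] <- c(u)
      } else if (abs(nd - d[w]) <= eps) {
        sigma[w] <- sigma[w] + sigma[u]
        pred[[w]] <- c(pred[[w]], u)
      }
    }
  }
  list(sigma = sigma, pred = pred, order = rev(order))
}

#' Full centrality table
#'
#' Degree, closeness and betweenness centralities per residue, with the
#' pairwise Pearson correlations across nodes attached (retrievable via
#' [glance()]). Correlations are `NA` when a centrality has zero variance
#' (e.g. vertex-transitive graphs).
#'
#' @inheritParams closeness_centrality
#' @return A tibble of class `centrality_table` with `node`, `label`,
#'   `chain`, `degree`, `degree_norm`, `closeness`, `betweenness`.
#' @export
centrality_table <- function(net, weights = c("unit", "inverse-hbond")) {
  weights <- match.arg(weights)
  deg <- degree_centrality(net)
  clo <- closeness_centrality(net, weights)
  btw <- betweenness_centrality(net, weights)
  out <- tibble(
    node = net$nodes$node, label = net$nodes$label, chain = net$nodes$chain,
    degree = deg$degree, degree_norm = deg$degree_norm,
    closeness = clo$closeness, betweenness = btw$betweenness
  )
  M <- cbind(deg = out$degree_norm, clo = out$closeness, btw = out$betweenness)
  cors <- matrix(NA_real_, 3, 3, dimnames = list(colnames(M), colnames(M)))
  for (i in 1:3) {
    for (j in 1:3) {
      if (sd(M[, i]) > 0 && sd(M[, j]) > 0) cors[i, j] <- cor(M[, i], M[, j])
    }
  }
  class(out) <- c("centrality_table", class(out))
  attr(out, "correlations") <- cors
  attr(out, "weights") <- weights
  out
}

#' @exportS3Method generics::glance
glance.centrality_table <- function(x, ...) {
  cors <- attr(x, "correlations")
  tibble(
    n_nodes = nrow(x),
    cor_degree_closeness = cors["deg", "clo"],
    cor_degree_betweenness = cors["deg", "btw"],
    cor_closeness_betweenness = cors["clo", "btw"]
  )
}

#' Residues above a betweenness threshold
#'
#' @param table A [centrality_table()].
#' @param cb_min Betweenness threshold (default 0.05).
#' @return Residues with `betweenness >= cb_min`, sorted descending; the
#'   empirical percentile of the threshold within the betweenness
#'   distribution is attached as attribute `"percentile"`.
#' @export
threshold_report <- function(table, cb_min = 0.05) {
  out <- dplyr::arrange(
    dplyr::filter(as_tibble(table), .data$betweenness >= cb_min),
    dplyr::desc(.data$betweenness)
  )
  attr(out, "percentile") <- 100 * mean(table$betweenness < cb_min)
  out
}

#' Betweenness difference between two states
#'
#' Per-residue `|C_B(A) - C_B(B)|` for residues present in both tables
#' (matched by label), with flags at `threshold` and at `map_threshold`.
#' Unmatched residues are reported in attribute `"unmatched"`.
#'
#' @param table_a,table_b [centrality_table()] objects for the two states.
#' @param threshold Reporting threshold on the absolute difference
#'   (default 0.02).
#' @param map_threshold Stricter structure-mapping threshold (default 0.03).
#' @return A tibble of class `centrality_diff` with `label`, `cb_a`, `cb_b`,
#'   `delta_cb` and logical `flagged`, `flagged_map`, sorted descending by
#'   `delta_cb`.
#' @export
centrality_diff <- function(table_a, table_b, threshold = 0.02,
                            map_threshold = 0.03) {
  common <- intersect(table_a$label, table_b$label)
  if (length(common) == 0) abort("The two tables share no residue labels.")
  a <- table_a[match(common, table_a$label), ]
  b <- table_b[match(common, table_b$label), ]
  out <- tibble(
    label = common,
    cb_a = a$betweenness, cb_b = b$betweenness,
    delta_cb = abs(a$betweenness - b$betweenness)
  )
  out$flagged <- out$delta_cb >= threshold
  out$flagged_map <- out$delta_cb >= map_threshold
  out <- dplyr::arrange(out, dplyr::desc(.data$delta_cb))
  class(out) <- c("centrality_diff", class(out))
  attr(out, "unmatched") <- list(
    a = setdiff(table_a$label, common), b = setdiff(table_b$label, common)
  )
  attr(out, "thresholds") <- c(threshold, map_threshold)
  out
}

#' Export a network as node-link JSON
#'
#' @param net A [build_rin()] network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rin_json <- function(net, path) {
  jsonlite::write_json(
    list(nodes = net$nodes, links = net$edges),
    path,
    dataframe = "rows", digits = NA, pretty = TRUE
  )
  invisible(path)
}
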