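star5 <- rin_from_edges(5, cbind(1, 2:5))
path4 <- rin_from_edges(4, cbind(1:3, 2:4))
cycle5 <- rin_from_edges(5, cbind(1:5, c(2:5, 1)))
complete5 <- rin_from_edges(5, t(utils::combn(5, 2)))

test_that("contacts follow the strict distance rule over the four center pairs", {
  # residues with CA and a CB side-chain center; third residue keeps N >= 3
  m <- make_atoms(
    name = rep(c("CA", "CB"), 3), element = "C",
    resseq = rep(1:3, each = 2),
    x = c(0, 0, 6.5, 6.5, 40, 40), y = c(0, 30, 0, -30, 0, 30), z = 0
  )
  net <- build_rin(m, cutoff = 7)
  e12 <- net$edges[net$edges$from == 1 & net$edges$to == 2, ]
  expect_equal(nrow(e12), 1)
  expect_equal(e12$contact_types, "bb-bb") # side chains 30 A away
  expect_equal(e12$distance, 6.5, tolerance = 1e-9)
  expect_equal(nrow(net$edges[net$edges$to == 3 | net$edges$from == 3, ]), 0)
  # exactly at the cutoff: no edge (strict <)
  m2 <- m
  m2$x[3:4] <- 7.0
  net2 <- build_rin(m2, cutoff = 7)
  expect_equal(nrow(net2$edges), 0)
})

test_that("designed inter-residue hydrogen bonds become the edge weight", {
  m <- make_atoms(
    name = c("CA", "N", "H", "SG", "HG", "CA", "O", "OD1", "CA"),
    element = c("C", "N", "H", "S", "H", "C", "O", "O", "C"),
    resseq = c(1, 1, 1, 1, 1, 2, 2, 2, 3),
    residue_name = c(rep("CYS", 5), rep("ASP", 3), "GLY"),
    x = c(0, 1, 2, 1, 2, 5, 3.5, 3.5, 0),
    y = c(0, 0, 0, 2, 2, 1, 0, 2, 40),
    z = 0
  )
  # N-H...O (d = 2.5, on-axis) and SG-HG...OD1 (d = 2.5, on-axis)
  net <- build_rin(m, cutoff = 7)
  e12 <- net$edges[net$edges$from == 1 & net$edges$to == 2, ]
  expect_equal(e12$hbond_count, 2L)
})

test_that("closed-form centralities are reproduced exactly", {
  cb_star <- betweenness_centrality(star5)
  cc_star <- closeness_centrality(star5)
  expect_equal(cb_star$betweenness, c(1, 0, 0, 0, 0))
  expect_equal(cc_star$closeness[1], 1)
  expect_equal(cc_star$closeness[2], 4 / 7)
  cb_path <- betweenness_centrality(path4)
  expect_equal(cb_path$betweenness, c(0, 2 / 3, 2 / 3, 0))
  cc_path <- closeness_centrality(path4)
  expect_equal(cc_path$closeness[1], 3 / (1 + 2 + 3))
  expect_equal(betweenness_centrality(cycle5)$betweenness, rep(1 / 6, 5))
  deg <- degree_centrality(complete5)
  expect_equal(deg$degree, rep(4L, 5))
  expect_equal(deg$degree_norm, rep(1, 5))
})

test_that("degree sums obey the handshake lemma and isolated nodes get zero", {
  g <- rin_from_edges(6, cbind(c(1, 1, 2), c(2, 3, 3)))
  deg <- degree_centrality(g)
  expect_equal(sum(deg$degree), 2 * nrow(g$edges))
  expect_equal(deg$degree[4:6], rep(0L, 3))
  expect_warning(cc <- closeness_centrality(g), "Isolated")
  expect_equal(cc$closeness[4:6], rep(0, 3))
})

test_that("Brandes and Dijkstra match exhaustive oracles on random graphs", {
  set.seed(2024)
  n_checked <- 0
  for (rep in 1:60) {
    n <- sample(4:12, 1)
    edges <- random_graph_edges(n, runif(1, 0.2, 0.7))
    if (nrow(edges) == 0) next
    net <- rin_from_edges(n, edges)
    A <- adj_matrix(n, as.matrix(net$edges[, c("from", "to")]))
    expect_equal(betweenness_centrality(net)$betweenness, brute_betweenness(A),
      tolerance = 1e-12
    )
    cc <- suppressWarnings(closeness_centrality(net)$closeness)
    expect_equal(cc, brute_closeness(A), tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 50)
})

test_that("betweenness agrees with igraph as an independent implementation", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    edges <- random_graph_edges(n, 0.5)
    if (nrow(edges) == 0) next
    net <- rin_from_edges(n, edges)
    g <- igraph::graph_from_edgelist(as.matrix(net$edges[, c("from", "to")]),
      directed = FALSE
    )
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
    ref <- igraph::betweenness(g) * 2 / ((n - 1) * (n - 2))
    expect_equal(betweenness_centrality(net)$betweenness, unname(ref),
      tolerance = 1e-10
    )
  }
})

test_that("normalised betweenness is bounded and zero for degree-1 nodes", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    edges <- random_graph_edges(n, 0.4)
    if (nrow(edges) == 0) next
    net <- rin_from_edges(n, edges)
    cb <- betweenness_centrality(net)$betweenness
    deg <- degree_centrality(net)$degree
    expect_true(all(cb >= -1e-15 & cb <= 1 + 1e-15))
    expect_equal(cb[deg <= 1], rep(0, sum(deg <= 1)))
  }
})

test_that("inverse-hbond edge lengths reroute shortest paths", {
  # square 1-2-3-4-1 plus no diagonal: paths 1->3 tie via 2 or 4; an H-bond
  # on the 1-2 edge shortens that route and concentrates betweenness on 2
  sq <- rin_from_edges(4, cbind(c(1, 2, 3, 4), c(2, 3, 4, 1)),
    hbond_count = c(3, 3, 0, 0)
  )
  cb_unit <- betweenness_centrality(sq)$betweenness
  expect_equal(cb_unit[2], cb_unit[4]) # symmetric without weights
  cb_w <- betweenness_centrality(sq, weights = "inverse-hbond")$betweenness
  expect_gt(cb_w[2], cb_w[4])
})

test_that("centrality tables carry correlations, degenerate cases give NA", {
  tab <- centrality_table(rin_from_edges(5, cbind(1, 2:5)))
  g <- glance(tab)
  expect_true(all(abs(c(
    g$cor_degree_closeness, g$cor_degree_betweenness,
    g$cor_closeness_betweenness
  )) <= 1))
  tab_cyc <- centrality_table(cycle5)
  expect_true(is.na(glance(tab_cyc)$cor_degree_closeness))
})

test_that("threshold reports filter, sort and locate the percentile", {
  tab <- centrality_table(star5)
  rep_hi <- threshold_report(tab, cb_min = 0.05)
  expect_equal(rep_hi$label, "G1")
  expect_equal(nrow(rep_hi), sum(tab$betweenness >= 0.05)) # independent scan
  expect_equal(attr(rep_hi, "percentile"), 80)
  none <- threshold_report(centrality_table(complete5), cb_min = 0.05)
  expect_equal(nrow(none), 0)
})

test_that("state differences are symmetric, thresholded and label-matched", {
  ta <- centrality_table(star5)
  expect_equal(sum(centrality_diff(ta, ta)$delta_cb), 0)
  expect_false(any(centrality_diff(ta, ta)$flagged))
  tb <- ta
  tb$betweenness[1] <- ta$betweenness[1] - 0.04
  d <- centrality_diff(ta, tb)
  expect_equal(d$delta_cb[d$label == "G1"], 0.04)
  expect_true(d$flagged[d$label == "G1"] && d$flagged_map[d$label == "G1"])
  d_rev <- centrality_diff(tb, ta)
  expect_equal(d$delta_cb, d_rev$delta_cb)
  tc <- tb
  tc$label <- paste0("X", seq_len(nrow(tc)))
  expect_error(centrality_diff(ta, tc), "share no residue")
})

test_that("a residue with 0.06 vs 0.02 betweenness is flagged at both levels", {
  ta <- centrality_table(path4)
  tb <- ta
  ta$betweenness[2] <- 0.06
  tb$betweenness[2] <- 0.02
  d <- centrality_diff(ta, tb)
  row <- d[d$label == "G2", ]
  expect_equal(row$delta_cb, 0.04)
  expect_true(row$flagged && row$flagged_map)
})

test_that("the edge set is invariant under rigid motion of the structure", {
  hub <- generate_hub_structure(3, seed = 15)
  net <- build_rin(hub)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  xyz <- as.matrix(hub[, c("x", "y", "z")]) %*% t(Rz)
  hub2 <- hub
  hub2$x <- xyz[, 1] + 13
  hub2$y <- xyz[, 2] - 4
  hub2$z <- xyz[, 3] + 6
  net2 <- build_rin(hub2)
  expect_equal(net2$edges[, c("from", "to", "contact_types")],
    net$edges[, c("from", "to", "contact_types")]
  )
  expect_equal(net2$edges$distance, net$edges$distance, tolerance = 1e-9)
})

test_that("network export writes readable node-link JSON", {
  p <- tempfile(fileext = ".json")
  write_rin_json(star5, p)
  parsed <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(nrow(parsed$nodes), 5)
  expect_equal(nrow(parsed$links), 4)
})
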