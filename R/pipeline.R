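#' Pipeline configuration
#'
#' Bundles the parameters of the full analysis chain (stability -> H-bonds ->
#' essential dynamics / free-energy landscape -> representative selection ->
#' residue interaction network -> centralities). Defaults follow the values
#' standard in this workflow: 3.5 A / 30 degrees for H-bonds, 7 A contact
#' cutoff, cosine-content bound 0.2, 300 K, top-20 low-energy clustering,
#' betweenness thresholds 0.05 (reporting) and 0.02 / 0.03 (state
#' differences).
#'
#' @param ensemble A [trajectory_ensemble()], or a path to a multi-model PDB.
#' @param output_dir Directory the stage outputs are written to.
#' @param energy Energy profile tibble or path to a two-column text file;
#'   `NULL` disables energy-based representative selection.
#' @param selection,rmsf_selection Selections for RMSD/SASA/ED and RMSF.
#' @param hbond_groups `NULL`, or `list(group_a =, group_b =)` selections for
#'   intergroup H-bond analysis (e.g. ligand vs protein).
#' @param hbond [hbond_criterion()].
#' @param n_pcs Number of projection components to write (capped at rank).
#' @param fel_bins,temperature,cosine_threshold,fel_force Landscape controls.
#' @param k,cluster_cutoff Representative-selection controls.
#' @param rin_cutoff,cb_min,diff_threshold,map_threshold Network controls.
#' @param sasa Compute the SASA series (slowest stability metric)?
#' @param seed Integer seed recorded in the manifest (analyses are
#'   deterministic; the seed matters when the ensemble itself is generated).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ensemble, output_dir, energy = NULL,
                            selection = "backbone", rmsf_selection = "calpha",
                            hbond_groups = NULL, hbond = hbond_criterion(),
                            n_pcs = 20, fel_bins = 32, temperature = 300,
                            cosine_threshold = 0.2, fel_force = FALSE,
                            k = 20, cluster_cutoff = 2.0,
                            rin_cutoff = 7.0, cb_min = 0.05,
                            diff_threshold = 0.02, map_threshold = 0.03,
                            sasa = TRUE, seed = 1) {
  structure(
    list(
      ensemble = ensemble, output_dir = output_dir, energy = energy,
      selection = selection, rmsf_selection = rmsf_selection,
      hbond_groups = hbond_groups, hbond = hbond,
      n_pcs = n_pcs, fel_bins = fel_bins, temperature = temperature,
      cosine_threshold = cosine_threshold, fel_force = fel_force,
      k = k, cluster_cutoff = cluster_cutoff,
      rin_cutoff = rin_cutoff, cb_min = cb_min,
      diff_threshold = diff_threshold, map_threshold = map_threshold,
      sasa = sasa, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

.write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(as.data.frame(df), con,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order, writing each stage's outputs
#' (TSV tables, node-link JSON, representative PDB) into
#' `config$output_dir` before the next stage starts. Reruns with identical
#' configuration and inputs reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest`: configuration echo, package version, per-output
#'   md5 hashes, collected warnings, and the in-memory stage results
#'   (including the centrality table used by [compare_states()]). Also
#'   written as `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }
  outp <- function(name) file.path(config$output_dir, name)
  written <- character()

  ens <- config$ensemble
  if (is.character(ens)) ens <- read_ensemble(ens)
  energy <- config$energy
  if (is.character(energy)) energy <- read_energy_profile(energy)
  results <- list()

  # -- stability ------------------------------------------------------------
  rmsd <- rmsd_series(ens, config$selection)
  .write_tsv(rmsd, outp("rmsd.tsv"), "time: ps\trmsd: angstrom")
  rmsf <- rmsf_table(ens, config$rmsf_selection)
  .write_tsv(rmsf, outp("rmsf.tsv"), "rmsf: angstrom (per residue, C-alpha)")
  written <- c(written, "rmsd.tsv", "rmsf.tsv")
  results$rmsd <- rmsd
  results$rmsf <- rmsf
  if (isTRUE(config$sasa)) {
    sasa <- sasa_series(ens, config$selection)
    .write_tsv(sasa, outp("sasa.tsv"), "time: ps\tsasa: nm^2")
    written <- c(written, "sasa.tsv")
    results$sasa <- sasa
  }

  # -- hydrogen bonds -------------------------------------------------------
  if (!is.null(config$hbond_groups)) {
    hg <- config$hbond_groups
    counts <- hbond_count_series(ens, hg$group_a, hg$group_b, config$hbond)
    occ <- occupancy_table(ens, hg$group_a, hg$group_b, config$hbond)
    .write_tsv(counts, outp("hbond_counts.tsv"), "time: ps\tn_hbonds: count")
    .write_tsv(occ, outp("hbond_occupancy.tsv"), "occupancy: fraction of frames")
    written <- c(written, "hbond_counts.tsv", "hbond_occupancy.tsv")
    results$hbond_counts <- counts
    results$occupancy <- occ
  }

  # -- essential dynamics and landscape ------------------------------------
  ed <- fit_essential_dynamics(ens, config$selection)
  .write_tsv(tidy(ed), outp("eigenvalues.tsv"), "eigenvalue: nm^2")
  k_proj <- min(config$n_pcs, length(ed$eigenvalues))
  proj <- project_ensemble(ens, ed, k = k_proj)
  .write_tsv(proj, outp("projections.tsv"), "time: ps\tpc*: nm")
  written <- c(written, "eigenvalues.tsv", "projections.tsv")
  results$ed <- ed
  results$projections <- proj
  cc <- c(cosine_content(proj, 1), cosine_content(proj, 2))
  results$cosine_content <- cc
  fel <- NULL
  if (all(cc <= config$cosine_threshold) || isTRUE(config$fel_force)) {
    fel <- free_energy_surface(proj,
      n_bins = config$fel_bins,
      temperature = config$temperature,
      cosine_threshold = config$cosine_threshold, force = TRUE
    )
    .write_tsv(tidy(fel), outp("fel.tsv"),
      sprintf("delta_g: kJ/mol at %g K; NA = unpopulated bin", config$temperature)
    )
    written <- c(written, "fel.tsv")
    results$fel <- fel
    results$fel_minimum_frames <- locate_minimum_frames(fel, proj)
  } else {
    note(
      "FEL skipped: cosine content (%.3f, %.3f) above %.2f and force = FALSE.",
      cc[1], cc[2], config$cosine_threshold
    )
  }

  # -- representative structure --------------------------------------------
  if (!is.null(energy)) {
    rep_set <- select_representative(ens, energy, config$selection,
      k = config$k, rmsd_cutoff = config$cluster_cutoff
    )
    .write_tsv(tidy(rep_set), outp("representative_clusters.tsv"),
      "energy: as supplied; cluster: single-linkage id"
    )
    written <- c(written, "representative_clusters.tsv")
    rep_frame <- rep_set$representative_frame
    results$representative <- rep_set
  } else if (!is.null(fel)) {
    rep_frame <- results$fel_minimum_frames[1]
    note("No energy series; representative taken from the FEL minimum basin.")
  } else {
    rep_frame <- 1L
    note("No energy series or landscape; representative defaulted to frame 1.")
  }
  rep_model <- ens$topology
  fc <- frame_coords(ens, rep_frame)
  rep_model$x <- fc[, 1]
  rep_model$y <- fc[, 2]
  rep_model$z <- fc[, 3]
  write_pdb(rep_model, outp("representative.pdb"))
  written <- c(written, "representative.pdb")
  results$representative_frame <- rep_frame

  # -- residue interaction network and centralities ------------------------
  net <- build_rin(rep_model, cutoff = config$rin_cutoff, criterion = config$hbond)
  write_rin_json(net, outp("network.json"))
  cent <- centrality_table(net)
  .write_tsv(cent, outp("centrality.tsv"),
    "degree_norm, closeness, betweenness: normalised to [0,1]"
  )
  rep_report <- threshold_report(cent, config$cb_min)
  .write_tsv(rep_report, outp("high_betweenness.tsv"),
    sprintf("residues with betweenness >= %g", config$cb_min)
  )
  written <- c(written, "network.json", "centrality.tsv", "high_betweenness.tsv")
  results$network <- net
  results$centrality <- cent

  cfg_echo <- config
  cfg_echo$ensemble <- if (is.character(config$ensemble)) config$ensemble else "<in-memory ensemble>"
  cfg_echo$energy <- if (is.character(config$energy)) config$energy else if (is.null(energy)) NULL else "<in-memory profile>"
  manifest <- structure(
    list(
      package_version = as.character(utils::packageVersion("rinflow")),
      config = unclass(cfg_echo),
      outputs = as.list(setNames(
        unname(tools::md5sum(file.path(config$output_dir, written))), written
      )),
      warnings = warnings_log,
      results = results
    ),
    class = "run_manifest"
  )
  to_write <- manifest[c("package_version", "config", "outputs", "warnings")]
  to_write$config$hbond <- unclass(to_write$config$hbond)
  jsonlite::write_json(to_write, outp("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "<run_manifest> rinflow %s: %d outputs, %d warning(s)\n",
    x$package_version, length(x$outputs), length(x$warnings)
  ))
  for (w in x$warnings) cat("  note:", w, "\n")
  invisible(x)
}

#' Compare centrality between analysed states
#'
#' Pairwise betweenness differences of each subsequent state against the
#' first (reference, e.g. apo) state.
#'
#' @param manifests A list of two or more [run_pipeline()] manifests (or
#'   bare [centrality_table()] objects), optionally named.
#' @param threshold,map_threshold Difference thresholds (defaults 0.02, 0.03).
#' @return A list of class `state_comparison`: per-pair [centrality_diff()]
#'   tables and a combined tibble of flagged residues per comparison.
#' @export
compare_states <- function(manifests, threshold = 0.02, map_threshold = 0.03) {
  if (length(manifests) < 2) abort("Need at least two states to compare.")
  tabs <- lapply(manifests, function(m) {
    if (inherits(m, "run_manifest")) m$results$centrality else m
  })
  nm <- names(manifests) %||% paste0("state", seq_along(manifests))
  nm[nm == ""] <- paste0("state", which(nm == ""))
  diffs <- list()
  flagged <- list()
  for (i in seq(2, length(tabs))) {
    d <- centrality_diff(tabs[[1]], tabs[[i]],
      threshold = threshold, map_threshold = map_threshold
    )
    key <- paste(nm[1], "vs", nm[i])
    diffs[[key]] <- d
    f <- d[d$flagged, c("label", "delta_cb")]
    if (nrow(f) > 0) f$comparison <- key
    flagged[[key]] <- f
  }
  structure(
    list(
      diffs = diffs,
      flagged = dplyr::bind_rows(flagged),
      thresholds = c(threshold, map_threshold)
    ),
    class = "state_comparison"
  )
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf(
    "<state_comparison> %d comparison(s); %d residue(s) flagged at |dCB| >= %g\n",
    length(x$diffs), nrow(x$flagged), x$thresholds[1]
  ))
  invisible(x)
}
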