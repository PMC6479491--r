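.standard_aa <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "HSD", "HSE", "HSP", "HID", "HIE", "HIP", "CYX"
)
.water_res <- c("HOH", "WAT", "TIP3", "SOL", "TIP", "SPC")

.default_backbone <- c("N", "CA", "C", "O")

.infer_element <- function(name) {
  # first alphabetic character of the atom name
  sym <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name))
  sym[!grepl("[A-Za-z]", name)] <- ""
  sym
}

.one_letter <- function(res3) {
  out <- suppressWarnings(bio3d::aa321(res3))
  out[is.na(out) | out == ""] <- "X"
  out
}

#' Author-style residue labels
#'
#' One-letter code plus the author residue number (e.g. `"Y314"`), the form
#' used in all user-facing reports.
#'
#' @param model Atom tibble.
#' @return Character vector, one label per atom row.
#' @export
residue_labels <- function(model) {
  paste0(.one_letter(model$residue_name), model$resseq)
}

.atom_tibble <- function(df) {
  tibble(
    serial = as.integer(df$serial),
    name = as.character(df$name),
    element = as.character(df$element),
    residue_index = as.integer(df$residue_index),
    residue_name = as.character(df$residue_name),
    chain = as.character(df$chain),
    resseq = as.integer(df$resseq),
    het = as.logical(df$het),
    x = as.numeric(df$x), y = as.numeric(df$y), z = as.numeric(df$z)
  )
}

# Validate coordinate fields of ATOM/HETATM lines, reporting the line number
# of the first malformed record.
.validate_pdb_lines <- function(lines, path) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) abort(sprintf("No ATOM/HETATM records found in '%s'.", path))
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      abort(sprintf("Malformed coordinate record at line %d of '%s'.", i, path))
    }
    xyz <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54)
    )))
    if (anyNA(xyz) || any(!is.finite(xyz))) {
      abort(sprintf("Malformed coordinate field at line %d of '%s'.", i, path))
    }
  }
  invisible(TRUE)
}

.bio3d_to_tibble <- function(atom, keep_water) {
  element <- atom$elesy
  missing_el <- is.na(element) | element == "" | element == " "
  element[missing_el] <- .infer_element(atom$elety[missing_el])
  df <- tibble(
    serial = atom$eleno, name = atom$elety, element = toupper(element),
    residue_name = atom$resid, chain = ifelse(is.na(atom$chain), "A", atom$chain),
    resseq = atom$resno,
    insert = ifelse(is.na(atom$insert), "", atom$insert),
    het = atom$type == "HETATM",
    occ = ifelse(is.na(atom$o), 1, atom$o),
    alt = ifelse(is.na(atom$alt), "", atom$alt),
    x = atom$x, y = atom$y, z = atom$z
  )
  if (!keep_water) df <- df[!(df$residue_name %in% .water_res), ]
  # alternate locations: keep highest occupancy; ties resolved to first listed
  if (any(df$alt != "")) {
    key <- paste(df$chain, df$resseq, df$insert, df$name)
    keep <- rep(TRUE, nrow(df))
    for (k in unique(key[df$alt != ""])) {
      idx <- which(key == k)
      if (length(idx) > 1) {
        best <- idx[which.max(df$occ[idx])]
        keep[setdiff(idx, best)] <- FALSE
      }
    }
    df <- df[keep, ]
  }
  rkey <- paste(df$chain, df$resseq, df$insert, df$residue_name)
  df$residue_index <- cumsum(c(TRUE, rkey[-1] != rkey[-length(rkey)])) - 1L
  .atom_tibble(df)
}

#' Read a structure from a PDB file
#'
#' Returns the first model of the file as an atom tibble. Alternate locations
#' are resolved to the highest-occupancy conformer (ties: first listed);
#' waters are dropped unless `keep_water = TRUE`. Missing element symbols are
#' inferred from the first alphabetic character of the atom name.
#'
#' @param path Path to a PDB-format text file.
#' @param keep_water Keep water (HOH/WAT/...) residues? Default `FALSE`.
#' @return A tibble with one row per atom: `serial`, `name`, `element`,
#'   `residue_index` (0-based sequential), `residue_name`, `chain`, `resseq`
#'   (author numbering), `het`, and coordinates `x`, `y`, `z` in angstroms.
#' @export
read_pdb <- function(path, keep_water = FALSE) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("File '%s' is empty.", path))
  .validate_pdb_lines(lines, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
    verbose = FALSE
  ))
  .bio3d_to_tibble(pdb$atom, keep_water = keep_water)
}

#' Write a structure to a PDB file
#'
#' @param model Atom tibble (see [read_pdb()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(model[, c("x", "y", "z")]))),
    type = ifelse(model$het, "HETATM", "ATOM"),
    resno = model$resseq, resid = model$residue_name,
    eleno = model$serial, elety = model$name,
    chain = model$chain, elesy = model$element
  )
  invisible(path)
}

# Per-model atom counts from raw lines; errors name the offending MODEL.
.scan_models <- function(lines, path) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    return(list(n_models = 1L, counts = sum(grepl("^(ATOM  |HETATM)", lines))))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) {
    abort(sprintf("Unbalanced MODEL/ENDMDL records in '%s'.", path))
  }
  counts <- mapply(function(s, e) sum(grepl("^(ATOM  |HETATM)", lines[s:e])),
    starts, ends
  )
  list(n_models = length(starts), counts = counts)
}

#' Read a coordinate ensemble from a multi-model PDB file
#'
#' One frame per `MODEL` block. Frame times are taken from
#' `REMARK 250 FRAME i TIME= t PS` header lines when present (the convention
#' [write_ensemble()] emits), else `0, stride, 2*stride, ...` ps.
#'
#' @inheritParams read_pdb
#' @param stride Frame spacing (ps) used when the file carries no times.
#' @return A [trajectory_ensemble()].
#' @export
read_ensemble <- function(path, stride = 1, keep_water = FALSE) {
  if (!file.exists(path)) abort(sprintf("File '%s' does not exist.", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("File '%s' is empty.", path))
  .validate_pdb_lines(lines, path)
  mods <- .scan_models(lines, path)
  if (mods$n_models > 1 && length(unique(mods$counts)) > 1) {
    bad <- which(mods$counts != mods$counts[1])[1]
    abort(sprintf(
      "Model %d of '%s' has %d atoms; model 1 has %d. All frames must match.",
      bad, path, mods$counts[bad], mods$counts[1]
    ))
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  topo <- .bio3d_to_tibble(pdb$atom, keep_water = keep_water)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na_all <- nrow(pdb$atom)
  coords <- aperm(array(t(xyz), dim = c(3, na_all, nf)), c(3, 2, 1))
  if (!keep_water) {
    keep <- !(pdb$atom$resid %in% .water_res)
    coords <- coords[, keep, , drop = FALSE]
  }
  tm <- regmatches(lines, regexec(
    "^REMARK 250 FRAME +[0-9]+ +TIME= *([-0-9.eE+]+)", lines
  ))
  times <- as.numeric(vapply(tm[lengths(tm) == 2], `[`, "", 2))
  if (length(times) != nf) times <- (seq_len(nf) - 1) * stride
  trajectory_ensemble(topo, coords, times = times)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Frame times are recorded in `REMARK 250` header lines so that
#' [read_ensemble()] round-trips them.
#'
#' @param ensemble A [trajectory_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(ensemble, path) {
  m <- ensemble$topology
  nf <- n_frames(ensemble)
  xyz <- matrix(NA_real_, nf, 3 * n_atoms(ensemble))
  for (i in seq_len(nf)) xyz[i, ] <- as.numeric(t(frame_coords(ensemble, i)))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(m$het, "HETATM", "ATOM"),
    resno = m$resseq, resid = m$residue_name,
    eleno = m$serial, elety = m$name, chain = m$chain, elesy = m$element
  )
  hdr <- sprintf("REMARK 250 FRAME %d TIME= %.4f PS", seq_len(nf), ensemble$times)
  writeLines(c(hdr, readLines(path, warn = FALSE)), path)
  invisible(path)
}
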