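#' Atom selections
#'
#' A small selection grammar over atom tibbles. Primitives:
#' `all`, `protein`, `backbone` (N, CA, C, O of amino-acid residues, see
#' `backbone_atoms`), `calpha`, `sidechain`, `heavy`, `ligand` (non-water
#' HETATM), `water`, `resid <n|n-m|n,m,...>` (author numbering),
#' `chain <id,...>`, `name <atom-name,...>`. Combine with `and`, `or`, `not`
#' and parentheses. Selection is deterministic and monotone: selecting within
#' a selection yields a subset.
#'
#' @param model Atom tibble (see [read_pdb()]).
#' @param expression Selection string, e.g. `"backbone and chain A"`.
#' @param backbone_atoms Atom names that constitute the backbone.
#' @return An integer vector of atom row indices (class `atom_selection`)
#'   with the expression stored as its `label` attribute.
#' @examples
#' \dontrun{
#' sel <- select_atoms(model, "calpha and resid 10-40")
#' }
#' @export
select_atoms <- function(model, expression,
                         backbone_atoms = c("N", "CA", "C", "O")) {
  toks <- .tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- .sel_expr(st, model, backbone_atoms)
  if (st$pos <= length(st$toks)) {
    abort(sprintf("Unexpected token '%s' in selection '%s'.",
      st$toks[st$pos], expression
    ))
  }
  structure(which(mask), class = "atom_selection", label = expression)
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf(
    "<atom_selection> '%s': %d atoms\n", attr(x, "label") %||% "?", length(x)
  ))
  invisible(x)
}

# Resolve a selection given either an expression string, an atom_selection,
# or a bare integer vector of indices. Returns a bare integer vector with a
# `label` attribute (safe for tibble row subsetting).
.resolve_selection <- function(model, selection) {
  if (inherits(selection, "atom_selection")) {
    if (length(selection) > 0 && max(selection) > nrow(model)) {
      abort("Selection indices exceed the model's atom count.")
    }
    lab <- attr(selection, "label")
    return(structure(as.integer(unclass(selection)), label = lab))
  }
  if (is.character(selection)) {
    sel <- select_atoms(model, selection)
    return(structure(as.integer(unclass(sel)), label = attr(sel, "label")))
  }
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (anyDuplicated(idx) || any(idx < 1) || any(idx > nrow(model))) {
      abort("Numeric selections must be unique, valid atom indices.")
    }
    return(structure(idx, label = attr(selection, "label") %||% "indices"))
  }
  abort("`selection` must be an expression string, atom_selection or indices.")
}

.tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1 || !nzchar(expression)) {
    abort("Selection expression must be a non-empty string.")
  }
  s <- gsub("\\(", " ( ", expression)
  s <- gsub("\\)", " ) ", s)
  s <- gsub(",", " , ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[toks != ""]
}

.sel_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
.sel_next <- function(st) {
  t <- .sel_peek(st)
  st$pos <- st$pos + 1L
  t
}

.sel_expr <- function(st, model, bb) {
  out <- .sel_term(st, model, bb)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "or") {
    .sel_next(st)
    out <- out | .sel_term(st, model, bb)
  }
  out
}

.sel_term <- function(st, model, bb) {
  out <- .sel_factor(st, model, bb)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "and") {
    .sel_next(st)
    out <- out & .sel_factor(st, model, bb)
  }
  out
}

.sel_factor <- function(st, model, bb) {
  tok <- .sel_peek(st)
  if (is.na(tok)) abort("Selection expression ended unexpectedly.")
  if (tolower(tok) == "not") {
    .sel_next(st)
    return(!.sel_factor(st, model, bb))
  }
  if (tok == "(") {
    .sel_next(st)
    out <- .sel_expr(st, model, bb)
    if (!identical(.sel_next(st), ")")) abort("Unbalanced parenthesis in selection.")
    return(out)
  }
  .sel_primitive(st, model, bb)
}

.sel_value_list <- function(st) {
  vals <- character()
  repeat {
    tok <- .sel_peek(st)
    if (is.na(tok) || tok %in% c(")", ",") ||
      tolower(tok) %in% c("and", "or", "not")) {
      if (!is.na(tok) && tok == ",") {
        .sel_next(st)
        next
      }
      break
    }
    vals <- c(vals, .sel_next(st))
  }
  if (length(vals) == 0) abort("Selection keyword expects at least one value.")
  vals
}

.sel_primitive <- function(st, model, bb) {
  tok <- tolower(.sel_next(st))
  is_protein <- model$residue_name %in% .standard_aa & !model$het
  switch(tok,
    all = rep(TRUE, nrow(model)),
    protein = is_protein,
    backbone = is_protein & model$name %in% bb,
    calpha = is_protein & model$name == "CA",
    sidechain = is_protein & !(model$name %in% bb),
    heavy = model$element != "H",
    ligand = model$het & !(model$residue_name %in% .water_res),
    water = model$residue_name %in% .water_res,
    resid = {
      vals <- .sel_value_list(st)
      keep <- rep(FALSE, nrow(model))
      for (v in vals) {
        if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^-?[0-9]+:-?[0-9]+$", v)) {
          parts <- as.integer(strsplit(v, "[-:]")[[1]][1:2])
          keep <- keep | (model$resseq >= parts[1] & model$resseq <= parts[2])
        } else if (grepl("^-?[0-9]+$", v)) {
          keep <- keep | model$resseq == as.integer(v)
        } else {
          abort(sprintf("Unknown token '%s' in resid list.", v))
        }
      }
      keep
    },
    chain = model$chain %in% .sel_value_list(st),
    name = model$name %in% toupper(.sel_value_list(st)),
    abort(sprintf("Unknown token '%s' in selection expression.", tok))
  )
}
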