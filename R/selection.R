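#' Select atoms from a topology by a small expression grammar
#'
#' Evaluates a selection expression against a topology and returns the
#' 1-based positions of the matching atoms. The grammar is deliberately
#' small: equality tests \code{field=value} joined by \code{and} / \code{or},
#' with parentheses for grouping; \code{and} binds tighter than \code{or}.
#' Recognised fields are \code{chain} (alias \code{chain_id}),
#' \code{residue_name}, \code{residue_number}, \code{atom_name},
#' \code{element} and \code{serial}. This is sufficient to resolve the atoms
#' the analyses need, e.g. \code{"atom_name=FE and residue_name=HEM"} for the
#' heme iron or \code{"atom_name=C30"} for lanosterol's oxidation centre.
#'
#' @param topology an [MDTopology-class] (or [MDTrajectory-class], whose
#'   topology is used).
#' @param spec selection expression string.
#' @return an [AtomSelection-class]; an empty selection is allowed but raises
#'   a warning.
#' @examples
#' top <- genTopologyTemplate(residue_numbers = 384:385,
#'                            residue_names = c("MET", "ILE"))
#' selectionIndices(selectAtoms(top, "atom_name=FE and residue_name=HEM"))
#' @export
selectAtoms <- function(topology, spec) {
  if (is(topology, "MDTrajectory")) topology <- topology@topology
  stopifnot(is(topology, "MDTopology"))
  mask <- evalSelection(topology@atoms, spec)
  idx <- which(mask)
  if (length(idx) == 0L)
    warnf("selection '%s' matched no atoms", spec)
  new("AtomSelection", spec = spec, indices = as.integer(idx))
}

## --- recursive-descent evaluator -------------------------------------------

selTokenize <- function(spec) {
  padded <- gsub("\\)", " ) ", gsub("\\(", " ( ", spec))
  padded <- gsub("\\s*=\\s*", "=", padded)
  toks <- strsplit(trimws(padded), "\\s+")[[1]]
  toks[nzchar(toks)]
}

evalSelection <- function(atoms, spec) {
  toks <- selTokenize(spec)
  if (length(toks) == 0L) stopf("empty selection expression")
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  peek <- function() if (st$pos <= length(st$toks)) st$toks[st$pos] else NA
  advance <- function() { t <- peek(); st$pos <- st$pos + 1L; t }

  parseTest <- function(tok) {
    if (is.na(tok)) stopf("selection '%s': unexpected end of expression", spec)
    if (!grepl("=", tok, fixed = TRUE))
      stopf("selection '%s': cannot parse token '%s'", spec, tok)
    kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L || !nzchar(kv[1]) || !nzchar(kv[2]))
      stopf("selection '%s': cannot parse token '%s'", spec, tok)
    field <- switch(kv[1],
      chain = , chain_id = atoms$chain_id,
      residue_name = atoms$residue_name,
      residue_number = atoms$residue_number,
      atom_name = atoms$atom_name,
      element = atoms$element,
      serial = atoms$serial,
      stopf("selection '%s': unknown field '%s'", spec, kv[1]))
    if (is.numeric(field)) {
      val <- suppressWarnings(as.numeric(kv[2]))
      if (is.na(val))
        stopf("selection '%s': non-numeric value '%s' for field '%s'",
              spec, kv[2], kv[1])
      field == val
    } else {
      field == kv[2]
    }
  }

  parseFactor <- function() {
    tok <- advance()
    if (identical(tok, "(")) {
      v <- parseExpr()
      if (!identical(advance(), ")"))
        stopf("selection '%s': missing closing parenthesis", spec)
      v
    } else if (identical(tok, ")") || identical(tok, "and") ||
               identical(tok, "or")) {
      stopf("selection '%s': cannot parse token '%s'", spec, tok)
    } else {
      parseTest(tok)
    }
  }

  parseTerm <- function() {
    v <- parseFactor()
    while (identical(peek(), "and")) {
      advance()
      v <- v & parseFactor()
    }
    v
  }

  parseExpr <- function() {
    v <- parseTerm()
    while (identical(peek(), "or")) {
      advance()
      v <- v | parseTerm()
    }
    v
  }

  res <- parseExpr()
  if (!is.na(peek()))
    stopf("selection '%s': cannot parse token '%s'", spec, peek())
  res
}

## Resolve a selection (object or spec string) to exactly one atom index.
resolveSingleAtom <- function(traj, sel, what = "selection") {
  idx <- if (is(sel, "AtomSelection")) sel@indices
         else selectAtoms(traj, sel)@indices
  if (length(idx) != 1L)
    stopf("%s must resolve exactly one atom, got %d", what, length(idx))
  idx
}
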