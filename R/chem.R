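# Structure handling: canonical SMILES, MolPrint2D atom environments,
# Tanimoto similarity.  All chemistry perception (parsing, aromaticity,
# molecular weight) is delegated to OpenBabel via ChemmineOB; the
# atom-environment fingerprint itself is computed here from the molecular
# graph.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to OpenBabel canonical SMILES, the dialect used
#' throughout the package for duplicate detection.  Unparsable inputs
#' yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @examples
#' canonicalizeSmiles(c("OCC", "CCO"))   # identical output
#' @export
canonicalizeSmiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", source = s),
                    error = function(e) "")
    can <- strsplit(out, "[\t\n]")[[1]][1]
    if (is.na(can) || !nzchar(can)) NA_character_ else can
  }, character(1), USE.NAMES = FALSE)
}

# Parse OpenBabel's molreport output into atoms (element, obtype) and a
# heavy-atom adjacency list.  Explicit hydrogens, if present, are removed.
.molReport <- function(smiles) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "MOLREPORT", source = smiles),
                  error = function(e) "")
  if (!nzchar(out)) return(NULL)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  mass <- as.numeric(sub("^MASS: *", "", grep("^MASS:", lines, value = TRUE)[1]))
  atom_lines <- grep("^ATOM:", lines, value = TRUE)
  bond_lines <- grep("^BOND:", lines, value = TRUE)
  if (!length(atom_lines)) return(NULL)
  am <- regmatches(atom_lines,
                   regexec("^ATOM:\\s+(\\d+)\\s+(\\S+)\\s+TYPE:\\s+(\\S+)", atom_lines))
  element <- vapply(am, `[`, "", 3L)
  obtype  <- vapply(am, `[`, "", 4L)
  n <- length(element)
  adj <- vector("list", n)
  if (length(bond_lines)) {
    bm <- regmatches(bond_lines,
                     regexec("START:\\s+(\\d+)\\s+END:\\s+(\\d+)", bond_lines))
    from <- as.integer(vapply(bm, `[`, "", 2L))
    to   <- as.integer(vapply(bm, `[`, "", 3L))
    for (i in seq_along(from)) {
      adj[[from[i]]] <- c(adj[[from[i]]], to[i])
      adj[[to[i]]]   <- c(adj[[to[i]]], from[i])
    }
  }
  heavy <- element != "H"
  list(element = element, obtype = obtype, adj = adj,
       heavy = heavy, mass = mass)
}

# Atom typing schemes for the fingerprint.  "element-aromatic" writes
# aromatic atoms (OpenBabel internal type ending in "ar") in lower case,
# SMILES-style; "openbabel" uses the raw OpenBabel internal atom type.
.atomTypes <- function(rep, scheme = c("element-aromatic", "openbabel")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    "element-aromatic" = ifelse(grepl("ar$", rep$obtype),
                                tolower(rep$element), rep$element),
    "openbabel" = rep$obtype)
}

# MolPrint2D environments over the heavy-atom graph: for each heavy atom,
# its type plus the sorted multisets of neighbour types at graph distance
# 1 and 2.  Returned as the set of distinct serialized feature strings.
.mpFingerprint <- function(rep, scheme = "element-aromatic") {
  type <- .atomTypes(rep, scheme)
  idx <- which(rep$heavy)
  feats <- vapply(idx, function(i) {
    d1 <- setdiff(rep$adj[[i]], i)
    d1 <- d1[rep$heavy[d1]]
    d2 <- setdiff(unique(unlist(rep$adj[d1])), c(i, d1))
    d2 <- d2[rep$heavy[d2]]
    paste(type[i],
          paste(.csort(type[d1]), collapse = ","),
          paste(.csort(type[d2]), collapse = ","),
          sep = "|")
  }, character(1))
  unique(feats)
}

#' Parse a SMILES string into a Structure
#'
#' Canonicalizes the SMILES, computes the MolPrint2D atom-environment
#' fingerprint, the average molecular weight and the heavy-atom count in
#' a single pass.  Unparsable SMILES raise a classed `ra_parse_error`
#' naming the offending input.
#'
#' @param smiles a single SMILES string.
#' @param scheme atom typing scheme for the fingerprint:
#'   `"element-aromatic"` (default; element symbol, lower case when the
#'   atom is aromatic) or `"openbabel"` (OpenBabel internal atom types).
#' @return a [Structure-class] object.
#' @examples
#' s <- structureFromSmiles("CCO")
#' s@heavyAtoms          # 3
#' length(s@fingerprint) # 3 distinct atom environments
#' @export
structureFromSmiles <- function(smiles, scheme = "element-aromatic") {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(smiles)) .parseError(smiles)
  can <- canonicalizeSmiles(smiles)
  if (is.na(can)) .parseError(smiles)
  rep <- .molReport(smiles)
  if (is.null(rep) || !any(rep$heavy)) .parseError(smiles)
  new("Structure",
      inputSmiles     = smiles,
      canonicalSmiles = can,
      fingerprint     = .mpFingerprint(rep, scheme),
      molWeight       = rep$mass,
      heavyAtoms      = sum(rep$heavy))
}

#' Parse many SMILES, collecting failures
#'
#' @param smiles character vector of SMILES.
#' @param scheme see [structureFromSmiles()].
#' @param onError `"error"` stops at the first unparsable SMILES;
#'   `"collect"` drops it and reports it in the `rejects` attribute.
#' @return named list of [Structure-class] objects keyed by input SMILES,
#'   with attribute `rejects` (character vector of unparsable inputs).
#' @export
parseStructures <- function(smiles, scheme = "element-aromatic",
                            onError = c("error", "collect")) {
  onError <- match.arg(onError)
  res <- list()
  rejects <- character()
  for (s in smiles) {
    st <- tryCatch(structureFromSmiles(s, scheme), ra_parse_error = function(e) e)
    if (inherits(st, "ra_parse_error")) {
      if (onError == "error") stop(st)
      rejects <- c(rejects, s)
    } else res[[s]] <- st
  }
  attr(res, "rejects") <- rejects
  res
}

#' MolPrint2D fingerprint of a structure
#'
#' Returns the set of atom-environment feature strings.  Each heavy atom
#' contributes one environment: its own atom type, the sorted multiset of
#' atom types at bond distance 1, and the sorted multiset at bond
#' distance 2 (shortest-path distances over the heavy-atom graph;
#' hydrogens are ignored).  Duplicate environments collapse, so the
#' number of features never exceeds the heavy-atom count and is invariant
#' to the atom ordering of the input SMILES.
#'
#' @param x a [Structure-class] object or a single SMILES string.
#' @param scheme atom typing scheme, see [structureFromSmiles()].
#' @return character vector: the set of feature strings.
#' @examples
#' molprint2d("c1ccccc1")  # benzene: one distinct environment
#' @export
molprint2d <- function(x, scheme = "element-aromatic") {
  if (is(x, "Structure")) return(x@fingerprint)
  structureFromSmiles(x, scheme)@fingerprint
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|A` \eqn{\cap} `B| / |A` \eqn{\cup} `B|` on the feature sets.  The
#' similarity of two structures is the Tanimoto index of their MolPrint2D
#' fingerprints.
#'
#' @param a,b [Structure-class] objects or character vectors of features.
#' @return similarity in `[0, 1]`.
#' @examples
#' tanimoto(c("x", "y", "z"), c("y", "z", "w"))  # 0.5
#' @export
tanimoto <- function(a, b) {
  if (is(a, "Structure")) a <- a@fingerprint
  if (is(b, "Structure")) b <- b@fingerprint
  a <- unique(a); b <- unique(b)
  if (!length(a) && !length(b))
    .raError("similarity of two empty fingerprints is undefined",
             class = "ra_similarity_error")
  length(intersect(a, b)) / length(union(a, b))
}
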