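## SMILES -> Molecule.  The chemistry (ring closure, aromaticity
## perception, kekulisation) is delegated to Open Babel through
## ChemmineOB; this file only reads the V2000 molblock Open Babel emits
## and applies organic-subset valence arithmetic for implicit hydrogens.

# default valences of the neutral organic subset
.STD_VALENCE <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                  F = 1, Cl = 1, Br = 1, I = 1)

#' Parse a SMILES string into a Molecule
#'
#' Converts SMILES to heavy-atom connectivity using Open Babel
#' (via \pkg{ChemmineOB}) and derives per-atom implicit-hydrogen counts
#' from standard organic-subset valence rules applied to the Kekulé bond
#' orders: implicit H = default valence minus the bond-order sum at the
#' atom.  Charged species and elements outside B, C, N, O, P, S and the
#' halogens are rejected.
#'
#' @param smiles a single SMILES string.
#' @param name compound name (defaults to the SMILES itself).
#' @param abbreviation short code (defaults to `name`).
#' @return a [Molecule-class] object.
#' @examples
#' \dontrun{
#' m <- parseSmiles("CC", "ethane")
#' molecularFormula(m)   # "C2H6"
#' }
#' @export
parseSmiles <- function(smiles, name = smiles, abbreviation = name) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    .stopf("tcaQSPR_parse_error", "smiles must be a single non-empty string")
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\t", name)),
    error = function(e) "")
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  cl <- grep("V2000", lines, fixed = TRUE)
  if (length(cl) != 1L)
    .stopf("tcaQSPR_parse_error", "unparsable SMILES: '%s'", smiles)
  counts <- lines[cl]
  nAtoms <- as.integer(substr(counts, 1, 3))
  nBonds <- as.integer(substr(counts, 4, 6))
  if (is.na(nAtoms) || nAtoms < 1L)
    .stopf("tcaQSPR_parse_error", "unparsable SMILES: '%s'", smiles)
  if (any(grepl("^M  (CHG|RAD|ISO)", lines)))
    .stopf("tcaQSPR_structural_error",
           "charged or radical species are not supported: '%s'", smiles)

  atomLines <- lines[cl + seq_len(nAtoms)]
  elements <- trimws(substr(atomLines, 32, 34))
  bad <- setdiff(elements, names(.STD_VALENCE))
  if (length(bad) > 0)
    .stopf("tcaQSPR_structural_error",
           "unsupported element(s) %s in '%s'",
           paste(bad, collapse = ", "), smiles)

  if (nBonds > 0) {
    bondLines <- lines[cl + nAtoms + seq_len(nBonds)]
    bonds <- cbind(as.integer(substr(bondLines, 1, 3)),
                   as.integer(substr(bondLines, 4, 6)))
    orders <- as.integer(substr(bondLines, 7, 9))
  } else {
    bonds <- matrix(integer(0), 0, 2)
    orders <- integer(0)
  }

  valUsed <- numeric(nAtoms)
  for (j in seq_len(nBonds)) {
    valUsed[bonds[j, 1]] <- valUsed[bonds[j, 1]] + orders[j]
    valUsed[bonds[j, 2]] <- valUsed[bonds[j, 2]] + orders[j]
  }
  hyd <- .STD_VALENCE[elements] - valUsed
  if (any(hyd < 0))
    .stopf("tcaQSPR_structural_error",
           "hypervalent atom (valence rules violated) in '%s'", smiles)

  tryCatch(
    new("Molecule",
        name = name, abbreviation = abbreviation, smiles = smiles,
        elements = unname(elements), hydrogens = as.integer(unname(hyd)),
        bonds = bonds),
    error = function(e) {
      if (inherits(e, "tcaQSPR_error")) stop(e)
      .stopf("tcaQSPR_structural_error", "%s (input '%s')",
             conditionMessage(e), smiles)
    })
}

.parseFormula <- function(formula) {
  toks <- regmatches(formula,
                     gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (paste(toks, collapse = "") != formula)
    .stopf("tcaQSPR_parse_error", "malformed molecular formula '%s'", formula)
  el <- gsub("[0-9]", "", toks)
  ct <- vapply(toks, function(t) {
    d <- gsub("[A-Za-z]", "", t)
    if (d == "") 1L else as.integer(d)
  }, integer(1))
  tapply(ct, el, sum)
}

#' Molecular formula of a Molecule
#'
#' Hill-ordered formula (carbon, hydrogen, then remaining elements
#' alphabetically) assembled from heavy atoms and implicit-hydrogen counts.
#' Used by the dataset loader to lock every fixture SMILES against the
#' published formula.
#'
#' @param mol a [Molecule-class] object.
#' @return a single string, e.g. `"C16H13ClN2O"`.
#' @export
molecularFormula <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  counts <- table(mol@elements)
  nH <- sum(mol@hydrogens)
  els <- names(counts)
  ord <- c(intersect(c("C"), els), if (nH > 0) "H",
           sort(setdiff(els, "C")))
  part <- vapply(ord, function(e) {
    k <- if (e == "H") nH else as.integer(counts[[e]])
    if (k == 1L) e else paste0(e, k)
  }, character(1))
  paste(part, collapse = "")
}
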