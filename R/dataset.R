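## The fifteen-drug study dataset: identities, curated SMILES, six
## physicochemical properties, and the published reference index tables.
##
## The published study cites PubChem for the structures but prints no
## SMILES; the strings shipped here are the standard structures of the
## named drugs and every record is locked by a molecular-formula
## cross-check at load time, so a wrong structure fails loudly.

.PROPERTY_COLS <- c("BP", "E", "FP", "MR", "P", "MV")
.INDEX_COLS <- c("W", "WW", "H", "D", "DH")

#' Load the TCA drug records
#'
#' Reads the packaged fixture (name, three-letter abbreviation, molecular
#' formula, SMILES, and the six physicochemical properties: boiling point
#' BP, enthalpy of vaporization E, flash point FP, molar refractivity MR,
#' polarizability P, molar volume MV).  Property values are carried as
#' unitless reals.  Each record's SMILES is parsed and its heavy-atom and
#' hydrogen counts are checked against the stated formula; a mismatch
#' raises a fixture integrity error naming the drug.
#'
#' @param path CSV file to read; defaults to the packaged fixture.
#' @return a data.frame with 15 validated records.
#' @examples
#' \dontrun{
#' drugs <- loadDrugs()
#' drugs[drugs$abbreviation == "DZM", .PROPERTY_COLS]
#' }
#' @export
loadDrugs <- function(path = system.file("extdata", "tca_drugs.csv",
                                         package = "tcaQSPR")) {
  if (!nzchar(path) || !file.exists(path))
    .stopf("tcaQSPR_fixture_error", "drug fixture file not found")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "abbreviation", "formula", "smiles", .PROPERTY_COLS)
  if (!all(need %in% names(df)))
    .stopf("tcaQSPR_fixture_error", "drug fixture lacks required columns")
  if (anyDuplicated(df$abbreviation))
    .stopf("tcaQSPR_fixture_error", "drug abbreviations are not unique")
  for (i in seq_len(nrow(df))) {
    mol <- parseSmiles(df$smiles[i], df$name[i], df$abbreviation[i])
    got <- molecularFormula(mol)
    if (!identical(got, df$formula[i]))
      .stopf("tcaQSPR_fixture_error",
             "SMILES/formula mismatch for %s: parsed %s, expected %s",
             df$name[i], got, df$formula[i])
  }
  df
}

#' Parse the fixture drugs into Molecule objects
#'
#' @param drugs a data.frame as returned by [loadDrugs()].
#' @return a named list of [Molecule-class] objects keyed by abbreviation.
#' @export
loadMolecules <- function(drugs = loadDrugs()) {
  mols <- lapply(seq_len(nrow(drugs)), function(i)
    parseSmiles(drugs$smiles[i], drugs$name[i], drugs$abbreviation[i]))
  names(mols) <- drugs$abbreviation
  mols
}

#' Load the published reference index tables
#'
#' Verbatim transcription of the published per-drug index values for one
#' hydrogen mode, with a logical `suspect` column marking heavy-mode rows
#' whose printed values are not reproduced by the stated H-suppressed
#' construction (see [discrepancyReport()] for the analysis).  Used by
#' tests, by the discrepancy report, and as the default input of the
#' regression-stage reproduction.
#'
#' @param mode `"heavy"` or `"all-h"`.
#' @return a data.frame with columns `drug, W, WW, H, D, DH, suspect`.
#' @export
loadReferenceIndices <- function(mode = c("heavy", "all-h")) {
  mode <- match.arg(mode)
  path <- system.file("extdata", "reference_indices.csv",
                      package = "tcaQSPR")
  if (!nzchar(path))
    .stopf("tcaQSPR_fixture_error", "reference index fixture not found")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$mode == mode, c("drug", .INDEX_COLS, "suspect")]
  if (nrow(df) == 0)
    .stopf("tcaQSPR_fixture_error", "no reference rows for mode '%s'", mode)
  rownames(df) <- NULL
  df
}
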