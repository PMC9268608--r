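#' Stereoisomer identifiers
#'
#' The four chiral forms of the screened lignan ligand, in the fixed column
#' order used throughout the package: `trans_minus`, `trans_plus`,
#' `cis_minus`, `cis_plus`.
#'
#' @return Character vector of length 4.
#' @examples
#' isomer_levels()
#' @export
isomer_levels <- function() {
  c("trans_minus", "trans_plus", "cis_minus", "cis_plus")
}

#' Protein functional groups
#'
#' The four mechanism-based groups the candidate proteins are classified
#' into: anti-apoptosis and survival, cell growth and proliferation,
#' metastasis, and signalling molecules.
#'
#' @return Character vector of length 4.
#' @export
protein_group_levels <- function() {
  c("anti_apoptosis_survival", "cell_growth_proliferation",
    "metastasis", "signaling")
}

#' Subcellular localizations and accessibility weights
#'
#' Drug-accessibility weighting by subcellular localization: membrane-bound
#' proteins have the highest chance of drug exposure (weight 3), cytoplasmic
#' proteins intermediate (2), and nuclear proteins the lowest (1).
#'
#' @param localization Character vector of localizations (`"membrane"`,
#'   `"cytoplasm"` or `"nucleus"`).
#' @return `localization_levels()` returns the three valid localization
#'   strings; `localization_weight()` returns the integer weight for each
#'   element of `localization`.
#' @examples
#' localization_weight(c("membrane", "nucleus"))
#' @export
localization_levels <- function() {
  c("membrane", "cytoplasm", "nucleus")
}

#' @rdname localization_levels
#' @export
localization_weight <- function(localization) {
  weights <- c(membrane = 3L, cytoplasm = 2L, nucleus = 1L)
  bad <- setdiff(unique(localization), names(weights))
  if (length(bad) > 0L) {
    stop("unknown localization(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(weights[localization])
}

#' Interaction types recognised in interaction tables
#'
#' @return Character vector: `pi_pi`, `hydrogen_bond`, `pi_sulfur`,
#'   `hydrophobic`.
#' @export
interaction_types <- function() {
  c("pi_pi", "hydrogen_bond", "pi_sulfur", "hydrophobic")
}
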