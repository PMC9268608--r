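#' @importFrom utils read.delim write.table read.csv write.csv
NULL

score_table_columns <- function() {
  c("protein", "pdb", "group", "localization", isomer_levels(),
    "inhibitor", "inhibitor_score")
}

numeric_score_columns <- function() {
  c(isomer_levels(), "inhibitor_score")
}

#' Construct and validate a docking-score table
#'
#' A score table holds one row per candidate protein: its PDB code,
#' functional group, subcellular localization, the docking score of each of
#' the four stereoisomers (kcal/mol, more negative = stronger predicted
#' binding), and the name and docking score of a known inhibitor of that
#' protein.
#'
#' @param df A data.frame with columns `protein`, `pdb`, `group`,
#'   `localization`, `trans_minus`, `trans_plus`, `cis_minus`, `cis_plus`,
#'   `inhibitor`, `inhibitor_score`.
#' @param provenance Free-text label recording where the table came from.
#' @return A `score_table` (a validated data.frame; row order preserved).
#' @seealso [load_score_table()], [example_score_table()]
#' @export
score_table <- function(df, provenance = "unspecified") {
  missing <- setdiff(score_table_columns(), names(df))
  if (length(missing) > 0L) {
    stop("score table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[, score_table_columns()]
  rownames(df) <- NULL
  for (col in c("protein", "pdb", "group", "localization", "inhibitor")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in numeric_score_columns()) {
    if (!is.numeric(df[[col]])) {
      stop("score column '", col, "' is not numeric", call. = FALSE)
    }
    if (anyNA(df[[col]]) || any(!is.finite(df[[col]]))) {
      bad <- which(is.na(df[[col]]) | !is.finite(df[[col]]))[1L]
      stop("non-finite score in column '", col, "', row ", bad, call. = FALSE)
    }
  }
  dup <- df$protein[duplicated(df$protein)]
  if (length(dup) > 0L) {
    stop("duplicate protein name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(df$group), protein_group_levels())
  if (length(bad_group) > 0L) {
    stop("unknown protein group(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  bad_loc <- setdiff(unique(df$localization), localization_levels())
  if (length(bad_loc) > 0L) {
    stop("unknown localization(s): ", paste(bad_loc, collapse = ", "),
         call. = FALSE)
  }
  bad_pdb <- !grepl("^[0-9][A-Za-z0-9]{3}$", df$pdb)
  if (any(bad_pdb)) {
    stop("malformed PDB code(s): ",
         paste(unique(df$pdb[bad_pdb]), collapse = ", "), call. = FALSE)
  }
  attr(df, "provenance") <- provenance
  class(df) <- c("score_table", "data.frame")
  df
}

#' Read a docking-score table from TSV or CSV
#'
#' @param path Path to a delimited text file with a header row naming the
#'   columns `protein`, `pdb`, `group`, `localization`, `trans_minus`,
#'   `trans_plus`, `cis_minus`, `cis_plus`, `inhibitor`, `inhibitor_score`.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return A [score_table()].
#' @examples
#' tab <- load_score_table(
#'   system.file("extdata", "table1_scores.tsv", package = "stereoscreen"))
#' nrow(tab)
#' @export
load_score_table <- function(path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (format == "tsv") "\t" else ","
  raw <- read.delim(path, sep = sep, colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(score_table_columns(), names(raw))
  if (length(missing) > 0L) {
    stop("score table at '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in numeric_score_columns()) {
    val <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(val) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop("non-numeric value '", raw[[col]][bad[1L]], "' in column '", col,
           "', row ", bad[1L], " of ", path, call. = FALSE)
    }
    raw[[col]] <- val
  }
  score_table(raw, provenance = path)
}

#' Write a docking-score table
#'
#' Inverse of [load_score_table()]: `load_score_table(write_score_table(x))`
#' reproduces `x`.
#'
#' @param table A [score_table()].
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path, format = c("tsv", "csv")) {
  stopifnot(inherits(table, "score_table"))
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  out <- as.data.frame(table)
  for (col in numeric_score_columns()) {
    out[[col]] <- format(out[[col]], digits = 15, trim = TRUE,
                         scientific = FALSE)
  }
  write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged example docking-score table
#'
#' Sixty candidate proteins of a CSF1R-centred breast-cancer progression
#' pathway with the docking scores of the four ligand stereoisomers and of a
#' known inhibitor each. Group sizes are 7 (anti-apoptosis/survival), 22
#' (cell growth/proliferation), 10 (metastasis) and 21 (signalling),
#' following the source table's section layout. Localizations were derived
#' from the published 3/2/1 accessibility weights (membrane/cytoplasm/
#' nucleus). One PDB code was normalised from a typeset "5 x 02" to `5X02`.
#'
#' @return A [score_table()] with 60 rows.
#' @export
example_score_table <- function() {
  load_score_table(system.file("extdata", "table1_scores.tsv",
                               package = "stereoscreen", mustWork = TRUE))
}

#' The packaged example interaction table
#'
#' Interacting residues, by interaction type, for the poses of the four
#' stereoisomers and the known inhibitor on CSF1R and EGFR. Residue labels
#' are kept exactly as published (including pexidartinib's `Arg459`).
#'
#' @return A list of [interaction_profile()] objects.
#' @export
example_interaction_profiles <- function() {
  load_interaction_table(system.file("extdata", "table3_interactions.tsv",
                                     package = "stereoscreen",
                                     mustWork = TRUE))
}

# ---- residue labels ---------------------------------------------------------

#' Parse and format residue labels
#'
#' Residue labels combine a three-letter amino-acid code with a sequence
#' number, e.g. `"Trp550"`. The code is compared case-insensitively and
#' canonicalised to title case.
#'
#' @param labels Character vector of residue labels.
#' @return `parse_residue()` returns a data.frame with columns `code` and
#'   `number`; `format_residue()` the canonical label strings.
#' @examples
#' parse_residue("TRP550")
#' @export
parse_residue <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Za-z]{3})([0-9]+)$", labels))
  bad <- labels[vapply(m, length, integer(1)) != 3L]
  if (length(bad) > 0L) {
    stop("unparseable residue label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  code <- vapply(m, `[`, character(1), 2L)
  code <- paste0(toupper(substr(code, 1L, 1L)), tolower(substr(code, 2L, 3L)))
  number <- as.integer(vapply(m, `[`, character(1), 3L))
  data.frame(code = code, number = number, stringsAsFactors = FALSE)
}

#' @rdname parse_residue
#' @export
format_residue <- function(labels) {
  p <- parse_residue(labels)
  paste0(p$code, p$number)
}

# ---- interaction profiles ---------------------------------------------------

#' Interaction profile of one ligand-protein pose
#'
#' Holds, for one (protein, ligand) pair, the set of interacting residues of
#' each interaction type (`pi_pi`, `hydrogen_bond`, `pi_sulfur`,
#' `hydrophobic`). Sets may be empty; residue labels are canonicalised via
#' [format_residue()].
#'
#' @param protein,ligand Character scalars naming the pose.
#' @param interactions Named list mapping interaction types to character
#'   vectors of residue labels.
#' @return An `interaction_profile` object.
#' @export
interaction_profile <- function(protein, ligand, interactions = list()) {
  bad <- setdiff(names(interactions), interaction_types())
  if (length(bad) > 0L) {
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  full <- setNames(vector("list", length(interaction_types())),
                   interaction_types())
  for (ty in interaction_types()) {
    res <- interactions[[ty]] %||% character(0)
    full[[ty]] <- if (length(res) > 0L) unique(format_residue(res))
                  else character(0)
  }
  structure(list(protein = protein, ligand = ligand, interactions = full),
            class = "interaction_profile")
}

#' @export
print.interaction_profile <- function(x, ...) {
  cat("Interaction profile:", x$protein, "/", x$ligand, "\n")
  for (ty in interaction_types()) {
    res <- x$interactions[[ty]]
    if (length(res) > 0L) cat(" ", ty, ":", paste(res, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read an interaction table
#'
#' Expects columns `protein`, `ligand`, `interaction_type` and `residues`
#' (semicolon-separated residue labels; may be empty). Rows for the same
#' (protein, ligand) pair are aggregated into a single profile.
#'
#' @param path Path to a TSV file.
#' @return A named list of [interaction_profile()] objects, keyed
#'   `"protein|ligand"`.
#' @export
load_interaction_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("protein", "ligand", "interaction_type", "residues")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0L) {
    stop("interaction table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(raw$interaction_type), interaction_types())
  if (length(bad) > 0L) {
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keys <- unique(paste(raw$protein, raw$ligand, sep = "|"))
  profiles <- setNames(vector("list", length(keys)), keys)
  for (key in keys) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    rows <- raw[raw$protein == parts[1L] & raw$ligand == parts[2L], ,
                drop = FALSE]
    ints <- list()
    for (i in seq_len(nrow(rows))) {
      res <- strsplit(rows$residues[i], ";", fixed = TRUE)[[1L]]
      res <- res[nzchar(trimws(res))]
      ty <- rows$interaction_type[i]
      ints[[ty]] <- c(ints[[ty]], trimws(res))
    }
    profiles[[key]] <- interaction_profile(parts[1L], parts[2L], ints)
  }
  profiles
}

#' Look up an interaction profile by protein and ligand
#'
#' Matching is case-insensitive on the ligand name so that inhibitor names
#' printed with different capitalisation still resolve.
#'
#' @param profiles A list of [interaction_profile()] objects.
#' @param protein,ligand Names of the pose.
#' @return The matching profile, or `NULL` when absent.
#' @export
find_profile <- function(profiles, protein, ligand) {
  for (p in profiles) {
    if (identical(p$protein, protein) &&
        tolower(p$ligand) == tolower(ligand)) {
      return(p)
    }
  }
  NULL
}

# ---- results serialization --------------------------------------------------

#' Write pipeline results to JSON or CSV
#'
#' JSON output has recursively sorted keys and 2-space indentation so that
#' repeated runs on identical inputs are byte-identical. CSV output requires
#' a data.frame.
#'
#' @param results A list (JSON) or data.frame (JSON or CSV).
#' @param path Output file path.
#' @param format `"json"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(results)) {
      stop("CSV output requires a data.frame", call. = FALSE)
    }
    write.csv(results, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(sort_keys(results), path, auto_unbox = TRUE,
                         digits = NA, pretty = 2, null = "null")
  }
  invisible(path)
}
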