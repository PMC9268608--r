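#' Competition ranks of the four isomer docking scores
#'
#' Re-expresses a protein's four isomer docking scores as 4-3-2-1 rank
#' scores: 4 for the best (most negative) predicted binding, down to 1 for
#' the worst. Ranks are competition ("max") ranks, `rank = 4 - (number of
#' isomers with a strictly better score)`, so tied scores share a rank.
#'
#' @param scores Numeric vector of four finite docking scores (kcal/mol),
#'   named by [isomer_levels()] or given in that order.
#' @return Named integer vector of ranks in isomer order.
#' @examples
#' competition_ranks(c(-10.60, -9.68, -9.62, -10.57)) # 4 2 1 3
#' @export
competition_ranks <- function(scores) {
  scores <- as_isomer_scores(scores)
  ranks <- vapply(scores, function(s) 4L - sum(scores < s), integer(1))
  setNames(ranks, isomer_levels())
}

as_isomer_scores <- function(scores) {
  if (length(scores) != 4L) {
    stop("expected exactly four isomer scores", call. = FALSE)
  }
  stopifnot_finite(scores, "isomer scores")
  if (!is.null(names(scores))) {
    missing <- setdiff(isomer_levels(), names(scores))
    if (length(missing) > 0L) {
      stop("isomer score(s) missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    scores <- scores[isomer_levels()]
  } else {
    names(scores) <- isomer_levels()
  }
  scores
}

#' Apply the accessibility weight to a rank vector
#'
#' Multiplies each 4-3-2-1 rank by the protein's drug-accessibility weight
#' (3 membrane, 2 cytoplasm, 1 nucleus).
#'
#' @param ranks Named integer vector from [competition_ranks()].
#' @param localization One of [localization_levels()].
#' @return Named integer vector of weighted ranks, with the weight attached
#'   as attribute `"weight"`.
#' @examples
#' apply_weight(competition_ranks(c(-10.60, -9.68, -9.62, -10.57)),
#'              "cytoplasm") # 8 4 2 6
#' @export
apply_weight <- function(ranks, localization) {
  w <- localization_weight(localization)
  structure(setNames(as.integer(ranks[isomer_levels()] * w),
                     isomer_levels()),
            weight = w)
}

#' Per-protein rank and weighted-rank table
#'
#' @param table A [score_table()].
#' @return A data.frame with one row per protein: group, localization,
#'   weight, the four ranks (`rank_<isomer>`) and the four weighted ranks
#'   (`weighted_<isomer>`), in the input row order.
#' @export
rank_table <- function(table) {
  stopifnot(inherits(table, "score_table"))
  iso <- isomer_levels()
  ranks <- t(apply(as.matrix(as.data.frame(table)[, iso]), 1L,
                   competition_ranks))
  weight <- localization_weight(table$localization)
  out <- data.frame(protein = table$protein, group = table$group,
                    localization = table$localization, weight = weight,
                    stringsAsFactors = FALSE)
  for (i in seq_along(iso)) out[[paste0("rank_", iso[i])]] <- ranks[, i]
  for (i in seq_along(iso)) {
    out[[paste0("weighted_", iso[i])]] <- ranks[, i] * weight
  }
  out
}

#' Summarise rank scores within one protein group
#'
#' Sums the 4-3-2-1 ranks and the weighted ranks (rank x accessibility
#' weight) over the proteins of one group and determines the preferred
#' isomer as the one attaining the maximal weighted sum. Ties for the
#' maximum are reported, not silently broken: `preferred_isomer` is the
#' first tied isomer in [isomer_levels()] order and `tied_isomers` lists
#' all of them.
#'
#' @param table A [score_table()].
#' @param group One of [protein_group_levels()].
#' @return A `group_score_summary`: list with `group`, `n_proteins`,
#'   `sum_scores`, `weighted_sums`, `preferred_isomer`, `tie`,
#'   `tied_isomers`.
#' @examples
#' tab <- example_score_table()
#' summarize_group(tab, "cell_growth_proliferation")$weighted_sums
#' @export
summarize_group <- function(table, group) {
  stopifnot(inherits(table, "score_table"))
  group <- match.arg(group, protein_group_levels())
  sub <- table[table$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("group '", group, "' has no proteins in this table", call. = FALSE)
  }
  rt <- rank_table(score_table(sub, provenance = attr(table, "provenance")))
  iso <- isomer_levels()
  sum_scores <- setNames(
    vapply(iso, function(i) sum(rt[[paste0("rank_", i)]]), numeric(1)), iso)
  weighted_sums <- setNames(
    vapply(iso, function(i) sum(rt[[paste0("weighted_", i)]]), numeric(1)),
    iso)
  best <- max(weighted_sums)
  tied <- iso[weighted_sums == best]
  structure(
    list(group = group,
         n_proteins = nrow(sub),
         sum_scores = as.integer(sum_scores) |> setNames(iso),
         weighted_sums = as.integer(weighted_sums) |> setNames(iso),
         preferred_isomer = tied[1L],
         tie = length(tied) > 1L,
         tied_isomers = tied),
    class = "group_score_summary")
}

#' @export
print.group_score_summary <- function(x, ...) {
  cat("Group:", x$group, sprintf("(%d proteins)\n", x$n_proteins))
  m <- rbind(`sum of ranks` = x$sum_scores,
             `weighted sum` = x$weighted_sums)
  print(m)
  cat("Preferred isomer:", x$preferred_isomer,
      if (x$tie) sprintf("(tied: %s)", paste(x$tied_isomers, collapse = ", "))
      else "", "\n")
  invisible(x)
}

#' Preferred isomer per protein group
#'
#' Runs [summarize_group()] for every group present in the table.
#'
#' @param table A [score_table()].
#' @return Named list of `group_score_summary` objects, one per group, in
#'   [protein_group_levels()] order.
#' @examples
#' rep <- preferred_isomer_report(example_score_table())
#' vapply(rep, `[[`, character(1), "preferred_isomer")
#' @export
preferred_isomer_report <- function(table) {
  stopifnot(inherits(table, "score_table"))
  groups <- intersect(protein_group_levels(), unique(table$group))
  setNames(lapply(groups, function(g) summarize_group(table, g)), groups)
}
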