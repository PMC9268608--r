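#' @importFrom stats var sd aov setNames
NULL

#' Variance of one protein's isomer docking scores
#'
#' Sample variance (n-1 denominator) and sample standard deviation of a
#' protein's stereoisomer docking scores. Large variance flags proteins
#' whose predicted binding is stereoselective. Published "SD" screens of
#' this kind are sometimes numerically the sample variance; both statistics
#' are therefore reported under unambiguous names.
#'
#' @param scores Either a single-row [score_table()] or a numeric vector of
#'   at least two finite scores.
#' @param protein Optional protein name (taken from the score table when
#'   one is supplied).
#' @return A list with `protein`, `n`, `sample_variance` ((kcal/mol)^2) and
#'   `sample_sd` (kcal/mol).
#' @examples
#' tab <- example_score_table()
#' isomer_variance(tab[tab$protein == "CSF1R", ])$sample_variance
#' @export
isomer_variance <- function(scores, protein = NULL) {
  if (inherits(scores, "score_table") || is.data.frame(scores)) {
    if (nrow(scores) != 1L) {
      stop("supply a single-row score table or a numeric vector",
           call. = FALSE)
    }
    protein <- protein %||% scores$protein
    scores <- as.numeric(scores[1L, isomer_levels()])
  }
  stopifnot_finite(scores, "scores")
  if (length(scores) < 2L) {
    stop("variance needs at least two scores", call. = FALSE)
  }
  v <- var(scores)
  list(protein = protein, n = length(scores),
       sample_variance = v, sample_sd = sqrt(v))
}

#' Rank proteins by isomer-score variability
#'
#' Computes [isomer_variance()] for each protein of a score table and
#' orders the result by descending sample variance (ties broken by protein
#' name, so the ordering is deterministic).
#'
#' @param table A [score_table()].
#' @param restrict Optional character vector restricting the computation to
#'   the named proteins; unknown names are an error.
#' @return A data.frame with columns `protein`, `n`, `sample_variance`,
#'   `sample_sd`, sorted by decreasing variance.
#' @export
rank_by_variability <- function(table, restrict = NULL) {
  stopifnot(inherits(table, "score_table"))
  if (!is.null(restrict)) {
    unknown <- setdiff(restrict, table$protein)
    if (length(unknown) > 0L) {
      stop("protein(s) not in table: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    table <- table[table$protein %in% restrict, , drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(table)), function(i) {
    iv <- isomer_variance(as.numeric(table[i, isomer_levels()]),
                          protein = table$protein[i])
    data.frame(protein = iv$protein, n = iv$n,
               sample_variance = iv$sample_variance,
               sample_sd = iv$sample_sd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$sample_variance, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA across isomer replicate scores
#'
#' Classic one-way analysis of variance of replicate docking scores (e.g.
#' repeated stochastic docking runs) grouped by isomer, fitted with
#' [stats::aov()]. A single score per isomer cannot support an ANOVA; each
#' group must have at least two replicates (use [isomer_variance()] for the
#' descriptive one-score-per-isomer case).
#'
#' @param replicates Named list mapping group labels (typically isomer
#'   names) to numeric vectors of replicate scores.
#' @param alpha Significance level for the `significant` flag (default
#'   0.01).
#' @return A list with `f_statistic`, `df_between`, `df_within`, `p_value`
#'   and `significant`.
#' @examples
#' one_way_anova(list(a = c(1, 2, 1.5), b = c(3, 3.5, 2.9)))
#' @export
one_way_anova <- function(replicates, alpha = 0.01) {
  if (!is.list(replicates) || length(replicates) < 2L) {
    stop("need at least two replicate groups", call. = FALSE)
  }
  sizes <- vapply(replicates, length, integer(1))
  if (any(sizes < 2L)) {
    stop("every group needs at least two replicates; ",
         "a single score per group is ill-posed for ANOVA", call. = FALSE)
  }
  for (g in names(replicates)) stopifnot_finite(replicates[[g]], g)
  dat <- data.frame(
    score = unlist(replicates, use.names = FALSE),
    grp = factor(rep(names(replicates), times = sizes)))
  fit <- aov(score ~ grp, data = dat)
  tab <- summary(fit)[[1L]]
  f <- tab[["F value"]][1L]
  p <- tab[["Pr(>F)"]][1L]
  list(f_statistic = f,
       df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L],
       p_value = p,
       significant = p < alpha)
}
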