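#' Energy criterion of the target-selection gate
#'
#' A candidate passes when the isomer's docking score is strictly lower
#' (more negative, i.e. stronger predicted binding) than the known
#' inhibitor's score. Ties fail.
#'
#' @param isomer_score,inhibitor_score Finite docking scores in kcal/mol;
#'   vectors are recycled elementwise.
#' @return Logical vector.
#' @examples
#' passes_energy_criterion(-11.84, -11.59) # TRUE
#' @export
passes_energy_criterion <- function(isomer_score, inhibitor_score) {
  stopifnot_finite(isomer_score, "isomer_score")
  stopifnot_finite(inhibitor_score, "inhibitor_score")
  isomer_score < inhibitor_score
}

#' Binding-site similarity as interacting-residue overlap
#'
#' Jaccard index |A intersect B| / |A union B| over the union of residue
#' labels across the selected interaction types of two poses on the same
#' protein. Serves as a reproducible proxy for the visual "same binding
#' site" judgement of the screening gate. When both residue unions are
#' empty the similarity is vacuously 1 and the result carries attribute
#' `vacuous = TRUE`.
#'
#' @param profile_a,profile_b [interaction_profile()] objects for the same
#'   protein.
#' @param types Character vector of interaction types to pool, or `"all"`.
#' @return Numeric scalar in \[0, 1\].
#' @examples
#' pr <- example_interaction_profiles()
#' residue_overlap(find_profile(pr, "CSF1R", "trans_minus"),
#'                 find_profile(pr, "CSF1R", "Pexidartinib")) # 1/6
#' @export
residue_overlap <- function(profile_a, profile_b, types = "all") {
  stopifnot(inherits(profile_a, "interaction_profile"),
            inherits(profile_b, "interaction_profile"))
  if (!identical(profile_a$protein, profile_b$protein)) {
    stop("profiles refer to different proteins: ", profile_a$protein,
         " vs ", profile_b$protein, call. = FALSE)
  }
  if (identical(types, "all")) types <- interaction_types()
  bad <- setdiff(types, interaction_types())
  if (length(bad) > 0L) {
    stop("unknown interaction type(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  a <- unique(unlist(profile_a$interactions[types], use.names = FALSE))
  b <- unique(unlist(profile_b$interactions[types], use.names = FALSE))
  if (length(a) == 0L && length(b) == 0L) {
    return(structure(1, vacuous = TRUE))
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Run the two-criterion target-selection gate over a score table
#'
#' For one isomer, evaluates every protein of the table against (1) the
#' energy criterion versus its known inhibitor and (2) the binding-site
#' similarity criterion (residue overlap of the isomer pose and the
#' inhibitor pose at or above `threshold`). Where interaction profiles for
#' the protein are unavailable the site criterion is recorded as `NA` and
#' the overall call falls back to the energy criterion alone, with
#' `site_data_available = FALSE` flagging the degradation.
#'
#' @param table A [score_table()].
#' @param profiles A list of [interaction_profile()] objects (may be
#'   empty).
#' @param isomer One of [isomer_levels()].
#' @param threshold Site-similarity threshold in \[0, 1\] (default 0.1: any
#'   shared pocket residue among typical small printed residue sets
#'   passes).
#' @param types Interaction types passed to [residue_overlap()].
#' @return A data.frame of target calls, one row per protein, sorted by
#'   protein name: scores, `energy_pass`, `site_similarity`, `site_pass`,
#'   `site_data_available`, `overall_pass`.
#' @export
call_targets <- function(table, profiles = list(), isomer,
                         threshold = 0.1, types = "all") {
  stopifnot(inherits(table, "score_table"))
  isomer <- match.arg(isomer, isomer_levels())
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  tab <- as.data.frame(table)[order(table$protein), , drop = FALSE]
  n <- nrow(tab)
  sim <- rep(NA_real_, n)
  site_pass <- rep(NA, n)
  site_avail <- rep(FALSE, n)
  for (i in seq_len(n)) {
    pa <- find_profile(profiles, tab$protein[i], isomer)
    pb <- find_profile(profiles, tab$protein[i], tab$inhibitor[i])
    if (!is.null(pa) && !is.null(pb)) {
      sim[i] <- as.numeric(residue_overlap(pa, pb, types = types))
      site_pass[i] <- sim[i] >= threshold
      site_avail[i] <- TRUE
    }
  }
  energy_pass <- passes_energy_criterion(tab[[isomer]], tab$inhibitor_score)
  overall <- ifelse(site_avail, energy_pass & site_pass, energy_pass)
  data.frame(protein = tab$protein,
             isomer = isomer,
             isomer_score = tab[[isomer]],
             inhibitor = tab$inhibitor,
             inhibitor_score = tab$inhibitor_score,
             energy_pass = energy_pass,
             site_similarity = sim,
             site_pass = site_pass,
             site_data_available = site_avail,
             overall_pass = overall,
             stringsAsFactors = FALSE)
}
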