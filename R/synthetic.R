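#' @importFrom stats rnorm lm coef
NULL

default_group_isomer_effects <- function() {
  # kcal/mol offsets (negative = better binding); trans_minus planted best
  # in three groups, cis_plus best in metastasis, mirroring the qualitative
  # structure the pipeline is meant to recover
  eff <- rbind(
    anti_apoptosis_survival   = c(-0.8,  0.0, -0.4, -0.3),
    cell_growth_proliferation = c(-0.8,  0.0, -0.4, -0.3),
    metastasis                = c(-0.4,  0.0, -0.3, -0.8),
    signaling                 = c(-0.8,  0.0, -0.4, -0.3))
  colnames(eff) <- isomer_levels()
  eff
}

#' Configuration for the docking-score table generator
#'
#' Defines a proteins-by-isomers score model: `score(protein, isomer) =
#' base_score_mean + group_isomer_effect + N(0, noise_sd^2)`, with a known
#' inhibitor scored at `base_score_mean + inhibitor_offset` and
#' localizations drawn from `localization_probabilities`. Defaults emulate
#' the screened study system: 15 proteins per group (60 total), base score
#' -9 kcal/mol, within-protein noise 0.5 kcal/mol, and planted effects
#' that make `trans_minus` the best isomer in three groups and `cis_plus`
#' the best in the metastasis group.
#'
#' @param proteins_per_group Number of proteins generated per group.
#' @param base_score_mean Baseline docking score (kcal/mol).
#' @param group_isomer_effects 4 x 4 numeric matrix (groups x isomers) of
#'   score offsets in kcal/mol; negative = better binding.
#' @param noise_sd Gaussian noise SD per score cell (kcal/mol, >= 0).
#' @param inhibitor_offset Offset of the inhibitor score from the baseline.
#' @param localization_probabilities Probabilities of membrane / cytoplasm /
#'   nucleus assignment (must sum to 1).
#' @param seed Integer seed governing all stochastic draws.
#' @return A `score_sim_config` list.
#' @export
score_sim_config <- function(proteins_per_group = 15L,
                             base_score_mean = -9,
                             group_isomer_effects =
                               default_group_isomer_effects(),
                             noise_sd = 0.5,
                             inhibitor_offset = 0,
                             localization_probabilities =
                               c(membrane = 0.10, cytoplasm = 0.75,
                                 nucleus = 0.15),
                             seed = 1L) {
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be >= 0", call. = FALSE)
  }
  if (proteins_per_group < 1L) {
    stop("proteins_per_group must be >= 1", call. = FALSE)
  }
  eff <- as.matrix(group_isomer_effects)
  if (!all(protein_group_levels() %in% rownames(eff)) ||
      !all(isomer_levels() %in% colnames(eff))) {
    stop("group_isomer_effects needs rows ", "for every protein group and ",
         "columns for every isomer", call. = FALSE)
  }
  p <- localization_probabilities
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("localization_probabilities must be 3 non-negative values ",
         "summing to 1", call. = FALSE)
  }
  names(p) <- localization_levels()
  structure(list(proteins_per_group = as.integer(proteins_per_group),
                 base_score_mean = base_score_mean,
                 group_isomer_effects =
                   eff[protein_group_levels(), isomer_levels()],
                 noise_sd = noise_sd,
                 inhibitor_offset = inhibitor_offset,
                 localization_probabilities = p,
                 seed = as.integer(seed)),
            class = "score_sim_config")
}

#' Generate a docking-score table with planted isomer preferences
#'
#' Draws a [score_table()] from a [score_sim_config()]. With `noise_sd =
#' 0` the competition ranks of every protein in a group equal the rank
#' order of that group's planted effects; at positive noise the planted
#' preferred isomer is recovered with a probability that falls as
#' `noise_sd` grows, which is what the recovery tests quantify. Identical
#' configs (including seed) give identical tables.
#'
#' @param config A [score_sim_config()].
#' @return A [score_table()].
#' @examples
#' tab <- generate_score_table(score_sim_config(seed = 7))
#' preferred_isomer_report(tab)$metastasis$preferred_isomer
#' @export
generate_score_table <- function(config) {
  stopifnot(inherits(config, "score_sim_config"))
  with_seed(config$seed, {
    rows <- list()
    k <- 0L
    for (g in protein_group_levels()) {
      for (i in seq_len(config$proteins_per_group)) {
        k <- k + 1L
        scores <- config$base_score_mean +
          config$group_isomer_effects[g, ] +
          rnorm(4L, 0, config$noise_sd)
        loc <- sample(localization_levels(), 1L,
                      prob = config$localization_probabilities)
        rows[[k]] <- data.frame(
          protein = sprintf("%s_%03d", g, i),
          pdb = sprintf("%d%03d", (k %% 9L) + 1L, k %% 1000L),
          group = g, localization = loc,
          t(scores),
          inhibitor = "reference_inhibitor",
          inhibitor_score = config$base_score_mean +
            config$inhibitor_offset,
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    names(df)[5:8] <- isomer_levels()
    score_table(df, provenance = sprintf("synthetic (seed %d)",
                                         config$seed))
  })
}

#' Configuration for the toy trajectory generator
#'
#' Defines a C-alpha pseudo-protein on a fixed helix-like scaffold
#' (radius 8 A, 10 residues per turn, 1.5 A rise per residue) whose
#' residues jitter with per-residue Gaussian amplitude `fluctuation_sd`.
#' The bound state additionally displaces `planted_shift` residues
#' radially from the scaffold centre of mass and carries a single ligand
#' particle at `ligand_start` Angstrom from the protein centre, drifting
#' outward at `ligand_drift` Angstrom/ns. Defaults are desk-scale stand-ins
#' for a 300 ns kinase-domain simulation: 60 residues, 300 frames at 1
#' ns/frame, 0.3 A fluctuations.
#'
#' @param n_residues Number of C-alpha pseudo-residues.
#' @param n_frames Number of frames (>= 2).
#' @param time_step ns per frame.
#' @param fluctuation_sd Per-residue Gaussian amplitude (Angstrom); scalar
#'   or length-`n_residues` vector, all >= 0.
#' @param planted_shift Named numeric vector: radial bound-state
#'   displacement (Angstrom) per residue index, e.g. `c("15" = 3)`.
#' @param ligand_drift Ligand drift speed (Angstrom/ns).
#' @param ligand_start Initial ligand distance from the protein centre
#'   (Angstrom).
#' @param seed Integer seed.
#' @return A `traj_sim_config` list.
#' @export
traj_sim_config <- function(n_residues = 60L, n_frames = 300L,
                            time_step = 1, fluctuation_sd = 0.3,
                            planted_shift = NULL, ligand_drift = 0,
                            ligand_start = 5, seed = 1L) {
  if (n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (n_residues < 3L) stop("n_residues must be >= 3", call. = FALSE)
  fl <- rep_len(fluctuation_sd, n_residues)
  if (any(fl < 0)) stop("fluctuation_sd must be >= 0", call. = FALSE)
  shift <- planted_shift %||% numeric(0)
  if (length(shift) > 0L) {
    ix <- as.integer(names(shift))
    if (anyNA(ix) || any(ix < 1L) || any(ix > n_residues)) {
      stop("planted_shift residue indices out of range 1..", n_residues,
           call. = FALSE)
    }
  }
  structure(list(n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 time_step = time_step,
                 fluctuation_sd = fl,
                 planted_shift = shift,
                 ligand_drift = ligand_drift,
                 ligand_start = ligand_start,
                 seed = as.integer(seed)),
            class = "traj_sim_config")
}

helix_scaffold <- function(n_residues) {
  i <- seq_len(n_residues)
  cbind(8 * cos(2 * pi * i / 10),
        8 * sin(2 * pi * i / 10),
        1.5 * i)
}

#' Generate a bound/free trajectory pair with planted structure
#'
#' Returns a ligand-bound and a ligand-free [trajectory()] over the same
#' pseudo-protein scaffold. The free state is the scaffold plus isotropic
#' per-residue Gaussian jitter; the bound state additionally moves each
#' `planted_shift` residue radially away from (positive shift) or towards
#' (negative) the scaffold centre of mass and appends one drifting ligand
#' particle, so that [delta_d_profile()] and [com_distance_series()]
#' recover the planted shifts and drift. Fixed-seed reproducible; the two
#' states use sub-seeds derived from `config$seed`.
#'
#' @param config A [traj_sim_config()].
#' @return List with elements `bound` and `free`.
#' @export
generate_trajectory_pair <- function(config) {
  stopifnot(inherits(config, "traj_sim_config"))
  nr <- config$n_residues
  scaffold <- helix_scaffold(nr)
  com <- colMeans(scaffold)
  atoms_protein <- data.frame(residue_index = seq_len(nr),
                              residue_name = "ALA",
                              atom_name = "CA",
                              mass = 12.011,
                              is_ligand = FALSE,
                              stringsAsFactors = FALSE)
  jitter_frames <- function(base, sub_seed, extra_row = NULL) {
    with_seed(sub_seed, {
      lapply(seq_len(config$n_frames), function(f) {
        co <- base + matrix(rnorm(nr * 3L, 0, config$fluctuation_sd),
                            ncol = 3L)
        if (!is.null(extra_row)) co <- rbind(co, extra_row(f))
        co
      })
    })
  }
  free <- trajectory(jitter_frames(scaffold, config$seed + 1L),
                     atoms_protein, time_step = config$time_step)

  shifted <- scaffold
  for (res in names(config$planted_shift)) {
    i <- as.integer(res)
    dir <- scaffold[i, ] - com
    dir <- dir / sqrt(sum(dir^2))
    shifted[i, ] <- scaffold[i, ] + config$planted_shift[[res]] * dir
  }
  lig_dir <- c(1, 0, 0)
  ligand_at <- function(f) {
    t_ns <- (f - 1L) * config$time_step
    com + (config$ligand_start + config$ligand_drift * t_ns) * lig_dir
  }
  atoms_bound <- rbind(atoms_protein,
                       data.frame(residue_index = nr + 1L,
                                  residue_name = "LIG",
                                  atom_name = "C1",
                                  mass = 12.011,
                                  is_ligand = TRUE,
                                  stringsAsFactors = FALSE))
  bound <- trajectory(jitter_frames(shifted, config$seed + 2L,
                                    extra_row = ligand_at),
                      atoms_bound, time_step = config$time_step)
  list(bound = bound, free = free)
}
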