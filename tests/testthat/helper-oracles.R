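# Independent oracles used to cross-check the implementation. These stay
# deliberately naive (explicit loops, textbook formulas) and share no code
# with the package internals.

# competition rank: 4 minus the number of strictly better (more negative)
# scores, counted with an explicit double loop
oracle_ranks <- function(scores) {
  n <- length(scores)
  out <- integer(n)
  for (i in seq_len(n)) {
    better <- 0L
    for (j in seq_len(n)) {
      if (scores[j] < scores[i]) better <- better + 1L
    }
    out[i] <- n - better
  }
  out
}

# two-pass textbook sample variance
oracle_variance <- function(x) {
  m <- sum(x) / length(x)
  ss <- 0
  for (xi in x) ss <- ss + (xi - m)^2
  ss / (length(x) - 1)
}

# one-way ANOVA from explicit sums of squares
oracle_anova <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ss_between <- 0
  ss_within <- 0
  for (g in groups) {
    ss_between <- ss_between + length(g) * (mean(g) - grand)^2
    ss_within <- ss_within + sum((g - mean(g))^2)
  }
  df_b <- length(groups) - 1
  df_w <- length(all) - length(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

# exhaustive residue-set Jaccard over the pooled types of two profiles
oracle_jaccard <- function(a, b, types = interaction_types()) {
  ra <- unique(unlist(a$interactions[types]))
  rb <- unique(unlist(b$interactions[types]))
  if (length(ra) == 0 && length(rb) == 0) return(1)
  inter <- 0
  for (r in ra) if (r %in% rb) inter <- inter + 1
  inter / length(unique(c(ra, rb)))
}

# small fixtures built in code ------------------------------------------------

toy_score_table <- function() {
  score_table(data.frame(
    protein = c("alpha", "beta", "gamma"),
    pdb = c("1ABC", "2DEF", "3GHI"),
    group = c("metastasis", "metastasis", "signaling"),
    localization = c("membrane", "nucleus", "cytoplasm"),
    trans_minus = c(-10.0, -8.0, -9.0),
    trans_plus = c(-9.0, -8.5, -7.0),
    cis_minus = c(-8.0, -9.5, -9.5),
    cis_plus = c(-7.0, -7.5, -9.5),
    inhibitor = c("inhA", "inhB", "inhC"),
    inhibitor_score = c(-9.5, -9.0, -8.0),
    stringsAsFactors = FALSE))
}

# trajectory with explicit coordinates: nres protein CAs on the x axis plus
# an optional ligand particle
line_trajectory <- function(frames, ligand = FALSE, time_step = 1) {
  nat <- nrow(frames[[1]])
  nres <- if (ligand) nat - 1L else nat
  atoms <- data.frame(
    residue_index = seq_len(nat),
    residue_name = c(rep("ALA", nres), if (ligand) "LIG"),
    atom_name = c(rep("CA", nres), if (ligand) "C1"),
    mass = 12.011,
    is_ligand = c(rep(FALSE, nres), if (ligand) TRUE),
    stringsAsFactors = FALSE)
  trajectory(frames, atoms, time_step = time_step)
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigid_motion <- function(co, rot, shift) {
  co %*% rot + matrix(shift, nrow(co), 3, byrow = TRUE)
}

# the generator's documented scaffold, rebuilt independently for tests
helix_scaffold_for_tests <- function(n) {
  i <- seq_len(n)
  cbind(8 * cos(2 * pi * i / 10), 8 * sin(2 * pi * i / 10), 1.5 * i)
}

shared_targets_12 <- function() {
  c("COX2", "Hsp90a", "Hsp90b", "cdc25A", "CDK2", "RagC", "CSF1R",
    "EGFR", "AKR1B1", "JAK3", "MNK2", "p38")
}
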