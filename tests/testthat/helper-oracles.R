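# Independent brute-force oracles, coded directly from the published
# point-assignment table and textbook formulas; deliberately not sharing
# any code path with the package.

# Exhaustive 48-row scoring table: explicit per-feature point lookup.
oracle_score_table <- function() {
  pts_wpoi <- c(`1` = 0, `2` = 0, `3` = 0, `4` = 1)
  pts_lhr <- c(`1` = 0, `2` = 1, `3` = 2)
  grid <- expand.grid(wpoi = 1:4, lhr = 1:3, lvi = c(FALSE, TRUE),
                      pni = c(FALSE, TRUE))
  grid$score <- pts_wpoi[as.character(grid$wpoi)] +
    pts_lhr[as.character(grid$lhr)] +
    ifelse(grid$lvi, 1, 0) + ifelse(grid$pni, 1, 0)
  grid$group <- ifelse(grid$score == 0, "low",
                       ifelse(grid$score <= 2, "intermediate", "high"))
  grid
}

# Unweighted kappa straight from the definition on a square cross-table.
oracle_kappa <- function(tab) {
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  (p_o - p_e) / (1 - p_e)
}

# Two-sided Fisher p for a 2x2 table by exhaustive hypergeometric
# enumeration over all tables with the observed margins.
oracle_fisher_2x2 <- function(a, b, c_, d) {
  m1 <- a + b; m2 <- c_ + d; k <- a + c_; n <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  probs <- vapply(support, function(x) {
    choose(m1, x) * choose(m2, k - x) / choose(n, k)
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Tie-corrected Mann-Whitney AUC by enumerating every case/control pair.
oracle_pairwise_auc <- function(cases, controls) {
  wins <- 0
  for (x in cases) for (y in controls) {
    wins <- wins + (x > y) + 0.5 * (x == y)
  }
  wins / (length(cases) * length(controls))
}

# Analytic ordinal AUC implied by a score pmf and a per-score LNM model.
oracle_model_auc <- function(score_probs, lnm_probs) {
  pos <- score_probs * lnm_probs
  neg <- score_probs * (1 - lnm_probs)
  num <- 0
  for (i in seq_along(pos)) {
    js <- seq_len(i - 1)
    num <- num + pos[i] * sum(neg[js]) + 0.5 * pos[i] * neg[i]
  }
  num / (sum(pos) * sum(neg))
}

# Small fully-specified cohort used across tests.
toy_cohort <- function() {
  tibble::tibble(
    patient_id = sprintf("T%02d", 1:6),
    age = c(55, 60, 65, 70, 75, 80),
    pt_stage = c("pT1", "pT1", "pT2", "pT2", "pT3", "pT1"),
    grade = c("G1", "G2", "G2", "G3", "G1", "G3"),
    wpoi = c(1, 1, 3, 4, 4, 2),
    lhr = c(1, 2, 3, 3, 3, 1),
    lvi = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE),
    pni = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    lnm = c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  )
}
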