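# Small deterministic fixtures shared across test files.

toy_table <- function(kind = "counts") {
  m <- matrix(c(4, 0, 6,
                2, 3, 5,
                0, 1, 9), nrow = 3,
              dimnames = list(c("sp1", "sp2", "sp3"), c("s1", "s2", "s3")))
  if (kind == "relative") m <- sweep(m, 2, colSums(m), "/")
  feature_table(m, kind = kind)
}

two_stage_design <- function(n_JU, n_AD, group = "A") {
  tibble::tibble(
    sample_id = c(sprintf("JU_%02d", seq_len(n_JU)), sprintf("AD_%02d", seq_len(n_AD))),
    group = group,
    stage = rep(c("JU", "AD"), c(n_JU, n_AD)),
    subject_id = c(sprintf("JU_%02d", seq_len(n_JU)), sprintf("AD_%02d", seq_len(n_AD))),
    role = "none", pair_id = NA_character_
  )
}

# Feature table with exact per-group positive counts at one stage, for
# exercising the prevalence rules.
prevalence_fixture <- function(n_pos_A, n_pos_B, n_A = 8, n_B = 8, stage = "MA") {
  m <- matrix(0, nrow = 1, ncol = n_A + n_B,
              dimnames = list("f1", c(sprintf("A%02d", seq_len(n_A)),
                                      sprintf("B%02d", seq_len(n_B)))))
  if (n_pos_A > 0) m[1, seq_len(n_pos_A)] <- 5
  if (n_pos_B > 0) m[1, n_A + seq_len(n_pos_B)] <- 5
  design <- tibble::tibble(
    sample_id = colnames(m),
    group = rep(c("A", "B"), c(n_A, n_B)),
    stage = stage,
    subject_id = colnames(m))
  list(table = feature_table(m, "counts"), design = design)
}

# Brute-force Spearman rho with mid-ranks, written independently of the
# package implementation (direct Pearson on rank vectors).
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Brute-force betaMNTD from first principles on explicit vectors.
brute_beta_mntd <- function(abund_a, abund_b, dist_mat) {
  fa <- abund_a / sum(abund_a); fb <- abund_b / sum(abund_b)
  ia <- which(abund_a > 0); ib <- which(abund_b > 0)
  s1 <- sum(vapply(ia, function(i) fa[i] * min(dist_mat[i, ib]), numeric(1)))
  s2 <- sum(vapply(ib, function(j) fb[j] * min(dist_mat[ia, j]), numeric(1)))
  (s1 + s2) / 2
}
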