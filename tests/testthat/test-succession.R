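test_that("prevalence rules: MA floor, JU guard, and antisymmetry", {
  # MA: 4/8 vs 0/8 at the 50% floor -> called up in A
  fx <- prevalence_fixture(4, 0, stage = "MA")
  calls <- differential_prevalence(fx$table, fx$design, "MA")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$direction, "up_in_A")

  # 3/8 vs 0/8 misses the 50% floor
  fx2 <- prevalence_fixture(3, 0, stage = "MA")
  expect_equal(nrow(differential_prevalence(fx2$table, fx2$design, "MA")), 0)

  # 4/8 vs 2/8: low group exceeds max_other
  fx3 <- prevalence_fixture(4, 2, stage = "MA")
  expect_equal(nrow(differential_prevalence(fx3$table, fx3$design, "MA")), 0)

  # JU guard at n = 7: 2 vs 1 not called, 3 vs 1 called, 2 vs 0 called
  ju <- function(a, b) {
    fx <- prevalence_fixture(a, b, n_A = 7, n_B = 7, stage = "JU")
    differential_prevalence(fx$table, fx$design, "JU")
  }
  expect_equal(nrow(ju(2, 1)), 0)
  expect_equal(nrow(ju(3, 1)), 1)
  expect_equal(nrow(ju(2, 0)), 1)

  # antisymmetry: swapping group labels flips direction, keeps the set
  fx4 <- prevalence_fixture(5, 1, stage = "AD")
  swapped <- fx4$design
  swapped$group <- ifelse(swapped$group == "A", "B", "A")
  c1 <- differential_prevalence(fx4$table, fx4$design, "AD")
  c2 <- differential_prevalence(fx4$table, swapped, "AD")
  expect_equal(c1$feature_id, c2$feature_id)
  expect_equal(c1$direction, "up_in_A")
  expect_equal(c2$direction, "up_in_B")
})

test_that("abundance screen: null feature, full separation, planted power", {
  set.seed(31)
  n <- 8
  design <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:(2 * n)),
    group = rep(c("A", "B"), each = n), stage = "MA",
    subject_id = sprintf("s%02d", 1:(2 * n)))
  base <- matrix(rpois(30 * 2 * n, 50), 30, 2 * n,
                 dimnames = list(sprintf("f%02d", 1:30), design$sample_id))

  # identical distribution: a constant feature is skipped, not called
  m0 <- base; m0["f01", ] <- 100
  calls0 <- abundance_screen(feature_table(m0, "counts"), design, "MA")
  expect_false("f01" %in% calls0$feature_id)

  # 100x shift with no overlap: called at the exact rank-test minimum
  m1 <- base
  m1["f02", design$group == "A"] <- 20000 + rpois(n, 100)
  m1["f02", design$group == "B"] <- 200 + rpois(n, 10)
  calls1 <- abundance_screen(feature_table(m1, "counts"), design, "MA")
  expect_true("f02" %in% calls1$feature_id)
  f2 <- calls1[calls1$feature_id == "f02", ]
  expect_equal(f2$p_value, 2 / choose(16, 8))  # exact two-sided minimum for 8 vs 8
  expect_equal(f2$direction, "up_in_A")
  expect_gt(f2$effect_size, 2)

  # planted 2-fold shift, 10% CV: called in >= 90% of simulations
  hits <- vapply(1:60, function(r) {
    set.seed(1000 + r)
    m <- base
    m["f03", design$group == "A"] <- round(rnorm(n, 20000, 2000))
    m["f03", design$group == "B"] <- round(rnorm(n, 10000, 1000))
    calls <- abundance_screen(feature_table(m, "counts"), design, "MA")
    "f03" %in% calls$feature_id
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("intergenerational consistency keeps concordant multi-stage calls only", {
  mk <- function(f, stage, dir) tibble::tibble(
    feature_id = f, stage = stage, basis = "prevalence", direction = dir)
  res <- intergenerational_consistency(
    dplyr::bind_rows(mk("x", "MA", "up_in_B"), mk("y", "MA", "up_in_B"),
                     mk("z", "MA", "up_in_A")),
    dplyr::bind_rows(mk("x", "JU", "up_in_B"), mk("y", "JU", "up_in_A")),
    mk("x", "AD", "up_in_B"))
  expect_equal(res$conserved$feature_id, "x")
  expect_equal(res$conserved$n_stages, 3)
  expect_equal(res$discordant$feature_id, "y")   # opposite directions
  # z called at one stage only: neither conserved nor discordant
  expect_false("z" %in% c(res$conserved$feature_id, res$discordant$feature_id))
  expect_error(intergenerational_consistency(mk("x", "MA", "up_in_B")),
               "2 distinct stages")
})

test_that("colonization classification matches the exact binomial oracle", {
  # 2/10 JU vs 9/10 AD: p from exact binomial(9; 10, 0.2), two-sided
  m <- matrix(0, 1, 20, dimnames = list("f1", c(sprintf("JU_%02d", 1:10),
                                                sprintf("AD_%02d", 1:10))))
  m[1, 1:2] <- 4        # 2 positive JU
  m[1, 11:19] <- 4      # 9 positive AD
  design <- two_stage_design(10, 10)
  calls <- classify_colonization(feature_table(m, "counts"), design, "A")
  expect_equal(calls$class, "late")
  # independent oracle: enumerate the two-sided exact binomial tail at p0 = 0.2
  dens <- dbinom(0:10, 10, 0.2)
  p_expected <- sum(dens[dens <= dbinom(9, 10, 0.2) * (1 + 1e-7)])
  expect_equal(calls$p_value, p_expected, tolerance = 1e-12)

  # identical prevalence: persistent
  m2 <- rbind(f1 = rep(c(4, 0, 4, 0), each = 5))
  colnames(m2) <- design$sample_id
  calls2 <- classify_colonization(feature_table(m2, "counts"), design, "A")
  expect_equal(calls2$class, "persistent")

  # absent everywhere: excluded
  m3 <- rbind(f1 = c(rep(4, 10), rep(0, 10)), f2 = 0)
  colnames(m3) <- design$sample_id
  calls3 <- classify_colonization(feature_table(m3, "counts"), design, "A")
  expect_false("f2" %in% calls3$feature_id)
})

test_that("colonization recovery on planted cohorts exceeds 90%", {
  tru <- succession_truth(rep(c("early", "persistent", "late"), each = 15),
                          p_JU = rep(c(0.9, 0.5, 0.1), each = 15),
                          p_AD = rep(c(0.1, 0.5, 0.9), each = 15))
  sim <- simulate_succession_cohort(tru, n_JU = 20, n_AD = 20, seed = 8)
  calls <- classify_colonization(sim$table, sim$design, "A")
  truth <- tru$class[match(calls$feature_id, tru$feature_id)]
  el <- truth %in% c("early", "late")
  expect_gte(mean(calls$class[el] == truth[el]), 0.9)
})

test_that("persistent false-call rate matches the exact enumeration of the procedure", {
  # The test plugs the estimated JU prevalence in as the binomial null, so its
  # realized type-I error exceeds the nominal alpha; the exact rate is
  # enumerable over (k_JU, k_AD) pairs and the empirical rate must match it.
  nJ <- 20; nA <- 20; p <- 0.5; alpha <- 0.1
  clamp <- 1 / (2 * nJ)
  rej_given_kj <- vapply(0:nJ, function(kj) {
    p0 <- min(max(kj / nJ, clamp), 1 - clamp)
    rej <- vapply(0:nA, function(ka) {
      stats::binom.test(ka, nA, p0)$p.value < alpha && ka / nA != kj / nJ
    }, logical(1))
    sum(stats::dbinom(0:nA, nA, p) * rej)
  }, numeric(1))
  exact_rate <- sum(stats::dbinom(0:nJ, nJ, p) * rej_given_kj)

  n_feat <- 80
  tru <- succession_truth(rep("persistent", n_feat),
                          p_JU = rep(p, n_feat), p_AD = rep(p, n_feat))
  sim <- simulate_succession_cohort(tru, n_JU = nJ, n_AD = nA, seed = 15)
  calls <- classify_colonization(sim$table, sim$design, "A", alpha = alpha)
  emp <- mean(calls$class != "persistent")
  se <- sqrt(exact_rate * (1 - exact_rate) / n_feat)
  expect_lt(abs(emp - exact_rate), 3 * se + 0.01)
})

test_that("trajectory comparison: diagonal null, acceleration labels, planted shift", {
  mkcalls <- function(delta, class) tibble::tibble(
    feature_id = sprintf("f%02d", seq_along(delta)),
    class = class, prev_JU = 0.2, prev_AD = 0.2 + delta, delta = delta,
    p_value = 0.5, neg_log10_p = 0.3, group = "g")

  # identical call lists: all points on the diagonal, p = 1
  same <- mkcalls(seq(-0.3, 0.4, length.out = 8), rep("persistent", 8))
  tc0 <- compare_trajectories(same, same)
  expect_equal(tc0$paired_wilcoxon_p, 1)
  expect_equal(tc0$fraction_above_diagonal, 0)

  # the (0, 50) configuration: persistent in exposed, late in control
  ctrl <- mkcalls(rep(0.5, 6), rep("late", 6))
  expo <- mkcalls(rep(0, 6), rep("persistent", 6))
  tc1 <- compare_trajectories(ctrl, expo)
  expect_true(all(tc1$points$x_exposed == 0 & tc1$points$y_control == 50))
  expect_true(all(tc1$points$interpretation == "accelerated in exposed"))
  expect_true(all(tc1$points$transition == "persistent->late"))

  # planted acceleration: exposed delta = control delta - 0.3 for 20 features
  set.seed(13)
  d_ctrl <- runif(20, 0.1, 0.5)
  ctrl2 <- mkcalls(d_ctrl, rep("late", 20))
  expo2 <- mkcalls(d_ctrl - 0.3, rep("persistent", 20))
  tc2 <- compare_trajectories(ctrl2, expo2)
  expect_lt(tc2$paired_wilcoxon_p, 0.01)
  expect_equal(tc2$fraction_above_diagonal, 1)

  expect_error(compare_trajectories(ctrl[1:3, ], expo[1:3, ]), "fewer than 5")
})

test_that("persistence sets count stage-membership patterns exactly", {
  m <- matrix(0, 4, 6, dimnames = list(
    c("onlyMA", "all3", "JUAD", "none"),
    c("MA1", "MA2", "JU1", "JU2", "AD1", "AD2")))
  m["onlyMA", "MA1"] <- 2
  m["all3", c("MA2", "JU1", "AD1")] <- 1
  m["JUAD", c("JU2", "AD2")] <- 3
  design <- tibble::tibble(
    sample_id = colnames(m), group = "A",
    stage = rep(c("MA", "JU", "AD"), each = 2),
    subject_id = colnames(m))
  ps <- persistence_sets(feature_table(m, "counts"), design, "A")
  memb <- ps$membership
  expect_equal(memb$pattern[memb$feature_id == "onlyMA"], "MA")
  expect_equal(memb$pattern[memb$feature_id == "all3"], "MA&JU&AD")
  expect_equal(memb$pattern[memb$feature_id == "JUAD"], "JU&AD")
  expect_equal(memb$pattern[memb$feature_id == "none"], "(absent)")
  expect_equal(sum(ps$pattern_counts$n), 4)
})

test_that("correlation network thresholds and spearman oracle", {
  # monotone pair: rho = 1, edge formed
  X <- rbind(x = c(1, 2, 3, 4, 5, 6))
  Y <- rbind(y = c(2, 4, 5, 7, 10, 20))
  net <- correlation_network(X, Y)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$rho, 1)

  # |rho| below 0.5 never forms an edge
  set.seed(2)
  found <- FALSE
  for (i in 1:50) {
    y2 <- rnorm(20)
    x2 <- rnorm(20)
    r <- brute_spearman(x2, y2)
    if (abs(r) < 0.5 && abs(r) > 0.4) {
      net2 <- correlation_network(rbind(a = x2), rbind(b = y2))
      expect_equal(nrow(net2$edges), 0)
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # 5-point fixture with a tie: matches the brute-force mid-rank formula
  x3 <- c(3, 1, 4, 1, 5)   # tie between the two 1s
  y3 <- c(2, 7, 1, 8, 3)
  net3 <- correlation_network(rbind(a = x3), rbind(b = y3),
                              r_threshold = 0, p_threshold = 1)
  expect_equal(net3$edges$rho, brute_spearman(x3, y3), tolerance = 1e-12)

  # constant feature skipped with a note
  expect_message(correlation_network(rbind(a = rep(1, 6)), Y), "constant")
})
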