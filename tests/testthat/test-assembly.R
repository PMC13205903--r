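test_that("betaMNTD: identical communities, hand fixture, picante cross-check", {
  tr <- simulate_tree(20, seed = 3)
  set.seed(4)
  m <- matrix(rbinom(20 * 6, 1, 0.5) * rpois(20 * 6, 10), 20, 6,
              dimnames = list(tr$tip.label, paste0("s", 1:6)))
  m[, 2] <- m[, 1]  # duplicate community
  m[rowSums(m) == 0, 1] <- 1
  ft <- feature_table(m, "counts")
  res <- beta_nti(ft, tr, n_null = 100, seed = 1)
  expect_equal(res$beta_mntd_obs[res$sample_i == "s1" & res$sample_j == "s2"], 0)

  # brute-force oracle on explicit vectors
  D <- ape::cophenetic.phylo(tr)[rownames(m), rownames(m)]
  for (k in sample(nrow(res), 5)) {
    a <- res$sample_i[k]; b <- res$sample_j[k]
    expect_equal(res$beta_mntd_obs[k], brute_beta_mntd(m[, a], m[, b], D),
                 tolerance = 1e-12)
  }

  # independent implementation: picante::comdistnt (abundance-weighted)
  skip_if_not_installed("picante")
  cd <- as.matrix(picante::comdistnt(t(m), D, abundance.weighted = TRUE))
  expect_equal(res$beta_mntd_obs, cd[cbind(res$sample_i, res$sample_j)],
               tolerance = 1e-10)
})

test_that("betaNTI flags degenerate star-tree geometry and cancels branch scaling", {
  star <- read_tree(text = "(a:1,b:1,c:1,d:1);")
  m <- matrix(c(5, 5, 0, 0, 0, 0, 5, 5), 4,
              dimnames = list(letters[1:4], c("s1", "s2")))
  ft <- feature_table(m, "counts")
  res <- expect_silent(beta_nti(ft, star, n_null = 100, seed = 2))
  expect_false(res$defined)
  expect_true(is.na(res$beta_nti))

  # uniform branch scaling cancels in the z-score
  tr <- simulate_tree(15, seed = 9)
  set.seed(10)
  m2 <- matrix(rbinom(15 * 4, 1, 0.4) * rpois(15 * 4, 8) + 0, 15, 4,
               dimnames = list(tr$tip.label, paste0("s", 1:4)))
  m2[rowSums(m2) == 0, 1] <- 1
  ft2 <- feature_table(m2, "counts")
  tr10 <- tr; tr10$edge.length <- tr$edge.length * 10
  r1 <- beta_nti(ft2, tr, n_null = 150, seed = 5)
  r2 <- beta_nti(ft2, tr10, n_null = 150, seed = 5)
  expect_equal(r1$beta_nti, r2$beta_nti, tolerance = 1e-9)
})

test_that("raup-crick bray: extreme ranks, bounds, and richness/abundance preservation", {
  set.seed(6)
  S <- 40
  m <- matrix(rbinom(S * 6, 1, 0.5) * rpois(S * 6, 30), S, 6,
              dimnames = list(sprintf("t%02d", 1:S), paste0("s", 1:6)))
  m[rowSums(m) == 0, 1] <- 1
  ft <- feature_table(m, "counts")
  res <- rc_bray(ft, n_null = 150, seed = 3)
  expect_true(all(res$rc_bray >= -1 & res$rc_bray <= 1))
  # null draws assert their own richness/total constraints internally; a
  # successful run implies they held for every draw
  expect_equal(nrow(res), choose(6, 2))

  # two near-identical samples: observed dissimilarity below every null
  m2 <- m
  m2[, 2] <- m2[, 1]; m2[1, 2] <- m2[1, 2] + 1
  res2 <- rc_bray(feature_table(m2, "counts"),
                  pairs = cbind("s1", "s2"), n_null = 200, seed = 4)
  expect_lte(res2$rc_bray, -0.95)

  expect_error(rc_bray(as_relative(ft)), "counts")
})

test_that("process classification reproduces the threshold rules on a boundary grid", {
  grid <- expand.grid(beta_nti = c(-2.5, -2.01, -2, -1, 0, 1, 2, 2.01, 2.5),
                      rc_bray = c(-1, -0.96, -0.95, -0.5, 0, 0.5, 0.95, 0.96, 1))
  cls <- classify_processes(grid)
  expected <- with(grid, ifelse(beta_nti > 2, "heterogeneous_selection",
                   ifelse(beta_nti < -2, "homogeneous_selection",
                   ifelse(rc_bray > 0.95, "dispersal_limitation",
                   ifelse(rc_bray < -0.95, "homogenizing_dispersal", "undominated")))))
  expect_equal(cls$pairs$process, expected)
  # exactly one label per defined pair; deterministic + stochastic = 1
  expect_equal(sum(cls$fractions$fraction), 1)
  expect_equal(cls$deterministic_fraction + cls$stochastic_fraction, 1)
  # undefined pairs counted and excluded
  grid2 <- rbind(grid, data.frame(beta_nti = NA, rc_bray = 0))
  expect_equal(classify_processes(grid2)$n_excluded, 1)
})

test_that("ncm fit: saturated taxa neutral, anti-neutral fixture fails, errors", {
  # a taxon dominant everywhere (mean share ~0.9) is predicted and observed
  # at frequency 1 and sits inside the neutral band
  set.seed(12)
  n <- 20
  m_dom <- rbind(
    dom = rep(900, n),
    matrix(rmultinom(n, 100, rep(1 / 12, 12)), 12, n,
           dimnames = list(sprintf("r%02d", 1:12), NULL)))
  colnames(m_dom) <- sprintf("s%02d", 1:n)
  fit_dom <- fit_ncm(feature_table(m_dom, "counts"))
  dom <- tidy(fit_dom)[tidy(fit_dom)$feature_id == "dom", ]
  expect_gt(dom$predicted_frequency, 0.999)
  expect_equal(dom$observed_frequency, 1)
  expect_equal(dom$state, "neutral")

  # neutral simulation at the standard study size: good fit, recovered m, and
  # most taxa inside the band (the band is approximate -- the plug-in mean
  # abundance is itself estimated, so nominal 95% under-covers somewhat)
  tru <- neutral_sim_truth(n_taxa = 150, m = 0.15, N = 800, n_samples = 40)
  fit <- fit_ncm(simulate_neutral_communities(tru, seed = 12))
  td <- tidy(fit)
  expect_gt(glance(fit)$r2, 0.5)
  expect_lte(mean(td$state != "neutral"), 0.20)

  # anti-neutral fixture: matched mean abundance, inverted occupancy -- no
  # occupancy-abundance curve can fit both blocks, so R2 must go negative.
  # forced block: 1 read in every sample (freq 1, p_bar = 0.002);
  # banned block: 150 reads in exactly one sample (freq 1/30, p_bar = 0.01);
  # filler carries the remaining reads so depths stay equal.
  n2 <- 30; depth <- 500
  m <- rbind(
    matrix(1, 29, n2, dimnames = list(sprintf("forced%02d", 1:29), NULL)),
    matrix(0, 30, n2, dimnames = list(sprintf("banned%02d", 1:30), NULL)),
    filler = rep(321, n2))
  for (j in 1:30) m[29 + j, j] <- 150
  colnames(m) <- sprintf("s%02d", 1:n2)
  expect_true(all(colSums(m) == depth))
  anti <- fit_ncm(feature_table(m, "counts"))
  expect_lt(glance(anti)$r2, 0)
  expect_gte(mean(tidy(anti)$state != "neutral"), 0.30)

  uneven <- feature_table(matrix(c(5, 5, 3, 4), 2,
                                 dimnames = list(c("a", "b"), c("s1", "s2"))), "counts")
  expect_error(fit_ncm(uneven), "unequal")
})

test_that("ncm fit recovers the planted migration rate", {
  tru <- neutral_sim_truth(n_taxa = 500, m = 0.1, N = 1000, n_samples = 60)
  fit <- fit_ncm(simulate_neutral_communities(tru, seed = 5))
  expect_lt(abs(fit$m_hat - 0.1) / 0.1, 0.5)
  expect_gt(fit$r2, 0.5)
  expect_equal(fit$Nm, fit$N * fit$m_hat)
})

test_that("dispersal shift follows the ordinal state rule", {
  mk <- function(states) {
    f <- list(taxa = tibble::tibble(feature_id = paste0("t", seq_along(states)),
                                    state = states))
    class(f) <- "ncm_fit"
    f
  }
  A <- mk(c("neutral", "above", "below", "neutral", "above"))
  B <- mk(c("above", "neutral", "above", "neutral", "below"))
  sh <- dispersal_shift(A, B)
  expect_equal(sh$shift,
               c("higher_in_B", "lower_in_B", "higher_in_B", "unchanged", "lower_in_B"))
  C <- mk("above"); C$taxa$feature_id <- "other_taxon"
  expect_error(dispersal_shift(A, C), "share no taxa")
})

test_that("co-occurrence network separates signs and enforces |r| > 0.8", {
  m <- rbind(
    focal = c(1, 2, 3, 4, 5, 6),
    anti  = c(6, 5, 4, 3, 2, 1),
    with_ = c(1.1, 2.2, 2.9, 4.2, 5.1, 6.3),
    noise = c(2, 1, 5, 3, 6, 4))
  rownames(m) <- c("focal", "anti", "with", "noise")
  colnames(m) <- paste0("s", 1:6)
  ft <- feature_table(m, "counts" )
  net <- cooccurrence_network(ft, focal = "focal")
  expect_equal(net$negative$target, "anti")
  expect_equal(net$negative$rho, -1)
  expect_equal(net$positive$target, "with")
  expect_false("noise" %in% c(net$positive$target, net$negative$target))

  # rho just below the threshold: no edge (rank correlation 0.79 is impossible
  # at n = 6; use n = 21 ranks engineered to rho < 0.8)
  set.seed(8)
  x <- 1:21
  repeat {
    y <- x + rnorm(21, 0, 6)
    r <- brute_spearman(x, y)
    if (r > 0.7 && r < 0.8) break
  }
  m2 <- rbind(a = x, b = y + abs(min(y)) + 1)
  colnames(m2) <- paste0("s", 1:21)
  net2 <- cooccurrence_network(feature_table(m2, "counts"), focal = "a")
  expect_equal(nrow(net2$positive) + nrow(net2$negative), 0)

  expect_error(cooccurrence_network(ft, focal = "missing"), "not in table")
})
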