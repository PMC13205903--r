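#' Beta nearest-taxon distances and betaNTI
#'
#' For each sample pair, the observed abundance-weighted beta mean nearest
#' taxon distance is
#' \deqn{\beta MNTD(A,B) = \tfrac12\Big[\sum_i f_{iA}\min_{j\in B} d_{ij} +
#'   \sum_j f_{jB}\min_{i\in A} d_{ij}\Big]}
#' with relative abundances \eqn{f} and patristic distances \eqn{d}. A null
#' distribution is built by shuffling tip labels across the regional pool
#' (every feature observed anywhere in the table), and
#' \eqn{\beta NTI = (obs - \bar{null}) / sd(null)}. Pairs whose null standard
#' deviation is zero (degenerate tree geometry) are flagged undefined.
#'
#' @param table A [feature_table()] (rarefied counts upstream is the
#'   intended workflow; relative abundances are accepted).
#' @param tree An [ape::phylo] tree whose tips cover all nonzero features.
#' @param pairs Two-column matrix/data frame of sample ID pairs, or `NULL`
#'   (default) for all sample pairs.
#' @param n_null Number of tip-label shuffles (default 1000, minimum 100).
#' @param seed Integer seed.
#' @param weighted Abundance-weighted (default) or presence/absence
#'   (`FALSE`) weighting.
#' @return A tibble: `sample_i`, `sample_j`, `beta_mntd_obs`, `null_mean`,
#'   `null_sd`, `beta_nti`, `defined`.
#' @export
beta_nti <- function(table, tree, pairs = NULL, n_null = 1000, seed = 0L,
                     weighted = TRUE) {
  stopifnot(is_feature_table(table))
  if (n_null < 100) stop("n_null must be at least 100", call. = FALSE)
  m <- unclass(table)
  pool <- rownames(m)[rowSums(m) > 0]
  missing_tips <- setdiff(pool, tree$tip.label)
  if (length(missing_tips)) {
    stop("features absent from tree: ", paste(utils::head(missing_tips, 5), collapse = ", "),
         call. = FALSE)
  }
  m <- m[pool, , drop = FALSE]
  f <- sweep(m, 2, colSums(m), "/")
  if (!weighted) {
    pa <- m > 0
    f <- sweep(pa, 2, colSums(pa), "/")
  }
  D <- ape::cophenetic.phylo(ape::keep.tip(tree, pool))[pool, pool]
  pair_idx <- resolve_pairs(pairs, colnames(m))

  bm_one <- function(D, ia, ib, fa, fb) {
    sub <- D[ia, ib, drop = FALSE]
    0.5 * (sum(fa * apply(sub, 1, min)) + sum(fb * apply(sub, 2, min)))
  }
  feat_sets <- lapply(seq_len(ncol(m)), function(s) which(m[, s] > 0))
  obs <- vapply(seq_len(nrow(pair_idx)), function(k) {
    a <- pair_idx[k, 1]; b <- pair_idx[k, 2]
    ia <- feat_sets[[a]]; ib <- feat_sets[[b]]
    bm_one(D, ia, ib, f[ia, a], f[ib, b])
  }, numeric(1))

  S <- length(pool)
  nulls <- with_seed(seed, {
    vapply(seq_len(n_null), function(r) {
      perm <- sample.int(S)
      Dp <- D[perm, perm]
      vapply(seq_len(nrow(pair_idx)), function(k) {
        a <- pair_idx[k, 1]; b <- pair_idx[k, 2]
        ia <- feat_sets[[a]]; ib <- feat_sets[[b]]
        bm_one(Dp, ia, ib, f[ia, a], f[ib, b])
      }, numeric(1))
    }, numeric(nrow(pair_idx)))
  })
  nulls <- matrix(nulls, nrow = nrow(pair_idx))
  null_mean <- rowMeans(nulls)
  null_sd <- apply(nulls, 1, stats::sd)
  defined <- null_sd > 1e-12
  bnti <- ifelse(defined, (obs - null_mean) / null_sd, NA_real_)
  tibble::tibble(
    sample_i = colnames(m)[pair_idx[, 1]],
    sample_j = colnames(m)[pair_idx[, 2]],
    beta_mntd_obs = obs,
    null_mean = null_mean, null_sd = null_sd,
    beta_nti = bnti, defined = defined
  )
}

resolve_pairs <- function(pairs, sample_ids) {
  if (is.null(pairs)) {
    idx <- which(upper.tri(diag(length(sample_ids))), arr.ind = TRUE)
    return(cbind(idx[, 1], idx[, 2]))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns", call. = FALSE)
  i <- match(pairs[, 1], sample_ids)
  j <- match(pairs[, 2], sample_ids)
  if (anyNA(i) || anyNA(j)) stop("pair sample IDs not in table", call. = FALSE)
  cbind(i, j)
}

#' Raup-Crick index on Bray-Curtis dissimilarity
#'
#' Observed Bray-Curtis dissimilarities are ranked against dissimilarities of
#' null community pairs built by abundance-weighted constrained
#' randomization: each null community keeps its sample's observed richness
#' (taxa drawn without replacement with probability proportional to regional
#' occurrence frequency, each seeded with one individual) and total abundance
#' (remaining individuals distributed multinomially proportional to regional
#' relative abundance over the drawn taxa). The index
#' \eqn{RC = 2[P(null < obs) + 0.5 P(null = obs)] - 1} lies in \eqn{[-1, 1]}.
#'
#' @param table A counts [feature_table()].
#' @param pairs Sample pairs as in [beta_nti()] (`NULL` = all pairs).
#' @param n_null Number of null pairs per observed pair (default 500,
#'   minimum 100).
#' @param seed Integer seed.
#' @return A tibble: `sample_i`, `sample_j`, `bray_obs`, `rc_bray`.
#' @export
rc_bray <- function(table, pairs = NULL, n_null = 500, seed = 0L) {
  stopifnot(is_feature_table(table))
  if (table_kind(table) != "counts") stop("rc_bray needs counts", call. = FALSE)
  if (n_null < 100) stop("n_null must be at least 100", call. = FALSE)
  m <- unclass(table)
  if (any(colSums(m > 0) == 0)) stop("sample with richness 0", call. = FALSE)
  occ <- rowMeans(m > 0)            # regional occurrence frequency
  relab <- rowSums(m) / sum(m)      # regional relative abundance
  S <- nrow(m)
  rich <- colSums(m > 0)
  tot <- round(colSums(m))
  pair_idx <- resolve_pairs(pairs, colnames(m))

  bray <- function(x, y) {
    s <- sum(x + y)
    if (s == 0) return(0)
    sum(abs(x - y)) / s
  }
  null_community <- function(s) {
    k <- rich[s]; n <- tot[s]
    taxa <- sample.int(S, k, prob = occ)
    x <- integer(S)
    x[taxa] <- 1L
    if (n > k) {
      p <- relab[taxa]
      extra <- drop(stats::rmultinom(1, n - k, p / sum(p)))
      x[taxa] <- x[taxa] + extra
    }
    stopifnot(sum(x > 0) == k, sum(x) == n)  # constraints hold by construction
    x
  }
  with_seed(seed, {
    res <- vapply(seq_len(nrow(pair_idx)), function(kp) {
      a <- pair_idx[kp, 1]; b <- pair_idx[kp, 2]
      obs <- bray(m[, a], m[, b])
      nulls <- vapply(seq_len(n_null), function(r) {
        bray(null_community(a), null_community(b))
      }, numeric(1))
      rc <- 2 * (mean(nulls < obs) + 0.5 * mean(nulls == obs)) - 1
      c(obs, rc)
    }, numeric(2))
    tibble::tibble(
      sample_i = colnames(m)[pair_idx[, 1]],
      sample_j = colnames(m)[pair_idx[, 2]],
      bray_obs = res[1, ],
      rc_bray = res[2, ]
    )
  })
}

#' Classify community-assembly processes from betaNTI and RC-Bray
#'
#' Applies the standard two-stage threshold rules per pair: heterogeneous
#' selection (betaNTI > +2), homogeneous selection (betaNTI < -2), and among
#' pairs with |betaNTI| <= 2: dispersal limitation (RC > +0.95), homogenizing
#' dispersal (RC < -0.95), undominated (|RC| <= 0.95). Selection-driven pairs
#' (|betaNTI| > 2) are the deterministic fraction; the rest are stochastic.
#'
#' @param results Tibble with columns `beta_nti` and `rc_bray` (e.g. a join
#'   of [beta_nti()] and [rc_bray()] outputs); rows with undefined (NA)
#'   betaNTI are excluded and counted.
#' @return A list of class `assembly_classification`: `pairs` (input plus
#'   `process`), `fractions` (tibble: `process`, `n`, `fraction`),
#'   `deterministic_fraction`, `stochastic_fraction`, `n_excluded`.
#' @export
classify_processes <- function(results) {
  stopifnot(all(c("beta_nti", "rc_bray") %in% names(results)))
  excluded <- is.na(results$beta_nti) | is.na(results$rc_bray)
  ok <- results[!excluded, , drop = FALSE]
  proc <- dplyr::case_when(
    ok$beta_nti > 2 ~ "heterogeneous_selection",
    ok$beta_nti < -2 ~ "homogeneous_selection",
    ok$rc_bray > 0.95 ~ "dispersal_limitation",
    ok$rc_bray < -0.95 ~ "homogenizing_dispersal",
    TRUE ~ "undominated"
  )
  ok$process <- proc
  levels_all <- c("heterogeneous_selection", "homogeneous_selection",
                  "dispersal_limitation", "homogenizing_dispersal", "undominated")
  fr <- tibble::tibble(process = levels_all,
                       n = vapply(levels_all, function(p) sum(proc == p), integer(1)))
  fr$fraction <- if (nrow(ok)) fr$n / nrow(ok) else 0
  det <- if (nrow(ok)) mean(abs(ok$beta_nti) > 2) else NA_real_
  structure(list(pairs = ok, fractions = fr,
                 deterministic_fraction = det,
                 stochastic_fraction = 1 - det,
                 n_excluded = sum(excluded)),
            class = "assembly_classification")
}

#' @export
print.assembly_classification <- function(x, ...) {
  cat(sprintf("<assembly_classification> %d pairs (%d excluded), deterministic %.1f%%\n",
              nrow(x$pairs), x$n_excluded, 100 * x$deterministic_fraction))
  print(as.data.frame(x$fractions), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.assembly_classification <- function(x, ...) x$pairs

#' @export
glance.assembly_classification <- function(x, ...) {
  out <- tidyr::pivot_wider(x$fractions[c("process", "fraction")],
                            names_from = "process", values_from = "fraction")
  dplyr::bind_cols(out, tibble::tibble(
    deterministic_fraction = x$deterministic_fraction,
    stochastic_fraction = x$stochastic_fraction,
    n_pairs = nrow(x$pairs), n_excluded = x$n_excluded))
}
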