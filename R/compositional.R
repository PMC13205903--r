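#' Centered log-ratio transform with multiplicative zero replacement
#'
#' Samples are first closed to relative abundances. Zeros are replaced by
#' `zero_factor` times the smallest nonzero relative abundance in the whole
#' table (multiplicative replacement), columns renormalized, then each value
#' becomes \eqn{\ln(x_i / g(x))} with \eqn{g} the column geometric mean, so
#' every column sums to 0.
#'
#' @param table A [feature_table()] (counts or relative).
#' @param zero_factor Multiplier applied to the global minimum nonzero
#'   relative abundance when imputing zeros (default 0.65).
#' @return A numeric matrix (features x samples) of CLR values.
#' @export
clr_transform <- function(table, zero_factor = 0.65) {
  stopifnot(is_feature_table(table))
  rel <- unclass(as_relative(table))
  if (any(rel == 0)) {
    repl <- zero_factor * min(rel[rel > 0])
    rel[rel == 0] <- repl
    rel <- sweep(rel, 2, colSums(rel), "/")
  }
  lg <- log(rel)
  sweep(lg, 2, colMeans(lg), "-")
}

#' Aitchison distances between samples
#'
#' Euclidean distance in CLR-transformed space; invariant to per-sample
#' rescaling of the input.
#'
#' @inheritParams clr_transform
#' @return A symmetric samples-by-samples distance matrix with zero diagonal.
#' @export
aitchison_distances <- function(table, zero_factor = 0.65) {
  clr <- clr_transform(table, zero_factor)
  d <- as.matrix(stats::dist(t(clr)))
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers the squared distance matrix and eigendecomposes it. All
#' eigenvalues are returned in decreasing order, negatives included, so the
#' quality of the Euclidean embedding can be judged; coordinates are returned
#' for the first `k` positive-eigenvalue axes.
#'
#' @param dm Symmetric distance matrix with sample IDs as dimnames (or a
#'   `dist`).
#' @param k Number of axes to return (default 2).
#' @return A list of class `pcoa_ord` with `points` (tibble: `sample_id`,
#'   `axis1 ... axisk`), `eigenvalues`, and `prop_explained` (relative to the
#'   sum of positive eigenvalues).
#' @export
pcoa <- function(dm, k = 2) {
  d <- as.matrix(dm)
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(d)))
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (k > nrow(d) - 1) stop("k cannot exceed n_samples - 1", call. = FALSE)
  cm <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE, add = FALSE)
  eig <- sort(cm$eig, decreasing = TRUE)
  pts <- cm$points
  if (ncol(pts) < k) {  # cmdscale drops axes with non-positive eigenvalues
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  colnames(pts) <- paste0("axis", seq_len(k))
  pos <- sum(eig[eig > 0])
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                              tibble::as_tibble(pts)),
    eigenvalues = eig,
    prop_explained = if (pos > 0) pmax(eig, 0) / pos else rep(0, length(eig))
  ), class = "pcoa_ord")
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (single grouping factor),
#' computed with [vegan::adonis2()]: pseudo-F from between/within sums of
#' squared distances, R-squared as the between fraction of total, and a
#' permutation p-value \eqn{(1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})}.
#'
#' @param dm Symmetric distance matrix (or `dist`) with sample IDs.
#' @param labels Grouping vector, one label per sample (>= 2 groups, each with
#'   >= 2 samples).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation stream.
#' @return A one-row tibble: `pseudo_F`, `R2`, `p_value`, `n_perm`, `df`.
#' @export
permanova <- function(dm, labels, n_perm = 999, seed = 0L) {
  d <- as.matrix(dm)
  labels <- as.factor(labels)
  if (length(labels) != nrow(d)) stop("one label per sample required", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(labels) < 2)) stop("every group needs at least 2 samples", call. = FALSE)
  if (sum(d^2) == 0) stop("degenerate input: all samples identical (zero total sum of squares)",
                          call. = FALSE)
  df <- data.frame(g = labels)
  fit <- with_seed(seed,
    vegan::adonis2(stats::as.dist(d) ~ g, data = df, permutations = n_perm))
  tibble::tibble(
    pseudo_F = fit$F[1],
    R2 = fit$R2[1],
    p_value = fit$`Pr(>F)`[1],
    n_perm = n_perm,
    df = fit$Df[1]
  )
}

#' Per-sample alpha diversity
#'
#' Shannon entropy \eqn{-\sum p \ln p}, Gini-Simpson \eqn{1 - \sum p^2}, or
#' bias-corrected Chao1 richness \eqn{S_{obs} + F_1(F_1 - 1)/(2(F_2 + 1))}
#' (counts only; computed with [vegan::estimateR()]).
#'
#' @param table A [feature_table()].
#' @param metric `"shannon"`, `"simpson"` or `"chao1"`.
#' @return A tibble with `sample_id` and the metric value.
#' @export
alpha_diversity <- function(table, metric = c("shannon", "simpson", "chao1")) {
  metric <- match.arg(metric)
  stopifnot(is_feature_table(table))
  m <- t(unclass(table))  # vegan wants samples in rows
  val <- switch(metric,
    shannon = vegan::diversity(m, index = "shannon"),
    simpson = vegan::diversity(m, index = "simpson"),
    chao1 = {
      if (table_kind(table) != "counts") {
        stop("chao1 requires a counts table", call. = FALSE)
      }
      unname(vegan::estimateR(round(m))["S.chao1", ])
    })
  tibble::tibble(sample_id = colnames(table), metric = metric,
                 value = as.numeric(val))
}

#' Partition beta diversity into turnover and nestedness
#'
#' For every between-group sample pair, presence/absence (abundance > 0)
#' Sorensen dissimilarity is split into its turnover (Simpson) and nestedness
#' components: with `a` shared and `b`, `c` unique features,
#' \eqn{\beta_{sor} = (b+c)/(2a+b+c)}, \eqn{\beta_{sim} = \min(b,c)/(a+\min(b,c))},
#' \eqn{\beta_{sne} = \beta_{sor} - \beta_{sim}}. The contrast-level turnover
#' proportion is the mean of \eqn{\beta_{sim}/\beta_{sor}} over pairs (pairs
#' with \eqn{\beta_{sor} = 0} are excluded); its significance comes from
#' shuffling group labels.
#'
#' @param table A [feature_table()].
#' @param labels Two-group label vector, one per sample.
#' @param n_perm Number of label shuffles (default 999).
#' @param seed Integer seed.
#' @param pairs Which sample pairs enter the contrast summary:
#'   `"between"` (default) or `"all"`.
#' @param alternative Sidedness of the permutation test on the turnover
#'   proportion (`"two.sided"`, `"greater"`, `"less"`).
#' @return A list of class `beta_partition`: `pairs` (tibble of per-pair
#'   components), `turnover_proportion`, `nestedness_proportion`,
#'   `permutation_p`, `n_perm`.
#' @export
partition_beta <- function(table, labels, n_perm = 999, seed = 0L,
                           pairs = c("between", "all"),
                           alternative = c("two.sided", "greater", "less")) {
  pairs <- match.arg(pairs)
  alternative <- match.arg(alternative)
  stopifnot(is_feature_table(table))
  labels <- as.character(labels)
  if (length(labels) != ncol(table)) stop("one label per sample required", call. = FALSE)
  groups <- unique(labels)
  if (length(groups) != 2) stop("partition_beta needs exactly 2 groups", call. = FALSE)
  if (any(table(labels) < 2)) stop("every group needs at least 2 samples", call. = FALSE)

  pa <- unclass(table) > 0
  comp <- pairwise_beta_components(pa)

  n_pairs <- length(comp$i)
  sel_between <- labels[comp$i] != labels[comp$j]
  use <- if (pairs == "between") sel_between else rep(TRUE, n_pairs)
  obs <- turnover_proportion_mean(comp_subset(comp, use))
  if (is.na(obs)) {
    stop("all selected pairs are identical (beta_sor = 0 everywhere)", call. = FALSE)
  }

  null_stats <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    lp <- sample(labels)
    usep <- if (pairs == "between") lp[comp$i] != lp[comp$j] else rep(TRUE, n_pairs)
    turnover_proportion_mean(comp_subset(comp, usep))
  }, numeric(1)))
  null_stats <- null_stats[!is.na(null_stats)]
  n_eff <- length(null_stats)
  p_ge <- (1 + sum(null_stats >= obs)) / (1 + n_eff)
  p_le <- (1 + sum(null_stats <= obs)) / (1 + n_eff)
  p <- switch(alternative,
              greater = p_ge, less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))

  pair_tbl <- tibble::tibble(
    sample_i = colnames(table)[comp$i],
    sample_j = colnames(table)[comp$j],
    between_group = sel_between,
    beta_sor = comp$sor, beta_sim = comp$sim, beta_sne = comp$sne
  )
  structure(list(
    pairs = pair_tbl,
    turnover_proportion = obs,
    nestedness_proportion = 1 - obs,
    permutation_p = p,
    n_perm = n_eff,
    pair_scope = pairs
  ), class = "beta_partition")
}

# Sorensen/Simpson/nestedness components for all sample pairs of a
# presence/absence matrix (features x samples).
pairwise_beta_components <- function(pa) {
  mode(pa) <- "integer"
  A <- crossprod(pa)            # shared features a for every pair
  rich <- diag(A)
  n <- ncol(pa)
  idx <- which(upper.tri(A), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  a <- unname(A[idx])
  b <- unname(rich[i]) - a
  c_ <- unname(rich[j]) - a
  minbc <- pmin(b, c_)
  sor <- ifelse(2 * a + b + c_ == 0, 0, (b + c_) / (2 * a + b + c_))
  sim <- ifelse(a + minbc == 0, 0, minbc / (a + minbc))
  list(i = i, j = j, sor = sor, sim = sim, sne = sor - sim)
}

turnover_proportion_mean <- function(comp) {
  keep <- comp$sor > 0
  if (!any(keep)) return(NA_real_)
  mean(comp$sim[keep] / comp$sor[keep])
}

# subset helper for the component list
`comp_subset` <- function(comp, sel) lapply(comp, function(x) x[sel])

#' @export
print.beta_partition <- function(x, ...) {
  cat(sprintf("<beta_partition> %d pairs (%s): turnover %.3f, nestedness %.3f, p = %.4g (%d perms)\n",
              nrow(x$pairs), x$pair_scope, x$turnover_proportion,
              x$nestedness_proportion, x$permutation_p, x$n_perm))
  invisible(x)
}

#' @export
tidy.beta_partition <- function(x, ...) x$pairs

#' @export
glance.beta_partition <- function(x, ...) {
  tibble::tibble(turnover_proportion = x$turnover_proportion,
                 nestedness_proportion = x$nestedness_proportion,
                 permutation_p = x$permutation_p, n_perm = x$n_perm,
                 n_pairs = nrow(x$pairs))
}

#' Niche breadth per feature
#'
#' Levins niche breadth \eqn{B = 1/\sum_j p_{ij}^2} with
#' \eqn{p_{ij} = x_{ij}/\sum_j x_{ij}}, the effective number of samples a
#' feature occupies, plus the Shannon variant \eqn{\exp(-\sum p \ln p)}
#' reported alongside as a robustness companion. Features absent from every
#' sample (or from the `subset`) are excluded with a warning.
#'
#' @param table A [feature_table()].
#' @param method Primary index, `"levins"` or `"shannon"` (both columns are
#'   always returned; `method` sets the `breadth` column).
#' @param subset Optional character vector of feature IDs to restrict to.
#' @return A tibble: `feature_id`, `b_levins`, `b_shannon`, `breadth`,
#'   `n_samples_used`.
#' @export
niche_breadth <- function(table, method = c("levins", "shannon"), subset = NULL) {
  method <- match.arg(method)
  stopifnot(is_feature_table(table))
  m <- unclass(table)
  if (!is.null(subset)) {
    missing_ids <- setdiff(subset, rownames(m))
    if (length(missing_ids)) {
      stop("subset features not in table: ", paste(missing_ids, collapse = ", "),
           call. = FALSE)
    }
    m <- m[subset, , drop = FALSE]
  }
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " feature(s) with zero total excluded", call. = FALSE)
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  if (!nrow(m)) stop("no features left after filtering", call. = FALSE)
  p <- sweep(m, 1, tot, "/")
  b_lev <- 1 / rowSums(p^2)
  plogp <- ifelse(p > 0, p * log(p), 0)
  b_sha <- exp(-rowSums(plogp))
  tibble::tibble(
    feature_id = rownames(m),
    b_levins = as.numeric(b_lev),
    b_shannon = as.numeric(b_sha),
    breadth = if (method == "levins") as.numeric(b_lev) else as.numeric(b_sha),
    n_samples_used = ncol(m)
  )
}
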