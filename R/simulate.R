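#' Ground-truth descriptors for the synthetic-data generators
#'
#' Each generator in successr is driven by an explicit truth object so that
#' parameter-recovery tests can compare estimates against known values.
#'
#' `neutral_sim_truth()` describes a set of local communities assembled
#' neutrally from a shared metacommunity with migration rate `m` (per-birth
#' probability that the recruit comes from the metacommunity rather than the
#' local community) and local community size `N` reads per sample. The default
#' metacommunity is a geometric rank-abundance series, which supplies the
#' rare-taxon tail the occupancy-abundance (Sloan) fit is sensitive to.
#'
#' @param n_taxa Number of metacommunity taxa (used when `meta` is NULL).
#' @param m Migration rate in (0, 1].
#' @param N Local community size (reads per sample).
#' @param n_samples Number of local communities to draw.
#' @param meta Optional explicit metacommunity relative-abundance vector
#'   (will be normalized); names become feature IDs.
#' @param geometric_k Decay of the default geometric series (0 < k < 1).
#' @return A list of class `neutral_sim_truth`.
#' @export
neutral_sim_truth <- function(n_taxa = 200, m = 0.1, N = 1000, n_samples = 50,
                              meta = NULL, geometric_k = 0.97) {
  if (is.null(meta)) {
    meta <- geometric_k ^ (seq_len(n_taxa) - 1)
    names(meta) <- sprintf("taxon_%04d", seq_len(n_taxa))
  }
  if (is.null(names(meta))) names(meta) <- sprintf("taxon_%04d", seq_along(meta))
  stopifnot(all(meta >= 0), sum(meta) > 0)
  meta <- meta / sum(meta)
  stopifnot(m > 0, m <= 1, N >= 1, n_samples >= 1, N * m > 0)
  structure(list(meta = meta, m = m, N = as.integer(N),
                 n_samples = as.integer(n_samples)),
            class = "neutral_sim_truth")
}

#' @rdname neutral_sim_truth
#' @param sources Matrix of K source profiles (taxa x sources; columns are
#'   normalized) with rownames as feature IDs.
#' @param alpha Mixing proportions of length K + 1; the last entry is the
#'   unknown-source proportion. Must sum to 1.
#' @param unknown Relative-abundance profile of the unknown source (same taxa
#'   as `sources`; normalized). Required when `alpha` puts mass on it.
#' @param sink_depth Reads per sink sample.
#' @export
mixture_truth <- function(sources, alpha, unknown = NULL, sink_depth = 10000) {
  sources <- as.matrix(sources)
  stopifnot(!is.null(rownames(sources)), all(sources >= 0))
  sources <- sweep(sources, 2, colSums(sources), "/")
  K <- ncol(sources)
  stopifnot(length(alpha) == K + 1, all(alpha >= 0),
            abs(sum(alpha) - 1) < 1e-9)
  if (is.null(unknown)) {
    if (alpha[K + 1] > 0) stop("alpha puts mass on the unknown source; supply its profile",
                               call. = FALSE)
    unknown <- rep(0, nrow(sources))
  }
  stopifnot(length(unknown) == nrow(sources), all(unknown >= 0))
  if (sum(unknown) > 0) unknown <- unknown / sum(unknown)
  structure(list(sources = sources, alpha = as.numeric(alpha),
                 unknown = as.numeric(unknown),
                 sink_depth = as.integer(sink_depth)),
            class = "mixture_truth")
}

#' @rdname neutral_sim_truth
#' @param classes Character vector of planted classes, one per feature, each
#'   `"early"`, `"persistent"` or `"late"`.
#' @param p_JU,p_AD Stage prevalences per feature, in `[0, 1]`. Must respect
#'   the class semantics: early means `p_JU > p_AD`, late the reverse,
#'   persistent equality.
#' @export
succession_truth <- function(classes, p_JU, p_AD) {
  stopifnot(length(classes) == length(p_JU), length(p_JU) == length(p_AD),
            all(classes %in% c("early", "persistent", "late")),
            all(p_JU >= 0 & p_JU <= 1), all(p_AD >= 0 & p_AD <= 1))
  ok <- (classes == "early" & p_JU > p_AD) |
    (classes == "late" & p_AD > p_JU) |
    (classes == "persistent" & p_JU == p_AD)
  if (!all(ok)) {
    stop("class/prevalence mismatch for feature(s) ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  }
  structure(tibble::tibble(
    feature_id = sprintf("taxon_%04d", seq_along(classes)),
    class = classes, p_JU = p_JU, p_AD = p_AD
  ), class = c("succession_truth", "tbl_df", "tbl", "data.frame"))
}

#' Simulate a pure-birth (Yule) tree
#'
#' Starts from two lineages; each split waits an exponential time with rate
#' equal to the current number of lineages, then splits a uniformly chosen
#' lineage; a final exponential wait with rate `n_tips` extends the tips to
#' the present. The tree is ultrametric with expected root-to-tip depth
#' \eqn{\sum_{k=2}^{n} 1/k}.
#'
#' @param n_tips Number of tips (at least 2).
#' @param seed Integer seed; the same seed yields an identical tree.
#' @return An [ape::phylo] tree with tips `t1 ... tn`.
#' @export
simulate_tree <- function(n_tips, seed = 0L) {
  if (n_tips < 2) stop("n_tips must be at least 2", call. = FALSE)
  with_seed(seed, {
    # Placeholder-substitution Newick assembly: %k marks active lineage k.
    nwk <- "(%{1},%{2});"
    born <- c(0, 0)
    active <- c(1L, 2L)
    next_id <- 3L
    t_now <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t_now <- t_now + stats::rexp(1, rate = k)
      j <- active[sample.int(k, 1)]
      len <- t_now - born[j]
      a <- next_id; b <- next_id + 1L; next_id <- next_id + 2L
      born[a] <- t_now; born[b] <- t_now
      nwk <- sub(sprintf("%%{%d}", j),
                 sprintf("(%%{%d},%%{%d}):%.12g", a, b, len), nwk, fixed = TRUE)
      active <- c(setdiff(active, j), a, b)
    }
    t_now <- t_now + stats::rexp(1, rate = n_tips)
    for (i in seq_along(active)) {
      j <- active[i]
      nwk <- sub(sprintf("%%{%d}", j),
                 sprintf("t%d:%.12g", i, t_now - born[j]), nwk, fixed = TRUE)
    }
    ape::read.tree(text = nwk)
  })
}

#' Simulate neutrally assembled local communities
#'
#' Two sampling schemes of the same neutral local-community model are
#' offered. The default, `"stationary"`, draws each sample's composition from
#' the stationary distribution of Hubbell local dynamics with immigration:
#' \eqn{\pi \sim Dirichlet(Nm \cdot p)} over the metacommunity profile
#' \eqn{p}, then counts \eqn{\sim Multinomial(N, \pi)} -- the exact
#' distribution whose marginals (taxon frequency \eqn{\sim Beta(Nm p, Nm(1-p))})
#' the occupancy-abundance neutral fit assumes, so the planted migration rate
#' is recoverable by [fit_ncm()]. The `"urn"` scheme instead assembles each
#' sample individual-by-individual: with probability `m` the recruit
#' immigrates from the metacommunity, otherwise it copies a uniformly chosen
#' existing individual (the first always immigrates). The urn is the
#' intuitive sequential picture (and at `m = 1` gives exactly iid multinomial
#' samples) but its copy amplification makes it more dispersed than the
#' stationary model, so fitted migration rates underestimate the planted `m`
#' by roughly 2-3x.
#'
#' @param truth A [neutral_sim_truth()].
#' @param seed Integer seed.
#' @param scheme `"stationary"` (default) or `"urn"`.
#' @return A [feature_table()] of counts, taxa x samples, each column summing
#'   to `truth$N`.
#' @export
simulate_neutral_communities <- function(truth, seed = 0L,
                                         scheme = c("stationary", "urn")) {
  stopifnot(inherits(truth, "neutral_sim_truth"))
  scheme <- match.arg(scheme)
  S <- length(truth$meta)
  draw_stationary <- function() {
    a <- truth$N * truth$m * truth$meta
    g <- stats::rgamma(S, shape = a)
    while (sum(g) == 0) g <- stats::rgamma(S, shape = a)
    drop(stats::rmultinom(1, truth$N, g / sum(g)))
  }
  draw_urn <- function() {
    ind <- integer(truth$N)
    migrate <- stats::runif(truth$N) < truth$m
    migrate[1] <- TRUE
    n_mig <- sum(migrate)
    ind[migrate] <- sample.int(S, n_mig, replace = TRUE, prob = truth$meta)
    for (i in which(!migrate)) ind[i] <- ind[sample.int(i - 1L, 1L)]
    tabulate(ind, nbins = S)
  }
  with_seed(seed, {
    cols <- vapply(seq_len(truth$n_samples), function(s) {
      if (scheme == "stationary") draw_stationary() else draw_urn()
    }, numeric(S))
    cols <- matrix(cols, nrow = S)
    dimnames(cols) <- list(names(truth$meta),
                           sprintf("sample_%03d", seq_len(truth$n_samples)))
    feature_table(cols, kind = "counts")
  })
}

#' Simulate a source-sink mixture cohort
#'
#' Source samples are multinomial draws from each source profile; each sink is
#' a multinomial draw from the planted mixture
#' \eqn{\sum_k \alpha_k \gamma_k + \alpha_{unknown} \gamma_{unknown}}.
#'
#' @param truth A [mixture_truth()].
#' @param n_sinks Number of sink samples (>= 1).
#' @param seed Integer seed.
#' @param source_depth Reads per source sample (default: sink depth).
#' @return A list with `table` (a counts [feature_table()]) and `design`
#'   (a study-design tibble with roles `source`/`sink`).
#' @export
simulate_source_sink <- function(truth, n_sinks = 10, seed = 0L,
                                 source_depth = NULL) {
  stopifnot(inherits(truth, "mixture_truth"), n_sinks >= 1)
  if (is.null(source_depth)) source_depth <- truth$sink_depth
  K <- ncol(truth$sources)
  mix <- drop(truth$sources %*% truth$alpha[seq_len(K)]) +
    truth$alpha[K + 1] * truth$unknown
  with_seed(seed, {
    src <- vapply(seq_len(K), function(k) {
      drop(stats::rmultinom(1, source_depth, truth$sources[, k]))
    }, numeric(nrow(truth$sources)))
    snk <- stats::rmultinom(n_sinks, truth$sink_depth, mix)
    m <- cbind(src, snk)
    src_ids <- if (!is.null(colnames(truth$sources))) colnames(truth$sources) else
      sprintf("source_%02d", seq_len(K))
    colnames(m) <- c(src_ids, sprintf("sink_%03d", seq_len(n_sinks)))
    rownames(m) <- rownames(truth$sources)
    design <- tibble::tibble(
      sample_id = colnames(m),
      group = "A",
      stage = rep(c("MA", "AD"), c(K, n_sinks)),
      subject_id = colnames(m),
      role = rep(c("source", "sink"), c(K, n_sinks)),
      pair_id = NA_character_
    )
    list(table = feature_table(m, kind = "counts"), design = as_study_design(design))
  })
}

#' Simulate a two-stage succession cohort
#'
#' Presence of each feature in each sample is Bernoulli with the planted
#' stage prevalence; present features receive log-normal(0, 1) abundances
#' converted to positive integer read counts. Only the presence/absence
#' structure carries signal, matching what prevalence-based classification
#' consumes.
#'
#' @param truth A [succession_truth()].
#' @param n_JU,n_AD Samples per stage (>= 2).
#' @param seed Integer seed.
#' @param group Group label stamped on the design (default "A").
#' @return A list with `table` (counts [feature_table()], possibly containing
#'   all-zero feature rows, which are retained) and `design`.
#' @export
simulate_succession_cohort <- function(truth, n_JU = 20, n_AD = 20, seed = 0L,
                                       group = "A") {
  stopifnot(inherits(truth, "succession_truth"), n_JU >= 2, n_AD >= 2)
  nf <- nrow(truth)
  with_seed(seed, {
    draw_stage <- function(p, n) {
      pres <- matrix(stats::runif(nf * n) < p, nrow = nf)
      ab <- matrix(0, nf, n)
      npos <- sum(pres)
      if (npos) ab[pres] <- pmax(1, round(1000 * stats::rlnorm(npos)))
      ab
    }
    ju <- draw_stage(truth$p_JU, n_JU)
    ad <- draw_stage(truth$p_AD, n_AD)
    m <- cbind(ju, ad)
    rownames(m) <- truth$feature_id
    colnames(m) <- c(sprintf("JU_%03d", seq_len(n_JU)), sprintf("AD_%03d", seq_len(n_AD)))
    design <- tibble::tibble(
      sample_id = colnames(m),
      group = group,
      stage = rep(c("JU", "AD"), c(n_JU, n_AD)),
      subject_id = colnames(m),
      role = "none", pair_id = NA_character_
    )
    list(table = feature_table(m, kind = "counts"), design = as_study_design(design))
  })
}

#' Simulate a two-group maternal transmission cohort
#'
#' Builds the source-sink layout the replicated source-tracking contrast
#' consumes: per group, `n_dams` maternal (MA) source samples and `n_sinks`
#' adult (AD) sink samples whose composition mixes the group's maternal
#' profile (weight `maternal_alpha[group]`) with a shared environmental
#' profile on a disjoint taxon block (the "unknown" source).
#'
#' @param maternal_alpha Named numeric of length 2: planted maternal
#'   contribution per group.
#' @param n_dams Maternal source samples per group.
#' @param n_sinks Sink samples per group.
#' @param n_taxa_maternal,n_taxa_env Sizes of the maternal and environmental
#'   taxon blocks.
#' @param depth Reads per sample.
#' @param seed Integer seed.
#' @return A list with `table` (counts [feature_table()]) and `design`.
#' @export
simulate_transmission_cohort <- function(maternal_alpha = c(A = 0.5, B = 0.3),
                                         n_dams = 3, n_sinks = 10,
                                         n_taxa_maternal = 80, n_taxa_env = 40,
                                         depth = 20000, seed = 0L) {
  stopifnot(length(maternal_alpha) == 2, !is.null(names(maternal_alpha)),
            all(maternal_alpha >= 0 & maternal_alpha <= 1))
  groups <- names(maternal_alpha)
  ids_mat <- sprintf("mat_%03d", seq_len(n_taxa_maternal))
  ids_env <- sprintf("env_%03d", seq_len(n_taxa_env))
  with_seed(seed, {
    base_env <- 0.9 ^ (seq_len(n_taxa_env) - 1)
    env_profile <- c(stats::setNames(rep(0, n_taxa_maternal), ids_mat),
                     stats::setNames(base_env / sum(base_env), ids_env))
    cols <- list(); design <- list()
    for (g in groups) {
      base_mat <- stats::rgamma(n_taxa_maternal, shape = 0.8)
      base_mat <- base_mat / sum(base_mat)
      mat_profile <- c(stats::setNames(base_mat, ids_mat),
                       stats::setNames(rep(0, n_taxa_env), ids_env))
      for (dmi in seq_len(n_dams)) {
        jit <- stats::rgamma(length(mat_profile), shape = 200 * mat_profile + 1e-9)
        jit <- jit / sum(jit)
        cols[[paste0(g, "_MA_", dmi)]] <- drop(stats::rmultinom(1, depth, jit))
        design[[length(design) + 1L]] <- tibble::tibble(
          sample_id = paste0(g, "_MA_", dmi), group = g, stage = "MA",
          subject_id = paste0(g, "_dam_", dmi), role = "source",
          pair_id = NA_character_)
      }
      a <- maternal_alpha[[g]]
      mix <- a * mat_profile + (1 - a) * env_profile
      for (si in seq_len(n_sinks)) {
        cols[[paste0(g, "_AD_", si)]] <- drop(stats::rmultinom(1, depth, mix))
        design[[length(design) + 1L]] <- tibble::tibble(
          sample_id = paste0(g, "_AD_", si), group = g, stage = "AD",
          subject_id = paste0(g, "_off_", si), role = "sink",
          pair_id = NA_character_)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- c(ids_mat, ids_env)
    list(table = feature_table(m, kind = "counts"),
         design = as_study_design(dplyr::bind_rows(design)))
  })
}
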