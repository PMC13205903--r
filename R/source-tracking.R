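#' EM source tracking for one sink community
#'
#' Decomposes a sink's counts as a multinomial mixture of K known source
#' profiles plus one unknown source:
#' \eqn{x_{sink} \sim Multinomial(\sum_k \alpha_k \gamma_k + \alpha_u \gamma_u)}.
#' Known-source profiles \eqn{\gamma_k} are fixed at the empirical source
#' frequencies (pseudocount 1); the unknown profile \eqn{\gamma_u} is
#' re-estimated every M-step from the residual responsibilities. Mixing
#' proportions start uniform over K + 1 components; iteration stops when the
#' log-likelihood gain drops below `tol` or after `n_iter_max` iterations
#' (1000 by default). The log-likelihood is non-decreasing across iterations
#' by construction and is asserted at every step.
#'
#' @param sources A counts [feature_table()] whose columns are the known
#'   source samples (one column per source), or a taxa-by-sources count
#'   matrix with dimnames.
#' @param sink Named (or source-aligned) count vector for the sink sample.
#' @param n_iter_max Maximum EM iterations (default 1000).
#' @param tol Convergence tolerance on the log-likelihood gain (default 1e-8).
#' @param seed Integer seed (reserved for stochastic variants; the default
#'   fit is deterministic).
#' @param update_sources If `TRUE`, known-source profiles are re-estimated
#'   jointly with the unknown profile instead of staying fixed.
#' @param unknown_support `"orphan"` (default) restricts the unknown
#'   profile's M-step re-estimation to taxa with zero total source count --
#'   the taxa through which an unknown source is actually identifiable; a
#'   fully `"free"` unknown profile can drift toward the sink composition
#'   itself (the one-component mixture of any sink is the sink), which
#'   inflates the unknown share when the true unknown contribution is small.
#' @return An object of class `source_contribution`: `contributions` (tibble
#'   with `source`, `alpha`), `alpha_unknown`, `log_likelihood`,
#'   `n_iterations`, `converged`.
#' @export
em_source_tracking <- function(sources, sink, n_iter_max = 1000, tol = 1e-8,
                               seed = 0L, update_sources = FALSE,
                               unknown_support = c("orphan", "free")) {
  unknown_support <- match.arg(unknown_support)
  if (is_feature_table(sources)) {
    if (table_kind(sources) != "counts") {
      stop("sources must be counts", call. = FALSE)
    }
    src <- unclass(sources)
  } else {
    src <- as.matrix(sources)
    if (any(src < 0) || any(src != round(src))) stop("sources must be counts", call. = FALSE)
  }
  if (is.null(colnames(src))) colnames(src) <- sprintf("source_%02d", seq_len(ncol(src)))
  if (!is.null(names(sink))) {
    all_ids <- union(rownames(src), names(sink))
    full_src <- matrix(0, length(all_ids), ncol(src),
                       dimnames = list(all_ids, colnames(src)))
    full_src[rownames(src), ] <- src
    x <- stats::setNames(numeric(length(all_ids)), all_ids)
    x[names(sink)] <- sink
    src <- full_src
  } else {
    if (length(sink) != nrow(src)) stop("unnamed sink must match source taxa", call. = FALSE)
    x <- as.numeric(sink)
  }
  if (sum(x) <= 0) stop("sink has zero total count", call. = FALSE)
  if (ncol(src) < 1) stop("need at least one source", call. = FALSE)

  K <- ncol(src)
  S <- nrow(src)
  gamma_known <- sweep(src + 1, 2, colSums(src + 1), "/")   # pseudocount 1
  # Unknown profile: uniform over sink taxa with zero total source count,
  # epsilon elsewhere.
  orphan <- rowSums(src) == 0 & x > 0
  gamma_u <- rep(1e-6, S)
  if (any(orphan)) gamma_u[orphan] <- 1
  gamma_u <- gamma_u / sum(gamma_u)

  alpha <- rep(1 / (K + 1), K + 1)
  gam <- cbind(gamma_known, unknown = gamma_u)
  loglik <- function(alpha, gam) {
    mix <- drop(gam %*% alpha)
    sum(x[x > 0] * log(mix[x > 0]))
  }
  ll_old <- loglik(alpha, gam)
  converged <- FALSE
  iter <- 0L
  while (iter < n_iter_max) {
    iter <- iter + 1L
    # E-step: responsibilities r_ik
    num <- sweep(gam, 2, alpha, "*")
    denom <- rowSums(num)
    denom[denom == 0] <- .Machine$double.xmin
    r <- num / denom
    # M-step
    wk <- unname(colSums(x * r))
    alpha <- wk / sum(wk)
    if (update_sources) {
      for (k in seq_len(K)) {
        g <- x * r[, k] + src[, k] + 1  # keep empirical anchor
        gam[, k] <- g / sum(g)
      }
    }
    gu <- x * r[, K + 1]
    if (unknown_support == "orphan") gu[!orphan] <- 0
    if (sum(gu) > 0) {
      # epsilon floor keeps the likelihood finite on the fixed support
      floor_mass <- rep(1e-12, S)
      gam[, K + 1] <- (gu + floor_mass) / sum(gu + floor_mass)
    }
    ll_new <- loglik(alpha, gam)
    if (ll_new < ll_old - 1e-6 * max(1, abs(ll_old))) {
      stop("EM log-likelihood decreased; this is a bug", call. = FALSE)
    }
    if (ll_new - ll_old < tol) {
      ll_old <- ll_new
      converged <- TRUE
      break
    }
    ll_old <- ll_new
  }
  stopifnot(abs(sum(alpha) - 1) < 1e-9)
  structure(list(
    contributions = tibble::tibble(source = colnames(src),
                                   alpha = alpha[seq_len(K)]),
    alpha_unknown = alpha[K + 1],
    log_likelihood = ll_old,
    n_iterations = iter,
    converged = converged
  ), class = "source_contribution")
}

#' @export
print.source_contribution <- function(x, ...) {
  cat(sprintf("<source_contribution> logLik %.2f, %d iterations%s\n",
              x$log_likelihood, x$n_iterations,
              if (x$converged) " (converged)" else ""))
  df <- rbind(as.data.frame(x$contributions),
              data.frame(source = "unknown", alpha = x$alpha_unknown))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.source_contribution <- function(x, ...) {
  dplyr::bind_rows(x$contributions,
                   tibble::tibble(source = "unknown", alpha = x$alpha_unknown))
}

#' @export
glance.source_contribution <- function(x, ...) {
  tibble::tibble(log_likelihood = x$log_likelihood,
                 n_iterations = x$n_iterations,
                 converged = x$converged,
                 alpha_unknown = x$alpha_unknown)
}

#' Replicated source tracking over stage transitions with a group contrast
#'
#' For each group and each `source_stage -> sink_stage` transition, runs the
#' EM decomposition of every sink against the group's source samples (pooled
#' per subject), repeats the analysis `n_repeats` times under derived seeds
#' (each repeat resamples every sink's counts multinomially at its own depth,
#' so repeats quantify estimation stability), and contrasts the total known
#' -source contribution between the two groups with a two-sided Wilcoxon
#' rank-sum test, Benjamini-Hochberg adjusted across transitions.
#'
#' The default contrast unit is the sink (each sink's mean contribution over
#' repeats), which keeps the test calibrated; `compare = "per_run"` instead
#' uses per-run group means, mirroring a common practice of comparing run
#' averages, but note those runs re-use the same sinks and the resulting test
#' is anti-conservative.
#'
#' @param table A counts [feature_table()].
#' @param design A study design tibble (see [as_study_design()]).
#' @param transitions List of 2-vectors `c(source_stage, sink_stage)`.
#' @param n_repeats Number of replicated runs (default 10).
#' @param seed Integer seed.
#' @param compare `"per_sink"` (default) or `"per_run"`.
#' @param n_iter_max,tol Passed to [em_source_tracking()].
#' @return A list of class `source_tracking_replicates` with
#'   `contributions` (tibble: group, transition, run, sink_id, alpha values)
#'   and `contrasts` (tibble: transition, group means, `p_value`, `p_adj`).
#' @export
replicate_source_tracking <- function(table, design, transitions,
                                      n_repeats = 10, seed = 0L,
                                      compare = c("per_sink", "per_run"),
                                      n_iter_max = 1000, tol = 1e-8) {
  compare <- match.arg(compare)
  stopifnot(is_feature_table(table), table_kind(table) == "counts")
  design <- align_design(table, design)
  groups <- unique(design$group)
  if (length(groups) != 2) stop("design must contain exactly 2 groups", call. = FALSE)
  if (!length(transitions)) stop("no transitions given", call. = FALSE)

  m <- unclass(table)
  rows <- list()
  for (tr_i in seq_along(transitions)) {
    tr <- transitions[[tr_i]]
    tr_label <- paste0(tr[1], "->", tr[2])
    for (g in groups) {
      src_samples <- design$sample_id[design$group == g & design$stage == tr[1]]
      sink_samples <- design$sample_id[design$group == g & design$stage == tr[2]]
      if (!length(src_samples) || !length(sink_samples)) {
        stop("transition ", tr_label, " has no source or sink samples in group ", g,
             call. = FALSE)
      }
      # pool sources per subject: one source community per subject
      src_subj <- design$subject_id[match(src_samples, design$sample_id)]
      pooled <- vapply(split(src_samples, src_subj), function(ss) {
        rowSums(m[, ss, drop = FALSE])
      }, numeric(nrow(m)))
      pooled <- matrix(pooled, nrow = nrow(m),
                       dimnames = list(rownames(m), names(split(src_samples, src_subj))))
      for (run in seq_len(n_repeats)) {
        run_seed <- (as.integer(seed) + 7919L * tr_i + 104729L * run +
                       13L * match(g, groups)) %% .Machine$integer.max
        for (sk in sink_samples) {
          x <- m[, sk]
          x_run <- if (n_repeats > 1) {
            with_seed(run_seed + match(sk, sink_samples),
                      drop(stats::rmultinom(1, sum(x), x / sum(x))))
          } else x
          names(x_run) <- rownames(m)
          fit <- em_source_tracking(pooled, x_run, n_iter_max = n_iter_max,
                                    tol = tol, seed = run_seed)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            transition = tr_label, group = g, run = run, sink_id = sk,
            alpha_known = 1 - fit$alpha_unknown,
            alpha_unknown = fit$alpha_unknown,
            converged = fit$converged
          )
        }
      }
    }
  }
  contrib <- dplyr::bind_rows(rows)

  contrasts <- NULL
  if (n_repeats < 2 && compare == "per_run") {
    warning("n_repeats = 1: per-run contrast skipped (no distribution)", call. = FALSE)
  } else {
    contrasts <- dplyr::bind_rows(lapply(unique(contrib$transition), function(tl) {
      sub <- contrib[contrib$transition == tl, ]
      unit <- if (compare == "per_sink") {
        dplyr::summarise(dplyr::group_by(sub, .data$group, .data$sink_id),
                         value = mean(.data$alpha_known), .groups = "drop")
      } else {
        dplyr::summarise(dplyr::group_by(sub, .data$group, .data$run),
                         value = mean(.data$alpha_known), .groups = "drop")
      }
      vA <- unit$value[unit$group == groups[1]]
      vB <- unit$value[unit$group == groups[2]]
      p <- tryCatch(
        suppressWarnings(stats::wilcox.test(vA, vB)$p.value),
        error = function(e) NA_real_)
      tibble::tibble(transition = tl,
                     mean_A = mean(vA), mean_B = mean(vB),
                     group_A = groups[1], group_B = groups[2],
                     p_value = p)
    }))
    contrasts$p_adj <- stats::p.adjust(contrasts$p_value, method = "BH")
  }
  structure(list(contributions = contrib, contrasts = contrasts,
                 compare = compare, n_repeats = n_repeats),
            class = "source_tracking_replicates")
}

#' @export
print.source_tracking_replicates <- function(x, ...) {
  cat(sprintf("<source_tracking_replicates> %d runs, contrast unit: %s\n",
              x$n_repeats, x$compare))
  if (!is.null(x$contrasts)) print(as.data.frame(x$contrasts), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.source_tracking_replicates <- function(x, ...) x$contributions

#' @export
glance.source_tracking_replicates <- function(x, ...) {
  if (is.null(x$contrasts)) return(tibble::tibble())
  x$contrasts
}
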