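#' Classify colonization patterns between juvenile and adult stages
#'
#' Each feature detected in at least one juvenile (JU) or adult (AD) sample
#' of the group is tested for a prevalence shift with a two-sided exact
#' binomial test of its AD positive count against the JU prevalence as the
#' null proportion, clamped symmetrically away from 0 and 1 at
#' \eqn{1/(2 n_{JU})}. Features with `p < alpha` (default 0.1) are classed
#' by the sign of the AD - JU prevalence difference: `late` (increasing),
#' `early` (decreasing); everything else is `persistent`.
#'
#' @param table A [feature_table()].
#' @param design A study design tibble.
#' @param group Group label to analyze.
#' @param alpha Significance level on the binomial p (default 0.1).
#' @param juvenile_stage,adult_stage Stage labels (defaults "JU", "AD").
#' @param alternative `"two.sided"` (default) or a one-sided alternative.
#' @return A tibble of colonization calls: `feature_id`, `class`, `prev_JU`,
#'   `prev_AD`, `delta` (prev_AD - prev_JU), `p_value`, `neg_log10_p`.
#' @export
classify_colonization <- function(table, design, group, alpha = 0.1,
                                  juvenile_stage = "JU", adult_stage = "AD",
                                  alternative = "two.sided") {
  stopifnot(is_feature_table(table))
  design <- align_design(table, design)
  sJ <- design$sample_id[design$group == group & design$stage == juvenile_stage]
  sA <- design$sample_id[design$group == group & design$stage == adult_stage]
  nJ <- length(sJ); nA <- length(sA)
  if (nJ == 0 || nA == 0) {
    stop("group ", group, " needs samples in both stages", call. = FALSE)
  }
  m <- unclass(table)
  kJ <- rowSums(m[, sJ, drop = FALSE] > 0)
  kA <- rowSums(m[, sA, drop = FALSE] > 0)
  keep <- (kJ + kA) > 0  # detected in at least one sample of JU or AD
  kJ <- kJ[keep]; kA <- kA[keep]
  ids <- rownames(m)[keep]
  prevJ <- kJ / nJ
  prevA <- kA / nA
  clamp <- 1 / (2 * nJ)
  p0 <- pmin(pmax(prevJ, clamp), 1 - clamp)
  pvals <- vapply(seq_along(ids), function(i) {
    stats::binom.test(kA[i], nA, p = p0[i], alternative = alternative)$p.value
  }, numeric(1))
  delta <- prevA - prevJ
  cls <- rep("persistent", length(ids))
  cls[pvals < alpha & delta > 0] <- "late"
  cls[pvals < alpha & delta < 0] <- "early"
  tibble::tibble(
    feature_id = ids, class = cls,
    prev_JU = prevJ, prev_AD = prevA, delta = delta,
    p_value = pvals, neg_log10_p = -log10(pvals),
    group = group
  )
}

#' Class proportions of a colonization-call table
#'
#' @param calls Output of [classify_colonization()].
#' @return A tibble with `class`, `n`, `proportion`.
#' @export
colonization_proportions <- function(calls) {
  calls |>
    dplyr::count(.data$class, name = "n") |>
    dplyr::mutate(proportion = .data$n / sum(.data$n))
}

#' Compare developmental trajectories between two groups
#'
#' Features classified in both groups are plotted as points
#' `(delta_exposed x 100, delta_control x 100)` where delta is the AD - JU
#' prevalence change; concordant development puts points on the `y = x`
#' diagonal. A two-sided paired Wilcoxon signed-rank test over the coordinate
#' pairs summarizes the overall divergence, and each point carries a
#' class-transition label plus an interpretation: points above the diagonal
#' (control change exceeding exposed change) mark taxa whose progression is
#' "accelerated in exposed" - they already sit at adult-like prevalence while
#' controls are still climbing.
#'
#' @param calls_control Colonization calls (see [classify_colonization()])
#'   for the control group (plotted on y).
#' @param calls_exposed Calls for the exposed group (plotted on x).
#' @return A list of class `trajectory_comparison`: `points` (tibble:
#'   `feature_id`, `x_exposed`, `y_control`, classes, `above_diagonal`,
#'   `interpretation`), `paired_wilcoxon_p`, `fraction_above_diagonal`,
#'   `n_shared`.
#' @export
compare_trajectories <- function(calls_control, calls_exposed) {
  shared <- intersect(calls_control$feature_id, calls_exposed$feature_id)
  if (length(shared) < 5) {
    stop("fewer than 5 features shared between the two call lists", call. = FALSE)
  }
  cc <- calls_control[match(shared, calls_control$feature_id), ]
  ce <- calls_exposed[match(shared, calls_exposed$feature_id), ]
  x <- ce$delta * 100
  y <- cc$delta * 100
  above <- y > x
  interp <- dplyr::case_when(
    y > x ~ "accelerated in exposed",
    y < x ~ "delayed in exposed",
    TRUE ~ "concordant")
  p <- if (all(x == y)) 1 else
    suppressWarnings(stats::wilcox.test(y, x, paired = TRUE)$p.value)
  pts <- tibble::tibble(
    feature_id = shared,
    x_exposed = x, y_control = y,
    class_exposed = ce$class, class_control = cc$class,
    transition = paste0(ce$class, "->", cc$class),
    above_diagonal = above,
    interpretation = interp
  )
  structure(list(points = pts,
                 paired_wilcoxon_p = p,
                 fraction_above_diagonal = mean(above),
                 n_shared = length(shared)),
            class = "trajectory_comparison")
}

#' @export
print.trajectory_comparison <- function(x, ...) {
  cat(sprintf("<trajectory_comparison> %d shared features, %.0f%% above diagonal, paired signed-rank p = %.4g\n",
              x$n_shared, 100 * x$fraction_above_diagonal, x$paired_wilcoxon_p))
  invisible(x)
}

#' @export
tidy.trajectory_comparison <- function(x, ...) x$points

#' @export
glance.trajectory_comparison <- function(x, ...) {
  tibble::tibble(paired_wilcoxon_p = x$paired_wilcoxon_p,
                 fraction_above_diagonal = x$fraction_above_diagonal,
                 n_shared = x$n_shared)
}

#' Stage persistence sets within a group
#'
#' A feature is "present" in a stage when its abundance exceeds zero in at
#' least one sample of that stage. Returns the per-feature stage membership
#' pattern and the pattern counts used for persistence network rendering.
#'
#' @param table A [feature_table()].
#' @param design A study design tibble.
#' @param group Group label to analyze.
#' @return A list of class `persistence_sets`: `membership` (tibble:
#'   `feature_id`, one logical column per stage, `pattern`) and
#'   `pattern_counts` (tibble: `pattern`, `n`).
#' @export
persistence_sets <- function(table, design, group) {
  stopifnot(is_feature_table(table))
  design <- align_design(table, design)
  design <- design[design$group == group, ]
  stages <- unique(design$stage)
  if (length(stages) < 2) stop("group needs at least 2 stages", call. = FALSE)
  m <- unclass(table)
  pres <- vapply(stages, function(st) {
    ss <- design$sample_id[design$stage == st]
    rowSums(m[, ss, drop = FALSE] > 0) > 0
  }, logical(nrow(m)))
  colnames(pres) <- stages
  pattern <- unname(apply(pres, 1, function(r) paste(stages[r], collapse = "&")))
  pattern[pattern == ""] <- "(absent)"
  membership <- dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(m)),
    tibble::as_tibble(pres),
    tibble::tibble(pattern = pattern))
  counts <- membership |>
    dplyr::count(.data$pattern, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n))
  structure(list(membership = membership, pattern_counts = counts,
                 stages = stages, group = group),
            class = "persistence_sets")
}

#' @export
print.persistence_sets <- function(x, ...) {
  cat(sprintf("<persistence_sets> group %s, stages: %s\n", x$group,
              paste(x$stages, collapse = ", ")))
  print(as.data.frame(x$pattern_counts), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.persistence_sets <- function(x, ...) x$membership
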