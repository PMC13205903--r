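#' Default prevalence rule sets per developmental stage
#'
#' The maternal (MA) stage, where the intervention acts directly, uses a 50%
#' prevalence floor; juvenile (JU) and adult (AD) stages use a relaxed 30%
#' floor, and JU additionally activates a guard against marginal contrasts:
#' when the low group has 0 positive samples the high group must have at
#' least 2, and when it has 1 the high group must have at least 3 (the guard
#' minima are then the binding requirement for the guarded stage). Floors are
#' applied as `ceiling(rate * n)` positives. `exact_floor_strict` mirrors the
#' stricter sub-rule used for functional features: a group sitting exactly at
#' the floor tolerates no positives in the other group.
#'
#' @param floor Prevalence floor as a fraction of group size.
#' @param max_other Maximum positives tolerated in the other group.
#' @param guard Activate the marginal-contrast guard.
#' @param exact_floor_strict Apply the at-threshold strict sub-rule.
#' @return A list rule config.
#' @export
prevalence_rule <- function(floor = 0.3, max_other = 1, guard = FALSE,
                            exact_floor_strict = FALSE) {
  stopifnot(floor > 0, floor <= 1, max_other >= 0)
  list(floor = floor, max_other = max_other, guard = guard,
       exact_floor_strict = exact_floor_strict)
}

#' @rdname prevalence_rule
#' @export
default_prevalence_rules <- function() {
  list(MA = prevalence_rule(floor = 0.5),
       JU = prevalence_rule(floor = 0.3, guard = TRUE),
       AD = prevalence_rule(floor = 0.3))
}

#' Differential-prevalence calls between two groups at one stage
#'
#' A feature is called differentially prevalent when one group clears the
#' stage's prevalence floor while the other group has at most one positive
#' sample (presence = abundance > 0); see [prevalence_rule()] for the JU
#' guard. Calls are antisymmetric: swapping the groups flips the direction
#' but not the set.
#'
#' @param table A [feature_table()].
#' @param design A study design tibble.
#' @param stage Stage label to analyze.
#' @param rule_set Named list of [prevalence_rule()]s (default
#'   [default_prevalence_rules()]); the rule for `stage` must exist.
#' @return A tibble of `differential_call` rows: `feature_id`, `stage`,
#'   `basis` ("prevalence"), `direction` (`up_in_<group>`), `n_pos_A`,
#'   `n_pos_B`, `prevalence_A`, `prevalence_B`.
#' @export
differential_prevalence <- function(table, design, stage,
                                    rule_set = default_prevalence_rules()) {
  stopifnot(is_feature_table(table))
  design <- align_design(table, design)
  if (!stage %in% design$stage) stop("unknown stage: ", stage, call. = FALSE)
  rule <- rule_set[[stage]]
  if (is.null(rule)) stop("no prevalence rule configured for stage ", stage,
                          call. = FALSE)
  sel <- design$stage == stage
  groups <- sort(unique(design$group[sel]))
  if (length(groups) != 2) stop("stage ", stage, " needs exactly 2 groups", call. = FALSE)
  sA <- design$sample_id[sel & design$group == groups[1]]
  sB <- design$sample_id[sel & design$group == groups[2]]
  nA <- length(sA); nB <- length(sB)
  if (nA < 3 || nB < 3) stop("both groups need at least 3 samples at stage ", stage,
                             call. = FALSE)
  m <- unclass(table)
  posA <- rowSums(m[, sA, drop = FALSE] > 0)
  posB <- rowSums(m[, sB, drop = FALSE] > 0)

  called_dir <- function(n_hi, n_hi_tot, n_lo, n_lo_tot) {
    if (n_lo > rule$max_other) return(FALSE)
    if (rule$guard) {
      need <- if (n_lo == 0) 2L else 3L
      return(n_hi >= need)
    }
    floor_count <- ceiling(rule$floor * n_hi_tot)
    if (floor_count > n_hi_tot) stop("rule floor exceeds group size", call. = FALSE)
    if (n_hi < floor_count) return(FALSE)
    if (rule$exact_floor_strict && n_hi == floor_count && n_lo > 0) return(FALSE)
    TRUE
  }
  up_A <- vapply(seq_len(nrow(m)), function(i) called_dir(posA[i], nA, posB[i], nB),
                 logical(1))
  up_B <- vapply(seq_len(nrow(m)), function(i) called_dir(posB[i], nB, posA[i], nA),
                 logical(1))
  keep <- up_A | up_B
  tibble::tibble(
    feature_id = rownames(m)[keep],
    stage = stage,
    basis = "prevalence",
    direction = ifelse(up_A[keep], paste0("up_in_", groups[1]),
                       paste0("up_in_", groups[2])),
    n_pos_A = posA[keep], n_pos_B = posB[keep],
    prevalence_A = posA[keep] / nA, prevalence_B = posB[keep] / nB,
    group_A = groups[1], group_B = groups[2],
    effect_size = NA_real_, p_value = NA_real_
  )
}

#' Abundance-based differential screen (two-class rank test + LDA effect size)
#'
#' The two-class core of the LDA-effect-size procedure: features pass when a
#' two-sided Wilcoxon rank-sum test on relative abundances gives
#' `p < p_threshold` and the log10 linear-discriminant effect size exceeds
#' `lda_threshold`. With two classes and one feature at a time the
#' discriminant axis is the feature itself, so the effect size is
#' `log10(1 + |mean_A - mean_B|)` on the counts-per-million scale
#' (relative abundance x 1e6), the conventional scale on which a score of 2
#' marks a >100-CPM shift.
#'
#' @param table A [feature_table()].
#' @param design A study design tibble.
#' @param stage Stage label to analyze.
#' @param lda_threshold Log10 effect-size threshold (default 2.0).
#' @param p_threshold Rank-test p threshold (0.05 for the directly exposed
#'   stage, 0.1 for later stages, per the calling convention).
#' @return A tibble of calls: `feature_id`, `stage`, `basis` ("abundance"),
#'   `direction`, `effect_size` (log10 LDA score), `p_value`.
#' @export
abundance_screen <- function(table, design, stage, lda_threshold = 2,
                             p_threshold = 0.05) {
  stopifnot(is_feature_table(table))
  design <- align_design(table, design)
  sel <- design$stage == stage
  if (!any(sel)) stop("unknown stage: ", stage, call. = FALSE)
  groups <- sort(unique(design$group[sel]))
  if (length(groups) != 2) stop("stage needs exactly 2 groups", call. = FALSE)
  sA <- design$sample_id[sel & design$group == groups[1]]
  sB <- design$sample_id[sel & design$group == groups[2]]
  if (length(sA) < 3 || length(sB) < 3) {
    stop("both groups need at least 3 samples", call. = FALSE)
  }
  rel <- unclass(as_relative(table))
  cpm <- rel * 1e6
  rows <- lapply(rownames(rel), function(f) {
    xa <- cpm[f, sA]; xb <- cpm[f, sB]
    if (stats::var(c(xa, xb)) == 0) return(NULL)  # constant feature: skipped
    p <- suppressWarnings(stats::wilcox.test(xa, xb)$p.value)
    eff <- log10(1 + abs(mean(xa) - mean(xb)))
    if (is.na(p) || p >= p_threshold || eff <= lda_threshold) return(NULL)
    tibble::tibble(
      feature_id = f, stage = stage, basis = "abundance",
      direction = if (mean(xa) > mean(xb)) paste0("up_in_", groups[1])
                  else paste0("up_in_", groups[2]),
      n_pos_A = sum(xa > 0), n_pos_B = sum(xb > 0),
      prevalence_A = mean(xa > 0), prevalence_B = mean(xb > 0),
      group_A = groups[1], group_B = groups[2],
      effect_size = eff, p_value = p
    )
  })
  dplyr::bind_rows(rows)
}

#' Intergenerationally consistent differential features
#'
#' Features called differential (by prevalence or abundance) in at least two
#' developmental stages with the same direction. Discordant features (called
#' in opposite directions at different stages) are excluded and reported
#' separately.
#'
#' @param ... Tibbles of differential calls (from
#'   [differential_prevalence()] / [abundance_screen()]), or a single list of
#'   them. Must cover at least two distinct stages.
#' @return A list of class `consistency_result`: `conserved` (tibble:
#'   `feature_id`, `direction`, `n_stages`, `stages`, `bases`) and
#'   `discordant` (tibble of excluded features with their directions).
#' @export
intergenerational_consistency <- function(...) {
  calls <- list(...)
  if (length(calls) == 1 && is.list(calls[[1]]) && !is.data.frame(calls[[1]])) {
    calls <- calls[[1]]
  }
  all_calls <- dplyr::bind_rows(calls)
  if (length(unique(all_calls$stage)) < 2) {
    stop("calls from at least 2 distinct stages are required", call. = FALSE)
  }
  per_feature <- all_calls |>
    dplyr::distinct(.data$feature_id, .data$stage, .data$direction, .data$basis) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::summarise(
      n_stages = dplyr::n_distinct(.data$stage),
      n_directions = dplyr::n_distinct(.data$direction),
      direction = .data$direction[1],
      stages = paste(sort(unique(.data$stage)), collapse = ","),
      bases = paste(sort(unique(.data$basis)), collapse = ","),
      .groups = "drop")
  conserved <- per_feature |>
    dplyr::filter(.data$n_stages >= 2, .data$n_directions == 1) |>
    dplyr::select("feature_id", "direction", "n_stages", "stages", "bases")
  discordant <- per_feature |>
    dplyr::filter(.data$n_directions > 1) |>
    dplyr::select("feature_id", "n_stages", "stages", "bases")
  structure(list(conserved = conserved, discordant = discordant),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  cat(sprintf("<consistency_result> %d conserved, %d discordant features\n",
              nrow(x$conserved), nrow(x$discordant)))
  invisible(x)
}

#' @export
tidy.consistency_result <- function(x, ...) x$conserved
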