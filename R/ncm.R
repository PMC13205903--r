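#' Fit the Sloan neutral community model
#'
#' Relates each taxon's occurrence frequency across samples to its mean
#' relative abundance \eqn{\bar p}. Under neutral assembly with local
#' community size N (the common rarefied depth) and migration rate m, the
#' expected frequency of detection above the limit \eqn{d = 1/N} is
#' \deqn{F(\bar p) = 1 - Beta(d;\; Nm\bar p,\; Nm(1 - \bar p))}
#' (regularized incomplete beta). The migration rate is estimated by least
#' squares on observed vs predicted frequencies via bounded scalar (Brent)
#' optimization over (1e-6, 1], run from 5 subinterval starts and keeping the
#' best SSE as a guard. \eqn{R^2 = 1 - SSR/SST} is left unclamped: negative
#' values mean the neutral expectation fits worse than a constant and signal
#' deterministic structuring. Per-taxon `ci_level` Wilson score intervals on
#' the predicted frequency (with the sample count as n) classify taxa as
#' `above` / `neutral` / `below` the neutral band.
#'
#' @param table A counts [feature_table()] with equal column sums (rarefy
#'   first; unequal depths are an error).
#' @param ci_level Confidence level for the neutral band (default 0.95).
#' @return An object of class `ncm_fit`: use [glance()] for `m_hat`, `N`,
#'   `Nm`, `r2`, `detection_limit`; [tidy()] for the per-taxon table
#'   (`mean_rel_abundance`, `observed_frequency`, `predicted_frequency`,
#'   `ci_low`, `ci_high`, `state`).
#' @export
fit_ncm <- function(table, ci_level = 0.95) {
  stopifnot(is_feature_table(table))
  if (table_kind(table) != "counts") stop("fit_ncm needs counts (rarefy first)",
                                          call. = FALSE)
  depths <- colSums(table)
  if (length(unique(depths)) != 1) {
    stop("unequal sample depths; rarefy to even depth first", call. = FALSE)
  }
  N <- unname(depths[1])
  m <- unclass(table)
  nonzero <- rowSums(m) > 0
  m <- m[nonzero, , drop = FALSE]
  if (nrow(m) < 10) stop("fewer than 10 taxa with nonzero totals", call. = FALSE)
  n_samp <- ncol(m)
  rel <- sweep(m, 2, colSums(m), "/")
  p_bar <- unname(rowMeans(rel))
  freq_obs <- unname(rowMeans(m > 0))
  d <- 1 / N

  predict_freq <- function(mig) {
    stats::pbeta(d, N * mig * p_bar, N * mig * (1 - p_bar), lower.tail = FALSE)
  }
  sse <- function(mig) sum((freq_obs - predict_freq(mig))^2)
  # Brent on 5 subintervals of (1e-6, 1], best SSE kept
  breaks <- exp(seq(log(1e-6), log(1), length.out = 6))
  cand <- lapply(seq_len(5), function(i) {
    stats::optimize(sse, lower = breaks[i], upper = breaks[i + 1])
  })
  best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "objective"))]]
  m_hat <- best$minimum
  pred <- predict_freq(m_hat)
  ssr <- sum((freq_obs - pred)^2)
  sst <- sum((freq_obs - mean(freq_obs))^2)
  r2 <- 1 - ssr / sst

  ci <- wilson_interval(pred, n_samp, ci_level)
  state <- dplyr::case_when(
    freq_obs > ci$high ~ "above",
    freq_obs < ci$low ~ "below",
    TRUE ~ "neutral")
  structure(list(
    m_hat = m_hat, N = N, Nm = N * m_hat, r2 = r2,
    detection_limit = d, ci_level = ci_level,
    n_samples = n_samp,
    taxa = tibble::tibble(
      feature_id = rownames(m),
      mean_rel_abundance = p_bar,
      observed_frequency = freq_obs,
      predicted_frequency = pred,
      ci_low = ci$low, ci_high = ci$high,
      state = state)
  ), class = "ncm_fit")
}

# Wilson score interval for a proportion p with n trials.
wilson_interval <- function(p, n, level) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, center - half), high = pmin(1, center + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("<ncm_fit> m = %.4g, N = %d, Nm = %.4g, R2 = %.3f (%d taxa, %d samples)\n",
              x$m_hat, x$N, x$Nm, x$r2, nrow(x$taxa), x$n_samples))
  st <- table(x$taxa$state)
  cat("  states:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ncm_fit <- function(x, ...) x$taxa

#' @export
glance.ncm_fit <- function(x, ...) {
  tibble::tibble(m_hat = x$m_hat, N = x$N, Nm = x$Nm, r2 = x$r2,
                 detection_limit = x$detection_limit,
                 n_samples = x$n_samples, n_taxa = nrow(x$taxa),
                 frac_above = mean(x$taxa$state == "above"),
                 frac_neutral = mean(x$taxa$state == "neutral"),
                 frac_below = mean(x$taxa$state == "below"))
}

#' Dispersal-state shifts between two neutral-model fits
#'
#' Orders the neutral-band states `below < neutral < above` and, for taxa
#' shared by the two fits, reports whether the state in fit B is higher
#' (higher dispersal in B), lower, or unchanged relative to fit A.
#'
#' @param fit_A,fit_B Objects from [fit_ncm()] (A is the reference, e.g.
#'   the control group).
#' @return A tibble: `feature_id`, `state_A`, `state_B`, `shift`
#'   (`higher_in_B` / `lower_in_B` / `unchanged`).
#' @export
dispersal_shift <- function(fit_A, fit_B) {
  stopifnot(inherits(fit_A, "ncm_fit"), inherits(fit_B, "ncm_fit"))
  shared <- intersect(fit_A$taxa$feature_id, fit_B$taxa$feature_id)
  if (!length(shared)) stop("fits share no taxa", call. = FALSE)
  ord <- c(below = 1L, neutral = 2L, above = 3L)
  sA <- fit_A$taxa$state[match(shared, fit_A$taxa$feature_id)]
  sB <- fit_B$taxa$state[match(shared, fit_B$taxa$feature_id)]
  tibble::tibble(
    feature_id = shared,
    state_A = sA, state_B = sB,
    shift = dplyr::case_when(
      ord[sB] > ord[sA] ~ "higher_in_B",
      ord[sB] < ord[sA] ~ "lower_in_B",
      TRUE ~ "unchanged")
  )
}
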