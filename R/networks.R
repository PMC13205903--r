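# Spearman rho with mid-rank ties for every row of X against every row of Y,
# with the asymptotic t approximation for p (the Hmisc::rcorr convention).
spearman_edges <- function(X, Y, r_threshold, p_threshold) {
  n <- ncol(X)
  if (n < 5) stop("need at least 5 matched samples", call. = FALSE)
  if (ncol(Y) != n) stop("matched sample columns required", call. = FALSE)
  const_x <- apply(X, 1, function(v) stats::var(v) == 0)
  const_y <- apply(Y, 1, function(v) stats::var(v) == 0)
  skipped <- c(rownames(X)[const_x], rownames(Y)[const_y])
  if (length(skipped)) {
    message("skipped constant feature(s): ", paste(unique(skipped), collapse = ", "))
  }
  X <- X[!const_x, , drop = FALSE]
  Y <- Y[!const_y, , drop = FALSE]
  if (!nrow(X) || !nrow(Y)) {
    return(tibble::tibble(source = character(), target = character(),
                          rho = numeric(), p_value = numeric(),
                          sign = character()))
  }
  rx <- t(apply(X, 1, rank))
  ry <- t(apply(Y, 1, rank))
  rho <- stats::cor(t(rx), t(ry))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  idx <- which(abs(rho) > r_threshold & p < p_threshold, arr.ind = TRUE)
  rho_sel <- rho[idx]
  tibble::tibble(
    source = rownames(X)[idx[, 1]],
    target = rownames(Y)[idx[, 2]],
    rho = rho_sel,
    p_value = p[idx],
    sign = ifelse(rho_sel > 0, "positive", "negative")
  )
}

#' Threshold Spearman correlation network between two feature sets
#'
#' Computes Spearman rank correlations (mid-rank ties) between every row of
#' `features_X` and every row of `features_Y` over matched sample columns and
#' keeps edges with `|rho| > r_threshold` and `p < p_threshold` (defaults
#' 0.5 and 0.05). When a third set `features_Z` is supplied (e.g. a second
#' phenotype panel), each X node is labeled by the concordance of its
#' significant correlations with Y and Z: `green` (both positive), `red`
#' (both negative), `blue` (discordant), `gray` (none). Betweenness
#' centrality is computed on the edge graph.
#'
#' @param features_X,features_Y Numeric matrices (features x samples) with
#'   rownames; columns must be the same samples in the same order.
#' @param r_threshold,p_threshold Edge thresholds.
#' @param features_Z Optional third matrix for concordance labeling.
#' @return A list of class `correlation_network`: `edges` (tibble: `source`,
#'   `target`, `rho`, `p_value`, `sign`), `nodes` (tibble with betweenness
#'   and, when `features_Z` is given, `concordance`).
#' @export
correlation_network <- function(features_X, features_Y, r_threshold = 0.5,
                                p_threshold = 0.05, features_Z = NULL) {
  X <- as.matrix(features_X); Y <- as.matrix(features_Y)
  edges <- spearman_edges(X, Y, r_threshold, p_threshold)
  concordance <- NULL
  if (!is.null(features_Z)) {
    Z <- as.matrix(features_Z)
    edges_z <- spearman_edges(X, Z, r_threshold, p_threshold)
    sig_sign <- function(e) {
      e |> dplyr::group_by(.data$source) |>
        dplyr::summarise(s = if (all(.data$rho > 0)) 1 else if (all(.data$rho < 0)) -1 else 0,
                         .groups = "drop")
    }
    sy <- sig_sign(edges); sz <- sig_sign(edges_z)
    nodes_x <- tibble::tibble(node = rownames(X))
    nodes_x$sy <- sy$s[match(nodes_x$node, sy$source)]
    nodes_x$sz <- sz$s[match(nodes_x$node, sz$source)]
    concordance <- dplyr::mutate(nodes_x, concordance = dplyr::case_when(
      !is.na(.data$sy) & !is.na(.data$sz) & .data$sy == 1 & .data$sz == 1 ~ "green",
      !is.na(.data$sy) & !is.na(.data$sz) & .data$sy == -1 & .data$sz == -1 ~ "red",
      !is.na(.data$sy) & !is.na(.data$sz) ~ "blue",
      TRUE ~ "gray"))[, c("node", "concordance")]
  }
  nodes <- network_nodes(edges)
  if (!is.null(concordance)) {
    nodes <- dplyr::left_join(nodes, concordance, by = "node")
  }
  structure(list(edges = edges, nodes = nodes,
                 r_threshold = r_threshold, p_threshold = p_threshold),
            class = "correlation_network")
}

network_nodes <- function(edges) {
  if (!nrow(edges)) return(tibble::tibble(node = character(), betweenness = numeric()))
  g <- igraph::graph_from_data_frame(edges[c("source", "target")], directed = FALSE)
  tibble::tibble(node = igraph::V(g)$name,
                 betweenness = igraph::betweenness(g))
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %d edges (|rho| > %.2f, p < %.2g), %d nodes\n",
              nrow(x$edges), x$r_threshold, x$p_threshold, nrow(x$nodes)))
  invisible(x)
}

#' @export
tidy.correlation_network <- function(x, ...) x$edges

#' Co-occurrence network around focal taxa
#'
#' Spearman correlations between each focal taxon and every other taxon of
#' the table; edges retained at `|rho| > r_threshold` (default 0.8) and
#' `p < p_threshold` (default 0.05), with positive and negative edge sets
#' returned separately (they are rendered as separate panels with shared
#' node positions).
#'
#' @param table A [feature_table()].
#' @param focal Character vector of focal feature IDs (must be in the table).
#' @param r_threshold,p_threshold Edge thresholds.
#' @return A list of class `cooccurrence_network`: `positive` and `negative`
#'   edge tibbles, plus `nodes` (with betweenness over the combined graph).
#' @export
cooccurrence_network <- function(table, focal, r_threshold = 0.8,
                                 p_threshold = 0.05) {
  stopifnot(is_feature_table(table))
  m <- unclass(table)
  missing_ids <- setdiff(focal, rownames(m))
  if (length(missing_ids)) {
    stop("focal features not in table: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  others <- setdiff(rownames(m), focal)
  edges <- spearman_edges(m[focal, , drop = FALSE], m[others, , drop = FALSE],
                          r_threshold, p_threshold)
  structure(list(
    positive = edges[edges$sign == "positive", ],
    negative = edges[edges$sign == "negative", ],
    nodes = network_nodes(edges),
    r_threshold = r_threshold, p_threshold = p_threshold
  ), class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %d positive / %d negative edges (|rho| > %.2f)\n",
              nrow(x$positive), nrow(x$negative), x$r_threshold))
  invisible(x)
}

#' @export
tidy.cooccurrence_network <- function(x, ...) {
  dplyr::bind_rows(x$positive, x$negative)
}
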