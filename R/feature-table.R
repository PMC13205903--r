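#' Construct a feature table
#'
#' A feature table holds a non-negative features-by-samples abundance matrix
#' together with a declared kind: raw sequence `counts` or `relative`
#' abundances (each sample column summing to 1). It is the common input to all
#' diversity, succession and assembly functions in successr.
#'
#' @param values Numeric matrix, features in rows, samples in columns, with
#'   unique rownames (feature IDs) and colnames (sample IDs).
#' @param kind Either `"counts"` or `"relative"`.
#' @return A `feature_table` object (a classed matrix with a `kind` attribute).
#' @examples
#' m <- matrix(c(4L, 0L, 6L, 2L, 3L, 5L), nrow = 3,
#'             dimnames = list(paste0("sp", 1:3), c("s1", "s2")))
#' ft <- feature_table(m, kind = "counts")
#' n_features(ft)
#' @export
feature_table <- function(values, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  validate_feature_table_values(values, kind)
  structure(values, kind = kind, class = c("feature_table", "matrix", "array"))
}

validate_feature_table_values <- function(values, kind) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("feature table needs feature IDs as rownames and sample IDs as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("feature table contains missing values", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]), call. = FALSE)
  }
  if (kind == "relative") {
    cs <- colSums(values)
    off <- which(abs(cs - 1) > 1e-9)
    if (length(off)) {
      stop("relative-abundance columns must sum to 1; offending sample(s): ",
           paste(colnames(values)[off], collapse = ", "), call. = FALSE)
    }
  }
  invisible(values)
}

#' @rdname feature_table
#' @param x Object to test or coerce.
#' @export
is_feature_table <- function(x) inherits(x, "feature_table")

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples (kind: %s)\n",
              nrow(x), ncol(x), table_kind(x)))
  nf <- min(nrow(x), 6L); ns <- min(ncol(x), 6L)
  print(unclass(x)[seq_len(nf), seq_len(ns), drop = FALSE])
  if (nrow(x) > nf || ncol(x) > ns) {
    cat(sprintf("... %d more features, %d more samples\n",
                nrow(x) - nf, ncol(x) - ns))
  }
  invisible(x)
}

#' @rdname feature_table
#' @export
table_kind <- function(x) attr(x, "kind")

#' @rdname feature_table
#' @export
n_features <- function(x) nrow(x)

#' @rdname feature_table
#' @export
n_samples <- function(x) ncol(x)

#' Convert a feature table to relative abundances
#'
#' Each sample column is divided by its total. All-zero columns are an error:
#' a sample with no observations has no composition.
#'
#' @param table A [feature_table()].
#' @return A `feature_table` of kind `"relative"`.
#' @export
as_relative <- function(table) {
  stopifnot(is_feature_table(table))
  if (table_kind(table) == "relative") return(table)
  cs <- colSums(table)
  if (any(cs == 0)) {
    stop("cannot normalize all-zero sample(s): ",
         paste(colnames(table)[cs == 0], collapse = ", "), call. = FALSE)
  }
  feature_table(sweep(unclass(table), 2, cs, "/"), kind = "relative")
}

#' Tidy a feature table into long format
#'
#' @param x A [feature_table()].
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `abundance`.
#' @export
tidy.feature_table <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "abundance")
}

#' Read a feature table from TSV
#'
#' The file must have one ID column (first column) and numeric abundance
#' cells. `orientation` declares whether features are rows (`"features"`,
#' default) or columns (`"samples"`, i.e. samples in rows); the table is
#' stored features-by-samples either way. Kind is inferred when not given:
#' integer-valued tables are counts; tables whose sample sums are all 1 (to
#' 1e-6) are relative; anything else must be declared explicitly (or
#' normalized with [as_relative()]).
#'
#' @param path Path to a TSV file.
#' @param orientation `"features"` (features as rows) or `"samples"`.
#' @param kind Optional `"counts"` or `"relative"`, overriding inference.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, orientation = c("features", "samples"),
                               kind = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("feature table TSV needs an ID column plus data columns",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate IDs in column 1 of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  num <- df[-1]
  bad_col <- which(!vapply(num, is.numeric, logical(1)))
  if (length(bad_col)) {
    stop("non-numeric cells in column '", names(num)[bad_col[1]], "' of ", path,
         call. = FALSE)
  }
  m <- as.matrix(num)
  rownames(m) <- ids
  if (orientation == "samples") m <- t(m)
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at row '%s', column '%s' of %s",
                 rownames(m)[bad[1]], colnames(m)[bad[2]], path), call. = FALSE)
  }
  if (is.null(kind)) {
    if (all(m == round(m))) {
      kind <- "counts"
    } else if (all(abs(colSums(m) - 1) <= 1e-6)) {
      m <- sweep(m, 2, colSums(m), "/")  # exact renormalization
      kind <- "relative"
    } else {
      stop("cannot infer kind: values are non-integer and sample sums are not 1; ",
           "pass kind = 'counts'/'relative' or normalize the table", call. = FALSE)
    }
  } else {
    kind <- match.arg(kind, c("counts", "relative"))
    if (kind == "relative") m <- sweep(m, 2, colSums(m), "/")
  }
  feature_table(m, kind = kind)
}

#' Write a feature table to TSV
#'
#' Values round-trip bit-exactly through [read_feature_table()].
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(is_feature_table(table))
  df <- tibble::as_tibble(unclass(table), rownames = "feature_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read or build a study design table
#'
#' The design maps each sample to its treatment group, developmental stage,
#' subject, source/sink role and (optionally) mother-offspring pair. It is a
#' plain tibble so it composes with dplyr verbs.
#'
#' @param path TSV with columns `sample_id`, `group`, `stage`, `subject_id`
#'   and optionally `role` (source/sink/none) and `pair_id`.
#' @return A tibble with those columns (`role` defaulting to `"none"`,
#'   `pair_id` to `NA`).
#' @export
read_study_design <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  as_study_design(df)
}

#' @rdname read_study_design
#' @param design A data frame with at least `sample_id`, `group`, `stage`,
#'   `subject_id`.
#' @export
as_study_design <- function(design) {
  design <- tibble::as_tibble(design)
  need <- c("sample_id", "group", "stage", "subject_id")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("study design lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(design$sample_id)) {
    stop("duplicate sample_id in study design", call. = FALSE)
  }
  if (!"role" %in% names(design)) design$role <- "none"
  design$role[is.na(design$role)] <- "none"
  if (!all(design$role %in% c("source", "sink", "none"))) {
    stop("role must be one of source/sink/none", call. = FALSE)
  }
  if (!"pair_id" %in% names(design)) design$pair_id <- NA_character_
  pid <- design$pair_id[!is.na(design$pair_id)]
  if (length(pid)) {
    singletons <- names(which(table(pid) < 2))
    if (length(singletons)) {
      stop("pair_id occurring in fewer than 2 samples: ",
           paste(singletons, collapse = ", "), call. = FALSE)
    }
  }
  design[c(need, "role", "pair_id", setdiff(names(design), c(need, "role", "pair_id")))]
}

# Checks that every sample of `table` is described by `design` exactly once
# and returns the design rows in table column order.
align_design <- function(table, design) {
  design <- as_study_design(design)
  miss <- setdiff(colnames(table), design$sample_id)
  if (length(miss)) {
    stop("samples absent from study design: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  design[match(colnames(table), design$sample_id), ]
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample column without replacement (multivariate
#' hypergeometric) down to `depth` reads, the standard evening-out step before
#' count-based null models and neutral-model fitting. Samples with fewer than
#' `depth` reads are dropped with a warning.
#'
#' @param table A [feature_table()] of kind `"counts"`.
#' @param depth Positive integer target depth, or `"min"` (default) for the
#'   minimum column sum.
#' @param seed Integer seed; subsampling is deterministic given the seed.
#' @return A `feature_table` of counts whose columns each sum to `depth`.
#' @export
rarefy <- function(table, depth = "min", seed = 0L) {
  stopifnot(is_feature_table(table))
  if (table_kind(table) != "counts") {
    stop("rarefy needs a counts table (got kind = 'relative')", call. = FALSE)
  }
  totals <- colSums(table)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.numeric(depth)
  if (length(depth) != 1 || is.na(depth) || depth <= 0 || depth != round(depth)) {
    stop("depth must be a positive integer or 'min'", call. = FALSE)
  }
  keep <- totals >= depth
  if (!all(keep)) {
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(table)[!keep], collapse = ", "), call. = FALSE)
  }
  m <- unclass(table)[, keep, drop = FALSE]
  if (ncol(m) == 0) stop("depth ", depth, " exceeds every sample total", call. = FALSE)
  res <- with_seed(seed, apply(m, 2, function(x) {
    tot <- sum(x)
    if (tot == depth) return(x)
    drawn <- sample.int(tot, depth)
    # map draw positions onto taxa via cumulative counts
    tabulate(findInterval(drawn - 1, cumsum(x)) + 1L, nbins = length(x))
  }))
  res <- matrix(res, nrow = nrow(m), dimnames = dimnames(m))
  feature_table(res, kind = "counts")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Runs expr under a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
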