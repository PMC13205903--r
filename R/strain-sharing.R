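#' Strain-sharing calls from a per-taxon strain phylogeny
#'
#' Tips of `tree` are sample identifiers carrying one taxon's strain
#' genotypes. The normalized phylogenetic distance between two samples is
#' their patristic distance divided by the tree's total branch length
#' (`nGD`); a sharing event is a mother-offspring pair with `nGD` strictly
#' below the identity threshold (0.03 by default). Paired records are sample
#' pairs sharing a `pair_id` in the design; unpaired records are cross-pair
#' mother-offspring combinations within the same group (all combinations up
#' to `max_unpaired`, then a seeded subsample).
#'
#' @param tree An [ape::phylo] strain tree whose tips are sample IDs.
#' @param design Study design tibble with `pair_id`, `group` and `stage`
#'   (sources/mothers vs offspring are told apart by `role` = "source" for
#'   the maternal sample when present, else by stage order).
#' @param threshold Strain identity threshold on nGD (default 0.03, strict
#'   `<`).
#' @param taxon Label stored on the records (default "taxon").
#' @param maternal_stage Stage label identifying the maternal samples
#'   (default `"MA"`).
#' @param max_unpaired Cap on unpaired combinations before subsampling
#'   (default 10000).
#' @param seed Integer seed for the unpaired subsample.
#' @return A tibble of strain pair records: `sample_i`, `sample_j`, `taxon`,
#'   `nGD`, `log10_nGD`, `pair_class` (`<group>_paired` / `<group>_unpaired`),
#'   `sharing_event`.
#' @export
strain_sharing <- function(tree, design, threshold = 0.03, taxon = "taxon",
                           maternal_stage = "MA", max_unpaired = 10000,
                           seed = 0L) {
  design <- as_study_design(design)
  tbl_total <- total_branch_length(tree)
  if (tbl_total <= 0) stop("tree has zero total branch length", call. = FALSE)
  tips <- tree$tip.label
  design <- design[design$sample_id %in% tips, ]
  if (!nrow(design)) stop("no design samples among tree tips", call. = FALSE)
  paired_ids <- design$pair_id[!is.na(design$pair_id)]
  if (!length(paired_ids)) stop("design has no pair_id among tree tips", call. = FALSE)

  pd <- ape::cophenetic.phylo(tree) / tbl_total

  is_maternal <- design$stage == maternal_stage |
    design$role == "source"
  mothers <- design[is_maternal, ]
  offspring <- design[!is_maternal, ]

  records <- list()
  # true pairs
  for (pid in unique(stats::na.omit(design$pair_id))) {
    mem <- design[!is.na(design$pair_id) & design$pair_id == pid, ]
    mo <- mem$sample_id[is_maternal[match(mem$sample_id, design$sample_id)]]
    of <- setdiff(mem$sample_id, mo)
    if (!length(mo) || !length(of)) next
    for (a in mo) for (b in of) {
      records[[length(records) + 1L]] <- tibble::tibble(
        sample_i = a, sample_j = b, group = mem$group[1], paired = TRUE)
    }
  }
  # unpaired: cross-pair maternal x offspring combos within group
  for (g in unique(design$group)) {
    mo <- mothers[mothers$group == g, ]
    of <- offspring[offspring$group == g, ]
    if (!nrow(mo) || !nrow(of)) next
    combos <- expand.grid(i = seq_len(nrow(mo)), j = seq_len(nrow(of)))
    same_pair <- !is.na(mo$pair_id[combos$i]) & !is.na(of$pair_id[combos$j]) &
      mo$pair_id[combos$i] == of$pair_id[combos$j]
    combos <- combos[!same_pair, , drop = FALSE]
    if (nrow(combos) > max_unpaired) {
      keep <- with_seed(seed, sample.int(nrow(combos), max_unpaired))
      combos <- combos[keep, , drop = FALSE]
    }
    if (nrow(combos)) {
      records[[length(records) + 1L]] <- tibble::tibble(
        sample_i = mo$sample_id[combos$i], sample_j = of$sample_id[combos$j],
        group = g, paired = FALSE)
    }
  }
  if (!length(records)) stop("no maternal-offspring pairs found", call. = FALSE)
  rec <- dplyr::bind_rows(records)
  rec$nGD <- pd[cbind(rec$sample_i, rec$sample_j)]
  rec$log10_nGD <- ifelse(rec$nGD > 0, log10(rec$nGD), -Inf)
  rec$pair_class <- paste0(rec$group, ifelse(rec$paired, "_paired", "_unpaired"))
  rec$sharing_event <- rec$nGD < threshold
  rec$taxon <- taxon
  rec[c("sample_i", "sample_j", "taxon", "nGD", "log10_nGD",
        "pair_class", "sharing_event", "group", "paired")]
}
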