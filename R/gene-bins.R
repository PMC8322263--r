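#' Assign SNPs to genes with flanking windows
#'
#' A SNP is assigned to every gene on its chromosome satisfying
#' `gene start - flank_bp <= pos <= gene end + flank_bp` (1-based inclusive
#' bounds); a SNP inside two overlapping genes is assigned to both. SNPs
#' matching no gene are returned separately as the unannotated set.
#'
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos` (extra columns
#'   pass through).
#' @param genes Tibble with columns `chrom`, `start`, `end`, `name` (BED-like,
#'   1-based inclusive).
#' @param flank_bp Flank in bp (default 10 kb).
#' @return A list of class `gene_assignment`: `$assignments` (one row per
#'   SNP-gene pair: `snp_id`, `chrom`, `pos`, `gene`), `$unannotated`
#'   (rows of `snps` matching no gene), `$flank_bp`.
#' @export
assign_snps_to_genes <- function(snps, genes, flank_bp = 1e4) {
  snps <- as_tibble(snps)
  genes <- as_tibble(genes)
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("chrom", "start", "end", "name") %in% names(genes)))
  hits <- inner_join(
    snps %>% select("snp_id", "chrom", "pos") %>% distinct(),
    genes %>% select("chrom", "start", "end", gene = "name"),
    by = "chrom", relationship = "many-to-many") %>%
    filter(.data$pos >= .data$start - flank_bp,
           .data$pos <= .data$end + flank_bp) %>%
    select("snp_id", "chrom", "pos", "gene") %>%
    arrange(.data$chrom, .data$pos, .data$gene)
  unannotated <- snps %>% filter(!.data$snp_id %in% hits$snp_id)
  structure(list(assignments = hits, unannotated = unannotated,
                 flank_bp = flank_bp),
            class = "gene_assignment")
}

#' @export
print.gene_assignment <- function(x, ...) {
  cat("<gene_assignment> ", dplyr::n_distinct(x$assignments$snp_id),
      " SNP(s) in ", dplyr::n_distinct(x$assignments$gene), " gene(s); ",
      nrow(x$unannotated), " unannotated\n", sep = "")
  invisible(x)
}

#' Merge genes with identical marker content into gene blocks
#'
#' Genes whose assigned marker sets are identical and nonempty (fully
#' overlapping or antisense pairs annotate exactly the same SNPs) are merged
#' into one gene block spanning the minimum start to the maximum end of the
#' members; identity of marker sets is transitive, so merging needs no
#' closure step. Genes with a unique (or empty) marker set pass through as
#' singleton groups. Genes absent from the annotation's universe are ignored.
#'
#' @param assignment A [assign_snps_to_genes()] result.
#' @param genes The gene table the assignment was computed from.
#' @return A tibble of groups: `group_id`, `group_name` (member names joined
#'   with `";"`), `chrom`, `start`, `end`, `n_genes`, `genes` (list-column),
#'   `snp_ids` (list-column, position-sorted), `n_snps`.
#' @export
merge_gene_blocks <- function(assignment, genes) {
  stopifnot(inherits(assignment, "gene_assignment"))
  genes <- as_tibble(genes)
  sets <- assignment$assignments %>%
    arrange(.data$chrom, .data$pos) %>%
    group_by(.data$gene) %>%
    summarise(key = paste(.data$snp_id, collapse = "|"),
              snp_ids = list(.data$snp_id), .groups = "drop")
  gene_tab <- genes %>%
    select("chrom", "start", "end", gene = "name") %>%
    left_join(sets, by = "gene") %>%
    mutate(key = dplyr::coalesce(.data$key, paste0("<empty>", .data$gene)),
           snp_ids = purrr::map(.data$snp_ids, ~ .x %||% character(0)))
  gene_tab %>%
    group_by(.data$key) %>%
    summarise(group_name = paste(sort(unique(.data$gene)), collapse = ";"),
              chrom = first(.data$chrom),
              start = min(.data$start), end = max(.data$end),
              n_genes = dplyr::n_distinct(.data$gene),
              genes = list(sort(unique(.data$gene))),
              snp_ids = .data$snp_ids[1],
              .groups = "drop") %>%
    mutate(n_snps = lengths(.data$snp_ids)) %>%
    arrange(.data$chrom, .data$start, .data$group_name) %>%
    mutate(group_id = row_number(), .before = 1) %>%
    select(-"key")
}

#' Collect all QC'd SNP p-values inside gene-block regions
#'
#' Gathers, per trait, every summary-statistics record (not only selected
#' signals) within `[block start - flank_bp, block end + flank_bp]` on the
#' block's chromosome — the SNP sets consumed by the pruning-based
#' experiment-wide threshold and by Brown gene scoring.
#'
#' @param groups One or more rows of [merge_gene_blocks()] output.
#' @param sumstats_list Named list (by trait) of harmonized tables.
#' @param flank_bp Flank in bp (default 10 kb), applied to block boundaries.
#' @return A tibble: `group_id`, `trait`, `snp_id`, `chrom`, `pos`, `freq`,
#'   `p`.
#' @export
collect_region_snps <- function(groups, sumstats_list, flank_bp = 1e4) {
  groups <- as_tibble(groups)
  purrr::imap_dfr(sumstats_list, function(ss, tr) {
    purrr::map_dfr(seq_len(nrow(groups)), function(i) {
      g <- groups[i, ]
      ss %>%
        filter(.data$chrom == g$chrom,
               .data$pos >= g$start - flank_bp,
               .data$pos <= g$end + flank_bp) %>%
        mutate(group_id = g$group_id, trait = tr, .before = 1) %>%
        select("group_id", "trait", "snp_id", "chrom", "pos", "freq", "p")
    })
  }) %>%
    arrange(.data$group_id, .data$trait, .data$pos)
}
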