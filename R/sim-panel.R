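#' Construct a genotype panel object
#'
#' A `genotype_panel` couples a marker map with a diploid dosage matrix
#' (individuals x markers, counts of `allele_b` in 0/1/2, `NA` for missing).
#' All LD quantities in the package are computed from this object.
#'
#' @param markers Data frame with columns `snp_id`, `chrom` (integer 1-22),
#'   `pos` (1-based bp), `allele_a`, `allele_b`; positions must be
#'   nondecreasing within chromosome and ids unique.
#' @param genotypes Numeric/integer matrix, individuals in rows, markers in
#'   columns (column order = marker order).
#' @param ancestral Optional list of per-block ancestral haplotype pools (used
#'   by the simulator; carried for truth-based checks).
#' @return An object of class `genotype_panel`.
#' @export
new_genotype_panel <- function(markers, genotypes, ancestral = NULL) {
  markers <- as_tibble(markers)
  need <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  miss <- setdiff(need, names(markers))
  if (length(miss)) abort(paste0("markers lacks column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(markers$snp_id)) abort("marker ids must be unique.")
  if (ncol(genotypes) != nrow(markers)) {
    abort("genotype columns must match marker rows.")
  }
  ooo <- markers %>%
    group_by(.data$chrom) %>%
    summarise(ok = !is.unsorted(.data$pos), .groups = "drop")
  if (!all(ooo$ok)) abort("positions must be nondecreasing within chromosome.")
  genotypes <- as.matrix(genotypes)
  colnames(genotypes) <- markers$snp_id
  fb <- colMeans(genotypes, na.rm = TRUE) / 2
  markers$freq_b <- unname(fb)
  markers$monomorphic <- apply(genotypes, 2, function(g) {
    g <- g[!is.na(g)]
    length(unique(g)) <= 1
  })
  structure(
    list(markers = markers, genotypes = genotypes,
         n_individuals = nrow(genotypes), ancestral = ancestral),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("<genotype_panel> ", x$n_individuals, " individuals x ",
      nrow(x$markers), " markers on ",
      dplyr::n_distinct(x$markers$chrom), " chromosome(s)\n", sep = "")
  invisible(x)
}

# block layout: fill chromosomes 1..22 left to right so that consecutive
# blocks are physically adjacent (genes may span two neighbouring blocks);
# blocks per chromosome is even so block pairs (2k-1, 2k) never straddle
block_layout <- function(config) {
  per_chr <- 2 * ceiling(config$n_blocks / 44)
  b <- seq_len(config$n_blocks)
  j <- (b - 1) %% per_chr
  tibble(
    block = b,
    chrom = (b - 1) %/% per_chr + 1L,
    start = 1000000L + j * (config$block_span_bp + config$block_gap_bp),
    end = 1000000L + j * (config$block_span_bp + config$block_gap_bp) +
      config$block_span_bp - 1L
  )
}

#' Simulate a block-structured diploid reference panel
#'
#' Each LD block holds a pool of ancestral haplotypes with random weights;
#' every individual draws two haplotypes per block (independently across
#' blocks), giving strong LD within blocks and none between blocks. Allele-B
#' target frequencies are drawn from `config$maf_range` and realised as the
#' cumulative weight of a random subset of ancestral haplotypes.
#'
#' @param config A [sim_config()].
#' @return A [new_genotype_panel()] object; markers carry a `block` column.
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- block_layout(config)
  K <- config$ancestral_haplotypes_per_block
  m <- config$snps_per_block
  n <- config$n_individuals
  pairs_ok <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                    c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))

  marker_rows <- vector("list", config$n_blocks)
  geno_blocks <- vector("list", config$n_blocks)
  ancestral <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    w <- runif(K, 0.5, 1.5)
    w <- w / sum(w)
    hap <- matrix(0L, nrow = K, ncol = m)
    for (s in seq_len(m)) {
      f_target <- runif(1, config$maf_range[1], config$maf_range[2])
      ord <- sample.int(K)
      carriers <- ord[seq_len(which(cumsum(w[ord]) >= f_target)[1])]
      if (length(carriers) == K && K > 1) carriers <- carriers[-K]
      hap[carriers, s] <- 1L
    }
    h1 <- sample.int(K, n, replace = TRUE, prob = w)
    h2 <- sample.int(K, n, replace = TRUE, prob = w)
    geno_blocks[[b]] <- hap[h1, , drop = FALSE] + hap[h2, , drop = FALSE]
    al <- pairs_ok[sample.int(nrow(pairs_ok), m, replace = TRUE), ,
                   drop = FALSE]
    pos <- layout$start[b] +
      floor(seq(0, config$block_span_bp - 1, length.out = m))
    marker_rows[[b]] <- tibble(
      snp_id = snp_id_make(b, seq_len(m)),
      chrom = layout$chrom[b],
      pos = as.integer(pos),
      allele_a = al[, 1],
      allele_b = al[, 2],
      block = b
    )
    ancestral[[b]] <- list(hap = hap, w = w)
  }
  markers <- bind_rows(marker_rows) %>% arrange(.data$chrom, .data$pos)
  geno <- do.call(cbind, geno_blocks)
  colnames(geno) <- unlist(purrr::map(marker_rows, "snp_id"))
  geno <- geno[, markers$snp_id, drop = FALSE]
  new_genotype_panel(markers, geno, ancestral = ancestral)
}

#' Simulate a BED-like gene annotation over a simulated panel
#'
#' Emits one gene per planted locus covering its blocks, a fully overlapping
#' antisense twin for the first planted locus (so gene-block merging is
#' exercised: the pair shares an identical marker set by construction),
#' background genes on every other remaining block (leaving the rest of the
#' markers unannotated), all separated by gaps larger than the downstream
#' flank.
#'
#' @param config A [sim_config()].
#' @param panel Panel from [simulate_reference_panel()].
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (1-based inclusive coordinates).
#' @export
simulate_gene_annotation <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "genotype_panel"))
  layout <- block_layout(config)
  gene_of_blocks <- function(blocks, name, strand = "+") {
    stopifnot(all(blocks %in% layout$block))
    ch <- unique(layout$chrom[layout$block %in% blocks])
    if (length(ch) != 1) {
      abort(paste0("gene '", name, "' spans blocks on different chromosomes."))
    }
    tibble(chrom = ch,
           start = max(1L, min(layout$start[layout$block %in% blocks]) - 1000L),
           end = max(layout$end[layout$block %in% blocks]) + 1000L,
           name = name, score = 0L, strand = strand)
  }
  used <- integer(0)
  rows <- list()
  for (pl in config$planted_loci) {
    rows[[length(rows) + 1]] <- gene_of_blocks(pl$blocks, pl$gene_name)
    used <- c(used, pl$blocks)
  }
  if (length(config$planted_loci) >= 1) {
    first <- config$planted_loci[[1]]
    rows[[length(rows) + 1]] <-
      gene_of_blocks(first$blocks, paste0(first$gene_name, "-AS1"),
                     strand = "-")
  }
  free <- setdiff(layout$block, used)
  bg <- free[seq_along(free) %% 2 == 1]  # every other free block: background
  for (b in bg) {
    rows[[length(rows) + 1]] <-
      gene_of_blocks(b, sprintf("BGGENE%03d", b))
  }
  bind_rows(rows) %>% arrange(.data$chrom, .data$start)
}
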