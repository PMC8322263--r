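#' Simulation configuration for a synthetic pleiotropy study
#'
#' Describes a block-structured diploid reference panel, a set of traits, and
#' the causal loci planted for each trait. Genotypes are built as mosaics of a
#' small pool of ancestral haplotypes per LD block, so linkage disequilibrium
#' is strong within a block and absent between blocks. Marker identifiers are
#' deterministic (`b<block>_s<index>`, e.g. `"b003_s07"`), so planted loci can
#' reference markers before the panel is generated.
#'
#' Blocks are laid left to right along autosomes 1..22 (consecutive blocks
#' share a chromosome until it is full), `block_span_bp` wide with
#' `block_gap_bp` between adjacent blocks.
#'
#' @param n_individuals Number of diploid individuals in the reference panel.
#' @param n_blocks Number of LD blocks.
#' @param snps_per_block Markers per block.
#' @param block_span_bp Width of one block in base pairs.
#' @param block_gap_bp Gap between adjacent blocks on a chromosome (bp). Must
#'   exceed twice the gene flank used downstream so genes on neighbouring
#'   blocks do not capture each other's markers.
#' @param ancestral_haplotypes_per_block Size of the ancestral haplotype pool
#'   each block's chromosomes are drawn from. `1` gives a monomorphic block.
#' @param maf_range Length-2 numeric in (0, 0.5], the target range of ancestral
#'   allele frequencies.
#' @param traits Character vector of trait names.
#' @param gwas_n_per_trait GWAS sample size per trait (recycled to match
#'   `traits`).
#' @param planted_loci List of [planted_locus()] objects.
#' @param decoy_fraction Fraction (of the panel marker count) of decoy rows
#'   appended to each simulated summary-statistics table that must fail QC
#'   (low INFO, low MAF, strand-ambiguous alleles, indels, non-autosomal).
#' @param seed Integer seed; all simulation output is a deterministic function
#'   of the configuration including this seed.
#'
#' @return An object of class `sim_config`.
#' @seealso [planted_locus()], [simulate_reference_panel()], [simulate_study()]
#' @export
sim_config <- function(n_individuals = 1000,
                       n_blocks = 10,
                       snps_per_block = 15,
                       block_span_bp = 50000L,
                       block_gap_bp = 50000L,
                       ancestral_haplotypes_per_block = 6,
                       maf_range = c(0.15, 0.5),
                       traits = c("traitA", "traitB"),
                       gwas_n_per_trait = 50000,
                       planted_loci = list(),
                       decoy_fraction = 0,
                       seed = 1L) {
  if (n_individuals < 2) abort("`n_individuals` must be >= 2.")
  if (n_blocks < 1) abort("`n_blocks` must be >= 1.")
  if (snps_per_block < 1) abort("`snps_per_block` must be >= 1.")
  if (ancestral_haplotypes_per_block < 1) {
    abort("`ancestral_haplotypes_per_block` must be >= 1.")
  }
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  if (length(traits) < 1) abort("at least one trait is required.")
  if (anyDuplicated(traits)) abort("trait names must be unique.")
  gwas_n <- rep_len(gwas_n_per_trait, length(traits))
  if (decoy_fraction < 0 || decoy_fraction > 1) {
    abort("`decoy_fraction` must be in [0, 1].")
  }
  for (pl in planted_loci) {
    if (!inherits(pl, "planted_locus")) {
      abort("`planted_loci` must be a list of planted_locus() objects.")
    }
    bad <- setdiff(pl$causal$trait, traits)
    if (length(bad)) {
      abort(paste0("planted locus '", pl$gene_name,
                   "' references unknown trait(s): ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      n_blocks = as.integer(n_blocks),
      snps_per_block = as.integer(snps_per_block),
      block_span_bp = as.integer(block_span_bp),
      block_gap_bp = as.integer(block_gap_bp),
      ancestral_haplotypes_per_block = as.integer(ancestral_haplotypes_per_block),
      maf_range = as.numeric(maf_range),
      traits = as.character(traits),
      gwas_n_per_trait = setNames(as.numeric(gwas_n), traits),
      planted_loci = planted_loci,
      decoy_fraction = as.numeric(decoy_fraction),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Declare a causal locus planted in the synthetic study
#'
#' A planted locus is a named gene together with the causal variants realising
#' one of the cross-trait scenarios the classifier must recover:
#' \describe{
#'   \item{`"I"`}{gene-level pleiotropy — at least two causal SNPs in distinct
#'     LD blocks, affecting distinct traits.}
#'   \item{`"II"`}{allelic heterogeneity — at least two causal SNPs in distinct
#'     LD blocks, all affecting the same trait.}
#'   \item{`"III"`}{SNP-level pleiotropy — one causal SNP listed under two or
#'     more traits.}
#'   \item{`"mixed"`}{both a shared causal SNP (two traits) and an
#'     LD-independent causal SNP.}
#'   \item{`"null"`}{a gene with no causal variants (specify `blocks`).}
#' }
#'
#' @param scenario One of `"I"`, `"II"`, `"III"`, `"mixed"`, `"null"`.
#' @param gene_name Gene name used in the annotation and the truth table.
#' @param causal A data frame with columns `snp_id`, `trait`, `lambda`
#'   (noncentrality of the causal variant on the z-scale). `snp_id` uses the
#'   deterministic `b<block>_s<index>` naming.
#' @param blocks Integer block indices covered by the gene. Defaults to the
#'   blocks of the causal SNPs; mandatory for `"null"` loci.
#'
#' @return An object of class `planted_locus`.
#' @export
planted_locus <- function(scenario, gene_name, causal = NULL, blocks = NULL) {
  scenario <- match.arg(scenario, c("I", "II", "III", "mixed", "null"))
  if (is.null(causal)) {
    causal <- tibble(snp_id = character(), trait = character(),
                     lambda = numeric())
  }
  causal <- as_tibble(causal)
  stopifnot(all(c("snp_id", "trait", "lambda") %in% names(causal)))
  causal_blocks <- snp_id_block(causal$snp_id)
  if (is.null(blocks)) {
    if (scenario == "null") abort("`blocks` is required for a null locus.")
    blocks <- sort(unique(causal_blocks))
  }
  check <- switch(
    scenario,
    I = nrow(causal) >= 2 && dplyr::n_distinct(causal_blocks) >= 2 &&
      dplyr::n_distinct(causal$trait) >= 2,
    II = nrow(causal) >= 2 && dplyr::n_distinct(causal_blocks) >= 2 &&
      dplyr::n_distinct(causal$trait) == 1,
    III = dplyr::n_distinct(causal$snp_id) == 1 &&
      dplyr::n_distinct(causal$trait) >= 2,
    mixed = {
      shared <- names(which(table(causal$snp_id) >= 2))
      length(shared) >= 1 && any(!causal$snp_id %in% shared)
    },
    null = nrow(causal) == 0
  )
  if (!check) {
    abort(paste0("causal variants of '", gene_name,
                 "' do not realise scenario ", scenario, "."))
  }
  structure(
    list(scenario = scenario, gene_name = gene_name, causal = causal,
         blocks = as.integer(sort(unique(blocks)))),
    class = "planted_locus"
  )
}

# deterministic marker naming: block b, index s within block
snp_id_make <- function(block, idx) sprintf("b%03d_s%02d", block, idx)

snp_id_block <- function(snp_id) {
  as.integer(sub("^b([0-9]+)_s[0-9]+$", "\\1", snp_id))
}

#' Truth table of planted loci
#'
#' One row per causal (SNP, trait) assignment plus one row per null locus,
#' used by tests and benchmark scoring to compare recovered classifications
#' with planted ones.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `gene_name`, `scenario`, `snp_id`, `trait`,
#'   `lambda` (NA for null loci).
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$planted_loci) == 0) {
    return(tibble(gene_name = character(), scenario = character(),
                  snp_id = character(), trait = character(),
                  lambda = numeric()))
  }
  rows <- purrr::map(config$planted_loci, function(pl) {
    if (nrow(pl$causal) == 0) {
      tibble(gene_name = pl$gene_name, scenario = pl$scenario,
             snp_id = NA_character_, trait = NA_character_, lambda = NA_real_)
    } else {
      mutate(pl$causal, gene_name = pl$gene_name, scenario = pl$scenario,
             .before = 1)
    }
  })
  bind_rows(rows)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_blocks, " blocks x ", x$snps_per_block,
      " SNPs, ", x$n_individuals, " individuals, ",
      length(x$traits), " trait(s), ", length(x$planted_loci),
      " planted locus/loci, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
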