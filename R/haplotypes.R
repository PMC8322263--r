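#' EM haplotype frequency estimation from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies over a small set of markers via
#' expectation-maximisation over each individual's compatible haplotype
#' pairs. Heterozygous sites contribute phase ambiguity; missing sites are
#' handled by summing over all compatible genotypes. Convergence when the
#' largest frequency change is below 1e-6, or after 500 iterations.
#'
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param snp_list 1-25 marker ids (the haplotype space is exponential).
#' @return A tibble with columns `haplotype` (allele letters in `snp_list`
#'   order), `frequency`, sorted by decreasing frequency; frequencies sum
#'   to 1. Attribute `"hap_alleles"`: a character matrix (haplotypes x
#'   markers) of the carried alleles.
#' @export
estimate_haplotypes <- function(panel, snp_list) {
  stopifnot(inherits(panel, "genotype_panel"))
  k <- length(snp_list)
  if (k < 1 || k > 25) abort("`snp_list` must hold 1 to 25 markers.")
  G <- panel$genotypes[, snp_list, drop = FALSE]

  dict <- new.env(parent = emptyenv())  # hap string -> integer index
  haps <- list()
  hap_index <- function(h) {
    key <- paste(h, collapse = "")
    idx <- dict[[key]]
    if (is.null(idx)) {
      idx <- length(haps) + 1L
      haps[[idx]] <<- h
      assign(key, idx, envir = dict)
    }
    idx
  }

  pair_i1 <- integer(0); pair_i2 <- integer(0); pair_ind <- integer(0)
  for (ind in seq_len(nrow(G))) {
    g <- G[ind, ]
    amb <- sum(g == 1, na.rm = TRUE) + 2 * sum(is.na(g))
    if (amb > 16) {
      abort("individual with too many ambiguous sites for exact enumeration.")
    }
    het <- which(!is.na(g) & g == 1)
    mis <- which(is.na(g))
    base1 <- ifelse(is.na(g), 0L, as.integer(g >= 1))
    base2 <- ifelse(is.na(g), 0L, as.integer(g == 2))
    free1 <- c(het, mis)   # sites where hap1's allele may vary
    free2 <- mis           # hap2 varies only at missing sites
    n1 <- 2^length(free1); n2 <- 2^length(free2)
    for (c1 in seq_len(n1) - 1L) {
      h1 <- base1
      if (length(free1)) {
        h1[free1] <- as.integer(bitwAnd(c1, 2^(seq_along(free1) - 1)) > 0)
      }
      for (c2 in seq_len(n2) - 1L) {
        h2 <- base2
        if (length(free2)) {
          h2[free2] <- as.integer(bitwAnd(c2, 2^(seq_along(free2) - 1)) > 0)
        }
        # hap2 complements hap1 at heterozygous sites
        if (length(het)) h2[het] <- 1L - h1[het]
        pair_i1 <- c(pair_i1, hap_index(h1))
        pair_i2 <- c(pair_i2, hap_index(h2))
        pair_ind <- c(pair_ind, ind)
      }
    }
  }

  H <- length(haps)
  f <- rep(1 / H, H)
  n_ind <- nrow(G)
  for (it in seq_len(500)) {
    w <- f[pair_i1] * f[pair_i2]
    tot <- rowsum(w, pair_ind)[, 1]  # individuals appear in order 1..n
    w <- w / tot[pair_ind]
    cnt <- rowsum(c(w, w), c(pair_i1, pair_i2))
    counts <- rep(0, H)
    counts[as.integer(rownames(cnt))] <- cnt[, 1]
    f_new <- counts / (2 * n_ind)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < 1e-6) break
  }

  hap_mat <- do.call(rbind, haps)
  mk <- panel$markers[match(snp_list, panel$markers$snp_id), ]
  allele_mat <- matrix("", nrow = H, ncol = k)
  for (s in seq_len(k)) {
    allele_mat[, s] <- ifelse(hap_mat[, s] == 1, mk$allele_b[s],
                              mk$allele_a[s])
  }
  lab <- apply(allele_mat, 1, paste, collapse = "")
  ord <- order(-f, lab)
  out <- tibble(haplotype = lab[ord], frequency = f[ord])
  attr(out, "hap_alleles") <- allele_mat[ord, , drop = FALSE]
  colnames(attr(out, "hap_alleles")) <- snp_list
  out
}

#' Four-gamete haplotype blocks
#'
#' Scans a chromosome region left to right and joins consecutive markers into
#' a block while every adjacent pair inside the block shows at most three of
#' the four possible two-marker haplotypes at estimated frequency at least
#' `gamete_freq_min`, and the block span stays within `window_bp`. Adjacent
#' pairs breaking either condition start a new block, so the blocks partition
#' the region's polymorphic markers.
#'
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param chrom Chromosome.
#' @param start,end Region bounds in bp (1-based inclusive; default whole
#'   chromosome).
#' @param window_bp Maximum block span in bp (default 500 kb).
#' @param gamete_freq_min Minimum estimated frequency for a two-marker
#'   haplotype to count as observed (default 0.01).
#' @return A tibble with columns `block_id`, `chrom`, `start`, `end`,
#'   `n_snps`, `snp_ids` (list-column).
#' @export
four_gamete_blocks <- function(panel, chrom, start = 1L, end = NULL,
                               window_bp = 5e5, gamete_freq_min = 0.01) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (is.null(end)) end <- max(panel$markers$pos[panel$markers$chrom == chrom])
  mk <- panel$markers %>%
    filter(.data$chrom == !!chrom, .data$pos >= start, .data$pos <= end,
           !.data$monomorphic) %>%
    arrange(.data$pos)
  if (nrow(mk) == 0) {
    return(tibble(block_id = integer(), chrom = integer(), start = integer(),
                  end = integer(), n_snps = integer(), snp_ids = list()))
  }
  pass <- function(i) {
    est <- estimate_haplotypes(panel, mk$snp_id[c(i, i + 1)])
    sum(est$frequency >= gamete_freq_min) <= 3
  }
  blocks <- list()
  a <- 1
  for (i in seq_len(nrow(mk) - 1)) {
    if (!pass(i) || mk$pos[i + 1] - mk$pos[a] > window_bp) {
      blocks[[length(blocks) + 1]] <- a:i
      a <- i + 1
    }
  }
  blocks[[length(blocks) + 1]] <- a:nrow(mk)
  purrr::imap_dfr(blocks, function(idx, b) {
    tibble(block_id = b, chrom = chrom, start = min(mk$pos[idx]),
           end = max(mk$pos[idx]), n_snps = length(idx),
           snp_ids = list(mk$snp_id[idx]))
  })
}

#' Place trait-associated alleles on common haplotypes
#'
#' Estimates haplotype frequencies over a block, keeps haplotypes with
#' frequency above `freq_min`, and reports, for each focal SNP, which of the
#' kept haplotypes carry its trait-associated allele. The report flags the
#' configuration where the flagged alleles of two focal SNPs (for different
#' traits) reside on disjoint haplotype sets — the signature of two trait
#' associations travelling on different haplotypes.
#'
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param block A row of [four_gamete_blocks()] output, or a character vector
#'   of member marker ids.
#' @param focal Data frame with columns `snp_id`, `trait`, `allele` (the
#'   trait-increasing/associated allele). All focal SNPs must lie in the
#'   block.
#' @param freq_min Report only haplotypes with frequency strictly above this
#'   (default 0.10).
#' @return A list of class `haplotype_report`: `$haplotypes` (kept tibble),
#'   `$focal` (per focal SNP: carrying haplotype labels, list-column),
#'   `$disjoint_pairs` (cross-trait focal pairs on disjoint haplotypes),
#'   `$different_haplotypes` (logical flag).
#' @export
haplotype_report <- function(panel, block, focal, freq_min = 0.10) {
  snps <- if (is.character(block)) block else block$snp_ids[[1]]
  focal <- as_tibble(focal)
  stopifnot(all(c("snp_id", "trait", "allele") %in% names(focal)))
  outside <- setdiff(focal$snp_id, snps)
  if (length(outside)) {
    abort(paste0("focal SNP(s) outside block: ",
                 paste(outside, collapse = ", ")))
  }
  est <- estimate_haplotypes(panel, snps)
  al <- attr(est, "hap_alleles")
  keep <- est$frequency > freq_min
  kept <- est[keep, , drop = FALSE]
  al <- al[keep, , drop = FALSE]
  carriers <- purrr::map(seq_len(nrow(focal)), function(i) {
    col <- match(focal$snp_id[i], snps)
    kept$haplotype[al[, col] == focal$allele[i]]
  })
  focal_out <- mutate(focal, haplotypes = carriers,
                      n_haplotypes = lengths(carriers))
  pairs <- list()
  if (nrow(focal) >= 2) {
    cmb <- utils::combn(nrow(focal), 2)
    for (q in seq_len(ncol(cmb))) {
      i <- cmb[1, q]; j <- cmb[2, q]
      if (focal$trait[i] == focal$trait[j]) next
      disjoint <- length(intersect(carriers[[i]], carriers[[j]])) == 0 &&
        length(carriers[[i]]) > 0 && length(carriers[[j]]) > 0
      pairs[[length(pairs) + 1]] <- tibble(
        snp_i = focal$snp_id[i], trait_i = focal$trait[i],
        snp_j = focal$snp_id[j], trait_j = focal$trait[j],
        disjoint = disjoint)
    }
  }
  pairs <- if (length(pairs)) bind_rows(pairs) else
    tibble(snp_i = character(), trait_i = character(),
           snp_j = character(), trait_j = character(), disjoint = logical())
  structure(list(haplotypes = kept, focal = focal_out,
                 disjoint_pairs = pairs[pairs$disjoint, , drop = FALSE],
                 different_haplotypes = any(pairs$disjoint)),
            class = "haplotype_report")
}

#' @export
print.haplotype_report <- function(x, ...) {
  cat("<haplotype_report> ", nrow(x$haplotypes), " haplotype(s) above cutoff; ",
      nrow(x$focal), " focal SNP(s); different-haplotype configuration: ",
      x$different_haplotypes, "\n", sep = "")
  invisible(x)
}
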