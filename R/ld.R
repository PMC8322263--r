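#' Pairwise linkage disequilibrium between two panel markers
#'
#' Signed Pearson correlation of allele-dosage vectors, with pairwise
#' deletion of missing genotypes. `ld_r2()` is its square.
#'
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param snp_i,snp_j Marker ids.
#' @return `ld_r()`: signed correlation in \[-1, 1\]; `NA_real_` when either
#'   marker is monomorphic (undefined LD). `ld_r2()`: squared correlation.
#' @export
ld_r <- function(panel, snp_i, snp_j) {
  stopifnot(inherits(panel, "genotype_panel"))
  g <- panel$genotypes[, c(snp_i, snp_j), drop = FALSE]
  ok <- stats::complete.cases(g)
  gi <- g[ok, 1]; gj <- g[ok, 2]
  if (stats::sd(gi) == 0 || stats::sd(gj) == 0) return(NA_real_)
  as.numeric(cor(gi, gj))
}

#' @rdname ld_r
#' @export
ld_r2 <- function(panel, snp_i, snp_j) ld_r(panel, snp_i, snp_j)^2

#' Signed LD correlation matrix for a marker list
#'
#' Pairwise-complete Pearson correlations of dosages, in the order of
#' `snp_list`, with unit diagonal. When `regularize = TRUE` the matrix is
#' floored to eigenvalue 1e-6 (and rescaled to unit diagonal) so downstream
#' factorizations are safe; an already-PSD matrix is returned unchanged.
#'
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param snp_list Nonempty character vector of marker ids.
#' @param regularize Apply the eigenvalue floor (default TRUE).
#' @return A symmetric matrix with `snp_list` dimnames.
#' @export
ld_matrix <- function(panel, snp_list, regularize = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"), length(snp_list) >= 1)
  bad <- setdiff(snp_list, panel$markers$snp_id)
  if (length(bad)) abort(paste0("markers not in panel: ",
                                paste(bad, collapse = ", ")))
  mono <- panel$markers$snp_id[panel$markers$monomorphic]
  off <- intersect(snp_list, mono)
  if (length(off)) {
    abort(paste0("monomorphic marker(s) in snp_list: ",
                 paste(off, collapse = ", ")))
  }
  G <- panel$genotypes[, snp_list, drop = FALSE]
  R <- cor(G, use = "pairwise.complete.obs")
  diag(R) <- 1
  if (regularize) R <- regularize_psd(R)
  dimnames(R) <- list(snp_list, snp_list)
  R
}

#' Windowed pairwise LD pruning
#'
#' Greedy position-ordered pruning: repeatedly find the leftmost pair of
#' surviving markers on the same chromosome, within `window_bp`, with
#' r-squared above `r2_thresh`, and remove the member with the smaller minor
#' allele frequency (ties: the larger position is removed). On exit no
#' surviving pair within a window exceeds the threshold. The result does not
#' depend on the input order of `snps` (markers are sorted by position
#' internally), and the count of retained markers is what the Bonferroni
#' stage consumes.
#'
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param snps Marker ids to prune (monomorphic markers are retained
#'   untouched: their LD is undefined).
#' @param window_bp Window in bp (default 10 Mb).
#' @param r2_thresh r-squared threshold (default 0.2); pairs strictly above
#'   it conflict.
#' @return A list of class `prune_result`: `$retained` (ids in map order),
#'   `$removed` (tibble `snp_id`, `partner`, `r2`), `$n_retained`.
#' @export
prune_pairwise <- function(panel, snps, window_bp = 1e7, r2_thresh = 0.2) {
  stopifnot(inherits(panel, "genotype_panel"))
  mk <- panel$markers %>%
    filter(.data$snp_id %in% snps) %>%
    arrange(.data$chrom, .data$pos)
  removed <- list()
  retained <- character(0)
  for (ch in unique(mk$chrom)) {
    sub <- mk %>% filter(.data$chrom == ch, !.data$monomorphic)
    retained <- c(retained,
                  mk$snp_id[mk$chrom == ch & mk$monomorphic])
    if (nrow(sub) <= 1) {
      retained <- c(retained, sub$snp_id)
      next
    }
    R2 <- cor(panel$genotypes[, sub$snp_id, drop = FALSE],
              use = "pairwise.complete.obs")^2
    maf <- pmin(sub$freq_b, 1 - sub$freq_b)
    pos <- sub$pos
    k <- nrow(sub)
    close_enough <- abs(outer(pos, pos, `-`)) <= window_bp
    conflict <- R2 > r2_thresh & close_enough
    conflict[lower.tri(conflict, diag = TRUE)] <- FALSE
    alive <- rep(TRUE, k)
    repeat {
      viol <- which(conflict & outer(alive, alive, `&`), arr.ind = TRUE)
      if (nrow(viol) == 0) break
      viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
      i <- viol[1, 1]; j <- viol[1, 2]
      drop_j <- maf[j] < maf[i] || (maf[j] == maf[i] && pos[j] >= pos[i])
      d <- if (drop_j) j else i
      keep <- if (drop_j) i else j
      alive[d] <- FALSE
      removed[[length(removed) + 1]] <-
        tibble(snp_id = sub$snp_id[d], partner = sub$snp_id[keep],
               r2 = R2[i, j])
    }
    retained <- c(retained, sub$snp_id[alive])
  }
  retained <- mk$snp_id[mk$snp_id %in% retained]
  structure(list(retained = retained, removed = bind_rows(removed),
                 n_retained = length(retained)),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat("<prune_result> ", x$n_retained, " retained, ",
      nrow(x$removed), " removed\n", sep = "")
  invisible(x)
}
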