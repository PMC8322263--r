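#' Write a genotype panel as PLINK 1 binary (.bed/.bim/.fam)
#'
#' SNP-major .bed with the standard 2-bit encoding (00 = two copies of A1,
#' 10 = heterozygote, 11 = zero copies of A1, 01 = missing). A1 is the
#' panel's counted allele (`allele_b`), A2 is `allele_a`.
#'
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param prefix Path prefix; `<prefix>.bed`, `.bim`, `.fam` are written.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  stopifnot(inherits(panel, "genotype_panel"))
  mk <- panel$markers
  readr::write_tsv(
    tibble(chrom = mk$chrom, snp_id = mk$snp_id, cm = 0, pos = mk$pos,
           a1 = mk$allele_b, a2 = mk$allele_a),
    paste0(prefix, ".bim"), col_names = FALSE)
  n <- panel$n_individuals
  readr::write_tsv(
    tibble(fid = sprintf("F%05d", seq_len(n)),
           iid = sprintf("I%05d", seq_len(n)),
           pat = 0, mat = 0, sex = 0, pheno = -9),
    paste0(prefix, ".fam"), col_names = FALSE)

  # 2-bit codes indexed by dosage of A1 (+1); NA -> 01b
  code <- c(`2` = 0x0, `1` = 0x2, `0` = 0x3)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(ncol(panel$genotypes))) {
    g <- panel$genotypes[, j]
    cc <- ifelse(is.na(g), 0x1, code[as.character(g)])
    length(cc) <- bytes_per_snp * 4
    cc[is.na(cc)] <- 0
    m <- matrix(cc, nrow = 4)
    writeBin(as.raw(m[1, ] + m[2, ] * 4 + m[3, ] * 16 + m[4, ] * 64), con)
  }
  invisible(prefix)
}

#' Read a PLINK 1 binary fileset into a genotype panel
#'
#' @param prefix Path prefix of an existing `.bed`/`.bim`/`.fam` trio.
#' @return A [genotype_panel][new_genotype_panel]; dosages count the .bim A1
#'   allele (stored as `allele_b`).
#' @export
read_plink <- function(prefix) {
  bim <- readr::read_tsv(
    paste0(prefix, ".bim"),
    col_names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
    col_types = "icnicc", progress = FALSE)
  fam <- readr::read_tsv(
    paste0(prefix, ".fam"),
    col_names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
    col_types = "cccccc", progress = FALSE)
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + ceiling(n / 4) * m)
  if (length(raw) < 3 || raw[1] != 0x6c || raw[2] != 0x1b) {
    abort("not a PLINK 1 .bed file.")
  }
  if (raw[3] != 0x01) abort("only SNP-major .bed files are supported.")
  body <- raw[-(1:3)]
  ints <- as.integer(body)
  # unpack all four 2-bit fields at once
  q <- rbind(ints %% 4, (ints %/% 4) %% 4, (ints %/% 16) %% 4, ints %/% 64)
  dos <- c(2L, NA_integer_, 1L, 0L)[q + 1L]
  G <- matrix(dos, nrow = ceiling(n / 4) * 4)[seq_len(n), , drop = FALSE]
  markers <- tibble(snp_id = bim$snp_id, chrom = bim$chrom, pos = bim$pos,
                    allele_a = bim$a2, allele_b = bim$a1)
  new_genotype_panel(markers, G)
}
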