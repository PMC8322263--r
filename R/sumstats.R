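#' Read a GWAS summary-statistics table
#'
#' Reads whitespace/tab-delimited summary statistics (GCTA ".ma"-style) into
#' the package's standard layout. Column names are matched case-insensitively
#' through `column_map`; the default map accepts the conventional header
#' `SNP CHR BP A1 A2 FREQ BETA SE P N INFO`. Rows whose mandatory numeric
#' fields do not parse are dropped and counted in the `"n_dropped"` attribute.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping standard names
#'   (`snp_id, chrom, pos, a1, a2, freq, beta, se, p, n, info`) to the file's
#'   column names. Entries missing from the default map fall back to the
#'   defaults.
#' @return A tibble of records with attribute `"n_dropped"`. An absent INFO
#'   column yields `info = NA` (treated as genotyped by [qc_filter()]).
#' @export
read_sumstats <- function(path, column_map = NULL) {
  defaults <- c(snp_id = "SNP", chrom = "CHR", pos = "BP", a1 = "A1",
                a2 = "A2", freq = "FREQ", beta = "BETA", se = "SE",
                p = "P", n = "N", info = "INFO")
  map <- defaults
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  names(raw) <- toupper(names(raw))
  mandatory <- c("snp_id", "chrom", "pos", "a1", "a2", "freq", "beta",
                 "se", "p", "n")
  for (std in mandatory) {
    if (!toupper(map[[std]]) %in% names(raw)) {
      abort(paste0("mandatory column '", map[[std]], "' (", std,
                   ") not found in ", path))
    }
  }
  has_info <- toupper(map[["info"]]) %in% names(raw)
  out <- tibble(
    snp_id = raw[[toupper(map[["snp_id"]])]],
    chrom_raw = raw[[toupper(map[["chrom"]])]],
    pos = suppressWarnings(as.integer(raw[[toupper(map[["pos"]])]])),
    a1 = toupper(raw[[toupper(map[["a1"]])]]),
    a2 = toupper(raw[[toupper(map[["a2"]])]]),
    freq = suppressWarnings(as.numeric(raw[[toupper(map[["freq"]])]])),
    beta = suppressWarnings(as.numeric(raw[[toupper(map[["beta"]])]])),
    se = suppressWarnings(as.numeric(raw[[toupper(map[["se"]])]])),
    p = suppressWarnings(as.numeric(raw[[toupper(map[["p"]])]])),
    n = suppressWarnings(as.numeric(raw[[toupper(map[["n"]])]])),
    info = if (has_info) {
      suppressWarnings(as.numeric(raw[[toupper(map[["info"]])]]))
    } else NA_real_
  )
  out$chrom <- suppressWarnings(as.integer(out$chrom_raw))
  out$chrom[toupper(out$chrom_raw) %in% c("X", "Y", "MT", "M", "XY")] <- 90L
  ok <- !is.na(out$pos) & !is.na(out$freq) & !is.na(out$beta) &
    !is.na(out$se) & !is.na(out$p) & !is.na(out$n) & !is.na(out$chrom)
  res <- out %>%
    filter(ok) %>%
    select("snp_id", "chrom", "pos", "a1", "a2", "freq", "beta", "se",
           "p", "n", "info")
  attr(res, "n_dropped") <- sum(!ok)
  res
}

#' QC filter parameters
#'
#' @param info_min Minimum imputation INFO score (records below are removed;
#'   `NA` INFO passes — absence of an INFO column is read as genotyped).
#' @param maf_min Minimum minor allele frequency, `min(freq, 1 - freq)`.
#' @return A list of class `qc_params`.
#' @export
qc_params <- function(info_min = 0.9, maf_min = 0.1) {
  structure(list(info_min = info_min, maf_min = maf_min),
            class = "qc_params")
}

BASES <- c("A", "C", "G", "T")
AMBIGUOUS <- c("A/T", "T/A", "C/G", "G/C")

#' Quality-control filtering of summary statistics
#'
#' Removes, in this order of reason attribution: non-autosomal records
#' (chromosome outside 1-22), indels (alleles not single A/C/G/T bases),
#' strand-ambiguous allele pairs (A/T, T/A, C/G, G/C), poorly imputed records
#' (INFO < `info_min`), low-frequency records (MAF < `maf_min`), and all
#' copies of duplicated SNP ids. The retained set is the conjunction of the
#' filter predicates, so it does not depend on the order.
#'
#' @param sumstats Tibble from [read_sumstats()] (or same layout).
#' @param params A [qc_params()].
#' @return A list of class `qc_result`: `$sumstats` (retained rows),
#'   `$removed` (tibble `snp_id`, `reason`), `$report` (tibble of counts per
#'   reason plus `retained`; removed + retained = input rows).
#' @export
qc_filter <- function(sumstats, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  x <- as_tibble(sumstats)
  pair <- paste0(x$a1, "/", x$a2)
  fail <- list(
    non_autosome = !(x$chrom %in% 1:22),
    indel = !(x$a1 %in% BASES) | !(x$a2 %in% BASES),
    ambiguous = (x$a1 %in% BASES) & (x$a2 %in% BASES) & pair %in% AMBIGUOUS,
    low_info = !is.na(x$info) & x$info < params$info_min,
    low_maf = pmin(x$freq, 1 - x$freq) < params$maf_min,
    duplicate = duplicated(x$snp_id) | duplicated(x$snp_id, fromLast = TRUE)
  )
  any_fail <- Reduce(`|`, fail)
  reason <- rep(NA_character_, nrow(x))
  for (nm in rev(names(fail))) reason[fail[[nm]]] <- nm
  removed <- tibble(snp_id = x$snp_id[any_fail], reason = reason[any_fail])
  n_by_reason <- vapply(names(fail),
                        function(nm) sum(reason == nm, na.rm = TRUE),
                        integer(1))
  report <- tibble(reason = c(names(fail), "retained"),
                   n = c(unname(n_by_reason), sum(!any_fail)))
  structure(list(sumstats = x[!any_fail, , drop = FALSE],
                 removed = removed, report = report),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> retained ", nrow(x$sumstats), ", removed ",
      nrow(x$removed), "\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Harmonize summary statistics to a reference panel
#'
#' Matches records to panel markers by SNP id. Records whose alleles equal
#' the panel alleles in reversed order have `beta` negated and `freq`
#' reflected (`1 - freq`); records absent from the panel, with an allele-set
#' mismatch, or with `|freq - panel freq| > freq_tol` after alignment are
#' dropped. Chromosome and position are taken from the panel map. `|beta|`,
#' `se` and `p` are never altered.
#'
#' @param sumstats QC'd tibble (or the `$sumstats` of a [qc_filter()] result).
#' @param panel A [genotype_panel][new_genotype_panel].
#' @param freq_tol Maximum tolerated absolute difference between the reported
#'   and panel effect-allele frequency (default 0.2).
#' @return Harmonized tibble (effect allele = panel `allele_b`) with attribute
#'   `"harmonize_report"`: counts of `not_in_panel`, `allele_mismatch`,
#'   `freq_mismatch`, `retained`.
#' @export
harmonize_to_panel <- function(sumstats, panel, freq_tol = 0.2) {
  if (inherits(sumstats, "qc_result")) sumstats <- sumstats$sumstats
  stopifnot(inherits(panel, "genotype_panel"))
  x <- as_tibble(sumstats)
  mk <- panel$markers %>%
    select("snp_id", panel_chrom = "chrom", panel_pos = "pos",
           "allele_a", "allele_b", "freq_b")
  j <- left_join(x, mk, by = "snp_id")
  in_panel <- !is.na(j$allele_b)
  same <- in_panel & j$a1 == j$allele_b & j$a2 == j$allele_a
  flip <- in_panel & j$a1 == j$allele_a & j$a2 == j$allele_b
  mismatch <- in_panel & !same & !flip
  j$beta[flip] <- -j$beta[flip]
  j$freq[flip] <- 1 - j$freq[flip]
  tmp <- j$a1[flip]; j$a1[flip] <- j$a2[flip]; j$a2[flip] <- tmp
  freq_bad <- (same | flip) & abs(j$freq - j$freq_b) > freq_tol
  keep <- (same | flip) & !freq_bad
  out <- j[keep, , drop = FALSE] %>%
    mutate(chrom = .data$panel_chrom, pos = .data$panel_pos) %>%
    select("snp_id", "chrom", "pos", "a1", "a2", "freq", "beta", "se",
           "p", "n", "info")
  attr(out, "harmonize_report") <- tibble(
    reason = c("not_in_panel", "allele_mismatch", "freq_mismatch", "retained"),
    n = c(sum(!in_panel), sum(mismatch), sum(freq_bad), sum(keep))
  )
  out
}
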