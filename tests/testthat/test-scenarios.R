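test_that("the experiment-wide Bonferroni threshold is 0.05 over the pruned count", {
  expect_equal(signif(compute_experiment_threshold(8772), 3), 5.70e-6)
  expect_equal(compute_experiment_threshold(1), 0.05)
  expect_equal(compute_experiment_threshold(1000), 5e-5)
  expect_error(compute_experiment_threshold(0), "positive")
})

# panel with two independent markers and one high-LD pair for r2 evidence
make_cls_panel <- function() {
  set.seed(60)
  a <- rbinom(400, 2, 0.4)
  b <- rbinom(400, 2, 0.4)            # independent of a
  a2 <- ifelse(rbinom(400, 1, 0.9) == 1, a, rbinom(400, 2, 0.4))  # r2 ~ 0.8
  toy_panel(cbind(a, b, a2), ids = c("sA", "sB", "sA2"),
            pos = c(1000L, 2000L, 3000L))
}

sig_row <- function(snp, trait, p_j = 1e-9, pos = 1000L) {
  tibble::tibble(trait = trait, snp_id = snp, chrom = 1L, pos = pos,
                 p_j = p_j)
}

test_that("the scenario decision rule reproduces all canonical cases", {
  panel <- make_cls_panel()
  alpha <- 5.7e-6
  # two LD-independent signals, two traits -> gene-level pleiotropy (I)
  cls <- classify_region(dplyr::bind_rows(sig_row("sA", "SCZ"),
                                          sig_row("sB", "EDU", pos = 2000L)),
                         panel, alpha)
  expect_equal(cls$scenario, "I")
  # two LD-independent signals, one trait -> allelic heterogeneity (II)
  cls <- classify_region(dplyr::bind_rows(sig_row("sA", "EDU"),
                                          sig_row("sB", "EDU", pos = 2000L)),
                         panel, alpha)
  expect_equal(cls$scenario, "II")
  # the same SNP selected for two traits -> SNP-level pleiotropy (III)
  cls <- classify_region(dplyr::bind_rows(sig_row("sA", "MDD"),
                                          sig_row("sA", "PUT")),
                         panel, alpha)
  expect_equal(cls$scenario, "III")
  expect_equal(cls$evidence[[1]]$r2, 1)
  # an LD-dependent pair (r2 >= 0.2) across traits is also III
  cls <- classify_region(dplyr::bind_rows(sig_row("sA", "MDD"),
                                          sig_row("sA2", "PUT",
                                                  pos = 3000L)),
                         panel, alpha)
  expect_equal(cls$scenario, "III")
  # dependent cross-trait pair plus an independent third -> mixed
  cls <- classify_region(dplyr::bind_rows(sig_row("sA", "MDD"),
                                          sig_row("sA2", "PUT", pos = 3000L),
                                          sig_row("sB", "MDD", pos = 2000L)),
                         panel, alpha)
  expect_equal(cls$scenario, "mixed")
  # one signal -> single; sub-threshold signals are ignored
  cls <- classify_region(dplyr::bind_rows(sig_row("sA", "MDD"),
                                          sig_row("sB", "PUT", p_j = 1e-3,
                                                  pos = 2000L)),
                         panel, alpha)
  expect_equal(cls$scenario, "single")
  # within-trait dependence only -> unclassified ("none")
  cls <- classify_region(dplyr::bind_rows(sig_row("sA", "MDD"),
                                          sig_row("sA2", "MDD",
                                                  pos = 3000L)),
                         panel, alpha)
  expect_equal(cls$scenario, "none")
})

test_that("classification is invariant to signal order and trait relabeling", {
  panel <- make_cls_panel()
  sigs <- dplyr::bind_rows(sig_row("sA", "X"), sig_row("sA2", "Y",
                                                       pos = 3000L),
                           sig_row("sB", "X", pos = 2000L))
  c1 <- classify_region(sigs, panel, 1e-5)
  c2 <- classify_region(sigs[c(3, 1, 2), ], panel, 1e-5)
  expect_equal(c1$scenario, c2$scenario)
  swapped <- dplyr::mutate(sigs, trait = ifelse(trait == "X", "Y", "X"))
  c3 <- classify_region(swapped, panel, 1e-5)
  expect_equal(c1$scenario, c3$scenario)
})

test_that("scenario counts recover planted loci and are threshold-monotone", {
  cfg <- benchmark_config(seed = 5, n_regions = 14)
  st <- simulate_study(cfg)
  h <- purrr::map(st$sumstats, ~ harmonize_to_panel(qc_filter(.x), st$panel))
  sigs <- select_signals_all(h, st$panel)
  asg <- assign_snps_to_genes(sigs, st$genes)
  groups <- merge_gene_blocks(asg, st$genes)
  tab <- tabulate_scenarios(sigs, groups, st$panel,
                            thresholds = c(gw = 5e-8, ew = 3e-4,
                                           sel = 1e-5))
  # monotone: stricter thresholds cannot classify more multi-signal groups
  multi <- tab %>% dplyr::filter(scenario %in% c("I", "II", "III", "mixed"))
  expect_true(all(multi$gw <= multi$sel))
  # oracle: expected label given which planted causals are detectable at
  # all (any marker of the causal block with |z| above the selection
  # threshold); the classifier must match this expectation exactly
  thr <- qnorm(1 - 5e-6)
  tru <- dplyr::filter(st$truth, !is.na(snp_id))
  det <- purrr::map_lgl(seq_len(nrow(tru)), function(i) {
    blk <- substr(tru$snp_id[i], 1, 4)
    ss <- dplyr::filter(h[[tru$trait[i]]], startsWith(snp_id, blk))
    any(abs(ss$beta / ss$se) > thr)
  })
  expected <- tru %>% dplyr::mutate(det = det) %>%
    dplyr::group_by(gene_name) %>%
    dplyr::group_modify(function(d, g) {
      dd <- d[d$det, ]
      if (nrow(dd) <= 1) return(tibble::tibble(expected = "single"))
      pairs <- utils::combn(nrow(dd), 2)
      depx <- FALSE; indep <- FALSE
      for (q in seq_len(ncol(pairs))) {
        i1 <- pairs[1, q]; j1 <- pairs[2, q]
        if (dd$snp_id[i1] == dd$snp_id[j1]) {
          if (dd$trait[i1] != dd$trait[j1]) depx <- TRUE
        } else indep <- TRUE
      }
      Tn <- length(unique(dd$trait))
      lab <- if (!depx) {
        if (Tn >= 2) "I" else if (indep) "II" else "none"
      } else if (!indep) "III" else "mixed"
      tibble::tibble(expected = lab)
    }) %>% dplyr::ungroup()
  cls <- classify_regions(sigs, groups, st$panel, 3e-4)
  rec <- score_recovery(cls, st$truth)
  cmp <- dplyr::inner_join(rec, expected, by = "gene_name")
  expect_equal(cmp$recovered, cmp$expected)
  # empty input gives an all-zero table
  empty <- tabulate_scenarios(sigs[0, ], groups, st$panel)
  expect_true(all(dplyr::select(empty, -scenario) == 0 |
                    empty$scenario == "single"))
})

test_that("trait-pair matrices split independent and dependent overlaps", {
  panel <- make_cls_panel()
  cls <- dplyr::bind_rows(
    dplyr::mutate(classify_region(dplyr::bind_rows(
      sig_row("sA", "A"), sig_row("sB", "B", pos = 2000L)), panel, 1e-5),
      group_id = 1),
    dplyr::mutate(classify_region(dplyr::bind_rows(
      sig_row("sA", "A"), sig_row("sA", "B")), panel, 1e-5),
      group_id = 2))
  M <- trait_pair_matrix(cls)
  expect_equal(M["A", "B"], 1L)  # upper: independent (Scenario I group)
  expect_equal(M["B", "A"], 1L)  # lower: dependent (Scenario III group)
  # conservation: totals match classification counts
  expect_equal(sum(M), 2L)
  # a mixed group contributes to both triangles
  cls_mixed <- dplyr::mutate(classify_region(dplyr::bind_rows(
    sig_row("sA", "A"), sig_row("sA2", "B", pos = 3000L),
    sig_row("sB", "A", pos = 2000L)), panel, 1e-5), group_id = 3)
  M2 <- trait_pair_matrix(cls_mixed)
  expect_equal(M2["A", "B"], 1L)
  expect_equal(M2["B", "A"], 1L)
})
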