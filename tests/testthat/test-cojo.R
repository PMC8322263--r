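test_that("a single record's joint statistics equal its marginal statistics", {
  rec <- toy_sumstats(snp_id = "s1", freq = 0.3, beta = 0.05, se = 0.011,
                      N = 20000)
  fit <- joint_fit(rec, matrix(1, 1, 1))
  expect_equal(fit$estimates$beta_j, rec$beta)
  expect_equal(fit$estimates$se_j, rec$se, tolerance = 1e-3)
  expect_equal(fit$estimates$p_j, rec$p, tolerance = 1e-2)
})

test_that("orthogonal predictors keep their marginal estimates in the joint model", {
  recs <- dplyr::bind_rows(
    toy_sumstats(snp_id = "s1", beta = 0.05, se = 0.011, N = 20000,
                 pos = 1000L),
    toy_sumstats(snp_id = "s2", beta = -0.04, se = 0.011, N = 20000,
                 pos = 2000L))
  fit <- joint_fit(recs, diag(2))
  expect_equal(fit$estimates$beta_j, recs$beta, tolerance = 1e-9)
  expect_equal(fit$estimates$se_j, recs$se, tolerance = 1e-3)
})

test_that("markers beyond the window are treated as uncorrelated", {
  recs <- dplyr::bind_rows(
    toy_sumstats(snp_id = "s1", beta = 0.05, se = 0.011, N = 20000,
                 pos = 1000L),
    toy_sumstats(snp_id = "s2", beta = 0.05, se = 0.011, N = 20000,
                 pos = 20000000L))
  R <- matrix(c(1, .9, .9, 1), 2)  # high nominal r, but 20 Mb apart
  fit <- joint_fit(recs, R, window_bp = 1e7)
  expect_equal(fit$estimates$beta_j, recs$beta, tolerance = 1e-9)
})

test_that("perfectly collinear joint models are refused with the pair named", {
  recs <- dplyr::bind_rows(
    toy_sumstats(snp_id = "s1", beta = 0.05, se = 0.011, pos = 1000L),
    toy_sumstats(snp_id = "s2", beta = 0.05, se = 0.011, pos = 2000L))
  expect_error(joint_fit(recs, matrix(c(1, 1, 1, 1), 2)),
               "collinear.*s[12].*s[12]")
})

test_that("summary-level joint fits match exact regression on individuals", {
  for (s in 1:10) {
    reg <- sim_region_individual(n = 5000, m = 10, seed = 500 + s)
    fit <- joint_fit(reg$sumstats, ld_matrix(reg$panel,
                                             reg$sumstats$snp_id))
    oracle <- exact_joint(reg)
    expect_lt(max(abs(fit$estimates$beta_j - oracle$beta)), 0.05)
  }
})

test_that("conditional statistics behave at the boundaries", {
  reg <- sim_region_individual(seed = 77)
  rec <- reg$sumstats[3, ]
  none <- conditional_p(rec, reg$sumstats[0, ], reg$panel)
  expect_equal(none$p_c, rec$p)
  expect_false(none$collinear)
  # candidate in near-perfect LD with a selected marker is flagged
  g <- reg$panel$genotypes[, 1]
  panel2 <- toy_panel(cbind(g, g, reg$panel$genotypes[, 2]))
  ss <- toy_sumstats(n = 3, N = 5000)
  ss$snp_id <- panel2$markers$snp_id
  cond <- conditional_p(ss[2, ], ss[1, ], panel2)
  expect_true(cond$collinear)
  # an orthogonal candidate keeps (approximately) its marginal p
  far <- which.min(abs(suppressWarnings(
    cor(reg$X[, 3], reg$X))[1, -3]))
  far_id <- reg$sumstats$snp_id[-3][far]
  sel <- reg$sumstats[reg$sumstats$snp_id == far_id, ]
  cond2 <- conditional_p(rec, sel, reg$panel)
  expect_equal(unname(log10(cond2$p_c)), log10(rec$p), tolerance = 0.35)
})

test_that("stepwise selection recovers a single strong planted signal", {
  cfg <- sim_config(n_individuals = 800, n_blocks = 2, snps_per_block = 8,
                    traits = "T1",
                    planted_loci = list(planted_locus(
                      "II", "G", tibble::tibble(
                        snp_id = c("b001_s04", "b002_s04"),
                        trait = "T1", lambda = c(8, 0)))),
                    seed = 13)
  st <- simulate_study(cfg)
  h <- harmonize_to_panel(qc_filter(st$sumstats$T1), st$panel)
  sig <- select_signals(h, st$panel, trait = "T1")
  expect_equal(nrow(sig), 1)
  # the causal marker or a near-perfect proxy
  expect_gte(ld_r2(st$panel, sig$snp_id, "b001_s04"), 0.8)
})

test_that("two LD-independent planted signals of one trait are both recovered", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_individuals = 800, n_blocks = 2, snps_per_block = 8,
                      traits = "T1",
                      planted_loci = list(planted_locus(
                        "II", "G", tibble::tibble(
                          snp_id = c("b001_s04", "b002_s04"),
                          trait = "T1", lambda = 8))),
                      seed = 1000 + s)
    st <- simulate_study(cfg)
    h <- harmonize_to_panel(qc_filter(st$sumstats$T1), st$panel)
    sig <- select_signals(h, st$panel, trait = "T1")
    b1 <- any(startsWith(sig$snp_id, "b001"))
    b2 <- any(startsWith(sig$snp_id, "b002"))
    hits <- hits + (b1 && b2)
  }
  expect_gte(hits, 9)
})

test_that("final signals of a trait are mutually below the collinearity cap", {
  st <- cached_small_study()
  h <- purrr::map(st$sumstats, ~ harmonize_to_panel(qc_filter(.x), st$panel))
  sigs <- select_signals_all(h, st$panel)
  for (tr in unique(sigs$trait)) {
    ids <- sigs$snp_id[sigs$trait == tr]
    if (length(ids) < 2) next
    R2 <- ld_matrix(st$panel, ids, regularize = FALSE)^2
    expect_lt(max(R2[upper.tri(R2)]), 0.9)
  }
})

test_that("null traits produce almost no false signals", {
  cfg <- sim_config(n_individuals = 500, n_blocks = 100,
                    snps_per_block = 10, traits = "T1", seed = 424)
  panel <- simulate_reference_panel(cfg)
  tru <- truth_table(cfg)
  n_sig <- purrr::map_int(1:60, function(s) {
    ss <- simulate_sumstats(panel, tru, "T1", n = 20000, seed = 9000 + s)
    h <- harmonize_to_panel(qc_filter(ss), panel)
    nrow(select_signals(h, panel))
  })
  # ~1000 markers at 1e-5 -> expected 0.01 false signals per run
  expect_lt(mean(n_sig), 0.1)
})

test_that("relaxing the threshold never loses a stricter-threshold signal on simple regions", {
  cfg <- sim_config(n_individuals = 800, n_blocks = 2, snps_per_block = 8,
                    traits = "T1",
                    planted_loci = list(planted_locus(
                      "II", "G", tibble::tibble(
                        snp_id = c("b001_s04", "b002_s04"),
                        trait = "T1", lambda = 7))),
                    seed = 99)
  st <- simulate_study(cfg)
  h <- harmonize_to_panel(qc_filter(st$sumstats$T1), st$panel)
  strict <- select_signals(h, st$panel, cojo_params(p_select = 1e-5))
  loose <- select_signals(h, st$panel, cojo_params(p_select = 1e-4))
  expect_true(all(strict$snp_id %in% loose$snp_id))
})
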