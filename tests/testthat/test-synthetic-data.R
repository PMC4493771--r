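test_that("config validation rejects malformed simulations", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(library_depth = 0), "depth")
  expect_error(sim_config(planted_fractions = c("+00" = 0.6, "-00" = 0.6)),
               "sum")
  expect_error(sim_config(planted_fractions = c("x00" = 0.1)), "pattern")
  expect_error(sim_config(planted_fractions = c("000" = 0.1)), "null")
  expect_error(sim_config(effect_log2fc = 1.5), ">= 2")
  expect_error(sim_config(gene_length_range = c(500, 200)), "range")
  expect_error(sim_config(dispersion = -0.1), "non-negative")
  expect_error(
    sim_config(annotation = list(n_terms = 5, term_size_range = c(2, 10),
                                 n_enriched_terms = 9,
                                 enrichment_strength = 0.5)),
    "n_enriched_terms")
})

test_that("no planted fractions means an all-null truth", {
  cfg <- sim_config(n_genes = 200, library_depth = 5e4,
                    planted_fractions = numeric(0), seed = 3)
  ex <- generate_experiment(cfg)
  expect_true(all(ex$truth$pattern == "null"))
  expect_true(all(ex$truth[c("lfc1", "lfc2", "lfc3")] == 0))
  expect_identical(colnames(ex$counts$counts), DTA_LIBRARIES)
})

test_that("identical seeds reproduce experiments bit-for-bit", {
  cfg <- sim_config(n_genes = 300, library_depth = 1e5,
                    control_drift_fraction = 0.05, seed = 99)
  a <- generate_experiment(cfg)
  b <- generate_experiment(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(generate_annotation(cfg, a$truth, "GO-like"),
                   generate_annotation(cfg, b$truth, "GO-like"))
  expect_identical(generate_ct_table(a$truth, 5, seed = 7),
                   generate_ct_table(b$truth, 5, seed = 7))
  # different seed, different draws
  cfg2 <- sim_config(n_genes = 300, library_depth = 1e5, seed = 100)
  expect_false(identical(generate_experiment(cfg2)$counts$counts,
                         a$counts$counts))
})

test_that("a planted (+,+,+) gene realises a four-fold mean count ratio", {
  # Poisson noise, effect exactly at the gate magnitude; Monte-Carlo mean
  # of the ETH1:CK1 count ratio over seed replicates vs the closed form
  nrep <- 1000
  ratios <- vapply(seq_len(nrep), function(s) {
    cfg <- sim_config(n_genes = 20, library_depth = 2e4, dispersion = 0,
                      planted_fractions = c("+++" = 0.05),
                      effect_log2fc = 2, seed = s)
    ex <- generate_experiment(cfg)
    i <- which(ex$truth$pattern == "+++")
    ex$counts$counts[i, "ETH1"] / ex$truth$baseline_mean[i]
  }, 0)
  # ETH1 counts are Poisson(4 * mu0): their mean over replicates, scaled
  # by mu0, estimates the planted ratio 4
  se <- sd(ratios) / sqrt(nrep)
  expect_lt(abs(mean(ratios) - 4), 3 * se)
})

test_that("planted log2 effects are recovered from deep Poisson counts", {
  cfg <- sim_config(n_genes = 2000, library_depth = 1e6, dispersion = 0,
                    planted_fractions = c("+00" = 0.05, "-0-" = 0.05),
                    effect_log2fc = 3, seed = 17)
  ex <- generate_experiment(cfg)
  planted <- ex$truth$pattern != "null" & ex$truth$baseline_mean >= 100
  obs <- log2(ex$counts$counts[planted, "ETH1"] /
                ex$counts$counts[planted, "CK1"])
  err <- obs - ex$truth$lfc1[planted]
  expect_lt(abs(mean(err)), 0.2)
  expect_lt(median(abs(err)), 0.2)
})

test_that("control drift lands only on null genes in CK1-CK3", {
  cfg <- sim_config(n_genes = 1000, library_depth = 2e5,
                    control_drift_fraction = 0.1, seed = 23)
  ex <- generate_experiment(cfg)
  expect_true(all(ex$truth$pattern[ex$truth$drift] == "null"))
  expect_gt(sum(ex$truth$drift), 0)
  # drift is cumulative from its onset
  d <- ex$truth[ex$truth$drift, ]
  started <- d$drift1 != 0
  expect_true(all(d$drift2[started] == d$drift1[started]))
})

test_that("annotation maps honour sizes, enrichment strength and errors", {
  cfg <- sim_config(n_genes = 500, library_depth = 1e5,
                    planted_fractions = c("+00" = 0.2),
                    annotation = list(n_terms = 30,
                                      term_size_range = c(5, 40),
                                      n_enriched_terms = 4,
                                      enrichment_strength = 1),
                    seed = 8)
  ex <- generate_experiment(cfg)
  annot <- generate_annotation(cfg, ex$truth, "KEGG-like")
  sizes <- table(annot$term_id)
  expect_true(all(sizes >= 5 & sizes <= 40))
  expect_equal(attr(annot, "vocabulary"), "KEGG-like")
  # maximal strength: enriched terms drawn entirely from planted genes
  nonnull <- ex$truth$gene_id[ex$truth$pattern != "null"]
  for (tm in attr(annot, "enriched_terms"))
    expect_true(all(annot$gene_id[annot$term_id == tm] %in% nonnull))

  # no enrichment planted: term membership is exchangeable with null genes
  cfg0 <- sim_config(n_genes = 500, library_depth = 1e5,
                     planted_fractions = c("+00" = 0.2),
                     annotation = list(n_terms = 30,
                                       term_size_range = c(5, 40),
                                       n_enriched_terms = 0,
                                       enrichment_strength = 0.5),
                     seed = 8)
  annot0 <- generate_annotation(cfg0, ex$truth, "GO-like")
  expect_length(attr(annot0, "enriched_terms"), 0)
  frac_nonnull <- mean(annot0$gene_id %in% nonnull)
  expect_lt(abs(frac_nonnull - 0.2), 0.07)

  cfg_bad <- sim_config(n_genes = 20, library_depth = 1e4,
                        annotation = list(n_terms = 3,
                                          term_size_range = c(5, 50),
                                          n_enriched_terms = 0,
                                          enrichment_strength = 0.5))
  ex_bad <- generate_experiment(cfg_bad)
  expect_error(generate_annotation(cfg_bad, ex_bad$truth), "exceeds")
})

test_that("Ct tables encode planted effects as cycle shifts", {
  cfg <- sim_config(n_genes = 100, library_depth = 1e4,
                    planted_fractions = c("+00" = 0.3, "0-0" = 0.2),
                    effect_log2fc = 2, seed = 13)
  ex <- generate_experiment(cfg)
  ct <- generate_ct_table(ex$truth, n_target_genes = 10, noise_sd = 0,
                          seed = 5)
  tg <- attr(ct, "targets")
  for (g in tg) {
    truth <- ex$truth[ex$truth$gene_id == g, ]
    cts <- ct[ct$gene_id == g & ct$replicate == 1, ]
    base <- cts$ct[cts$sample == "0d"]
    # +2 log2 units at day 1 shows as a Ct exactly 2 cycles below 0 d
    expect_equal(cts$ct[cts$sample == "1d"], base - truth$lfc1)
    expect_equal(cts$ct[cts$sample == "2d"], base - truth$lfc2)
  }
  # references constant at zero noise
  refs <- ct[ct$is_reference, ]
  expect_equal(length(unique(refs$ct[refs$gene_id == "EF1a"])), 1L)
  expect_error(generate_ct_table(ex$truth, 10, noise_sd = -1), "noise")
  expect_error(generate_ct_table(ex$truth, 1e4), "exceeds")
})

test_that("the delta-delta-Ct pipeline recovers planted directions", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 300, library_depth = 1e5,
                      planted_fractions = c("+00" = 0.1, "-00" = 0.1,
                                            "+++" = 0.05, "---" = 0.05),
                      effect_log2fc = 3, seed = 400 + s)
    ex <- generate_experiment(cfg)
    ct <- generate_ct_table(ex$truth, n_target_genes = 41, noise_sd = 0.2,
                            seed = 400 + s)
    re <- delta_delta_ct(ct)
    tg <- attr(ct, "targets")
    ok <- vapply(tg, function(g) {
      want <- ex$truth$lfc1[ex$truth$gene_id == g]
      got <- re$re[re$gene_id == g & re$sample == "1d"]
      if (want > 0) got > 1.5 else if (want < 0) got < 1 / 1.5
      else got < 1.5 && got > 1 / 1.5
    }, logical(1))
    mean(ok)
  }, 0)
  expect_gte(mean(hits), 0.95)
})
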