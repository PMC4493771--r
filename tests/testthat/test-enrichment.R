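test_that("hypergeometric enrichment matches combinatorial ground truth", {
  genes <- sprintf("g%02d", 1:20)
  term <- data.frame(term_id = "T1", gene_id = genes[1:5])
  study <- genes[1:5]
  r <- hypergeom_enrich(study, genes, term)
  # all 5 study genes in a 5-gene term from a 20-gene universe
  expect_equal(r$pvalue, 1 / choose(20, 5))
  # exhaustive enumeration of every 5-subset of the background
  subsets <- combn(20, 5)
  k_obs <- colSums(subsets <= 5)
  expect_equal(r$pvalue, mean(k_obs >= 5))
  expect_equal(as.data.frame(r)[, c("k", "K", "n", "N")],
               data.frame(k = 5L, K = 5L, n = 5L, N = 20L))

  # term covering the whole background is never enriched
  all_term <- data.frame(term_id = "T2", gene_id = genes)
  r2 <- hypergeom_enrich(genes[3:9], genes, all_term)
  expect_equal(r2$pvalue, 1)
  expect_false(r2$significant)

  expect_error(hypergeom_enrich(character(0), genes, term), "non-empty")
  expect_error(hypergeom_enrich(c(study, "zz"), genes, term), "subset")
  expect_warning(
    hypergeom_enrich(study, genes,
                     data.frame(term_id = "T1",
                                gene_id = c(genes[1:5], "alien"))),
    "dropped")
})

test_that("annotation tables round-trip with their vocabulary header", {
  annot <- data.frame(term_id = c("GO:1", "GO:1", "GO:2"),
                      gene_id = c("A", "B", "A"))
  attr(annot, "vocabulary") <- "GO-like"
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation(annot, path)
  back <- load_annotation(path)
  expect_equal(attr(back, "vocabulary"), "GO-like")
  expect_equal(back$term_id, annot$term_id)
  expect_equal(back$gene_id, annot$gene_id)
  expect_error(load_annotation(withr::local_tempfile(lines = "a\tb")),
               "term_id")
})

test_that("null study sets give approximately uniform p-values", {
  set.seed(31)
  ks <- vapply(1:10, function(i) {
    genes <- sprintf("g%04d", 1:1000)
    annot <- do.call(rbind, lapply(1:500, function(t)
      data.frame(term_id = sprintf("T%03d", t),
                 gene_id = sample(genes, sample(50:200, 1)))))
    study <- sample(genes, 250)
    r <- suppressWarnings(hypergeom_enrich(study, genes, annot))
    as.numeric(suppressWarnings(
      stats::ks.test(r$pvalue, "punif"))$statistic)
  }, 0)
  expect_lt(median(ks), 0.1)
})

test_that("storey q-values scale BH by the null proportion", {
  set.seed(32)
  p <- c(runif(80), runif(20)^6)
  q <- storey_qvalue(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(q <= bh_fdr(p) + 1e-12))
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  expect_equal(q, pmin(1, pi0 * bh_fdr(p)))
})

test_that("candidate screening is the union of the two significant branches", {
  resp <- c("A", "B", "C", "D")
  mk_res <- function(terms, sig) {
    data.frame(term_id = terms, k = 1L, K = 2L, n = 2L, N = 10L,
               pvalue = 0.01, adjusted = ifelse(sig, 0.01, 0.5),
               significant = sig)
  }
  annot_go <- data.frame(term_id = c("T1", "T1", "T2"),
                         gene_id = c("A", "B", "E"))
  annot_kegg <- data.frame(term_id = c("P1", "P1", "P2"),
                           gene_id = c("B", "C", "D"))
  cs <- select_candidates(mk_res("T1", TRUE), mk_res(c("P1", "P2"),
                                                     c(TRUE, FALSE)),
                          annot_go, annot_kegg, resp)
  expect_equal(cs$go_branch, c("A", "B"))
  expect_equal(cs$kegg_branch, c("B", "C"))
  expect_equal(cs$candidates, c("A", "B", "C"))
  expect_equal(unname(cs$sizes), c(2L, 2L, 1L, 3L))
  # inclusion-exclusion holds exactly
  expect_equal(cs$sizes[["union"]],
               cs$sizes[["go"]] + cs$sizes[["kegg"]] -
                 cs$sizes[["intersection"]])

  # no significant terms: empty candidate set
  cs0 <- select_candidates(mk_res("T1", FALSE), mk_res("P1", FALSE),
                           annot_go, annot_kegg, resp)
  expect_length(cs0$candidates, 0)
})

test_that("candidate sets match a brute-force union over random fixtures", {
  set.seed(33)
  for (i in 1:10) {
    genes <- sprintf("g%02d", 1:50)
    resp <- sample(genes, 25)
    annot <- function(pfx, nt) data.frame(
      term_id = sample(sprintf("%s%d", pfx, 1:nt), 120, replace = TRUE),
      gene_id = sample(genes, 120, replace = TRUE))
    ag <- annot("T", 8); ak <- annot("P", 6)
    rg <- suppressWarnings(hypergeom_enrich(resp, genes, ag, threshold = 0.6))
    rk <- suppressWarnings(hypergeom_enrich(resp, genes, ak, threshold = 0.6))
    cs <- select_candidates(rg, rk, ag, ak, resp)
    oracle <- union(
      intersect(resp, ag$gene_id[ag$term_id %in% rg$term_id[rg$significant]]),
      intersect(resp, ak$gene_id[ak$term_id %in% rk$term_id[rk$significant]]))
    expect_setequal(cs$candidates, oracle)
    expect_true(all(cs$candidates %in% resp))
  }
})

test_that("planted enriched terms rank ahead of background terms", {
  hits <- vapply(1:10, function(s) {
    cfg <- sim_config(n_genes = 1000, library_depth = 5e5,
                      planted_fractions = c("+00" = 0.06, "---" = 0.06),
                      annotation = list(n_terms = 50,
                                        term_size_range = c(10, 60),
                                        n_enriched_terms = 5,
                                        enrichment_strength = 0.8),
                      seed = 300 + s)
    ex <- generate_experiment(cfg)
    annot <- generate_annotation(cfg, ex$truth, "GO-like")
    study <- ex$truth$gene_id[ex$truth$pattern != "null"]
    r <- suppressWarnings(
      hypergeom_enrich(study, ex$truth$gene_id, annot))
    mean(attr(annot, "enriched_terms") %in% r$term_id[1:5])
  }, 0)
  expect_gte(mean(hits), 0.9)
})
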