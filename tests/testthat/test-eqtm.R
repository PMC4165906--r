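test_that("cis pair construction is boundary-inclusive and strand-oriented", {
  ann <- data.frame(probe_id = c("cg1", "cg2", "cg3"),
                    chromosome = "chr1",
                    position = c(1100000, 1100001, 999500),
                    strand = "+", gene = "", subregion = "Intergenic",
                    tss_distance = NA, stringsAsFactors = FALSE)
  tss <- data.frame(gene = c("Gplus", "Gminus"), chromosome = "chr1",
                    tss = 1000000, strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  pairs <- build_cis_pairs(ann, tss, window = 100000)
  plus <- pairs[pairs$gene_id == "Gplus", ]
  # exactly 100,000 bp away: included; 100,001: excluded
  expect_true("cg1" %in% plus$probe_id)
  expect_false("cg2" %in% plus$probe_id)
  expect_identical(plus$tss_distance[plus$probe_id == "cg1"], 100000)
  # minus-strand gene: a CpG 3'-ward in genome coordinates is upstream
  minus <- pairs[pairs$gene_id == "Gminus", ]
  expect_identical(minus$tss_distance[minus$probe_id == "cg1"], -100000)
  expect_identical(minus$tss_distance[minus$probe_id == "cg3"], 500)
})

test_that("multiple TSS rows collapse to the nearest per (CpG, gene)", {
  ann <- data.frame(probe_id = "cg1", chromosome = "chr1", position = 5000,
                    strand = "+", gene = "", subregion = "Intergenic",
                    tss_distance = NA, stringsAsFactors = FALSE)
  tss <- data.frame(gene = "G", chromosome = "chr1", tss = c(1000, 6000),
                    strand = "+", stringsAsFactors = FALSE)
  pairs <- build_cis_pairs(ann, tss)
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$tss_distance, -1000)
})

test_that("pair correlation matches a hand-computed Pearson oracle", {
  m <- make_matrix(c(0.1, 0.3, 0.5, 0.55, 0.8), 1,
                   samples = sprintf("s%d", 1:5))
  rownames(m) <- "cg1"
  e <- make_matrix(c(2.0, 2.2, 3.1, 2.9, 4.0), 1,
                   samples = sprintf("s%d", 1:5))
  rownames(e) <- "G1"
  pairs <- data.frame(probe_id = "cg1", gene_id = "G1", tss_distance = 0)
  got <- correlate_pairs(m, e, pairs)
  want <- pearson_oracle(m[1, ], e[1, ])
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p_raw, want$p, tolerance = 1e-12)
  expect_identical(got$n_used, 5)
})

test_that("exact linear coupling gives |r| = 1 and rescaling leaves r unchanged", {
  set.seed(12)
  b <- runif(10)
  m <- make_matrix(b, 1, samples = sprintf("s%d", 1:10)); rownames(m) <- "cg1"
  e <- make_matrix(2 * b, 1, samples = sprintf("s%d", 1:10)); rownames(e) <- "G1"
  pairs <- data.frame(probe_id = "cg1", gene_id = "G1", tss_distance = 0)
  got <- correlate_pairs(m, e, pairs)
  expect_equal(got$r, 1, tolerance = 1e-12)
  expect_lt(got$p_raw, 1e-12)
  e2 <- e * 17 - 3
  expect_equal(correlate_pairs(m, e2, pairs)$r, got$r, tolerance = 1e-12)
})

test_that("independent pairs are not significant after Bonferroni at n = 104", {
  set.seed(90)
  n <- 104
  m <- matrix(rbeta(20 * n, 4, 4), 20, n,
              dimnames = list(sprintf("cg%02d", 1:20), sprintf("s%03d", 1:n)))
  e <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("G%02d", 1:20), sprintf("s%03d", 1:n)))
  pairs <- data.frame(probe_id = rownames(m), gene_id = rownames(e),
                      tss_distance = 0)
  got <- correlate_pairs(m, e, pairs)
  expect_true(all(abs(got$r) < 0.4))
  expect_identical(sum(got$significant), 0L)
  expect_identical(attr(got, "m_tests"), 20L)
  # Bonferroni p = min(1, p * m)
  expect_equal(got$p_bonferroni, pmin(1, got$p_raw * 20), tolerance = 1e-12)
})

test_that("zero-variance and missing-heavy pairs are skipped, not tested", {
  m <- matrix(c(rep(0.5, 5), runif(5)), 2, 5, byrow = TRUE,
              dimnames = list(c("cg01", "cg02"), sprintf("s%d", 1:5)))
  e <- make_matrix(rnorm(10), 2, samples = sprintf("s%d", 1:5))
  rownames(e) <- c("G1", "G2")
  pairs <- data.frame(probe_id = c("cg01", "cg02"), gene_id = c("G1", "G2"),
                      tss_distance = 0)
  expect_message(got <- correlate_pairs(m, e, pairs), "skipped")
  expect_identical(got$probe_id, "cg02")
  expect_identical(attr(got, "m_tests"), 1L)
})

test_that("region-level correlation skips absent genes and counts m correctly", {
  set.seed(41)
  n <- 20
  rm1 <- matrix(rbeta(3 * n, 4, 4), 3, n,
                dimnames = list(c("G1|TSS200", "G2|Body", "G9|Body"),
                                sprintf("s%02d", 1:n)))
  e <- matrix(rnorm(2 * n), 2, n,
              dimnames = list(c("G1", "G2"), sprintf("s%02d", 1:n)))
  e["G1", ] <- -rm1["G1|TSS200", ]  # exact negative coupling
  expect_message(got <- correlate_regions(rm1, e), "skipped 1")
  expect_identical(attr(got, "m_tests"), 2L)
  expect_false("G9|Body" %in% got$target)
  expect_equal(got$r[got$target == "G1|TSS200"], -1, tolerance = 1e-12)
})

test_that("direction summaries count per stratum and allow overlapping gene sets", {
  res <- data.frame(
    gene_id = c("A", "A", "B", "C"),
    subregion = c("Body", "TSS200", "Body", "Body"),
    tss_distance = c(5000, -100, 800, 1200),
    r = c(0.5, -0.6, 0.4, -0.3),
    significant = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  s <- summarize_directions(res, by = "subregion")
  body <- s$strata[s$strata$stratum == "Body", ]
  expect_identical(body$n_positive, 2L)
  expect_identical(s$strata$n_negative[s$strata$stratum == "TSS200"], 1L)
  # gene A is in both direction sets
  expect_true("A" %in% s$genes_positive && "A" %in% s$genes_negative)
  # empty input: no division by zero
  s0 <- summarize_directions(res[res$r > 10, , drop = FALSE])
  expect_identical(nrow(s0$strata), 0L)
  expect_identical(s0$genes_positive, character(0))
})

test_that("planted promoter-negative / body-positive pattern is recovered", {
  co <- simulate_cohort(simulate_config(
    n_normal = 40, n_dcis = 0, n_ibc = 60, n_cpgs = 400,
    n_diff_normal_dcis = 0, n_diff_dcis_ibc = 0,
    n_eqtm = 40, n_signature = 0, seed = 19))
  pairs <- build_cis_pairs(co$annotation, co$tss)
  got <- suppressMessages(correlate_pairs(co$beta, co$expression, pairs))
  got$subregion <- co$annotation$subregion[match(got$probe_id,
                                                 co$annotation$probe_id)]
  s <- summarize_directions(got, by = "subregion")
  prom <- s$strata$stratum %in% c("TSS1500", "TSS200", "5UTR", "FirstExon")
  expect_gt(sum(s$strata$n_negative[prom]), sum(s$strata$n_positive[prom]))
  body <- s$strata$stratum %in% c("Body", "3UTR")
  expect_gt(sum(s$strata$n_positive[body]), sum(s$strata$n_negative[body]))
})
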