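# Diversity estimators, chi-square tests and the exact differentiation test.

test_that("gene diversity matches the published spectra and edge cases", {
  q <- gene_diversity(freq_spectrum(table1_queix_counts))
  expect_equal(round(q$value, 4), 0.9263)
  expect_equal(round(q$sd, 4), 0.0431)
  b <- gene_diversity(freq_spectrum(table1_bot_counts))
  expect_equal(round(b$value, 4), 0.8352)
  expect_equal(round(b$sd, 4), 0.0617)

  expect_equal(gene_diversity(freq_spectrum(c(7)))$value, 0)
  expect_equal(gene_diversity(freq_spectrum(c(1, 1, 1, 1)))$value, 1)
  expect_error(gene_diversity(freq_spectrum(c(1))), "n < 2")
})

test_that("gene diversity is invariant to relabeling and bounded", {
  set.seed(17)
  for (i in 1:25) {
    counts <- sample(1:6, sample(2:8, 1), replace = TRUE)
    g1 <- gene_diversity(freq_spectrum(counts))
    g2 <- gene_diversity(freq_spectrum(sample(counts)))
    expect_equal(g1$value, g2$value)
    expect_gte(g1$value, 0); expect_lte(g1$value, 1)
    expect_gte(g1$sd, 0)
  }
})

test_that("nucleotide diversity agrees with the brute-force pairwise oracle", {
  # two sequences differing at 1 of 318 sites
  w <- ref_window()
  m1 <- hap_motif(character(), "a", w)
  m2 <- hap_motif("16223T", "b", w)
  pi2 <- nucleotide_diversity(list(m1, m2), c(1, 1))
  expect_equal(pi2$value, 1 / 318)

  # identical sequences
  expect_equal(nucleotide_diversity(list(m1, m1), c(2, 3))$value, 0)

  # the ancient C-haplogroup subset (four resolved motifs, 12 teeth)
  b <- read_haplotype_table(fixture_path("botocudo.tsv"))
  cres <- b[vapply(b, is_resolved, TRUE)]
  motifs <- lapply(cres, function(r) r$motif)
  counts <- vapply(cres, function(r) r$count, 1L)
  est <- nucleotide_diversity(motifs, counts)
  # the frequency-weighted estimator with the n/(n-1) correction equals the
  # plain mean difference over ordered pairs of distinct individuals
  expect_equal(est$value, pi_bruteforce(motifs, counts, 318),
               tolerance = 1e-12)
  expect_equal(est$value, 2.106061 / 318, tolerance = 1e-6)

  # random spectra against the oracle (transition-only alleles so that any
  # position shared between motifs carries the same derived state)
  set.seed(23)
  ts_motif <- function(k) {
    pos <- sample(16045:16362, k)
    tr <- c(A = "G", G = "A", C = "T", T = "C")
    hap_motif(vapply(pos, function(p) paste0(p, tr[[ref_base(p)]]), ""))
  }
  for (i in 1:5) {
    ms <- lapply(1:4, function(j) ts_motif(sample(0:5, 1)))
    cs <- sample(1:3, 4, replace = TRUE)
    est <- nucleotide_diversity(ms, cs)
    expect_equal(est$value, pi_bruteforce(ms, cs, 318), tolerance = 1e-12)
  }

  expect_error(nucleotide_diversity(list(m1, NULL), c(1, 1)), "unresolved")
})

test_that("haplogroup_table reproduces the published percentages", {
  q <- read_haplotype_table(fixture_path("queix.tsv"))
  calls <- classify_records(q)
  tab <- haplogroup_table(list(QUEIX = calls), list(QUEIX = q))
  expect_equal(tab$table["QUEIX", c("B", "C", "D")],
               c(B = 4L, C = 14L, D = 2L))
  expect_equal(tab$percent["QUEIX", c("B", "C", "D")],
               c(B = 20.0, C = 70.0, D = 10.0))
  # MGNE printed counts
  mg <- mgne_haplogroup_counts()
  expect_equal(round(100 * mg / sum(mg), 1),
               c(A = 37.5, B = 29.2, C = 16.7, D = 16.7))
})

test_that("pearson_chi2 reproduces the published statistic and decomposes", {
  tab <- rbind(QUEIX = c(0, 4, 14, 2), MGNE = c(9, 7, 4, 4))
  out <- pearson_chi2(tab)
  expect_equal(signif(out$statistic, 3), 15.8)
  expect_equal(out$statistic, sum(out$contributions))
  expect_equal(out$df, 3L)

  # table equal to its expectation
  eq <- rbind(c(10, 20), c(10, 20))
  expect_equal(pearson_chi2(eq)$statistic, 0)
  # hand-calculated 2x2
  expect_equal(pearson_chi2(rbind(c(10, 0), c(0, 10)))$statistic, 20)
  expect_error(pearson_chi2(rbind(c(0, 0), c(1, 2))), "degenerate")
  expect_error(pearson_chi2(matrix(1:2, 1)), "2x2")
})

test_that("mc_chi2_pvalue is reproducible and add-one corrected", {
  tab <- rbind(c(0, 4, 14, 2), c(9, 7, 4, 4))
  r1 <- mc_chi2_pvalue(tab, 2000L, seed = 7L)
  r2 <- mc_chi2_pvalue(tab, 2000L, seed = 7L)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)                  # never exactly zero
  expect_lt(r1$p, 0.01)
  expect_equal(r1$replicates, 2000L)
  expect_equal(r1$seed, 7L)
  # expectation-shaped table: p near 1
  eq <- rbind(c(10, 20), c(10, 20))
  expect_gt(mc_chi2_pvalue(eq, 500L, seed = 3L)$p, 0.5)
  expect_error(mc_chi2_pvalue(tab, 100L), "seed")
})

test_that("exact test equals the hypergeometric criterion on 2x2 tables", {
  set.seed(41)
  for (i in 1:12) {
    a <- c(x = sample(0:8, 1), y = sample(1:8, 1))
    b <- c(x = sample(1:8, 1), y = sample(0:8, 1))
    if (sum(a) == 0 || sum(b) == 0) next
    p_pkg <- exact_differentiation_test(freq_spectrum(a),
                                        freq_spectrum(b))$p
    m <- rbind(a, b)
    if (any(colSums(m) == 0)) next
    p_fisher <- stats::fisher.test(m)$p.value
    expect_equal(p_pkg, p_fisher, tolerance = 1e-6)
  }
})

test_that("identical spectra are undifferentiated under enumeration", {
  s <- freq_spectrum(c(a = 3, b = 1, c = 4, d = 4, e = 1, f = 1))
  out <- exact_differentiation_test(s, s)
  expect_equal(out$method, "exact-rr")
  expect_equal(out$p, 1.0)
})

test_that("MCMC and enumeration agree on small 2xk tables", {
  set.seed(59)
  for (i in 1:4) {
    a <- stats::setNames(sample(0:6, 4, replace = TRUE), letters[1:4])
    b <- stats::setNames(sample(0:6, 4, replace = TRUE), letters[1:4])
    a[1] <- a[1] + 1L; b[2] <- b[2] + 1L  # both non-empty
    p_enum <- exact_differentiation_test(freq_spectrum(a),
                                         freq_spectrum(b))$p
    p_mcmc <- exact_differentiation_test(freq_spectrum(a), freq_spectrum(b),
                                         max_enumeration = 1,
                                         steps = 100000L, seed = 11L)$p
    expect_lt(abs(p_enum - p_mcmc), 0.02)
  }
  expect_error(
    exact_differentiation_test(freq_spectrum(c(a = 1)),
                               freq_spectrum(c(b = 2)),
                               max_enumeration = 1),
    "seed")
})

test_that("category mismatch is rejected for unnamed spectra", {
  expect_error(exact_differentiation_test(freq_spectrum(c(1, 2, 3)),
                                          freq_spectrum(c(1, 2))),
               "mismatch")
})
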