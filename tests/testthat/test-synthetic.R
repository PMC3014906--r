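# Synthetic-data generator: determinism, truth recovery, drift behaviour.

test_that("simulation is deterministic given parameters and seed", {
  p <- sim_params(size = 40L, generations = 8L)
  a <- simulate_matrilineal_population(p, n_sample = 20L, seed = 11L)
  b <- simulate_matrilineal_population(p, n_sample = 20L, seed = 11L)
  expect_equal(a$truth, b$truth)
  expect_equal(lapply(a$records, function(r) motif_tokens(r$motif)),
               lapply(b$records, function(r) motif_tokens(r$motif)))
  c <- simulate_matrilineal_population(p, n_sample = 20L, seed = 12L)
  expect_false(identical(a$truth$motif, c$truth$motif))
})

test_that("zero mutation rate propagates founder motifs unchanged", {
  p <- sim_params(founder_motifs = list(C = c("16223T", "16298C", "16325C",
                                              "16327T")),
                  founder_freqs = c(C = 1), mu = 0, size = 30L,
                  generations = 10L)
  out <- simulate_matrilineal_population(p, n_sample = 15L, seed = 4L)
  for (r in out$records)
    expect_equal(motif_tokens(r$motif),
                 c("16223T", "16298C", "16325C", "16327T"))
  expect_true(all(out$truth$haplogroup == "C"))
})

test_that("admixture fraction behaves at the boundaries and binomially", {
  amer <- lapply(default_hvsi_rules(), function(r) hap_motif(r$required))
  other <- list(hap_motif(c("16069T", "16126C")))   # non-Amerindian motif
  z <- simulate_admixed_samples(amer, other, 0, 30L, seed = 2L)
  expect_false(any(z$truth$amerindian))
  o <- simulate_admixed_samples(amer, other, 1, 30L, seed = 2L)
  expect_true(all(o$truth$amerindian))

  # fraction 0.27, n = 74: overall screened fraction within binomial CI
  tot <- 0L; n_seeds <- 30L
  for (s in seq_len(n_seeds)) {
    sim <- simulate_admixed_samples(amer, other, 0.27, 74L, seed = 100L + s)
    calls <- classify_records(sim$records)
    scr <- amerindian_screen(sim$records, calls)
    expect_equal(length(scr$subset), sum(sim$truth$amerindian))
    tot <- tot + sum(sim$truth$amerindian)
  }
  phat <- tot / (74 * n_seeds)
  se <- sqrt(0.27 * 0.73 / (74 * n_seeds))
  expect_lt(abs(phat - 0.27), 4 * se)
})

test_that("pedigree generator shares motifs within matrilines only", {
  pool <- lapply(1:6, function(i) random_motif(4))
  sim <- simulate_pedigree(10L, 25L, pool, seed = 77L)
  expect_length(sim$records, 25L)
  m <- build_matrilines(sim$ped)
  expect_equal(nrow(check_matriline_motifs(m, sim$records)), 0L)
  # one founder female per matriline containing sampled members
  expect_length(Filter(function(x)
    any(vapply(sim$records, function(r) r$id, "") %in% x$members), m), 10L)
})

test_that("artifact-free ancient samples round-trip to the source motif", {
  src <- list(t1 = hap_motif(c("16223T", "16298C", "16325C", "16327T"), "t1"),
              t2 = hap_motif(c("16051G", "16189C"), "t2"))
  out <- simulate_ancient_samples(src, phantom_rate = 0, dropout_frag2 = 0,
                                  seed = 6L)
  expect_equal(nrow(out$truth), 0L)
  for (lab in names(src)) {
    got <- ancient_consensus_motif(out$reads[[lab]], lab)
    expect_equal(motif_tokens(got$motif), motif_tokens(src[[lab]]))
    expect_length(got$discordant, 0L)
    expect_equal(got$covered, 15989:16410)
  }
})

test_that("injected phantoms land in the discordant set, never validated", {
  src <- stats::setNames(
    lapply(1:6, function(i) random_motif(3, label = paste0("t", i))),
    paste0("t", 1:6))
  set.seed(1)  # generator uses its own substream; this guards the fixtures
  out <- simulate_ancient_samples(src, phantom_rate = 1.2, seed = 21L)
  expect_gt(nrow(out$truth), 0L)
  for (lab in names(src)) {
    got <- ancient_consensus_motif(out$reads[[lab]], lab)
    inj <- out$truth$phantom[out$truth$tooth == lab]
    expect_true(all(inj %in% got$discordant))
    expect_false(any(inj %in% motif_tokens(got$motif)))
    # validated set equals the source motif exactly
    expect_equal(motif_tokens(got$motif), motif_tokens(src[[lab]]))
  }
})

test_that("fragment-2 dropout truncates coverage at 16251", {
  src <- list(t1 = hap_motif(c("16223T", "16298C"), "t1"))
  out <- simulate_ancient_samples(src, dropout_frag2 = 1, seed = 9L)
  got <- ancient_consensus_motif(out$reads$t1, "t1")
  expect_equal(max(got$covered), 16251L)
  # thin overlap downstream: match vs full-range references is indeterminate
  # once min_overlap exceeds the shared range
  rec <- sample_record("t1", "ANC", 1L, got$motif, covered = got$covered)
  ref <- sample_record("ref", "DB", 1L,
                       hap_motif(c("16223T", "16298C"), "ref"))
  expect_equal(exact_match(rec, list(ref), min_overlap = 250L)$status,
               "indeterminate")
  expect_equal(exact_match(rec, list(ref), min_overlap = 150L)$status,
               "found")
})

test_that("bottlenecks depress gene diversity in paired simulations", {
  n_pairs <- 30L
  lower <- 0L
  for (s in seq_len(n_pairs)) {
    flat <- sim_params(size = 60L, generations = 12L)
    bott <- sim_params(size = c(rep(60L, 3L), rep(2L, 6L), rep(60L, 3L)),
                       generations = 12L)
    d_flat <- gene_diversity(spectrum_from_records(
      simulate_matrilineal_population(flat, 40L, seed = 500L + s)$records,
      by = "motif"))
    d_bott <- gene_diversity(spectrum_from_records(
      simulate_matrilineal_population(bott, 40L, seed = 500L + s)$records,
      by = "motif"))
    if (d_bott$value < d_flat$value) lower <- lower + 1L
  }
  expect_gte(lower / n_pairs, 0.95)
})

test_that("drift variance grows as population size shrinks", {
  # haplogroup composition deviates more from founder frequencies in small
  # populations
  dev <- function(size, s) {
    p <- sim_params(size = size, generations = 10L)
    out <- simulate_matrilineal_population(p, 30L, seed = 900L + s)
    obs <- table(factor(out$truth$haplogroup,
                        levels = names(p$founder_freqs))) / 30
    sum((as.numeric(obs) - p$founder_freqs)^2)
  }
  small <- vapply(1:25, function(s) dev(10L, s), 1.0)
  big <- vapply(1:25, function(s) dev(200L, s), 1.0)
  expect_gt(mean(small), mean(big))
})

test_that("make_study_fixtures reproduces the shipped fixture files", {
  dir <- withr::local_tempdir()
  paths <- make_study_fixtures(dir)
  for (nm in names(paths)) {
    expect_identical(readLines(paths[[nm]]),
                     readLines(fixture_path(basename(paths[[nm]]))),
                     label = nm)
  }
  # and the emitted tables round-trip through core I/O
  q <- read_haplotype_table(paths[["queix"]])
  expect_equal(sum(vapply(q, function(r) r$count, 1L)), 20L)
  b <- read_haplotype_table(paths[["botocudo"]])
  expect_equal(sum(vapply(b, function(r) r$count, 1L)), 14L)
})
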