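# Core motif calling, fragment merging, strand filtering and table I/O.

test_that("reference window invariants hold", {
  w <- ref_window()
  expect_equal(w$start, 16045L)
  expect_equal(w$end, 16362L)
  expect_equal(nchar(w$sequence), 318L)
  expect_error(ref_window(16200, 16100), "end")
  expect_error(ref_window(15000, 16100), "outside")
})

test_that("sequence_to_motif identifies exactly the differing positions", {
  w <- ref_window()
  # identity
  m0 <- sequence_to_motif(w$sequence, w)
  expect_equal(nrow(m0$variants), 0L)
  expect_equal(attr(m0, "covered"), w$start:w$end)

  # applying the founder-C alleles reproduces the founder-C motif
  founder <- hap_motif(c("16223T", "16298C", "16325C", "16327T"), "C", w)
  m1 <- sequence_to_motif(motif_to_sequence(founder), w)
  expect_equal(motif_tokens(m1), c("16223T", "16298C", "16325C", "16327T"))

  # ambiguity codes are dropped from variants and coverage
  s <- motif_to_sequence(founder)
  substr(s, 1, 1) <- "N"                       # position 16045
  substr(s, 16223 - 16045 + 1, 16223 - 16045 + 1) <- "N"
  m2 <- sequence_to_motif(s, w)
  expect_equal(motif_tokens(m2), c("16298C", "16325C", "16327T"))
  expect_false(16045L %in% attr(m2, "covered"))
  expect_false(16223L %in% attr(m2, "covered"))

  expect_error(sequence_to_motif("ACGT", w), "length")
  bad <- w$sequence; substr(bad, 5, 5) <- "Z"
  expect_error(sequence_to_motif(bad, w), "IUPAC")
})

test_that("motif_to_sequence realises Table-1 style motifs", {
  w <- ref_window()
  mg37 <- hap_motif(c("16223T", "16325C", "16362C"), "MG37", w)
  s <- motif_to_sequence(mg37)
  expect_equal(sum(strsplit(s, "")[[1]] !=
                     strsplit(w$sequence, "")[[1]]), 3L)
  # full-column motif: Hamming distance equals the variant count
  all26 <- hap_motif(c("16051G", "16111T", "16113C", "16117C", "16126C",
                       "16129A", "16153A", "16166G", "16172C", "16178C",
                       "16189C", "16213A", "16217C", "16223T", "16224C",
                       "16260T", "16278T", "16287T", "16295T", "16298C",
                       "16311C", "16325C", "16327T", "16335G", "16356C",
                       "16362C"), "all", w)
  expect_equal(sum(strsplit(motif_to_sequence(all26), "")[[1]] !=
                     strsplit(w$sequence, "")[[1]]), 26L)
})

test_that("sequence_to_motif and motif_to_sequence are mutually inverse", {
  set.seed(421)
  for (i in 1:100) {
    m <- random_motif(sample(0:8, 1))
    s <- motif_to_sequence(m)
    back <- sequence_to_motif(s, m$window)
    expect_equal(motif_tokens(back, drop_polyc = FALSE),
                 motif_tokens(m, drop_polyc = FALSE))
    expect_identical(motif_to_sequence(back), s)
  }
})

test_that("variant parsing validates tokens and classifies substitutions", {
  v <- parse_variants(c("16223T", "16113C", "16166d"))
  expect_equal(v$klass, c("transition", "transversion", "indel"))
  expect_equal(v$ref, c("C", "A", "A"))
  expect_error(parse_variants("16223C"), "equals")       # ref == alt
  expect_error(parse_variants("banana"), "parse")
  expect_error(parse_variants("15000T"), "reference base")
  expect_error(hap_motif(c("16223T", "16223G")), "duplicate")
  expect_error(hap_motif("15989G"), "outside")   # embedded but off-window
  # poly-C indels are flagged and dropped from canonical tokens by default
  m <- hap_motif(c("16189C", "16183.1C"))
  expect_equal(motif_tokens(m), "16189C")
  expect_equal(motif_tokens(m, drop_polyc = FALSE), c("16183.1C", "16189C"))
})

test_that("merge_fragments builds a consensus over the two amplicons", {
  full <- ref_window(15989, 16410)
  f1 <- frag_read(15989, 16251, substr(full$sequence, 1, 16251 - 15988))
  f2 <- frag_read(16190, 16410, substr(full$sequence, 16190 - 15988,
                                       16410 - 15988), strand = "reverse")
  mg <- merge_fragments(list(f1, f2))
  expect_equal(mg$window$start, 15989L)
  expect_equal(mg$window$end, 16410L)
  expect_identical(mg$consensus, full$sequence)
  expect_equal(nrow(mg$conflicts), 0L)
  expect_equal(mg$covered, 15989:16410)

  # order invariance
  mg2 <- merge_fragments(list(f2, f1))
  expect_identical(mg2$consensus, mg$consensus)

  # duplicate reads
  mg3 <- merge_fragments(list(f1, f1))
  expect_identical(mg3$consensus, f1$bases)
  expect_equal(nrow(mg3$conflicts), 0L)

  # one disagreeing overlap position -> N + one conflict
  b2 <- f2$bases
  k <- 16200 - 16190 + 1
  substr(b2, k, k) <- setdiff(c("A", "C", "G", "T"),
                              substr(b2, k, k))[1]
  f2b <- frag_read(16190, 16410, b2)
  mg4 <- merge_fragments(list(f1, f2b))
  expect_equal(nrow(mg4$conflicts), 1L)
  expect_equal(mg4$conflicts$pos, 16200)
  expect_equal(substr(mg4$consensus, 16200 - 15988, 16200 - 15988), "N")
  expect_false(16200L %in% mg4$covered)

  # internal gap
  g1 <- frag_read(15989, 16100, substr(full$sequence, 1, 16100 - 15988))
  g2 <- frag_read(16300, 16410, substr(full$sequence, 16300 - 15988,
                                       16410 - 15988))
  expect_error(merge_fragments(list(g1, g2)), "gap")
})

test_that("strand_concordance_filter partitions the union of calls", {
  f <- c("16223T", "16298C", "16325C")
  expect_equal(strand_concordance_filter(f, f),
               list(validated = f, discordant = character()))
  r <- strand_concordance_filter(c(f, "16051G"), f)
  expect_equal(r$validated, f)
  expect_equal(r$discordant, "16051G")
  # partition property on random strand sets
  set.seed(77)
  for (i in 1:25) {
    a <- motif_tokens(random_motif(sample(0:6, 1)))
    b <- motif_tokens(random_motif(sample(0:6, 1)))
    out <- strand_concordance_filter(a, b)
    expect_setequal(c(out$validated, out$discordant), union(a, b))
    expect_length(intersect(out$validated, out$discordant), 0)
  }
  # empty inputs allowed
  expect_equal(strand_concordance_filter(character(), character()),
               list(validated = character(), discordant = character()))
})

test_that("packaged haplotype tables parse to the published counts", {
  q <- read_haplotype_table(fixture_path("queix.tsv"))
  expect_length(q, 13L)
  expect_equal(sum(vapply(q, function(r) r$count, 1L)), 20L)
  expect_true(all(vapply(q, is_resolved, TRUE)))

  b <- read_haplotype_table(fixture_path("botocudo.tsv"))
  expect_length(b, 6L)
  expect_equal(sum(vapply(b, function(r) r$count, 1L)), 14L)
  unres <- vapply(b, Negate(is_resolved), TRUE)
  expect_equal(sort(vapply(b[unres], function(r) r$id, "")),
               c("Bot05", "Bot06"))
  expect_equal(vapply(b[unres], function(r) r$haplogroup, ""), c("B", "B"))
})

test_that("haplotype tables round-trip losslessly", {
  # empty table
  p <- withr::local_tempfile(fileext = ".tsv")
  write_haplotype_table(list(), p)
  # header-only file: no rows
  expect_length(read_haplotype_table(p), 0L)

  set.seed(99)
  recs <- lapply(1:50, function(i)
    sample_record(sprintf("R%02d", i), sample(c("P1", "P2"), 1),
                  sample(1:5, 1), random_motif(sample(0:6, 1))))
  write_haplotype_table(recs, p)
  back <- read_haplotype_table(p)
  expect_length(back, 50L)
  for (i in 1:50) {
    expect_equal(back[[i]]$id, recs[[i]]$id)
    expect_equal(back[[i]]$count, recs[[i]]$count)
    expect_equal(back[[i]]$population, recs[[i]]$population)
    expect_equal(motif_tokens(back[[i]]$motif, drop_polyc = FALSE),
                 motif_tokens(recs[[i]]$motif, drop_polyc = FALSE))
  }
})

test_that("FASTA round-trips through ape", {
  p <- withr::local_tempfile(fileext = ".fasta")
  w <- ref_window()
  seqs <- c(s1 = w$sequence,
            s2 = motif_to_sequence(hap_motif("16223T", "s2", w)))
  write_fasta(seqs, p)
  back <- read_fasta(p)
  expect_equal(back, seqs)
})

test_that("malformed tables fail with line information", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("label\tpopulation\tcount\tvariants\twindow_start\twindow_end",
               "H1\tP\t1\t16223X\t16045\t16362"), p)
  expect_error(read_haplotype_table(p), "line 2")
  writeLines(c("label\tpopulation\tcount\tvariants\twindow_start\twindow_end",
               "H1\tP\t1\t15000T\t16045\t16362"), p)
  expect_error(read_haplotype_table(p), "line 2")
  writeLines(c("label\tpopulation\tcount", "H1\tP\t1"), p)
  expect_error(read_haplotype_table(p), "missing column")
})
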