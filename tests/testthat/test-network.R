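# Minimum-spanning and median-joining networks.

test_that("pairwise_distance counts the symmetric difference", {
  w <- ref_window()
  founder <- hap_motif(c("16223T", "16298C", "16325C", "16327T"), "C", w)
  bot03 <- hap_motif(c("16051G", "16223T", "16298C", "16325C", "16327T"),
                     "Bot03", w)
  mg31 <- hap_motif(c("16051G", "16172C", "16223T", "16295T", "16298C",
                      "16325C", "16327T", "16335G"), "MG31", w)
  expect_equal(pairwise_distance(founder, founder), 0)
  expect_equal(pairwise_distance(founder, bot03), 1)
  expect_equal(pairwise_distance(founder, mg31), 4)
  # weighted
  wts <- c(`16051` = 5)
  expect_equal(pairwise_distance(founder, bot03, wts), 5)
  # agrees with the sequence-level oracle on random motifs
  set.seed(3)
  for (i in 1:15) {
    ms <- random_binary_motifs(2, sample(2:8, 1))
    expect_equal(pairwise_distance(ms[[1]], ms[[2]]),
                 seq_hamming(ms[[1]], ms[[2]]))
  }
  expect_error(pairwise_distance(founder,
                                 hap_motif("16223T", window = ref_window(16045, 16300))),
               "windows differ")
})

test_that("minimum_spanning_network keeps every tie edge of some MST", {
  w <- ref_window()
  # two motifs -> single edge
  two <- minimum_spanning_network(list(hap_motif("16223T", "a", w),
                                       hap_motif("16298C", "b", w)))
  expect_equal(nrow(two$edges), 1L)
  expect_equal(two$edges$weight, 2)

  # three pairwise-equidistant motifs -> triangle kept
  tri <- minimum_spanning_network(list(hap_motif("16223T", "a", w),
                                       hap_motif("16298C", "b", w),
                                       hap_motif("16325C", "c", w)))
  expect_equal(nrow(tri$edges), 3L)

  # duplicates collapse with summed frequencies
  dup <- minimum_spanning_network(list(hap_motif("16223T", "a", w),
                                       hap_motif("16223T", "b", w)),
                                  freq = c(2L, 3L))
  expect_equal(nrow(dup$M), 1L)
  expect_equal(dup$freq, 5L)

  # agreement with exhaustive MST enumeration on random instances
  set.seed(71)
  for (i in 1:10) {
    n <- sample(3:5, 1)
    ms <- random_binary_motifs(n, sample(3:7, 1))
    net <- minimum_spanning_network(ms)
    D <- matrix(0, n, n)
    for (a in 1:n) for (b in 1:n) D[a, b] <- seq_hamming(ms[[a]], ms[[b]])
    oracle <- msn_bruteforce(D)
    got <- matrix(FALSE, n, n)
    for (r in seq_len(nrow(net$edges)))
      got[net$edges$from[r], net$edges$to[r]] <- TRUE
    got <- got | t(got)
    expect_equal(got, oracle)
  }
})

test_that("median_joining solves the three-singleton star", {
  w <- ref_window()
  ms <- list(hap_motif("16051G", "a", w), hap_motif("16126C", "b", w),
             hap_motif("16129A", "c", w))
  net <- median_joining(ms)
  expect_equal(nrow(net$M), 4L)
  expect_equal(sum(!net$sampled), 1L)
  med <- which(!net$sampled)
  expect_true(all(net$M[med, ] == 0L))          # the empty (background) motif
  expect_equal(nrow(net$edges), 3L)
  expect_true(all(net$edges$weight == 1))

  # single motif: one node, no edges
  single <- median_joining(list(hap_motif("16223T", "x", w)))
  expect_equal(nrow(single$M), 1L)
  expect_equal(nrow(single$edges), 0L)

  # multistate sites are refused
  expect_error(median_joining(list(hap_motif("16223T", "x", w),
                                   hap_motif("16223G", "y", w))),
               "multistate")
})

test_that("median-joining output always contains an MST of sampled motifs", {
  set.seed(123)
  for (i in 1:8) {
    n <- sample(3:6, 1)
    ms <- random_binary_motifs(n, sample(3:8, 1))
    net <- median_joining(ms)
    # connected
    g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                       directed = FALSE,
                                       vertices = data.frame(
                                         name = seq_len(nrow(net$M))))
    expect_true(igraph::is_connected(g))
    # every sampled motif is a node
    expect_equal(sum(net$sampled), n)
    # total length never exceeds the sampled-only MST length
    D <- matrix(0, n, n)
    for (a in 1:n) for (b in 1:n) D[a, b] <- seq_hamming(ms[[a]], ms[[b]])
    expect_lte(network_length(net), mst_bruteforce(D))
  }
})

test_that("epsilon-0 networks keep only medians on sampled shortest paths", {
  set.seed(321)
  for (i in 1:6) {
    ms <- random_binary_motifs(sample(3:5, 1), sample(3:7, 1))
    net <- median_joining(ms, epsilon = 0)
    if (!any(!net$sampled)) next
    g <- igraph::graph_from_data_frame(
      data.frame(from = net$edges$from, to = net$edges$to,
                 weight = net$edges$weight),
      directed = FALSE, vertices = data.frame(name = seq_len(nrow(net$M))))
    dm <- igraph::distances(g)
    s_idx <- which(net$sampled)
    for (x in which(!net$sampled)) {
      on_path <- any(vapply(s_idx, function(s)
        any(abs(dm[s, x] + dm[x, s_idx] - dm[s, s_idx]) < 1e-9 &
              s_idx != s), TRUE))
      expect_true(on_path)
    }
  }
})

test_that("network export round-trips nodes and edges", {
  w <- ref_window()
  ms <- list(hap_motif("16051G", "a", w), hap_motif("16126C", "b", w),
             hap_motif("16129A", "c", w))
  net <- median_joining(ms)
  base <- file.path(withr::local_tempdir(), "net")
  export_network(net, base)
  nodes <- read.delim(paste0(base, ".nodes.tsv"), stringsAsFactors = FALSE)
  edges <- read.delim(paste0(base, ".edges.tsv"), stringsAsFactors = FALSE)
  expect_equal(nrow(nodes), nrow(net$M))
  expect_equal(nrow(edges), nrow(net$edges))
  expect_equal(sum(edges$weight), sum(net$edges$weight))
  expect_equal(sum(nodes$is_median), sum(!net$sampled))
  expect_error(export_network(net, base, format = "gml2"), "unknown format")
})

test_that("the C-haplogroup figure set has the founder as internal node", {
  figs <- figure_c_motifs()
  net <- median_joining(unname(figs), freq = rep(1L, length(figs)))
  expect_true("MG27" %in% net$labels)     # founder C is a sampled node
  expect_true(is_cut_node(net, "MG27"))
  # Bot04 and MG31 collapse to one node when networked together
  b <- read_haplotype_table(fixture_path("botocudo.tsv"))
  bres <- b[vapply(b, is_resolved, TRUE)]
  joint <- c(unname(figs), lapply(bres, function(r) r$motif))
  net2 <- median_joining(joint, freq = rep(1L, length(joint)))
  expect_true(any(grepl("Bot04", net2$labels) & grepl("MG31", net2$labels)))
})
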