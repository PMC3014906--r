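# Shared test helpers: random fixture generators and independent oracles.
# Oracles deliberately avoid the code paths they check (plain loops over
# sequences / edges instead of the package's set algebra).

hvsi <- function() ref_window()

# random motif: k substitutions at distinct positions, random non-reference
# (and, unless multistate generation is allowed, transition) alleles
random_motif <- function(k, window = hvsi(), label = NA_character_) {
  pos <- sample(window$start:window$end, k)
  toks <- vapply(pos, function(p) {
    ref <- ref_base(p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    paste0(p, alt)
  }, "")
  hap_motif(toks, label = label, window = window)
}

# random binary motifs over a small shared token alphabet (biallelic sites,
# suitable for network tests)
random_binary_motifs <- function(n_motifs, n_sites, window = hvsi()) {
  pos <- sample(window$start:window$end, n_sites)
  toks <- vapply(pos, function(p) {
    ref <- ref_base(p)
    paste0(p, sample(setdiff(c("A", "C", "G", "T"), ref), 1L))
  }, "")
  repeat {
    M <- matrix(sample(0:1, n_motifs * n_sites, replace = TRUE),
                nrow = n_motifs)
    if (!anyDuplicated(apply(M, 1, paste, collapse = ""))) break
  }
  lapply(seq_len(n_motifs), function(i)
    hap_motif(toks[M[i, ] == 1L], label = paste0("m", i), window = window))
}

# oracle: Hamming distance by direct sequence comparison
seq_hamming <- function(a, b) {
  sa <- strsplit(motif_to_sequence(a), "")[[1]]
  sb <- strsplit(motif_to_sequence(b), "")[[1]]
  sum(sa != sb)
}

# oracle: nucleotide diversity by brute-force loop over all ordered pairs of
# individual sequences (expanding counts), d_ij from seq_hamming
pi_bruteforce <- function(motifs, counts, L) {
  seqs <- rep(lapply(motifs, motif_to_sequence), counts)
  n <- length(seqs)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    si <- strsplit(seqs[[i]], "")[[1]]; sj <- strsplit(seqs[[j]], "")[[1]]
    tot <- tot + sum(si != sj)
  }
  # mean over ordered pairs = sum / (n (n-1)); per site
  tot / (n * (n - 1)) / L
}

# oracle: minimum spanning tree weight by exhaustive enumeration of all
# (n-1)-edge subsets that span (n <= 6)
mst_bruteforce <- function(D) {
  n <- nrow(D)
  stopifnot(n <= 6)
  pairs <- t(utils::combn(n, 2))
  best <- Inf
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    g <- igraph::graph_from_edgelist(pairs[sel, , drop = FALSE],
                                     directed = FALSE)
    if (igraph::vcount(g) < n) next
    if (igraph::is_connected(g) &&
        igraph::ecount(g) == n - 1) {
      wt <- sum(D[pairs[sel, , drop = FALSE]])
      best <- min(best, wt)
    }
  }
  best
}

# edges present in at least one minimum spanning tree, by enumeration
msn_bruteforce <- function(D) {
  n <- nrow(D)
  pairs <- t(utils::combn(n, 2))
  best <- mst_bruteforce(D)
  keep <- matrix(FALSE, n, n)
  for (sel in utils::combn(nrow(pairs), n - 1, simplify = FALSE)) {
    e <- pairs[sel, , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) < n) next
    if (igraph::is_connected(g) && abs(sum(D[e]) - best) < 1e-9)
      keep[e] <- TRUE
  }
  keep | t(keep)
}

# median closure of a set of binary rows: all majority vectors of triples,
# iterated to closure (capped)
median_closure <- function(M, cap = 64L) {
  key <- function(x) paste(x, collapse = "")
  seen <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(M))) assign(key(M[i, ]), TRUE, seen)
  added <- TRUE
  while (added && nrow(M) < cap) {
    added <- FALSE
    trips <- utils::combn(nrow(M), 3)
    for (c0 in seq_len(ncol(trips))) {
      m <- as.integer(colSums(M[trips[, c0], , drop = FALSE]) >= 2)
      k <- key(m)
      if (is.null(seen[[k]])) {
        assign(k, TRUE, seen)
        M <- rbind(M, m)
        added <- TRUE
        if (nrow(M) >= cap) break
      }
    }
  }
  M
}

# oracle: minimum total length over MSTs of sampled rows augmented by any
# subset of their median closure
median_steiner_bruteforce <- function(M_sampled) {
  clo <- median_closure(M_sampled)
  extra <- clo[-seq_len(nrow(M_sampled)), , drop = FALSE]
  hamd <- function(A) {
    n <- nrow(A); D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      D[i, j] <- sum(A[i, ] != A[j, ])
    D
  }
  mst_w <- function(D) {
    g <- igraph::graph_from_adjacency_matrix(D, weighted = TRUE,
                                             mode = "undirected")
    sum(igraph::E(igraph::mst(g))$weight)
  }
  best <- mst_w(hamd(M_sampled))
  ne <- nrow(extra)
  if (ne > 0 && ne <= 12) {
    for (mask in seq_len(2^ne - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(ne) - 1)) > 0)
      best <- min(best, mst_w(hamd(rbind(M_sampled, extra[sel, , drop = FALSE]))))
    }
  }
  best
}

table1_queix_counts <- c(1, 1, 1, 1, 1, 3, 1, 2, 5, 1, 1, 1, 1)
table1_bot_counts <- c(3, 1, 4, 4, 1, 1)
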