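# Median-joining haplotype networks.
#
# Motifs are treated as binary vectors over the varied positions (rCRS allele
# vs one derived allele per site; multistate sites are rejected rather than
# approximated). The network is grown from the minimum-spanning network (all
# edges belonging to at least one MST, ties kept) by repeatedly adding
# majority (median) vectors of connected triplets whose connection cost is
# within epsilon of the iteration minimum, then pruned of unsampled medians
# that support no shortest path between sampled haplotypes.

#' Weighted Hamming distance between motifs
#'
#' Sum of site weights over the symmetric difference of the two variant sets
#' (poly-cytosine length variants excluded by the package convention).
#'
#' @param a,b [hap_motif()] sharing a window.
#' @param weights optional named numeric vector (position -> weight, default
#'   1 per position).
#' @return non-negative number.
#' @export
pairwise_distance <- function(a, b, weights = NULL) {
  if (!same_window(a, b)) stop("motif windows differ", call. = FALSE)
  ta <- motif_tokens(a); tb <- motif_tokens(b)
  diff <- c(setdiff(ta, tb), setdiff(tb, ta))
  if (!length(diff)) return(0)
  pos <- as.character(floor(parse_variants(diff)$pos))
  if (is.null(weights)) length(diff)
  else sum(ifelse(is.na(weights[pos]), 1, weights[pos]))
}

# ---- internal binary encoding ------------------------------------------

# Encode motifs as a binary matrix over the union of varied positions.
# Errors on multistate sites (two different derived alleles at one position).
encode_binary <- function(motifs) {
  toks <- lapply(motifs, motif_tokens)
  all_tok <- unique(unlist(toks))
  if (length(all_tok)) {
    pv <- parse_variants(all_tok)
    dup <- duplicated(floor(pv$pos))
    if (any(dup))
      stop("multistate site(s) not supported: position ",
           paste(unique(floor(pv$pos)[dup]), collapse = ", "), call. = FALSE)
    ord <- order(pv$pos)
    all_tok <- all_tok[ord]
    pos <- floor(pv$pos)[ord]
  } else pos <- integer()
  M <- matrix(0L, nrow = length(motifs), ncol = length(all_tok))
  for (i in seq_along(motifs)) M[i, match(toks[[i]], all_tok)] <- 1L
  list(M = M, tokens = all_tok, pos = pos)
}

bits_to_tokens <- function(bits, tokens) tokens[bits == 1L]
bit_key <- function(bits) paste(bits, collapse = "")

ham <- function(x, y, w) sum(w[x != y])

# Minimum-spanning network over a binary matrix: edge (i,j) is kept iff i and
# j lie in different components of the graph of all strictly shorter edges.
# Kruskal level-by-level with all ties kept; deterministic by construction.
msn_build <- function(M, w) {
  n <- nrow(M)
  out <- data.frame(from = integer(), to = integer(), weight = numeric())
  if (n <= 1L) return(out)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    D[i, j] <- D[j, i] <- ham(M[i, ], M[j, ], w)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (lev in sort(unique(D[upper.tri(D)]))) {
    pairs <- which(upper.tri(D) & abs(D - lev) < 1e-9, arr.ind = TRUE)
    sel <- apply(pairs, 1, function(ij) find(ij[1]) != find(ij[2]))
    keep <- pairs[sel, , drop = FALSE]
    if (nrow(keep)) {
      out <- rbind(out, data.frame(from = keep[, 1], to = keep[, 2],
                                   weight = lev))
      for (r in seq_len(nrow(keep))) {
        a <- find(keep[r, 1]); b <- find(keep[r, 2])
        if (a != b) parent[a] <- b
      }
    }
  }
  out
}

make_network <- function(M, tokens, labels, freq, sampled, w) {
  edges <- msn_build(M, w)
  if (nrow(edges)) {
    edges$positions <- vapply(seq_len(nrow(edges)), function(r) {
      d <- which(M[edges$from[r], ] != M[edges$to[r], ])
      paste(tokens[d], collapse = ";")
    }, "")
  } else edges$positions <- character()
  structure(list(M = M, tokens = tokens, labels = labels, freq = freq,
                 sampled = sampled, edges = edges, weights = w),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network %d nodes (%d sampled, %d median), %d edges>\n",
              nrow(x$M), sum(x$sampled), sum(!x$sampled), nrow(x$edges)))
  invisible(x)
}

#' Minimum-spanning network of haplotype motifs
#'
#' Contains every edge appearing in at least one minimum spanning tree
#' (Kruskal passes with all ties kept); duplicate motifs are collapsed with
#' summed frequencies.
#'
#' @param motifs list of [hap_motif()] sharing a window.
#' @param freq integer frequencies (default 1 each).
#' @param weights optional named site weights (position -> weight).
#' @return Object of class `haplo_network` (fields `labels`, `freq`,
#'   `sampled`, `edges`, plus the binary encoding).
#' @export
minimum_spanning_network <- function(motifs, freq = NULL, weights = NULL) {
  if (!length(motifs)) stop("at least one motif required", call. = FALSE)
  if (is.null(freq)) freq <- rep(1L, length(motifs))
  enc <- encode_binary(motifs)
  key <- apply(enc$M, 1, bit_key)
  first <- !duplicated(key)
  grp <- match(key, key[first])
  M <- enc$M[first, , drop = FALSE]
  labels <- vapply(split(seq_along(motifs), grp), function(ix)
    paste(sort(vapply(motifs[ix], function(m)
      if (is.na(m$label)) "?" else m$label, "")), collapse = "/"), "")
  fr <- as.integer(tapply(freq, grp, sum))
  w <- rep(1, ncol(M))
  if (!is.null(weights)) {
    hitw <- weights[as.character(enc$pos)]
    w <- ifelse(is.na(hitw), 1, hitw)
  }
  make_network(M, enc$tokens, unname(labels), fr, rep(TRUE, nrow(M)), w)
}

#' Median-joining network
#'
#' @param motifs list of [hap_motif()] sharing a window (binary sites).
#' @param freq integer frequencies.
#' @param epsilon non-negative cost relaxation (Network-software default 0).
#' @param weights optional named site weights.
#' @param max_iter iteration cap; exceeding it is an error reporting the
#'   node count reached.
#' @return `haplo_network`; median nodes carry labels `mv1`, `mv2`, ... and
#'   `sampled = FALSE`.
#' @export
median_joining <- function(motifs, freq = NULL, epsilon = 0,
                           weights = NULL, max_iter = 25L) {
  net <- minimum_spanning_network(motifs, freq, weights)
  M <- net$M; w <- net$weights
  labels <- net$labels; fr <- net$freq; sampled <- net$sampled
  if (ncol(M) == 0L || nrow(M) == 1L) return(net)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter)
      stop(sprintf("median-joining did not converge in %d iterations (%d nodes)",
                   max_iter, nrow(M)), call. = FALSE)
    edges <- msn_build(M, w)
    adj <- vector("list", nrow(M))
    for (r in seq_len(nrow(edges))) {
      adj[[edges$from[r]]] <- c(adj[[edges$from[r]]], edges$to[r])
      adj[[edges$to[r]]] <- c(adj[[edges$to[r]]], edges$from[r])
    }
    have <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(M))) assign(bit_key(M[i, ]), TRUE, have)
    cand <- list(); cost <- numeric()
    for (v in seq_len(nrow(M))) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      prs <- utils::combn(sort(nb), 2L)
      for (cix in seq_len(ncol(prs))) {
        u <- prs[1, cix]; t <- prs[2, cix]
        med <- as.integer((M[u, ] + M[v, ] + M[t, ]) >= 2L)
        k <- bit_key(med)
        if (!is.null(have[[k]])) next
        cst <- ham(M[u, ], med, w) + ham(M[v, ], med, w) + ham(M[t, ], med, w)
        if (is.null(cand[[k]]) || cst < cost[[k]]) {
          cand[[k]] <- med; cost[[k]] <- cst
        }
      }
    }
    if (!length(cand)) break
    cmin <- min(unlist(cost))
    add <- names(cand)[unlist(cost) <= cmin + epsilon + 1e-9]
    for (k in add) {
      M <- rbind(M, cand[[k]])
      labels <- c(labels, sprintf("mv%d", sum(!sampled) + 1L))
      fr <- c(fr, 0L); sampled <- c(sampled, FALSE)
    }
  }
  # Reduction: drop unsampled medians of degree <= 2 lying on no shortest
  # path between sampled nodes; repeat until stable.
  repeat {
    edges <- msn_build(M, w)
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$from, to = edges$to, weight = edges$weight),
      directed = FALSE, vertices = data.frame(name = seq_len(nrow(M))))
    deg <- igraph::degree(g)
    dmat <- igraph::distances(g)
    drop <- integer()
    for (x in which(!sampled)) {
      if (deg[x] > 2L) next
      s_idx <- which(sampled)
      on_path <- FALSE
      for (s in s_idx) {
        for (t in s_idx[s_idx > s]) {
          if (abs(dmat[s, x] + dmat[x, t] - dmat[s, t]) < 1e-9) {
            on_path <- TRUE; break
          }
        }
        if (on_path) break
      }
      if (!on_path) drop <- c(drop, x)
    }
    if (!length(drop)) break
    keep <- setdiff(seq_len(nrow(M)), drop)
    M <- M[keep, , drop = FALSE]
    labels <- labels[keep]; fr <- fr[keep]; sampled <- sampled[keep]
  }
  make_network(M, net$tokens, labels, fr, sampled, w)
}

#' Length of the shortest spanning structure in a network
#'
#' The minimum total weight of a tree spanning all sampled haplotypes, where
#' the network's median vectors are optional Steiner points: the minimum over
#' subsets of median nodes of the MST weight of (sampled union subset).
#' Median subsets are enumerated exactly up to 15 medians; beyond that the
#' all-node MST is returned as an upper bound.
#'
#' @param net a `haplo_network`.
#' @return numeric length.
#' @export
network_length <- function(net) {
  n <- nrow(net$M)
  if (n <= 1L) return(0)
  mst_w <- function(rows) {
    A <- net$M[rows, , drop = FALSE]
    k <- nrow(A)
    if (k <= 1L) return(0)
    D <- matrix(0, k, k)
    for (i in seq_len(k)) for (j in seq_len(k))
      D[i, j] <- ham(A[i, ], A[j, ], net$weights)
    g <- igraph::graph_from_adjacency_matrix(D, weighted = TRUE,
                                             mode = "undirected")
    sum(igraph::E(igraph::mst(g))$weight)
  }
  s_idx <- which(net$sampled)
  m_idx <- which(!net$sampled)
  if (length(m_idx) == 0L) return(mst_w(s_idx))
  if (length(m_idx) > 15L) return(mst_w(seq_len(n)))
  best <- mst_w(s_idx)
  for (mask in seq_len(2^length(m_idx) - 1)) {
    sel <- m_idx[bitwAnd(mask, 2^(seq_along(m_idx) - 1)) > 0]
    best <- min(best, mst_w(c(s_idx, sel)))
  }
  best
}

#' Export / import a network as node and edge tables
#'
#' Lossless plain-text representation: `<base>.nodes.tsv` (id, label, motif
#' tokens, frequency, is_median) and `<base>.edges.tsv` (from, to, positions,
#' weight), with deterministic node ordering.
#'
#' @param net a `haplo_network`.
#' @param base output path prefix.
#' @param format `"tsv"` (the only supported token).
#' @return `base`, invisibly.
#' @export
export_network <- function(net, base, format = "tsv") {
  if (!identical(format, "tsv"))
    stop("unknown format token: ", format, call. = FALSE)
  nodes <- data.frame(
    id = seq_len(nrow(net$M)), label = net$labels,
    motif = apply(net$M, 1, function(b)
      if (any(b == 1L)) paste(net$tokens[b == 1L], collapse = ";") else "."),
    frequency = net$freq, is_median = as.integer(!net$sampled),
    stringsAsFactors = FALSE)
  edges <- net$edges[order(net$edges$from, net$edges$to),
                     c("from", "to", "positions", "weight")]
  utils::write.table(nodes, paste0(base, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(edges, paste0(base, ".edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(base)
}

#' Is a node an internal (cut) vertex of the network?
#'
#' @param net a `haplo_network`.
#' @param label node label to test.
#' @return logical: removing the node disconnects the network.
#' @export
is_cut_node <- function(net, label) {
  idx <- which(net$labels == label)
  if (!length(idx)) stop("no node labelled ", label, call. = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$from, to = net$edges$to),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(net$M))))
  idx[1] %in% igraph::articulation_points(g)
}
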