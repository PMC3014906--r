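# Ancient-DNA fragment handling: two-amplicon consensus and strand-concordance
# filtering of phantom mutations.
#
# Ancient HVSI sequences are recovered from two overlapping amplicons
# (defaults 15989-16251 and 16190-16410), each sequenced on both strands.
# Bases supported by a single read are taken as-is; positions where reads
# disagree are reported as conflicts and set to N, never guessed. Sequencing
# artifacts ("phantom mutations") are screened by calling variants on each
# strand separately and keeping only strand-concordant calls.

#' A called sequence fragment
#'
#' @param start,end 1-based inclusive rCRS range of the read.
#' @param bases called bases (length must equal the range length).
#' @param strand `"forward"` or `"reverse"` (orientation metadata; bases are
#'   always stored in reference orientation).
#' @return An object of class `frag_read`.
#' @export
frag_read <- function(start, end, bases, strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  w <- ref_window(start, end)
  bases <- toupper(bases)
  if (nchar(bases) != window_length(w))
    stop(sprintf("fragment bases length %d != range length %d",
                 nchar(bases), window_length(w)), call. = FALSE)
  structure(list(window = w, bases = bases, strand = strand),
            class = "frag_read")
}

#' Merge overlapping fragment reads into a consensus
#'
#' Positions covered by one read take that base; positions covered by several
#' reads must agree, otherwise the position is reported as a conflict and set
#' to `N` in the consensus. The merge is invariant to the order of the reads.
#'
#' @param reads list of [frag_read()] objects whose union range is contiguous.
#' @return A list with `window` (union range), `consensus` (character string,
#'   conflicts as N), `covered` (integer positions excluding conflicts) and
#'   `conflicts` (data.frame of position and observed bases).
#' @export
merge_fragments <- function(reads) {
  if (!length(reads)) stop("at least one read required", call. = FALSE)
  stopifnot(all(vapply(reads, inherits, TRUE, "frag_read")))
  lo <- min(vapply(reads, function(r) r$window$start, 1L))
  hi <- max(vapply(reads, function(r) r$window$end, 1L))
  pos <- lo:hi
  depth <- integer(length(pos))
  for (r in reads) depth[(r$window$start:r$window$end) - lo + 1L] <-
    depth[(r$window$start:r$window$end) - lo + 1L] + 1L
  if (any(depth == 0L))
    stop("internal gap: uncovered position(s) ",
         paste(pos[depth == 0L], collapse = ", "), call. = FALSE)
  cons <- character(length(pos))
  confl_pos <- integer(); confl_obs <- character()
  obs <- vector("list", length(pos))
  for (r in reads) {
    idx <- (r$window$start:r$window$end) - lo + 1L
    b <- strsplit(r$bases, "")[[1]]
    for (k in seq_along(idx)) obs[[idx[k]]] <- c(obs[[idx[k]]], b[k])
  }
  for (k in seq_along(pos)) {
    u <- unique(obs[[k]])
    if (length(u) == 1L) cons[k] <- u
    else {
      cons[k] <- "N"
      confl_pos <- c(confl_pos, pos[k])
      confl_obs <- c(confl_obs, paste(sort(obs[[k]]), collapse = "/"))
    }
  }
  list(window = ref_window(lo, hi),
       consensus = paste(cons, collapse = ""),
       covered = pos[cons != "N"],
       conflicts = data.frame(pos = confl_pos, observed = confl_obs,
                              stringsAsFactors = FALSE))
}

#' Strand-concordance filter for phantom mutations
#'
#' Variants are accepted only when seen on both strands; strand-private calls
#' are flagged as discordant (candidate phantom mutations) and never silently
#' included. The two output sets partition the union of the inputs.
#'
#' @param forward,reverse character vectors of variant tokens called on the
#'   forward and reverse strand over the same covered range.
#' @return list with `validated` (intersection, sorted) and `discordant`
#'   (symmetric difference, sorted).
#' @export
strand_concordance_filter <- function(forward, reverse) {
  forward <- unique(as.character(forward))
  reverse <- unique(as.character(reverse))
  srt <- function(x) x[order(parse_variants(x)$pos)]
  validated <- intersect(forward, reverse)
  discordant <- setdiff(union(forward, reverse), validated)
  list(validated = if (length(validated)) srt(validated) else character(),
       discordant = if (length(discordant)) srt(discordant) else character())
}
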