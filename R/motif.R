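# Variant tokens and haplotype motifs.
#
# A variant is written in the field's compact notation: the rCRS position
# immediately followed by the derived allele ("16223T"). Deletions use the
# suffix "d" ("16166d"); insertions use position.index+base ("16193.1C").
# A haplotype motif is the canonical (position-sorted, duplicate-free) set of
# variants distinguishing one sequence from the rCRS within a window.

#' Parse variant tokens
#'
#' @param tokens character vector of tokens such as `"16051G"`, `"16166d"`
#'   (deletion) or `"16193.1C"` (insertion).
#' @return A data.frame with columns `token`, `pos` (numeric; insertions carry
#'   a fractional index), `ref`, `alt`, `klass` (transition / transversion /
#'   indel) and `polyc` (logical: length variant in the 16180-16195
#'   poly-cytosine tract).
#' @export
parse_variants <- function(tokens) {
  tokens <- as.character(tokens)
  n <- length(tokens)
  out <- data.frame(token = tokens, pos = numeric(n), ref = character(n),
                    alt = character(n), klass = character(n),
                    polyc = logical(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    tk <- toupper(trimws(tokens[i]))
    if (grepl("^[0-9]+\\.[0-9]+[ACGT]$", tk)) {          # insertion
      pos <- as.numeric(sub("^([0-9]+\\.[0-9]+).*$", "\\1", tk))
      alt <- sub("^[0-9.]+", "", tk)
      out$pos[i] <- pos; out$ref[i] <- ""; out$alt[i] <- alt
      out$klass[i] <- "indel"
    } else if (grepl("^[0-9]+D$", tk)) {                 # deletion
      pos <- as.integer(sub("D$", "", tk))
      out$pos[i] <- pos; out$ref[i] <- ref_base(pos); out$alt[i] <- "-"
      out$klass[i] <- "indel"
      tk <- paste0(pos, "d")
    } else if (grepl("^[0-9]+[ACGT]$", tk)) {            # substitution
      pos <- as.integer(sub("[ACGT]$", "", tk))
      alt <- sub("^[0-9]+", "", tk)
      ref <- ref_base(pos)
      if (ref == alt)
        stop(sprintf("variant '%s': derived allele equals rCRS reference",
                     tokens[i]), call. = FALSE)
      out$pos[i] <- pos; out$ref[i] <- ref; out$alt[i] <- alt
      out$klass[i] <- if (is_transition(ref, alt)) "transition" else "transversion"
    } else {
      stop(sprintf("cannot parse variant token '%s'", tokens[i]), call. = FALSE)
    }
    out$token[i] <- tk
    out$polyc[i] <- out$klass[i] == "indel" &&
      floor(out$pos[i]) >= 16180 && floor(out$pos[i]) <= 16195
  }
  out
}

#' Construct a haplotype motif
#'
#' @param tokens character vector of variant tokens (may be empty).
#' @param label haplotype name (e.g. `"MG33"`).
#' @param window a [ref_window()]; all variant positions must fall inside it.
#' @return An object of class `hap_motif`: fields `label`, `window`,
#'   `variants` (parsed, position-sorted data.frame).
#' @examples
#' hap_motif(c("16223T", "16298C", "16325C", "16327T"), label = "founderC")
#' @export
hap_motif <- function(tokens = character(), label = NA_character_,
                      window = ref_window()) {
  stopifnot(inherits(window, "ref_window"))
  v <- parse_variants(tokens)
  if (anyDuplicated(v$pos))
    stop("duplicate variant positions in motif: ",
         paste(v$pos[duplicated(v$pos)], collapse = ", "), call. = FALSE)
  bad <- floor(v$pos) < window$start | floor(v$pos) > window$end
  if (any(bad))
    stop("variant position(s) outside window: ",
         paste(v$token[bad], collapse = ", "), call. = FALSE)
  v <- v[order(v$pos), , drop = FALSE]
  rownames(v) <- NULL
  structure(list(label = label, window = window, variants = v),
            class = "hap_motif")
}

#' @export
print.hap_motif <- function(x, ...) {
  cat(sprintf("<hap_motif %s [%d-%d] %s>\n",
              if (is.na(x$label)) "(unnamed)" else x$label,
              x$window$start, x$window$end,
              if (nrow(x$variants)) paste(x$variants$token, collapse = " ")
              else "(reference)"))
  invisible(x)
}

#' Variant tokens of a motif
#'
#' @param motif a `hap_motif`.
#' @param drop_polyc drop poly-cytosine length variants (the default
#'   convention for classification, matching and distances).
#' @return character vector of canonical tokens.
#' @export
motif_tokens <- function(motif, drop_polyc = TRUE) {
  v <- motif$variants
  if (drop_polyc) v <- v[!v$polyc, , drop = FALSE]
  v$token
}

same_window <- function(a, b)
  a$window$start == b$window$start && a$window$end == b$window$end

#' Call a haplotype motif from a sequence
#'
#' Compares a called sequence against the rCRS over a window and returns the
#' positions where it differs. IUPAC ambiguity codes (including N) are
#' excluded both from the variant set and from the covered positions, which
#' are attached as attribute `"covered"`.
#'
#' @param seq single character string, same length as the window.
#' @param window a [ref_window()].
#' @param label optional haplotype label.
#' @return A `hap_motif`; `attr(, "covered")` holds the rCRS positions with
#'   unambiguous data.
#' @export
sequence_to_motif <- function(seq, window = ref_window(), label = NA_character_) {
  stopifnot(length(seq) == 1L)
  seq <- toupper(seq)
  L <- window_length(window)
  if (nchar(seq) != L)
    stop(sprintf("sequence length %d does not match window length %d",
                 nchar(seq), L), call. = FALSE)
  obs <- strsplit(seq, "")[[1]]
  if (!all(obs %in% .IUPAC))
    stop("non-IUPAC character(s) in sequence: ",
         paste(unique(obs[!obs %in% .IUPAC]), collapse = ", "), call. = FALSE)
  refs <- strsplit(window$sequence, "")[[1]]
  pos <- window$start:window$end
  unambig <- obs %in% c("A", "C", "G", "T")
  diffs <- unambig & obs != refs
  m <- hap_motif(paste0(pos[diffs], obs[diffs]), label = label, window = window)
  attr(m, "covered") <- pos[unambig]
  m
}

#' Realise a motif as a sequence
#'
#' Applies a motif's substitutions to the rCRS window; the inverse of
#' [sequence_to_motif()] on indel-free motifs.
#'
#' @param motif a `hap_motif` without indel variants.
#' @return Character string of the window's length.
#' @export
motif_to_sequence <- function(motif) {
  stopifnot(inherits(motif, "hap_motif"))
  v <- motif$variants
  if (any(v$klass == "indel"))
    stop("motif contains indel variants; cannot realise as fixed-length sequence",
         call. = FALSE)
  if (nrow(v) && any(v$ref != ref_base(v$pos)))
    stop("variant reference allele inconsistent with rCRS", call. = FALSE)
  s <- strsplit(motif$window$sequence, "")[[1]]
  idx <- as.integer(v$pos) - motif$window$start + 1L
  s[idx] <- v$alt
  paste(s, collapse = "")
}
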