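# Sample records and frequency spectra.

#' A sampled individual (or collapsed haplotype row)
#'
#' The unit moved through the pipeline: an individual or a haplotype-table row
#' with a multiplicity, carrying a motif (possibly unresolved), the positions
#' actually covered by data, and optional per-strand calls.
#'
#' @param id sample / haplotype identifier.
#' @param population population label (e.g. `"QUEIX"`, `"MGNE"`, `"BOT"`).
#' @param count positive integer multiplicity (Table-1 style "number of
#'   samples").
#' @param motif a [hap_motif()] or `NULL` for an unresolved (withheld)
#'   sequence.
#' @param haplogroup optional reported haplogroup label (used for spectra of
#'   unresolved records).
#' @param covered integer vector of covered rCRS positions; defaults to the
#'   motif's window (or the default HVSI window when unresolved).
#' @param strand_calls optional list with elements `forward` and `reverse`
#'   (variant token vectors).
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(id, population, count = 1L, motif = NULL,
                          haplogroup = NA_character_, covered = NULL,
                          strand_calls = NULL) {
  count <- as.integer(count)
  if (is.na(count) || count < 1L) stop("count must be >= 1", call. = FALSE)
  if (!is.null(motif)) {
    stopifnot(inherits(motif, "hap_motif"))
    if (is.null(covered)) {
      covered <- attr(motif, "covered")
      if (is.null(covered)) covered <- motif$window$start:motif$window$end
    }
    vpos <- as.integer(floor(motif$variants$pos))
    if (!all(vpos %in% covered))
      stop("motif variant positions not all within covered set", call. = FALSE)
  } else if (is.null(covered)) {
    covered <- integer()
  }
  structure(list(id = as.character(id), population = as.character(population),
                 count = count, motif = motif,
                 haplogroup = as.character(haplogroup),
                 covered = as.integer(covered), strand_calls = strand_calls),
            class = "sample_record")
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record %s pop=%s n=%d %s>\n", x$id, x$population,
              x$count,
              if (is.null(x$motif)) "motif=unresolved"
              else paste(motif_tokens(x$motif, drop_polyc = FALSE),
                         collapse = " ")))
  invisible(x)
}

is_resolved <- function(rec) !is.null(rec$motif)

#' Frequency spectrum of haplotypes or haplogroups in one population
#'
#' @param counts named non-negative integer vector (category -> count).
#' @param population population label.
#' @return Object of class `freq_spectrum` with `counts`, `n` and
#'   `population`.
#' @export
freq_spectrum <- function(counts, population = NA_character_) {
  keep <- counts > 0
  nm <- names(counts)
  counts <- as.integer(counts[keep])
  if (!is.null(nm)) names(counts) <- nm[keep]
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(list(population = as.character(population),
                 counts = counts, n = sum(counts)),
            class = "freq_spectrum")
}

#' Spectrum of haplotypes from sample records
#'
#' Counts records weighted by multiplicity, keyed either by haplotype label
#' (`by = "label"`, the Table-1 convention: unresolved motifs still count as
#' observed lineages) or by the motif itself (`by = "motif"`: records with
#' identical variant sets pool into one category; unresolved records are an
#' error under this keying).
#'
#' @param records list of [sample_record()].
#' @param population optional label for the spectrum.
#' @param by `"label"` or `"motif"`.
#' @return A [freq_spectrum()].
#' @export
spectrum_from_records <- function(records, population = NA_character_,
                                  by = c("label", "motif")) {
  by <- match.arg(by)
  labs <- if (by == "label") vapply(records, function(r) r$id, "")
  else {
    if (any(!vapply(records, is_resolved, TRUE)))
      stop("unresolved motifs cannot be keyed by motif", call. = FALSE)
    vapply(records, function(r)
      paste(motif_tokens(r$motif), collapse = ";"), "")
  }
  cnt <- vapply(records, function(r) r$count, 1L)
  agg <- tapply(cnt, labs, sum)
  freq_spectrum(stats::setNames(as.integer(agg), names(agg)),
                population = population)
}
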