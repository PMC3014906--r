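# Exact haplotype matching within and between sample sets and against
# reference databases, over the shared sequenced range.
#
# A match requires identity of the variant sets restricted to the overlap of
# the two records' covered ranges; below a minimum usable overlap the
# comparison is "indeterminate" rather than a claimed novelty.

restrict_tokens <- function(rec, cov) {
  tk <- motif_tokens(rec$motif)
  if (!length(tk)) return(character())
  p <- floor(parse_variants(tk)$pos)
  sort(tk[p %in% cov])
}

#' Exact match of a query against reference records
#'
#' @param query a resolved [sample_record()].
#' @param references list of [sample_record()] (unresolved ones are skipped).
#' @param min_overlap minimum number of jointly covered positions for a
#'   determinate comparison (default 250).
#' @return list of class `match_report`: `query`, `matched` (labels),
#'   `status` (`"found"`/`"novel"`/`"indeterminate"`), `shared_window`
#'   (size of the largest usable overlap).
#' @export
exact_match <- function(query, references, min_overlap = 250L) {
  if (!is_resolved(query))
    stop("query motif is unresolved", call. = FALSE)
  qcov <- query$covered
  matched <- character()
  usable <- 0L
  for (r in references) {
    if (!is_resolved(r)) next
    joint <- intersect(qcov, r$covered)
    usable <- max(usable, length(joint))
    if (length(joint) < min_overlap) next
    if (identical(restrict_tokens(query, joint), restrict_tokens(r, joint)))
      matched <- c(matched, r$id)
  }
  status <- if (length(matched)) "found"
            else if (usable >= min_overlap) "novel" else "indeterminate"
  structure(list(query = query$id, matched = matched, status = status,
                 shared_window = usable), class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("%s: %s%s\n", x$query, x$status,
              if (length(x$matched))
                paste0(" (", paste(x$matched, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Cross-population shared haplotypes
#'
#' All exact-match pairs between two sample sets, with count-weighted
#' individual tallies.
#'
#' @param pop_a,pop_b lists of [sample_record()].
#' @param min_overlap see [exact_match()].
#' @return data.frame with columns `a`, `b`, `count_a`, `count_b`.
#' @export
shared_haplotypes <- function(pop_a, pop_b, min_overlap = 250L) {
  if (!length(pop_a) || !length(pop_b))
    stop("both populations must be non-empty", call. = FALSE)
  out <- data.frame(a = character(), b = character(),
                    count_a = integer(), count_b = integer(),
                    stringsAsFactors = FALSE)
  for (ra in pop_a) {
    if (!is_resolved(ra)) next
    rep <- exact_match(ra, pop_b, min_overlap)
    for (lab in rep$matched) {
      rb <- pop_b[[which(vapply(pop_b, function(r) r$id, "") == lab)[1]]]
      out <- rbind(out, data.frame(a = ra$id, b = lab, count_a = ra$count,
                                   count_b = rb$count,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Novelty screen against a reference database
#'
#' @param queries list of [sample_record()].
#' @param database list of [sample_record()] (non-empty).
#' @param min_overlap see [exact_match()].
#' @return list with `reports` (per-query `match_report`s) and `novel`
#'   (count of queries with status `"novel"`).
#' @export
novelty_screen <- function(queries, database, min_overlap = 250L) {
  if (!length(database)) stop("database must be non-empty", call. = FALSE)
  reports <- lapply(queries, function(q)
    if (is_resolved(q)) exact_match(q, database, min_overlap)
    else structure(list(query = q$id, matched = character(),
                        status = "indeterminate", shared_window = 0L),
                   class = "match_report"))
  list(reports = reports,
       novel = sum(vapply(reports, function(r)
         identical(r$status, "novel"), TRUE)))
}

#' Contamination check against personnel profiles
#'
#' Thin wrapper over [exact_match()]: any ancient-sample motif identical to a
#' personnel HVSI profile over the usable overlap is flagged.
#'
#' @param samples list of [sample_record()] (e.g. ancient teeth).
#' @param personnel list of [sample_record()] (laboratory personnel).
#' @param min_overlap see [exact_match()].
#' @return data.frame with columns `sample`, `personnel`.
#' @export
contamination_check <- function(samples, personnel, min_overlap = 250L) {
  out <- data.frame(sample = character(), personnel = character(),
                    stringsAsFactors = FALSE)
  if (!length(personnel)) return(out)
  for (s in samples) {
    if (!is_resolved(s)) next
    rep <- exact_match(s, personnel, min_overlap)
    for (lab in rep$matched)
      out <- rbind(out, data.frame(sample = s$id, personnel = lab,
                                   stringsAsFactors = FALSE))
  }
  out
}
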