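# Matrilineal deduplication from three-generation pedigrees.
#
# Individuals sharing an unbroken maternal line carry the same mtDNA (barring
# new mutation), so population samples must keep a single representative per
# matriline. Matrilines are found by following mother links to a founder
# female; individuals with unknown mothers are their own founders (lineages
# are never merged without evidence).

#' Partition a pedigree into matrilines
#'
#' @param ped pedigree data.frame ([read_pedigree()] columns: `family`, `id`,
#'   `father`, `mother`, `sex`, `sampled`; `"0"` = unknown parent).
#' @return list of matrilines, each `list(founder, members)`; ordered by
#'   founder id. Every individual appears in exactly one matriline.
#' @export
build_matrilines <- function(ped) {
  ids <- ped$id
  if (anyDuplicated(ids))
    stop("duplicate individual id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  mother <- stats::setNames(ped$mother, ids)
  known <- mother != "0"
  miss <- setdiff(unique(mother[known]), ids)
  if (length(miss))
    stop("mother(s) referenced but absent from pedigree: ",
         paste(miss, collapse = ", "), call. = FALSE)
  sex <- stats::setNames(ped$sex, ids)
  not_female <- unique(mother[known][sex[mother[known]] == 1L])
  if (length(not_female))
    stop("mother link(s) to male individual(s): ",
         paste(not_female, collapse = ", "), call. = FALSE)
  founder_of <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    cur <- id; seen <- character()
    while (mother[[cur]] != "0") {
      if (cur %in% seen)
        stop("cycle in mother links involving: ", cur, call. = FALSE)
      seen <- c(seen, cur)
      cur <- mother[[cur]]
      if (!is.na(founder_of[[cur]])) { cur <- founder_of[[cur]]; break }
    }
    founder_of[[id]] <- cur
    founder_of[seen] <- cur
  }
  split_ids <- split(ids, founder_of[ids])
  out <- lapply(sort(names(split_ids)), function(f)
    list(founder = f, members = sort(split_ids[[f]])))
  out
}

#' Select one representative per matriline
#'
#' @param matrilines output of [build_matrilines()].
#' @param records list of [sample_record()]; record ids must be pedigree ids.
#' @param policy `"lexicographic-id"` (deterministic default) or `"random"`.
#' @param seed required for the random policy.
#' @return list of selected [sample_record()], one per matriline that has at
#'   least one sampled member with data; matrilines without sampled members
#'   are skipped with a warning.
#' @export
select_representatives <- function(matrilines, records,
                                   policy = c("lexicographic-id", "random"),
                                   seed = NULL) {
  policy <- match.arg(policy)
  if (policy == "random" && is.null(seed))
    stop("random policy requires a seed", call. = FALSE)
  byid <- stats::setNames(records, vapply(records, function(r) r$id, ""))
  pick <- character()
  empty <- character()
  rng <- if (policy == "random") make_rng(seed, "select-representatives")
  for (m in matrilines) {
    cand <- sort(intersect(m$members, names(byid)))
    if (!length(cand)) { empty <- c(empty, m$founder); next }
    pick <- c(pick, if (policy == "lexicographic-id") cand[1]
              else with_rng(rng, sample(cand, 1L)))
  }
  if (length(empty))
    warning("matriline(s) without sampled members skipped: ",
            paste(empty, collapse = ", "), call. = FALSE)
  unname(byid[pick])
}

#' Check motif identity within matrilines
#'
#' Optional consistency check: members of one matriline should carry
#' identical motifs (mtDNA is matrilineally inherited).
#'
#' @param matrilines output of [build_matrilines()].
#' @param records list of [sample_record()].
#' @return data.frame of inconsistent matrilines (founder, ids); zero rows
#'   when consistent.
#' @export
check_matriline_motifs <- function(matrilines, records) {
  byid <- stats::setNames(records, vapply(records, function(r) r$id, ""))
  bad_f <- character(); bad_ids <- character()
  for (m in matrilines) {
    cand <- intersect(m$members, names(byid))
    if (length(cand) < 2L) next
    keys <- vapply(cand, function(id) {
      r <- byid[[id]]
      if (is.null(r$motif)) "?" else paste(motif_tokens(r$motif),
                                           collapse = ";")
    }, "")
    if (length(unique(keys)) > 1L) {
      bad_f <- c(bad_f, m$founder)
      bad_ids <- c(bad_ids, paste(cand, collapse = ","))
    }
  }
  data.frame(founder = bad_f, ids = bad_ids, stringsAsFactors = FALSE)
}
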