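# Multi-tier mtDNA haplogroup classification.
#
# Three evidence tiers are supported, mirroring the classical Amerindian
# screen: (1) HVSI control-region motifs, (2) an RFLP marker panel on coding
# positions (site gain/loss or the region-V 9 bp deletion), and (3) a
# coding-region minisequencing panel refining major haplogroups into the
# Amerindian branches (A2/B2/C1/D1). A combined call cross-checks the tiers.

#' Default HVSI motif rules
#'
#' Founder control-region motifs of the Native American haplogroups. Only
#' the B and C motifs are fixed by the classical literature quoted in most
#' Amerindian surveys; A and D follow the same sources and are configurable
#' via [read_motif_rules()].
#'
#' @return list of rules; each rule is `list(haplogroup, required, forbidden)`
#'   with `required`/`forbidden` character vectors of variant tokens.
#' @export
default_hvsi_rules <- function() {
  list(
    list(haplogroup = "A",
         required = c("16111T", "16223T", "16290T", "16319A", "16362C"),
         forbidden = character()),
    list(haplogroup = "B", required = c("16189C", "16217C"),
         forbidden = character()),
    list(haplogroup = "C",
         required = c("16223T", "16298C", "16325C", "16327T"),
         forbidden = character()),
    list(haplogroup = "D", required = c("16223T", "16325C", "16362C"),
         forbidden = character())
  )
}

#' Read / write HVSI motif rules
#'
#' TSV with columns `haplogroup`, `required`, `forbidden` (semicolon-separated
#' tokens, `.` for none).
#'
#' @param path file path.
#' @return list of motif rules (see [default_hvsi_rules()]).
#' @export
read_motif_rules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  lapply(seq_len(nrow(df)), function(i) {
    sp <- function(x) if (identical(trimws(x), ".") || x == "") character()
                      else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    req <- sp(df$required[i])
    if (!length(req)) stop("rule with empty required set at line ", i + 1L,
                           call. = FALSE)
    forb <- if ("forbidden" %in% names(df)) sp(df$forbidden[i]) else character()
    if (length(intersect(req, forb)))
      stop("rule required/forbidden sets overlap at line ", i + 1L,
           call. = FALSE)
    list(haplogroup = df$haplogroup[i], required = req, forbidden = forb)
  })
}

#' @rdname read_motif_rules
#' @param rules list of motif rules.
#' @export
write_motif_rules <- function(rules, path) {
  df <- do.call(rbind, lapply(rules, function(r)
    data.frame(haplogroup = r$haplogroup,
               required = paste(r$required, collapse = ";"),
               forbidden = if (length(r$forbidden))
                 paste(r$forbidden, collapse = ";") else ".",
               stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Classify a motif by HVSI rules
#'
#' A rule is a candidate when at least `length(required) - max_mismatch`
#' (and at least one) of its required variants are present in the motif and
#' no forbidden variant is. Among candidates the rule with the most required
#' variants present (the most specific supported rule) wins; a tie between
#' haplogroups yields `"unclassified"` with the ambiguity flag set. The
#' mismatch tolerance absorbs single back-mutations at rule-defining sites
#' (e.g. founder-C lineages that lost 16327T); `max_mismatch = 0` restores
#' strict containment.
#'
#' @param motif a [hap_motif()].
#' @param rules list of motif rules (default [default_hvsi_rules()]).
#' @param max_mismatch non-negative integer; per rule, capped at
#'   `length(required) - 1`.
#' @return list with `haplogroup` (label or `"unclassified"`), `rule`
#'   (winning rule or `NULL`), `score` (required variants present),
#'   `mismatches` and `ambiguous` flag.
#' @export
classify_hvsi <- function(motif, rules = default_hvsi_rules(),
                          max_mismatch = 1L) {
  stopifnot(inherits(motif, "hap_motif"), length(rules) >= 1L)
  toks <- motif_tokens(motif, drop_polyc = TRUE)
  best <- list(haplogroup = "unclassified", rule = NULL, score = -1L,
               mismatches = NA_integer_, ambiguous = FALSE)
  best_score <- -1L; tied <- FALSE
  for (r in rules) {
    if (length(intersect(r$forbidden, toks))) next
    present <- sum(r$required %in% toks)
    miss <- length(r$required) - present
    if (present == 0L || miss > min(max_mismatch, length(r$required) - 1L))
      next
    if (present > best_score) {
      best_score <- present
      best <- list(haplogroup = r$haplogroup, rule = r, score = present,
                   mismatches = miss, ambiguous = FALSE)
      tied <- FALSE
    } else if (present == best_score && r$haplogroup != best$haplogroup) {
      tied <- TRUE
    }
  }
  if (tied)
    best <- list(haplogroup = "unclassified", rule = NULL, score = best_score,
                 mismatches = NA_integer_, ambiguous = TRUE)
  best
}

#' Default RFLP marker panel
#'
#' Diagnostic coding-region restriction sites of the Native American
#' haplogroups: A = +663 HaeIII (site gain), C = -13259 HincII (loss),
#' D = -5176 AluI (loss), X = -1715 DdeI (loss); B = region-V 9 bp deletion.
#'
#' @return data.frame with columns `marker`, `haplogroup`, `site`, `enzyme`,
#'   `polarity` (`gain`/`loss`/`deletion`).
#' @export
default_rflp_markers <- function() {
  data.frame(
    marker = c("663_HaeIII", "9bp_del", "13259_HincII", "5176_AluI",
               "1715_DdeI"),
    haplogroup = c("A", "B", "C", "D", "X"),
    site = c(663L, NA, 13259L, 5176L, 1715L),
    enzyme = c("HaeIII", NA, "HincII", "AluI", "DdeI"),
    polarity = c("gain", "deletion", "loss", "loss", "loss"),
    stringsAsFactors = FALSE
  )
}

#' Type a sample from RFLP marker calls
#'
#' @param calls named character vector; names are marker ids from the panel,
#'   values are site states: `"present"`/`"absent"` for restriction sites and
#'   `"deleted"`/`"normal"` for the 9 bp region-V deletion.
#' @param markers marker panel (default [default_rflp_markers()]).
#' @return list with `haplogroup` (label or `"unclassified"`) and `conflict`
#'   flag (more than one diagnostic state observed).
#' @export
type_rflp <- function(calls, markers = default_rflp_markers()) {
  if (!length(calls)) stop("at least one marker call required", call. = FALSE)
  unknown <- setdiff(names(calls), markers$marker)
  if (length(unknown))
    stop("unknown marker id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  hit <- character()
  for (i in seq_len(nrow(markers))) {
    m <- markers$marker[i]
    if (!m %in% names(calls)) next
    state <- calls[[m]]
    diagnostic <- switch(markers$polarity[i],
                         gain = identical(state, "present"),
                         loss = identical(state, "absent"),
                         deletion = identical(state, "deleted"))
    if (isTRUE(diagnostic)) hit <- c(hit, markers$haplogroup[i])
  }
  if (length(hit) == 1L) list(haplogroup = hit, conflict = FALSE)
  else if (length(hit) == 0L) list(haplogroup = "unclassified",
                                   conflict = FALSE)
  else list(haplogroup = "unclassified", conflict = TRUE)
}

#' Default coding-region minisequencing panel
#'
#' Positions whose derived state assigns the Amerindian branches: B2
#' (11177, 3547, 4977, 6473, 9950), D1 (2092) and C (15487, 14318) which,
#' together with HVSI 16325C, specifies C1. A position is "derived" when the
#' called allele differs from the embedded rCRS ancestral base.
#'
#' @return list of rules `list(subhaplogroup, positions, hvsi_addendum)`.
#' @export
default_coding_panel <- function() {
  list(
    list(subhaplogroup = "B2",
         positions = c(11177L, 3547L, 4977L, 6473L, 9950L),
         hvsi_addendum = character()),
    list(subhaplogroup = "D1", positions = 2092L, hvsi_addendum = character()),
    list(subhaplogroup = "C1", positions = c(15487L, 14318L),
         hvsi_addendum = "16325C")
  )
}

#' Classify coding-panel (minisequencing) calls
#'
#' @param panel_calls named character vector: rCRS position -> called allele
#'   (`A`/`C`/`G`/`T`/`N`).
#' @param rules panel rules (default [default_coding_panel()]).
#' @param hvsi_motif optional [hap_motif()] used for rules carrying an HVSI
#'   addendum (e.g. C1 requires 16325C).
#' @return list with `subhaplogroup` (label or `"unknown"`) and, when
#'   unknown, `missing` listing unmet positions per candidate rule.
#' @export
classify_panel <- function(panel_calls, rules = default_coding_panel(),
                           hvsi_motif = NULL) {
  if (!length(panel_calls))
    stop("calls at one or more panel positions required", call. = FALSE)
  alleles <- toupper(as.character(panel_calls))
  if (!all(alleles %in% c("A", "C", "G", "T", "N")))
    stop("panel allele(s) outside {A,C,G,T,N}: ",
         paste(unique(alleles[!alleles %in% c("A", "C", "G", "T", "N")]),
               collapse = ", "), call. = FALSE)
  pos <- as.integer(names(panel_calls))
  derived <- !is.na(pos) & alleles != "N" & alleles != ref_base(pos)
  derived_pos <- pos[derived]
  missing <- list()
  for (r in rules) {
    unmet <- setdiff(r$positions, derived_pos)
    hvsi_ok <- !length(r$hvsi_addendum) ||
      (!is.null(hvsi_motif) &&
         all(r$hvsi_addendum %in% motif_tokens(hvsi_motif)))
    if (!length(unmet) && hvsi_ok)
      return(list(subhaplogroup = r$subhaplogroup, missing = NULL))
    if (length(unmet) < length(r$positions))
      missing[[r$subhaplogroup]] <- unmet
  }
  list(subhaplogroup = "unknown", missing = missing)
}

.SUB_TO_MAJOR <- c(A2 = "A", B2 = "B", C1 = "C", D1 = "D",
                   A = "A", B = "B", C = "C", D = "D", X = "X")

#' Combine evidence tiers into one haplogroup call
#'
#' Tiers that agree at the major-haplogroup level are combined at the finest
#' available resolution (a panel sub-haplogroup such as C1 refines an HVSI or
#' RFLP C). Any contradiction between two tiers yields `"unclassified"` with
#' `concordant = FALSE`. The combined call is never finer than its evidence.
#'
#' @param hvsi,rflp,panel tier labels (character) or `NA` when the tier was
#'   not run; `"unclassified"`/`"unknown"` count as absent evidence.
#' @param id sample identifier carried into the call.
#' @return list of class `haplogroup_call`: `id`, `tiers`, `final`,
#'   `concordant`, `trace` (labels of contributing tiers).
#' @export
combined_call <- function(hvsi = NA_character_, rflp = NA_character_,
                          panel = NA_character_, id = NA_character_) {
  tiers <- c(hvsi = hvsi, rflp = rflp, panel = panel)
  informative <- !is.na(tiers) & !tiers %in% c("unclassified", "unknown")
  if (!any(!is.na(tiers)))
    stop("at least one tier must be available", call. = FALSE)
  inf <- tiers[informative]
  if (!length(inf)) {
    final <- "unclassified"; concordant <- NA; trace <- character()
  } else {
    major <- .SUB_TO_MAJOR[inf]
    if (anyNA(major)) major[is.na(major)] <- inf[is.na(major)]
    if (length(unique(major)) > 1L) {
      final <- "unclassified"; concordant <- FALSE; trace <- character()
    } else {
      sub <- inf[inf %in% names(.SUB_TO_MAJOR)[1:4]]  # A2/B2/C1/D1
      final <- if (length(sub)) sub[[1]] else unique(unname(major))
      concordant <- TRUE
      trace <- names(inf)
    }
  }
  structure(list(id = id, tiers = tiers, final = unname(final),
                 concordant = concordant, trace = trace),
            class = "haplogroup_call")
}

#' Screen records for Amerindian matrilineages
#'
#' @param records list of [sample_record()].
#' @param calls list of `haplogroup_call` (same order as `records`).
#' @param amerindian_labels final labels counted as Amerindian.
#' @return list with `subset` (Amerindian records), `fraction` (count-weighted;
#'   `NaN` on empty input) and `counts` (per final label).
#' @export
amerindian_screen <- function(records, calls,
                              amerindian_labels = c("A", "B", "C", "D", "X",
                                                    "A2", "B2", "C1", "D1")) {
  stopifnot(length(records) == length(calls))
  if (!length(records))
    return(list(subset = list(), fraction = NaN, counts = integer()))
  finals <- vapply(calls, function(cl) cl$final, "")
  cnt <- vapply(records, function(r) r$count, 1L)
  amer <- finals %in% amerindian_labels
  list(subset = records[amer],
       fraction = sum(cnt[amer]) / sum(cnt),
       counts = tapply(cnt, finals, sum))
}

#' Classify a set of records end to end (HVSI tier)
#'
#' Convenience wrapper: HVSI-classifies every resolved record and wraps the
#' result in `haplogroup_call`s; unresolved records fall back on their
#' reported haplogroup when present.
#'
#' @param records list of [sample_record()].
#' @param rules motif rules.
#' @param max_mismatch see [classify_hvsi()].
#' @return list of `haplogroup_call`.
#' @export
classify_records <- function(records, rules = default_hvsi_rules(),
                             max_mismatch = 1L) {
  lapply(records, function(r) {
    if (is_resolved(r)) {
      hv <- classify_hvsi(r$motif, rules, max_mismatch)$haplogroup
      combined_call(hvsi = hv, id = r$id)
    } else if (!is.na(r$haplogroup)) {
      combined_call(hvsi = r$haplogroup, id = r$id)
    } else {
      combined_call(hvsi = "unclassified", id = r$id)
    }
  })
}
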