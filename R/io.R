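# Plain-text I/O: haplotype tables (Table-1 dialect), FASTA, strand-call and
# pedigree files. All tabular files are UTF-8, tab-delimited, with a header
# row. Variant columns hold semicolon-separated "16051G"-style tokens; "."
# means the reference motif (no variants) and "?" an unresolved (withheld)
# sequence.

#' Read a haplotype table
#'
#' Required columns: `label`, `population`, `count`, `variants`,
#' `window_start`, `window_end`. An optional `haplogroup` column carries the
#' reported haplogroup (kept for unresolved rows).
#'
#' @param path file path.
#' @return list of [sample_record()].
#' @export
read_haplotype_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("label", "population", "count", "variants",
            "window_start", "window_end")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("haplotype table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    line <- i + 1L  # header is line 1
    win <- tryCatch(ref_window(as.integer(df$window_start[i]),
                               as.integer(df$window_end[i])),
                    error = function(e)
                      stop(sprintf("line %d: %s", line, conditionMessage(e)),
                           call. = FALSE))
    vtok <- trimws(df$variants[i])
    motif <- if (identical(vtok, "?")) NULL else {
      toks <- if (identical(vtok, ".") || vtok == "") character()
              else strsplit(vtok, ";", fixed = TRUE)[[1]]
      tryCatch(hap_motif(trimws(toks), label = df$label[i], window = win),
               error = function(e)
                 stop(sprintf("line %d: %s", line, conditionMessage(e)),
                      call. = FALSE))
    }
    hg <- if ("haplogroup" %in% names(df)) df$haplogroup[i] else NA_character_
    out[[i]] <- sample_record(df$label[i], df$population[i],
                              as.integer(df$count[i]), motif,
                              haplogroup = hg,
                              covered = if (is.null(motif)) integer()
                                        else win$start:win$end)
  }
  out
}

#' Write a haplotype table
#'
#' @param records list of [sample_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(records, path) {
  if (!length(records)) {
    utils::write.table(
      data.frame(label = character(), population = character(),
                 count = integer(), variants = character(),
                 window_start = integer(), window_end = integer(),
                 haplogroup = character()),
      path, sep = "\t", quote = FALSE, row.names = FALSE,
      fileEncoding = "UTF-8")
    return(invisible(path))
  }
  rows <- lapply(records, function(r) {
    if (is.null(r$motif)) {
      win <- ref_window(); vtok <- "?"
    } else {
      win <- r$motif$window
      tk <- motif_tokens(r$motif, drop_polyc = FALSE)
      vtok <- if (length(tk)) paste(tk, collapse = ";") else "."
    }
    data.frame(label = r$id, population = r$population, count = r$count,
               variants = vtok, window_start = win$start,
               window_end = win$end, haplogroup = r$haplogroup,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write FASTA sequences
#'
#' Thin wrappers around ape's FASTA support; sequences are returned as a
#' named character vector of upper-case base strings (labels = sample ids).
#'
#' @param path file path.
#' @return `read_fasta`: named character vector.
#' @export
read_fasta <- function(path) {
  dna <- ape::read.FASTA(path)
  out <- vapply(as.character(dna), function(x)
    toupper(paste(x, collapse = "")), "")
  names(out) <- names(dna)
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  dna <- ape::as.DNAbin(lapply(seqs, function(s)
    strsplit(tolower(s), "")[[1]]))
  ape::write.FASTA(dna, path)
  invisible(path)
}

#' Read per-strand variant calls
#'
#' TSV with columns `id`, `strand` (`forward`/`reverse`) and `variants`
#' (semicolon-separated tokens, `.` for none).
#'
#' @param path file path.
#' @return named list: per id, a list with `forward` and `reverse` token
#'   vectors.
#' @export
read_strand_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("id", "strand", "variants")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("strand-call table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$strand %in% c("forward", "reverse")))
    stop("strand must be 'forward' or 'reverse'", call. = FALSE)
  ids <- unique(df$id)
  out <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) {
    sub <- df[df$id == id, , drop = FALSE]
    get <- function(s) {
      v <- sub$variants[sub$strand == s]
      if (!length(v) || identical(trimws(v[1]), ".")) character()
      else trimws(strsplit(v[1], ";", fixed = TRUE)[[1]])
    }
    out[[id]] <- list(forward = get("forward"), reverse = get("reverse"))
  }
  out
}

#' Read a pedigree table
#'
#' LINKAGE/PED column conventions: `family`, `id`, `father`, `mother`, `sex`
#' (1 = male, 2 = female, 0 = unknown), `sampled` (0/1); `0` denotes an
#' unknown parent.
#'
#' @param path file path.
#' @return data.frame with those columns (`sampled` logical).
#' @export
read_pedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("family", "id", "father", "mother", "sex", "sampled")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pedigree missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$sex <- as.integer(df$sex)
  df$sampled <- as.integer(df$sampled) == 1L
  df
}

#' @rdname read_pedigree
#' @param ped pedigree data.frame as returned by `read_pedigree`.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  ped$sampled <- as.integer(ped$sampled)
  utils::write.table(ped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
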