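# Embedded rCRS control-region segment and reference-window handling.
#
# Coordinates throughout the package are 1-based rCRS (NC_012920) positions,
# windows inclusive on both ends. Only the segment 15989-16410 is embedded:
# it covers the classic HVSI sequencing window (16045-16362) and the two
# overlapping ancient-DNA amplicons (15989-16251, 16190-16410).

.RCRS_START <- 15989L
.RCRS_END <- 16410L

# rCRS bases over 15989..16410, verified against the reference alleles of the
# 26 HVSI positions used by the packaged haplotype fixtures.
.RCRS_SEGMENT <- paste0(
  "CCCAAAGCTAAGATTCTAATTTAAACTATTCTCTGTTCTTTCATGGGGAAGCAGATTTGG",
  "GTACCACCCAAGTATTGACTCACCCATCAACAACCGCTATGTATTTCGTACATTACTGCC",
  "AGCCACCATGAATATTGTACGGTACCATAAATACTTGACCACCTGTAGTACATAAAAACC",
  "CAATCCACATCAAAACCCCCTCCCCATGCTTACAAGCAAGTACAGCAATCAACCCTCAAC",
  "TATCACACATCAACTGCAACTCCAAAGCCACCCCTCACCCACTAGGATACCAACAAACCT",
  "ACCCACCCTTAACAGTACATAGTACATAAAGCCATTTACCGTACATAGCACATTACAGTC",
  "AAATCCCTTCTCGTCCCCATGGATGACCCCCCTCAGATAGGGGTCCCTTGACCACCATCC",
  "TC"
)

# rCRS (ancestral) bases at the coding-region positions used by the default
# RFLP and minisequencing panels; the full coding region is not embedded.
.RCRS_CODING <- c(
  `663` = "A", `1715` = "C", `2092` = "C", `3547` = "A", `4977` = "T",
  `5176` = "A", `6473` = "C", `9950` = "T", `11177` = "C", `13259` = "G",
  `14318` = "T", `15487` = "A"
)

#' Reference window over the embedded rCRS segment
#'
#' Construct a reference window, i.e. a contiguous stretch of the revised
#' Cambridge Reference Sequence with 1-based inclusive rCRS coordinates.
#' Only windows inside the embedded segment 15989-16410 are supported.
#'
#' @param start,end 1-based inclusive rCRS positions; `end >= start`.
#' @return An object of class `ref_window` with fields `start`, `end` and
#'   `sequence` (reference bases over `[start, end]`).
#' @examples
#' w <- ref_window()         # default HVSI window 16045-16362 (318 bp)
#' nchar(w$sequence)
#' @export
ref_window <- function(start = 16045L, end = 16362L) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || end < start)
    stop("invalid window: end must be >= start", call. = FALSE)
  if (start < .RCRS_START || end > .RCRS_END)
    stop(sprintf("window [%d,%d] outside embedded rCRS segment [%d,%d]",
                 start, end, .RCRS_START, .RCRS_END), call. = FALSE)
  structure(list(start = start, end = end,
                 sequence = substr(.RCRS_SEGMENT, start - .RCRS_START + 1L,
                                   end - .RCRS_START + 1L)),
            class = "ref_window")
}

#' @export
print.ref_window <- function(x, ...) {
  cat(sprintf("<ref_window rCRS %d-%d (%d bp)>\n", x$start, x$end,
              x$end - x$start + 1L))
  invisible(x)
}

window_length <- function(w) w$end - w$start + 1L

#' Reference base at an rCRS position
#'
#' @param pos integer vector of rCRS positions within 15989-16410, or one of
#'   the embedded coding-panel positions.
#' @return Character vector of reference bases.
#' @export
ref_base <- function(pos) {
  pos <- as.integer(pos)
  out <- character(length(pos))
  inwin <- pos >= .RCRS_START & pos <= .RCRS_END
  out[inwin] <- vapply(pos[inwin], function(p)
    substr(.RCRS_SEGMENT, p - .RCRS_START + 1L, p - .RCRS_START + 1L), "")
  if (any(!inwin)) {
    key <- as.character(pos[!inwin])
    hit <- .RCRS_CODING[key]
    if (anyNA(hit))
      stop("no embedded reference base at position(s): ",
           paste(key[is.na(hit)], collapse = ", "), call. = FALSE)
    out[!inwin] <- unname(hit)
  }
  out
}

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
            "B", "D", "H", "V", "N")
.PURINES <- c("A", "G")
.PYRIMIDINES <- c("C", "T")

is_transition <- function(ref, alt) {
  (ref %in% .PURINES & alt %in% .PURINES) |
    (ref %in% .PYRIMIDINES & alt %in% .PYRIMIDINES)
}
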