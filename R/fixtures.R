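# Packaged study fixtures: the published HVSI haplotype tables for the
# Queixadinha (QUEIX) rural sample and the museum Botocudo teeth, the
# cosmopolitan-control (MGNE) haplogroup counts, the C-haplogroup network
# motif set, and a reference-database fixture reproducing the published
# found/novel match pattern. All are emitted as plain TSV by
# make_study_fixtures() and also shipped under inst/extdata/.

.FOUNDER_C <- c("16223T", "16298C", "16325C", "16327T")

table1_data <- function() {
  q <- list(
    MG18 = list(1L, "B", c("16178C", "16189C", "16217C")),
    MG22 = list(1L, "B", c("16178C", "16189C", "16217C", "16223T")),
    MG23 = list(1L, "B", c("16111T", "16178C", "16189C", "16217C")),
    MG24 = list(1L, "B", c("16117C", "16178C", "16189C", "16217C")),
    MG28 = list(1L, "C", c("16223T", "16298C", "16325C", "16327T", "16362C")),
    MG30 = list(3L, "C", c("16051G", "16217C", "16223T", "16287T", "16298C",
                           "16325C", "16327T")),
    MG31 = list(1L, "C", c("16051G", "16172C", "16223T", "16295T", "16298C",
                           "16325C", "16327T", "16335G")),
    MG32 = list(2L, "C", c("16126C", "16223T", "16298C", "16325C", "16327T")),
    MG33 = list(5L, "C", c("16166G", "16223T", "16224C", "16260T", "16298C",
                           "16325C", "16327T", "16356C")),
    MG34 = list(1L, "C", c("16113C", "16223T", "16295T", "16298C", "16311C",
                           "16325C")),
    MG36 = list(1L, "C", c("16223T", "16325C", "16327T")),
    MG37 = list(1L, "D", c("16223T", "16325C", "16362C")),
    MG39 = list(1L, "D", c("16153A", "16213A", "16223T", "16278T", "16311C",
                           "16362C"))
  )
  b <- list(
    Bot01 = list(3L, "C", .FOUNDER_C),
    Bot02 = list(1L, "C", c("16129A", .FOUNDER_C)),
    Bot03 = list(4L, "C", c("16051G", .FOUNDER_C)),
    Bot04 = list(4L, "C", c("16051G", "16172C", "16223T", "16295T", "16298C",
                            "16325C", "16327T", "16335G")),
    Bot05 = list(1L, "B", NULL),   # sequence withheld -> unresolved
    Bot06 = list(1L, "B", NULL)
  )
  list(queix = q, botocudo = b)
}

rows_to_records <- function(rows, population) {
  win <- ref_window()
  lapply(names(rows), function(lab) {
    x <- rows[[lab]]
    motif <- if (is.null(x[[3]])) NULL else hap_motif(x[[3]], lab, win)
    sample_record(lab, population, x[[1]], motif, haplogroup = x[[2]],
                  covered = if (is.null(motif)) integer()
                            else win$start:win$end)
  })
}

#' Packaged study sample sets
#'
#' @param which `"queix"` (13 rural haplotypes, 20 samples) or `"botocudo"`
#'   (6 ancient haplotypes, 14 teeth, two with withheld sequences).
#' @return list of [sample_record()].
#' @export
study_records <- function(which = c("queix", "botocudo")) {
  which <- match.arg(which)
  t1 <- table1_data()
  rows_to_records(t1[[which]], if (which == "queix") "QUEIX" else "BOT")
}

#' Published cosmopolitan-control haplogroup counts
#'
#' Amerindian matrilineages among the 100 cosmopolitan controls (MGNE):
#' haplogroup A 9, B 7, C 4, D 4.
#'
#' @return named integer vector.
#' @export
mgne_haplogroup_counts <- function()
  c(A = 9L, B = 7L, C = 4L, D = 4L)

#' Motif set of the C-haplogroup network figure
#'
#' The seven QUEIX C-haplogroup motifs plus the two cosmopolitan nodes:
#' MG27 (the founder Amerindian C motif itself) and MG29 (no published
#' motif; a SYNTHETIC founder-derived stand-in, founder C + 16304C).
#'
#' @return named list of [hap_motif()].
#' @export
figure_c_motifs <- function() {
  t1 <- table1_data()$queix
  cidx <- names(t1)[vapply(t1, function(x) x[[2]] == "C", TRUE)]
  win <- ref_window()
  out <- lapply(cidx, function(lab) hap_motif(t1[[lab]][[3]], lab, win))
  names(out) <- cidx
  out$MG27 <- hap_motif(.FOUNDER_C, "MG27", win)
  out$MG29 <- hap_motif(c(.FOUNDER_C, "16304C"), "MG29", win)  # synthetic
  out
}

#' Reference-database fixture for the novelty screen
#'
#' A small stand-in for the external multi-thousand-sequence HVSI panel,
#' reproducing the published found/novel pattern: it contains the four
#' haplogroup founder motifs and the lineages reported as already known
#' (MG28-, MG32-, MG36-, MG37- and Bot02-type), so that 9 of the 13 QUEIX
#' haplotypes screen as novel.
#'
#' @return list of [sample_record()] (population `"DB"`).
#' @export
novelty_database <- function() {
  win <- ref_window()
  mk <- function(lab, toks) sample_record(
    lab, "DB", 1L, hap_motif(toks, lab, win), covered = win$start:win$end)
  rules <- default_hvsi_rules()
  founders <- lapply(rules, function(r) mk(paste0("DB_founder_", r$haplogroup),
                                           r$required))
  t1 <- table1_data()
  known <- list(
    mk("DB_MG28_type", t1$queix$MG28[[3]]),
    mk("DB_MG32_type", t1$queix$MG32[[3]]),
    mk("DB_MG36_type", t1$queix$MG36[[3]]),
    mk("DB_MG37_type", t1$queix$MG37[[3]]),
    mk("DB_Bot02_type", t1$botocudo$Bot02[[3]])
  )
  c(founders, known)
}

#' Write the packaged fixtures to a directory
#'
#' Emits `queix.tsv`, `botocudo.tsv`, `mgne_haplogroups.tsv`,
#' `figure_c_motifs.tsv` and `novelty_db.tsv`.
#'
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
make_study_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    queix = file.path(dir, "queix.tsv"),
    botocudo = file.path(dir, "botocudo.tsv"),
    mgne = file.path(dir, "mgne_haplogroups.tsv"),
    figure = file.path(dir, "figure_c_motifs.tsv"),
    db = file.path(dir, "novelty_db.tsv")
  )
  write_haplotype_table(study_records("queix"), paths["queix"])
  write_haplotype_table(study_records("botocudo"), paths["botocudo"])
  cnts <- mgne_haplogroup_counts()
  utils::write.table(
    data.frame(haplogroup = names(cnts), count = as.integer(cnts)),
    paths["mgne"], sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  figs <- figure_c_motifs()
  fig_rec <- lapply(names(figs), function(lab)
    sample_record(lab, if (grepl("^MG2[79]$", lab)) "MGNE" else "QUEIX",
                  1L, figs[[lab]]))
  write_haplotype_table(fig_rec, paths["figure"])
  write_haplotype_table(novelty_database(), paths["db"])
  invisible(paths)
}

#' Path to a shipped fixture file
#'
#' @param file fixture file name (e.g. `"queix.tsv"`).
#' @return absolute path inside the installed package.
#' @export
fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mtlineage")
  if (p == "") stop("no packaged fixture ", file, call. = FALSE)
  p
}
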