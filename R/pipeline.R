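# Pipeline orchestration and command-line interface.
#
# Subcommands mirror the analysis stages: dedup (matriline filter), classify,
# stats, network, match, simulate, and run-all, which chains
# dedup -> classify -> stats -> network -> match on haplotype tables and
# emits a summary report. Every stage writes a machine-readable manifest
# (inputs, parameters, seed, package version); manifests contain no
# timestamps, so identical configurations produce byte-identical outputs.

log_msg <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), sprintf(...))
}

write_manifest <- function(out_dir, stage, inputs, params, seed = NA,
                           status = "ok") {
  man <- list(stage = stage, inputs = inputs, params = params,
              seed = seed, status = status,
              package = "mtlineage",
              version = as.character(utils::packageVersion("mtlineage")))
  jsonlite::write_json(man, file.path(out_dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

require_file <- function(path, what) {
  if (is.null(path) || is.na(path) || !file.exists(path))
    stop(sprintf("missing input (%s): %s", what,
                 if (is.null(path)) "<unset>" else path), call. = FALSE)
  path
}

#' Classification stage
#'
#' Reads a haplotype table, classifies every record by the HVSI tier and
#' writes a classification report TSV plus a manifest.
#'
#' @param table_path haplotype table path.
#' @param out_dir output directory.
#' @param rules_path optional motif-rules TSV; default rules otherwise.
#' @param max_mismatch see [classify_hvsi()].
#' @return path of the report, invisibly.
#' @export
stage_classify <- function(table_path, out_dir, rules_path = NULL,
                           max_mismatch = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_haplotype_table(require_file(table_path, "haplotype table"))
  rules <- if (is.null(rules_path)) default_hvsi_rules()
           else read_motif_rules(require_file(rules_path, "rules file"))
  calls <- classify_records(records, rules, max_mismatch)
  rep <- data.frame(
    sample = vapply(calls, function(x) x$id, ""),
    hvsi = vapply(calls, function(x) x$tiers[["hvsi"]], ""),
    rflp = vapply(calls, function(x) as.character(x$tiers[["rflp"]]), ""),
    panel = vapply(calls, function(x) as.character(x$tiers[["panel"]]), ""),
    final = vapply(calls, function(x) x$final, ""),
    concordant = vapply(calls, function(x) as.character(x$concordant), ""),
    trace = vapply(calls, function(x) paste(x$trace, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  out <- file.path(out_dir, "classification.tsv")
  utils::write.table(rep, out, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  write_manifest(out_dir, "classify", list(table = table_path,
                                           rules = rules_path),
                 list(max_mismatch = max_mismatch))
  invisible(out)
}

#' Matriline-deduplication stage
#'
#' @param ped_path pedigree TSV.
#' @param table_path haplotype table of sampled individuals.
#' @param out_dir output directory.
#' @param policy,seed see [select_representatives()].
#' @return path of the deduplicated haplotype table, invisibly.
#' @export
stage_dedup <- function(ped_path, table_path, out_dir,
                        policy = "lexicographic-id", seed = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ped <- read_pedigree(require_file(ped_path, "pedigree"))
  records <- read_haplotype_table(require_file(table_path, "haplotype table"))
  mats <- build_matrilines(ped)
  reps <- select_representatives(mats, records, policy = policy,
                                 seed = if (is.na(seed)) NULL else seed)
  out <- file.path(out_dir, "dedup.tsv")
  write_haplotype_table(reps, out)
  write_manifest(out_dir, "dedup", list(pedigree = ped_path,
                                        table = table_path),
                 list(policy = policy, matrilines = length(mats),
                      representatives = length(reps)), seed = seed)
  invisible(out)
}

#' Statistics stage
#'
#' Gene diversity (haplotype spectrum), nucleotide diversity over resolved
#' motifs, and a stats report TSV; every stochastic line records method,
#' seed and replicates.
#'
#' @param table_path haplotype table.
#' @param out_dir output directory.
#' @param seed integer seed for stochastic statistics.
#' @return path of the report, invisibly.
#' @export
stage_stats <- function(table_path, out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_haplotype_table(require_file(table_path, "haplotype table"))
  spec <- spectrum_from_records(records)
  gd <- gene_diversity(spec)
  res <- unname(vapply(records, is_resolved, TRUE))
  pi <- if (sum(vapply(records[res], function(r) r$count, 1L)) >= 2L) {
    if (any(!res))
      warning("unresolved motif(s) excluded from nucleotide diversity: ",
              paste(vapply(records[!res], function(r) r$id, ""),
                    collapse = ", "), call. = FALSE)
    nucleotide_diversity(lapply(records[res], function(r) r$motif),
                         vapply(records[res], function(r) r$count, 1L))
  } else NULL
  lines <- data.frame(
    statistic = c("gene_diversity", "gene_diversity_sd",
                  if (!is.null(pi)) c("nucleotide_diversity",
                                      "nucleotide_diversity_sd")),
    value = c(round(gd$value, 4), round(gd$sd, 4),
              if (!is.null(pi)) c(signif(pi$value, 6), signif(pi$sd, 6))),
    method = c(gd$method, gd$method,
               if (!is.null(pi)) c(pi$method, pi$method)),
    seed = NA, stringsAsFactors = FALSE)
  out <- file.path(out_dir, "stats.tsv")
  utils::write.table(lines, out, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  write_manifest(out_dir, "stats", list(table = table_path), list(),
                 seed = seed)
  invisible(out)
}

#' Network stage
#'
#' @param table_path haplotype table (resolved motifs only are used).
#' @param out_dir output directory.
#' @param epsilon median-joining relaxation.
#' @return base path of the exported node/edge tables, invisibly.
#' @export
stage_network <- function(table_path, out_dir, epsilon = 0) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  records <- read_haplotype_table(require_file(table_path, "haplotype table"))
  res <- records[vapply(records, is_resolved, TRUE)]
  net <- median_joining(lapply(res, function(r) r$motif),
                        freq = vapply(res, function(r) r$count, 1L),
                        epsilon = epsilon)
  base <- file.path(out_dir, "network")
  export_network(net, base)
  write_manifest(out_dir, "network", list(table = table_path),
                 list(epsilon = epsilon, nodes = nrow(net$M),
                      medians = sum(!net$sampled)))
  invisible(base)
}

#' Matching stage
#'
#' @param table_path query haplotype table.
#' @param db_path reference-database haplotype table.
#' @param out_dir output directory.
#' @param min_overlap see [exact_match()].
#' @return path of the match report, invisibly.
#' @export
stage_match <- function(table_path, db_path, out_dir, min_overlap = 250L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  queries <- read_haplotype_table(require_file(table_path, "haplotype table"))
  db <- read_haplotype_table(require_file(db_path, "database table"))
  scr <- novelty_screen(queries, db, min_overlap)
  rep <- data.frame(
    query = vapply(scr$reports, function(r) r$query, ""),
    status = vapply(scr$reports, function(r) r$status, ""),
    matched = vapply(scr$reports, function(r)
      paste(r$matched, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  out <- file.path(out_dir, "matches.tsv")
  utils::write.table(rep, out, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  write_manifest(out_dir, "match", list(table = table_path, db = db_path),
                 list(min_overlap = min_overlap, novel = scr$novel))
  invisible(out)
}

#' Simulation stage
#'
#' The packaged `"queixadinha-like"` scenario: a drifted Amerindian pool with
#' C-haplogroup excess, an admixed rural sample (27% Amerindian), a
#' three-generation pedigree over-drawing 173 samples from 74 matrilines, and
#' ancient teeth with strand artifacts.
#'
#' @param out_dir output directory.
#' @param seed integer seed (mandatory).
#' @param scenario scenario name (only `"queixadinha-like"` is packaged).
#' @return named vector of emitted file paths, invisibly.
#' @export
stage_simulate <- function(out_dir, seed, scenario = "queixadinha-like") {
  if (!identical(scenario, "queixadinha-like"))
    stop("unknown scenario: ", scenario, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  params <- sim_params(
    founder_freqs = c(A = 0, B = 0.2, C = 0.7, D = 0.1),
    size = c(rep(200L, 10L), rep(30L, 3L), rep(200L, 7L)))  # bottleneck
  pop <- simulate_matrilineal_population(params, n_sample = 74L, seed = seed)
  ped <- simulate_pedigree(74L, 173L,
                           lapply(pop$records, function(r) r$motif),
                           seed = seed)
  teeth_src <- lapply(pop$records[1:14], function(r) r$motif)
  names(teeth_src) <- sprintf("tooth%02d", 1:14)
  anc <- simulate_ancient_samples(teeth_src, phantom_rate = 0.5,
                                  dropout_frag2 = 0.1, seed = seed)
  paths <- c(population = file.path(out_dir, "sim_population.tsv"),
             truth = file.path(out_dir, "sim_truth.tsv"),
             pedigree = file.path(out_dir, "sim_pedigree.tsv"),
             sampled = file.path(out_dir, "sim_sampled.tsv"))
  write_haplotype_table(pop$records, paths["population"])
  utils::write.table(pop$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  write_pedigree(ped$ped, paths["pedigree"])
  write_haplotype_table(ped$records, paths["sampled"])
  write_manifest(out_dir, "simulate", list(),
                 list(scenario = scenario, n_population = 74L,
                      n_pedigree_sampled = 173L, n_teeth = 14L,
                      phantom_rate = 0.5, dropout_frag2 = 0.1),
                 seed = seed)
  invisible(paths)
}

#' Run the full analysis on two haplotype tables
#'
#' Chains classify -> stats -> network -> match for a target population and a
#' comparison population, computes the haplogroup contingency test, the
#' cross-population shared haplotypes, and writes a summary report.
#'
#' @param table_path target haplotype table (e.g. the rural sample).
#' @param compare_path comparison haplotype table (e.g. ancient teeth).
#' @param db_path reference database table for the novelty screen.
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param replicates Monte-Carlo replicates for the chi-square p-value.
#' @return path of the summary report, invisibly.
#' @export
run_all <- function(table_path, compare_path, db_path, out_dir, seed = 1L,
                    replicates = 10000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg("run-all: classify")
  stage_classify(table_path, out_dir)
  log_msg("run-all: stats")
  stage_stats(table_path, out_dir, seed = seed)
  log_msg("run-all: network")
  stage_network(table_path, out_dir)
  log_msg("run-all: match")
  stage_match(table_path, db_path, out_dir)

  records <- read_haplotype_table(table_path)
  comp <- read_haplotype_table(compare_path)
  calls_a <- classify_records(records)
  calls_b <- classify_records(comp)
  tabs <- haplogroup_table(
    list(target = calls_a, compare = calls_b),
    list(target = records, compare = comp))
  chi <- tryCatch(mc_chi2_pvalue(tabs$table, replicates, seed = seed),
                  error = function(e) NULL)
  shared <- shared_haplotypes(records, comp)
  gd <- gene_diversity(spectrum_from_records(records))
  sm <- c(
    sprintf("haplotypes\t%d", length(records)),
    sprintf("samples\t%d", sum(vapply(records, function(r) r$count, 1L))),
    sprintf("gene_diversity\t%.4f\t%.4f", gd$value, gd$sd),
    sprintf("haplogroup_pct_%s\t%.1f", colnames(tabs$percent),
            tabs$percent["target", ]),
    if (!is.null(chi))
      sprintf("chi2\t%.4g\tp\t%.4g\tseed\t%d\treplicates\t%d",
              chi$statistic, chi$p, seed, replicates),
    sprintf("shared_haplotypes\t%s",
            if (nrow(shared)) paste(sprintf("%s=%s(%d)", shared$a, shared$b,
                                            shared$count_b), collapse = ";")
            else "none"))
  out <- file.path(out_dir, "summary.tsv")
  writeLines(sm, out)
  write_manifest(out_dir, "run-all",
                 list(table = table_path, compare = compare_path,
                      db = db_path),
                 list(replicates = replicates), seed = seed)
  invisible(out)
}

#' Command-line entry point
#'
#' `mtl_cli(c("classify", "--table", "t.tsv", "--out-dir", "out"))` etc.
#' Subcommands: `classify`, `dedup`, `stats`, `network`, `match`,
#' `simulate`, `run-all`. Returns (invisibly) 0 on success, 1 on failure
#' (partial outputs are preserved and a failure manifest written when
#' possible).
#'
#' @param args character vector of command-line arguments.
#' @return invisible integer exit status.
#' @export
mtl_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mtlineage <classify|dedup|stats|network|match|simulate|run-all>",
    "[--table F] [--compare F] [--db F] [--pedigree F] [--rules F]",
    "[--out-dir D] [--seed N] [--epsilon E] [--min-overlap N]",
    "[--replicates N] [--policy P] [--scenario S]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(`out-dir` = "mtlineage-out", seed = "1", epsilon = "0",
              `min-overlap` = "250", replicates = "10000",
              policy = "lexicographic-id", scenario = "queixadinha-like")
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) { message("missing value for --", key)
      return(invisible(1L)) }
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  res <- tryCatch({
    ok <- switch(cmd,
      classify = stage_classify(opt$table, opt$`out-dir`, opt$rules),
      dedup = stage_dedup(opt$pedigree, opt$table, opt$`out-dir`,
                          policy = opt$policy,
                          seed = as.integer(opt$seed)),
      stats = stage_stats(opt$table, opt$`out-dir`,
                          seed = as.integer(opt$seed)),
      network = stage_network(opt$table, opt$`out-dir`,
                              epsilon = as.numeric(opt$epsilon)),
      match = stage_match(opt$table, opt$db, opt$`out-dir`,
                          min_overlap = as.integer(opt$`min-overlap`)),
      simulate = stage_simulate(opt$`out-dir`, as.integer(opt$seed),
                                scenario = opt$scenario),
      `run-all` = run_all(opt$table, opt$compare, opt$db, opt$`out-dir`,
                          seed = as.integer(opt$seed),
                          replicates = as.integer(opt$replicates)),
      { message("unknown subcommand: ", cmd); message(usage); NULL })
    if (is.null(ok)) 1L else 0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    try(write_manifest(opt$`out-dir`, paste0(cmd, "-failed"), list(),
                       list(error = conditionMessage(e)), status = "failed"),
        silent = TRUE)
    1L
  })
  invisible(res)
}
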