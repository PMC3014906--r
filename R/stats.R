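# Population statistics: Nei gene (haplotype) diversity with sampling
# variance, nucleotide diversity, haplogroup contingency tables, Pearson and
# Monte-Carlo chi-square, and the Raymond-Rousset exact test of population
# differentiation.

#' Gene (haplotype) diversity with Nei's sampling variance
#'
#' Unbiased gene diversity \eqn{\hat H = n(1 - \sum p_i^2)/(n-1)} and the
#' standard deviation from Nei's (1987) sampling variance
#' \deqn{V(\hat H) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   (\sum p_i^2)^2\right] + \sum p_i^2 - (\sum p_i^2)^2\right\}.}
#'
#' @param spectrum a [freq_spectrum()] (or bare count vector) with `n >= 2`.
#' @return list of class `diversity_estimate`: `value`, `sd`, `n`, `method`.
#' @examples
#' gene_diversity(freq_spectrum(c(3, 1, 4, 4, 1, 1)))  # 0.8352 +/- 0.0617
#' @export
gene_diversity <- function(spectrum) {
  counts <- if (inherits(spectrum, "freq_spectrum")) spectrum$counts
            else as.integer(spectrum)
  n <- sum(counts)
  if (n < 2L) stop("gene diversity undefined for n < 2", call. = FALSE)
  p <- counts / n
  s2 <- sum(p^2); s3 <- sum(p^3)
  H <- n * (1 - s2) / (n - 1)
  V <- (2 / (n * (n - 1))) * (2 * (n - 2) * (s3 - s2^2) + s2 - s2^2)
  structure(list(value = H, sd = sqrt(max(V, 0)), n = n,
                 method = "nei1987"), class = "diversity_estimate")
}

#' @export
print.diversity_estimate <- function(x, ...) {
  cat(sprintf("%.6f +/- %.6f  (n = %d, %s)\n", x$value, x$sd, x$n, x$method))
  invisible(x)
}

#' Pairwise differences between two motifs over jointly covered positions
#'
#' @param a,b [hap_motif()] objects sharing a window.
#' @param covered_a,covered_b optional covered position vectors; defaults to
#'   the full window.
#' @param drop_polyc exclude poly-cytosine length variants (default).
#' @return integer count of differing positions within the joint coverage.
#' @export
motif_differences <- function(a, b, covered_a = NULL, covered_b = NULL,
                              drop_polyc = TRUE) {
  if (!same_window(a, b)) stop("motif windows differ", call. = FALSE)
  full <- a$window$start:a$window$end
  if (is.null(covered_a)) covered_a <- full
  if (is.null(covered_b)) covered_b <- full
  joint <- intersect(covered_a, covered_b)
  restr <- function(m, cov) {
    tk <- motif_tokens(m, drop_polyc = drop_polyc)
    if (!length(tk)) return(character())
    p <- floor(parse_variants(tk)$pos)
    tk[p %in% cov]
  }
  ta <- restr(a, joint); tb <- restr(b, joint)
  length(setdiff(ta, tb)) + length(setdiff(tb, ta))
}

#' Nucleotide diversity with sampling variance
#'
#' Mean per-site pairwise difference,
#' \eqn{\hat\pi = \frac{n}{n-1}\sum_i\sum_j \hat p_i \hat p_j d_{ij} / L},
#' with \eqn{d_{ij}} counted over jointly covered positions. The standard
#' deviation uses Tajima's (1983) total sampling variance
#' \eqn{V = \frac{n+1}{3(n-1)L}\pi + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2}.
#'
#' @param motifs list of [hap_motif()] (all resolved, shared window).
#' @param counts integer multiplicities (same length as `motifs`).
#' @param L number of sites (defaults to the window length).
#' @return `diversity_estimate` (method tag `"nei-tajima1983"`).
#' @export
nucleotide_diversity <- function(motifs, counts, L = NULL) {
  if (any(vapply(motifs, is.null, TRUE)))
    stop("unresolved motifs present at index: ",
         paste(which(vapply(motifs, is.null, TRUE)), collapse = ", "),
         call. = FALSE)
  stopifnot(length(motifs) == length(counts))
  counts <- as.integer(counts)
  n <- sum(counts)
  if (n < 2L) stop("nucleotide diversity undefined for n < 2", call. = FALSE)
  if (is.null(L)) L <- window_length(motifs[[1]]$window)
  if (L <= 0) stop("L must be positive", call. = FALSE)
  p <- counts / n
  k <- length(motifs)
  acc <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    acc <- acc + p[i] * p[j] * motif_differences(motifs[[i]], motifs[[j]])
  pi_hat <- (n / (n - 1)) * acc / L
  V <- (n + 1) / (3 * (n - 1) * L) * pi_hat +
    2 * (n^2 + n + 3) / (9 * n * (n - 1)) * pi_hat^2
  structure(list(value = pi_hat, sd = sqrt(max(V, 0)), n = n,
                 method = "nei-tajima1983"), class = "diversity_estimate")
}

#' Haplogroup contingency table with percentages
#'
#' @param calls_by_pop named list: population -> list of `haplogroup_call`.
#' @param records_by_pop named list: population -> list of [sample_record()]
#'   (for count weights), same structure.
#' @return list with `table` (matrix populations x haplogroups) and
#'   `percent` (row percentages, 1 decimal).
#' @export
haplogroup_table <- function(calls_by_pop, records_by_pop) {
  stopifnot(identical(names(calls_by_pop), names(records_by_pop)))
  rows <- lapply(names(calls_by_pop), function(popn) {
    calls <- calls_by_pop[[popn]]; recs <- records_by_pop[[popn]]
    if (!length(calls)) return(stats::setNames(integer(), character()))
    finals <- vapply(calls, function(cl) {
      mj <- unname(.SUB_TO_MAJOR[cl$final])
      if (is.na(mj)) cl$final else mj
    }, "")
    cnt <- vapply(recs, function(r) r$count, 1L)
    tapply(cnt, finals, sum)
  })
  cats <- sort(unique(unlist(lapply(rows, names))))
  tab <- matrix(0L, nrow = length(rows), ncol = length(cats),
                dimnames = list(names(calls_by_pop), cats))
  for (i in seq_along(rows))
    tab[i, names(rows[[i]])] <- as.integer(rows[[i]])
  pct <- round(100 * tab / pmax(rowSums(tab), 1L), 1)
  list(table = tab, percent = pct)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pearson chi-square statistic of a contingency table
#'
#' No continuity correction, no cell collapsing. Per-cell contributions are
#' returned for audit; the statistic is their sum.
#'
#' @param tab integer matrix (>= 2 rows and columns, positive margins).
#' @return list with `statistic`, `df`, `contributions`, `expected`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("need at least a 2x2 table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: zero row or column margin", call. = FALSE)
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  contrib <- (tab - exp)^2 / exp
  list(statistic = sum(contrib), df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
       contributions = contrib, expected = exp)
}

#' Monte-Carlo chi-square p-value (fixed margins)
#'
#' Replicate tables are drawn with both margins fixed (permutation null, via
#' `r2dtable`); the p-value uses the add-one correction
#' \eqn{p = (1 + \#\{\chi^2_{rep} \ge \chi^2_{obs}\})/(R + 1)} and therefore
#' never reports zero.
#'
#' @param tab integer contingency table.
#' @param replicates number of replicate tables (>= 1).
#' @param seed integer seed (mandatory; recorded in the result).
#' @return list of class `differentiation_result`: `statistic`, `p`,
#'   `method = "mc-chi2"`, `replicates`, `seed`.
#' @export
mc_chi2_pvalue <- function(tab, replicates = 10000L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  replicates <- as.integer(replicates)
  stopifnot(replicates >= 1L)
  obs <- pearson_chi2(tab)$statistic
  rng <- make_rng(seed, "mc-chi2")
  reps <- with_rng(rng, stats::r2dtable(replicates, rowSums(tab),
                                        colSums(tab)))
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- vapply(reps, function(m) sum((m - exp)^2 / exp), 1.0)
  p <- (1 + sum(stat >= obs - 1e-12)) / (replicates + 1)
  structure(list(statistic = obs, p = p, method = "mc-chi2",
                 replicates = replicates, seed = seed),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %s, p = %.6g (%s, seed %s)\n", x$method,
              if (is.null(x$statistic)) "-" else format(x$statistic),
              x$p,
              if (!is.null(x$replicates)) paste(x$replicates, "replicates")
              else paste(x$steps, "MCMC steps"),
              format(x$seed)))
  invisible(x)
}

# Probability of a 2xk table under the multivariate hypergeometric null with
# both margins fixed: prod_j C(c_j, a_j) / C(N, n1), in logs.
.log_table_prob <- function(a, colsums, n1, N) {
  sum(lchoose(colsums, a)) - lchoose(N, n1)
}

# Enumerate all first rows a (vector over k categories) with sum n1 and
# 0 <= a_j <= c_j. Returns matrix, one row per table.
.enumerate_tables <- function(colsums, n1) {
  k <- length(colsums)
  rows <- list(integer(0))
  sums <- 0L
  acc <- list(list(a = integer(0), s = 0L))
  for (j in seq_len(k)) {
    nxt <- list()
    rest <- if (j < k) sum(colsums[(j + 1L):k]) else 0L
    for (st in acc) {
      lo <- max(0L, n1 - st$s - rest)
      hi <- min(colsums[j], n1 - st$s)
      if (hi < lo) next
      for (v in lo:hi)
        nxt[[length(nxt) + 1L]] <- list(a = c(st$a, v), s = st$s + v)
    }
    acc <- nxt
  }
  do.call(rbind, lapply(acc, function(st) st$a))
}

#' Raymond-Rousset exact test of population differentiation
#'
#' Tests haplotype-frequency differentiation between two populations: the
#' p-value is the null probability of tables (margins fixed) no more probable
#' than the observed one under the multivariate hypergeometric distribution.
#' Small tables are fully enumerated; larger ones use a Metropolis Markov
#' chain over one-unit swaps between categories (burn-in and chain length
#' recorded in the result). On 2x2 tables the enumeration reproduces the
#' two-sided Fisher exact probability-mass criterion.
#'
#' @param spec_a,spec_b [freq_spectrum()] objects over shared categories
#'   (category names must match where both are named).
#' @param max_enumeration enumerate exhaustively when the number of tables is
#'   at most this bound.
#' @param steps,burnin MCMC chain parameters (used beyond the bound).
#' @param seed integer seed (mandatory for the MCMC route).
#' @return `differentiation_result` with `p`, `method` (`"exact-rr"` or
#'   `"exact-rr-mcmc"`), and chain metadata when stochastic.
#' @export
exact_differentiation_test <- function(spec_a, spec_b,
                                       max_enumeration = 200000,
                                       steps = 100000L, burnin = 2000L,
                                       seed = NULL) {
  stopifnot(inherits(spec_a, "freq_spectrum"),
            inherits(spec_b, "freq_spectrum"))
  if (spec_a$n == 0L || spec_b$n == 0L)
    stop("both populations must be non-empty", call. = FALSE)
  na <- names(spec_a$counts); nb <- names(spec_b$counts)
  if (!is.null(na) && !is.null(nb)) {
    cats <- sort(union(na, nb))
    a <- stats::setNames(integer(length(cats)), cats)
    b <- a
    a[na] <- spec_a$counts; b[nb] <- spec_b$counts
  } else if (length(spec_a$counts) == length(spec_b$counts)) {
    a <- spec_a$counts; b <- spec_b$counts
  } else {
    stop("category mismatch between spectra (unnamed, different lengths)",
         call. = FALSE)
  }
  colsums <- a + b
  keep <- colsums > 0
  a <- a[keep]; colsums <- colsums[keep]
  k <- length(colsums)
  n1 <- sum(a); N <- sum(colsums)
  logp_obs <- .log_table_prob(a, colsums, n1, N)
  n_tables <- prod(pmin(colsums, n1) + 1)
  if (n_tables <= max_enumeration) {
    tabs <- .enumerate_tables(colsums, n1)
    lp <- apply(tabs, 1, .log_table_prob, colsums = colsums, n1 = n1, N = N)
    p <- sum(exp(lp)[lp <= logp_obs + 1e-9])
    return(structure(list(statistic = NULL, p = min(p, 1), method = "exact-rr",
                          replicates = NULL, seed = NA, steps = NULL),
                     class = "differentiation_result"))
  }
  if (is.null(seed)) stop("seed is mandatory for the MCMC route",
                          call. = FALSE)
  rng <- make_rng(seed, "exact-rr-mcmc")
  cur <- a; logp_cur <- logp_obs
  hits <- 0L; kept <- 0L
  with_rng(rng, {
    total <- burnin + steps
    for (it in seq_len(total)) {
      jj <- sample.int(k, 2L)
      j1 <- jj[1]; j2 <- jj[2]
      # move one unit of population A from category j1 to j2
      if (cur[j1] > 0L && cur[j2] < colsums[j2]) {
        prop <- cur
        prop[j1] <- prop[j1] - 1L; prop[j2] <- prop[j2] + 1L
        logp_prop <- .log_table_prob(prop, colsums, n1, N)
        if (log(stats::runif(1)) < logp_prop - logp_cur) {
          cur <- prop; logp_cur <- logp_prop
        }
      }
      if (it > burnin) {
        kept <- kept + 1L
        if (logp_cur <= logp_obs + 1e-9) hits <- hits + 1L
      }
    }
  })
  structure(list(statistic = NULL, p = (1 + hits) / (kept + 1),
                 method = "exact-rr-mcmc", replicates = NULL, seed = seed,
                 steps = steps, burnin = burnin),
            class = "differentiation_result")
}
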