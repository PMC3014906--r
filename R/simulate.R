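# Seeded synthetic-data generator.
#
# Emulates the statistical structure the analysis assumes, so the whole
# pipeline can run and be validated without the study's raw samples:
# haplogroup-structured founder motifs evolving under matrilineal
# Wright-Fisher drift (optional bottleneck), admixed modern populations,
# three-generation pedigrees with shared matrilines, and ancient teeth
# sequenced as two overlapping amplicons per strand with injected
# strand-private phantom mutations. Every output is deterministic given
# (parameters, seed) and is accompanied by truth labels.

#' Simulation parameters
#'
#' @param founder_motifs named list haplogroup -> variant token vector;
#'   defaults to the classifier's default founder motifs so that synthetic
#'   truth and classification rules agree by construction.
#' @param founder_freqs founder haplogroup frequencies (sum to 1).
#' @param mu per-site per-generation mutation probability.
#' @param ts_tv transition:transversion bias (default 20, control-region
#'   realism).
#' @param generations number of Wright-Fisher generations.
#' @param size effective matrilineal population size, or a vector giving the
#'   size trajectory per generation (bottlenecks as temporary reductions).
#' @param window sequencing window.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(founder_motifs = NULL,
                       founder_freqs = NULL,
                       mu = 2e-4, ts_tv = 20, generations = 20L,
                       size = 200L, window = ref_window()) {
  if (is.null(founder_motifs)) {
    rules <- default_hvsi_rules()
    founder_motifs <- stats::setNames(lapply(rules, `[[`, "required"),
                                      vapply(rules, `[[`, "", "haplogroup"))
  }
  if (is.null(founder_freqs))
    founder_freqs <- stats::setNames(
      rep(1 / length(founder_motifs), length(founder_motifs)),
      names(founder_motifs))
  stopifnot(abs(sum(founder_freqs) - 1) < 1e-8, mu >= 0, ts_tv > 0)
  structure(list(founder_motifs = founder_motifs,
                 founder_freqs = founder_freqs, mu = mu, ts_tv = ts_tv,
                 generations = as.integer(generations), size = size,
                 window = window),
            class = "sim_params")
}

.transition_of <- c(A = "G", G = "A", C = "T", T = "C")

# Mutate one lineage's token set: per-site Bernoulli(mu); a hit at a
# currently-derived site reverts it, a hit elsewhere creates the site's
# derived allele. Site alt alleles are fixed run-wide (binary-site model).
mutate_tokens <- function(tokens, params, site_alt) {
  L <- window_length(params$window)
  nhit <- stats::rbinom(1L, L, params$mu)
  if (nhit == 0L) return(list(tokens = tokens, site_alt = site_alt))
  pos_hit <- params$window$start - 1L +
    sample.int(L, nhit, replace = FALSE)
  for (p in pos_hit) {
    key <- as.character(p)
    cur <- grep(paste0("^", p, "[ACGT]$"), tokens, value = TRUE)
    if (length(cur)) {
      tokens <- setdiff(tokens, cur)          # back mutation to rCRS
    } else {
      alt <- site_alt[[key]]
      if (is.null(alt)) {
        ref <- ref_base(p)
        alt <- if (stats::runif(1) < params$ts_tv / (params$ts_tv + 1))
          .transition_of[[ref]]
        else sample(setdiff(setdiff(c("A", "C", "G", "T"), ref),
                            .transition_of[[ref]]), 1L)
        site_alt[[key]] <- alt
      }
      tokens <- c(tokens, paste0(p, alt))
    }
  }
  list(tokens = tokens, site_alt = site_alt)
}

#' Simulate a matrilineal population under drift
#'
#' Wright-Fisher copying of whole mtDNA motifs (no recombination) with
#' per-generation per-site mutation on binary sites and an optional
#' bottleneck encoded in the size trajectory.
#'
#' @param params a [sim_params()].
#' @param n_sample individuals sampled at the final generation.
#' @param seed integer seed (mandatory).
#' @return list with `records` (list of [sample_record()], ids `S1..`,
#'   population `"SIM"`) and `truth` (data.frame: id, haplogroup, motif).
#' @export
simulate_matrilineal_population <- function(params, n_sample = 74L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(inherits(params, "sim_params"))
  sizes <- if (length(params$size) == 1L)
    rep(params$size, params$generations) else params$size
  if (any(sizes < 1L)) stop("extinct lineage pool: size 0", call. = FALSE)
  rng <- make_rng(seed, "wright-fisher")
  hg <- names(params$founder_motifs)
  with_rng(rng, {
    n0 <- sizes[1]
    anc <- sample(hg, n0, replace = TRUE, prob = params$founder_freqs)
    pop <- lapply(anc, function(h) params$founder_motifs[[h]])
    site_alt <- as.list(stats::setNames(
      vapply(unique(unlist(params$founder_motifs)), function(tk)
        sub("^[0-9]+", "", tk), ""),
      vapply(unique(unlist(params$founder_motifs)), function(tk)
        sub("[ACGT]$", "", tk), "")))
    for (g in seq_len(params$generations)) {
      n_next <- sizes[min(g, length(sizes))]
      parent <- sample.int(length(pop), n_next, replace = TRUE)
      anc <- anc[parent]
      pop <- lapply(pop[parent], function(tk) {
        r <- mutate_tokens(tk, params, site_alt)
        site_alt <<- r$site_alt
        r$tokens
      })
    }
    take <- sample.int(length(pop), n_sample, replace = n_sample > length(pop))
    ids <- sprintf("S%03d", seq_len(n_sample))
    records <- lapply(seq_len(n_sample), function(i)
      sample_record(ids[i], "SIM", 1L,
                    hap_motif(pop[[take[i]]], ids[i], params$window)))
    truth <- data.frame(
      id = ids, haplogroup = anc[take],
      motif = vapply(take, function(j)
        paste(sort(pop[[j]]), collapse = ";"), ""),
      stringsAsFactors = FALSE)
    list(records = records, truth = truth)
  })
}

#' Draw admixed samples from two motif pools
#'
#' Each sample's motif comes from the Amerindian pool with the given
#' probability, otherwise from the non-Amerindian pool (pools are kept on
#' distinct motif spaces by construction, so truth is unambiguous).
#'
#' @param amerindian,other lists of [hap_motif()] pools.
#' @param fraction Amerindian admixture fraction in `[0, 1]`.
#' @param n number of samples.
#' @param seed integer seed.
#' @return list with `records` and `truth` (data.frame id, amerindian flag).
#' @export
simulate_admixed_samples <- function(amerindian, other, fraction, n, seed) {
  stopifnot(length(amerindian) >= 1L, length(other) >= 1L,
            fraction >= 0, fraction <= 1)
  rng <- make_rng(seed, "admixture")
  with_rng(rng, {
    is_amer <- stats::runif(n) < fraction
    ids <- sprintf("AD%03d", seq_len(n))
    records <- lapply(seq_len(n), function(i) {
      pool <- if (is_amer[i]) amerindian else other
      m <- pool[[sample.int(length(pool), 1L)]]
      sample_record(ids[i], "ADMIX", 1L,
                    hap_motif(motif_tokens(m, drop_polyc = FALSE), ids[i],
                              m$window))
    })
    list(records = records,
         truth = data.frame(id = ids, amerindian = is_amer,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a three-generation pedigree with shared matrilines
#'
#' Builds `n_founders` matrilineal families (founder female, her children,
#' her daughters' children), assigns each founder a motif from a pool, and
#' over-draws `n_sampled` sampled individuals from the matrilineal members
#' (each matriline sampled at least once) to exercise deduplication.
#'
#' @param n_founders number of founder females (matrilines).
#' @param n_sampled total sampled individuals (>= `n_founders`).
#' @param motif_pool list of [hap_motif()] assigned to founders (recycled by
#'   sampling with replacement).
#' @param mean_children mean sibship size (Poisson, min 1).
#' @param seed integer seed.
#' @return list with `ped` (pedigree data.frame), `records` (sampled
#'   individuals carrying their matriline's motif) and `truth` (data.frame
#'   id, matriline founder).
#' @export
simulate_pedigree <- function(n_founders = 74L, n_sampled = 173L,
                              motif_pool, mean_children = 3, seed) {
  stopifnot(n_founders >= 1L, n_sampled >= n_founders,
            length(motif_pool) >= 1L)
  rng <- make_rng(seed, "pedigree")
  with_rng(rng, {
    fam <- character(); id <- character(); father <- character()
    mother <- character(); sex <- integer()
    matri <- character()  # matriline founder per matrilineal member
    add <- function(f, i, fa, mo, sx) {
      fam <<- c(fam, f); id <<- c(id, i); father <<- c(father, fa)
      mother <<- c(mother, mo); sex <<- c(sex, sx)
    }
    for (k in seq_len(n_founders)) {
      f <- sprintf("F%03d", k)
      gm <- paste0(f, "_gm")            # founder female, generation 1
      add(f, gm, "0", "0", 2L)
      matri <- c(matri, stats::setNames(gm, gm))
      nkid <- max(1L, stats::rpois(1L, mean_children))
      for (c1 in seq_len(nkid)) {
        kid <- sprintf("%s_c%d", f, c1)
        sx <- sample(1:2, 1L)
        add(f, kid, "0", gm, sx)
        matri <- c(matri, stats::setNames(gm, kid))
        if (sx == 2L) {                  # daughters have children
          ngk <- max(1L, stats::rpois(1L, mean_children))
          for (c2 in seq_len(ngk)) {
            gkid <- sprintf("%s_g%d", kid, c2)
            add(f, gkid, "0", kid, sample(1:2, 1L))
            matri <- c(matri, stats::setNames(gm, gkid))
          }
        }
      }
    }
    members <- names(matri)
    founders <- sprintf("F%03d_gm", seq_len(n_founders))
    # one guaranteed sample per matriline, then over-draw
    pick <- vapply(founders, function(gm) {
      cand <- members[matri == gm]
      cand[sample.int(length(cand), 1L)]
    }, "")
    extra <- setdiff(members, pick)
    n_extra <- n_sampled - n_founders
    if (n_extra > 0L)
      pick <- c(pick, extra[sample.int(length(extra), n_extra)])
    ped <- data.frame(family = fam, id = id, father = father,
                      mother = mother, sex = sex,
                      sampled = id %in% pick, stringsAsFactors = FALSE)
    fm <- motif_pool[sample.int(length(motif_pool), n_founders,
                                replace = TRUE)]
    names(fm) <- founders
    records <- lapply(sort(unname(pick)), function(i) {
      m <- fm[[matri[[i]]]]
      sample_record(i, "PED", 1L,
                    hap_motif(motif_tokens(m, drop_polyc = FALSE), i,
                              m$window))
    })
    list(ped = ped, records = records,
         truth = data.frame(id = sort(unname(pick)),
                            matriline = vapply(sort(unname(pick)),
                                               function(i) matri[[i]], ""),
                            stringsAsFactors = FALSE))
  })
}

#' Simulate ancient teeth as per-strand two-fragment reads
#'
#' Per tooth: two overlapping amplicons (defaults 15989-16251, 16190-16410),
#' each on both strands, with optional fragment-2 dropout and strand-private
#' phantom variants injected at a given rate (never on both strands).
#'
#' @param motifs named list of source [hap_motif()] (one per tooth).
#' @param phantom_rate expected phantom mutations per strand per tooth.
#' @param dropout_frag2 probability that fragment 2 drops out entirely.
#' @param seed integer seed.
#' @return list with `reads` (per tooth: list of forward/reverse
#'   [frag_read()] lists) and `truth` (data.frame tooth, strand, phantom
#'   token).
#' @export
simulate_ancient_samples <- function(motifs, phantom_rate = 0,
                                     dropout_frag2 = 0, seed) {
  rng <- make_rng(seed, "ancient")
  frags <- list(c(15989L, 16251L), c(16190L, 16410L))
  full <- ref_window(15989L, 16410L)
  with_rng(rng, {
    reads <- list(); tr_tooth <- character(); tr_strand <- character()
    tr_tok <- character()
    for (lab in names(motifs)) {
      m <- motifs[[lab]]
      base_seq <- motif_to_sequence(
        hap_motif(motif_tokens(m, drop_polyc = FALSE), lab, full))
      strands <- list(forward = base_seq, reverse = base_seq)
      # phantoms go to reference-state positions only and are never placed
      # twice at one position within a tooth, so each injected token is
      # guaranteed to surface in the strand-discordant set
      eligible <- which(strsplit(base_seq, "")[[1]] ==
                          strsplit(full$sequence, "")[[1]])
      for (s in names(strands)) {
        nph <- min(stats::rpois(1L, phantom_rate), length(eligible))
        if (nph > 0L) {
          idx <- eligible[sample.int(length(eligible), nph)]
          eligible <- setdiff(eligible, idx)
          for (k in idx) {
            p <- 15988L + k
            cur <- substr(base_seq, k, k)
            alt <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
            substr(strands[[s]], k, k) <- alt
            tr_tooth <- c(tr_tooth, lab); tr_strand <- c(tr_strand, s)
            tr_tok <- c(tr_tok, paste0(p, alt))
          }
        }
      }
      drop2 <- stats::runif(1) < dropout_frag2
      tooth <- list(forward = list(), reverse = list())
      for (s in names(strands)) {
        use <- if (drop2) frags[1] else frags
        tooth[[s]] <- lapply(use, function(fr)
          frag_read(fr[1], fr[2],
                    substr(strands[[s]], fr[1] - 15988L, fr[2] - 15988L),
                    strand = s))
      }
      reads[[lab]] <- tooth
    }
    list(reads = reads,
         truth = data.frame(tooth = tr_tooth, strand = tr_strand,
                            phantom = tr_tok, stringsAsFactors = FALSE))
  })
}

#' Recover a validated motif from simulated ancient reads
#'
#' The ancient-sample workflow: merge each strand's fragments into a strand
#' consensus, call per-strand variants, and keep only strand-concordant
#' calls.
#'
#' @param tooth one element of `simulate_ancient_samples()$reads`.
#' @param label sample label for the resulting motif.
#' @return list with `motif` (validated [hap_motif()] over the merged
#'   window), `discordant` (candidate phantoms), `covered` (positions read
#'   on both strands without conflict).
#' @export
ancient_consensus_motif <- function(tooth, label = NA_character_) {
  per_strand <- lapply(tooth, function(rds) {
    mg <- merge_fragments(rds)
    mot <- sequence_to_motif(mg$consensus, mg$window)
    list(tokens = motif_tokens(mot, drop_polyc = FALSE),
         covered = attr(mot, "covered"), window = mg$window)
  })
  flt <- strand_concordance_filter(per_strand$forward$tokens,
                                   per_strand$reverse$tokens)
  covered <- intersect(per_strand$forward$covered,
                       per_strand$reverse$covered)
  win <- per_strand$forward$window
  m <- hap_motif(flt$validated, label, win)
  attr(m, "covered") <- covered
  list(motif = m, discordant = flt$discordant, covered = covered)
}
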