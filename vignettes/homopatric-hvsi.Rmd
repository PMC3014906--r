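---
title: "Methods: HVSI haplotype analysis of extinct-population matrilineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HVSI haplotype analysis of extinct-population matrilineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtlineage)
```

This vignette is the package's own account of its models and of the design
choices made where the methodology left them open. It states no empirical
result that the test suite and the acceptance script do not themselves
compute.

## Coordinates, motifs and the reference window

All coordinates are 1-based rCRS (NC_012920) positions; windows are
inclusive on both ends. Only the control-region segment 15989–16410 is
embedded (verified base-by-base against the published reference alleles of
the 26 HVSI positions used by the packaged tables); it covers the default
HVSI window 16045–16362 (318 bp) and both ancient-DNA amplicons. A
haplotype *motif* is the canonical, position-sorted set of differences from
the reference, written position + derived allele (`16223T`), with `16166d`
for deletions and `16193.1C` for insertions.

**Poly-cytosine tract.** Length variation around 16184–16193 is recorded
as indel variants but excluded by default from classification, matching and
distances (`motif_tokens(drop_polyc = TRUE)`). This is the standard
forensic convention: the tract mutates so fast that length states carry
almost no lineage information and would split otherwise identical
haplotypes. The variants remain available (`drop_polyc = FALSE`) for users
who need them.

**Ambiguity.** How heteroplasmic or ambiguous bases in modern samples
should be handled is not specified by the source methodology; this package
treats any IUPAC ambiguity (including `N`) as missing — excluded from both
the variant set and the covered positions. Conflicting bases in the
two-amplicon ancient consensus become `N`, never a guess.

## Haplogroup classification

Three evidence tiers mirror the classical Amerindian screen.

**HVSI motif rules.** Defaults: B = {16189C, 16217C}; C = {16223T, 16298C,
16325C, 16327T}; D = {16223T, 16325C, 16362C}; A = {16111T, 16223T,
16290T, 16319A, 16362C}. B and C are fixed by the published founder
motifs; A and D follow the haplogroup literature those motifs come from and
are configurable through a rules file, because the original screen typed A
and D by RFLP rather than by sequence.

**Mismatch tolerance.** A strict "rule fully contained in the motif" match
fails on real data: in the packaged tables three lineages each lack exactly
one site of their haplogroup's founder motif (a back-mutation or a
founder-rule mismatch: one C lineage without 16327T, one without 16298C,
one D lineage without 16325C). `classify_hvsi` therefore accepts a rule
when at least `length(required) - max_mismatch` of its required variants
are present (default `max_mismatch = 1`, never more than
`length(required) - 1`, and at least one required variant must be present);
specificity is the number of required variants actually present, the most
specific supported rule wins, and a specificity tie between haplogroups
returns `unclassified` with an ambiguity flag. `max_mismatch = 0` restores
strict containment. Because the C motif strictly contains the D core
(16223T, 16325C), specificity ordering — not rule order — decides, and the
classifier is invariant to the listing order of rules.

**RFLP tier.** One diagnostic state per haplogroup (site gain +663 HaeIII
for A, region-V 9-bp deletion for B, site losses 13259 HincII / 5176 AluI /
1715 DdeI for C / D / X). Exactly one diagnostic observed gives the call;
several give `unclassified` with a conflict flag. Haplogroup M and the
finer Amerindian-X screen are not shipped as defaults: the available marker
(−1715 DdeI) cannot discriminate Amerindian X sub-lineages, and no M
criteria are defined in the source; both can be added via the rules
interface.

**Coding panel.** The minisequencing tier assigns B2 (positions 11177,
3547, 4977, 6473, 9950), D1 (2092) and C — which with HVSI 16325C
specifies C1 (15487, 14318). The published description names positions but
not alleles, so a position counts as *derived* when the called allele
differs from the embedded rCRS ancestral base; the ancestral bases at those
eight positions are embedded alongside the reference window.

**Combination.** Tiers that agree at the major-haplogroup level combine at
the finest supported resolution (a panel C1 refines an HVSI/RFLP C); any
contradiction yields `unclassified` with `concordant = FALSE`. The final
label is never finer than its evidence: without a panel call there is no
sub-haplogroup.

## Matrilines

Matrilines are found by following mother links to a founder female;
individuals with unknown mothers are their own founders — conservative, in
that lineages are never merged without evidence. The published study
reduced 173 sampled villagers to 74 matrilineally unrelated individuals but
does not say how representatives were chosen; the default policy here is
lexicographically smallest id (reproducible), with a seeded random policy
as the alternative. An optional check (`check_matriline_motifs`) verifies
that members of one matriline carry identical motifs; it is offered, not
assumed, since the source does not state whether such verification was
done.

## Statistics

*Gene diversity.* \(\hat H = n(1-\sum p_i^2)/(n-1)\), with standard
deviation from Nei's (1987) sampling variance
\(V(\hat H) = \frac{2}{n(n-1)}\{2(n-2)[\sum p_i^3 - (\sum p_i^2)^2] +
\sum p_i^2 - (\sum p_i^2)^2\}\). This estimator pair was chosen because it
exactly reproduces both published standard deviations from the packaged
count spectra; the source names only the software used.

*Nucleotide diversity.* \(\hat\pi = \frac{n}{n-1}\sum_{i\ne j} p_i p_j
d_{ij}/L\) with \(d_{ij}\) counted over jointly covered positions only (no
imputation); the variance is Tajima's (1983) total sampling variance, and
the method tag on the result records the formula used. The published π for
the ancient teeth covers two withheld sequences and is therefore not
reproducible from public data; the tests instead verify the estimator
against a brute-force pairwise loop on the resolved C-haplogroup subset.

*χ² tests.* Pearson's statistic without continuity correction or cell
collapsing (this choice reproduces the published statistic on the printed
2×4 haplogroup table). The Monte-Carlo p-value draws replicate tables with
both margins fixed (`r2dtable`) and uses the add-one correction
\(p = (1 + \#\{\chi^2_{rep} \ge \chi^2_{obs}\})/(R+1)\), so p is never
reported as zero.

*Exact differentiation test.* The probability, under the multivariate
hypergeometric null with fixed margins, of tables no more probable than the
one observed. Tables whose state space is at most `max_enumeration`
(default 2×10⁵) are fully enumerated — on 2×2 tables this is exactly the
two-sided Fisher probability-mass criterion — and larger tables use a
Metropolis chain over one-unit swaps between categories (symmetric
proposal; burn-in, chain length and seed recorded in the result). Ties in
table probability are compared with a 10⁻⁹ log-space tolerance.

## Median-joining networks

Varied positions are treated as binary (reference vs one derived allele):
every site in the packaged tables is biallelic, and the per-site majority
of a triplet is then an exact median. Multistate sites raise an explicit
error rather than silently approximating quasi-medians.

Construction: (1) the minimum-spanning network — all edges belonging to at
least one MST, computed by Kruskal levels with every tie kept, so the
result is deterministic without tie-break heuristics; (2) for every
connected triplet, the majority vector is a candidate median, and all
candidates whose star cost is within `epsilon` of the iteration minimum are
added (default `epsilon = 0`, unit weights — the defaults of the standard
network software; the source does not state its settings); (3) after
convergence, unsampled medians of degree ≤ 2 lying on no shortest path
between sampled nodes are deleted iteratively.

`network_length` is the weight of the lightest spanning structure contained
in the network, treating medians as *optional* Steiner points (minimum over
median subsets of the MST of sampled ∪ subset). This is the quantity the
median augmentation is meant to reduce; an MST over *all* nodes would
penalise harmless extra medians. The acceptance property compares this
length, at a generous `epsilon = 2` exploration setting, with a brute-force
minimum over all subsets of the median closure of the sampled motifs on
small instances; monotonicity of the *edge set* in epsilon is not asserted,
because recomputing the minimum-spanning network after adding medians can
legitimately retire edges that a smaller epsilon kept.

## Matching

A match is identity of the variant sets restricted to the intersection of
the covered ranges; below `min_overlap` (default 250 positions) the verdict
is *indeterminate*, never *novel* — a novelty claim must not rest on a thin
overlap. The packaged reference database is a small synthetic stand-in
reproducing the published found/novel pattern of the 13 modern haplotypes;
the real multi-thousand-sequence panels are external and not shipped, so a
green novelty test establishes correct screen behaviour, not real-world
novelty.

## Synthetic data: the stated world

The generator emulates the demographic structure the analysis assumes:

- **Founder motifs** default to the classifier's default A/B/C/D motifs, so
  synthetic truth and classification rules agree by construction.
- **Drift** is matrilineal Wright–Fisher copying of whole motifs (mtDNA
  does not recombine) with per-site per-generation mutation
  (default µ = 2×10⁻⁴ per site), binary sites on top of founder motifs and
  a 20:1 transition:transversion bias — control-region realism; the source
  is silent on both, and the values are fixed here once.
- **Bottlenecks** are temporary reductions in the size trajectory (the
  published discussion attributes the observed C-excess and low diversity
  to founder effects/bottlenecks; the generator makes that scenario
  constructible, not inferred).
- **Admixture** draws each sample from the Amerindian pool with probability
  0.27 in the packaged "queixadinha-like" scenario (the published
  Amerindian fraction), from a disjoint motif space otherwise.
- **Pedigrees** are three-generation matrilineal families; 173 samples
  over-drawn from 74 founder females reproduces the published
  deduplication scenario as a *template*, with every matriline sampled at
  least once.
- **Ancient reads** are two amplicons per strand with optional fragment-2
  dropout and strand-private phantom variants (never both strands, only at
  reference-state positions, never twice at one position), so every
  injected artifact is guaranteed to surface in the discordant set.

What the generator does **not** emulate: recurrent multistate hits at
realistic rates, post-mortem damage spectra (deamination C→T gradients),
heteroplasmy, or any real demographic history of the vanished population —
the bottleneck settings are scenario knobs, not inferences. A green
end-to-end test therefore establishes that the pipeline recovers the truth
of a well-behaved world, not that the published history is correct.

## Numerical and reproducibility choices

- All randomness flows from one master seed through named substreams
  (`make_rng`/`with_rng`); no stage reads or perturbs the global RNG state,
  and identical parameters + seed give byte-identical outputs (manifests
  carry no timestamps).
- Monte-Carlo p-values use the add-one correction; exact-test tie
  comparison uses a 10⁻⁹ log tolerance; MSN levels compare weights with a
  10⁻⁹ tolerance.
- Degenerate inputs fail loudly: n < 2 for diversities, zero margins for
  χ², unresolved motifs in sequence-based statistics (they must be excluded
  explicitly by the caller), internal gaps in fragment merging, multistate
  sites in networks.

## Known limitations

- The HVSI motif rules are a four-haplogroup founder panel, not a
  phylotree-scale classifier; lineages outside A–D/X simply come back
  `unclassified`.
- The exact test's MCMC route is asymptotically exact but stochastic; the
  enumeration bound should be raised when memory allows rather than trusted
  blindly near the boundary.
- Median-joining is a heuristic: the closure-optimum property is verified
  on small instances, not guaranteed in general (raising `epsilon` explores
  more candidate medians at the cost of network size).
- The embedded reference covers 15989–16410 plus eight coding positions
  only; analyses outside that range require a different reference build.
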