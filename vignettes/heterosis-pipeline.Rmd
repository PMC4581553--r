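---
title: "Classifying gene action in a three-library hybrid transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying gene action in a three-library hybrid transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Interspecific hybridization between *Brassica napus* (an allotetraploid
carrying the A and C subgenomes) and *Brassica rapa* (A genome) produces F1
hybrids whose vigour — heterosis — has a transcriptional footprint. A common
design sequences exactly three mRNA libraries, one per line: parent 1 (P1),
parent 2 (P2) and the hybrid (F1), each a pool of plants with no biological
replicates. The analytical questions are:

1. which genes are expressed in which line, and which are hybrid-activated
   or hybrid-silenced;
2. which genes are differentially expressed between lines, given a single
   library per line;
3. for each differentially expressed gene (DEG), what *gene action* the
   hybrid shows relative to its parents: additivity, high- or low-parent
   dominance, over- or underdominance, or partial dominance;
4. whether particular dominance classes accumulate on particular
   chromosomes or subgenomes, and in particular functional (GO) categories;
5. whether transposon-like genes are activated, silenced or shifted in the
   hybrid;
6. whether qPCR validation agrees in direction with the sequencing calls.

`midparent` implements this pipeline end to end on a per-gene count table,
together with a synthetic-data generator that produces three-library count
tables with a known truth, so every stage is testable without any external
data.

# Quantification and expression calls

Abundance is RPKM, $10^9 C / (N L)$ for a gene of length $L$ bp with $C$
uniquely mapped reads in a library of $N$ mapped reads. Because counts are
uniquely mapped, library sizes are supplied explicitly (a YAML sidecar or a
named vector), never inferred from column sums.

No detection rule accompanies typical published expressed-gene counts, so
the package uses an explicit, configurable one: a gene is *expressed* in a
library when its count is at least `min_count` (default 5) **and** its RPKM
is at least `min_rpkm` (default 0.5). The count floor guards against a few
stray reads in short genes; the RPKM floor makes the rule comparable across
lengths and depths. The seven-region partition of the three expressed sets
(`venn_partition()`) then yields the hybrid-specific sets directly:
activated-in-hybrid is the F1-only region, silenced-in-hybrid is the
parents-only intersection.

# The exact test

With one library per line, the only quantifiable noise is counting noise.
Conditional on count $x$ in a library of $N_1$ reads, the
posterior-predictive distribution of the count $y$ for the same gene in a
second library of $N_2$ reads (flat prior on the rate) is

$$p(y \mid x) \;=\; \frac{r^y\,(x+y)!}{x!\,y!\,(1+r)^{x+y+1}},
  \qquad r = N_2/N_1,$$

the Audic–Claverie distribution — a negative binomial with size $x+1$ and
success probability $N_1/(N_1+N_2)$. `ac_probability()` computes it in log
space (`lgamma`), so counts of any magnitude are safe; a brute-force
factorial evaluation and `dnbinom()` serve as independent cross-checks in
the test suite.

`ac_test()` returns a two-sided p-value by minimum-likelihood ordering: the
sum of $p(y' \mid x)$ over all $y'$ no more probable than the observed $y$.
The distribution is unimodal, so the sum reduces to two tail sums whose
boundaries are found by binary search; ties in the ordering are absorbed by
a relative log-tolerance of $10^{-9}$. One-sided tails are available via
`sided=`.

Numerical and inferential choices worth knowing:

* **Asymmetry.** The minimum-likelihood two-sided p-value is not symmetric
  under swapping the libraries, even at $r = 1$: the two directions order
  outcomes under different predictive distributions (negative binomials of
  size $x+1$ vs $y+1$). At $r=1$, $x=0$, $y=1$ the two directions give 0.5
  and 1.0. The pmf itself *is* symmetric at $r=1$, and the p-value
  discrepancy shrinks quickly with the counts. Contrasts are therefore
  always run in a fixed orientation (parent or midparent as $x$, hybrid as
  $y$).
* **Poisson assumption.** The test is exact for Poisson counting noise
  only. Extra-Poisson (biological) variance between pooled libraries is
  invisible to a design without replicates and makes the test
  anticonservative; see "Limitations" below.
* **Multiple testing.** Benjamini–Hochberg within each contrast
  (`bh_fdr()`, a wrapper over `p.adjust`), significance at FDR < 0.05 by
  default.

`run_contrasts()` tests every gene in four contrasts: P1 vs F1, P2 vs F1,
the parents against each other (needed to order the parents), and the
*additivity contrast* MP vs F1, where the midparent pseudo-count is the mean
parental rate rescaled to the hybrid's depth,
$\mathrm{round}\!\big(\tfrac12 (x_{P1}/N_{P1} + x_{P2}/N_{P2})\,N_{F1}\big)$,
tested at $N_1 = N_2 = N_{F1}$. Rounding is configurable
(`midparent_rounding`).

Per-contrast `direction` is decided by the FDR alone. The RPKM fold filter
(default $|\log_2$ ratio$| \ge 1$ with pseudocount 1) acts only on *DEG
selection*: a gene enters the DEG set when at least one parent-vs-hybrid
contrast is both significant and above the fold floor. Keeping the filter
out of the per-contrast signs keeps "F1 ≈ parent" judgements purely
statistical; keeping it in DEG selection screens out shifts that are
detectable only because depth is high.

# Gene action and midparent heterosis

Each DEG is classified from three signed outcomes — F1 vs P1, F1 vs P2,
F1 vs MP, each $+1$ (F1 significantly higher), $0$ (not significant) or
$-1$ — plus the parents' relative order. The decision tree, applied in
order:

| branch | condition | mode |
|---|---|---|
| 1 | F1 ≈ MP | ADD |
| 2 | F1 above both parents | ODO |
| 3 | F1 below both parents | UDO |
| 4 | parents differ, F1 ≈ the higher parent | HPD |
| 5 | parents differ, F1 ≈ the lower parent | LPD |
| 6 | F1 strictly between the parents, above MP / below MP | PPD / NPD |
| 7 | anything else | OTHER |

"≈" is operationalised as non-significance of the corresponding exact-test
contrast at the configured FDR: the underlying reports never quantify the
approximation, and tying it to the same test keeps the eight categories a
partition. Two consequences are deliberate: when the parents are not
significantly different, HPD and LPD are unreachable (there is no "higher
parent" to match); and OTHER is exactly the residual branch — e.g. a gene
departing from the midparent while matching both of two statistically
indistinguishable parents.

Midparent heterosis is reported per gene on the RPKM scale:

$$\mathrm{MPH} = \frac{h - (P_1+P_2)/2}{(P_1+P_2)/2} \times 100 + 100,$$

so the midparent maps to 100. Genes whose parental midparent RPKM is
exactly zero get `NA` rather than an infinity.

# Enrichment scans, TE calls, qPCR

`hypergeom_enrich()` is the upper-tail hypergeometric test
$P(X \ge k)$ for a query set of $n$ genes with $k$ in the unit, against a
background of $N$ genes with $K$ in the unit (`phyper`; full combinatorial
enumeration is the oracle in the tests). Design choices:

* **Chromosome scan** (`chromosome_scan()`): one test per
  (chromosome, mode) pair, background = all classified DEGs with a
  chromosome. The scan asks where expression variation *landed among DEGs*,
  not whether a chromosome is gene-rich; using all genes as background
  would confound the two. Upper tail only ("accumulation"); BH across the
  whole scan; per-subgenome (A/C/unassigned) totals attached.
* **GO enrichment** (`go_enrich()`): one test per term with at least
  `min_genes` (default 3) background genes — singleton terms otherwise
  dominate the BH correction. No DAG propagation: a term's gene set is its
  direct annotations. `enrichment_matrix()` pivots several scans into the
  term-by-set matrix behind a heat map.
* **TE regulation** (`classify_te()`): presence/absence shifts take
  precedence over quantitative ones. Active = expressed in F1 and in
  neither parent; Inactive = expressed in at least one parent, absent in
  F1; Up/Down = shared expression with a significant midparent-contrast
  shift. The classes are mutually exclusive by construction; TE genes
  fitting none (e.g. expressed nowhere) are dropped with a notice.

qPCR validation uses the standard $2^{-\Delta\Delta C_t}$ with replicates
averaged on the Ct scale and a named calibrator sample.
`qpcr_concordance()` counts sign agreement between the qPCR fold and the
transcriptome direction of the matching contrast; folds of exactly 1 and
`none` directions carry no sign and are reported in a separate neutral
column rather than silently counted either way.

# The synthetic-data generator

`simulate_hybrid()` draws, per gene: a base abundance (log-normal, default
median 100 RPKM, sdlog 1 — with the default 2×10⁶-read libraries and
~1.3 kb genes this gives a median expected count of ~260 and total expected
counts close to the library size), a length (log-normal, mean ≈ 1.3 kb,
floor 200 bp, mimicking a de novo assembly), a true mode (default mixture
proportional to the published dominance-pattern counts), and a chromosome
(weights reproducing the A : C : unplaced mass of the mapped genes, with an
optional injected (chromosome, mode, fold) excess for power studies). The
parents sit `effect_fold` apart (default 2) around the base abundance with
the high parent chosen at random; the hybrid rate follows the mode:

* ADD: parental mean; HPD/LPD: the high/low parent;
* ODO/UDO: `effect_fold` beyond the outer parent;
* PPD/NPD: the *geometric midpoint* between the midparent and the high/low
  parent. (A multiplicative displacement of the midparent by
  $\sqrt{\mathrm{effect\_fold}}$ looks natural but leaves the valid range:
  at effect_fold 2 it lands 6% *above* the high parent, which is
  overdominance, not partial dominance. The geometric midpoint stays
  strictly between the midparent and the parent for any effect_fold > 1.)

Counts are Poisson (`dispersion = 0`) or negative binomial with variance
$\mu + \phi\mu^2$ (default $\phi = 0.1$). Expected counts are
`rate × length × lib_size` with rate in RPKM × 10⁻⁹ units, so a gene's
expected RPKM equals its configured abundance. GO terms are sparse random
sets (default 50 terms, ~25 genes each) and a small fraction of genes
(default 0.5%) is TE-flagged. A fixed seed gives byte-identical output.

What the generator does *not* emulate: homoeologous cross-mapping between
the A and C copies (counts are taken as unambiguous, as the upstream unique
mapping assumes), 3′ coverage bias, lane effects, and any correlation
between a gene's mode and its expression level. Passing tests on this
generator therefore demonstrate the statistical machinery, not robustness
to mapping artefacts.

# What recovery on synthetic data can and cannot show

Two facts, established analytically and confirmed by the package's own
tests, bound what mode-recovery experiments can achieve:

* **Overdispersion breaks "≈" calls.** With $\phi = 0.1$ the standard
  deviation of the log count ratio between two libraries is about
  $\sqrt{2\phi} \approx 0.45$ *independent of depth*, while the exact test
  expects $\sqrt{2/\lambda}$. At high expression essentially every
  additivity contrast comes out significant, so ADD/HPD/LPD recovery
  collapses (measured ADD recovery ≈ 0.1 on the default scenario). This is
  not an implementation defect but the known cost of testing without
  replicates; it is the reason replicate-aware models exist.
* **Partial dominance is intrinsically faint.** Any PPD/NPD geometry that
  stays strictly between the parents sits at most 1.33-fold — and at the
  geometric midpoint 1.155-fold — from the midparent. Detecting a
  1.155-fold difference with 90% power needs expected counts near 1000,
  so even noiseless expected counts below that are correctly judged
  "not significantly different from midparent" and fall into ADD.

The test suite therefore verifies the classifier itself in a regime where
power is adequate (Poisson counts, base abundance ~2000 RPKM, stratum of
expected counts ≥ 2000: every mode recovered at ≥ 0.9, noiseless recovery
exact), and separately reports recovery under the default noisy scenario
for what it is. `recovery_report()` restricts its headline numbers to genes
that were actually classified, with an optional expression stratum
(`min_expected_count`).

# Problem sizes and runtimes

The shipped tests simulate 300–5,000 genes per scenario, run the equal-rate
null at 2,000 genes, verify the exact test against brute-force enumeration
over the full $x, y \le 30$ grid at $r \in \{0.5, 1, 2\}$, and replicate
the injected-enrichment scan 20 times — sizes chosen so the whole suite
runs in about a minute on one core while keeping Monte-Carlo error well
below the asserted margins.

# Known limitations

* No replicate-aware inference: the exact test quantifies counting noise
  only. With biological replicates, a negative-binomial GLM (DESeq2/edgeR)
  is the right tool; this package deliberately implements the
  single-library design.
* RPKM is the only normalisation; no between-sample normalisation
  (TMM/median-of-ratios) is applied, matching the upstream design where
  library-size ratios enter the test directly.
* The two-sided p-value's direction asymmetry at small counts (above).
* GO enrichment ignores the ontology graph.
* The expected midparent count is rounded to an integer before testing;
  at very low counts this quantisation can move a borderline additivity
  call.
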