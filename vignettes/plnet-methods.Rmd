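---
title: "Phenotypic-linkage networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic-linkage networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plnet)
library(data.table)
```

## The problem

Many complex-disease analyses need a single weighted gene network whose
links mean something concrete: *these two genes, when disrupted, tend to
produce the same phenotype*. plnet builds such phenotypic-linkage
networks (PLNs) by calibrating heterogeneous gene-pair evidence —
co-expression, shared pathway or domain annotations, co-citation,
protein interactions — against a phenotypic benchmark derived from
mouse-knockout phenotype annotations, then provides the downstream
statistics used to ask where disease genes converge in the network:
diffusion prioritization from seed genes, community detection,
covariate-matched permutation enrichment, interval-shift nulls for GWAS
loci, case/control variant burden, and tissue-specificity enrichment.

## The phenotypic benchmark

Phenotype annotations live on an ontology (a DAG of `is_a`
relations). Each annotated gene's profile is propagated upward: a gene
annotated to a specific term implicitly carries every more general
ancestor. The information content of a term is

$$\mathrm{ic}(t) = -\ln \frac{n_t}{N},$$

where $n_t$ counts annotated genes carrying $t$ after propagation and
$N$ is the annotated-gene universe. A root annotating every gene has
IC 0; rarer terms are more informative. IC is monotone non-increasing
from child to parent, which the tests assert edge-by-edge.

Two genes' phenotypic similarity combines Resnik term similarity — the
IC of the most-informative common ancestor (MICA) — across their
profiles. We aggregate with the symmetric **best-match sum**
("cumulative" similarity): every term of each profile contributes the
IC of its best counterpart on the other profile, and the two directed
sums are averaged. We chose the sum over the more common best-match
*average* for a structural reason: the toolkit supports
branch-restricted benchmarks (below), and restricting a profile to a
subset of terms must never *increase* a pair's similarity. A sum of
non-negative best matches shrinks monotonically as terms are removed;
an average does not (dropping a profile's weakest terms raises it), and
we verified the violation on a six-term fixture before fixing the
choice. Under the sum, identical single-term profiles $\{t\}$ still
score $\mathrm{ic}(t)$, and profiles sharing only an IC-0 root score 0.

A benchmark stores the similarity of every unordered gene pair plus the
overall median, which plays the role of the similarity expected for a
random pair. A *branch-restricted* benchmark keeps only genes annotated
under designated high-level branch roots (e.g. the handful of
disease-relevant top categories) and restricts profiles to terms under
those roots, giving a disease-focused calibration target.

## Evaluating and rescoring evidence

Each evidence dataset scores gene pairs on its own arbitrary scale. To
make scales commensurable, pairs covered by the benchmark are sorted by
descending raw score (ties broken lexicographically by pair id so
binning is reproducible) and cut into bins of 500 pairs (100 in the
small synthetic runs used by the tests). Plotting each bin's median
benchmark similarity against coverage yields the dataset's evaluation
curve; bins whose median exceeds the benchmark overall median are
*informative*.

The informativeness threshold is the median raw score of the last bin
in the *leading contiguous run* of informative bins — a single cutoff,
deliberately ignoring later rebounds. One guard is needed: under pure
noise each bin's median fluctuates symmetrically around the overall
median, so a worthless dataset still opens with a short spurious run
about half the time. We therefore require the leading run to span at
least `min_run = 5` bins; a spurious 5-bin run has probability about
$2^{-5}\approx 3\%$ under the null, and no sensible rescoring curve can
be fitted from fewer points anyway. Datasets failing this rule return
an explicit "uninformative" sentinel and are dropped with a warning,
not an error.

Over the informative bins we fit a polynomial of median similarity on
median raw score. The order grows from 1, accepting order $n+1$ while
the nested-model ANOVA F-test gives $p < 0.01$, capped at degree 6 to
bound overfitting. Raw scores at or above the threshold are then mapped
through the polynomial and clamped into
$[0, \max(\text{informative bin medians})]$, so every link weight is a
non-negative predicted phenotype similarity. The curve is *fitted* on
benchmark-covered pairs but *applied* to all pairs, which is how the
final network extends beyond phenotype-annotated genes.

## Integration: the penalized weighted sum

When several datasets score the same pair, the rescored values
$L_0 \ge L_1 \ge \dots \ge L_n$ combine as

$$WS = L_0 + \sum_{i=1}^{n} \frac{L_i}{D \cdot i},$$

the rank-penalized weighted sum: corroborating evidence helps, but with
rapidly diminishing returns governed by the free divisor $D$. $D$ is
selected from 1–20 by recomputing WS for all benchmark-covered pairs,
binning by WS rank, and regressing bin median similarity on bin rank;
the $D$ with the smallest regression F-test p-value wins, ties going to
the smallest $D$. We regress on bin *rank* (coverage position) rather
than on the WS value because WS scales differ across $D$, which would
make score-axis regressions incomparable. Whether to use all pairs or
benchmark pairs only was open; we use benchmark pairs, since similarity
is undefined elsewhere. Finally only the top $M$ links are retained
(1,000,000 at corpus scale; a few thousand in the synthetic runs), with
boundary ties again resolved by pair id so truncation is
bit-reproducible.

## Diffusion prioritization

Seed-gene signal spreads by the iterative-ranking update

$$f^{t+1} = \alpha f^0 + (1-\alpha)\,U f^t,$$

run for a fixed 100 iterations with back probability $\alpha = 0.5$ and
$f^0$ uniform over the seeds. $U$ column-normalizes link weights
($U_{ij} = w_{ij}/\text{wdeg}(j)$, the random-walk-with-restart
convention), which guarantees geometric convergence for any
$\alpha > 0$; the exact fixed point
$f^\star = \alpha (I - (1-\alpha)U)^{-1} f^0$ is implemented as an
independent check and agrees with the iteration to $10^{-6}$ max-norm
on random networks. Per-gene significance (`p_mono`) compares each
observed score with scores from random seed sets of equal size, sampled
uniformly (the literal reading of the procedure; degree-matched seed
nulls were considered and not adopted). Isolated genes score 0 with
`p_mono` 1.

## Communities

Louvain community detection runs on the weighted graph via igraph,
optimizing resolution-scaled modularity

$$Q = \sum_c \left[ \frac{w_c^{in}}{W} - \gamma \left(\frac{s_c}{2W}\right)^2 \right],
\qquad \gamma = \frac{1}{\text{resolution}},$$

so that *increasing* the user-facing resolution merges communities —
the convention of the network-visualization tools this workflow grew up
with. Because the greedy sweep depends on node visit order, the
returned partition is the best of 10 deterministic restarts (sub-seeds
derived from the user seed); on an exhaustive sample of small graphs
this reaches the true maximum-modularity partition, where single runs
occasionally stall in local optima. Communities are relabeled
deterministically (size-descending, ties by smallest member id), so
"community 5" means the same thing across reruns with one seed.
Downstream analyses keep communities of at least 20 genes.

## Permutation statistics and their nulls

All enrichment-style tests share one machinery: an observed statistic,
`n_perm` null draws, and the add-one empirical p-value
$(1+r)/(1+n)$, which is never 0 and bounded below by $1/(n+1)$.

Random gene sets are matched on nuisance covariates — coding-sequence
length always, network degree where connectivity itself would bias the
statistic — by joint decile binning: each target gene is replaced by a
uniform draw (without replacement within a draw) from universe genes in
the same joint bin, with empty bins falling back to the nearest
nonempty bin by bin-index (Manhattan) distance. The matching algorithm
itself was unspecified upstream; decile binning is simple, fast and
auditable, and the calibration tests confirm uniform p-values under
matched-null resampling.

Genomic-interval nulls use circular shifts in gene-rank space: each
chromosome's intervals move together by one shared random offset with
wrap-around. This preserves exactly the two properties that matter —
every interval keeps its gene count, and the intervals' relative
spacing (genomic clustering) is untouched.

Specific tests: community/set enrichment counts set genes inside a
community (CDS-length matching only, as for membership counts);
functional clustering sums link weights inside a set (CDS length and
degree matched); the two-set variant sums links internal to
$A \cup B$ and resamples both sets; interval/community enrichment
counts intervals harbouring at least one community gene against
shifted intervals; annotation and tissue enrichment run one shared
batch of matched draws across all terms/tissues and BH-adjust.
Bonferroni and BH adjustments delegate to `stats::p.adjust`. All tests
are one-sided in the enrichment direction except the variant-burden
rate difference, which is two-sided on $|d|$ (sidedness was unstated
upstream; a risk difference can go either way).

## Variant burden

For a gene set and a case/control panel,
$d_{obs} = x_{cases}/n_{cases} - x_{controls}/n_{controls}$ compares
per-individual variant rates, with significance from permuting labels
at fixed group sizes. The logistic model
$\mathrm{logit}\,P(Y=1) = \beta_0 + \beta_1 X$ (with $X$ the
per-individual variant count; a per-gene-count variant is available)
gives $OR = e^{\beta_1}$ with a Wald 95% interval, matching the
symmetric intervals reported in this literature. Complete separation is
flagged (`converged = FALSE`) rather than reported as an estimate. The
upstream per-gene association test (e.g. SKAT-O) is *not*
reimplemented; its p-values are consumed as input by the
$\sum -\log_{10} p$ gene-set burden, nulled against CDS-length-matched
gene sets.

## Tissue specificity

Within each tissue, genes are ranked by mean expression (ascending,
midranks for ties; higher expression means a higher scaled rank — the
direction was unstated upstream and is chosen so specificity peaks
where expression peaks), scaled to $[0,1]$ by $(r-1)/(n-1)$, and each
gene's cross-tissue vector is Euclidean-normalized. The result is
invariant to any monotone transformation of within-tissue expression.
Genes bottom-ranked everywhere would yield a zero vector; they are
flagged and assigned the uniform vector $1/\sqrt{T}$ rather than
dropped, as are exactly-tied genes. Set-level enrichment sums the
set's components per tissue against CDS-length-matched draws, with BH
adjustment across tissues.

## The synthetic study conditions

Every input format has a generator with planted structure, so the whole
pipeline is testable without external corpora. The defaults define the
study conditions used throughout the tests and the acceptance script:

* Ontology: balanced `is_a` tree, depth 4, branching 3 (121 terms),
  with 3 designated branch roots — a miniature of a phenotype
  vocabulary organized under a few dozen top categories.
* Genes: 120 annotated genes (150 in the acceptance script), 6–8
  planted modules of 12 genes; module members draw their 3 leaf terms
  from a small shared leaf cluster inside one branch, so within-module
  phenotypic similarity exceeds between-module similarity.
* Evidence: four datasets with informativeness 1, 0.8, 0.6 and 0 (pure
  noise), each a noisy monotone transform of true benchmark similarity
  (Gaussian noise, sd 0.1) covering 60% of pairs — emulating a
  compendium in which sources vary in quality and coverage and at
  least one is worthless.
* Network: stochastic block model, 4 blocks of 50, within-block edge
  probability 0.3, between 0.01, unit weights.
* Case/control: 2,000 + 2,000 individuals, 10 risk genes with
  Poisson(0.02) carrier counts, per-variant odds ratio 1.5 planted
  through a logistic model whose intercept is solved for a 50% case
  fraction.
* Expression: 10 tissues, log-normal baseline, one 20-gene set
  up-shifted 5-fold in one tissue; intervals: 12 intervals of exactly
  5 consecutive genes on 4 chromosomes.

These generators reproduce the *structure* the statistics target —
modularity, monotone evidence, planted risk and specificity — but not
the marginal distributions of real corpora (annotation-depth skew,
scale-free degree tails, LD between variants, batch effects in
expression). Passing tests therefore demonstrate correctness of the
algorithms and calibration of the nulls, not end-to-end performance on
consortium-scale data, whose headline figures depend on corpora this
package deliberately does not bundle.

A single master seed fans out to per-component seeds via
`derive_seed(master, tag) = (master * 7919 + sum(utf8(tag)) * 104729)
mod (2^31 - 1)`, so any stage can be reproduced in isolation; every
randomized function takes an explicit seed recorded in its output.

## Numerical and degenerate-input choices

* Score ties everywhere break lexicographically by pair or gene id;
  all orderings are total, so every artifact is byte-reproducible.
* Polynomial growth stops early if the current fit is numerically
  exact (residual sum of squares below $10^{-12}$), where the nested F
  is undefined.
* Rescored weights are clamped to be non-negative; zero-weight links
  are dropped before network construction.
* `weighted_sum` of a single value is that value; empty input is an
  error, and pairs dropped by a dataset's threshold contribute nothing
  (not zero) to WS.
* Diffusion on genes unreachable from every seed returns exactly 0.
* Problem sizes in the test suite (benchmarks of ~7,000–20,000 pairs,
  networks of 200 genes, 500-replicate calibrations at `n_perm = 199`)
  were chosen as the smallest instances at which each statistical
  property is clearly resolvable.

## Known limitations

* Only `is_a` relations are traversed; `part_of` and other relations
  are ignored, and only annotation-frequency IC is offered (no
  descendant-count IC, no Lin/Jiang–Conrath variants).
* No alternative integration schemes (Bayesian log-likelihood ratios,
  learned weights) and no heat-kernel or directed diffusion.
* Permutation nulls are exact but Monte-Carlo: p-values are bounded
  below by $1/(n_{perm}+1)$, which matters when adjusting across many
  tests.
* Interval derivation from LD structure is upstream of this package;
  intervals arrive as BED plus a gene order.
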