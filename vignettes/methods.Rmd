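---
title: "Models and methods behind haplopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind haplopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplopop)
```

haplopop implements the standard mitochondrial phylogeography workflow —
diversity, differentiation, networks, demographic history — for samples
organised in a strict hierarchy (range > area > collection site). This
vignette records the statistical models, the numerical choices, and the
places where the design was genuinely open and a decision had to be made.

## Data model and missing data

An alignment is a character matrix over `{A,C,G,T}` plus missing symbols
(`N`, `-`, IUPAC ambiguity codes). Two policies matter downstream:

* **Haplotype collapsing is exact-match.** Sequences differing only at a
  position where either carries missing data are *not* merged. Merging
  across missing data would fabricate identity and silently inflate modal
  haplotype counts; the cost of the conservative policy is that a
  low-quality sequence can appear as a spurious rare haplotype, which is
  visible (and fixable) rather than hidden.
* **Distances use pairwise deletion.** Each pair is compared on the sites
  where both carry a plain base. Segregating-site counts use the same
  rule column-wise (a column is variable when at least two distinct
  non-missing bases occur).

The NUMT screen translates a declared coding sub-region in a declared
frame with NCBI translation table 5 (invertebrate mitochondrial; stops
are only `TAA`/`TAG` there). The frame is never auto-detected: choosing
the frame that minimises stop codons would mask exactly the pseudogenes
the screen exists to catch.

## Diversity

Gene diversity is Nei's bias-corrected heterozygosity analogue
$H = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, with Nei's (1987)
sampling variance. Nucleotide diversity is
$\pi = \frac{n}{n-1}\sum_{i<j} 2 p_i p_j d_{ij}$ with $d_{ij}$ the K2P
distance between haplotypes in substitutions per site; the identity
$\pi = $ mean pairwise distance over sample pairs is used as an oracle in
the tests. K2P-corrected $\pi$ and *raw* mean pairwise differences
$\hat k$ are both exposed because the mismatch machinery needs raw
counts. Statistics are reported at four decimals; at the 1–2 mutation
scale typical of intraspecific mtDNA the K2P correction is tiny, so $\pi$
and the p-distance version agree to the second decimal.

## AMOVA and the exact test

The two-level AMOVA decomposes squared pairwise distances into
among-group ($\sigma_a^2$), among-population-within-group ($\sigma_b^2$)
and within-population ($\sigma_c^2$) components using the standard
expected-mean-square coefficients for unbalanced designs, and reports
$\Phi_{CT} = \sigma_a^2/\sigma_T^2$,
$\Phi_{SC} = \sigma_b^2/(\sigma_b^2+\sigma_c^2)$,
$\Phi_{ST} = (\sigma_a^2+\sigma_b^2)/\sigma_T^2$. A convention worth
stating: raw difference counts **are** squared Euclidean distances in
site-indicator space, so a raw-count matrix is used as-is
(`squared = TRUE`); model-corrected distances should be passed with
`squared = FALSE`, which squares the entries first. Permutation schemes
follow the level being tested: whole populations among groups
($\Phi_{CT}$), samples among populations within groups ($\Phi_{SC}$),
samples among populations ignoring groups ($\Phi_{ST}$); p-values count
permuted statistics $\ge$ observed, with the $+1$ correction. Negative
variance components are reported as estimated, not clipped — they are
informative about near-zero structure. Note that with few populations
per group the $\Phi_{CT}$ permutation distribution is coarse (there are
only $\binom{P}{P_1}/2$ distinct assignments), which bounds the smallest
attainable p-value; this is a property of the design, not the
implementation.

The exact test of differentiation runs a Metropolis chain over
population-by-haplotype tables with fixed margins: each step proposes
moving one unit around a random 2×2 submatrix, accepted with probability
$\min(1, ad/((b{+}1)(c{+}1)))$, the ratio of conditional table
probabilities; the p-value is the fraction of post-burn-in states whose
log-probability ($-\sum \log x_{ij}!$) does not exceed the observed
table's. Defaults (100,000 steps, 10,000 dememorisation) match common
practice; a batch-means standard error accompanies the estimate.

## Statistical-parsimony networks

The connection limit is the largest step count $j$ whose probability of
parsimony is at least the cut-off (default 0.95). The probability model
follows the statistical-parsimony framework: sites evolve independently
as a two-state process; conditional on a path of expected length
$\lambda$ substitutions per site, a differing site carries exactly one
change with probability $\lambda/\sinh\lambda$ and an identical site
carries none with probability $1/\cosh\lambda$, so
$P(\text{parsimony}) = (\operatorname{sech}\lambda)^{L-j}
(\lambda/\sinh\lambda)^{j}$. $\lambda$ is integrated over its posterior
given $j$ differences in $L$ sites (uniform prior on the per-site
difference probability $q$, i.e. $q \mid j \sim \mathrm{Beta}(j{+}1,
L{-}j{+}1)$ truncated below $1/2$, with $\lambda = -\log(1-2q)/2$),
evaluated by adaptive quadrature. For $L = 1697$ at 95% this gives an
11-step limit — comfortably above the 7-step diameter of the bundled
dataset, so its 32 haplotypes join a single network. The estimator is
monotone in $L$ and never reports less than one step.

Agglomeration processes pairs by increasing distance (ties: higher
combined frequency first, then lexicographic ids — the historical tool's
internal order is undocumented, so determinism is the design goal).
A $d$-step connection inserts $d-1$ zero-count median nodes; a
same-component pair is connected only when the new path would be
*strictly* shorter than the existing one, which is what creates
reticulations. Loops are broken by deleting the least-supported cycle
edge under three ordered criteria — smallest combined endpoint frequency;
then smallest combined endpoint degree (tip over interior); then
endpoints sharing no collection site — with a logged lexicographic
tie-break. After resolution a connected network is a tree
(`edges = nodes - 1`), and in the all-unit-distance case a minimum
spanning tree over the observed haplotypes.

## Neutrality tests

Tajima's $D$ uses the 1989 constants
($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$) with $S$ segregating sites and
$\hat k$ mean pairwise differences. Its p-value is one-tailed lower,
$P(D_{sim} \le D_{obs})$, over genealogies simulated at constant size
conditional on the observed $S$ (Hudson's fixed-S scheme: exactly $S$
mutations placed multinomially by branch length). One-tailed lower
matches the expansion-scanning use of the test and common software
convention; the output documents it.

Fu's $F_s = \ln(S'/(1-S'))$ with
$S' = \Pr(K \ge k_{obs} \mid \theta = \hat k)$ under the Ewens sampling
distribution, computed from unsigned Stirling numbers of the first kind
by a log-space recursion (stable to $n$ in the hundreds). The p-value is
$P(F_{s,sim} \le F_{s,obs})$ over constant-size simulations at
$\theta = \hat k$ — Fu's original conditioning, chosen here because the
fixed-S scheme conditions on the wrong statistic for $F_s$. Following
the usual convention, $F_s$ is treated as significant at the 5% level
only when $p < 0.02$; calibration checks in the test suite use that
threshold.

## Mismatch distributions and dating

Under sudden expansion the coalescence "age" $x$ of a random pair (in
units where the expected pairwise difference count equals $x$) has the
two-phase exponential density
$f(x) = e^{-x/\theta_1}/\theta_1$ for $x<\tau$ and
$e^{-\tau/\theta_1} e^{-(x-\tau)/\theta_0}/\theta_0$ beyond, and the
difference count is Poisson($x$). Integrating gives a closed form: the
class probabilities are a geometric($\theta_1$) term damped by a
regularised-gamma factor plus $e^{-\tau/\theta_1}$ times a
Poisson($\tau$)–geometric($\theta_0$) convolution. The implementation
evaluates this with cumulative products/sums (the regularised gamma over
consecutive integer shapes is a Poisson tail) and folds the tail mass
beyond the last observed class into it, so expectations always sum to
one. Limits are honoured exactly: $\tau = 0$ gives the equilibrium
geometric in $\theta_0$ (independent of $\theta_1$);
$\theta_1 \to \infty, \theta_0 \to 0$ gives Poisson($\tau$).

Fitting minimises $SSD = \sum_i (x_i - F_i)^2$ by L-BFGS-B with an
analytic gradient (verified against central differences in the tests)
from four deterministic starts, keeping the best; bounds are
$\tau \in [0, 2d]$ ($d$ = largest observed class) and
$\theta_0, \theta_1 \in [10^{-6}, 10^5]$ (the upper bound standing in for
"infinite" post-expansion size). The parametric bootstrap simulates $B$
coalescent samples of size $n$ under the fitted model, refits each with
the *identical* four-start estimator — reusing the parent estimate as the
only start narrows the bootstrap distribution and invalidates the CI —
and reports $p_{SSD}$ and $p_r$ (fractions of simulated statistics at
least as large as observed) plus the 2.5/97.5 percentile interval for
$\tau$. $B$ defaults to 10,000; the test suite uses 500. The least
squares $\hat\tau$ is upward-biased at moderate sample sizes (a known
property of the estimator, visible in the coverage test), and the
percentile interval inherits that bias; it is kept because it is the
standard reporting convention for this analysis.

Expansion ages convert to years as $t = \tau/(2 \cdot rate \cdot L)$
with `rate` the divergence rate per site per year; the package defaults
carry the two rates commonly applied to insect mtDNA, $2.3\times10^{-8}$
and $2.6\times10^{-8}$ (2.3%/2.6% divergence per Myr). CI endpoints
transform identically.

## The synthetic-data generator

The coalescent simulator works directly in mutational-time units:
lineage pairs coalesce at rate $1/\theta(x)$ and every lineage mutates at
rate $1/2$, so simulator parameters plug into $F_i(\tau, \theta_0,
\theta_1)$ with no rescaling, and the step-expansion pairwise age density
equals the fitted model by construction. Mutations follow the
infinite-sites model on distinct columns with a uniformly chosen
replacement base; transitions and transversions are *not* modelled
asymmetrically, which matches the analytical mismatch theory being
tested but means simulated K2P distances essentially equal p-distances —
fine at intraspecific divergences, not a test of the K2P correction
itself. An optional coding-region mode draws a stop-free ancestral
backbone and redirects any substitution that would create an internal
stop, so simulated mitochondrial fragments always pass the NUMT screen.
The two-range scenario coalesces each deme under its own expansion
history up to the split time, then merges survivors into an ancestral
pool; there is no migration, recombination or selection.

The deterministic bundled dataset reproduces a two-range outbreak
sampling design exactly at the count level: 130 samples over 23 sites in
seven areas and three ranges, collapsing to 32 haplotypes with modal
counts 34 and 20, two range-shared haplotypes, and star topologies
around both modal haplotypes. Step assignments beyond those fixed by the
design (which satellite attaches where, the two-step placement of the
outlying range) are arbitrary but deterministic and documented in the
source; they affect nucleotide diversity and network layout but no
haplotype count, so every count-based summary is exact while
$\pi$-level numbers are only qualitatively comparable to any real
dataset. A note on a design ambiguity: the underlying study design is
internally inconsistent about which haplotype the outlying range shares
with the second range; the bundled dataset follows the per-site count
table (shares the second range's modal haplotype), not the prose.

What passing tests on this generator do *not* show: robustness to
homoplasy (real mtDNA shows recurrent mutation — the real data have
fewer variable sites than haplotypes, which infinite-sites data cannot
reproduce), to sequencing error, to ambiguous bases, or to
rate heterogeneity across sites.

## Test problem sizes and calibration conventions

The statistical acceptance checks run at sizes chosen to give stable
Monte-Carlo verdicts on one CPU: 500 constant-size replicates
($n = 30$, $\theta = 5$, 200 null simulations per p-value) for
calibration of $D$ and $F_s$; 100 step-expansion replicates ($n = 40$,
$\tau = 5$, 100-fold growth) for power and mismatch unimodality
(assessed as a single local maximum after 3-bin moving-average
smoothing); and 100 replicates ($n = 50$, $\tau = 3$, $\theta_0 = 1$,
$\theta_1 = 50$) with $B = 500$ bootstrap refits for CI coverage. Under
these conditions the unimodality rate sits essentially at its 90%
reference line — isolated far-tail difference classes survive 3-bin
smoothing as genuine (if negligible) secondary modes — so that check is
expected to hover around its threshold.

## Known limitations

* Locus-by-locus AMOVA in the missing-data-weighted sense is not
  implemented; per-partition AMOVAs and the concatenated analysis stand
  in for it (the bundled data have no per-locus missingness).
* The network module implements the connection-limit + agglomeration
  core of statistical parsimony, not probability-weighted root placement
  or clade nesting.
* The exact-test chain is a single run; for tables far larger than the
  defaults were chosen for, users should raise the chain length and watch
  the reported standard error.
* No multiple-testing correction is applied anywhere; tables report raw
  p-values, and the pipeline documents this.
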