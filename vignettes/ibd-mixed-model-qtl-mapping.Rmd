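---
title: "IBD-based mixed-model QTL mapping in multiparental populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IBD-based mixed-model QTL mapping in multiparental populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Multiparental populations (MPPs) — diallels, nested association mapping
(NAM) panels and multiparent advanced generation intercrosses (MAGIC) —
combine the broad diversity of association panels with the controlled
structure of biparental crosses. Mapping quantitative trait loci (QTLs) in
them raises two modelling questions: how to define a QTL effect when more
than two founder alleles segregate, and how to control the multilevel
relatedness of offspring within and across families. `ibdqtl` answers both
with a single pipeline: founder-origin (identity-by-descent, IBD)
probabilities are reconstructed along the genome by a hidden Markov model
(HMM) and turned into *genetic predictors* — the expected number of alleles
each offspring inherited from each founder — which then carry multiallelic
random QTL effects inside a REML mixed model.

## The six models

All models act on a phenotype vector $Y$ ($N$ individuals in $F$ families
from $P$ founders) with family intercepts $X\beta$ fixed. The tested locus
$q$ contributes $M_q a_q$, where $M_q$ is the $N \times P$ predictor matrix
(twice the posterior founder-origin probability; rows sum to 2) and
$a_q \sim N(0, I_P\sigma_q^2)$ is the vector of random parental effects.
The models differ in how they treat the genomic background and the
residual:

| model          | background                  | residual             |
|----------------|-----------------------------|----------------------|
| `IBD.SQM_U`    | —                           | uniform              |
| `IBD.SQM_F`    | —                           | family-specific      |
| `IBD.MQM_F`    | cofactors $\sum_c M_c a_c$  | family-specific      |
| `IBD.Kin_F`    | polygenic $g$, kinship $K$  | family-specific      |
| `IBD.MQMkin_F` | cofactors + polygenic       | family-specific      |
| `IBS.Kin`      | polygenic                   | uniform              |

`IBS.Kin` is the GWAS benchmark: the locus enters as a fixed allele-dosage
covariate $X_q\lambda_q$ tested by a Wald test. The five IBD models test
$H_0\!: \sigma_q^2 = 0$ with the likelihood ratio
$\mathrm{LRT} = \max(0,\, 2(\ell_A - \ell_0))$ referred to the boundary
mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$, so $p = \tfrac12
\Pr(\chi^2_1 \ge \mathrm{LRT})$ and $p = 1$ at zero. A single family (as in
MAGIC) degenerates the fixed part to a global intercept and makes the `_F`
residual uniform, so `IBD.SQM_F` and `IBD.SQM_U` coincide there — the test
suite asserts this equivalence to 1e-8.

Kinship is VanRaden's IBS genomic relationship matrix,
$K = WW^\top / (2\sum_k p_k(1-p_k))$ with dosages centred by twice the
pooled-sample allele frequency and missing dosages mean-imputed per marker
(the pooled-frequency and mean-imputation choices are conventions; the
sources are silent on both). Scans use the leave-one-chromosome-out (LOCO)
matrix of the scanned chromosome to avoid proximal contamination.

## IBD reconstruction

Offspring at F6 are nearly fully inbred, so the hidden state at a locus is
the single founder of origin (admissible states: the family's two parents,
or all founders in MAGIC; the prior $\pi$ is uniform over them). Along a
chromosome the origin chain uses the kernel

$$T(i \to j \mid d) = e^{-\rho d}\,1\{i=j\} + (1 - e^{-\rho d})\,\pi_j,$$

with $d$ the map distance in Morgan and $\rho$ the *junction density* —
expected founder-origin junctions per Morgan on an offspring genome. An
exact pedigree-recursive prior is out of scope here; instead $\rho$ is
calibrated per design by simulating the breeding pedigree and counting
realized junctions (about 1.9/Morgan for biparental F6 families, about
2.9/Morgan for 4-way MAGIC; the Haldane–Waddington limit of 2 for
biparental selfing is recovered at deep generations). Emissions allow a
genotyping error rate $e$ (default 0.005, configurable; the upstream
error-model parameters are not published, so this is a free default):
an observed homozygous dosage consistent with the founder allele has
probability $1-e$, an inconsistent one $e$; missing observations — and
observed heterozygotes, the rare residual F6 heterozygotes — are treated
as uninformative, which avoids a $P^2$ paired-state space. Posteriors come
from a scaled forward–backward recursion, vectorized over offspring; a
log-domain variant exists purely as a numerical cross-check (agreement
to 1e-9 is asserted in tests, as is exact agreement with brute-force path
enumeration on small chromosomes to 1e-10). Whether the original analyses
decoded NAM/diallel families jointly or per family is not stated; decoding
here is per family. Markers with missing founder genotypes are dropped
before decoding.

## The scan procedure

The genome scan refits the null model once per chromosome × cofactor
configuration, not per marker, and warm-starts each alternative fit from
the neighbouring marker's solution. The significance threshold is
Bonferroni, $T = -\log_{10}(\alpha/m)$, with an explicit override (the
reference simulation experiments use 4.2 on 462 markers; the formula gives
4.66 at $\alpha = 0.01$ — the 4.2 actually used upstream is not derivable
from the formula, so it is reproduced as a configured override rather than
guessed at).

Cofactor models iterate: scan, select cofactors greedily, rescan with the
cofactors as additional random effects (their own variances, as the model
table specifies — not fixed covariates), until the selected set is
unchanged between rounds or 10 rounds elapse. Correlated cofactors some
20–25 cM apart can produce a two-cycle (jointly they absorb each other's
signal, the depleted profile selects a smaller set, which lets the pair
reappear); when a round's selection repeats any earlier round's selection
the iteration stops immediately on the current profile — whose greedy
selection is exactly the recurring set — and the report carries a
`stabilized = FALSE` flag. Two windows matter and they
are deliberately different:

* **In-model exclusion (±10 cM)**: when the tested marker lies within
  10 cM of a cofactor on the same chromosome, that cofactor is dropped
  from the model for that test (the composite-interval-mapping convention,
  which yields full profiles). A strict mode (`window_mode = "skip"`)
  instead skips such markers entirely, reproducing the literal "no tests
  within the window" procedure.
* **Selection/merging mask (20 cM)**: the greedy selection masks all
  markers within 20 cM of a chosen peak. Masking only the ±10 cM
  half-width was tried first and rejected: single-QTL likelihood profiles
  have shoulders wider than 10 cM, so the half-width mask admits shoulder
  markers of an already selected peak as spurious extra cofactors, which
  then absorb the whole chromosome in the next round and make the
  iteration oscillate between a many-cofactor and an empty set. The 20 cM
  mask also guarantees called QTLs are pairwise more than 20 cM apart.

Whether a cofactor's own position should be re-tested each round is not
specified upstream; under the drop convention it is tested (with itself
removed), which is what keeps profiles complete.

A simulated major QTL counts as *detected* when the peak marker on its
chromosome exceeds $T$ and lies within 20 cM of the true position; the
peak distance is the *resolution*. Resolution is averaged over successful
replicates in the headline summary (whether upstream averages included
failed replicates is unstated; both conventions are computed, the
successful-only one is headline). False positives are super-threshold
markers on the QTL-free chromosome 5 of the final profile; their expected
count is $m_\text{null} \cdot R \cdot 10^{-T}$ (3.47 for 110 markers,
500 runs, $T = 4.2$).

Model choice uses $\mathrm{BIC} = (DF_\text{fixed}+DF_\text{var})
\ln(n-r+DF_\text{fixed}) - 2\ln L_\text{max}$ (smaller is better, ties
broken toward fewer variance parameters), each candidate refitted jointly
with its own final QTL set; parental effects at the selected QTLs are the
BLUPs $\hat a_q = \hat\sigma_q^2 M_q^\top \hat P y$.

## REML engine

$V(\theta) = \sigma_q^2 M_qM_q^\top + \sum_c \sigma_c^2 M_cM_c^\top +
\sigma_g^2 K + R(\theta)$ is maximized by average-information (AI) updates
with step halving on the REML log-likelihood, a second starting point as a
local-optimum guard, and an L-BFGS-B fallback on log-variances with the
analytic score. Everything is dense Cholesky at $N \le$ a few thousand —
simplicity over scale, matching the intended population sizes. Numerical
choices worth knowing:

* Variances are bounded below: residual components at
  $10^{-8}\,\mathrm{var}(y)$ (this floor also prevents degenerate
  zero-variance families of small $n_k$ in `_F` models), others at 0.
* A non-residual variance that converges to the boundary is snapped to
  exactly 0 when the profile likelihood is non-increasing there; this
  gives the LRT its honest point mass at 0.
* Convergence: relative log-likelihood change below 1e-8.
* The reported log-likelihood is the full REML log-likelihood (with its
  constant), so differences give the LRT and $\ln L_\text{max}$ feeds the
  BIC directly.
* `IBS.Kin` scans refit variance components per marker by default; a fast
  mode reuses the null components across a chromosome (documented
  approximation, checked in tests to correlate > 0.98 with the exact
  profile).

The engine is validated against closed forms (balanced one-way ANOVA,
OLS $t^2$), a refined 200×200 likelihood-grid oracle on a 12-observation
toy, and lme4 on random-intercept data.

## What the simulator emulates

The generator reproduces the reference simulation setting: four inbred
founders whose alleles are i.i.d. Bernoulli(0.5) per marker (the real
founder genomes are not packaged — only their statistical role matters),
overwritten at the three major-QTL markers so that 2, 1 and 3 founders
carry the trait-increasing allele; a 462-marker map on five chromosomes
(110 markers on the null chromosome 5, as the false-positive arithmetic
requires; 88 at 1 cM spacing on each of chromosomes 1–4, chosen so the
stated minor-QTL placement rule lands exactly 24 minors: majors at 44 cM
on 87 cM chromosomes give 6 minors each at ±20, ±30, ±40 cM, plus 6 on a
10 cM grid on chromosome 4). The exact chromosome lengths of the original
consensus map are not published; this fixture is a stand-in with a
realistic genome length (about 4.6 Morgan). Offspring are bred by
Poisson crossovers (mean = chromosome length in Morgan, uniform positions,
no interference, no obligate chiasma) and single-seed descent to F6;
lines branch at F2 — the standard RIL convention, as the branching
generation is not stated upstream. The funnel product of a MAGIC cross
counts as generation 1, so every design undergoes the same five selfing
rounds and residual heterozygosity is near $2^{-5}$. Genotypes are masked
missing completely at random at 5%; phenotypes follow
$Y = \sum_{3} 0.4\,z + \sum_{24} 0.1\,z + \varepsilon$,
$\varepsilon \sim N(0,1)$, with $z \in \{1,-1,0\}$ for the
allele-1 homozygote, allele-2 homozygote and residual heterozygote
(emitted as dosage 1 in the genotype table, indicator 0 in the trait).

What a green test does *not* establish: the generator has no genotyping
errors in founders, no segregation distortion, no marker-density
heterogeneity, no linkage-map error and no non-genetic family effects —
real MPP data have all of these, which is exactly why the HMM error rate
and the family-specific residuals are worth carrying in the models even
though the simulated world only mildly exercises them.

## Known limitations

* Only the three supported designs (and only 4-way MAGIC funnels);
  arbitrary pedigrees need an exact pedigree prior, which the calibrated
  kernel deliberately replaces at desk scale.
* Fully-inbred decoding: F2-style heterozygous populations would need the
  paired-origin state space that is out of scope here.
* Dense algebra limits $N$ to a few thousand.
* The variance-component test is underpowered for QTLs segregating in a
  single family (visible as low power for simQTL3 in NAM); a fixed-effect
  Wald test is the appropriate fallback there.
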