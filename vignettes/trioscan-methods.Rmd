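---
title: "Family-based association testing with trioscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based association testing with trioscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscan)
```

# Scope

`trioscan` analyses nuclear families ascertained for multiple affected
offspring (affected sib pairs, ASP), the design used in family studies
of celiac disease and other autoimmune disorders.  The pipeline covers:
hard-calling and quality control of imputed genotypes, the transmission
disequilibrium test (TDT) in a hard-call and an expected-count form, an
HLA-stratified TDT ranked by a weighted chi-square, multi-criteria
marker selection, a two-locus penetrance-model interaction analysis on
case/pseudo-control tables, and delta-delta Ct quantification of
follow-up qPCR expression data.  A seeded simulator generates
ascertained families with exactly the structure these stages assume, so
every stage is testable without external data.

# The TDT and its expected-count form

For a biallelic marker, each parent heterozygous A1/A2 transmits one
allele to the affected child; under no linkage and no association the
transmission is 50:50.  With `t` transmissions of A1 and `u` of A2
accumulated over parents, the statistic

$$\chi^2 = \frac{(t-u)^2}{t+u}$$

is referred to a 1-df chi-square upper tail.  `count_transmissions()`
implements the classical bookkeeping; the ambiguous double-heterozygote
trio (both parents and child A1/A2) contributes (1, 1), the average of
its two phase resolutions.

Genotype imputation yields a posterior triplet per genotype rather than
a call.  `hard_call()` applies the conventional strict rule: call the
genotype whose posterior exceeds 0.95, otherwise missing.  The
expected-count TDT avoids discarding uncertain trios:
`expected_transmissions()` enumerates the 27 joint genotype
configurations of a trio, weights each by the product of the three
members' posteriors, zeroes Mendelian-impossible configurations,
renormalises over the consistent mass, and averages the classical
counts.  Renormalisation keeps each trio's contribution on the same
scale as a hard-called trio (a trio with no consistent mass above
1e-9 is skipped).  The same chi-square functional is then applied to
the real-valued counts; its null distribution is approximately that of
the classical TDT, which the suite checks by simulation.  With
degenerate (certain) posteriors the expected counts reduce exactly to
hard-call counts — a property test enforces this identity.

Both affected siblings of an ASP family contribute their trios by
default; `one_per_family = TRUE` restricts to the first affected
offspring, the convention the interaction stage always uses.

# Mendelian masking and QC

Genotype errors surface as Mendelian inconsistencies.  At each marker a
fully-typed inconsistent trio has all three genotypes set to missing
(`mendelian_mask()`); trios with a missing member are vacuously
consistent and are not checked, mirroring how standard tools report
family-wise inconsistencies on called genotypes.  `marker_qc()` retains
markers with call rate strictly above 0.97 and reports the founder
(parental) minor allele frequency against a 0.01 threshold; the MAF
filter is reporting-only by default because imputed panels are usually
pre-filtered upstream.

# The stratified TDT

Homozygous carriers of the HLA-DQB1*02 risk allele carry a
substantially higher baseline risk, so risk factors outside HLA are
expected to be relatively more important in the remaining children.
`assign_stratum()` labels an offspring `high` when it carries
DQA1*02/05 and two copies of DQB1*02, `low` otherwise, and the TDT is
run separately in each stratum.  Markers are ranked by the combined
statistic

$$W = \frac{\sum_g (t_g-u_g)^2}{\sum_g (t_g+u_g)},$$

which weights each stratum by its informative transmissions, reduces
exactly to the plain chi-square with one stratum, and carries no
p-value — it is a ranking score.  Strata with `t+u = 0` drop out of
both sums.

# Marker selection and regions

Three inclusion criteria feed the downstream analyses (all comparisons
strict, matching their usual "less than" phrasing):

1. expected-count TDT p-value < 3.0e-4;
2. replication: internal p < 0.01, external p < 0.05, product
   < 5.0e-5, and the same allelic direction after harmonising the
   external effect allele to the panel's A1 (markers whose external
   allele matches neither panel allele are dropped from this criterion
   with a warning);
3. effect size: transmission ratio t/u below 0.2 or above 5 (u = 0
   counts as infinite) with p < 2.0e-3.

A marker is selected when it passes any criterion.  Selected markers
are merged into regions by a single sorted pass per chromosome: gaps of
100 kb or more split regions, so within-region adjacent gaps are
< 100 kb.  The extended HLA interval (chromosome 6, 27–34 Mb) is
excluded from selection; a designated HLA tag marker can be re-added as
an interaction partner.  Gene annotation attaches the up-to-5 nearest
genes within 250 kb of the marker (distance to the nearer interval
endpoint, 0 inside the gene, ties broken by symbol), falling back to
the single nearest gene when none is in range.

# Two-locus interaction model

For a pair of unlinked selected markers, one affected offspring per
family supplies a case genotype pair and the untransmitted parental
alleles supply a matched pseudo-control pair
(`pseudo_control_genotype()`, the dosage identity
`father + mother − child`).  Let `n` and `m` be the paired 3×3 count
matrices.  With Hardy–Weinberg, no-LD genotype frequencies
$g_{ij} = h^A_i h^B_j$ and penetrance matrix $f$, the log-likelihood is

$$\ell = \sum_{ij} n_{ij}\,
\log\frac{g_{ij} f_{ij}}{\sum_{kl} g_{kl} f_{kl}}
 + \sum_{ij} m_{ij}\, \log g_{ij}.$$

Four nested models are compared: `M0` (constant `f`, no association),
the Risch heterogeneity model `MR`
($f_{ij} = 1-(1-\alpha_i)(1-\beta_j)$: risk from either locus
independently), the multiplicative model `MM`
($f_{ij} = \alpha_i\beta_j$) and the general model `MG` (free 3×3
matrix).  `MM` is the best-fitting model when at least one member of
the pair is a false positive, so the `MM`-versus-`MG` test (`P_M2`)
filters chance pairs; `P_02` (`M0`-versus-`MG`) screens for any joint
association and `P_12` (`MR`-versus-`MG`) separates epistasis from
heterogeneity.

**Maximisation.**  The case term depends on `f` only up to scale.
Under `MG` the case cell probabilities are therefore unrestricted and
under `MM` they form an arbitrary product distribution, while the
pseudo-control term alone determines the frequency estimates.  This
gives exact closed forms: `MG` pairs the saturated case fit with
pseudo-control-margin allele frequencies; `MM` pairs the independence
case fit with the same frequencies; `M0` pools both tables into one
Hardy–Weinberg fit.  Only `MR` has no closed form and is maximised by
bounded L-BFGS-B (frequencies in [0.001, 0.999], penetrance factors in
[1e-6, 1−1e-6]) from a moment start, a constant-penetrance start at
the `M0` optimum (guaranteeing the nesting inequality after
optimisation), and ten seeded random restarts, best restart kept.  The
closed forms are exact maxima, so the nesting
$\ell_{M0} \le \ell_{MR}, \ell_{MM} \le \ell_{MG}$ holds by
construction; the suite cross-checks all fits against grid-search and
direct numeric optimisation oracles.

**Degrees of freedom.**  The case distribution identifies `f` only up
to scale, so the identifiable parameter counts are 2 (`M0`), 6 (`MM`),
7 (`MR`) and 10 (`MG`), giving 8, 4 and 3 df for `P_02`, `P_M2` and
`P_12`.  The likelihood-ratio statistic is clipped at zero before the
chi-square tail.  A 1000-replicate null simulation in the acceptance
suite confirms that `P_02` holds its level at these df.

**Classification.**  A pair is reported when `P_02 < 1e-4`; among
reported pairs, `P_M2 ≥ 0.05` is multiplicative-consistent, otherwise
`P_12 < 1e-4` labels epistasis and `P_12 > 0.05` heterogeneity;
p-values between the two bounds stay reported but unlabelled.  Under
the null, `round(n_pairs × 0.05)` reported pairs are expected to
reject `MM` by chance (`expected_null_pairs()`).

Pairs are enumerated across regions only (within-region pairs are
LD-confounded), and pairs with fewer than 20 complete families are
skipped.

# Delta-delta Ct expression analysis

Each sample's reference value is the arithmetic mean Ct of the
configured reference genes (ACTB, EPCAM and PGK1 by default) — on the
quantity scale the geometric mean of their $2^{-Ct}$ values.  The
relative quantity of a target is $2^{-\Delta Ct}$ with
$\Delta Ct = Ct_{target} - Ct_{ref}$.  Fold change is the ratio of
group mean quantities reported as a magnitude ≥ 1 with an UP/DOWN
direction (control mean normalised to 1; an exact tie reports UP).
Groups are compared by a two-sided Welch t-test on ΔCt values — chosen
because ΔCt is the scale on which qPCR noise is approximately normal;
a Mann–Whitney option is provided since published tables rarely state
the test.  Bonferroni correction multiplies by the number of assays
with a computable p-value (38 in the motivating dataset, exposed as a
parameter); undetected assays are recorded but excluded from the
multiplier.

# The simulator: what it emulates, and what it does not

`simulate_families()` draws parents from Hardy–Weinberg equilibrium at
independent loci, transmits alleles Mendelianly, assigns affection from
the configured penetrance components (combined as
$1-\prod_c(1-f_c)$), and keeps families with at least the ascertained
number of affected offspring, repeating until the target count.
Defaults are fixed at the study conditions: 97 nuclear families, two
offspring, ascertainment on ≥ 2 affected, and a genotype-independent
background penetrance of 0.10 — the order of the sibling recurrence
risk of celiac disease.  The stratification locus proxies the HLA rule
as "high iff homozygous for the risk allele".  `blur_posteriors()`
mixes the true-genotype indicator with a symmetric Dirichlet(1,1,1)
draw; λ = 0.05 keeps roughly 90 % of genotypes above the 0.95 calling
threshold, the regime reported for well-imputed panels, and λ = 0
reduces expected counts to hard calls exactly.

Planted effect sizes used in the validation suite were chosen once as
"strong" exemplars of their model class: a single-locus effect with
genotype relative risks (1, 3, 9) on baseline 0.05; an epistatic pair
with penetrance 0.02 rising to 0.40 only when both loci carry a risk
allele; and a heterogeneity pair with Risch factors
α = β = (0.01, 0.20, 0.35), all at risk-allele frequency 0.3.  Null
calibration runs use a constant penetrance of 0.5: with
genotype-independent affection, ascertainment is unbiased by
construction and the retention rate (1/4 of attempted families) keeps
replicate counts practical; only attempt counts, not the null
distribution, depend on this value.

The simulator deliberately omits linkage disequilibrium and haplotype
structure (matching the interaction model's no-LD assumption),
population stratification, and genotyping-error mechanisms beyond the
Dirichlet blur.  Passing tests therefore demonstrate correctness of
the statistical machinery under the model's own assumptions, not
robustness to LD-induced confounding in real panels — within-region
pairs are excluded from the interaction scan for exactly that reason.

# Numerical choices and degenerate inputs

* Posterior triplets may sum to less than 1 (residual missingness);
  sums above 1 + 1e-6 are rejected.
* The hard-call threshold comparison is strict (`> 0.95`), so a
  posterior of exactly 0.95 stays missing; QC retention is strict the
  other way (call rate must exceed 0.97).
* Markers with `t + u = 0` are flagged non-informative with missing
  statistic and p-value; transmission odds are missing when `u = 0`.
* Allele frequency estimates are clamped to [0.001, 0.999] before
  entering Hardy–Weinberg terms, so the likelihood never sees a zero
  genotype-class frequency with observed counts.
* `0·log 0` terms in the saturated and independence fits are 0.
* Restart ties in the `MR` fit break toward the earliest start
  (deterministic given the seed); the global RNG state is restored
  after seeded draws inside fits.
* Region building, selection and classification are pure functions of
  their inputs; pipeline artifacts (TSVs and JSON manifests without
  timestamps) re-run byte-identically from a fixed seed.

# Problem sizes in the validation suite

The suite simulates at sizes chosen to make the statistical assertions
sharp but quick: 1000 null replicates of 100 families for LRT
calibration, 100 replicates of 500 families per planted interaction
model for discrimination and parameter recovery, 300 replicates of 80
families for TDT level checks, and a 50-family end-to-end pipeline
run.  The full suite completes in a few minutes on one core.

# Known limitations

* The expected-count TDT's chi-square reference is approximate; at
  extreme blur (λ near 1) most genotypes are uninformative and the
  statistic loses calibration along with power.
* The interaction likelihood treats the pseudo-control distribution as
  unconditional Hardy–Weinberg; conditioning on parental genotypes
  would change the frequency terms under strong single-locus
  association.  The implemented form is the one validated by the null
  calibration.
* The weighted chi-square is a ranking statistic without an attached
  null distribution.
* GRAIL-style recombination-hotspot gene assignment is not
  implemented; the 250-kb distance rule is the sole annotator.
* Efficiency-corrected (Pfaffl) qPCR quantification and reference-gene
  stability selection are out of scope; reference genes are an input.
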