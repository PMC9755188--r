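---
title: "Across-breed GWAS with breed prevalence phenotypes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Across-breed GWAS with breed prevalence phenotypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedscan)
```

## The problem

Whole-genome sequencing repositories of purebred dogs record breed and sex
but no disease phenotypes. For complex orthopedic diseases — hip dysplasia,
elbow dysplasia, cruciate ligament rupture — what *is* known is each
breed's epidemiological disease prevalence. Because strong artificial
selection and bottlenecks have enriched large-effect risk alleles
differentially across breeds, a genome-wide association scan can contrast
*breeds* rather than individuals: every dog carries its breed's prevalence
as a quantitative stand-in phenotype, and association is driven by variants
whose allele frequencies co-vary with prevalence across breeds.

This design has two structural difficulties that shape everything in this
package: breed representation in repositories is extremely unbalanced (one
to dozens of dogs per breed), and breed identity is itself the dominant
axis of genetic variation, so population-structure confounding is severe by
construction. `breedscan` implements four association engines that take
different positions on this trade-off, together with the QC, breed
verification, relatedness and reporting machinery around them, and a
cohort simulator that makes the whole chain testable.

## Quality control and the filter ledger

Two filtering stages mirror standard practice. The site-quality stage
retains biallelic single-nucleotide variants with site quality at or above
a floor (default 20; "under the floor" is removed, so a site exactly at 20
survives). The genotype stage then removes, in this order: samples with
genotyping rate at or below 90%; sites with call rate at or below 99%;
sites with minor allele frequency at or below 0.05 (computed on non-missing
calls *after* sample removal, so sites monomorphic in the retained cohort
fall to the MAF rule); and sites with heterozygous calls in haploid cells
(male X/Y, declared via a chromosome configuration — no pseudoautosomal
inference is attempted). All three numeric thresholds are inclusive
removals, following the protocol's wording. The order matters and is
asserted by a test on a fixture where reversing sample and site filtering
changes the outcome.

Every stage emits a `filter_ledger` with the invariant
`input = retained + sum(removed)`. Hardy–Weinberg equilibrium is computed
for every retained site with an exact conditional test (two-sided: the
p-value sums the probabilities of heterozygote counts no more likely than
the observed one, given the allele counts) but is *reported*, not
filtered, by default: the ledger counts failures at 1e-7 and 5e-5. An
optional `hwe_filter` threshold enables removal. Under strong breed
structure a Wahlund excess of homozygotes is expected, which is why
reporting-only is the default.

## Breed verification

Mislabelled breeds corrupt a breed-phenotype scan at the source, so the
package verifies labels genetically: 100 bootstrap resamples of sites (the
standard phylogenetic bootstrap) each yield a pairwise identity-by-state
distance matrix (`1 - (IBS2 + 0.5 IBS1)/sites`, equivalently the mean of
`|g_i - g_j|/2` over mutually observed sites), a neighbor-joining tree is
built from each, and a strict majority-rule consensus retains exactly the
bipartitions present in more than half of the trees — no greedy completion
with minority splits, so unsupported regions of the tree stay unresolved
rather than wrongly resolved.

Neighbor joining is the classical rate-corrected agglomeration; ties in
the Q-criterion break toward the lowest-index pair so results are
deterministic, and negative branch lengths are clamped to zero with a
count (both are conventions, not estimates). The test suite checks NJ
against additive distances to 1e-9 and cross-checks topologies against an
independent implementation.

"Does not cluster within its breed" needs an operational definition. The
literal phrase "the largest clade containing most of the breed" is
degenerate — every superset of such a clade up to the whole tree also
contains most of the breed. The rule used here: a breed's *home clade* is
the consensus split side maximising (breed members present) minus
(non-members present), restricted to sides holding more than half of the
breed's samples; ties prefer the side with more breed members, then the
smaller side. Members outside their breed's home clade are flagged, with
the clade membership evidence in the report. Monophyletic breeds produce
no flags; single-sample breeds are skipped because one sample cannot
cluster. On two-level simulated cohorts with a Balding–Nichols divergence
of 0.1 at each level and 500 sites, injected cross-breed relabellings are
flagged essentially completely; at per-level divergence near 0.05 the
bootstrap consensus loses resolution and sensitivity degrades — that is a
property of the data, and the package reports unresolved breeds rather
than guessing.

## Relatedness and structure covariates

The centered genomic relationship matrix is
`K = (1/p) * sum_s (g_s - mean(g_s))(g_s - mean(g_s))'` over all p sites,
with missing dosages mean-imputed per site (count logged) and monomorphic
sites contributing zero but counted in p — the centered (not standardised)
construction used by the common mixed-model tools; a standardised variant
sits behind a flag. `K 1 = 0` holds by construction and is asserted to
1e-9. Its eigendecomposition supplies both the mixed model's rotation and
the eigenvector covariates of the haplotype scan.

The number of eigenvector covariates comes from a scree rule: the elbow is
the position maximising the second difference of the eigenvalue sequence
over positions 2..k_max. When the second differences decay monotonically
(no distinct elbow, e.g. geometric decay) the smallest admissible value is
returned with a low-confidence flag. Scree inspection is a judgment call
in practice, so a manual override always wins and is recorded — reproducing
published choices (six or eight eigenvectors for the two dataset families)
is done via the override.

## The four association engines

**Linear mixed model.** `y = W a + x b + u + e` with `u ~ N(0, sg2 K)`,
`e ~ N(0, se2 I)`; sex (female 0, male 1, unknown mean-imputed) is the
default covariate beside the intercept. The restricted likelihood is
profiled over the variance ratio `r = sg2/se2` on a log grid spanning
[1e-5, 1e5] with golden-section refinement to 1e-6 relative tolerance;
after one eigendecomposition of K each evaluation is O(n). The Wald
statistic `(b/se)^2` is referred to `F(1, n - c - 1)`. By default the
ratio is re-optimised per SNP; `per_snp_r = FALSE` reuses the null-model
ratio for every SNP — the standard genome-scale approximation, accurate
when single-SNP effects are small, and the mode used for the package's own
large replicate studies. SNPs collinear with the covariates become flagged
degenerate rows with p = 1 rather than disappearing, so row counts are
predictable. A known behavior worth stating plainly: a breed-constant
phenotype is almost fully explained by the breed-block component of K, so
the fitted ratio sits at the upper search bound and the GLS whitening
shrinks exactly the between-breed contrasts that carry across-breed
signal. The mixed model is therefore conservative in this design —
visible in the package's own power study, where it recovers a planted
variant somewhat less reliably than the weighted least squares scan.

**Binary case-control.** Breeds with prevalence at or below a low cut
become controls (0), at or above a high cut cases (1); intermediate breeds
are excluded, and infeasible cuts produce an error listing the nearest
feasible ones. The 0/1 phenotype then goes through *exactly* the mixed
model machinery (the linear approximation to the liability model). The
stringent/lenient cut points are explicit parameters: the source
protocol's exact values live in supplementary material and are not
hard-coded here.

**Haplotype scan.** Fixed 4-SNP windows slide by one SNP within each
chromosome (`s - 3` windows for s sites). Within a window, haplotype
frequencies are estimated by a standard EM over unphased genotypes
(individuals with any missing call in the window are excluded with a
count; convergence at a maximum frequency change below 1e-8 or 1000
iterations; the observed-data log-likelihood is nondecreasing by
construction and asserted in tests). Haplotypes below frequency 0.01 pool
into a rare class. The test is an omnibus F comparing the regression of
the phenotype on covariates plus (H - 1) expected haplotype dosage columns
(one dropped; dosages sum to 2) against covariates alone. Structure
correction uses fixed eigenvector covariates rather than a random effect,
which under-corrects a breed-constant phenotype — genomic inflation well
above 1 is the expected signature here, and the package asserts its
direction, not its value. Per-SNP significance is the minimum p over the
windows covering the SNP, with the covering-window count reported
alongside, since a window method reports SNP counts only through such a
mapping.

**Weighted least squares.** The novel engine for unbalanced repositories:
collapse genotypes to a breeds-by-SNPs matrix of mean dosages, compute
principal components from the relationship matrix of those breed rows, and
fit per SNP `y ~ pc1 + ... + pc5 + x_j` by weighted least squares with
weights equal to each breed's share of the genotyped sample population —
breeds averaged from more dogs carry proportionally more weight, instead of
discarding dogs to balance the design. The slope's two-sided t-test uses
`n - n_pcs - 2` degrees of freedom. Because weights are proportions,
scaling all breed counts leaves results unchanged. SNPs for which some
breed has no genotyped call are dropped with a logged count.

## Significance machinery

Bonferroni thresholds are `alpha/n_tests` at full precision with
3-significant-figure display; with the published SNP-set sizes 7,586,942
and 7,026,774 they reproduce the printed genome-wide cutoffs 6.59e-9 and
7.12e-9. False-discovery control uses Benjamini–Hochberg step-up q-values
(the empirical-null local-FDR tool used alongside Bonferroni in the source
protocol is a separate algorithm; its outputs are not reproduction targets
here, and BH is the transparent, assumption-light replacement). The
genomic inflation factor is the field-standard median ratio: p-values are
transformed to 1-df chi-square quantiles and the median is divided by
0.4549364. Significant SNPs collapse into regions while same-chromosome
gaps stay at or below 500 kb (configurable; published candidate tables
imply merging but state no rule). Gene annotation lists intervals
overlapping a region by at least one base pair, strand-agnostic, with no
flanking on either side; BED input is converted from 0-based half-open
coordinates at the boundary.

## The simulator and what passing tests mean

The generator produces what the analysis assumes and nothing more. An
ancestral allele frequency `p0 ~ U(0.05, 0.95)` per SNP; clade frequencies
from a Beta distribution with Balding–Nichols dispersion F1; breed
frequencies likewise around their clade with F2 (two levels, so the
verification stage faces real hierarchical signal). A single `fst`
argument is the compounded breed-level divergence `F1 + F2 - F1 F2`,
split evenly across levels unless both are given explicitly. Genotypes are
Binomial(2, p_breed); missingness is uniform; site quality is normal
(mean 45, sd 15, truncated at zero — leaving roughly 5% of sites under
the quality floor of 20 so the filters have work to do); sexes are drawn
at 24/73/3% female/male/unknown, the ratio of the motivating cohort.

Breed prevalence follows a logistic liability:
`prevalence_b = plogis(intercept + sum_j beta_j (2 p_bj - 2 p0_j))`,
with the intercept at `qlogis(0.15)` (a mid-range baseline for the
diseases in question) and causal SNPs drawn from ancestral frequencies in
[0.2, 0.8] — across-breed scans target common variants shared across
breeds, so planting rare causals would simulate a different design.
Effects operate through breed-level frequencies because the phenotype is a
breed attribute. By default the link is exact (no noise term); an optional
breed-level noise sd models non-genetic breed variation and is what the
null-calibration studies use (at 0.5 on the logit scale), since with no
causal variants and no noise the phenotype would be constant and the null
would be untestable.

The default cohort shape is 27 breeds totalling 230 dogs with sizes
between 1 and 59 — the shape of the motivating repository panel. The
package's replicate studies use 30 breeds with 6–60 dogs each (drawn
uniformly when no total is requested), 5,000 SNPs on 10 chromosomes,
compounded FST 0.2 and one causal SNP of slope 1.5; at these sizes a
50-replicate power study runs in a few minutes on one CPU. What these
tests show: the machinery recovers planted common large-effect variants,
stays calibrated under a structured null, and flags injected label errors.
What they do not show: behavior under linkage disequilibrium (sites are
independent given breed frequencies), under selection or pedigree
structure, or at sequencing scale (millions of sites) — the simulator has
no LD, so haplotype-window results on it exercise correctness, not the LD
patterns that motivate window methods on real data.

## Numerical choices and degenerate inputs

Dosage entries outside {0, 1, 2, NA} are rejected at construction.
Eigenvalues in [-1e-10, 0) are clamped to zero and counted. The REML
search returns the boundary with a warning flag when the optimum lies at
the grid edge. Collinear or constant test units always produce flagged
`degenerate` rows with p = 1. P-values that underflow to zero are reported
at the smallest positive double so that `p in (0, 1]` holds throughout.
Exact Hardy–Weinberg probabilities are computed in log space and agree
with full enumeration to 1e-12 for all totals up to 50. Empty cohorts or
panels after filtering raise errors naming the stage. All randomised
procedures (bootstrap, simulator) take explicit seeds and restore the
caller's RNG state.

## Known limitations

The mixed model's conservatism on breed-constant phenotypes is inherent
to putting breed structure in the random effect while the signal is a
between-breed contrast; the weighted least squares scan is the package's
answer, and the two should be read together. The haplotype scan's fixed
eigenvector correction leaves genomic inflation; its thresholds should be
interpreted with the reported lambda at hand. Breed verification is
within-cohort only (an external reference panel can be supplied as extra
samples, but no external data are fetched), and its resolution is bounded
by the bootstrap consensus — weakly diverged breeds stay unresolved rather
than being force-resolved. The binary dichotomisation discards
intermediate breeds by design; its power depends on the cuts chosen.
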