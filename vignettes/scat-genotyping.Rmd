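---
title: "Validating microsatellite panels on noninvasive scat samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating microsatellite panels on noninvasive scat samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scatgen)
```

## The problem

Elusive, low-density carnivores are hard to study by capture or camera
trapping, so population monitoring increasingly relies on DNA from
field-collected scat.  Scat DNA is degraded and inhibitor-rich: loci fail
to amplify, one allele of a heterozygote drops out (the sample then looks
homozygous), PCR artifacts introduce false alleles, and null alleles
(template variants that never amplify) inflate apparent homozygosity.
Before a microsatellite panel is used to count or identify individuals,
it has to be validated: how error-prone is each locus on scat, how
informative is it, and how many loci are needed before two different
animals could not plausibly share a profile?

`scatgen` implements that validation workflow for codominant
microsatellite genotypes: paired comparison of scat genotypes against
high-quality blood references from the same animals, multiple-tubes
consensus calling, per-locus diversity and quality statistics, identity
and parentage-exclusion power with PIC-ranked minimal panel selection,
and reference-anchored individual identification — plus a synthetic-data
generator that emulates the whole observation process with ground truth
retained, so every estimator in the package can be checked by parameter
recovery.

## Data model

A `genotype_table` is a data frame with metadata columns (`sample_id`,
`sample_type` blood/scat, `sex`, `individual_label` linking matched
samples, `replicate` for PCR replicates) and two integer allele columns
per locus (`<locus>_a`, `<locus>_b`, fragment sizes in bp, assumed
pre-binned).  A genotype is either fully called or fully missing — a
half-called pair is rejected as a format error rather than silently
repaired, because a locus is either readable or it is not.  Allele pairs
are stored sorted, so `(124, 120)` and `(120, 124)` are one genotype.
CSV files round-trip exactly; GenePop files (2- or 3-digit coding,
auto-detected) round-trip the ids, loci and genotypes, since the format
has no metadata fields.

## The synthetic observation process

`generate_dataset()` draws, per locus, visible-allele frequencies from a
symmetric Dirichlet, optionally appends one null allele at fixed
frequency $r$ (visible mass rescaled to $1-r$), and gives every
individual two gene copies per locus under Hardy–Weinberg equilibrium.
Each scat PCR replicate then passes through four stages in a fixed
order:

1. **null masking** — a null-carrying heterozygote appears homozygous
   for its visible allele; null/null is missing.  This is a template
   property, so it applies to blood too and fires in every replicate;
2. **locus failure** with probability `p_fail`;
3. **allelic dropout**: each allele of a (post-null) heterozygote drops
   independently with probability `p_ado`; both dropping gives a missing
   call;
4. **false allele** with probability `p_fa`: one allele is replaced by a
   uniformly chosen different allele from the locus's visible set, so
   observations stay diploid.

The order null → failure → dropout → false allele reflects the physical
layering (template property, reaction-level failure, amplification
artifacts); the error taxonomy itself does not prescribe a generative
order, so this is a package design choice.  Every discrepancy between
truth and observation is covered by an event-log entry, which is what
makes parameter-recovery tests possible.

### Default study design and calibration

The defaults mirror a realistic pilot validation of a small felid
population: a 9-locus dinucleotide panel with 2–6 visible alleles per
locus, 8 blood-referenced individuals of which four have matched scats
(2, 2, 2 and 7), 70 field scats from 6 additional unknown animals, and
5 PCR replicates per scat.  Published per-sample error percentages for
such panels are *realized* quantities — multiples of 1/9 over the
panel — never per-event probabilities, so the per-replicate rates were
calibrated once: `p_fail = 0.15`, `p_ado = 0.20`, `p_fa = 0.05`,
`null_freq = 0.10` at the first locus and 0 elsewhere.  These values
keep single-replicate per-sample missing/dropout-like/false-allele
percentages inside the ranges reported for wild felid scat panels
(roughly 0–45 %, 0–56 % and 0–33 %), while the five-replicate consensus
workflow keeps matched scats assignable to their references.  They are
the generator's study conditions, not tuning knobs.

```{r simulate}
cfg <- sim_config(seed = 1)
ds <- generate_dataset(cfg)
ds$reference
ds$scat
```

## Consensus calling (multiple tubes)

`consensus_genotype()` confirms an allele seen in at least `min_confirm`
(default 2) non-missing replicates.  Two confirmed alleles give a
heterozygote.  A homozygote is called only when the confirmed allele was
*unchallenged* — no other allele observed in any replicate.  A competing
allele seen once is exactly the signature a dropout-surviving true
allele would leave, so the call is left missing rather than guessed;
three confirmed alleles are a conflict, also missing.  This is the
conservative reading of the multiple-tubes rule; the alternative
(calling the homozygote over a singly-seen competitor) manufactures
dropout-like discordances downstream.

## Paired error metrics

`error_profile()` links scats to blood references by `individual_label`
and scores each locus as *match*, *mismatch* or *unreadable*.  A
mismatch with a heterozygous reference and a scat homozygous for one of
the reference alleles is *dropout-like*; any other disagreement is a
*false allele*.  Per-sample percentages are locus counts over the
panel (hence multiples of 1/9 for nine loci), rounded half-up to two
decimals, the convention under which 4/9 prints as 44.44 and 8/13 of
samples as 61.54 %.

Per-locus rates keep their denominators: the dropout-like rate uses
readable heterozygous-reference comparisons (the standard convention for
allelic dropout), the false-allele rate all readable comparisons.  Two
model-inverted estimators are added because the raw rates are not the
per-event probabilities: on homozygous references dropout is invisible
and every false allele is visible, so the hom-reference mismatch rate
estimates `p_fa` directly; on heterozygous references, the dropout-like
rate is corrected for false alleles that mimic dropout (probability
$1/(k-1)$ of hitting the partner allele) and for the exclusion of
double-dropout comparisons (readable heterozygotes show exactly-one-drop
with probability $2p/(1+p)$, inverted as $\hat p = d/(2-d)$).  Because
null masking affects blood and scat identically, these estimators are
insensitive to null alleles.

## Per-locus statistics

For each locus and sample type, `locus_stats_by_type()` reports observed
allele count, observed heterozygosity, Nei's unbiased expected
heterozygosity $\frac{2n}{2n-1}(1-\sum p_i^2)$ (the small-sample
correction matters at 4–13 samples per group), Botstein's polymorphic
information content
$\mathrm{PIC} = 1-\sum p_i^2-\sum_{i<j}2p_i^2p_j^2$ (> 0.6 treated as
highly informative), rarefied allelic richness
$A_r=\sum_i\bigl[1-\binom{2N-N_i}{g}/\binom{2N}{g}\bigr]$ at a common
gene-copy size $g$ (default: the smallest readable gene-copy total
across the groups, so blood and scat are comparable), the EM null-allele
frequency, and an exact-conditional Hardy–Weinberg p-value.

**Null-allele EM.**  Under HWE with one null allele, an observed
homozygote $i/i$ is a mixture of true $i/i$ (weight $p_i^2$) and
$i/\mathrm{null}$ (weight $2p_ir$); blanks are treated as candidate
null/null homozygotes — an interpretive choice appropriate for scat,
where a blank plausibly is a null homozygote or a failure, and the
reason adding blanks can only increase $\hat r$.  Gene-counting EM
iterates to tolerance $10^{-8}$ (cap 10 000, non-convergence flagged,
not raised).  EM approaches the $r=0$ boundary sublinearly, so after
convergence the fit is compared against the boundary solution
(gene-count frequencies, $r=0$) and snapped there when the boundary
likelihood is at least as high.  At the boundary the estimate behaves
like $\max(0,\text{hom excess}/2)$, with sampling SD near 0.01 at 500
individuals — single estimates therefore fluctuate above 0.01 even when
no nulls exist, and "no false positives" is a statement about the mean
across replicates, which is how the test-suite phrases it.

**HWE.**  Asymptotic chi-square tests are unreliable at these sample
sizes, so the test conditions on the observed allele counts (Levene's
distribution): diallelic loci with ≤ 50 gene copies are enumerated
exactly; everything else uses Monte Carlo shuffling of gene copies with
an explicit seed and the `(hits + 1)/(B + 1)` estimator.  Monomorphic
loci return p = 1 flagged untestable.  Raw p-values are reported without
multiple-testing correction, with the locus count stated so users can
correct downstream.

## Identity and exclusion power

Per locus, from allele frequencies under HWE:

* $P_{ID} = \sum p_i^4+\sum_{i<j}(2p_ip_j)^2$ — probability two
  unrelated individuals share a genotype;
* $P_{IDsib} = \tfrac14+\tfrac12\sum p_i^2+\tfrac12(\sum p_i^2)^2
  -\tfrac14\sum p_i^4$ — the full-sib analogue, always the larger;
* conservative $P_{ID} = (\max_i p_i)^2$, assuming the target is
  homozygous for the most common allele;
* $P_{E2}$ — probability of excluding a random non-parent as second
  parent when one parent is known.  No closed form is taken on trust:
  the implementation *is* the enumeration over known-parent genotypes,
  transmitted alleles and candidate genotypes with Mendelian weights,
  and the Jamieson–Taylor closed form is only used as an independent
  cross-check in the tests.

Multilocus power multiplies per-locus values over (assumed unlinked)
loci; combined exclusion is $1-\prod(1-P_{E2,\ell})$.
`min_panel_by_pic()` ranks loci by descending PIC (ties broken
lexicographically for determinism) and drops the lowest-PIC locus
repeatedly, recording the remaining panel's cumulative $P_{ID}$ and
$P_{IDsib}$ — the sequential-exclusion trajectory used to find the
smallest panel that still "detects identity".  The sibling criterion
(default threshold 0.01) gates the minimal panel: full sibs are the
hardest realistic pair to tell apart, so this is the conservative choice
customary in noninvasive genetics; the threshold and the choice of
criterion are configurable.  If even the full panel misses the
threshold, the full panel is returned flagged, never an error.

```{r power}
ip <- identity_power(ds$reference)
st <- locus_stats(ds$reference, n_permutations = 200, seed = 1)
panel <- min_panel_by_pic(st, ip, pid_threshold = 0.01)
panel$minimal_panel
panel$achieved_pid_sib
```

## Individual identification

`match_to_references()` compares each consensus scat genotype against
every blood reference over the loci readable in both.  A reference
qualifies at `min_overlap >= 5` compared loci (five informative loci is
the size of a minimal discriminating panel, and fewer shared loci make
the match probability uninformative), at most `max_mismatch = 1`
mismatch, every mismatch dropout-explained (a homozygote matching one
allele of the other side's heterozygote — applied symmetrically, since
in scat–scat comparisons either side may have dropped an allele), and
compatible sex when both are known (sex mismatch is a hard veto).
Exactly one qualifying reference assigns the query; two or more leave it
*ambiguous* — never force-assigned, because silently wrong assignments
are what inflate individual counts in naive analyses; none makes it a
candidate new individual.  Queries overlapping fewer than `min_overlap`
loci with every reference are *insufficient data*.

Unassigned queries are clustered by the same rule as a graph; connected
components become `NEW_1..NEW_k` in first-appearance order, and
non-clique components are flagged `chain_merge` (a ≈ b ≈ c with a ≉ c
may be one animal seen through two bad scats, or two animals bridged by
an intermediate — the flag says a human should look).

For exploration, `codominant_distance_matrix()` implements the standard
squared codominant distance (0/1/2/3/4 by shared-allele pattern), scaled
per pair by panel/compared to offset missing loci, and `pcoa()` performs
classical metric scaling by explicit double-centering and
eigendecomposition.  Negative eigenvalues — possible because the
distance is not guaranteed Euclidean, and aggravated by missing-data
scaling — are reported rather than dropped, and the ordination should be
read as exploratory.

```{r identify}
cons <- consensus_table(ds$scat)
matches <- match_to_references(cons, ds$reference)
table(matches$decision)
```

## What passing tests do and do not show

The generator emulates locus failure, allelic dropout, false alleles,
null alleles and replicate structure, under HWE, with unlinked loci and
unrelated individuals.  It does not model stutter artifacts,
contamination or mixed-source scats, allele-size-dependent degradation,
relatedness structure, or scoring/binning error.  Parameter recovery and
identification accuracy on these simulations therefore validate the
estimators and the decision rules *under the stated error model*; on
real scat data, where errors are correlated with amplicon length and
samples may be mixtures, the printed error profiles remain meaningful
but the guarantees do not transfer automatically.  The identification
defaults were deliberately tuned for integrity over yield: real degraded
samples land in *ambiguous*/*insufficient data* rather than being
guessed.

## Numerical choices and problem sizes

Rarefaction uses `exp(lchoose(...))` with the convention
$\binom{a}{b}=0$ for $a<b$; frequency vectors are validated to sum to 1
within $10^{-8}$; percentage rounding is half-up (so 61.538 prints
61.54).  Reported p-values from Monte Carlo use the add-one estimator
and are reproducible under the stated seed.  The test-suite exercises
the estimator oracles over all frequency vectors with up to six alleles
on a 0.05 grid (≈ 1.7 × 10⁴ cases), parameter recovery on 500
blood–scat pairs for each of 20 seeds, and identification integrity on
20 replicates of the default design — sizes chosen to make 3-SE
recovery bands a few hundredths wide while keeping the default test run
comfortably fast.
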