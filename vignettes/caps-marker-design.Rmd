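---
title: "Designing CAPS/PCR-RFLP markers from population resequencing data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing CAPS/PCR-RFLP markers from population resequencing data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsforge)
```

## The problem

A CAPS (cleaved amplified polymorphic sequence, also called PCR-RFLP)
marker turns a SNP into a cheap gel-scorable assay: one allele completes a
restriction enzyme's recognition site and the other destroys it, so after
PCR amplification and digestion a homozygote for the *digest allele* shows
two fragments, the other homozygote shows the single uncut amplicon, and a
heterozygote shows all three bands. Developing a panel of such markers
from whole-genome resequencing of a population — here modelled on a
predominantly selfing *Arabidopsis lyrata* ssp. *lyrata* population —
means walking a candidate SNP through a cascade of population-genetic and
sequence-level filters before any primer is designed. `capsforge`
implements that cascade end to end, plus a synthetic-data generator that
makes every stage testable without any sequencing data.

## The filtering model

**Basic filters.** Starting from a multi-sample VCF, sites are kept only
if they are biallelic SNPs, not fixed for the alternate allele
(frequency ≤ 0.999), genotyped in at least 15 of 22 samples, and have a
minor allele frequency (computed over typed samples) of at least 0.20.
Boundaries are inclusive throughout (MAF = 0.20 and 15 typed samples are
retained).

**Exact Hardy–Weinberg tests.** Conditional on the observed allele
counts, the heterozygote count at a site in Hardy–Weinberg proportions
has an exact discrete distribution; `hwe_exact()` evaluates it with the
standard numerically stable ratio recurrence. Three p-values are
reported: the two-sided `p_hwe` (sum over configurations no more probable
than the observed one, plain tails, no mid-p), the deficit tail
`p_deficit` = P(het ≤ observed), and the excess tail `p_excess` =
P(het ≥ observed). In a selfing population heterozygote *deficit* is the
biological expectation; heterozygote *excess* at low coverage is
typically an artifact of reads from duplicated regions co-mapping to one
locus ("pseudo-SNPs"). The excess screen therefore **retains** sites with
`p_excess ≥ 0.5` — sites leaning toward excess are removed. The tail
comparison, threshold, and direction are all configurable via
`filter_params()`.

**Tiered retention.** Sites typed in 17+ samples are kept outright
(tier A). Sites with 16 samples (tier B) must additionally lean toward
deficit (`p_deficit < p_excess`). Sites at the 15-sample floor (tier C)
must also have at least 11 samples called at read depth ≥ 2; a tier-C
site with no depth information is rejected, which is the conservative
reading of a missing DP field.

**Duplicate screen.** For each surviving candidate, 41 bp and 201 bp
windows centred on the SNP are searched against every supplied genome by
seed-and-extend local alignment (exact k-mer seeds of 11/16 nt, gapped
extension with megablast-like scoring: match +1, mismatch −2, gap open
2.5, gap extend 0.5; identity = matches / alignment columns including
gaps). The hit at the candidate's own locus is the expected self-hit; any
*second* hit in the same genome with identity ≥ 0.90 that overlaps the
SNP marks a duplicated region and the candidate is removed. Because the
scoring and word sizes of the original search tools are not uniquely
determined, these values are declared package defaults and exposed as
arguments.

**Enzyme selection.** The SNP must be *embedded* in a recognition site:
for each catalog enzyme, both allele versions of the reference flank are
scanned in a window one recognition-length either side of the SNP, and a
candidate is emitted only when exactly one allele version matches
(overlapping the SNP) and the other does not. IUPAC degeneracy is
honoured on the enzyme side only — an `N` or ambiguity code in the
subject sequence never certifies a site. A local uniqueness rule rejects
candidates whose enzyme has a constitutive site (present for both
alleles) within 150 bp of the SNP.

**Linkage pruning.** Pairwise linkage is measured as the squared Pearson
correlation of reference-allele dosages (0/1/2) over samples typed at
both sites, for all same-contig pairs within 1000 kbp. Pairs with
r² > 0.2 are resolved greedily in coordinate order, dropping the site
with more missing data, then (on ties) the lower user-supplied
enzyme-accessibility rank, then the larger coordinate. The greedy
resolution is deterministic and the survivor set provably contains no
pair above the threshold; on small instances it stays within one site of
the exhaustive maximum independent set (a property the test suite
checks).

**Primer design.** Primers may only sit in *conserved* flank positions:
positions not covered by the REF span of any variant record at which any
sample is non-reference or untyped (heterozygous positions would be
IUPAC-coded and untyped ones `N` in the per-sample consensus flanks, and
a primer must bind every haplotype). Within those regions the search is
exhaustive: lengths 15–25 nt, GC 20–80%, nearest-neighbor Tm 57–63 °C
with pair difference ≤ 3 °C, each primer 150–600 bp from the recognition
site, amplicon 590–1000 bp, and both digest fragments ≥ 100 bp. Melting
temperatures use the unified nearest-neighbor thermodynamic parameter
set at 50 mM monovalent cation and 250 nM primer with the entropic salt
correction — the implementation agrees with an independent thermodynamic
calculator to < 0.05 °C on frozen reference values. Pairs are ranked by
`|Tm_f − 60| + |Tm_r − 60| + |ΔTm| + |amplicon − 750|/150`; the amplicon
term uses a 150 bp-per-°C equivalence so a 150 bp deviation from the
750 bp target costs as much as one degree of Tm drift, keeping the two
scales commensurate. Ranking ties break on coordinates, so the design is
fully deterministic. The pipeline then walks the ranked list and accepts
the first pair whose amplicon contains no constitutive site of the same
enzyme (the non-target digest check), mirroring how a designer would
re-place primers after inspecting a restriction map.

**Cut-position convention.** A catalog entry stores the recognition
sequence and the cut offsets of both strands measured from the 5′ end of
the recognition on the top strand (`NdeI CATATG 2 4`); offsets may lie
outside the recognition span for offset cutters such as MnlI
(`CCTC(7/6)` → offsets 11/10). For a match on the amplicon's sense
strand the sense-strand cut sits `cut_top` bases into the match; for a
reverse-strand match it sits `L − cut_bottom` bases in. `fragment_up` is
the distance from the amplicon 5′ end to that cut, and
`fragment_up + fragment_down = amplicon_length` is asserted on every
emitted spec.

## The synthetic-data generator

`simulate_caps_study()` emulates the study conditions the filters assume:
22 diploid samples from a partially selfing population with inbreeding
coefficient F = 0.41 (genotype frequencies `p² + Fpq`, `2pq(1 − F)`,
`q² + Fpq`), mean sequencing depth 3.5× modelled as independent Poisson
draws per call with depth 0 ⇔ missing genotype (the simplest mechanism
producing the observed missing-data load; the depth rule of tier C only
needs thresholds, so no more detailed model is warranted). The reference
is i.i.d. sequence at GC 0.5 with no repeat structure, so duplicate
screening is exercised only by explicitly planted duplications. Planted
markers (alternate-allele frequency uniform on 0.35–0.5, one per contig,
centred so a full 1000 bp flank fits) use six-base cutters by default so
that amplicons rarely contain incidental constitutive sites. Decoys are
planted for the two sequence-level failure modes: *duplicate decoys*
(CAPS sites whose 201 bp neighbourhood is copied elsewhere at 95%
identity) and *linked decoys* (CAPS sites whose dosage vector is a noisy
copy of a marker's with extra missing calls, so pruning must drop the
decoy, not the marker). Background variation is a set of rare variants
(alternate frequency uniform on 0.02–0.12, kept out of the planted
flanks) representing the sub-threshold rare-variant load typical of
selfing populations; the MAF filter is expected to remove it, keeping the
planted-marker recovery experiment interpretable.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: linked blocks and recombination structure
(sites are drawn independently), sequencing error and genotype-likelihood
uncertainty (calls are either correct or missing), indel polymorphism,
repeat families beyond the planted duplications, and population
structure. Recovery of every planted marker on this generator
demonstrates the pipeline's plumbing and decision rules, not robustness
to mis-called genotypes.

## Numerical choices and degenerate inputs

* Exact-test tail sums use a relative tolerance of 1e−9 when comparing
  configuration probabilities, the standard guard against ties computed
  in floating point; equality with a full-enumeration oracle holds to
  1e−10 over every configuration with n ≤ 25.
* A monomorphic site has a single configuration and all three HWE
  p-values equal 1. A site with zero typed samples has undefined
  statistics and is rejected with reason `missingness`.
* MAF ties (exactly 50:50) report the alternate allele as minor in
  `site_stats()`, and both alleles in assay summaries.
* `dosage_r2()` returns `NA` (pair skipped, logged in `pairs`) when
  fewer than two shared samples exist or either vector is constant after
  pairwise deletion.
* Flanks clipped at contig edges carry a warning and a shortened
  sequence rather than an error; the SNP offset is adjusted.
* Band scoring uses a ±5% per-fragment tolerance by default as a gel
  resolution proxy; the score/predict inverse property is exact at
  tolerance 0.
* The exact HWE test is discrete and therefore conservative: its
  empirical size at nominal α = 0.05 is below 0.05 (around 0.02 at 22
  samples). The calibration check is accordingly one-sided (size never
  exceeds nominal beyond binomial error) — asserting size *equal* to
  nominal would be wrong for any exact discrete test.

## Design decisions that were genuinely open

* **Direction of the excess screen.** The screen is implemented as
  *retain* `p_excess ≥ 0.5`. Removing the excess-leaning half of sites is
  the operation consistent with both the biology (selfing ⇒ deficit
  expected) and the arithmetic of the motivating dataset, where the large
  majority of sites leaned toward excess and only the deficit-leaning
  minority survived. Threshold and direction are configurable.
* **Missingness floor.** The floor is expressed as "fewer than 15 of 22
  typed ⇒ removed", matching the described intent rather than any
  particular tool flag's literal semantics.
* **Tier boundaries** are read as exclusive bands (17+, exactly 16,
  exactly 15) since the published per-tier counts only sum under that
  reading.
* **One consensus sequence per sample.** Heterozygous and untyped indels
  inside flanks are masked as `N` over the REF span instead of expanding
  per-haplotype sequences; homozygous-alternate indels are applied
  literally. This keeps one sequence per sample and guarantees primers
  never sit on an uncertain position.
* **Enzyme accessibility** as a pruning tie-break is not operationalized
  anywhere upstream; it is exposed as an optional user-supplied ranking
  and neutral by default.
* **Marker panel fixture.** The packaged 17-locus *A. lyrata* panel ships
  for report-format and digest-arithmetic tests. Its locus-3 row is
  internally inconsistent (187 + 718 ≠ 701) and is carried as published
  with a `fragments_consistent` flag rather than silently corrected;
  arithmetic checks exclude it. Re-deriving the panel's sequences would
  require the MN47 reference assembly and is deliberately not a test
  dependency.

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen so the full suite completes in a few minutes on one core: the HWE
oracle sweep covers all ~1700 configurations with n ≤ 25; calibration
uses 10^4 simulated sites; inbreeding recovery uses 2000 sites × 22
samples; the end-to-end experiment uses seven 12 kb contigs, five planted
markers, two duplicate decoys, two linked decoys, and 40 background
variants. These sizes are stated here as the package's reference
experiment; all of them scale up linearly through `sim_config()`.

## Known limitations

* The duplicate screen is a desk-scale seed-and-extend search, not a
  full BLAST reimplementation: no E-values, no masking, and seeds are
  exact k-mers (a diverged duplicate with no exact 16-mer in the 201 bp
  window could be missed; at the 90% identity threshold this is
  vanishingly rare).
* Primer design checks thermodynamics and placement but not secondary
  structure, primer-dimer formation, or multiplex compatibility, and the
  package does not attempt dCAPS (mismatch-primer) designs.
* Genotype likelihoods (PL/GL) are ignored; calls are taken as written
  in GT.
* Band scoring assumes complete digestion; partial-digest patterns are
  reported as `unreadable` rather than modelled.
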