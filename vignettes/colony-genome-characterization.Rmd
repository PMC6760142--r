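---
title: "Methods: characterizing a transgenic mouse colony genome"
author: "mutacolony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing a transgenic mouse colony genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacolony)
```

# The system being modeled

The MutaMouse is a transgenic CD2F1-background mouse carrying a head-to-tail
tandem array of roughly 29 copies of a 47,588 bp lambda-gt10/lacZ shuttle
vector on chromosome 3. The strain descends from a single cross of two
[BALB/cJ x DBA/2J]F1 hybrids around 1990 and has been bred since as a closed
outbred colony; geographically separated colonies have since diverged. Four
analysis problems arise when such a genome is characterized by sequencing,
and this package implements all four plus the simulators needed to test them
without any external data:

1. **Variant provenance** — which variants were inherited from BALB/cJ,
   which from DBA/2J, which are previously cataloged, and which are
   colony-private.
2. **CNV/SV integration** — copy-number calls from binned read depth and
   from aCGH probe log2 ratios, their consensus across animals and methods,
   and the classification of coarse array calls as *simple* versus
   *complex* (composed of several finer events).
3. **The transgene locus** — variants carried by *every* copy of the
   tandem array (constitutional) versus a subset of copies, and the
   structure of the integration junction reconstructed from chimeric long
   reads.
4. **Colony divergence** — homozygous-variant partitioning between
   colonies, pairwise genotype discordance, runs of homozygosity, and a
   neighbor-joining tree.

# Coordinate conventions

Internal arithmetic uses 0-based half-open intervals where it matters
(BED output); all printed coordinates, VCF output and variant keys are
1-based inclusive. Published breakpoint coordinates are quoted with two
different length conventions in practice — a deletion reported as
`chr3:37,971,249-38,436,675` has length 465,426 only under `end - start`,
while a 370 bp inversion at `chr3:38,436,306-38,436,675` requires
`end - start + 1`. `intervalLength()` therefore takes an explicit
`convention` argument rather than guessing one global rule.

# Variant identity

All set algebra runs over normalized keys `chrom:pos:ref:alt`. Indel
alleles are left-normalized (shared suffix stripped, then shared prefix,
keeping one anchor base) so representation differences cannot break exact
matching. Membership is tested on position *and* alleles; matching on
position alone would conflate distinct alternates at multi-allelic sites.
The five provenance classes — `both_parents`, `a_only`, `b_only`,
`known_nonparental`, `private` — are defined by set membership against the
two parental catalogs and the known-variant catalog, in that order, and
partition any input by construction. A variant counts as carried by a
sample whether heterozygous or homozygous; zygosity matters only in the
divergence analyses.

# The forward-time colony simulator

`simulateColony()` is the package's study-condition generator, not a test
fixture: its defaults encode the husbandry the analyses assume.

* Founders are two identical F1 hybrids, each carrying one strain-A and one
  strain-B haplotype; the strain catalogs may overlap (shared ancestral
  variants).
* Each later generation is the offspring of 40 breeding females (colony
  records give 20-60; 40 is the midpoint and the package default), paired
  randomly with non-siblings where any non-sibling is available. The
  founding cross itself is necessarily a sibling-equivalent mating.
* Meiosis draws Poisson(1) crossovers per chromosome with a random starting
  phase.
* De novo variants arrive Poisson per genome per generation (default 0.5 on
  the simulator's tens-of-megabases genomes — a deliberate scale-down of
  the few dozen de novo SNVs per real mouse genome per generation), enter
  heterozygous on one haplotype, and may drift to homozygosity.
* An optional single-generation bottleneck re-founds the colony from a few
  pairs. In the two-colony design (`simulateColonyPair()`), both colonies
  share the same founders and the second experiences the bottleneck. The
  default bottleneck placement in the package's experiments is generation
  54 of 78, the position implied by a colony restart about two-thirds of
  the way through the breeding history.
* Catalog false negatives (`founderKnownExtra`) and genuinely private
  founder variation (`founderPrivate`) are planted heterozygous on single
  founder haplotypes, so all five provenance classes segregate.

Every emitted variant carries its truth class, and identical seeds give
byte-identical VCF output. What the generator does **not** emulate:
genotyping error, linkage to recombination hotspots, selection, and
realistic per-chromosome variant density. Tests passing on this generator
therefore validate the *logic* of the analyses (set algebra, window
arithmetic, drift direction), not robustness to real-data artifacts.

# CNV observation models and callers

Coverage is Poisson per 250 bp bin with mean `baseDepth * copyNumber/2`
(overlap-weighted at event edges); aCGH probes sit at jittered kilobase
spacing with mean `log2(copyNumber/2)` inside events and Gaussian noise
(sd 0.15 by default; copy 0 is floored at `log2(0.05)` to avoid minus
infinity).

`callDepthCnvs()` flags bins whose depth ratio leaves [0.75, 1.25] —
thresholds chosen to separate copy 1 and 3 from diploid noise at 30x and
above — merges same-direction candidate runs across gaps of up to 2 bins
(so one noisy bin cannot split a real event), and tests each merged run
with a Poisson-approximate z-test on its total read count. The `alpha`
level is applied family-wise with a Bonferroni correction over the number
of bins scanned. This last choice is load-bearing: candidate runs are
pre-selected for extreme bins, so correcting only over the runs actually
tested does not control the scan-wide error rate, and two-bin noise runs
at genome scale would otherwise dominate the call set.

`segmentProbes()` is deliberately simple — maximal runs of at least 3
consecutive probes beyond ±0.3 log2 units — because the package's
contribution downstream of it is the consensus and complexity logic, not
array segmentation.

Consensus across animals retains a call only when every animal has a
same-type call at ≥50% reciprocal overlap (the field's standard matching
criterion; the threshold is a parameter). Cross-method integration
clusters calls by single-linkage over the same criterion and assigns each
merged event to exactly one Venn region. An array call is *complex* when
more than one depth call overlaps it — any overlap, not strict
containment, because depth calls routinely cross array-call edges.

# The transgene array as a high-ploidy pool

All copies of the array are collapsed onto monomer coordinates, so a
pooled pileup behaves like a sample of ploidy ~29. A constitutional
variant appears at allele fraction near 1; a single-copy variant near
1/29. `callConstitutionalVariants()` calls a site constitutional at
fraction ≥ 0.9 (tolerating sequencing error rather than demanding exactly
29/29) and *partial* when the fraction is at least `1/(copyNumber + 2)` —
the same detection floor as genotyping a 29-copy array at ploidy 31 — and
a one-sided binomial test rejects the sequencing-error null at alpha 0.01.
Alleles are aggregated per position, so a multi-allelic constitutional
site (the monomer's position 44,629 carries three alternates) counts once;
the bundled fixture therefore yields 18 constitutional sites.

# Junction reconstruction

Long reads are segmented by exact k-mer anchoring (k = 15, unique
reference k-mers only) followed by chaining. Chains are exact-diagonal
anchor groups split at read gaps: under the simulator's substitution-only
long-read error model, anchors from one block never leave their diagonal,
so a gap-penalty chaining DP would add machinery without changing any
result. This is a design choice that would need revisiting for real
indel-rich long reads, and is stated as such here.

Reconstruction takes medians over supporting reads: the deletion span is
the gap between the outermost retained host blocks, an inversion is a
minus-strand host block *between* the upstream host flank and the first
transgene block (minus-strand matches elsewhere in a read are chance
inverted repeats and are ignored), inserted bases are the consensus of
the unlabeled read sequence at the upstream junction, and per-junction
microhomology is recomputed from the references at the reconstructed
breakpoints. No chimeric read at all yields a `found = FALSE` model, not
an error.

The reference generator constrains a handful of bases at junction edges
(and rejects-and-redraws windows whose junction-edge k-mers are not
unique) so that the configured geometry — breakpoint positions, inserted
base count, and the exact downstream microhomology length — is guaranteed
by construction. These constraints are generator-validity conditions, not
tuning: without them a 1-in-4 chance base coincidence would silently shift
a junction by one base and invalidate exactness tests.

# Divergence statistics

Discordance is `(#differing sites) / (#sites non-missing in both)`, a
pseudometric on complete data reported in [0, 1]; published discordance
figures from external tools are on a tool-specific scale and are not
reproduced numerically. A variant counts for a colony in the homozygous
partition when at least one of its samples is homozygous-alternate
(an all-samples mode is available behind a flag). Runs of homozygosity use
a sliding window of 50 called sites with a one-heterozygote allowance and
a 1 Mb length filter — a rule-based detector, not an HMM, which is
adequate on the simulator's noise-free genotypes. Neighbor joining is
implemented in the package (Studier-Keppler Q criterion, standard branch
updates, three-point closure); `ape` supplies only the tree container and
serves as the independent cross-check in the tests. Monophyly of each
colony is assessed after midpoint rooting.

# Numerical and scale choices

Problem sizes in the tests are chosen to exercise every code path at
desk scale: synthetic genomes of 10-30 Mb, colonies of 80 animals bred
for the full 78 generations, 50k-variant provenance runs, 10 Mb coverage
tracks at 50x, and 20-seed replication for the directional claims
(bottleneck reduces colony-private homozygous variation; colonies
separate on the tree). Significance defaults — alpha 0.05 family-wise for
the depth caller, alpha 0.01 for the partial-variant binomial test — are
stated in the function documentation and are all overridable. Degenerate
inputs follow one rule: impossible configurations error early
(overlapping truth events, deletions outside the host window), while
legitimately empty results (no chimeric reads, no candidate runs) return
empty or `found = FALSE` values.

# Known limitations

* The simulators' genomes are small and uniform; no attempt is made to
  model mm10-scale structure, repeat content, or alignment artifacts.
* The read segmenter assumes substitution-only errors; indel-rich reads
  would require banded chaining and is out of scope.
* The aCGH segmenter is a threshold-run stand-in, not a changepoint
  method.
* Absolute variant counts from real colonies (millions of SNVs per
  animal) are not reproducible at this scale and are not targets of the
  test suite; the suite checks logic, calibration, and direction.
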