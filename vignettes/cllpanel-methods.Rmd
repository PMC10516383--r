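---
title: "cllpanel: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cllpanel: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cllpanel` implements the analysis side of a CLL-focused capture
sequencing panel: reconstruction and annotation of full-length IGH and
IGL V(D)J rearrangements, stereotyped-subset assignment, IGLV3-21
position-110 (R110) determination, calling of the four recurrent CLL
copy-number alterations from per-target coverage, and VAF-tiered somatic
variant filtering. This vignette explains each model, its assumptions and
tunable parameters, what the built-in simulator does and does not
emulate, and the design decisions taken where the problem left the design
open.

## 1. Rearrangement reconstruction from soft-clipped reads

### Model

V(D)J recombination joins a trimmed germline V segment, optional
untemplated (N) nucleotides and a trimmed D segment (heavy chain only),
and a trimmed germline J segment. A read aligner mapping capture reads of
such a locus aligns each junction-spanning read to the segment carrying
most of its bases and leaves the partner-side bases as a terminal
soft-clip at the breakpoint. Capture panels tile both sides of the
junction deeply, so both the V-side and the J-side breakpoints accumulate
many independent clips — unlike whole-genome data, where mate-pair rescue
dominates. The reconstruction therefore works entirely from soft-clips:

1. **Evidence.** Every soft-clip of length ≥ `min_clip` (default 10 nt)
   on a read with MAPQ ≥ `min_mapq` (20) overlapping an ig-role target
   becomes one evidence item, with the breakpoint converted to a
   segment-local offset in reading orientation (minus-strand segments
   flip the clip side and reverse-complement the clipped bases; the flip
   happens once, here, and nothing downstream sees strand).
2. **Clustering.** Evidence sharing segment and clip side is clustered by
   single linkage with window `window` (5 nt); clusters under
   `min_support` (3 reads) are dropped — this is what suppresses chimeric
   artifacts. The cluster breakpoint is the modal offset, ties resolved
   toward the smaller offset.
3. **Assembly.** For each V-cluster × J-cluster pair of one locus the
   candidate is: per-column majority consensus of the V body up to the
   breakpoint (read consensus where covered — so SHM is captured —
   germline where uncovered, with coverage recorded in
   `per_base_support`), then the right-clip consensus, joined by the
   best suffix/prefix overlap of ≥ `min_overlap` (20 nt) at mismatch rate
   ≤ `max_mismatch_rate` (5%) to the left-clip consensus plus the J body.
   Majority ties are broken deterministically by base priority
   A &lt; C &lt; G &lt; T and flagged in the candidate metadata.
4. **Ranking.** Score = `support · log2(1 + length) · meanMAPQ/60`, ties
   by (V name, J name); the top candidate is the reported clonal
   rearrangement. Clusters that cannot be paired are reported separately
   as incomplete, never as the clonal result.

Mate-pair bridging is not implemented: with 2 × 300 bp reads the clip
overlap across a &lt; 60 nt junction always exceeds `min_overlap` by a
wide margin, so the overlap join is the only route a junction can need.
Unjoinable pairs yield no candidate rather than a guessed one.

### Why depth matters more for the J side

With 300 bp reads over a ~360 nt rearrangement, a junction-spanning read
is J-anchored only when most of its bases lie in the short J segment, so
the number of J-side clips scales roughly as
`depth · |J| / read_len`. Three supporting clips are near-guaranteed from
about 50× onward; the panel's working coverage is ≈ 1500×, and all
study simulations here run at 100× — comfortably above the threshold
while keeping the test suite fast.

## 2. Germline identity and SHM classification

Identity is `100 · matches / (matches + mismatches + gap columns)` with
every indel column counting once — the convention of standard IG
annotation services. Two details are pinned down deliberately:

* **The evaluated span is FR1 through the FR3 end boundary** (region
  bounds travel with the reference bundle). An ends-free alignment
  cannot distinguish a mutated V-terminal base from junction trimming —
  both look like "the germline stops matching here" — so identity over
  the junction-adjacent germline CDR3 bases is ill-defined; the FR1–FR3
  span is the only definition under which annotated identity can agree
  with simulated truth *exactly*, and it mirrors clinical practice of
  excluding the junction from the SHM count.
* **Terminal clipping is paired back.** The local alignment engine
  (affine gaps: open 6, extend 1; match +1, mismatch −2; configurable)
  clips terminal mismatch runs. Clipped 5′ columns are paired back
  one-to-one and compared base by base, so a genuine mutation at FR1
  position 1 still counts as exactly one mismatch, and a clipped match
  still counts as a match. The J assignment does the same at its 3′ end.

Identity is rounded half-up to two decimals *before* classification,
which makes the borderline band well-defined: ≥ 98.00 unmutated,
&lt; 98.00 mutated, 97.00–97.99 borderline. V assignments must cover
≥ `min_v_span` (100) evaluated columns — without this floor, an unrelated
allele matching a short 100%-identical core would outrank the true allele
— and are flagged when under 150. D genes are called by best ungapped
local match in the junction (≥ 5 nt at ≥ 80% identity, either
orientation), thresholds that follow common junction-analysis practice.

CDR3/junction extraction maps the conserved Cys-104 and Trp/Phe-118
anchor codons through the alignments (gapless extrapolation past aligned
ends, `NA` inside gaps); productivity requires an anchor-to-anchor
distance divisible by three, intact anchors, and no stop codon in the
translated V-through-J sequence.

## 3. Stereotyped subsets

Assignment is resource-driven and positionwise: gates on exact CDR3
amino-acid length and allele-agnostic V-gene membership, then counts
motif mismatches against per-position allowed sets, assigning the subset
with the fewest mismatches within its budget (ties by subset id). This is
a deliberate, reproducible simplification relative to profile-based
assigners; it is sufficient for the published major subsets'
length-plus-motif structure. The package bundles *clearly labelled
synthetic* definitions for testing only — real analyses must supply a
curated definitions TSV, whose version string is echoed into every
report.

## 4. IGLV3-21 R110

Lambda V genes reach IMGT position 110 at their 3′ end, so the reference
bundle carries the position-110 codon as an annotated offset on each
IGLV3-21 allele (validated against the germline residue at load time)
rather than computing full IMGT numbering. After IGL reconstruction and
allele assignment (*02 vs *04 are separated by ordinary best-identity
scoring over their diagnostic positions), the codon is mapped through the
alignment and translated; arginine means R110-positive. A codon falling
in a gap, truncated from the assembly, or covered by fewer than
`min_support` (10) reads is *indeterminate* — the gate can lower
sensitivity but can never produce a false negative, and at the panel's
coverage it is essentially free. Calls are only ever made when the best
V is an IGLV3-21 allele.

## 5. Copy-number calling

The model is the standard open log2-ratio formulation. With a panel of
normals, each target's depth is divided by its median across the normals;
ratios are then recentred on the sample's median *backbone* ratio and
log2-transformed, so the backbone median is exactly zero. The backbone is
defined as the cna_backbone-role targets **not** assigned to any
recurrent CNA region: centring on the lesion-prone targets themselves
would let a real del(13q) shift its own reference and systematically
shrink every call, which is why CNV pipelines exclude variable regions
from the reference.

QC precedes calling: the uniformity metric is the IQR of backbone log2
ratios, with `qc_pass` at ≤ 0.5. A failed sample is reported as QC-failed
with no calls at all. Per region the median log2 ratio over informative
targets drives the call — deletion at ≤ −0.2 (only for 17p/11q/13q), gain
at ≥ +0.15 (only for trisomy 12, the direction gate), `uncallable` under
`min_targets` (3) informative targets. Clonal fractions invert the
expected ratio (`f = 2(1 − 2^m)` for deletions, `f = 2(2^m − 1)` for the
trisomy), clipped to [0, 1]. The −0.2 threshold sits just above the
log2(0.85) ≈ −0.234 expected for a 30% deletion clone, which fixes the
sensitivity floor the panel design must support (next section).

## 6. The read simulator: what it emulates, and what it does not

The simulator is first-class, tested code: every acceptance property in
this package is measured against its truth records.

* **Bundle.** `simulate_reference_bundle()` builds a fully synthetic
  germline set with realistic geometry — V alleles of ~300 nt with
  FR1/CDR1/FR2/CDR2/FR3 bounds and a Cys anchor, D segments of 12–22 nt,
  J segments of 39–48 nt with Trp/Phe anchors, IGLV3-21 alleles extended
  through an annotated position-110 codon (germline glycine GGG, one
  substitution away from arginine CGG) — plus one target per segment,
  one 420 nt target per driver gene, and the CNA coverage bins. No
  licensed germline database content is reproduced.
* **Rearrangements.** Trims (never through an anchor), untemplated N
  regions, uniform SHM over the FR1–FR3 span to the closest achievable
  identity at or above the target, and an optional productivity loop
  that redraws geometry and mutations (bounded attempts) until the
  junction is in frame and stop-free. Truth records carry the sequence,
  the mutation list, the identity with the same denominator the
  annotator uses, and the junction geometry.
* **Reads.** Paired 2 × 300 bp fragments (mean 500, sd 60) are emitted as
  *pre-aligned* records: fully aligned inside segments, soft-clipped at
  junction breakpoints with the clipped bases from the rearranged side —
  aligner behavior without an aligner, which keeps junction evidence
  deterministic and removes an external dependency. Base qualities are a
  constant Q30; quality modeling is not part of the method. Per-base
  substitution errors are optional; an error-free run at depth ≥ 30
  reconstructs the truth exactly from the union of clips.
* **Coverage and variants.** CNA profiles are per-target expected depths
  (multiplier `1 − f/2` for deletions, `1 + f/2` for the trisomy) under
  mean-one lognormal noise of a given CV; variants are spiked into
  overlapping reads as independent Bernoulli draws at the target VAF,
  with the realized count recorded in truth.

Not modeled: PCR duplicates, empirical error profiles, capture-efficiency
bias beyond per-target multiplicative noise, GC effects, indel SHM, and
subclonal rearrangement mixtures. Passing tests therefore demonstrate the
*algorithmic* correctness of the pipeline under controlled conditions,
not robustness to every artifact of real libraries.

## 7. Study conditions and problem sizes

The package's measured operating characteristics (test suite and
`scripts/acceptance.R`) use these fixed conditions, chosen once as
realistic for this assay class:

* 100 seeded IGH simulations with target identities spanning 90–100%,
  depth 100× (error-free, and separately at 0.2% per-base error) — 100×
  is well inside the panel's ≈ 1500× working coverage and safely above
  the J-side evidence threshold derived in section 1.
* 200 random (germline, mutated) pairs for the identity oracle check
  against an independent linear-gap Needleman–Wunsch implementation.
* 25 R110-spiked plus 25 unspiked IGLV3-21*04 simulations at depth 100.
* CNA: 250 coverage bins of 120 nt per recurrent region plus 500 neutral
  backbone bins, 10 panel normals, multiplicative noise CV 0.1,
  base depth 1500×. The bin count follows from the sensitivity floor:
  at CV 0.1 the per-bin log2 ratio noise is ≈ 0.16, so detecting the
  0.034 margin between log2(0.85) and the −0.2 threshold in ≥ 95% of
  samples needs the region median's standard error (≈ 0.2/√n) plus the
  centring error of the neutral backbone to stay near 0.015 — hence
  hundreds of bins per region, the granularity at which bin-level
  coverage callers operate on targeted panels.
* Variants: spikes at 1500× driver coverage; tier boundaries checked at
  VAF 0.92%, 2.5% and 3.0%.

## 8. Numerical choices and degenerate inputs

* Half-up rounding to 2 decimals (`round_half_up`) before every identity
  classification; base R's banker's rounding would make 97.995
  ambiguous.
* All internal coordinates are 0-based half-open; 1-based coordinates
  exist only at the SAM/VCF/report boundary.
* Consensus ties: base priority A &lt; C &lt; G &lt; T, flagged.
  Allele/candidate/subset ties: lexicographic by name. Modal-breakpoint
  ties: smallest offset.
* Zero-depth positions in the V body fall back to germline and are
  visible as zeros in `per_base_support` (germline fallback biases
  identity upward, which is why the support vector is part of the
  candidate).
* Empty inputs degrade explicitly: no clips → no candidates; no IGL
  candidate → `no_rearrangement`; a QC-failed coverage profile → no CNA
  calls; a depth-0 position → no variant record. `run_pipeline()` marks
  failed stages "not evaluable" and always produces a report;
  serialization has a stable key order and no timestamps, so identical
  inputs give byte-identical JSON.

## 9. Known limitations

* The kappa locus is carried by the data model but has no dedicated
  analysis path.
* Identity over FR1–FR3 means mutations in the germline-encoded CDR3
  stub are invisible to the SHM percentage (they still appear in the
  junction sequence).
* The pileup variant caller is a reference implementation for making the
  VAF tiers and the end-to-end path testable; assembly-based indel
  calling, UMI handling and strand-bias modeling are out of scope, and
  externally produced VCFs can be filtered instead.
* Stereotypy matching is positionwise, not profile-based; borderline
  subset members may differ from a statistical assigner.
* del(13q) focal versus broad lesions are not distinguished; a region is
  one label set.
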