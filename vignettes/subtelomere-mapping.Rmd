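---
title: "Single-molecule nick maps of subtelomeres: models and methods"
author: "telonick"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule nick maps of subtelomeres: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telonick)
```

# The measurement

Nanochannel optical genome mapping images single DNA molecules of
150 kb and longer after a nicking endonuclease (Nt.BspQI, recognition
sequence `GCTCTTC`) has deposited fluorescent labels at its recognition
sites.  A molecule is therefore an ordered list of label positions along a
measured length — a barcode at ~kb resolution.  Subtelomeres are a natural
target for this technology: the distal ~500 kb of each chromosome arm is a
mosaic of segmentally duplicated subtelomeric repeat elements (SREs) that
defeats short reads and clone maps, and it terminates in a (TTAGGG)n
telomere repeat tract that contains no nicking motif at all.  That last
fact carries the package's headline measurement: a telomere-terminal
molecule overhangs the reference's telomeric end by an unlabeled stretch
whose length *is* the telomere tract.

For a p-arm molecule entering the channel telomere-first, with its first
matched label at molecule position $m^\*$ aligned to reference site
$r^\*$, the tract length is $m^\* - r^\*$; entering the other way it is
$L - m^\* - r^\*$ for molecule length $L$; q-arms are symmetric about the
reference terminus.  A 205 kb molecule with labels at 25, 50 and 175 kb
matching sites at 12, 37 and 162 kb yields $25 - 12 = 13$ kb either way:

```{r worked}
ref <- build_reference_map("5p", sites = c(12000, 37000, 162000),
                           length = 200000, arm = "p", distal_offset = 0)
fwd <- molecule("fwd", 205000, c(25000, 50000, 175000))
est <- estimate_telomere_length(fwd, align_molecule(fwd, ref), ref)
est$length
```

The estimator uses the telomere-proximal *matched* pair, not the
molecule's raw first label, because the first label may be a spurious
(false-positive) one; unmatched labels in the overhang beyond roughly one
per 10 kb set the `overhang_labels_present` flag instead.  Negative raw
overhangs (the terminal site distal of the molecule end under sizing
noise) clamp to zero with a flag, and molecules whose telomeric end falls
more than `terminal_slack` (1.5 kb) short of the reference's telomeric end
are refused — they are interior fragments and measure no telomere.

# Alignment model

Molecule label patterns are aligned to reference nick maps by dynamic
programming over both orientations (the instrument cannot distinguish
strands or directions; reference maps are strand-collapsed).  The score is
a natural-log likelihood ratio between "this molecule comes from this
placement" and "this molecule is a random genomic molecule" with label
density $\lambda$ (default 1/9300 bp, the genome-average Nt.BspQI site
density):

* a matched inter-label interval of molecule length $x$ against reference
  length $y$ contributes $\log(1-f_n) + \log\varphi(x-y;\,\sigma(y)) -
  \log\lambda$, with the sizing model $\sigma(y) = \sqrt{(0.03\,y)^2 +
  250^2}$ bp;
* a spanned-but-unlabeled reference site costs $-\log f_n$ and an
  unexplained label $-\log f_p$ ($f_n = f_p = 0.1$, the platform's
  miss/spurious rates);
* every bp of molecule extent the placement explains earns
  $\lambda(1-f_p)$ — the Poisson integrals of the two hypotheses — so a
  long *label-free* overhang beyond the telomeric reference end is itself
  evidence for a telomeric placement.  That credit is bounded by a maximum
  plausible tract length (`max_tract`, 50 kb); beyond it, and beyond the
  centromeric end, the reference cannot evaluate the molecule and the
  extent scores neutral.

The half-squared sizing z-score of one interval is capped at `sv_cap`
(10), so a single large insertion or deletion costs a flat outlier penalty
instead of vetoing the placement; such intervals surface through
`detect_outliers()` as signed size residuals.

**Confidence.** The reported confidence is $\max(0, \text{score})$ — the
evidence that the molecule belongs to the locus at all.  Placement
*uniqueness* inside segmental duplications is deliberately a separate
filter: `anchor_check()` requires a matched site inside unique (1-copy)
subtelomeric DNA, mirroring the field's practice of selecting molecules
"long enough to extend into 1-copy regions" and *additionally* excluding
alignments below a quality score of 20.  We adopt the threshold 20
nominally; the scale is this package's own.  A second-best-placement
margin was considered and rejected: a 3-label molecule such as the worked
example above admits mirror-image partial placements that match one of
its two intervals exactly, capping any margin-based confidence at a few
nats regardless of how clean the alignment is, while its LLR against the
random-molecule null — driven largely by the long label-free stretches —
is what actually grows with molecule information content.  Shuffled-site
decoy maps (`decoy_maps()`) validate the threshold: fewer than 0.1% of
random molecules at genomic label density reach it.

# Simulator

`build_diploid_subtelomere()` realizes sequences from an architectural
spec: a literal (TTAGGG)n tract per haplotype, SRE blocks drawn from a
deterministic registry keyed by block id (so two subtelomeres naming the
same block receive identical sequence — segmental duplication), a 1-copy
region, and per-haplotype edits (insertions, deletions, single nick-site
loss, tandem arrays with shared unit sequences and differing copy
numbers).  Planted nick sites keep a 3 kb minimum separation: the imaging
cannot resolve closer labels, and it keeps backbones free of accidental
inverted nick pairs (INPs) — two close sites on opposite strands whose
simultaneous nicking breaks the duplex.  INP breakage scenarios plant
their loci explicitly (`haplotype_truth(inp_positions = )`), and the
simulator then fragments spanning molecules with the configured
probability.

`simulate_molecules()` draws molecules to a coverage target: log-normal
lengths (median 250 kb, configurable upward for long-molecule scenarios)
truncated at 150 kb, uniform genomic placement clipped at the chromosome
ends, with shear breaks never falling inside the telomere tract (a
terminal molecule retains the full tract distal of its start).  Each
spanned site is labeled with probability 0.9; spurious labels arrive as a
Poisson process with expectation 0.1 per true site (a per-bp
interpretation is available via `fp_mode`); every inter-label segment
receives independent Gaussian sizing noise of SD
$\sqrt{(0.03\,\ell)^2+250^2}$; each molecule is reversed with probability
1/2.  Hidden truth (haplotype, origin interval, orientation, pre-noise
label counts) rides along for testing.

What the simulator does *not* emulate: chimeric molecules, imaging/stage
drift, backbone-intensity artifacts, somatic mosaicism, and
subtelomeric telomere-like repeat islands.  Passing tests therefore show
that the algorithms are correct under the stated error model, not that
the error model exhausts real nanochannel data.

# Consensus, haplotypes, variants

Aligned molecules are projected into reference coordinates
piecewise-linearly between matched pairs, slope 1 beyond them.  Projected
positions are clustered in 1-D (single linkage, 1.5 kb tolerance); a
cluster becomes a consensus site with at least 3 supporting molecules and
30% of spanning molecules (tolerating the 10% miss rate with margin).
Two reliability rules matter near structural variants: unmatched
end-segment labels extrapolated into the reference body are dropped (an
alignment that did not bridge an insertion projects a displaced stub
there), and a molecule's claimed span stops vouching for site presence at
the first reference site beyond its outermost matched pair — so label-free
novel DNA (an array, an insertion) casts no false "absent" votes.
Consensus *positions* are reference-projected, but consensus *interval
lengths* are medians of measured molecule-metric distances, because
interpolation erases size differences.

Haplotype features are proposed from bimodality: a site supported by
20–80% of spanning molecules — and missing from more molecules than the
10% miss rate can explain (binomial tail < 0.005) — becomes a
`site_presence` feature; an interval between confident sites whose
measured lengths split into modes at least 10 kb apart becomes an
`interval_length` feature, measured over the candidate region expanded by
one confident site on each side.  The expansion absorbs a specific
alignment pathology: a spurious label near a large SV can mimic the
distal anchor almost perfectly, shifting the size residual into the
neighboring interval; the expanded span measures the variant identically
either way.  Molecules are assigned by a vote weighted by feature quality
(inter-mode gap over pooled within-mode SD; presence features carry a
fixed moderate weight), features that disagree with the resulting
partition are pruned, and groups below 5 members are discarded.  One
group is a homozygous call, two a heterozygous one.

Under the platform's 10% miss rate, assignment on a *single* discriminant
site has an intrinsic accuracy ceiling near 94.7%: a carrier molecule
whose one discriminating label went unlabeled is indistinguishable from a
non-carrier.  Size-based (interval) discriminants do not share this
ceiling — their errors are sizing-noise-limited and in practice rare.

`call_svs()` compares a consensus map with the reference through
mutual-nearest anchor sites: measured minus reference span beyond 20 kb
in magnitude becomes an insertion or deletion (the field's large-SV
convention; smaller indels are reportable per molecule via
`detect_outliers()` at a 5 kb default); consensus sites inside reference
gap intervals become `gap_fill` calls with their delineated extent; and
a positive telomeric extension becomes `distal_extension`.  Codes follow
the conventional tabulation — `g` for gap-related calls, `sv` for large
indels — with `h` prefixed by `annotate_haplotype_codes()` when a call is
not shared (same type, position within 15 kb, size within
max(10 kb, 20%)) by every haplotype group.

`trio_consistency()` matches child haplotypes to parents under the
Mendelian constraint (one from each parent), scoring candidate pairs by
*discordance*: unmatched sites in the common extent plus matched-anchor
intervals whose measured lengths differ by more than max(6 kb, 10%).
Site sharing alone cannot distinguish insertion or array haplotypes —
their novel content is label-free or projected onto reference
coordinates — which is why the interval term exists.  Identical parental
candidates produce a consistent but `ambiguous` assignment; a child
haplotype more than one discordance away from every parental haplotype
flags inconsistency.

# Design choices and numerical conventions

* Coordinates are 0-based, half-open throughout; the nicking site
  coordinate is the motif window start on the top strand for both
  strands, which makes the reverse-complement mirror identity exact at
  the default nick offset of 0.  Any window containing `N` matches
  nothing, so assembly gaps are label-free by construction.
* Gap representation: an unsequenced telomere-adjacent stretch is modeled
  by `distal_unrepresented` (reference trimmed) with `distal_offset`
  either known (subtracted from estimates) or unknown (estimates flagged
  `gap_haplotype_overestimate`; their mean exceeds truth by the
  unrepresented distance — the gap-haplotype overestimation reported with
  asterisks in summary tables).  Note that this law concerns molecules
  that truly contain the chromosome end; fragments that sheared inside
  the unrepresented stretch measure no telomere and drag a naive mean
  low, which is why validation conditions on simulator truth there.
* De novo overlap-layout-consensus assembly is out of scope: consensus
  maps are reference-anchored with end extension, which suffices for
  everything expressed relative to a reference (gap fills, distal
  extensions, haplotypes, SVs) but cannot discover a subtelomere with no
  reference at all.
* Tie-breaks: equal-score alignments prefer more matched pairs, then
  forward orientation.  Simulation is bit-reproducible given a seed;
  registry sequences (blocks, insertion alleles, array units) are keyed
  by id with a preserved RNG stream so the same allele recurs identically
  across individuals.
* Aggregation reports the arithmetic mean, sample SD ($n-1$; blank for
  single-molecule groups) and count per telomere and haplotype, in kb
  with one decimal in the summary writer.
* Validation problem sizes: scenario subtelomeres are ~280–470 kb with
  ~30–50 nick sites, simulated at 20–40× coverage (a few dozen to a few
  hundred molecules); the property suites use 200 random alignment
  instances, 100 random 50 kb digests, and 50 planted SVs of 20–150 kb.

# Known limitations

* Sparse molecules (few labels) pass the confidence threshold mainly on
  the strength of their clean extent; against a site-poor toy reference
  this is intended, but against decoys their placement margin is small —
  anchoring, not confidence, is the uniqueness guarantee.
* Reference-free content is only delineated, not assembled: sites inside
  gaps and beyond the telomeric end get consensus positions by
  extrapolated projection, with accuracy degrading with distance from the
  anchored region.
* The telomere estimator cannot detect that a fragment broke inside the
  tract or inside an unrepresented distal stretch; such molecules
  underestimate, and in gap haplotypes every molecule overestimates by
  the unknown offset.  Both effects are inherent to the measurement, not
  artifacts of this implementation.
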