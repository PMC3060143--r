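---
title: "Comparative analysis of transposon-shaped orthologous regions: models and methods"
author: "retroscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative analysis of transposon-shaped orthologous regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroscape)
```

## The problem

Orthologous genomic regions of closely related plant species — for
example a gene-rich chromosome arm segment shared by Asian rice, its
wild progenitor, African rice and an outgroup species — can differ
dramatically in size and structure while retaining colinear gene
clusters. Most of the difference is contributed by LTR-retrotransposons:
elements that insert (creating a short target-site duplication, TSD, of
the host sequence on both flanks), decay into solo LTRs by unequal
recombination, are removed wholesale by large deletions, and occasionally
mark the breakpoints of segmental inversions. Because the two long
terminal repeats of an element are identical at insertion and diverge
under the molecular clock afterwards, each intact element carries its own
insertion date.

`retroscape` implements the full inference chain used in such studies —
clone anchoring, colinearity comparison, TSD polarization of insertions,
K2P dating, duplication phylogenies with gain/loss parsimony, and
population-level insertion-marker haplotyping — together with a synthetic
region-evolution simulator whose ground truth makes every stage
testable end to end.

## The simulator

`simulate_ancestral_region()` builds an ancestor with two conserved gene
clusters separated by a spacer; `evolve_lineage()` derives a lineage by
applying, in logged order: background substitutions, TE insertions,
solo-LTR reductions, large indels, a segmental inversion and a segmental
duplication. Every event is recorded in a truth log whose replay
(`replay_truth_log()`) reproduces the derived sequence byte-for-byte; a
fixed seed makes all outputs identical across runs.

Design choices that matter:

* **Coordinates are 1-based inclusive throughout**, the R/Bioconductor
  convention. GFF3 output therefore needs no frame conversion, and
  IRanges arithmetic is used directly. (A 0-based half-open internal
  frame would buy nothing here and would put every boundary off by one
  relative to the containers the package already uses.)
* **Substitutions are applied first**, before the structural events,
  although they represent divergence accumulated over the whole lineage
  age. Applying them first confines them to ancestral material: an
  element inserted 0.15 Mya should not carry 0.5 My worth of
  lineage substitutions on top of its own LTR divergence. The TSD copies
  of later insertions duplicate the already-substituted site, so the two
  copies are exactly identical at creation, as they are in reality.
  A consequence worth remembering: an element planted in the *ancestor*
  keeps diverging during the lineage phase, so its expected observed age
  is its pre-split age plus the lineage age.
* **The substitution process is a true Kimura two-parameter process**,
  with transition:transversion ratio 2:1 by default (configurable) and
  closed-form transition probabilities, so multiple hits per site occur
  with their correct probabilities. Raw (uncorrected) divergence between
  two LTRs of total divergence $d$ is therefore slightly below $d$, and
  the K2P correction used by the dating module inverts the generator's
  process exactly — which is what makes age recovery unbiased rather
  than approximately right. The tests assert the raw divergence against
  the process's closed form and the corrected distance against
  $2 r T$.
* **TSD mechanics**: an insertion at site $s$ with TSD length $t$
  (default 5 bp, the empirically typical value for these elements)
  yields `flank + TSD + element + TSD + flank`, adding
  `element length + t` bp. Solo-LTR reduction deletes the internal
  domain plus one LTR, leaving a single LTR between the original TSD
  pair. An inversion breakpoint inside an element splits its annotation
  into `.1`/`.2` fragments linked by a `parent` field.
* **Indels and inversions never split gene annotations unless explicitly
  requested** (`allow_genes = TRUE`), mirroring the fact that such
  events are reported in these regions only when annotation makes them
  visible.
* **Placement**: sampled insertion sites keep a 1.5-kb margin from
  existing annotations, and in a pair simulation the second lineage's
  sampled sites additionally keep 3 kb (ancestral frame) from the first
  lineage's. This keeps planted events structurally distinct — each
  insertion produces its own inter-block gap and faces a clean empty
  target site in the other region, the configuration TSD polarization is
  built for. Two lineages hitting the same site is biologically possible
  (insertion hotspots exist) but undecidable by TSD evidence; such a
  case, if constructed explicitly with `site =`, is reported
  `ambiguous`.

What the generator does **not** emulate: real TE family sequences
(elements are labeled random sequences with LTR structure, so
family-level homology search is out of scope); nested insertions;
element-internal deletion by illegitimate recombination; and any
population-genetic process — marker frequencies in
`generate_population()` are specified per subpopulation, not evolved
through a coalescent. Passing tests therefore demonstrate that the
inference chain is correct *given* the structural signatures, not that
those signatures survive every kind of real-data decay; the
flank-divergence knob (`add_flank_divergence()`) probes robustness to
sequence decay only.

## Clone anchoring

`map_end_pair()` applies the three orthologous-clone criteria: at least
one uniquely mapping end; ends in forward/reverse (opposite-strand)
orientation; implied span within 100–500 kb (configurable). Hits come
from exact 31-mer seeding plus ungapped extension with +1/−1 scoring; an
end is *unique* when its best hit scores at least 1.2× the best hit at
any other locus. The margin is a package choice — the selection rule in
the field is stated qualitatively — and is exposed as a parameter, as is
the flank extension of the reference, since it is genuinely open whether
the span criterion was evaluated on the core or the extended region.
`select_tiling_clones()` is a left-to-right sweep that, for interval
spans, returns a minimum-cardinality subset achieving the maximum
possible coverage; tests verify equivalence with brute-force enumeration
on small instances.

## Colinearity and insertion polarization

`build_colinearity_blocks()` chains k-mers that occur exactly once in
each region (both strands of the second region considered; k = 21 by
default). Forward anchors share a diagonal, inverted anchors an
anti-diagonal; chains break at anchor gaps above `max_gap` (1 kb) and
blocks below `min_block` (1 kb) are discarded. Block identity is the
per-base identity of the ungapped alignment the diagonal implies — seeds
alone would trivially give 1.0. Boundary k-mers can make neighboring
blocks overlap by a few bases; overlaps up to 2k are trimmed, larger
conflicts dropped longest-first, so blocks are disjoint and forward
blocks monotone in both regions (asserted by tests on every output).

`classify_te_insertions()` polarizes: an element covered ≥ 80% by blocks
in its own region is *shared*; an uncovered element is tested for the
insertion signature — equal `tsd_length` flanks (TSD) and a single copy
of the site at the position projected through the nearest block's
affine map (the *empty site*). Both tests allow `max_mismatch`
mismatches (default 0, because intact TSDs in these comparisons are
exact; set 1 for diverged flanks). Any incomplete evidence — including
an empty site destroyed by a deletion on the other side, or an element
truncated at a block edge — yields `ambiguous`, never a forced call.
That is the designed failure mode: on noiseless pairs the calls match
the truth log exactly, and under 2% flank divergence with
`max_mismatch = 1` accuracy stays above 95% with errors being
ambiguities, not wrong-lineage assignments.

`call_indels()` reports inter-block gap differences at or above 3 kb
(the conventional reporting threshold for "large" indels in these
comparisons), with the option to suppress gaps already explained by
TSD-positive insertion calls. `call_inversions()` turns maximal runs of
inverted blocks into calls and reports annotations (and split-fragment
parents) intersecting the breakpoints within a 50-bp tolerance.

## Dating

`k2p_distance()` computes transition and transversion proportions P and
Q over columns where both sequences carry an unambiguous base (pairwise
deletion; ambiguity codes are never counted as differences) and

$$K = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

Estimates are flagged invalid — never NaN — when a log argument is
non-positive (saturation) or fewer than `min_sites = 50` columns remain;
the floor keeps noise-dominated short alignments out of downstream
matrices. `date_ltr_insertion()` aligns the two LTRs globally
(Needleman–Wunsch via Biostrings, match 1, mismatch −1, gap open 4,
extend 1 — deterministic, no external aligner) and converts distance to
time as $T = K / (2r)$ with $r = 1.3\times10^{-8}$
substitutions/site/year by default, the rate conventionally used for
these grass comparisons; $r$ is always carried in the output, never
silent. The same machinery dates paralog duplications and ortholog
divergences (`date_divergence()`).

## Phylogenies, duplication timing, parsimony

`neighbor_joining()` is the canonical Q-criterion agglomeration with a
deterministic tie-break (lowest current index pair). Negative branch
lengths are clamped to zero in the returned tree with raw values kept in
the `raw_edge_length` attribute. On additive matrices it recovers the
generating topology exactly with branch lengths at numerical precision;
`ape::nj` serves as an independent cross-check in the tests, never as
the implementation.

Reading duplication timing off a tree is formalized as a
clade-composition rule rather than by eye: *before the split* when every
paralog class forms its own clade containing multiple species; *after
the split* when leaves group by species; otherwise — including clades
supported only by zero-length branches — *unresolved*. A duplication
falling essentially at the split has no operational criterion, so the
classifier deliberately returns `unresolved` for it.

`score_gain_loss_scenarios()` replays user-specified gain/loss event
sets (segmental events may cover several genes; ancestral presence at
the root costs nothing) and ranks feasible scenarios by event count. The
exhaustive minimum enumerates binary states over internal nodes (root
state free), counts state changes on edges, and merges same-edge,
same-direction changes into single segmental events. The merge is
optimistic — it ignores gene adjacency — so the reported minimum is a
lower bound for every submitted scenario, which is the invariant the
ranking needs. Enumeration is limited to small instances (a guard
rejects anything beyond ~2×10^5 assignment combinations); the instances
this analysis needs are tiny.

## Population haplotypes

`call_junction_presence()` emulates junction PCR with exact primer
matching (the simulated varieties warrant exactness; a mismatch
tolerance would only make sense for real data): a convergent primer pair
within `max_amplicon = 5000` bp is productive; a productive
insertion-junction assay calls *present*, a productive empty-site assay
*absent*, neither *missing*, both *missing with a conflict flag*. The
simulator's elements default to 6 kb so that an occupied site can never
amplify as an empty site. Inversion-boundary assays reuse the same
machinery.

Frequencies are present/(present+absent) per subpopulation with missing
calls excluded; *fixed* means frequency 1 with at least one informative
call; *diagnostic* means fixed in one group and at frequency 0 in all
others. The binary distance is the simple mismatch proportion over
markers informative in both varieties (the coefficient used upstream of
the clustering is not standardized in the field; Jaccard is offered as
an option), and `cluster_varieties()` hands the matrix to the same
neighbor-joining implementation.

In the two-subpopulation study condition (20+20 varieties, 6 diagnostic
markers fixed in one group and absent in the other, 6 shared markers),
the shared markers segregate at frequency 0.5 in both groups. Fully
fixed shared markers would be uninformative and make every within-group
distance zero — a degenerate star; intermediate frequencies are also
what the real panels show for most non-diagnostic insertions.

## Numerical choices and problem sizes

* Synthetic comparisons run on 250–500 kb regions with 12–40 planted
  elements; Monte-Carlo calibrations use 200 replicate elements per age
  (1-kb LTRs) and 50 replicate populations. These sizes put the
  Monte-Carlo standard errors well below the effects being measured
  while keeping the full suite fast to run routinely.
* Age-recovery checks compare the mean estimate against truth within
  two standard errors of the replicate mean — an unbiasedness test, not
  a tolerance band.
* All RNG flows through explicit seeds; the acceptance script derives
  every stage's seed from a single `--seed`.

## Known limitations

* Solo LTRs and truncated elements are classified from annotations; de
  novo LTR discovery is out of scope, as is TE family classification.
* The block mapper assumes unique k-mers exist at useful density; highly
  repetitive regions (e.g. inside long identical LTR pairs) contribute
  no anchors and fall back to `ambiguous` classifications.
* Empty-site projection extrapolates the nearest block's affine map; a
  site separated from its flanking block by an unrelated indel can
  project incorrectly — in the simulated conditions this does not occur,
  and on real data it would surface as an ambiguity.
* The parsimony search's event-merging ignores gene order, so its
  minimum can undercut a physically realistic scenario; it is a bound,
  not a reconstruction.
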