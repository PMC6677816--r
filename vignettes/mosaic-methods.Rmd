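---
title: "Dissecting chimeric rRNA genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting chimeric rRNA genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrnamosaic)
```

## The problem

When a bacterium takes up a foreign copy of a gene it already carries --
the 16S rRNA gene is the canonical example -- homologous recombination can
splice donor and host sequence into a mosaic ("chimeric") gene. Given a
sequenced recombinant and the two candidate parents, three questions follow:

1. **Where are the crossovers?** Which tracts of the recombinant descend
   from which parent, and where are the recombination boundaries?
2. **What homology made them possible?** A crossover needs a tract of
   contiguous local identity between the parents; how long are these shared
   stretches, and how short can they be and still support a crossover?
3. **Where do boundaries fall structurally?** Mapped onto an annotation of
   the molecule (for instance accretion-model segments of 16S rRNA, ranked
   by their inferred age in ribosome evolution), do boundaries concentrate
   in particular regions?

`rrnamosaic` answers these with a deterministic, fully testable pipeline,
plus a mechanistic simulator that generates chimera libraries with known
ground truth so every stage can be validated without any external data.

## Alignment substrate

Parents are each globally aligned to the recombinant (affine-gap
Needleman-Wunsch via Biostrings) and merged on the recombinant's
coordinates into a three-row alignment. Scoring defaults are
`match = +2, mismatch = -1, gap_open = -5, gap_extend = -1` (a gap run of
length $L$ costs $\mathrm{open} + L\cdot\mathrm{ext}$): parents in the
75--97% identity range differ mostly by scattered substitutions, and these
penalties keep gaps rare so that downstream shared stretches are not
fragmented artificially. Percent identity supports three denominator
conventions (`trim_ends`, `all`, `ungapped`) because published identity
tables rarely state theirs; `trim_ends` (exclude terminal overhangs) is the
default. Identity is computed on a fixed alignment and is symmetric in the
two rows; note that re-aligning with the arguments swapped may select a
different co-optimal alignment when ties exist.

## Minimal-crossover mosaic inference

A **discriminating site** is a gap-free alignment column where the parents
differ. Columns with a gap in any row never serve as sites: insertion and
deletion differences contribute to identity but the boundary convention
speaks of nucleotides, so indel regions are excluded from boundary calling
(they are tallied separately).

Labelling each site $i$ with a parent $\ell_i \in \{A, B\}$, the mosaic is
the minimizer of

$$ C(\ell) \;=\; c_s \cdot \#\{i : \ell_{i+1} \neq \ell_i\}
   \;+\; c_m \cdot \#\{i : s_i \text{ contradicts } \ell_i\}, $$

where $s_i$ is the observed state (`matches_A`, `matches_B`,
`matches_neither`; the last contradicts both labels equally). The optimum
is found by dynamic programming over sites $\times$ \{A, B\}, with
deterministic tie-breaking: lowest cost, then fewest segments, then a first
segment assigned to the host parent (parent A), reflecting the host-genome
context of a gene-targeting assay. The DP is verified in the test suite
against exhaustive enumeration of all $2^n$ labelings.

**Choosing the costs.** The defaults $c_s = 2$, $c_m = 1$ make one de novo
mutation cheaper than two extra crossovers, so isolated non-parental bases
are read as mutations, not micro-recombination. The costs are log-scale
weights: if per-site mutation is much rarer than a per-interval crossover
(e.g. a simulated library with per-base mutation rate $10^{-3}$ but several
crossovers per clone), a likelihood-consistent setting prices a mismatch
well above a switch (we use $c_m = 6$ in such analyses); and when mutations
can be excluded outright, $c_m = \infty$ gives the pure minimal-crossover
path whose labels track the site states exactly. One consequence of the
defaults worth knowing: a terminal run of the opposite parent spanning two
sites ties the single-crossover explanation (cost $c_s = 2$) with the
two-mutation one (cost $2 c_m = 2$), and the fewer-segments tie-break then
suppresses the switch; an internal two-site run (a switch in and out,
$2 c_s = 4$) is read outright as two mutations -- conservative boundary
calling by design.

**Boundary reporting.** Each breakpoint is reported two ways: as the
conventional point -- the first discriminating nucleotide attributable to
the new parent -- and as the **ambiguity interval** between the flanking
discriminating sites of the two segments. The true crossover is
unidentifiable inside the homologous tract between the sites, so the
interval is the honest answer and the point is the citable one. All
reported positions are 1-based on the recombinant's own ungapped
coordinates; alignment columns are carried alongside.

## Shared stretches and breakpoint homology

Shared stretches are maximal runs of identical, gap-free columns between
the parents; gaps terminate a stretch because a crossover needs contiguous
identity. The homology length attributed to a breakpoint is the full length
of the stretch lying strictly between its flanking discriminating sites --
not the inter-site distance -- since the crossover can sit anywhere in the
identical tract; both numbers are emitted (`homology_length`,
`between_sites`) because either convention appears in the literature. If
gap columns split the inter-site span, the longest candidate stretch is
returned with `n_candidates` recording the ambiguity; adjacent
discriminating columns yield an explicit zero-length sentinel.

## Structural mapping

Boundary points transfer to a reference coordinate system (e.g. a
well-studied numbering of 16S rRNA) through a global alignment; positions
opposite a reference gap return the nearest 5' reference position, flagged
inexact. Segment/helix annotations are user-supplied TSV or BED --
accretion-segment coordinates belong to the published structural analyses
they come from, and baking them in silently would couple the package to one
reference; the test fixtures use an explicitly synthetic annotation.
Counting uses 1-based inclusive intervals; a point on a segment edge
belongs to the segment containing that exact position. `oldest_fraction()`
reports the share of boundaries in the $k$ lowest age ranks out of **all**
boundaries, unassigned ones included, and is non-decreasing in $k$.

## Composition statistics

`classify_msa_columns()` partitions alignment columns into gapped,
consensus (unanimous) and discriminating; `gc_by_class()` reports each
sequence's GC% within each class. Two conventions are exposed: the default
treats any non-unanimous gap-free column as discriminating for every
sequence; `pairwise_focal` classifies per sequence against a focal
reference. Under the default, consensus columns are unanimous, so the
consensus GC is identical across sequences -- the per-representative and
averaged readings coincide by construction. A class with zero columns is
reported `NA`, never 0. The invariant that the column-count-weighted
recombination of class GC equals whole gap-free-sequence GC is enforced in
the tests to $10^{-9}$ relative.

## The simulator

The generator emulates the mechanism thought to produce complex chimeras in
a polyploid, naturally transformable host: **(1)** double-crossover
integration of a donor construct (host-identical flank + donor gene +
host-identical flank) into one genome copy; **(2)** iterative intragenomic
gene conversion between copies; **(3)** resolution of the transient
heterozygous ("Hetero") state by fixing one copy; optionally **(4)**
deterministic serial-dilution enrichment of fitter genotypes.

Study conditions and defaults:

* `ploidy = 4` -- the host is polyploid with no published copy number; four
  copies is a realistic round figure and the value is configurable.
* `l_min = 9` bases -- the minimum contiguous identity for a crossover,
  matching the shortest homology observed to support chimerization.
* `flank_len = 1000` bases -- targeting constructs of the emulated kind
  carry roughly a kilobase of homology either side of a ~1.5 kb gene.
* `conversion_cycles = 3`, `tract_mean = 300` (geometric tract lengths) --
  conversion tract statistics are not reported for this system; a few
  hundred bases per event is typical of bacterial gene conversion, and the
  number of effective cycles before resolution is small.
* `dilution = 1/1000`, `n_cycles = 5` -- the enrichment regime.
* Benchmarks default to a 1521-base gene (the host 16S locus length implied
  by its genome coordinates) at 85.9% parent identity and GC 62%,
  emulating the focal moderately-diverged donor.

Crossover eligibility is defined once, against the **parents**: a crossover
point must lie inside a host/donor shared stretch of length at least
`l_min` (flanks count as shared identity). Genome copies are mosaics of the
two parents, so any two copies are automatically identical across such a
stretch; this single definition makes the invariant "every breakpoint's
homology is at least `l_min`" hold by construction at mutation rate 0.
Crossover positions are uniform over eligible points -- no positional
preference beyond homology is assumed.

**Ground truth.** Per-base parent-of-origin labels are threaded through
every splice. The recorded true crossovers are the *observable* ones: label
boundaries that flip the parent assignment between consecutive
discriminating positions. A conversion tract that contains no
discriminating site changes no base -- no sequence-level crossover exists
to find, and counting such events would make exact recovery impossible in
principle. The raw label structure is retained (run-length encoded) for
anyone who wants mechanistic event counts instead.

**What the simulator does not model:** indels (parents are generated
ungapped at equal length; mutations are substitutions), selection during
conversion, plasmid persistence beyond the integration event,
position-dependent recombination preferences, and drift in the enrichment
step (which is deliberately deterministic: each cycle solves
$\sum_i f_i e^{r_i t} = 1/\text{dilution}$ for the cycle time $t$ by Newton
iteration, grows, renormalizes). Passing recovery tests on simulated
libraries therefore demonstrates correctness of the inference machinery
under the stated mechanism, not robustness to alignment error, indel
polymorphism or sequencing artefacts in real data.

## Growth curves

`doubling_time()` fits ordinary least squares to $\ln(\mathrm{OD})$ versus
time and reports $\ln 2 / \text{slope}$. Published doubling times rarely
state their fitting window, so the automatic mode scans all contiguous
windows of at least 4 points, requires a positive slope, and maximizes
$R^2$ (ties: longer window, then earlier); the window and diagnostics are
always exposed so a specific published choice can be mimicked with an
explicit window. Non-positive slopes yield a `no_growth` marker rather than
a number, matching the "NA, no growth observed" convention of growth-curve
figures. The estimator is invariant to OD rescaling and time shifts.

## Numerical and scale choices

Problem sizes in the routine test and validation runs are chosen to keep a
full run around a minute on one core while still exercising every code
path at realistic dimensions: DP-versus-enumeration on 500 instances of up
to 12 sites (4096 labelings each), a 100-clone benchmark at full gene
length (1521 bases), 200 random alignments for the stretch oracle.
Alignment determinism is inherited from the underlying aligner's fixed
traceback; mosaic determinism comes from the lexicographic tie-break; the
simulator threads a single RNG stream so one seed fixes an entire
benchmark byte-for-byte.

## Worked example

```{r example}
set.seed(1)
parents <- make_parent_pair(length = 1521, target_identity = 85.9, gc = 62)
cfg <- sim_config(flank_len = 500, conversion_cycles = 3)
bench <- generate_benchmark(cfg, n_clones = 10, seed = 42, parents = parents)
dplyr::count(bench$truth, class)

chim <- which(bench$truth$class == "chimera")[1]
aln <- align_triple(bench$sequences[chim, ], parents[1, ], parents[2, ])
sites <- find_discriminating_sites(aln)
path <- infer_mosaic(sites, mismatch_cost = Inf)
glance(path)
boundary_points(path)
bench$truth$crossovers[chim]  # ground truth for comparison

stretches <- shared_stretches(aln)
breakpoint_homology(path, stretches)[, c("breakpoint", "boundary_pos",
                                         "homology_length")]
```

## Known limitations

* Exactly two candidate parents; no probabilistic (HMM / sliding-window)
  recombination detection, by scope.
* Boundary calling ignores indel differences entirely; a crossover falling
  inside an indel-divergent region is localized only to the nearest
  flanking substitution sites.
* Reproducing published identity percentages for specific gene pairs
  depends on the original (unstated) aligner and denominator; the
  convention flags cover the plausible options but cannot guarantee a match.
* The simulator's substitution-only genome model keeps every copy in one
  coordinate frame; systems with frequent indel polymorphism need external
  alignment care before inference.
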