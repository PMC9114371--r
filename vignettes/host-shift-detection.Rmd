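---
title: "Detecting endosymbiont host shifts from ortholog similarity"
author: "hostshiftr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting endosymbiont host shifts from ortholog similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hostshiftr)
```

## The inference

Obligate intracellular endosymbionts such as *Wolbachia* are transmitted
mostly vertically, through the female germline. Under strict vertical
transmission the symbiont diversifies together with its host, so symbiont
and host gene divergences accumulate in proportion: if the symbiont's
substitution rate is a factor $c$ of the host's, a host pair at divergence
$d_H$ carries symbionts at divergence roughly $c \, d_H$. A **host shift**
— horizontal transfer of the symbiont between host lineages — breaks this
proportionality in a characteristic direction: the two hosts keep their
deep divergence while their symbionts become near-identical, because the
recipient's symbiont lineage was replaced recently by the donor's.

`hostshiftr` operationalises this contrast. For a pair of symbiont strains
$(a, b)$ carried by host species $(A, B)$ it computes the per-gene identity
of single-copy orthologs for both the symbiont pair and the host pair, and
classifies the pair from the two mean similarities $\bar{s}_{\mathrm{symb}}$
and $\bar{s}_{\mathrm{host}}$:

* $\bar{s}_{\mathrm{host}} > h_{\max}$: **uninformative** — the hosts are so
  close that vertical transmission through a recent common ancestor,
  hybridisation or introgression cannot be excluded;
* otherwise $\bar{s}_{\mathrm{symb}} \ge s_{\min}$: **host_shift** — the
  symbionts are far too similar for the hosts' divergence under any clock;
* otherwise: **codivergence**.

The defaults $s_{\min} = 0.93$ and $h_{\max} = 0.80$ reflect the empirical
separation this method exploits in arthropod *Wolbachia*: shifted symbiont
lineages 93–99.9% identical across distantly related hosts whose own
single-copy orthologs are only 40–80% identical. Both thresholds are
configuration (`threshold_config()`), are echoed into every output, and the
classification is a pure, monotone function of the two means — per-gene
vectors and bootstrap confidence intervals are reported alongside but never
change a label.

The third label exists deliberately: without it, closely related hosts with
(necessarily) similar symbionts would be over-called as shifts even though
vertical routes exist. Classification uses means rather than a formal test
because the separation the method relies on is large (tens of percentage
points) compared with the sampling noise of ~50 genes; the bootstrap
interval documents that noise.

## Similarity and its gap conventions

Similarity is the fraction of identical aligned columns between two
equal-length rows of an alignment, kept as a fraction in $[0,1]$
internally and rendered as percentages only at output. Three gap
conventions are exposed (`pairwise_identity()`):

* `all` (default): every column counts and a column matches iff the two
  characters are equal — so gap/gap and N/N count as matches. This mirrors
  similarity matrices computed on full alignments with gaps retained.
  Whether a gap/gap column should count as a match is a genuine convention
  choice; we state it (match) and make it switchable rather than hiding it.
* `exclude_either`: columns gapped in either sequence are dropped first.
* `exclude_both`: only columns gapped in both are dropped.

Sequences are normalised on input to the six-letter alphabet
`{A,C,G,T,N,-}`; `U` and IUPAC ambiguity codes become `N` with a warning
count. This keeps identity semantics exact character equality, at the cost
of treating rare ambiguity codes as matches only against `N`.

Descriptive statistics (`summary_stats()`) use the sample standard
deviation ($n-1$) and linearly interpolated quartiles, matching the common
dataframe `describe` convention used for per-gene similarity tables. Modes
of per-row maxima (`cross_group_stats()`) are taken after rounding to two
decimals in percent, ties broken toward the smaller value, because a mode
on continuous fractions is otherwise ill-defined.

## Dedup, lineages, trees

Genome assemblies of the same symbiont lineage sampled from many host
populations are often byte-identical over the concatenated orthologs.
`collapse_identical()` groups them and keeps the lexicographically smallest
identifier — deterministic, idempotent, and conservative (only exact
duplicates collapse).

`cluster_lineages()` then groups the remaining strains into lineages:
single-linkage connected components of the graph with an edge wherever
divergence ($1 - $ similarity) is strictly below `max_divergence`
(default `2e-4`, i.e. 0.02%). Single linkage is the right notion here
because a lineage is a clade of mutually *chained* near-identical strains,
not a centroid ball; at such tight thresholds the similarity graph and a
phylogeny-based grouping coincide. The threshold is read as a proportion of
sites (0.0002), not 2%; it is exposed as a parameter precisely because that
reading is a convention. One representative per lineage is drawn uniformly
with a user seed (`select_representatives()`), mirroring the practice of
random representative selection, while identical-group representatives stay
deterministic.

For tree-level incongruence the package builds neighbor-joining trees on
$1 - $ similarity (`nj_tree()`, negative branch estimates clamped to zero)
and reports the Robinson–Foulds bipartition distance
(`robinson_foulds()`), normalised by $2(n-3)$. NJ is a deliberate,
desk-scale stand-in for likelihood tree inference: it is exact on additive
distances (verified in the test suite up to 12 leaves) and fast enough to
validate end to end; externally inferred trees can be supplied as Newick
(`parse_newick()`). RF on symbiont-vs-host trees requires identical leaf
sets, so symbiont strains are relabelled by host species and collapsed to
one strain per host (`map_symbiont_leaves()`).

## The clock model

`calibrate_clock_ratio()` estimates the symbiont/host rate ratio $c$ as the
median of `symb_divergence / host_divergence` over reference codiverging
pairs (the median resists contamination by undetected shifts).
`run_pipeline()` uses the pairs it has itself labelled `codivergence` as
that reference set. The reported codivergence expectation is the linear
floor $\max(0, 1 - c\,d_H)$ — adequate at the small symbiont divergences
where the expectation matters, and deliberately simple since it only
annotates calls and never changes a label. Note that raw ($p$-distance)
divergence ratios understate $c$ at saturating host divergences; when the
goal is to *estimate* $c$ accurately rather than annotate calls, use
Jukes–Cantor distances (`jc_distance()`), as the validation suite does.

## The simulator

`generate_dataset()` produces fully labelled datasets with the statistical
structure the inference assumes:

* **Host tree** (`simulate_host_tree()`): forward pure-birth (Yule)
  process, seeded; height normalised to 1 so every rate is per unit tree
  height.
* **Cophylogeny** (`simulate_cophylogeny()`): the symbiont genealogy equals
  the host tree except at host-shift events — Poisson with rate $\lambda$
  per unit branch length, plus optional forced events — each of which
  replaces the recipient host's symbiont lineage with the donor's at the
  event time. The implementation traces, backwards in time, which host
  lineage carries each sampled symbiont; two symbionts coalesce the moment
  they occupy the same host lineage. This makes the ground truth exact: a
  shift at age $a$ leaves the donor–recipient symbiont distance at exactly
  $2a$.
* **Sequences** (`evolve_sequences()`): Jukes–Cantor without indels, so the
  true alignment is positional identity and no aligner is needed; expected
  identity at distance $d$ is $\tfrac14 + \tfrac34 e^{-4d/3}$
  (`jc_expected_identity()`).

Default study conditions, chosen once from the JC closed form and held
fixed: 50 genes of 900 aligned sites per strain; per-strain per-gene
dropout 0.02 (mean ~49 recovered genes, emulating incomplete ortholog
recovery); host substitution rate 0.5 per unit height, which puts maximally
distant host pairs near 45% identity and informative pairs in the 45–75%
band; clock ratio $c = 0.5$ (endosymbiont slower than host nuclear genes),
which keeps every codiverging informative pair below the 0.93 call
threshold — at the host-informativeness boundary ($\bar{s}_{\mathrm{host}}
= 0.80$, host distance $0.233$) the codiverging symbiont expectation is
$\approx 0.89$, a safe margin below $s_{\min}$ given per-pair standard
errors of order $10^{-3}$ on 45 kb. `pick_shift_pairs()` encodes the
complementary construction for positive controls: forced shifts are placed
between hosts whose divergence predates the present by at least 0.35 (host
identity below 0.72 by the closed form) and whose leaves are "isolated"
(nearest relative at least 0.2 old), so that no *unshifted* pair can reach
the symbiont threshold through a shared recent relative of a donor or
recipient.

What the simulator does **not** emulate: indels and alignment error,
substitution-model misspecification (GTR-like rate heterogeneity),
recombination between symbiont lineages, multiple infections per host,
host-tree extinction, and contamination (e.g. reads from endoparasitoids).
Passing the simulation-based checks therefore validates the *inference
logic* under clock-like evolution with clean orthologs — not robustness to
those real-data complications, which enter upstream of this package's
inputs.

## Numerical and design details

* Coordinates are 0-based half-open everywhere (partition maps); gene
  concatenation order is lexicographic in `gene_id`, and all lexicographic
  operations use C-locale (radix) ordering, so outputs are locale- and
  platform-stable.
* Missing genes are gap-padded by default (`pad_gaps`), keeping the maximum
  possible number of genes per strain; `drop_strain` is available when a
  complete matrix is required.
* Undefined similarities (empty denominators) propagate as `NA`, are
  written as `NA`, and are treated as above-threshold during clustering.
* Every stochastic step (representative draw, bootstrap, all simulator
  stages) takes an explicit integer seed and restores the caller's RNG
  state; `run_pipeline()` and `generate_dataset()` are byte-for-byte
  reproducible from their configuration plus seed, and the pipeline writes
  a manifest with MD5 checksums of every artifact.
* Neighbor-joining tie-breaking follows the underlying canonical
  implementation; negative branch estimates are clamped to zero with the
  clamped total logged. Newick output is canonicalised (children ordered by
  smallest descendant label, branch lengths at 6 decimals) so equal trees
  serialise identically.

## Problem sizes used in validation

The test suite validates at sizes where every oracle is exact or its
sampling error is well characterised: the similarity oracle on 100 random
alignments up to 10 × 200; the JC closed form on 200 genes × 900 sites at
four distances; NJ consistency on 50 random trees of 4–12 leaves; clock
recovery on 50 replicates × 3 ratios at 10 hosts × 50 genes; and shift
recovery on 20 replicates of 12 hosts with 3 forced shifts each. These are
the package's chosen validation conditions; larger runs scale linearly in
strains² × sites.

## Known limitations

* The decision rule is a threshold contrast of means, not a likelihood
  model of the cophylogeny; it flags *recent* shifts between *distant*
  hosts and is silent on direction (donor vs recipient) and on shifts
  between close hosts (labelled uninformative by design).
* The host-shift fraction counts host species operationally over the pairs
  actually classified; it is not a rate estimate.
* `gap_mode = "all"` makes similarity depend on assembly completeness when
  strains are gap-padded; per-gene statistics (which skip missing genes)
  are the robust quantity in that regime, and they are what classification
  uses.
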