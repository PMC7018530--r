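---
title: "Methods: dual-level flagellin diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-level flagellin diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagdiv)
```

# The problem

Flagellin, the subunit protein of the bacterial flagellar filament, has an
unusual architecture: its N- and C-terminal domains (D0/D1), which build the
filament core, diverge at the slow pace of housekeeping genes, while the
central surface-exposed region (D2/D3) is hypervariable — so variable that
different variants of the central region often cannot be aligned at all,
even within one species. Variation therefore exists at two distinct levels:

* **HVR forms** — classes of variable-region sequence with *no meaningful
  alignment* between classes (these correspond to H-antigen groups in
  serotyping);
* **isoforms** — distinct sequences *within* a form, differing by SNP-level
  changes.

`flagdiv` implements the complete analysis chain for this structure:
curation of candidate flagellins, deduplication, clustering, a
bit-score-ratio cluster network, HVR form/isoform typing, a per-taxon
diversity regression, and synonymous/nonsynonymous mutation curves. A
synthetic data generator with exact ground truth makes every stage testable
without downloading any sequence database.

# Pairwise alignment and the bit score ratio

All similarity computations rest on exact Smith–Waterman local alignment
with affine gaps, implemented in C++ (`align_local()`). Defaults are the
standard gapped-protein-search settings: BLOSUM62, gap open −11, gap extend
−1 (a gap of length $g$ costs $11 + g$), with Karlin–Altschul parameters
$\lambda = 0.267$, $K = 0.041$ converting a raw score $S$ to bits:

$$S' = \frac{\lambda S - \ln K}{\ln 2}.$$

Exact dynamic programming replaces heuristic seeded search deliberately: at
the scale this package targets (hundreds to a few thousand sequences) it is
affordable, and it removes all seeding nondeterminism. The traceback
tie-break is pinned (diagonal over gap-in-subject over gap-in-query; at
equal scores the earliest cell wins), because while the optimal *score* is
unique, identity and coverage depend on the path. Identity is defined as
matches over all alignment columns (gap columns included); coverage of a
sequence is its aligned span over its length.

The **bit score ratio** between proteins $a$ and $b$ is

$$\mathrm{BSR}(a,b) = \frac{S'(a,b)}{\min\{S'(a,a),\, S'(b,b)\}}
  \in [0, 1],$$

the symmetric variant of the ratio (minimum of the two self-scores in the
denominator, clipped at 1), chosen because the cluster network is an
undirected graph and needs one number per unordered pair.

An important numerical fact shapes a default further down: under BLOSUM62
the optimal local score of two *unrelated* random proteins is essentially
never 0 (any single identical residue pair already scores positively), so
random pairs sit at a small positive BSR floor, around 0.02–0.05 for
proteins of a few hundred residues.

# Curation

The curation funnel mirrors a multi-version database construction: domain
filter → optional homolog fishing → re-scan → FlgL removal → exclusion
list, with every input accounted for in exactly one of accepted/rejected.

The domain detector is a sliding-window PSSM scorer (`scan_domains()`):
profiles are per-position log~2~ odds against a uniform background, built
from example domain sequences (`pssm_from_sequences()`) or read from TSV.
The acceptance threshold defaults to half the consensus (column-maxima)
score, which cleanly separates true domain carriers from random windows in
all our simulations; both the profiles and thresholds are plain data, so
profiles derived from any external domain resource can be dropped in
unchanged. Domain placement is constrained to the expected protein half
(N-terminal, C-terminal, or anywhere).

Bacterial flagellins must carry both terminal domains; archaeal flagellins
carry the single archaeal domain. The flagellin/FlgL decision — the two
proteins share conserved domains and are frequently misannotated for one
another — is a two-profile likelihood ratio: the FLAG_N score is compared
with the score under an FlgL discriminant profile, with ties going to
flagellin. Homolog fishing (`fish_homologs()`) pulls pool sequences whose
best BSR against any seed reaches `min_bsr`; the default 0.4 sits far above
the random-pair BSR floor and well below within-family BSRs, and fished
candidates are re-scanned by the domain filter before acceptance.

# Deduplication, clustering and the spanning forest

Deduplication (`deduplicate()`) is exact string equality on the full-length
protein — the unique/total distinction that the diversity statistic is
built on. The representative of a duplicate class is the lexicographically
smallest member id, for run-to-run determinism.

Clustering (`greedy_cluster()`) is single-pass greedy set cover: sequences
sorted by descending length (ties by id), each unassigned sequence founds a
cluster, and later sequences join the first representative they match at
`min_identity` (default 0.3) with coverage of the shorter sequence at least
`min_coverage` (default 0.8). This is the algorithmic core that cascaded
identity clusterers approximate; both thresholds are exposed because any
particular published cluster count is configuration-dependent.

Cluster-to-cluster similarity is the **maximum BSR over cross pairs**; the
spanning forest minimizes distance $1 - \mathrm{BSR}$ per connected
component with Kruskal's algorithm (deterministic lexicographic tie-break).
Edges at or below `link_threshold` are removed first. The default threshold
is 0.1, *not* 0: because of the positive BSR floor of unrelated proteins
noted above, a zero threshold would link every cluster pair — including
bacterial to archaeal clusters, whose proteins are non-homologous — into
one component. 0.1 sits above that floor and below any within-superkingdom
cross-cluster similarity we generate, and reproduces the expected
behaviour: bacterial and archaeal clusters never share a component, and
clusters that do share ancestry (e.g. archaeal tail forms sharing their
N-domain) are linked into superclusters.

`summarize_composition()` reports per-cluster phylum proportions (the
pie-chart table) and the fraction of clusters containing two or more named
phyla, rounded to the nearest percent; `"Unknown"` never counts toward the
multi-phylum call.

# HVR typing

`partition_gene()` cuts a flagellin gene into the first 570 bp and last
300 bp (conserved C1/C2) and the middle variable region; protein mode uses
the equivalent 190/100 aa boundaries (570/3 and 300/3). Whether the
non-alignability judgement is made on DNA or protein is not prescribed;
both modes are provided and protein mode is the default in the pipeline.

"No alignment" between HVR forms is operationalized by `alignable()`: two
regions are alignable iff their best local alignment has identity ≥ 0.35
*and* covers ≥ 0.5 of the shorter region. The coverage clause matters:
short spurious local alignments between random regions can reach moderate
identity, but essentially never at half-region coverage. The defaults sit
between observed within-form identities (> 0.9) and cross-form, near-random
identities. Forms are the connected components of this relation (single
linkage — the faithful reading of "no alignment with any *other* form"),
isoforms are the distinct region strings within a form, and both levels get
deterministic ids (descending membership, then lexicographic
representative). `nj_tree()` builds neighbor-joining trees (negative branch
lengths clamped to 0) from score-derived distances
$d = 1 - S(a,b)/\min\{S(a,a), S(b,b)\}$ (`score_distance_matrix()`).

# Diversity regression

For each taxon the diversity statistic is the **unique-sequence ratio**
$u/t$ (unique proteins over total observations). `fit_loglog()` fits
ordinary least squares of $\log_{10} u$ on $\log_{10} t$ across taxa and
reports $R^2$, the two-sided slope t-test, and the pointwise 95% confidence
band of the mean response — the gray band of the standard regression plot.
Base-10 logarithms are a display choice only; $R^2$, the p-value and all
classifications are base-invariant. `classify_diversity()` calls a taxon
above/on/below the line by comparing its residual with the band half-width
at its abscissa; classifications are invariant under rescaling all counts
by a common factor (the intercept absorbs the shift). A minimum-count
filter is available but off by default.

# Selection curves

`codon_align()` aligns coding sequences by translating them, aligning the
proteins progressively (guide order: descending length; each new protein is
aligned globally, affine gaps, against the column-average profile of the
growing alignment), and back-threading gaps onto the DNA as whole-codon
gaps. Pre-aligned codon matrices can be supplied directly
(`codon_alignment_from_strings()`), bypassing the aligner.

`count_syn_nonsyn()` implements pathway counting between two codons: the
mean over all orderings of the differing positions of the number of
synonymous and nonsynonymous single-base steps, so that syn + nonsyn always
equals the codons' Hamming distance. Pathways through stop codons are
excluded from the average; in the (rare) case that every pathway crosses a
stop, all pathways are used and the result is flagged. Potential
synonymous/nonsynonymous site counts are computed alongside
(`syn_nonsyn_sites()`) but the headline curves are raw cumulative counts.

`cumulative_curves()` walks the reference sequence N→C and accumulates, per
reference codon, the *mean* pathway counts of all non-reference rows
against the reference (sums over pairs are available via a flag), plus the
number of gap runs opening at that position (insertions relative to the
reference roll forward onto the next reference codon). All three series are
non-decreasing by construction. The reference may be named or drawn
uniformly under a caller-supplied seed.

# The synthetic generator

`generate_panel()` produces the study conditions every stage is tested
under, together with a per-record truth table. Defaults, chosen once as the
reference conditions:

| parameter | default | what it encodes |
|---|---|---|
| forms per species | 26 | a species-scale H-antigen form inventory |
| isoforms per form | 3 | SNP-level within-form variation |
| conserved N/C length | 190/100 aa | the C1/C2 ↔ 570/300 bp boundaries |
| variable length | 120–220 aa in 3 morphotype classes | length variation between morphotypes |
| conserved substitution rate (per sequence) | 0.01 | purifying selection on D0/D1 |
| within-form SNP rate | 0.02 | near-neutral variable-region drift |
| species divergence | 0.40 | housekeeping-level separation of species lineages |
| FlgL decoys | 10 (5 single-domain, 5 two-domain mimics) | the curation confounder |
| archaeal records | 12 in 4 tail forms | the single-domain archaeal class |
| silent (synonymous) rate | 0.06 conserved / 0.01 variable | silent variation concentrating in the conserved gene regions |
| observation multiplicity | 1 + Geometric(mean 1) | duplicate observations of one unique protein |

Variable-region form ancestors are drawn *independently at random*, not
evolved from a common root: the defining property of HVR forms is the
absence of recoverable common ancestry at this level, and independence is
the direct way to generate it. Mutual non-alignability is certified at
generation time with the same `alignable()` predicate the typing stage
uses; a clashing ancestor is redrawn under an incremented sub-seed, with a
message. Coding sequences are built codon-consistently: each ancestor gets
a fixed codon template, replaced residues get a random codon of the new
amino acid, and silent codon resampling is applied at the per-region rates
above — giving the selection module realistic synonymous variation with no
internal stops. FlgL decoys reuse the focal species' own conserved domains
(FlgL is a within-genome paralog) with a distinct discriminant segment.
All randomness flows from one seed through fixed per-stage sub-seeds, so a
panel is byte-reproducible from its configuration.

What the generator does **not** emulate: real phylogenetic correlation
structure inside conserved domains (species are independent draws from a
root, not a tree), horizontal-transfer dynamics over time, sequencing or
assembly error, and database-scale taxon sampling bias. Passing the
end-to-end tests therefore demonstrates that the algorithms recover the
dual-level structure they are designed for — not that any particular real
corpus would be curated error-free.

With these defaults, one panel is ~100 unique proteins in ~220 observation
records; the end-to-end chain (curation → deduplication → clustering →
spanning forest → HVR typing) runs in well under a minute, and the whole
test suite in a few minutes, on one CPU. These scales were chosen so that
exact, exhaustive checking (all cross pairs, all codon pairs, full
enumeration oracles) stays routine.

# Numerical and degenerate-input conventions

* A local alignment with no positive-scoring pair has raw score 0, an empty
  path and BSR 0; a sequence whose *self* bit score is non-positive is
  rejected as degenerate.
* Sequences shorter than a domain profile yield no hit (not an error);
  genes of ≤ 870 bp (≤ 290 aa) cannot be partitioned and error with the
  minimum length.
* The regression requires ≥ 3 taxa and a non-degenerate abscissa; ratios
  require `0 < n_unique ≤ n_total`.
* Codons containing `N` or a gap contribute (0, 0) to mutation counts and
  are flagged rather than dropped silently.
* All orderings, representatives and identifiers are tie-broken
  lexicographically (radix order), so every stage is deterministic given
  its inputs and seed.

# Known limitations

* Exact all-vs-all Smith–Waterman scales quadratically; beyond ~10⁴ unique
  sequences a seeded/heuristic aligner would be needed in front of the BSR
  stage.
* The greedy clusterer is order-dependent by design (longest-first); it
  approximates, not reproduces, any particular cascaded clustering run.
* The FlgL discriminant is only as good as its profile; on real data it
  should be built from curated FlgL sequences rather than the synthetic
  stand-in.
* The confidence-band classification treats taxa independently; no
  phylogenetic correction is attempted.
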