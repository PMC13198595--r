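---
title: "Methods: vHPO discovery and stress-expression analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vHPO discovery and stress-expression analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhpotools)
```

Vanadium-dependent haloperoxidases (vHPOs) oxidize halides with hydrogen
peroxide using vanadate as prosthetic group; in marine algae they drive
halogenation chemistry and are candidates for stress-response roles. This
package implements a complete desk-side workflow for finding vHPO-like
genes in assembled transcriptomes and for quantifying the wet-lab
measurements that usually accompany such a survey: bromoperoxidase
activity assays, RT-qPCR relative expression, and chlorophyll-fluorescence
stress readouts. This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the validation
shows.

## Candidate discovery

### Six-frame ORF extraction

Assembled contigs are conceptually translated in all six frames under the
standard genetic code. Within each frame, every segment between
consecutive in-frame stops (or contig edges) contributes at most one
open reading frame: the one starting at the **first** ATG of the
segment, i.e. the longest Met-initiated product. Where several ATGs
share a segment the downstream ones are recorded as alternative starts
(`n_alt_starts`) rather than emitted as separate candidates; this keeps
the output deterministic and matches the "longest plausible protein"
convention. ORFs running off the contig end are emitted with
`has_stop = FALSE` because assembled transcripts are frequently
3'-truncated and discarding partials would silently drop real genes.

Parameters and conventions:

* `min_aa` (default 100 residues) — the minimum protein length; the
  count **includes** the initial methionine and excludes the stop. The
  convention is configurable since length cutoffs are sometimes quoted
  without the Met.
* Coordinates are 0-based, half-open, always on the forward strand, with
  the strand carried separately (BED convention; `end - start` is always
  `3 * aa_len`).
* Codons containing `N` translate to `X` and do **not** terminate an
  ORF; candidates with more than 5% `X` are flagged (`x_flag`) instead
  of dropped, preserving candidates from slightly noisy assemblies.

The Kozak start-context scan tests the 7-nt window from position −3 to
+4 around the ATG against `RxxATGG`, with R strictly a purine (A/G) — a
literal reading of the consensus, with no IUPAC extension. Fewer than
3 nt upstream or 1 nt downstream yields `indeterminate` rather than a
guess. Deduplication keeps one representative per identical protein
(lexicographically smallest contig id), scoped per species by default
because identical sequences from different species are biologically
distinct observations.

### Homology classification

BLAST-style search is replaced by an exact Smith–Waterman local
alignment (Gotoh affine-gap algorithm, implemented in C++) against the
five reference enzymes that anchor the three structural vHPO groups:
group 1 (1UP8, 5LPC, 5AA6 — algal/cyanobacterial bromoperoxidases),
group 2 (4CIT — bacterial iodoperoxidase), group 3 (1IDQ — fungal
chloroperoxidase). At desk scale (tens to hundreds of candidates) the
exact algorithm needs no heuristics and makes scores reproducible.
Scoring uses BLOSUM62 with gap open 11 / extend 1 — the BLAST protein
defaults — under the convention that a gap run of length $L$ costs
$11 + L$. The traceback is deterministic: the maximal cell with the
smallest coordinates is chosen, and at each step diagonal is preferred
over up over left.

E-values are deliberately out of scope; instead `min_score` is a raw
score threshold whose default (73) is the 99th percentile of best
scores obtained by residue-shuffled sequences against the reference set
(`calibrate_min_score()`), i.e. a 1% empirical false-assignment rate on
the shuffled null. Group assignment uses the best raw score, not
percent identity, because the three groups share almost no sequence
identity with each other while membership within a group is what the
score measures.

The three vanadate-binding motifs are **data, not code**: a table of
(reference, motif, position, expected residue, role) rows shipped next
to the reference FASTA, so that reference sets can be swapped without
touching the classifier. Classification is a pure function of the motif
states:

1. no group, or a motif with *no* aligned site → `rejected`;
2. the covalent histidine (motif 3) substituted → `predicted_inactive`
   — this His forms the covalent bond to vanadate, so its loss is
   expected to abolish catalysis regardless of overall homology;
3. the covalent histidine unaligned → `rejected` (no evidence either
   way; we do not assert inactivity from a missing residue);
4. fewer than `min_conserved_frac` (default 0.6) of the
   vanadate-binding sites conserved → `rejected`;
5. everything conserved → `putative_vHPO`; otherwise
   `putative_vHPO_atypical`.

The atypical tier exists because the motif-2 histidine of group-2
enzymes is recurrently replaced by serine or threonine in catalytically
active bacterial homologs; discarding such candidates would be wrong,
asserting full typicality would too.

### Sequence features

Average (not monoisotopic) residue masses are used, matching how enzyme
masses are conventionally reported in kDa. The isoelectric point uses
the Bjellqvist pK set (side chains D 4.05, E 4.45, C 9.0, Y 10.0,
H 5.98, K 10.0, R 12.0; C-terminus 3.55; residue-specific N-terminal
values with 7.5 fallback) under the Henderson–Hasselbalch charge model.
The net charge is strictly decreasing in pH, so the pI is found by
bisection on [0, 14]; iteration stops when the bracket is below `tol`
(default 1e-3 pH) *and* the residual charge is below 1e-3 elementary
units — the second condition matters on flat stretches of the titration
curve, the first on steep ones. Signal peptides, localization and
domain annotations are pass-through columns read from user-supplied
tables, never computed here: those predictions belong to their
dedicated external tools. When an annotation provides a cleavage site,
mature-sequence mass and pI are reported alongside the full-sequence
values. Range summaries ("complete enzymes") include only ORFs with
`has_stop = TRUE`.

## Activity kinetics

The thymol-blue bromination assay tracks the dibrominated product at
620 nm. The rate is an ordinary least-squares slope, either over the
full trace or over the *best linear window*: the longest contiguous
window of ≥ 5 points with $r^2 \ge 0.98$, earliest among equal lengths.
$r^2$ is defined as 1 for an exact fit, including a constant trace, so
a zero-activity blank is handled without special cases. Conversion to
concentration uses Beer–Lambert with $\varepsilon$ = 37.2 mM⁻¹cm⁻¹;
one unit is 1 nmol TBBr₂ per minute, so mM/min × assay volume in µL
gives U directly. The optical pathlength is a required configuration
value (default 1 cm, recorded in every result) because microplate
pathlengths vary and hiding a default would silently bias U. The assay
direction (product signal rising or falling) is likewise configuration,
with rising as default; optional blank-trace subtraction is provided as
standard practice. Fraction pooling selects everything at or above a
configurable fraction (default 0.5) of the peak activity and, by
default, restricts to the contiguous run containing the maximum — the
usual rule for pooling a chromatographic peak.

## Expression analysis

All relative expression follows the 2^−ΔΔCq method with amplification
efficiency fixed at 2 (no efficiency correction). Technical duplicates
are averaged arithmetically on the Cq scale before any transformation —
duplicates monitor run-to-run variability, so averaging before
differencing is the conservative aggregation. ΔCq is target minus
reference gene per biological sample. Two calibrator schemes are
implemented: *to control* (subtract the arithmetic mean control ΔCq of
the same time point and gene — averaging on the ΔCq scale, i.e. a
geometric mean on the linear scale, configurable) and *to t0* (subtract
the same thallus's own baseline ΔCq, which cancels inter-individual
baselines by pairing).

A deliberately enforced boundary: the statistical tests refuse any
table still on the Cq/ΔCq cycle scale. Cq is an exponent; only the
2^− transformed values are on a scale where means and t statistics are
meaningful. (The Mann–Whitney variability check is rank-based and
therefore operates on ΔCq legitimately.)

Dunnett's many-to-one comparisons are computed against a seeded
Monte-Carlo reference distribution of the max-|t| statistic for the
actual group sizes (default 100 000 draws), rather than multivariate-t
quadrature: the procedure is transparent, testable by simulation, and
bit-reproducible under a fixed seed. Adjusted p-values are additionally
floored at the raw p to keep the adjustment monotone. The one-sample t
family applies a Bonferroni-corrected level `family_alpha / m`,
reported at 4 decimals (0.05/9 → 0.0056). Normality (Shapiro–Wilk) and
variance-homogeneity (F test) checks are computed as warnings only and
never gate the pipeline. The Mann–Whitney p-value is exact (null U
distribution) for tie-free samples with $n_1 n_2 \le 400$ and a normal
approximation with tie and continuity correction otherwise.

PSII stress is quantified as the percentual reduction of Fv/Fm from
each thallus's own t0, corrected by **subtracting** the control group's
mean reduction at the same time point (difference-in-differences, the
most literal reading of "corrected by the respective control"); a ratio
alternative is available via `method = "ratio"`.

## Synthetic data and what the validation shows

The generators produce seeded, byte-reproducible inputs with explicit
truth tables, sized to the study design they emulate:

* **Transcriptomes** — reference proteins mutated to a target identity
  (motif sites held fixed unless a substitution is planted),
  reverse-translated with uniform synonymous codons (no codon-usage
  model; codon bias is irrelevant to protein-level discovery), embedded
  at random strands/frames in ~50% GC background with an in-frame stop
  directly upstream of the planted start. Identities below 40% are
  refused because group assignment is undefined at that divergence.
* **Kinetics** — the standard 21-point, 0–10 min grid with Gaussian
  noise on a linear signal.
* **qPCR** — reference Cq ~ N(21, 1); biological noise on the ΔCq
  (log) scale shared per thallus across time points, technical noise on
  the Cq scale per replicate. This matches the
  multiplicative-biology/additive-measurement structure the ΔΔCq method
  assumes, and makes the paired t0 scheme exact when technical noise is
  zero.
* **Fv/Fm** — baselines ~ N(0.67, 0.03), the unstressed condition;
  realized percent reductions ~ N(planted damage, 2.4) in every group,
  so the planted value is the expected control-corrected damage.

Validation problem sizes (chosen to exercise the estimators at the
scale of the emulated study while keeping the default test run fast):
50 random 1-kb contigs against a brute-force ORF enumerator; 100 random
pairs of length ≤ 8 against exhaustive alignment enumeration; 50 random
sequences against a 1e-4 pH grid scan; fold-change recovery at n = 50
thalli; Dunnett calibration with 20 000 null replicates against the
implementation's own 100 000-draw critical value; end-to-end discovery
on 10 planted + 8 background contigs at 60% identity.

What passing these tests does **not** show: the generators contain no
assembly artifacts, chimeras, frameshifts, codon bias, primer
efficiency deviations from 2, or fluorometer drift. Recovery of planted
truth demonstrates that the estimators are correct under their own
model assumptions, not that the assumptions hold for any particular
field dataset.

## Reference fixture

The packaged reference set (`vhpo_refs_synthetic.faa`,
`vhpo_motifs_synthetic.tsv`) is **synthetic**: constructed sequences
reproducing the group structure (a homologous group-1 triple, two
unrelated singletons) and the motif layout (three motifs, covalent His
in motif 3, the substitution-prone His in motif 2) of the five
structurally characterized anchor enzymes. It exists so the package
installs, validates and simulates without network access. For real
curation work, supply the PDB-derived sequences and a motif table
transcribed from the structures via `load_reference_set()`; every
function takes the reference set as an argument.

## Known limitations

* Alignment is rigorously exact but $O(nm)$ per pair; for
  genome-scale candidate sets a heuristic prefilter would be needed.
* The score threshold calibration is specific to the reference set in
  use; recalibrate after swapping references.
* Dunnett adjusted p-values carry Monte-Carlo error (~±0.005 at the
  default 100 000 draws near p = 0.05).
* The deposited-sequence benchmarks (`kozak_benchmark()`,
  `motif_substitution_benchmark()`) require the corresponding GenBank
  download; they are not runnable offline.
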