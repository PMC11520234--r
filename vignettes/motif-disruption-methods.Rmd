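---
title: "Scoring TF binding-site disruption by SNVs and indels: methods and conventions"
author: "motifdisruptr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring TF binding-site disruption by SNVs and indels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifdisruptr)
```

## The problem

Regulatory variants act largely by changing transcription factor (TF)
binding. A fast first-pass assessment asks: for a given variant and a given
TF position weight matrix (PWM), how does the best achievable motif match
near the variant differ between the reference and the alternate allele?
`motifdisruptr` answers this for single-nucleotide variants (SNVs),
multi-nucleotide variants (MNVs) and short insertions/deletions, and can
corroborate predicted disruptions with observed ChIP-seq binding from a
locally built, ReMap2022-layout peak database.

## The model

### Motifs and scores

A motif of width $w$ is a position probability matrix $P \in (0,1]^{w
\times 4}$ over A, C, G, T with a background vector $b$. Count or frequency
matrices (JASPAR PFM, MEME minimal) are smoothed by adding
$\kappa\, b_j$ to each cell of a position and renormalizing, with
pseudocount $\kappa = 0.8$ by default; this keeps every probability
strictly positive so the log-odds matrix

$$ L_{ij} = \log_2 \frac{P_{ij}}{b_j} $$

is finite. A window $x_1\ldots x_w$ scores $S(x) = \sum_i L_{i,x_i}$; the
relative score min–max normalizes $S$ to $[0,1]$ over the motif's
attainable range $[\min S, \max S]$. The consensus (per-position argmax)
attains the maximum exactly. Log base 2 is a convention only — every
reported quantity depends on score orderings and the normalized scale, not
on the base. Scoring is standardized on log-odds with this normalized
relative score; the choice is recorded in every run manifest.

### Scanning alleles

For a normalized variant with reference span $[s, e)$ and motif width $w$,
the reference allele sequence is the genome over $[s-(w-1),\, e+(w-1))$ and
the alternate allele sequence substitutes the ALT string. This context
width is the minimal complete window set: every width-$w$ window that
overlaps at least one varying position is scanned, and none that cannot
overlap it is. Both strands are scanned (the minus strand by scoring the
reverse-complement motif over the forward sequence); the reported match is
the highest-scoring window — equivalently the lowest p-value, since the
p-value is monotone in the score. Ties break deterministically: leftmost
window, then the plus strand. Windows containing non-ACGT characters are
skipped; if nothing is scannable a flagged sentinel (p-value 1, relative
score 0) is returned. The best match is reported per allele even when it
does not overlap that allele's variant span; a flag records the overlap.

The effect size is

$$ \Delta = \mathrm{rel}_{\mathrm{ALT}} - \mathrm{rel}_{\mathrm{REF}}, $$

negative for disruption, positive for creation. The sign convention is
stated in all outputs because the plain phrase "difference between the best
match on the two alleles" is ambiguous. Strength calls use $|\Delta| \ge
0.4$ (strong) and $0.1 \le |\Delta| < 0.4$ (weak); these are configuration
defaults on the normalized scale, not literature values, and are exposed as
`--strong-threshold` / `--weak-threshold`.

### Exact match p-values

The null model is an i.i.d. background sequence of motif width, using the
motif's own stored background (a single source of truth per motif; a
genome-wide background estimator is deliberately out of scope). Per-position
log-odds are discretized to integer multiples of a granularity
$\varepsilon$ and the distribution of the width-$w$ sum is built by
iterated convolution of the four-point per-position distributions —
$O(w \cdot \mathrm{range} \cdot 4)$ and exact for the discretized scores.
The default $\varepsilon = (\max S - \min S)/10^4$ keeps the discretization
error of any p-value far below reporting precision while the DP range stays
around $10^4 w$ bins. The p-value is per window (a match p-value), not
corrected for the number of windows scanned; the scanned window count is
reported so users can correct if they wish.

Numerical details worth knowing:

* Query scores are binned by rounding ($\lfloor S/\varepsilon + 0.5
  \rfloor$) and clamped into the realized support; scores at or below the
  true minimum return exactly 1 and scores meaningfully above the maximum
  return 0. A $10^{-9}$ relative tolerance absorbs the few ulp by which a
  maximal window sum can exceed the precomputed maximum under a different
  summation order.
* Threshold inversion (`score_for_pvalue()`) returns the smallest binned
  score whose upper tail is at most $\alpha$; when $\alpha$ is below the
  smallest attainable nonzero tail mass the maximum bin is returned with an
  `attainable = FALSE` attribute.
* A motif and its reverse complement have identical null distributions.

### Variant normalization

Internally every coordinate is 0-based half-open; 1-based conventions exist
only at the VCF/name-field boundaries. Raw edits are normalized by trimming
the longest shared prefix then suffix (this undoes the VCF anchor base),
and pure indels are left-aligned through repeat tracts — the edit is
shifted left while the resulting haplotype is unchanged. Left-alignment
follows the VCF normalization convention because indel representation in
repeats is otherwise ambiguous and reproducible coordinates require a
canonical form. Normalization is idempotent, and applying REF→ALT then
ALT→REF to any containing sequence is the identity. Overlapping variants
are scored independently of one another (joint haplotype scoring is out of
scope and documented as such).

### Edge-relative indel coordinates

A motif created inside an insertion has no reference-genome coordinates, so
matches around indels are located relative to the variant's edges on the
allele where the match lies. With match window $[m_s, m_e]$ (0-based,
inclusive) and variant span $[v_s, v_e)$ on that allele:

$$ c_{\mathrm{start}} = m_s - v_s, \qquad
   c_{\mathrm{end}} = (m_e + 1) - v_e. $$

Negative values are upstream of the corresponding edge, positive values
downstream, and 0 means exact edge coincidence (a zero at the start anchors
to the variant start; a zero at the end anchors half-open to the variant
end). The no-zero counting alternative (edges at ±1) was rejected for
arithmetic simplicity. The four overlap geometries follow:

| geometry | condition | meaning |
|---|---|---|
| `spanning` | $c_s < 0,\ c_e > 0$ | motif extends past both edges (split by the indel seen from the other allele) |
| `contained` | $c_s \ge 0,\ c_e \le 0$ | motif entirely within the variant bases |
| `upstream_overlap` | $c_s < 0,\ c_e \le 0$ | motif covers the start edge |
| `downstream_overlap` | $c_s \ge 0,\ c_e > 0$ | motif covers the end edge |

Geometry and coordinates are computed from the better-scoring allele's
match; SNVs and MNVs are labeled `snv_window`. Insertions and deletions are
treated symmetrically — an insertion in one allele is a deletion from the
other allele's perspective — and swapping REF and ALT exactly negates the
effect and swaps the per-allele matches (a tested invariant).

## Peak evidence

`build_peak_db()` parses BED files whose name field uses the ReMap2022
layout `accession.TF.biotype` (periods beyond the first two belong to the
biotype), deduplicates and stably sorts records, and serializes them to a
single versioned text file with a magic header; rebuilds from identical
inputs are byte-identical. Annotation attaches, for every result whose
better-allele p-value is below $\alpha = 10^{-4}$, all overlapping peaks
whose TF matches the motif's TF. Matching is case-insensitive with
separator characters removed (`NKX2-1` = `NKX2.1`), optionally expanded to
a user-supplied TF family table. Overlap uses half-open semantics on the
variant's reference span; a pure insertion's zero-length breakpoint is
widened by one base each side, since it could otherwise never overlap any
peak — this widening is a documented choice, not a database convention.
Results failing $\alpha$ are explicitly marked `not-evaluated`, never
dropped, and motifs absent from a supplied mapping are marked `unmappable`.
The p-value filter intentionally uses the better allele: binding evidence
concerns whether a site exists on either allele.

## Exports

The TSV export is lossless (numbers at 17 significant digits) and
round-trips through `read_results_tsv()`; the SQL export writes a
database-agnostic `CREATE TABLE` plus `INSERT` script with the same
columns. The BED9 browser track encodes either disruptiveness
($x = |\Delta|$, score mode) or motif quality
($x = \max(0, 1 - p/\alpha)$, p-value mode) as `score = round(1000 x)` and
as a 5-step single-hue blue ramp (`#EFF3FF` → `#08519C`, strictly
decreasing luminance): darker always means stronger. The numeric mapping
from effect/p-value to color is this package's convention — only
"darker = stronger" is inherited from practice. Matches lying on the
alternate allele of an indel are drawn over the breakpoint widened by one
base with an `alt-allele-match` note in the name field, because their true
position is not representable on the reference.

Exported pairs are filtered by default to better-allele $p < 10^{-4}$,
matching the evidence filter; both alleles' statistics are always printed
for reported pairs. The command-line interface (`scan`, `builddb`,
`annotate`, `export`) writes a run manifest (inputs, package version,
parameters, and the sign/coordinate/tie-break conventions above) next to
its outputs so any run can be reproduced; the manifest timestamp is the
only non-deterministic output byte.

## The synthetic fixture generator

Hermetic testing uses seeded synthetic data rather than downloads:
`make_genome()` draws i.i.d. bases (uniform by default);
`random_motifs()` samples sharply informative motifs of widths 8–12 (one
dominant base per position, counts 12–20 against 0–3, consensus never a
homopolymer); `plant_and_mutate()` writes consensus sites into the genome
and constructs one variant per plan class — SNV at the most informative
position, interior deletion, motif-splitting insertion, motif-creating
insertions (contained and edge-overlapping), and a far-away neutral SNV.
Insertion sequences are constrained so VCF left-alignment cannot shift them
and junction bases cannot silently recreate the planted consensus, which
makes the intended direction and geometry of every variant deterministic.
Sites are separated by at least `max(3w, 150)` bases: `3w` prevents window
interference between sites, and 150 keeps each site's ChIP peak
(half-width 50) from reaching any neighboring variant so exactly one peak
matches each planted disruption. Toy chromosomes are 10 kb and 8 kb — large
enough for twelve well-separated sites, small enough that the full suite
runs in seconds.

What this emulates — and what it does not: i.i.d. background sequence has
no repeats, GC structure, or motif look-alikes beyond chance; planted sites
are perfect consensus matches; peaks are rectangles centered on sites.
Passing tests therefore demonstrate the correctness of the scoring,
coordinate, p-value and annotation machinery, not calibration on real
genomes, where background composition and degenerate sites make effect
sizes and p-values less crisp.

## Worked example

```{r example}
fx <- write_fixture_bundle(file.path(tempdir(), "fx"), seed = 42)
res <- score_variants(fx$variants, fx$motifs, fx$genome)
db <- build_peak_db(fx$peaks_bed)
ann <- annotate_results(res, db, tf_map = read_tf_map(fx$tf_map))
subset(ann, vid == "var002_del_span" & motif_id == "SYNM002",
       select = c(effect, direction, geometry, coord_start, coord_end,
                  ref_pvalue, evidence_status, peak_count))
```

## Known limitations

* Each variant is scored independently; nearby variants on one haplotype
  are not combined.
* The null model is zeroth-order i.i.d.; dinucleotide backgrounds are not
  supported.
* The match p-value is per window; users comparing motifs of different
  widths should account for the reported window counts.
* rsID input requires a local lookup table; there is no network access to
  dbSNP, and peak databases must already be on the correct assembly (no
  liftover).
* Structural variants, breakends and IUPAC-ambiguous motif alphabets are
  rejected at parse time.
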