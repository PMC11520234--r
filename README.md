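# motifdisruptr

Scores genetic variants — SNVs, multi-nucleotide variants, and short
insertions/deletions — against transcription factor (TF) position weight
matrices to predict binding-site disruption, and corroborates predictions
with TF ChIP-seq peaks from a locally built, ReMap2022-layout BED database.
It is aimed at regulatory-genomics analysts who need a scriptable,
fully offline first-pass annotation of candidate variants.

## What it computes

For a motif of width *w* with smoothed position probabilities *P* and
background *b*, windows score by log-odds
*S(x) = Σᵢ log₂(P[i, xᵢ] / b[xᵢ])*, min–max normalized to a relative score
in [0, 1]. For each (variant, motif) pair the package:

* builds the reference- and alternate-allele sequences with exactly
  *w − 1* bases of context (the minimal set of windows that can overlap the
  variant) and finds the best match on each allele over both strands;
* attaches an **exact match p-value** P(S ≥ s) under an i.i.d. background,
  computed by dynamic-programming convolution of the discretized
  per-position score distributions (granularity: 1/10⁴ of the score range);
* reports the **effect size** Δ = rel(ALT) − rel(REF) (negative =
  disruption, positive = site creation) with strong/weak/neutral calls at
  |Δ| ≥ 0.4 / 0.1;
* locates indel-overlapping matches in **edge-relative coordinates**
  (offsets of the motif's start/end from the variant's start/end; negative
  = upstream, 0 = exact coincidence) with a geometry label —
  `upstream_overlap`, `contained`, `downstream_overlap`, or `spanning` —
  because a motif created inside an insertion has no reference
  coordinates;
* optionally attaches overlapping ChIP-seq peaks whose TF matches the
  motif (case/punctuation-insensitive, with optional TF-family expansion)
  for results passing the p < 1e-4 evidence filter.

Inputs: VCF 4.x, a BED6 dialect with `chrom:pos:REF:ALT` name fields, or a
local rsID lookup TSV; genome FASTA; JASPAR PFM or MEME minimal motif
libraries; ReMap-layout peak BEDs. Outputs: lossless TSV, SQL script, and
BED9 browser tracks color-ramped by effect size or p-value, plus a
reproducibility manifest.

## Worked example

Everything below is generated — no downloads. The seeded fixture bundle
plants motif consensus sites in a toy genome and constructs variants with
known intended outcomes:

```r
library(motifdisruptr)

fx  <- write_fixture_bundle(file.path(tempdir(), "fx"), seed = 42)
res <- score_variants(fx$variants, fx$motifs, fx$genome)
db  <- build_peak_db(fx$peaks_bed)
ann <- annotate_results(res, db, tf_map = read_tf_map(fx$tf_map))

subset(ann, vid == "var002_del_span" & motif_id == "SYNM002",
       select = c(effect, direction, geometry, coord_start, coord_end,
                  ref_pvalue, evidence_status, peak_count))
#>    effect direction geometry coord_start coord_end ref_pvalue evidence_status peak_count
#> 5 -0.2504 disrupted spanning          -1         1  2.384e-07       evaluated          1
```

This variant deletes the interior of a planted 11-bp site (consensus
`CACGAAATCAG`): the reference allele carries a perfect match (p ≈ 2.4e-7),
the deletion removes it (Δ = −0.25, `disrupted`), the motif overhangs the
deletion by one base on each side (`spanning`, coordinates −1/+1), and one
matching TF2 ChIP-seq peak overlaps the variant (`peak_count = 1`).

The same run from a shell:

```sh
Rscript exec/motifdisruptr builddb --peaks fx/peaks.bed --out fx/peakdb.txt
Rscript exec/motifdisruptr scan \
  --variants fx/variants.vcf --format vcf \
  --genome fx/genome.fa --motifs fx/motifs.jaspar \
  --peakdb fx/peakdb.txt --tf-map fx/tf_map.tsv \
  --out-prefix results/run --seed 1
```

which writes `run.tsv`, `run.bed` (BED9, `itemRgb` track), `run.sql` and
`run.manifest.json` (inputs, parameters and the sign/coordinate
conventions of the run).

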