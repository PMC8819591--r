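# raacdip

Classify immunoglobulins from primary sequence using a five-letter reduced
amino-acid alphabet, λ-gap dipeptide compositions, auto-cross covariance
(ACC) descriptors, MRMD feature selection, and a minimal two-feature
gain-ratio decision-tree model.

## The science in one page

Immunoglobulin domains share conserved sequence contexts that survive a
drastic simplification of the amino-acid alphabet. raacdip maps each protein
onto the reduced alphabet {G, F, V, C, W} (clusters GPHNDERQKAST → G,
FY → F, VMIL → V, C → C, W → W) and describes it by:

* **75 λ-gap dipeptide frequencies** — for λ ∈ {0, 1, 2}, the frequency of
  each ordered reduced-letter pair separated by λ residues,
  f<sub>u</sub> = n<sub>u</sub><sup>λ</sup> / Σ<sub>u</sub> n<sub>u</sub><sup>λ</sup>;
* **18 ACC features** — lagged auto- and cross-covariances (lags 1–2) of
  three standardized physicochemical profiles (Kyte–Doolittle
  hydrophobicity, Hopp–Woods hydrophilicity, side-chain mass) of the
  unreduced sequence.

The 93-dimensional description is then shrunk: **MRMD** ranks features by
|Pearson correlation with the class| plus mean distance to the other feature
columns; nested ranking prefixes are cross-validated and the smallest
near-optimal prefix kept; greedy backward elimination then reduces the
subset to **two features**, which on immunoglobulin-like data are the λ = 1
dipeptides `F*C` and `G*C` (F/Y, one skipped residue, then C — and likewise
for the large G cluster). The mechanism is a conserved immunoglobulin-domain
motif whose …Y-T-C tail reduces to F-G-C, contributing exactly one `F*C`
occurrence per motif copy. Models are evaluated by stratified 10-fold
cross-validation with SE = TP/(TP+FN), SP = TN/(TN+FP), and accuracy.

A seeded synthetic-data generator reproduces the statistical shape of the
problem (109 motif-bearing positives vs 119 decoy-enriched negatives,
lengths 100–500, Swiss-Prot background composition), so the whole pipeline
runs end to end without downloads.

## Worked example

```r
library(raacdip)

ds  <- generate_dataset(generator_config(seed = 7))   # 109 + 119 sequences
res <- run_pipeline_records(ds$records, model = "tree", folds = 10, seed = 7)

res$final_features
#> [1] "F*C" "G*C"

print(res$cv)
#> 10-fold CV (tree, seed 7): SE 0.853, SP 0.882, accuracy 0.868
#> pooled counts: TP 93, TN 105, FP 14, FN 16

print(res$rule)
#> threshold rule: positive iff (x > 0 and y <= 6) (training accuracy 0.917)

class_summaries(res$scatter)
#>      label feature   n n_zero min q25 median q75 max
#> 1 positive       x 109      2   0   1      1   1   3
#> 2 positive       y 109     12   0   1      2   4   9
#> 3 negative       x 119     86   0   0      0   1   3
#> 4 negative       y 119      1   0   4      7  11  24
```

Reading the output: the pipeline rediscovers the two motif-driven features
from all 93. The two-feature tree classifies held-out sequences with 86.8%
accuracy; the fitted integer rule says a sequence is an immunoglobulin when
its `F*C` count (x) is at least 1 and its `G*C` count (y) is at most 6. The
class summaries show the separation mechanism: 86/119 negatives have a zero
`F*C` count (only 2/109 positives do), while negatives carry systematically
higher `G*C` counts.

The motif mechanism itself:

```r
reduce_sequence("ISNVTREDAGTYTC")
#> [1] "VGGVGGGGGGGFGC"
motif_feature_contribution("ISNVTREDAGTYTC", feature = "F*C")
#> [1] 1
```

## Command line

A thin front-end is installed at `exec/raacdip`:

```sh
Rscript exec/raacdip simulate --n-pos 109 --n-neg 119 --seed 7 --pos pos.fasta --neg neg.fasta
Rscript exec/raacdip run --pos pos.fasta --neg neg.fasta --seed 7 --out-dir out/
Rscript exec/raacdip run --pos pos.fasta --neg neg.fasta --features 'FC*,GC*' --model tree
Rscript exec/raacdip motif --in pos.fasta --motif ISNVTREDAGTYTC --max-mismatches 2
```

`run` writes `features.tsv`, `ranking.tsv`, `trajectory.tsv`,
`cv_report.tsv` and `scatter.tsv`, all reproducible from the inputs and the
seed.

## Package layout

* `R/io.R` — FASTA reading/writing (via Biostrings) and sequence
  canonicalization; label TSV support.
* `R/raac.R` — reduction schemes: `default_scheme()`, `parse_scheme()`,
  `reduce_sequence()`.
* `R/features.R` — dipeptide counts/frequencies, ACC, feature-matrix
  assembly and TSV round-trip.
* `R/mrmd.R` — relevance, distance, combined ranking, prefix selection.
* `R/classify.R` — gain-ratio tree, forest analogue, stratified CV, metrics.
* `R/reduce_dim.R` — greedy backward elimination / forward selection.
* `R/rule2d.R` — two-feature scatter, integer threshold rule, class
  summaries.
* `R/motif.R` — Hamming-tolerant motif scanning and motif-to-feature
  attribution.
* `R/synthetic.R` — seeded dataset generator with insertion manifest.
* `vignettes/reduced-alphabet-classification.Rmd` — the methods vignette:
  model, defaults, generator design, numerical conventions, limitations.
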