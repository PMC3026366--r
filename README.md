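# tlgrn — time-lagged information-theoretic GRN inference

`tlgrn` reconstructs directed gene regulatory networks (GRNs) from
time-series expression data sampled at equally spaced time points.  It is
aimed at systems-biology analysts working with short time courses
(microarray-era cell-cycle experiments, in-silico benchmark data) who want
an information-theoretic method that accounts for regulatory *delays*
instead of assuming every interaction acts within one sampling interval.

## The method in brief

Expression is quantized to ON/OFF states per gene (median split after
trimming one outlier per extreme).  For every ordered gene pair a
**non-negative regulatory lag** is estimated:

τ(A→B) = (time of B's first expression change after A's initial
up-regulation) − (time of A's initial up-regulation),

which is ≥ 1 by construction — differencing the two genes' initial-change
times, the older approach, leaves one direction of every asynchronous pair
negative.  Pairs are scored with **time-lagged mutual information**:

TLMI(A;B; τ) = MI( A[1..m−τ], B[τ+1..m] ),   MI(A;B) = H(A) + H(B) − H(A,B),

in bits, and every observed score is tried as an edge threshold.  The
network minimizing a description length is selected:

* **network MDL** — λ·(model bits: k·log₂n parent naming + 2ᵏ-entry CPT
  memory per gene) + data bits (Laplace-smoothed conditional code);
* **PMDL** — predictive (Krichevsky–Trofimov sequential) code length only,
  followed by pruning of indirect edges whose time-lagged *conditional* MI
  given a co-regulator falls below 0.1 bits.

A synchronous Boolean-network simulator with per-edge delays and flip
noise provides ground-truth-known benchmark data, and the evaluation
module scores inferred networks by directed-edge precision
P = Ce/(Ce+Fe) and recall R = Ce/(Ce+Me), with data-size sweep and
MI-saturation-curve utilities.  The methods vignette
(`vignettes/time-lagged-grn-inference.Rmd`) documents the model,
parameters and design choices in full.

## Worked example

```r
library(tlgrn)

model <- randomBooleanNetwork(8, seed = 42)   # ground-truth Boolean GRN
bm <- simulateSeries(model, 50, seed = 43)    # 8 x 50 binary time course
bm
#> BinaryExpressionSeries: 8 genes x 50 time points (51.0% ON)

fit <- inferPMDL(bm, timeLagged = TRUE)
fit
#> GRNInference (pmdl): 10 edges at threshold 0.03976 bits (55 candidates swept)

tn <- trueNetwork(model)
tn
#> GeneNetwork: 8 genes, 15 directed edges
precisionRecall(confusionCounts(tn, inferredNetwork(fit)))
#>   Ce Me Fe precision    recall     ratio
#> 1  5 10  5       0.5 0.3333333 0.6666667
```

The threshold sweep selected the candidate network whose predictive code
length was minimal (threshold 0.0398 bits over the TLMI scores); of its 10
directed edges, 5 are present in the generating network, giving precision
0.50 against a complete-digraph baseline of 15/56 ≈ 0.27, and recall 0.33.
`sweepTrace(fit)` exposes the full description-length trace of all 55
candidate thresholds.

The same workflow is scriptable from a shell via the thin CLI in
`inst/scripts/tlgrn`:

```sh
tlgrn simulate -n 8 -m 50 --seed 42 -o data.tsv --true-net truth.tsv
tlgrn infer pmdl data.tsv --assume-binary --time-lagged -o net.tsv
tlgrn evaluate --true truth.tsv --inferred net.tsv
```

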