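---
title: "Gene-pair doublet features: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-pair doublet features: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geneDoublets)
```

## The model

`geneDoublets` treats two-class expression classification as a feature
engineering problem. Individual genes can be weak biomarkers when the
biology acts on gene *combinations*: two co-regulated genes may each carry
large shared variation (so their marginal class signal is buried) while a
simple function of the pair — their difference, sum, product, or
within-sample ordering — separates the classes cleanly. The package builds
those pair functions, called *doublets*, and feeds them to unmodified
off-the-shelf classifiers.

For gene vectors $g_a, g_b \in \mathbb{R}^M$ over $M$ samples:

* sumdiff doublets: $g_a + g_b$ (the *positive* doublet, up-up/down-down
  co-movement) and $g_a - g_b$ (the *negative* doublet, up-down movement
  and, through its sign, the expression order of the pair);
* mul doublets: $g_a \cdot g_b$ elementwise — amplifies the co-movement
  relations but discards order;
* sign doublets: $\mathrm{sign}(g_a - g_b)$ — keeps *only* the
  within-sample order, and is therefore exactly invariant under any
  strictly increasing transform of the expression values (a rank feature
  in the spirit of top-scoring-pairs classifiers).

Both genes and doublets are scored with the two-sample t-score
$t = (\bar{x}_1 - \bar{x}_2)\big/\sqrt{s_1^2/n_1 + s_2^2/n_2}$,
where subscripts index the two classes. The Welch (per-class variance)
form is the default because it stays calibrated under unequal class
variances, which doublet construction itself induces (a sum of two genes
has inflated variance); a pooled-variance Student form is available via
`method = "pooled"`. Class 1 is always the lexicographically smaller
label, fixing the sign convention.

### Unique-doublet selection

`select_unique_doublets()` implements the selection algorithm end to end:

1. t-scores for all $N$ genes; 2. rank by $|t|$ descending;
3. keep the top $K = \max(2, \lfloor N \cdot \text{fraction}/100 \rfloor)$
   genes; 4. build all doublets of the $K$ genes ($K(K-1)$ rows for
   sumdiff, $K(K-1)/2$ otherwise); 5. t-scores for every doublet;
6. rank doublets by $|t|$ descending; 7.–8. scan in that order and keep a
   doublet iff neither member gene is already used; 9. return the kept
   list.

The result is a matching on the top-$K$ genes: at most
$\lfloor K/2 \rfloor$ doublets, no gene repeated. In sumdiff mode the sum
and diff features of the same pair compete as two candidates in one ranked
list; both consume both genes, so at most one survives. The conventional
fraction grid is 0.2, 0.4, 0.6, 0.8, 1, 2, 4 and 10 percent, but any
fraction in $(0, 100]$ is accepted — the complexity is quadratic in $K$,
not $N$, and at desk scale the dense $K(K-1) \times M$ matrix is built
outright rather than streamed.

### Evaluation

`loocv()` estimates accuracy by leave-one-out cross-validation with
*in-fold selection*: for every fold, gene scoring, ranking, doublet
construction, doublet scoring and greedy pruning are all recomputed on the
$M-1$ training samples, the held-out sample is mapped through the trained
doublet definitions (`transform_samples()`), and only then predicted.
Selecting features on the full matrix before CV is the classic source of
optimistic bias in small-sample expression studies; here the held-out
sample influences nothing. The raw baseline deliberately uses **all** $N$
genes, not the top-$K$ subset, so the comparison is "classifier as usually
run" versus "classifier on doublets".

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `floor`, `ceiling` | 10, 16000 | raw intensity | conventional Affymetrix clip window; floor > 0 makes the log defined |
| `log_base` | 2 | — | microarray convention (fold changes in bits) |
| `sd_denominator` | n−1 | — | sample sd in standardization |
| `fraction_pct` | 10 | % of genes | top-gene pool for pairing; grid 0.2–10 in the sweep |
| t-score `method` | welch | — | robust to unequal class variances; pooled available |
| kNN `k` | 3 | neighbours | odd k avoids most vote ties in two classes |
| NB `var_floor` | 1e-9 | variance | keeps log-densities finite for near-constant features (sign doublets are ±1-valued and can be class-constant) |
| NSC `threshold` | 0 | shrinkage Δ | plain (standardized) nearest centroid; a grid can be swept |
| SVM kernel | linear | — | high-dimension / low-sample convention |

Preprocessing is applied once, before CV: all three steps are per-value or
per-sample (column-wise) and use no cross-sample statistics, so they are
fold-independent and cannot leak. All inputs — cDNA or oligonucleotide —
are treated uniformly by the pipeline.

## The synthetic generator

Real two-class microarray compendia are large external downloads; the
package instead tests every claim on `simulate_dataset()`, which emulates,
on the post-log scale (values $\approx$ standard normal), the three data
regimes each doublet family targets:

* **DE genes** — a mean shift `delta_de` in class 2: classical single-gene
  signal, the baseline any method should find.
* **Difference pairs** — both members share a per-sample latent
  $N(0, \sigma_{shared}^2)$ term and one member adds `delta_pair` in
  class 2. Marginally each member has variance
  $\sigma_{shared}^2 + \sigma_{base}^2$, so its single-gene t is small,
  but the pair difference cancels the shared term: exactly the structure a
  diff doublet recovers.
* **Reversal pairs** — members sit at $\pm\,\texttt{delta\_pair}/2$ around
  a *common* per-sample base value, with the ordering swapped between
  classes; each sample follows its class pattern with probability
  `p_reversal`. The shared base makes the within-pair order deterministic
  given the pattern, so at `p_reversal = 1` the sign doublet is constant
  within class and opposite between classes — perfect separation by
  construction. Members are individually shifted by
  $\pm\,\texttt{delta\_pair}/2$ between classes, so (unlike difference-pair
  members) they do rank into small top-K lists.

One global seed drives a per-component seed sequence (background, DE
genes, difference pairs, reversal pairs), so enabling one signal block
does not perturb the values generated for another. `as_raw_scale()`
re-exports a dataset on the raw intensity scale (inverse log, centred in
the clip window) so the full clip/log/standardize pipeline can be
exercised end to end.

What the generator does **not** emulate: probe-level effects,
intensity-dependent variance (MA-curvature), batch effects, correlated
background beyond the planted pairs, or class-imbalanced designs beyond
what `n_samples_per_class` allows per class. Passing tests therefore show
the algorithmic claims (selection correctness, leakage-freedom, the
advantage of pair features *when pair structure exists*), not performance
on any real cohort.

## Study conditions used in the simulation tests

The simulation-based checks fix these conditions:

* *Leakage null*: $N = 500$, $M = 40$, no signal, 20 label permutations,
  sumdiff-kNN at fraction 2 %. Mean accuracy must sit within 3 binomial
  standard errors of the majority-class fraction — selection bias would
  push it far above.
* *Shared-noise advantage*: $N = 200$, $M = 60$, 10 difference pairs,
  $\sigma_{shared} = 3$, `delta_pair` $= 2$, seeds 1–25; sumdiff-kNN must
  beat raw kNN by ≥ 10 accuracy points on average. Selection runs at
  fraction 100 %. The fraction matters structurally: the *unshifted*
  member of a difference pair has near-zero marginal t, so in a small
  top-K list the planted pairs can never form — only with all genes as
  candidates does the diff doublet (whose own t is large) become
  constructible and the advantage the construction implies appear. This is
  a property of the scenario, not a tuning knob: the greedy algorithm
  accepts any fraction, and 100 % is the honest setting for a claim about
  pair recovery.
* *Order reversal*: $N = 200$, $M = 60$, 5 reversal pairs,
  `p_reversal` $= 0.95$, seeds 1–25; sign-kNN at fraction 10 % must
  average ≥ 0.9. Here fraction 10 % ($K = 20$) suffices because reversal
  members are individually DE and rank into the top-K on their own.
* *Recovery*: as the advantage scenario but with `delta_pair` $= 3$ — a
  deliberately strong planted signal — selection at fraction 100 %;
  ≥ 70 % of the top-10 selected doublets must join two members of the
  same planted pair.

These sizes run in a few minutes on one CPU; they were chosen as the
smallest designs in which the constructions' expected effects are large
relative to simulation noise.

## Numerical choices and degenerate inputs

* **Zero-denominator t-scores.** A feature constant within each class has
  a zero standard error. If its class means are also equal it gets
  $t = 0$; otherwise it separates the classes perfectly and is assigned
  $\mathrm{sign}(\bar{x}_1 - \bar{x}_2) \cdot (\max |t_{finite}| + 1)$ so
  it ranks first instead of crashing the ranking. This matters in
  practice: a perfect sign doublet on reversal data is exactly such a
  feature.
* **Ties.** Gene and doublet rankings use a stable sort on $|t|$ with the
  input (construction) order as tie-break — lexicographic pair order, sum
  before diff — so results are byte-identical across runs and platforms.
  kNN breaks distance ties by training index and vote ties by the nearest
  tied neighbour's class, then the lexicographically smaller label.
  `sign(0) = 0` preserves the antisymmetry of the sign transform; after
  per-sample standardization exact ties are rare.
* **Missing values.** The loader rejects missing cells by default, naming
  the offending gene and sample; optional per-gene mean imputation is
  behind `impute = "gene_mean"`. Complete matrices are the norm for the
  intended inputs, so rejection is the safe default.
* **Undersized classes.** Variance computation needs two samples per
  class; scoring and every LOOCV training fold enforce this with explicit
  errors.

## Known limitations

* Two classes only; multi-class extension is out of scope.
* Doublets are unrestricted gene pairs; pathway-restricted pairing and
  higher-order combinations (triplets) are not implemented.
* The nearest-shrunken-centroid implementation covers the standard
  soft-thresholding form with a fixed threshold; it does not perform
  internal cross-validated threshold selection.
* LOOCV only — no k-fold variants or nested hyperparameter tuning; the
  sweep grid is a straight Cartesian product.
* The synthetic generator's independence assumptions (i.i.d. background,
  independent pairs) make its null sharper than real expression data,
  where correlation inflates the spread of extreme t-scores.
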