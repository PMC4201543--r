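---
title: "Methods: how caspcleave predicts caspase cleavage sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how caspcleave predicts caspase cleavage sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The prediction problem

Caspases cleave their substrates almost exclusively C-terminal to an
aspartate: in Schechter–Berger nomenclature the scissile bond lies between
P1 (nearly always D, sporadically E) and P1′. Specificity beyond P1 is
real but soft — effector caspases prefer an acidic P4 and E at P3, and a
small uncharged residue (A, G, S, T, N) at P1′ — so candidate aspartates
vastly outnumber true sites and a scoring model is needed to rank them.

`caspcleave` models the 8-residue context P5–P3′ of each candidate bond.
Three ingredients go into the classifier:

1. **A background-normalized position weight matrix (PWM).** Annotated
   cleavage windows are aligned on the scissile bond and the frequency of
   each amino acid at each of the 8 positions is divided by the background
   amino-acid distribution; the model works with `log2` of that ratio.
   With a total pseudocount weight `pc` distributed across residues in
   proportion to the background `b(i)`, the entry for amino acid `i` at
   position `j` is

   `log2( (count(i,j) + pc * b(i)) / ((n_j + pc) * b(i)) )`

   where `n_j` counts unpadded residues observed at position `j`. This
   form keeps every entry finite and conserves probability mass exactly:
   `sum_i b(i) * 2^PWM(i,j) = 1` at every position, which the test suite
   asserts for every matrix it builds.

2. **Predicted structural context.** Each window position carries a
   secondary-structure label (`H` helix, `E` sheet, `_` loop) and a
   disorder label (`.` ordered, `*` disordered), predicted on the
   full-length protein and then sliced per window. Cleavage sites in
   folded proteins are enriched in exposed loops and disordered segments,
   which is why these labels help rank otherwise similar motifs.

3. **A random forest** over the encoded features, 1500 trees, unlimited
   depth, classification threshold 0.5 on the positive-class probability.
   Naive Bayes, a CART decision tree and an RBF-kernel SVM (gamma 0.01,
   cost 1, scaled inputs) are available behind the same interface for
   comparison, but the forest is the production model.

## Training-set construction

Positives are one window per annotated site, deduplicated on the 8-mer so
all training strings are unique. Negatives use the sliding-window rule:
for a verified site at P1 = p, the residues at its P3, P2, P1′ and P2′
positions (offsets −2, −1, +1, +2) are tentatively declared pseudo-P1 and
their windows labelled non-cleavage. This yields at most four negatives
per site — a ~1:4 class ratio — and concentrates the negative class on
the hardest cases: near-site contexts that overlap the true motif.
Candidates identical to a positive window are dropped (a verified
positive must not be relabelled); terminal sites keep all four candidates
through `X` padding. Splits for hold-out evaluation are stratified by
class so both partitions preserve the ratio.

## Feature layout

The PWM can be presented to the classifier in two layouts
(`casp_config(pwm_layout = ...)`):

* `"per_aa"` (default): for every position and every amino acid, the PWM
  value if that residue is observed there, else 0 — a PWM-scaled one-hot
  encoding, 160 numerics. This preserves residue *identity* at each
  position.
* `"compact"`: only the observed residue's PWM value per position
  (8 numerics).

The per-amino-acid layout is the default because the offset negatives are
structured: an offset −2 negative always carries the source site's P1
aspartate at its P2′, an offset +1 negative carries it at P2, and so on.
The compact summary collapses exactly the residue-identity information
that separates these shifted windows from genuine sites, and in our
calibration experiments it costs about three points of hold-out kappa at
the study scale. Structure labels enter as categorical factors in either
layout, so switching the structure source never changes feature shape.

## Structure prediction

External secondary-structure and disorder predictors are deliberately not
re-implemented; converted outputs of any per-residue predictor can be
supplied as a three-line-per-protein text file. The bundled baseline
keeps the package self-contained: Chou–Fasman helix/sheet propensities
averaged over a 7-residue window (argmax over {helix, sheet, loop}, ties
to loop), and a FoldIndex-style charge–hydropathy rule over a 9-residue
window for disorder (`2.785 * <hydropathy> − |<net charge>| − 1.151 < 0`
flags disorder, with Kyte–Doolittle hydropathy rescaled to [0, 1]). The
baseline is deterministic and total — every residue of every input gets
exactly one label of each kind.

## Scanning, motifs, variants, orthologs

Scanning scores every D (optionally also E) in a protein and reports
P5–P5′ display windows with `-` at the bond, sorted by descending score.
Motif queries use a bond-anchored grammar (`DEVD-A/G/S/T`: alternatives
with `/`, wildcard `X`); hits are scored through exactly the same path as
scanning, which the tests assert. Variant re-scoring recomputes the score
at a fixed P1 after an amino-acid substitution; by default structure is
re-predicted on the mutated sequence (the conservative choice — a
substitution can alter local structure), but fixed labels can be supplied
instead, in which case a variant outside P5–P3′ provably cannot move the
score. Ortholog mapping aligns substrate and ortholog globally (BLOSUM62,
gap open 10, extend 0.5 — Needleman–Wunsch with affine gaps rather than
an external alignment binary) and transfers each P1 through the
alignment; a site is conserved when the aligned residue is D or E, since
E can sporadically substitute at P1.

## The synthetic generator and what it does (not) emulate

`synth_generate()` draws background residues i.i.d. from a fixed
human-proteome-average composition and plants cleavage sites whose
P5–P3′ residues follow the "casp3-like" matrix: P4 D-rich (0.55), P3
E-rich (0.50), P1 fixed at D, P1′ preferring A > G > S > T > N (0.28 /
0.22 / 0.14 / 0.09 / 0.05), other positions background. The P1′ ranking
follows the field's preference order for small P1′ residues and is what
makes a T→A substitution at P1′ score-increasing in the case study. The
`effect_size` dial interpolates every non-P1 column linearly in
probability space toward the background, so 0 and 1 are exact endpoints;
P1 stays D regardless, mirroring the near-absolute aspartate requirement.
Planted sites sit at interior positions at least 12 residues apart.

Two negative constructions exist for different purposes. The
sliding-window rule above is the training construction. For calibration
we instead sample *background windows centered on D*
(`sample_background_windows()`): at effect size 0 these are exchangeable
with planted sites, so a leak-free cross-validated AUC must sit near 0.5.
The offset construction cannot serve as this null — even at effect 0 its
pseudo-P1 is rarely D, which alone sustains AUC well above 0.5.

The generator emulates composition, motif strength, class ratio and
coordinate bookkeeping of real training data. It does **not** emulate
position-to-position correlations within real motifs (residues are drawn
independently per position), homology between substrates, true
structural context (the baseline labels are propensity smoothing, not
real structure), or ortholog evolution. Passing tests on synthetic data
therefore demonstrate the pipeline's correctness and calibration, not
field performance on curated substrates.

## Numerical and procedural choices

* Pseudocount: total weight 1, background-proportional — preserves the
  mass-conservation identity exactly while keeping absent residues finite;
  entries shrink monotonically toward 0 as the pseudocount grows.
* Cross-validation: stratified folds seeded from the configuration. By
  default the PWM is computed once from all positives and reused across
  folds, matching the published procedure; this leaks a little held-out
  information through the features (about +0.06 AUC on a null dataset),
  so `refit_pwm = TRUE` recomputes the PWM inside each training fold and
  is used for all calibration claims.
* Ties in scan output are broken by ascending position; the yes/no class
  is `score >= 0.5`.
* Degenerate metric cells (e.g. precision with no positive calls) are
  reported `NA`, never coerced to 0.
* Misclassification cost is the generic `cost_fp * fp + cost_fn * fn`
  with both weights defaulting to 1 and configurable.
* Problem sizes used by the test suite: the study-scale corpus is 520
  proteins / 661 sites (matching the curated corpus scale); calibration
  properties use 200 planted sites vs 800 negatives with 300–500 trees
  and 3-seed averages; PWM parameter recovery uses 5,000 planted windows,
  asserting mean absolute entrywise deviation ≤ 0.15 log2 units (the
  estimator is unbiased; a *maximum*-deviation bound at this sample size
  would be dominated by the rarest residues, whose per-cell standard
  error alone approaches 0.2 log2 units).

## Known limitations

Scores are probabilities under a 1:4 near-site negative model, not
cleavage efficiencies; over-prediction on full proteomes is expected, as
for all substrate predictors, because substrate availability and exosites
are invisible to sequence windows. No per-caspase assignment is
attempted — the training signal merges caspase families with overlapping
specificity. E-at-P1 scanning reuses the same PWM (its E column at P1),
which is a toggle, not a separately trained model.

## A worked example

```{r example}
library(caspcleave)
library(dplyr)

fx <- make_fixture("tiny")
ts <- build_training_set(fx$records, fx$annotations)
pwm <- compute_pwm(filter(ts, label == "positive"),
                   compute_background(fx$records))
st <- predict_structures(fx$records)
model <- casp_train(ts, pwm, st, casp_config(n_trees = 200, seed = 1))

scan_proteins(model, fx$records[1, ], structures = st)
search_motif(fx$records, "D-A/G/S/T", model = model, structures = st)
autoplot(pwm)
```
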