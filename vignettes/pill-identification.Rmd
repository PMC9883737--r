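---
title: "Pill identification by imprint recognition and similarity retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pill identification by imprint recognition and similarity retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Regulatory pill databases describe each registered pill by its
*characteristics*: three appearance *features* — shape (11 classes), colour
(16 classes) and form (tablet or capsule) — plus the *imprint*, the string of
characters stamped on its two faces. Features alone cannot identify a pill
(a large fraction of pills are white round tablets); the imprint is the
discriminating signal, but it is hard to read automatically: character
detectors confuse visually similar symbols (`O`/`0`, `I`/`1`), miss
characters, and emit them in no particular order.

`pillidr` implements a two-step system around that difficulty:

1. **Recognition.** A single-shot grid detector finds imprinted characters
   and their 2D coordinates; a multitask classifier predicts shape, colour
   and form from the image; and a character-level sequence-to-sequence
   *corrector* turns the noisy unordered detection set into the canonical
   imprint string.
2. **Retrieval.** The predicted characteristics are scored against every
   database record with a five-term additive similarity, and the top-k
   candidates are returned. Because identification is retrieval rather than
   classification, newly registered pills are identifiable without
   retraining — only the database grows.

The canonical imprint writes the front face, an underscore, then the back
face (`"M10_KI"`); the lowercase ligature `"mg"` is the single lowercase
exception in an otherwise uppercase-and-digits vocabulary and is treated as
one token everywhere.

## The similarity score

For a query with predicted features $(s, c, f)$ and imprint $a$, each
database pill with features $(s', c', f')$ and imprint $b$ receives

$$
S \;=\; \tfrac13\,[s{=}s'] + \tfrac13\,[c{=}c'] + \tfrac13\,[f{=}f']
\;+\; \mathrm{sim}_{\mathrm{edit}}(a,b) \;+\; \mathrm{sim}_{\mathrm{overlap}}(a,b)
\;\in\; [0, 3].
$$

The two imprint terms deliberately outweigh the features. They are:

* **Normalized edit similarity** $= 2m/(|a|+|b|)$, where $m$ is the number
  of aligned equal tokens in a minimum-cost Levenshtein script chosen, among
  all minimum-cost scripts, to maximize matches (a dynamic program ordering
  states lexicographically by (cost, &minus;matches)). Equivalently
  $(|a|+|b|-d-x)/(|a|+|b|)$ with $d$ the edit distance and $x$ the
  substitutions in that script.
* **Overlap similarity** $= 2\,|a \cap b|/(|a|+|b|)$ over the token
  multisets, an order-free Dice-style term that retains value when the
  ordering is wrong but the symbols are right.

Both formulas are reconstructions pinned by worked examples rather than
copied from a printed equation: for the pair (`M10_KI`, `M10SPC_`) they give
exactly $6/13$ and $8/13$, and for (`M10_KI`, `M10_Kb`) both give $10/12$,
which together with the identity pair ($12/12$) fixes the normalizations
uniquely among the natural candidates. Each formula lives behind a single
function (`normalized_edit_similarity()`, `overlap_similarity()`) so an
alternative could be swapped in. All terms are exact small rationals;
`total_score()` carries integer numerators and denominators, and decimals
appear only for display. Ranking ties are broken by `pill_id` so retrieval
is deterministic.

```{r}
library(pillidr)
src <- list(shape = "square", color = "orange", form = "tablet",
            imprint = "M10_KI")
targets <- tibble::tibble(
  pill_id = c("target1", "target2", "target3"),
  shape = "square", color = c("pink", "pink", "orange"), form = "tablet",
  imprint = c("M10_KI", "M10_Kb", "M10SPC_"))
rank_database(src, targets, k = 3)
```

## The synthetic study conditions

No pill database ships with the package; a generator reproduces the study
conditions instead.

`generate_pill_database()` samples features independently from the published
marginal distributions of the NLM reference database (round 46.18%, oval
35.01%, oblong 15.46%; white 42.27%, yellow 12.68%, pink 8.93%, orange
8.64%, blue 8.44%, brown 5.76%, green 5.53%; 85% tablets / 15% capsules;
the remaining probability mass spread uniformly over the rare classes).
Imprints draw 2–8 tokens per face (the databases do not publish an
imprint-length distribution, so this range is a synthetic choice covering
typical short codes through longer ingredient strings), with the `"mg"`
token appearing at rate 0.06. At least 10% of records are forced to share
their full feature triple with another record while differing in imprint, so
retrieval cannot succeed on features alone — mirroring the dominance of
white round tablets in real databases. A further 15% of records are
generated as *confusable siblings*: the same imprint as another record
except for one position swapped to a different detector-confusable symbol,
emulating the dosage families and look-alike codes (`M10` vs `MIO`) that
make imprint retrieval genuinely hard and give the correction step its
value.

`render_pill()` draws a reference image: front face left, back face right,
filled silhouettes on a neutral background (the semicircle realizes the
"others" class), capsules as two-tone bodies whose dominant half carries the
record's single colour label, and imprints in a built-in 5×7 bitmap face so
that every character box is exact by construction. Text is laid out in up to
four rows whose widths are constrained by the silhouette's usable width at
each row; an imprint that cannot be placed raises an explicit overflow error
rather than being truncated.

`corrupt_detections()` is the detector-noise model: symmetric confusion
pairs (`O↔0`, `I↔1`, `B↔8`, `S↔5`, `Z↔2`) applied at rate 0.3, dropout at
rate 0.05, Gaussian coordinate jitter (sd 0.01 of the image), and order
shuffling. These defaults are the corruption benchmark used by the tests
and the evaluation pipeline.

What the generator does **not** emulate: photographic variation (lighting,
perspective, focus), broken or partial pills, symbol/logo imprints,
lowercase imprints beyond `"mg"`, and consumer-grade photos. Passing tests
therefore demonstrate that the algorithms are implemented correctly and
that the system behaves as designed under controlled detector noise — not
that any particular accuracy would be obtained on real photographs.

## The three models

All three models are written in base R matrix code with hand-derived
gradients (the test suite pins the seq2seq backward pass against finite
differences). Training is a pure function of its inputs and the
configuration seed.

**Detector.** A single-shot grid predictor in the YOLO family: the image is
tiled into square cells (8 px at the default geometry) and one shared
network — a stride-`cell` convolution with kernel `2*cell` followed by a
dense layer — predicts per cell an objectness score, box offsets and size.
Greedy non-maximum suppression runs at IoU 0.45, highest confidence first,
ties broken by lower cell index (the underlying study does not state its
NMS settings; these are fixed here for reproducibility). Each surviving
detection is then re-classified from a window centred on its box centre,
first snapped onto the local ink centroid (triangularly weighted so a
neighbouring glyph's ink at the window edge cannot drag the centre): centred
glyphs are far easier to separate than arbitrary sub-cell phases, the
centroid fixes the cell-boundary cases where the regression errs by a few
pixels, and train-time jitter of ±2 px makes the classifier robust to what
error remains. Non-maximum suppression also removes any second claim within
0.8 cell widths of a kept centre, since a character centred on a cell
boundary is otherwise claimed by both neighbouring cells. A detection's
confidence is the minimum of its objectness and its class probability. Orientation is normalized first:
the silhouette's second-moment principal axis is rotated to horizontal,
with silhouettes whose moment-axis ratio is within 5% of circular left
untouched (a circle has no defined major axis). Full-scale systems would
use a fine-tuned deep detector here; the interface (`train_detector()` /
`detect_characters()`) is deliberately narrow so one can be substituted.

**Feature classifier.** Three softmax heads $z_k = \mathrm{softmax}(w_k p)$
for shape, colour and form over a shared backbone output $p$, trained by
minibatch SGD (learning rate 0.1, weight decay $10^{-4}$, batch 10) on the
summed cross-entropy $\sum_k w_k \mathrm{CE}_k$ with all head weights 1.
The backbone is a small dense residual network on the 12×24 downsampled
image rather than a deep convolutional stack: on synthetic renders the
features are low-frequency (silhouette, dominant colour, two-tone split),
interpreted-R convolutions would dominate the runtime, and the head
structure — the part that matters to the loss and the interface — is
unchanged and backbone-pluggable. Inverse-frequency oversampling
(sampling probability proportional to the product of the three labels'
inverse frequencies) equalizes class exposure for the rare shapes and
colours.

**Corrector.** The centrepiece: an attention-based bidirectional
character-level seq2seq model consuming *coordinate-encoded* characters.
Each detection enters as one-hot(char) ⧺ (x, y); a linear embedding
(width 45) feeds a bidirectional GRU encoder; the decoder is a GRU with
additive (concat) attention over the encoder states, trained by teacher
forcing on $\prod_j p(\mathrm{tgt}_j \mid \mathrm{tgt}_{<j},
\mathrm{src})$ with Adam (learning rate $10^{-3}$, batch 50). The
coordinates are what let the model recover the true character order from a
shuffled detection set; the coordinate-ablation test (zeroing x, y at train
and test) verifies that they carry real signal. Detections are sorted into reading
order before encoding — face, then text row (rows recovered by clustering y
within a face, because within a row the y differences are pure jitter), then
x — a convention only, since order robustness comes from training on
shuffled corruptions; the coordinate-ablated variant skips both the sort and
the coordinates, as sorting by position is itself coordinate use. The underscore is an ordinary
vocabulary token during training and decoding; since detections never
contain it (it is a face boundary, not a printed character), the model must
*insert* it from the coordinates. Decoding is greedy (argmax per step, the
study being silent on search), bounded at 24 tokens, and post-filtered to
keep at most the first underscore. Optionally (`context_mode =
"features"`), the pill's shape/colour/form labels are embedded, summed and
used as the encoder's initial hidden state — the minimal standard way to
let the features act as context for the imprint; a paired test shows the
context helps exactly when imprints correlate with a feature.

## Evaluation design

`pillid_evaluate()` renders one image per query pill, normalizes
orientation per face, detects characters, **injects the configured
corruption** between detection and correction, predicts features, corrects
(or not, under `ablate = "corrector"`), and ranks. The injection is a
deliberate design choice of the synthetic study: on clean synthetic renders
the toy detector is nearly exact, so the corruption model supplies the
confusion/drop/scramble errors that a full-scale detector exhibits on real
photographs, and the corrector is measured against exactly the noise it was
trained to undo. Ablation switches (`"shape"`, `"color"`, `"form"`,
`"imprint"`) zero score terms, reproducing the qualitative ablation
findings: removing the imprint terms collapses top-1 accuracy to the
feature-duplicate chance level of the database, while removing any single
feature term barely matters.

## Numerical choices and degenerate inputs

* Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) with global gradient-norm clipping
  at 5 for the corrector; plain SGD with the same clip for detector and
  features; uniform ±√(6/(fan-in+fan-out)) initialization.
* Empty inputs: an empty detection set corrects to the empty imprint; two
  empty imprints have similarity 1; an empty image errors in orientation
  normalization ("no foreground") and detects nothing.
* The lexicographic DP prefers substitution on ties; ranking ties break by
  `pill_id`; NMS ties break by cell index. All three rules exist only to
  make results reproducible.
* Probability tables must sum to 1 within 1e-9 and be non-negative;
  violations are rejected naming the offending feature.

## Desk-scale problem sizes

The package's tests and reproduction script run the full system at sizes
chosen for a laptop CPU: databases of 40–360 pills, 96×192 px renders,
detectors trained on 300 images (40 epochs, learning rate 0.05 — the toy
detector's own calibration; the full-scale defaults of `detector_config()`
follow the published system), feature classifiers with hidden width 64 for
25 epochs, and correctors with hidden width 64 for 12 epochs on ~5,000
corruption pairs. At these sizes the corrector reaches ≥ 80% exact-match on
held-out corruptions, both recognition models exceed their 95%/0.9 recovery
bars, and end-to-end top-1 with the corrector clearly exceeds top-1
without it. Accuracies that full-scale systems report on the national
reference databases (MFDS, NLM) require that external data and GPU-scale
training; they are neither reproducible in this setting nor claimed, and the
package's claims are the property-level ones its tests compute.

## Limitations

* The renderer's regularity (one font, fixed glyph sizes, clean
  backgrounds) makes detection far easier than on photographs; the
  detector's numbers say nothing about camera images.
* The corrector learns the imprint distribution of the database it is
  trained on; wholly out-of-distribution imprints degrade toward the raw
  detector reading.
* Single colour label per capsule (the dominant half) discards the second
  colour, as the scoring scheme requires.
* `"rectangle"` is kept as an 11th shape value; data sets that fold it into
  `square` should do so before training.
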