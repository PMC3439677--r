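---
title: "Classifying weak co-regulator ChIP-seq peaks by integrating biological evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying weak co-regulator ChIP-seq peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coregpeaks)
```

## The problem

Co-regulator proteins such as SRC-1/NCOA1 shape transcription by binding
DNA-binding factors (here estrogen receptor α), not DNA itself. ChIP-seq
against a co-regulator therefore measures secondary protein–DNA contact and
produces weak tag pileups: at conventional caller cutoffs most functional
sites are missed, while relaxed cutoffs flood the call set with noise.
`coregpeaks` reframes the decision as supervised classification over a
pooled candidate set, so that several weak but independent lines of
evidence — sequence composition, chromatin state, primary-factor binding,
and transcriptional outcome — jointly decide each candidate.

## Candidate pooling

Candidates are the union of the peak sets of several callers run at
relaxed cutoffs. Peaks sharing at least one base pair on the same
chromosome are merged transitively into one candidate spanning
`min(start)..max(end)`. The shared-base-pair criterion is the same one used
for the primary-TF overlap feature; since no separate merge rule is
mandated by the design, applying one criterion uniformly is the minimal
consistent choice. The candidate summit is the summit of the
highest-scoring contributing peak (each caller's score is its own
confidence proxy; ties go to the leftmost summit for determinism), because
the summit anchors every sequence-derived feature. Coordinates are 0-based
half-open throughout, matching the BED-family inputs, and summits are
stored as absolute positions so window extraction is caller-independent.

## The 67 features

| block | columns | definition |
|---|---|---|
| trigram presence | 1–64 | each of `AAA…TTT` (lexicographic) present at least once in the ±300 bp summit window |
| nucleosome occupancy | 65 | mean predicted per-base occupancy over summit ±50 bp strictly greater than 0.75 |
| primary-TF overlap | 66 | ≥1 bp shared with any ERα peak |
| sensitive gene | 67 | nearest-TSS gene is co-regulator-sensitive |

Tunable parameters (`feature_config()`): `seq_flank` (default 300 bp — a
600 bp window), `occ_flank` (default 50 bp, roughly one nucleosome;
the window is inclusive of both endpoints, 101 positions, which pins the
mean bit-exactly), `occ_threshold` (default 0.75, compared strictly), and
`gene_max_distance` (default unlimited — plain nearest-TSS mapping, the
default behaviour of common peak-annotation tools; a 50 kb cap is exposed
for analyses that require TSS proximity).

Design notes:

* Trigram scanning is forward-strand only by default (`both_strands`
  switches it); windows containing `N` match nothing.
* Windows are clamped at chromosome edges, never padded: padding would
  manufacture trigram absences indistinguishable from real ones while
  falsifying coordinates.
* Occupancy positions with no data count as 0 — "no evidence of
  occupancy" — which is conservative given the strict 0.75 cut.
* Peaks whose chromosome carries no gene (or none within the cap) get a 0
  sensitive-gene bit rather than being dropped, so the feature matrix stays
  aligned with the candidate pool.
* Gene-distance ties break to the smaller TSS, then lexicographic gene id.

In 600 bp of typical sequence nearly every trigram occurs at least once,
so the presence/absence block is close to constant and contributes little
separation; it is retained because the feature definition is
presence/absence by design, and on real genomes locally biased composition
can still register. The ROC ranking (below) makes the actual contribution
of each feature measurable rather than assumed.

## Bernoulli naïve Bayes

Each feature is modeled as an independent Bernoulli per class. Parameters
use Laplace add-one smoothing, `theta[c,j] = (n_cj + 1) / (n_c + 2)`:
with only 18 validated positives, unsmoothed maximum likelihood puts exact
zeros into the likelihood product and a single feature flip would veto a
class outright. Smoothing also guarantees every `theta` lies in
`[1/(n_c+2), (n_c+1)/(n_c+2)]`, strictly inside (0,1). Posteriors are
computed in log space and renormalized, so `P(pos|x) + P(neg|x) = 1` to
machine precision. The positive call threshold is 0.8 and the comparison
is inclusive (posterior ≥ 0.8); at 0.5 the rule reduces to argmax.
Training keeps all positives and draws `ratio` negatives per positive
(1:1, 1:2 or 1:3; 1:2 is the default design) uniformly without replacement
under a seed.

Cross-validation is stratified 9-fold; metrics (precision, recall,
accuracy) are computed on the confusion matrix pooled over held-out folds
rather than averaged per fold, because with 18 positives a fold holds only
two and per-fold rates would be quantized to halves.

Feature informativeness is ranked by `|AUC − 0.5|`, where AUC is the
empirical ROC area of the single feature as a score for the positive
class, computed with midrank tie handling (equivalently the normalized
Mann–Whitney U). The absolute deviation treats anti-correlated features
(AUC < 0.5) as informative, and criterion ties resolve to the lower
feature index.

## k-means baseline

The unsupervised baseline is k-means with k = 2 under the city-block (L1)
metric. The centroid update is the component-wise median — the exact L1
minimizer — not the mean; assignment ties go to the lower cluster index;
a run converges when assignments stop changing, and the total L1 distance
is non-increasing across iterations. Because Lloyd iterations only find
local optima, the best of 20 seeded random initializations (two distinct
random rows) is kept, and clusters are relabeled so cluster 1 is the
larger. An input of identical rows is rejected.

## Self-training

The semi-supervised variant wraps NB in self-training. Starting from
`L0 = P ∪ N0` with as many sampled control negatives as positives, each
iteration fits a classifier on `L_t`, scores the unlabeled pool, promotes
the `m` highest-posterior instances as pseudo-positives (posterior ties
break by ascending candidate id), draws `m` fresh negatives from the
control reservoir, and appends both to the labeled set — so `|L_t|` grows
by exactly `2m` per completed iteration. The loop stops when the unlabeled
pool empties, the iteration cap (default 75) is reached, or the reservoir
cannot supply a full matching draw (the last case stops cleanly before
promotion, avoiding an undefined partial sample). The final classifier is
then applied to the remaining unlabeled instances. `m` defaults to 5, so
a capped run promotes a few hundred pseudo-labels — the scale at which
self-training either stabilizes or visibly degrades; `m = 0` reduces
bitwise to the supervised fit on `L0`, a property the tests assert. An
optional evaluator (typically ERE containment of the current positive
calls) is recorded per iteration; an empty call set records ratio 0 with
an explicit flag.

## Motif evaluation

Predicted peak sets are scored by the fraction of peaks containing an
estrogen response element within ±300 bp of the summit. The scanner is a
standard log₂-odds PWM: frequencies from counts with pseudocount 0.5,
uniform background, both strands scanned, `N`-containing windows excluded,
ties resolved to the leftmost hit (forward strand first). A peak "contains"
the motif when its best hit reaches a fixed fraction (default 0.8) of the
matrix's maximum achievable score. This per-peak containment call is
deliberately simpler than set-level over-representation statistics with
resampled p-values: the quantity tabulated per peak set is literally "how
many peaks have the motif", and a transparent threshold makes that
reproducible. The packaged matrix is synthetic, built from the palindromic
consensus `GGTCAnnnTGACC` (count 10 at each consensus base, all-zero rows
at the three free positions, which score 0 after the pseudocount); any
JASPAR-format matrix can be substituted. Because the containment threshold
is a score fraction rather than a calibrated p-value, absolute containment
ratios are comparable only within a run — across peak sets — not against
ratios produced by other motif software.

## The synthetic data generator

`generate_synthetic()` creates the statistical structure the classifier
assumes, with known ground truth: true sites carry a planted ERE at the
summit (probability 0.9), elevated occupancy (0.85), frequent ERα overlap
(0.8) and frequent sensitive nearest genes (0.6); decoys carry the same
signals at background rates (0.1 / 0.5 / 0.1 / 0.05). Three pseudo-callers
re-report sites with independent 20% miss rates and Gaussian summit jitter
(sd 20 bp, truncated into the peak), an IgG-like negative pool is drawn at
least 2 kb from every site, and 18 true sites form the labeled positives.

Choices worth stating:

* **Genome size.** Two chromosomes of 1 Mb of i.i.d. uniform bases host
  the default 600 sites at the required ≥2 kb spacing with room for the
  flanking windows; uniform composition keeps the trigram block
  uninformative except through the planted motif, so the evidence features
  carry the class signal by construction.
* **Occupancy support.** The elevated-occupancy region extends ±200 bp
  around the site center so that the ±50 bp occupancy window of a
  jittered summit still lies inside it; each site's constant level gets
  uniform ±0.05 noise, realizing "window mean = configured level ± noise"
  exactly.
* **Background genes.** Besides the one TSS placed within 1 kb of each
  site, 300 non-sensitive genes are scattered uniformly. A genome-wide
  annotation is what nearest-TSS mapping operates on in practice; without
  background genes every distal control region would inherit a
  site-adjacent gene and the sensitive-gene bit would be artificially
  correlated for negatives.
* The generator does **not** emulate read-level noise, fragment-length
  effects, GC or repeat structure, caller-specific score distributions, or
  motif degeneracy (planted EREs are exact consensus instances). Passing
  tests on synthetic data therefore demonstrate the correctness and
  integration of the machinery under the assumed signal structure, not
  performance on real chromatin.

Problem sizes: the test-suite exercises 90-site bundles on 2×200 kb
genomes for speed and the acceptance analysis the full 600-site default on
2×1 Mb; both complete in seconds to a couple of minutes on one CPU.

## Numerical conventions and degenerate inputs

* Strict vs inclusive comparisons are fixed where ambiguity existed:
  occupancy mean must exceed 0.75 strictly; the NB posterior threshold is
  inclusive.
* All RNG-dependent steps (negative sampling, CV folds, k-means restarts,
  self-training draws, the generator) take explicit seeds and restore the
  caller's RNG state; identical seeds reproduce outputs byte-for-byte.
* Empty peak sets yield containment ratio `NaN` (flagged, never silently
  0); a classifier that calls nothing positive reports precision `NaN`.
* Malformed inputs fail with the offending line number (peak files), the
  offending peak id (feature building), or the stage name (pipeline).

## Known limitations

* With 18 positives the fitted parameters are coarse, and candidates whose
  evidence is split (e.g. no primary-TF overlap but a sensitive gene) sit
  near the 0.8 posterior threshold: their calls — hence recall — can flip
  with the particular draw of training negatives. This is a property of
  the method at this training scale, visible directly in the synthetic
  runs.
* Laplace smoothing with unequal class sizes slightly penalizes features
  that are constant-1 in both classes (the near-constant trigram block
  acts as a small uniform offset against the larger class); the effect is
  absorbed by the threshold but worth knowing when interpreting
  posteriors.
* The containment evaluation shares the ERE matrix with the generator's
  planted motif, which is exactly the intended circularity for validating
  machinery — and exactly why synthetic containment ratios say nothing
  about discovery power on real sequence.
* Only naïve Bayes and the k-means baseline are implemented; the
  classifier interface (binary matrix in, labels/posteriors out) is
  deliberately small so alternatives can be slotted in.
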