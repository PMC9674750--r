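---
title: "Methods: zero-shot language-to-vision mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zero-shot language-to-vision mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

How can a word whose referent we have never seen acquire a visual
representation? If word meanings are represented as distributional vectors
(estimated from how words are used in text) and visual experience as deep
convolutional network features (one vector per image), then the regularities
linking the two systems can be *learned* from the words for which both are
available, and *extrapolated* to the rest of the lexicon. `crossmap`
implements this pipeline end to end: the vector-space containers, the linear
mapping model, the neighborhood measures that predict where the mapping
should work well, the item-selection procedures used to test it on people,
a two-alternative forced-choice (2AFC) response simulator, and the
mixed-effects logistic analysis of such responses.

## The mapping model

The core object is a linear map from the language space to a reduced visual
space,

$$\hat v = M \cdot l, \qquad \hat v_j = \sum_i M_{ij}\, l_i,$$

with $M$ estimated by the least-squares criterion
$\arg\min_M \sum_k \lVert v_k - M\,l_k \rVert^2$ — equivalently a linear
regression with multiple predictors and multiple dependent variables. There
is deliberately no intercept (the model is the pure product above) and no
regularization by default; a ridge penalty (`lambda`) exists for
ill-conditioned inputs but defaults to 0. The solver is a rank-revealing
pseudoinverse with a relative singular-value cutoff of `1e-10`: it is
deterministic, robust to rank deficiency, and agrees with the
normal-equations solution to high precision on well-conditioned problems
(this equivalence is tested).

Two training regimes pair language vectors with visual targets:

* **prototype** — one pair per label; the target is the mean of the label's
  image vectors. With a full-scale inventory this gives one pair per
  grounded label (7,801 pairs at published scale).
* **exemplar** — `exemplar_k = 20` individual images per label are the
  targets (156,020 pairs at published scale).

Because the visual dimensionality controls the parameter count of $M$, the
visual side is reduced by truncated SVD before fitting, separately per
regime; the default output dimensionality is 300 (reducing 4,096-dimensional
CNN activations to 300 at published scale, so $M$ is $400 \times 300$ rather
than $400 \times 4096$).

Retrieval turns a predicted vector into an image. The *exemplar scheme*
returns the image whose reduced feature vector has the highest cosine to the
prediction. The *prototype scheme* first finds the most similar prototype,
then — within that label — the image most similar to the *prototype* (not to
the prediction); the second stage deliberately compares images against the
winning prototype. Cosine is used at every stage, including prototype
stage 2, where the metric was a genuinely open choice; we resolve it to
cosine for consistency with the rest of the geometry.

## Numerical conventions

Small, arbitrary-looking decisions are fixed once so results are
reproducible across platforms:

* **SVD sign ambiguity** — each singular vector is flipped so its
  largest-magnitude component is positive; geometry is unaffected but
  serialized models become byte-stable.
* **Neighbor ties** — equal cosines are broken by lexicographic label
  order; ranks use competition ranking (ties share the minimum rank).
* **Vectors are stored unnormalized** — normalization happens only inside
  the cosine. Whether language vectors should be length-normalized before
  mapping is unknown; we default to not normalizing.
* **Zero vectors** — cosine against a zero vector is an error, never a
  silent 0.
* **Median split** — words exactly at the median concreteness go to the
  abstract side.
* **Grid bins** — equal-width bins over each variable's observed range,
  left-closed, with the top bin closed (the maximum lands in the top bin).
* **word2vec text dialect** — the `"count dim"` header is mandatory;
  strictness beats guessing.

## Neighborhood measures

For a target word $w$ and the $n$ visually grounded training items $t_i$,
the package computes the count of training items among the word's 50 nearest
neighbors (the categorical far/near/maximum measure) and four continuous
measures: the nearest training item's similarity and rank, and the mean
training rank and mean training similarity
$\tfrac1n \sum_{i=1}^{n} \cos(w, t_i)$. Ranks are 1-based positions in the
full similarity ordering of the supplied lexicon, with the target excluded;
a target that is itself a training label is excluded from its own profile.

## Item selection

Two designs are implemented. The **factorial design** crosses a median split
on concreteness with the neighbor count: seeded random samples of
zero-neighbor words (*far*), the count-maximizing words (*abstract/near*,
*concrete/maximum*), and a *concrete/near* set whose summed neighbor count
matches the abstract/near total as closely as possible. The matching is an
exact 0/1-knapsack dynamic programme over achievable (size, sum) states
rather than per-item greedy matching: greedy selection can miss the best
achievable mean by a visible margin (we measured ~0.04 counts on a
23-of-30 configuration), while the DP is provably optimal for the summed
count, is deterministic, and is just as fast at these sizes.

The **continuous design** decorrelates concreteness from mean training
similarity by segmenting both observed ranges into 10 bins (100 cells) and
sampling up to 4 items per cell. One property of this sampler deserves
emphasis because it is easy to get wrong: over the *full* grid, the sparsely
populated extreme cells of two correlated Gaussian-like variables lie along
their joint major axis, so uniform-over-cells sampling *upweights* the most
correlated points and can increase the correlation. The decorrelation comes
from restricting sampling to a central rectangle window where off-axis cells
are populated. The window is exposed as a parameter (default: all cells, for
transparency); the package's own checks use a central 6×6 rectangle
(bins 3–8 on both axes), under which a pooled correlation of ~0.53 drops to
~0.2 or below in essentially every seeded replicate.

## The synthetic world

`generate_world()` produces every input the pipeline needs. Language vectors
live on the unit sphere (times a random positive length in [0.5, 1.5]): each
word's cosine alignment with a hub direction is driven by a latent Gaussian
$z = \rho\,c + \sqrt{1-\rho^2}\,\varepsilon$, where $c$ is the word's latent
concreteness, and the grounded training labels cluster tightly around the
hub (alignment 0.85–0.98). This makes more concrete words sit nearer (in
cosine) to the visually grounded part of the lexicon, with realized
correlation between concreteness ratings and mean training similarity close
to $\rho$ (the monotone transforms attenuate it by only a few percent, per
the Gaussian-copula arcsine identity). A hidden planted matrix $M^*$ maps
language to vision; each image of a grounded label is
$l\,M^* + \mathcal N(0, \texttt{noise\_sd}^2)$ per coordinate. $M^*$ has
unit-variance entries so visual features are $O(1)$ and `noise_sd` reads as
scatter relative to signal scale.

Defaults are desk-scale study conditions chosen once: 2,000 target words
plus 80 grounded labels (~4% grounded — matching the *sparsity* of grounded
labels in a full space, 7,801 of 300,000, which is what controls how often a
word has zero visual neighbors among its top 50), $\rho = 0.53$ (the
naturally observed concreteness/neighborhood correlation that the binned
sampler must then undo), 20 images per label, and `noise_sd = 0.5`
(moderate scatter: zero-shot retrieval succeeds well above chance but far
from perfectly).

What the generator deliberately does *not* emulate: the heavy-tailed
frequency-rank structure of real lexicons beyond a log-normal sketch,
polysemy and multi-label annotation noise, the anisotropy of trained
embedding spaces, and any nonlinearity in the true language-vision relation.
Passing tests therefore show that the machinery is correct and calibrated
under a linear world with a controllable confound — not that the linear
model suffices for real image features.

`simulate_trials()` generates 2AFC responses from a mixed-effects logistic
model: $P(\text{choose model image}) =
\mathrm{logistic}(\beta_0 + \beta_c x_c + \beta_n x_n + \beta_{cn} x_c x_n
+ u_{\text{participant}} + u_{\text{item}})$ with independent Gaussian
random intercepts, plus 10 catch trials per participant answered correctly
with probability $1 - \texttt{catch\_error\_rate}$.

## Analysis

Participants failing more than 2 of 10 catch trials are excluded entirely
(default threshold: 8 of 10 correct). The GLMM is fitted with
`lme4::glmer()` — the standard Laplace-approximation implementation for
crossed logistic random intercepts — behind a stable `fit_glmm()` surface
that records coefficients, random-intercept variances, the log-likelihood,
and the fixed-effect linear-predictor variance. Random slopes are out of
scope (they routinely fail to converge for this design). Categorical
designs use treatment coding with abstract/far first, so the intercept codes
that reference condition. Coefficient tests are Wald; model comparison is by
likelihood-ratio tests, with backward elimination in a fixed order
(interaction first, then each main effect, $\alpha = 0.05$). A boundary
(singular) fit — a random-intercept variance estimated at zero — is treated
as a legitimate estimate, not a convergence failure.

Marginal and conditional $R^2$ use the variance-partition closed form with
$\pi^2/3$ as the logistic residual variance:
$R^2_m = \sigma^2_f / (\sigma^2_f + \Sigma\tau^2 + \pi^2/3)$ and
$R^2_c = (\sigma^2_f + \Sigma\tau^2) / (\sigma^2_f + \Sigma\tau^2 +
\pi^2/3)$, with $\sigma^2_f$ the variance of the fixed-effect linear
predictor.

## Calibration and problem sizes

The test suite and the acceptance script size their simulations for a
single-core desk run, chosen once: the likelihood-ratio test's type-I error
is estimated from 200 null replicates at 16 participants × 24 items
(observed rate ~0.04–0.05 at $\alpha = 0.05$); recovery of a planted fixed
effect of 1.0 uses 20 replicates at 60 participants × 100 items (Wald
coverage ~95%); the qualitative replay of the two experimental outcome
patterns (intercept-only final model when only the intercept is real; both
main effects retained when both are real) uses 15 replicates at 30
participants × 48 items. Zero-shot retrieval uses a 200-word world with 60
grounded labels, holding out 25: at `noise_sd = 0` the fitted map equals the
planted one to machine precision and held-out retrieval is exact; accuracy
decays through ~0.5 at moderate noise toward chance (1/60) at high noise.

## Limitations

* The mapping is linear by design; the package does not implement nonlinear
  or deep mapping functions, nor image *generation* from predicted vectors.
* CNN inference, embedding training, and image decoding are out of scope:
  the package consumes feature tables and word2vec-format text spaces.
* Multi-label resolution uses the frequency column of whatever norms table
  is supplied; at published scale that role was played by corpus frequency.
* The Wald intervals and the $\chi^2$ reference for the LRT are asymptotic;
  at very small sizes (few items or participants) their calibration
  degrades, which is why the calibration checks fix their own sizes.
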