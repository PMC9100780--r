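---
title: "Active dendrites, sparse representations, and continual learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active dendrites, sparse representations, and continual learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adnet)
```

## The model

Standard point neurons compute a weighted sum followed by a fixed
non-linearity. Pyramidal neurons in cortex are different: most of their
synapses sit on distal dendritic segments that integrate input locally
and *modulate* the soma rather than drive it. `adnet` implements an
abstraction of this: the **Active Dendrites Neuron**.

Each hidden neuron receives two inputs. The feedforward input $x$
produces the usual pre-activation

$$\hat t = w^\top x + b,$$

while a *context vector* $c$ (a task descriptor) is seen by $S$
independent dendritic segments with weight vectors $u_1, \dots, u_S$
(no bias terms). The segment with the strongest response is selected
and gates the neuron through a sigmoid:

$$\hat y = (w^\top x + b)\;\sigma(u_{j^*}^\top c).$$

Two selection rules are available. Plain `max` gating takes
$j^* = \arg\max_j u_j^\top c$. The default, **absolute max gating**,
takes $j^* = \arg\max_j |u_j^\top c|$ and keeps the sign, so a segment
that has learned a strongly *negative* response to a context can turn
its neuron off for that context — with plain max a single positive
segment would always rescue the neuron. Since $\sigma \in [0,1]$,
gating only ever attenuates: $|\hat y| \le |\hat t|$.

Each hidden layer then applies **k-Winner-Take-All** (kWTA): the top
$k = \max(1, \mathrm{round}(\rho \cdot n))$ activations in the layer
are kept verbatim and all others are set to exactly zero, where $\rho$
is the activation density (e.g. $\rho = 0.05$ keeps 102 of 2048
units). Ties at the threshold are broken toward the lowest index so
the winner count is always exactly $k$ and runs are reproducible.
Feedforward weights additionally carry a fixed random binary mask
drawn once at initialization: a weight sparsity of $s$ zeroes
$\mathrm{round}(s\cdot n)$ entries *of every weight matrix, including
the output head*, permanently. Biases are never masked. This
convention reproduces the published non-zero parameter counts exactly
(`count_nonzero_params()` is tested against a brute-force census and
against the printed totals).

The combination matters for learning dynamics. During backpropagation
only neurons that survived kWTA have non-zero gradients, so losers'
feedforward rows are untouched by a step; and within a winning neuron
only the selected segment $j^*$ receives a dendritic update. Each step
therefore touches a small context-dependent subnetwork, which is what
protects earlier tasks from interference. These locality properties
are asserted bit-exactly in the test suite, and the full gradient is
checked against central finite differences.

Gradient flow conventions: winners pass gradients unchanged and losers
receive exactly zero (kWTA), the max/absolute-max selection routes the
dendritic gradient entirely to $j^*$ (subgradient of the max), and
masked weights receive zero gradient and are re-masked after every
Adam update. The loss is softmax cross-entropy over a single shared
head — one 10-unit output layer reused by all tasks, so no task
information leaks through the output structure.

## Context vectors

In the multi-task setting the context is simply a one-hot task ID
(`onehot_context()`). For continual learning the package implements
the prototype method, in three regimes:

* **Task-aware (`prototype_given`).** When task boundaries are known
  during training, task $\tau$'s context is its input-space prototype
  $p_\tau = \frac{1}{|V_\tau|}\sum_{x \in V_\tau} x$, computed over the
  task's full training set before its first epoch.
* **Task-free (`prototype_inferred`).** Without task information, each
  incoming batch $X$ is compared with every existing cluster $Y_j$ (in
  creation order) with an unpaired multivariate $t$-test. The batch
  joins the first cluster whose test does not reject, updating its
  prototype; if all reject, a new cluster is created with prototype
  $\mathrm{mean}(X)$. The inductive bias is that a batch contains one
  task only.
* **At test time** no task information is ever used in the prototype
  regimes: each test example is routed to its nearest prototype in
  Euclidean distance, $\arg\min_\tau \|x' - p_\tau\|_2$.

The batch test uses Hotelling's $t^2$,

$$t^2 = \frac{|X||Y_j|}{|X|+|Y_j|}
        (\bar x - \bar y)^\top \Sigma^{-1} (\bar x - \bar y),$$

with the pooled sample covariance $\Sigma$ inverted by Moore–Penrose
pseudo-inverse (so singular covariances in high dimension are
handled), transformed to

$$f = \frac{|X|+|Y_j|-d-1}{d\,(|X|+|Y_j|-2)}\,t^2
      \sim F(d,\; |X|+|Y_j|-d-1)$$

under the null. We reject equal means when the upper tail probability
of $f$ falls below `alpha`. For $d = 1$ the statistic reduces exactly
to the squared classical unpaired $t$ statistic, which the tests use
as an independent oracle across 50 seeded instances.

Two numerical choices deserve explanation:

* **`alpha` defaults to 0.001.** A sequential training run performs
  one test per batch per existing cluster — hundreds of tests. Each
  false rejection against the matching cluster risks splitting a task
  into two clusters, so the *family-wise* error across a run, roughly
  (number of batches) × alpha, is the quantity to control; 0.001 keeps
  it below ~10% for typical runs here. The threshold is configurable
  (`context_store(alpha = ...)`).
* **Streaming sufficient statistics.** Each cluster keeps its exact
  count, mean and centered scatter matrix updated by the pairwise
  (Chan-style) rule, plus a FIFO-capped set of raw exemplars (default
  2048). The cap bounds memory; prototypes and the test's pooled
  covariance always reflect *every* absorbed sample, so capping does
  not degrade the test. Whether one should instead recompute the
  covariance from stored raw samples is underdetermined; the streaming
  choice is exact for the statistics actually used.
* **Degenerate dimension.** The F transform requires
  $|X|+|Y_j| > d+1$; below that the test object carries `NA` and
  `assign_batch()` callers should pool more samples or reduce $d$
  (an optional diagonal-covariance mode exists for very high $d$).

## Task streams

`build_permuted_tasks()` constructs the standard permuted-image
benchmark: task 1 is the raw data (identity permutation) and every
later task applies one fixed random pixel permutation to all of its
train and test images, labels untouched. Images are scaled to
$[0, 1]$ and never mean-centered, because prototypes are input-space
means and must live in the input domain. MNIST IDX files are read
with `read_idx()` (big-endian header, unsigned-byte payload); the
package never downloads data. By default the full supplied train/test
split is used per task; `holdout_test = TRUE` instead carves the last
10,000 training images off as the test set, covering the other split
convention that appears in the literature.

Because MNIST itself cannot be bundled, `generate_synthetic_stream()`
produces a stream with the same statistical structure, used by the
tests and examples:

* 10 balanced classes; class $k$'s samples are
  $\mathcal N(\mu_0 + a\,\sigma e_k,\ \sigma^2 I)$ in $d = 64$
  dimensions with separation $a = 5$ and $\sigma = 1$, so pairwise
  class-mean distances are $\ge 5\sqrt{2}\,\sigma$ and a
  nearest-centroid oracle exceeds 99% accuracy — classes are separable
  by input mean, like digit images;
* $\mu_0$ is a fixed non-constant baseline, uniform per coordinate on
  $[-2\sigma, 2\sigma]$, playing the role of the structured mean image:
  permuting a non-constant vector moves it, so task prototypes are far
  apart and nearest-prototype routing is essentially perfect. The
  baseline is centered on zero deliberately: a large common-mean
  offset would make all task prototypes nearly collinear, which is an
  artifact real pixel data does not exhibit to that degree;
* tasks $\tau > 1$ permute the base samples exactly as permutedMNIST
  does; 2,000 train and 500 test samples per task, 5 tasks by default.

What the generator does *not* emulate: within-class manifold structure
(digits vary in style; Gaussians do not), anisotropic pixel
correlations, bounded pixel ranges, and the 12× larger scale. Passing
the bundled benchmark therefore demonstrates the *mechanisms* —
context-gated subnetworks, winner-only updates, prototype routing —
not the headline accuracies of full-scale experiments, which require
the real MNIST download and hours of training.

## The continual-learning harness

`train_continual()` visits tasks strictly in order; batches are drawn
from the current task only (shuffled within task), and finished tasks
are never revisited. The optimizer is Adam with standard defaults.
When the stream's task count matches a tuned row ($T \in \{2, 5, 10,
25, 50, 100\}$) the per-$T$ reference learning rates and epoch counts
are used; otherwise the $T = 10$ row applies. Dense ReLU baselines
(`matched_mlp_spec()` sizes one to at least the dendritic network's
non-zero parameter count) train through the identical loop, head,
loss, and optimizer.

For the bundled synthetic benchmark the tests use 20 epochs per task
at learning rate $3\times 10^{-3}$: the reference schedules assume
~235 batches of 256 per epoch, while the small stream has 8, so more
epochs are required for the same number of updates. Evaluation is
final-only by default, with `eval_history = TRUE` recording accuracy
on all seen tasks after each task — the matrix used to measure
forgetting.

On this benchmark (seeds 0–2), the dendritic network's final mean
accuracy exceeds the parameter-matched MLP's by roughly 35–40
percentage points; the MLP's task-1 accuracy collapses from ~0.99 to
near chance while the dendritic network retains most of it; and the
task-free clustering recovers exactly the 5 tasks with every batch
assigned to its own task's cluster. These are exactly the claims
asserted in `tests/testthat/test-acceptance.R`, which computes them
afresh on every run.

## Subnetwork analyses

`activation_frequency()` measures, per task and neuron, how often the
neuron survives kWTA on that task's test inputs (contexts chosen by
nearest prototype, as at evaluation). For a kWTA layer every sample
activates exactly $k$ units, so each row means exactly $k/n$ — a
useful exactness check. `subnetwork_overlap()` thresholds the
frequency matrix (default 0.1, a choice made here; the reference work
describes overlap only qualitatively) and reports pairwise Jaccard
indices; `dendrite_responses()` returns the raw $u_j^\top c$ tensor
before gating, signed, taking no position on why trained responses
skew positive in continual learning.

One observation specific to this benchmark: the overlap reduction
after training appears in the **first** hidden layer, which processes
the permuted pixels directly and must develop task-specific feature
detectors. The second hidden layer feeds the shared 10-unit head, and
because all tasks here have *identical* class structure (the same
base samples permuted), class-coding neurons are legitimately reused
across tasks there — its overlap can rise with training. Subnetworks
are "overlapping but distinct", and tasks as closely related as these
should share capacity; analyses therefore report the layer explicitly.

## Limitations

* Training is plain R matrix algebra (BLAS-bound); full-scale
  2×2048-unit, 100-task experiments are out of scope for the bundled
  examples, though the architecture and counts support them.
* The t-test calibration assumes roughly Gaussian batch means; heavily
  multimodal batches (violating the one-task-per-batch bias) are not
  detected.
* Synaptic-consolidation regularizers and reinforcement-learning
  training loops are intentionally out of scope; the `mt10-policy`
  preset exists for architecture and parameter-count work only.

## Reproducibility

Every stochastic component consumes seeds derived from a master seed
through a fixed counter scheme (`run-cl` writes them into a run
manifest), so two runs with one manifest produce identical reports —
asserted in the test suite. Analyses and training scale linearly in
batch size and layer width; the full test suite, including the
benchmark trainings, runs in a few minutes on one CPU.
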