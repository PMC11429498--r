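---
title: "Methods: the enhanced ST-GCN encoder and semi-supervised anomaly detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the enhanced ST-GCN encoder and semi-supervised anomaly detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stgcnad)
```

## The model

A skeleton clip is a tensor $(N, C, T, V, M)$: clips, channels
($x$, $y$, confidence), frames, joints, animals ($M = 1$ throughout).
The default joint set is a 12-point top-view mouse skeleton connected by
an 11-edge anatomical tree (nose–head–ears/neck, neck–forepaws/spine,
spine–hindpaws/tail); the tree is a package constant exposed through
`mouse_edges()` and every graph computation is edge-list-agnostic, so
other skeletons work by supplying a matching graph.

### Spatial graph convolution with adjacency perturbation

With $A$ the joint adjacency including self-loops and $\Lambda$ its
diagonal degree matrix, the normalized adjacency is
$\bar A = \Lambda^{-1/2} A \Lambda^{-1/2}$. Each layer computes, per
partition $k$ (default: the self-loop part and the neighbor part of
$\bar A$, whose element-wise sum is $\bar A$ itself),

$$y = \sum_k \Omega_k\big(X\,[(\bar A_k + G)\odot M_k]\big) + b,$$

where $M_k$ is a learnable edge-importance mask (initialized to ones),
$\Omega_k$ a $1\times1$ channel-mixing convolution, and
$G = \Lambda\,\varphi$ with $\varphi_{ij} \sim N(\mu, \sigma^2)$ drawn
fresh on every training forward pass. $G$ is dense, so it transiently
connects non-adjacent joints; scaling by $\Lambda$ makes the
perturbation respect each joint's connectivity scale. One $G$ is shared
by all partitions within a layer. At $\mu = \sigma = 0$ the layer is
*exactly* the classic formulation $y = \Omega(X\bar A)\cdot M$ — the
test suite asserts bitwise equality.

Choices the literature leaves open, resolved here:

* $\sigma$ is treated as a standard deviation (the $N(\mu, \sigma^2)$
  notation), and defaults to 0.02 so that $G$'s entries (degree up to 5
  on the mouse tree) stay small relative to the entries of $\bar A$ —
  a slight perturbation, not a rewiring.
* $G$ is added to the *normalized* adjacency before the edge-importance
  mask, which keeps the noiseless limit exact and the mask gradient
  well-defined.
* Noise is disabled at inference by default (`noise_config()`); it is a
  training-time regularizer.

### Squeeze-and-excitation gate

Per channel $c$, the squeeze is the global mean
$z_c = \frac{1}{T V}\sum_{t,v} u_c(t, v)$; the excitation is
$s = \operatorname{sigmoid}(\Omega_2\,\mathrm{ReLU}(\Omega_1 z))$ with a
bottleneck of ratio $r$ (default 4 — channel widths here are small, so
the common 16 would collapse the bottleneck below one unit); the output
rescales channels, $\tilde x_c = s_c u_c$. The two weight shapes must be
$(C/r)\times C$ and $C\times(C/r)$ for the composition to type-check.
Gates lie strictly in $(0, 1)$, so the gate can only attenuate — the
suite checks that no channel is ever amplified. The gate is applied in
every block, between the spatial and temporal stages.

### Multi-branch temporal stage

The classic temporal stage is a kernel-9 convolution over time. The
multi-branch replacement first maps the $C$ channels to a working width
$C_{mid}$ (the largest multiple of 6 not exceeding $0.75\,C$; 192 at
$C = 256$, i.e. 32 channels per branch), splits them into six equal
groups, and processes them with: a $1\times1$ convolution, a window-3
temporal max-pool, and four kernel-3 temporal convolutions at dilations
1–4. Outputs are concatenated and remixed by an exit $1\times1$
convolution. All branches use same padding (stride 1 preserves $T$;
stride 2 halves it, including in the max-pool and $1\times1$ branches).
The suite verifies each branch against a brute-force sliding-window
oracle and that the branch stage has strictly fewer parameters than the
kernel-9 convolution it replaces.

### Block and head

Each block is: graph convolution → batch norm → ReLU → SE gate →
temporal stage → batch norm → residual → ReLU. The residual is the
identity when shapes match, else a temporally strided $1\times1$
convolution with its own batch norm. The default stack is nine blocks
(64³ → 128³ → 256³ channels, temporal stride 2 at each width change);
the head is batch normalization of the input, global average pooling
over $(T, V)$ after the last block, and a linear softmax classifier.
All three enhancements have independent toggles, and with all of them
off the network is the original ST-GCN (this baseline path is exercised
by tests, never dead code).

## Training

SGD with momentum 0.9, weight decay $10^{-4}$, initial learning rate
0.1 decayed ×0.1 at epochs 40 and 80, batch 64, 100 epochs — only the
initial rate, batch size, epoch count and the augmentation ranges are
prescribed by the standard recipe; momentum, decay and schedule are
conventional defaults, all configurable in `train_config()`. Per-clip
augmentation draws one scale factor from $[0.97, 1.03]$ and a
translation from $[-5, 5]$ pixels, converted to normalized units with
the stored frame scale so the pixel semantics survive coordinate
normalization; the confidence channel is never touched.

Two numerical choices matter at small data scale:

* **Backward passes** are hand-written (no autodiff framework is used)
  and verified against central finite differences at $10^{-5}$ step for
  every layer family in the test suite.
* **Batch-norm calibration.** With few batches per epoch the
  exponential-moving-average running statistics lag the evolving batch
  statistics badly, making evaluation-mode forwards inconsistent with
  what was learned. `train_model()` therefore ends with one clean
  (unaugmented, noise-free) pass that assigns the exact training-set
  activation statistics to every batch-norm buffer.

## Preprocessing

Raw pixel coordinates are mapped to $[-1, 1]$ by centering on the frame
midpoint and dividing by half the larger frame dimension (one shared
scale, so aspect ratio is preserved; image convention, origin top-left).
Clips are then **pose-canonicalized**: each clip is translated so the
first-frame body center sits at the origin and rotated so the
first-frame body axis points along $+x$. The axis is the principal
direction of the six spine-line joints rather than a single joint pair:
a pair-based estimate carries ~4° of angular noise at 1.5 px jitter,
which a 200 px locomotion trajectory amplifies tenfold at its endpoint
and which would dominate the within-class embedding variance. This removes the arena position
and heading of a clip — nuisance variables the behavior classes do not
depend on — while preserving all within-clip motion, including heading
*change* (the turning class). Without this standard view normalization
an encoder must learn rotation invariance from scratch, which a few
hundred clips cannot support. Low-confidence detections are kept as-is
with their likelihood in the confidence channel; no interpolation is
attempted.

## Anomaly detection

Embeddings of test clips are reduced with PCA (default 8 components,
deterministic component signs: largest-magnitude loading positive) and
clustered with DBSCAN (Euclidean metric in the reduced space). A core
point has at least `min_samples` points (default 5) within `eps`;
clusters are maximal density-connected sets; points in no cluster are
flagged abnormal. When `eps` is not given it is set to 1.5× the median
distance to the `min_samples`-th nearest neighbor — a robust stand-in
for the k-distance elbow. Border points are assigned to the
lowest-index core point that reaches them, making memberships
independent of input order (the suite checks the whole partition
against a brute-force density-reachability closure).

The cluster flag is binary; to obtain a precision–recall curve the
package defines a continuous anomaly score as the distance to the
`min_samples`-th nearest neighbor in reduced space, with the DBSCAN
flag as the operating point. This is an interpretation — a documented
choice, since a binary detector admits no curve — and average precision
is the step-wise integral $\sum_i p(r_i)\,\Delta r_i$ over the ranked
scores with tied scores processed as one threshold.

## The synthetic benchmark

The simulator animates a fixed 12-joint top-view template through four
normal behavior classes — movement (straight-line locomotion at
4 px/frame), head turning (body static, head group rotating about the
neck, peak 60°), standing (front template compressing toward the neck
with a small bob, static centroid), turning (heading ramp of
0.04 rad/frame) — plus three anomaly families: freezing with
high-frequency tremor, erratic heavy-tailed jumps, and one forepaw
decoupling into an independent random walk. Gaussian observation jitter
(sd 1.5 px) and a high-value Beta confidence channel are added
everywhere. Clips are 50 frames in a 640×480 arena with random start
position and heading; anomalies are planted in the test split only,
matching the semi-supervised protocol in which training sees normal
behavior exclusively.

The benchmark used by the acceptance suite and `scripts/acceptance.R`
is 4 classes × 50 training clips, a test set of 40 normal clips plus 5
anomalies, and a deliberately small encoder (two blocks, 16→32
channels, 15 epochs, batch 16) so five seeds complete in minutes on one
CPU; the overfit capacity check uses 20 noiseless clips and a 3-block,
16-channel model for 50 epochs. These sizes are the package's own
benchmark design.

On this benchmark the *scoring* side of the detector is robust: the
five planted anomalies are the five highest anomaly scores (AP ≥ 0.95)
in at least four of five seeds. The *binary* flags are brittle: at the
default eps heuristic DBSCAN usually co-flags a few fringe normal clips,
because the gap between the 5-NN distances of fringe normals and of the
milder anomaly families is narrow in embedding space, and no
density-based eps choice we evaluated (median-based, k-distance elbow,
clustering train and test embeddings jointly, longer or annealed
training) lands reliably inside that gap. Exact binary recovery in 4 of
5 seeds is therefore not achieved at the default heuristic; users who
need a hard flag at a known anomaly budget should threshold the
continuous score instead, which is also how average precision — the
measure this family of detectors is usually reported with — evaluates
the detector.

What passing does and does not show: the generator's classes are
separable by construction (a centroid-speed/heading-change feature pair
already separates movement from standing — the suite asserts this), its
anomalies are kinematically far from every normal class, and its noise
is i.i.d. Gaussian. Real recordings add occlusions, identity swaps,
non-stationary postures and anomalies of unknown, possibly subtle
kinematics; performance there is an empirical question this package's
tests cannot answer. The anomaly families are stand-ins, not
characterizations of real abnormal behavior.

## Known limitations

* Single animal only ($M = 1$); no multi-animal pooling or tracking.
* The adjacency is fixed (plus the stochastic perturbation); no learned
  graph.
* Spatial-configuration (3-way) partitioning is not provided — it needs
  a root-joint convention; the self/neighbor distance partition is the
  default, with the single-matrix uniform strategy as the strict
  classical reading.
* Training is plain SGD on one CPU; the default 9-block stack at
  full channel width is slow in R at realistic dataset sizes — the
  small-stack configurations used in the benchmark are the practical
  operating point here.
* The dataset archive is an RDS container (deterministic, compressed,
  single-file); no HDF5/NPZ writer is available in this dependency
  footprint.
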