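---
title: "Colorimetric sensor analysis of yeast culture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colorimetric sensor analysis of yeast culture: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

During a *Saccharomyces cerevisiae* batch culture, the volatile compounds
above the medium change with the growth stage.  A colorimetric
(olfactory-visualization) sensor — a 4x3 grid of eleven porphyrin dyes and
one pH indicator printed on a silica plate — converts that odor profile into
a color change that can be photographed.  The analysis task is regression:
predict the culture's optical density (OD600, the standard proxy for cell
concentration) from the sensor's color response, and decide which of the
dye/channel combinations are worth manufacturing, since porphyrins are
expensive.

The pipeline in this package has four stages:

1. **Feature extraction.**  Each sample contributes a pre-reaction and a
   post-reaction image of the array.  After preprocessing (channel-max
   grayscale, 3x3 median filter, Otsu threshold, morphological opening and
   closing), the twelve spot centers are taken as connected-component
   centroids and a circular region of interest of radius 15 px is placed on
   each.  The signed difference of ROI mean gray values, after minus before,
   per channel, gives 36 color components (ΔR, ΔG, ΔB for each dye).
2. **Regression.**  A single-hidden-layer back-propagation neural network
   (BPNN) maps selected components to OD.
3. **Feature selection.**  Ant colony optimization (ACO) searches over
   component subsets, scoring each subset by a weighted mean absolute
   deviation of the BPNN's predictions (the *BestCost* objective).
4. **Frequency protocol.**  Because the search is stochastic, it is
   repeated (50 times at full scale) and components are ranked by how often
   they appear in the per-run best subset; thresholds on that count define
   nested candidate sensor sets ("cases") that are then refitted and
   compared.

# The regression model

The network has inputs $x_i$ (selected color components), one sigmoid
hidden layer and a linear output:

$$H_j = \sigma\!\Big(\sum_i w_{ij} x_i - \theta_j\Big), \qquad
\hat y = \sum_j H_j v_j - b, \qquad \sigma(z) = \frac{1}{1+e^{-z}}.$$

The loss per epoch is $E = \frac{1}{N}\sum_k \tfrac12 (\hat y_k - y_k)^2$,
minimized by gradient descent with a classical momentum term.  Defaults
(`bpnn_control()`): 10 hidden neurons, learning rate 0.1, momentum 0.1,
initial weights uniform on $[-0.3, 0.3]$ with zero thresholds, at most 1000
epochs, stopping early when $E \le 0.01$.

Numerical choices that needed deciding:

* **Output activation.**  The output node is linear.  OD values reach 9.1;
  a sigmoid output could not represent them without target rescaling, and
  the output-layer equation is stated without an activation.
* **Scaling.**  Inputs *and* target are min–max scaled to $[0,1]$ using
  calibration-set ranges.  Raw components span hundreds of gray levels and
  would saturate the hidden sigmoids immediately at learning rate 0.1.  The
  error goal 0.01 applies to $E$ on the scaled target, which is the
  convention of the MATLAB-style tooling this procedure descends from; on
  the raw OD scale an $E$ of 0.01 (RMSE 0.14) is unreachable for this data.
  Predictions are mapped back to OD units.
* **Update mode.**  Default is per-sample ("online") updates in data order,
  the classical reading of back-propagation; full-batch updates are
  available (`update = "batch"`).  At the fixed learning rate 0.1,
  full-batch descent is an order of magnitude too slow to fit even a
  noiseless linear target within 1000 epochs, while online updates reach
  $R^2 > 0.99$; we therefore treat online as the operative variant.  The
  batch gradient is retained because it is the analytically checkable
  object: tests verify it against central finite differences and verify
  that one batch epoch equals one explicit gradient/momentum step.
* The inner loop is compiled (Rcpp); the wrapper selection trains thousands
  of networks.

# The selection objective and search

For a candidate subset, a BPNN is trained on the calibration set restricted
to those components and the objective is

$$\mathrm{BestCost} \;=\; 0.75 \cdot \overline{|y - \hat y|}_{\mathrm{cal}}
\;+\; 0.25 \cdot \overline{|y - \hat y|}_{\mathrm{val}},$$

the weighted mean absolute deviation over the calibration and validation
sets.  Note that the validation set participates in the objective; this
leaks validation information into selection.  We implement it as stated —
it is the protocol being studied — and note that the validation metrics of
the final refitted cases are therefore mildly optimistic.

The ACO encoding treats each of the 36 components as a node with two
states, *include* and *exclude*; an ant chooses a state per component,
giving a subset mask.  State probabilities follow the standard rule
$p_j \propto \tau_j^{\alpha} \eta_j^{\beta}$ with pheromone $\tau$ and
visibility $\eta$.  Defaults (`aco_control()`): 20 ants, 100 iterations,
$\tau_0 = 1$, $\alpha = \beta = 1$, evaporation $\rho = 0.05$.  Per
iteration every ant deposits $Q/L$ on each state it chose, with $L$ its
BestCost and $Q = 1$ (ant-cycle model: cheaper solutions deposit more;
costs below $10^{-12}$ are clamped).  The best-so-far solution is tracked
elitistically; the convergence iteration is the last improvement larger
than $10^{-6}$.

Further decisions where the procedure was underdetermined:

* **Visibility.**  The procedure states the visibility exponent
  $\beta = 1$ without defining $\eta$.  A uniform $\eta$ would make
  $\beta$ inert, so the default uses the standard wrapper-selection
  heuristic: the include-state visibility of a component is its absolute
  Pearson correlation with OD on the calibration set (exclude-state
  visibility is the complement).  This gives the colony a sensible prior —
  constructions start near plausibly informative subsets instead of
  coin-flip masks of ~18 components — and is what makes the reduced-budget
  searches (10 ants, 30 iterations) converge to parsimonious subsets.  A
  `uniform` mode is available for ablation.
* **Evaporation.**  The conventional update keeps $(1-\rho)\tau$.  A
  `literal` mode implements the update with $\rho$ multiplying the old
  pheromone (i.e. keeping $\rho\tau$, a 95% loss per iteration), which is
  the printed form of the rule; it is not the default because it contradicts
  the stated meaning of an evaporation *coefficient* of 0.05.
* **Minimum subset size 1**, enforced by forcing in the highest
  include-probability component.
* Pheromone is floored at $10^{-6}$; within a run, identical masks are
  evaluated once (the per-subset fit is seeded from the run seed, so the
  cache is exact, and cache hits do not consume random numbers).
* Repeated runs use seeds `base_seed + 1, ..., base_seed + n_runs`;
  frequency ties in `select_by_frequency()` break by count then component
  index.

# What the synthetic study emulates

No sensor images or OD tables ship with laboratory studies of this design,
so `generate_dataset()` reproduces the *statistical shape* of one:

* **Design**: 8 culture batches, 19 sampling times (0–72 h every 4 h), 152
  samples; the first 6 batches form the calibration set (114 samples), the
  last 2 the validation set (38).
* **Growth**: logistic OD curves,
  $od(t) = b + K/(1 + e^{-r(t - t_0)})$, defaults $K = 9.119$, $r = 0.25$
  /h, $t_0 = 36$ h, $b = 0.001$, so a batch spans OD 0.001–9.12.
  Batch-to-batch variability enters as log-normal jitter on $K$ (CV 3%)
  and $r$ (CV 8%) and Gaussian jitter on $t_0$ (SD 1.5 h).
* **OD measurement**: absorbance reads are linear only in 0.1–0.65, so
  dense samples are diluted by the smallest factor from the 1-2-5 ladder
  that brings the read at or below 0.65; the reported OD is the dilution
  factor times the mean of three noisy reads (read SD 0.005).  Samples
  below the window are read undiluted — no dilution can raise a reading.
* **Sensor response**: component $c$ responds as
  $\Delta_c = \beta_c \, od/(od + K_c) + \varepsilon$, a saturating
  monotone link with Gaussian read noise (SD 2 gray levels).  The default
  array has two strongly informative components, FTPPFeCl:B
  ($\beta = -90$) and MTPPTE:B ($\beta = +81$), two weak ones, TPPMnCl:B
  ($-4$) and BTB:B ($+3.5$), all with half-saturation at OD 4, and 32
  noise-only components.
* **Batch drift**: every component additionally receives a per-batch
  offset, $N(0, 4)$ gray levels, constant within a batch.  This is the
  footprint of dye cross-sensitivity to uncontrolled conditions (ambient
  temperature and humidity, plate-to-plate coating variation) that real
  arrays exhibit between experiments.  It matters for the method: without
  any cross-batch structure in the non-informative components, adding them
  to a subset can only ever improve a 0.75-train-weighted objective (extra
  inputs are free capacity), and wrapper selection would have nothing to
  penalize.  With drift, a non-informative component presents the network
  with values in held-out batches that fall outside its calibration range,
  degrading validation deviations — which is exactly the mechanism by which
  the frequency protocol separates real sensors from redundant ones.
* **Images**: spot discs (radius 20 px, centers on a 60 px grid) are
  painted with a fixed per-dye palette plus small per-sample jitter; the
  after image adds the rounded component responses.  Extraction recovers an
  injected vector to within ±1 gray level, and spot centroids to within
  1 px, which the tests verify round-trip.

What the generator does **not** emulate: illumination gradients, camera
noise and optics, within-spot texture, temporal sensor aging, nonlinear
dye interactions, or any mechanistic VOC chemistry.  Passing tests
demonstrate that the algorithms are implemented correctly and that the
protocol recovers planted structure under realistic noise — not that a
physical array of these twelve dyes would achieve any particular accuracy.

# Problem sizes used in tests and the acceptance script

Full-scale defaults (20 ants x 100 iterations x 50 runs) are the study
settings, but the package's own checks run the search at a reduced scale
chosen to keep a complete verification under half an hour on one core: 10
ants, 30 iterations and 10 repeated runs per experiment for recovery
checks (with per-subset fits capped at 500 epochs), 20 ants x 50
iterations x 100 seeded runs for the 4-component exhaustive-oracle
comparison, and a 4-batch / 5-run configuration for the end-to-end
determinism checks; the full suite completes in about two minutes.  The selection behaviour at these sizes is
qualitatively the same as at full scale; only the frequency resolution
(counts out of 10 rather than 50) is coarser.

# Known limitations

* The validation-in-objective leakage discussed above is faithful to the
  protocol but statistically impure; `evaluate_subset()` exposes the data
  split, so a nested split can be substituted by the caller.
* "RMSECV" here is the calibration-set RMSE of the single fitted model for
  the fixed batch-wise split; no k-fold rotation is performed.
* With the saturating response, OD resolution above ~OD 6 is intrinsically
  poor (the response flattens), which bounds attainable RMSEP on dense
  cultures regardless of the model.
* The per-sample update order is the data order; shuffling between epochs
  would break exact seeded reproducibility and is not done.
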