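---
title: "Star-graph trace invariants of Raman spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Star-graph trace invariants of Raman spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanSG)
```

## The problem

Carbon nanotubes (CNTs) interact with mitochondria, and a central toxicological
question is whether a given CNT preparation perturbs mitochondrial respiration.
High-resolution respirometry measures the mitochondrial oxygen mass flux
J~m~(O~2~) (pmol/s) as the negative time derivative of the chamber oxygen
concentration, through the canonical respiratory states: basal respiration
(V2), transient ADP-stimulated respiration (V3, visible as decaying pulses
after each ADP titration) and uncoupled respiration (V4) after addition of an
uncoupler such as FCCP.

`ramanSG` implements a nano-QSTR approach to predicting that flux from the
CNTs' Raman spectra: the spectrum is converted into a *star graph* (SG), the
graph is summarized by matrix trace invariants (spectral moments), and those
invariants enter a perturbation-theory machine-learning (PTML) regression
together with the experimental conditions of each assay.

## The star-graph transform

### From spectrum to sequence

The Raman-shift axis from 0 to 1800 cm^-1^ is split into 18 bins of
100 cm^-1^; each retained point of the spectrum contributes the letter of its
bin ("a" for \[0, 100), ..., "r" for the last bin, which is closed at
1800 cm^-1^). Eighteen bins is a hard cap: the alphabet never extends past
"r", and a finer `bin_width` than the range allows is refused. For CNT spectra
this window covers the physically meaningful bands: the D band near
1350 cm^-1^ (letter "n"), reporting defects and covalent functionalization,
and the G band near 1580 cm^-1^ (letter "p"), the graphitic tangential mode.

The order in which points enter the sequence is a genuine design choice: an
encoding along ascending shift would make the sequence independent of the
intensities, so by default points are ordered by *descending intensity* (ties
broken by ascending shift), which makes the descriptor sensitive to the shape
of the spectrum — the most intense band owns the first branch. Both modes are
provided (`ordering = "intensity_desc"` or `"shift_asc"`), together with an
intensity `threshold`, a `top_n` peak count, and an alternative mode that bins
the intensity axis (`axis = "intensity"`). None of these modes is asserted to
be the historical choice of any particular study; they are labelled options.

### From sequence to graph, and the two adjacency matrices

Node 0 is the center. Sequence position *i* becomes node *i*, attached to the
branch of its character: the first occurrence of a character links to the
center, each later occurrence links to the previous node of the same
character. The resulting plain graph is always a tree (one new edge per
node), encoded in the adjacency matrix **A**. The *embedded* matrix **A**~e~
adds an edge between every pair of consecutive sequence positions
("recurrence information"), so its edge set is a superset of the plain one and
the graph generally contains cycles.

### Trace invariants

The descriptors are Tr~k~ = trace(**A**^k^) and Tre~k~ = trace(**A**~e~^k^)
for k = 0–5: the numbers of closed walks of length k, also known as the
spectral moments of the adjacency matrix. Useful identities, all enforced as
tests: Tr~0~ is the node count, Tr~1~ = 0 (no self-loops), Tr~2~ twice the
edge count, Tr~3~ = 0 for the plain tree (no triangles), and Tre~2~ ≥ Tr~2~.

Traces are computed by repeated sparse matrix multiplication. Closed-walk
counts are integers, and for the graph sizes this package meets (up to a few
thousand nodes, k ≤ 5) they stay far below 2^53^, so double arithmetic is
exact; the implementation asserts integrality and rounds. The test suite
cross-checks 100 random sequences against an independent dense brute-force
matrix-power routine, requiring exact equality.

## The PTML model

Each respirometry case (one flux measurement at one time under one condition
combination) is described by Eq.-(1)-style features:

$$J_m(O_2)_{pred} = a_0 + a_1\,J_m(O_2)_{expected} + a_2\,f(t)
 + \sum_{k=0}^{5} b_k\,\Delta Tr_k(c_j) + \sum_{k=0}^{5} c_k\,\Delta Tre_k(c_j)$$

* `Jm_expected` is the mean measured flux over all cases sharing the case's
  combination of experimental conditions (replicate flag, CNT type,
  functionalization, solvent), averaged over time. The grouping is
  configurable because "subsets of experimental conditions" admits several
  readings; the full four-condition combination is the default.
* `f(t)` is the identity by default — the assay time is itself an input
  feature — with a hook for other monotone transforms.
* The moving-average (MA) operators ΔTr~k~(c~j~) = Tr~k~ − ⟨Tr~k~(c~j~)⟩
  measure the deviation of a CNT's invariant from the mean invariant over all
  cases sharing one experimental condition level; this is the
  perturbation-theory ingredient. By default the reference means average over
  cases (time-expanded, so heavily measured CNTs weigh more); averaging over
  distinct CNT spectra is available (`average_over = "cnts"`).
* Control cases (blank solution, CNT id "0") carry all-zero invariants so
  their deviations are defined; dropping them instead is a documented option.

The full design matrix has 2 + 2·6·4 = 50 feature columns. The named subset
`"paper8"` keeps the expected flux, time and six MA operators (one or two per
condition) — the shape of the final feature set that survives a 0.9
correlation filter on the full study data. Note that odd plain moments
(ΔTr~1~, ΔTr~3~, ΔTr~5~) are structurally zero for trees and are dropped by
the zero-variance check during normalization rather than special-cased.

## Regression pipeline

Following the workflow of RRegrs-style pipelines, normalization (z-score per
feature over the whole dataset, target untouched) and the Pearson correlation
filter (cutoff 0.9, caret's `findCorrelation` heuristic: the member of the
worst pair with the larger mean absolute correlation is removed) are applied
*before* splitting. This is the fidelity-preserving default; fitting the
scaler on the training part only is available via `apply_scaler()` for
leakage-safe workflows.

Data are split 10 times into random 75/25 train/test partitions. Three
regressors are provided: ordinary least squares (LM), a single-hidden-layer
neural network (logistic hidden units, linear output, L2 weight decay, fixed
500-iteration cap, no early stopping; default grid sizes 1–400 and decays
0–0.2) and a random forest (mtry = ⌊p/3⌋, tree grid 5–1500). Hyperparameters
are chosen by repeated 10-fold cross-validation on the training part; a
single-row grid skips CV. R² defaults to the squared Pearson correlation
between observed and predicted (the RRegrs convention); `rsq = "ssr"` gives
1 − SSE/SST.

Model selection maximizes test R², ties broken by minimal test RMSE; among
random forests whose test RMSE is within 1% of the best, the fewest trees
wins (the 1% band is an implementation choice — the parsimony rule itself is
the method's stated preference for the lowest tree count with best
statistics).

The RROC curve plots total over-estimation OVER(s) = Σ max(e~i~, 0) against
total under-estimation UNDER(s) = Σ min(e~i~, 0) of the residuals shifted by
a constant s — the regression analogue of sweeping a classification
threshold. The default shift grid spans ± the residual range in 201 steps
(another implementation choice; any grid can be passed).

## The synthetic study generator

The real study's deposited dataset (32,940 cases: 9 CNTs × 2 replicates ×
~1830 one-second time points) is not bundled, so the generator produces a
structurally matching stand-in with known ground truth:

* **Spectra.** Sums of Lorentzian bands — the standard Raman line shape — on
  a 5 cm^-1^ grid with additive Gaussian noise clipped at zero: a G band at
  1580 cm^-1^, a D band at 1350 cm^-1^ whose amplitude is larger for
  functionalized (COOH/OH) CNTs, a radial-breathing mode below 300 cm^-1^ for
  single/double-walled types, and small jitter so same-class CNTs differ.
* **Flux profiles.** Basal (V2) flux plus exponentially decaying ADP pulse
  transients (V3) and a multiplicative uncoupler step inside a 750–1250 s
  window (V4). These echo the qualitative regimes of real traces without any
  claim of quantitative fidelity.
* **The generative link.** The default `flux_model = "ptml"` draws one basal
  profile per experimental group, defines the group's *true* expected flux as
  its time average, and sets the case flux to the linear PTML combination of
  that truth, time and the MA operators, plus iid Gaussian noise with sd equal
  to `noise_frac` (default 0.1) of the signal sd. Defining the true expected
  flux this way breaks the circularity that would arise from defining it as
  the group mean of the very flux being generated, while the pipeline's own
  `expected_flux()` remains a consistent estimator of (an affine transform
  of) it. Consequently, coefficient-recovery checks regress the flux on the
  generator's returned truth design — the oracle is OLS consistency against
  the generative truth. `flux_model = "respirometry"` instead uses the
  time-resolved profile itself (pulses + uncoupler step, strongly nonlinear
  in t) plus a small linear MA term; it is the nonlinear link on which
  flexible learners (RF) should and do beat the linear model, qualitatively
  mirroring the LM < NN < RF ordering seen on real data.
* **Default generative coefficients** put one or two MA terms on each
  experimental condition across a spread of moment orders, scaled so each
  term contributes on the order of 1 pmol/s against basal fluxes of
  30–60 pmol/s. Spectra are encoded with an intensity threshold of 1 a.u.
  (so sequence lengths, hence Tr~0~/Tr~2~, vary across CNTs) rather than a
  fixed peak count, keeping every default-truth column non-degenerate.
* The paper-scale default is `n_times = 1830` (9 × 2 × 1830 = 32,940 cases).
  Tests and the acceptance script use `n_times = 111` (1998 cases — the
  nearest multiple of the 18 series to two thousand) and 10 splits, sizes at
  which every check runs in seconds while the OLS standard errors are still
  small enough for 3-standard-error coefficient recovery to be a meaningful
  bound.

### What the generator does not emulate

Real CNT Raman spectra carry baseline drift, cosmic-ray spikes and
instrument-response structure that the Lorentzian-plus-noise model omits
(spectral preprocessing is explicitly out of scope); real flux noise is
autocorrelated within a run, whereas the generator's is iid; and the
generative link is exactly the model family being fitted. Passing tests
therefore demonstrate the correctness and internal consistency of the
transform, the feature construction and the pipeline — not the predictive
validity of the descriptors on laboratory data.

## Numerical and degenerate-input choices

* Duplicate Raman shifts are averaged, not rejected — deterministic and
  order-independent; negative intensities are clipped to 0 with a warning.
* Points outside the binned range are discarded with a warning; an encoding
  with no retained point is an error ("empty spectral sequence").
* Equal-intensity ties in the ordering are broken by ascending shift, so
  permuting input rows never changes the invariants.
* The trace routine asserts integrality (tolerance 10^-6^) before rounding.
* Zero-variance feature columns are dropped with a warning before scaling;
  an all-constant table is an error.
* `make_splits` uses `round(0.75 n)` training cases; splits are drawn
  independently per index from one seeded stream.
* Every stochastic fit records the derived sub-seed it ran under in its
  results row.

## Known limitations

* The exact point-to-sequence rule of the original SG tooling is not
  published for spectra; the package's two orderings are explicit options,
  and numeric descriptor values depend on that choice.
* The NN iteration cap (500) and the RF mtry convention (⌊p/3⌋) are stated
  defaults, configurable, but other historical defaults may differ.
* With the full four-condition grouping, `Jm_expected` absorbs all
  group-constant structure of the target, so MA features mostly add value
  for *extrapolation to new CNTs*, which a random split does not measure;
  this is a property of the PTML design itself, discussed above for the
  generator.
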