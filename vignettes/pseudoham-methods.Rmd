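---
title: "Methods: pseudo-Hamiltonian eigenvalue models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pseudo-Hamiltonian eigenvalue models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoham)
```

This vignette documents what the package computes, every modelling
assumption, and the numerical choices behind them. Units are fixed at all
module boundaries: coordinates in Ångström, energies in eV.

## 1. The model

### Inputs and targets

A molecule is an `atomic_structure`: atomic numbers `z_a` and Cartesian
positions `r_a` (open boundary conditions, no periodicity). The targets are
an `eigen_record`: up to `n_max` ascending energies inside a fixed energy
window, a validity mask (padding slots trail the valid ones and carry 0,
never read), an occupation count, and a level-of-theory tag.

### Encoder

The encoder is a continuous-filter message-passing network of the SchNet
family, built only from interatomic distances, so every prediction is
invariant to rigid motions by construction and permutation-equivariant at
the feature level.

* **Element embedding.** Each atom starts as a learned `F`-vector indexed by
  `z_a` (table size `z_max`, default 10 — H through Ne).
* **Distance featurization.** Each pair distance `d` within the cutoff
  (default 5 Å) is expanded in `K` Gaussians
  `exp(-γ (d − μ_k)²)` on evenly spaced centers `μ_k ∈ [0, cutoff]`; the
  default `γ` places the width at the center spacing. Messages are damped by
  the smooth cosine cutoff `0.5 (cos(π d / cutoff) + 1)`, which vanishes
  with zero slope at the cutoff, so features vary continuously as an atom
  crosses the graph boundary.
* **Interaction blocks** (default `T = 3`, benchmark workflows use 2). Each
  block computes a filter `W(d)` from the radial basis through a two-layer
  network, forms messages `(x W_in)[neighbor] ∘ W(d)`, scatter-sums them
  onto the receiving atom, passes the aggregate through atom-wise layers,
  and adds the result to the input features (residual update). The
  nonlinearity everywhere is the shifted softplus
  `ssp(x) = ln(0.5 eˣ + 0.5)` (smooth, `ssp(0) = 0`, derivative
  `sigmoid(x)`).

Defaults (`F = 128`, `T = 3`, `K = 25`, cutoff 5 Å) are sized for CPU work;
the original work's exact layer sizes are not public, so the architecture
family is fixed and the sizes are package choices.

### The three heads

All heads share the same pattern — two atom-wise layers on the final
features, **sum-pooling over atoms**, plus an output bias — and differ only
in output dimension:

* **single** (`1S`): one scalar; a family of `n_max` independent single
  models covers a spectrum.
* **multistate** (`MS`): an `n_max`-vector regressed directly against the
  sorted targets.
* **hamiltonian**: `n_max(n_max+1)/2` outputs interpreted as the upper
  triangle (diagonal included) of a symmetric matrix `H`. The triangle is
  mirrored, which makes `H_ij == H_ji` *bitwise* — symmetry by construction
  rather than by symmetrization of a full matrix (fewer parameters, exact
  symmetry; the source text is silent on which variant was used). The
  prediction is `eigen(H)`'s ascending eigenvalues. No ordering constraint
  is imposed on `H` itself; order comes solely from sorting after
  diagonalization.

`n_max` is a user choice, independent of molecule size: the matrix dimension
"scales with the number of eigenvalues defined by the user".

Parameter budgets are matched across heads for fair comparison: for the
hamiltonian head, `pseudoham()` picks the hidden width whose total count is
closest to the multistate head's on the same encoder (within 1 %).

The output bias is initialized to the mask-weighted mean training spectrum
(placed on the matrix diagonal for the hamiltonian head, so the initial
eigenvalues are approximately that spectrum). This centers the energy scale
and stabilizes early training; slots that are padding throughout the
training set inherit the previous slot's mean so the initial diagonal stays
sorted.

### Gradients

No autodiff framework is used; forward and backward passes are hand-written
in vectorized base R and verified against central finite differences in the
test suite. The gradient through the diagonalization is the standard result
for a simple eigenvalue of a symmetric matrix:
`∂ε_i/∂H = u_i u_iᵀ` with `u_i` the corresponding eigenvector; the loss
gradient with respect to `H` is `U diag(g) Uᵀ`. Because off-diagonal
triangle entries feed two matrix positions, their gradient picks up a
factor 2 under the mirror parameterization.

**Degeneracies.** The formula is singular at exactly degenerate
eigenvalues. LAPACK still returns an orthogonal eigenbasis there, so the
backward pass is well-defined almost always; if a non-finite gradient does
occur, the matrix is re-diagonalized with a ±1e−10 uniform diagonal jitter
and the event is counted (`fit$degenerate_backward`). Near-degenerate
encounters (gap < 1e−8 eV) in `eigenvalue_gradient()` are flagged via the
`"degenerate"` attribute.

## 2. Loss, training, evaluation

The loss is the masked L2: per molecule, the **mean** over valid slots of
the squared difference between prediction and reference, slots matched
index-wise with both sides ascending; then the **mean** over molecules.
Padding slots contribute exactly zero, including zero gradient. The mean
(rather than sum) convention is a documented choice — the source's
reduction convention is not visible — and makes the loss scale-free in
`n_max` and batch size: batch-size-1 accumulation equals the full-batch
loss to 1e−10 (a tested property).

Index-wise matching after sorting is also a choice (the assignment rule is
never stated); it is consistent with a sorted-diagonal output and an
indexed sum.

Optimization is Adam (hand-implemented) with plateau learning-rate decay
and early stopping on validation loss; the best-validation checkpoint is
retained. Training is bit-reproducible given the seed on one thread: all
package randomness flows through `with_seed()`, which restores the caller's
RNG state.

`evaluate()` reports mask-aware per-slot and aggregate MAE/RMSE, the
per-molecule worst-case error, and HOMO/LUMO slot errors, where the HOMO
slot is each record's occupation count (1-based) and LUMO the next slot.

## 3. Δ-ML corrector

Given a frozen, fitted base model and high-level reference records, the
delta targets are `Δ_i = ε_high,i − ε_base,i` on the valid slots, aligned
by the same ascending index-wise rule as the loss. A **multistate** model is
trained on these deltas — it sees only the structure, exactly like any MS
model; the base prediction is not an input. The models are trained
separately and stacked only at prediction time:
`ε_corrected = ε_base + Δ` (pure addition, exact algebra).

Two baselines are supported behind one switch: `baseline = "ml"` (default;
the base model's own predictions — usable on new molecules without any
reference calculation) and `baseline = "reference"` (base-level reference
energies; more accurate where they exist, but requires `base_values` at
prediction time). The corrector is trained from a cold start; whether the
original work reuses base encoder weights is not stated, so cold start is
the documented choice. At prediction time the corrector's *raw, unsorted*
output is added to the base prediction: sorting the deltas would destroy
their slot identity.

## 4. Spectra

`pseudo_voigt()` is `η L + (1 − η) G` with both components **unit-area**
normalized and sharing the FWHM `Γ`:

* `L(x) = (Γ/2π) / ((x − c)² + (Γ/2)²)`
* `G(x) = (2/Γ) √(ln 2 / π) exp(−4 ln 2 (x − c)² / Γ²)`

Defaults: `η = 0.3` (30 % Lorentzian / 70 % Gaussian), `Γ = 0.5` eV (0.3 eV
is the common narrow alternative), grid step 0.01 eV. "Width" is read as a
shared FWHM with unit-area components — the most common Pseudo-Voigt
convention; the formulas are fixed above so all tests are self-contained.
Closed-form anchors: at the center, `η = 0, Γ = 0.5` gives
`(2/0.5)√(ln2/π) ≈ 1.878875` and `η = 1` gives `2/(π·0.5) ≈ 1.273240`.

`make_spectrum()` sums unit-weight lineshapes over the selected states —
occupied only in photoemission mode (no photoionization cross sections),
all valid states otherwise. Note the Lorentzian tail converges slowly: about
1.9 % of unit area lies outside ±5 Γ and 1.2 % outside ±8 Γ, so area
checks at the 1 % level need grids tens of FWHM wide.

`gaussian_envelope()` places a unit-area Gaussian of given FWHM on every
valid eigenvalue of every record and sums — the dataset-level view of a
level-of-theory shift. `spectrum_error()` compares two spectra only near
the reference's local maxima (default half-width: one FWHM); the "vicinity"
definition is this package's own. Spectra are reported on the eigenvalue
axis; flipping to binding energy is presentation, not computation.

## 5. The synthetic tight-binding generator

Real reference data for this problem are external quantum-chemistry
computations. So that the full pipeline is testable offline, the package
ships a tight-binding oracle that is **deliberately non-physical**: its only
job is to produce labels with the right statistical structure, in a
DFT-like range (≈ −30 to +5 eV).

* One s-like orbital per H, four per C/N/O; on-site energies
  H −13.6, C −11.4, N −13.0, O −14.8 eV.
* Every orbital pair on atoms `a ≠ b` with `d ≤ 4 Å` couples with
  `β₀ exp(−ζ (d − d₀))`, `β₀ = −8` eV, `ζ = 1.8` Å⁻¹, `d₀ = 1` Å.
* Occupation = ⌊valence electrons / 2⌋ (H 1, C 4, N 5, O 6).

It does **not** emulate: self-consistency, charge transfer, spin, realistic
Slater–Koster angular dependence, or any quantitative agreement with DFT.
It **does** produce what the method needs: smooth matrix elements, exact
degeneracies (identical orbitals on an atom yield flat, lone-pair-like
levels), eigenvalue crossings along geometric paths, and variable state
counts across compounds.

The "high level of theory" is a smooth GW-like shift: occupied states move
down by `0.8 + 2.0/N_a` eV and virtual states up by `0.6 + 1.5/N_a` eV —
positive for all sizes, so the gap always widens and ordering never changes.

**Energy window.** `select_window()` keeps states at or above `window_low`
up to `states_above_homo` slots past the HOMO (2 ⇒ through LUMO+1). If more
survive than `n_max`, the *deepest* are dropped: the window is anchored at
the frontier, where the application value is. Occupation is recounted
within the window. The operation is idempotent.

**Benchmark suite** (`make_benchmark_suite()`, all randomness from one
seed via fixed offsets):

* **A** — 1000 perturbed water-like geometries (σ = 0.05 Å); window −70 eV
  so all 6 levels are always valid. Single-compound configuration ensemble.
* **B** — a 50-frame scan of an O–H bond (0.75 → 3.6 Å) next to a
  decoupled C–N–C–H fragment beyond the TB cutoff: the descending O–H
  bonding level sweeps through the fragment's flat levels, producing exact
  crossings inside the window while all matrix elements stay smooth. A
  noisy ensemble around the path (`$train_pool`) serves as training data.
* **C** — 2000 random H/C/N/O chains of 2–12 atoms; window −18 eV to
  LUMO+1, `n_max = 10`, variable valid counts.
* **D** — dataset C labelled at both levels of theory.

## 6. Benchmark workflows and problem sizes

`run_benchmark_fig1()` (three-head comparison + learning curve),
`run_benchmark_delta()` (Δ-ML recovery with a 12:1 base/delta size ratio,
versus direct small-set training), and `run_benchmark_path()` (smoothness
along dataset B's path, with the reference Lipschitz bound from Weyl's
inequality: no sorted eigenvalue can jump more than the spectral norm of
the frame-to-frame Hamiltonian difference).

Desk-scale sizes are package choices, not tuned values: encoder `F = 32`,
`T = 2`, `K = 20`; Adam lr 1e−2, batch 64; **training runs to
early-stopping convergence** (validation patience 30, plateau decay,
400-epoch cap chosen so that early stopping, not the cap, ends training).
The single-state family trains at the first model seed only (it is the most
expensive third of the comparison and its claim is per-slot, not
per-seed-median).

## 7. Classic modelling interface

`pseudoham()` is the single fitting entry point, returning a classed object
with `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`, and
`plot` methods; `delta_fit()` returns the corrector with its own `predict`.
A thin command-line wrapper (`inst/scripts/pseudoham-cli.R`) exposes
`generate`, `train`, `predict`, `spectrum`, and `benchmark` subcommands
over the same functions.

```{r, eval = FALSE}
suite <- make_benchmark_suite(seed = 42, sizes = list(A = 300L), only = "A")
fit <- pseudoham(suite$A, head = "hamiltonian",
                 encoder = encoder_config(n_features = 32, n_blocks = 2,
                                          n_rbf = 20),
                 control = train_control(lr = 1e-2, max_epochs = 150,
                                         seed = 1),
                 seed = 1)
summary(fit)
```
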