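---
title: "Methods: engines, numerics, and surrogate models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: engines, numerics, and surrogate models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the physical conventions, numerical settings (and how
they were validated), the machine-learning design, and the known limitations
of `excitonet`.

## Model and conventions

### Frenkel exciton Hamiltonian

A complex with $N$ pigments is described by a real symmetric matrix
$H \in \mathbb{R}^{N\times N}$ in cm$^{-1}$: diagonal entries are site
excitation energies $\varepsilon_m$, off-diagonal entries electronic
couplings $V_{mn}$. `sample_hamiltonian()` draws entries uniformly within
per-complex ranges (`dataset_ranges()`):

| label | sites | diagonal (cm$^{-1}$) | off-diagonal (cm$^{-1}$) |
|-------|------:|----------------------|--------------------------|
| FMO   |  8    | [12000, 12800]       | [−100, 100]              |
| RC    |  8    | [14800, 15000]       | [−50, 50]                |
| CP43  | 21    | [14800, 15100]       | [−60, 60]                |
| CP47  | 24    | [14500, 15300]       | [−100, 100]              |

Flattening (`flatten_hamiltonian()`) stores the full matrix row by row
($N^2$ features), so feature vectors are a lossless bijection with the
matrix.

### Units

Energies are cm$^{-1}$, times fs (transfer times reported in ps). The
conversion $\omega\,[\mathrm{rad/fs}] = 2\pi c\,[\mathrm{cm/fs}] \cdot
\tilde\nu\,[\mathrm{cm}^{-1}]$ uses $c = 2.99792458\times10^{-5}$ cm/fs;
$k_B = 0.695034800$ cm$^{-1}$/K. A bath correlation time $\nu^{-1} = 50$ fs
corresponds to $\nu \approx 106.18$ cm$^{-1}$.

### Trapping and loss

Irreversible capture at the acceptor and exciton decay are anti-Hermitian
additions to the Hamiltonian,
$$H_\mathrm{eff} = H - \tfrac{i}{2}\Gamma_\mathrm{trap}
\lvert\mathrm{acc}\rangle\langle\mathrm{acc}\rvert -
\tfrac{i}{2}\Gamma_\mathrm{loss}\,\mathbb{1},$$
with the convention that an isolated population subject to rate $\Gamma$
decays as $e^{-\Gamma t}$. Defaults: $\Gamma_\mathrm{trap}^{-1} = 1$ ps,
$\Gamma_\mathrm{loss}^{-1} = 0.25$ ns.

### Transfer observables

From the acceptor population $\rho_\mathrm{acc}(t)$:
$$\eta = \Gamma_\mathrm{trap}\!\int_0^\infty \rho_\mathrm{acc}\,dt,
\qquad
\bar t = \frac{\int_0^\infty t\,\rho_\mathrm{acc}\,dt}
              {\int_0^\infty \rho_\mathrm{acc}\,dt}.$$
`transfer_statistics()` integrates the stored trajectory by the trapezoid
rule and corrects for a truncated horizon by fitting an exponential to
$\log\rho_\mathrm{acc}$ over the final 20% of the grid, then adding the
closed-form tail moments. On monoexponential test signals the recovered
$\bar t$ is exact to $10^{-6}$ even when ~2% of the integral lies beyond
the horizon.

## Engines

### HEOM

`propagate_heom()` implements the hierarchical equations of motion for one
overdamped Drude–Lorentz mode per site,
$J(\omega) = 2\lambda\nu\omega/(\omega^2+\nu^2)$, in the high-temperature
(single exponential) representation $C_m(t) \approx c\,e^{-\nu t}$ with
$c = \lambda\nu\left(\cot(\beta\hbar\nu/2) - i\right)$, plus the standard
time-local low-temperature correction term
$\Delta = \lambda\big(2/(\beta\nu) - \cot(\beta\nu/2)\big)$ (enabled by
default). Auxiliary density operators (ADOs) are scaled for numerical
stability; the hierarchy is truncated at depth $D$ with
$\binom{N+D}{D}$ ADOs. The sink enters through $H_\mathrm{eff}$ applied to
every ADO. Integration is fixed-step RK4 in C++ (Armadillo), with the site
energies shifted by their mean before propagation (a global phase for
populations) to keep the RK4 step large.

Two structural facts are exploited and verified against an independent
plain-R hierarchy oracle to $10^{-6}$ (machine precision in practice):
for this hierarchy every ADO stays Hermitian, so the commutator reduces to
$-i(M - M^\dagger)$ with $M = H_\mathrm{eff} A$, and all $M_k$ are computed
in a single batched matrix product.

### Depth convergence

`converged_transfer_time()` sweeps $D, D+2, \dots$ and accepts when
consecutive $\bar t$ agree within 1% (relative). Measured sequences at the
default bath (35 cm$^{-1}$, 50 fs, 300 K): Hamiltonians sampled in the FMO
and RC ranges converge at the first (2, 4) pair with gaps of 0.1–0.9%;
deeper levels change $\bar t$ by $<0.1\%$.

### Time step validation

$\bar t$ computed with $dt = 8$ fs agrees with $dt = 4$ fs to
$\sim 3\times10^{-6}$ relative and with $dt = 2$ fs to 5–7 digits on FMO-
and RC-range samples at depths 2 and 4, far below the 1% depth tolerance;
the propagation horizon of 100 ps combined with the exponential tail
correction reproduces 200 ps-horizon results to $\sim 2\times10^{-5}$.

### Secular Redfield

`propagate_secular_redfield()` works in the exciton basis
($H = C E C^\top$). Downhill rates for $\omega_{ab} = E_a - E_b$:
$$k_{a\to b} = 2 J(\omega_{ab})\,(n(\omega_{ab})+1)
\sum_m |c_m^a|^2 |c_m^b|^2$$
(angular units), uphill rates by exact detailed balance, and the
$\omega \to 0$ channel by the analytic limit $2J n \to 4\lambda k_B T/\nu$.
Pure dephasing uses the same limit with site-overlap differences; trapping
contributes per-exciton rates $\Gamma_a = \Gamma_\mathrm{trap}|c_\mathrm{acc}^a|^2$.
Detailed balance makes the Pauli generator similar to a symmetric matrix,
so propagation is evaluated in closed form through its spectral
decomposition — there is no integration error. Site populations are
recovered by back-transformation including the decaying donor coherences.

Because the secular model traps from exciton populations while the
site-basis acceptor population also carries coherence oscillations, the
site-basis probability ledger (excited + trapped + lost = 1) holds exactly
only after the donor coherences have decayed (a few ps); before that it
deviates by up to $\sim 3\times10^{-3}$ by construction. The test suite
therefore checks the HEOM ledger pointwise to $10^{-5}$ and the Redfield
ledger as a late-time flux balance to better than $10^{-5}$.

### Limits connecting the engines

- $\lambda \to 0$: HEOM and the unitary+sink reference propagator agree
  pointwise to $10^{-6}$; secular Redfield agrees in $\bar t$ to 0.1%
  provided the horizon covers several multiples of $\bar t$ (without
  relaxation, transfer is slow and the tail otherwise dominates).
- On the biological FMO Hamiltonian, Redfield underestimates the HEOM
  transfer time by ~7%, close to literature reports. On uniformly sampled
  FMO-range Hamiltonians, however, this implementation's deviations are
  mixed in sign (roughly half positive), with Redfield *over*estimating
  $\bar t$ on the slowest-transfer samples — see the limitations section.

## Databases and selection

`build_database()` samples Hamiltonians (per-record seeds `seed + i`),
labels them with the chosen engine, and returns a tibble of flattened
features plus `transfer_time_ps`, `efficiency`, `engine`, `seed`, `split`.
`pca_select()` standardizes features, projects onto principal components
covering ≥ 95% of variance (configurable), and greedily picks a max–min
diverse subset starting from the point farthest from the centroid. On
small instances the greedy max–min dispersion is at least half the
brute-force optimum (the classic 2-approximation), which the tests verify.

## Surrogates

`mlp_architecture()` fixes the output layer at 2 neurons (transfer time,
efficiency) with softplus activation so predictions are always positive.
Hidden activations come from {rectifier, tanh, logistic, softsign,
softplus}. Features are standardized; targets are divided by their
training means. Training (`train_mlp()`) minimizes MSE on scaled targets
plus an L2 penalty on hidden-layer weights (output layer unpenalized) with
Adam, and stops once the validation mean relative absolute transfer-time
error has increased over three full consecutive epochs, restoring the best
weights. Initialization is variance-scaled (Glorot) and deterministic per
seed.

`bayes_optimize()` tunes six hyperparameters — learning rate and L2
strength (log scale), hidden layers, neurons per layer, one activation
choice, and the number of training points — with a Gaussian-process
surrogate (RBF kernel on the encoded unit cube, lengthscale chosen by
marginal likelihood) and expected improvement over seeded candidate sets;
`method = "random"` is a pure random-search fallback. Failed evaluations
are penalized with a large finite value and logged in the trace.

At desk scale (3000 Redfield-labelled FMO-range records, 2000 PCA-selected
training points), a single-hidden-layer rectifier network with 1024
neurons, learning rate $5\times10^{-4}$, batch size 50, and L2 $10^{-7}$
reaches a held-out transfer-time error below 15%. Accuracy at this
training-set size is data-limited: nearby configurations and training
seeds land in the 14–18% range, and substantially better errors require
substantially larger labelled databases.

## Evaluation

`mean_relative_absolute_error()` is
$100 \cdot \mathrm{mean}(|t_\mathrm{pred} - t_\mathrm{ref}|/t_\mathrm{ref})$.
`make_report()` aggregates errors per predictor and split, computes signed
relative deviations $(t_\mathrm{ref}-t_\mathrm{approx})/t_\mathrm{ref}$,
histogram summaries, and — when both a network and a Redfield predictor are
supplied — the fraction of records where the network is strictly more
accurate. Reports round-trip exactly through JSON and expose
`tidy()`/`glance()`/`autoplot()`.

## Known limitations

- **High-temperature bath representation.** One exponential mode per site
  plus the time-local correction; valid near room temperature for
  moderate $\lambda$, not at low temperature.
- **Absolute transfer times for the biological FMO Hamiltonian.** With the
  bundled literature 8-site FMO matrix (donor pigment 8, acceptor
  pigment 3) this implementation gives converged HEOM
  $\bar t \approx 4.54$ ps and Redfield $\approx 4.22$ ps, whereas
  published reference values for this setup are 7.95 ps (HEOM) and
  7.48 ps (Redfield). The *ratio* HEOM/Redfield (1.077) matches the
  published ratio (1.063) closely, and all relative statements
  (underestimation, $\Delta\tau$
  scales on sampled ranges) reproduce, but the absolute scale differs by
  ~1.75×. The most plausible causes are undocumented convention
  differences in the reference setup (initial state or rate conventions,
  or a different Hamiltonian variant); the discrepancy is stated here
  rather than hidden by rescaling.
- **Redfield deviation statistics on sampled Hamiltonians.** Literature
  reports that secular Redfield systematically underestimates transfer
  times on sampled FMO-range Hamiltonians, with mean relative absolute
  deviations near 9.6% (FMO ranges) and 8.6% (RC ranges). This
  implementation reproduces the RC-range figure, and reproduces the
  underestimation on the biological FMO Hamiltonian, but on uniformly
  sampled FMO-range Hamiltonians it yields a smaller mean deviation
  (≈ 4.8% over 12 seeds) with mixed signs (5 of 12 positive; 28 of 50 on
  a larger screen). Redfield overestimates $\bar t$ precisely on the
  slowest-transfer samples, where secular rates miss environment-assisted
  transport channels. The published Redfield rate normalization is not
  printed in the reference work, so an exact match of these statistics
  cannot be verified; the rate prefactor is isolated in
  `secular_rates()` should recalibration ever be warranted.
- **Desk-scale surrogate accuracy.** The few-percent transfer-time errors
  reported for networks trained on $10^4$-scale exactly-labelled databases
  are out of reach for the 3000-record desk-scale pipeline shipped in the
  tests; the <15% figure above is the honest desk-scale result.
- **21- and 24-site complexes.** Converged-depth HEOM for CP43/CP47 is not
  desk scale. The suite documents a reduced-depth check instead: depth
  increments contract (depth 1→2 change below 5% and smaller than the
  0→1 change), consistent with convergence at modest additional depth.
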