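# excitonet

Exciton transfer dynamics and neural-network surrogates for
light-harvesting complexes.

`excitonet` studies excitation energy transfer (EET) in pigment–protein
complexes described by Frenkel exciton Hamiltonians (site energies and
electronic couplings in cm⁻¹). It provides:

- **Two open-quantum-system engines** with phenomenological trapping at an
  acceptor site and uniform exciton loss:
  - hierarchical equations of motion (**HEOM**) with a Drude–Lorentz bath,
    scaled auxiliary density operators, and a time-local low-temperature
    correction — numerically exact at converged hierarchy depth;
  - a **secular Redfield** master equation in the exciton basis, propagated
    in closed form through the spectral decomposition of its rate generator.
- **Transfer observables**: efficiency η and mean transfer time t̄ from the
  acceptor-population trajectory, with an exponential tail correction for
  truncated horizons.
- **Database tooling**: uniform Hamiltonian sampling within per-complex
  parameter ranges (FMO, RC, CP43, CP47), engine-labelled record tibbles,
  train/validation/test splits, and diverse training-set selection by greedy
  farthest-point sampling in a PCA-reduced feature space.
- **Surrogate models**: multi-layer perceptrons mapping a flattened
  Hamiltonian to (t̄, η), with softplus outputs, Adam training, a
  3-epoch early-stopping rule, and Gaussian-process Bayesian hyperparameter
  optimization (expected improvement, random-search fallback).
- **Evaluation**: mean relative absolute transfer-time errors per data split,
  signed-deviation histograms, and network-vs-Redfield comparisons, plus a
  scriptable command-line interface.

The package is tidyverse-native: records are tibbles, results have
`tidy()`/`glance()` methods and `ggplot2::autoplot()` visualizations.

## Quick start

```r
library(excitonet)

# A Frenkel Hamiltonian sampled from the FMO parameter neighborhood
h <- sample_hamiltonian(dataset_ranges("FMO"), seed = 1)

bath <- bath_parameters(lambda_cm1 = 35, nu_inv_fs = 50, temperature_K = 300)
sink <- sink_parameters(donor = 1, acceptor = 3,
                        gamma_trap_ps = 1, gamma_loss_ps = 1 / 250)

# Numerically exact label: HEOM with automatic depth convergence
conv <- converged_transfer_time(h, bath, sink)
conv$stats$transfer_time_ps

# Fast approximate label: secular Redfield
traj <- propagate_secular_redfield(h, bath, sink)
transfer_statistics(traj, sink)

# Population dynamics
ggplot2::autoplot(traj)
```

Building a labelled database and training a surrogate:

```r
db <- build_database(dataset_ranges("FMO"), n = 3000, engine = "redfield",
                     bath = bath, sink = sink, seed = 42)
db <- split_dataset(db, n_valid = 500, n_test = 500, seed = 1)

pool  <- which(db$split == "pool")
train <- db[pool[pca_select(db[pool, ], 2000)], ]
valid <- db[db$split == "valid", ]

scalers <- fit_scalers(train)
arch  <- mlp_architecture(ncol(feature_matrix(train)), hidden = 1024,
                          activations = "rectifier", learning_rate = 5e-4)
model <- train_mlp(init_mlp(arch, seed = 7), train, valid, scalers,
                   training_config(batch_size = 50, max_epochs = 500))

predict(model, db[db$split == "test", ])
```

Hyperparameter search:

```r
space <- hyperparameter_space()
res <- bayes_optimize(function(cfg) { ... }, space, budget = 50, seed = 1)
res$best
```

## Command line

An `eet` script is installed under `system.file("cli", "eet")`:

```sh
eet generate --dataset-label FMO --n 3000 --engine redfield --seed 42 --out db.csv
eet select   --db db.csv --k 2000 --out db_train.csv
eet train    --db db_train.csv --neurons 1024 --layers 1 --activation rectifier --out model.json
eet simulate --engine heom --hamiltonian h.json --out stats.json
eet predict  --model model.json --hamiltonian h.json
eet evaluate --db db.csv --model model.json --out report.json
eet hpo      --db db_train.csv --budget 50 --seed 1
```

Exit codes: `0` success, `2` argument error, `3` convergence error, `1`
any other failure. A `--config file` of `key: value` pairs supplies
defaults; explicit flags win.

## Documentation

See the methods vignette (`vignettes/methods.Rmd`) for the physical
conventions, numerical settings and their validation, the machine-learning
design, and known limitations.
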