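# molbayes

Bayesian graph-convolutional regression for molecular property
prediction with calibrated uncertainty, in pure R.

Quantitative structure–property models are increasingly used to decide
which compounds get synthesized or assayed. For that decision the mean
test error is not enough: the user needs to know *which* predictions to
trust, and the model needs to know which unlabelled compounds would
teach it the most. molbayes is for computational chemists and
method developers who want those two capabilities — trustworthy
per-molecule uncertainty and uncertainty-driven experiment selection —
from a message-passing (graph-convolutional) fingerprint model, with
every inference component implemented transparently and validated
against analytic oracles.

## The model in brief

Molecules enter as SMILES and become attributed graphs (atom features
x_v, bond features e_vw; parsing via Open Babel through ChemmineOB).
Hidden states start at h_v^0 = x_v and are updated by message passing,

    m_v^t = sum_{w in N(v)} [ h_w^{t-1} ; e_vw ]
    h_v^t = sigmoid( H_{deg(v)}^t [ h_v^{t-1} ; m_v^t ; 1 ] ),

with a learned matrix H_N^t per step t and vertex degree N. A softmax
readout sums per-atom probability vectors into a fingerprint
f = sum_t sum_v softmax(W_t [h_v^t; 1]) — invariant to atom
relabelling — and a two-hidden-layer relu head outputs the predicted
mean and the log aleatoric variance log sigma(x)^2. With observations
y_i = F(x_i, theta) + N(0, sigma(x_i)^2), the log posterior

    log P(theta | D) = sum_i [ -(y_i - F(x_i,theta))^2 / (2 sigma_i^2)
                               - 1/2 log sigma_i^2 ] + log P(theta)

is maximized (MAP), sampled approximately by Monte-Carlo dropout
(Bernoulli unit masks at train and prediction time), or sampled by
Stein variational gradient descent (SVGD), in which N parameter
"particles" follow

    theta_i <- theta_i + eta * phi(theta_i)
    phi(theta_i) = (1/N) sum_j [ k(theta_j,theta_i) grad_j log P(theta_j|D)
                                 + grad_{theta_j} k(theta_j,theta_i) ].

Predictions decompose the variance of N stochastic passes (or
particles) into **epistemic** (spread of the predictive means) plus
**aleatoric** (mean predicted noise variance) — the sum is exact by
construction. A semi-supervised mode first learns the message-passing
weights from unlabelled structures alone (a paragraph-vector-style
negative-sampling objective over atom environments), freezes them, and
trains only readout and head on labels — the configuration that matters
in the low-data/active-learning regime. Diagnostics include
confidence–error curves, variance–error Spearman correlation, a
scaffold-held-out uncertainty probe, Bemis–Murcko scaffold splitting
and an epistemic-uncertainty active-learning loop.

## Worked example

```r
library(molbayes)

# a labelled synthetic benchmark: 600 molecules from three scaffold
# families; property = 0.25*heavy + 1.0*aromatic rings + 0.75*heteroatoms,
# noise sd = 0.2 + 0.2*heteroatoms (both known exactly per molecule)
lib  <- generate_molecule_library(600, c("benzene", "pyridine", "chain"),
                                  seed = 1)
task <- label_library(lib, seed = 2)
ds   <- task$dataset

train <- mol_dataset(ds$smiles[1:480],   ds$y[1:480])
test  <- mol_dataset(ds$smiles[481:600], ds$y[481:600])

fit <- molbayes_fit(train,
                    config     = mpnn_config(n_steps = 2, n_hidden = 12),
                    model_kind = "semisupervised",
                    inference  = "dropout",
                    steps = 700, seed = 1)
preds <- predict(fit, test, seed = 3)
head(round(preds, 3))
#>    mean var_epistemic var_aleatoric var_total
#> 1 3.117         0.028         1.943     1.971
#> 2 3.203         0.033         1.983     2.016
#> 3 2.994         0.012         1.848     1.859
#> 4 3.176         0.037         1.986     2.023
#> 5 3.270         0.046         2.033     2.079
#> 6 2.935         0.009         1.767     1.776
```

Each row is one test molecule: the predicted property, the variance due
to limited data (epistemic), the predicted measurement-noise variance
(aleatoric), and their sum. The uncertainty is usable for ranking:

```r
sqrt(mean((preds$mean - test$y)^2))
#> [1] 1.614
cor(preds$var_aleatoric, task$truth$sigma_true[481:600]^2,
    method = "spearman")
#> [1] 0.637
confidence_error_curve(preds, test$y, grid = c(25, 50, 75, 100))
#>   percentile     error variance_kind metric
#> 1         25 0.7729471         total   rmse
#> 2         50 0.9874840         total   rmse
#> 3         75 1.3108347         total   rmse
#> 4        100 1.6138743         total   rmse
```

The quarter of predictions the model is most confident about carries
less than half the error of the full test set (0.77 vs 1.61), and the
predicted aleatoric variance rank-correlates with the generator's true
noise map even at this small training size. Real CSV datasets (a SMILES
column plus a numeric property column) enter through `read_dataset()`;
a command-line interface (`exec/molbayes`) wraps the same functions as
`synth`, `train`, `evaluate` and `active-learn` subcommands.

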