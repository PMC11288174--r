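# petkin

Joint kinetic parameter identification for the irreversible two-tissue
compartment model of dynamic PET — without metabolite analysis of blood
samples.

## The problem

Quantitative dynamic PET with an irreversibly trapped tracer (FDG-like)
models each anatomical region *i* by

```
dC_F/dt = K1 * C_P - (k2 + k3) * C_F,      C_F(0) = 0
dC_B/dt = k3 * C_F,                        C_B(0) = 0
```

where `C_P` is the arterial plasma concentration of non-metabolized
tracer and the scanner measures (after blood-volume correction) the total
tissue activity `C_T = C_F + C_B` at frame times `t_1 .. t_T`. The rate
constants `K1, k2, k3` (1/min) are the clinical readout. Standard
practice obtains `C_P` from arterial blood samples via costly plasma
separation and metabolite analysis. `petkin` implements the alternative:
parametrize `C_P` as a polyexponential `sum_j lambda_j exp(mu_j t)` and
the parent plasma fraction as a biexponential
`f(t) = A exp(xi1 t) + (1 - A) exp(xi2 t)` with `f(0) = 1`, and estimate
the kinetic rates of all regions *jointly* with the input-curve and
fraction parameters from tissue curves plus easily measured whole-blood
activity `C_WB = C_P / f`.

The package is aimed at researchers in PET pharmacokinetics and in
parameter identification for ODE models. It provides:

* the closed-form tissue response and joint forward operator
  (`ct_closed_form()`, `forward_operator()`), with numerically stable
  handling of the degenerate exponent configurations;
* checkable sufficient conditions for unique identifiability
  (`check_assumption_A()`, `check_lemma11()`, `min_timepoints()`:
  `T >= 2(p+3)`, i.e. 14 time points for the degree-4 input model;
  `min_blood_samples()`), and the K1/input scale-ambiguity machinery
  (`align_scale()`);
* an iteratively regularized Gauss–Newton solver with analytic Jacobian,
  per-parameter-type geometric regularization schedules
  `a * 2^(-i/c)`, domain projection and Morozov discrepancy stopping
  (`run_irgnm()`, `irgnm_step()`, `fit_problem()`);
* a synthetic study: ground-truth brain configuration, 25-frame
  acquisition schedule, calibrated signal-proportional noise at three
  count settings (`delta_y` = 0.003 / 0.011 / 0.07), randomized
  initializations `x0 = x_true (1 + sigma gamma)`, and a 20-replicate
  experiment protocol with divergence accounting
  (`run_experiment()`);
* plain-text I/O (long-format TAC CSV, parameter JSON) and a CLI wrapper
  (`inst/cli/petkin.R`) with `simulate`, `fit`, `check` and `experiment`
  subcommands.

## Worked example

Recover all kinetic parameters at the normal count setting from strongly
perturbed starts (`delta_x = 0.3`), with the parent fraction known and a
noiseless whole-blood curve (the "reduced" setup):

```r
library(petkin)
res <- run_experiment("reduced", "normal", delta_x = 0.3, n_reps = 20,
                      master_seed = 1)
res
#> <petkin_experiment> reduced, normal count, delta_x = 0.3: 3/20 replicates dropped
#>          region parameter truth    mean        sd
#> 1       frontal        K1 0.157 0.15674 0.0005478
#> 2       frontal        k2 0.174 0.17277 0.0020944
#> 3       frontal        k3 0.118 0.11732 0.0008921
#> 4      temporal        K1 0.161 0.16072 0.0005175
#> 5      temporal        k2 0.179 0.17783 0.0017124
#> 6      temporal        k3 0.096 0.09546 0.0006094
#> 7     occipital        K1 0.177 0.17676 0.0006443
#> 8     occipital        k2 0.159 0.15812 0.0019851
#> 9     occipital        k3 0.088 0.08756 0.0007651
#> 10 white_matter        K1 0.100 0.09991 0.0003465
#> 11 white_matter        k2 0.161 0.16041 0.0015543
#> 12 white_matter        k3 0.047 0.04678 0.0003751
```

Each row compares a ground-truth rate constant with the mean and standard
deviation of its reconstruction over the replicates kept by the protocol
(non-divergent and stopped by the discrepancy principle): every rate is
recovered to within a fraction of a percent despite the 30% perturbation
level of the initializations.

Check identifiability of a configuration before fitting:

```r
check_assumption_A(ground_truth_config()$params)
#> <identifiability report>
#>   assumption (A) satisfied: TRUE
#>   largest region subset with distinct k3 and k2+k3: 4
#>   required tissue time points T >= 14
#>   required whole-blood samples q >= 4
```

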