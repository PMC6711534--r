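# oedmicro

In-silico evaluation and optimization of sampling schedules for dynamic
(non-isothermal) microbial inactivation experiments.

## The problem

Fitting the dynamic Bigelow model

    dlogN/dt = -(1/D_ref) · 10^((T(t) − T_ref)/z)

to plate counts taken during a time-varying thermal treatment yields the
decimal reduction time `D_ref` (min) and the thermal sensitivity `z`
(°C). How precisely those parameters come out depends heavily on *when*
the samples are taken — and a design that looks reasonable (evenly
spaced points) can be dramatically less informative than an optimized
one with the same experimental effort, or can even get *worse* as
points are added.

`oedmicro` lets a food-safety researcher assess this before any
laboratory work, with two complementary tools:

* **Monte Carlo precision prediction** — simulate noisy experiments on a
  candidate design (additive Gaussian noise on the log counts,
  replicated sampling), refit the model by least squares, and report
  the fraction of simulations in which each parameter's relative
  standard error meets a precision target (default ≤ 0.1).
* **Fisher-information design comparison** — build the 2×2 Fisher
  Information Matrix from the local sensitivity functions
  `∂logN/∂D_ref` and `∂logN/∂z`, rank designs by the D-criterion
  `det(FIM)` (penalized for sampling points closer than a minimum
  spacing, default 3 s), search for D-optimal sampling times, and
  report how many uniform points match a small optimal design.

Everything is exact for piecewise-linear temperature profiles: the
model and both sensitivity functions are integrated in closed form per
linear segment. Three case-study profiles are built in (A: 30→60 °C at
0.5 °C/min; B: 30→60→30 °C at ±1 °C/min; C: 45→65 °C at 10 °C/min),
with case-study kinetics `D_57.5 = 3.9` min, `z = 4.2` °C for
*Listeria monocytogenes*.

## Worked example

```r
library(oedmicro)

params <- bigelow_params()           # D_57.5 = 3.9 min, z = 4.2 degC, logN0 = 8
profA  <- built_in_profile("A")      # 30 -> 60 degC over 60 min

# D-optimal 10-point design
oed <- optimize_design(profA, params, n = 10, seed = 42)
oed
#> D-optimal design for profile 'A' (n = 10, seed = 42, 20000 evaluations)
#> Sampling design with 10 points (min):
#>   55.9519, 56.0825, 56.198, 56.3101, 56.425, 56.5542, 59.8051, 59.8734, 59.9376, 60
#> FIM summary (n = 10): det = 539.329, 1/det = 0.00185416, penalty = 7.92267, objective = 531.406
```

The optimizer concentrates every sample near t = 56 min (the interior
extremum of the z-sensitivity; the profile crosses `T_ref` there) and
t = 60 min (the joint sensitivity maximum) — the two landmarks that
carry essentially all the information about `(D_ref, z)`.

```r
# Predicted precision: optimal vs uniform design, 100 noisy experiments each
monte_carlo_precision(oed$design, profA, params, seed = 42, fit_logN0 = FALSE)
#> Monte Carlo precision over 100 simulations (sigma = 0.25, 3 reps):
#>   converged: 100%
#>   rel SE <= 0.1: D-value 100%, z-value 100%
#>   mean estimates: D_ref = 3.922 min, z = 4.192 degC

monte_carlo_precision(uniform_design(10, 60), profA, params, seed = 42)
#> Monte Carlo precision over 100 simulations (sigma = 0.25, 3 reps):
#>   converged: 100%
#>   rel SE <= 0.1: D-value 83%, z-value 2%
#>   mean estimates: D_ref = 3.958 min, z = 4.214 degC
```

With the same ten points and three replicates, the optimal design meets
the 10% relative-error target for both parameters in every simulated
experiment; the uniform design almost never pins down the z-value. (The
uniform-design run uses the default fit, which also estimates the
initial count `logN0` — what a real experiment would have to do; the
optimal-design run fixes it, since a two-cluster design cannot support
a third parameter. Estimates stay centred on the true values in both
cases — the designs differ in precision, not bias.) In information
currency:

```r
uniform_equivalent_n(profA, params, oed_n = 3, seed = 42)
#> [1] 19
```

a uniform design needs 19 points to match the Fisher-information
determinant of a D-optimal design with only 3.

## Command line

A thin wrapper over the same functions lives at `inst/cli/oedmicro`
(installed under `system.file("cli", "oedmicro", package = "oedmicro")`):

```sh
oedmicro oed profile=A n_points=10 seed=17 --out results/
oedmicro mc  profile=B design=uniform n_points=10 --out results/
oedmicro --help     # every key with its default
```

Outputs are CSV/JSON stamped with the configuration hash and seed; exit
status 2 flags configuration errors, 1 runtime failures.

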