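# hdokin

Kinetic modelling of microbial hexane-2,3-diol (2,3-HDO) pathway flux.

Engineered *E. coli* strains make 2,3-HDO through the lumped chain

```
glucose --Ka1/Kb1--> butyryl-CoA --PduP--> butanal --Ka3--> hexane-2,3-diol
                          |
                          +--thioesterases (Ka2)--> butyrate
```

A fast butyryl-CoA supply route (PhaB-PhaJ) yields product curves that rise
quickly and then stall, while a slow route (FadB) rises steadily. The
candidate explanation is substrate inhibition of PduP, modelled with the
Haldane rate law

    v(B) = Vmax * B / (Km + B + B^2 / Ki)

which is unimodal in the butyryl-CoA concentration B with its maximum at
sqrt(Km * Ki). `hdokin` provides, for scientists analysing such sparse
fermentation time courses:

* the four lumped ODE model variants (with/without the thioesterase drain,
  with/without substrate inhibition), a fast compiled adaptive integrator
  (Dormand-Prince 5(4) plus an L-stable Rosenbrock scheme for the stiff
  inhibition variants), and a Bateman closed-form oracle for the linear
  chain;
* staged nonlinear least-squares fitting of the free rate constants,
  residual sum of squares, AIC = n*ln(RSS/n) + 2k, and AIC-based model
  comparison (`staged_fit_protocol()`, `compare_models()`);
* cumulative butyryl-CoA production/consumption flux accounting
  (`cumulative_flux()`);
* a synthetic time-course generator with known ground truth for parameter
  recovery and model-selection studies (`paper_like_fixtures()`,
  `recovery_experiment()`);
* fermentation performance metrics: mM <-> g/L titer conversion, substrate
  yield (g/g) and volumetric productivity (g/L/h);
* a command-line interface (`hdokin_cli()`, `inst/scripts/hdokin`) over
  tidy CSV time courses and JSON configs.

## Worked example

Generate the three synthetic fermentation datasets (parental strain,
PhaB-PhaJ knockout, FadB knockout; 5 points each over 0-96 h, 5%
proportional noise) and run the staged fitting protocol:

```r
library(hdokin)

fx <- paper_like_fixtures(seed = 42)   # ground truth carried as attributes
sf <- staged_fit_protocol(fx$mr40, fx$dko_phabj, fx$dko_fadb)
sf$comparison
#> Model comparison by AIC (preferred: substrate_inhibition  )
#>                 label        rss n k        aic delta_aic
#>  substrate_inhibition   2.359738 5 2  0.2455644   0.00000
#>         no_inhibition 187.289362 5 1 20.1160845  19.87052
```

The knockout data were generated with substrate inhibition active, and the
protocol recovers that: the inhibition model wins by delta AIC ~ 19.9 (a
difference above 2 is considered decisive; below 2 the comparison is
flagged inconclusive). The stage-3 fit reports the fitted constants, with
`Ka1`/`Ka3` fixed from stage 1 and `Km` held at the literature PduP value:

```r
sf$stage3
#> Least-squares fit of DKO_PHABJ_INHIB
#>   RSS = 2.35974 (n = 5, k = 2)  AIC = 0.2456  converged: TRUE
#>    Ka1 = 0.0498457
#>    Ka3 = 0.135979
#>   *Vmax = 7.06076
#>    Km = 0.00087
#>   *Ki = 3.9443
#>   (* = fitted)
```

RSS is in mM^2 over the n = 5 observed 2,3-HDO concentrations; `Vmax` is in
mM/h, `Km`/`Ki` in mM, first-order constants in 1/h. (At 5% noise `Vmax`
and `Ki` compensate each other; the generating values were 9.54 and 2.6.)

Fermentation performance numbers from a shake-flask endpoint — 91.1 mM
2,3-HDO from 40 g/L glucose in 96 h:

```r
str(metrics_report(91.1, "mM", "hexane-2,3-diol", 40, 96))
#> List of 4
#>  $ titer_mM        : num 91.1
#>  $ titer_gL        : num 10.8
#>  $ yield_gg        : num 0.269
#>  $ productivity_gLh: num 0.112
```

i.e. 10.77 g/L, 0.269 g/g, 0.112 g/L/h.

The same pipeline is scriptable:

```sh
Rscript inst/scripts/hdokin generate --out fixtures --seed 42
Rscript inst/scripts/hdokin staged-fit \
    --mr40 fixtures/mr40.csv --dko fixtures/dko_phabj.csv \
    --fadb fixtures/dko_fadb.csv --out staged.json
Rscript inst/scripts/hdokin metrics --input runs.csv --out report.csv
```

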