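# phostat

Transport-centric modeling of the *Saccharomyces cerevisiae* Pho regulon.

## The problem

Budding yeast senses inorganic phosphate (Pi) internally: the
Pho80p/Pho85p kinase reads the intracellular concentration ("iPi") and
phosphorylates the master transcription factor Pho4p, which is cytoplasmic
when fully phosphorylated and nuclear when dephosphorylated. The classical
view — import rate tracks the external concentration ("ePi"), so iPi varies
continuously and dedicated negative-feedback loops stabilize the response —
struggles to explain why the starvation response occupies three discrete,
robust programs (off / plateau / on) with a bistable, hysteretic transition
between off and plateau.

`phostat` implements an alternative: **transporter biophysics does the
control**. A membrane *carrier* (alternating-access uniporter) couples
influx and efflux through a shared carrier pool; at saturating external
substrate its import rate becomes independent of ePi, so a constant
consumption demand pins iPi to a robust set point. Two carriers of
different affinity — constitutive low-affinity transporters (inactivated
post-translationally by Spl2p) and Pho4-induced high-affinity transporters
— then establish exactly two robust iPi levels, and a three-level Pho4
nuclear transfer function plus two promoter classes (plateau vs decoupled)
produce the full off/plateau/on program, including commitment (hysteresis)
on return to rich phosphate.

## The core quantities

For a symmetric carrier with loaded-translocation rate $k_2$,
empty-translocation rate $k_4$, dissociation constant $K_d$ on both faces
and total amount $e_t$, with occupancies
$\theta_{o,i} = s_{o,i}/(K_d + s_{o,i})$, the steady-state net import rate
is

$$J = \frac{e_t k_2 k_4 (\theta_o - \theta_i)}
     {k_2(\theta_o + \theta_i) + k_4(2 - \theta_o - \theta_i)},$$

against the uncoupled Michaelis–Menten comparator
$J_{\mathrm{MM}} = e_t (k_2\theta_o - k_4\theta_i)$. Inverting either law
at a constant demand $J$ gives the internal-vs-external concentration
curve, the critical external concentration below which the cell starves,
and a robustness index (fold-change of the set point across an external
range anchored to each model's own critical point).

The package also implements the image-histogram nuclear-localization
score — the excess probability mass of a median-normalized frame above the
tail quantile of a pooled pre-starvation reference — an activated-cell
median trace statistic, and seeded generators of synthetic microscopy
images and single-cell reporter populations so every stage is testable
without experimental data.

## Worked example

```r
library(phostat)

p <- transporter_params(k2 = 4, k4 = 4, Kd = 10, et = 10)
carrier_flux(p, s_out = 30, s_in = 0)
#> [1] 15

# critical external concentration at demand J = 15
critical_external(p, 15, model = "carrier")   #> [1] 30
critical_external(p, 15, model = "mm")        #> [1] 6

# internal set point saturates for the carrier, keeps tracking for MM
solve_internal(p, 15, s_out = 1e8, model = "carrier")$s_in  #> 3.333332
solve_internal(p, 15, s_out = 1e8, model = "mm")$s_in       #> 16.66666

# fold-change of the set point between 2x and 20x the critical point:
# near 1 = robust; the carrier wins
robustness_index(p, 15, 2, 20, model = "carrier")  #> [1] 2.540107
robustness_index(p, 15, 2, 20, model = "mm")       #> [1] 5.902128
```

The regulon state machine reproduces the three programs and their
hysteresis:

```r
rp <- regulon_params()
down <- regulon_sweep(rp, direction = "down_from_rich")
up   <- regulon_sweep(rp, direction = "up_from_starved")
cbind(s_out = down$s_out, down = down$label,
      up = rev(up$label))
#>  s_out  down      up
#>   1000  "OFF"     "PLATEAU"   <- commitment: the plateau persists
#>    500  "OFF"     "PLATEAU"      after return to rich phosphate
#>    250  "PLATEAU" "PLATEAU"
#>    ...  "PLATEAU" "PLATEAU"
#>     18  "PLATEAU" "PLATEAU"
#>      7  "ON"      "ON"
#>    ...  "ON"      "ON"
```

Within the plateau the internal set point barely moves (s_in 0.25–0.34,
a 1.4-fold change over a 50-fold ePi range) while the decoupled reporter
stays at basal level — the perfect-adaptation phenomenology. Disabling
Spl2 inhibition (`regulon_params(K_S = Inf)`) removes both the bistable
window and the hysteresis.

A command-line wrapper is included:

```sh
Rscript inst/exec/phostat transport surface \
  --sout-grid 30,60 --sin-grid 0,5 --out surface.csv
Rscript inst/exec/phostat regulon sweep --direction both --out states.csv
```

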