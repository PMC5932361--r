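# i3gauxin

Dynamic simulation of indole glucosinolate (I3G) hydrolysis and its impact
on auxin signaling in *Arabidopsis thaliana*.

When cruciferous plants are attacked, myrosinase enzymes (MYR) hydrolyse
I3G into two kinds of products at once: indole-3-acetonitrile (IAN), which
nitrilases (NIT) convert into the auxin indole-3-acetic acid (IAA), and
reactive isothiocyanate derivatives (indole-3-carbinol and I3M conjugates
with cysteine, ascorbate or glutathione) that competitively occupy the TIR1
auxin receptor. One input therefore drives both a positive and a negative
path to the same output — a type-3 incoherent feedforward loop — and the
observable of interest, the TIR1:IAA complex concentration, responds with a
transient drop, a recovery, and an overshoot. `i3gauxin` is for plant
defense and hormone-signaling researchers who want to explore this loop
quantitatively: it packages the published kinetic parameters, integrates
the model through the two attack scenarios, and reduces trajectories to
response metrics.

## The model

Five coupled ODEs (concentrations in uM, time in minutes), with hydrolysis
gated by a scenario switch α ∈ {0, 1} and the nitrile-specifier fraction
β ∈ [0, 1] splitting the hydrolysis flux
F(I3G) = MYR · V<sub>max,MYR</sub> · I3G / (K<sub>M,MYR</sub> + I3G):

    dIAN/dt       = β α F(I3G) − τ_IAN IAN
    dAnt/dt       = (1−β) α F(I3G) − τ_Ant Ant − k_on^Ant T_f Ant + k_off^Ant [TIR1:Ant]
    dIAA/dt       = θ + F_NIT(IAN) − τ_IAA IAA − k_on^IAA T_f IAA + k_off^IAA [TIR1:IAA]
    d[TIR1:IAA]/dt = k_on^IAA T_f IAA − k_off^IAA [TIR1:IAA]
    d[TIR1:Ant]/dt = k_on^Ant T_f Ant − k_off^Ant [TIR1:Ant]

with free receptor T_f = TIR1 − [TIR1:IAA] − [TIR1:Ant], nitrilase flux
F_NIT Michaelis–Menten in IAN, basal IAA synthesis θ, and off-rates derived
from docking dissociation constants via k_off = K_D · k_on
(k_on = 60 uM⁻¹ min⁻¹). The I3G pool and all protein levels are constant.
Two protocols are simulated from the no-hydrolysis steady state: the
**mustard oil bomb** (α = 1 for 1 min, tissue disruption) and **sustained
cell-autonomous hydrolysis** (α held at 1, biotrophic infection).

## Worked example

Myrosin cells concentrate MYR up to ~100-fold above the seedling average.
What does triggering the mustard oil bomb next to them do to auxin
signaling?

```r
library(i3gauxin)
p <- scale_parameter(default_parameters(), "myr", 100)
traj <- simulate_scenario(p, hydrolysis_scenario("bomb"))
compute_metrics(traj)
#> <i3g_metrics>
#>   baseline TIR1:IAA: 1.59018e-08 uM
#>   drop: 1.05122e-08 uM (2.95-fold) at t = 1 min
#>   recovery (deficit < 5% of peak): 22.39 min
#>   overshoot: +1.596e-09 uM at t = 58.4 min
#>   final: 1.59724e-08 uM (1.004 x baseline)
```

Reading: before the attack ~1.6×10⁻⁸ uM of receptor is in the signaling
TIR1:IAA complex (the receptor pool itself is only 1.595×10⁻⁵ uM). The
1-min hydrolysis burst floods the cell with antagonist conjugates, which
outcompete IAA and collapse TIR1:IAA almost 3-fold within a minute. As the
antagonists decay (τ = 0.125 min⁻¹) the deficit is erased in ~22 min; the
IAA produced from the nitrile branch then pushes signaling ~10% *above*
baseline, peaking near one hour, before everything relaxes back (within
0.4% of baseline by 24 h).

Sweeps and panels chain the same way:

```r
fold_sweep(default_parameters(), "myr", c(1, 10, 100, 1000)) |>
  autoplot(metric = "fold_decrease")
antagonist_panel(scenario = hydrolysis_scenario("sustained"))
```

A command-line front end over the same functions lives at
`inst/cli/i3gauxin.R` (verbs `run`, `sweep`, `panel`, `heatmap`).

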