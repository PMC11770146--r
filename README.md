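# depspin

Dielectrophoresis (DEP) lets an inhomogeneous AC electric field move
polarizable particles — beads, cells — without contact: particles are pulled
toward field maxima at electrode edges (positive DEP) or pushed away
(negative DEP) depending on the sign of the Clausius–Mossotti factor.
Conventional DEP devices need cleanroom electrodes and wired high-voltage
sources. A cheaper route is to etch the electrodes into a standard printed
circuit board, power them *wirelessly* through an inductive coil link, and
boost the electrode voltage by making the receiver coil and its capacitance
a resonant LC tank — all on a spinning disc, so the centrifugal body force
doubles as a built-in wash step.

`depspin` is the design-and-simulation toolkit for that platform, aimed at
anyone sizing such a device: it answers, before any board is ordered,
*where will my tank resonate, what capacitor do I need, what voltage reaches
the electrodes, which particles are positive-DEP at my drive frequency, and
will the trap survive the spin?*

The four model layers:

* **Resonant inductive link** — tank capacitance
  `C = C_electrode + C_coil + C_add` with
  `C_electrode = n·2εhl/d` and `C_coil = επ(r_out² − r_in²)/d_coil`,
  resonance `f = 1/(2π√(LC))`, mutual inductance `M = k√(L₁L₂)`,
  quality factor `Q = 2πfL/R`, link efficiency `η = k²Q₁Q₂/(1+k²Q₁Q₂)`,
  plus a coupled two-mesh frequency sweep and a least-squares calibration
  of `(k, R)` against measured receiver-voltage curves.
* **Dielectric response** — complex permittivity
  `ε*(f) = ε − jσ/(2πf)`, Clausius–Mossotti factor
  `K(f) = (ε_p* − ε_m*)/(ε_p* + 2ε_m*)`, crossover frequencies, and the
  DEP force `F = 2πr³ε_m·Re[K(f)]·∇|E|²` for homogeneous spheres.
* **Electrode field** — finite-difference Laplace solve of one periodic
  unit cell of the interdigitated array, giving `|E|²` and `∇|E|²`.
* **Particle transport** — overdamped trajectories under DEP, Stokes drag
  and the centrifugal force `(4/3)πr³Δρ·ω²R`, classified trapped / washed,
  with trapping maps and minimum holding voltages.

## Worked example

The shipped `reference_disc` fixture describes a receiver disc with a
13-turn, 22 mm/10 mm planar coil (4.6 µH), a measured 35 pF parasitic tank
capacitance and a 450 pF capacitor across the coil:

```r
library(depspin)

# What capacitor moves a bare 12.5 MHz tank down to 3.37 MHz?
required_added_capacitance(4.6e-6, 35e-12, 3.37e6)
#> [1] 4.498670e-10        # ~450 pF

case <- load_case(depspin_example("polystyrene_beads"))
report <- run_design(case, resolution = 96, t_max = 150, wash_periods = 3)
report
#> Design report for 'polystyrene_beads'
#>   C_electrode  19.8 pF   C_coil  12 pF   C_parasitic  35 pF
#>   C_total  22.1 nF   recommended C_add  22 nF
#>   bare resonance  12.5 MHz   tank resonance  499 kHz   sweep peak  497 kHz
#>   receiver voltage at drive  13.8 Vpp  (peak  13.9 Vpp )
#>   Re[K] at drive  0.6277   crossover  1.29 MHz
#>   trap check:  trapped
```

Reading the report: the bead disc's tank is tuned with a 22.1 nF capacitor
so it resonates at the 500 kHz drive (`recommended C_add` confirms that
choice); the 20 Vpp source then delivers 13.8 Vpp to the electrodes through
the coil link. At 500 kHz the beads sit below their 1.29 MHz crossover, so
`Re[K] = 0.63 > 0` — positive DEP, attraction to electrode edges — and the
trap check finds the reference particle held at an edge against the
1000 RPM centrifugal wash. Re-running with `v_pp = 0` in
`trapping_map()` washes every start position: the on/off contrast of a
spin-with-field versus spin-without-field experiment.

The same layers are available directly: `sweep_receiver_voltage()`,
`fit_coupling_and_loss()`, `cm_spectrum()`, `solve_unit_cell()`,
`simulate_trajectory()`, `minimum_holding_voltage()`. A thin command-line
front end ships in `inst/cli/depspin` (subcommands `design-resonance`,
`sweep`, `cm-spectrum`, `trap-check`, `run-all`, `make-fixture`).

See `vignettes/depspin-methods.Rmd` for the models, assumptions and
numerical choices.

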