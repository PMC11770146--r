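---
title: "Models and numerical methods behind depspin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods behind depspin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depspin)
```

depspin models dielectrophoretic (DEP) particle manipulation on electrodes
etched into an ordinary printed circuit board, powered wirelessly through a
resonant inductive link, on a spinning (lab-on-a-disc) platform.  The
package covers four coupled layers — the receiver resonant circuit, the
dielectric response of the suspended particles, the electric field of the
electrode array, and the particle transport that decides whether DEP
trapping survives the centrifugal wash.  This vignette records the models,
their assumptions, and the numerical choices, in enough detail that a user
can judge what a passing test suite does and does not demonstrate about a
real device.

## The receiver tank and the inductive link

The receiver disc carries a planar spiral coil closed by the capacitance of
its own structures.  The total capacitance is the sum of three terms:
the interdigitated electrode array, treated as parallel plates facing each
other across the inter-finger gap,
$C_{electrode} = n \cdot 2\varepsilon h l / d_{electrode}$; the two copper
planes of the coil facing each other through the board,
$C_{coil} = \varepsilon \pi (r_{outer}^2 - r_{inner}^2) / d_{coil}$; and an
optional surface-mount capacitor $C_{add}$.  The tank resonates at
$f = 1/(2\pi\sqrt{LC})$.  These are first-order estimates: fringing fields,
the trace-to-trace capacitance within a layer, and connector parasitics are
all neglected, which is why `receiver_tank()` accepts a measured parasitic
override.  In practice the override is obtained by inverting the resonance
formula on a measured peak (`capacitance_from_resonance()`), which for the
reference device (4.6 µH coil, bare peak at 12.5 MHz) gives 35 pF; adding
the 450 pF capacitor the same device carries moves the predicted resonance
to 3.37 MHz, consistent with its measured peak of about 3.5 MHz.

A note on the reference coil inductance: the fixture stores 4.6 µH.  This
is the value consistent with the 12.5 MHz bare resonance and a 35 pF tank
(4.6 mH would put the bare resonance three orders of magnitude lower), and
planar spiral coils of 13 turns at this diameter measure in the
single-digit µH range.  Users supply their own measured inductance in SI
units and it is taken at face value; the package deliberately does not
predict inductance from geometry, because the stacking of turns across the
two copper layers is a fabrication detail the geometric description does
not capture.

The frequency sweep solves the two-mesh phasor circuit per frequency: the
source (amplitude $V_{pp}/2$ behind its output resistance) drives the
transmitter coil $(R_1, L_1)$; the receiver mesh is the coil $(R_2, L_2)$
in series with the total tank capacitance, coupled through
$j\omega M$ with $M = k\sqrt{L_1 L_2}$.  The electrode voltage is the
capacitor voltage.  This is the simplest topology that reproduces a single
receiver-voltage peak; the electrodes are a purely capacitive load, i.e.
the conductive loading by the sample is not modelled, and the transmitter
amplitude droop that a real amplifier shows at high frequency is
represented only through the source resistance.  All voltages in and out
are peak-to-peak, matching how bench instruments report them.

The coupling coefficient $k$ and the receiver coil resistance of an
assembled device are rarely known, so `fit_coupling_and_loss()` recovers
both from a measured receiver-voltage curve by bounded Levenberg–Marquardt
least squares.  The error surface in $(k, R)$ develops local minima for
sharply resonant curves; the fit therefore starts from every point of a
coarse log-spaced $6 \times 6$ grid and then polishes the best result with
a profile scan in $R$.  On noise-free synthetic curves this recovers both
parameters to machine precision; on measured curves the residual norm
reported with the fit is the honest measure of model adequacy.

## Dielectric response of the particles

Particles are homogeneous dielectric spheres with complex permittivity
$\varepsilon^*(f) = \varepsilon_r\varepsilon_0 - j\sigma/(2\pi f)$ in a
homogeneous medium, giving the Clausius–Mossotti factor
$K(f) = (\varepsilon_p^* - \varepsilon_m^*)/(\varepsilon_p^* +
2\varepsilon_m^*)$ and the time-averaged DEP force
$F_{DEP} = 2\pi r^3 \varepsilon_m \mathrm{Re}[K(f)] \nabla|E|^2$.  For this
model $\mathrm{Re}[K]$ is a single-relaxation spectrum bounded in
$[-0.5, 1]$, monotone between its conductivity-dominated low-frequency
plateau and its permittivity-dominated high-frequency plateau, with at most
one crossover; `crossover_frequency()` locates it by bisection after a
log-spaced sign scan.

No shell model is implemented.  This matters for interpreting the two
shipped particle fixtures:

* **Polystyrene beads.** Bulk polystyrene ($\varepsilon_r = 2.55$,
  $\sigma \approx 0$) in water is negative-DEP at every frequency.  Real
  micron-scale beads in low-conductivity water show positive DEP at low
  frequency because surface conductance dominates; the fixture represents
  this with an effective homogeneous $\sigma_p = 8\times10^{-3}$ S/m
  (surface conductance $K_s \approx 10$ nS on a 2.5 µm radius), which
  places the crossover near 1.3 MHz.  The bead-trapping demonstrations
  therefore run at 500 kHz, inside the model's positive-DEP band.  A bench
  device driving beads at several MHz can trap them for reasons (surface
  conduction fine structure, pearl-chaining) this homogeneous model does
  not capture — the package's trap/wash contrast is a qualitative
  reproduction, not a quantitative prediction at the bench frequency.
* **Yeast.** The fixture's $\varepsilon_r = 60$, $\sigma = 0.2$ S/m are
  effective placeholder values chosen to reproduce the sign of the
  observed behaviour (strong positive DEP in deionised water at 3.5 MHz,
  cells collecting at electrode edges); they are not measured properties,
  and only sign/qualitative conclusions should be drawn from them.

## The electrode unit cell field

One period of the interdigitated array (a $+V_{pp}/4$ finger, a gap, a
$-V_{pp}/4$ finger, a gap) is solved as a 2-D Laplace problem
$\nabla^2\phi = 0$: Dirichlet electrodes on the floor, insulating gaps and
top wall (homogeneous Neumann), periodic lateral boundaries.  The ±$V_{pp}/4$
convention makes the differential peak-to-peak electrode voltage equal the
stated $V_{pp}$; the solved field is the amplitude field and the DEP force
uses it directly, so the usual RMS factor of the time average is absorbed
into the force-calibration convention rather than carried separately.
Assumptions: translational invariance along the fingers (finger length of
millimetres against gaps of ~125 µm), flat electrodes (35 µm copper against
the 125 µm gap — the step geometry at the copper edge is not resolved), and
a homogeneous medium (a uniform permittivity rescales energy, not the shape
of the solution; electrode polarisation and double layers are neglected).
The channel height above the fingers defaults to 100 µm and is
configurable; field strength decays exponentially away from the floor with
the array period as length scale, so this choice matters for trapping
predictions.

Numerics: 5-point finite differences, assembled sparse and solved by a
direct factorisation (Matrix package); the relative residual is checked
against $10^{-8}$ and is in practice at rounding level.  $E$, $|E|^2$ and
$\nabla|E|^2$ follow by central differences (one-sided at walls), and
`field_at()` interpolates bilinearly with exact values at nodes.  The field
at an electrode edge is genuinely singular ($|E| \sim r^{-1/2}$ at the
mixed Dirichlet/Neumann corner), so nodal values adjacent to the edge grow
without bound under refinement — that is the physics that concentrates
particles at edges, not a solver defect.  Convergence is therefore
verified on fixed interior lines (changes under 2% between 128 and 256
nodes per period), and the default resolution of 128 resolves the 75/125
µm geometry with ~3 µm cells.

## Particle transport and trap classification

Micron beads in water at these forces have Reynolds and Stokes numbers far
below one, so the dynamics are overdamped: $v = F/(6\pi\mu r)$ with the
net force the sum of the DEP term (interpolated from the field map) and
the centrifugal body force $(4/3)\pi r^3(\rho_p - \rho_m)\omega^2 R$
directed along the unit cell's lateral axis (fingers perpendicular to the
disc radius; orientation configurable).  The AC period at hundreds of kHz
is far below the transport timescale, so only the time-averaged DEP force
enters.  Sedimentation normal to the disc is ignored: particles are
assumed to have settled to the electrode plane, which is where trapping is
decided.  Defaults: 2.5 µm radius, $\rho_p = 1050$, $\rho_m = 1000$
kg/m³, $\mu = 10^{-3}$ Pa·s — standard polystyrene-in-water constants.

Integration is explicit Euler with an adaptive cap: no step may move the
particle more than half a grid cell, which keeps the scheme stable in the
steep near-edge field without a global small step.  Outcomes:

* **trapped** — either the windowed mean speed (time-averaged position
  over 0.25 s windows) falls below 0.1 µm/s within 1.5 grid cells of an
  electrode edge, or the discrete trajectory is pinned at an edge in a
  limit cycle around the field maximum (detected as path length far
  exceeding net displacement, a criterion independent of the step size);
* **washed** — cumulative lateral drift exceeds a set number of unit-cell
  periods (default 5; the demonstrations use 2–3 to shorten runs);
* **undecided** — neither within the time horizon.

With the drive off, the trajectory reduces to the closed-form terminal
drift $v = (2/9)\Delta\rho\,\omega^2 R\, r^2/\mu$, which the simulator
reproduces to rounding error — the oracle for the drag/centrifugal
balance.  Because $F_{DEP} \propto V^2$ and $F_c \propto \omega^2 R$,
`minimum_holding_voltage()` rescales a single field solve rather than
re-solving per voltage, and its bisection result scales as
$\sqrt{\omega^2 R}$ (verified at 2% bisection tolerance).  The absolute
trap-speed threshold breaks this scaling only marginally, at voltages
within the bisection tolerance of the transition.

The disc-radial position of the electrode region defaults to 25 mm.  It
is not a measured value; together with the placeholder dielectric
constants this is why the trap demonstrations are qualitative (on/off
contrast, monotonicity in voltage, scaling laws) rather than quantitative
capture predictions.

## Configuration, fixtures and reproducibility

Design cases are YAML files with SI values and unit-suffixed keys
(`inductance_h`, `gap_m`, ...); unknown sections or keys are rejected and
every validation message names the offending field path.  YAML was chosen
over other config formats because it is the R-native choice with a
first-class parser.  `make_fixture()` writes the three named presets and,
with `name = "random"`, seeded randomized cases drawn from documented
physical ranges (coil inductances 1–10 µH, resistances 0.5–10 Ω, gaps
50–250 µm, coupling 0.05–0.5, medium conductivities $10^{-5}$–$10^{-2}$
S/m) for property testing; generation is byte-reproducible for a given
seed.  `run_design()` executes the whole chain — capacitance estimates,
resonance, capacitor recommendation (targeting the drive frequency), sweep,
Clausius–Mossotti factor at the drive, field solve at the transferred
receiver voltage, trap check — and aborts with the stage name on any
failure.  Reports are deterministic for a given configuration and seed and
carry an MD5 hash of the configuration.

Problem sizes in the shipped tests and in `scripts/acceptance.R` were
chosen to exercise each claim at the scale where its behaviour is
established: sweeps of 201–1001 frequencies, 20 random calibration
recoveries, $10^4$ random material pairs for the Clausius–Mossotti bounds,
field solves at 128 nodes per period (64 for trajectory-heavy runs), and
trap maps of 9 lattice starts over the unit cell.

## Known limitations

* No shell models for cells; yeast parameters are effective placeholders.
* No sample conductivity loading of the tank, no amplifier model beyond a
  source resistance.
* 2-D field only; copper thickness folded into a flat boundary.
* No particle–particle interactions: the pearl chains that form at edges
  in real experiments are outside the model, as are electrothermal and
  AC-electroosmotic flows, Coriolis forces, and channel flow.
* The trap classification depends on configurable thresholds; its
  defaults were set from the physics (speed scale far below the drift
  speed, capture radius of order the cell size) and are not fitted to any
  measurement.
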