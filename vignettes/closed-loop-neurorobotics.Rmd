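---
title: "Closed-loop neurorobotics with neuroloop: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop neurorobotics with neuroloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroloop)
```

`neuroloop` couples a spiking neural network to a simulated robot in a
closed perception–action loop. This vignette is the package's own account
of the models it implements, the parameters that matter, the places where
the design was genuinely open and what was decided there, and what the
packaged experiments do and do not demonstrate.

## The synchronization model

Two simulations advance side by side: a 2D kinematic world and a spiking
network. The closed-loop engine (CLE) steps both by the same fixed
timestep `cle_dt` (default 20 ms, a typical camera-rate control period;
the network subdivides it into `neural_dt` = 1 ms inner steps, the
conventional point-neuron resolution). After both have completed a step,
every registered *transfer function* (TF) runs against frozen snapshots of
the world's topics and the network's devices. TF outputs — device settings,
actuator commands, monitor records — are buffered and applied at the start
of the *next* step.

This buffering is the engine's core contract: **information produced by
one simulation during step n is first observable by the other simulation
during step n + 1**. It makes "parallel" execution well defined without
threads (the two step functions are called sequentially, but neither can
see the other's in-step output), and it makes whole runs bit-reproducible.
The impulse-probe tests assert the contract in both directions. A
consequence worth knowing: halving `cle_dt` changes trajectories unless TF
outputs happen to be step-constant, because commands land one (shorter)
step later. That is inherent to fixed-step co-simulation, not a defect.

Determinism is managed by deriving one RNG stream per stochastic component
(the network's Poisson generators, each stateful TF) from the master seed
by hashing the component's name, so adding a monitor TF cannot perturb a
trajectory.

The simulation lifecycle is a fixed state machine: `created` →
`initialized` → `started` ⇄ `paused` → `stopped`, with `fail` → `halted`
legal from every state and re-initialization allowed from the two terminal
states. Illegal transitions raise; nothing is silently ignored. Reset is
parametrized by target — robot pose, brain state, environment (screen
contents) — restoring only the selected parts. Simulated time and monitor
logs deliberately survive a reset: preserving them keeps an interactively
edited experiment auditable end to end.

## The spiking core

Neurons are leaky integrate-and-fire with exponential-decay current
synapses:

$$\tau_m \dot v = -(v - v_{rest}) + R_m I(t), \qquad
  \tau_s \dot I_{syn} = -I_{syn},$$

where a presynaptic spike adds its weight (nA) to $I_{syn}$
instantaneously. Integration is exponential-Euler per state variable,
holding inputs constant across each step — exact for DC drive, which is why
the closed-form tests (first spike at $\tau_m \ln 2$ under half-threshold
current, steady state $v_{rest} + R_m I$) hold to machine precision at the
grid points. Threshold crossing resets $v$ and starts an absolute
refractory period; delays are rounded up to whole steps and handled by a
ring-buffer event queue.

Defaults (`lif_params()`): $\tau_m$ 20 ms, $v_{rest} = v_{reset}$ −70 mV,
$v_{thresh}$ −55 mV, $\tau_{refrac}$ 2 ms, $\tau_s$ 5 ms, $R_m$ 10 MΩ —
ordinary cortical-model values. Nothing in the packaged experiments
depends on them being biologically exact; what matters is the resulting
rate dynamics, which the behavioral tests pin down.

One numerical caveat is documented by the dense-timestep test: *first*
spike times converge to a dt/100 reference within one coarse step, but
k-th spike times of a periodically firing neuron do not, because the
per-interspike-interval quantization error (up to one step) accumulates
linearly. Any fixed-step threshold model behaves this way; tests that
compare long spike trains across timesteps would be testing the
quantization, not the model.

Five device kinds connect TFs to the network: Poisson spike generators and
DC current generators on the input side; spike recorders, population-rate
recorders (trailing-window spikes / (window × population size)), and leaky
integrators on the output side. The leaky integrator is itself a
non-spiking membrane (threshold disabled, default τ 10 ms in isolation; the
Braitenberg config uses 20 ms) kicked by a fixed voltage per source spike —
a linear readout, as the superposition test verifies.

## The world

The robot base is a differential-drive unicycle (the four-wheeled original
only ever receives left/right wheel speeds, so the extra wheels carry no
information). Pose integration uses the closed-form arc solution rather
than Euler, so two steps of dt compose exactly to one step of 2dt — a
property the engine's determinism tests lean on. The camera is an
equiangular horizontal raycaster: each pixel column is a ray in the field
of view (default 90°, 64×64), colored by the nearest intersected screen
with a vertical fill given by the screen's apparent height; screens are
oriented segments with physical width and height and can display a solid
color or a circle-on-background pattern (the tracking target). Arms are
planar revolute chains advanced kinematically under joint limits. There
are no dynamics, contacts, or occlusion-free guarantees beyond
nearest-hit; that is out of scope by design.

Actuator commands travel over a publish/subscribe topic bus with
latest-value semantics and take effect at the next world step, mirroring
the CLE's one-step contract at the world boundary.

Timed events (screen color/pattern changes) are quantized to CLE step
boundaries: an event at time *t* fires at the first boundary whose
simulated time reaches *t*, in declaration order on ties, exactly once
across pause/resume. Quantization trades the original asynchronous
event machinery for determinism, which the packaged experiments need more.

## Transfer functions

A TF declares its kind (`robot2neuron`, `neuron2robot`, `robot2robot`,
`robot2monitor`, `neuron2monitor`), its topic subscriptions/publications,
and its devices; registration validates all of it against the loaded brain
and world before the simulation can start (monitor TFs cannot touch
devices or actuators; robot2robot TFs cannot touch devices at all). Bodies
are pure functions of their bound snapshot except for an explicit per-TF
state object — needed by the babbling controller and the retina chain.
Evaluation order is registration order; because outputs are buffered and
never visible within the step, permuting non-conflicting TFs cannot change
a trajectory (tested). If two TFs write one shared device, the later
registration wins and a warning is logged.

The packaged TF library implements the red-detection pipeline: a pixel is
"red" iff R ≥ 2G, R ≥ 2B and R ≥ 64 (a declared rule — the original names
the operation but no thresholds); per-half red ratios map to three Poisson
rates, `r_max·left`, `r_max·right`, and a "go" channel `r_max·(1 −
max(left, right))` with `r_max` = 2000 Hz. The go channel is a
reconstruction: with two image halves feeding three sensor neurons,
something must drive the search behavior in the absence of red, and a
drive that dies as red appears is the simplest wiring that produces the
documented search-then-approach switch. Wheel commands come from the two
actor leaky integrators: with normalized deflections $u_L, u_R \in [0,1]$
(deflection / 3 mV, clamped), `left = k(uL − β·uR)`, `right = k(uR −
β·uL)`, k = 1 m/s, β = 0.5 — equal deflections drive straight, an
imbalance with $u_R > u_L$ turns counterclockwise (positive heading rate),
matching the documented search direction.

## The Braitenberg brain

Eight neurons: three sensors, three relays, two actors. Sensors receive
the Poisson inputs (input weights 0.6 nA/spike for the red channels,
0.15 nA/spike for go — the go channel is deliberately weaker so it cannot
saturate its pathway and drown the red signal). Each sensor drives its
relay (2 nA); the two red sensors also *inhibit* the go relay (−10 nA), so
any detected red silences the search drive. Relays project crosswise to
the actors (left red ratio → right actor and vice versa, 2 nA), which
steers the robot toward the side showing more red; the go relay drives the
right actor (2 nA), producing counterclockwise rotation in place when
nothing is red. All brain cells use a 5 mV threshold so every stage stays
responsive over the 0–300 Hz range the inputs produce. These weights are
the package's own design, chosen so the printed behavioral contract holds
(search counterclockwise without red; actor rates converge and motion
straightens as red fills the view); no weights exist to copy.

The packaged arena puts two 2 m × 2 m screens 2.5 m from the robot, ±29°
off axis, both blue, with a timed event turning the right one red at
t = 6 s. With the 64×64 camera a centered screen at starting distance
yields per-half red ratios around 0.3 — comfortably above the sensor
threshold — rising toward 1 on approach.

## The retina chain

Each of the two opponent pathways composes five microcircuits per frame
(20 ms): a narrow Gaussian center (σ 1 px) on its own color channel, low-
passed at τ 50 ms; a broad Gaussian surround (σ 4 px) on the *other*
channel; a leaky single compartment integrating center minus surround
(τ 20 ms, gains $g_e$ 1.0, $g_i$ 0.6); a rectifier; and a depressing
short-term-plasticity stage (resource depletion 0.02 per unit output per
ms, recovery τ 500 ms). Pathway 2 is the exact channel mirror of pathway
1, so swapping R and G in the input swaps the outputs — an identity the
tests assert, and with identity nonlinearity and STP disabled the chain
reduces to linear spatio-temporal filtering (superposition holds). The
exact microcircuit wiring of the original opponency model is not published;
this composition is a faithful-but-reconstructed chain and should be read
as such.

The gain asymmetry plus STP produce the opponency sensitization: under
sustained input the pathway adapts, after the *opposite* color it is
recovered, so green appearing where red was evokes a larger response than
green after gray (tested directly). The same adaptation makes the retina
fundamentally a *change* detector: a static scene fades in seconds. That
shapes the tracking controller below.

One horizontal stripe (default row 9 of a 320×17 camera) of both pathway
maps — stacked, pathway 1 then pathway 2, 640 values; stacking was chosen
over interleaving as the layout is otherwise unspecified — is scaled
(gain 6 nA per unit) into per-neuron DC currents for layer 1 of the
readout brain: 2 × 320 current-to-spike converters, then 640 layer-2
integrators, each pooling a 7-neuron window (stride 1, truncated at the
edges, never crossing the pathway boundary) — 1,280 neurons in all. The
640+640 split and the truncated windows are declared reconstructions
around the published totals (1,280 neurons, fan-in 7, 320-pixel stripe).
Layer 2 uses a 5 mV threshold so that a handful of active window inputs —
a moving edge — suffices to fire it. The target centroid is the
spike-count-weighted mean pixel position over a trailing 200 ms window
across both pathway blocks, declared absent below a 2-spike floor.

The eye is a single pan joint carrying the camera (bearing and pan
positive toward the right of the image; the world keeps its standard
counterclockwise-positive heading). Because the retina only reports
change, the eye controller holds the last decoded target bearing in base
coordinates and servos the pan toward it (gain 6 /s, saturation 1.5
rad/s) — a saccade-target memory. Without it, the servo stalls as soon as
its own success removes the retinal slip that fed it. With it, step
targets are captured with a small overshoot and a slowly translating
target is pursued with bounded error; both behaviors, like the ≥ 0.9
fixed-eye decoding correlation, are asserted on 6–8 s runs.

## Motor babbling and the forward model

The sensorimotor experiment uses no brain network at all: a stateful
robot-to-robot controller alternates between commanding a random pose
within the joint limits, observing the resulting joints and TCP from the
world (ground-truth forward kinematics), performing one incremental
least-squares update, and probing a held-out random pose to log the
prediction error. One iteration = one update + one evaluation; iteration
0 is the untrained zero map, so its error is the distance from the origin
to the first evaluation TCP.

The estimator is linear least squares on the tensor basis
$\bigotimes_j (1, \cos\theta_j, \sin\theta_j)$ — 27 features for three
joints — with sufficient statistics accumulated per sample and a $10^{-9}$
ridge for definiteness before the basis is covered. The original work used
a Bézier-map learner that is not printed anywhere usable; this basis was
chosen instead because planar revolute-chain FK lies *exactly* in its span
(expand the cosines of cumulative angles by angle addition), so the
experiment's semantics — babble, evaluate, watch the error collapse — are
preserved while the fit provably reaches machine precision once ~27
samples in general position have arrived. That is strictly stronger than
the published 1 cm at iteration 40, and the acceptance suite measures the
published form (mean error at iteration 40 over 10 seeds ≤ 1 cm).

## Problem sizes and what the tests show

The packaged runs are deliberately desk-scale: Braitenberg 10–24 s of
simulated time (500–1,200 closed-loop steps, 8 neurons), tracking 6–8 s
(1,280 neurons, ~6,000–8,000 neural steps), sensorimotor 41 iterations
(~84 steps) per seed. These sizes make every behavioral claim in the test
suite reproducible in seconds while exercising the full loop; nothing in
the implementation caps them, and longer runs only cost linear time.

The synthetic world emulates the *structure* of the original experiments —
colored screens, a moving circle target, kinematic bodies — not their
visual richness: there is no lighting, texture, sensor noise, or contact
physics. Passing tests therefore demonstrate the correctness of the
coupling machinery, the neural and retinal dynamics, and the controllers
under clean conditions; they do not certify robustness to real-camera
noise or 3D dynamics. Behavioral thresholds (final distance 0.5 m, search
displacement 0.2 m, 2° capture, 0.9 correlation) are this artifact's own
acceptance constants for qualitative published behaviors, since the
original figures are not tabulated anywhere.

## Degenerate inputs and tie-breaks

Empty brain descriptions build a zero-neuron network whose step is a
no-op; an all-zero spike-count window decodes to "absent" rather than a
centroid; an absent centroid commands zero pan velocity (hold); odd image
widths assign the center column to the left half in red detection;
simultaneous timed events fire in declaration order; duplicate TF names
replace in place, keeping evaluation position; projection delays round up
to whole neural steps with a one-step minimum. TF exceptions, non-finite
neural state, and event actions on missing entities all route through the
lifecycle to `halted` with a diagnostic, never a partial step.
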