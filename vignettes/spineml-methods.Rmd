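---
title: "Declared dynamics, executable semantics: methods behind the spineml engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Declared dynamics, executable semantics: methods behind the spineml engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineml)
```

## The model class

A SpineML component is a hybrid dynamical system. Within each *regime* a
set of state variables evolves under declared time derivatives; variables
without a derivative in the active regime are held constant (this is how a
refractory period is expressed: a regime with no derivative for the
membrane potential). Three kinds of transition connect regimes:

* **OnCondition** — a boolean trigger over state, parameters, received
  analogue values and the reserved simulation time `t`;
* **OnEvent** — fired by an instantaneous, valueless message (a spike);
* **OnImpulse** — fired by an event carrying a value (e.g. a synaptic
  weight). Inside the handler the delivered value is bound to the name of
  the receiving port, so `I_Syn = I_Syn + impulse_in` accumulates an
  impulse arriving on port `impulse_in`.

Any transition may assign state variables (simultaneously: every
right-hand side sees pre-assignment values), emit events or impulses, and
switch regime. Ports are the only communication surface. Analogue ports
carry a value every step; an analogue *reduce* port sums any number of
incoming signals (only summation is defined; the field is kept in the
schema should other operators ever be wanted). An analogue *send* port
must share its name with the parameter, state variable or alias whose
value it exposes — that convention is what makes "log port `v`" and
"connect `v` to `v_pre`" well defined, and the validator enforces it.

Networks instantiate components. A projection's synapse expands to one
weight-update instance per generated connection and one post-synapse
instance per destination neuron, joined in the chain
pre-neuron → weight update (events) → post-synapse (impulses) →
destination neuron (analogue, usually into a reduce port), with an
optional feedback edge from the destination neuron back to the weight
update. The low-level layer (groups plus generic inputs) connects
arbitrary sets port-to-port and is strictly additive: a model using only
populations and projections elaborates identically whether or not
low-level support is considered.

## The expression language

The dialect leaves the `MathInline` grammar open, so this implementation
fixes one: C-style arithmetic (`+ - * /`, unary minus, parentheses),
comparisons (`> < >= <= == !=`), boolean connectives (`&& || !`) and the
function set `exp`, `log`, `ln`, `sin`, `cos`, `sqrt`, `pow`, `fabs` —
the function vocabulary shared by the related component-description
languages this dialect descends from. `log` and `ln` are both natural
logarithms. Precedence and associativity follow C. Boolean operators are
legal only where a truth value is expected (triggers); the validator
rejects them inside time derivatives. Parse trees serialise to a
canonical text (minimal parentheses, original numeric lexemes), and
`parse(serialize(parse(s)))` is the structural identity — the property
the XML round-trip tests lean on.

## Elaboration and determinism

Elaboration expands every component set into per-instance numeric vectors.
Properties not set in the network layer default to 0; a partial value
list sets the listed instances and leaves the rest at 0. All instance
indices visible to a user (value lists, connection lists, log files) are
0-based. Distributions are parameterised as declared in the schema —
note that `NormalDistribution` takes a **variance**, not a standard
deviation — and `PoissonDistribution` draws integer counts with the given
mean. Fixed-probability connectivity samples every ordered source/target
pair independently; self-connections are allowed when a set projects to
itself. Every stochastic element (distribution draw, connectivity draw,
Poisson input) either carries its own seed in the XML or receives one
derived deterministically from the elaboration seed, so a fixed seed
yields a bitwise-identical flat model and, downstream, bitwise-identical
logs. Generated benchmark files embed explicit seeds, making the files
alone a complete description.

## The step semantics

The reference engine advances all instances synchronously with a fixed
step `dt`, executing five phases in a fixed order (the dialect itself
does not prescribe one, so this engine's order is part of its contract):

1. **analogue propagation** — receive ports are filled from send-port
   values computed at the end of the previous step; reduce ports sum all
   arrivals and read zero with none; experiment current inputs are added;
2. **integration** — the active regime's derivatives, evaluated at the
   step's start time with receive-port values held constant, advance the
   state by forward Euler or classical RK4;
3. **delivery** — due events and impulses fire their handlers; several
   impulses reaching one instance in the same step are applied
   sequentially, so no increment is lost;
4. **conditions** — triggers are evaluated on the post-integration state
   at the end-of-step time; per instance, the first true trigger in
   document order fires (at most one regime transition per instance per
   step — document order is the tie-break, and it is deliberate that this
   is a stated convention rather than an ambient ambiguity);
5. **logging** — the clock advances and post-step values are recorded.

A message emitted in step *k* with delay *d* is delivered during phase 3
of step `floor((t_emit + d)/dt + 0.5)` with `t_emit = (k+1)·dt`: delays
round to the nearest multiple of `dt`, and zero-delay messages arrive in
the next step. Delivering strictly in the *next* step avoids any
within-step ordering ambiguity between senders and receivers, at the cost
of one step of latency per chain stage — with `dt = 0.1` ms, a spike
influences its post-synaptic target after two steps (0.2 ms), which is
within the delay resolution anyone running at that step size has already
accepted. Analogue edges have zero latency within phase 1 but read
previous-step send values (a synchronous-update contract), so the result
does not depend on the order in which sets are processed.

Numeric failures (a non-finite state value after integration) abort the
run naming the instance set, variable and time; division by zero and
domain errors inside the slow-path expression evaluator name the
offending subexpression.

## Integrators

Forward Euler (`x += dt·f(x, t)`) and classical four-stage RK4 are
implemented; both leave variables without derivatives untouched. On an
exponential relaxation the measured global-error orders are ≈1 and ≈4
(the acceptance script fits the slopes over `dt ∈ {0.2, 0.1, 0.05}` ms
and obtains ≈0.997 and ≈4.003). Triggers are still checked once per step,
so threshold-crossing times are located to `dt` regardless of integrator
— the reason the closed-form LIF period check uses a `2·dt` band.

## The benchmark generator

`benchmark_spec()` encodes the standard excitatory/inhibitory random
network used for cross-simulator benchmarking, in its current-based
(CUBA) form: 4000 leaky integrate-and-fire neurons (80% excitatory),
fixed-probability 0.02 connectivity among all four ordered population
pairs, impulse-incremented exponentially decaying synaptic currents
(`tau_syn` 5 ms excitatory / 10 ms inhibitory), membrane parameters
`tau_m = 20` ms, `v_thresh = -50` mV, `v_reset = -60` mV,
`tau_refractory = 5` ms, and a resting potential of `-49` mV — just above
threshold, so every cell is intrinsically active and network activity is
self-sustaining without external drive, which is what makes the
no-input experiment file meaningful. `c_m = 20` nF makes a synaptic
current of `w` nA contribute `w/20` mV/ms, so the weights
(`+1.62`/`-9` nA) reproduce the voltage-jump convention commonly used for
this benchmark's published parameter sets. Initial membrane potentials
are uniform on `(-60, -50)` mV. The original study's exact weight and
initialisation files are not recoverable, so these values are labelled
configuration, not normative: the package's own checks are structural
(population sizes, derived instance counts), closed-form (single-cell
oracles) and qualitative (sustained, refractory-bounded irregular firing
at a few Hz), none of which depend on matching an exact published trace.

What the generated fixtures do *not* emulate: conductance-based synapses,
distance-dependent connectivity, heterogeneous cell parameters,
plasticity, or the long-tailed in-degree structure of anatomical
circuits. Passing the benchmark smoke test therefore demonstrates that
the declared semantics execute correctly at scale, not that the package
reproduces any particular biological dataset.

## Problem sizes and runtime

The test-suite and acceptance-script sizes are chosen so the full battery
runs in about a minute on a single core while still exercising every code
path at meaningful scale: the full 4000-neuron / ~320 000-connection
benchmark for 1 s at `dt = 0.1` ms (10 000 steps), single-cell oracles
for 0.2–0.3 s at `dt` down to 0.01 ms, connectivity statistics at
3200×3200 over 20 seeds, and determinism checks on a 400-neuron copy of
the benchmark. The engine evaluates compiled expressions over whole
instance vectors, so cost scales with steps × expressions, not with
instances; larger or longer runs scale linearly.

## Known limitations

* The engine is an interpreter; it trades raw speed for fidelity to the
  declared semantics and is intended as a reference, not a
  high-performance simulator.
* Only the `sum` reduce operator is implemented.
* Experiment-layer current inputs target analogue reduce ports (where
  they sum with network traffic); spike sources drive every instance of
  their target set.
* Weight updates with continuous internal dynamics work, but nothing in
  the fixture set exercises learning rules; the feedback port chain is
  elaborated and tested structurally only.
* Distance-based and CSA connectivity are not built in; they are the
  intended use of the connectivity plug-in registry
  (`register_connectivity()`).
* Explicit connection lists are stored as XML or CSV text; no binary
  format is provided.
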