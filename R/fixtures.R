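## Programmatic builders for the worked-example components and networks:
## a leaky integrate-and-fire neuron body with refractory period, a
## fixed-weight update, an exponentially decaying post-synaptic current, a
## gap-junction coupling component, the Vogels-Abbott excitatory/inhibitory
## benchmark network, and a two-neuron gap-junction fixture.

#' Standard component fixtures
#'
#' `make_lif_component()` builds a leaky integrate-and-fire neuron body
#' with two regimes: `integrating` (initial), where
#' `dv/dt = (I_Syn + i_offset)/c_m + (v_rest - v)/tau_m` and crossing
#' `v > v_thresh` resets `v`, records the spike time and emits a `spike`
#' event, and `refractory`, which holds the state until the alias
#' `refractory_end = t_spike + tau_refractory` is passed. The membrane
#' potential `v` is exposed on an analogue send port and synaptic current
#' arrives on the analogue reduce port `I_Syn`.
#'
#' `make_fixed_weight_component()` turns each spike event arriving on
#' `spike_in` into an impulse carrying the synaptic weight `w`.
#'
#' `make_exp_psc_component()` is an exponentially decaying post-synaptic
#' current: `dI_Syn/dt = -I_Syn/tau_syn`, incremented by the value of each
#' impulse arriving on `impulse_in`, with `I_Syn` exposed on an analogue
#' send port.
#'
#' `make_gap_junction_component()` couples two membrane potentials
#' electrically: given analogue inputs `v_pre` and `v_post` and a coupling
#' conductance `g`, it emits the antisymmetric pair of currents
#' `I_pre = g*(v_post - v_pre)` and `I_post = g*(v_pre - v_post)`.
#'
#' @return a `spineml_component` that passes [validate_component()].
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
make_lif_component <- function() {
  component_class(
    name = "LIF", type = "neuron_body",
    parameters = list(
      sp_parameter("c_m", "nF"),
      sp_parameter("tau_m", "ms"),
      sp_parameter("tau_refractory", "ms"),
      sp_parameter("v_thresh", "mV"),
      sp_parameter("v_reset", "mV"),
      sp_parameter("v_rest", "mV"),
      sp_parameter("i_offset", "nA")),
    state_variables = list(
      sp_state_variable("v", "mV"),
      sp_state_variable("t_spike", "ms")),
    aliases = list(
      sp_alias("refractory_end", "t_spike + tau_refractory", "ms")),
    ports = list(
      sp_port("I_Syn", "receive", "analog", reduce_op = "sum",
              dimension = "nA"),
      sp_port("spike", "send", "event"),
      sp_port("v", "send", "analog", dimension = "mV")),
    regimes = list(
      sp_regime("integrating",
        time_derivatives = list(
          v = "(I_Syn + i_offset)/c_m + (v_rest - v)/tau_m"),
        on_conditions = list(on_condition(
          trigger = "v > v_thresh", target_regime = "refractory",
          state_assignments = list(v = "v_reset", t_spike = "t"),
          event_outputs = "spike"))),
      sp_regime("refractory",
        on_conditions = list(on_condition(
          trigger = "t > refractory_end",
          target_regime = "integrating")))),
    initial_regime = "integrating")
}

#' @rdname fixtures
#' @export
make_fixed_weight_component <- function() {
  component_class(
    name = "FixedWeight", type = "weight_update",
    parameters = list(sp_parameter("w", "nA")),
    ports = list(
      sp_port("spike_in", "receive", "event"),
      sp_port("impulse_out", "send", "impulse", dimension = "nA")),
    regimes = list(
      sp_regime("on",
        on_events = list(on_event(
          src_port = "spike_in", target_regime = "on",
          impulse_outputs = list(impulse_out = "w"))))),
    initial_regime = "on")
}

#' @rdname fixtures
#' @export
make_exp_psc_component <- function() {
  component_class(
    name = "ExpPsc", type = "postsynapse",
    parameters = list(sp_parameter("tau_syn", "ms")),
    state_variables = list(sp_state_variable("I_Syn", "nA")),
    ports = list(
      sp_port("impulse_in", "receive", "impulse", dimension = "nA"),
      sp_port("I_Syn", "send", "analog", dimension = "nA")),
    regimes = list(
      sp_regime("decay",
        time_derivatives = list(I_Syn = "-I_Syn/tau_syn"),
        on_impulses = list(on_impulse(
          src_port = "impulse_in", target_regime = "decay",
          state_assignments = list(I_Syn = "I_Syn + impulse_in"))))),
    initial_regime = "decay")
}

#' @rdname fixtures
#' @export
make_gap_junction_component <- function() {
  component_class(
    name = "GapJunction", type = "generic",
    parameters = list(sp_parameter("g", "uS")),
    aliases = list(
      sp_alias("I_pre", "g*(v_post - v_pre)", "nA"),
      sp_alias("I_post", "g*(v_pre - v_post)", "nA")),
    ports = list(
      sp_port("v_pre", "receive", "analog", dimension = "mV"),
      sp_port("v_post", "receive", "analog", dimension = "mV"),
      sp_port("I_pre", "send", "analog", dimension = "nA"),
      sp_port("I_post", "send", "analog", dimension = "nA")),
    regimes = list(sp_regime("on")),
    initial_regime = "on")
}

#' Benchmark specification
#'
#' Parameters of the Vogels-Abbott excitatory/inhibitory network in its
#' current-based (CUBA) form: `n_total` leaky integrate-and-fire neurons
#' split into an excitatory and an inhibitory population, random
#' fixed-probability connectivity among all four population pairs,
#' delta-current synapses shaped by exponentially decaying post-synaptic
#' currents. With the default membrane parameters the resting potential
#' sits just above threshold, so activity is self-sustaining and no
#' external input is required. The numeric defaults are configuration, not
#' normative values.
#'
#' @param n_total total number of neurons.
#' @param exc_fraction fraction of neurons that are excitatory.
#' @param connect_probability connection probability for every ordered
#'   population pair.
#' @param weight_exc,weight_inh synaptic impulse weights (nA).
#' @param delay_ms connection delay (ms).
#' @param v_rest,v_thresh,v_reset membrane potentials (mV).
#' @param tau_m membrane time constant (ms).
#' @param c_m membrane capacitance (nF).
#' @param tau_refractory absolute refractory period (ms).
#' @param tau_syn_exc,tau_syn_inh synaptic decay time constants (ms).
#' @param v_init_min,v_init_max bounds of the uniform initial membrane
#'   potential distribution (mV).
#' @param duration_s,dt_ms simulation length (s) and step (ms).
#' @param seed integer seed from which all connectivity and property seeds
#'   are derived.
#' @return a list of class `spineml_benchmark_spec`.
#' @export
benchmark_spec <- function(n_total = 4000, exc_fraction = 0.8,
                           connect_probability = 0.02,
                           weight_exc = 1.62, weight_inh = -9,
                           delay_ms = 0.1,
                           v_rest = -49, v_thresh = -50, v_reset = -60,
                           tau_m = 20, c_m = 20, tau_refractory = 5,
                           tau_syn_exc = 5, tau_syn_inh = 10,
                           v_init_min = -60, v_init_max = -50,
                           duration_s = 1, dt_ms = 0.1, seed = 1L) {
  stopifnot(exc_fraction > 0, exc_fraction < 1,
            connect_probability >= 0, connect_probability <= 1)
  structure(as.list(environment()), class = "spineml_benchmark_spec")
}

#' Build the Vogels-Abbott benchmark model on disk
#'
#' Writes a complete, self-consistent three-layer model: the component
#' files (`LIF.xml`, `FixedWeight.xml`, `ExpPsc.xml`), the network file
#' (`model.xml`) with an `Excitatory` population of
#' `round(n_total * exc_fraction)` neurons and an `Inhibitory` population
#' of the rest, four fixed-probability projections, and an experiment file
#' (`experiment.xml`) logging the spikes of both populations. All
#' stochastic elements carry explicit seeds derived from `spec$seed`, so
#' the files fully determine the elaborated model.
#'
#' @param spec a [benchmark_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written file paths.
#' @export
build_vogels_abbott <- function(spec = benchmark_spec(), dir) {
  stopifnot(inherits(spec, "spineml_benchmark_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  n_exc <- as.integer(round(spec$n_total * spec$exc_fraction))
  n_inh <- as.integer(spec$n_total - n_exc)

  paths <- list(
    lif = file.path(dir, "LIF.xml"),
    weight = file.path(dir, "FixedWeight.xml"),
    psc = file.path(dir, "ExpPsc.xml"),
    network = file.path(dir, "model.xml"),
    experiment = file.path(dir, "experiment.xml"))
  write_component(make_lif_component(), paths$lif)
  write_component(make_fixed_weight_component(), paths$weight)
  write_component(make_exp_psc_component(), paths$psc)

  lif_props <- function(vseed) list(
    property_spec("c_m", fixed_value(spec$c_m)),
    property_spec("tau_m", fixed_value(spec$tau_m)),
    property_spec("tau_refractory", fixed_value(spec$tau_refractory)),
    property_spec("v_thresh", fixed_value(spec$v_thresh)),
    property_spec("v_reset", fixed_value(spec$v_reset)),
    property_spec("v_rest", fixed_value(spec$v_rest)),
    property_spec("v", uniform_distribution(spec$v_init_min,
                                            spec$v_init_max, seed = vseed)))

  mk_synapse <- function(src, dst, w, tau, cseed) {
    synapse(
      fixed_probability_connection(spec$connect_probability,
                                   delay_ms = spec$delay_ms, seed = cseed),
      weight_update(name = paste0(src, "_to_", dst, "_weight"),
                    url = "FixedWeight.xml",
                    properties = list(property_spec("w", fixed_value(w))),
                    input_src_port = "spike", input_dst_port = "spike_in"),
      post_synapse(name = paste0(src, "_to_", dst, "_psc"),
                   url = "ExpPsc.xml",
                   properties = list(
                     property_spec("tau_syn", fixed_value(tau))),
                   input_src_port = "impulse_out",
                   input_dst_port = "impulse_in",
                   output_src_port = "I_Syn", output_dst_port = "I_Syn"))
  }

  s <- spec$seed
  net <- network_model(populations = list(
    population("Excitatory", "LIF.xml", n_exc,
               properties = lif_props(derive_seed(s, 1L)),
               projections = list(
                 projection("Excitatory", list(mk_synapse(
                   "Exc", "Exc", spec$weight_exc, spec$tau_syn_exc,
                   derive_seed(s, 11L)))),
                 projection("Inhibitory", list(mk_synapse(
                   "Exc", "Inh", spec$weight_exc, spec$tau_syn_exc,
                   derive_seed(s, 12L)))))),
    population("Inhibitory", "LIF.xml", n_inh,
               properties = lif_props(derive_seed(s, 2L)),
               projections = list(
                 projection("Excitatory", list(mk_synapse(
                   "Inh", "Exc", spec$weight_inh, spec$tau_syn_inh,
                   derive_seed(s, 21L)))),
                 projection("Inhibitory", list(mk_synapse(
                   "Inh", "Inh", spec$weight_inh, spec$tau_syn_inh,
                   derive_seed(s, 22L))))))))
  write_network(net, paths$network)

  ex <- experiment(
    model_url = "model.xml", duration_s = spec$duration_s,
    dt_ms = spec$dt_ms, integrator = "forward_euler",
    logs = list(log_output("exc_spikes", "Excitatory", "spike"),
                log_output("inh_spikes", "Inhibitory", "spike")),
    name = "vogels_abbott")
  write_experiment(ex, paths$experiment)
  invisible(paths)
}

#' Build the two-neuron gap-junction fixture
#'
#' A minimal low-level-layer model: two single-neuron populations whose
#' membrane potentials are coupled through a one-instance gap-junction
#' group via four generic inputs (each membrane potential into the
#' junction, each coupling current back into the corresponding neuron's
#' synaptic input).
#'
#' @param g coupling conductance (uS).
#' @param v1,v2 initial membrane potentials of the two neurons (mV).
#' @param v_thresh spike threshold; the default is high enough that the
#'   fixture stays subthreshold.
#' @return list with `network` (a `spineml_network`) and `components`
#'   (named by url, for use as a [resolve_references()] loader).
#' @export
make_gap_junction_fixture <- function(g = 0.05, v1 = -70, v2 = -50,
                                      v_thresh = 1000) {
  lif_props <- function(v0) list(
    property_spec("c_m", fixed_value(20)),
    property_spec("tau_m", fixed_value(20)),
    property_spec("tau_refractory", fixed_value(5)),
    property_spec("v_thresh", fixed_value(v_thresh)),
    property_spec("v_reset", fixed_value(-60)),
    property_spec("v_rest", fixed_value(v0)),
    property_spec("v", fixed_value(v0)))
  net <- network_model(
    populations = list(
      population("n1", "LIF.xml", 1L, properties = lif_props(v1)),
      population("n2", "LIF.xml", 1L, properties = lif_props(v2))),
    groups = list(
      group("gj", "GapJunction.xml", 1L,
            properties = list(property_spec("g", fixed_value(g))))),
    inputs = list(
      generic_input("n1", "gj", "v", "v_pre", one_to_one_connection()),
      generic_input("n2", "gj", "v", "v_post", one_to_one_connection()),
      generic_input("gj", "n1", "I_pre", "I_Syn", one_to_one_connection()),
      generic_input("gj", "n2", "I_post", "I_Syn", one_to_one_connection())))
  list(network = net,
       components = list("LIF.xml" = make_lif_component(),
                         "GapJunction.xml" = make_gap_junction_component()))
}
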