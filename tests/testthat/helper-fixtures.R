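# Shared builders for small test models; everything is constructed in code.

lif_property_set <- function(v0 = -60, v_rest = -60, v_thresh = -50,
                             v_reset = -60, tau_m = 20, c_m = 20,
                             tau_ref = 5) {
  list(
    property_spec("c_m", fixed_value(c_m)),
    property_spec("tau_m", fixed_value(tau_m)),
    property_spec("tau_refractory", fixed_value(tau_ref)),
    property_spec("v_thresh", fixed_value(v_thresh)),
    property_spec("v_reset", fixed_value(v_reset)),
    property_spec("v_rest", fixed_value(v_rest)),
    property_spec("v", fixed_value(v0)))
}

# a one-population LIF model elaborated and ready to simulate
single_lif_flat <- function(size = 1L, ...) {
  net <- network_model(populations = list(
    population("n", "LIF.xml", size, properties = lif_property_set(...))))
  elaborate(resolve_references(net, list("LIF.xml" = make_lif_component())),
            seed = 1L)
}

# pure exponential relaxation towards v_rest; no ports other than the
# logged membrane potential
decay_component <- function() {
  component_class("Decay", "generic",
    parameters = list(sp_parameter("v_rest", "mV"),
                      sp_parameter("tau_m", "ms")),
    state_variables = list(sp_state_variable("v", "mV")),
    ports = list(sp_port("v", "send", "analog", dimension = "mV")),
    regimes = list(sp_regime("on",
      time_derivatives = list(v = "(v_rest - v)/tau_m"))))
}

decay_flat <- function(v0 = -70, v_rest = -50, tau_m = 20) {
  net <- network_model(populations = list(
    population("d", "Decay.xml", 1L, properties = list(
      property_spec("v_rest", fixed_value(v_rest)),
      property_spec("tau_m", fixed_value(tau_m)),
      property_spec("v", fixed_value(v0))))))
  elaborate(resolve_references(net, list("Decay.xml" = decay_component())),
            seed = 1L)
}

# spike source -> fixed-weight update -> exponential PSC chain built with
# the low-level layer (two groups joined by a generic input)
psc_chain_flat <- function(w = 2.5, tau_syn = 10, delay_ms = 0) {
  net <- network_model(
    groups = list(
      group("wu", "FW.xml", 1L,
            properties = list(property_spec("w", fixed_value(w)))),
      group("psc", "PSC.xml", 1L,
            properties = list(property_spec("tau_syn", fixed_value(tau_syn))))),
    inputs = list(generic_input("wu", "psc", "impulse_out", "impulse_in",
                                one_to_one_connection(delay_ms))))
  elaborate(resolve_references(net, list(
    "FW.xml" = make_fixed_weight_component(),
    "PSC.xml" = make_exp_psc_component())), seed = 1L)
}

# two LIF populations joined by a single synapse, for elaboration-count
# and event-conservation checks
two_pop_net <- function(n_src = 2L, n_dst = 2L,
                        connectivity = one_to_one_connection(),
                        w = 1, tau_syn = 5, src_props = lif_property_set(),
                        projections = TRUE) {
  syn <- synapse(connectivity,
    weight_update("wu", "FW.xml",
                  properties = list(property_spec("w", fixed_value(w))),
                  input_src_port = "spike", input_dst_port = "spike_in"),
    post_synapse("psc", "PSC.xml",
                 properties = list(property_spec("tau_syn",
                                                 fixed_value(tau_syn))),
                 input_src_port = "impulse_out",
                 input_dst_port = "impulse_in",
                 output_src_port = "I_Syn", output_dst_port = "I_Syn"))
  network_model(populations = list(
    population("src", "LIF.xml", n_src, properties = src_props,
               projections = if (projections)
                 list(projection("dst", list(syn))) else list()),
    population("dst", "LIF.xml", n_dst, properties = lif_property_set())))
}

two_pop_loader <- function() {
  list("LIF.xml" = make_lif_component(),
       "FW.xml" = make_fixed_weight_component(),
       "PSC.xml" = make_exp_psc_component())
}

# theoretical inter-spike period of a LIF under constant current I
lif_period <- function(I, c_m = 20, tau_m = 20, tau_ref = 5, v_rest = -60,
                       v_thresh = -50, v_reset = -60) {
  v_inf <- v_rest + (I / c_m) * tau_m
  tau_ref + tau_m * log((v_inf - v_reset) / (v_inf - v_thresh))
}
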