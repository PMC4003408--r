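test_that("a LIF at rest with no input is a fixed point", {
  flat <- single_lif_flat(v0 = -60, v_rest = -60)
  e <- experiment("m", 0.05, 0.1, logs = list(
    log_output("v", "n", "v"), log_output("s", "n", "spike")))
  logs <- simulate(flat, e, seed = 1)
  expect_true(all(logs$logs$v$data$value == -60))
  expect_identical(nrow(logs$logs$s$data), 0L)
  expect_identical(nrow(logs$logs$v$data), logs$n_steps)  # one row per step
})

test_that("constant-current LIF reproduces the closed-form period", {
  flat <- single_lif_flat(v0 = -60, v_rest = -60)
  for (dt in c(0.1, 0.05)) {
    e <- experiment("m", 0.4, dt,
      inputs = list(input_constant_current("n", "I_Syn", 15)),
      logs = list(log_output("s", "n", "spike")))
    st <- simulate(flat, e, seed = 1)$logs$s$data
    expect_gt(nrow(st), 5)
    expect_lt(abs(mean(diff(st$t_ms)) - lif_period(15)), 2 * dt)
  }
})

test_that("an impulse drives the documented exponential PSC decay", {
  w <- 2.5; tau <- 10; dt <- 0.1
  flat <- psc_chain_flat(w = w, tau_syn = tau)
  e <- experiment("m", 0.2, dt, integrator = "rk4",
    inputs = list(input_explicit_spike_source("wu", "spike_in", 50)),
    logs = list(log_output("i", "psc", "I_Syn")))
  d <- simulate(flat, e, seed = 1)$logs$i$data
  first <- which(d$value > 0)[1]
  # the impulse lands with the full weight, then decays as w*exp(-dt/tau)
  expect_equal(d$value[first], w)
  sel <- seq(first, nrow(d))
  expected <- w * exp(-(d$t_ms[sel] - d$t_ms[first]) / tau)
  expect_lt(max(abs(d$value[sel] / expected - 1)), 1e-6)
})

test_that("message delivery honours the delay-rounding rule", {
  dt <- 0.1; t0 <- 20
  for (delay in c(0, 0.1, 0.34, 0.75, 2)) {
    flat <- psc_chain_flat(delay_ms = delay)
    e <- experiment("m", 0.05, dt,
      inputs = list(input_explicit_spike_source("wu", "spike_in", t0)),
      logs = list(log_output("i", "psc", "I_Syn"),
                  log_output("imp", "wu", "impulse_out")))
    logs <- simulate(flat, e, seed = 1)
    # the weight update fires in the step after the spike lands
    t_emit <- logs$logs$imp$data$t_ms[1]
    expect_equal(t_emit, (floor(t0 / dt + 0.5) + 1) * dt)
    # its impulse is delivered during step floor((t_emit + d)/dt + 0.5),
    # so the increment is first visible in that step's log row
    d <- logs$logs$i$data
    first <- which(d$value > 0)[1]
    expect_equal(d$t_ms[first],
                 (floor((t_emit + delay) / dt + 0.5) + 1) * dt,
                 info = paste("delay", delay))
  }
})

test_that("reduce ports sum their arrivals and zero-fill without any", {
  # k identical constant sources all feed one reduce port
  src <- component_class("Const", "generic",
    parameters = list(sp_parameter("c", "nA")),
    aliases = list(sp_alias("out", "c + 0*t", "nA")),
    ports = list(sp_port("out", "send", "analog", dimension = "nA")),
    regimes = list(sp_regime("on")))
  sink <- component_class("Sink", "generic",
    aliases = list(sp_alias("total", "I + 0*t", "nA")),
    ports = list(sp_port("I", "receive", "analog", reduce_op = "sum",
                         dimension = "nA"),
                 sp_port("total", "send", "analog", dimension = "nA")),
    regimes = list(sp_regime("on")))
  for (k in c(1L, 3L, 5L)) {
    net <- network_model(
      groups = list(group("s", "C.xml", k, properties = list(
                      property_spec("c", fixed_value(0.7)))),
                    group("r", "S.xml", 1L)),
      inputs = list(generic_input("s", "r", "out", "I",
                                  all_to_all_connection())))
    flat <- elaborate(resolve_references(net, list("C.xml" = src,
                                                   "S.xml" = sink)), 1)
    e <- experiment("m", 0.005, 0.1,
                    logs = list(log_output("tot", "r", "total")))
    vals <- simulate(flat, e, seed = 1)$logs$tot$data$value
    expect_equal(vals, rep(k * 0.7, length(vals)), info = paste("k =", k))
  }
  # no arrivals: the port reads zero
  net <- network_model(groups = list(group("r", "S.xml", 1L)))
  flat <- elaborate(resolve_references(net, list("S.xml" = sink)), 1)
  e <- experiment("m", 0.005, 0.1,
                  logs = list(log_output("tot", "r", "total")))
  expect_true(all(simulate(flat, e, seed = 1)$logs$tot$data$value == 0))
})

test_that("a fired trigger switches the regime before the next derivative", {
  # after the spike the refractory regime has no derivative for v, so the
  # logged trace must sit exactly at v_reset for the whole refractory gap
  flat <- single_lif_flat(v0 = -60, v_rest = -60, v_reset = -58)
  e <- experiment("m", 0.1, 0.1,
    inputs = list(input_constant_current("n", "I_Syn", 15)),
    logs = list(log_output("v", "n", "v"), log_output("s", "n", "spike")))
  logs <- simulate(flat, e, seed = 1)
  v <- logs$logs$v$data
  t_spk <- logs$logs$s$data$t_ms[1]
  held <- v$value[v$t_ms >= t_spk & v$t_ms <= t_spk + 5]
  expect_true(all(held == -58))
})

test_that("refractoriness bounds every inter-spike interval", {
  flat <- single_lif_flat(size = 5L, v0 = -52, v_rest = -60)
  e <- experiment("m", 0.3, 0.1,
    inputs = list(input_constant_current("n", "I_Syn", 25)),
    logs = list(log_output("s", "n", "spike")))
  st <- simulate(flat, e, seed = 1)$logs$s$data
  ss <- spike_stats(st, 300, n_instances = 5)
  expect_gt(length(ss$pooled_isis), 0)
  expect_true(all(ss$pooled_isis >= 5))
})

test_that("every emitted event is delivered exactly once", {
  # one-to-one synapse: each pre spike emitted before the horizon yields
  # exactly one weight-update impulse emission
  net <- two_pop_net(3L, 3L,
                     src_props = lif_property_set(v0 = -55, v_rest = -45))
  flat <- elaborate(resolve_references(net, two_pop_loader()), seed = 1)
  e <- experiment("m", 0.2, 0.1, logs = list(
    log_output("pre", "src", "spike"),
    log_output("imp", "wu", "impulse_out")))
  logs <- simulate(flat, e, seed = 1)
  pre <- logs$logs$pre$data
  imp <- logs$logs$imp$data
  horizon <- (logs$n_steps - 1) * 0.1  # spikes later than this are in flight
  expect_gt(nrow(pre), 0)
  expect_identical(nrow(imp), sum(pre$t_ms <= horizon + 1e-9))
})

test_that("several impulses reaching one instance in a step all apply", {
  # two sources spiking in the same step, fanning into one PSC instance
  net <- two_pop_net(2L, 1L, connectivity = all_to_all_connection(),
                     w = 1.5, tau_syn = 1e6,
                     src_props = lif_property_set(v0 = -51, v_rest = -45))
  flat <- elaborate(resolve_references(net, two_pop_loader()), seed = 1)
  e <- experiment("m", 0.01, 0.1, logs = list(
    log_output("pre", "src", "spike"), log_output("i", "psc", "I_Syn")))
  logs <- simulate(flat, e, seed = 1)
  expect_identical(nrow(logs$logs$pre$data), 2L)  # both fire in step one
  i <- logs$logs$i$data
  expect_equal(max(i$value), 2 * 1.5)             # both impulses landed
})

test_that("identical seeds give bitwise-identical logs", {
  net <- two_pop_net(10L, 10L,
                     connectivity = fixed_probability_connection(0.5),
                     src_props = lif_property_set(v0 = -52, v_rest = -45))
  res <- resolve_references(net, two_pop_loader())
  run <- function(seed) {
    flat <- elaborate(res, seed = seed)
    e <- experiment("m", 0.2, 0.1, inputs = list(
      input_poisson_spike_source("wu", "spike_in", 20)),
      logs = list(log_output("s", "dst", "spike"),
                  log_output("v", "dst", "v")))
    simulate(flat, e, seed = seed)
  }
  expect_identical(run(11L), run(11L))
  # and a different seed changes the (stochastic) model
  expect_false(identical(run(11L), run(12L)))
})

test_that("integrator steps match their definitions", {
  # f = 0 leaves the state untouched under both methods
  for (m in c("forward_euler", "rk4"))
    expect_equal(integrator_step(list(v = parse_expression("0")),
                                 list(v = 3), 0, 0.1, m)$v, 3)
  # one Euler step of dv/dt = 1
  expect_equal(integrator_step(list(v = parse_expression("1")),
                               list(v = 0), 0, 0.1, "forward_euler")$v, 0.1)
  # one RK4 step of dv/dt = -v/tau is the 4th-order Taylor polynomial
  h <- 0.5; tau <- 2
  got <- integrator_step(list(v = parse_expression("-v/tau")),
                         list(v = 1, tau = tau), 0, h, "rk4")$v
  x <- -h / tau
  expect_equal(got, 1 + x + x^2 / 2 + x^3 / 6 + x^4 / 24, tolerance = 1e-12)
})

test_that("global error scales at the integrator's order", {
  flat <- decay_flat()
  v_exact <- -50 + (-70 + 50) * exp(-100 / 20)
  err <- function(dt, method) {
    e <- experiment("m", 0.1, dt, integrator = method,
                    logs = list(log_output("v", "d", "v")))
    d <- simulate(flat, e, seed = 1)$logs$v$data
    abs(d$value[nrow(d)] - v_exact)
  }
  dts <- c(0.4, 0.2, 0.1)
  sl <- function(method) {
    es <- vapply(dts, err, 0, method = method)
    unname(stats::coef(stats::lm(log(es) ~ log(dts)))[2])
  }
  expect_lt(abs(sl("forward_euler") - 1), 0.3)
  expect_lt(abs(sl("rk4") - 4), 0.3)
})

test_that("time-varying current inputs follow their step function", {
  flat <- decay_flat(v0 = 0, v_rest = 0, tau_m = 1e9)
  # reuse the decay component: a current into a fresh reduce port is not
  # available here, so drive the gap-junction sink instead
  sink <- component_class("Sink", "generic",
    aliases = list(sp_alias("y", "I + 0*t", "nA")),
    ports = list(sp_port("I", "receive", "analog", reduce_op = "sum",
                         dimension = "nA"),
                 sp_port("y", "send", "analog", dimension = "nA")),
    regimes = list(sp_regime("on")))
  net <- network_model(groups = list(group("r", "S.xml", 1L)))
  flat <- elaborate(resolve_references(net, list("S.xml" = sink)), 1)
  e <- experiment("m", 0.02, 1, inputs = list(
    input_time_varying_current("r", "I", c(0, 5, 10), c(1, 3, 0))),
    logs = list(log_output("y", "r", "y")))
  d <- simulate(flat, e, seed = 1)$logs$y$data
  expect_equal(d$value[d$t_ms %in% c(1, 5)], c(1, 1))
  expect_equal(d$value[d$t_ms %in% c(6, 10)], c(3, 3))
  expect_equal(d$value[d$t_ms %in% c(11, 20)], c(0, 0))
})

test_that("numeric blow-ups abort with instance context", {
  bad <- component_class("Blow", "generic",
    state_variables = list(sp_state_variable("x", "none")),
    regimes = list(sp_regime("on",
      time_derivatives = list(x = "x*x"))))
  net <- network_model(groups = list(group("b", "B.xml", 1L,
    properties = list(property_spec("x", fixed_value(1))))))
  flat <- elaborate(resolve_references(net, list("B.xml" = bad)), 1)
  e <- experiment("m", 1, 1, logs = list())
  expect_error(simulate(flat, e, seed = 1),
               class = "spineml_numeric_error", regexp = "\"x\".*\"b\"")
})

test_that("logs can be written as CSV in the documented layout", {
  flat <- single_lif_flat()
  e <- experiment("m", 0.005, 0.1,
    inputs = list(input_constant_current("n", "I_Syn", 15)),
    logs = list(log_output("vm", "n", "v"), log_output("spk", "n", "spike")))
  logs <- simulate(flat, e, seed = 1)
  dir <- withr::local_tempdir()
  paths <- write_logs(logs, dir)
  expect_setequal(basename(paths), c("vm.csv", "spk.csv"))
  expect_identical(readLines(file.path(dir, "vm.csv"), n = 1),
                   "t_ms,index,value")
  expect_identical(readLines(file.path(dir, "spk.csv"), n = 1), "t_ms,index")
})
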