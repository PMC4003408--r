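test_that("the LIF worked example parses to the expected structure", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_component(make_lif_component(), path)
  lif <- read_component(path)
  expect_length(lif$regimes, 2L)
  expect_setequal(vapply(lif$regimes, `[[`, "", "name"),
                  c("integrating", "refractory"))
  expect_identical(lif$initial_regime, "integrating")
  expect_identical(nrow(validate_component(lif)), 0L)
  # the refractory regime holds its state: no time derivatives
  refr <- Filter(function(r) r$name == "refractory", lif$regimes)[[1]]
  expect_length(refr$time_derivatives, 0L)
  # the synaptic input is an analogue reduce port, the spike an event port
  isyn <- Filter(function(p) p$name == "I_Syn", lif$ports)[[1]]
  expect_identical(isyn$reduce_op, "sum")
  spk <- Filter(function(p) p$name == "spike", lif$ports)[[1]]
  expect_identical(spk$mode, "event")
})

test_that("comparison operators are entity-escaped in the XML text", {
  txt <- as.character(write_component(make_lif_component()))
  expect_match(txt, "v &gt; v_thresh", fixed = TRUE)
  expect_no_match(txt, "v > v_thresh", fixed = TRUE)
})

test_that("read/write round-trip is the identity on all fixtures", {
  fixtures <- list(make_lif_component(), make_fixed_weight_component(),
                   make_exp_psc_component(), make_gap_junction_component())
  for (cc in fixtures) {
    expect_identical(nrow(validate_component(cc)), 0L, info = cc$name)
    expect_identical(read_component(write_component(cc)), cc, info = cc$name)
  }
  # a minimal class: one parameter, one empty regime, no aliases or ports
  minimal <- component_class("Minimal",
    parameters = list(sp_parameter("p", "none")),
    regimes = list(sp_regime("only")))
  expect_identical(read_component(write_component(minimal)), minimal)
  txt <- as.character(write_component(minimal))
  expect_no_match(txt, "Alias", fixed = TRUE)
})

test_that("validation flags unresolved symbols", {
  bad <- component_class("Bad",
    state_variables = list(sp_state_variable("v", "mV")),
    regimes = list(sp_regime("on",
      on_conditions = list(on_condition("v > foo", "on")))))
  d <- validate_component(bad)
  expect_identical(sum(d$rule == "unresolved-symbol"), 1L)
  expect_match(d$message[d$rule == "unresolved-symbol"], "foo")
})

test_that("validation flags initial-regime violations", {
  two_init <- component_class("TwoInit",
    regimes = list(sp_regime("a"), sp_regime("b")),
    initial_regime = c("a", "b"))
  expect_identical(sum(validate_component(two_init)$rule ==
                       "multiple-initial"), 1L)
  none <- component_class("NoInit", regimes = list(sp_regime("a")))
  none$initial_regime <- NULL
  expect_identical(sum(validate_component(none)$rule == "initial-regime"), 1L)
})

test_that("validation covers dimensions, cycles, names and booleans", {
  d <- validate_component(component_class("BadDim",
    parameters = list(sp_parameter("p", "furlong")),
    regimes = list(sp_regime("on"))))
  expect_identical(sum(d$rule == "unknown-dimension"), 1L)

  d <- validate_component(component_class("Cycle",
    aliases = list(sp_alias("a", "b + 1"), sp_alias("b", "a + 1")),
    regimes = list(sp_regime("on"))))
  expect_identical(sum(d$rule == "alias-cycle"), 1L)

  d <- validate_component(component_class("Dup",
    parameters = list(sp_parameter("x"), sp_parameter("x")),
    regimes = list(sp_regime("on"))))
  expect_identical(sum(d$rule == "duplicate-name"), 1L)

  d <- validate_component(component_class("BoolDeriv",
    state_variables = list(sp_state_variable("v", "mV")),
    regimes = list(sp_regime("on",
      time_derivatives = list(v = "v > 0")))))
  expect_identical(sum(d$rule == "boolean-in-derivative"), 1L)

  d <- validate_component(component_class("BadReduce",
    state_variables = list(sp_state_variable("v", "mV")),
    ports = list(sp_port("v", "send", "analog", reduce_op = "sum",
                         dimension = "mV")),
    regimes = list(sp_regime("on"))))
  expect_identical(sum(d$rule == "reduce-op-placement"), 1L)

  d <- validate_component(component_class("BadTarget",
    state_variables = list(sp_state_variable("v", "mV")),
    regimes = list(sp_regime("on",
      on_conditions = list(on_condition("v > 0", "elsewhere"))))))
  expect_identical(sum(d$rule == "unknown-target-regime"), 1L)
})

test_that("structural violations in XML raise schema errors with a path", {
  no_dyn <- "<ComponentClass name='X'><Parameter name='p'/></ComponentClass>"
  expect_error(read_component(no_dyn), class = "spineml_schema_error",
               regexp = "Dynamics")
  unknown <- paste0("<ComponentClass name='X'><Bogus/>",
                    "<Dynamics><Regime name='a' initial='true'/></Dynamics>",
                    "</ComponentClass>")
  err <- tryCatch(read_component(unknown), error = identity)
  expect_s3_class(err, "spineml_schema_error")
  expect_match(conditionMessage(err), "Bogus")
  expect_match(conditionMessage(err), "/")  # an element path is included
})

test_that("writing an invalid component is refused with diagnostics", {
  bad <- component_class("Bad",
    state_variables = list(sp_state_variable("v", "mV")),
    regimes = list(sp_regime("on",
      on_conditions = list(on_condition("v > foo", "on")))))
  expect_error(write_component(bad), class = "spineml_validation_error")
})
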