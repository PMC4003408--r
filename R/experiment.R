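## Experiment layer: simulation settings, external input drivers and log
## requests. Time conventions: duration in seconds, dt and spike times in
## milliseconds.

#' Experiment input drivers and log requests
#'
#' Inputs drive a named port of every instance of a target component set:
#' a constant current, a piecewise-constant time-varying current (the value
#' at time t is the last specified value at or before t), a Poisson spike
#' source (an independent train per target instance) or an explicit list of
#' spike times. Current inputs target analogue receive ports (summed with
#' network traffic on reduce ports); spike sources target event receive
#' ports.
#'
#' @param target component-set name.
#' @param port port name on the target's component.
#' @return an input driver or log request object.
#' @name experiment-inputs
NULL

#' @rdname experiment-inputs
#' @param value current value.
#' @export
input_constant_current <- function(target, port, value) {
  structure(list(kind = "constant_current", target = target, port = port,
                 value = as.numeric(value)),
            class = "spineml_input")
}

#' @rdname experiment-inputs
#' @param times_ms,values step-function knots: `values[i]` applies from
#'   `times_ms[i]` (inclusive) until the next knot.
#' @export
input_time_varying_current <- function(target, port, times_ms, values) {
  stopifnot(length(times_ms) == length(values), !is.unsorted(times_ms))
  structure(list(kind = "time_varying_current", target = target, port = port,
                 times_ms = as.numeric(times_ms), values = as.numeric(values)),
            class = "spineml_input")
}

#' @rdname experiment-inputs
#' @param rate_hz mean rate of each independent Poisson train.
#' @param seed optional integer seed.
#' @export
input_poisson_spike_source <- function(target, port, rate_hz, seed = NULL) {
  structure(list(kind = "poisson_spike_source", target = target, port = port,
                 rate_hz = as.numeric(rate_hz),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "spineml_input")
}

#' @rdname experiment-inputs
#' @export
input_explicit_spike_source <- function(target, port, times_ms) {
  structure(list(kind = "explicit_spike_source", target = target, port = port,
                 times_ms = as.numeric(times_ms)),
            class = "spineml_input")
}

#' @rdname experiment-inputs
#' @param name log (file) name, unique within the experiment.
#' @export
log_output <- function(name, target, port) {
  structure(list(name = name, target = target, port = port),
            class = "spineml_log_request")
}

#' Construct an experiment
#'
#' @param model_url network-layer file the experiment simulates (resolved
#'   relative to the experiment file's directory by [run_experiment()]).
#' @param duration_s simulated duration in seconds.
#' @param dt_ms integration step in milliseconds.
#' @param integrator `"forward_euler"` or `"rk4"` (classical fourth-order
#'   Runge-Kutta).
#' @param inputs list of input drivers.
#' @param logs list of [log_output()] requests.
#' @param name experiment name.
#' @param simulator simulator-name hint carried through the XML; this
#'   reference engine parses and ignores it.
#' @return object of class `spineml_experiment`.
#' @export
experiment <- function(model_url, duration_s, dt_ms,
                       integrator = c("forward_euler", "rk4"),
                       inputs = list(), logs = list(),
                       name = "experiment", simulator = "reference") {
  integrator <- match.arg(integrator)
  structure(list(name = name, model_url = model_url,
                 duration_s = as.numeric(duration_s),
                 dt_ms = as.numeric(dt_ms), integrator = integrator,
                 simulator = simulator, inputs = inputs, logs = logs),
            class = "spineml_experiment")
}

#' @export
print.spineml_experiment <- function(x, ...) {
  cat(sprintf("<Experiment \"%s\": %gs at dt=%gms (%s), %d input(s), %d log(s)>\n",
              x$name, x$duration_s, x$dt_ms, x$integrator,
              length(x$inputs), length(x$logs)))
  invisible(x)
}

n_steps_of <- function(e) {
  as.integer(ceiling(e$duration_s * 1000 / e$dt_ms - 1e-9))
}

#' Read an experiment from XML
#'
#' @param x path, XML string or `xml_document`.
#' @return a `spineml_experiment`. Unknown integrator names raise a
#'   `spineml_schema_error`; numeric invariants (positive duration and dt)
#'   are reported by [validate_experiment()] instead.
#' @export
read_experiment <- function(x) {
  root <- xml2::xml_root(xml_doc_of(x))
  if (xml2::xml_name(root) == "SpineML")
    root <- xml2::xml_find_first(root, "./Experiment")
  if (inherits(root, "xml_missing") || xml2::xml_name(root) != "Experiment")
    stop_spineml("document does not contain an Experiment element",
                 "spineml_schema_error")
  name <- xml2::xml_attr(root, "name")
  if (is.na(name)) name <- "experiment"
  model <- xml2::xml_find_first(root, "./Model")
  if (inherits(model, "xml_missing"))
    schema_stop(root, "missing Model element")
  sim <- xml2::xml_find_first(root, "./Simulation")
  if (inherits(sim, "xml_missing"))
    schema_stop(root, "missing Simulation element")
  integ <- xml2::xml_attr(sim, "integration_method")
  if (is.na(integ)) integ <- "forward_euler"
  if (!integ %in% c("forward_euler", "rk4"))
    schema_stop(sim, sprintf("unknown integration method \"%s\"", integ))
  simulator <- xml2::xml_attr(sim, "simulator")
  if (is.na(simulator)) simulator <- "reference"

  inputs <- list(); logs <- list()
  for (ch in xml2::xml_children(root)) {
    nm <- xml2::xml_name(ch)
    if (nm %in% c("Model", "Simulation")) next
    if (nm == "LogOutput") {
      logs[[length(logs) + 1L]] <- log_output(
        req_attr(ch, "name"), req_attr(ch, "target"), req_attr(ch, "port"))
    } else if (nm == "ConstantInput") {
      inputs[[length(inputs) + 1L]] <- input_constant_current(
        req_attr(ch, "target"), req_attr(ch, "port"), num_attr(ch, "value"))
    } else if (nm == "TimeVaryingInput") {
      pts <- xml2::xml_find_all(ch, "./TimePointValue")
      inputs[[length(inputs) + 1L]] <- input_time_varying_current(
        req_attr(ch, "target"), req_attr(ch, "port"),
        as.numeric(xml2::xml_attr(pts, "time")),
        as.numeric(xml2::xml_attr(pts, "value")))
    } else if (nm == "PoissonSpikeInput") {
      inputs[[length(inputs) + 1L]] <- input_poisson_spike_source(
        req_attr(ch, "target"), req_attr(ch, "port"), num_attr(ch, "rate"),
        int_attr_or_null(ch, "seed"))
    } else if (nm == "ExplicitSpikeInput") {
      st <- xml2::xml_find_all(ch, "./SpikeTime")
      inputs[[length(inputs) + 1L]] <- input_explicit_spike_source(
        req_attr(ch, "target"), req_attr(ch, "port"),
        as.numeric(xml2::xml_attr(st, "time")))
    } else {
      schema_stop(ch, sprintf("unknown element \"%s\" in Experiment", nm))
    }
  }
  experiment(model_url = req_attr(model, "network_layer_url"),
             duration_s = num_attr(sim, "duration"),
             dt_ms = num_attr(sim, "dt"), integrator = integ,
             inputs = inputs, logs = logs, name = name,
             simulator = simulator)
}

#' Write an experiment to XML
#'
#' @param e a `spineml_experiment`.
#' @param path optional file path.
#' @return the `xml_document`, invisibly when `path` is given.
#' @export
write_experiment <- function(e, path = NULL) {
  stopifnot(inherits(e, "spineml_experiment"))
  doc <- xml2::xml_new_root("SpineML")
  ex <- xml2::xml_add_child(doc, "Experiment", name = e$name)
  xml2::xml_add_child(ex, "Model", network_layer_url = e$model_url)
  xml2::xml_add_child(ex, "Simulation", simulator = e$simulator,
                      duration = fmt_num(e$duration_s),
                      dt = fmt_num(e$dt_ms),
                      integration_method = e$integrator)
  for (inp in e$inputs) {
    if (inp$kind == "constant_current") {
      xml2::xml_add_child(ex, "ConstantInput", target = inp$target,
                          port = inp$port, value = fmt_num(inp$value))
    } else if (inp$kind == "time_varying_current") {
      nd <- xml2::xml_add_child(ex, "TimeVaryingInput", target = inp$target,
                                port = inp$port)
      for (i in seq_along(inp$times_ms))
        xml2::xml_add_child(nd, "TimePointValue",
                            time = fmt_num(inp$times_ms[i]),
                            value = fmt_num(inp$values[i]))
    } else if (inp$kind == "poisson_spike_source") {
      nd <- xml2::xml_add_child(ex, "PoissonSpikeInput", target = inp$target,
                                port = inp$port, rate = fmt_num(inp$rate_hz))
      if (!is.null(inp$seed)) xml2::xml_set_attr(nd, "seed", inp$seed)
    } else if (inp$kind == "explicit_spike_source") {
      nd <- xml2::xml_add_child(ex, "ExplicitSpikeInput", target = inp$target,
                                port = inp$port)
      for (tm in inp$times_ms)
        xml2::xml_add_child(nd, "SpikeTime", time = fmt_num(tm))
    }
  }
  for (lg in e$logs)
    xml2::xml_add_child(ex, "LogOutput", name = lg$name, target = lg$target,
                        port = lg$port)
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Validate an experiment
#'
#' Checks the experiment's numeric invariants (positive duration and step,
#' at least one step, non-negative rates, unique log names) and, when a
#' flat model is supplied, that every input and log target resolves to a
#' component set and a port of a compatible mode.
#'
#' @param e a `spineml_experiment`.
#' @param flat optional `spineml_flat` model to resolve targets against.
#' @return a diagnostics data frame (zero rows when valid).
#' @export
validate_experiment <- function(e, flat = NULL) {
  d <- diag_frame()
  if (!is.finite(e$duration_s) || e$duration_s <= 0)
    d <- diag_bind(d, diag_row("invalid-duration", "Simulation",
      "simulation duration must be > 0"))
  if (!is.finite(e$dt_ms) || e$dt_ms <= 0)
    d <- diag_bind(d, diag_row("invalid-dt", "Simulation",
      "integration step dt must be > 0"))
  else if (is.finite(e$duration_s) && e$duration_s > 0 && n_steps_of(e) < 1L)
    d <- diag_bind(d, diag_row("invalid-steps", "Simulation",
      "duration/dt must allow at least one step"))
  lognames <- vapply(e$logs, `[[`, "", "name")
  if (anyDuplicated(lognames))
    d <- diag_bind(d, diag_row("duplicate-log-name", "LogOutput",
      "log names must be unique"))
  for (inp in e$inputs)
    if (inp$kind == "poisson_spike_source" &&
        (!is.finite(inp$rate_hz) || inp$rate_hz < 0))
      d <- diag_bind(d, diag_row("invalid-rate",
        paste0("Input[", inp$target, ".", inp$port, "]"),
        "Poisson rate must be >= 0"))
  if (is.null(flat)) return(d)

  port_of <- function(target, port, where) {
    s <- flat$sets[[target]]
    if (is.null(s)) {
      d <<- diag_bind(d, diag_row("unknown-target", where,
        sprintf("no component set named \"%s\"", target)))
      return(NULL)
    }
    p <- comp_find_port(s$component, port)
    if (is.null(p))
      d <<- diag_bind(d, diag_row("unknown-port", where,
        sprintf("component set \"%s\" has no port \"%s\"", target, port)))
    p
  }
  for (inp in e$inputs) {
    where <- paste0("Input[", inp$target, ".", inp$port, "]")
    p <- port_of(inp$target, inp$port, where)
    if (is.null(p)) next
    if (inp$kind %in% c("constant_current", "time_varying_current")) {
      if (!(p$direction == "receive" && p$mode == "analog"))
        d <- diag_bind(d, diag_row("input-mode-mismatch", where,
          "current inputs must target an analogue receive port"))
    } else {
      if (!(p$direction == "receive" && p$mode == "event"))
        d <- diag_bind(d, diag_row("input-mode-mismatch", where,
          "spike sources must target an event receive port"))
    }
  }
  for (lg in e$logs) {
    where <- paste0("LogOutput[", lg$name, "]")
    p <- port_of(lg$target, lg$port, where)
    if (is.null(p)) next
    if (p$direction != "send")
      d <- diag_bind(d, diag_row("log-not-send-port", where,
        sprintf("logged port \"%s\" is not a send port", lg$port)))
  }
  d
}

## Resolved mode ("analog" or "event") of each log request: analogue send
## ports log values each step, event and impulse send ports log emission
## times.
log_modes <- function(e, flat) {
  vapply(e$logs, function(lg) {
    p <- comp_find_port(flat$sets[[lg$target]]$component, lg$port)
    if (p$mode == "analog") "analog" else "event"
  }, "")
}
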