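## Component layer: ComponentClass definitions.
##
## A ComponentClass is a hybrid dynamical unit: read-only parameters,
## state variables driven by per-regime time derivatives, aliases (named
## expressions over parameters/states/other aliases), ports for
## analogue/event/impulse communication, and regimes linked by transitions
## (OnCondition triggers, OnEvent and OnImpulse handlers).

as_spineml_expr <- function(x) {
  if (inherits(x, "spineml_expr")) x else parse_expression(x)
}

#' Component building blocks
#'
#' Constructors for the pieces of a [component_class()]: parameters, state
#' variables, aliases, ports, regimes and regime transitions. Expressions
#' may be given as strings (parsed with [parse_expression()]) or as
#' `spineml_expr` objects.
#'
#' @param name element name (a valid identifier).
#' @param dimension SI unit string, one of `spineml_si_units` (e.g. `"mV"`,
#'   `"ms"`, `"nA"`, or `"none"`).
#' @return a list with the corresponding class attribute.
#' @name component-parts
NULL

#' @rdname component-parts
#' @export
sp_parameter <- function(name, dimension = "none") {
  structure(list(name = name, dimension = dimension),
            class = "spineml_parameter")
}

#' @rdname component-parts
#' @export
sp_state_variable <- function(name, dimension = "none") {
  structure(list(name = name, dimension = dimension),
            class = "spineml_state_variable")
}

#' @rdname component-parts
#' @param expression alias body.
#' @export
sp_alias <- function(name, expression, dimension = "none") {
  structure(list(name = name, dimension = dimension,
                 expression = as_spineml_expr(expression)),
            class = "spineml_alias")
}

#' @rdname component-parts
#' @param direction `"send"` or `"receive"`.
#' @param mode `"analog"`, `"event"` or `"impulse"`.
#' @param reduce_op reduce operator for analogue receive ports that combine
#'   several incoming signals; only `"sum"` is defined.
#' @export
sp_port <- function(name, direction = c("send", "receive"),
                    mode = c("analog", "event", "impulse"),
                    reduce_op = NULL, dimension = "none") {
  structure(list(name = name, direction = match.arg(direction),
                 mode = match.arg(mode), reduce_op = reduce_op,
                 dimension = dimension),
            class = "spineml_port")
}

#' @rdname component-parts
#' @param trigger boolean expression fired when it first becomes true.
#' @param target_regime name of the regime entered by the transition.
#' @param state_assignments named list `variable -> expression` applied
#'   simultaneously (right-hand sides see pre-assignment values).
#' @param event_outputs character vector of event send port names to emit on.
#' @param impulse_outputs named list `port -> expression` giving the value
#'   carried by each emitted impulse.
#' @export
on_condition <- function(trigger, target_regime, state_assignments = list(),
                         event_outputs = character(),
                         impulse_outputs = list()) {
  structure(list(trigger = as_spineml_expr(trigger),
                 target_regime = target_regime,
                 state_assignments = lapply(state_assignments, as_spineml_expr),
                 event_outputs = as.character(event_outputs),
                 impulse_outputs = lapply(impulse_outputs, as_spineml_expr)),
            class = "spineml_on_condition")
}

#' @rdname component-parts
#' @param src_port name of the event receive port that fires the handler.
#' @export
on_event <- function(src_port, target_regime, state_assignments = list(),
                     event_outputs = character(), impulse_outputs = list()) {
  structure(list(src_port = src_port, target_regime = target_regime,
                 state_assignments = lapply(state_assignments, as_spineml_expr),
                 event_outputs = as.character(event_outputs),
                 impulse_outputs = lapply(impulse_outputs, as_spineml_expr)),
            class = "spineml_on_event")
}

#' @rdname component-parts
#' @export
#' @details In `on_impulse` handlers the delivered impulse value is bound to
#'   the name of the receiving port, so e.g. an impulse arriving on port
#'   `I_in` can be accumulated with the assignment `I_Syn = I_Syn + I_in`.
on_impulse <- function(src_port, target_regime, state_assignments = list(),
                       event_outputs = character(), impulse_outputs = list()) {
  structure(list(src_port = src_port, target_regime = target_regime,
                 state_assignments = lapply(state_assignments, as_spineml_expr),
                 event_outputs = as.character(event_outputs),
                 impulse_outputs = lapply(impulse_outputs, as_spineml_expr)),
            class = "spineml_on_impulse")
}

#' @rdname component-parts
#' @param time_derivatives named list `state variable -> expression` giving
#'   d(variable)/dt while the regime is active; variables without a
#'   derivative are held constant.
#' @param on_conditions,on_events,on_impulses lists of transitions.
#' @export
sp_regime <- function(name, time_derivatives = list(), on_conditions = list(),
                      on_events = list(), on_impulses = list()) {
  structure(list(name = name,
                 time_derivatives = lapply(time_derivatives, as_spineml_expr),
                 on_conditions = on_conditions,
                 on_events = on_events,
                 on_impulses = on_impulses),
            class = "spineml_regime")
}

#' Construct a ComponentClass
#'
#' @param name class name.
#' @param type optional role hint: `"neuron_body"`, `"weight_update"`,
#'   `"postsynapse"` or `"generic"`. The role a component actually plays is
#'   determined by where the network layer instantiates it; the hint is
#'   carried through the XML but not required.
#' @param parameters,state_variables,aliases,ports,regimes lists built with
#'   the [component-parts] constructors.
#' @param initial_regime name of the initial regime.
#' @return object of class `spineml_component`.
#' @seealso [read_component()], [write_component()], [validate_component()],
#'   [make_lif_component()]
#' @export
component_class <- function(name, type = "generic", parameters = list(),
                            state_variables = list(), aliases = list(),
                            ports = list(), regimes = list(),
                            initial_regime = NULL) {
  if (is.null(initial_regime) && length(regimes) > 0L)
    initial_regime <- regimes[[1]]$name
  structure(list(name = name, type = type, parameters = parameters,
                 state_variables = state_variables, aliases = aliases,
                 ports = ports, regimes = regimes,
                 initial_regime = initial_regime),
            class = "spineml_component")
}

#' @export
print.spineml_component <- function(x, ...) {
  cat(sprintf("<ComponentClass \"%s\" (%s)>\n", x$name, x$type))
  cat(sprintf("  %d parameter(s), %d state variable(s), %d alias(es), %d port(s)\n",
              length(x$parameters), length(x$state_variables),
              length(x$aliases), length(x$ports)))
  cat(sprintf("  regimes: %s (initial: %s)\n",
              paste(vapply(x$regimes, `[[`, "", "name"), collapse = ", "),
              x$initial_regime %||% "<none>"))
  invisible(x)
}

comp_param_names <- function(c) vapply(c$parameters, `[[`, "", "name")
comp_state_names <- function(c) vapply(c$state_variables, `[[`, "", "name")
comp_alias_names <- function(c) vapply(c$aliases, `[[`, "", "name")
comp_port_names <- function(c) vapply(c$ports, `[[`, "", "name")

comp_find_port <- function(c, name) {
  for (p in c$ports) if (p$name == name) return(p)
  NULL
}

## Symbols visible inside a component's expressions: parameters, state
## variables, aliases, receive-port values, and the reserved simulation
## time symbol t.
comp_scope <- function(c) {
  recv <- vapply(Filter(function(p) p$direction == "receive" &&
                          p$mode == "analog", c$ports), `[[`, "", "name")
  c(comp_param_names(c), comp_state_names(c), comp_alias_names(c),
    recv, "t")
}

#' Validate a ComponentClass
#'
#' Checks the structural invariants of a component definition: a single
#' initial regime, unique names, resolvable symbols in every expression,
#' acyclic alias definitions, valid SI dimension strings, well-formed ports
#' and transitions, and real-valued (non-boolean) time derivatives.
#'
#' @param c a `spineml_component`.
#' @return a diagnostics data frame (zero rows if the component is valid)
#'   with columns `rule`, `element`, `message`, `severity`.
#' @export
validate_component <- function(c) {
  d <- diag_frame()
  here <- function(sub) paste0("ComponentClass[", c$name, "]/", sub)

  ## regimes and the initial marker
  rnames <- vapply(c$regimes, `[[`, "", "name")
  if (length(c$regimes) == 0L)
    d <- diag_bind(d, diag_row("no-regime", here("Dynamics"),
                               "a component must declare at least one regime"))
  if (anyDuplicated(rnames))
    d <- diag_bind(d, diag_row("duplicate-regime", here("Dynamics"),
                               "regime names must be unique"))
  if (length(c$initial_regime) > 1L) {
    d <- diag_bind(d, diag_row("multiple-initial", here("Dynamics"),
      sprintf("%d regimes are marked initial; exactly one is required",
              length(c$initial_regime))))
  } else if (length(c$regimes) > 0L) {
    n_init <- if (is.null(c$initial_regime)) 0L
              else sum(rnames == c$initial_regime)
    if (n_init != 1L)
      d <- diag_bind(d, diag_row("initial-regime", here("Dynamics"),
        "exactly one regime must be marked initial"))
  }

  ## name uniqueness: value symbols (parameters, state variables, aliases)
  ## form one namespace; port names another. An analogue send port must
  ## reuse the name of the symbol it exposes; any other port colliding
  ## with a value symbol would shadow it.
  val_names <- c(comp_param_names(c), comp_state_names(c),
                 comp_alias_names(c))
  for (nm in unique(val_names[duplicated(val_names)]))
    d <- diag_bind(d, diag_row("duplicate-name", here(nm),
      sprintf("name \"%s\" is used more than once", nm)))
  pnames <- comp_port_names(c)
  for (nm in unique(pnames[duplicated(pnames)]))
    d <- diag_bind(d, diag_row("duplicate-name", here(nm),
      sprintf("port name \"%s\" is used more than once", nm)))
  for (p in c$ports)
    if (!(p$direction == "send" && p$mode == "analog") &&
        p$name %in% val_names)
      d <- diag_bind(d, diag_row("duplicate-name", here(p$name),
        sprintf("port \"%s\" collides with a declared value symbol", p$name)))

  ## dimensions
  for (p in c(c$parameters, c$state_variables, c$aliases, c$ports)) {
    if (p$mode %||% "analog" == "event") next  # event ports carry no value
    if (!is_valid_dimension(p$dimension))
      d <- diag_bind(d, diag_row("unknown-dimension", here(p$name),
        sprintf("dimension \"%s\" is not in the SI unit table", p$dimension)))
  }

  ## ports
  for (p in c$ports) {
    if (!is.null(p$reduce_op)) {
      if (!(p$direction == "receive" && p$mode == "analog"))
        d <- diag_bind(d, diag_row("reduce-op-placement", here(p$name),
          "reduce_op is only valid on analogue receive ports"))
      else if (!identical(p$reduce_op, "sum"))
        d <- diag_bind(d, diag_row("unknown-reduce-op", here(p$name),
          sprintf("unsupported reduce operator \"%s\"", p$reduce_op)))
    }
    if (p$direction == "send" && p$mode == "analog" &&
        !(p$name %in% c(comp_param_names(c), comp_state_names(c),
                        comp_alias_names(c))))
      d <- diag_bind(d, diag_row("unresolved-send-port", here(p$name),
        "an analogue send port must share its name with a parameter, state variable or alias"))
  }

  scope <- comp_scope(c)
  states <- comp_state_names(c)
  check_expr <- function(e, where, extra = character()) {
    miss <- setdiff(free_symbols(e), c(scope, extra))
    for (nm in miss)
      d <<- diag_bind(d, diag_row("unresolved-symbol", where,
        sprintf("symbol \"%s\" in \"%s\" does not resolve", nm, e$source)))
  }

  ## aliases: resolvable and acyclic
  anames <- comp_alias_names(c)
  deps <- list()
  for (a in c$aliases) {
    check_expr(a$expression, here(paste0("Alias[", a$name, "]")))
    deps[[a$name]] <- intersect(free_symbols(a$expression), anames)
  }
  if (length(deps) > 0L) {
    order_ok <- character(0)
    remaining <- names(deps)
    repeat {
      ready <- remaining[vapply(remaining, function(nm)
        all(deps[[nm]] %in% order_ok), TRUE)]
      if (length(ready) == 0L) break
      order_ok <- c(order_ok, ready)
      remaining <- setdiff(remaining, ready)
    }
    if (length(remaining) > 0L)
      d <- diag_bind(d, diag_row("alias-cycle", here("Dynamics"),
        sprintf("alias definitions form a cycle: %s",
                paste(remaining, collapse = ", "))))
  }

  check_transition_body <- function(tr, where, extra = character()) {
    for (v in names(tr$state_assignments)) {
      if (!(v %in% states))
        d <<- diag_bind(d, diag_row("assign-non-state", where,
          sprintf("state assignment targets \"%s\", which is not a state variable", v)))
      check_expr(tr$state_assignments[[v]], where, extra)
    }
    for (pn in tr$event_outputs) {
      p <- comp_find_port(c, pn)
      if (is.null(p) || p$direction != "send" || p$mode != "event")
        d <<- diag_bind(d, diag_row("bad-event-output", where,
          sprintf("EventOut names \"%s\", which is not an event send port", pn)))
    }
    for (pn in names(tr$impulse_outputs)) {
      p <- comp_find_port(c, pn)
      if (is.null(p) || p$direction != "send" || p$mode != "impulse")
        d <<- diag_bind(d, diag_row("bad-impulse-output", where,
          sprintf("ImpulseOut names \"%s\", which is not an impulse send port", pn)))
      check_expr(tr$impulse_outputs[[pn]], where, extra)
    }
    if (!(tr$target_regime %in% rnames))
      d <<- diag_bind(d, diag_row("unknown-target-regime", where,
        sprintf("target regime \"%s\" does not exist", tr$target_regime)))
  }

  for (r in c$regimes) {
    rwhere <- here(paste0("Regime[", r$name, "]"))
    tdv <- names(r$time_derivatives)
    if (anyDuplicated(tdv))
      d <- diag_bind(d, diag_row("duplicate-derivative", rwhere,
        "a state variable may have at most one time derivative per regime"))
    for (v in tdv) {
      if (!(v %in% states))
        d <- diag_bind(d, diag_row("derivative-non-state", rwhere,
          sprintf("time derivative targets \"%s\", which is not a state variable", v)))
      e <- r$time_derivatives[[v]]
      check_expr(e, rwhere)
      if (expr_contains_boolean(e))
        d <- diag_bind(d, diag_row("boolean-in-derivative", rwhere,
          sprintf("time derivative \"%s\" uses boolean operators", e$source)))
    }
    for (tr in r$on_conditions) {
      twhere <- paste0(rwhere, "/OnCondition")
      check_expr(tr$trigger, twhere)
      if (!expr_is_boolean(tr$trigger))
        d <- diag_bind(d, diag_row("trigger-not-boolean", twhere,
          sprintf("trigger \"%s\" is not a boolean expression", tr$trigger$source)))
      check_transition_body(tr, twhere)
    }
    for (tr in r$on_events) {
      twhere <- paste0(rwhere, "/OnEvent[", tr$src_port, "]")
      p <- comp_find_port(c, tr$src_port)
      if (is.null(p) || p$direction != "receive" || p$mode != "event")
        d <- diag_bind(d, diag_row("bad-event-source", twhere,
          sprintf("OnEvent source \"%s\" is not an event receive port", tr$src_port)))
      check_transition_body(tr, twhere)
    }
    for (tr in r$on_impulses) {
      twhere <- paste0(rwhere, "/OnImpulse[", tr$src_port, "]")
      p <- comp_find_port(c, tr$src_port)
      if (is.null(p) || p$direction != "receive" || p$mode != "impulse")
        d <- diag_bind(d, diag_row("bad-impulse-source", twhere,
          sprintf("OnImpulse source \"%s\" is not an impulse receive port", tr$src_port)))
      ## the delivered value is bound to the receiving port's name
      check_transition_body(tr, twhere, extra = tr$src_port)
    }
  }
  d
}

## ---------------------------------------------------------------- XML I/O

xml_doc_of <- function(x) {
  if (inherits(x, "xml_document")) x
  else if (inherits(x, "xml_node")) x
  else xml2::read_xml(x)
}

schema_stop <- function(node, msg) {
  stop_spineml(sprintf("%s (at %s)", msg, xml2::xml_path(node)),
               "spineml_schema_error")
}

req_attr <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) schema_stop(node, sprintf("missing required attribute \"%s\"", name))
  v
}

read_mathinline <- function(node) {
  mi <- xml2::xml_find_first(node, "./MathInline")
  if (inherits(mi, "xml_missing"))
    schema_stop(node, "missing MathInline child")
  parse_expression(trimws(xml2::xml_text(mi)))
}

.port_elements <- c(
  AnalogSendPort = "send.analog", AnalogReceivePort = "receive.analog",
  AnalogReducePort = "receive.analog.reduce",
  EventSendPort = "send.event", EventReceivePort = "receive.event",
  ImpulseSendPort = "send.impulse", ImpulseReceivePort = "receive.impulse"
)

read_transition_body <- function(node) {
  sa <- list(); ev <- character(); im <- list()
  for (ch in xml2::xml_children(node)) {
    nm <- xml2::xml_name(ch)
    if (nm == "StateAssignment")
      sa[[req_attr(ch, "variable")]] <- read_mathinline(ch)
    else if (nm == "EventOut")
      ev <- c(ev, req_attr(ch, "port"))
    else if (nm == "ImpulseOut")
      im[[req_attr(ch, "port")]] <- read_mathinline(ch)
    else if (!nm %in% c("Trigger", "MathInline"))
      schema_stop(ch, sprintf("unknown element \"%s\" in transition", nm))
  }
  list(state_assignments = sa, event_outputs = ev, impulse_outputs = im)
}

#' Read a ComponentClass from XML
#'
#' Accepts a file path, a string of XML, or a parsed `xml_document`. The
#' document root may be `ComponentClass` itself or a `SpineML` wrapper
#' containing one. Structural violations raise an error of class
#' `spineml_schema_error` naming the offending element path.
#'
#' @param x path, XML string or `xml_document`.
#' @return a `spineml_component`.
#' @export
read_component <- function(x) {
  root <- xml2::xml_root(xml_doc_of(x))
  if (xml2::xml_name(root) == "SpineML")
    root <- xml2::xml_find_first(root, "./ComponentClass")
  if (inherits(root, "xml_missing") || xml2::xml_name(root) != "ComponentClass")
    stop_spineml("document does not contain a ComponentClass element",
                 "spineml_schema_error")
  name <- req_attr(root, "name")
  type <- xml2::xml_attr(root, "type")
  if (is.na(type)) type <- "generic"

  params <- list(); ports <- list(); dyn <- NULL
  for (ch in xml2::xml_children(root)) {
    nm <- xml2::xml_name(ch)
    if (nm == "Parameter") {
      dim <- xml2::xml_attr(ch, "dimension"); if (is.na(dim)) dim <- "none"
      params[[length(params) + 1L]] <- sp_parameter(req_attr(ch, "name"), dim)
    } else if (nm %in% names(.port_elements)) {
      spec <- strsplit(.port_elements[[nm]], ".", fixed = TRUE)[[1]]
      dim <- xml2::xml_attr(ch, "dimension"); if (is.na(dim)) dim <- "none"
      rop <- NULL
      if (length(spec) == 3L) {
        rop <- xml2::xml_attr(ch, "reduce_op")
        if (is.na(rop)) rop <- "sum"
      }
      ports[[length(ports) + 1L]] <- sp_port(req_attr(ch, "name"),
        direction = spec[1], mode = spec[2], reduce_op = rop, dimension = dim)
    } else if (nm == "Dynamics") {
      dyn <- ch
    } else {
      schema_stop(ch, sprintf("unknown element \"%s\" in ComponentClass", nm))
    }
  }
  if (is.null(dyn))
    schema_stop(root, "missing Dynamics element")

  states <- list(); aliases <- list(); regimes <- list()
  initial <- character(0)
  for (ch in xml2::xml_children(dyn)) {
    nm <- xml2::xml_name(ch)
    if (nm == "StateVariable") {
      dim <- xml2::xml_attr(ch, "dimension"); if (is.na(dim)) dim <- "none"
      states[[length(states) + 1L]] <- sp_state_variable(req_attr(ch, "name"), dim)
    } else if (nm == "Alias") {
      dim <- xml2::xml_attr(ch, "dimension"); if (is.na(dim)) dim <- "none"
      aliases[[length(aliases) + 1L]] <-
        sp_alias(req_attr(ch, "name"), read_mathinline(ch), dim)
    } else if (nm == "Regime") {
      rname <- req_attr(ch, "name")
      if (identical(xml2::xml_attr(ch, "initial"), "true"))
        initial <- c(initial, rname)
      tds <- list(); ocs <- list(); oes <- list(); ois <- list()
      for (el in xml2::xml_children(ch)) {
        enm <- xml2::xml_name(el)
        if (enm == "TimeDerivative") {
          tds[[req_attr(el, "variable")]] <- read_mathinline(el)
        } else if (enm == "OnCondition") {
          trg <- xml2::xml_find_first(el, "./Trigger")
          if (inherits(trg, "xml_missing"))
            schema_stop(el, "OnCondition is missing its Trigger")
          body <- read_transition_body(el)
          ocs[[length(ocs) + 1L]] <- on_condition(
            read_mathinline(trg), req_attr(el, "target_regime"),
            body$state_assignments, body$event_outputs, body$impulse_outputs)
        } else if (enm == "OnEvent") {
          body <- read_transition_body(el)
          oes[[length(oes) + 1L]] <- on_event(
            req_attr(el, "src_port"), req_attr(el, "target_regime"),
            body$state_assignments, body$event_outputs, body$impulse_outputs)
        } else if (enm == "OnImpulse") {
          body <- read_transition_body(el)
          ois[[length(ois) + 1L]] <- on_impulse(
            req_attr(el, "src_port"), req_attr(el, "target_regime"),
            body$state_assignments, body$event_outputs, body$impulse_outputs)
        } else {
          schema_stop(el, sprintf("unknown element \"%s\" in Regime", enm))
        }
      }
      regimes[[length(regimes) + 1L]] <-
        sp_regime(rname, tds, ocs, oes, ois)
    } else {
      schema_stop(ch, sprintf("unknown element \"%s\" in Dynamics", nm))
    }
  }
  if (length(initial) == 0L && length(regimes) > 0L)
    initial <- NULL  # validator reports the missing marker
  cc <- component_class(name, type, params, states, aliases, ports, regimes,
                        initial_regime = initial)
  if (length(initial) == 0L) cc$initial_regime <- NULL
  cc
}

write_transition_body <- function(parent, tr) {
  for (v in names(tr$state_assignments)) {
    sa <- xml2::xml_add_child(parent, "StateAssignment", variable = v)
    xml2::xml_add_child(sa, "MathInline",
                        serialize_expression(tr$state_assignments[[v]]))
  }
  for (pn in tr$event_outputs)
    xml2::xml_add_child(parent, "EventOut", port = pn)
  for (pn in names(tr$impulse_outputs)) {
    io <- xml2::xml_add_child(parent, "ImpulseOut", port = pn)
    xml2::xml_add_child(io, "MathInline",
                        serialize_expression(tr$impulse_outputs[[pn]]))
  }
}

#' Write a ComponentClass to XML
#'
#' Refuses to serialise an invalid component. Comparison operators inside
#' expressions are emitted with XML-safe entity escapes (`>` becomes
#' `&gt;`).
#'
#' @param c a `spineml_component` that passes [validate_component()].
#' @param path optional file path; when given the document is also written
#'   to disk.
#' @return the `xml_document`, invisibly when `path` is given.
#' @export
write_component <- function(c, path = NULL) {
  d <- validate_component(c)
  if (nrow(d) > 0L)
    stop_spineml(paste0("refusing to write an invalid component:\n",
                        paste(sprintf("  [%s] %s: %s", d$severity, d$rule,
                                      d$message), collapse = "\n")),
                 "spineml_validation_error", diagnostics = d)
  doc <- xml2::xml_new_root("ComponentClass", name = c$name, type = c$type)
  for (p in c$parameters)
    xml2::xml_add_child(doc, "Parameter", name = p$name, dimension = p$dimension)
  for (p in c$ports) {
    el <- names(.port_elements)[match(
      paste0(p$direction, ".", p$mode, if (!is.null(p$reduce_op)) ".reduce" else ""),
      .port_elements)]
    nd <- xml2::xml_add_child(doc, el, name = p$name)
    if (p$mode != "event") xml2::xml_set_attr(nd, "dimension", p$dimension)
    if (!is.null(p$reduce_op)) xml2::xml_set_attr(nd, "reduce_op", p$reduce_op)
  }
  dyn <- xml2::xml_add_child(doc, "Dynamics")
  for (s in c$state_variables)
    xml2::xml_add_child(dyn, "StateVariable", name = s$name, dimension = s$dimension)
  for (a in c$aliases) {
    nd <- xml2::xml_add_child(dyn, "Alias", name = a$name, dimension = a$dimension)
    xml2::xml_add_child(nd, "MathInline", serialize_expression(a$expression))
  }
  for (r in c$regimes) {
    rn <- xml2::xml_add_child(dyn, "Regime", name = r$name)
    if (identical(r$name, c$initial_regime))
      xml2::xml_set_attr(rn, "initial", "true")
    for (v in names(r$time_derivatives)) {
      td <- xml2::xml_add_child(rn, "TimeDerivative", variable = v)
      xml2::xml_add_child(td, "MathInline",
                          serialize_expression(r$time_derivatives[[v]]))
    }
    for (tr in r$on_conditions) {
      oc <- xml2::xml_add_child(rn, "OnCondition",
                                target_regime = tr$target_regime)
      trg <- xml2::xml_add_child(oc, "Trigger")
      xml2::xml_add_child(trg, "MathInline", serialize_expression(tr$trigger))
      write_transition_body(oc, tr)
    }
    for (tr in r$on_events) {
      oe <- xml2::xml_add_child(rn, "OnEvent", src_port = tr$src_port,
                                target_regime = tr$target_regime)
      write_transition_body(oe, tr)
    }
    for (tr in r$on_impulses) {
      oi <- xml2::xml_add_child(rn, "OnImpulse", src_port = tr$src_port,
                                target_regime = tr$target_regime)
      write_transition_body(oi, tr)
    }
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}
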