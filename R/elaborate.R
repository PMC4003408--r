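## Reference resolution and elaboration of a network into a flat instance
## graph: per-instance value vectors for every component set, and directed,
## delayed port-binding edges for the synapse chains and generic inputs.

#' Build a component loader
#'
#' [resolve_references()] locates component definitions through a loader
#' function mapping a `url` attribute to a `spineml_component`. This helper
#' builds one from a directory of component XML files; a named list of
#' components (keyed by url) or any function `url -> component` works too.
#'
#' @param dir directory containing component XML files.
#' @return function(url) -> `spineml_component`.
#' @export
component_loader <- function(dir) {
  force(dir)
  function(url) {
    path <- file.path(dir, url)
    if (!file.exists(path))
      stop_spineml(sprintf("component file \"%s\" not found in %s", url, dir),
                   "spineml_schema_error")
    read_component(path)
  }
}

as_loader <- function(loader) {
  if (is.function(loader)) return(loader)
  if (is.character(loader) && length(loader) == 1L)
    return(component_loader(loader))
  if (is.list(loader))
    return(function(url) {
      if (is.null(loader[[url]]))
        stop_spineml(sprintf("no component registered for url \"%s\"", url),
                     "spineml_schema_error")
      loader[[url]]
    })
  stop("loader must be a function, a directory path or a named list")
}

check_port_binding <- function(comp, port_name, direction, modes, where, d) {
  p <- comp_find_port(comp, port_name)
  if (is.null(p))
    return(diag_bind(d, diag_row("unknown-port", where,
      sprintf("component \"%s\" has no port \"%s\"", comp$name, port_name))))
  if (p$direction != direction)
    d <- diag_bind(d, diag_row("direction-mismatch", where,
      sprintf("port \"%s\" of \"%s\" is a %s port where a %s port is required",
              port_name, comp$name, p$direction, direction)))
  if (!p$mode %in% modes)
    d <- diag_bind(d, diag_row("mode-mismatch", where,
      sprintf("port \"%s\" of \"%s\" has mode %s (expected %s)",
              port_name, comp$name, p$mode, paste(modes, collapse = "/"))))
  d
}

check_properties <- function(comp, properties, where, d) {
  ok <- c(comp_param_names(comp), comp_state_names(comp))
  for (pr in properties)
    if (!pr$name %in% ok)
      d <- diag_bind(d, diag_row("unknown-property", where,
        sprintf("\"%s\" is not a parameter or state variable of component \"%s\"",
                pr$name, comp$name)))
  d
}

#' Resolve component references in a network model
#'
#' Loads every component referenced by url, validates it, binds it to its
#' instance set, and checks that every named port exists with the required
#' direction and mode, that property names refer to declared parameters or
#' state variables, and that generic inputs connect ports of matching
#' modes.
#'
#' @param m a `spineml_network`.
#' @param loader a function `url -> spineml_component`, a directory path, or
#'   a named list of components keyed by url (see [component_loader()]).
#' @return an object of class `spineml_resolved`: a list with `model` (the
#'   network with a `component` bound to every instance set) and
#'   `diagnostics` (zero rows when resolution succeeded).
#' @export
resolve_references <- function(m, loader) {
  stopifnot(inherits(m, "spineml_network"))
  loader <- as_loader(loader)
  d <- diag_frame()
  cache <- new.env(parent = emptyenv())
  load_comp <- function(url, where) {
    if (exists(url, envir = cache, inherits = FALSE))
      return(get(url, envir = cache))
    comp <- tryCatch(loader(url), error = function(e) {
      d <<- diag_bind(d, diag_row("missing-component", where,
        conditionMessage(e)))
      NULL
    })
    if (!is.null(comp)) {
      cd <- validate_component(comp)
      if (nrow(cd) > 0L) {
        d <<- diag_bind(d, cd)
        comp <- NULL
      }
    }
    assign(url, comp, envir = cache)
    comp
  }

  pop_by_name <- function(name) {
    for (p in m$populations) if (p$neuron$name == name) return(p)
    NULL
  }

  for (pi in seq_along(m$populations)) {
    p <- m$populations[[pi]]
    where <- paste0("Population[", p$neuron$name, "]")
    comp <- load_comp(p$neuron$url, where)
    m$populations[[pi]]$neuron$component <- comp
    if (!is.null(comp))
      d <- check_properties(comp, p$neuron$properties, where, d)
  }
  for (pi in seq_along(m$populations)) {
    p <- m$populations[[pi]]
    pre_comp <- p$neuron$component
    for (ji in seq_along(p$projections)) {
      pj <- p$projections[[ji]]
      dst_pop <- pop_by_name(pj$dst_population)
      if (is.null(dst_pop))
        d <- diag_bind(d, diag_row("unknown-population",
          sprintf("Projection[%s->%s]", p$neuron$name, pj$dst_population),
          sprintf("destination population \"%s\" does not exist",
                  pj$dst_population)))
      dst_comp <- if (is.null(dst_pop)) NULL else dst_pop$neuron$component
      for (si in seq_along(pj$synapses)) {
        sy <- pj$synapses[[si]]
        where <- sprintf("Projection[%s->%s]/Synapse[%d]", p$neuron$name,
                         pj$dst_population, si)
        wu <- sy$weight_update
        wu_comp <- load_comp(wu$url, paste0(where, "/WeightUpdate"))
        m$populations[[pi]]$projections[[ji]]$synapses[[si]]$weight_update$component <- wu_comp
        ps <- sy$post_synapse
        ps_comp <- load_comp(ps$url, paste0(where, "/PostSynapse"))
        m$populations[[pi]]$projections[[ji]]$synapses[[si]]$post_synapse$component <- ps_comp

        if (!is.null(pre_comp) && !is.null(wu_comp)) {
          pre_port <- comp_find_port(pre_comp, wu$input_src_port)
          d <- check_port_binding(pre_comp, wu$input_src_port, "send",
                                  c("event", "impulse", "analog"),
                                  paste0(where, "/WeightUpdate@input_src_port"), d)
          d <- check_port_binding(wu_comp, wu$input_dst_port, "receive",
                                  if (is.null(pre_port)) c("event", "impulse", "analog")
                                  else pre_port$mode,
                                  paste0(where, "/WeightUpdate@input_dst_port"), d)
          d <- check_properties(wu_comp, wu$properties,
                                paste0(where, "/WeightUpdate"), d)
        }
        if (!is.null(wu_comp) && !is.null(ps_comp)) {
          wu_out <- comp_find_port(wu_comp, ps$input_src_port)
          d <- check_port_binding(wu_comp, ps$input_src_port, "send",
                                  c("event", "impulse", "analog"),
                                  paste0(where, "/PostSynapse@input_src_port"), d)
          d <- check_port_binding(ps_comp, ps$input_dst_port, "receive",
                                  if (is.null(wu_out)) c("event", "impulse", "analog")
                                  else wu_out$mode,
                                  paste0(where, "/PostSynapse@input_dst_port"), d)
          d <- check_properties(ps_comp, ps$properties,
                                paste0(where, "/PostSynapse"), d)
        }
        if (!is.null(ps_comp) && !is.null(dst_comp)) {
          ps_out <- comp_find_port(ps_comp, ps$output_src_port)
          d <- check_port_binding(ps_comp, ps$output_src_port, "send",
                                  c("analog", "event", "impulse"),
                                  paste0(where, "/PostSynapse@output_src_port"), d)
          d <- check_port_binding(dst_comp, ps$output_dst_port, "receive",
                                  if (is.null(ps_out)) c("analog", "event", "impulse")
                                  else ps_out$mode,
                                  paste0(where, "/PostSynapse@output_dst_port"), d)
        }
        if (!is.null(wu$feedback_src_port) && !is.null(dst_comp) &&
            !is.null(wu_comp)) {
          fb <- comp_find_port(dst_comp, wu$feedback_src_port)
          d <- check_port_binding(dst_comp, wu$feedback_src_port, "send",
                                  c("event", "impulse", "analog"),
                                  paste0(where, "/WeightUpdate@feedback_src_port"), d)
          d <- check_port_binding(wu_comp, wu$feedback_dst_port, "receive",
                                  if (is.null(fb)) c("event", "impulse", "analog")
                                  else fb$mode,
                                  paste0(where, "/WeightUpdate@feedback_dst_port"), d)
        }
      }
    }
  }
  for (gi in seq_along(m$groups)) {
    g <- m$groups[[gi]]
    where <- paste0("Group[", g$name, "]")
    comp <- load_comp(g$url, where)
    m$groups[[gi]]$component <- comp
    if (!is.null(comp)) d <- check_properties(comp, g$properties, where, d)
  }

  find_set <- function(name) {
    for (p in m$populations) if (p$neuron$name == name)
      return(list(component = p$neuron$component, size = p$neuron$size))
    for (g in m$groups) if (g$name == name)
      return(list(component = g$component, size = g$size))
    NULL
  }
  for (inp in m$inputs) {
    where <- sprintf("Input[%s.%s -> %s.%s]", inp$src, inp$src_port,
                     inp$dst, inp$dst_port)
    src <- find_set(inp$src); dst <- find_set(inp$dst)
    if (is.null(src))
      d <- diag_bind(d, diag_row("unknown-component-set", where,
        sprintf("no component set named \"%s\"", inp$src)))
    if (is.null(dst))
      d <- diag_bind(d, diag_row("unknown-component-set", where,
        sprintf("no component set named \"%s\"", inp$dst)))
    if (!is.null(src) && !is.null(dst) && !is.null(src$component) &&
        !is.null(dst$component)) {
      sp <- comp_find_port(src$component, inp$src_port)
      d <- check_port_binding(src$component, inp$src_port, "send",
                              c("analog", "event", "impulse"),
                              paste0(where, "@src_port"), d)
      d <- check_port_binding(dst$component, inp$dst_port, "receive",
                              if (is.null(sp)) c("analog", "event", "impulse")
                              else sp$mode,
                              paste0(where, "@dst_port"), d)
    }
  }
  structure(list(model = m, diagnostics = d), class = "spineml_resolved")
}

#' @export
print.spineml_resolved <- function(x, ...) {
  cat("<resolved SpineML network>\n")
  print(x$diagnostics)
  invisible(x)
}

## One set entry in a flat model: every parameter and state variable of the
## component expanded to a per-instance vector (unset -> 0).
make_instance_set <- function(name, kind, comp, size, properties, base_seed,
                              counter) {
  vals <- list()
  nms <- c(comp_param_names(comp), comp_state_names(comp))
  for (nm in nms) vals[[nm]] <- numeric(max(size, 0L))
  for (pr in properties) {
    counter$n <- counter$n + 1L
    if (size > 0L)
      vals[[pr$name]] <- instantiate_property(pr, size,
        rng_seed = derive_seed(base_seed, counter$n))
    else counter$n <- counter$n  # keep the seed sequence stable
  }
  list(name = name, kind = kind, component = comp, size = as.integer(size),
       values = vals)
}

edge_frame <- function(src_set = character(), src_port = character(),
                       src_instance = integer(), dst_set = character(),
                       dst_port = character(), dst_instance = integer(),
                       delay_ms = numeric()) {
  data.frame(src_set = src_set, src_port = src_port,
             src_instance = as.integer(src_instance),
             dst_set = dst_set, dst_port = dst_port,
             dst_instance = as.integer(dst_instance),
             delay_ms = as.numeric(delay_ms), stringsAsFactors = FALSE)
}

#' Elaborate a resolved network into a flat instance graph
#'
#' Expands every component set into per-instance parameter/state vectors
#' and builds the directed port-binding edges: one weight-update instance
#' per generated connection, one post-synapse instance per destination
#' neuron per synapse, the pre-neuron -> weight-update -> post-synapse ->
#' destination-neuron chain (plus optional feedback edges), and all generic
#' input connections. Edge instance indices are 0-based.
#'
#' @param resolved result of [resolve_references()] with no diagnostics.
#' @param seed base seed used to derive deterministic sub-seeds for every
#'   connectivity draw and property instantiation that does not carry its
#'   own seed. The same seed always yields an identical flat model.
#' @return an object of class `spineml_flat`: list with `sets` (named list
#'   of instance sets), `edges` (a data frame), `diagnostics`.
#' @export
elaborate <- function(resolved, seed = 1L) {
  stopifnot(inherits(resolved, "spineml_resolved"))
  if (nrow(resolved$diagnostics) > 0L)
    stop_spineml("cannot elaborate: resolution produced diagnostics",
                 "spineml_validation_error",
                 diagnostics = resolved$diagnostics)
  m <- resolved$model
  counter <- new.env(parent = emptyenv()); counter$n <- 0L
  sets <- list()
  edges <- list()
  d <- diag_frame()

  add_set <- function(s) {
    if (!is.null(sets[[s$name]]))
      d <<- diag_bind(d, diag_row("duplicate-set-name", s$name,
        sprintf("component set name \"%s\" is not unique", s$name)))
    sets[[s$name]] <<- s
  }

  for (p in m$populations)
    add_set(make_instance_set(p$neuron$name, "neuron", p$neuron$component,
                              p$neuron$size, p$neuron$properties, seed,
                              counter))
  for (g in m$groups)
    add_set(make_instance_set(g$name, "group", g$component, g$size,
                              g$properties, seed, counter))

  pop_size <- function(name) sets[[name]]$size

  for (p in m$populations) {
    for (pj in p$projections) {
      for (si in seq_along(pj$synapses)) {
        sy <- pj$synapses[[si]]
        n_src <- p$neuron$size
        n_dst <- pop_size(pj$dst_population)
        counter$n <- counter$n + 1L
        conns <- build_connectivity(sy$connectivity, n_src, n_dst,
                                    rng_seed = derive_seed(seed, counter$n))
        wu <- sy$weight_update; ps <- sy$post_synapse
        wu_set <- make_instance_set(wu$name, "weight_update", wu$component,
                                    nrow(conns), wu$properties, seed, counter)
        ps_set <- make_instance_set(ps$name, "post_synapse", ps$component,
                                    n_dst, ps$properties, seed, counter)
        add_set(wu_set); add_set(ps_set)
        nc <- nrow(conns)
        if (nc > 0L) {
          ## pre-synaptic neuron -> weight update (per connection, delayed)
          edges[[length(edges) + 1L]] <- edge_frame(
            rep(p$neuron$name, nc), rep(wu$input_src_port, nc), conns$src,
            rep(wu$name, nc), rep(wu$input_dst_port, nc), seq_len(nc) - 1L,
            conns$delay_ms)
          ## weight update -> post-synapse (per connection)
          edges[[length(edges) + 1L]] <- edge_frame(
            rep(wu$name, nc), rep(ps$input_src_port, nc), seq_len(nc) - 1L,
            rep(ps$name, nc), rep(ps$input_dst_port, nc), conns$dst,
            numeric(nc))
          if (!is.null(wu$feedback_src_port))
            edges[[length(edges) + 1L]] <- edge_frame(
              rep(pj$dst_population, nc), rep(wu$feedback_src_port, nc),
              conns$dst, rep(wu$name, nc), rep(wu$feedback_dst_port, nc),
              seq_len(nc) - 1L, numeric(nc))
        }
        ## post-synapse -> destination neuron (per destination instance)
        if (n_dst > 0L)
          edges[[length(edges) + 1L]] <- edge_frame(
            rep(ps$name, n_dst), rep(ps$output_src_port, n_dst),
            0:(n_dst - 1L), rep(pj$dst_population, n_dst),
            rep(ps$output_dst_port, n_dst), 0:(n_dst - 1L), numeric(n_dst))
      }
    }
  }

  for (inp in m$inputs) {
    counter$n <- counter$n + 1L
    conns <- build_connectivity(inp$connectivity, sets[[inp$src]]$size,
                                sets[[inp$dst]]$size,
                                rng_seed = derive_seed(seed, counter$n))
    if (nrow(conns) > 0L)
      edges[[length(edges) + 1L]] <- edge_frame(
        rep(inp$src, nrow(conns)), rep(inp$src_port, nrow(conns)), conns$src,
        rep(inp$dst, nrow(conns)), rep(inp$dst_port, nrow(conns)), conns$dst,
        conns$delay_ms)
  }

  edges <- if (length(edges) > 0L) do.call(rbind, edges) else edge_frame()

  ## every non-reduce analogue receive port needs exactly one incoming edge
  for (s in sets) {
    for (prt in s$component$ports) {
      if (prt$direction == "receive" && prt$mode == "analog" &&
          is.null(prt$reduce_op) && s$size > 0L) {
        sel <- edges$dst_set == s$name & edges$dst_port == prt$name
        cnt <- tabulate(edges$dst_instance[sel] + 1L, nbins = s$size)
        if (any(cnt != 1L))
          d <- diag_bind(d, diag_row("analog-fanin",
            paste0(s$name, ".", prt$name),
            sprintf(paste0("non-reduce analogue receive port must have ",
                           "exactly 1 incoming edge (instances with 0 or >1: %d)"),
                    sum(cnt != 1L))))
      }
    }
  }

  structure(list(sets = sets, edges = edges, seed = as.integer(seed),
                 diagnostics = d),
            class = "spineml_flat")
}

#' @export
print.spineml_flat <- function(x, ...) {
  cat(sprintf("<flat SpineML model: %d set(s), %d instance(s), %d edge(s)>\n",
              length(x$sets),
              sum(vapply(x$sets, `[[`, 0L, "size")), nrow(x$edges)))
  for (s in x$sets)
    cat(sprintf("  %s [%s] size %d (%s)\n", s$name, s$kind, s$size,
                s$component$name))
  invisible(x)
}
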