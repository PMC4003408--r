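## Network layer: populations/projections (high level) and groups/generic
## inputs (low level), plus elaboration into a flat instance graph.
##
## Instance indices are 0-based everywhere a user sees them (XML value
## lists, connection lists, CSV logs); internal R code converts to 1-based
## positions at the elaboration boundary.

#' Property value specifications
#'
#' A property sets a parameter or state variable of every instance in a
#' component set. Values can be a single fixed value, seeded draws from a
#' uniform, normal (parameterised by mean and *variance*) or Poisson
#' distribution, or an explicit, possibly partial, per-instance value list.
#' Instances not covered by a value list — and properties never mentioned at
#' all — default to 0.
#'
#' @param value,min,max,mean,variance distribution parameters.
#' @param seed optional integer seed making the draws reproducible.
#' @param index 0-based instance indices (value lists may be partial and out
#'   of order).
#' @param values values matching `index`.
#' @return a property value object.
#' @name property-values
NULL

#' @rdname property-values
#' @export
fixed_value <- function(value) {
  structure(list(value = as.numeric(value)),
            class = c("spineml_fixed_value", "spineml_property_value"))
}

#' @rdname property-values
#' @export
uniform_distribution <- function(min, max, seed = NULL) {
  structure(list(min = as.numeric(min), max = as.numeric(max),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = c("spineml_uniform", "spineml_property_value"))
}

#' @rdname property-values
#' @export
normal_distribution <- function(mean, variance, seed = NULL) {
  structure(list(mean = as.numeric(mean), variance = as.numeric(variance),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = c("spineml_normal", "spineml_property_value"))
}

#' @rdname property-values
#' @export
poisson_distribution <- function(mean, seed = NULL) {
  structure(list(mean = as.numeric(mean),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = c("spineml_poisson", "spineml_property_value"))
}

#' @rdname property-values
#' @export
value_list <- function(index, values) {
  structure(list(index = as.integer(index), values = as.numeric(values)),
            class = c("spineml_value_list", "spineml_property_value"))
}

#' @rdname property-values
#' @param name parameter or state-variable name the property sets.
#' @param pv a property value object.
#' @export
property_spec <- function(name, pv) {
  stopifnot(inherits(pv, "spineml_property_value"))
  structure(list(name = name, value = pv), class = "spineml_property")
}

#' Instantiate a property over a component set
#'
#' Expands a property value specification into a numeric vector with one
#' entry per instance. Distribution draws use the specification's own seed
#' when present, otherwise `rng_seed`; with neither, the current RNG stream
#' is consumed.
#'
#' @param p a [property_spec()] or a bare property value object.
#' @param size number of instances (>= 1).
#' @param rng_seed fallback integer seed.
#' @return numeric vector of length `size`.
#' @export
instantiate_property <- function(p, size, rng_seed = NULL) {
  if (inherits(p, "spineml_property")) p <- p$value
  stopifnot(inherits(p, "spineml_property_value"), size >= 1L)
  size <- as.integer(size)
  seed <- p$seed %||% rng_seed
  draw <- function(fn) if (is.null(seed)) fn() else with_seed(seed, fn())
  if (inherits(p, "spineml_fixed_value")) {
    rep(p$value, size)
  } else if (inherits(p, "spineml_uniform")) {
    draw(function() stats::runif(size, p$min, p$max))
  } else if (inherits(p, "spineml_normal")) {
    if (p$variance < 0)
      stop_spineml("normal distribution variance must be >= 0",
                   "spineml_validation_error")
    draw(function() stats::rnorm(size, p$mean, sqrt(p$variance)))
  } else if (inherits(p, "spineml_poisson")) {
    draw(function() as.numeric(stats::rpois(size, p$mean)))
  } else if (inherits(p, "spineml_value_list")) {
    if (anyDuplicated(p$index))
      stop_spineml("value list indices must be unique",
                   "spineml_validation_error")
    if (any(p$index < 0L | p$index >= size))
      stop_spineml(sprintf(
        "value list index out of range [0, %d)", size),
        "spineml_validation_error")
    out <- numeric(size)
    out[p$index + 1L] <- p$values
    out
  } else stop("unknown property value class")
}

## ------------------------------------------------------- connectivity

#' Connectivity specifications
#'
#' Connectivity between a source and a destination component set. The
#' built-in kinds are one-to-one, all-to-all, fixed-probability (each
#' ordered source/destination pair connected independently with probability
#' `probability`; self-connections are allowed when a set projects to
#' itself) and an explicit connection list. Delays are in milliseconds;
#' list connectivity carries a per-row delay, the other kinds a single
#' shared delay.
#'
#' @param delay_ms shared connection delay in ms (>= 0).
#' @param probability connection probability in `[0, 1]`.
#' @param seed optional integer seed for the fixed-probability draw.
#' @param connections data frame with columns `src`, `dst` (0-based
#'   instance indices) and `delay_ms`.
#' @return a connectivity object.
#' @seealso [build_connectivity()], [register_connectivity()]
#' @name connectivity
NULL

#' @rdname connectivity
#' @export
one_to_one_connection <- function(delay_ms = 0) {
  structure(list(kind = "one_to_one", delay_ms = as.numeric(delay_ms)),
            class = c("spineml_one_to_one", "spineml_connectivity"))
}

#' @rdname connectivity
#' @export
all_to_all_connection <- function(delay_ms = 0) {
  structure(list(kind = "all_to_all", delay_ms = as.numeric(delay_ms)),
            class = c("spineml_all_to_all", "spineml_connectivity"))
}

#' @rdname connectivity
#' @export
fixed_probability_connection <- function(probability, delay_ms = 0,
                                         seed = NULL) {
  probability <- as.numeric(probability)
  if (is.na(probability) || probability < 0 || probability > 1)
    stop_spineml("connection probability must lie in [0, 1]",
                 "spineml_validation_error")
  structure(list(kind = "fixed_probability", probability = probability,
                 delay_ms = as.numeric(delay_ms),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = c("spineml_fixed_probability", "spineml_connectivity"))
}

#' @rdname connectivity
#' @export
connection_list <- function(connections) {
  stopifnot(is.data.frame(connections),
            all(c("src", "dst") %in% names(connections)))
  if (is.null(connections$delay_ms)) connections$delay_ms <- 0
  connections <- data.frame(src = as.integer(connections$src),
                            dst = as.integer(connections$dst),
                            delay_ms = as.numeric(connections$delay_ms))
  if (any(connections$delay_ms < 0))
    stop_spineml("connection delays must be >= 0", "spineml_validation_error")
  structure(list(kind = "connection_list", connections = connections),
            class = c("spineml_connection_list", "spineml_connectivity"))
}

empty_connections <- function() {
  data.frame(src = integer(0), dst = integer(0), delay_ms = numeric(0))
}

#' Generate the connection table for a connectivity specification
#'
#' @param c a connectivity object.
#' @param n_src,n_dst source and destination set sizes (>= 1).
#' @param rng_seed fallback seed used when the specification carries none;
#'   fixed seeds make generation fully deterministic.
#' @return data frame with columns `src`, `dst` (0-based) and `delay_ms`.
#'   All-to-all tables enumerate sources fastest within each destination.
#' @export
build_connectivity <- function(c, n_src, n_dst, rng_seed = NULL) {
  UseMethod("build_connectivity")
}

#' @export
build_connectivity.spineml_one_to_one <- function(c, n_src, n_dst,
                                                  rng_seed = NULL) {
  if (n_src != n_dst)
    stop_spineml(sprintf(
      "one-to-one connectivity requires equal set sizes (got %d and %d)",
      n_src, n_dst), "spineml_validation_error")
  data.frame(src = 0:(n_src - 1L), dst = 0:(n_src - 1L),
             delay_ms = rep(c$delay_ms, n_src))
}

#' @export
build_connectivity.spineml_all_to_all <- function(c, n_src, n_dst,
                                                  rng_seed = NULL) {
  data.frame(src = rep(0:(n_src - 1L), times = n_dst),
             dst = rep(0:(n_dst - 1L), each = n_src),
             delay_ms = rep(c$delay_ms, n_src * n_dst))
}

#' @export
build_connectivity.spineml_fixed_probability <- function(c, n_src, n_dst,
                                                         rng_seed = NULL) {
  if (c$probability == 0) return(empty_connections())
  seed <- c$seed %||% rng_seed
  total <- as.double(n_src) * as.double(n_dst)
  pick <- function() which(stats::runif(total) < c$probability)
  idx <- if (is.null(seed)) pick() else with_seed(seed, pick())
  if (length(idx) == 0L) return(empty_connections())
  data.frame(src = as.integer((idx - 1L) %% n_src),
             dst = as.integer((idx - 1L) %/% n_src),
             delay_ms = rep(c$delay_ms, length(idx)))
}

#' @export
build_connectivity.spineml_connection_list <- function(c, n_src, n_dst,
                                                       rng_seed = NULL) {
  cn <- c$connections
  if (nrow(cn) > 0L && (any(cn$src < 0L | cn$src >= n_src) ||
                        any(cn$dst < 0L | cn$dst >= n_dst)))
    stop_spineml("connection list indices out of range",
                 "spineml_validation_error")
  cn
}

#' Read or write an explicit connection list as CSV
#'
#' The CSV format has columns `src`, `dst` (0-based instance indices) and
#' `delay_ms`.
#'
#' @param path file path.
#' @return `read_connection_csv` returns a [connection_list()];
#'   `write_connection_csv` returns `path` invisibly.
#' @export
read_connection_csv <- function(path) {
  connection_list(utils::read.csv(path))
}

#' @rdname read_connection_csv
#' @param c a [connection_list()].
#' @export
write_connection_csv <- function(c, path) {
  stopifnot(inherits(c, "spineml_connection_list"))
  utils::write.csv(c$connections, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ------------------------------------------- network model constructors

#' Network model constructors
#'
#' A network is a set of populations (each a component instance set plus
#' outgoing projections), low-level groups (component instance sets that do
#' not represent neuron bodies, e.g. gap junctions), and generic inputs
#' (direct port-to-port connections for non-synaptic communication).
#'
#' @param name instance-set name, unique within the network.
#' @param url component file the set instantiates, resolved by the loader
#'   passed to [resolve_references()].
#' @param size number of instances (>= 1). Weight updates and post-synapses
#'   carry no size: theirs is derived from the connectivity pattern and the
#'   destination population size respectively.
#' @param properties list of [property_spec()] objects.
#' @return a network object part.
#' @name network-model
NULL

#' @rdname network-model
#' @param projections list of [projection()] objects originating from this
#'   population.
#' @export
population <- function(name, url, size, properties = list(),
                       projections = list()) {
  size <- as.integer(size)
  if (is.na(size) || size < 1L)
    stop_spineml("population size must be >= 1", "spineml_validation_error")
  structure(list(neuron = list(name = name, url = url, size = size,
                               properties = properties),
                 projections = projections),
            class = "spineml_population")
}

#' @rdname network-model
#' @param dst_population name of the destination population.
#' @param synapses list of [synapse()] objects.
#' @export
projection <- function(dst_population, synapses) {
  structure(list(dst_population = dst_population, synapses = synapses),
            class = "spineml_projection")
}

#' @rdname network-model
#' @param connectivity a connectivity object (see [connectivity]).
#' @param weight_update list from [weight_update()].
#' @param post_synapse list from [post_synapse()].
#' @export
synapse <- function(connectivity, weight_update, post_synapse) {
  stopifnot(inherits(connectivity, "spineml_connectivity"))
  structure(list(connectivity = connectivity, weight_update = weight_update,
                 post_synapse = post_synapse),
            class = "spineml_synapse")
}

#' @rdname network-model
#' @param input_src_port,input_dst_port the port chain into the component:
#'   for a weight update, a send port on the pre-synaptic neuron and a
#'   receive port on the weight update (typically event ports carrying
#'   spikes); for a post-synapse, a send port on the weight update and a
#'   receive port on the post-synapse (typically impulse ports).
#' @param feedback_src_port,feedback_dst_port optional back-channel from the
#'   post-synaptic neuron to the weight update (for learning rules).
#' @export
weight_update <- function(name, url, properties = list(),
                          input_src_port, input_dst_port,
                          feedback_src_port = NULL, feedback_dst_port = NULL) {
  structure(list(name = name, url = url, properties = properties,
                 input_src_port = input_src_port,
                 input_dst_port = input_dst_port,
                 feedback_src_port = feedback_src_port,
                 feedback_dst_port = feedback_dst_port),
            class = "spineml_weight_update")
}

#' @rdname network-model
#' @param output_src_port,output_dst_port the port pair linking the
#'   post-synapse to the destination neuron (typically an analogue send port
#'   feeding the neuron's analogue reduce port).
#' @export
post_synapse <- function(name, url, properties = list(),
                         input_src_port, input_dst_port,
                         output_src_port, output_dst_port) {
  structure(list(name = name, url = url, properties = properties,
                 input_src_port = input_src_port,
                 input_dst_port = input_dst_port,
                 output_src_port = output_src_port,
                 output_dst_port = output_dst_port),
            class = "spineml_post_synapse")
}

#' @rdname network-model
#' @export
group <- function(name, url, size, properties = list()) {
  size <- as.integer(size)
  if (is.na(size) || size < 1L)
    stop_spineml("group size must be >= 1", "spineml_validation_error")
  structure(list(name = name, url = url, size = size,
                 properties = properties),
            class = "spineml_group")
}

#' @rdname network-model
#' @param src,dst names of the source and destination component sets.
#' @param src_port,dst_port the connected ports; their modes must agree
#'   (analogue to analogue, event to event, impulse to impulse).
#' @export
generic_input <- function(src, dst, src_port, dst_port, connectivity) {
  stopifnot(inherits(connectivity, "spineml_connectivity"))
  structure(list(src = src, dst = dst, src_port = src_port,
                 dst_port = dst_port, connectivity = connectivity),
            class = "spineml_generic_input")
}

#' @rdname network-model
#' @param populations,groups,inputs lists of the corresponding objects.
#' @export
network_model <- function(populations = list(), groups = list(),
                          inputs = list()) {
  structure(list(populations = populations, groups = groups,
                 inputs = inputs),
            class = "spineml_network")
}

#' @export
print.spineml_network <- function(x, ...) {
  cat(sprintf("<SpineML network: %d population(s), %d group(s), %d generic input(s)>\n",
              length(x$populations), length(x$groups), length(x$inputs)))
  for (p in x$populations)
    cat(sprintf("  Population %s (size %d, %d projection(s))\n",
                p$neuron$name, p$neuron$size, length(p$projections)))
  for (g in x$groups)
    cat(sprintf("  Group %s (size %d)\n", g$name, g$size))
  invisible(x)
}
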