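## Network layer XML reader/writer and the connectivity plug-in registry.

.connectivity_registry <- new.env(parent = emptyenv())

#' Register a connectivity element
#'
#' The network reader resolves connectivity XML elements through a
#' registry, so new connection primitives (distance-based rules, CSA, ...)
#' can be plugged in without touching the core reader — the XML-schema
#' analogue of a substitution group. A registration maps an element name to
#' a reader, and an S3 class to a writer; generation behaviour is supplied
#' by an S3 method for [build_connectivity()] on that class.
#'
#' @param element XML element name (e.g. `"FixedProbabilityConnection"`).
#' @param read function(xml_node) returning a `spineml_connectivity`.
#' @param class S3 class of the objects produced by `read`.
#' @param write function(parent_node, connectivity) appending the element.
#' @return invisibly, the element name.
#' @export
register_connectivity <- function(element, read, class, write) {
  assign(element, list(element = element, read = read, class = class,
                       write = write),
         envir = .connectivity_registry)
  invisible(element)
}

#' @rdname register_connectivity
#' @export
registered_connectivity_elements <- function() {
  sort(ls(.connectivity_registry))
}

connectivity_entry_for_class <- function(c) {
  for (el in ls(.connectivity_registry)) {
    e <- get(el, envir = .connectivity_registry)
    if (inherits(c, e$class)) return(e)
  }
  stop_spineml(sprintf("no registered writer for connectivity of class %s",
                       paste(class(c), collapse = "/")),
               "spineml_schema_error")
}

num_attr <- function(node, name, default = NA_real_) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else as.numeric(v)
}

int_attr_or_null <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else as.integer(v)
}

read_delay <- function(node, default = 0) {
  dn <- xml2::xml_find_first(node, "./Delay")
  if (inherits(dn, "xml_missing")) return(default)
  num_attr(dn, "value", default)
}

write_delay <- function(parent, delay_ms) {
  xml2::xml_add_child(parent, "Delay",
                      value = format(delay_ms, scientific = FALSE))
}

register_builtin_connectivity <- function() {
  register_connectivity("OneToOneConnection",
    read = function(node) one_to_one_connection(read_delay(node)),
    class = "spineml_one_to_one",
    write = function(parent, c) {
      nd <- xml2::xml_add_child(parent, "OneToOneConnection")
      write_delay(nd, c$delay_ms)
    })
  register_connectivity("AllToAllConnection",
    read = function(node) all_to_all_connection(read_delay(node)),
    class = "spineml_all_to_all",
    write = function(parent, c) {
      nd <- xml2::xml_add_child(parent, "AllToAllConnection")
      write_delay(nd, c$delay_ms)
    })
  register_connectivity("FixedProbabilityConnection",
    read = function(node) {
      p <- num_attr(node, "probability")
      if (is.na(p)) schema_stop(node, "missing probability attribute")
      fixed_probability_connection(p, read_delay(node),
                                   int_attr_or_null(node, "seed"))
    },
    class = "spineml_fixed_probability",
    write = function(parent, c) {
      nd <- xml2::xml_add_child(parent, "FixedProbabilityConnection",
        probability = format(c$probability, scientific = FALSE))
      if (!is.null(c$seed)) xml2::xml_set_attr(nd, "seed", c$seed)
      write_delay(nd, c$delay_ms)
    })
  register_connectivity("ConnectionList",
    read = function(node) {
      rows <- xml2::xml_find_all(node, "./Connection")
      connection_list(data.frame(
        src = as.integer(xml2::xml_attr(rows, "src")),
        dst = as.integer(xml2::xml_attr(rows, "dst")),
        delay_ms = {
          dl <- as.numeric(xml2::xml_attr(rows, "delay_ms"))
          ifelse(is.na(dl), 0, dl)
        }))
    },
    class = "spineml_connection_list",
    write = function(parent, c) {
      nd <- xml2::xml_add_child(parent, "ConnectionList")
      cn <- c$connections
      for (i in seq_len(nrow(cn)))
        xml2::xml_add_child(nd, "Connection", src = cn$src[i], dst = cn$dst[i],
                            delay_ms = format(cn$delay_ms[i], scientific = FALSE))
    })
}

read_connectivity_node <- function(node) {
  el <- xml2::xml_name(node)
  if (!exists(el, envir = .connectivity_registry))
    stop_spineml(sprintf(
      paste0("connectivity element \"%s\" has no registered extension ",
             "(at %s); see register_connectivity()"),
      el, xml2::xml_path(node)), "spineml_schema_error")
  get(el, envir = .connectivity_registry)$read(node)
}

## ----------------------------------------------------------- properties

.prop_value_elements <- c("FixedValue", "UniformDistribution",
                          "NormalDistribution", "PoissonDistribution",
                          "ValueList")

read_property <- function(node) {
  name <- req_attr(node, "name")
  ch <- xml2::xml_children(node)
  if (length(ch) != 1L)
    schema_stop(node, "Property must contain exactly one value element")
  vn <- ch[[1]]
  pv <- switch(xml2::xml_name(vn),
    FixedValue = fixed_value(num_attr(vn, "value")),
    UniformDistribution = uniform_distribution(
      num_attr(vn, "minimum"), num_attr(vn, "maximum"),
      int_attr_or_null(vn, "seed")),
    NormalDistribution = normal_distribution(
      num_attr(vn, "mean"), num_attr(vn, "variance"),
      int_attr_or_null(vn, "seed")),
    PoissonDistribution = poisson_distribution(
      num_attr(vn, "mean"), int_attr_or_null(vn, "seed")),
    ValueList = {
      rows <- xml2::xml_find_all(vn, "./Value")
      value_list(as.integer(xml2::xml_attr(rows, "index")),
                 as.numeric(xml2::xml_attr(rows, "value")))
    },
    schema_stop(vn, sprintf("unknown property value element \"%s\"",
                            xml2::xml_name(vn))))
  property_spec(name, pv)
}

fmt_num <- function(x) format(x, scientific = FALSE, digits = 15)

write_property <- function(parent, p) {
  nd <- xml2::xml_add_child(parent, "Property", name = p$name)
  pv <- p$value
  if (inherits(pv, "spineml_fixed_value")) {
    xml2::xml_add_child(nd, "FixedValue", value = fmt_num(pv$value))
  } else if (inherits(pv, "spineml_uniform")) {
    vn <- xml2::xml_add_child(nd, "UniformDistribution",
                              minimum = fmt_num(pv$min),
                              maximum = fmt_num(pv$max))
    if (!is.null(pv$seed)) xml2::xml_set_attr(vn, "seed", pv$seed)
  } else if (inherits(pv, "spineml_normal")) {
    vn <- xml2::xml_add_child(nd, "NormalDistribution",
                              mean = fmt_num(pv$mean),
                              variance = fmt_num(pv$variance))
    if (!is.null(pv$seed)) xml2::xml_set_attr(vn, "seed", pv$seed)
  } else if (inherits(pv, "spineml_poisson")) {
    vn <- xml2::xml_add_child(nd, "PoissonDistribution",
                              mean = fmt_num(pv$mean))
    if (!is.null(pv$seed)) xml2::xml_set_attr(vn, "seed", pv$seed)
  } else if (inherits(pv, "spineml_value_list")) {
    vn <- xml2::xml_add_child(nd, "ValueList")
    for (i in seq_along(pv$index))
      xml2::xml_add_child(vn, "Value", index = pv$index[i],
                          value = fmt_num(pv$values[i]))
  } else stop("unknown property value class")
  invisible(nd)
}

read_properties <- function(node) {
  lapply(xml2::xml_find_all(node, "./Property"), read_property)
}

## -------------------------------------------------------------- network

#' Read a network model from XML
#'
#' The document root is a `SpineML` element containing `Population` (high
#' level) plus optionally `Group` and `Input` (low-level) children.
#' Connectivity elements are resolved through the plug-in registry;
#' unregistered elements raise a `spineml_schema_error`.
#'
#' @param x path, XML string or `xml_document`.
#' @return a `spineml_network`.
#' @export
read_network <- function(x) {
  root <- xml2::xml_root(xml_doc_of(x))
  if (xml2::xml_name(root) != "SpineML")
    stop_spineml("network document root must be SpineML",
                 "spineml_schema_error")
  pops <- list(); groups <- list(); inputs <- list()
  for (ch in xml2::xml_children(root)) {
    nm <- xml2::xml_name(ch)
    if (nm == "Population") {
      neuron <- xml2::xml_find_first(ch, "./Neuron")
      if (inherits(neuron, "xml_missing"))
        schema_stop(ch, "Population is missing its Neuron element")
      projs <- lapply(xml2::xml_find_all(ch, "./Projection"), function(pj) {
        syns <- lapply(xml2::xml_find_all(pj, "./Synapse"), function(sy) {
          kids <- xml2::xml_children(sy)
          conn <- NULL; wu <- NULL; ps <- NULL
          for (k in kids) {
            knm <- xml2::xml_name(k)
            if (knm == "WeightUpdate") {
              wu <- weight_update(
                name = req_attr(k, "name"), url = req_attr(k, "url"),
                properties = read_properties(k),
                input_src_port = req_attr(k, "input_src_port"),
                input_dst_port = req_attr(k, "input_dst_port"),
                feedback_src_port = {
                  v <- xml2::xml_attr(k, "feedback_src_port")
                  if (is.na(v)) NULL else v
                },
                feedback_dst_port = {
                  v <- xml2::xml_attr(k, "feedback_dst_port")
                  if (is.na(v)) NULL else v
                })
            } else if (knm == "PostSynapse") {
              ps <- post_synapse(
                name = req_attr(k, "name"), url = req_attr(k, "url"),
                properties = read_properties(k),
                input_src_port = req_attr(k, "input_src_port"),
                input_dst_port = req_attr(k, "input_dst_port"),
                output_src_port = req_attr(k, "output_src_port"),
                output_dst_port = req_attr(k, "output_dst_port"))
            } else {
              conn <- read_connectivity_node(k)
            }
          }
          if (is.null(conn)) schema_stop(sy, "Synapse has no connectivity element")
          if (is.null(wu)) schema_stop(sy, "Synapse has no WeightUpdate")
          if (is.null(ps)) schema_stop(sy, "Synapse has no PostSynapse")
          synapse(conn, wu, ps)
        })
        projection(req_attr(pj, "dst_population"), syns)
      })
      pops[[length(pops) + 1L]] <- population(
        name = req_attr(neuron, "name"), url = req_attr(neuron, "url"),
        size = as.integer(req_attr(neuron, "size")),
        properties = read_properties(neuron), projections = projs)
    } else if (nm == "Group") {
      groups[[length(groups) + 1L]] <- group(
        name = req_attr(ch, "name"), url = req_attr(ch, "url"),
        size = as.integer(req_attr(ch, "size")),
        properties = read_properties(ch))
    } else if (nm == "Input") {
      conn_nodes <- Filter(function(k) xml2::xml_name(k) != "Property",
                           xml2::xml_children(ch))
      if (length(conn_nodes) != 1L)
        schema_stop(ch, "Input must contain exactly one connectivity element")
      inputs[[length(inputs) + 1L]] <- generic_input(
        src = req_attr(ch, "src"), dst = req_attr(ch, "dst"),
        src_port = req_attr(ch, "src_port"),
        dst_port = req_attr(ch, "dst_port"),
        connectivity = read_connectivity_node(conn_nodes[[1]]))
    } else {
      schema_stop(ch, sprintf("unknown element \"%s\" in SpineML network", nm))
    }
  }
  m <- network_model(pops, groups, inputs)
  pnames <- vapply(pops, function(p) p$neuron$name, "")
  gnames <- vapply(groups, `[[`, "", "name")
  if (anyDuplicated(c(pnames, gnames)))
    stop_spineml("population/group names must be unique",
                 "spineml_schema_error")
  for (p in pops) for (pj in p$projections)
    if (!pj$dst_population %in% pnames)
      stop_spineml(sprintf(
        "projection from \"%s\" targets unknown population \"%s\"",
        p$neuron$name, pj$dst_population), "spineml_schema_error")
  m
}

#' Write a network model to XML
#'
#' @param m a `spineml_network`.
#' @param path optional file path.
#' @return the `xml_document`, invisibly when `path` is given.
#' @export
write_network <- function(m, path = NULL) {
  stopifnot(inherits(m, "spineml_network"))
  doc <- xml2::xml_new_root("SpineML")
  for (p in m$populations) {
    pn <- xml2::xml_add_child(doc, "Population")
    nn <- xml2::xml_add_child(pn, "Neuron", name = p$neuron$name,
                              url = p$neuron$url, size = p$neuron$size)
    for (pr in p$neuron$properties) write_property(nn, pr)
    for (pj in p$projections) {
      pjn <- xml2::xml_add_child(pn, "Projection",
                                 dst_population = pj$dst_population)
      for (sy in pj$synapses) {
        syn <- xml2::xml_add_child(pjn, "Synapse")
        connectivity_entry_for_class(sy$connectivity)$write(syn, sy$connectivity)
        wu <- sy$weight_update
        wun <- xml2::xml_add_child(syn, "WeightUpdate", name = wu$name,
                                   url = wu$url,
                                   input_src_port = wu$input_src_port,
                                   input_dst_port = wu$input_dst_port)
        if (!is.null(wu$feedback_src_port)) {
          xml2::xml_set_attr(wun, "feedback_src_port", wu$feedback_src_port)
          xml2::xml_set_attr(wun, "feedback_dst_port", wu$feedback_dst_port)
        }
        for (pr in wu$properties) write_property(wun, pr)
        ps <- sy$post_synapse
        psn <- xml2::xml_add_child(syn, "PostSynapse", name = ps$name,
                                   url = ps$url,
                                   input_src_port = ps$input_src_port,
                                   input_dst_port = ps$input_dst_port,
                                   output_src_port = ps$output_src_port,
                                   output_dst_port = ps$output_dst_port)
        for (pr in ps$properties) write_property(psn, pr)
      }
    }
  }
  for (g in m$groups) {
    gn <- xml2::xml_add_child(doc, "Group", name = g$name, url = g$url,
                              size = g$size)
    for (pr in g$properties) write_property(gn, pr)
  }
  for (inp in m$inputs) {
    gi <- xml2::xml_add_child(doc, "Input", src = inp$src, dst = inp$dst,
                              src_port = inp$src_port,
                              dst_port = inp$dst_port)
    connectivity_entry_for_class(inp$connectivity)$write(gi, inp$connectivity)
  }
  if (!is.null(path)) {
    xml2::write_xml(doc, path)
    return(invisible(doc))
  }
  doc
}
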