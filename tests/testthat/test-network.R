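test_that("property instantiation follows the default-0 and list rules", {
  expect_equal(instantiate_property(fixed_value(-60), 3), c(-60, -60, -60))
  # a partial, out-of-order value list fills unlisted instances with 0
  expect_equal(instantiate_property(value_list(2L, 5.0), 4), c(0, 0, 5, 0))
  expect_equal(instantiate_property(value_list(c(3L, 0L), c(1, 2)), 4),
               c(2, 0, 0, 1))
  expect_error(instantiate_property(value_list(4L, 1), 4),
               class = "spineml_validation_error")
  expect_error(instantiate_property(value_list(c(1L, 1L), c(1, 2)), 4),
               class = "spineml_validation_error")
})

test_that("distribution draws are seeded and statistically sane", {
  z <- instantiate_property(normal_distribution(0, 1, seed = 7), 10000)
  expect_lt(abs(mean(z)), 4 / sqrt(10000))        # CLT bound
  expect_lt(abs(stats::sd(z) - 1), 0.05)
  u <- instantiate_property(uniform_distribution(-60, -50, seed = 3), 1000)
  expect_true(all(u >= -60 & u <= -50))
  p <- instantiate_property(poisson_distribution(4, seed = 5), 1000)
  expect_true(all(p == round(p) & p >= 0))
  expect_lt(abs(mean(p) - 4), 4 * sqrt(4 / 1000))
  # same seed, same vector; the global RNG stream is untouched
  set.seed(99); before <- runif(1); set.seed(99)
  a <- instantiate_property(normal_distribution(0, 1, seed = 11), 50)
  expect_identical(a, instantiate_property(normal_distribution(0, 1,
                                                               seed = 11), 50))
  expect_identical(runif(1), before)
})

test_that("connectivity generation matches its definitions", {
  expect_identical(nrow(build_connectivity(
    fixed_probability_connection(0), 10, 10)), 0L)
  expect_identical(nrow(build_connectivity(
    fixed_probability_connection(1), 3, 4)), 12L)
  o <- build_connectivity(one_to_one_connection(0.5), 3, 3)
  expect_equal(o$src, 0:2)
  expect_equal(o$dst, 0:2)
  expect_equal(o$delay_ms, rep(0.5, 3))
  expect_error(build_connectivity(one_to_one_connection(), 3, 4),
               class = "spineml_validation_error")
  a <- build_connectivity(all_to_all_connection(), 3, 4)
  expect_identical(nrow(a), 12L)
  expect_identical(anyDuplicated(paste(a$src, a$dst)), 0L)
  cl <- connection_list(data.frame(src = c(0, 2), dst = c(1, 0),
                                   delay_ms = c(0.5, 1)))
  expect_equal(build_connectivity(cl, 3, 2), cl$connections)
  expect_error(build_connectivity(cl, 2, 1),
               class = "spineml_validation_error")
  expect_error(fixed_probability_connection(1.5),
               class = "spineml_validation_error")
})

test_that("fixed-probability counts sit inside binomial bounds", {
  n <- 200; p <- 0.1
  sigma <- sqrt(n * n * p * (1 - p))
  for (seed in 1:5) {
    cn <- build_connectivity(fixed_probability_connection(p, seed = seed),
                             n, n)
    expect_lt(abs(nrow(cn) - n * n * p), 4 * sigma)
  }
  # deterministic under a fixed seed
  c1 <- build_connectivity(fixed_probability_connection(p, seed = 42), n, n)
  c2 <- build_connectivity(fixed_probability_connection(p, seed = 42), n, n)
  expect_identical(c1, c2)
})

test_that("connection lists round-trip through CSV", {
  cl <- connection_list(data.frame(src = c(0, 1, 5), dst = c(2, 0, 3),
                                   delay_ms = c(0, 0.5, 1.25)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_connection_csv(cl, path)
  expect_identical(read_connection_csv(path), cl)
})

test_that("network XML round-trips and checks its references", {
  dir <- withr::local_tempdir()
  build_vogels_abbott(benchmark_spec(n_total = 100, seed = 3), dir)
  m <- read_network(file.path(dir, "model.xml"))
  expect_length(m$populations, 2L)
  expect_identical(m$populations[[1]]$neuron$name, "Excitatory")
  expect_identical(m$populations[[1]]$neuron$size, 80L)
  expect_identical(m$populations[[2]]$neuron$size, 20L)
  m2 <- read_network(write_network(m))
  expect_identical(m2, m)
})

test_that("unknown connectivity elements go through the plug-in registry", {
  xml <- paste0(
    "<SpineML><Population><Neuron name='a' url='LIF.xml' size='2'/>",
    "<Projection dst_population='a'><Synapse>",
    "<DistanceConnection sigma='1'/>",
    "<WeightUpdate name='w' url='FW.xml' input_src_port='spike'",
    " input_dst_port='spike_in'/>",
    "<PostSynapse name='p' url='PSC.xml' input_src_port='impulse_out'",
    " input_dst_port='impulse_in' output_src_port='I_Syn'",
    " output_dst_port='I_Syn'/>",
    "</Synapse></Projection></Population></SpineML>")
  expect_error(read_network(xml), class = "spineml_schema_error",
               regexp = "DistanceConnection")
  register_connectivity("DistanceConnection",
    read = function(node) all_to_all_connection(),
    class = "spineml_all_to_all",
    write = function(parent, c) xml2::xml_add_child(parent,
                                                    "DistanceConnection"))
  withr::defer(rm("DistanceConnection",
                  envir = spineml:::.connectivity_registry))
  m <- read_network(xml)
  expect_s3_class(m$populations[[1]]$projections[[1]]$synapses[[1]]$connectivity,
                  "spineml_all_to_all")
  expect_true("DistanceConnection" %in% registered_connectivity_elements())
})

test_that("reference resolution reports binding problems", {
  res <- resolve_references(two_pop_net(), two_pop_loader())
  expect_identical(nrow(res$diagnostics), 0L)

  # weight-update input destination pointing at a send port
  bad <- two_pop_net()
  bad$populations[[1]]$projections[[1]]$synapses[[1]]$weight_update$input_dst_port <- "impulse_out"
  d <- resolve_references(bad, two_pop_loader())$diagnostics
  expect_true("direction-mismatch" %in% d$rule)

  # property name unknown to the component
  bad <- two_pop_net()
  bad$populations[[1]]$neuron$properties <- list(
    property_spec("nonesuch", fixed_value(1)))
  d <- resolve_references(bad, two_pop_loader())$diagnostics
  expect_true("unknown-property" %in% d$rule)

  # missing component url
  loader <- two_pop_loader(); loader[["LIF.xml"]] <- NULL
  d <- resolve_references(two_pop_net(), loader)$diagnostics
  expect_true("missing-component" %in% d$rule)

  # generic input with mismatched port modes
  fx <- make_gap_junction_fixture()
  fx$network$inputs[[1]]$src_port <- "spike"   # event port into an analog port
  d <- resolve_references(fx$network, fx$components)$diagnostics
  expect_true("mode-mismatch" %in% d$rule)
})

test_that("elaboration produces the hand-enumerated instance graph", {
  res <- resolve_references(two_pop_net(2L, 2L), two_pop_loader())
  flat <- elaborate(res, seed = 1)
  expect_identical(nrow(flat$diagnostics), 0L)
  expect_identical(flat$sets$wu$size, 2L)    # one per connection
  expect_identical(flat$sets$psc$size, 2L)   # one per destination neuron
  expect_identical(nrow(flat$edges), 6L)     # 2 per chain stage
  stages <- paste(flat$edges$src_set, flat$edges$dst_set)
  expect_equal(sort(unique(stages)), c("psc dst", "src wu", "wu psc"))

  # an empty projection list leaves neuron instances only
  res <- resolve_references(two_pop_net(projections = FALSE),
                            two_pop_loader())
  flat <- elaborate(res, seed = 1)
  expect_identical(nrow(flat$edges), 0L)
  expect_setequal(names(flat$sets), c("src", "dst"))

  # the gap-junction fixture: 2 neurons + 1 junction + 4 analogue edges
  fx <- make_gap_junction_fixture()
  flat <- elaborate(resolve_references(fx$network, fx$components), seed = 1)
  expect_identical(nrow(flat$diagnostics), 0L)
  expect_identical(nrow(flat$edges), 4L)
  expect_length(flat$sets, 3L)
})

test_that("instance counts obey the derived-size law across configurations", {
  for (seed in 1:4) {
    set.seed(seed)
    n_src <- sample(2:6, 1); n_dst <- sample(2:6, 1)
    conn <- switch(sample(3, 1),
      all_to_all_connection(),
      fixed_probability_connection(runif(1), seed = seed),
      one_to_one_connection())
    if (inherits(conn, "spineml_one_to_one")) n_dst <- n_src
    net <- two_pop_net(n_src, n_dst, connectivity = conn)
    flat <- elaborate(resolve_references(net, two_pop_loader()), seed = seed)
    n_conn <- sum(flat$edges$src_set == "src" & flat$edges$dst_set == "wu")
    expect_identical(flat$sets$wu$size, n_conn)       # WU count = connections
    expect_identical(flat$sets$psc$size, n_dst)       # PSC count = dst size
  }
})

test_that("elaboration is bitwise deterministic in its seed", {
  net <- two_pop_net(4L, 5L,
                     connectivity = fixed_probability_connection(0.5))
  res <- resolve_references(net, two_pop_loader())
  expect_identical(elaborate(res, seed = 7), elaborate(res, seed = 7))
})

test_that("the feedback port chain adds neuron-to-weight-update edges", {
  net <- two_pop_net(2L, 2L)
  wu <- net$populations[[1]]$projections[[1]]$synapses[[1]]$weight_update
  wu$feedback_src_port <- "spike"; wu$feedback_dst_port <- "spike_in"
  net$populations[[1]]$projections[[1]]$synapses[[1]]$weight_update <- wu
  flat <- elaborate(resolve_references(net, two_pop_loader()), seed = 1)
  fb <- flat$edges$src_set == "dst" & flat$edges$dst_set == "wu"
  expect_identical(sum(fb), 2L)
})
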