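test_that("all fixture components validate cleanly", {
  expect_identical(nrow(validate_component(make_lif_component())), 0L)
  expect_identical(nrow(validate_component(make_fixed_weight_component())), 0L)
  expect_identical(nrow(validate_component(make_exp_psc_component())), 0L)
  expect_identical(nrow(validate_component(make_gap_junction_component())), 0L)
  expect_length(make_lif_component()$regimes, 2L)
})

test_that("a gap junction between equal potentials carries no current", {
  fx <- make_gap_junction_fixture(v1 = -55, v2 = -55)
  flat <- elaborate(resolve_references(fx$network, fx$components), seed = 1)
  e <- experiment("m", 0.02, 0.1, logs = list(
    log_output("ip", "gj", "I_pre"), log_output("iq", "gj", "I_post")))
  logs <- simulate(flat, e, seed = 1)
  expect_true(all(logs$logs$ip$data$value == 0))
  expect_true(all(logs$logs$iq$data$value == 0))
})

test_that("the benchmark builder writes a complete, consistent model", {
  dir <- withr::local_tempdir()
  paths <- build_vogels_abbott(benchmark_spec(n_total = 200, seed = 5), dir)
  expect_true(all(file.exists(unlist(paths))))
  m <- read_network(paths$network)
  expect_identical(m$populations[[1]]$neuron$size, 160L)
  expect_identical(m$populations[[2]]$neuron$size, 40L)
  # four projections, one per ordered population pair
  expect_identical(sum(lengths(lapply(m$populations, `[[`,
                                      "projections"))), 4L)
  res <- resolve_references(m, component_loader(dir))
  expect_identical(nrow(res$diagnostics), 0L)
  flat <- elaborate(res, seed = 5)
  expect_identical(nrow(flat$diagnostics), 0L)
  # derived-size law across all four synapses
  for (nm in names(flat$sets)) {
    s <- flat$sets[[nm]]
    if (s$kind == "weight_update")
      expect_identical(s$size, sum(flat$edges$dst_set == nm &
                                   flat$edges$src_set %in%
                                     c("Excitatory", "Inhibitory")))
    if (s$kind == "post_synapse") {
      dst <- if (grepl("_to_Exc_", nm)) "Excitatory" else "Inhibitory"
      expect_identical(s$size, flat$sets[[dst]]$size)
    }
  }
})

test_that("zero connection probability yields no synaptic connections", {
  dir <- withr::local_tempdir()
  build_vogels_abbott(benchmark_spec(n_total = 50, connect_probability = 0),
                      dir)
  m <- read_network(file.path(dir, "model.xml"))
  flat <- elaborate(resolve_references(m, component_loader(dir)), seed = 1)
  syn <- flat$edges$src_set %in% c("Excitatory", "Inhibitory") &
    grepl("weight$", flat$edges$dst_set)
  expect_identical(sum(syn), 0L)
  for (s in flat$sets)
    if (s$kind == "weight_update") expect_identical(s$size, 0L)
})

test_that("generated files survive the full read/write round-trip", {
  dir <- withr::local_tempdir()
  paths <- build_vogels_abbott(benchmark_spec(n_total = 60, seed = 2), dir)
  for (p in c(paths$lif, paths$weight, paths$psc)) {
    cc <- read_component(p)
    expect_identical(read_component(write_component(cc)), cc, info = p)
  }
  m <- read_network(paths$network)
  expect_identical(read_network(write_network(m)), m)
  e <- read_experiment(paths$experiment)
  expect_identical(read_experiment(write_experiment(e)), e)
})

test_that("spike statistics match closed forms on regular trains", {
  T_ms <- 20
  train <- data.frame(t_ms = seq(T_ms, 1000, by = T_ms), index = 0L)
  ss <- spike_stats(train, duration_ms = 1000)
  expect_equal(ss$per_instance$cv_isi, 0)
  expect_equal(ss$per_instance$rate_hz, 1000 / T_ms)
  expect_true(all(ss$pooled_isis == T_ms))
})

test_that("Poisson trains give CV near 1 and the nominal rate", {
  set.seed(314)
  rate <- 10; dur_s <- 100
  trains <- lapply(0:4, function(i) {
    ts <- cumsum(rexp(2 * rate * dur_s, rate)) * 1000
    data.frame(t_ms = ts[ts < dur_s * 1000], index = i)
  })
  ss <- spike_stats(do.call(rbind, trains), duration_ms = dur_s * 1000)
  expect_true(all(abs(ss$per_instance$cv_isi - 1) < 0.05))
  expect_true(all(abs(ss$per_instance$rate_hz - rate) <
                    4 * sqrt(rate / dur_s)))
})

test_that("silent and near-silent instances are handled explicitly", {
  ss <- spike_stats(data.frame(t_ms = numeric(0), index = integer(0)),
                    duration_ms = 1000)
  expect_identical(nrow(ss$per_instance), 0L)
  expect_length(ss$pooled_isis, 0L)

  # one spike: no ISI, CV undefined but the instance is counted
  ss <- spike_stats(data.frame(t_ms = 10, index = 0L), duration_ms = 1000,
                    n_instances = 2)
  expect_identical(ss$per_instance$n_spikes, c(1L, 0L))
  expect_true(all(is.na(ss$per_instance$cv_isi)))
  expect_identical(ss$n_cv_excluded, 2L)

  # the discard window removes early spikes from the analysis
  train <- data.frame(t_ms = c(5, 10, 200, 210, 220), index = 0L)
  ss <- spike_stats(train, duration_ms = 1000, discard_initial_ms = 100)
  expect_identical(ss$per_instance$n_spikes, 3L)
  expect_equal(ss$pooled_isis, c(10, 10))
})

test_that("per-instance statistics can be exported as CSV", {
  train <- data.frame(t_ms = seq(10, 500, by = 10), index = 0L)
  ss <- spike_stats(train, duration_ms = 500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_stats(ss, path)
  expect_identical(readLines(path, n = 1), "instance,n_spikes,rate_hz,cv_isi")
})
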