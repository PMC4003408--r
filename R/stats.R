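## Spike-train statistics over event logs: per-instance inter-spike
## intervals, their coefficient of variation, and mean firing rates.

#' Spike-train statistics from an event log
#'
#' Computes, per instance, the inter-spike intervals (successive spike-time
#' differences after discarding an initial transient), their coefficient of
#' variation `CV = sd(ISI)/mean(ISI)` and the mean rate
#' `count / effective duration`. Instances with fewer than two spikes after
#' the discard have no defined CV; they are excluded from the CV column
#' (`NA`) and counted in `n_cv_excluded`.
#'
#' @param events an event log: a data frame with columns `t_ms` and
#'   `index` (0-based), or an entry of a `spineml_logs` object.
#' @param duration_ms total logged duration in ms.
#' @param discard_initial_ms initial transient to drop before analysis
#'   (e.g. while a network reaches equilibrium).
#' @param n_instances number of instances in the logged set; defaults to
#'   the largest index seen plus one. Instances that never spike get rate 0.
#' @return an object of class `spineml_spike_stats`: list with
#'   `per_instance` (data frame `instance`, `n_spikes`, `rate_hz`,
#'   `cv_isi`), `pooled_isis` (numeric vector of all ISIs), `isis`
#'   (per-instance list), `n_cv_excluded` and the analysis window.
#' @export
spike_stats <- function(events, duration_ms, discard_initial_ms = 0,
                        n_instances = NULL) {
  if (is.list(events) && !is.data.frame(events) && !is.null(events$data))
    events <- events$data
  stopifnot(is.data.frame(events), all(c("t_ms", "index") %in% names(events)),
            duration_ms > discard_initial_ms)
  ev <- events[events$t_ms > discard_initial_ms, , drop = FALSE]
  if (is.null(n_instances))
    n_instances <- if (nrow(events) == 0L) 0L else max(events$index) + 1L
  n_instances <- as.integer(n_instances)
  eff_ms <- duration_ms - discard_initial_ms

  isis <- vector("list", n_instances)
  counts <- integer(n_instances)
  if (nrow(ev) > 0L) {
    ord <- order(ev$index, ev$t_ms)
    idx <- ev$index[ord] + 1L
    tms <- ev$t_ms[ord]
    counts <- tabulate(idx, nbins = n_instances)
    split_t <- split(tms, factor(idx, levels = seq_len(n_instances)))
    isis <- lapply(split_t, function(x) if (length(x) >= 2L) diff(x)
                   else numeric(0))
  }
  cv <- vapply(seq_len(n_instances), function(i) {
    x <- isis[[i]]
    if (length(x) < 1L || counts[i] < 2L) return(NA_real_)
    m <- mean(x)
    if (m == 0) return(NA_real_)
    stats::sd(x) / m
  }, 0)
  per <- data.frame(
    instance = seq_len(n_instances) - 1L,
    n_spikes = counts,
    rate_hz = counts / (eff_ms / 1000),
    cv_isi = cv)
  structure(list(per_instance = per,
                 pooled_isis = unlist(isis, use.names = FALSE) %||% numeric(0),
                 isis = isis,
                 n_cv_excluded = sum(is.na(cv)),
                 duration_ms = duration_ms,
                 discard_initial_ms = discard_initial_ms),
            class = "spineml_spike_stats")
}

#' @export
print.spineml_spike_stats <- function(x, ...) {
  p <- x$per_instance
  cat(sprintf("<spike stats: %d instance(s), %d spike(s), window %g-%g ms>\n",
              nrow(p), sum(p$n_spikes), x$discard_initial_ms, x$duration_ms))
  if (nrow(p) > 0L)
    cat(sprintf("  mean rate %.3g Hz, mean CV(ISI) %.3g (%d instance(s) without CV)\n",
                mean(p$rate_hz), mean(p$cv_isi, na.rm = TRUE),
                x$n_cv_excluded))
  invisible(x)
}

#' Write per-instance spike statistics as CSV
#'
#' Columns: `instance`, `n_spikes`, `rate_hz`, `cv_isi`.
#'
#' @param stats a `spineml_spike_stats`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_spike_stats <- function(stats, path) {
  stopifnot(inherits(stats, "spineml_spike_stats"))
  utils::write.table(stats$per_instance, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
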