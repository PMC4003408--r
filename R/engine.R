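## Reference interpreter for elaborated models.
##
## Each step of size dt executes five phases in a fixed order:
##   1. analogue propagation: every analogue receive port is filled from
##      the send-port values computed at the end of the previous step;
##      reduce ports sum all arrivals (zero when none), experiment current
##      inputs are added;
##   2. numerical integration of the active regime's time derivatives
##      (forward Euler or classical RK4), evaluated at the step's start
##      time t_k with receive-port values held constant;
##   3. delivery of due events and impulses, firing OnEvent/OnImpulse
##      handlers (several impulses reaching one instance in the same step
##      are applied sequentially);
##   4. OnCondition triggers evaluated on the post-integration state at
##      t_{k+1}; the first true trigger per instance (document order) fires
##      its assignments, outputs and regime switch;
##   5. the clock advances and post-step values are logged at t_{k+1}.
##
## An output emitted in step k with delay d is delivered during the phase 3
## of step round((t_emit + d)/dt) where t_emit = (k+1)*dt, i.e. delays are
## rounded to the nearest multiple of dt and zero-delay messages arrive in
## the next step. State assignments within a transition are simultaneous:
## all right-hand sides see pre-assignment values.

## regime-indexed compiled dynamics for one instance set
compile_set_plan <- function(s) {
  comp <- s$component
  rnames <- vapply(comp$regimes, `[[`, "", "name")
  alias_names <- comp_alias_names(comp)

  topo_aliases <- function() {
    remaining <- comp$aliases
    ordered <- list(); done <- character(0)
    while (length(remaining) > 0L) {
      ready <- vapply(remaining, function(a)
        all(intersect(free_symbols(a$expression), alias_names) %in% done), TRUE)
      if (!any(ready)) stop("alias cycle (validation should have caught this)")
      for (a in remaining[ready]) {
        ordered[[length(ordered) + 1L]] <-
          list(name = a$name, lang = compile_expression(a$expression))
        done <- c(done, a$name)
      }
      remaining <- remaining[!ready]
    }
    ordered
  }

  compile_body <- function(tr, value_sym = NULL) {
    syms <- character(0)
    assigns <- lapply(tr$state_assignments, function(e) {
      syms <<- c(syms, free_symbols(e)); compile_expression(e)
    })
    impulses <- lapply(tr$impulse_outputs, function(e) {
      syms <<- c(syms, free_symbols(e)); compile_expression(e)
    })
    syms <- setdiff(unique(syms), value_sym)
    list(assigns = assigns, events = tr$event_outputs, impulses = impulses,
         target = match(tr$target_regime, rnames),
         syms = syms, value_sym = value_sym,
         needs_aliases = any(syms %in% alias_names))
  }

  regimes <- vector("list", length(comp$regimes))
  onevent <- list(); onimpulse <- list()
  deriv_vars <- character(0); deriv_syms <- character(0)
  for (ri in seq_along(comp$regimes)) {
    r <- comp$regimes[[ri]]
    derivs <- lapply(r$time_derivatives, compile_expression)
    for (e in r$time_derivatives) deriv_syms <- c(deriv_syms, free_symbols(e))
    deriv_vars <- union(deriv_vars, names(derivs))
    conds <- lapply(r$on_conditions, function(tr) {
      b <- compile_body(tr)
      b$trigger <- compile_expression(tr$trigger)
      b
    })
    regimes[[ri]] <- list(derivs = derivs, conds = conds)
    for (tr in r$on_events) {
      h <- compile_body(tr); h$regime <- ri
      onevent[[tr$src_port]] <- c(onevent[[tr$src_port]], list(h))
    }
    for (tr in r$on_impulses) {
      h <- compile_body(tr, value_sym = tr$src_port); h$regime <- ri
      onimpulse[[tr$src_port]] <- c(onimpulse[[tr$src_port]], list(h))
    }
  }

  list(
    name = s$name, size = s$size,
    n_regimes = length(comp$regimes),
    initial_regime = match(comp$initial_regime, rnames),
    aliases = topo_aliases(),
    has_aliases = length(comp$aliases) > 0L,
    regimes = regimes,
    regimes_with_derivs = which(vapply(regimes, function(r)
      length(r$derivs) > 0L, TRUE)),
    regimes_with_conds = which(vapply(regimes, function(r)
      length(r$conds) > 0L, TRUE)),
    deriv_vars = deriv_vars,
    derivs_use_aliases = any(unique(deriv_syms) %in% alias_names),
    onevent = onevent, onimpulse = onimpulse
  )
}

#' Advance state variables by one step
#'
#' The fixed-step integrators used by the engine, exposed for direct use.
#' Forward Euler applies `x <- x + dt * f(x, t)`; `rk4` the classical
#' four-stage update. Variables without a derivative are left unchanged.
#'
#' @param derivatives named list `variable -> spineml_expr` (or compiled
#'   expression) for d(variable)/dt.
#' @param state named list of current values (may include parameters and
#'   other bindings the derivatives reference).
#' @param t current time (ms).
#' @param dt step (ms).
#' @param method `"forward_euler"` or `"rk4"`.
#' @return named list: updated values for the derivative variables.
#' @export
integrator_step <- function(derivatives, state, t, dt,
                            method = c("forward_euler", "rk4")) {
  method <- match.arg(method)
  langs <- lapply(derivatives, function(d)
    if (inherits(d, "spineml_expr")) compile_expression(d) else d)
  env <- as.environment(c(state, list(t = t)))
  parent.env(env) <- baseenv()
  vars <- names(langs)
  x0 <- mget(vars, env)
  evalf <- function() lapply(langs, eval, envir = env)
  if (method == "forward_euler") {
    f <- evalf()
    return(stats::setNames(lapply(vars, function(v) x0[[v]] + dt * f[[v]]), vars))
  }
  stage <- function(xs, tt) {
    for (v in vars) assign(v, xs[[v]], envir = env)
    assign("t", tt, envir = env)
    evalf()
  }
  k1 <- evalf()
  k2 <- stage(stats::setNames(lapply(vars, function(v)
    x0[[v]] + dt / 2 * k1[[v]]), vars), t + dt / 2)
  k3 <- stage(stats::setNames(lapply(vars, function(v)
    x0[[v]] + dt / 2 * k2[[v]]), vars), t + dt / 2)
  k4 <- stage(stats::setNames(lapply(vars, function(v)
    x0[[v]] + dt * k3[[v]]), vars), t + dt)
  stats::setNames(lapply(vars, function(v)
    x0[[v]] + dt / 6 * (k1[[v]] + 2 * k2[[v]] + 2 * k3[[v]] + k4[[v]])), vars)
}

#' Simulate an elaborated model
#'
#' Runs the declared hybrid dynamics for `ceiling(duration/dt)` steps and
#' returns the requested logs. The run is fully deterministic for a fixed
#' `(flat, experiment, seed)` triple.
#'
#' @param flat a `spineml_flat` model with no diagnostics.
#' @param e a `spineml_experiment` validating cleanly against `flat`.
#' @param seed integer seed for experiment-level randomness (Poisson spike
#'   sources without their own seed).
#' @return an object of class `spineml_logs`: a named list of log entries,
#'   each with `name`, `target`, `port`, `mode` (`"analog"` or `"event"`)
#'   and `data` (`t_ms`/`index`/`value` for analogue logs, `t_ms`/`index`
#'   for event logs; `index` is 0-based and rows are time-ordered).
#' @seealso [write_logs()], [run_experiment()]
#' @export
simulate <- function(flat, e, seed = 1L) {
  stopifnot(inherits(flat, "spineml_flat"), inherits(e, "spineml_experiment"))
  if (nrow(flat$diagnostics) > 0L)
    stop_spineml("flat model has diagnostics; refusing to simulate",
                 "spineml_validation_error", diagnostics = flat$diagnostics)
  ed <- validate_experiment(e, flat)
  if (nrow(ed) > 0L)
    stop_spineml(paste0("experiment does not validate:\n",
                        paste(sprintf("  [%s] %s: %s", ed$severity, ed$rule,
                                      ed$message), collapse = "\n")),
                 "spineml_validation_error", diagnostics = ed)

  dt <- e$dt_ms
  n_steps <- n_steps_of(e)
  set_names <- names(flat$sets)
  n_sets <- length(flat$sets)
  sid <- function(nm) match(nm, set_names)

  plans <- lapply(flat$sets, compile_set_plan)
  envs <- vector("list", n_sets)
  regime <- vector("list", n_sets)
  for (i in seq_len(n_sets)) {
    s <- flat$sets[[i]]
    env <- new.env(parent = baseenv())
    for (nm in names(s$values)) assign(nm, s$values[[nm]], envir = env)
    for (p in s$component$ports)
      if (p$direction == "receive" && p$mode == "analog")
        assign(p$name, numeric(s$size), envir = env)
    assign("t", 0, envir = env)
    envs[[i]] <- env
    regime[[i]] <- rep.int(plans[[i]]$initial_regime %||% 1L, s$size)
  }
  active <- which(vapply(flat$sets, `[[`, 0L, "size") > 0L)

  recompute_aliases <- function(i) {
    env <- envs[[i]]
    for (a in plans[[i]]$aliases) assign(a$name, eval(a$lang, env), envir = env)
  }

  ## ---- classify edges, build emission bundles and analogue groups
  edges <- flat$edges
  port_mode <- function(set_nm, port_nm)
    comp_find_port(flat$sets[[set_nm]]$component, port_nm)$mode
  emode <- character(nrow(edges))
  if (nrow(edges) > 0L) {
    key <- paste0(edges$src_set, "\r", edges$src_port)
    for (k in unique(key)) {
      rows <- which(key == k)
      emode[rows] <- port_mode(edges$src_set[rows[1]], edges$src_port[rows[1]])
    }
  }

  ## out[[set]][[port]] = list of bundles (one per dst set/port/delay)
  out <- lapply(seq_len(n_sets), function(i) list())
  ev_rows <- which(emode %in% c("event", "impulse"))
  if (length(ev_rows) > 0L) {
    sub <- edges[ev_rows, , drop = FALSE]
    sub$ds <- 1L + as.integer(floor(sub$delay_ms / dt + 0.5))
    gkey <- paste0(sub$src_set, "\r", sub$src_port, "\r", sub$dst_set, "\r",
                   sub$dst_port, "\r", sub$ds)
    for (k in unique(gkey)) {
      rows <- sub[gkey == k, , drop = FALSE]
      i <- sid(rows$src_set[1])
      n <- flat$sets[[i]]$size
      si1 <- rows$src_instance + 1L
      ord <- order(si1)
      cnts <- tabulate(si1, nbins = n)
      bundle <- list(dst_set = sid(rows$dst_set[1]),
                     dst_port = rows$dst_port[1],
                     ds = rows$ds[1],
                     dst_inst = rows$dst_instance[ord] + 1L,
                     cnts = cnts, begin = cumsum(cnts) - cnts)
      prt <- rows$src_port[1]
      out[[i]][[prt]] <- c(out[[i]][[prt]], list(bundle))
    }
  }

  ## analogue input groups per (dst set, dst port)
  an_rows <- which(emode == "analog")
  analog_in <- lapply(seq_len(n_sets), function(i) list())
  cache_syms <- lapply(seq_len(n_sets), function(i) character(0))
  if (length(an_rows) > 0L) {
    sub <- edges[an_rows, , drop = FALSE]
    dkey <- paste0(sub$dst_set, "\r", sub$dst_port)
    for (k in unique(dkey)) {
      rows <- sub[dkey == k, , drop = FALSE]
      di <- sid(rows$dst_set[1])
      dprt <- rows$dst_port[1]
      n_dst <- flat$sets[[di]]$size
      p <- comp_find_port(flat$sets[[di]]$component, dprt)
      groups <- list()
      skey <- paste0(rows$src_set, "\r", rows$src_port)
      for (sk in unique(skey)) {
        g <- rows[skey == sk, , drop = FALSE]
        gi <- sid(g$src_set[1])
        msrc <- g$src_instance + 1L
        mdst <- g$dst_instance + 1L
        n_src <- flat$sets[[gi]]$size
        ident <- (nrow(g) == n_dst) && (n_src == n_dst) &&
          !is.unsorted(mdst) && all(mdst == seq_len(n_dst)) &&
          all(msrc == seq_len(n_dst))
        groups[[length(groups) + 1L]] <- list(
          src_set = gi, sym = g$src_port[1], msrc = msrc, mdst = mdst,
          identity = ident, dup = anyDuplicated(mdst) > 0L)
        cache_syms[[gi]] <- union(cache_syms[[gi]], g$src_port[1])
      }
      analog_in[[di]][[length(analog_in[[di]]) + 1L]] <- list(
        port = dprt, reduce = !is.null(p$reduce_op), groups = groups,
        const = 0, tv = NULL)
    }
  }

  ## every analogue receive port with an experiment input but no edges
  ## still needs an entry
  for (inp in e$inputs) {
    if (!inp$kind %in% c("constant_current", "time_varying_current")) next
    di <- sid(inp$target)
    hit <- FALSE
    for (ai in seq_along(analog_in[[di]]))
      if (analog_in[[di]][[ai]]$port == inp$port) hit <- TRUE
    if (!hit)
      analog_in[[di]][[length(analog_in[[di]]) + 1L]] <- list(
        port = inp$port, reduce = TRUE, groups = list(), const = 0, tv = NULL)
  }
  for (inp in e$inputs) {
    if (!inp$kind %in% c("constant_current", "time_varying_current")) next
    di <- sid(inp$target)
    for (ai in seq_along(analog_in[[di]])) {
      if (analog_in[[di]][[ai]]$port != inp$port) next
      if (inp$kind == "constant_current") {
        analog_in[[di]][[ai]]$const <- analog_in[[di]][[ai]]$const + inp$value
      } else {
        tk <- (seq_len(n_steps) - 1L) * dt
        pos <- findInterval(tk + 1e-9, inp$times_ms)
        vals <- c(0, inp$values)[pos + 1L]
        prev <- analog_in[[di]][[ai]]$tv
        analog_in[[di]][[ai]]$tv <- if (is.null(prev)) vals else prev + vals
      }
    }
  }

  ## ---- logging
  modes <- log_modes(e, flat)
  n_logs <- length(e$logs)
  log_mat <- vector("list", n_logs)
  log_ev <- vector("list", n_logs)
  ev_log_idx <- lapply(seq_len(n_sets), function(i) list())
  for (li in seq_len(n_logs)) {
    lg <- e$logs[[li]]
    i <- sid(lg$target)
    if (modes[li] == "analog") {
      log_mat[[li]] <- matrix(NA_real_, nrow = flat$sets[[i]]$size,
                              ncol = n_steps)
      cache_syms[[i]] <- union(cache_syms[[i]], lg$port)
    } else {
      acc <- new.env(parent = emptyenv())
      acc$t <- list(); acc$i <- list(); acc$n <- 0L
      log_ev[[li]] <- acc
      ev_log_idx[[i]][[lg$port]] <- c(ev_log_idx[[i]][[lg$port]], li)
    }
  }
  needs_cache <- which(lengths(cache_syms) > 0L)
  alias_cached <- vapply(seq_len(n_sets), function(i)
    any(cache_syms[[i]] %in% vapply(plans[[i]]$aliases, `[[`, "", "name")),
    TRUE)

  ## ---- pending event/impulse queue keyed by absolute step index
  q <- new.env(parent = emptyenv())
  enqueue <- function(step, entry) {
    k <- as.character(step)
    cur <- q[[k]]
    q[[k]] <- if (is.null(cur)) list(entry) else c(cur, list(entry))
  }

  emit <- function(i, port, inst, vals, k) {
    lis <- ev_log_idx[[i]][[port]]
    if (!is.null(lis)) {
      tm <- (k + 1) * dt
      for (li in lis) {
        acc <- log_ev[[li]]
        acc$n <- acc$n + 1L
        acc$t[[acc$n]] <- tm
        acc$i[[acc$n]] <- inst - 1L
      }
    }
    for (b in out[[i]][[port]] %||% list()) {
      cnt <- b$cnts[inst]
      tot <- sum(cnt)
      if (tot == 0L) next
      rows <- rep.int(b$begin[inst], cnt) + sequence(cnt)
      enqueue(k + b$ds, list(
        set = b$dst_set, port = b$dst_port, inst = b$dst_inst[rows],
        vals = if (is.null(vals)) NULL else rep.int(vals, cnt)))
    }
  }

  fire_handlers <- function(i, handlers, inst, vals, k) {
    env <- envs[[i]]
    rv <- regime[[i]]
    for (h in handlers) {
      keep <- if (plans[[i]]$n_regimes > 1L) rv[inst] == h$regime
              else rep(TRUE, length(inst))
      hi <- inst[keep]
      hv <- if (is.null(vals)) NULL else vals[keep]
      while (length(hi) > 0L) {
        first <- !duplicated(hi)
        i2 <- hi[first]
        v2 <- if (is.null(hv)) NULL else hv[first]
        if (h$needs_aliases) recompute_aliases(i)
        lst <- list()
        for (snm in h$syms) {
          val <- get(snm, envir = env)
          lst[[snm]] <- if (length(val) > 1L) val[i2] else val
        }
        if (!is.null(h$value_sym)) lst[[h$value_sym]] <- v2
        if (length(h$assigns) > 0L) {
          res <- lapply(h$assigns, eval, envir = lst, enclos = baseenv())
          for (v in names(res)) {
            cur <- get(v, envir = env)
            cur[i2] <- res[[v]]
            assign(v, cur, envir = env)
          }
        }
        for (p in h$events) emit(i, p, i2, NULL, k)
        for (p in names(h$impulses)) {
          val <- eval(h$impulses[[p]], lst, baseenv())
          if (length(val) == 1L && length(i2) > 1L) val <- rep(val, length(i2))
          emit(i, p, i2, val, k)
        }
        if (!is.na(h$target) && h$target != h$regime)
          regime[[i]][i2] <<- h$target
        hi <- hi[!first]
        if (!is.null(hv)) hv <- hv[!first]
      }
    }
  }

  ## ---- prefill the queue from experiment spike sources
  for (ii in seq_along(e$inputs)) {
    inp <- e$inputs[[ii]]
    i <- sid(inp$target)
    n <- flat$sets[[i]]$size
    if (inp$kind == "explicit_spike_source") {
      for (tm in inp$times_ms) {
        step <- max(0L, as.integer(floor(tm / dt + 0.5)))
        if (step < n_steps)
          enqueue(step, list(set = i, port = inp$port, inst = seq_len(n),
                             vals = NULL))
      }
    } else if (inp$kind == "poisson_spike_source") {
      if (inp$rate_hz <= 0) next
      sseed <- inp$seed %||% derive_seed(seed, 7000L + ii)
      dur_ms <- n_steps * dt
      with_seed(sseed, {
        for (j in seq_len(n)) {
          ts <- numeric(0); tcur <- 0
          repeat {
            tcur <- tcur + stats::rexp(1, inp$rate_hz) * 1000
            if (tcur >= dur_ms) break
            ts[[length(ts) + 1L]] <- tcur
          }
          for (step in unique(pmax(0L, as.integer(floor(ts / dt + 0.5)))))
            if (step < n_steps)
              enqueue(step, list(set = i, port = inp$port, inst = j,
                                 vals = NULL))
        }
      })
    }
  }

  ## ---- send-value cache (end-of-previous-step values)
  cache <- vector("list", n_sets)
  refresh_cache <- function(i) {
    if (alias_cached[i]) recompute_aliases(i)
    env <- envs[[i]]
    cache[[i]] <<- mget(cache_syms[[i]], envir = env)
  }
  for (i in intersect(needs_cache, active)) refresh_cache(i)

  ## ---- main loop
  finite_check <- function(i, k) {
    env <- envs[[i]]
    for (v in plans[[i]]$deriv_vars) {
      val <- get(v, envir = env)
      if (anyNA(val) || !all(is.finite(val)))
        stop_spineml(sprintf(
          "non-finite value of \"%s\" in set \"%s\" at t=%g ms",
          v, set_names[i], (k + 1) * dt), "spineml_numeric_error")
    }
  }

  rk4 <- e$integrator == "rk4"
  for (k in 0:(n_steps - 1L)) {
    tk <- k * dt

    ## phase 1: analogue propagation
    for (i in active) {
      ports <- analog_in[[i]]
      if (length(ports) == 0L) next
      env <- envs[[i]]
      n <- flat$sets[[i]]$size
      for (a in ports) {
        acc <- numeric(n)
        for (g in a$groups) {
          sv <- cache[[g$src_set]][[g$sym]]
          if (g$identity) {
            acc <- acc + sv
          } else if (!g$dup) {
            acc[g$mdst] <- acc[g$mdst] + sv[g$msrc]
          } else {
            rs <- rowsum(sv[g$msrc], g$mdst)
            ti <- as.integer(rownames(rs))
            acc[ti] <- acc[ti] + rs[, 1L]
          }
        }
        if (a$const != 0) acc <- acc + a$const
        if (!is.null(a$tv)) acc <- acc + a$tv[k + 1L]
        assign(a$port, acc, envir = env)
      }
    }

    ## phase 2: integration at t_k
    for (i in active) {
      ps <- plans[[i]]
      if (length(ps$regimes_with_derivs) == 0L) next
      env <- envs[[i]]
      assign("t", tk, envir = env)
      if (ps$has_aliases && ps$derivs_use_aliases) recompute_aliases(i)
      rv <- regime[[i]]
      vars <- ps$deriv_vars
      x0 <- mget(vars, envir = env)
      newx <- x0
      single <- ps$n_regimes == 1L
      for (r in ps$regimes_with_derivs) {
        idx <- if (single) NULL else which(rv == r)
        if (!single && length(idx) == 0L) next
        derivs <- ps$regimes[[r]]$derivs
        if (!rk4) {
          for (v in names(derivs)) {
            f <- eval(derivs[[v]], env)
            nv <- x0[[v]] + dt * f
            if (single) newx[[v]] <- nv else newx[[v]][idx] <- nv[idx]
          }
        } else {
          dvars <- names(derivs)
          evalf <- function() lapply(derivs, eval, envir = env)
          restore <- function() for (v in vars) assign(v, x0[[v]], envir = env)
          stage <- function(kk, fac, tt) {
            for (v in dvars) assign(v, x0[[v]] + fac * kk[[v]], envir = env)
            assign("t", tt, envir = env)
            if (ps$has_aliases && ps$derivs_use_aliases) recompute_aliases(i)
            evalf()
          }
          if (ps$has_aliases && ps$derivs_use_aliases) recompute_aliases(i)
          k1 <- evalf()
          k2 <- stage(k1, dt / 2, tk + dt / 2)
          k3 <- stage(k2, dt / 2, tk + dt / 2)
          k4 <- stage(k3, dt, tk + dt)
          restore(); assign("t", tk, envir = env)
          for (v in dvars) {
            nv <- x0[[v]] + dt / 6 * (k1[[v]] + 2 * k2[[v]] + 2 * k3[[v]] + k4[[v]])
            if (single) newx[[v]] <- nv else newx[[v]][idx] <- nv[idx]
          }
        }
      }
      for (v in vars) assign(v, newx[[v]], envir = env)
      finite_check(i, k)
    }

    ## phases 3-4 see the post-integration clock
    for (i in active) assign("t", tk + dt, envir = envs[[i]])

    ## phase 3: deliver due events/impulses
    key <- as.character(k)
    entries <- q[[key]]
    if (!is.null(entries)) {
      rm(list = key, envir = q)
      groups <- list()
      for (en in entries) {
        gk <- paste0(en$set, "\r", en$port)
        g <- groups[[gk]]
        if (is.null(g)) {
          groups[[gk]] <- en
        } else {
          g$inst <- c(g$inst, en$inst)
          if (!is.null(en$vals)) g$vals <- c(g$vals, en$vals)
          groups[[gk]] <- g
        }
      }
      for (g in groups) {
        prt <- comp_find_port(flat$sets[[g$set]]$component, g$port)
        hs <- if (is.null(prt) || prt$mode == "event")
          plans[[g$set]]$onevent[[g$port]]
        else plans[[g$set]]$onimpulse[[g$port]]
        if (!is.null(hs)) fire_handlers(g$set, hs, g$inst, g$vals, k)
      }
    }

    ## phase 4: OnCondition triggers on the post-integration state
    for (i in active) {
      ps <- plans[[i]]
      if (length(ps$regimes_with_conds) == 0L) next
      env <- envs[[i]]
      if (ps$has_aliases) recompute_aliases(i)
      rv <- regime[[i]]
      fired <- NULL
      for (r in ps$regimes_with_conds) {
        in_r <- if (ps$n_regimes == 1L) NULL else rv == r
        for (cond in ps$regimes[[r]]$conds) {
          cv <- eval(cond$trigger, env)
          sel <- if (is.null(in_r)) cv else in_r & cv
          if (!is.null(fired)) sel <- sel & !fired
          idx <- which(sel)
          if (length(idx) == 0L) next
          if (is.null(fired)) fired <- logical(flat$sets[[i]]$size)
          fired[idx] <- TRUE
          if (length(cond$assigns) > 0L) {
            res <- lapply(cond$assigns, eval, envir = env)
            for (v in names(res)) {
              cur <- get(v, envir = env)
              rhs <- res[[v]]
              cur[idx] <- if (length(rhs) > 1L) rhs[idx] else rhs
              assign(v, cur, envir = env)
            }
          }
          for (p in cond$events) emit(i, p, idx, NULL, k)
          for (p in names(cond$impulses)) {
            val <- eval(cond$impulses[[p]], env)
            val <- if (length(val) > 1L) val[idx] else rep(val, length(idx))
            emit(i, p, idx, val, k)
          }
          regime[[i]][idx] <- cond$target
        }
      }
    }

    ## phase 5: advance the clock, refresh send caches, log
    for (i in intersect(needs_cache, active)) refresh_cache(i)
    for (li in seq_len(n_logs)) {
      if (modes[li] != "analog") next
      lg <- e$logs[[li]]
      i <- sid(lg$target)
      log_mat[[li]][, k + 1L] <- cache[[i]][[lg$port]]
    }
  }

  ## ---- finalise logs
  logs <- list()
  for (li in seq_len(n_logs)) {
    lg <- e$logs[[li]]
    if (modes[li] == "analog") {
      n <- nrow(log_mat[[li]])
      data <- data.frame(
        t_ms = rep(seq_len(n_steps) * dt, each = n),
        index = rep(0:(n - 1L), times = n_steps),
        value = as.vector(log_mat[[li]]))
    } else {
      acc <- log_ev[[li]]
      if (acc$n == 0L) {
        data <- data.frame(t_ms = numeric(0), index = integer(0))
      } else {
        lens <- lengths(acc$i[seq_len(acc$n)])
        data <- data.frame(
          t_ms = rep(unlist(acc$t[seq_len(acc$n)]), times = lens),
          index = unlist(acc$i[seq_len(acc$n)]))
      }
    }
    logs[[lg$name]] <- list(name = lg$name, target = lg$target,
                            port = lg$port, mode = modes[li], data = data)
  }
  structure(list(logs = logs, dt_ms = dt, duration_s = e$duration_s,
                 n_steps = n_steps, seed = as.integer(seed)),
            class = "spineml_logs")
}

#' @export
print.spineml_logs <- function(x, ...) {
  cat(sprintf("<simulation logs: %d step(s) of %g ms>\n", x$n_steps, x$dt_ms))
  for (lg in x$logs)
    cat(sprintf("  %s [%s] %s.%s: %d row(s)\n", lg$name, lg$mode, lg$target,
                lg$port, nrow(lg$data)))
  invisible(x)
}

#' Write simulation logs as CSV
#'
#' One file per log request, named `<logname>.csv`: analogue logs have
#' columns `t_ms,index,value`, event logs `t_ms,index` (0-based instance
#' indices).
#'
#' @param logs a `spineml_logs` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_logs <- function(logs, dir) {
  stopifnot(inherits(logs, "spineml_logs"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (lg in logs$logs) {
    path <- file.path(dir, paste0(lg$name, ".csv"))
    utils::write.table(lg$data, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Load, elaborate and simulate a three-layer model from disk
#'
#' Reads an experiment file, loads the network it references (relative to
#' the experiment's directory) and all components (relative urls), resolves
#' and elaborates the model, validates the experiment against it and runs
#' the simulation.
#'
#' @param path experiment XML file.
#' @param seed integer seed for elaboration and simulation.
#' @param outdir optional directory to write CSV logs into.
#' @return a `spineml_logs` object.
#' @export
run_experiment <- function(path, seed = 1L, outdir = NULL) {
  e <- read_experiment(path)
  dir <- dirname(normalizePath(path))
  m <- read_network(file.path(dir, e$model_url))
  res <- resolve_references(m, component_loader(dir))
  if (nrow(res$diagnostics) > 0L)
    stop_spineml(paste0("model does not resolve:\n",
                        paste(sprintf("  [%s] %s: %s",
                                      res$diagnostics$severity,
                                      res$diagnostics$rule,
                                      res$diagnostics$message),
                              collapse = "\n")),
                 "spineml_validation_error", diagnostics = res$diagnostics)
  flat <- elaborate(res, seed = seed)
  logs <- simulate(flat, e, seed = seed)
  if (!is.null(outdir)) write_logs(logs, outdir)
  logs
}
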