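#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `code` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards so library code never perturbs user randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic derived seeds, kept inside 32-bit integer range.
derive_seed <- function(base, k) {
  b <- as.double(base) %% 2147483647
  as.integer((b * 48271 + as.double(k) * 16807 + 1) %% 2147483647)
}

## Diagnostics are plain data frames: one row per finding.
diag_frame <- function(rule = character(), element = character(),
                       message = character(), severity = character()) {
  structure(
    data.frame(rule = rule, element = element, message = message,
               severity = severity, stringsAsFactors = FALSE),
    class = c("spineml_diagnostics", "data.frame")
  )
}

diag_row <- function(rule, element, message, severity = "error") {
  diag_frame(rule, element, message, severity)
}

diag_bind <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0L, list(...))
  if (length(parts) == 0L) return(diag_frame())
  structure(do.call(rbind, parts),
            class = c("spineml_diagnostics", "data.frame"))
}

#' @export
print.spineml_diagnostics <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No diagnostics.\n")
  } else {
    cat(nrow(x), "diagnostic(s):\n")
    for (i in seq_len(nrow(x)))
      cat(sprintf("  [%s] %s at %s: %s\n", x$severity[i], x$rule[i],
                  x$element[i], x$message[i]))
  }
  invisible(x)
}

stop_spineml <- function(msg, class, ...) {
  stop(structure(class = c(class, "spineml_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

## SI unit strings accepted for the `dimension` attribute of parameters,
## state variables, aliases and ports. Simulators map each entry to a base
## dimension and scale by table lookup; "none" marks dimensionless quantities.
spineml_si_units <- c(
  "V", "mV", "uV", "A", "mA", "uA", "nA", "pA", "S", "mS", "uS", "nS",
  "F", "uF", "nF", "pF", "s", "ms", "us", "Hz", "none"
)

is_valid_dimension <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && x %in% spineml_si_units
}
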