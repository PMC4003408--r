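## Math expression support for MathInline bodies.
##
## The grammar is C-like: + - * / with unary minus, parentheses, the
## comparison operators > < >= <= == !=, the boolean operators && || !,
## and the function set exp, log, ln, sin, cos, sqrt, pow, fabs.
## Numeric literals keep their source lexeme so serialisation round-trips
## exactly; identifiers are resolved against per-instance bindings at
## evaluation time.

.sp_functions <- c(exp = 1L, log = 1L, ln = 1L, sin = 1L, cos = 1L,
                   sqrt = 1L, pow = 2L, fabs = 1L)

.sp_prec <- c("||" = 1L, "&&" = 2L, "==" = 3L, "!=" = 3L,
              "<" = 4L, ">" = 4L, "<=" = 4L, ">=" = 4L,
              "+" = 5L, "-" = 5L, "*" = 6L, "/" = 6L)

.sp_bool_ops <- c("||", "&&", "==", "!=", "<", ">", "<=", ">=", "!")

expr_node_num <- function(text) {
  list(kind = "num", value = as.numeric(text), text = text)
}
expr_node_sym <- function(name) list(kind = "sym", name = name)
expr_node_op <- function(op, args) list(kind = "op", op = op, args = args)
expr_node_call <- function(fn, args) list(kind = "call", fn = fn, args = args)

sp_tokenize <- function(text) {
  pat <- paste0(
    "[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?|\\.[0-9]+([eE][+-]?[0-9]+)?",
    "|[A-Za-z_][A-Za-z0-9_]*",
    "|&&|\\|\\||<=|>=|==|!=",
    "|[-+*/(),<>!]"
  )
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    starts <- integer(0); lens <- integer(0)
  } else {
    starts <- as.integer(m); lens <- attr(m, "match.length")
  }
  ## every character outside a token must be whitespace
  covered <- rep(FALSE, nchar(text))
  for (i in seq_along(starts))
    covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  bad <- which(!covered & !grepl("^[[:space:]]$", chars))
  if (length(bad) > 0L)
    stop_spineml(sprintf(
      "syntax error in \"%s\": unexpected character '%s' at offset %d",
      text, chars[bad[1]], bad[1]), "spineml_parse_error",
      offset = bad[1])
  toks <- substring(text, starts, starts + lens - 1L)
  type <- ifelse(grepl("^[0-9.]", toks), "num",
          ifelse(grepl("^[A-Za-z_]", toks), "ident", "punct"))
  list(tok = toks, type = type, pos = starts, n = length(toks))
}

#' Parse a MathInline expression
#'
#' Parses the arithmetic/relational expression language used inside
#' `MathInline` elements into an expression tree. The grammar follows C
#' conventions for precedence and associativity and admits the functions
#' `exp`, `log`, `ln`, `sin`, `cos`, `sqrt`, `pow` and `fabs`. XML entity
#' escapes (`&gt;` and friends) are assumed to have been decoded already by
#' the XML reader.
#'
#' @param text a single non-empty string.
#' @return an object of class `spineml_expr`: a list with elements `root`
#'   (the tree) and `source` (the canonical serialised form of the input).
#' @examples
#' e <- parse_expression("t > t_spike + tau_refractory")
#' free_symbols(e)
#' evaluate_expression(parse_expression("exp(-(t)/tau_syn)"),
#'                     list(t = 0, tau_syn = 10))
#' @export
parse_expression <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop_spineml("expression text must be a single non-empty string",
                 "spineml_parse_error")
  st <- sp_tokenize(text)
  i <- 1L
  peek <- function() if (i <= st$n) st$tok[i] else ""
  peek_type <- function() if (i <= st$n) st$type[i] else "eof"
  pos_here <- function() if (i <= st$n) st$pos[i] else nchar(text) + 1L
  fail <- function(msg) {
    stop_spineml(sprintf("syntax error in \"%s\" at offset %d: %s",
                         text, pos_here(), msg),
                 "spineml_parse_error", offset = pos_here())
  }
  advance <- function() { tk <- st$tok[i]; i <<- i + 1L; tk }
  expect <- function(tk) if (peek() == tk) advance() else
    fail(sprintf("expected '%s'", tk))

  parse_primary <- function() {
    tp <- peek_type()
    if (tp == "num") return(expr_node_num(advance()))
    if (tp == "ident") {
      nm <- advance()
      if (peek() == "(") {
        if (!nm %in% names(.sp_functions))
          stop_spineml(sprintf(
            "unknown function \"%s\" in \"%s\" at offset %d", nm, text,
            st$pos[i - 1L]), "spineml_parse_error", offset = st$pos[i - 1L])
        advance()
        args <- list(parse_binary(1L))
        while (peek() == ",") { advance(); args <- c(args, list(parse_binary(1L))) }
        expect(")")
        if (length(args) != .sp_functions[[nm]])
          fail(sprintf("function %s takes %d argument(s), got %d",
                       nm, .sp_functions[[nm]], length(args)))
        return(expr_node_call(nm, args))
      }
      return(expr_node_sym(nm))
    }
    if (peek() == "(") {
      advance()
      e <- parse_binary(1L)
      expect(")")
      return(e)
    }
    fail("expected a literal, identifier or '('")
  }

  parse_unary <- function() {
    if (peek() == "-") { advance(); return(expr_node_op("neg", list(parse_unary()))) }
    if (peek() == "!") { advance(); return(expr_node_op("not", list(parse_unary()))) }
    parse_primary()
  }

  parse_binary <- function(min_prec) {
    lhs <- parse_unary()
    repeat {
      op <- peek()
      pr <- .sp_prec[op]
      if (is.na(pr) || pr < min_prec) return(lhs)
      advance()
      rhs <- parse_binary(pr + 1L)  # left-associative
      lhs <- expr_node_op(unname(op), list(lhs, rhs))
    }
  }

  root <- parse_binary(1L)
  if (i <= st$n) fail(sprintf("unexpected token '%s'", peek()))
  ## the stored source is the canonical serialisation, so structurally
  ## equal trees compare identical() regardless of input whitespace
  structure(list(root = root, source = serialize_node(root)),
            class = "spineml_expr")
}

node_prec <- function(node) {
  if (node$kind == "op") {
    if (node$op %in% c("neg", "not")) return(7L)
    return(unname(.sp_prec[node$op]))
  }
  8L
}

serialize_node <- function(node) {
  wrap <- function(child, need) {
    s <- serialize_node(child)
    if (need) paste0("(", s, ")") else s
  }
  switch(node$kind,
    num = node$text,
    sym = node$name,
    call = paste0(node$fn, "(",
                  paste(vapply(node$args, serialize_node, ""), collapse = ", "),
                  ")"),
    op = {
      if (node$op == "neg") {
        paste0("-", wrap(node$args[[1]], node_prec(node$args[[1]]) < 7L))
      } else if (node$op == "not") {
        paste0("!", wrap(node$args[[1]], node_prec(node$args[[1]]) < 7L))
      } else {
        p <- node_prec(node)
        paste0(wrap(node$args[[1]], node_prec(node$args[[1]]) < p),
               " ", node$op, " ",
               wrap(node$args[[2]], node_prec(node$args[[2]]) <= p))
      }
    },
    stop("unknown node kind"))
}

#' Serialise an expression tree back to text
#'
#' Produces a textual form that parses back to a structurally identical tree.
#' Parentheses are inserted only where required by precedence or
#' associativity.
#'
#' @param expr a `spineml_expr`.
#' @return a string.
#' @export
serialize_expression <- function(expr) {
  stopifnot(inherits(expr, "spineml_expr"))
  serialize_node(expr$root)
}

#' @export
print.spineml_expr <- function(x, ...) {
  cat("<MathInline> ", serialize_expression(x), "\n", sep = "")
  invisible(x)
}

#' Free symbols of an expression
#'
#' @param expr a `spineml_expr`.
#' @return sorted character vector of the identifiers appearing as leaves.
#' @export
free_symbols <- function(expr) {
  stopifnot(inherits(expr, "spineml_expr"))
  acc <- character(0)
  walk <- function(node) {
    if (node$kind == "sym") acc[[length(acc) + 1L]] <<- node$name
    else if (node$kind %in% c("op", "call"))
      for (a in node$args) walk(a)
  }
  walk(expr$root)
  sort(unique(acc))
}

## TRUE if the tree contains any comparison/boolean operator (used to reject
## boolean arithmetic where a real-valued expression is required).
expr_contains_boolean <- function(expr) {
  found <- FALSE
  walk <- function(node) {
    if (found) return()
    if (node$kind == "op") {
      if (node$op %in% .sp_bool_ops) { found <<- TRUE; return() }
      for (a in node$args) walk(a)
    } else if (node$kind == "call") for (a in node$args) walk(a)
  }
  walk(expr$root)
  found
}

## TRUE if the root yields a boolean (comparison or boolean connective).
expr_is_boolean <- function(expr) {
  n <- expr$root
  n$kind == "op" && n$op %in% .sp_bool_ops
}

#' Evaluate an expression against bindings
#'
#' Walks the tree directly, checking every symbol is bound and flagging
#' numeric-domain violations (division by zero, `log`/`ln` of a non-positive
#' value, `sqrt` of a negative value) with the offending subexpression named.
#' Values may be vectors; arithmetic follows R's elementwise recycling of
#' scalars.
#'
#' @param expr a `spineml_expr`.
#' @param env named list or environment mapping symbol names to numeric
#'   values.
#' @return numeric vector, or logical vector for comparisons/boolean
#'   operators.
#' @export
evaluate_expression <- function(expr, env) {
  stopifnot(inherits(expr, "spineml_expr"))
  if (is.environment(env)) lookup <- function(nm)
    if (exists(nm, envir = env, inherits = FALSE)) get(nm, envir = env) else NULL
  else lookup <- function(nm) env[[nm]]
  ev <- function(node) {
    switch(node$kind,
      num = node$value,
      sym = {
        v <- lookup(node$name)
        if (is.null(v))
          stop_spineml(sprintf("unbound symbol \"%s\" in \"%s\"",
                               node$name, expr$source),
                       "spineml_eval_error", symbol = node$name)
        v
      },
      call = {
        a <- lapply(node$args, ev)
        switch(node$fn,
          exp = exp(a[[1]]),
          log = , ln = {
            if (any(a[[1]] <= 0))
              stop_spineml(sprintf("log of non-positive value in \"%s\"",
                                   serialize_node(node)),
                           "spineml_domain_error")
            log(a[[1]])
          },
          sin = sin(a[[1]]),
          cos = cos(a[[1]]),
          sqrt = {
            if (any(a[[1]] < 0))
              stop_spineml(sprintf("sqrt of negative value in \"%s\"",
                                   serialize_node(node)),
                           "spineml_domain_error")
            sqrt(a[[1]])
          },
          pow = a[[1]]^a[[2]],
          fabs = abs(a[[1]]))
      },
      op = {
        if (node$op == "neg") return(-ev(node$args[[1]]))
        if (node$op == "not") return(!ev(node$args[[1]]))
        l <- ev(node$args[[1]]); r <- ev(node$args[[2]])
        switch(node$op,
          "+" = l + r, "-" = l - r, "*" = l * r,
          "/" = {
            if (any(r == 0))
              stop_spineml(sprintf("division by zero in \"%s\"",
                                   serialize_node(node)),
                           "spineml_domain_error")
            l / r
          },
          ">" = l > r, "<" = l < r, ">=" = l >= r, "<=" = l <= r,
          "==" = l == r, "!=" = l != r,
          "&&" = as.logical(l) & as.logical(r),
          "||" = as.logical(l) | as.logical(r))
      })
  }
  ev(expr$root)
}

## Compile a tree to an R language object for fast vectorised evaluation in
## the simulation engine. Semantics match evaluate_expression minus the
## domain checks (the engine checks for non-finite state after each step).
compile_expression <- function(expr) {
  comp <- function(node) {
    switch(node$kind,
      num = node$value,
      sym = as.name(node$name),
      call = {
        a <- lapply(node$args, comp)
        fn <- switch(node$fn, ln = "log", fabs = "abs", pow = "^", node$fn)
        as.call(c(list(as.name(fn)), a))
      },
      op = {
        a <- lapply(node$args, comp)
        op <- switch(node$op, neg = "-", not = "!", "&&" = "&", "||" = "|",
                     node$op)
        as.call(c(list(as.name(op)), a))
      })
  }
  comp(expr$root)
}
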