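# Boolean rule expressions: literals with optional time delays, negation,
# conjunction, disjunction, and the constants 0/1.

#' Construct rule-expression nodes
#'
#' Low-level constructors for the expression trees used to represent Boolean
#' update rules. Most users will obtain expressions from [parse_rule()] or a
#' rule file instead of building them by hand.
#'
#' @param node Node (regulator) name.
#' @param delay Non-negative integer; `0` denotes the ordinary synchronous
#'   regulator (value at the previous time step). A delay `k >= 1` written
#'   `X(-k)` reads the value of `X` exactly `k` steps before the state being
#'   computed, so `X(-1)` is equivalent to a plain literal.
#' @param x,... Sub-expressions.
#' @param value Constant value, 0 or 1.
#' @return A `rule_expr` object.
#' @seealso [parse_rule()], [format_rule()]
#' @export
rx_lit <- function(node, delay = 0L) {
  stopifnot(is.character(node), length(node) == 1L, nzchar(node))
  delay <- as.integer(delay)
  stopifnot(length(delay) == 1L, !is.na(delay), delay >= 0L)
  structure(list(op = "lit", node = node, delay = delay), class = "rule_expr")
}

#' @rdname rx_lit
#' @export
rx_not <- function(x) {
  stopifnot(inherits(x, "rule_expr"))
  structure(list(op = "not", x = x), class = "rule_expr")
}

#' @rdname rx_lit
#' @export
rx_and <- function(...) {
  args <- list(...)
  stopifnot(length(args) >= 1L, all(vapply(args, inherits, TRUE, "rule_expr")))
  if (length(args) == 1L) return(args[[1L]])
  structure(list(op = "and", args = args), class = "rule_expr")
}

#' @rdname rx_lit
#' @export
rx_or <- function(...) {
  args <- list(...)
  stopifnot(length(args) >= 1L, all(vapply(args, inherits, TRUE, "rule_expr")))
  if (length(args) == 1L) return(args[[1L]])
  structure(list(op = "or", args = args), class = "rule_expr")
}

#' @rdname rx_lit
#' @export
rx_const <- function(value) {
  value <- as.integer(value)
  stopifnot(length(value) == 1L, value %in% c(0L, 1L))
  structure(list(op = "const", value = value), class = "rule_expr")
}

# --- tokenizer ---------------------------------------------------------------

# Token kinds: lparen, rparen, not, and, or, name, delay, const.
# Bare names may contain letters, digits, "_", "-" and "/" (e.g. ARP2/3,
# F-actin_new); names with other characters (spaces) must be double-quoted.
tokenize_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(kind, value, pos) {
    toks[[length(toks) + 1L]] <<- list(kind = kind, value = value, pos = pos)
  }
  while (i <= n) {
    ch <- substr(text, i, i)
    rest <- substr(text, i, n)
    if (grepl("^\\s", ch)) {
      i <- i + 1L
    } else if (ch %in% c("&", "∧")) {
      push("and", "&", i); i <- i + 1L
    } else if (ch %in% c("|", "∨")) {
      push("or", "|", i); i <- i + 1L
    } else if (ch %in% c("!", "¬")) {
      push("not", "!", i); i <- i + 1L
    } else if (ch == ")") {
      push("rparen", ")", i); i <- i + 1L
    } else if (ch == "(") {
      m <- regmatches(rest, regexpr("^\\(-[0-9]+\\)", rest))
      if (length(m) == 1L && nzchar(m)) {
        k <- as.integer(sub("^\\(-([0-9]+)\\)$", "\\1", m))
        if (k < 1L) {
          stop(sprintf("invalid delay '%s' at position %d: delay must be >= 1",
                       m, i), call. = FALSE)
        }
        push("delay", k, i)
        i <- i + nchar(m)
      } else if (grepl("^\\(\\s*-", rest)) {
        stop(sprintf("malformed delay suffix at position %d", i), call. = FALSE)
      } else {
        push("lparen", "(", i); i <- i + 1L
      }
    } else if (ch == "\"") {
      m <- regmatches(rest, regexpr("^\"[^\"]*\"", rest))
      if (length(m) == 0L || !nzchar(m)) {
        stop(sprintf("unterminated quoted name at position %d", i),
             call. = FALSE)
      }
      nm <- substr(m, 2L, nchar(m) - 1L)
      if (!nzchar(nm)) stop(sprintf("empty quoted name at position %d", i),
                            call. = FALSE)
      push("name", nm, i)
      i <- i + nchar(m)
    } else if (grepl("^[01]([^A-Za-z0-9_]|$)", rest)) {
      push("const", as.integer(ch), i); i <- i + 1L
    } else if (grepl("^[A-Za-z]", ch)) {
      m <- regmatches(rest, regexpr("^[A-Za-z][A-Za-z0-9_/.-]*", rest))
      push("name", m, i)
      i <- i + nchar(m)
    } else {
      stop(sprintf("unknown token '%s' at position %d", ch, i), call. = FALSE)
    }
  }
  toks
}

# --- recursive-descent parser ------------------------------------------------
# expr   := term ( '|' term )*
# term   := factor ( '&' factor )*
# factor := '!' factor | '(' expr ')' | const | name delay?
# '|' and '&' parse as flat n-ary nodes, so parsing the canonical printed
# form reproduces the tree exactly.

#' Parse a Boolean rule expression
#'
#' Parses a rule string over literals, negation (`!` or `¬`),
#' conjunction (`&` or `∧`), disjunction (`|` or `∨`), parentheses
#' and the constants `0`/`1`. A literal may carry a time-delay suffix
#' `(-k)` with `k >= 1`: when the rule is evaluated to produce the state at
#' time `t + 1`, a literal `X(-k)` reads the value of `X` at time
#' `t + 1 - k` (so `X(-1)` is the ordinary regulator). Names with characters
#' outside letters, digits, `_`, `-`, `/` must be double-quoted.
#'
#' @param text A single rule string.
#' @return A `rule_expr` expression tree.
#' @examples
#' parse_rule("!PRKD1")
#' parse_rule("RAC1(-2)")
#' parse_rule("(CFL1 & ARP2/3) | (RHOA(-3) & !CFL1)")
#' @export
parse_rule <- function(text) {
  toks <- tokenize_rule(text)
  if (length(toks) == 0L) stop("empty rule expression", call. = FALSE)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  expect <- function(kind) {
    t <- peek()
    if (is.null(t)) {
      stop(sprintf("unexpected end of expression (expected %s)", kind),
           call. = FALSE)
    }
    if (t$kind != kind) {
      stop(sprintf("unexpected token '%s' at position %d (expected %s)",
                   as.character(t$value), t$pos, kind), call. = FALSE)
    }
    advance()
  }

  parse_factor <- function() {
    t <- peek()
    if (is.null(t)) stop("unexpected end of expression", call. = FALSE)
    if (t$kind == "not") {
      advance()
      return(rx_not(parse_factor()))
    }
    if (t$kind == "lparen") {
      advance()
      e <- parse_expr()
      expect("rparen")
      return(e)
    }
    if (t$kind == "const") {
      advance()
      return(rx_const(t$value))
    }
    if (t$kind == "name") {
      advance()
      d <- peek()
      if (!is.null(d) && d$kind == "delay") {
        advance()
        return(rx_lit(t$value, d$value))
      }
      return(rx_lit(t$value, 0L))
    }
    stop(sprintf("unexpected token '%s' at position %d",
                 as.character(t$value), t$pos), call. = FALSE)
  }

  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.null(peek()) && peek()$kind == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    do.call(rx_and, args)
  }

  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.null(peek()) && peek()$kind == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    do.call(rx_or, args)
  }

  e <- parse_expr()
  t <- peek()
  if (!is.null(t)) {
    stop(sprintf("unexpected token '%s' at position %d after expression end",
                 as.character(t$value), t$pos), call. = FALSE)
  }
  e
}

# --- printer -----------------------------------------------------------------

needs_quoting <- function(name) !grepl("^[A-Za-z][A-Za-z0-9_/.-]*$", name)

format_name <- function(name) {
  if (needs_quoting(name)) paste0("\"", name, "\"") else name
}

#' Print a rule expression canonically
#'
#' Produces the canonical ASCII form (`&`, `|`, `!`) with clarifying
#' parentheses around any compound sub-expression whose connective differs
#' from its parent. `parse_rule(format_rule(e))` reproduces `e` exactly.
#'
#' @param expr A `rule_expr`.
#' @return A single character string.
#' @export
format_rule <- function(expr) {
  stopifnot(inherits(expr, "rule_expr"))
  fmt <- function(e, parent) {
    switch(e$op,
      const = as.character(e$value),
      lit = paste0(format_name(e$node),
                   if (e$delay > 0L) sprintf("(-%d)", e$delay) else ""),
      not = {
        if (e$x$op %in% c("and", "or")) paste0("!(", fmt(e$x, "top"), ")")
        else paste0("!", fmt(e$x, "not"))
      },
      and = {
        s <- paste(vapply(e$args, fmt, "", "and"), collapse = " & ")
        if (parent == "top") s else paste0("(", s, ")")
      },
      or = {
        s <- paste(vapply(e$args, fmt, "", "or"), collapse = " | ")
        if (parent == "top") s else paste0("(", s, ")")
      }
    )
  }
  fmt(expr, "top")
}

#' @export
print.rule_expr <- function(x, ...) {
  cat(format_rule(x), "\n")
  invisible(x)
}

#' @export
format.rule_expr <- function(x, ...) format_rule(x)

# --- structural helpers ------------------------------------------------------

# All literals in an expression, as data.frame(node, delay).
rule_literals <- function(expr) {
  acc <- list()
  walk <- function(e) {
    switch(e$op,
      lit = acc[[length(acc) + 1L]] <<- list(node = e$node, delay = e$delay),
      not = walk(e$x),
      and = ,
      or = for (a in e$args) walk(a),
      const = NULL
    )
  }
  walk(expr)
  if (length(acc) == 0L) {
    return(data.frame(node = character(), delay = integer()))
  }
  data.frame(node = vapply(acc, `[[`, "", "node"),
             delay = vapply(acc, `[[`, 0L, "delay"))
}

rule_sources <- function(expr) unique(rule_literals(expr)$node)

is_const_rule <- function(expr) expr$op == "const"

# Evaluate an expression on a 0/1 assignment (named integer vector or
# environment-like list). Delays are resolved through `lookup(node, delay)`.
eval_rule <- function(expr, lookup) {
  ev <- function(e) {
    switch(e$op,
      const = e$value,
      lit = lookup(e$node, e$delay),
      not = 1L - ev(e$x),
      and = {
        for (a in e$args) if (ev(a) == 0L) return(0L)
        1L
      },
      or = {
        for (a in e$args) if (ev(a) == 1L) return(1L)
        0L
      }
    )
  }
  ev(expr)
}

# Rewrite every literal through `f(node, delay) -> rule_expr`.
map_literals <- function(expr, f) {
  walk <- function(e) {
    switch(e$op,
      lit = f(e$node, e$delay),
      not = rx_not(walk(e$x)),
      and = do.call(rx_and, lapply(e$args, walk)),
      or = do.call(rx_or, lapply(e$args, walk)),
      const = e
    )
  }
  walk(expr)
}

rule_max_delay <- function(expr) {
  lits <- rule_literals(expr)
  if (nrow(lits) == 0L) 0L else max(lits$delay)
}
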