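# Compile time-delayed regulators into delay-register chains, producing a
# plain synchronous network.

#' Expand time delays into register chains
#'
#' A literal `X(-k)` evaluated while computing the state at time `t + 1`
#' reads `X` at time `t + 1 - k`; `X(-1)` is therefore the ordinary
#' synchronous regulator. The expansion realizes this with a shift-register
#' chain per delayed source: register `X.d1` holds `X` delayed by one step
#' (`X.d1(t) = X(t - 1)`), `X.d2` by two, and so on; a source used with
#' maximum delay `k` contributes `k - 1` registers. Each delayed literal
#' `X(-k)` with `k >= 2` is rewritten to the plain literal `X.d(k-1)`,
#' and `X(-1)` to `X`. The result is an ordinary synchronous Boolean
#' network over biological nodes plus registers.
#'
#' At any fixed point of the expanded network each register equals its
#' source, so restricting a fixed point to the biological nodes yields a
#' fixed point of the original rule system with delayed literals read as
#' plain literals.
#'
#' @param net A `boolean_network`.
#' @return An object of classes `expanded_network` and `boolean_network`
#'   with extra elements `biological` (names of non-register nodes) and
#'   `registers` (data.frame with columns `register`, `source`, `depth`).
#' @examples
#' net <- expand_delays(build_cfl1_model())
#' length(net$nodes)      # 33 biological nodes + 5 registers
#' net$registers
#' @export
expand_delays <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  if (inherits(net, "expanded_network")) return(net)

  max_delay <- integer(0)
  for (n in net$nodes) {
    lits <- rule_literals(net$rules[[n]])
    for (i in seq_len(nrow(lits))) {
      src <- lits$node[i]
      d <- lits$delay[i]
      if (d > 0L) {
        max_delay[src] <- max(d, if (src %in% names(max_delay))
          max_delay[[src]] else 0L)
      }
    }
  }

  reg_name <- function(src, depth) sprintf("%s.d%d", src, depth)
  registers <- data.frame(register = character(), source = character(),
                          depth = integer(), stringsAsFactors = FALSE)
  reg_rules <- list()
  for (src in names(max_delay)) {
    k <- max_delay[[src]]
    for (depth in seq_len(k - 1L)) {
      rn <- reg_name(src, depth)
      if (rn %in% net$nodes) {
        stop(sprintf("register name '%s' collides with an existing node", rn),
             call. = FALSE)
      }
      # X.d1(t+1) = X(t);  X.dj(t+1) = X.d(j-1)(t)
      reg_rules[[rn]] <- if (depth == 1L) rx_lit(src)
                         else rx_lit(reg_name(src, depth - 1L))
      registers <- rbind(registers,
                         data.frame(register = rn, source = src,
                                    depth = depth, stringsAsFactors = FALSE))
    }
  }

  rewrite <- function(expr) {
    map_literals(expr, function(node, delay) {
      if (delay <= 1L) rx_lit(node) else rx_lit(reg_name(node, delay - 1L))
    })
  }
  new_rules <- lapply(net$rules, rewrite)
  all_rules <- c(new_rules, reg_rules)

  out <- boolean_network(all_rules)
  out$biological <- net$nodes
  out$registers <- registers
  attr(out, "header") <- attr(net, "header")
  class(out) <- c("expanded_network", "boolean_network")
  out
}

#' @export
print.expanded_network <- function(x, ...) {
  cat(sprintf("Expanded synchronous network: %d biological nodes + %d registers\n",
              length(x$biological), nrow(x$registers)))
  NextMethod()
}

# Biological nodes of a (possibly expanded) network.
biological_nodes <- function(net) {
  if (inherits(net, "expanded_network")) net$biological else net$nodes
}

# --- compiled form -----------------------------------------------------------
# Per node: 0-based regulator indices and a truth table indexed by the
# regulator bit pattern (regulator j contributes bit 2^j). This is the form
# consumed by the C++ simulation core.
compile_network <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  if (!inherits(net, "expanded_network")) net <- expand_delays(net)
  nodes <- net$nodes
  idx <- stats::setNames(seq_along(nodes), nodes)
  regs <- vector("list", length(nodes))
  tts <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    rule <- net$rules[[nodes[i]]]
    src <- rule_sources(rule)
    k <- length(src)
    if (k > 20L) {
      stop(sprintf("node '%s' has in-degree %d (> 20); truth-table compilation refused",
                   nodes[i], k), call. = FALSE)
    }
    tt <- integer(2^k)
    for (pat in seq_len(2^k) - 1L) {
      vals <- stats::setNames(bitwAnd(bitwShiftR(pat, seq_len(k) - 1L), 1L), src)
      tt[pat + 1L] <- eval_rule(rule, function(node, delay) vals[[node]])
    }
    regs[[i]] <- as.integer(idx[src] - 1L)
    tts[[i]] <- tt
  }
  list(nodes = nodes, regs = regs, tts = tts,
       bio = as.integer(idx[biological_nodes(net)] - 1L),
       net = net)
}
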