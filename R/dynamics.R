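# Synchronous dynamics: stepping, trajectories, attractors, basins.

as_state <- function(net, state) {
  nodes <- net$nodes
  if (is.null(names(state))) {
    stopifnot(length(state) == length(nodes))
    state <- stats::setNames(as.integer(state), nodes)
  } else {
    missing <- setdiff(nodes, names(state))
    if (length(missing) > 0L) {
      stop(sprintf("state does not assign node(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    state <- stats::setNames(as.integer(state[nodes]), nodes)
  }
  stopifnot(all(state %in% c(0L, 1L)))
  state
}

#' Synchronous update of a network state
#'
#' Applies one synchronous step: every node simultaneously takes the value
#' of its rule evaluated on the current state. Delayed rules are compiled
#' away first via [expand_delays()].
#'
#' @param net A `boolean_network` (expanded automatically if needed).
#' @param state Named (or network-ordered) 0/1 vector over all nodes of the
#'   expanded network.
#' @return Named integer 0/1 vector: the successor state.
#' @export
next_state <- function(net, state) {
  cn <- compile_network(net)
  s <- as_state(cn$net, state)
  res <- .cpp_simulate(cn$regs, cn$tts, unname(s), 1L)
  stats::setNames(res$states[2L, ], cn$nodes)
}

#' Canonical initial state: only KRAS active
#'
#' The reference starting condition for the CFL1 model: KRAS active
#' (reflecting the near-universal activating KRAS mutations of pancreatic
#' ductal adenocarcinoma) and every other biological node inactive. Delay
#' registers are initialized constant-history, i.e. to their source's
#' initial value.
#'
#' @param net A `boolean_network` containing a node named `KRAS`
#'   (expanded automatically).
#' @return Named integer 0/1 vector over the expanded network's nodes.
#' @export
canonical_initial_state <- function(net) {
  xnet <- expand_delays(net)
  if (!"KRAS" %in% biological_nodes(xnet)) {
    stop("network has no node named 'KRAS'", call. = FALSE)
  }
  s <- stats::setNames(rep(0L, length(xnet$nodes)), xnet$nodes)
  s["KRAS"] <- 1L
  init_registers(xnet, s)
}

# Set registers to constant-history values given the biological part of a
# state: every register takes its source's current value.
init_registers <- function(xnet, state) {
  if (inherits(xnet, "expanded_network") && nrow(xnet$registers) > 0L) {
    state[xnet$registers$register] <- state[xnet$registers$source]
  }
  state
}

#' Simulate a synchronous trajectory
#'
#' Iterates the synchronous update from `init` until a previously visited
#' state recurs (entering the attractor cycle) or `max_steps` updates have
#' been applied. The trajectory is fully deterministic.
#'
#' @param net A `boolean_network` (expanded automatically).
#' @param init Initial state (named or network-ordered 0/1 vector over the
#'   expanded nodes); defaults to [canonical_initial_state()] when the
#'   network has a KRAS node.
#' @param max_steps Maximum number of updates before reporting the
#'   trajectory as unresolved (default 1000).
#' @return A `bn_trajectory`: list with `states` (matrix, rows = time steps
#'   starting at 0, columns = nodes), `transient` (steps before cycle
#'   entry), `cycle_length`, `resolved` (logical) and `nodes`. The final row
#'   repeats the first cycle state, closing the loop.
#' @export
simulate_network <- function(net, init = NULL, max_steps = 1000L) {
  stopifnot(max_steps >= 1L)
  cn <- compile_network(net)
  if (is.null(init)) init <- canonical_initial_state(cn$net)
  s <- as_state(cn$net, init)
  res <- .cpp_simulate(cn$regs, cn$tts, unname(s), as.integer(max_steps))
  states <- res$states
  colnames(states) <- cn$nodes
  rownames(states) <- paste0("t", seq_len(nrow(states)) - 1L)
  structure(list(states = states,
                 transient = if (res$resolved) res$transient else NA_integer_,
                 cycle_length = if (res$resolved) res$cycle_length
                                else NA_integer_,
                 resolved = res$resolved,
                 nodes = cn$nodes,
                 biological = biological_nodes(cn$net)),
            class = "bn_trajectory")
}

#' @export
print.bn_trajectory <- function(x, ...) {
  if (x$resolved) {
    cat(sprintf("Synchronous trajectory: transient %d, cycle length %d (%s)\n",
                x$transient, x$cycle_length,
                if (x$cycle_length == 1L) "fixed point" else "cycle"))
  } else {
    cat(sprintf("Synchronous trajectory: UNRESOLVED after %d steps\n",
                nrow(x$states) - 1L))
  }
  invisible(x)
}

#' First activation time of a node
#'
#' @param traj A `bn_trajectory` from [simulate_network()].
#' @param node Node name.
#' @return The least time step `t` (initial state is `t = 0`) at which the
#'   node is active, or `NA` if it is never active within the trajectory.
#' @export
first_activation <- function(traj, node) {
  stopifnot(inherits(traj, "bn_trajectory"))
  if (!node %in% colnames(traj$states)) {
    stop(sprintf("unknown node '%s'", node), call. = FALSE)
  }
  w <- which(traj$states[, node] == 1L)
  if (length(w) == 0L) NA_integer_ else unname(w[1L]) - 1L
}

# --- attractors --------------------------------------------------------------

make_attractor <- function(states, nodes, biological, basin = NA_integer_) {
  colnames(states) <- nodes
  # canonical phase: rotate the cycle so the lexicographically least
  # biological bit-string sequence comes first (registers carry only phase)
  L <- nrow(states)
  bio_rows <- apply(states[, biological, drop = FALSE], 1L, paste,
                    collapse = "")
  if (L > 1L) {
    rots <- vapply(seq_len(L), function(r) {
      paste(bio_rows[((seq_len(L) + r - 2L) %% L) + 1L], collapse = "|")
    }, "")
    best <- which(rots == min(rots))[1L]
    states <- states[((seq_len(L) + best - 2L) %% L) + 1L, , drop = FALSE]
  }
  bio_states <- states[, biological, drop = FALSE]
  key <- paste(apply(bio_states, 1L, paste, collapse = ""), collapse = "|")
  structure(list(states = states, bio_states = bio_states,
                 length = nrow(states), key = key, basin = basin),
            class = "bn_attractor")
}

#' @export
print.bn_attractor <- function(x, ...) {
  cat(sprintf("Attractor: cycle length %d%s\n", x$length,
              if (x$length == 1L) " (fixed point)" else ""))
  act <- colnames(x$bio_states)[colSums(x$bio_states) == nrow(x$bio_states)]
  cat("  always active:", if (length(act)) paste(act, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Is a node active in every state of an attractor?
#'
#' @param attr A `bn_attractor`.
#' @param node Node name.
#' @return Logical.
#' @export
attractor_active <- function(attr, node) {
  stopifnot(inherits(attr, "bn_attractor"))
  if (!node %in% colnames(attr$states)) {
    stop(sprintf("unknown node '%s'", node), call. = FALSE)
  }
  all(attr$states[, node] == 1L)
}

make_attractor_set <- function(attractors, n_starts, seed, n_unresolved = 0L,
                               method = "sampled") {
  keys <- vapply(attractors, `[[`, "", "key")
  stopifnot(!anyDuplicated(keys))
  structure(list(attractors = stats::setNames(attractors, keys),
                 n_starts = n_starts, seed = seed,
                 n_unresolved = n_unresolved, method = method),
            class = "bn_attractor_set")
}

#' @export
print.bn_attractor_set <- function(x, ...) {
  cat(sprintf("Attractor set (%s): %d attractor(s)", x$method,
              length(x$attractors)))
  if (!is.na(x$n_starts)) cat(sprintf(", %d start states", x$n_starts))
  cat("\n")
  for (a in x$attractors) {
    cat(sprintf("  cycle length %d, basin %s\n", a$length,
                ifelse(is.na(a$basin), "-", a$basin)))
  }
  if (x$n_unresolved > 0L) {
    cat(sprintf("  (%d unresolved trajectories)\n", x$n_unresolved))
  }
  invisible(x)
}

#' Exact fixed-point enumeration
#'
#' Enumerates all states `x` with `f(x) = x` of the expanded synchronous
#' network by backtracking search with three-valued constraint propagation
#' (complete: no sampling involved). Suitable for networks up to roughly 40
#' nodes; longer cycles are found by [find_attractors()].
#'
#' @param net A `boolean_network` (expanded automatically).
#' @return A `bn_attractor_set` whose attractors are all fixed points,
#'   ordered by state encoding; basin counts are `NA`.
#' @export
fixed_points <- function(net) {
  cn <- compile_network(net)
  m <- .cpp_fixed_points(cn$regs, cn$tts)
  attractors <- lapply(seq_len(nrow(m)), function(i) {
    make_attractor(m[i, , drop = FALSE], cn$nodes,
                   biological_nodes(cn$net))
  })
  make_attractor_set(attractors, n_starts = NA_integer_, seed = NA_integer_,
                     method = "exact fixed points")
}

# Sample uniform random start states: biological nodes independent
# Bernoulli(1/2); registers constant-history from the sampled source values
# (or independently random if register_init = "random").
sample_starts <- function(xnet, n_starts, register_init = "constant") {
  nodes <- xnet$nodes
  m <- matrix(as.integer(stats::runif(n_starts * length(nodes)) > 0.5),
              nrow = n_starts, ncol = length(nodes),
              dimnames = list(NULL, nodes))
  if (register_init == "constant" && inherits(xnet, "expanded_network") &&
      nrow(xnet$registers) > 0L) {
    m[, xnet$registers$register] <- m[, xnet$registers$source]
  }
  m
}

#' Sampled attractor enumeration with basin counts
#'
#' Simulates to the attractor from `n_starts` uniformly random initial
#' states (biological nodes sampled independently; delay registers
#' initialized constant-history from their sampled source), deduplicates
#' attractors by the canonical key of the cycle restricted to biological
#' nodes, and merges in the exact fixed points from [fixed_points()] (with
#' basin count 0 if never sampled). Reproducible given `seed`.
#'
#' @param net A `boolean_network` (expanded automatically).
#' @param n_starts Number of random start states (>= 1).
#' @param seed Integer seed for start-state sampling.
#' @param max_steps Per-trajectory step bound; trajectories not resolved
#'   within it are counted in `n_unresolved`, never dropped silently.
#' @param register_init `"constant"` (default: registers copy their sampled
#'   source value) or `"random"` (registers sampled independently, covering
#'   the full expanded state space).
#' @param include_exact Merge exact fixed points into the result
#'   (default `TRUE`).
#' @return A `bn_attractor_set`; attractor basin counts sum to
#'   `n_starts - n_unresolved`. The per-start attractor assignment is kept
#'   in the `assignment` element.
#' @export
find_attractors <- function(net, n_starts = 1e5, seed = 1L,
                            max_steps = 10000L,
                            register_init = c("constant", "random"),
                            include_exact = TRUE) {
  stopifnot(n_starts >= 1L)
  register_init <- match.arg(register_init)
  cn <- compile_network(net)
  set.seed(seed)
  starts <- sample_starts(cn$net, as.integer(n_starts), register_init)
  res <- .cpp_attractors(cn$regs, cn$tts, starts, cn$bio,
                         as.integer(max_steps))
  attractors <- mapply(function(states, basin) {
    make_attractor(states, cn$nodes, biological_nodes(cn$net), basin)
  }, res$cycles, as.list(res$basin), SIMPLIFY = FALSE)
  sampled_keys <- vapply(attractors, `[[`, "", "key")
  if (include_exact) {
    keys <- sampled_keys
    fp <- fixed_points(cn$net)
    for (a in fp$attractors) {
      if (!a$key %in% keys) {
        a$basin <- 0L
        attractors[[length(attractors) + 1L]] <- a
        keys <- c(keys, a$key)
      }
    }
  }
  all_keys <- vapply(attractors, `[[`, "", "key")
  ord <- order(all_keys)
  attractors <- attractors[ord]
  out <- make_attractor_set(attractors, n_starts = as.integer(n_starts),
                            seed = as.integer(seed),
                            n_unresolved = res$n_unresolved)
  # per-start assignment, re-indexed to the sorted attractor order
  out$assignment <- match(sampled_keys, all_keys[ord])[res$assignment]
  out
}

#' Basin-of-attraction fractions
#'
#' @inheritParams find_attractors
#' @return Named numeric vector: per attractor key, the fraction of sampled
#'   starts reaching it; an extra `"unresolved"` entry appears when any
#'   trajectory failed to resolve. Fractions sum to 1.
#' @export
basin_fractions <- function(net, n_starts = 1e5, seed = 1L,
                            max_steps = 10000L) {
  aset <- find_attractors(net, n_starts = n_starts, seed = seed,
                          max_steps = max_steps)
  fr <- vapply(aset$attractors, function(a) a$basin / aset$n_starts, 0)
  if (aset$n_unresolved > 0L) {
    fr <- c(fr, unresolved = aset$n_unresolved / aset$n_starts)
  }
  fr
}

# --- export helpers ----------------------------------------------------------

#' Export a trajectory as a CSV grid
#'
#' Writes the machine-readable activity grid of a trajectory: rows are
#' nodes in network order, columns are time steps (`t0`, `t1`, ...), cells
#' are 0/1.
#'
#' @param traj A `bn_trajectory`.
#' @param file Output path.
#' @param biological_only Drop delay registers from the rows (default TRUE).
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, file, biological_only = TRUE) {
  stopifnot(inherits(traj, "bn_trajectory"))
  m <- t(traj$states)
  if (biological_only) m <- m[traj$biological, , drop = FALSE]
  df <- data.frame(node = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, file, row.names = FALSE, quote = TRUE)
  invisible(file)
}

#' Export an attractor set as JSON
#'
#' @param aset A `bn_attractor_set`.
#' @param file Output path, or `NULL` to return the JSON string.
#' @return The JSON text, invisibly when written to a file.
#' @export
write_attractor_set_json <- function(aset, file = NULL) {
  stopifnot(inherits(aset, "bn_attractor_set"))
  obj <- list(
    method = aset$method,
    n_starts = aset$n_starts,
    seed = aset$seed,
    n_unresolved = aset$n_unresolved,
    attractors = lapply(unname(aset$attractors), function(a) {
      list(key = a$key, cycle_length = a$length, basin = a$basin,
           states = as.data.frame(a$bio_states))
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                          na = "null")
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}
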