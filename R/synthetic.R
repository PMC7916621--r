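# Seeded generators: two-class expression matrices, random Boolean
# networks, and a brute-force attractor oracle.

#' Generate a two-class synthetic expression matrix
#'
#' Emulates a normalized (log-scale) microarray comparison of tumor versus
#' normal tissue: per gene, normal samples draw from Normal(mu0, sigma) and
#' tumor samples from Normal(mu0 + delta_g, sigma). Technical replicates of
#' a sample share its latent biological value and add independent
#' measurement noise of standard deviation `replicate_sd`. Deterministic
#' given `seed`.
#'
#' @param genes Character vector of gene names.
#' @param n_per_class Samples per class (tumor and normal), >= 1.
#' @param delta Per-gene tumor shift in expression units; scalar or vector
#'   along `genes`.
#' @param sigma Biological noise sd (> 0), default 1.
#' @param mu0 Baseline mean, default 6 (a typical normalized log2 level).
#' @param replicates Optional named integer vector: for the given sample
#'   names (e.g. `c(tumor_01 = 3)`), the number of technical replicates to
#'   emit instead of a single column.
#' @param replicate_sd Technical noise sd, default `sigma / 2`.
#' @param seed Integer seed (required).
#' @return A [labeled_expression()].
#' @examples
#' m <- synth_expression(c("AURKA", "TCF7L2"), n_per_class = 10,
#'                       delta = 3, seed = 7)
#' @export
synth_expression <- function(genes, n_per_class, delta = 0, sigma = 1,
                             mu0 = 6, replicates = NULL,
                             replicate_sd = sigma / 2, seed) {
  stopifnot(is.character(genes), length(genes) >= 1L, n_per_class >= 1L,
            sigma > 0, !missing(seed))
  delta <- rep_len(delta, length(genes))
  set.seed(as.integer(seed))
  samples <- c(sprintf("normal_%02d", seq_len(n_per_class)),
               sprintf("tumor_%02d", seq_len(n_per_class)))
  labels <- rep(c("normal", "tumor"), each = n_per_class)
  means <- matrix(mu0, length(genes), length(samples))
  means[, labels == "tumor"] <- means[, labels == "tumor"] + delta
  latent <- means + matrix(stats::rnorm(length(means), sd = sigma),
                           nrow(means), ncol(means))
  if (is.null(replicates) || length(replicates) == 0L) {
    vals <- latent
    dimnames(vals) <- list(genes, samples)
    return(labeled_expression(vals, labels))
  }
  stopifnot(!is.null(names(replicates)),
            all(names(replicates) %in% samples), all(replicates >= 1L))
  cols <- list()
  labs <- character()
  groups <- character()
  cn <- character()
  for (i in seq_along(samples)) {
    s <- samples[i]
    k <- if (s %in% names(replicates)) replicates[[s]] else 1L
    for (r in seq_len(k)) {
      v <- latent[, i] + if (k > 1L) {
        stats::rnorm(length(genes), sd = replicate_sd)
      } else 0
      cols[[length(cols) + 1L]] <- v
      labs <- c(labs, labels[i])
      groups <- c(groups, if (k > 1L) s else NA_character_)
      cn <- c(cn, if (k > 1L) sprintf("%s_rep%d", s, r) else s)
    }
  }
  vals <- do.call(cbind, cols)
  dimnames(vals) <- list(genes, cn)
  labeled_expression(vals, labs, groups)
}

#' Generate a seeded random Boolean network
#'
#' Random rules are random truth tables over up to `k` sampled regulators;
#' with probability `delay_prob` a regulator literal carries a time delay
#' of 2 or 3 steps. Small node counts keep the expanded state space within
#' reach of the brute-force oracle.
#'
#' @param n Node count (<= 14).
#' @param k Maximum in-degree (default 3).
#' @param delay_prob Probability that a literal is delayed (default 0).
#' @param seed Integer seed (required).
#' @return A `boolean_network` with nodes `N1 ... Nn`.
#' @export
random_network <- function(n, k = 3L, delay_prob = 0, seed) {
  stopifnot(n >= 1L, n <= 14L, k >= 1L, !missing(seed))
  set.seed(as.integer(seed))
  nodes <- paste0("N", seq_len(n))
  rules <- list()
  for (i in seq_len(n)) {
    deg <- sample.int(min(k, n), 1L)
    regs <- sample(nodes, deg)
    tt <- sample(c(0L, 1L), 2^deg, replace = TRUE)
    delays <- ifelse(stats::runif(deg) < delay_prob,
                     sample(c(2L, 3L), deg, replace = TRUE), 0L)
    lits <- lapply(seq_len(deg), function(j) rx_lit(regs[j], delays[j]))
    if (all(tt == 0L)) {
      rules[[nodes[i]]] <- rx_const(0L)
    } else if (all(tt == 1L)) {
      rules[[nodes[i]]] <- rx_const(1L)
    } else {
      # sum of products over the minterms of the sampled truth table
      terms <- lapply(which(tt == 1L) - 1L, function(pat) {
        facs <- lapply(seq_len(deg), function(j) {
          if (bitwAnd(bitwShiftR(pat, j - 1L), 1L) == 1L) lits[[j]]
          else rx_not(lits[[j]])
        })
        do.call(rx_and, facs)
      })
      rules[[nodes[i]]] <- do.call(rx_or, terms)
    }
  }
  boolean_network(rules)
}

#' Brute-force attractor enumeration (oracle)
#'
#' Tabulates the full synchronous transition function over every state of
#' the expanded network and follows each state to its attractor, giving the
#' exact attractor set and exact basin sizes. Intended as an independent
#' oracle for validating the sampled search on small networks; refuses
#' state spaces larger than `2^max_bits`.
#'
#' @param net A `boolean_network` (expanded automatically).
#' @param max_bits Largest admissible expanded node count (default 20).
#' @return A `bn_attractor_set` with exact basin counts over all
#'   `2^n` states.
#' @export
brute_force_attractors <- function(net, max_bits = 20L) {
  cn <- compile_network(net)
  nb <- length(cn$nodes)
  if (nb > max_bits) {
    stop(sprintf("state space 2^%d exceeds the 2^%d brute-force limit",
                 nb, max_bits), call. = FALSE)
  }
  N <- 2^nb
  states <- 0:(N - 1)
  succ <- integer(N)
  next_bits <- integer(N)
  for (i in seq_len(nb)) {
    r <- cn$regs[[i]]
    idx <- rep(0L, N)
    for (j in seq_along(r)) {
      idx <- idx + bitwShiftL(bitwAnd(bitwShiftR(states, r[j]), 1L), j - 1L)
    }
    succ <- succ + bitwShiftL(cn$tts[[i]][idx + 1L], i - 1L)
  }
  # follow every state to its attractor; attractor id per state
  attr_of <- rep(NA_integer_, N)
  cycles <- list()
  for (s0 in states) {
    if (!is.na(attr_of[s0 + 1L])) next
    path <- integer(0)
    pos <- new.env(hash = TRUE, size = 64L)
    s <- s0
    repeat {
      known <- attr_of[s + 1L]
      if (!is.na(known)) { aid <- known; break }
      p <- get0(as.character(s), envir = pos)
      if (!is.null(p)) {
        cyc <- path[(p + 1L):length(path)]
        aid <- length(cycles) + 1L
        cycles[[aid]] <- cyc
        break
      }
      assign(as.character(s), length(path), envir = pos)
      path <- c(path, s)
      s <- succ[s + 1L]
    }
    attr_of[path + 1L] <- aid
  }
  basin <- tabulate(attr_of, nbins = length(cycles))
  decode <- function(enc) {
    vapply(seq_len(nb), function(i) bitwAnd(bitwShiftR(enc, i - 1L), 1L), 0L)
  }
  bio_names <- biological_nodes(cn$net)
  attractors <- lapply(seq_along(cycles), function(a) {
    m <- t(vapply(cycles[[a]], decode, integer(nb)))
    make_attractor(m, cn$nodes, bio_names, basin[a])
  })
  attractors <- attractors[order(vapply(attractors, `[[`, "", "key"))]
  make_attractor_set(attractors, n_starts = N, seed = NA_integer_,
                     method = "brute force")
}
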