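# Boolean networks: ordered node list, one update rule per node.

#' Construct a Boolean network
#'
#' A Boolean network assigns each named node one update rule (a
#' [`rule_expr`][parse_rule]). Node order is fixed and defines the canonical
#' state encoding used throughout the package. Rules may reference regulators
#' with time delays; [expand_delays()] compiles such a network into a plain
#' synchronous one.
#'
#' @param rules Named list of `rule_expr` objects (names are the target
#'   nodes, in the desired node order) or a named character vector of rule
#'   strings which will be passed through [parse_rule()].
#' @return An object of class `boolean_network` with elements `nodes`
#'   (character vector) and `rules` (named list of `rule_expr`).
#' @examples
#' toy <- boolean_network(c(A = "1", B = "A", C = "!B"))
#' network_summary(toy)
#' @export
boolean_network <- function(rules) {
  if (is.character(rules)) rules <- lapply(rules, parse_rule)
  stopifnot(is.list(rules), length(rules) >= 1L)
  nodes <- names(rules)
  if (is.null(nodes) || any(!nzchar(nodes))) {
    stop("every rule must be named by its target node", call. = FALSE)
  }
  if (anyDuplicated(nodes)) {
    dup <- unique(nodes[duplicated(nodes)])
    stop(sprintf("duplicate rule for node(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  stopifnot(all(vapply(rules, inherits, TRUE, "rule_expr")))
  for (tgt in nodes) {
    lits <- rule_literals(rules[[tgt]])
    unknown <- setdiff(lits$node, nodes)
    if (length(unknown) > 0L) {
      stop(sprintf("rule for '%s' references undeclared node(s): %s",
                   tgt, paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(nodes = nodes, rules = rules), class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network with %d nodes\n", length(x$nodes)))
  for (n in x$nodes) {
    cat(sprintf("  %s <- %s\n", format_name(n), format_rule(x$rules[[n]])))
  }
  invisible(x)
}

#' Constant nodes of a network
#'
#' @param net A `boolean_network`.
#' @return Character vector of nodes whose rule is the constant 0 or 1.
#' @export
constant_nodes <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  net$nodes[vapply(net$rules, is_const_rule, TRUE)]
}

# Deterministic machine identifiers: non-alphanumeric characters -> "_".
#' Internal node identifiers
#'
#' Display names keep the punctuation of the underlying biology
#' (`ARP2/3`, `F-actin_new`, `S-phase`); this helper maps them to
#' deterministic identifiers safe for file systems and column names.
#'
#' @param names Character vector of display names.
#' @return Character vector of identifiers.
#' @export
node_ids <- function(names) gsub("[^A-Za-z0-9]+", "_", names)

# --- rule file format --------------------------------------------------------
# One line per node: `target, expression`, preceded by the header
# `targets, factors`; `#` starts a comment. Delays as `(-k)` suffix; names
# with characters outside [A-Za-z0-9_/.-] are double-quoted.

#' Write a network to the plain-text rule format
#'
#' Serializes a network in the `targets, factors` dialect used by common
#' Boolean-network tools: a header line, then one `target, expression` line
#' per node in node order, ASCII connectives, delays as `(-k)` suffixes.
#' [read_network()] inverts this exactly.
#'
#' @param net A `boolean_network`.
#' @param file Path to write to, or `NULL` to return the text.
#' @param header Optional character vector of comment lines (written with a
#'   leading `# `). Defaults to the header the network was read with, if any,
#'   so `write_network(read_network(f))` reproduces `f` byte for byte.
#' @return Invisibly (or visibly if `file` is `NULL`) the serialized text as
#'   a single string.
#' @export
write_network <- function(net, file = NULL, header = attr(net, "header")) {
  stopifnot(inherits(net, "boolean_network"))
  lines <- character()
  if (!is.null(header) && length(header) > 0L) lines <- paste0("# ", header)
  lines <- c(lines, "targets, factors")
  for (n in net$nodes) {
    lines <- c(lines, sprintf("%s, %s", format_name(n),
                              format_rule(net$rules[[n]])))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(file)) return(txt)
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL)
  invisible(txt)
}

#' Read a network from the plain-text rule format
#'
#' @param file Path to a rule file, or a character vector of lines via
#'   `text =`.
#' @param text Optional character scalar/vector holding the file content.
#' @return A `boolean_network`.
#' @export
read_network <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    stopifnot(is.character(file), length(file) == 1L)
    if (!file.exists(file)) stop(sprintf("no such file: %s", file),
                                 call. = FALSE)
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  }
  rules <- list()
  order <- character()
  seen_header <- FALSE
  comments <- character()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      if (!seen_header) comments <- c(comments, sub("^#\\s?", "", ln))
      next
    }
    if (!seen_header && grepl("^targets\\s*,\\s*factors$", ln)) {
      seen_header <- TRUE
      next
    }
    # split target from expression on the first comma outside quotes
    chars <- strsplit(ln, "")[[1]]
    inq <- FALSE
    cut <- NA_integer_
    for (j in seq_along(chars)) {
      if (chars[j] == "\"") inq <- !inq
      if (chars[j] == "," && !inq) { cut <- j; break }
    }
    if (is.na(cut)) {
      stop(sprintf("line %d: expected 'target, expression'", i),
           call. = FALSE)
    }
    tgt_raw <- trimws(substr(ln, 1L, cut - 1L))
    expr_raw <- trimws(substr(ln, cut + 1L, nchar(ln)))
    tgt <- sub("^\"(.*)\"$", "\\1", tgt_raw)
    if (!nzchar(tgt)) stop(sprintf("line %d: empty target", i), call. = FALSE)
    if (tgt %in% order) {
      stop(sprintf("line %d: duplicate rule for node '%s'", i, tgt),
           call. = FALSE)
    }
    rule <- tryCatch(parse_rule(expr_raw), error = function(e) {
      stop(sprintf("line %d (%s): %s", i, tgt, conditionMessage(e)),
           call. = FALSE)
    })
    order <- c(order, tgt)
    rules[[tgt]] <- rule
  }
  if (length(order) == 0L) stop("no rules found", call. = FALSE)
  # boolean_network() re-checks undeclared regulators; prefix line context
  net <- tryCatch(boolean_network(rules[order]), error = function(e) {
    stop(sprintf("invalid rule file: %s", conditionMessage(e)), call. = FALSE)
  })
  if (length(comments) > 0L) attr(net, "header") <- comments
  net
}

#' Summarize a network
#'
#' Reports node and edge counts. An edge is a distinct regulator-to-target
#' pair; multiple literal occurrences and delayed variants of the same
#' regulator collapse to one edge.
#'
#' @param net A `boolean_network`.
#' @return A list with `n_nodes`, `n_constant`, `n_edges` (distinct
#'   regulator-target pairs), `n_literals` (literal occurrences across all
#'   rules) and `regulators` (named integer vector of distinct in-degrees).
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "boolean_network"))
  indeg <- vapply(net$nodes, function(n) {
    length(rule_sources(net$rules[[n]]))
  }, 0L)
  nlit <- sum(vapply(net$nodes, function(n) {
    nrow(rule_literals(net$rules[[n]]))
  }, 0L))
  list(
    n_nodes = length(net$nodes),
    n_constant = length(constant_nodes(net)),
    n_edges = sum(indeg),
    n_literals = nlit,
    regulators = indeg
  )
}

#' The cofilin-1 (CFL1) pancreatic-cancer Boolean model
#'
#' Returns the curated 33-node logical model of CFL1 signalling in
#' pancreatic ductal adenocarcinoma, covering actin remodelling
#' (RHOA/RAC1/LIMK/SSH1L, ARP2/3, old and new F-actin), CFL1 regulation
#' (phosphorylated and active forms as separate nodes), the canonical
#' KRAS-PI3K axis, cell-cycle entry (MYC, CCND1, RB, E2F, CCNE1, S-phase)
#' and apoptosis (pooled pro-/anti-apoptotic proteins, CYCS, caspases).
#' KRAS is modelled as constitutively active (constant 1), reflecting the
#' near-universal activating KRAS mutations of this tumor type. Three
#' regulators act with time delays: `RHOA(-3)` on new F-actin,
#' `RAC1(-2)` on ARP2/3 and `Phosphorylated-CFL1(-3)` on RAC1,
#' abstracting multi-step linear signalling cascades.
#'
#' The model is bundled as the plain-text rule file
#' `system.file("extdata", "cfl1_model.bn", package = "cfl1bn")`.
#'
#' @return A `boolean_network` with 33 nodes.
#' @examples
#' net <- build_cfl1_model()
#' length(net$nodes)
#' format_rule(net$rules[["Caspases"]])
#' @export
build_cfl1_model <- function() {
  path <- system.file("extdata", "cfl1_model.bn", package = "cfl1bn")
  if (!nzchar(path)) stop("bundled model file not found", call. = FALSE)
  net <- read_network(path)
  # static self-check: a mismatch here is a packaging defect
  stopifnot(length(net$nodes) == 33L, "KRAS" %in% constant_nodes(net))
  net
}
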