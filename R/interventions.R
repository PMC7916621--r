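# Clamp-style interventions (knockout / overexpression) and exhaustive
# screening for apoptosis induction.

#' Define an intervention (set of clamped nodes)
#'
#' An intervention fixes one or more nodes to constant values, the in-silico
#' analogue of RNAi knockout (clamp to 0) or constitutive activation (clamp
#' to 1). The empty intervention is the wild type.
#'
#' @param clamps Named integer vector of 0/1 clamp values, names are node
#'   names; may be empty.
#' @param label Optional display label; defaults to a canonical
#'   `node:=value` form.
#' @return An `intervention` object.
#' @examples
#' intervention(c(STAT3 = 0))
#' intervention(c(CFL1 = 1, AURKA = 0))
#' @export
intervention <- function(clamps = integer(), label = NULL) {
  clamps <- stats::setNames(as.integer(clamps), names(clamps))
  if (length(clamps) > 0L) {
    stopifnot(!is.null(names(clamps)), all(nzchar(names(clamps))),
              all(clamps %in% c(0L, 1L)))
    if (anyDuplicated(names(clamps))) {
      stop("clamped nodes must be distinct", call. = FALSE)
    }
  }
  if (is.null(label)) {
    label <- if (length(clamps) == 0L) "wild-type"
             else paste(sprintf("%s:=%d", names(clamps), clamps),
                        collapse = ",")
  }
  structure(list(clamps = clamps, label = label), class = "intervention")
}

#' @export
print.intervention <- function(x, ...) {
  cat(sprintf("Intervention: %s\n", x$label))
  invisible(x)
}

#' Composite siRNA-style CFL1 knockout
#'
#' An siRNA depletes total cofilin-1 protein, removing both forms the model
#' distinguishes; the composite intervention therefore clamps both `CFL1`
#' (active, unphosphorylated) and `Phosphorylated-CFL1` to 0. This differs
#' from clamping `CFL1` alone, which leaves e.g. STAT3 activatable through
#' the phosphorylated form.
#'
#' @return An `intervention` of size 2, labelled `CFL1_siRNA`.
#' @export
cfl1_sirna_knockout <- function() {
  intervention(c("CFL1" = 0L, "Phosphorylated-CFL1" = 0L),
               label = "CFL1_siRNA")
}

#' Apply an intervention to a network
#'
#' Replaces each clamped node's rule by the clamped constant; all other
#' rules are untouched and the input network is not modified.
#'
#' @param net A `boolean_network` (unexpanded; expansion happens at
#'   simulation time, so clamps also pin the delayed history of a node).
#' @param iv An [intervention()].
#' @return A `boolean_network` with the clamped rules.
#' @export
apply_intervention <- function(net, iv) {
  stopifnot(inherits(net, "boolean_network"), inherits(iv, "intervention"))
  unknown <- setdiff(names(iv$clamps), net$nodes)
  if (length(unknown) > 0L) {
    stop(sprintf("cannot clamp unknown node(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  rules <- net$rules
  for (n in names(iv$clamps)) rules[[n]] <- rx_const(iv$clamps[[n]])
  out <- boolean_network(rules)
  attr(out, "intervention") <- iv
  out
}

#' Enumerate the intervention universe
#'
#' All interventions clamping 1 up to `max_size` distinct eligible nodes,
#' each to 0 or 1, in deterministic order (singles in node order with clamp
#' value 0 then 1, then node pairs in lexicographic index order with value
#' combinations 00, 01, 10, 11). The caspase node is excluded by default:
#' caspase activity is the screening readout, so clamping it would beg the
#' question. For the 33-node CFL1 model this yields
#' `2 * 32 + 4 * choose(32, 2) = 2048` interventions at `max_size = 2`.
#'
#' @param net A `boolean_network`.
#' @param max_size 1 or 2.
#' @param exclude Nodes that may not be clamped (default `"Caspases"` when
#'   present in the network).
#' @return List of [intervention()] objects; the eligible node set is
#'   attached as attribute `eligible`.
#' @export
enumerate_interventions <- function(net, max_size = 2L,
                                    exclude = intersect("Caspases",
                                                        net$nodes)) {
  stopifnot(inherits(net, "boolean_network"), max_size %in% c(1L, 2L))
  eligible <- setdiff(net$nodes, exclude)
  ivs <- list()
  for (n in eligible) {
    for (v in c(0L, 1L)) {
      ivs[[length(ivs) + 1L]] <- intervention(stats::setNames(v, n))
    }
  }
  if (max_size >= 2L && length(eligible) >= 2L) {
    for (i in seq_len(length(eligible) - 1L)) {
      for (j in seq.int(i + 1L, length(eligible))) {
        for (vi in c(0L, 1L)) {
          for (vj in c(0L, 1L)) {
            ivs[[length(ivs) + 1L]] <- intervention(
              stats::setNames(c(vi, vj), eligible[c(i, j)]))
          }
        }
      }
    }
  }
  attr(ivs, "eligible") <- eligible
  ivs
}

#' Does an intervention induce apoptosis?
#'
#' Applies the intervention, enumerates attractors of the intervened
#' network (exact fixed points plus sampled cycles), and checks the
#' caspase node. The verdict is `"full"` iff every attractor has caspases
#' active in every cycle state; otherwise `"partial"` (some caspase-active
#' attractor exists) or `"none"`. Trajectories that fail to resolve yield
#' verdict `"undetermined"`.
#'
#' @param net A `boolean_network` containing the marker node.
#' @param iv An [intervention()].
#' @param n_starts,seed,max_steps Passed to [find_attractors()].
#' @param marker Apoptosis marker node (default `"Caspases"`).
#' @return List with `verdict`, `fraction` (basin fraction of
#'   caspase-active attractors among resolved starts), `n_attractors` and
#'   the `bn_attractor_set` as `attractors`.
#' @export
induces_apoptosis <- function(net, iv, n_starts = 1e5, seed = 1L,
                              max_steps = 10000L, marker = "Caspases") {
  stopifnot(marker %in% net$nodes)
  inet <- apply_intervention(net, iv)
  aset <- find_attractors(inet, n_starts = n_starts, seed = seed,
                          max_steps = max_steps)
  active <- vapply(aset$attractors, attractor_active, TRUE, node = marker)
  basins <- vapply(aset$attractors, `[[`, 0L, "basin")
  resolved <- aset$n_starts - aset$n_unresolved
  fraction <- if (resolved > 0L) sum(basins[active]) / resolved else NA_real_
  verdict <- if (aset$n_unresolved > 0L) "undetermined"
             else if (all(active)) "full"
             else if (any(active)) "partial"
             else "none"
  list(verdict = verdict, fraction = fraction,
       n_attractors = length(aset$attractors), attractors = aset)
}

# Phenotype markers of the CFL1 model.
PHENOTYPE_MARKERS <- c(apoptosis = "Caspases", proliferation = "S-phase",
                       migration = "F-actin_new")

#' Classify an attractor into phenotypes
#'
#' Phenotype flags are computed from the attractor states alone: apoptosis
#' (caspases active in every cycle state), proliferation (S-phase active
#' throughout), migration (newly polymerized F-actin active throughout) and
#' arrest (neither S-phase nor caspases active in any state).
#'
#' @param attr A `bn_attractor` over the CFL1 model's node set.
#' @param markers Named character vector mapping the `apoptosis`,
#'   `proliferation` and `migration` flags to marker nodes.
#' @return Named logical vector with elements `apoptosis`, `proliferation`,
#'   `migration`, `arrest`.
#' @export
classify_attractor <- function(attr, markers = PHENOTYPE_MARKERS) {
  stopifnot(inherits(attr, "bn_attractor"),
            all(c("apoptosis", "proliferation", "migration") %in%
                  names(markers)))
  missing <- setdiff(markers, colnames(attr$states))
  if (length(missing) > 0L) {
    stop(sprintf("attractor lacks marker node(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  apop <- attractor_active(attr, markers[["apoptosis"]])
  prol <- attractor_active(attr, markers[["proliferation"]])
  migr <- attractor_active(attr, markers[["migration"]])
  arrest <- all(attr$states[, markers[["proliferation"]]] == 0L) &&
            all(attr$states[, markers[["apoptosis"]]] == 0L)
  c(apoptosis = apop, proliferation = prol, migration = migr,
    arrest = arrest)
}

#' Exhaustive intervention screening for apoptosis induction
#'
#' Evaluates [induces_apoptosis()] over the full universe from
#' [enumerate_interventions()] and reports, per intervention, the verdict
#' and the basin fraction of caspase-active attractors. Fully reproducible
#' given `seed` (every intervention is evaluated with the same start-state
#' seed).
#'
#' @param net A `boolean_network`.
#' @param max_size Largest intervention size (1 or 2).
#' @param n_starts Random start states per intervention.
#' @param seed Integer seed.
#' @param exclude Nodes excluded from clamping (default the caspase node).
#' @param max_steps Per-trajectory step bound.
#' @param progress Print a progress line every 256 interventions.
#' @return A `screening_report`: list with `results` (data.frame with one
#'   row per intervention: label, size, verdict, caspase basin fraction,
#'   attractor count), `single_hits` and `pair_hits` (labels with verdict
#'   `"full"`; pair hits annotate whether they contain a single hit),
#'   `universe_size`, `n_starts`, `seed`.
#' @export
screen_interventions <- function(net, max_size = 2L, n_starts = 1000L,
                                 seed = 1L,
                                 exclude = intersect("Caspases", net$nodes),
                                 max_steps = 10000L, progress = FALSE) {
  ivs <- enumerate_interventions(net, max_size = max_size, exclude = exclude)
  n <- length(ivs)
  label <- character(n)
  size <- integer(n)
  verdict <- character(n)
  fraction <- numeric(n)
  n_attr <- integer(n)
  for (i in seq_len(n)) {
    iv <- ivs[[i]]
    r <- induces_apoptosis(net, iv, n_starts = n_starts, seed = seed,
                           max_steps = max_steps)
    label[i] <- iv$label
    size[i] <- length(iv$clamps)
    verdict[i] <- r$verdict
    fraction[i] <- r$fraction
    n_attr[i] <- r$n_attractors
    if (progress && i %% 256L == 0L) {
      message(sprintf("screened %d/%d interventions", i, n))
    }
  }
  results <- data.frame(label = label, size = size, verdict = verdict,
                        caspase_basin_fraction = fraction,
                        n_attractors = n_attr, stringsAsFactors = FALSE)
  full <- results$verdict == "full"
  single_hits <- results$label[full & results$size == 1L]
  pair_labels <- results$label[full & results$size == 2L]
  contains_single <- vapply(pair_labels, function(lb) {
    parts <- strsplit(lb, ",", fixed = TRUE)[[1]]
    any(parts %in% single_hits)
  }, TRUE, USE.NAMES = FALSE)
  structure(list(results = results,
                 single_hits = single_hits,
                 pair_hits = if (length(pair_labels)) {
                   data.frame(label = pair_labels,
                              contains_single_hit = contains_single,
                              stringsAsFactors = FALSE)
                 } else {
                   data.frame(label = character(),
                              contains_single_hit = logical())
                 },
                 universe_size = n, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), max_size = as.integer(max_size)),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("Intervention screen: %d interventions (max size %d), %d starts each\n",
              x$universe_size, x$max_size, x$n_starts))
  cat(sprintf("  full-verdict single clamps: %s\n",
              if (length(x$single_hits)) paste(x$single_hits, collapse = ", ")
              else "(none)"))
  cat(sprintf("  full-verdict pairs: %d (%d containing a single hit)\n",
              nrow(x$pair_hits), sum(x$pair_hits$contains_single_hit)))
  invisible(x)
}

#' Export a screening report
#'
#' @param report A `screening_report`.
#' @param json,csv Output paths (`NULL` to skip either).
#' @return The report, invisibly.
#' @export
write_screening_report <- function(report, json = NULL, csv = NULL) {
  stopifnot(inherits(report, "screening_report"))
  if (!is.null(csv)) {
    utils::write.csv(report$results, csv, row.names = FALSE, quote = TRUE)
  }
  if (!is.null(json)) {
    obj <- list(universe_size = report$universe_size,
                max_size = report$max_size,
                n_starts = report$n_starts, seed = report$seed,
                single_hits = as.list(report$single_hits),
                pair_hits = report$pair_hits,
                results = report$results)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"), json)
  }
  invisible(report)
}
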