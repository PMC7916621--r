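# ROC-threshold binarization of labeled two-class expression data.

#' Labeled expression matrix
#'
#' Container for a genes-by-samples matrix of normalized (log-scale)
#' expression values with a binary class label per sample and an optional
#' technical-replicate grouping.
#'
#' @param values Numeric matrix, rows = genes (rownames required),
#'   columns = samples (colnames required).
#' @param labels Per-sample class labels: `"tumor"` (positive) or
#'   `"normal"` (negative); character or factor, length `ncol(values)`.
#' @param replicate_groups Optional character vector, length
#'   `ncol(values)`: samples sharing a group id are technical replicates of
#'   one biological sample. `NA` entries are singleton samples.
#' @return A `labeled_expression` object.
#' @export
labeled_expression <- function(values, labels, replicate_groups = NULL) {
  stopifnot(is.matrix(values), is.numeric(values),
            !is.null(rownames(values)), !is.null(colnames(values)))
  labels <- as.character(labels)
  if (length(labels) != ncol(values)) {
    stop("need one class label per sample", call. = FALSE)
  }
  if (anyNA(labels) || !all(labels %in% c("tumor", "normal"))) {
    stop("labels must be 'tumor' or 'normal' with no missing values",
         call. = FALSE)
  }
  if (!is.null(replicate_groups)) {
    stopifnot(length(replicate_groups) == ncol(values))
    replicate_groups <- as.character(replicate_groups)
  }
  structure(list(values = values,
                 labels = stats::setNames(labels, colnames(values)),
                 replicate_groups = replicate_groups),
            class = "labeled_expression")
}

#' @export
print.labeled_expression <- function(x, ...) {
  cat(sprintf("Labeled expression matrix: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values), sum(x$labels == "tumor"),
              sum(x$labels == "normal")))
  if (!is.null(x$replicate_groups)) {
    ng <- length(unique(stats::na.omit(x$replicate_groups)))
    cat(sprintf("  replicate groups: %d\n", ng))
  }
  invisible(x)
}

#' Average technical replicates
#'
#' Collapses every replicate group to a single sample holding the per-gene
#' arithmetic mean; class labels are preserved. A group mixing tumor and
#' normal labels is an error. Idempotent: the output has no replicate
#' groups left.
#'
#' @param m A [labeled_expression()].
#' @return A `labeled_expression` with one column per biological sample.
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "labeled_expression"))
  if (is.null(m$replicate_groups)) return(m)
  groups <- m$replicate_groups
  groups[is.na(groups)] <- paste0(".singleton.", which(is.na(groups)))
  uniq <- unique(groups)
  vals <- matrix(NA_real_, nrow(m$values), length(uniq),
                 dimnames = list(rownames(m$values), NULL))
  labs <- character(length(uniq))
  cn <- character(length(uniq))
  for (i in seq_along(uniq)) {
    cols <- which(groups == uniq[i])
    lab <- unique(m$labels[cols])
    if (length(lab) != 1L) {
      stop(sprintf("replicate group '%s' mixes class labels", uniq[i]),
           call. = FALSE)
    }
    vals[, i] <- rowMeans(m$values[, cols, drop = FALSE])
    labs[i] <- lab
    cn[i] <- colnames(m$values)[cols[1L]]
  }
  colnames(vals) <- cn
  labeled_expression(vals, labs)
}

#' ROC-optimal binarization threshold for one gene
#'
#' Chooses the cutpoint maximizing Youden's J (sensitivity + specificity
#' - 1) over candidate thresholds at the midpoints between consecutive
#' sorted distinct values, with the ROC direction determined by the labels:
#' if tumors tend to lie below normals, the orientation is flipped so that
#' J is maximized for the label-consistent classifier (the convention of
#' common ROC software with automatic direction). Calls are always
#' `active = value > threshold`, so on down-shifted genes tumors come out
#' inactive. Ties are broken toward the smallest qualifying threshold, and
#' toward the upward direction.
#'
#' @param values Numeric vector of expression values for one gene.
#' @param labels `"tumor"`/`"normal"` per value.
#' @return List with `threshold`, `direction` (`"up"` if tumor-active),
#'   `auc` (label-oriented, >= 0.5 unless degenerate), `sensitivity`,
#'   `specificity` and `j` at the chosen cutpoint, and `degenerate`
#'   (`TRUE` when all values coincide).
#' @export
roc_threshold <- function(values, labels) {
  labels <- as.character(labels)
  stopifnot(length(values) == length(labels),
            all(labels %in% c("tumor", "normal")))
  pos <- values[labels == "tumor"]
  neg <- values[labels == "normal"]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  sv <- sort(unique(values))
  if (length(sv) < 2L) {
    return(list(threshold = NA_real_, direction = "up", auc = 0.5,
                sensitivity = NA_real_, specificity = NA_real_,
                j = NA_real_, degenerate = TRUE))
  }
  cand <- (sv[-length(sv)] + sv[-1L]) / 2
  # Mann-Whitney AUC for the tumor-high orientation, ties counted half
  r <- rank(values)
  auc_up <- (sum(r[labels == "tumor"]) -
             length(pos) * (length(pos) + 1) / 2) /
            (length(pos) * length(neg))
  sens_up <- vapply(cand, function(c) mean(pos > c), 0)
  spec_up <- vapply(cand, function(c) mean(neg <= c), 0)
  j_up <- sens_up + spec_up - 1
  sens_dn <- vapply(cand, function(c) mean(pos <= c), 0)
  spec_dn <- vapply(cand, function(c) mean(neg > c), 0)
  j_dn <- sens_dn + spec_dn - 1
  best_up <- max(j_up)
  best_dn <- max(j_dn)
  if (best_up >= best_dn) {
    k <- which(j_up == best_up)[1L]
    list(threshold = cand[k], direction = "up", auc = auc_up,
         sensitivity = sens_up[k], specificity = spec_up[k], j = j_up[k],
         degenerate = FALSE)
  } else {
    k <- which(j_dn == best_dn)[1L]
    list(threshold = cand[k], direction = "down", auc = 1 - auc_up,
         sensitivity = sens_dn[k], specificity = spec_dn[k], j = j_dn[k],
         degenerate = FALSE)
  }
}

#' Binarize an expression matrix by per-gene ROC thresholds
#'
#' Averages technical replicates, then derives one [roc_threshold()] per
#' requested gene and calls each sample `active` when its value lies
#' strictly above the gene's threshold, `inactive` otherwise. Also reports
#' the per-gene fraction of tumor samples called active.
#'
#' @param m A [labeled_expression()].
#' @param genes Genes to binarize (default: all rows); an absent gene is an
#'   error naming the missing identifiers.
#' @return A `binarization_result`: list with `thresholds` (data.frame:
#'   gene, threshold, direction, auc, sensitivity, specificity, j,
#'   tumor_active_fraction), `calls` (character matrix genes x samples of
#'   `"active"`/`"inactive"`), `labels`.
#' @export
binarize_matrix <- function(m, genes = rownames(m$values)) {
  stopifnot(inherits(m, "labeled_expression"))
  missing <- setdiff(genes, rownames(m$values))
  if (length(missing) > 0L) {
    stop(sprintf("gene(s) not in matrix: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  m <- average_replicates(m)
  res <- lapply(genes, function(g) roc_threshold(m$values[g, ], m$labels))
  calls <- matrix("inactive", length(genes), ncol(m$values),
                  dimnames = list(genes, colnames(m$values)))
  taf <- numeric(length(genes))
  for (i in seq_along(genes)) {
    thr <- res[[i]]$threshold
    if (!is.na(thr)) {
      calls[i, m$values[genes[i], ] > thr] <- "active"
    }
    taf[i] <- mean(calls[i, m$labels == "tumor"] == "active")
  }
  thresholds <- data.frame(
    gene = genes,
    threshold = vapply(res, `[[`, 0, "threshold"),
    direction = vapply(res, `[[`, "", "direction"),
    auc = vapply(res, `[[`, 0, "auc"),
    sensitivity = vapply(res, `[[`, 0, "sensitivity"),
    specificity = vapply(res, `[[`, 0, "specificity"),
    j = vapply(res, `[[`, 0, "j"),
    tumor_active_fraction = taf,
    stringsAsFactors = FALSE
  )
  structure(list(thresholds = thresholds, calls = calls, labels = m$labels),
            class = "binarization_result")
}

#' @export
print.binarization_result <- function(x, ...) {
  cat(sprintf("Binarization of %d gene(s) across %d samples\n",
              nrow(x$thresholds), ncol(x$calls)))
  print(x$thresholds[, c("gene", "threshold", "j", "tumor_active_fraction")],
        row.names = FALSE)
  invisible(x)
}

#' Read expression and label CSV files
#'
#' Expression CSV: first column gene names, remaining columns samples.
#' Label CSV: columns `sample`, `class` (`tumor`/`normal`) and optionally
#' `replicate_group`.
#'
#' @param expr_file,label_file Paths to the two CSV files.
#' @return A [labeled_expression()].
#' @export
read_labeled_expression <- function(expr_file, label_file) {
  ex <- utils::read.csv(expr_file, check.names = FALSE,
                        stringsAsFactors = FALSE)
  vals <- as.matrix(ex[, -1L, drop = FALSE])
  rownames(vals) <- ex[[1L]]
  lab <- utils::read.csv(label_file, stringsAsFactors = FALSE)
  if (!all(c("sample", "class") %in% names(lab))) {
    stop("label file needs columns 'sample' and 'class'", call. = FALSE)
  }
  missing <- setdiff(colnames(vals), lab$sample)
  extra <- setdiff(lab$sample, colnames(vals))
  if (length(missing) || length(extra)) {
    stop(sprintf("sample mismatch between matrix and labels: %s",
                 paste(c(missing, extra), collapse = ", ")), call. = FALSE)
  }
  lab <- lab[match(colnames(vals), lab$sample), ]
  rg <- if ("replicate_group" %in% names(lab)) {
    g <- as.character(lab$replicate_group)
    g[!nzchar(g) | is.na(g)] <- NA_character_
    g
  } else NULL
  labeled_expression(vals, lab$class, rg)
}

#' Write binarization outputs
#'
#' @param result A `binarization_result`.
#' @param thresholds_csv,calls_csv,roc_json Output paths (`NULL` to skip).
#' @return The result, invisibly.
#' @export
write_binarization <- function(result, thresholds_csv = NULL,
                               calls_csv = NULL, roc_json = NULL) {
  stopifnot(inherits(result, "binarization_result"))
  if (!is.null(thresholds_csv)) {
    utils::write.csv(result$thresholds, thresholds_csv, row.names = FALSE)
  }
  if (!is.null(calls_csv)) {
    df <- data.frame(gene = rownames(result$calls), result$calls,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, calls_csv, row.names = FALSE)
  }
  if (!is.null(roc_json)) {
    writeLines(jsonlite::toJSON(result$thresholds, dataframe = "rows",
                                auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, na = "null"), roc_json)
  }
  invisible(result)
}
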