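# Target profiling: annotation-category composition, organ distribution,
# expression thresholding into target-organ edges, and a generic
# hypergeometric enrichment with Benjamini-Hochberg correction.

#' Category composition of an annotation table
#'
#' Percentage of term-gene associations falling in each annotation category
#' (e.g. the biological process / molecular function / cellular component
#' split of a GO annotation).  Counts associations, not distinct terms,
#' matching how category pie percentages are conventionally computed.
#'
#' @param annotations Data frame with columns `term_id`, `category`, `gene`
#'   (a `term_name` column is carried along if present); one row per
#'   term-gene association.  Duplicate rows are collapsed.
#' @return Data frame (`category`, `n_associations`, `percent`) sorted by
#'   count descending; percentages sum to 100.
#' @export
category_composition <- function(annotations) {
  req <- c("term_id", "category", "gene")
  if (!all(req %in% names(annotations))) {
    stop("annotations need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  annotations <- unique(annotations[, req])
  if (!nrow(annotations)) stop("empty annotation table", call. = FALSE)
  tab <- table(annotations$category)
  out <- data.frame(category = names(tab),
                    n_associations = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$n_associations / sum(out$n_associations)
  out <- out[order(-out$n_associations, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Organ distribution of targets
#'
#' For each organ of a target-organ network, the number of targets highly
#' expressed there and the percentage of all targets that represents (e.g.
#' "30 of 50 targets in retina = 60%").
#'
#' @param to A target-organ `bipartite_network`.
#' @param n_targets_total Denominator: total number of targets in the
#'   analysis (not only those with organ edges).
#' @return Data frame (`organ`, `n_targets`, `percent`) sorted by count
#'   descending, organ ascending; organs without targets are omitted.
#' @export
organ_distribution <- function(to, n_targets_total) {
  stopifnot(inherits(to, "bipartite_network"), to$kind == "target-organ")
  if (n_targets_total <= 0) stop("n_targets_total must be positive",
                                 call. = FALSE)
  if (length(to$right_degree) &&
      n_targets_total < max(to$right_degree)) {
    stop("n_targets_total smaller than an organ's target count",
         call. = FALSE)
  }
  deg <- to$right_degree[to$right_degree > 0]
  out <- data.frame(organ = names(deg), n_targets = as.integer(deg),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$n_targets / n_targets_total
  out <- out[order(-out$n_targets, out$organ), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Threshold an expression matrix into target-organ edges
#'
#' Operationalizes "highly expressed in an organ" as expression at least
#' `factor` times the target's median expression across organs (default
#' factor 3).  The rule is deterministic and nested: a larger factor always
#' yields a subset of the edges of a smaller one.
#'
#' @param expr Non-negative numeric matrix, targets in rows (rownames = ids),
#'   organs in columns (colnames = organ ids).
#' @param factor Multiple-of-median cut-off, > 0.
#' @return A `herb_edgelist` of kind `"target-organ"`.  Targets whose whole
#'   row is zero produce no edges and a warning.
#' @export
threshold_expression <- function(expr, factor = 3) {
  expr <- as.matrix(expr)
  if (any(expr < 0, na.rm = TRUE)) stop("negative expression values",
                                        call. = FALSE)
  if (factor <= 0) stop("factor must be positive", call. = FALSE)
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs target rownames and organ colnames",
         call. = FALSE)
  }
  zero_rows <- rownames(expr)[rowSums(expr) == 0]
  if (length(zero_rows)) {
    warning("all-zero expression row(s): ",
            paste(zero_rows, collapse = ", "), call. = FALSE)
  }
  med <- apply(expr, 1L, median)
  hit <- expr >= factor * med & expr > 0
  idx <- which(hit, arr.ind = TRUE)
  edge_list(rownames(expr)[idx[, 1L]], colnames(expr)[idx[, 2L]],
            "target-organ")
}

#' Hypergeometric enrichment with Benjamini-Hochberg correction
#'
#' For each annotation term, tests over-representation of the query gene set
#' by the upper-tail hypergeometric probability of drawing at least the
#' observed overlap, then adjusts p-values across terms by the
#' Benjamini-Hochberg step-up procedure.
#'
#' @param genes Query gene set; must be contained in `universe`.
#' @param annotations Annotation data frame (`term_id`, `category`, `gene`,
#'   optionally `term_name`); memberships are intersected with the universe.
#' @param universe Background gene set.
#' @param alpha FDR level for the significance flag, default 0.05.
#' @return Data frame per term: `term_id`, `term_name`, `category`,
#'   `n_term`, `overlap`, `fold`, `p`, `p_adjust`, `significant`; sorted by
#'   `p` then term id.  Terms with zero overlap get p = 1.
#' @export
enrich <- function(genes, annotations, universe, alpha = 0.05) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  genes <- unique(as.character(genes))
  if (length(setdiff(genes, universe))) {
    stop("query genes outside the universe: ",
         paste(setdiff(genes, universe), collapse = ", "), call. = FALSE)
  }
  req <- c("term_id", "category", "gene")
  if (!all(req %in% names(annotations))) {
    stop("annotations need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  annotations <- annotations[annotations$gene %in% universe, , drop = FALSE]
  if (!nrow(annotations)) stop("no annotations within the universe",
                               call. = FALSE)
  terms <- split(annotations, annotations$term_id)
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(terms, function(tt) {
    members <- unique(tt$gene)
    K <- length(members)
    k <- length(intersect(members, genes))
    p <- if (k == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tt$term_id[1L],
               term_name = if ("term_name" %in% names(tt))
                 tt$term_name[1L] else tt$term_id[1L],
               category = tt$category[1L],
               n_term = K, overlap = k,
               fold = (k / n) / (K / N), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjust < alpha
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
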