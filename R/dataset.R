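# Domain containers: ingredient/target tables, edge lists, and the full
# dataset bundle that the pipeline stages pass around.

EDGE_KINDS <- c("compound-target", "target-pathway", "target-organ")

#' Construct an edge list between two node classes
#'
#' An edge list is the raw material of a bipartite network: a set of
#' (left, right) pairs tagged with the data sources that reported them.
#' Duplicate pairs are collapsed and their source tags unioned, so the
#' result is a set, independent of input order.
#'
#' @param left,right Character vectors of equal length: node ids on each side.
#' @param kind One of `"compound-target"`, `"target-pathway"`,
#'   `"target-organ"`.
#' @param sources Optional character vector (or list of character vectors) of
#'   provenance tags, one per input row; defaults to `"unspecified"`.
#' @return A `herb_edgelist`: a data frame with columns `left`, `right` and a
#'   list column `sources`, carrying the `kind` as an attribute.
#' @examples
#' el <- edge_list(c("M1", "M1"), c("T-22", "T-22"), "compound-target",
#'                 sources = c("HIT", "SEA"))
#' nrow(el)            # 1: the duplicate pair is merged
#' el$sources[[1]]     # both tags kept
#' @export
edge_list <- function(left, right, kind, sources = NULL) {
  kind <- match.arg(kind, EDGE_KINDS)
  left <- as.character(left)
  right <- as.character(right)
  if (length(left) != length(right)) {
    stop("`left` and `right` must have the same length", call. = FALSE)
  }
  if (is.null(sources)) sources <- rep("unspecified", length(left))
  if (!is.list(sources)) sources <- as.list(as.character(sources))
  if (length(sources) != length(left)) {
    stop("`sources` must align with the edges", call. = FALSE)
  }
  if (length(left)) {
    key <- paste(left, right, sep = "\r")
    ord <- !duplicated(key)
    merged <- lapply(split(sources, factor(key, levels = key[ord])),
                     function(s) sort(unique(unlist(s))))
    out <- data.frame(left = left[ord], right = right[ord],
                      stringsAsFactors = FALSE)
    out$sources <- unname(merged[paste(out$left, out$right, sep = "\r")])
    # canonical row order: left then right, so merging files is
    # order-independent
    o <- order(out$left, out$right)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(left = character(), right = character(),
                      stringsAsFactors = FALSE)
    out$sources <- list()
  }
  structure(out, kind = kind, class = c("herb_edgelist", "data.frame"))
}

#' @export
print.herb_edgelist <- function(x, ...) {
  cat(sprintf("<%s edge list: %d edges>\n", attr(x, "kind"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

edge_kind <- function(x) attr(x, "kind")

#' Bundle all inputs of a herb-pair analysis into one dataset
#'
#' @param ingredients Ingredient table as returned by [read_ingredients()]:
#'   columns `ingredient_id`, `name`, list column `herbs`, the four
#'   descriptors `mw`, `clogp`, `nhdon`, `nhacc`, `ob`, `dl`, and logical
#'   `rescue`.
#' @param targets Target table (`target_id`, `name`, `uniprot_id`, `gene`).
#' @param pathways,organs Character vectors of pathway / organ identifiers.
#' @param ct,tp,to Edge lists of the matching kinds (see [edge_list()]).
#' @param litcounts Named non-negative integer vector: disease-related
#'   literature count per ingredient id (the weight \eqn{c_i} in the
#'   contribution index).
#' @param herbs Declared herb label set (default the Huangqi/Huanglian pair).
#' @return A validated `herb_dataset` object.
#' @seealso [validate_dataset()], [read_dataset()], [generate_dataset()]
#' @export
herb_dataset <- function(ingredients, targets,
                         pathways = character(), organs = character(),
                         ct = NULL, tp = NULL, to = NULL,
                         litcounts = integer(),
                         herbs = c("Huangqi", "Huanglian")) {
  if (is.null(ct)) ct <- edge_list(character(), character(), "compound-target")
  if (is.null(tp)) tp <- edge_list(character(), character(), "target-pathway")
  if (is.null(to)) to <- edge_list(character(), character(), "target-organ")
  x <- structure(list(ingredients = ingredients, targets = targets,
                      pathways = as.character(pathways),
                      organs = as.character(organs),
                      ct = ct, tp = tp, to = to,
                      litcounts = litcounts, herbs = herbs),
                 class = "herb_dataset")
  validate_dataset(x)
  x
}

#' Validate the referential integrity of a dataset
#'
#' Checks every invariant the downstream stages rely on: unique ingredient,
#' target and gene ids; herb attributions drawn from the declared label set;
#' OB in \[0, 100\] and DL in \[0, 1\] where present; every edge endpoint
#' resolvable against its node table; literature counts keyed by known
#' ingredient ids.
#'
#' @param x A `herb_dataset`.
#' @return `x`, invisibly; aborts with a descriptive error otherwise.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "herb_dataset"))
  ing <- x$ingredients
  tg <- x$targets
  if (anyDuplicated(ing$ingredient_id)) {
    stop("duplicate ingredient id: ",
         ing$ingredient_id[duplicated(ing$ingredient_id)][1L], call. = FALSE)
  }
  if (anyDuplicated(tg$target_id)) {
    stop("duplicate target id: ",
         tg$target_id[duplicated(tg$target_id)][1L], call. = FALSE)
  }
  if (anyDuplicated(tg$gene)) {
    stop("duplicate gene symbol: ",
         tg$gene[duplicated(tg$gene)][1L], call. = FALSE)
  }
  bad_herb <- setdiff(unique(unlist(ing$herbs)), x$herbs)
  if (length(bad_herb)) {
    stop("unknown herb label: ", paste(bad_herb, collapse = ", "),
         call. = FALSE)
  }
  check_range <- function(v, lo, hi, what) {
    bad <- which(!is.na(v) & (v < lo | v > hi))
    if (length(bad)) {
      stop(sprintf("%s out of range [%g, %g] in row %d", what, lo, hi,
                   bad[1L]), call. = FALSE)
    }
  }
  check_range(ing$ob, 0, 100, "OB")
  check_range(ing$dl, 0, 1, "DL")
  check_range(ing$mw, 0, Inf, "MW")
  check_range(ing$nhdon, 0, Inf, "nHDon")
  check_range(ing$nhacc, 0, Inf, "nHAcc")
  check_ids <- function(el, left_ok, right_ok, what) {
    miss_l <- setdiff(el$left, left_ok)
    miss_r <- setdiff(el$right, right_ok)
    if (length(miss_l) || length(miss_r)) {
      stop(sprintf("%s edges reference unknown ids: %s", what,
                   paste(c(miss_l, miss_r), collapse = ", ")), call. = FALSE)
    }
  }
  check_ids(x$ct, ing$ingredient_id, tg$target_id, "compound-target")
  check_ids(x$tp, tg$target_id, x$pathways, "target-pathway")
  check_ids(x$to, tg$target_id, x$organs, "target-organ")
  extra <- setdiff(names(x$litcounts), ing$ingredient_id)
  if (length(extra)) {
    stop("literature counts for unknown ingredient ids: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (any(x$litcounts < 0)) stop("negative literature count", call. = FALSE)
  invisible(x)
}

#' @export
print.herb_dataset <- function(x, ...) {
  cat("<herb_dataset>\n")
  cat(sprintf("  herbs:       %s\n", paste(x$herbs, collapse = " + ")))
  cat(sprintf("  ingredients: %d   targets: %d   pathways: %d   organs: %d\n",
              nrow(x$ingredients), nrow(x$targets), length(x$pathways),
              length(x$organs)))
  cat(sprintf("  edges:       C-T %d, T-P %d, T-O %d;  literature counts: %d\n",
              nrow(x$ct), nrow(x$tp), nrow(x$to), length(x$litcounts)))
  invisible(x)
}

# Named list ingredient_id -> character vector of herb labels.
herb_attribution <- function(ingredients) {
  setNames(ingredients$herbs, ingredients$ingredient_id)
}
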