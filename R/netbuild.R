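# Bipartite network construction with exact degree bookkeeping.  The
# target-pathway degrees computed here are the d_i feeding the network
# efficacy of each ingredient.

SIDE_LABELS <- list("compound-target" = c("compound", "target"),
                    "target-pathway" = c("target", "pathway"),
                    "target-organ" = c("target", "organ"))

#' Build a bipartite network from an edge list
#'
#' @param edges A `herb_edgelist` (see [edge_list()] / [read_edges()]).
#' @param left_universe,right_universe Id vectors the edge endpoints must
#'   come from; default to the ids observed in the edges.  The two universes
#'   must be disjoint (bipartiteness).
#' @param include_isolates If `FALSE` (default), only nodes with at least
#'   one edge enter the network — matching what a Cytoscape import of an
#'   edge file shows — and isolated universe members are reported in the
#'   `isolates` field.  If `TRUE`, all universe members are nodes (isolates
#'   with degree 0).
#' @return A `bipartite_network`: `kind`, sorted `left_nodes` /
#'   `right_nodes`, the deduplicated `edges` data frame, named degree maps
#'   `left_degree` / `right_degree`, `side_labels`, and `isolates` (list
#'   with `left`, `right`).
#' @examples
#' el <- edge_list(c("a", "a", "b"), c("x", "y", "x"), "compound-target")
#' net <- build_network(el)
#' net$left_degree["a"]   # 2
#' @export
build_network <- function(edges, left_universe = NULL, right_universe = NULL,
                          include_isolates = FALSE) {
  stopifnot(inherits(edges, "herb_edgelist"))
  kind <- edge_kind(edges)
  left_universe <- sort(unique(as.character(left_universe %||% edges$left)))
  right_universe <- sort(unique(as.character(right_universe %||% edges$right)))
  if (length(intersect(left_universe, right_universe))) {
    stop("left and right universes overlap; bipartite sides must be disjoint",
         call. = FALSE)
  }
  bad <- c(setdiff(edges$left, left_universe),
           setdiff(edges$right, right_universe))
  if (length(bad)) {
    stop("edge endpoints outside the declared universes: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  iso_l <- setdiff(left_universe, edges$left)
  iso_r <- setdiff(right_universe, edges$right)
  if (include_isolates) {
    left_nodes <- left_universe
    right_nodes <- right_universe
  } else {
    left_nodes <- setdiff(left_universe, iso_l)
    right_nodes <- setdiff(right_universe, iso_r)
  }
  ldeg <- setNames(integer(length(left_nodes)), left_nodes)
  rdeg <- setNames(integer(length(right_nodes)), right_nodes)
  if (nrow(edges)) {
    tl <- table(edges$left)
    tr <- table(edges$right)
    ldeg[names(tl)] <- as.integer(tl)
    rdeg[names(tr)] <- as.integer(tr)
  }
  structure(list(kind = kind,
                 left_nodes = left_nodes, right_nodes = right_nodes,
                 edges = data.frame(left = edges$left, right = edges$right,
                                    stringsAsFactors = FALSE),
                 left_degree = ldeg, right_degree = rdeg,
                 side_labels = SIDE_LABELS[[kind]],
                 isolates = list(left = iso_l, right = iso_r)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  st <- network_stats(x)
  cat(sprintf("<%s network: %d %ss, %d %ss, %d edges>\n", x$kind,
              st$n_left, x$side_labels[1L], st$n_right, x$side_labels[2L],
              st$n_edges))
  invisible(x)
}

#' Per-node degree table of a bipartite network
#'
#' @param network A `bipartite_network`.
#' @return Data frame (`id`, `side`, `degree`) sorted by degree descending,
#'   id ascending — the deterministic ranking used everywhere a hub list is
#'   reported (e.g. the highest-degree compound of a C-T network).
#' @export
degree_table <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  df <- data.frame(
    id = c(network$left_nodes, network$right_nodes),
    side = c(rep(network$side_labels[1L], length(network$left_nodes)),
             rep(network$side_labels[2L], length(network$right_nodes))),
    degree = c(unname(network$left_degree[network$left_nodes]),
               unname(network$right_degree[network$right_nodes])),
    stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Targets regulated by both herbs
#'
#' A target is "shared" — the operational signature of synergy in this
#' analysis — when its incident ingredient set spans both herbs of the pair.
#' An ingredient attributed to both herbs counts toward both, so a target
#' hit only by one dual-herb compound is shared.
#'
#' @param ct A compound-target `bipartite_network`.
#' @param herb_of Named list: ingredient id -> character vector of herb
#'   labels (see `herb_attribution()` or build it yourself).  Every compound
#'   appearing in the network must be attributed.
#' @param herbs The two herb labels; defaults to the labels observed.
#' @return Sorted character vector of shared target ids.
#' @export
shared_targets <- function(ct, herb_of, herbs = NULL) {
  stopifnot(inherits(ct, "bipartite_network"),
            ct$kind == "compound-target")
  missing_attr <- setdiff(ct$edges$left, names(herb_of))
  if (length(missing_attr)) {
    stop("no herb attribution for ingredient(s): ",
         paste(missing_attr, collapse = ", "), call. = FALSE)
  }
  if (is.null(herbs)) herbs <- sort(unique(unlist(herb_of[ct$edges$left])))
  if (length(herbs) != 2L) {
    stop("shared-target analysis needs exactly two herb labels", call. = FALSE)
  }
  hit <- split(ct$edges$left, ct$edges$right)
  shared <- vapply(hit, function(compounds) {
    labs <- unique(unlist(herb_of[unique(compounds)]))
    all(herbs %in% labs)
  }, logical(1L))
  sort(names(hit)[shared])
}

#' Summary statistics of a bipartite network
#'
#' @param network A `bipartite_network`.
#' @return List of integer-exact counts: nodes per side, edge count, degree
#'   min / mean / max per side, and isolated-universe-member counts.
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "bipartite_network"))
  dstats <- function(d) {
    if (!length(d)) return(list(min = 0L, mean = 0, max = 0L))
    list(min = min(d), mean = mean(d), max = max(d))
  }
  list(n_left = length(network$left_nodes),
       n_right = length(network$right_nodes),
       n_edges = nrow(network$edges),
       left_degree = dstats(network$left_degree),
       right_degree = dstats(network$right_degree),
       n_isolated_left = length(network$isolates$left),
       n_isolated_right = length(network$isolates$right))
}
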