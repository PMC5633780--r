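# Tabular input (CSV/TSV with auto-detected delimiter) and network /
# dataset interchange formats (SIF, GraphML, JSON).

DATASET_FORMAT_VERSION <- "1.0"

# Sniff the delimiter from the header line: tab wins if present, else comma.
detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.csv(path, sep = detect_delim(path), stringsAsFactors = FALSE,
           check.names = FALSE, na.strings = c("NA", "N/A", ""))
}

# Rename user columns to the canonical header set. `col_map` maps canonical
# name -> the name used in the file.
apply_col_map <- function(df, required, col_map = NULL, path) {
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      idx <- match(col_map[[canon]], names(df))
      if (is.na(idx)) {
        stop(sprintf("column '%s' (mapped to '%s') not found in %s",
                     col_map[[canon]], canon, path), call. = FALSE)
      }
      names(df)[idx] <- canon
    }
  }
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read an ingredient table
#'
#' Reads a CSV/TSV of herbal ingredients with their ADME scores and herb
#' attribution.  The canonical header is `ingredient_id`, `name`, `herb`,
#' `mw`, `clogp`, `nhdon`, `nhacc`, `ob`, `dl`, `rescue`; files with other
#' headers are accommodated with `col_map`.  A `herb` cell naming both herbs
#' separated by `/` yields membership in both herb sets (one row, not two).
#' Missing numeric cells (`NA`, `N/A`, empty) become missing values — never
#' zeros — so that, e.g., a polysaccharide mixture with no computed OB/DL is
#' routed through the rescue path rather than silently failing a threshold.
#'
#' @param path File path.
#' @param herbs Declared herb label set; any other label is a hard error.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @return A data frame of validated ingredient records with a list column
#'   `herbs`.
#' @examples
#' tab1 <- system.file("extdata", "huangqi_huanglian_ingredients.csv",
#'                     package = "herbnp")
#' ing <- read_ingredients(tab1)
#' nrow(ing)   # 43 active ingredients
#' @export
read_ingredients <- function(path, herbs = c("Huangqi", "Huanglian"),
                             col_map = NULL) {
  df <- read_table_auto(path)
  required <- c("ingredient_id", "name", "herb", "ob", "dl")
  df <- apply_col_map(df, required, col_map, path)
  for (opt in c("mw", "clogp", "nhdon", "nhacc")) {
    if (!opt %in% names(df)) df[[opt]] <- rep(NA_real_, nrow(df))
  }
  if (!"rescue" %in% names(df)) df$rescue <- rep(FALSE, nrow(df))
  dup <- df$ingredient_id[duplicated(df$ingredient_id)]
  if (length(dup)) {
    stop("duplicate ingredient id: ", dup[1L], call. = FALSE)
  }
  herb_sets <- lapply(strsplit(as.character(df$herb), "/", fixed = TRUE),
                      function(h) sort(trimws(h)))
  unknown <- setdiff(unique(unlist(herb_sets)), herbs)
  if (length(unknown)) {
    stop("unknown herb label: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num <- function(v) suppressWarnings(as.numeric(v))
  out <- data.frame(ingredient_id = as.character(df$ingredient_id),
                    name = as.character(df$name), stringsAsFactors = FALSE)
  out$herbs <- herb_sets
  out$mw <- num(df$mw)
  out$clogp <- num(df$clogp)
  out$nhdon <- num(df$nhdon)
  out$nhacc <- num(df$nhacc)
  out$ob <- num(df$ob)
  out$dl <- num(df$dl)
  out$rescue <- as.logical(df$rescue)
  out$rescue[is.na(out$rescue)] <- FALSE
  for (chk in list(c("ob", 0, 100), c("dl", 0, 1))) {
    v <- out[[chk[1L]]]
    bad <- which(!is.na(v) & (v < as.numeric(chk[2L]) | v > as.numeric(chk[3L])))
    if (length(bad)) {
      stop(sprintf("%s out of range in row %d of %s", toupper(chk[1L]),
                   bad[1L], path), call. = FALSE)
    }
  }
  out
}

#' Read a target table
#'
#' @param path File path to a CSV/TSV with columns `target_id`, `name`,
#'   `uniprot_id`, `gene` (remappable via `col_map`).
#' @param col_map Optional canonical-to-file column name mapping.
#' @return Data frame of target records; duplicate target ids or gene
#'   symbols are hard errors.
#' @export
read_targets <- function(path, col_map = NULL) {
  df <- read_table_auto(path)
  required <- c("target_id", "name", "uniprot_id", "gene")
  df <- apply_col_map(df, required, col_map, path)
  dup <- df$target_id[duplicated(df$target_id)]
  if (length(dup)) stop("duplicate target id: ", dup[1L], call. = FALSE)
  dupg <- df$gene[duplicated(df$gene)]
  if (length(dupg)) stop("duplicate gene symbol: ", dupg[1L], call. = FALSE)
  data.frame(target_id = as.character(df$target_id),
             name = as.character(df$name),
             uniprot_id = as.character(df$uniprot_id),
             gene = as.character(df$gene), stringsAsFactors = FALSE)
}

#' Read an edge table
#'
#' Two-column (`left`, `right`) CSV/TSV with an optional third `source`
#' column of provenance tags.  Duplicate pairs are collapsed with their
#' source tags unioned, so downloads of the same interaction from several
#' prediction servers merge cleanly.
#'
#' @param path File path.
#' @param kind Edge kind: `"compound-target"`, `"target-pathway"` or
#'   `"target-organ"`.
#' @param left_universe,right_universe Optional id vectors to validate
#'   endpoints against.
#' @param lenient If `FALSE` (default) an edge referencing an unknown id is a
#'   hard error; if `TRUE` such edges are dropped with a warning giving the
#'   count (web-server exports are messy).
#' @return A `herb_edgelist`.
#' @export
read_edges <- function(path, kind, left_universe = NULL,
                       right_universe = NULL, lenient = FALSE) {
  kind <- match.arg(kind, EDGE_KINDS)
  df <- read_table_auto(path)
  if (ncol(df) < 2L) stop("edge table needs at least two columns",
                          call. = FALSE)
  left <- as.character(df[[1L]])
  right <- as.character(df[[2L]])
  sources <- if (ncol(df) >= 3L) as.character(df[[3L]]) else NULL
  keep <- rep(TRUE, length(left))
  if (!is.null(left_universe)) keep <- keep & left %in% left_universe
  if (!is.null(right_universe)) keep <- keep & right %in% right_universe
  if (!all(keep)) {
    if (lenient) {
      warning(sprintf("dropped %d edge(s) with unresolvable ids from %s",
                      sum(!keep), path), call. = FALSE)
      left <- left[keep]; right <- right[keep]
      if (!is.null(sources)) sources <- sources[keep]
    } else {
      bad <- c(setdiff(left, left_universe %||% left),
               setdiff(right, right_universe %||% right))
      stop("edge references unknown id(s): ",
           paste(unique(bad), collapse = ", "), call. = FALSE)
    }
  }
  edge_list(left, right, kind, sources)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a literature-count table
#'
#' Two-column CSV/TSV: ingredient id, non-negative integer count of
#' disease-related publications.
#'
#' @param path File path.
#' @return Named integer vector keyed by ingredient id.
#' @export
read_litcounts <- function(path) {
  df <- read_table_auto(path)
  if (ncol(df) < 2L) stop("literature-count table needs two columns",
                          call. = FALSE)
  counts <- suppressWarnings(as.integer(df[[2L]]))
  if (anyNA(counts) || any(counts < 0)) {
    stop("literature counts must be non-negative integers", call. = FALSE)
  }
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate ingredient id in literature counts: ",
         ids[duplicated(ids)][1L], call. = FALSE)
  }
  setNames(counts, ids)
}

#' Export a bipartite network for external tools
#'
#' Three interchange formats are supported. `"sif"` writes Cytoscape simple
#' interaction format lines (`left <kind> right`); `"graphml"` writes GraphML
#' via igraph with `node_class` (side label) and `degree` vertex attributes;
#' `"json"` writes a self-contained envelope that [read_network()] restores
#' exactly.
#'
#' @param network A `bipartite_network` (see [build_network()]).
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "graphml", "json")) {
  stopifnot(inherits(network, "bipartite_network"))
  format <- match.arg(format)
  if (format == "sif") {
    lines <- sprintf("%s\t%s\t%s", network$edges$left, network$kind,
                     network$edges$right)
    writeLines(lines, path)
  } else if (format == "graphml") {
    g <- as_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    env <- list(format_version = DATASET_FORMAT_VERSION,
                kind = network$kind,
                left_nodes = network$left_nodes,
                right_nodes = network$right_nodes,
                edges = network$edges)
    jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a JSON-exported bipartite network
#'
#' @param path Path written by [write_network()] with `format = "json"`.
#' @return The restored `bipartite_network`.
#' @export
read_network <- function(path) {
  env <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- env$edges
  if (is.null(edges) || !length(edges)) {
    edges <- data.frame(left = character(), right = character(),
                        stringsAsFactors = FALSE)
  }
  el <- edge_list(edges$left, edges$right, env$kind)
  build_network(el, left_universe = as.character(env$left_nodes),
                right_universe = as.character(env$right_nodes),
                include_isolates = TRUE)
}

# igraph view of a bipartite network; used for GraphML export and as a
# cross-check in the test-suite.
as_igraph <- function(network) {
  verts <- data.frame(
    name = c(network$left_nodes, network$right_nodes),
    node_class = c(rep(network$side_labels[1L], length(network$left_nodes)),
                   rep(network$side_labels[2L], length(network$right_nodes))),
    stringsAsFactors = FALSE)
  verts$degree <- c(network$left_degree[network$left_nodes],
                    network$right_degree[network$right_nodes])
  igraph::graph_from_data_frame(network$edges[, c("left", "right")],
                                directed = FALSE, vertices = verts)
}

#' Write / read a full dataset as one JSON envelope
#'
#' The envelope is versioned (`format_version` field) and captures every
#' component of a [herb_dataset()] so that `read_dataset(write_dataset(x))`
#' reproduces `x` exactly.
#'
#' @param x A `herb_dataset`.
#' @param path Output (input) file path.
#' @return `write_dataset`: `path` invisibly; `read_dataset`: the restored,
#'   re-validated `herb_dataset`.
#' @export
write_dataset <- function(x, path) {
  stopifnot(inherits(x, "herb_dataset"))
  ing <- x$ingredients
  ing$herbs <- vapply(ing$herbs, paste, "", collapse = "/")
  ser_edges <- function(el) {
    list(kind = edge_kind(el),
         left = el$left, right = el$right,
         sources = lapply(el$sources, as.list))
  }
  env <- list(format_version = DATASET_FORMAT_VERSION,
              herbs = x$herbs,
              ingredients = ing,
              targets = x$targets,
              pathways = x$pathways,
              organs = x$organs,
              ct = ser_edges(x$ct), tp = ser_edges(x$tp),
              to = ser_edges(x$to),
              litcounts = as.list(x$litcounts))
  jsonlite::write_json(env, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  env <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(env$format_version)) {
    stop("not a herbnp dataset envelope (no format_version)", call. = FALSE)
  }
  ing <- env$ingredients
  ing$herbs <- lapply(strsplit(ing$herbs, "/", fixed = TRUE), sort)
  for (col in c("mw", "clogp", "nhdon", "nhacc", "ob", "dl")) {
    ing[[col]] <- as.numeric(ing[[col]])
  }
  ing$rescue <- as.logical(ing$rescue)
  de <- function(e) {
    edge_list(as.character(unlist(e$left)), as.character(unlist(e$right)),
              e$kind,
              sources = lapply(e$sources, function(s) unlist(s)))
  }
  lit <- unlist(env$litcounts)
  lit <- if (is.null(lit)) integer() else {
    setNames(as.integer(lit), names(lit))
  }
  herb_dataset(ingredients = ing, targets = env$targets,
               pathways = as.character(env$pathways),
               organs = as.character(env$organs),
               ct = de(env$ct), tp = de(env$tp), to = de(env$to),
               litcounts = lit, herbs = as.character(env$herbs))
}
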