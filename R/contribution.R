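# The headline statistic: network efficacy (NE) per ingredient and the
# literature-weighted contribution index (CI) with the cumulative top-N rule.

#' Network efficacy of an ingredient
#'
#' For ingredient \eqn{j}, \eqn{NE(j) = \sum_{i=1}^{n} d_i}: the sum, over
#' the \eqn{n} targets adjacent to \eqn{j} in the compound-target network,
#' of each target's degree \eqn{d_i} in the target-pathway network.  A
#' target that sits in no pathway contributes 0 (dropping it from the sum
#' gives the same number).
#'
#' @param ct Compound-target `bipartite_network`.
#' @param tp Target-pathway `bipartite_network`.
#' @param ingredient_id Single ingredient id; must be in `ct`'s left
#'   universe (a compound with no predicted targets has NE 0).
#' @return Non-negative integer.
#' @examples
#' ct <- build_network(edge_list(c("j", "j"), c("t1", "t2"),
#'                               "compound-target"))
#' tp <- build_network(edge_list(c("t1", "t1", "t1", "t2", "t2"),
#'                               c("p1", "p2", "p3", "p1", "p4"),
#'                               "target-pathway"))
#' network_efficacy(ct, tp, "j")  # 3 + 2 = 5
#' @export
network_efficacy <- function(ct, tp, ingredient_id) {
  stopifnot(inherits(ct, "bipartite_network"),
            inherits(tp, "bipartite_network"),
            ct$kind == "compound-target", tp$kind == "target-pathway")
  known <- union(ct$left_nodes, ct$isolates$left)
  if (!ingredient_id %in% known) {
    stop("unknown ingredient: ", ingredient_id, call. = FALSE)
  }
  targets <- unique(ct$edges$right[ct$edges$left == ingredient_id])
  if (!length(targets)) return(0L)
  d <- tp$left_degree[targets]
  d[is.na(d)] <- 0L   # target absent from the T-P network
  as.integer(sum(d))
}

# NE for every ingredient in the C-T universe at once.
network_efficacy_all <- function(ct, tp) {
  ids <- union(ct$left_nodes, ct$isolates$left)
  setNames(vapply(ids, function(j) network_efficacy(ct, tp, j), integer(1L)),
           ids)
}

#' Literature-weighted contribution index
#'
#' Converts per-ingredient network efficacy into the contribution index
#' \deqn{CI(j) = \frac{c_j \, NE(j)}{\sum_{i=1}^{m} c_i \, NE(i)} \times
#' 100\%,} where \eqn{c_i} is the count of disease-related literature for
#' ingredient \eqn{i} and \eqn{m} the number of ingredients.  CIs sum to
#' 100% by construction; an ingredient with no literature or no network
#' efficacy contributes 0.  The ranking is deterministic: CI descending,
#' ties broken by NE descending, then id ascending.
#'
#' @param ne Named non-negative vector of network efficacies (see
#'   [network_efficacy()]).
#' @param litcounts Named non-negative vector of literature counts.
#'   Ingredients present in `ne` but absent here default to count 0 with a
#'   warning (no literature, no weight).
#' @return A `contribution_result`: `ne`, `ci` (percent), `ranking`,
#'   `cumulative` (cumulative CI along the ranking), and `litcounts` as
#'   used.
#' @examples
#' contribution_index(c(a = 3, b = 1), c(a = 1, b = 1))$ci  # 75, 25
#' @export
contribution_index <- function(ne, litcounts) {
  if (is.null(names(ne)) || any(!nzchar(names(ne)))) {
    stop("`ne` must be a named vector", call. = FALSE)
  }
  if (any(ne < 0) || any(litcounts < 0)) {
    stop("negative NE or literature count", call. = FALSE)
  }
  ids <- names(ne)
  missing_lit <- setdiff(ids, names(litcounts))
  if (length(missing_lit)) {
    warning(sprintf("%d ingredient(s) without literature counts given weight 0",
                    length(missing_lit)), call. = FALSE)
  }
  cc <- setNames(numeric(length(ids)), ids)
  have <- intersect(ids, names(litcounts))
  cc[have] <- litcounts[have]
  mass <- cc * ne
  denom <- sum(mass)
  if (denom <= 0) {
    stop("all c_i * NE(i) products are zero; check the literature counts ",
         "and the C-T/T-P networks", call. = FALSE)
  }
  ci <- 100 * mass / denom
  ord <- order(-ci, -ne, ids)
  ranking <- ids[ord]
  structure(list(ne = ne, ci = ci, litcounts = cc,
                 ranking = ranking,
                 cumulative = setNames(cumsum(ci[ord]), ranking)),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, n = 10L, ...) {
  cat(sprintf("Contribution indices for %d ingredients (sum %.2f%%)\n",
              length(x$ci), sum(x$ci)))
  top <- utils::head(x$ranking, n)
  df <- data.frame(ingredient = top,
                   NE = unname(x$ne[top]),
                   lit = unname(x$litcounts[top]),
                   CI = sprintf("%.2f%%", x$ci[top]),
                   cumulative = sprintf("%.2f%%", x$cumulative[top]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.contribution_result <- function(object, threshold = 85, ...) {
  top <- top_contributors(object, threshold)
  cat(sprintf("Top %d ingredient(s) exceed %g%% cumulative CI: %s\n",
              length(top), threshold, paste(top, collapse = ", ")))
  invisible(top)
}

#' Minimal top set of contributors
#'
#' The smallest prefix of the CI ranking whose cumulative CI is strictly
#' greater than the threshold ("more than 85%" is read as >, so a cumulative
#' of exactly 85.00 does not stop the prefix).  If the threshold is never
#' exceeded (only possible at threshold 100), the full ranking is returned.
#'
#' @param result A `contribution_result`.
#' @param threshold Percent in (0, 100], default 85.
#' @return Character vector of ingredient ids, in ranking order, with the
#'   per-rank cumulative CI attached as the `cumulative` attribute.
#' @export
top_contributors <- function(result, threshold = 85) {
  stopifnot(inherits(result, "contribution_result"))
  if (!is.finite(threshold) || threshold <= 0 || threshold > 100) {
    stop("threshold must be in (0, 100]", call. = FALSE)
  }
  cum <- result$cumulative
  n <- if (any(cum > threshold)) which(cum > threshold)[1L] else length(cum)
  structure(result$ranking[seq_len(n)], cumulative = unname(cum[seq_len(n)]))
}

#' Stability of the top set under literature-count noise
#'
#' Literature counts are the softest input of the contribution index (they
#' depend on a bibliometric snapshot), so this companion check perturbs them
#' with multiplicative lognormal noise and reports how often each ingredient
#' stays in the top set.
#'
#' @param ct,tp Built compound-target and target-pathway networks.
#' @param litcounts Named literature-count vector.
#' @param perturbation Relative noise level: `sdlog` of the multiplicative
#'   lognormal factor (0 = no noise).
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed; results are deterministic given the seed.
#' @param threshold Cumulative-CI threshold passed to [top_contributors()].
#' @return Named numeric vector in \[0, 1\]: per-ingredient frequency of
#'   top-set membership.
#' @export
weight_sensitivity <- function(ct, tp, litcounts, perturbation = 0.05,
                               reps = 200L, seed = 1L, threshold = 85) {
  stopifnot(reps >= 1L, perturbation >= 0)
  ne <- network_efficacy_all(ct, tp)
  ids <- names(ne)
  hits <- setNames(numeric(length(ids)), ids)
  set.seed(as.integer(seed))
  for (r in seq_len(reps)) {
    noise <- if (perturbation > 0) {
      rlnorm(length(litcounts), meanlog = 0, sdlog = perturbation)
    } else rep(1, length(litcounts))
    lit_r <- litcounts * noise
    top <- top_contributors(
      suppressWarnings(contribution_index(ne, lit_r)), threshold)
    hits[top] <- hits[top] + 1
  }
  hits / reps
}
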