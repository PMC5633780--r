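# Seeded synthetic datasets with the statistical structure the pipeline
# assumes (two overlapping per-herb compound sets, OB/DL mixtures straddling
# the screening cut-offs, degree-heterogeneous C-T graphs with planted hubs,
# bounded pathway sizes, organ-specific expression, heavy-tailed literature
# counts) plus planted ground truth for end-to-end recovery tests.

#' Specification of a synthetic herb-pair dataset
#'
#' The defaults emulate the published Huangqi/Huanglian study conditions:
#' 112 + 64 compounds with 5 shared (171 distinct), about a quarter of
#' compounds passing both ADME thresholds, 50 targets, 30 pathways with 2-13
#' member targets, compound-target hubs up to degree 33, and heavy-tailed
#' (discretized lognormal) literature counts.  Five planted dominant
#' contributors jointly carry 87% of the literature-weighted efficacy mass,
#' mirroring a top-5 set that exceeds the 85% cumulative-CI rule.
#'
#' @param seed Integer seed; one seed drives deterministic per-component
#'   sub-streams, so e.g. adding organs does not perturb compound sampling.
#' @param n_herb_a,n_herb_b Compound counts per herb (each including the
#'   shared compounds); `n_shared` of them belong to both.
#' @param n_shared Number of compounds attributed to both herbs.
#' @param herbs The two herb labels.
#' @param pass_fraction Probability that a compound passes both thresholds.
#' @param rescue_fraction Fraction of threshold-failing compounds flagged as
#'   literature-rescued.
#' @param ob_min,dl_min The screening cut-offs the OB/DL mixtures straddle.
#' @param n_targets,n_pathways,n_organs Node counts of the three right-hand
#'   universes.
#' @param ct_max_degree Planted hub degree and cap of the compound-target
#'   degree law.
#' @param ct_exponent Power-law exponent of the compound degree distribution
#'   (larger = fewer hubs).
#' @param pathway_size_range Min/max targets per pathway.
#' @param organ_specific_fraction Fraction of targets given organ-specific
#'   overexpression.
#' @param organ_fold Expression fold of the organ-specific boosts.
#' @param expression_factor Multiple-of-median cut-off used to derive the
#'   target-organ edges from the expression matrix.
#' @param lit_meanlog,lit_sdlog Lognormal parameters of the literature
#'   counts.
#' @param n_planted Number of planted dominant contributors (0 disables
#'   planting).
#' @param planted_share Share of total literature-weighted efficacy mass
#'   carried jointly (and equally) by the planted set.
#' @return A `synthetic_spec` list, validated for internal consistency.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_herb_a = 112L, n_herb_b = 64L, n_shared = 5L,
                           herbs = c("Huangqi", "Huanglian"),
                           pass_fraction = 0.25, rescue_fraction = 0.17,
                           ob_min = 30, dl_min = 0.18,
                           n_targets = 50L, n_pathways = 30L,
                           n_organs = 30L,
                           ct_max_degree = 33L, ct_exponent = 1.6,
                           pathway_size_range = c(2L, 13L),
                           organ_specific_fraction = 0.3, organ_fold = 30,
                           expression_factor = 3,
                           lit_meanlog = 2, lit_sdlog = 1.5,
                           n_planted = 5L, planted_share = 0.87) {
  spec <- list(seed = as.integer(seed),
               n_herb_a = as.integer(n_herb_a),
               n_herb_b = as.integer(n_herb_b),
               n_shared = as.integer(n_shared), herbs = herbs,
               pass_fraction = pass_fraction,
               rescue_fraction = rescue_fraction,
               ob_min = ob_min, dl_min = dl_min,
               n_targets = as.integer(n_targets),
               n_pathways = as.integer(n_pathways),
               n_organs = as.integer(n_organs),
               ct_max_degree = as.integer(ct_max_degree),
               ct_exponent = ct_exponent,
               pathway_size_range = as.integer(pathway_size_range),
               organ_specific_fraction = organ_specific_fraction,
               organ_fold = organ_fold,
               expression_factor = expression_factor,
               lit_meanlog = lit_meanlog, lit_sdlog = lit_sdlog,
               n_planted = as.integer(n_planted),
               planted_share = planted_share)
  validate_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_spec <- function(spec) {
  with(spec, {
    if (n_shared > min(n_herb_a, n_herb_b)) {
      stop("n_shared exceeds a herb's compound count", call. = FALSE)
    }
    if (any(c(n_herb_a, n_herb_b, n_shared, n_targets, n_pathways,
              n_organs) < 0)) {
      stop("counts must be non-negative", call. = FALSE)
    }
    if (ct_max_degree > n_targets) {
      stop("hub degree cannot exceed the number of targets", call. = FALSE)
    }
    if (pathway_size_range[1L] < 1L || pathway_size_range[2L] > n_targets ||
        pathway_size_range[1L] > pathway_size_range[2L]) {
      stop("invalid pathway size range", call. = FALSE)
    }
    if (pass_fraction < 0 || pass_fraction > 1 ||
        rescue_fraction < 0 || rescue_fraction > 1) {
      stop("fractions must be in [0, 1]", call. = FALSE)
    }
    if (length(herbs) != 2L || anyDuplicated(herbs)) {
      stop("need two distinct herb labels", call. = FALSE)
    }
    if (planted_share <= 0 || planted_share >= 1) {
      stop("planted_share must be in (0, 1)", call. = FALSE)
    }
    if (seed > 2^31 - 1000) stop("seed too large", call. = FALSE)
  })
  invisible(spec)
}

# Fixed offsets give each generation component its own reproducible
# sub-stream of the master seed.
sub_seed <- function(spec, component) {
  offsets <- c(compounds = 101L, ct = 211L, tp = 307L, to = 401L,
               lit = 503L, plant = 601L)
  set.seed(spec$seed + offsets[[component]])
}

#' Generate a complete synthetic dataset with planted ground truth
#'
#' Deterministic given `spec$seed`.  The returned dataset passes full
#' [validate_dataset()] checks and round-trips through the JSON envelope;
#' the ground-truth record holds the generator's own bookkeeping (computed
#' with independent nested loops, not the package's analysis functions) for
#' use as an oracle: planted dominant contributors and their realized mass
#' share, per-ingredient network efficacy, shared targets, the expression
#' matrix and the planted organ-specific edges, and the pass/rescue/exclude
#' assignment.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `dataset` (a `herb_dataset`) and `truth`.
#' @examples
#' sim <- generate_dataset(synthetic_spec(seed = 1))
#' nrow(sim$dataset$ingredients)  # 171 distinct compounds
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  validate_spec(spec)

  ## --- compounds: herb attribution, OB/DL mixture, rescue flags ---------
  sub_seed(spec, "compounds")
  n_a_only <- spec$n_herb_a - spec$n_shared
  n_b_only <- spec$n_herb_b - spec$n_shared
  ids <- c(sprintf("A-%03d", seq_len(n_a_only)),
           sprintf("B-%03d", seq_len(n_b_only)),
           sprintf("S-%02d", seq_len(spec$n_shared)))
  herbs_list <- c(rep(list(spec$herbs[1L]), n_a_only),
                  rep(list(spec$herbs[2L]), n_b_only),
                  rep(list(sort(spec$herbs)), spec$n_shared))
  n <- length(ids)
  pass <- runif(n) < spec$pass_fraction
  # right-skewed OB/DL on the proper side of each cut-off
  ob_hi <- function(k) pmin(spec$ob_min + rgamma(k, shape = 1.5, scale = 15),
                            100)
  ob_lo <- function(k) spec$ob_min * rbeta(k, 1.2, 2.2)
  dl_hi <- function(k) pmin(spec$dl_min + rgamma(k, shape = 1.5,
                                                 scale = 0.18), 1)
  dl_lo <- function(k) spec$dl_min * rbeta(k, 1.2, 2.2)
  ob <- numeric(n); dl <- numeric(n)
  ob[pass] <- ob_hi(sum(pass)); dl[pass] <- dl_hi(sum(pass))
  nf <- sum(!pass)
  if (nf) {
    mode <- sample.int(3L, nf, replace = TRUE)  # 1 ob, 2 dl, 3 both fail
    ob[!pass] <- ifelse(mode != 2L, ob_lo(nf), ob_hi(nf))
    dl[!pass] <- ifelse(mode != 1L, dl_lo(nf), dl_hi(nf))
  }
  rescue <- !pass & runif(n) < spec$rescue_fraction
  ing <- data.frame(ingredient_id = ids,
                    name = paste("compound", ids), stringsAsFactors = FALSE)
  ing$herbs <- herbs_list
  ing$mw <- rlnorm(n, log(350), 0.35)
  ing$clogp <- rnorm(n, 2, 1.8)
  ing$nhdon <- as.numeric(rpois(n, 3))
  ing$nhacc <- as.numeric(rpois(n, 6))
  ing$ob <- ob
  ing$dl <- dl
  ing$rescue <- rescue

  targets <- data.frame(target_id = sprintf("T-%02d", seq_len(spec$n_targets)),
                        name = sprintf("synthetic target %02d",
                                       seq_len(spec$n_targets)),
                        uniprot_id = sprintf("P%05d", seq_len(spec$n_targets)),
                        gene = sprintf("GENE%02d", seq_len(spec$n_targets)),
                        stringsAsFactors = FALSE)
  pathways <- sprintf("pw-%02d", seq_len(spec$n_pathways))
  organs <- sprintf("organ-%02d", seq_len(spec$n_organs))

  active <- ids[pass | rescue]
  if (spec$n_planted > length(active)) {
    stop("fewer active compounds than planted contributors requested",
         call. = FALSE)
  }

  ## --- planted dominant contributors ------------------------------------
  sub_seed(spec, "plant")
  planted <- if (spec$n_planted > 0L) {
    sort(sample(active, spec$n_planted))
  } else character()

  ## --- compound-target edges: heterogeneous degrees, planted hubs -------
  sub_seed(spec, "ct")
  degs <- sample(seq_len(spec$ct_max_degree), length(active), replace = TRUE,
                 prob = seq_len(spec$ct_max_degree)^(-spec$ct_exponent))
  names(degs) <- active
  hub_ids <- if (length(planted)) planted else active[1L]
  degs[hub_ids] <- spec$ct_max_degree
  target_weight <- rlnorm(spec$n_targets, 0, 0.8)
  ct_left <- character(0); ct_right <- character(0)
  for (j in active) {
    tg <- sample(targets$target_id, degs[[j]], prob = target_weight)
    ct_left <- c(ct_left, rep(j, length(tg)))
    ct_right <- c(ct_right, tg)
  }
  ct <- edge_list(ct_left, ct_right, "compound-target",
                  sources = rep("synthetic", length(ct_left)))

  ## --- target-pathway edges ---------------------------------------------
  sub_seed(spec, "tp")
  sizes <- sample(seq(spec$pathway_size_range[1L],
                      spec$pathway_size_range[2L]),
                  spec$n_pathways, replace = TRUE)
  tp_left <- character(0); tp_right <- character(0)
  for (p in seq_len(spec$n_pathways)) {
    members <- sample(targets$target_id, sizes[p])
    tp_left <- c(tp_left, members)
    tp_right <- c(tp_right, rep(pathways[p], sizes[p]))
  }
  tp <- edge_list(tp_left, tp_right, "target-pathway",
                  sources = rep("synthetic", length(tp_left)))

  ## --- expression matrix and target-organ edges -------------------------
  sub_seed(spec, "to")
  expr <- matrix(rlnorm(spec$n_targets * spec$n_organs, log(10), 0.2),
                 nrow = spec$n_targets,
                 dimnames = list(targets$target_id, organs))
  n_specific <- round(spec$organ_specific_fraction * spec$n_targets)
  specific_targets <- sample(targets$target_id, n_specific)
  planted_to <- data.frame(left = character(), right = character(),
                           stringsAsFactors = FALSE)
  for (t in specific_targets) {
    k <- sample(1:2, 1L)
    os <- sample(organs, k)
    expr[t, os] <- expr[t, os] * spec$organ_fold
    planted_to <- rbind(planted_to,
                        data.frame(left = t, right = os,
                                   stringsAsFactors = FALSE))
  }
  to <- threshold_expression(expr, spec$expression_factor)

  ## --- literature counts, boosted on the planted set --------------------
  sub_seed(spec, "lit")
  lit <- setNames(as.integer(round(rlnorm(n, spec$lit_meanlog,
                                          spec$lit_sdlog))), ids)
  # generator-side NE bookkeeping by plain nested loops (kept independent
  # of the analysis code so it can serve as an oracle)
  tp_deg <- setNames(integer(spec$n_targets), targets$target_id)
  for (t in tp$left) tp_deg[t] <- tp_deg[t] + 1L
  ne <- setNames(integer(length(active)), active)
  for (j in active) {
    for (t in unique(ct$right[ct$left == j])) ne[j] <- ne[j] + tp_deg[[t]]
  }
  realized_share <- NA_real_
  if (length(planted)) {
    if (any(ne[planted] == 0L)) {
      stop("planted contributor has zero network efficacy; ",
           "increase pathway coverage", call. = FALSE)
    }
    rest <- setdiff(active, planted)
    rest_mass <- sum(as.numeric(lit[rest]) * ne[rest])
    if (rest_mass == 0) rest_mass <- 1
    per_member <- spec$planted_share * rest_mass /
      ((1 - spec$planted_share) * length(planted))
    lit[planted] <- as.integer(ceiling(per_member / ne[planted]))
    mass <- as.numeric(lit[active]) * ne[active]
    realized_share <- sum(mass[active %in% planted]) / sum(mass)
  }

  ## --- shared targets, generator-side loop ------------------------------
  herb_of <- setNames(ing$herbs, ing$ingredient_id)
  shared <- character(0)
  for (t in unique(ct$right)) {
    labs <- unique(unlist(herb_of[unique(ct$left[ct$right == t])]))
    if (all(spec$herbs %in% labs)) shared <- c(shared, t)
  }

  dataset <- herb_dataset(ingredients = ing, targets = targets,
                          pathways = pathways, organs = organs,
                          ct = ct, tp = tp, to = to, litcounts = lit,
                          herbs = spec$herbs)
  truth <- list(planted = planted, realized_share = realized_share,
                ne = ne, shared_targets = sort(shared),
                planted_to_edges = {
                  pe <- planted_to[order(planted_to$left, planted_to$right), ]
                  rownames(pe) <- NULL
                  pe
                },
                expression = expr,
                passed = ids[pass], rescued = ids[rescue],
                excluded = ids[!pass & !rescue],
                ct_degrees = degs)
  list(dataset = dataset, truth = truth)
}

#' Synthetic edge/literature complement for real ingredient and target tables
#'
#' Generates compound-target, target-pathway and target-organ edge lists
#' plus literature counts for caller-supplied ingredient and target tables
#' (e.g. the packaged transcribed tables, whose original edges came from
#' web servers and are not deposited).  Uses the same seeded machinery as
#' [generate_dataset()].
#'
#' @param ingredients,targets Tables as returned by [read_ingredients()] /
#'   [read_targets()].
#' @param seed Integer seed.
#' @param spec A [synthetic_spec()] supplying the structural knobs; node
#'   counts are taken from the supplied tables.
#' @return A `herb_dataset` combining the supplied tables with synthetic
#'   edges, organs, pathways and literature counts.
#' @export
generate_edge_complement <- function(ingredients, targets, seed = 1L,
                                     spec = synthetic_spec(seed = seed)) {
  spec$seed <- as.integer(seed)
  spec$n_targets <- nrow(targets)
  spec$ct_max_degree <- min(spec$ct_max_degree, nrow(targets))
  spec$pathway_size_range[2L] <- min(spec$pathway_size_range[2L],
                                     nrow(targets))
  labels <- sort(unique(unlist(ingredients$herbs)))
  if (length(labels) == 2L) spec$herbs <- labels
  validate_spec(spec)

  pathways <- sprintf("pw-%02d", seq_len(spec$n_pathways))
  organs <- sprintf("organ-%02d", seq_len(spec$n_organs))
  sr <- screen_ingredients(ingredients, spec$ob_min, spec$dl_min)
  active <- sort(c(sr$passed, sr$rescued))
  if (!length(active)) stop("no active ingredients to connect", call. = FALSE)

  sub_seed(spec, "ct")
  degs <- sample(seq_len(spec$ct_max_degree), length(active), replace = TRUE,
                 prob = seq_len(spec$ct_max_degree)^(-spec$ct_exponent))
  names(degs) <- active
  degs[active[1L]] <- spec$ct_max_degree
  target_weight <- rlnorm(nrow(targets), 0, 0.8)
  ct_left <- character(0); ct_right <- character(0)
  for (j in active) {
    tg <- sample(targets$target_id, degs[[j]], prob = target_weight)
    ct_left <- c(ct_left, rep(j, length(tg)))
    ct_right <- c(ct_right, tg)
  }
  ct <- edge_list(ct_left, ct_right, "compound-target",
                  sources = rep("synthetic", length(ct_left)))

  sub_seed(spec, "tp")
  sizes <- sample(seq(spec$pathway_size_range[1L],
                      spec$pathway_size_range[2L]),
                  spec$n_pathways, replace = TRUE)
  tp_left <- character(0); tp_right <- character(0)
  for (p in seq_len(spec$n_pathways)) {
    members <- sample(targets$target_id, sizes[p])
    tp_left <- c(tp_left, members)
    tp_right <- c(tp_right, rep(pathways[p], sizes[p]))
  }
  tp <- edge_list(tp_left, tp_right, "target-pathway",
                  sources = rep("synthetic", length(tp_left)))

  sub_seed(spec, "to")
  expr <- matrix(rlnorm(nrow(targets) * spec$n_organs, log(10), 0.2),
                 nrow = nrow(targets),
                 dimnames = list(targets$target_id, organs))
  n_specific <- round(spec$organ_specific_fraction * nrow(targets))
  for (t in sample(targets$target_id, n_specific)) {
    os <- sample(organs, sample(1:2, 1L))
    expr[t, os] <- expr[t, os] * spec$organ_fold
  }
  to <- threshold_expression(expr, spec$expression_factor)

  sub_seed(spec, "lit")
  lit <- setNames(as.integer(round(rlnorm(nrow(ingredients),
                                          spec$lit_meanlog,
                                          spec$lit_sdlog))),
                  ingredients$ingredient_id)

  herb_dataset(ingredients = ingredients, targets = targets,
               pathways = pathways, organs = organs,
               ct = ct, tp = tp, to = to, litcounts = lit,
               herbs = spec$herbs)
}

#' Packaged transcriptions of the published ingredient and target tables
#'
#' Returns the 43 active ingredients (ids, names, herb attribution, OB, DL,
#' rescue flags) and 50 disease-related targets (UniProt accessions and gene
#' symbols) of the Huangqi/Huanglian study, transcribed from the published
#' tables and shipped under `inst/extdata/`.  The four molecular descriptors
#' are not printed in those tables and are missing here.
#'
#' @return List with data frames `ingredients` (43 rows) and `targets`
#'   (50 rows).
#' @export
fixture_paper_tables <- function() {
  list(ingredients = read_ingredients(
         system.file("extdata", "huangqi_huanglian_ingredients.csv",
                     package = "herbnp")),
       targets = read_targets(
         system.file("extdata", "huangqi_huanglian_targets.csv",
                     package = "herbnp")))
}
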