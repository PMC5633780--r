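# End-to-end orchestration: screen -> networks -> NE/CI -> profiles, from a
# single serializable config, with a machine-readable report.

#' Assemble a pipeline configuration
#'
#' Exactly one of `input` (paths to ingredient/target/edge/literature
#' tables) or `simulate` (a [synthetic_spec()], or a list of its arguments)
#' must be given.
#'
#' @param input Named list of file paths: `ingredients`, `targets`, `ct`,
#'   `tp`, `to`, `litcounts`.  Alternatively pass a ready-made
#'   [herb_dataset()] as `dataset`.
#' @param simulate A [synthetic_spec()] or argument list for one.
#' @param dataset Optional in-memory `herb_dataset` (overrides both).
#' @param ob_min,dl_min ADME screening thresholds.
#' @param ci_threshold Cumulative-CI cut-off for the top set, percent.
#' @param outdir Output directory for the stage artifacts (created if
#'   needed); `NULL` suppresses file output.
#' @param seed Integer seed governing all randomness (simulation and
#'   sensitivity analysis).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, dataset = NULL,
                            ob_min = 30, dl_min = 0.18, ci_threshold = 85,
                            outdir = NULL, seed = 1L) {
  n_sources <- sum(!is.null(input), !is.null(simulate), !is.null(dataset))
  if (n_sources != 1L) {
    stop("provide exactly one of `input`, `simulate` or `dataset`",
         call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate, "synthetic_spec")) {
    simulate <- do.call(synthetic_spec, c(list(seed = seed), simulate))
  }
  structure(list(input = input, simulate = simulate, dataset = dataset,
                 ob_min = ob_min, dl_min = dl_min,
                 ci_threshold = ci_threshold, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full herb-pair analysis
#'
#' Executes the whole pipeline: load or simulate the dataset, ADME-screen
#' the ingredients, build the active-ingredient C-T network and the T-P /
#' T-O networks, compute network efficacies and contribution indices,
#' extract the cumulative top set, and profile shared targets and organ
#' distribution.  When `config$outdir` is set, each stage's artifact is
#' written there (`screen.json`, `ct.sif`/`ct.json`, `tp.json`, `to.json`,
#' `ci.json`, `organs.json`, `report.json`).  Deterministic given the
#' config seed.
#'
#' @param config A [pipeline_config()].
#' @return A `herbnp_report`: list with the dataset, screen result,
#'   networks, contribution result, top set, organ distribution, shared
#'   targets and a flat `counts` summary.
#' @examples
#' rep <- run_pipeline(pipeline_config(
#'   simulate = synthetic_spec(seed = 1, n_herb_a = 30, n_herb_b = 20,
#'                             n_shared = 2, n_targets = 20, n_pathways = 10,
#'                             ct_max_degree = 10, n_planted = 2)))
#' rep$counts$n_active
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  ds <- stage("load", {
    if (!is.null(config$dataset)) {
      validate_dataset(config$dataset)
      config$dataset
    } else if (!is.null(config$simulate)) {
      generate_dataset(config$simulate)$dataset
    } else {
      ing <- read_ingredients(config$input$ingredients)
      tg <- read_targets(config$input$targets)
      ct <- read_edges(config$input$ct, "compound-target",
                       left_universe = ing$ingredient_id,
                       right_universe = tg$target_id)
      tp <- read_edges(config$input$tp, "target-pathway",
                       left_universe = tg$target_id)
      to <- read_edges(config$input$to, "target-organ",
                       left_universe = tg$target_id)
      lit <- read_litcounts(config$input$litcounts)
      herb_dataset(ing, tg, pathways = sort(unique(tp$right)),
                   organs = sort(unique(to$right)), ct = ct, tp = tp,
                   to = to, litcounts = lit,
                   herbs = sort(unique(unlist(ing$herbs))))
    }
  })

  sr <- stage("screen", screen_ingredients(ds$ingredients, config$ob_min,
                                           config$dl_min))
  active <- sort(c(sr$passed, sr$rescued))

  nets <- stage("networks", {
    ct_edges <- ds$ct[ds$ct$left %in% active, , drop = FALSE]
    ct_el <- edge_list(ct_edges$left, ct_edges$right, "compound-target",
                       ct_edges$sources)
    list(ct = build_network(ct_el, left_universe = active,
                            right_universe = ds$targets$target_id),
         tp = build_network(ds$tp, left_universe = ds$targets$target_id,
                            right_universe = ds$pathways),
         to = build_network(ds$to, left_universe = ds$targets$target_id,
                            right_universe = ds$organs))
  })

  contrib <- stage("contribution", {
    ne <- network_efficacy_all(nets$ct, nets$tp)
    suppressWarnings(contribution_index(ne, ds$litcounts))
  })
  top <- top_contributors(contrib, config$ci_threshold)

  profiles <- stage("profile", {
    herb_of <- herb_attribution(ds$ingredients)
    shared <- if (length(ds$herbs) == 2L) {
      shared_targets(nets$ct, herb_of, herbs = ds$herbs)
    } else character()
    organs <- if (nrow(nets$to$edges)) {
      organ_distribution(nets$to, nrow(ds$targets))
    } else NULL
    list(shared_targets = shared, organ_distribution = organs)
  })

  per_herb <- vapply(ds$herbs, function(h) {
    sum(vapply(ds$ingredients$herbs[ds$ingredients$ingredient_id %in% active],
               function(hs) h %in% hs, logical(1L)))
  }, integer(1L))

  counts <- list(n_ingredients = nrow(ds$ingredients),
                 n_active = length(active),
                 n_passed = length(sr$passed),
                 n_rescued = length(sr$rescued),
                 n_excluded = length(sr$excluded),
                 n_active_per_herb = as.list(per_herb),
                 n_targets = nrow(ds$targets),
                 n_ct_edges = nrow(nets$ct$edges),
                 n_shared_targets = length(profiles$shared_targets),
                 n_top = length(top),
                 top_cumulative_ci = max(attr(top, "cumulative")))

  report <- structure(list(dataset = ds, screen = sr, networks = nets,
                           contribution = contrib, top_set = top,
                           shared_targets = profiles$shared_targets,
                           organ_distribution = profiles$organ_distribution,
                           counts = counts, config = config),
                      class = "herbnp_report")

  if (!is.null(config$outdir)) stage("write", write_report(report))
  report
}

write_report <- function(report) {
  outdir <- report$config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sr <- report$screen
  jsonlite::write_json(list(ob_min = sr$ob_min, dl_min = sr$dl_min,
                            passed = sr$passed, rescued = sr$rescued,
                            excluded = sr$excluded),
                       file.path(outdir, "screen.json"),
                       auto_unbox = TRUE, digits = NA)
  write.csv(sr$audit, file.path(outdir, "screen_audit.csv"),
            row.names = FALSE)
  for (k in c("ct", "tp", "to")) {
    write_network(report$networks[[k]], file.path(outdir, paste0(k, ".sif")),
                  "sif")
    write_network(report$networks[[k]], file.path(outdir, paste0(k, ".json")),
                  "json")
  }
  cr <- report$contribution
  jsonlite::write_json(
    list(ne = as.list(cr$ne), ci = as.list(cr$ci),
         ranking = cr$ranking, cumulative = as.list(cr$cumulative),
         top_set = as.character(report$top_set),
         threshold = report$config$ci_threshold),
    file.path(outdir, "ci.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(report$organ_distribution)) {
    jsonlite::write_json(report$organ_distribution,
                         file.path(outdir, "organs.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(report$counts, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.herbnp_report <- function(x, ...) {
  cat("Herb-pair network pharmacology report\n")
  cat(sprintf("  ingredients: %d (%d active: %d passed + %d rescued)\n",
              x$counts$n_ingredients, x$counts$n_active, x$counts$n_passed,
              x$counts$n_rescued))
  ph <- x$counts$n_active_per_herb
  cat(sprintf("  actives per herb: %s\n",
              paste(sprintf("%s %d", names(ph), unlist(ph)),
                    collapse = ", ")))
  cat(sprintf("  targets: %d (%d regulated by both herbs)\n",
              x$counts$n_targets, x$counts$n_shared_targets))
  cat(sprintf("  top %d contributor(s) reach %.2f%% cumulative CI: %s\n",
              x$counts$n_top, x$counts$top_cumulative_ci,
              paste(x$top_set, collapse = ", ")))
  invisible(x)
}
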