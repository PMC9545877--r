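#' Pipeline configuration
#'
#' Validated configuration for [run_full_pipeline()]. Unknown keys are
#' rejected; the full configuration is serialized into the run's provenance
#' record.
#'
#' @param input one of: `list(type = "fixture")` (the packaged network,
#'   estimation skipped), `list(type = "csv", responses = path,
#'   items = path)`, or `list(type = "simulate", n = ..., match_correlations
#'   = ...)` (the calibrated generator).
#' @param method correlation type for estimation.
#' @param n_lambda,lambda_min_ratio path grid controls.
#' @param seed root seed for every stochastic stage.
#' @param bootstrap list: `enabled`, `B`.
#' @param case_dropping list: `enabled`, `B`, `drop_grid`.
#' @param clique list: `k`, `I` for a fixed solution, or `search = TRUE`
#'   with `k_range`, `I_range`, `step`, `n_permutations`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = list(type = "simulate", n = 1041),
                            method = "pearson",
                            n_lambda = 100, lambda_min_ratio = 0.01,
                            seed = 1L,
                            bootstrap = list(enabled = FALSE, B = 1000),
                            case_dropping = list(enabled = FALSE, B = 1000,
                                                 drop_grid = seq(0.05, 0.75,
                                                                 by = 0.05)),
                            clique = list(k = 3, I = 0.225, search = FALSE)) {
  cfg <- list(input = input, method = method, n_lambda = n_lambda,
              lambda_min_ratio = lambda_min_ratio, seed = as.integer(seed),
              bootstrap = bootstrap, case_dropping = case_dropping,
              clique = clique)
  known_input <- c("type", "responses", "items", "n", "match_correlations")
  if (!is.list(cfg$input) || is.null(cfg$input$type) ||
      !cfg$input$type %in% c("fixture", "csv", "simulate"))
    stop("input$type must be one of fixture/csv/simulate", call. = FALSE)
  unknown <- setdiff(names(cfg$input), known_input)
  if (length(unknown))
    stop("unknown input keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  stopifnot(method %in% c("pearson", "spearman", "polychoric"))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with the [pipeline_config()] fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load/simulate responses, scale scores, network
#' estimation (skipped for the fixture input), centrality, bridge expected
#' influence, clique percolation, and (when enabled) the bootstrap stability
#' analyses. All module outputs are written to `out_dir` as CSV/JSON/GraphML
#' plus a deterministic provenance record; wall-clock timings go to
#' `run.log`. With the same configuration and seed the CSV/JSON outputs are
#' byte-identical across runs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list of in-memory results; `out_dir` is populated.
#' @export
run_full_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "run.log")
  cat("", file = logf)
  t_all <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    cat(sprintf("%-14s %8.2fs\n", name, proc.time()[3] - t0),
        file = logf, append = TRUE)
    res
  }
  results <- list()

  loaded <- stage("input", {
    inp <- config$input
    if (inp$type == "fixture") {
      list(net = lad_network(), data = NULL)
    } else {
      data <- if (inp$type == "csv") {
        items <- if (!is.null(inp$items)) read_item_metadata(inp$items)
                 else default_items()
        read_response_table(inp$responses, items)
      } else {
        spec <- lad_generator_spec(
          n = inp$n %||% 1041L, seed = config$seed,
          match_correlations = inp$match_correlations %||% TRUE)
        generate_responses(spec)
      }
      write_response_table(data, file.path(out_dir, "responses.csv"))
      list(net = NULL, data = data)
    }
  })
  data <- loaded$data
  net <- loaded$net

  if (!is.null(data)) {
    results$scores <- stage("scale_scores", compute_scale_scores(data))
    utils::write.csv(results$scores$summary,
                     file.path(out_dir, "scale_scores.csv"),
                     row.names = FALSE)
    net <- stage("estimate", estimate_network(
      data, method = config$method, n_lambda = config$n_lambda,
      lambda_min_ratio = config$lambda_min_ratio))
    write_fit_report(net, file.path(out_dir, "fit_report.json"))
  }
  results$network <- net
  write_weights_matrix(net, file.path(out_dir, "network.csv"))
  write_graphml(net, file.path(out_dir, "network.graphml"))

  results$centrality <- stage("centrality", centrality_table(net))
  utils::write.csv(results$centrality, file.path(out_dir, "centrality.csv"),
                   row.names = FALSE)

  results$bridge <- stage("bridge", bridge_expected_influence(net))
  utils::write.csv(as.data.frame(results$bridge),
                   file.path(out_dir, "bridge.csv"), row.names = FALSE)

  results$cliques <- stage("cliques", {
    cc <- config$clique
    if (isTRUE(cc$search)) {
      sr <- cpm_parameter_search(
        net, k_range = cc$k_range %||% 3:6,
        I_range = cc$I_range %||% c(0.40, 0.01),
        step = cc$step %||% 0.005,
        n_permutations = cc$n_permutations %||% 100,
        seed = child_seed(config$seed, "cpm-search"))
      utils::write.csv(sr$grid, file.path(out_dir, "clique_grid.csv"),
                       row.names = FALSE)
      sr$solution
    } else {
      percolate(net, cc$k %||% 3, cc$I %||% 0.225)
    }
  })
  write_clique_solution(results$cliques, file.path(out_dir, "cliques.json"))

  if (!is.null(data) && isTRUE(config$bootstrap$enabled)) {
    results$edge_stability <- stage("edge_boot", bootstrap_edges(
      data, B = config$bootstrap$B %||% 1000,
      seed = child_seed(config$seed, "edge-boot"), method = config$method))
    utils::write.csv(results$edge_stability$edge_ci,
                     file.path(out_dir, "edge_ci.csv"), row.names = FALSE)
  }
  if (!is.null(data) && isTRUE(config$case_dropping$enabled)) {
    results$cs <- stage("case_drop", case_dropping(
      data, B = config$case_dropping$B %||% 1000,
      drop_grid = config$case_dropping$drop_grid %||%
        seq(0.05, 0.75, by = 0.05),
      seed = child_seed(config$seed, "case-drop"), method = config$method))
    jsonlite::write_json(list(
      cs_coefficients = as.list(results$cs$cs_coefficients),
      cs_curve = results$cs$cs_curve),
      file.path(out_dir, "cs.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns")
  }

  prov <- list(package = "symptomnet",
               version = as.character(utils::packageVersion("symptomnet")),
               config = unclass(config))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cat(sprintf("%-14s %8.2fs\n", "total", proc.time()[3] - t_all),
      file = logf, append = TRUE)
  invisible(results)
}
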