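#' Configuration for an end-to-end analysis run
#'
#' @param filter A [filter_config()].
#' @param thresholds An [int_thresholds()].
#' @param stages Character vector of analysis stages to run, a subset of
#'   `c("qc", "morphometry", "connectivity", "selectivity",
#'   "reciprocity")`.
#' @param seed Master seed for the permutation null.
#' @param n_iterations,n_bins,selectivity_threshold,weight Parameters of
#'   the selectivity null (see [shuffle_null()]).
#' @param reciprocity_pairs List of 2-vectors of type labels; pairings
#'   absent from the dataset are skipped. Defaults to the three classical
#'   pairings STN-GPi, STN-GPe and MSN-TAN.
#' @return A list of class `run_config`.
#' @export
run_config <- function(filter = filter_config(),
                       thresholds = int_thresholds(),
                       stages = c("qc", "morphometry", "connectivity",
                                  "selectivity", "reciprocity"),
                       seed = 0,
                       n_iterations = 100, n_bins = 30,
                       selectivity_threshold = 0.9,
                       weight = c("area", "count"),
                       reciprocity_pairs = list(c("STN", "GPi"),
                                                c("STN", "GPe"),
                                                c("MSN", "TAN"))) {
  weight <- match.arg(weight)
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(filter = filter, thresholds = thresholds, stages = stages,
                 seed = seed, n_iterations = n_iterations, n_bins = n_bins,
                 selectivity_threshold = selectivity_threshold,
                 weight = weight, reciprocity_pairs = reciprocity_pairs),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in fixed order on a connectome (or
#' generates one first from a [generator_config()]): synapse and
#' completeness QC, morphometry with interneuron classification,
#' connectivity matrices under all three normalisations, the pallidal
#' selectivity permutation null, and reciprocity statistics for the
#' configured type pairings. The run configuration and seed are embedded
#' verbatim in the report, making every number reproducible from the
#' report plus the input data.
#'
#' @param x A [connectome()] or a [generator_config()].
#' @param config A [run_config()].
#' @return A list of class `bg_report` with one element per executed
#'   stage plus `config`; a failing stage is recorded under `$errors`
#'   without discarding completed stages.
#' @export
run_all <- function(x, config = run_config()) {
  if (inherits(x, "generator_config")) {
    x <- generate_connectome(x)$dataset
  }
  stopifnot(inherits(x, "connectome"))
  report <- list(config = config, errors = list())
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return()
    res <- tryCatch(fun(), error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) report[[name]] <<- res
  }

  syn_f <- NULL
  run_stage("qc", function() {
    syn <- filter_synapses(x$synapses, config$filter)
    cc <- filter_complete_cells(x, config = config$filter)
    fr <- filter_projecting_fragments(x, config = config$filter)
    nb <- dendrite_near_boundary(x)
    syn_f <<- syn
    list(synapse_audit = qc_audit(syn),
         complete_cells = cc, complete_cell_audit = qc_audit(cc),
         fragments = fr, fragment_audit = qc_audit(fr),
         near_boundary = nb)
  })
  if (is.null(syn_f)) syn_f <- filter_synapses(x$synapses, config$filter)
  prs <- pair_connections(syn_f)

  run_stage("morphometry", function() {
    feats <- morphometry_features(x)
    list(features = feats,
         int_classes = classify_int(feats, config$thresholds)[
           , c("cell_id", "type", "int_class")])
  })
  run_stage("connectivity", function() {
    list(global = type_matrix(prs, x, "global"),
         output_rows = type_matrix(prs, x, "output_rows"),
         input_columns = type_matrix(prs, x, "input_columns"),
         io_fractions = io_fractions(prs, x))
  })
  run_stage("selectivity", function() {
    gp <- msn_gp_synapses(syn_f, x)
    list(null = shuffle_null(gp, n_iterations = config$n_iterations,
                             n_bins = config$n_bins,
                             threshold = config$selectivity_threshold,
                             weight = config$weight, seed = config$seed),
         ratios = gp_ratio(gp, weight = config$weight))
  })
  run_stage("reciprocity", function() {
    present <- unique(x$cells$type)
    res <- list()
    for (p in config$reciprocity_pairs) {
      if (all(p %in% present)) {
        res[[paste(p, collapse = "-")]] <-
          reciprocity_stats(prs, x, p[1], p[2])
      }
    }
    res
  })
  structure(report, class = "bg_report")
}

#' @export
print.bg_report <- function(x, ...) {
  stages <- setdiff(names(x), c("config", "errors"))
  cat("<bg_report> stages:", paste(stages, collapse = ", "), "\n")
  if (length(x$errors)) {
    cat("  failed:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a machine-readable report
#'
#' Serialises the summary-level content of a [run_all()] report (audits,
#' matrices, null summaries, reciprocity summaries, and the full
#' configuration) as JSON.
#'
#' @param report A `bg_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    config = report$config[c("seed", "n_iterations", "n_bins",
                             "selectivity_threshold", "weight", "stages")],
    filter = unclass(report$config$filter))
  if (!is.null(report$qc)) {
    out$qc <- list(synapse_audit = report$qc$synapse_audit,
                   complete_cell_audit = report$qc$complete_cell_audit,
                   fragment_audit = report$qc$fragment_audit)
  }
  if (!is.null(report$morphometry)) {
    out$morphometry <- list(
      int_class_counts = as.list(table(report$morphometry$int_classes$
                                         int_class)))
  }
  if (!is.null(report$connectivity)) {
    out$connectivity <- list(
      types = report$connectivity$global$types,
      global = report$connectivity$global$area,
      output_rows = report$connectivity$output_rows$area,
      input_columns = report$connectivity$input_columns$area)
  }
  if (!is.null(report$selectivity)) {
    out$selectivity <- as.list(selectivity_excess(report$selectivity$null))
    out$selectivity$pooled_modal_bin_center <-
      modal_bin_center(colSums(report$selectivity$null$iteration_hists))
  }
  if (!is.null(report$reciprocity)) {
    out$reciprocity <- lapply(report$reciprocity, function(r) r$summary)
  }
  if (length(report$errors)) out$errors <- report$errors
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Generate and analyse a small demonstration connectome
#'
#' Convenience wrapper: generates a down-scaled synthetic Area X-like
#' connectome and runs every analysis stage on it.
#'
#' @param seed Seed for both generation and the permutation null.
#' @return A list with `dataset`, `ground_truth` and `report`.
#' @export
bg_demo <- function(seed = 1) {
  g <- generate_connectome(generator_config(
    seed = seed,
    n_per_type = c(MSN = 300, GPe = 10, GPi = 15, STN = 20, TAN = 4,
                   LTS = 6, INT1 = 12, INT2 = 12, INT3 = 12,
                   HVC_axon = 60, LMAN_axon = 20, DA_axon = 20)))
  rep <- run_all(g$dataset, run_config(seed = seed))
  list(dataset = g$dataset, ground_truth = g$ground_truth, report = rep)
}
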