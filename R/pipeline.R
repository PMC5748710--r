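#' Configuration of a full association study
#'
#' Collects every input path and tuning parameter of one pipeline run. The
#' defaults mirror a genome-scale STRING study: 1000 permutation sets and
#' score bounds 150-999.
#'
#' @param network path to a protein.links network file
#' @param query_set path to the query gene-set file (one ID per line)
#' @param classes path to the two-column class-catalog TSV
#' @param id_map optional path to a raw-to-network ID-mapping TSV
#' @param n_permutations number of random sets (default 1000)
#' @param seed integer RNG seed for the random-set draw
#' @param min_score,max_score accepted score range of the network file
#' @param thresholds optional explicit PT-curve threshold grid (default: the
#'   permutation grid)
#' @param out_dir optional output directory; when set, [run_study()] writes
#'   all result tables there
#' @param report_cutoff p-value cutoff of the significant-gene report table
#'   (presentation only; never used inside scoring)
#' @return object of class `run_config`
#' @export
run_config <- function(network, query_set, classes, id_map = NULL,
                       n_permutations = 1000L, seed = 1L,
                       min_score = 150L, max_score = 999L,
                       thresholds = NULL, out_dir = NULL,
                       report_cutoff = 0.05) {
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  structure(list(network = network, query_set = query_set, classes = classes,
                 id_map = id_map,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), min_score = as.integer(min_score),
                 max_score = as.integer(max_score), thresholds = thresholds,
                 out_dir = out_dir, report_cutoff = report_cutoff),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys are the arguments of [run_config()]; relative paths are
#' resolved against the config file's directory. `overrides` (a named list,
#' e.g. from command-line flags) take precedence over file values.
#'
#' @param path YAML file
#' @param overrides named list of [run_config()] arguments
#' @return a [run_config()]
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  keep <- intersect(names(cfg), names(formals(run_config)))
  cfg <- cfg[keep]
  for (k in names(overrides)) if (!is.null(overrides[[k]])) cfg[[k]] <- overrides[[k]]
  base <- dirname(normalizePath(path))
  for (k in c("network", "query_set", "classes", "id_map", "out_dir")) {
    if (!is.null(cfg[[k]]) && !grepl("^(/|[A-Za-z]:)", cfg[[k]])) {
      cfg[[k]] <- file.path(base, cfg[[k]])
    }
  }
  do.call(run_config, cfg)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Score and rank all classes of a study held in memory
#'
#' The computational core of [run_study()], usable directly on in-memory
#' objects (e.g. a [generate_study()] result): maps and filters the query
#' set and every class onto the network, draws one shared random-set
#' collection whose set size equals the filtered query size, scores every
#' class gene (MIS and permutation p-value), and ranks the classes by exact
#' PT-curve AUC. Classes with no gene on the network are skipped with a
#' warning.
#'
#' @param network a [ppi_network()]
#' @param query_set the query [gene_set()]
#' @param catalog a [class_catalog()]
#' @param n_permutations number of random sets
#' @param seed integer RNG seed of the random-set draw
#' @param mapping optional raw-to-network ID map (see [read_id_map()])
#' @param thresholds optional explicit PT-curve grid
#' @return list with `results` (ranked list of [class_association()]s),
#'   `skipped` (names of empty classes), `query` (the [map_and_filter()]
#'   result for the query set), `dropped` (per-class dropped IDs), and
#'   `random_sets`
#' @export
associate_classes <- function(network, query_set, catalog,
                              n_permutations = 1000L, seed = 1L,
                              mapping = NULL, thresholds = NULL) {
  qf <- map_and_filter(query_set, network, mapping)
  if (!length(qf$set$members)) {
    stop("no query gene maps onto the network")
  }
  random_sets <- sample_random_sets(network,
                                    set_size = length(qf$set$members),
                                    n_sets = n_permutations, seed = seed)
  results <- list()
  skipped <- character()
  dropped <- list()
  for (s in catalog$classes) {
    cf <- map_and_filter(s, network, mapping)
    dropped[[s$name]] <- cf$dropped
    if (!length(cf$set$members)) {
      warning("class '", s$name, "' has no genes on the network; skipped")
      skipped <- c(skipped, s$name)
      next
    }
    rec <- score_disease_class(cf$set, qf$set, random_sets, network)
    res <- class_association(s$name, rec, n_perm = n_permutations,
                             n_genes_input = length(s$members))
    if (!is.null(thresholds)) {
      res$curve <- pt_curve(rec$p_value, thresholds = thresholds)
    }
    results[[s$name]] <- res
  }
  if (!length(results)) stop("every class is empty after filtering")
  list(results = rank_classes(results), skipped = skipped, query = qf,
       dropped = dropped, random_sets = random_sets)
}

#' Run the full association study
#'
#' Executes the whole pipeline: read the network, query set, class catalog
#' and optional ID map; map and filter the query set and every class onto
#' the network; draw one shared random-set collection (size = filtered query
#' size); score every gene of every class (MIS + permutation p-value); build
#' per-class PT curves and exact AUCs; rank classes by AUC. If
#' `config$out_dir` is set, writes `gene_results.tsv`,
#' `significant_genes.tsv` (p-value below `report_cutoff`),
#' `class_summary.tsv`, `pt_curves.tsv` and `run_metadata.json`.
#'
#' Classes left empty after network filtering are excluded from scoring and
#' ranking (with a warning) but still appear in the summary table with `NA`
#' AUC and rank.
#'
#' @param config a [run_config()]
#' @return object of class `study_result`: list with `results` (ranked list
#'   of [class_association()] objects), `summary` (data.frame), `gene_table`
#'   (per-gene data.frame with a `class` column), `curves` (long-format
#'   data.frame), `meta` (run metadata list)
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "run_config"))
  network <- with_stage("read_network",
    read_string_links(config$network, config$min_score, config$max_score))
  query_raw <- with_stage("read_query_set",
    read_gene_set(config$query_set, name = "query"))
  catalog <- with_stage("read_class_catalog",
    read_class_catalog(config$classes))
  mapping <- if (!is.null(config$id_map)) {
    with_stage("read_id_map", read_id_map(config$id_map))
  } else NULL

  assoc <- with_stage("associate_classes",
    associate_classes(network, query_raw, catalog,
                      n_permutations = config$n_permutations,
                      seed = config$seed, mapping = mapping,
                      thresholds = config$thresholds))
  results <- assoc$results
  skipped <- assoc$skipped
  qf <- assoc$query

  summary <- class_summary(results)
  if (length(skipped)) {
    summary <- rbind(summary, data.frame(
      class_name = skipped,
      n_genes_input = vapply(skipped, function(nm)
        length(catalog$classes[[nm]]$members), integer(1L)),
      n_genes_in_network = 0L, auc = NA_real_, rank = NA_integer_,
      stringsAsFactors = FALSE))
  }
  gene_table <- do.call(rbind, lapply(results, function(r) {
    cbind(r$records[, "gene", drop = FALSE], class = r$class_name,
          r$records[, c("mis", "lambda", "p_value")])
  }))
  rownames(gene_table) <- NULL
  curves <- do.call(rbind, lapply(results, function(r) {
    data.frame(class = r$class_name, threshold = r$curve$thresholds,
               proportion = r$curve$proportions, stringsAsFactors = FALSE)
  }))
  rownames(curves) <- NULL

  meta <- list(
    seed = config$seed, n_permutations = config$n_permutations,
    score_bounds = c(config$min_score, config$max_score),
    n_network_nodes = length(network$nodes),
    n_network_edges = nrow(network$edges),
    query_size_input = length(query_raw$members),
    query_size_in_network = length(qf$set$members),
    query_dropped = qf$dropped,
    class_dropped = assoc$dropped,
    skipped_classes = skipped,
    report_cutoff = config$report_cutoff,
    package_version = as.character(utils::packageVersion("misrank")))

  out <- structure(list(results = results, summary = summary,
                        gene_table = gene_table, curves = curves,
                        meta = meta),
                   class = "study_result")
  if (!is.null(config$out_dir)) {
    with_stage("write_outputs",
               write_study_results(out, config$out_dir,
                                   report_cutoff = config$report_cutoff))
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("Association study: %d classes, %d scored genes, %d permutations (seed %d)\n",
              nrow(x$summary), nrow(x$gene_table), x$meta$n_permutations,
              x$meta$seed))
  top <- x$summary[!is.na(x$summary$rank), ]
  top <- top[order(top$rank), ][seq_len(min(5L, nrow(top))), ]
  cat("Top classes by AUC:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %2d. %-24s AUC %.4f (%d genes)\n", top$rank[i],
                top$class_name[i], top$auc[i], top$n_genes_in_network[i]))
  }
  invisible(x)
}

#' Write all result tables of a study
#'
#' @param result a [run_study()] result
#' @param dir output directory (created if missing)
#' @param report_cutoff p-value cutoff of the significant-gene table
#' @return named vector of written paths, invisibly
#' @export
write_study_results <- function(result, dir, report_cutoff = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genes = file.path(dir, "gene_results.tsv"),
             significant = file.path(dir, "significant_genes.tsv"),
             summary = file.path(dir, "class_summary.tsv"),
             curves = file.path(dir, "pt_curves.tsv"),
             meta = file.path(dir, "run_metadata.json"))
  data.table::fwrite(result$gene_table, paths[["genes"]], sep = "\t",
                     na = "NA")
  sig <- result$gene_table[result$gene_table$p_value < report_cutoff, ]
  data.table::fwrite(sig, paths[["significant"]], sep = "\t", na = "NA")
  data.table::fwrite(result$summary, paths[["summary"]], sep = "\t",
                     na = "NA")
  data.table::fwrite(result$curves, paths[["curves"]], sep = "\t", na = "NA")
  jsonlite::write_json(result$meta, paths[["meta"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
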