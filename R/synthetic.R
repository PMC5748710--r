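#' Integer score samplers for synthetic networks
#'
#' Returns a sampler `function(n)` drawing `n` integer edge scores in
#' `[low, high]`. `"uniform"` draws uniformly (few ties: the cleanest setting
#' for calibrating the strict-exceedance permutation p-value). `"skewed"`
#' weights low scores geometrically (rate chosen so the density drops by ~e
#' every 170 score units), mimicking the low-confidence-heavy score
#' distribution of STRING-style networks and stressing tie handling.
#'
#' @param type `"uniform"` or `"skewed"`
#' @param low,high inclusive integer score bounds
#' @return function of one argument `n`, with attributes `low`/`high`
#' @export
score_sampler <- function(type = c("uniform", "skewed"), low = 150L,
                          high = 999L) {
  type <- match.arg(type)
  low <- as.integer(low); high <- as.integer(high)
  if (low > high) stop("low must be <= high")
  # sample.int keeps a degenerate low == high range literal
  f <- if (type == "uniform") {
    function(n) low - 1L + sample.int(high - low + 1L, n, replace = TRUE)
  } else {
    w <- exp(-(0:(high - low)) / 170)
    function(n) low - 1L + sample.int(high - low + 1L, n, replace = TRUE,
                                      prob = w)
  }
  structure(f, low = low, high = high, type = type)
}

#' Generate an Erdős–Rényi background PPI network
#'
#' Each of the `choose(n_proteins, 2)` node pairs receives an edge
#' independently with probability `edge_probability`; every present edge
#' gets an integer score from `sampler`. Node IDs are `P00001, P00002, ...`.
#' Fully reproducible from `seed`.
#'
#' @param n_proteins number of nodes (>= 2)
#' @param edge_probability edge presence probability in (0, 1)
#' @param sampler a [score_sampler()] (default: uniform on 150-999)
#' @param seed integer RNG seed
#' @return a [ppi_network()] whose score bounds are the sampler's
#' @export
generate_background_network <- function(n_proteins, edge_probability,
                                        sampler = score_sampler(), seed = 1L) {
  if (n_proteins < 2L) stop("n_proteins must be >= 2")
  if (!(edge_probability > 0 && edge_probability < 1)) {
    stop("edge_probability must lie in (0, 1)")
  }
  set.seed(seed)
  g <- igraph::sample_gnp(n_proteins, edge_probability)
  ends <- igraph::as_edgelist(g, names = FALSE)
  if (!nrow(ends)) stop("generated network has no edges; raise edge_probability")
  ids <- sprintf("P%05d", seq_len(n_proteins))
  net <- ppi_network(
    data.frame(p1 = ids[ends[, 1L]], p2 = ids[ends[, 2L]],
               score = sampler(nrow(ends))),
    min_score = attr(sampler, "low"), max_score = attr(sampler, "high"))
  # isolated vertices are legitimate nodes of the universe
  net$nodes <- sort(unique(c(net$nodes, ids)))
  net$.cache <- new.env(parent = emptyenv())
  net
}

#' Plant a class-to-query association signal into a network
#'
#' For each class gene independently, with probability `strength`, adds one
#' edge from that gene to a uniformly chosen query member with a uniform
#' integer score in `[score_low, score_high]`. A planted edge overwrites any
#' existing score on that pair; all other edges are untouched. `strength`
#' is the ground-truth association level recovered by the pipeline.
#'
#' @param network a [ppi_network()]
#' @param class_genes [gene_set()] of class members (network nodes)
#' @param query_set [gene_set()] of query members (network nodes, non-empty)
#' @param strength planting probability in `[0, 1]`
#' @param score_low,score_high inclusive planted-score range; the default
#'   band 950-999 matches the MIS range typical of strongly associated genes
#'   on STRING-scored networks
#' @param seed integer RNG seed
#' @return a new [ppi_network()] with the planted edges
#' @export
plant_class_association <- function(network, class_genes, query_set,
                                    strength, score_low = 950L,
                                    score_high = 999L, seed = 1L) {
  if (!length(query_set$members)) stop("query set is empty")
  if (strength < 0 || strength > 1) stop("strength must lie in [0, 1]")
  if (!all(class_genes$members %in% network$nodes) ||
      !all(query_set$members %in% network$nodes)) {
    stop("class and query genes must all be network nodes")
  }
  set.seed(seed)
  planted <- class_genes$members[stats::runif(length(class_genes$members)) <
                                   strength]
  if (!length(planted)) return(network)
  partner <- sample(query_set$members, length(planted), replace = TRUE)
  # a planted gene can be its own query partner only if sets overlap; re-draw
  clash <- planted == partner
  while (any(clash)) {
    if (length(query_set$members) == 1L) stop("cannot plant a self-edge")
    partner[clash] <- sample(query_set$members, sum(clash), replace = TRUE)
    clash <- planted == partner
  }
  score <- score_low - 1L +
    sample.int(score_high - score_low + 1L, length(planted), replace = TRUE)

  e <- data.table::copy(network$edges)
  add <- data.table::data.table(protein1 = pmin(planted, partner),
                                protein2 = pmax(planted, partner),
                                score = as.integer(score))
  add <- add[!duplicated(add, by = c("protein1", "protein2"))]
  e <- e[!add, on = c("protein1", "protein2")]   # overwrite, not max
  out <- ppi_network(rbind(e, add), min_score = network$score_bounds[1L],
                     max_score = max(network$score_bounds[2L], score_high))
  out$nodes <- network$nodes
  out$.cache <- new.env(parent = emptyenv())
  out
}

#' Specification of a synthetic association study
#'
#' @param n_proteins network size
#' @param edge_probability background edge probability; the default 0.1
#'   gives a mean degree of ~20 on the default 200-node network, preserving
#'   the well-connected character of genome-scale PPI networks at desk scale
#' @param query_size query-set size (default 20, i.e. 10% of the default
#'   universe)
#' @param classes data.frame with columns `name`, `n_genes`, `strength`, and
#'   optionally `score_low`, `score_high` (defaults 950/999)
#' @param sampler_type `"uniform"` or `"skewed"` background score sampler
#' @param score_low,score_high background score bounds
#' @param disjoint if `TRUE` (default) query and class gene blocks are
#'   pairwise disjoint, which requires
#'   `query_size + sum(n_genes) <= n_proteins`; if `FALSE`, class genes are
#'   drawn uniformly from the non-query nodes and may overlap across classes
#' @param seed integer RNG seed
#' @return object of class `synthetic_study_spec`
#' @export
synthetic_study_spec <- function(n_proteins = 200L, edge_probability = 0.1,
                                 query_size = 20L, classes,
                                 sampler_type = "uniform",
                                 score_low = 150L, score_high = 999L,
                                 disjoint = TRUE, seed = 1L) {
  classes <- as.data.frame(classes)
  stopifnot(all(c("name", "n_genes", "strength") %in% names(classes)))
  if (is.null(classes$score_low)) classes$score_low <- 950L
  if (is.null(classes$score_high)) classes$score_high <- 999L
  if (anyDuplicated(classes$name)) stop("class names must be unique")
  if (any(classes$strength < 0 | classes$strength > 1)) {
    stop("planting strengths must lie in [0, 1]")
  }
  if (any(classes$score_low < score_low | classes$score_high > score_high)) {
    stop("planted score range must lie within the global score bounds")
  }
  if (disjoint && query_size + sum(classes$n_genes) > n_proteins) {
    stop("disjoint layout infeasible: query_size + sum(n_genes) > n_proteins")
  }
  if (query_size + max(classes$n_genes) > n_proteins) {
    stop("a class plus the query set exceeds the universe")
  }
  structure(list(n_proteins = as.integer(n_proteins),
                 edge_probability = edge_probability,
                 query_size = as.integer(query_size), classes = classes,
                 sampler_type = sampler_type,
                 score_low = as.integer(score_low),
                 score_high = as.integer(score_high),
                 disjoint = isTRUE(disjoint), seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Generate a complete synthetic study
#'
#' Builds the background network, assigns query and class genes (disjoint
#' blocks by default), plants each class's association signal at its
#' configured strength, and returns the study together with its ground
#' truth. All randomness derives from `spec$seed`.
#'
#' @param spec a [synthetic_study_spec()]
#' @return object of class `synthetic_study`: list with `network`
#'   ([ppi_network()]), `query_set` ([gene_set()]), `catalog`
#'   ([class_catalog()]), `truth` (named numeric vector of planting
#'   strengths), and `spec`
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "synthetic_study_spec"))
  sampler <- score_sampler(spec$sampler_type, spec$score_low, spec$score_high)
  net <- generate_background_network(spec$n_proteins, spec$edge_probability,
                                     sampler, seed = spec$seed)
  set.seed(spec$seed + 1L)
  nodes <- sample(net$nodes)          # random block layout
  query <- gene_set(nodes[seq_len(spec$query_size)], name = "query")
  pool <- nodes[-seq_len(spec$query_size)]

  cls <- spec$classes
  sets <- vector("list", nrow(cls))
  offset <- 0L
  for (i in seq_len(nrow(cls))) {
    k <- cls$n_genes[i]
    members <- if (spec$disjoint) {
      m <- pool[offset + seq_len(k)]
      offset <- offset + k
      m
    } else sample(pool, k)
    sets[[i]] <- gene_set(members, name = cls$name[i])
  }
  catalog <- class_catalog(sets, provenance = "synthetic")

  for (i in seq_len(nrow(cls))) {
    if (cls$strength[i] > 0) {
      net <- plant_class_association(net, sets[[i]], query,
                                     strength = cls$strength[i],
                                     score_low = cls$score_low[i],
                                     score_high = cls$score_high[i],
                                     seed = spec$seed + 1L + i)
    }
  }
  structure(list(network = net, query_set = query, catalog = catalog,
                 truth = stats::setNames(cls$strength, cls$name),
                 spec = spec),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", length(x$network$nodes), "nodes,",
      nrow(x$network$edges), "edges;", length(x$query_set$members),
      "query genes;", length(x$catalog$classes), "classes\n")
  invisible(x)
}

#' Write a synthetic study to disk in the pipeline's input dialects
#'
#' Emits `network.links.txt` (STRING protein.links dialect),
#' `query_genes.txt` (one ID per line), `class_catalog.tsv` (two-column TSV)
#' and `truth.json` (class -> planting strength), all directly consumable by
#' the readers in this package and by the command-line driver.
#'
#' @param study a [generate_study()] result
#' @param dir output directory (created if missing)
#' @return named character vector of the four paths, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(network = file.path(dir, "network.links.txt"),
             query = file.path(dir, "query_genes.txt"),
             catalog = file.path(dir, "class_catalog.tsv"),
             truth = file.path(dir, "truth.json"))
  write_string_links(study$network, paths[["network"]])
  writeLines(study$query_set$members, paths[["query"]])
  rows <- unlist(lapply(study$catalog$classes, function(s) {
    paste(s$name, s$members, sep = "\t")
  }), use.names = FALSE)
  writeLines(rows, paths[["catalog"]])
  jsonlite::write_json(as.list(study$truth), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
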