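#' Maximum interaction score of a gene against a target set
#'
#' `MIS(g) = max { S(g, g') : g' in the target set }`, the largest edge score
#' between `gene` and any member of `target_set` on the weighted network. The
#' gene itself is excluded from the target set, so a gene belonging to both
#' the query set and a disease class never matches itself. Returns `0L` when
#' no edge links the gene to the set -- a sentinel below the minimum real
#' score, so an unconnected gene can never look associated.
#'
#' @param gene a protein ID; must be a network node (filter upstream with
#'   [map_and_filter()])
#' @param target_set a [gene_set()] (or character vector of IDs)
#' @param network a [ppi_network()]
#' @return integer MIS
#' @export
max_interaction_score <- function(gene, target_set, network) {
  if (!(gene %in% network$nodes)) {
    stop("gene '", gene, "' is not a network node; was it filtered?")
  }
  members <- if (inherits(target_set, "gene_set")) target_set$members else
    as.character(target_set)
  members <- setdiff(members, gene)
  if (!length(members)) return(0L)
  nb <- adjacency_index(network)[[gene]]
  hit <- nb$score[nb$nbr %in% members]
  if (length(hit)) max(hit) else 0L
}

#' Sample the random gene sets of the permutation null
#'
#' Draws `n_sets` sets of `set_size` distinct node IDs, each a uniform sample
#' from the full node universe of the network (query-set members included:
#' the null imposes no exclusion). The collection is reproducible from
#' `seed` and is meant to be drawn once per study and reused for every gene
#' of every class, so all p-values share one null.
#'
#' @param network a [ppi_network()]
#' @param set_size members per set (conventionally the size of the
#'   network-mapped query set)
#' @param n_sets number of permutation sets (default 1000)
#' @param seed integer RNG seed
#' @return object of class `random_set_collection`: list with `sets` (list of
#'   character vectors), `set_size`, `n_sets`, `universe_size`, `seed`, and a
#'   member-to-set inverted index used by [permutation_pvalue()].
#' @export
sample_random_sets <- function(network, set_size, n_sets = 1000L, seed = 1L) {
  nodes <- network$nodes
  if (set_size > length(nodes)) {
    stop("set_size (", set_size, ") exceeds the node universe (",
         length(nodes), ")")
  }
  if (n_sets < 1L) stop("n_sets must be >= 1")
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) sample(nodes, set_size))
  index <- split(rep(seq_len(n_sets), each = set_size),
                 unlist(sets, use.names = FALSE))
  structure(list(sets = sets, set_size = as.integer(set_size),
                 n_sets = as.integer(n_sets),
                 universe_size = length(nodes), seed = as.integer(seed),
                 index = index),
            class = "random_set_collection")
}

#' @export
print.random_set_collection <- function(x, ...) {
  cat("Random set collection:", x$n_sets, "sets of", x$set_size,
      "nodes (universe", x$universe_size, ", seed", x$seed, ")\n")
  invisible(x)
}

#' Per-set maximum interaction scores of one gene
#'
#' `MIS_i(g) = max { S(g, g') : g' in D_i }` for every random set `D_i`, with
#' `g` removed from `D_i` when present. Exposed mainly for inspection; the
#' p-value path in [permutation_pvalue()] only needs the exceedance count.
#'
#' @param gene protein ID (network node)
#' @param random_sets a [sample_random_sets()] collection
#' @param network a [ppi_network()]
#' @return integer vector of length `n_sets`
#' @export
random_set_mis <- function(gene, random_sets, network) {
  if (!(gene %in% network$nodes)) stop("gene '", gene, "' is not a network node")
  nb <- adjacency_index(network)[[gene]]
  res <- integer(random_sets$n_sets)
  # neighbours come sorted by descending score: first hit per set is its max
  keep <- nb$nbr != gene          # no-op on loop-free networks, kept explicit
  nbr <- nb$nbr[keep]; sc <- nb$score[keep]
  for (k in seq_along(nbr)) {
    ids <- random_sets$index[[nbr[k]]]
    if (is.null(ids)) next
    unset <- ids[res[ids] == 0L]
    if (length(unset)) res[unset] <- sc[k]
  }
  res
}

#' Permutation p-value of one gene's MIS
#'
#' Compares the observed `MIS(g)` against the null scores `MIS_i(g)` over the
#' shared random sets: the exceedance count `lambda` is the number of sets
#' whose `MIS_i(g)` is strictly higher than the observed MIS, and
#' `p = lambda / n_sets` exactly, so p-values live on the grid
#' `{0, 1/n, ..., 1}` and `p = 0` is attainable. Ties do not count toward
#' `lambda`; relative to the conventional `(lambda + 1) / (n + 1)` estimator
#' this is anti-conservative under score ties (see the package vignette).
#'
#' @param gene protein ID (network node)
#' @param query_mis the observed MIS from [max_interaction_score()], computed
#'   with the same self-exclusion convention
#' @param random_sets a [sample_random_sets()] collection
#' @param network a [ppi_network()]
#' @return one-row data.frame: `gene`, `mis`, `lambda`, `p_value`
#' @export
permutation_pvalue <- function(gene, query_mis, random_sets, network) {
  if (!inherits(random_sets, "random_set_collection") ||
      random_sets$n_sets < 1L) {
    stop("random_sets must be a non-empty random_set_collection")
  }
  nb <- adjacency_index(network)[[gene]]
  if (is.null(nb)) stop("gene '", gene, "' is not a network node")
  # MIS_i(g) > query_mis  <=>  D_i contains a neighbour scored above query_mis
  hot <- nb$nbr[nb$score > query_mis & nb$nbr != gene]
  lambda <- if (length(hot)) {
    length(unique(unlist(random_sets$index[hot], use.names = FALSE)))
  } else 0L
  data.frame(gene = gene, mis = as.integer(query_mis),
             lambda = as.integer(lambda),
             p_value = lambda / random_sets$n_sets,
             stringsAsFactors = FALSE)
}

#' Score every gene of one disease class against the query set
#'
#' For each class gene (in catalog order) computes the MIS against the query
#' set and its permutation p-value over the shared random-set collection.
#'
#' @param class_genes a network-filtered [gene_set()] (one disease class)
#' @param query_set the network-filtered query [gene_set()]
#' @param random_sets a [sample_random_sets()] collection, reused across all
#'   classes of a run
#' @param network a [ppi_network()]
#' @return data.frame with one row per class gene: `gene`, `mis`, `lambda`,
#'   `p_value`. Zero rows (with a warning) if the class is empty.
#' @export
score_disease_class <- function(class_genes, query_set, random_sets, network) {
  genes <- class_genes$members
  if (!length(genes)) {
    warning("class '", class_genes$name, "' has no genes after filtering")
    return(data.frame(gene = character(), mis = integer(), lambda = integer(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(genes, function(g) {
    mis <- max_interaction_score(g, query_set, network)
    permutation_pvalue(g, mis, random_sets, network)
  })
  do.call(rbind, rows)
}
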