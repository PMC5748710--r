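#' Weighted protein-protein interaction network
#'
#' Constructs an undirected, integer-weighted PPI network from an edge table.
#' Edges are stored once per unordered protein pair; symmetric duplicates
#' (`a b s` and `b a s`) collapse to a single edge and conflicting scores for
#' the same pair are an error, so the score function `S(p1, p2)` is
#' well-defined and symmetric. Self-loops are rejected.
#'
#' @param edges data.frame-like with three columns: two protein IDs and an
#'   integer score (column names are ignored; order matters).
#' @param min_score,max_score inclusive bounds every score must satisfy when
#'   `validate_scores` is `TRUE`. Defaults match the STRING combined-score
#'   range 150-999.
#' @param validate_scores if `FALSE`, scores outside `[min_score, max_score]`
#'   are accepted (they must still be integers).
#' @return An object of class `ppi_network`: a list with elements
#'   `edges` (data.table `protein1`, `protein2`, `score`, pair-canonical with
#'   `protein1 < protein2`), `nodes` (sorted character vector),
#'   `score_bounds`, and `n_duplicates` (collapsed symmetric records).
#' @examples
#' net <- ppi_network(data.frame(a = c("p1", "p2"), b = c("p2", "p3"),
#'                               s = c(500L, 150L)))
#' edge_score(net, "p3", "p2")
#' @export
ppi_network <- function(edges, min_score = 150L, max_score = 999L,
                        validate_scores = TRUE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) != 3L) {
    stop("`edges` must have exactly three columns (protein1, protein2, score)")
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  s <- edges[[3L]]
  if (is.character(s)) {
    bad <- !grepl("^[-+]?[0-9]+$", s)
    if (any(bad)) {
      stop("non-integer score in edge table (first offender: '", s[which(bad)[1L]], "')")
    }
    s <- as.integer(s)
  }
  if (!is.numeric(s) || anyNA(s) || any(s != as.integer(s))) {
    stop("edge scores must be integers without missing values")
  }
  s <- as.integer(s)
  if (any(a == b)) {
    stop("self-loops are not allowed (node '", a[which(a == b)[1L]], "')")
  }
  if (validate_scores && length(s) &&
      (min(s) < min_score || max(s) > max_score)) {
    off <- which(s < min_score | s > max_score)[1L]
    stop("edge score ", s[off], " outside [", min_score, ", ", max_score,
         "]; pass validate_scores = FALSE to relax")
  }

  dt <- data.table::data.table(protein1 = pmin(a, b), protein2 = pmax(a, b),
                               score = s)
  n_records <- nrow(dt)
  dt <- unique(dt)
  # same unordered pair with two distinct scores: S(p1,p2) would be ambiguous
  dup_pair <- duplicated(dt, by = c("protein1", "protein2"))
  if (any(dup_pair)) {
    i <- which(dup_pair)[1L]
    stop("conflicting scores for pair (", dt$protein1[i], ", ", dt$protein2[i],
         ")")
  }
  data.table::setkeyv(dt, c("protein1", "protein2"))

  structure(
    list(edges = dt,
         nodes = sort(unique(c(dt$protein1, dt$protein2))),
         score_bounds = c(min_score, max_score),
         n_duplicates = n_records - nrow(dt),
         .cache = new.env(parent = emptyenv())),
    class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("Weighted PPI network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  cat("  score bounds [", x$score_bounds[1L], ", ", x$score_bounds[2L],
      "]; ", x$n_duplicates, " symmetric duplicate record(s) collapsed\n",
      sep = "")
  invisible(x)
}

#' Number of nodes / edges of a PPI network
#' @param network a [ppi_network()]
#' @return integer count
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(network) nrow(network$edges)

#' Interaction score between two proteins
#'
#' Symmetric lookup of `S(p1, p2)`; `0L` if the proteins are not connected.
#'
#' @param network a [ppi_network()]
#' @param p1,p2 protein IDs
#' @return integer score, `0L` for absent edges
#' @export
edge_score <- function(network, p1, p2) {
  key <- data.table::data.table(protein1 = pmin(p1, p2),
                                protein2 = pmax(p1, p2))
  hit <- network$edges[key, on = c("protein1", "protein2")]$score
  hit[is.na(hit)] <- 0L
  hit
}

# Adjacency index: node -> list(nbr = character, score = integer), sorted by
# descending score. Built once per network and cached.
adjacency_index <- function(network) {
  cache <- network$.cache
  if (!is.null(cache$adj)) return(cache$adj)
  e <- network$edges
  from <- c(e$protein1, e$protein2)
  to <- c(e$protein2, e$protein1)
  sc <- c(e$score, e$score)
  o <- order(from, -sc, to, method = "radix")
  from <- from[o]; to <- to[o]; sc <- sc[o]
  runs <- rle(from)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  adj <- vector("list", length(network$nodes))
  names(adj) <- network$nodes
  for (i in seq_along(runs$values)) {
    idx <- starts[i]:ends[i]
    adj[[runs$values[i]]] <- list(nbr = to[idx], score = sc[idx])
  }
  empty <- list(nbr = character(), score = integer())
  for (n in network$nodes) if (is.null(adj[[n]])) adj[[n]] <- empty
  cache$adj <- adj
  adj
}

read_text_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")   # reads plain text too
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a STRING-style protein.links file
#'
#' Parses the whitespace-separated `protein1 protein2 combined_score` dialect
#' used by STRING's `protein.links` downloads (plain or gzip-compressed). A
#' first line whose third field is non-numeric is treated as a header. STRING
#' lists every interaction in both orientations; the two records collapse to
#' one undirected edge and must carry the same score.
#'
#' @inheritParams ppi_network
#' @param path path to the links file (`.gz` accepted)
#' @return a [ppi_network()]; `$n_duplicates` counts the collapsed records.
#' @seealso [write_string_links()]
#' @export
read_string_links <- function(path, min_score = 150L, max_score = 999L,
                              validate_scores = TRUE) {
  lines <- read_text_lines(path)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("empty links file: ", path)

  parts <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(parts)
  if (any(nf != 3L)) {
    bad <- which(nf != 3L)[1L]
    stop("malformed line ", line_no[bad], " in ", path, ": expected 3 fields, found ",
         nf[bad])
  }
  m <- matrix(unlist(parts), ncol = 3L, byrow = TRUE)
  if (!grepl("^[-+]?[0-9]+$", m[1L, 3L])) {   # header line
    m <- m[-1L, , drop = FALSE]
    line_no <- line_no[-1L]
    if (!nrow(m)) stop("links file contains only a header: ", path)
  }
  bad <- !grepl("^[-+]?[0-9]+$", m[, 3L])
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("malformed line ", line_no[i], " in ", path,
         ": non-integer score '", m[i, 3L], "'")
  }
  ppi_network(data.frame(p1 = m[, 1L], p2 = m[, 2L],
                         score = as.integer(m[, 3L])),
              min_score = min_score, max_score = max_score,
              validate_scores = validate_scores)
}

#' Write a network in the protein.links dialect
#'
#' Emits one line per undirected edge (single orientation, canonical pair
#' order) with a `protein1 protein2 combined_score` header; re-reading the
#' file with [read_string_links()] reproduces the edge map exactly.
#'
#' @param network a [ppi_network()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_string_links <- function(network, path) {
  e <- network$edges
  writeLines(c("protein1 protein2 combined_score",
               paste(e$protein1, e$protein2, e$score)), path)
  invisible(path)
}
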