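#' Named gene set
#'
#' A named collection of unique protein/gene IDs: the query set, one disease
#' class's genes, or one randomly drawn permutation set.
#'
#' @param members character vector of IDs; duplicates are dropped, keeping the
#'   first occurrence.
#' @param name set label
#' @return object of class `gene_set` with elements `name`, `members`, and
#'   `n_duplicates` (count of dropped repeats).
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- as.character(members)
  if (!length(members)) stop("gene set '", name, "' is empty")
  dup <- duplicated(members)
  structure(list(name = name, members = members[!dup],
                 n_duplicates = sum(dup)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "': ", length(x$members), " members\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$members)

#' Read a gene set from a one-ID-per-line file
#'
#' Blank lines and `#` comments are ignored; duplicate IDs are dropped with
#' the count recorded in `$n_duplicates`.
#'
#' @param path path to the file
#' @param name set label (defaults to the file name)
#' @return a [gene_set()]
#' @export
read_gene_set <- function(path, name = NULL) {
  if (is.null(name)) name <- basename(path)
  lines <- trimws(read_text_lines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no gene IDs in ", path)
  gene_set(lines, name = name)
}

#' Disease-class catalog
#'
#' An ordered mapping from class name to [gene_set()]. A gene may belong to
#' several classes but appears at most once within a class.
#'
#' @param sets list of [gene_set()]s with unique names
#' @param provenance free-text note on where the catalog came from
#' @return object of class `class_catalog`
#' @export
class_catalog <- function(sets, provenance = "") {
  if (!length(sets)) stop("catalog has no classes")
  nm <- vapply(sets, function(s) s$name, character(1L))
  if (anyDuplicated(nm)) stop("duplicate class name: ", nm[duplicated(nm)][1L])
  names(sets) <- nm
  structure(list(classes = sets, provenance = provenance),
            class = "class_catalog")
}

#' @export
print.class_catalog <- function(x, ...) {
  cat("Disease-class catalog:", length(x$classes), "classes\n")
  sizes <- vapply(x$classes, function(s) length(s$members), integer(1L))
  for (i in seq_along(sizes)) {
    cat("  ", names(sizes)[i], ": ", sizes[i], " genes\n", sep = "")
  }
  invisible(x)
}

#' Read a class catalog from a two-column TSV
#'
#' Each line is one membership, `class_name<TAB>gene_id`. Class order follows
#' first appearance; a repeated (class, gene) row is kept once with a warning.
#'
#' @param path path to the TSV
#' @param provenance free-text source note (defaults to the path)
#' @return a [class_catalog()]
#' @export
read_class_catalog <- function(path, provenance = path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty class catalog: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    stop("malformed catalog row ", which(nf != 2L)[1L], " in ", path,
         ": expected 2 tab-separated fields")
  }
  cls <- trimws(vapply(parts, `[`, character(1L), 1L))
  gene <- trimws(vapply(parts, `[`, character(1L), 2L))
  if (any(!nzchar(cls)) || any(!nzchar(gene))) {
    stop("empty field in class catalog ", path)
  }
  dup <- duplicated(paste0(cls, "\t", gene))
  if (any(dup)) {
    warning(sum(dup), " duplicated (class, gene) row(s) in ", path,
            "; kept once")
    cls <- cls[!dup]; gene <- gene[!dup]
  }
  sets <- lapply(unique(cls), function(cn) gene_set(gene[cls == cn], name = cn))
  class_catalog(sets, provenance = provenance)
}

#' Read a raw-ID to network-ID mapping table
#'
#' Two-column TSV, `raw_id<TAB>network_id` (e.g. gene symbol to Ensembl
#' peptide ID). The mapping is static: no online lookups are performed.
#'
#' @param path path to the TSV
#' @return named character vector (names = raw IDs, values = network IDs)
#' @export
read_id_map <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("empty ID map: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("malformed ID-map row ", which(lengths(parts) != 2L)[1L], " in ", path)
  }
  stats::setNames(trimws(vapply(parts, `[`, character(1L), 2L)),
                  trimws(vapply(parts, `[`, character(1L), 1L)))
}

#' Map gene IDs onto the network and drop genes not in it
#'
#' Applies an optional raw-to-network ID mapping (IDs absent from the mapping
#' pass through unchanged), then keeps only genes that are nodes of the
#' network. The same operation is applied to the query set and to every
#' disease class, mirroring the exclusion of genes that do not occur in the
#' PPI network.
#'
#' @param genes a [gene_set()]
#' @param network a [ppi_network()]
#' @param mapping optional named character vector (see [read_id_map()])
#' @return list with `set` (filtered [gene_set()], possibly empty members
#'   replaced by an error upstream) and `dropped` (raw IDs, input order).
#'   If two raw IDs map to the same network ID, a warning is issued and the
#'   ID is kept once.
#' @export
map_and_filter <- function(genes, network, mapping = NULL) {
  raw <- genes$members
  mapped <- raw
  if (!is.null(mapping)) {
    hit <- raw %in% names(mapping)
    mapped[hit] <- unname(mapping[raw[hit]])
  }
  in_net <- mapped %in% network$nodes
  kept <- mapped[in_net]
  if (anyDuplicated(kept)) {
    warning("multiple input IDs map to the same network ID in set '",
            genes$name, "'; kept once")
    kept <- kept[!duplicated(kept)]
  }
  set <- if (length(kept)) gene_set(kept, name = genes$name) else
    structure(list(name = genes$name, members = character(),
                   n_duplicates = 0L), class = "gene_set")
  list(set = set, dropped = raw[!in_net])
}
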