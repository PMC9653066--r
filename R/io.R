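#' Count matrix with paired sample metadata
#'
#' The central container of the package: a taxa-by-samples matrix of
#' non-negative integer counts together with per-sample metadata giving the
#' treatment group and the pair (block) each sample belongs to, mirroring a
#' paired sampling design (treated site and matched untreated site).
#'
#' @param counts numeric matrix, taxa in rows and samples in columns, with
#'   `rownames` (taxon ids) and `colnames` (sample ids). Entries must be
#'   non-negative integers.
#' @param metadata data.frame with columns `sample_id`, `group` and `pair`,
#'   one row per sample. Row order is matched to `colnames(counts)`.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   and `metadata`.
#' @examples
#' m <- matrix(c(5L, 0L, 1L, 2L, 3L, 4L), nrow = 3,
#'             dimnames = list(paste0("OTU_", 1:3), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"),
#'                  group = c("A", "B"), pair = c("p1", "p1"))
#' count_matrix(m, md)
#' @export
count_matrix <- function(counts, metadata) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have taxon rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon ids in counts", call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids in counts", call. = FALSE)
  bad <- which(is.na(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("counts must be non-negative integers; offending cell: taxon '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]),
         call. = FALSE)
  need <- c("sample_id", "group", "pair")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata)))
    stop("metadata must be a data.frame with columns sample_id, group, pair",
         call. = FALSE)
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  if (anyNA(metadata$sample_id))
    stop(sprintf("metadata missing for sample '%s'",
                 setdiff(colnames(counts), metadata$sample_id)[1]), call. = FALSE)
  if (anyNA(metadata$group) || anyNA(metadata$pair))
    stop("every sample needs a non-missing group and pair", call. = FALSE)
  if (all(rowSums(counts) == 0))
    stop("no taxon with a positive total count", call. = FALSE)
  storage.mode(counts) <- "integer"
  rownames(metadata) <- NULL
  structure(list(counts = counts,
                 metadata = metadata[, need, drop = FALSE]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d taxa x %d samples (%d groups, %d pairs)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$metadata$group)),
              length(unique(x$metadata$pair))))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Taxon and sample accessors
#' @param x a `count_matrix`
#' @return character vector of ids, or the group/pair factor per sample.
#' @export
taxon_ids <- function(x) rownames(x$counts)

#' @rdname taxon_ids
#' @export
sample_ids <- function(x) colnames(x$counts)

#' @rdname taxon_ids
#' @export
sample_groups <- function(x) x$metadata$group

#' @rdname taxon_ids
#' @export
sample_pairs <- function(x) x$metadata$pair

#' Within-sample relative abundances
#'
#' Proportions are always recomputed from counts (columns scaled to sum 1);
#' they are never read from file.
#'
#' @param x a `count_matrix`
#' @return numeric matrix of the same shape as `x$counts`.
#' @export
relative_abundance <- function(x) {
  tot <- colSums(x$counts)
  if (any(tot == 0))
    stop(sprintf("sample '%s' has zero total count",
                 colnames(x$counts)[which(tot == 0)[1]]), call. = FALSE)
  sweep(x$counts, 2, tot, "/")
}

#' Subset a count matrix by taxa and/or samples
#' @param x a `count_matrix`
#' @param taxa,samples character or logical/integer index vectors
#' @return a `count_matrix`
#' @export
subset_counts <- function(x, taxa = NULL, samples = NULL) {
  cnt <- x$counts
  if (!is.null(taxa)) cnt <- cnt[taxa, , drop = FALSE]
  if (!is.null(samples)) cnt <- cnt[, samples, drop = FALSE]
  md <- x$metadata[match(colnames(cnt), x$metadata$sample_id), , drop = FALSE]
  count_matrix(cnt, md)
}

#' Read a count table and its sample metadata
#'
#' Supports the common OTU-table TSV export (first column taxon id, header
#' row of sample ids, tab-separated) and the BIOM JSON (v1) dialect.
#'
#' @param path path to the count table.
#' @param metadata path to a metadata TSV with columns `sample_id`, `group`,
#'   `pair`, or an equivalent data.frame.
#' @param format `"tsv"` or `"biom"`.
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, metadata, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.character(metadata)) metadata <- read_metadata(metadata)
  if (format == "tsv") {
    tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    if (!is.numeric(m)) {
      bad <- which(!vapply(tab, is.numeric, logical(1)))[1]
      stop(sprintf("non-numeric counts in column '%s'", names(tab)[bad]),
           call. = FALSE)
    }
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("reading BIOM files requires the 'biomformat' package", call. = FALSE)
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
  }
  count_matrix(m, metadata)
}

#' @rdname read_counts
#' @param x a `count_matrix` to write; the metadata is written to
#'   `paste0(path, ".metadata.tsv")` unless `metadata_path` is given.
#' @param metadata_path optional explicit metadata destination.
#' @export
write_counts <- function(x, path, format = c("tsv", "biom"),
                         metadata_path = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                     check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("writing BIOM files requires the 'biomformat' package", call. = FALSE)
    biomformat::write_biom(biomformat::make_biom(x$counts), path)
  }
  mp <- metadata_path %||% paste0(path, ".metadata.tsv")
  write.table(x$metadata, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_counts
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  md <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "group", "pair")
  miss <- setdiff(need, names(md))
  if (length(miss) > 0)
    stop(sprintf("metadata is missing column '%s'", miss[1]), call. = FALSE)
  md
}

#' Function-by-sample relative abundance table
#'
#' Container for predicted functional profiles (relative abundances of
#' functional categories per sample), as produced upstream by functional
#' prediction tools and consumed here for group comparisons.
#'
#' @param values numeric matrix, functions in rows, samples in columns, with
#'   dimnames; finite and non-negative.
#' @return object of class `function_table` (the validated matrix).
#' @export
function_table <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have function rownames and sample colnames", call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("values must be finite and >= 0; offending cell: function '%s', sample '%s'",
                 rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]),
         call. = FALSE)
  structure(values, class = c("function_table", "matrix"))
}

#' @rdname function_table
#' @param path file path
#' @export
read_function_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                    check.names = FALSE)
  function_table(as.matrix(tab))
}

#' @rdname function_table
#' @param x a `function_table`
#' @export
write_function_table <- function(x, path) {
  df <- data.frame(function_id = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write rooted trees in Newick format
#'
#' Thin validating wrappers around [ape::read.tree()] / [ape::write.tree()].
#' Malformed input (unbalanced parentheses) is rejected with the character
#' position of the imbalance.
#'
#' @param path file path
#' @return an [ape::phylo] tree
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") depth <- depth - 1
    if (depth < 0)
      stop(sprintf("malformed Newick: unbalanced ')' at position %d", i),
           call. = FALSE)
  }
  if (depth != 0)
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("malformed Newick: could not parse tree", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("tree has duplicate leaf names", call. = FALSE)
  if (!is.null(tr$edge.length) && any(!is.finite(tr$edge.length)))
    stop("tree has non-finite branch lengths", call. = FALSE)
  tr
}

#' @rdname read_newick
#' @param tree an [ape::phylo] object
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Export a co-occurrence network
#'
#' Writes the graph with its per-edge correlation, adjusted p-value and sign
#' either as GraphML or as a tab-separated edge list.
#'
#' @param network a [co_network] (or plain igraph graph)
#' @param path destination file
#' @param format `"graphml"` or `"edgelist_tsv"`
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  g <- as_igraph(network)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
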