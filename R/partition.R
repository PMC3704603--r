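# The Partition is the universal currency between clustering, refinement,
# concordance scoring and the registry: an assignment of sequence ids to
# cluster labels.

#' Partitions of sequence ids into clusters
#'
#' A partition is a named character vector mapping each sequence id (name)
#' to a cluster label (value), of class `partition`. By default labels are
#' canonicalized so that they are a deterministic function of content, not
#' of insertion order: each cluster is labelled by its lexicographically
#' smallest member id.
#'
#' @param assignment Named character vector (or coercible), names = ids,
#'   values = cluster labels.
#' @param canonical Relabel clusters by their smallest member id (default
#'   `TRUE`). Use `FALSE` to preserve externally meaningful labels such as
#'   registry URIs.
#' @return A `partition` object.
#' @examples
#' new_partition(c(s1 = "x", s2 = "x", s3 = "y"))
#' @export
new_partition <- function(assignment, canonical = TRUE) {
  x <- as.character(assignment)
  ids <- names(assignment)
  if (is.null(ids) || any(!nzchar(ids))) stop("assignment must be named by sequence id")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("sequence id assigned twice: ", dup[1L])
  if (anyNA(x) || any(!nzchar(x))) stop("cluster labels must be non-empty")
  names(x) <- ids
  if (canonical && length(x)) {
    smallest <- vapply(split(ids, x), min, "")
    x <- unname(smallest[x])
    names(x) <- ids
  }
  x <- x[order(names(x))]
  class(x) <- "partition"
  x
}

#' @export
print.partition <- function(x, ...) {
  k <- length(unique(unclass(x)))
  cat(sprintf("Partition: %d sequences in %d clusters\n", length(x), k))
  sizes <- sort(table(unclass(x)), decreasing = TRUE)
  show <- utils::head(sizes, 8L)
  cat("  sizes:", paste(show, collapse = " "),
      if (length(sizes) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Partition utilities
#'
#' `n_clusters()` counts the clusters of a partition;
#' `partition_members()` lists member ids keyed by cluster label.
#'
#' @param partition A [new_partition()].
#' @return An integer count, or a named list of character vectors.
#' @export
n_clusters <- function(partition) length(unique(unclass(partition)))

#' @rdname n_clusters
#' @export
partition_members <- function(partition)
  split(names(partition), unclass(partition))

#' Test whether two partitions induce the same grouping
#'
#' Label-agnostic: compares the set of member sets.
#' @param a,b `partition` objects over the same ids.
#' @return `TRUE` or `FALSE`.
#' @export
same_partition <- function(a, b) {
  if (!setequal(names(a), names(b))) return(FALSE)
  ca <- new_partition(stats::setNames(as.character(a), names(a)))
  cb <- new_partition(stats::setNames(as.character(b), names(b)))
  identical(unclass(ca), unclass(cb))
}

#' Write and read partitions as TSV
#'
#' Two columns `sequence_id` and `cluster_label`, sorted by cluster label
#' then sequence id. `read_partition(write_partition(p))` reproduces `p`
#' exactly.
#'
#' @param partition A `partition`.
#' @param path File path.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(sequence_id = names(partition),
                   cluster_label = as.character(partition),
                   stringsAsFactors = FALSE)
  df <- df[order(df$cluster_label, df$sequence_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @param canonical Passed to [new_partition()].
#' @export
read_partition <- function(path, canonical = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("sequence_id", "cluster_label"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  new_partition(stats::setNames(df$cluster_label, df$sequence_id),
                canonical = canonical)
}
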