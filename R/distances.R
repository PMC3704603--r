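# Uncorrected p-distance computation with pairwise deletion, sparse
# neighbour graphs, and per-dataset divergence summaries. Distances are
# kept as exact integer pairs (mismatches, compared sites) wherever
# thresholds are compared, removing floating-point boundary effects at
# d == t exactly.

# Encode aligned sequences as an integer matrix: A,C,G,T -> 1..4, every
# ambiguity code and '-' -> 0. Rows named by id. Errors on unequal lengths.
encode_seqs <- function(records) {
  records <- as_seq_records(records)
  lens <- nchar(records$seq)
  if (length(unique(lens)) > 1L)
    stop("sequences must be aligned to equal length (got lengths ",
         paste(utils::head(unique(lens)), collapse = ", "), ")")
  n <- nrow(records)
  L <- if (n) lens[1L] else 0L
  m <- matrix(0L, n, L, dimnames = list(records$id, NULL))
  if (n) {
    code <- stats::setNames(rep(0L, 256L), rawToChar(as.raw(0:255), multiple = TRUE))
    code[c("A", "C", "G", "T")] <- 1:4
    for (i in seq_len(n))
      m[i, ] <- code[strsplit(records$seq[i], "", fixed = TRUE)[[1L]]]
  }
  m
}

# Threshold comparison on exact integers. Thresholds are quoted to three
# decimals; d <= thr  <=>  1000*mism <= round(1000*thr)*sites.
le_thr <- function(mism, sites, thr) 1000 * mism <= round(1000 * thr) * sites
lt_thr <- function(mism, sites, thr) 1000 * mism < round(1000 * thr) * sites

#' Uncorrected pairwise distance between two aligned sequences
#'
#' Mismatches over compared sites, where compared sites are the positions
#' at which both sequences carry an unambiguous base (A/C/G/T). Gaps and
#' ambiguity codes are excluded by pairwise deletion and are never counted
#' as matches, even when compatible. When fewer than `min_overlap` sites
#' remain, the distance is undefined and `NA` is returned (treated as
#' exceeding any cutoff downstream).
#'
#' @param a,b Aligned sequences of equal length (character scalars).
#' @param min_overlap Minimum compared sites for a defined distance
#'   (default 300).
#' @return Proportion in `[0, 1]`, or `NA` when undefined.
#' @examples
#' p_distance("AAAA", "AAAT")  # 0.25
#' p_distance("AAN-", "AAG-", min_overlap = 1)  # 0 over 2 compared sites
#' @export
p_distance <- function(a, b, min_overlap = 300L) {
  if (nchar(a) != nchar(b)) stop("sequences have unequal lengths")
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  acgt <- c("A", "C", "G", "T")
  ok <- av %in% acgt & bv %in% acgt
  sites <- sum(ok)
  if (sites < min_overlap) return(NA_real_)
  sum(av[ok] != bv[ok]) / sites
}

# All-pairs mismatch and compared-site counts via indicator cross-products;
# exact integers. Returns list(ids, mism, sites) of class "pdist".
pdist_matrix <- function(enc) {
  n <- nrow(enc)
  valid <- enc > 0L
  storage.mode(valid) <- "integer"
  sites <- tcrossprod(valid)
  match <- matrix(0, n, n)
  for (b in 1:4) {
    ind <- enc == b
    storage.mode(ind) <- "integer"
    match <- match + tcrossprod(ind)
  }
  mism <- sites - match
  storage.mode(mism) <- "integer"
  storage.mode(sites) <- "integer"
  dimnames(mism) <- dimnames(sites) <- list(rownames(enc), rownames(enc))
  structure(list(ids = rownames(enc), mism = mism, sites = sites),
            class = "pdist")
}

# numeric distance matrix with NA where overlap < min_overlap
pdist_d <- function(pd, min_overlap = 300L) {
  d <- pd$mism / pd$sites
  d[pd$sites < min_overlap] <- NA_real_
  diag(d) <- 0
  d
}

#' Sparse graph of pairwise distances at or below a cutoff
#'
#' Nodes are sequences; edges link pairs whose defined p-distance is
#' `<= cutoff`. Undefined distances (overlap below `min_overlap`) never
#' create edges. The result is deterministic for a given record set
#' regardless of input order.
#'
#' @param records Aligned [seq_records] (equal lengths).
#' @param cutoff Proportion; edges above it are dropped.
#' @param min_overlap Minimum compared sites for a defined distance.
#' @return A `dist_graph`: list with `ids`, `edges` (data frame `a`, `b`,
#'   `mism`, `sites`, `d` with `a < b`), and `cutoff`.
#' @export
build_dist_graph <- function(records, cutoff, min_overlap = 300L) {
  records <- as_seq_records(records)
  enc <- encode_seqs(records)
  pd <- pdist_matrix(enc)
  n <- length(pd$ids)
  if (n < 2L) {
    edges <- data.frame(a = character(), b = character(), mism = integer(),
                        sites = integer(), d = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    ut <- upper.tri(pd$mism)
    keep <- ut & pd$sites >= min_overlap & le_thr(pd$mism, pd$sites, cutoff)
    idx <- which(keep, arr.ind = TRUE)
    a <- pd$ids[idx[, 1L]]
    b <- pd$ids[idx[, 2L]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    edges <- data.frame(a = a, b = b,
                        mism = pd$mism[idx], sites = pd$sites[idx],
                        d = pd$mism[idx] / pd$sites[idx],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(ids = sort(pd$ids), edges = edges, cutoff = cutoff,
                 min_overlap = as.integer(min_overlap)),
            class = "dist_graph")
}

#' @export
print.dist_graph <- function(x, ...) {
  cat(sprintf("dist_graph: %d nodes, %d edges at cutoff %.3f\n",
              length(x$ids), nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Divergence summary of a labelled dataset
#'
#' Reports, in percent: the mean over species (with two or more members)
#' of the maximum intraspecific p-distance, and the mean over species of
#' the minimum p-distance from any member to any heterospecific member
#' (nearest-neighbour distance, per-species averaging convention). Species
#' without a heterospecific comparator are excluded from the
#' nearest-neighbour mean; if none has one, that statistic is `NA`.
#'
#' @param records Aligned [seq_records] with at least one species label.
#' @param min_overlap Minimum compared sites for a defined distance.
#' @return List of class `dataset_summary`: `n_species`, `n_sequences`,
#'   `seqs_per_species`, `mean_max_intraspecific` (%),
#'   `mean_nn_distance` (%).
#' @export
dataset_summary <- function(records, min_overlap = 300L) {
  records <- as_seq_records(records)
  lab <- records[!is.na(records$species), , drop = FALSE]
  if (!nrow(lab)) stop("no records carry a species label")
  enc <- encode_seqs(lab)
  d <- pdist_d(pdist_matrix(enc), min_overlap)
  sp <- lab$species
  species <- sort(unique(sp))
  max_intra <- vapply(species, function(s) {
    idx <- which(sp == s)
    if (length(idx) < 2L) return(NA_real_)
    max(d[idx, idx], na.rm = TRUE)
  }, 0)
  nn <- vapply(species, function(s) {
    idx <- which(sp == s)
    other <- which(sp != s)
    if (!length(other)) return(NA_real_)
    block <- d[idx, other, drop = FALSE]
    if (all(is.na(block))) return(NA_real_)
    min(block, na.rm = TRUE)
  }, 0)
  structure(list(
    n_species = length(species),
    n_sequences = nrow(lab),
    seqs_per_species = nrow(lab) / length(species),
    mean_max_intraspecific = 100 * mean(max_intra, na.rm = TRUE),
    mean_nn_distance = if (all(is.na(nn))) NA_real_ else 100 * mean(nn, na.rm = TRUE)
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf(
    "%d species, %d sequences (%.1f per species)\n",
    x$n_species, x$n_sequences, x$seqs_per_species))
  cat(sprintf("  mean max-intraspecific distance: %.2f%%\n",
              x$mean_max_intraspecific))
  cat(sprintf("  mean nearest-neighbour distance: %s\n",
              if (is.na(x$mean_nn_distance)) "undefined (single species)"
              else sprintf("%.2f%%", x$mean_nn_distance)))
  invisible(x)
}
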