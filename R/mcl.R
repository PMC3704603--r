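# Markov-clustering refinement of single-linkage OTUs with
# Silhouette-based selection over the inflation grid. Refinement operates
# on small groups: OTUs with three or more members showing sequence
# variation, with near neighbours (below the founder cutoff) collapsed
# into a single unit first.

#' Select refinement groups
#'
#' OTUs with fewer than three members, or whose members lack any sequence
#' variation, cannot be further partitioned and are excluded. OTUs whose
#' minimum inter-OTU distance falls below the founder cutoff (4.4%) are
#' collapsed into a single refinement unit before Markov clustering, so
#' their separation is validated rather than assumed.
#'
#' @param partition Single-linkage [new_partition()].
#' @param graph A [build_dist_graph()] with `cutoff >= founder_cutoff`.
#' @param cfg A [resl_config()].
#' @return List of character id vectors (disjoint refinement groups).
#' @export
select_refinement_groups <- function(partition, graph, cfg = resl_config()) {
  stopifnot(inherits(graph, "dist_graph"))
  if (round(1000 * graph$cutoff) < round(1000 * cfg$founder_cutoff))
    stop("graph cutoff is below the founder cutoff")
  mem <- partition_members(partition)
  e <- graph$edges
  cl_of <- stats::setNames(rep(names(mem), lengths(mem)), unlist(mem))
  ca <- cl_of[e$a]; cb <- cl_of[e$b]
  # variation within an OTU: any within pair differing (an absent edge
  # implies d > cutoff > 0, hence variation)
  zero_within <- stats::setNames(integer(length(mem)), names(mem))
  w <- which(ca == cb & e$mism == 0L)
  if (length(w)) {
    tab <- table(ca[w])
    zero_within[names(tab)] <- as.integer(tab)
  }
  has_variation <- vapply(names(mem), function(l) {
    n <- length(mem[[l]])
    n >= 2L && zero_within[[l]] < choose(n, 2L)
  }, TRUE)
  # collapse OTUs linked by an inter-OTU distance < founder_cutoff
  inter <- which(ca != cb & lt_thr(e$mism, e$sites, cfg$founder_cutoff))
  g <- igraph::graph_from_data_frame(
    data.frame(a = ca[inter], b = cb[inter], stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = names(mem)))
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  out <- list()
  for (grp in groups) {
    ids <- unlist(mem[grp], use.names = FALSE)
    eligible <- if (length(grp) > 1L) length(ids) >= 3L
      else length(ids) >= 3L && has_variation[[grp]]
    if (eligible) out[[length(out) + 1L]] <- sort(ids)
  }
  stage_log("refine", "%d refinement group(s) selected", length(out))
  out
}

#' Initialize the column-stochastic matrix of a refinement group
#'
#' Edge weights are similarities rescaled to the link threshold,
#' `w = max(0, 1 - d / t)`: a pair at distance 0 carries weight 1 and a
#' pair at or beyond the single-linkage threshold carries none, so the
#' random walk only mixes across separations strictly inside the
#' threshold — the structures a fixed threshold would overlook. A
#' self-loop of weight 1 is added to every node and each column is
#' divided by its sum, giving a column-stochastic matrix `M` where
#' `M[i, j]` is the probability of walking from node `j` to node `i`. An
#' isolated node keeps only its self-loop and is carried as its own
#' attractor.
#'
#' @param group Character vector of sequence ids.
#' @param graph A [build_dist_graph()] containing the group.
#' @param cfg A [resl_config()].
#' @return List of class `stoch_matrix`: `node_ids` (sorted) and `M`.
#' @export
init_stochastic <- function(group, graph, cfg = resl_config()) {
  ids <- sort(group)
  stopifnot(all(ids %in% graph$ids))
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  e <- graph$edges
  keep <- e$a %in% ids & e$b %in% ids &
    le_thr(e$mism, e$sites, cfg$founder_cutoff)
  ee <- e[keep, , drop = FALSE]
  if (nrow(ee)) {
    w <- pmax(0, 1 - ee$d / cfg$t)
    W[cbind(ee$a, ee$b)] <- w
    W[cbind(ee$b, ee$a)] <- w
  }
  diag(W) <- 1
  M <- sweep(W, 2L, colSums(W), "/")
  structure(list(node_ids = ids, M = M), class = "stoch_matrix")
}

col_normalize <- function(M) sweep(M, 2L, colSums(M), "/")

#' Markov clustering
#'
#' Iterates expansion (matrix squaring) and inflation (elementwise
#' Hadamard power `r` followed by column rescaling) until the max-norm
#' change drops below `epsilon` or `max_iter` is reached. Clusters are
#' extracted from the limit matrix: attractors are the rows with a
#' positive diagonal entry; each node joins the attractor with the largest
#' incoming probability, ties broken toward the lexicographically smallest
#' attractor id. Deterministic for fixed input; `r = 1` makes inflation
#' the identity, so a connected group converges to a single cluster.
#'
#' @param sm A `stoch_matrix` from [init_stochastic()].
#' @param r Inflation parameter, `>= 1`.
#' @param epsilon Convergence tolerance (max-norm).
#' @param max_iter Iteration cap; non-convergence returns the current
#'   extraction with a `converged = FALSE` attribute.
#' @return A [new_partition()] of the group's node ids, with attributes
#'   `converged` and `iterations`.
#' @export
mcl <- function(sm, r, epsilon = 1e-6, max_iter = 100L) {
  stopifnot(inherits(sm, "stoch_matrix"), r >= 1)
  M <- sm$M
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Mn <- col_normalize((M %*% M)^r)
    delta <- max(abs(Mn - M))
    M <- Mn
    if (delta < epsilon) { converged <- TRUE; break }
  }
  if (!converged)
    stage_log("mcl", "no convergence after %d iterations (r = %.1f)",
              max_iter, r)
  ids <- sm$node_ids
  attractors <- which(diag(M) > epsilon)
  if (!length(attractors)) attractors <- seq_along(ids)
  tie_tol <- sqrt(epsilon)  # residual convergence noise never decides ties
  assign <- vapply(seq_along(ids), function(j) {
    col <- M[attractors, j]
    best <- attractors[col >= max(col) - tie_tol]
    ids[min(best)]   # lexicographic tie-break via sorted node ids
  }, "")
  part <- new_partition(stats::setNames(assign, ids))
  attr(part, "converged") <- converged
  attr(part, "iterations") <- it
  part
}

#' Silhouette index of a partition
#'
#' For node `i`, `a(i)` is the mean distance to the other members of its
#' cluster and `b(i)` the smallest mean distance to another cluster;
#' `s(i) = (b - a) / max(a, b)`. Members of singleton clusters contribute
#' `s = 0`, and a single-cluster partition scores 0 by convention. The
#' index is the mean of `s(i)` over all nodes, in `[-1, 1]`.
#'
#' @param partition A [new_partition()] of the group.
#' @param d Full symmetric matrix of pairwise distances over the group
#'   (dimnames = ids). Undefined entries (`NA`) are dropped from the
#'   means.
#' @return Numeric score.
#' @export
silhouette_index <- function(partition, d) {
  ids <- names(partition)
  stopifnot(all(ids %in% rownames(d)))
  labs <- as.character(partition)
  cl <- unique(labs)
  if (length(cl) < 2L) return(0)
  s <- vapply(seq_along(ids), function(i) {
    own <- ids[labs == labs[i] & ids != ids[i]]
    if (!length(own)) return(0)
    a <- mean(d[ids[i], own], na.rm = TRUE)
    b <- min(vapply(setdiff(cl, labs[i]), function(cc)
      mean(d[ids[i], ids[labs == cc]], na.rm = TRUE), 0))
    if (is.nan(a) || is.nan(b) || max(a, b) == 0) return(0)
    (b - a) / max(a, b)
  }, 0)
  mean(s)
}

# Refine one group: run MCL across the inflation grid, score each
# candidate with the silhouette index on full within-group p-distances,
# keep the best (ties: fewer clusters, then smaller r).
refine_group <- function(group, graph, d_full, cfg) {
  sm <- init_stochastic(group, graph, cfg)
  dg <- d_full[group, group, drop = FALSE]
  best <- NULL
  candidates <- data.frame(r = cfg$inflation_grid, k = NA_integer_,
                           silhouette = NA_real_)
  for (gi in seq_along(cfg$inflation_grid)) {
    r <- cfg$inflation_grid[gi]
    part <- mcl(sm, r, epsilon = cfg$epsilon, max_iter = cfg$max_iter)
    sc <- silhouette_index(part, dg)
    k <- n_clusters(part)
    candidates$k[gi] <- k
    candidates$silhouette[gi] <- sc
    better <- is.null(best) || sc > best$silhouette ||
      (sc == best$silhouette && (k < best$k ||
        (k == best$k && r < best$r)))
    if (better) best <- list(r = r, k = k, silhouette = sc, partition = part)
  }
  best$candidates <- candidates
  best
}

#' Markov-clustering refinement of a single-linkage partition
#'
#' For each refinement group (see [select_refinement_groups()]), Markov
#' clustering is run at every inflation value of the grid, each candidate
#' partition is scored with the Silhouette index over the group's full
#' pairwise p-distances, and the maximum-score scheme is kept (ties broken
#' toward fewer clusters, then smaller inflation). OTUs outside any
#' refinement group pass through unchanged; nodes are never merged across
#' refinement groups beyond the initial collapse of near neighbours.
#'
#' @param partition Single-linkage [new_partition()].
#' @param records Aligned [seq_records] (the partition's sequences).
#' @param cfg A [resl_config()].
#' @param graph Optional precomputed [build_dist_graph()] at
#'   `founder_cutoff`.
#' @param details Return refinement details alongside the partition.
#' @return The refined [new_partition()] (the OTU boundaries); with
#'   `details = TRUE`, a list with `partition`, `groups`, and a
#'   per-group list `refinement` of selected `r`, cluster count and
#'   silhouette score.
#' @export
resl_refine <- function(partition, records, cfg = resl_config(),
                        graph = NULL, details = FALSE) {
  records <- as_seq_records(records)
  if (is.null(graph))
    graph <- build_dist_graph(records, cutoff = cfg$founder_cutoff,
                              min_overlap = cfg$min_overlap)
  groups <- select_refinement_groups(partition, graph, cfg)
  assign <- stats::setNames(as.character(partition), names(partition))
  if (length(groups)) {
    d_full <- pdist_d(pdist_matrix(encode_seqs(records)), cfg$min_overlap)
    info <- vector("list", length(groups))
    for (gi in seq_along(groups)) {
      res <- refine_group(groups[[gi]], graph, d_full, cfg)
      sub <- res$partition
      assign[names(sub)] <- paste0("g", gi, ".", as.character(sub))
      info[[gi]] <- res
    }
  } else info <- list()
  out <- new_partition(assign)
  if (!details) return(out)
  list(partition = out, groups = groups, refinement = info)
}
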