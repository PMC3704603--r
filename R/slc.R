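# Single-linkage clustering at threshold t: the exhaustive graph
# formulation and the representative-based streaming variant, whose
# 2t founder shortcut is exact under the triangle inequality. Also the
# threshold sweep used to study how OTU recovery varies with t.

#' Single-linkage clustering from a distance graph
#'
#' Clusters are the connected components of the subgraph containing edges
#' with `d <= t`: no member of any cluster is closer than the threshold to
#' any sequence in another cluster, while cluster diameters may exceed the
#' threshold (chaining).
#'
#' @param graph A [build_dist_graph()] result with `cutoff >= t`.
#' @param t Link threshold (proportion).
#' @return A canonical [new_partition()] over all graph ids.
#' @export
slc_naive <- function(graph, t) {
  stopifnot(inherits(graph, "dist_graph"))
  if (round(1000 * graph$cutoff) < round(1000 * t))
    stop("graph cutoff (", graph$cutoff, ") is below threshold t = ", t)
  e <- graph$edges
  keep <- le_thr(e$mism, e$sites, t)
  g <- igraph::graph_from_data_frame(e[keep, c("a", "b"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = graph$ids))
  comp <- igraph::components(g)$membership
  new_partition(stats::setNames(as.character(comp), names(comp)))
}

# Distances (mismatches, sites) from encoded row i to encoded rows idx.
dist_to_many <- function(enc, i, idx) {
  a <- enc[i, ]
  B <- enc[idx, , drop = FALSE]
  va <- a > 0L
  VB <- B > 0L
  both <- VB & rep(va, each = nrow(B))
  sites <- rowSums(both)
  mism <- rowSums(both & (B != rep(a, each = nrow(B))))
  list(mism = as.integer(mism), sites = as.integer(sites))
}

#' Streaming single-linkage clustering
#'
#' Processes records one at a time, comparing each against cluster
#' representatives only. Clusters whose nearest representative lies within
#' `2t` are expanded to a full member comparison; a record farther than
#' `2t` from every representative founds a new cluster. Representatives
#' form a t-cover (the first member is one; any joining member farther
#' than `t` from all current representatives becomes one), which makes the
#' shortcut exact under the triangle inequality: the outcome equals
#' [slc_naive()] and is unaffected by input order. Records whose distance
#' to a representative is undefined (low overlap) fall back to exhaustive
#' comparison against that cluster; records with no defined distances
#' become singletons.
#'
#' @param records Aligned [seq_records].
#' @param t Link threshold (proportion).
#' @param cfg A [resl_config()]; supplies `founder_cutoff` and
#'   `min_overlap`.
#' @return A canonical [new_partition()].
#' @export
slc_streaming <- function(records, t = 0.022, cfg = resl_config(t = t)) {
  records <- as_seq_records(records)
  enc <- encode_seqs(records)
  n <- nrow(enc)
  if (!n) return(new_partition(stats::setNames(character(), character())))
  min_ov <- cfg$min_overlap
  members <- list()   # integer row indices per cluster
  reps <- list()
  for (i in seq_len(n)) {
    k <- length(members)
    joined <- integer(0)
    if (k) {
      rep_idx <- unlist(reps, use.names = FALSE)
      rep_cl <- rep.int(seq_len(k), lengths(reps))
      dr <- dist_to_many(enc, i, rep_idx)
      defined <- dr$sites >= min_ov
      near <- defined & le_thr(dr$mism, dr$sites, cfg$founder_cutoff)
      candidates <- unique(c(rep_cl[near], rep_cl[!defined]))
      for (cl in candidates) {
        dm <- dist_to_many(enc, i, members[[cl]])
        hit <- dm$sites >= min_ov & le_thr(dm$mism, dm$sites, t)
        if (any(hit)) joined <- c(joined, cl)
      }
    }
    if (!length(joined)) {
      members[[k + 1L]] <- i
      reps[[k + 1L]] <- i
    } else {
      joined <- sort(joined)
      tgt <- joined[1L]
      # bridge: merge all clusters this record links to
      for (cl in rev(joined[-1L])) {
        members[[tgt]] <- c(members[[tgt]], members[[cl]])
        reps[[tgt]] <- c(reps[[tgt]], reps[[cl]])
        members[[cl]] <- NULL
        reps[[cl]] <- NULL
      }
      dm <- dist_to_many(enc, i, reps[[tgt]])
      covered <- any(dm$sites >= min_ov & le_thr(dm$mism, dm$sites, t))
      members[[tgt]] <- c(members[[tgt]], i)
      if (!covered) reps[[tgt]] <- c(reps[[tgt]], i)
    }
  }
  lab <- character(n)
  for (cl in seq_along(members)) lab[members[[cl]]] <- as.character(cl)
  new_partition(stats::setNames(lab, rownames(enc)))
}

#' Threshold sweep
#'
#' Runs single-linkage clustering across a grid of thresholds and scores
#' each partition against species labels, reproducing the
#' threshold-response analysis used to select the operating threshold.
#' OTU counts decrease weakly as the threshold rises, and the partitions
#' are nested.
#'
#' @param records Aligned [seq_records] with species labels.
#' @param lo,hi,step Threshold range and increment (proportions). A step
#'   larger than the range degenerates to the single threshold `lo`.
#' @param min_overlap Minimum compared sites for a defined distance.
#' @return A data frame of class `resl_sweep` with columns `t`, `n_otus`,
#'   `n_match`, `n_merge`, `n_split`, `n_mixture`; the attribute
#'   `best_thresholds` holds the threshold(s) maximizing `n_match`.
#' @export
threshold_sweep <- function(records, lo = 0.001, hi = 0.060, step = 0.001,
                            min_overlap = 300L) {
  records <- as_seq_records(records)
  truth <- stats::setNames(records$species, records$id)
  truth <- truth[!is.na(truth)]
  if (!length(truth)) stop("threshold_sweep requires species labels")
  thresholds <- if (step > hi - lo) lo else seq(lo, hi, by = step)
  graph <- build_dist_graph(records, cutoff = hi, min_overlap = min_overlap)
  rows <- lapply(thresholds, function(t) {
    part <- slc_naive(graph, t)
    conc <- classify_species(part, truth)
    data.frame(t = t, n_otus = n_clusters(part),
               n_match = conc$counts[["MATCH"]],
               n_merge = conc$counts[["MERGE"]],
               n_split = conc$counts[["SPLIT"]],
               n_mixture = conc$counts[["MIXTURE"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "best_thresholds") <- out$t[out$n_match == max(out$n_match)]
  class(out) <- c("resl_sweep", "data.frame")
  out
}

#' @export
plot.resl_sweep <- function(x, ...) {
  graphics::plot(x$t * 100, x$n_match, type = "l", lwd = 2,
                 xlab = "threshold (%)", ylab = "species", col = "forestgreen",
                 ylim = c(0, max(x$n_match, x$n_merge, x$n_split)), ...)
  graphics::lines(x$t * 100, x$n_merge, col = "goldenrod", lwd = 2)
  graphics::lines(x$t * 100, x$n_split, col = "darkorange", lwd = 2)
  graphics::lines(x$t * 100, x$n_mixture, col = "firebrick", lwd = 2)
  graphics::legend("right", c("MATCH", "MERGE", "SPLIT", "MIXTURE"),
                   col = c("forestgreen", "goldenrod", "darkorange",
                           "firebrick"), lwd = 2, bty = "n")
  invisible(x)
}
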