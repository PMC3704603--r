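# Independent oracles used to validate the package implementations.
# Each shares no code with the functions it checks.

# --- union-find single-linkage oracle ---------------------------------

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

# single linkage as union-find over the brute-force all-pairs filter
oracle_slc <- function(records, t, min_overlap = 300L) {
  n <- nrow(records)
  parent <- seq_len(n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d <- p_distance(records$seq[i], records$seq[j],
                        min_overlap = min_overlap)
        if (!is.na(d) && d <= t + 1e-12) {
          ri <- uf_find(parent, i)
          rj <- uf_find(parent, j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  new_partition(stats::setNames(as.character(roots), records$id))
}

# same oracle at scale: distances from ape's C implementation (raw
# p-distance, pairwise deletion), clustering by hand-written union-find
oracle_slc_fast <- function(records, t) {
  stopifnot(requireNamespace("ape", quietly = TRUE))
  n <- nrow(records)
  bin <- ape::as.DNAbin(lapply(stats::setNames(records$seq, records$id),
                               function(s) strsplit(tolower(s), "")[[1L]]))
  D <- as.matrix(ape::dist.dna(bin, model = "raw",
                               pairwise.deletion = TRUE))
  parent <- seq_len(n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!is.na(D[i, j]) && D[i, j] <= t + 1e-12) {
        ri <- uf_find(parent, i)
        rj <- uf_find(parent, j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), function(i) uf_find(parent, i), 0L)
  new_partition(stats::setNames(as.character(roots), records$id))
}

# --- concordance oracles ----------------------------------------------

# category walk over the explicit species-OTU bipartite graph
oracle_classify <- function(partition, truth) {
  truth <- truth[!is.na(truth)]
  cl <- unclass(partition)[names(truth)]
  out <- character(0)
  for (s in unique(truth)) {
    my_ids <- names(truth)[truth == s]
    my_otus <- unique(cl[my_ids])
    impure <- vapply(my_otus, function(o) {
      occupants <- names(cl)[cl == o]
      any(truth[occupants] != s)
    }, TRUE)
    out[s] <- if (length(my_otus) == 1L && !any(impure)) "MATCH"
      else if (length(my_otus) > 1L && !any(impure)) "SPLIT"
      else if (length(my_otus) == 1L) "MERGE"
      else "MIXTURE"
  }
  out
}

# direct contingency-table evaluation of the clustering F-measure
oracle_f_measure <- function(partition, truth) {
  truth <- truth[!is.na(truth)]
  cl <- unclass(partition)[names(truth)]
  total <- 0
  n <- length(truth)
  for (s in unique(truth)) {
    ni <- sum(truth == s)
    best <- 0
    for (o in unique(cl)) {
      nij <- sum(truth == s & cl == o)
      if (nij == 0) next
      nj <- sum(cl == o)
      P <- nij / nj
      R <- nij / ni
      best <- max(best, 2 * P * R / (P + R))
    }
    total <- total + ni / n * best
  }
  total
}

# --- independent MCL reference (numpy, via the system python) ----------

# Standalone implementation of the expansion/inflation recurrence and the
# attractor extraction, sharing no code with the package.
oracle_mcl_py <- function(M, r, epsilon = 1e-6, max_iter = 100L) {
  fin <- tempfile(fileext = ".csv")
  fout <- tempfile(fileext = ".txt")
  utils::write.table(M, fin, sep = ",", row.names = FALSE, col.names = FALSE)
  script <- sprintf('
import numpy as np
M = np.loadtxt("%s", delimiter=",", ndmin=2)
r = %.17g; eps = %.17g
for _ in range(%d):
    E = M @ M
    I = np.power(E, r)
    I = I / I.sum(axis=0, keepdims=True)
    delta = np.abs(I - M).max()
    M = I
    if delta < eps:
        break
att = np.where(np.diag(M) > eps)[0]
if att.size == 0:
    att = np.arange(M.shape[0])
assign = []
for j in range(M.shape[1]):
    col = M[att, j]
    assign.append(int(att[col >= col.max() - eps**0.5].min()))
with open("%s", "w") as fh:
    fh.write(" ".join(str(a) for a in assign) + "\\n")
', fin, r, epsilon, max_iter, fout)
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", sf, stdout = TRUE, stderr = TRUE)
  stopifnot(file.exists(fout))
  as.integer(strsplit(readLines(fout), " ")[[1L]])
}

# --- random instance generators ---------------------------------------

# random labelled partition instances for concordance checks
random_partition_instance <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("r%03d", seq_len(n))
  truth <- stats::setNames(sample(sprintf("sp%02d", 1:max(2, n %/% 4)), n,
                                  replace = TRUE), ids)
  part <- new_partition(stats::setNames(
    sample(sprintf("c%02d", 1:max(2, n %/% 3)), n, replace = TRUE), ids))
  list(truth = truth, partition = part)
}

# random symmetric weighted graph as a stochastic matrix
random_stoch_matrix <- function(n, seed, p_edge = 0.4) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (stats::runif(1) < p_edge) W[i, j] <- W[j, i] <- stats::runif(1)
  diag(W) <- 1
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(W) <- list(ids, ids)
  structure(list(node_ids = ids, M = sweep(W, 2, colSums(W), "/")),
            class = "stoch_matrix")
}

# small simulated instance with varied clustering difficulty
random_sim_instance <- function(seed) {
  set.seed(seed)
  n_species <- sample(5:25, 1)
  per <- sample(2:12, 1)
  intra <- stats::runif(1, 0, 0.02)
  nn <- stats::runif(1, max(intra + 0.005, 0.025), 0.12)
  simulate_barcodes(sim_spec(n_species = n_species, seqs_per_species = per,
                             intra_max = intra, nn_target = nn,
                             seed = seed))
}
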