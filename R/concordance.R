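# Concordance between a partition and prior taxonomy: the four
# species-to-OTU association categories (MATCH, SPLIT, MERGE, MIXTURE) on
# both the species and the OTU side, and the clustering F-measure.

#' Classify species and OTUs into concordance categories
#'
#' Species side: a species is a MATCH when all its specimens sit in an OTU
#' with no other members; a SPLIT when it spreads over two or more OTUs
#' that each have no other members; a MERGE when it sits in a single OTU
#' shared with another species; and a MIXTURE when its placement involves
#' both a merge and a split. OTU side (symmetric): an OTU MATCHes when it
#' contains exactly all members of exactly one species, is a MERGE when it
#' holds two or more complete species, a SPLIT part when it holds a proper
#' subset of a single species, and a MIXTURE otherwise. Records without a
#' species label are excluded from scoring but may remain in the
#' partition.
#'
#' @param partition A [new_partition()].
#' @param truth Named character vector, sequence id to species.
#' @return A `concordance` object: `species_category`, `otu_category`,
#'   `counts`, `percent` (species side), `otu_counts`, `n_species`,
#'   `n_otus` (clusters holding at least one labelled record),
#'   `n_otus_total`, and `f_measure`.
#' @export
classify_species <- function(partition, truth) {
  truth <- truth[!is.na(truth)]
  if (!length(truth)) stop("no labelled records to score")
  missing <- setdiff(names(truth), names(partition))
  if (length(missing))
    stop("labelled record absent from partition: ", missing[1L])
  ids <- names(truth)
  cl <- as.character(unclass(partition)[ids])
  sp <- as.character(truth)
  tab <- table(species = sp, otu = cl)
  species <- rownames(tab)
  otus <- colnames(tab)
  sp_sizes <- rowSums(tab)
  otu_sizes <- colSums(tab)

  otu_pure <- colSums(tab > 0) == 1L            # one species only
  sp_single <- rowSums(tab > 0) == 1L           # one OTU only
  # OTU holds the complete membership of each species it touches
  otu_complete <- vapply(seq_along(otus), function(j) {
    touched <- tab[, j] > 0
    all(tab[touched, j] == sp_sizes[touched])
  }, TRUE)

  species_category <- vapply(seq_along(species), function(i) {
    in_otus <- which(tab[i, ] > 0)
    pure <- otu_pure[in_otus]
    if (length(in_otus) == 1L) {
      if (pure) "MATCH" else "MERGE"
    } else {
      if (all(pure)) "SPLIT" else "MIXTURE"
    }
  }, "")
  names(species_category) <- species

  otu_category <- vapply(seq_along(otus), function(j) {
    nsp <- sum(tab[, j] > 0)
    if (nsp == 1L) {
      i <- which(tab[, j] > 0)
      if (tab[i, j] == sp_sizes[i]) "MATCH" else "SPLIT"
    } else if (otu_complete[j]) "MERGE" else "MIXTURE"
  }, "")
  names(otu_category) <- otus

  cats <- c("MATCH", "SPLIT", "MERGE", "MIXTURE")
  counts <- vapply(cats, function(cc) sum(species_category == cc), 0L)
  otu_counts <- vapply(cats, function(cc) sum(otu_category == cc), 0L)
  structure(list(
    species_category = species_category,
    otu_category = otu_category,
    counts = counts,
    percent = 100 * counts / length(species),
    otu_counts = otu_counts,
    n_species = length(species),
    n_otus = length(otus),
    n_otus_total = n_clusters(partition),
    f_measure = f_measure(partition, truth)
  ), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Concordance: %d species vs %d OTUs (F-measure %.3f)\n",
              x$n_species, x$n_otus, x$f_measure))
  for (cc in names(x$counts))
    cat(sprintf("  %-8s %4d species (%.1f%%)\n", cc, x$counts[[cc]],
                x$percent[[cc]]))
  invisible(x)
}

#' Clustering F-measure
#'
#' For species `i` and cluster `j` with `n_i`, `n_j` and `n_ij` members,
#' precision `P = n_ij / n_j`, recall `R = n_ij / n_i` and
#' `F(i, j) = 2PR / (P + R)`. The score is
#' `sum_i (n_i / n) max_j F(i, j)`, in `(0, 1]`, and equals 1 exactly when
#' the partition reproduces the species grouping.
#'
#' @inheritParams classify_species
#' @return Numeric score.
#' @export
f_measure <- function(partition, truth) {
  truth <- truth[!is.na(truth)]
  if (!length(truth)) stop("no labelled records to score")
  missing <- setdiff(names(truth), names(partition))
  if (length(missing))
    stop("labelled record absent from partition: ", missing[1L])
  cl <- as.character(unclass(partition)[names(truth)])
  tab <- table(as.character(truth), cl)
  n_i <- rowSums(tab)
  n_j <- colSums(tab)
  n <- sum(tab)
  fmax <- vapply(seq_len(nrow(tab)), function(i) {
    P <- tab[i, ] / n_j
    R <- tab[i, ] / n_i[i]
    f <- ifelse(P + R > 0, 2 * P * R / (P + R), 0)
    max(f)
  }, 0)
  sum(n_i / n * fmax)
}

#' Aggregate concordance reports across datasets
#'
#' Pooled percentages are species-weighted (total species per category
#' over total species across reports); per-dataset means are also
#' reported to disambiguate the two conventions. Includes the
#' OTU-count/species-count pairs needed for count-correspondence
#' regressions.
#'
#' @param reports List of `concordance` objects.
#' @return List of class `concordance_summary` with `pooled_percent`,
#'   `mean_percent`, `total_counts`, and a per-dataset data frame
#'   `datasets` (n_species, n_otus, f_measure, percentage per category).
#' @export
summarize_concordance <- function(reports) {
  if (!length(reports)) stop("need at least one report")
  stopifnot(all(vapply(reports, inherits, TRUE, "concordance")))
  cats <- c("MATCH", "SPLIT", "MERGE", "MIXTURE")
  counts <- vapply(reports, function(r) r$counts[cats], integer(4L))
  counts <- matrix(counts, nrow = 4L,
                   dimnames = list(cats, NULL))
  nsp <- vapply(reports, `[[`, 0L, "n_species")
  pct <- sweep(counts, 2L, nsp, "/") * 100
  datasets <- data.frame(
    n_species = nsp,
    n_otus = vapply(reports, `[[`, 0L, "n_otus_total"),
    f_measure = vapply(reports, `[[`, 0, "f_measure"),
    t(pct))
  structure(list(
    pooled_percent = 100 * rowSums(counts) / sum(nsp),
    mean_percent = rowMeans(pct),
    total_counts = rowSums(counts),
    datasets = datasets
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Concordance across %d dataset(s), %d species\n",
              nrow(x$datasets), sum(x$datasets$n_species)))
  for (cc in names(x$pooled_percent))
    cat(sprintf("  %-8s pooled %5.1f%%  per-dataset mean %5.1f%%\n",
                cc, x$pooled_percent[[cc]], x$mean_percent[[cc]]))
  invisible(x)
}
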