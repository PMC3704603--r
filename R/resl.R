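#' Refined single-linkage OTU delineation
#'
#' Fits the full OTU-delineation procedure to a set of COI barcode
#' sequences: stage-1 quality filtering, frame-anchored alignment,
#' single-linkage clustering at threshold `t`, and Markov-clustering
#' refinement of eligible clusters with Silhouette-based selection over
#' the inflation grid. The result holds both the initial and the refined
#' partition (the OTU boundaries) together with per-stage diagnostics.
#'
#' @param x Input sequences: a [seq_records] data frame, a named
#'   character vector, or a FASTA file path.
#' @param t Single-linkage threshold as a proportion (default 0.022).
#' @param inflation Inflation grid for refinement (default
#'   `seq(1.0, 2.4, by = 0.2)`).
#' @param config Full [resl_config()]; overrides `t` and `inflation` when
#'   supplied.
#' @param meta Optional metadata data frame (see [read_metadata_tsv()])
#'   supplying species labels.
#' @param qc Run the stage-1 quality filter (default `TRUE`).
#' @param contaminants Optional contaminant references for QC.
#' @return An object of class `resl` with components `records` (input),
#'   `aligned` (post-QC aligned records), `qc` (the `qc_report`),
#'   `config`, `slc` (initial partition), `otus` (refined partition),
#'   `groups` and `refinement` (per-group selected inflation, cluster
#'   count and silhouette), and `concordance` (when species labels are
#'   present).
#' @examples
#' sim <- simulate_barcodes(sim_spec(n_species = 5, seqs_per_species = 4,
#'                                   seed = 7))
#' fit <- resl(sim$records)
#' fit
#' @export
resl <- function(x, t = 0.022, inflation = seq(1.0, 2.4, by = 0.2),
                 config = NULL, meta = NULL, qc = TRUE,
                 contaminants = NULL) {
  cfg <- config %||% resl_config(t = t, inflation_grid = inflation)
  records <- as_seq_records(x)
  if (!is.null(meta)) records <- join_metadata(records, meta)
  if (!nrow(records)) stop("no input sequences")
  qc_rep <- if (qc) qc_filter(records, cfg, contaminants)
    else list(passed = records$id, rejected = character())
  kept <- records[records$id %in% qc_rep$passed, , drop = FALSE]
  if (!nrow(kept)) stop("no sequences passed quality control")
  aligned <- frame_align(kept, cfg)
  graph <- build_dist_graph(aligned, cutoff = cfg$founder_cutoff,
                            min_overlap = cfg$min_overlap)
  slc <- slc_streaming(aligned, t = cfg$t, cfg = cfg)
  ref <- resl_refine(slc, aligned, cfg, graph = graph, details = TRUE)
  conc <- NULL
  truth <- stats::setNames(aligned$species, aligned$id)
  if (any(!is.na(truth)))
    conc <- classify_species(ref$partition, truth)
  structure(list(
    records = records, aligned = aligned, qc = qc_rep, config = cfg,
    graph = graph, slc = slc, otus = ref$partition, groups = ref$groups,
    refinement = ref$refinement, concordance = conc,
    call = match.call()
  ), class = "resl")
}

#' Extract the OTU partition from a fitted object
#'
#' @param object A `resl` fit.
#' @param stage `"refined"` (default) or `"slc"` for the initial
#'   single-linkage partition.
#' @return A [new_partition()].
#' @export
otu_partition <- function(object, stage = c("refined", "slc")) {
  stopifnot(inherits(object, "resl"))
  switch(match.arg(stage), refined = object$otus, slc = object$slc)
}

#' @export
print.resl <- function(x, ...) {
  cat("Refined single-linkage OTU delineation\n")
  cat(sprintf("  %d sequences in, %d passed QC\n",
              nrow(x$records), nrow(x$aligned)))
  cat(sprintf("  t = %.1f%%, founder cutoff = %.1f%%\n",
              100 * x$config$t, 100 * x$config$founder_cutoff))
  cat(sprintf("  initial clusters: %d; refined OTUs: %d (%d group(s) refined)\n",
              n_clusters(x$slc), n_clusters(x$otus), length(x$groups)))
  if (!is.null(x$concordance))
    cat(sprintf("  concordance: %.1f%% MATCH, F-measure %.3f\n",
                x$concordance$percent[["MATCH"]], x$concordance$f_measure))
  invisible(x)
}

#' @export
summary.resl <- function(object, ...) {
  sizes <- table(unclass(object$otus))
  ref <- if (length(object$refinement))
    data.frame(
      group = seq_along(object$refinement),
      n = lengths(object$groups),
      r = vapply(object$refinement, `[[`, 0, "r"),
      k = vapply(object$refinement, `[[`, 0L, "k"),
      silhouette = vapply(object$refinement, `[[`, 0, "silhouette"))
  else NULL
  structure(list(
    n_in = nrow(object$records),
    n_passed = nrow(object$aligned),
    qc_reasons = table(object$qc$rejected),
    n_otus = n_clusters(object$otus),
    size_distribution = table(factor(as.integer(sizes))),
    refinement = ref,
    concordance = object$concordance,
    config = object$config
  ), class = "summary.resl")
}

#' @export
print.summary.resl <- function(x, ...) {
  cat(sprintf("Sequences: %d in, %d passed QC\n", x$n_in, x$n_passed))
  if (length(x$qc_reasons))
    for (r in names(x$qc_reasons))
      cat(sprintf("  rejected %s: %d\n", r, x$qc_reasons[[r]]))
  cat(sprintf("OTUs: %d\n", x$n_otus))
  cat("  cluster sizes: ")
  print(x$size_distribution)
  if (!is.null(x$refinement)) {
    cat("Refined groups (selected inflation r, clusters k, silhouette):\n")
    print(x$refinement, row.names = FALSE)
  }
  if (!is.null(x$concordance)) print(x$concordance)
  invisible(x)
}

#' Assign new sequences to fitted OTUs
#'
#' Applies the founder rule: a new sequence linking at `<= t` to a member
#' of an existing OTU is assigned its label; one farther than the founder
#' cutoff from everything (or linking to nothing at `t`) is reported as a
#' new founder (`"<new>"`). Sequences must be in the fit's alignment
#' coordinate system.
#'
#' @param object A `resl` fit.
#' @param newdata [seq_records] (or coercible) of new sequences.
#' @param ... Unused.
#' @return Named character vector: OTU label or `"<new>"` per sequence.
#' @export
predict.resl <- function(object, newdata, ...) {
  newdata <- as_seq_records(newdata)
  cfg <- object$config
  ref_enc <- encode_seqs(object$aligned)
  out <- stats::setNames(character(nrow(newdata)), newdata$id)
  labels <- unclass(object$otus)[rownames(ref_enc)]
  for (i in seq_len(nrow(newdata))) {
    # placeholder id avoids collisions with ids already in the fit
    enc <- encode_seqs(seq_records(c(".query.", rownames(ref_enc)),
                                   c(newdata$seq[i], object$aligned$seq)))
    d <- dist_to_many(enc, 1L, seq_len(nrow(ref_enc)) + 1L)
    hit <- d$sites >= cfg$min_overlap & le_thr(d$mism, d$sites, cfg$t)
    out[i] <- if (any(hit)) {
      labs <- unique(labels[hit])
      sort(labs)[1L]
    } else "<new>"
  }
  out
}

#' @export
plot.resl <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  sizes <- as.integer(table(unclass(x$otus)))
  graphics::hist(sizes, breaks = seq(0.5, max(sizes) + 0.5, by = 1),
                 main = "OTU sizes", xlab = "members", col = "grey80")
  if (length(x$refinement)) {
    sil <- vapply(x$refinement, `[[`, 0, "silhouette")
    k <- vapply(x$refinement, `[[`, 0L, "k")
    graphics::plot(k, sil, xlab = "clusters after refinement",
                   ylab = "silhouette", main = "Refined groups", pch = 19)
  } else {
    graphics::plot.new()
    graphics::title(main = "No groups refined")
  }
  invisible(x)
}
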