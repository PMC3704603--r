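# Stage-1 quality checks (length, ambiguity, stop codons, contaminant
# screen) and the frame-anchored alignment contract. COI barcodes are
# overwhelmingly indel-free, so codon-frame anchoring plus pass-through of
# pre-aligned input reproduces the distance structure the clustering
# needs without a full profile aligner.

# Stop codons of a genetic code, derived from seqinr's translation tables.
stop_codons <- function(numcode) {
  codons <- apply(expand.grid(c("a", "c", "g", "t"), c("a", "c", "g", "t"),
                              c("a", "c", "g", "t"),
                              stringsAsFactors = FALSE)[, 3:1], 1, paste,
                  collapse = "")
  aa <- vapply(codons, function(cd)
    seqinr::translate(strsplit(cd, "")[[1L]], numcode = numcode), "")
  toupper(codons[aa == "*"])
}

# Count internal stop codons (complete codons, excluding the final one)
# when reading `seq` from 1-based offset `frame` (0, 1, or 2). Codons with
# ambiguity codes or gaps are never counted as stops.
count_internal_stops <- function(seq, frame, stops) {
  s <- substring(seq, frame + 1L)
  n_codon <- nchar(s) %/% 3L
  if (n_codon < 2L) return(0L)
  starts <- 3L * (seq_len(n_codon - 1L) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  sum(codons %in% stops)
}

best_frame <- function(seq, stops) {
  counts <- vapply(0:2, function(f) count_internal_stops(seq, f, stops), 0L)
  f <- which.min(counts) - 1L   # ties -> smallest offset
  list(frame = f, stops = counts[f + 1L], all = counts)
}

#' Stage-1 quality filter
#'
#' Applies, in order: minimum length (`min_len` non-gap nucleotides),
#' ambiguous-base proportion (rejected when strictly greater than
#' `max_ambig`), stop-codon screen (rejected when the best forward reading
#' frame still contains an internal stop codon under the configured
#' genetic code), and an optional contaminant screen (rejected when the
#' p-distance to any supplied contaminant reference falls below
#' `contaminant_cutoff`). Failures are report entries, never errors.
#'
#' @param records [seq_records] to screen.
#' @param cfg A [resl_config()].
#' @param contaminants Optional [seq_records] of contaminant references.
#' @return A `qc_report`: list with `passed` (ids) and `rejected` (named
#'   character vector of reason codes `TOO_SHORT`, `TOO_AMBIGUOUS`,
#'   `STOP_CODON`, `CONTAMINANT`). `passed` and `rejected` are disjoint and
#'   cover the input.
#' @export
qc_filter <- function(records, cfg = resl_config(), contaminants = NULL) {
  records <- as_seq_records(records)
  stops <- stop_codons(genetic_code_number(cfg$genetic_code))
  reasons <- character(0)
  for (i in seq_len(nrow(records))) {
    seq <- records$seq[i]
    bare <- gsub("-", "", seq, fixed = TRUE)
    n <- nchar(bare)
    n_ambig <- n - sum(strsplit(bare, "", fixed = TRUE)[[1L]] %in%
                         c("A", "C", "G", "T"))
    reason <- if (n < cfg$min_len) "TOO_SHORT"
      else if (n_ambig > cfg$max_ambig * n) "TOO_AMBIGUOUS"
      else if (best_frame(bare, stops)$stops > 0L) "STOP_CODON"
      else if (!is.null(contaminants) &&
               is_contaminant(bare, contaminants, cfg)) "CONTAMINANT"
      else NA_character_
    if (!is.na(reason)) reasons[records$id[i]] <- reason
  }
  rep <- list(passed = setdiff(records$id, names(reasons)),
              rejected = reasons)
  class(rep) <- "qc_report"
  stage_log("qc", "%d in, %d passed, %d rejected",
            nrow(records), length(rep$passed), length(rep$rejected))
  rep
}

is_contaminant <- function(seq, contaminants, cfg) {
  contaminants <- as_seq_records(contaminants)
  for (ref in gsub("-", "", contaminants$seq, fixed = TRUE)) {
    L <- min(nchar(seq), nchar(ref))
    d <- p_distance(substr(seq, 1L, L), substr(ref, 1L, L),
                    min_overlap = min(cfg$min_overlap, L))
    if (!is.na(d) && d < cfg$contaminant_cutoff) return(TRUE)
  }
  FALSE
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d passed, %d rejected\n",
              length(x$passed), length(x$rejected)))
  if (length(x$rejected)) {
    tab <- table(x$rejected)
    for (r in names(tab)) cat(sprintf("  %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Frame-anchored alignment
#'
#' If the input is already of equal length (pre-aligned, possibly with
#' gaps) it is returned unchanged. Otherwise each sequence is trimmed to
#' the forward reading frame with the fewest internal stop codons (ties
#' broken toward the smallest offset), then anchored to the longest
#' sequence by the codon shift (multiple of 3) minimizing the pairwise
#' mismatch proportion, and padded with terminal gaps to a common length.
#' Non-gap characters are never altered; stripping gaps recovers each
#' trimmed input exactly.
#'
#' @param records [seq_records] that passed QC.
#' @param cfg A [resl_config()].
#' @return Aligned [seq_records] of equal length.
#' @export
frame_align <- function(records, cfg = resl_config()) {
  records <- as_seq_records(records)
  if (nrow(records) < 1L) return(records)
  lens <- nchar(records$seq)
  if (length(unique(lens)) == 1L) return(records)  # pass-through contract
  stops <- stop_codons(genetic_code_number(cfg$genetic_code))
  trimmed <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    seq <- gsub("-", "", records$seq[i], fixed = TRUE)
    bf <- best_frame(seq, stops)
    if (bf$stops > 0L)
      stop("NO_FRAME: no stop-free reading frame for sequence '",
           records$id[i], "'")
    trimmed[i] <- substring(seq, bf$frame + 1L)
  }
  tl <- nchar(trimmed)
  ref_i <- order(-tl, records$id)[1L]   # longest, ties -> smallest id
  ref <- trimmed[ref_i]
  Lref <- tl[ref_i]
  out <- records
  for (i in seq_len(nrow(records))) {
    L <- tl[i]
    shifts <- seq(0L, Lref - L, by = 3L)
    if (!length(shifts)) shifts <- 0L
    best_s <- shifts[1L]; best_d <- Inf
    for (s in shifts) {
      a <- trimmed[i]
      b <- substr(ref, s + 1L, s + L)
      d <- p_distance(a, b, min_overlap = min(cfg$min_overlap, L))
      if (!is.na(d) && d < best_d) { best_d <- d; best_s <- s }
    }
    out$seq[i] <- paste0(strrep("-", best_s), trimmed[i],
                         strrep("-", Lref - L - best_s))
  }
  stage_log("align", "%d sequences anchored to length %d", nrow(out), Lref)
  validate_seq_records(out)
}
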