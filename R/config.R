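#' Configuration for refined single-linkage OTU delineation
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' All distances and thresholds are proportions internally (e.g. `0.022`);
#' the command-line interface accepts and prints percentages (`2.2`).
#'
#' @param t Single-linkage clustering threshold, as a proportion. Sequences
#'   linked at p-distance `<= t` fall in the same initial cluster. Default
#'   0.022 (2.2%).
#' @param founder_cutoff Founder rule cutoff, as a proportion. A new
#'   sequence farther than this from every existing cluster founds a new
#'   one. Default `2 * t` (4.4%); also the edge cutoff of the refinement
#'   graph.
#' @param inflation_grid Ordered vector of Markov-clustering inflation
#'   parameters tried during refinement. Default `seq(1.0, 2.4, by = 0.2)`
#'   (eight candidates).
#' @param min_len Minimum number of non-gap nucleotides a record must carry
#'   to pass quality control. Default 500.
#' @param max_ambig Maximum tolerated proportion of ambiguous bases
#'   (strictly greater is rejected). Default 0.01.
#' @param genetic_code Genetic code used for stop-codon screening. One of
#'   `"invertebrate mitochondrial"` (default), `"vertebrate mitochondrial"`,
#'   `"standard"`, or an NCBI translation-table number.
#' @param epsilon Max-norm convergence tolerance of the Markov-clustering
#'   iteration. Default 1e-6.
#' @param max_iter Iteration cap for Markov clustering. Default 100.
#' @param min_overlap Minimum number of jointly unambiguous sites required
#'   for a pairwise distance to be defined. Default 300.
#' @param contaminant_cutoff p-distance below which a record is flagged as
#'   matching a contaminant reference. Default 0.05.
#' @param seed Optional integer seed recorded with the configuration.
#'
#' @return An object of class `resl_config` (a named list).
#' @examples
#' cfg <- resl_config()
#' cfg$t
#' @export
resl_config <- function(t = 0.022,
                        founder_cutoff = 2 * t,
                        inflation_grid = seq(1.0, 2.4, by = 0.2),
                        min_len = 500L,
                        max_ambig = 0.01,
                        genetic_code = "invertebrate mitochondrial",
                        epsilon = 1e-6,
                        max_iter = 100L,
                        min_overlap = 300L,
                        contaminant_cutoff = 0.05,
                        seed = NULL) {
  stopifnot(is.numeric(t), length(t) == 1L, is.numeric(founder_cutoff))
  if (!(t > 0 && t < founder_cutoff && founder_cutoff <= 1))
    stop("require 0 < t < founder_cutoff <= 1 (got t = ", t,
         ", founder_cutoff = ", founder_cutoff, ")")
  inflation_grid <- as.numeric(inflation_grid)
  if (length(inflation_grid) < 1L || any(inflation_grid < 1.0) ||
      is.unsorted(inflation_grid, strictly = TRUE))
    stop("inflation_grid must be strictly increasing with all values >= 1.0")
  if (min_len < 1L) stop("min_len must be positive")
  if (max_ambig < 0 || max_ambig > 1) stop("max_ambig must be in [0, 1]")
  cfg <- list(
    t = t,
    founder_cutoff = founder_cutoff,
    inflation_grid = inflation_grid,
    min_len = as.integer(min_len),
    max_ambig = max_ambig,
    genetic_code = genetic_code,
    epsilon = epsilon,
    max_iter = as.integer(max_iter),
    min_overlap = as.integer(min_overlap),
    contaminant_cutoff = contaminant_cutoff,
    seed = seed
  )
  class(cfg) <- "resl_config"
  cfg
}

#' @export
print.resl_config <- function(x, ...) {
  cat("RESL configuration\n")
  cat(sprintf("  t (link threshold):  %.3f (%.1f%%)\n", x$t, 100 * x$t))
  cat(sprintf("  founder cutoff:      %.3f (%.1f%%)\n",
              x$founder_cutoff, 100 * x$founder_cutoff))
  cat(sprintf("  inflation grid:      %s\n",
              paste(format(x$inflation_grid), collapse = ", ")))
  cat(sprintf("  QC: min_len %d bp, max_ambig %.1f%%, code '%s'\n",
              x$min_len, 100 * x$max_ambig, x$genetic_code))
  invisible(x)
}

# Map a genetic-code name to the NCBI translation table number used by
# seqinr. Only stop-codon positions matter downstream.
genetic_code_number <- function(code) {
  if (is.numeric(code)) return(as.integer(code))
  switch(tolower(code),
    "invertebrate mitochondrial" = 5L,
    "invert-mito" = 5L,
    "vertebrate mitochondrial" = 2L,
    "vert-mito" = 2L,
    "standard" = 1L,
    stop("unknown genetic code: ", code)
  )
}

#' Read and write flat key=value configuration files
#'
#' The on-disk format mirrors [resl_config()]: one `key = value` pair per
#' line, `#` comments allowed. Thresholds in the file are proportions.
#'
#' @param path File path.
#' @return `read_config()` returns a `resl_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  args <- list()
  for (i in seq_along(keys)) {
    v <- vals[i]
    args[[keys[i]]] <- if (keys[i] %in% c("genetic_code")) v
      else if (keys[i] == "inflation_grid")
        as.numeric(strsplit(v, ",", fixed = TRUE)[[1L]])
      else as.numeric(v)
  }
  do.call(resl_config, args)
}

#' @rdname read_config
#' @param cfg A `resl_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "resl_config"))
  flat <- cfg[!vapply(cfg, is.null, TRUE)]
  lines <- vapply(names(flat), function(k) {
    v <- flat[[k]]
    sprintf("%s = %s", k, paste(format(v, scientific = FALSE), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Structured stage logging: counts in/out and rejection reasons. Quiet by
# default; toggled with options(binclust.verbose = TRUE).
stage_log <- function(stage, ...) {
  if (isTRUE(getOption("binclust.verbose", FALSE)))
    message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}
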