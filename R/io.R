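# Readers and writers for the external formats the tool touches: FASTA
# sequence files (with optional key=value header metadata), metadata TSV,
# and partition TSV.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")
AMBIG_CHARS <- setdiff(IUPAC_CHARS, c("A", "C", "G", "T", "-"))

#' Barcode sequence records
#'
#' A set of barcode reads is a data frame of class `seq_records` with
#' columns `id` (unique, non-empty), `seq` (IUPAC nucleotide string; `-`
#' only in aligned input) and `species` (optional Linnaean binomial, `NA`
#' when unknown). Additional columns carry free metadata (country,
#' institution, ...).
#'
#' @param id Character vector of unique sequence identifiers.
#' @param seq Character vector of IUPAC nucleotide strings.
#' @param species Optional character vector of species labels (`NA` for
#'   unlabelled records).
#' @param ... Further metadata columns of the same length.
#' @return A `seq_records` data frame.
#' @examples
#' seq_records(c("s1", "s2"), c("ACGT", "ACGA"), species = c("A sp", NA))
#' @export
seq_records <- function(id, seq, species = NA_character_, ...) {
  df <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                   species = rep_len(as.character(species), length(id)),
                   ..., stringsAsFactors = FALSE)
  validate_seq_records(df)
}

validate_seq_records <- function(df) {
  stopifnot(is.data.frame(df), all(c("id", "seq") %in% names(df)))
  if (!"species" %in% names(df)) df$species <- NA_character_
  if (any(!nzchar(df$id) | is.na(df$id))) stop("sequence ids must be non-empty")
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1L])
  if (any(!nzchar(df$seq) | is.na(df$seq))) {
    stop("empty sequence for id: ", df$id[which(!nzchar(df$seq) | is.na(df$seq))[1L]])
  }
  for (i in seq_len(nrow(df))) {
    chars <- strsplit(df$seq[i], "", fixed = TRUE)[[1L]]
    bad <- which(!chars %in% IUPAC_CHARS)
    if (length(bad))
      stop(sprintf("illegal character '%s' at position %d in sequence '%s'",
                   chars[bad[1L]], bad[1L], df$id[i]))
  }
  rownames(df) <- NULL
  class(df) <- c("seq_records", "data.frame")
  df
}

as_seq_records <- function(x) {
  if (inherits(x, "seq_records")) {
    if (!"species" %in% names(x)) x$species <- NA_character_
    return(x)
  }
  if (is.character(x) && !is.null(names(x)))
    return(seq_records(names(x), unname(x)))
  if (is.data.frame(x)) return(validate_seq_records(x))
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_fasta(x))
  stop("cannot interpret input as sequence records")
}

#' Read barcode sequences from FASTA
#'
#' The header token before the first whitespace becomes the record id; the
#' remainder of the header is parsed as `key=value` metadata (values may
#' contain spaces; a new key starts at the next ` word=` token). A
#' `species=` entry populates the species label. Sequences are upper-cased.
#' Windows and Unix line endings are both accepted.
#'
#' @param path FASTA file path.
#' @return A [seq_records] data frame (zero rows for an empty file).
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 species=Apis mellifera", "ACGT"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(seq_records(character(), character())[0, , drop = FALSE])
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not FASTA: first line does not start with '>'")
  idx <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, "", collapse = "")
  # headers with no sequence lines yield empty strings
  full <- character(sum(hdr))
  full[as.integer(names(seqs))] <- seqs
  ids <- sub("\\s.*$", "", headers)
  rest <- trimws(sub("^\\S+", "", headers))
  meta <- lapply(rest, parse_header_meta)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate sequence id: ", dup[1L])
  species <- vapply(meta, function(m) m[["species"]] %||% NA_character_, "")
  df <- data.frame(id = ids, seq = toupper(full), species = species,
                   stringsAsFactors = FALSE)
  extra_keys <- setdiff(unique(unlist(lapply(meta, names))), "species")
  for (k in extra_keys)
    df[[k]] <- vapply(meta, function(m) m[[k]] %||% NA_character_, "")
  validate_seq_records(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_header_meta <- function(rest) {
  if (!nzchar(rest)) return(list())
  # split at tokens that open a new key=...; values may contain spaces
  starts <- gregexpr("(^|\\s)[A-Za-z_][A-Za-z0-9_]*=", rest)[[1L]]
  if (starts[1L] == -1L) return(list())
  starts <- as.integer(starts)
  ends <- c(starts[-1L] - 1L, nchar(rest))
  out <- list()
  for (i in seq_along(starts)) {
    piece <- trimws(substr(rest, starts[i], ends[i]))
    eq <- regexpr("=", piece, fixed = TRUE)
    out[[substr(piece, 1L, eq - 1L)]] <- trimws(substr(piece, eq + 1L, nchar(piece)))
  }
  out
}

#' Write sequence records to FASTA
#'
#' Headers carry the id plus `species=` (when present), reproducing the
#' dialect [read_fasta()] parses; the round trip is lossless.
#'
#' @param records A [seq_records] data frame.
#' @param path Output file path.
#' @export
write_fasta <- function(records, path) {
  records <- as_seq_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- paste0(">", records$id[i])
    if (!is.na(records$species[i]))
      hdr <- paste0(hdr, " species=", records$species[i])
    writeLines(c(hdr, records$seq[i]), con)
  }
  invisible(path)
}

#' Read per-sequence metadata from TSV
#'
#' Requires at least the columns `sequence_id` and `species`; all other
#' columns are kept as free metadata. Empty species cells yield no species
#' label (`NA`).
#'
#' @param path TSV file path with a header row.
#' @return Data frame keyed by `sequence_id`.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  for (col in c("sequence_id", "species"))
    if (!col %in% names(df)) stop("missing required column: ", col)
  dup <- df$sequence_id[duplicated(df$sequence_id)]
  if (length(dup)) stop("duplicated sequence_id: ", dup[1L])
  df$species[!nzchar(df$species)] <- NA_character_
  rownames(df) <- NULL
  df
}

#' Attach metadata to sequence records
#'
#' @param records A [seq_records] data frame.
#' @param meta A metadata data frame from [read_metadata_tsv()].
#' @return `records` with species labels (and extra metadata columns)
#'   filled in from `meta` by id.
#' @export
join_metadata <- function(records, meta) {
  records <- as_seq_records(records)
  m <- match(records$id, meta$sequence_id)
  hit <- !is.na(m)
  records$species[hit] <- meta$species[m[hit]]
  for (k in setdiff(names(meta), c("sequence_id", "species"))) {
    if (!k %in% names(records)) records[[k]] <- NA_character_
    records[[k]][hit] <- meta[[k]][m[hit]]
  }
  validate_seq_records(records)
}
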