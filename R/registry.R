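# Persistent OTU registry: stable BOLD-style identifiers, incremental
# assignment of new sequences, merge/split lifecycle, decimalized expert
# partitions and compliance flags. Persistence is a human-readable
# append-only event log plus a derived JSON snapshot; replaying the log
# from empty reproduces the registry state exactly, so original
# identifiers are never lost.
#
# Audit events: FOUND, JOIN, MERGE, SPLIT, MOVE, PARTITION, plus FLAG
# (an extension: compliance-flag changes must be evented for the replay
# invariant to hold).

#' Next registry identifier
#'
#' Identifiers have the form `BOLD:` + three uppercase letters + four
#' digits. From nothing the first identifier is `BOLD:AAA0001`; digits
#' increment to 9999, then the letters increment in big-endian base-26
#' (`AAA` to `AAB`) with the digits resetting to 0000. Identifiers are
#' never reused.
#'
#' @param last The previously issued URI, or `NULL` for the first.
#' @return The next URI string.
#' @examples
#' next_uri(NULL)            # "BOLD:AAA0001"
#' next_uri("BOLD:AAA9999")  # "BOLD:AAB0000"
#' @export
next_uri <- function(last = NULL) {
  if (is.null(last) || is.na(last)) return("BOLD:AAA0001")
  m <- regmatches(last, regexec("^BOLD:([A-Z]{3})([0-9]{4})$", last))[[1L]]
  if (length(m) != 3L) stop("invalid URI: ", last)
  letters3 <- m[2L]
  num <- as.integer(m[3L])
  if (num < 9999L) return(sprintf("BOLD:%s%04d", letters3, num + 1L))
  if (letters3 == "ZZZ") stop("registry identifier space exhausted (ZZZ9999)")
  ls <- match(strsplit(letters3, "", fixed = TRUE)[[1L]], LETTERS)
  for (i in 3:1) {
    if (ls[i] < 26L) { ls[i] <- ls[i] + 1L; break }
    ls[i] <- 1L
  }
  sprintf("BOLD:%s0000", paste(LETTERS[ls], collapse = ""))
}

#' Create an empty BIN registry
#'
#' @param cfg A [resl_config()] governing assignment thresholds and
#'   refinement.
#' @return A `bin_registry` object (functional: operations return an
#'   updated copy).
#' @export
bin_registry <- function(cfg = resl_config()) {
  structure(list(
    entries = list(),
    seqs = character(),
    registered_at = integer(),
    compliance = logical(),
    events = empty_events(),
    counter = 0L,
    last_uri = NULL,
    cfg = cfg
  ), class = "bin_registry")
}

empty_events <- function() data.frame(
  counter = integer(), event = character(), uris = character(),
  ids = character(), extra = character(), stringsAsFactors = FALSE)

#' @export
print.bin_registry <- function(x, ...) {
  active <- vapply(x$entries, function(e) e$status == "ACTIVE", TRUE)
  cat(sprintf("BIN registry: %d BINs (%d active), %d sequences, %d events\n",
              length(x$entries), sum(active), length(x$seqs),
              nrow(x$events)))
  invisible(x)
}

append_event <- function(reg, event, uris, ids = character(), extra = "") {
  reg$counter <- reg$counter + 1L
  reg$events <- rbind(reg$events, data.frame(
    counter = reg$counter, event = event,
    uris = paste(uris, collapse = ","),
    ids = paste(ids, collapse = ","), extra = extra,
    stringsAsFactors = FALSE))
  reg
}

# greedy deterministic t-cover over sorted member ids
recompute_reps <- function(reg, members) {
  members <- sort(members)
  if (length(members) <= 1L) return(members)
  enc <- encode_seqs(seq_records(members, reg$seqs[members]))
  reps <- 1L
  for (i in seq_along(members)[-1L]) {
    d <- dist_to_many(enc, i, reps)
    covered <- any(d$sites >= reg$cfg$min_overlap &
                     le_thr(d$mism, d$sites, reg$cfg$t))
    if (!covered) reps <- c(reps, i)
  }
  members[reps]
}

entry_flag <- function(reg, members) {
  comp <- reg$compliance[members]
  if (any(comp, na.rm = TRUE)) "GREEN" else "YELLOW"
}

# --- event application (shared by live operations and replay) ----------

apply_event <- function(reg, event, uris, ids, extra = "") {
  switch(event,
    FOUND = {
      uri <- uris
      reg$entries[[uri]] <- list(
        uri = uri, members = ids, reps = ids, founder = ids,
        status = "ACTIVE", into = NA_character_, partitions = NULL,
        flag = entry_flag(reg, ids), created = reg$counter)
      reg$last_uri <- uri
      reg
    },
    JOIN = {
      uri <- uris
      e <- reg$entries[[uri]]
      e$members <- c(e$members, ids)
      d <- tryCatch({
        enc <- encode_seqs(seq_records(c(ids, e$reps),
                                       reg$seqs[c(ids, e$reps)]))
        dist_to_many(enc, 1L, seq_along(e$reps) + 1L)
      }, error = function(err) NULL)
      covered <- !is.null(d) && any(d$sites >= reg$cfg$min_overlap &
                                      le_thr(d$mism, d$sites, reg$cfg$t))
      if (!covered) e$reps <- c(e$reps, ids)
      e$flag <- entry_flag(reg, e$members)
      reg$entries[[uri]] <- e
      reg
    },
    MERGE = {
      older <- uris[1L]; newer <- uris[2L]
      en <- reg$entries[[newer]]; eo <- reg$entries[[older]]
      eo$members <- sort(c(eo$members, en$members))
      eo$reps <- recompute_reps(reg, eo$members)
      eo$flag <- entry_flag(reg, eo$members)
      en$status <- "SYNONYMIZED"; en$into <- older
      en$members <- character(); en$reps <- character()
      reg$entries[[older]] <- eo
      reg$entries[[newer]] <- en
      reg
    },
    SPLIT = {
      src <- uris[1L]
      for (uri in uris[-1L]) {
        reg$entries[[uri]] <- list(
          uri = uri, members = character(), reps = character(),
          founder = NA_character_, status = "ACTIVE",
          into = NA_character_, partitions = NULL, flag = "YELLOW",
          created = reg$counter)
        reg$last_uri <- uri
      }
      reg
    },
    MOVE = {
      from <- uris[1L]; to <- uris[2L]
      ef <- reg$entries[[from]]; et <- reg$entries[[to]]
      ef$members <- setdiff(ef$members, ids)
      et$members <- sort(c(et$members, ids))
      if (is.na(et$founder) || !length(et$founder)) {
        ra <- reg$registered_at[et$members]
        et$founder <- et$members[order(ra, et$members)][1L]
      }
      ef$reps <- recompute_reps(reg, ef$members)
      et$reps <- recompute_reps(reg, et$members)
      ef$flag <- entry_flag(reg, ef$members)
      et$flag <- entry_flag(reg, et$members)
      reg$entries[[from]] <- ef
      reg$entries[[to]] <- et
      reg
    },
    PARTITION = {
      uri <- uris
      specs <- jsonlite::fromJSON(extra, simplifyVector = FALSE)
      reg$entries[[uri]]$partitions <- if (length(specs))
        match_decimal_partitions(reg, uri, specs) else NULL
      reg
    },
    FLAG = {
      comp <- jsonlite::fromJSON(extra, simplifyVector = TRUE)
      reg$compliance[names(comp)] <- as.logical(comp)
      for (uri in uris) {
        e <- reg$entries[[uri]]
        e$flag <- entry_flag(reg, e$members)
        reg$entries[[uri]] <- e
      }
      reg
    },
    stop("unknown event: ", event)
  )
}

emit <- function(reg, event, uris, ids = character(), extra = "") {
  reg <- append_event(reg, event, uris, ids, extra)
  apply_event(reg, event, uris, ids, extra)
}

# --- operations --------------------------------------------------------

#' Assign a new sequence to the registry
#'
#' If the record's p-distance to every active BIN's representatives
#' exceeds the founder cutoff (4.4%), it founds a new BIN. Otherwise the
#' candidate BINs are compared in full: a link at `<= t` joins that BIN,
#' and a record bridging two or more BINs merges them (the more recently
#' registered identifiers are synonymized into the oldest). A joined BIN
#' that has grown to three or more members with sequence variation is
#' re-refined by Markov clustering, which may split it (the founder's
#' group keeps the URI).
#'
#' @param reg A [bin_registry()].
#' @param record One-row [seq_records] (aligned to the registry's
#'   coordinate system) or a single named sequence.
#' @return List with `uri` (the active BIN the record landed in) and
#'   `registry` (updated state).
#' @export
registry_assign <- function(reg, record) {
  stopifnot(inherits(reg, "bin_registry"))
  record <- as_seq_records(record)
  stopifnot(nrow(record) == 1L)
  id <- record$id
  if (id %in% names(reg$seqs)) stop("record id already registered: ", id)
  if (length(reg$seqs) && nchar(record$seq) != nchar(reg$seqs[[1L]]))
    stop("record length differs from the registry alignment")
  cfg <- reg$cfg
  reg$seqs[id] <- record$seq
  reg$registered_at[id] <- reg$counter + 1L
  if (!(id %in% names(reg$compliance))) reg$compliance[id] <- FALSE

  active <- names(reg$entries)[vapply(reg$entries, function(e)
    e$status == "ACTIVE", TRUE)]
  joined <- character()
  if (length(active)) {
    all_reps <- unlist(lapply(active, function(u) reg$entries[[u]]$reps))
    rep_uri <- rep(active, vapply(active, function(u)
      length(reg$entries[[u]]$reps), 0L))
    enc <- encode_seqs(seq_records(c(id, all_reps),
                                   c(record$seq, reg$seqs[all_reps])))
    dr <- dist_to_many(enc, 1L, seq_along(all_reps) + 1L)
    defined <- dr$sites >= cfg$min_overlap
    near <- defined & le_thr(dr$mism, dr$sites, cfg$founder_cutoff)
    candidates <- unique(c(rep_uri[near], rep_uri[!defined]))
    for (uri in candidates) {
      mem <- reg$entries[[uri]]$members
      encm <- encode_seqs(seq_records(c(id, mem),
                                      c(record$seq, reg$seqs[mem])))
      dm <- dist_to_many(encm, 1L, seq_along(mem) + 1L)
      if (any(dm$sites >= cfg$min_overlap & le_thr(dm$mism, dm$sites, cfg$t)))
        joined <- c(joined, uri)
    }
  }
  if (!length(joined)) {
    uri <- next_uri(reg$last_uri)
    reg <- emit(reg, "FOUND", uri, id)
    return(list(uri = uri, registry = reg))
  }
  created <- vapply(joined, function(u) reg$entries[[u]]$created, 0L)
  joined <- joined[order(created)]
  target <- joined[1L]
  for (u in joined[-1L]) reg <- registry_merge(reg, target, u)
  reg <- emit(reg, "JOIN", target, id)
  reg <- maybe_rerefine(reg, target)
  list(uri = registry_resolve(reg, target), registry = reg)
}

# Re-run MCL refinement on a BIN that has grown to >= 3 members showing
# sequence variation; a multi-cluster outcome triggers a split.
maybe_rerefine <- function(reg, uri) {
  e <- reg$entries[[uri]]
  if (length(e$members) < 3L || !is.null(e$partitions)) return(reg)
  recs <- seq_records(e$members, reg$seqs[e$members])
  graph <- build_dist_graph(recs, cutoff = reg$cfg$founder_cutoff,
                            min_overlap = reg$cfg$min_overlap)
  if (all(graph$edges$mism == 0L) &&
      nrow(graph$edges) == choose(length(e$members), 2L))
    return(reg)  # no variation
  d_full <- pdist_d(pdist_matrix(encode_seqs(recs)), reg$cfg$min_overlap)
  res <- refine_group(e$members, graph, d_full, reg$cfg)
  if (res$k <= 1L) return(reg)
  groups <- unname(partition_members(res$partition))
  registry_split(reg, uri, groups)
}

#' Merge two BINs
#'
#' Following taxonomic convention the more recently registered BIN is
#' synonymized into the older one; its members transfer and its URI
#' resolves (transitively) to the surviving BIN. BINs carrying decimal
#' partitions must be cleared before they can merge.
#'
#' @param reg A [bin_registry()].
#' @param a,b URIs of two active BINs (either order).
#' @return Updated registry.
#' @export
registry_merge <- function(reg, a, b) {
  for (u in c(a, b)) {
    e <- reg$entries[[u]]
    if (is.null(e)) stop("unknown URI: ", u)
    if (e$status != "ACTIVE") stop("cannot merge synonymized BIN: ", u)
    if (!is.null(e$partitions))
      stop("BIN ", u, " carries decimal partitions; clear them before merging")
  }
  first <- if (reg$entries[[a]]$created <= reg$entries[[b]]$created) a else b
  second <- setdiff(c(a, b), first)
  emit(reg, "MERGE", c(first, second))
}

#' Split a BIN into groups
#'
#' The group containing the original founder keeps the source URI; every
#' other group receives a fresh URI (groups ordered by their earliest
#' registered member). MOVE events record every relocated id.
#'
#' @param reg A [bin_registry()].
#' @param source URI of the BIN to split.
#' @param groups List of disjoint member-id vectors whose union is the
#'   BIN's membership (at least two groups).
#' @return Updated registry.
#' @export
registry_split <- function(reg, source, groups) {
  e <- reg$entries[[source]]
  if (is.null(e)) stop("unknown URI: ", source)
  if (e$status != "ACTIVE") stop("cannot split synonymized BIN: ", source)
  if (!is.null(e$partitions))
    stop("BIN ", source, " carries decimal partitions; clear them before splitting")
  if (length(groups) < 2L) stop("a split needs at least two groups")
  flat <- unlist(groups)
  if (anyDuplicated(flat) || !setequal(flat, e$members))
    stop("groups must be disjoint and cover the BIN's members exactly")
  has_founder <- vapply(groups, function(g) e$founder %in% g, TRUE)
  if (!any(has_founder)) stop("founder missing from all groups")
  keep <- which(has_founder)
  others <- groups[-keep]
  ord <- order(vapply(others, function(g)
    min(reg$registered_at[g]), 0L),
    vapply(others, min, ""))
  others <- others[ord]
  new_uris <- character(length(others))
  last <- reg$last_uri
  for (i in seq_along(others)) { last <- next_uri(last); new_uris[i] <- last }
  reg <- emit(reg, "SPLIT", c(source, new_uris))
  for (i in seq_along(others))
    reg <- emit(reg, "MOVE", c(source, new_uris[i]), sort(others[[i]]))
  reg
}

#' Resolve a URI to its active BIN
#'
#' Synonymized identifiers resolve transitively; resolution is total over
#' every URI ever issued. Decimal URIs (`BOLD:XXX0000.1`) resolve to
#' their parent.
#'
#' @param reg A [bin_registry()].
#' @param uri Any issued URI.
#' @return The active URI.
#' @export
registry_resolve <- function(reg, uri) {
  uri <- sub("\\.[0-9]+$", "", uri)
  e <- reg$entries[[uri]]
  if (is.null(e)) stop("unknown URI: ", uri)
  while (e$status == "SYNONYMIZED") e <- reg$entries[[e$into]]
  e$uri
}

#' Look up the members of a URI (including decimal partitions)
#'
#' @param reg A [bin_registry()].
#' @param uri An issued URI, optionally with a decimal suffix.
#' @return Character vector of member ids.
#' @export
registry_members <- function(reg, uri) {
  m <- regmatches(uri, regexec("^(.*?)(\\.([0-9]+))?$", uri))[[1L]]
  base <- m[2L]; suffix <- m[4L]
  e <- reg$entries[[registry_resolve(reg, base)]]
  if (!nzchar(suffix) || is.na(suffix)) return(e$members)
  p <- e$partitions
  if (is.null(p)) stop("BIN ", base, " has no decimal partitions")
  hit <- which(vapply(p, function(x) x$suffix == paste0(".", suffix), TRUE))
  if (!length(hit)) stop("no partition ", uri)
  p[[hit]]$members
}

match_decimal_partitions <- function(reg, uri, specs) {
  e <- reg$entries[[uri]]
  members <- e$members
  match_counts <- matrix(FALSE, length(members), length(specs))
  for (si in seq_along(specs)) {
    diag_list <- specs[[si]]
    for (mi in seq_along(members)) {
      seqv <- strsplit(reg$seqs[[members[mi]]], "", fixed = TRUE)[[1L]]
      ok <- all(vapply(diag_list, function(dg)
        seqv[as.integer(dg$pos)] == toupper(dg$state), TRUE))
      match_counts[mi, si] <- ok
    }
  }
  nhit <- rowSums(match_counts)
  if (any(nhit != 1L))
    stop("members matching zero or multiple subgroups: ",
         paste(members[nhit != 1L], collapse = ", "))
  lapply(seq_along(specs), function(si) list(
    suffix = paste0(".", si),
    specs = specs[[si]],
    members = members[match_counts[, si]]))
}

#' Decimalized expert partition of a BIN
#'
#' An expert may divide a BIN by specifying diagnostic nucleotide
#' positions and states; subgroups are labelled `uri.1`, `uri.2`, ... in
#' specification order. Every member must match exactly one subgroup's
#' diagnostics. The parent BIN remains active and queryable.
#'
#' @param reg A [bin_registry()].
#' @param uri URI of an active BIN.
#' @param specs List of subgroup specifications, each a list of
#'   `list(pos = <alignment position>, state = <nucleotide>)` diagnostics.
#' @return Updated registry.
#' @export
registry_decimal_partition <- function(reg, uri, specs) {
  e <- reg$entries[[uri]]
  if (is.null(e)) stop("unknown URI: ", uri)
  if (e$status != "ACTIVE") stop("cannot partition synonymized BIN: ", uri)
  L <- nchar(reg$seqs[[e$members[1L]]])
  for (sg in specs) for (dg in sg)
    if (dg$pos < 1L || dg$pos > L)
      stop("diagnostic position out of range: ", dg$pos)
  emit(reg, "PARTITION", uri,
       extra = jsonlite::toJSON(specs, auto_unbox = TRUE))
}

#' Clear the decimal partitions of a BIN
#'
#' @inheritParams registry_decimal_partition
#' @return Updated registry.
#' @export
registry_clear_partition <- function(reg, uri) {
  e <- reg$entries[[uri]]
  if (is.null(e)) stop("unknown URI: ", uri)
  emit(reg, "PARTITION", uri, extra = "[]")
}

#' Update compliance data and recompute a BIN's flag
#'
#' A BIN is flagged GREEN when at least one member is fully compliant
#' (voucher, country and trace availability all present), YELLOW
#' otherwise. Flags are recomputed automatically when membership changes.
#'
#' @param reg A [bin_registry()].
#' @param uri URI of an active BIN.
#' @param compliance Data frame with columns `id`, `voucher`, `country`,
#'   `trace` (logicals).
#' @return Updated registry.
#' @export
registry_set_flag <- function(reg, uri, compliance) {
  stopifnot(all(c("id", "voucher", "country", "trace") %in% names(compliance)))
  full <- compliance$voucher & compliance$country & compliance$trace
  comp <- stats::setNames(as.logical(full), compliance$id)
  emit(reg, "FLAG", uri,
       extra = jsonlite::toJSON(as.list(comp), auto_unbox = TRUE))
}

#' Current partition of registered sequences by active BIN
#'
#' @param reg A [bin_registry()].
#' @return A [new_partition()] (labels = active URIs, not canonicalized).
#' @export
registry_partition <- function(reg) {
  assign <- character()
  for (e in reg$entries)
    if (e$status == "ACTIVE" && length(e$members))
      assign[e$members] <- e$uri
  new_partition(assign, canonical = FALSE)
}

#' Audit log access and replay
#'
#' `registry_events()` returns the append-only audit log;
#' `registry_replay()` rebuilds a registry from an event log and the
#' sequence store, reproducing the state exactly.
#'
#' @param reg A [bin_registry()].
#' @return `registry_events()`: data frame of events.
#' @export
registry_events <- function(reg) reg$events

#' @rdname registry_events
#' @param events Event data frame.
#' @param seqs Named character vector of registered aligned sequences.
#' @param registered_at Named integer vector (id to event counter).
#' @param cfg The [resl_config()] the registry was built with.
#' @export
registry_replay <- function(events, seqs, registered_at, cfg = resl_config()) {
  reg <- bin_registry(cfg)
  reg$seqs <- seqs
  reg$registered_at <- registered_at
  reg$compliance <- stats::setNames(rep(FALSE, length(seqs)), names(seqs))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    uris <- strsplit(ev$uris, ",", fixed = TRUE)[[1L]]
    ids <- if (nzchar(ev$ids)) strsplit(ev$ids, ",", fixed = TRUE)[[1L]]
      else character()
    reg <- append_event(reg, ev$event, uris, ids, ev$extra)
    reg <- apply_event(reg, ev$event, uris, ids, ev$extra)
  }
  reg
}

#' Persist and reload a registry directory
#'
#' Writes `events.log` (append-only TSV) and `state.json` (derived
#' snapshot) under `dir`.
#'
#' @param reg A [bin_registry()].
#' @param dir Directory path (created if needed).
#' @return `read_registry()` returns the reloaded `bin_registry`.
#' @export
write_registry <- function(reg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(reg$events, file.path(dir, "events.log"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  snap <- list(
    seqs = as.list(reg$seqs),
    registered_at = as.list(reg$registered_at),
    compliance = as.list(reg$compliance),
    counter = reg$counter,
    last_uri = reg$last_uri,
    config = reg$cfg[c("t", "founder_cutoff", "min_overlap", "min_len",
                       "max_ambig", "epsilon", "max_iter")],
    entries = reg$entries
  )
  jsonlite::write_json(snap, file.path(dir, "state.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  events <- utils::read.delim(file.path(dir, "events.log"),
                              stringsAsFactors = FALSE,
                              colClasses = c(counter = "integer",
                                             event = "character",
                                             uris = "character",
                                             ids = "character",
                                             extra = "character"))
  events$extra[is.na(events$extra)] <- ""
  snap <- jsonlite::fromJSON(file.path(dir, "state.json"),
                             simplifyVector = FALSE)
  cfg <- do.call(resl_config, lapply(snap$config, identity))
  reg <- registry_replay(
    events,
    seqs = unlist(snap$seqs),
    registered_at = vapply(snap$registered_at, as.integer, 0L),
    cfg = cfg)
  comp <- vapply(snap$compliance, as.logical, TRUE)
  reg$compliance[names(comp)] <- comp
  for (uri in names(reg$entries))
    reg$entries[[uri]]$flag <- entry_flag(reg, reg$entries[[uri]]$members)
  reg
}
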