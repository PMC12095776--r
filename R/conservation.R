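#' Read BLAST tabular hits (outfmt 6)
#'
#' Parses the 12 standard columns of NCBI BLAST tabular output
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore). Subject coordinates may run high-to-low (minus
#' strand); query coordinates are normalised so q_start <= q_end.
#'
#' @param path BLAST outfmt-6 file; may be empty (no hits).
#' @return data.frame of hits with typed columns.
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "align_length",
            "mismatch", "gapopen", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    out$query_id <- character(0)
    out$subject_id <- character(0)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 12)
  if (length(bad) > 0) {
    stop("malformed BLAST tabular row in '", path, "' at line ", bad[1],
         " (", lengths(parts)[bad[1]], " fields, need >= 12)", call. = FALSE)
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:12))
  df <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                   stringsAsFactors = FALSE)
  numeric_cols <- cols[3:12]
  for (j in seq_along(numeric_cols)) {
    v <- suppressWarnings(as.numeric(m[, j + 2]))
    if (anyNA(v)) {
      stop("non-numeric field in '", path, "' at line ",
           which(is.na(v))[1], ", column ", j + 2, call. = FALSE)
    }
    df[[numeric_cols[j]]] <- v
  }
  if (any(df$q_start > df$q_end)) {
    i <- df$q_start > df$q_end
    tmp <- df$q_start[i]
    df$q_start[i] <- df$q_end[i]
    df$q_end[i] <- tmp
  }
  if (any(df$align_length < 1) || any(df$q_start < 1) ||
      any(pmin(df$s_start, df$s_end) < 1)) {
    stop("coordinates and alignment lengths must be positive in '", path,
         "'", call. = FALSE)
  }
  df
}

#' Retain BLAST hits by matched-base count
#'
#' A hit is kept when its number of matched (identical) bases, estimated
#' as round(align_length x pct_identity / 100), reaches
#' \code{cfg$min_hit_bases}. The raw-alignment-length reading is
#' available via \code{mode = "length"}.
#'
#' @param hits data.frame from [read_blast_tab()].
#' @param cfg a [gradr_config()].
#' @param mode "matched" (default) or "length".
#' @return Filtered hit data.frame.
#' @export
retain_hits <- function(hits, cfg = gradr_config(),
                        mode = c("matched", "length")) {
  mode <- match.arg(mode)
  if (nrow(hits) == 0) return(hits)
  score <- if (mode == "matched") {
    round(hits$align_length * hits$pct_identity / 100)
  } else {
    hits$align_length
  }
  hits[score >= cfg$min_hit_bases, , drop = FALSE]
}

# Merge 1-based inclusive intervals; returns matrix with columns start, end.
merge_intervals <- function(start, end) {
  if (length(start) == 0) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out <- list()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      out[[length(out) + 1]] <- c(ms, me)
      ms <- start[i]; me <- end[i]
    }
  }
  out[[length(out) + 1]] <- c(ms, me)
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m
}

# Total query bases covered by the union of hit query intervals.
union_coverage <- function(hits) {
  m <- merge_intervals(hits$q_start, hits$q_end)
  sum(m[, "end"] - m[, "start"] + 1)
}

#' Select the orthologous subject window
#'
#' The orthologous locus of a query in a target genome is the subject
#' window of span at most \code{cfg$window_bp} whose hits jointly cover
#' the most query sequence. Candidate windows are anchored at each hit's
#' lower subject coordinate (an anchored enumeration provably contains an
#' optimum for union-coverage scoring); a window's score is the union
#' query coverage of the hits falling entirely inside it. When hits map
#' to multiple loci and a synteny hint is supplied, candidates
#' overlapping the hinted region are considered first.
#'
#' @param hits retained hits (one query, one species; any subjects).
#' @param cfg a [gradr_config()].
#' @param synteny_hint optional list(subject_id, start, end) marking the
#'   syntenic region.
#' @return list: subject_id, window_start, window_end (bounding range of
#'   the winning hits), hits (rows inside the window), coverage (query
#'   bases covered). With no hits: empty window, coverage 0.
#' @export
select_ortholog_window <- function(hits, cfg = gradr_config(),
                                   synteny_hint = NULL) {
  if (nrow(hits) == 0) {
    return(list(subject_id = NA_character_, window_start = NA_real_,
                window_end = NA_real_, hits = hits, coverage = 0))
  }
  s_lo <- pmin(hits$s_start, hits$s_end)
  s_hi <- pmax(hits$s_start, hits$s_end)
  cand <- lapply(seq_len(nrow(hits)), function(i) {
    anchor <- s_lo[i]
    inside <- hits$subject_id == hits$subject_id[i] &
      s_lo >= anchor & s_hi <= anchor + cfg$window_bp
    idx <- which(inside)
    list(subject_id = hits$subject_id[i],
         anchor = anchor,
         span_end = anchor + cfg$window_bp,
         idx = idx,
         coverage = union_coverage(hits[idx, , drop = FALSE]))
  })
  hinted <- rep(FALSE, length(cand))
  if (!is.null(synteny_hint)) {
    hinted <- vapply(cand, function(w) {
      w$subject_id == synteny_hint$subject_id &&
        w$anchor <= synteny_hint$end && w$span_end >= synteny_hint$start
    }, logical(1))
  }
  pick_best <- function(ws) {
    cov <- vapply(ws, `[[`, numeric(1), "coverage")
    best <- ws[cov == max(cov)]
    sid <- vapply(best, `[[`, character(1), "subject_id")
    anc <- vapply(best, `[[`, numeric(1), "anchor")
    best[[order(sid, anc)[1]]]
  }
  w <- if (any(hinted)) pick_best(cand[hinted]) else pick_best(cand)
  list(subject_id = w$subject_id,
       window_start = min(s_lo[w$idx]),
       window_end = max(s_hi[w$idx]),
       hits = hits[w$idx, , drop = FALSE],
       coverage = w$coverage)
}

#' Percent base conservation of a query within a window
#'
#' Merges the query intervals of the hits inside the orthologous window
#' and scores each covered query position by the percent identity of the
#' best (highest-identity) hit covering it, avoiding double counting
#' where hits overlap. The unweighted mode counts covered positions
#' regardless of identity.
#'
#' @param query_length length of the (clipped) query sequence in bases.
#' @param hits hits inside the selected window.
#' @param weighted weight positions by best covering identity (default);
#'   FALSE counts plain coverage.
#' @return Percent in [0, 100].
#' @export
percent_conservation <- function(query_length, hits, weighted = TRUE) {
  stopifnot(query_length >= 1)
  if (nrow(hits) == 0) return(0)
  best <- numeric(query_length)
  for (i in seq_len(nrow(hits))) {
    lo <- max(1, hits$q_start[i])
    hi <- min(query_length, hits$q_end[i])
    if (lo > hi) next
    w <- if (weighted) hits$pct_identity[i] / 100 else 1
    seg <- lo:hi
    best[seg] <- pmax(best[seg], w)
  }
  min(100, 100 * sum(best) / query_length)
}

#' Conservation table across species
#'
#' Runs hit retention, window selection and percent-conservation scoring
#' for every (query, species) pair. Species without a hit entry, or whose
#' hits are all discarded by the retention filter, score 0% with an empty
#' window.
#'
#' @param per_species_hits named list (species -> hit data.frame, any
#'   number of queries per file).
#' @param query_lengths named numeric vector of (clipped) query lengths.
#' @param cfg a [gradr_config()].
#' @param synteny_hints optional nested list:
#'   \code{hints[[species]][[query_id]]} = list(subject_id, start, end).
#' @param weighted passed to [percent_conservation()].
#' @return Long-format data.frame: query_id, species, subject_id,
#'   window_start, window_end, pct_base_conservation, n_hits_in_window.
#' @export
conservation_table <- function(per_species_hits, query_lengths,
                               cfg = gradr_config(), synteny_hints = NULL,
                               weighted = TRUE) {
  if (is.null(names(query_lengths)) || anyNA(query_lengths)) {
    stop("query_lengths must be a complete named vector", call. = FALSE)
  }
  rows <- list()
  for (sp in names(per_species_hits)) {
    hits_sp <- retain_hits(per_species_hits[[sp]], cfg)
    for (q in names(query_lengths)) {
      h <- hits_sp[hits_sp$query_id == q, , drop = FALSE]
      hint <- if (!is.null(synteny_hints)) synteny_hints[[sp]][[q]] else NULL
      w <- select_ortholog_window(h, cfg, synteny_hint = hint)
      rows[[length(rows) + 1]] <- data.frame(
        query_id = q, species = sp,
        subject_id = w$subject_id,
        window_start = w$window_start, window_end = w$window_end,
        pct_base_conservation = percent_conservation(query_lengths[[q]],
                                                     w$hits,
                                                     weighted = weighted),
        n_hits_in_window = nrow(w$hits),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-species conservation summary
#'
#' Median and quartiles of percent base conservation per species, the
#' quantities drawn as box plots when species are ordered by evolutionary
#' distance.
#'
#' @param tbl output of [conservation_table()].
#' @return data.frame: species, n, q1, median, q3.
#' @export
conservation_summary <- function(tbl) {
  sp <- unique(tbl$species)
  do.call(rbind, lapply(sp, function(s) {
    v <- tbl$pct_base_conservation[tbl$species == s]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(species = s, n = length(v), q1 = q[1], median = q[2],
               q3 = q[3], stringsAsFactors = FALSE)
  }))
}
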