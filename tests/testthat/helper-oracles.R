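# Independent brute-force oracles used to check the implementation.
# These deliberately use different formulas/algorithms than the package.

# Pearson r via the raw-sums computational formula.
oracle_pearson <- function(a, b) {
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt(n * sum(a^2) - sum(a)^2) * sqrt(n * sum(b^2) - sum(b)^2)
  num / den
}

# Pooled-variance two-sample two-tailed t-test from the textbook formula.
oracle_student_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Percent conservation by explicit per-position scan over all hits.
oracle_pct_conservation <- function(query_length, hits, weighted = TRUE) {
  total <- 0
  for (pos in seq_len(query_length)) {
    best <- 0
    for (i in seq_len(nrow(hits))) {
      if (hits$q_start[i] <= pos && pos <= hits$q_end[i]) {
        w <- if (weighted) hits$pct_identity[i] / 100 else 1
        best <- max(best, w)
      }
    }
    total <- total + best
  }
  min(100, 100 * total / query_length)
}

# Union query coverage of a hit subset via a position vector.
oracle_coverage <- function(hits, qlen = max(hits$q_end)) {
  cov <- logical(qlen)
  for (i in seq_len(nrow(hits))) cov[hits$q_start[i]:hits$q_end[i]] <- TRUE
  sum(cov)
}

# Best window by exhaustive enumeration of every hit-anchored window,
# scoring coverage with the position-vector oracle.
oracle_window <- function(hits, window_bp, synteny_hint = NULL) {
  s_lo <- pmin(hits$s_start, hits$s_end)
  s_hi <- pmax(hits$s_start, hits$s_end)
  best <- NULL
  consider <- function(i, hinted_only) {
    anchor <- s_lo[i]
    if (hinted_only &&
        !(hits$subject_id[i] == synteny_hint$subject_id &&
          anchor <= synteny_hint$end &&
          anchor + window_bp >= synteny_hint$start)) return(NULL)
    idx <- which(hits$subject_id == hits$subject_id[i] &
                   s_lo >= anchor & s_hi <= anchor + window_bp)
    list(idx = idx,
         coverage = oracle_coverage(hits[idx, , drop = FALSE]),
         subject_id = hits$subject_id[i], anchor = anchor)
  }
  hinted_only <- FALSE
  if (!is.null(synteny_hint)) {
    any_hinted <- any(vapply(seq_len(nrow(hits)), function(i) {
      !is.null(consider(i, TRUE))
    }, logical(1)))
    hinted_only <- any_hinted
  }
  for (i in seq_len(nrow(hits))) {
    w <- consider(i, hinted_only)
    if (is.null(w)) next
    if (is.null(best) || w$coverage > best$coverage ||
        (w$coverage == best$coverage &&
         order(c(w$subject_id, best$subject_id))[1] == 1 &&
         w$subject_id != best$subject_id) ||
        (w$coverage == best$coverage && w$subject_id == best$subject_id &&
         w$anchor < best$anchor)) {
      best <- w
    }
  }
  best
}

# Brute-force re-evaluation of the full interactor filter chain, written
# directly from the method's rules (no shared code with the package).
oracle_interactors <- function(rna_id, rna_profiles, protein_profiles,
                               oops, rna_compartment, prot_loc_cyt,
                               prot_loc_nuc, mito_ids, cfg) {
  comp <- rna_compartment[[rna_id]]
  keep <- character()
  for (p in rownames(protein_profiles)) {
    if (!p %in% oops$protein_id) next
    i <- match(p, oops$protein_id)
    is_rbp <- oops$fold_change[i] >= cfg$oops_fc_min &&
      oops$p_value[i] <= cfg$oops_p_max
    if (!is_rbp) next
    cytv <- prot_loc_cyt[p, ]; nucv <- prot_loc_nuc[p, ]
    pct_nuc <- 100 * nucv / (cytv + nucv)
    if (comp == "cytoplasmic") {
      ok <- all(cytv > 0) && !all(pct_nuc >= cfg$opposing_compartment_pct)
    } else {
      ok <- all(nucv > 0) &&
        !all((100 - pct_nuc) >= cfg$opposing_compartment_pct)
      if (p %in% mito_ids) ok <- FALSE
    }
    if (!ok) next
    r <- oracle_pearson(rna_profiles[rna_id, ], protein_profiles[p, ])
    if (r >= cfg$r_min) keep <- c(keep, p)
  }
  sort(keep)
}

# Small deterministic blast-hit constructor.
make_hits <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r[["q"]] %||% "q1",
               subject_id = r[["s"]] %||% "chr1",
               pct_identity = r[["id"]] %||% 100,
               align_length = r[["len"]] %||%
                 (r[["qe"]] - r[["qs"]] + 1),
               mismatch = 0, gapopen = 0,
               q_start = r[["qs"]], q_end = r[["qe"]],
               s_start = r[["ss"]], s_end = r[["se"]],
               evalue = 1e-10, bitscore = 50,
               stringsAsFactors = FALSE)
  }))
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
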