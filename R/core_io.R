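#' Construct a gradient profile matrix
#'
#' A gradient matrix holds one sedimentation profile per entity: abundance
#' (RPKM for RNAs, LFQ for proteins) in each gradient fraction, ordered
#' from the top of the gradient to the bottom. Stored as a numeric matrix
#' with entity ids as row names.
#'
#' @param values numeric matrix, rows = entities, columns = fractions.
#' @param entity_class "rna" or "protein".
#' @return A \code{gradient_matrix}.
#' @export
gradient_matrix <- function(values, entity_class = c("rna", "protein")) {
  entity_class <- match.arg(entity_class)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values))) {
    stop("gradient matrix requires entity ids as row names", call. = FALSE)
  }
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup) > 0) {
    stop("duplicated entity_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) {
    stop("gradient matrix contains missing values; complete profiles are ",
         "required (sedimentation shape is the signal, imputation is refused)",
         call. = FALSE)
  }
  if (any(values < 0)) {
    bad <- rownames(values)[apply(values < 0, 1, any)]
    stop("negative abundance for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  }
  structure(values, entity_class = entity_class, class = "gradient_matrix")
}

#' Read a gradient profile matrix from TSV
#'
#' Expects a header row naming the fractions in gradient (top to bottom)
#' order, with the entity id in the first column. Ragged rows and negative
#' or duplicated entries are rejected.
#'
#' @param path TSV file path.
#' @param entity_class "rna" or "protein".
#' @return A \code{gradient_matrix}.
#' @export
read_gradient_matrix <- function(path, entity_class = c("rna", "protein")) {
  entity_class <- match.arg(entity_class)
  lines <- readLines(path)
  if (length(lines) < 2) stop("gradient matrix file '", path,
                              "' has no data rows", call. = FALSE)
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  if (length(unique(nfield)) != 1) {
    bad <- which(nfield != nfield[1])[1]
    stop("ragged row in '", path, "' at line ", bad,
         " (expected ", nfield[1], " fields, found ", nfield[bad], ")",
         call. = FALSE)
  }
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  m2 <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                dimnames = list(ids, colnames(m))))
  if (anyNA(m2) && !anyNA(m)) {
    stop("non-numeric abundance value in '", path, "'", call. = FALSE)
  }
  gradient_matrix(m2, entity_class)
}

#' Write a gradient profile matrix to TSV
#'
#' Values are written with full precision so that a write/read round-trip
#' reproduces them exactly.
#'
#' @param x a \code{gradient_matrix}.
#' @param path output TSV path.
#' @export
write_gradient_matrix <- function(x, path) {
  df <- data.frame(entity_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  write_tsv(df, path)
  invisible(path)
}

# Full-precision TSV writer shared by all modules ('.' decimal, no quoting).
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- vapply(df[[j]], function(v) format(v, digits = 17,
                                                  scientific = FALSE,
                                                  trim = TRUE),
                      character(1))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Assemble a count table
#'
#' Bundles raw read counts, RPKM values and the sample sheet used by the
#' expressed-RNA filter. Counts and RPKM share dimensions and dimnames;
#' each sample carries a condition and a replicate label.
#'
#' @param counts integer matrix (entities x samples) of raw read counts.
#' @param rpkm numeric matrix of matching dimensions.
#' @param samples data.frame with columns \code{sample_id},
#'   \code{condition}, \code{replicate}; one row per column of
#'   \code{counts}.
#' @return A list of class \code{count_table}.
#' @export
count_table <- function(counts, rpkm, samples) {
  counts <- as.matrix(counts)
  rpkm <- as.matrix(rpkm)
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (!identical(dim(counts), dim(rpkm))) {
    stop("counts and rpkm dimensions differ", call. = FALSE)
  }
  if (nrow(samples) != ncol(counts)) {
    stop("sample sheet rows must match count-table columns", call. = FALSE)
  }
  if (!identical(colnames(counts), as.character(samples$sample_id))) {
    stop("count-table column names must equal sample_id in order",
         call. = FALSE)
  }
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (anyNA(rpkm) || any(rpkm < 0)) {
    stop("RPKM values must be non-negative", call. = FALSE)
  }
  structure(list(counts = counts, rpkm = rpkm,
                 samples = data.frame(samples, stringsAsFactors = FALSE)),
            class = "count_table")
}

#' Read a count table from TSV files
#'
#' @param counts_path TSV of raw counts, first column entity_id, one column
#'   per sample.
#' @param rpkm_path TSV of RPKM values in the same layout.
#' @param samples_path TSV sample sheet with columns sample_id, condition,
#'   replicate.
#' @return A \code{count_table}.
#' @export
read_count_table <- function(counts_path, rpkm_path, samples_path) {
  rd <- function(p) {
    df <- read.delim(p, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  samples <- read.delim(samples_path, check.names = FALSE,
                        colClasses = "character")
  count_table(rd(counts_path), rd(rpkm_path), samples)
}

#' Expressed-RNA filter
#'
#' Keeps an RNA when (i) its RPKM is at least \code{cfg$rpkm_min} in
#' \emph{all} replicates of at least one condition, and (ii) at least
#' \code{cfg$min_reads} raw reads were detected in at least one sample.
#' Entities on the exemption list are always retained (used for focal
#' RNAs that must stay in downstream analyses regardless of the filter).
#'
#' The read minimum is applied as a per-sample maximum; the alternative
#' per-condition-sum reading is available via \code{reads_rule = "sum"}.
#'
#' @param ct a \code{count_table}.
#' @param cfg a [gradr_config()].
#' @param exempt character vector of entity ids always kept.
#' @param reads_rule "max" (default; max single-sample count) or "sum"
#'   (per-condition total).
#' @return A filtered \code{count_table}.
#' @export
filter_expressed <- function(ct, cfg = gradr_config(), exempt = character(),
                             reads_rule = c("max", "sum")) {
  stopifnot(inherits(ct, "count_table"))
  reads_rule <- match.arg(reads_rule)
  if (nrow(ct$counts) == 0) return(ct)
  conds <- unique(ct$samples$condition)
  rpkm_ok <- rep(FALSE, nrow(ct$rpkm))
  for (cc in conds) {
    idx <- ct$samples$condition == cc
    rpkm_ok <- rpkm_ok |
      apply(ct$rpkm[, idx, drop = FALSE] >= cfg$rpkm_min, 1, all)
  }
  if (reads_rule == "max") {
    reads_ok <- apply(ct$counts, 1, max) >= cfg$min_reads
  } else {
    sums <- sapply(conds, function(cc) {
      rowSums(ct$counts[, ct$samples$condition == cc, drop = FALSE])
    })
    reads_ok <- apply(as.matrix(sums), 1, max) >= cfg$min_reads
  }
  keep <- (rpkm_ok & reads_ok) | rownames(ct$counts) %in% exempt
  count_table(ct$counts[keep, , drop = FALSE],
              ct$rpkm[keep, , drop = FALSE], ct$samples)
}

#' Compute RPKM from raw counts and feature lengths
#'
#' Reads per kilobase of transcript per million mapped reads, with the
#' per-sample library size taken as the column sum of the supplied counts.
#' Provided as a convenience; pipelines that compute RPKM upstream can
#' supply it directly.
#'
#' @param counts integer matrix (entities x samples).
#' @param lengths_bp numeric vector of feature lengths in bp, named by or
#'   ordered as the rows of \code{counts}.
#' @return Numeric matrix of RPKM values.
#' @export
compute_rpkm <- function(counts, lengths_bp) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths_bp)) && !is.null(rownames(counts))) {
    lengths_bp <- lengths_bp[rownames(counts)]
  }
  if (length(lengths_bp) != nrow(counts) || anyNA(lengths_bp)) {
    stop("lengths_bp must cover every row of counts", call. = FALSE)
  }
  lib <- colSums(counts)
  if (any(lib == 0)) stop("library size of zero in at least one sample",
                          call. = FALSE)
  sweep(counts / (lengths_bp / 1000), 2, lib / 1e6, "/")
}

#' Read a one-id-per-line text file
#'
#' Used for mitochondrial-protein exclusion lists and expressed-RNA
#' exemption lists. Blank lines and lines starting with '#' are skipped.
#'
#' @param path text file path.
#' @return Character vector of ids.
#' @export
read_id_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
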