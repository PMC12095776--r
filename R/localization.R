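#' Spike-in normalisation of RPKM values
#'
#' Subcellular-fractionation RNA-seq is normalised to an exogenous
#' spike-in added in equal mass to every sample: each sample's RPKMs are
#' divided by the percentage of reads mapping to the spike-in genome in
#' that sample. Samples that recovered less endogenous RNA (hence a
#' higher spike-in share) are thereby scaled down. The opposite reading
#' (multiply by the spike percentage) is available via \code{mode}.
#'
#' @param rpkm numeric matrix (entities x samples), columns named by
#'   sample_id.
#' @param spikes data.frame with columns sample_id, human_reads,
#'   spike_reads covering every column of \code{rpkm}.
#' @param mode "divide" (default) or "multiply".
#' @return Matrix of normalised values, same shape as \code{rpkm}.
#' @export
spikein_normalize <- function(rpkm, spikes, mode = c("divide", "multiply")) {
  mode <- match.arg(mode)
  rpkm <- as.matrix(rpkm)
  if (!all(colnames(rpkm) %in% spikes$sample_id)) {
    stop("every rpkm sample needs a spike-in record", call. = FALSE)
  }
  spikes <- spikes[match(colnames(rpkm), spikes$sample_id), ]
  if (any(spikes$spike_reads <= 0)) {
    stop("spike_reads must be > 0 (normalisation undefined otherwise)",
         call. = FALSE)
  }
  frac <- spikes$spike_reads / (spikes$spike_reads + spikes$human_reads)
  pct <- frac * 100
  if (mode == "divide") sweep(rpkm, 2, pct, "/") else sweep(rpkm, 2, pct, "*")
}

#' Percent signal per compartment
#'
#' Converts paired cytoplasmic/nuclear signals to percentages summing to
#' 100. Entities with zero total signal are undefined and returned as NA
#' (flagged ambiguous by callers, excluded downstream).
#'
#' @param cyt,nuc non-negative numeric vectors of equal length.
#' @return data.frame with \code{pct_cyt} and \code{pct_nuc}.
#' @export
#' @examples
#' percent_compartment(3, 1) # 75 / 25
percent_compartment <- function(cyt, nuc) {
  if (any(c(cyt, nuc) < 0, na.rm = TRUE)) {
    stop("compartment signals must be non-negative", call. = FALSE)
  }
  tot <- cyt + nuc
  pct_cyt <- ifelse(tot > 0, 100 * cyt / tot, NA_real_)
  data.frame(pct_cyt = pct_cyt, pct_nuc = 100 - pct_cyt)
}

#' Build a localization table from replicate signal matrices
#'
#' @param cyt,nuc numeric matrices (entities x replicates) of cytoplasmic
#'   and nuclear signal with identical dimnames.
#' @param entity_class "rna" or "protein".
#' @return A list of class \code{localization_table} holding the signal
#'   matrices, per-replicate percent-nuclear values and the mean percent
#'   cytoplasmic (over replicates with nonzero total signal).
#' @export
localization_table <- function(cyt, nuc, entity_class = c("rna", "protein")) {
  entity_class <- match.arg(entity_class)
  cyt <- as.matrix(cyt)
  nuc <- as.matrix(nuc)
  if (!identical(dimnames(cyt), dimnames(nuc)) ||
      !identical(dim(cyt), dim(nuc))) {
    stop("cyt and nuc matrices must share dimensions and dimnames",
         call. = FALSE)
  }
  if (any(cyt < 0) || any(nuc < 0)) {
    stop("compartment signals must be non-negative", call. = FALSE)
  }
  tot <- cyt + nuc
  pct_nuc <- ifelse(tot > 0, 100 * nuc / tot, NA_real_)
  mean_pct_cyt <- apply(100 - pct_nuc, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  structure(list(cyt = cyt, nuc = nuc, pct_nuclear = pct_nuc,
                 mean_pct_cytoplasmic = mean_pct_cyt,
                 entity_class = entity_class),
            class = "localization_table")
}

#' Read a localization table from TSV
#'
#' Expects entity_id first, then cytoplasmic replicate columns prefixed
#' \code{cyt_} and nuclear columns prefixed \code{nuc_}.
#'
#' @param path TSV file path.
#' @param entity_class "rna" or "protein".
#' @return A \code{localization_table}.
#' @export
read_localization_table <- function(path,
                                    entity_class = c("rna", "protein")) {
  entity_class <- match.arg(entity_class)
  df <- read.delim(path, check.names = FALSE)
  ccols <- grep("^cyt_", names(df))
  ncols <- grep("^nuc_", names(df))
  if (length(ccols) == 0 || length(ncols) == 0 ||
      length(ccols) != length(ncols)) {
    stop("localization table '", path,
         "' needs matching cyt_* and nuc_* columns", call. = FALSE)
  }
  cyt <- as.matrix(df[, ccols, drop = FALSE])
  nuc <- as.matrix(df[, ncols, drop = FALSE])
  rownames(cyt) <- rownames(nuc) <- df[[1]]
  colnames(cyt) <- colnames(nuc) <- paste0("rep", seq_along(ccols))
  localization_table(cyt, nuc, entity_class)
}

#' Compartment call for RNAs
#'
#' An RNA is called cytoplasmic when its mean percent-cytoplasmic signal
#' across usable replicates exceeds the threshold (default 50; exactly at
#' the threshold is called nuclear — the documented tie-break), nuclear
#' otherwise, and ambiguous when no replicate has signal.
#'
#' @param loc a \code{localization_table} with entity_class "rna".
#' @param cfg a [gradr_config()]; \code{rna_pct_cyt_min} is the threshold.
#' @return Named character vector: "cytoplasmic", "nuclear" or
#'   "ambiguous".
#' @export
call_rna_compartment <- function(loc, cfg = gradr_config()) {
  stopifnot(inherits(loc, "localization_table"))
  m <- loc$mean_pct_cytoplasmic
  out <- ifelse(is.na(m), "ambiguous",
                ifelse(m > cfg$rna_pct_cyt_min, "cytoplasmic", "nuclear"))
  setNames(out, rownames(loc$cyt))
}

#' Compartment eligibility for proteins
#'
#' A protein is eligible as a cytoplasmic interactor when it was detected
#' (signal > 0) in the cytoplasmic fraction in \emph{all} replicates and
#' is \emph{not} at least \code{cfg$opposing_compartment_pct}% nuclear in
#' all replicates. The nuclear rule is the mirror image. The two rules do
#' not partition the proteome: a protein near 50/50 can be eligible for
#' both compartments.
#'
#' @param loc a \code{localization_table} with entity_class "protein".
#' @param compartment "cytoplasmic" or "nuclear".
#' @param cfg a [gradr_config()]; \code{replicates} is the expected
#'   replicate count and \code{opposing_compartment_pct} the exclusion
#'   threshold.
#' @return Named logical vector over proteins.
#' @export
protein_compartment_eligibility <- function(loc,
                                            compartment = c("cytoplasmic",
                                                            "nuclear"),
                                            cfg = gradr_config()) {
  stopifnot(inherits(loc, "localization_table"))
  compartment <- match.arg(compartment)
  if (ncol(loc$cyt) != cfg$replicates) {
    stop("expected ", cfg$replicates, " replicates, found ", ncol(loc$cyt),
         call. = FALSE)
  }
  if (compartment == "cytoplasmic") {
    detected <- rowSums(loc$cyt > 0) == ncol(loc$cyt)
    opposing <- loc$pct_nuclear
  } else {
    detected <- rowSums(loc$nuc > 0) == ncol(loc$nuc)
    opposing <- 100 - loc$pct_nuclear
  }
  # a replicate with no signal cannot attest >= threshold in the opposing
  # compartment
  all_opposing <- apply(opposing, 1, function(v) {
    all(!is.na(v) & v >= cfg$opposing_compartment_pct)
  })
  setNames(detected & !all_opposing, rownames(loc$cyt))
}

#' Remove mitochondrial proteins
#'
#' Set difference against a user-supplied mitochondrial annotation list.
#' Applied in the nuclear-RNA branch of the interactor prediction, where
#' nuclear-mitochondrial interactions are implausible.
#'
#' @param proteins character vector of protein ids.
#' @param mito_list character vector of mitochondrial protein ids.
#' @return \code{proteins} without members of \code{mito_list}.
#' @export
exclude_mitochondrial <- function(proteins, mito_list) {
  setdiff(proteins, mito_list)
}
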