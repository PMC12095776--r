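#' Row-Z-score a profile or profile matrix
#'
#' Centers each sedimentation profile to mean 0 and scales it to standard
#' deviation 1 across fractions. Constant profiles have no shape and are
#' flagged degenerate (NA rows) rather than transformed; they are skipped
#' by the correlation stage. Pearson correlation is invariant to this
#' transform, so it affects visualisation only.
#'
#' @param x numeric vector (one profile) or matrix (entities x fractions).
#' @return Same shape as \code{x}; degenerate rows all-NA, with a
#'   \code{degenerate} attribute naming them for matrices.
#' @export
zscore_profile <- function(x) {
  if (is.matrix(x)) {
    cls <- class(x)
    out <- t(apply(unclass(x), 1, zscore_profile))
    dimnames(out) <- dimnames(x)
    deg <- rownames(out)[apply(is.na(out), 1, all)]
    return(structure(out, degenerate = deg))
  }
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x)) / s
}

#' Pearson correlation of two sedimentation profiles
#'
#' Sample Pearson correlation coefficient between two equal-length
#' fraction profiles. Constant profiles carry no co-sedimentation
#' information; they yield an error so callers skip (and log) the pair.
#'
#' @param a,b numeric vectors of equal length.
#' @return Correlation in [-1, 1].
#' @export
profile_pearson <- function(a, b) {
  if (length(a) != length(b)) {
    stop("profiles differ in length", call. = FALSE)
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop("constant profile: correlation undefined", call. = FALSE)
  }
  cor(a, b, method = "pearson")
}

#' Assemble the combined evidence dataset
#'
#' Joins the four evidence layers into the single tabular dataset the
#' predictor operates on: gradient profiles for RNAs and proteins, the
#' OOPS enrichment table, compartment calls/eligibility from subcellular
#' fractionation, and the mitochondrial exclusion list. Ids present in
#' one layer but unresolvable in another are recorded in the
#' \code{unmatched} element (and messaged) rather than silently dropped.
#'
#' @param rna_profiles \code{gradient_matrix} of RNA profiles.
#' @param protein_profiles \code{gradient_matrix} of protein profiles.
#' @param oops data.frame with protein_id, fold_change, p_value.
#' @param rna_compartment named character vector of RNA compartment calls
#'   (from [call_rna_compartment()]).
#' @param protein_elig_cyt,protein_elig_nuc named logical vectors of
#'   compartment eligibility (from [protein_compartment_eligibility()]).
#' @param mito_list character vector of mitochondrial protein ids.
#' @return A list of class \code{combined_dataset}.
#' @export
combined_dataset <- function(rna_profiles, protein_profiles, oops,
                             rna_compartment, protein_elig_cyt,
                             protein_elig_nuc, mito_list = character()) {
  stopifnot(inherits(rna_profiles, "gradient_matrix"),
            inherits(protein_profiles, "gradient_matrix"))
  if (ncol(rna_profiles) != ncol(protein_profiles)) {
    stop("RNA and protein profiles must cover the same fractions",
         call. = FALSE)
  }
  prot <- rownames(protein_profiles)
  unmatched <- list(
    no_oops = setdiff(prot, oops$protein_id),
    no_localization = setdiff(prot, union(names(protein_elig_cyt),
                                          names(protein_elig_nuc))),
    no_profile = setdiff(oops$protein_id, prot),
    rna_no_compartment = setdiff(rownames(rna_profiles),
                                 names(rna_compartment))
  )
  n_un <- sum(lengths(unmatched))
  if (n_un > 0) {
    message("combined_dataset: ", n_un,
            " id(s) unresolvable across layers (see $unmatched)")
  }
  structure(list(rna_profiles = rna_profiles,
                 protein_profiles = protein_profiles,
                 oops = oops,
                 rna_compartment = rna_compartment,
                 protein_elig_cyt = protein_elig_cyt,
                 protein_elig_nuc = protein_elig_nuc,
                 mito_list = as.character(mito_list),
                 unmatched = unmatched),
            class = "combined_dataset")
}

# Candidate proteins for one compartment: RNA-binding, compartment-eligible,
# with a usable profile, minus mitochondrial proteins in the nuclear branch.
candidate_proteins <- function(ds, compartment, cfg) {
  rbps <- call_rbps(ds$oops, cfg)
  elig <- if (compartment == "cytoplasmic") ds$protein_elig_cyt
          else ds$protein_elig_nuc
  cand <- intersect(rbps, names(elig)[elig])
  cand <- intersect(cand, rownames(ds$protein_profiles))
  if (compartment == "nuclear") {
    cand <- exclude_mitochondrial(cand, ds$mito_list)
  }
  sort(cand)
}

#' Predict protein interactors for one RNA
#'
#' Implements the per-RNA prediction: restrict the proteome to RNA-binding
#' proteins eligible in the RNA's compartment (removing mitochondrial
#' proteins for nuclear RNAs), correlate each remaining protein's gradient
#' profile with the RNA's, sort by descending Pearson r, and mark proteins
#' with r >= \code{cfg$r_min} as candidate interactors. The full scored
#' table is returned so that r-vs-p scatter plots can show non-passing
#' proteins too; \code{passed} identifies the predictions.
#'
#' @param rna_id RNA to query; must have a profile and a compartment call.
#' @param ds a [combined_dataset()].
#' @param cfg a [gradr_config()].
#' @return data.frame: rna_id, protein_id, pearson_r, oops_fc, oops_p,
#'   compartment, passed, rank (dense rank by descending r among passing
#'   proteins, ties broken by protein id; NA for non-passing rows).
#' @export
predict_interactors <- function(rna_id, ds, cfg = gradr_config()) {
  stopifnot(inherits(ds, "combined_dataset"))
  if (!rna_id %in% rownames(ds$rna_profiles)) {
    stop("unknown rna_id: ", rna_id, call. = FALSE)
  }
  comp <- ds$rna_compartment[[rna_id]]
  if (is.null(comp) || is.na(comp) || comp == "ambiguous") {
    stop("RNA '", rna_id, "' has no usable compartment call", call. = FALSE)
  }
  prof <- as.numeric(unclass(ds$rna_profiles)[rna_id, ])
  if (sd(prof) == 0) {
    stop("RNA '", rna_id, "' has a constant (degenerate) profile",
         call. = FALSE)
  }
  cand <- candidate_proteins(ds, comp, cfg)
  pm <- unclass(ds$protein_profiles)
  usable <- cand[apply(pm[cand, , drop = FALSE], 1, sd) > 0]
  skipped <- setdiff(cand, usable)
  if (length(skipped) > 0) {
    message("predict_interactors(", rna_id, "): skipped ", length(skipped),
            " constant protein profile(s)")
  }
  r <- vapply(usable, function(p) profile_pearson(prof, pm[p, ]), numeric(1))
  oi <- match(usable, ds$oops$protein_id)
  out <- data.frame(rna_id = rna_id,
                    protein_id = usable,
                    pearson_r = unname(r),
                    oops_fc = ds$oops$fold_change[oi],
                    oops_p = ds$oops$p_value[oi],
                    compartment = comp,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pearson_r, out$protein_id), , drop = FALSE]
  out$passed <- out$pearson_r >= cfg$r_min
  out$rank <- NA_integer_
  out$rank[out$passed] <- seq_len(sum(out$passed))
  rownames(out) <- NULL
  out
}

#' Predict interactors for every RNA in the dataset
#'
#' Applies [predict_interactors()] to each RNA with a usable profile and
#' compartment call, returning one long-format table. RNAs that cannot be
#' scored (ambiguous compartment, degenerate profile) are skipped and
#' listed in the \code{skipped} attribute; a per-RNA summary of candidate
#' and passing counts is attached as the \code{summary} attribute.
#'
#' @param ds a [combined_dataset()].
#' @param cfg a [gradr_config()].
#' @param passed_only keep only passing rows (default FALSE).
#' @return Long-format data.frame of predictions grouped by rna_id.
#' @export
interactome_all <- function(ds, cfg = gradr_config(), passed_only = FALSE) {
  stopifnot(inherits(ds, "combined_dataset"))
  rnas <- rownames(ds$rna_profiles)
  res <- list()
  skipped <- character()
  for (rna in rnas) {
    tab <- tryCatch(predict_interactors(rna, ds, cfg),
                    error = function(e) {
                      message("interactome_all: skipping ", rna, " (",
                              conditionMessage(e), ")")
                      NULL
                    })
    if (is.null(tab)) skipped <- c(skipped, rna) else res[[rna]] <- tab
  }
  out <- if (length(res) > 0) do.call(rbind, res) else
    data.frame(rna_id = character(), protein_id = character(),
               pearson_r = numeric(), oops_fc = numeric(),
               oops_p = numeric(), compartment = character(),
               passed = logical(), rank = integer())
  rownames(out) <- NULL
  if (passed_only) out <- out[out$passed, , drop = FALSE]
  smry <- if (nrow(out) > 0) {
    agg <- aggregate(cbind(n_candidates = passed | TRUE,
                           n_passed = passed) ~ rna_id,
                     data = out, FUN = sum)
    agg
  } else data.frame(rna_id = character(), n_candidates = integer(),
                    n_passed = integer())
  structure(out, skipped = skipped, summary = smry)
}

#' Pairwise profile correlation matrix with clustering
#'
#' Pearson correlation matrix over the gradient profiles of a protein set
#' (typically the union of predicted interactors), with average-linkage
#' hierarchical clustering on the distance 1 - r. The leaf order groups
#' co-sedimenting machineries into contiguous blocks.
#'
#' @param protein_ids character vector (>= 2) of proteins with
#'   non-degenerate profiles.
#' @param ds a [combined_dataset()] (or a \code{gradient_matrix} of
#'   protein profiles).
#' @return list with \code{r} (symmetric matrix, unit diagonal),
#'   \code{hclust}, and \code{leaf_order} (ids in dendrogram order).
#' @export
interactor_correlation_matrix <- function(protein_ids, ds) {
  pm <- if (inherits(ds, "combined_dataset")) unclass(ds$protein_profiles)
        else unclass(ds)
  protein_ids <- unique(as.character(protein_ids))
  missing <- setdiff(protein_ids, rownames(pm))
  if (length(missing) > 0) {
    stop("no profile for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  pm <- pm[protein_ids, , drop = FALSE]
  ok <- apply(pm, 1, sd) > 0
  pm <- pm[ok, , drop = FALSE]
  if (nrow(pm) < 2) {
    stop("need >= 2 proteins with non-degenerate profiles", call. = FALSE)
  }
  r <- cor(t(pm), method = "pearson")
  hc <- hclust(as.dist(1 - r), method = "average")
  list(r = r, hclust = hc, leaf_order = rownames(r)[hc$order])
}

#' Write a correlation matrix and its dendrogram
#'
#' @param icm result of [interactor_correlation_matrix()].
#' @param matrix_path output TSV for the correlation matrix.
#' @param tree_path output Newick file for the dendrogram.
#' @export
write_correlation_matrix <- function(icm, matrix_path, tree_path = NULL) {
  df <- data.frame(protein_id = rownames(icm$r), as.data.frame(icm$r),
                   check.names = FALSE)
  write_tsv(df, matrix_path)
  if (!is.null(tree_path)) {
    ape::write.tree(ape::as.phylo(icm$hclust), file = tree_path)
  }
  invisible(matrix_path)
}
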