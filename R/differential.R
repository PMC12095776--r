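#' Replicate-group enrichment test
#'
#' Fold-change plus two-sample t-test for one protein, comparing a
#' treatment group (e.g. OOPS RNase+ eluate LFQ) to a control group
#' (no-RNase elution). The fold-change is the ratio of linear-scale group
#' means; the p-value comes from a two-tailed Student's t-test (equal
#' variance by default, Welch behind a flag), computed on log2-transformed
#' abundances when \code{log_transform} is TRUE — the convention for
#' label-free quantification data. Zeros are replaced by \code{floor}
#' before the log transform (and only there); with the floor unset it
#' defaults to half the smallest nonzero value across both groups.
#'
#' Degenerate inputs follow documented conventions: if both groups are
#' constant, p is 1 when their means are equal and 0 otherwise.
#'
#' @param treat numeric vector of treatment abundances (length >= 2).
#' @param ctrl numeric vector of control abundances (length >= 2).
#' @param log_transform test on log2 scale (default TRUE).
#' @param var_equal pooled-variance Student's t-test (default TRUE); FALSE
#'   gives the Welch variant.
#' @param floor abundance substituted for zeros before the log transform.
#' @return A one-row data.frame: \code{fold_change}, \code{log2_fc},
#'   \code{p_value}, \code{t_stat}, \code{df}.
#' @export
#' @examples
#' enrichment_test(c(8, 10, 12), c(2, 2.5, 1.5))
enrichment_test <- function(treat, ctrl, log_transform = TRUE,
                            var_equal = TRUE, floor = NULL) {
  treat <- as.numeric(treat)
  ctrl <- as.numeric(ctrl)
  if (sum(is.finite(treat)) < 2 || sum(is.finite(ctrl)) < 2) {
    stop("enrichment_test requires >= 2 finite values per group",
         call. = FALSE)
  }
  treat <- treat[is.finite(treat)]
  ctrl <- ctrl[is.finite(ctrl)]
  if (any(c(treat, ctrl) < 0)) {
    stop("abundances must be non-negative", call. = FALSE)
  }
  fc <- mean(treat) / mean(ctrl)
  xs <- c(treat, ctrl)
  if (log_transform) {
    if (is.null(floor)) {
      nz <- xs[xs > 0]
      if (length(nz) == 0) {
        floor <- 1 # all-zero pathological case; any positive constant works
      } else {
        floor <- min(nz) / 2
      }
    }
    tv <- log2(pmax(treat, floor))
    cv <- log2(pmax(ctrl, floor))
  } else {
    tv <- treat
    cv <- ctrl
  }
  if (sd(tv) == 0 && sd(cv) == 0) {
    p <- if (isTRUE(all.equal(mean(tv), mean(cv)))) 1 else 0
    tt <- list(statistic = c(t = if (p == 1) 0 else Inf),
               parameter = c(df = length(tv) + length(cv) - 2))
  } else {
    tt <- t.test(tv, cv, var.equal = var_equal)
    p <- tt$p.value
  }
  data.frame(fold_change = fc, log2_fc = log2(fc), p_value = p,
             t_stat = unname(tt$statistic), df = unname(tt$parameter))
}

#' Set all-zero control groups to a mean of 100
#'
#' For capture experiments (ChIRP-MS style) where a protein is detected
#' exclusively in the treatment captures, the control group is entirely
#' zero and the fold-change is undefined. Such control groups are
#' artificially set so their mean is 100, which yields finite
#' fold-changes for treatment-exclusive proteins; affected rows are
#' flagged. Groups with any nonzero value are untouched.
#'
#' @param ctrl numeric matrix of control abundances, one row per protein.
#' @return list with \code{ctrl} (modified matrix) and \code{imputed}
#'   (logical per row).
#' @export
impute_all_zero_controls <- function(ctrl) {
  ctrl <- as.matrix(ctrl)
  all_zero <- rowSums(ctrl != 0) == 0 & ncol(ctrl) > 0
  ctrl[all_zero, ] <- 100
  list(ctrl = ctrl, imputed = all_zero)
}

#' Per-protein enrichment over a replicate table
#'
#' Applies [enrichment_test()] row-wise to paired treatment/control
#' matrices, with a single abundance floor computed across the whole table
#' (half the smallest nonzero abundance) so that rows are comparable.
#' Optionally applies the all-zero-control imputation first (capture-MS
#' convention) and reports Benjamini-Hochberg adjusted p-values as an
#' extra column.
#'
#' @param treat numeric matrix (proteins x replicates).
#' @param ctrl numeric matrix with identical row names.
#' @param impute_zero_ctrl apply [impute_all_zero_controls()] first.
#' @param log_transform,var_equal passed to [enrichment_test()].
#' @return data.frame: protein_id, fold_change, log2_fc, p_value,
#'   neg_log10_p, p_adj, ctrl_imputed.
#' @export
enrichment_table <- function(treat, ctrl, impute_zero_ctrl = FALSE,
                             log_transform = TRUE, var_equal = TRUE) {
  treat <- as.matrix(treat)
  ctrl <- as.matrix(ctrl)
  if (!identical(rownames(treat), rownames(ctrl))) {
    stop("treatment and control tables must list the same proteins in ",
         "the same order", call. = FALSE)
  }
  imputed <- rep(FALSE, nrow(treat))
  if (impute_zero_ctrl) {
    imp <- impute_all_zero_controls(ctrl)
    ctrl <- imp$ctrl
    imputed <- imp$imputed
  }
  nz <- c(treat, ctrl)
  nz <- nz[nz > 0]
  floor <- if (length(nz) > 0) min(nz) / 2 else 1
  rows <- lapply(seq_len(nrow(treat)), function(i) {
    enrichment_test(treat[i, ], ctrl[i, ], log_transform = log_transform,
                    var_equal = var_equal, floor = floor)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(protein_id = rownames(treat), out,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$neg_log10_p <- -log10(out$p_value)
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$ctrl_imputed <- imputed
  out
}

#' Call RNA-binding proteins from OOPS enrichment records
#'
#' A protein is an RNA-binding protein when its RNase+/- elution
#' fold-change is at least \code{cfg$oops_fc_min} and its t-test p-value
#' is at most \code{cfg$oops_p_max}. Both bounds are inclusive.
#'
#' @param oops data.frame with columns protein_id, fold_change, p_value
#'   (as produced by [enrichment_table()]).
#' @param cfg a [gradr_config()].
#' @return Character vector of RNA-binding protein ids.
#' @export
call_rbps <- function(oops, cfg = gradr_config()) {
  req <- c("protein_id", "fold_change", "p_value")
  if (!all(req %in% names(oops))) {
    stop("OOPS table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  keep <- oops$fold_change >= cfg$oops_fc_min & oops$p_value <= cfg$oops_p_max
  keep[is.na(keep)] <- FALSE
  as.character(oops$protein_id[keep])
}

#' Read an OOPS/capture replicate abundance table
#'
#' TSV with protein_id first, then treatment replicate columns prefixed
#' \code{treat_} and control columns prefixed \code{ctrl_}.
#'
#' @param path TSV file path.
#' @return list with matrices \code{treat} and \code{ctrl}.
#' @export
read_replicate_table <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  tcols <- grep("^treat_", names(df))
  ccols <- grep("^ctrl_", names(df))
  if (length(tcols) == 0 || length(ccols) == 0) {
    stop("replicate table '", path, "' needs treat_* and ctrl_* columns",
         call. = FALSE)
  }
  t_m <- as.matrix(df[, tcols, drop = FALSE])
  c_m <- as.matrix(df[, ccols, drop = FALSE])
  rownames(t_m) <- rownames(c_m) <- df[[1]]
  list(treat = t_m, ctrl = c_m)
}
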