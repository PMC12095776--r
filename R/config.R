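#' Analysis configuration
#'
#' Collects every numeric threshold used across the pipeline. Defaults are
#' the values used throughout the method: RNA-binding proteins require an
#' OOPS RNase+/- elution fold-change >= 2 at t-test p <= 0.05; candidate
#' interactors require profile Pearson r >= 0.5; a protein is excluded from
#' a compartment when it is >= 60% in the opposing compartment in all
#' replicates; expressed RNAs require RPKM >= 0.5 in all replicates of at
#' least one condition and >= 10 reads; BLAST hits are retained at >= 20
#' matched bases and orthologous windows span at most 100 kb; gradients
#' have 22 fractions.
#'
#' @param oops_fc_min minimum OOPS elution fold-change (linear scale) for an
#'   RNA-binding-protein call.
#' @param oops_p_max maximum OOPS t-test p-value for an RNA-binding-protein
#'   call.
#' @param r_min minimum profile Pearson r for a candidate interactor.
#' @param opposing_compartment_pct percent signal in the opposing compartment
#'   at or above which, in all replicates, a protein is ineligible for a
#'   compartment.
#' @param rpkm_min minimum RPKM required in all replicates of at least one
#'   condition for an RNA to count as expressed.
#' @param min_reads minimum raw read count (maximum over samples) for an RNA
#'   to count as expressed.
#' @param min_hit_bases minimum matched bases for a BLAST hit to be retained.
#' @param window_bp maximum span (bp) of the orthologous subject window.
#' @param n_fractions number of gradient fractions.
#' @param rna_pct_cyt_min mean percent-cytoplasmic strictly above which an
#'   RNA is called cytoplasmic (at or below: nuclear).
#' @param replicates expected replicate count for compartment proteomics.
#' @param rng_seed integer seed consumed by stochastic helpers.
#' @return A list of class \code{gradr_config}.
#' @export
#' @examples
#' cfg <- gradr_config()
#' cfg$r_min
gradr_config <- function(oops_fc_min = 2,
                         oops_p_max = 0.05,
                         r_min = 0.5,
                         opposing_compartment_pct = 60,
                         rpkm_min = 0.5,
                         min_reads = 10L,
                         min_hit_bases = 20L,
                         window_bp = 100000L,
                         n_fractions = 22L,
                         rna_pct_cyt_min = 50,
                         replicates = 3L,
                         rng_seed = 1L) {
  cfg <- list(
    oops_fc_min = as.numeric(oops_fc_min),
    oops_p_max = as.numeric(oops_p_max),
    r_min = as.numeric(r_min),
    opposing_compartment_pct = as.numeric(opposing_compartment_pct),
    rpkm_min = as.numeric(rpkm_min),
    min_reads = as.integer(min_reads),
    min_hit_bases = as.integer(min_hit_bases),
    window_bp = as.integer(window_bp),
    n_fractions = as.integer(n_fractions),
    rna_pct_cyt_min = as.numeric(rna_pct_cyt_min),
    replicates = as.integer(replicates),
    rng_seed = as.integer(rng_seed)
  )
  thresholds <- c("oops_fc_min", "oops_p_max", "r_min",
                  "opposing_compartment_pct", "rpkm_min", "min_reads",
                  "min_hit_bases", "window_bp")
  for (nm in thresholds) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("config threshold '", nm, "' must be strictly positive",
           call. = FALSE)
    }
  }
  if (cfg$n_fractions < 3L) {
    stop("n_fractions must be >= 3", call. = FALSE)
  }
  structure(cfg, class = "gradr_config")
}

#' Read a configuration from a YAML file
#'
#' Keys missing from the file keep their defaults; unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path YAML file with any subset of [gradr_config()] fields.
#' @return A \code{gradr_config}.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must contain a key: value mapping",
                          call. = FALSE)
  known <- names(formals(gradr_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(gradr_config, raw)
}

#' @export
print.gradr_config <- function(x, ...) {
  cat("gradr configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
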