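#' Specification for a synthetic co-sedimentome
#'
#' Describes a planted ground truth the simulator turns into every input
#' table the predictor consumes: RNA-protein complexes co-sedimenting as
#' Gaussian peaks over the gradient, RNase-dependent OOPS enrichment for
#' true RNA-binding proteins, compartment-restricted detection, replicate
#' noise and spike-in read counts.
#'
#' Default condition: two well-separated complexes (peaks at fractions 5
#' and 18, width 1.5) over 22 fractions, one cytoplasmic and one nuclear,
#' with three replicates, multiplicative log-normal noise of sd 0.1 and a
#' four-fold OOPS elution effect for true RNA-binding proteins.
#'
#' @param n_fractions gradient fractions (default 22).
#' @param complexes list of complexes, each a list with peak_fraction,
#'   peak_width, n_proteins, n_rnas, compartment ("cytoplasmic" or
#'   "nuclear").
#' @param n_background_proteins proteins with random sedimentation peaks,
#'   not in any complex.
#' @param frac_background_rbp fraction of background proteins that are
#'   true RNA-binding proteins (pass OOPS despite not co-sedimenting).
#' @param frac_background_mito fraction of background proteins annotated
#'   mitochondrial.
#' @param noise_sd sd of multiplicative log-normal noise on fraction
#'   values and replicate abundances.
#' @param oops_effect RNase+/- abundance ratio of true RNA-binding
#'   proteins (> 1).
#' @param replicates replicate count for OOPS and fractionation tables.
#' @param spike_fraction_range range the per-sample spike-in read
#'   fraction is drawn from.
#' @param rng_seed integer seed; the single source of randomness.
#' @return list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_fractions = 22L,
                            complexes = list(
                              list(peak_fraction = 5, peak_width = 1.5,
                                   n_proteins = 8L, n_rnas = 3L,
                                   compartment = "cytoplasmic"),
                              list(peak_fraction = 18, peak_width = 1.5,
                                   n_proteins = 8L, n_rnas = 3L,
                                   compartment = "nuclear")),
                            n_background_proteins = 30L,
                            frac_background_rbp = 0.3,
                            frac_background_mito = 0.2,
                            noise_sd = 0.1,
                            oops_effect = 4,
                            replicates = 3L,
                            spike_fraction_range = c(0.01, 0.03),
                            rng_seed = 1L) {
  spec <- list(n_fractions = as.integer(n_fractions),
               complexes = complexes,
               n_background_proteins = as.integer(n_background_proteins),
               frac_background_rbp = frac_background_rbp,
               frac_background_mito = frac_background_mito,
               noise_sd = noise_sd,
               oops_effect = oops_effect,
               replicates = as.integer(replicates),
               spike_fraction_range = spike_fraction_range,
               rng_seed = as.integer(rng_seed))
  if (length(spec$complexes) == 0 && spec$n_background_proteins == 0) {
    stop("infeasible spec: no complexes and no background proteins",
         call. = FALSE)
  }
  for (cx in spec$complexes) {
    if (cx$peak_fraction < 1 || cx$peak_fraction > spec$n_fractions) {
      stop("peak_fraction outside the gradient", call. = FALSE)
    }
    if (cx$peak_width <= 0) stop("peak_width must be > 0", call. = FALSE)
    if (!cx$compartment %in% c("cytoplasmic", "nuclear")) {
      stop("complex compartment must be cytoplasmic or nuclear",
           call. = FALSE)
    }
  }
  if (spec$frac_background_rbp < 0 || spec$frac_background_rbp > 1 ||
      spec$frac_background_mito < 0 || spec$frac_background_mito > 1) {
    stop("background fractions must lie in [0, 1]", call. = FALSE)
  }
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spec$oops_effect <= 1) stop("oops_effect must be > 1", call. = FALSE)
  structure(spec, class = "simulation_spec")
}

# Gaussian sedimentation shape scaled to a peak abundance of 100.
peak_shape <- function(n_fractions, peak, width) {
  s <- dnorm(seq_len(n_fractions), mean = peak, sd = width)
  100 * s / max(s)
}

# Multiplicative log-normal noise; exactly 1 when sd is 0 so that
# noiseless complex members share identical profiles.
ln_noise <- function(n, sd) {
  if (sd == 0) rep(1, n) else exp(rnorm(n, 0, sd))
}

#' Simulate a co-sedimentome with planted ground truth
#'
#' Generates gradient profiles, OOPS replicate tables, cytoplasm/nucleus
#' localization tables, spike-in read counts and a mitochondrial list
#' from a [simulation_spec()], together with the planted truth
#' (interactions, RNA-binding proteins, compartments). Identical seeds
#' give byte-identical output files.
#'
#' Complex members share a Gaussian sedimentation shape perturbed by
#' log-normal noise; complex proteins are all true RNA-binding proteins
#' with an RNase+/- ratio of \code{oops_effect}, background proteins
#' have ratio ~1 unless planted as background RNA-binding proteins.
#' Entities carry 80-95% of their signal in their own compartment, so
#' every complex member is detectable and compartment-eligible there.
#'
#' @param spec a [simulation_spec()].
#' @param out_dir optional directory; when given, all tables are written
#'   as TSV/text in the formats the readers expect, plus the truth.
#' @return list with elements \code{rna_profiles}, \code{protein_profiles}
#'   (gradient matrices), \code{oops} (treat/ctrl matrices),
#'   \code{rna_loc}, \code{protein_loc} (localization tables),
#'   \code{spikes}, \code{mito_ids} and \code{truth} (list: interactions
#'   data.frame, rbp_ids, compartment_of, mito_ids).
#' @export
simulate_cosedimentome <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$rng_seed)
  nf <- spec$n_fractions
  reps <- spec$replicates

  rna_ids <- character(); prot_ids <- character()
  rna_rows <- list(); prot_rows <- list()
  compartment_of <- character()
  interactions <- list()

  for (k in seq_along(spec$complexes)) {
    cx <- spec$complexes[[k]]
    shape <- peak_shape(nf, cx$peak_fraction, cx$peak_width)
    r_ids <- sprintf("RNA_C%d_%02d", k, seq_len(cx$n_rnas))
    p_ids <- sprintf("PROT_C%d_%02d", k, seq_len(cx$n_proteins))
    for (id in r_ids) rna_rows[[id]] <- shape * ln_noise(nf, spec$noise_sd)
    for (id in p_ids) prot_rows[[id]] <- shape * ln_noise(nf, spec$noise_sd)
    rna_ids <- c(rna_ids, r_ids)
    prot_ids <- c(prot_ids, p_ids)
    compartment_of[c(r_ids, p_ids)] <- cx$compartment
    interactions[[k]] <- expand.grid(rna_id = r_ids, protein_id = p_ids,
                                     stringsAsFactors = FALSE)
  }
  complex_prots <- prot_ids

  bg_ids <- character()
  if (spec$n_background_proteins > 0) {
    bg_ids <- sprintf("PROT_BG_%03d", seq_len(spec$n_background_proteins))
    for (id in bg_ids) {
      pk <- runif(1, 1, nf)
      wd <- runif(1, 1, 3)
      prot_rows[[id]] <- peak_shape(nf, pk, wd) * ln_noise(nf, spec$noise_sd)
    }
    prot_ids <- c(prot_ids, bg_ids)
    compartment_of[bg_ids] <- ifelse(runif(length(bg_ids)) < 0.5,
                                     "cytoplasmic", "nuclear")
  }

  n_bg_rbp <- round(spec$frac_background_rbp * length(bg_ids))
  bg_rbps <- if (n_bg_rbp > 0) sample(bg_ids, n_bg_rbp) else character()
  rbp_ids <- c(complex_prots, bg_rbps)
  n_mito <- round(spec$frac_background_mito * length(bg_ids))
  mito_ids <- if (n_mito > 0) sample(bg_ids, n_mito) else character()

  rna_profiles <- gradient_matrix(do.call(rbind, rna_rows), "rna")
  protein_profiles <- gradient_matrix(do.call(rbind, prot_rows), "protein")

  # OOPS replicate tables: true RNA-binding proteins elute oops_effect-fold
  # more after RNase treatment; others elute equally.
  base <- exp(rnorm(length(prot_ids), log(1000), 0.5))
  names(base) <- prot_ids
  treat <- matrix(0, length(prot_ids), reps,
                  dimnames = list(prot_ids, paste0("treat_", seq_len(reps))))
  ctrl <- matrix(0, length(prot_ids), reps,
                 dimnames = list(prot_ids, paste0("ctrl_", seq_len(reps))))
  for (id in prot_ids) {
    eff <- if (id %in% rbp_ids) spec$oops_effect else 1
    treat[id, ] <- base[id] * eff * ln_noise(reps, spec$noise_sd)
    ctrl[id, ] <- base[id] * ln_noise(reps, spec$noise_sd)
  }

  # Localization: 80-95% of signal in the home compartment per replicate.
  make_loc <- function(ids, class) {
    tot <- matrix(exp(rnorm(length(ids) * reps, log(500), 0.3)),
                  length(ids), reps, dimnames = list(ids, NULL))
    share <- matrix(runif(length(ids) * reps, 0.80, 0.95),
                    length(ids), reps)
    home_cyt <- compartment_of[ids] == "cytoplasmic"
    share[!home_cyt, ] <- 1 - share[!home_cyt, ]
    cyt <- tot * share
    nuc <- tot - cyt
    colnames(cyt) <- colnames(nuc) <- paste0("rep", seq_len(reps))
    localization_table(cyt, nuc, class)
  }
  rna_loc <- make_loc(rna_ids, "rna")
  protein_loc <- make_loc(prot_ids, "protein")

  spike_frac <- runif(2 * reps, spec$spike_fraction_range[1],
                      spec$spike_fraction_range[2])
  human_reads <- rep(1e6, 2 * reps)
  spikes <- data.frame(
    sample_id = c(paste0("cyt_rep", seq_len(reps)),
                  paste0("nuc_rep", seq_len(reps))),
    human_reads = as.integer(human_reads),
    spike_reads = as.integer(round(human_reads * spike_frac /
                                     (1 - spike_frac))),
    stringsAsFactors = FALSE)

  truth <- list(interactions = do.call(rbind, interactions),
                rbp_ids = sort(rbp_ids),
                compartment_of = compartment_of,
                mito_ids = sort(mito_ids))

  sim <- list(rna_profiles = rna_profiles,
              protein_profiles = protein_profiles,
              oops = list(treat = treat, ctrl = ctrl),
              rna_loc = rna_loc, protein_loc = protein_loc,
              spikes = spikes, mito_ids = sort(mito_ids), truth = truth,
              spec = spec)

  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

#' Write simulator output to a directory
#'
#' Emits every file the prediction pipeline consumes plus the serialized
#' ground truth, all as plain TSV/text.
#'
#' @param sim result of [simulate_cosedimentome()].
#' @param out_dir output directory (created if needed).
#' @return \code{out_dir}, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_gradient_matrix(sim$rna_profiles, fp("rna_profiles.tsv"))
  write_gradient_matrix(sim$protein_profiles, fp("protein_profiles.tsv"))
  write_tsv(data.frame(protein_id = rownames(sim$oops$treat),
                       sim$oops$treat, sim$oops$ctrl, check.names = FALSE),
            fp("oops.tsv"))
  loc_df <- function(loc) {
    cyt <- loc$cyt; nuc <- loc$nuc
    colnames(cyt) <- paste0("cyt_", colnames(cyt))
    colnames(nuc) <- paste0("nuc_", colnames(nuc))
    data.frame(entity_id = rownames(cyt), cyt, nuc, check.names = FALSE)
  }
  write_tsv(loc_df(sim$rna_loc), fp("rna_localization.tsv"))
  write_tsv(loc_df(sim$protein_loc), fp("protein_localization.tsv"))
  write_tsv(sim$spikes, fp("spikein.tsv"))
  writeLines(sim$mito_ids, fp("mito_proteins.txt"))
  write_tsv(sim$truth$interactions, fp("truth_interactions.tsv"))
  write_tsv(data.frame(entity_id = names(sim$truth$compartment_of),
                       compartment = unname(sim$truth$compartment_of),
                       is_rbp = names(sim$truth$compartment_of) %in%
                         sim$truth$rbp_ids,
                       is_mito = names(sim$truth$compartment_of) %in%
                         sim$truth$mito_ids),
            fp("truth_entities.tsv"))
  invisible(out_dir)
}

#' Build a combined dataset from simulator output
#'
#' Runs the evidence-layer derivations (OOPS enrichment testing and
#' RNA-binding calls, compartment calls and eligibility) on simulator
#' tables and assembles the [combined_dataset()] the predictor takes.
#'
#' @param sim result of [simulate_cosedimentome()].
#' @param cfg a [gradr_config()].
#' @return A \code{combined_dataset}.
#' @export
as_combined_dataset <- function(sim, cfg = gradr_config()) {
  oops <- enrichment_table(sim$oops$treat, sim$oops$ctrl)
  combined_dataset(
    rna_profiles = sim$rna_profiles,
    protein_profiles = sim$protein_profiles,
    oops = oops,
    rna_compartment = call_rna_compartment(sim$rna_loc, cfg),
    protein_elig_cyt = protein_compartment_eligibility(sim$protein_loc,
                                                       "cytoplasmic", cfg),
    protein_elig_nuc = protein_compartment_eligibility(sim$protein_loc,
                                                       "nuclear", cfg),
    mito_list = sim$mito_ids)
}

#' Score predictions against planted ground truth
#'
#' Precision, recall and F1 of the passed (rna, protein) pairs against
#' the planted interactions. An empty prediction set has undefined
#' precision; it is reported as 0 with \code{empty_pred = TRUE}.
#'
#' @param pred prediction table from [interactome_all()] (or any
#'   data.frame with rna_id, protein_id and passed columns; rows with
#'   \code{passed} FALSE are ignored).
#' @param truth truth list from the simulator (or a data.frame of
#'   interactions).
#' @return list: precision, recall, f1, n_pred, n_truth, empty_pred.
#' @export
score_predictions <- function(pred, truth) {
  ti <- if (is.data.frame(truth)) truth else truth$interactions
  if ("passed" %in% names(pred)) pred <- pred[pred$passed, , drop = FALSE]
  pred_pairs <- unique(paste(pred$rna_id, pred$protein_id, sep = "\r"))
  truth_pairs <- unique(paste(ti$rna_id, ti$protein_id, sep = "\r"))
  pred_univ <- unique(c(pred$rna_id, pred$protein_id))
  truth_univ <- unique(c(ti$rna_id, ti$protein_id))
  if (length(pred_pairs) > 0 &&
      length(intersect(pred_univ, truth_univ)) == 0) {
    stop("prediction and truth refer to disjoint entity universes",
         call. = FALSE)
  }
  tp <- length(intersect(pred_pairs, truth_pairs))
  empty <- length(pred_pairs) == 0
  precision <- if (empty) 0 else tp / length(pred_pairs)
  recall <- if (length(truth_pairs) == 0) NA_real_ else
    tp / length(truth_pairs)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_pred = length(pred_pairs), n_truth = length(truth_pairs),
       empty_pred = empty)
}

#' Read simulator output back from a directory
#'
#' Inverse of [write_simulation()]; used by the command-line pipeline.
#'
#' @param dir directory written by [write_simulation()].
#' @return list in the shape of [simulate_cosedimentome()] output
#'   (without \code{spec}).
#' @export
read_simulation <- function(dir) {
  fp <- function(f) file.path(dir, f)
  truth_int <- read.delim(fp("truth_interactions.tsv"),
                          colClasses = "character")
  ent <- read.delim(fp("truth_entities.tsv"))
  list(rna_profiles = read_gradient_matrix(fp("rna_profiles.tsv"), "rna"),
       protein_profiles = read_gradient_matrix(fp("protein_profiles.tsv"),
                                               "protein"),
       oops = read_replicate_table(fp("oops.tsv")),
       rna_loc = read_localization_table(fp("rna_localization.tsv"), "rna"),
       protein_loc = read_localization_table(fp("protein_localization.tsv"),
                                             "protein"),
       spikes = read.delim(fp("spikein.tsv")),
       mito_ids = read_id_list(fp("mito_proteins.txt")),
       truth = list(interactions = truth_int,
                    rbp_ids = as.character(ent$entity_id[ent$is_rbp]),
                    compartment_of = setNames(as.character(ent$compartment),
                                              ent$entity_id),
                    mito_ids = as.character(ent$entity_id[ent$is_mito])))
}
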