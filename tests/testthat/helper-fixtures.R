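# Shared in-code fixtures.

# Ten-protein hand-built dataset exercising every filter rule:
# an RBP failing fold-change, one failing p, compartment-ineligible
# proteins, a mitochondrial protein with near-perfect correlation to the
# nuclear RNA, and proteins on either side of the r threshold.
make_filter_fixture <- function() {
  nf <- 10
  base_cyt <- dnorm(1:nf, 3, 1); base_cyt <- 100 * base_cyt / max(base_cyt)
  base_nuc <- dnorm(1:nf, 8, 1); base_nuc <- 100 * base_nuc / max(base_nuc)
  ramp <- seq(1, 10, length.out = nf)

  rna <- rbind(RNA_CYT = base_cyt, RNA_NUC = base_nuc)
  prot <- rbind(
    P_good_cyt   = base_cyt,                 # perfect cytoplasmic partner
    P_good_nuc   = base_nuc,                 # perfect nuclear partner
    P_lowfc      = base_cyt,                 # correlates, fails OOPS fc
    P_highp      = base_cyt,                 # correlates, fails OOPS p
    P_wrongcomp  = base_cyt,                 # correlates, nuclear-only
    P_mito       = base_nuc * c(1.02, rep(1, nf - 1)), # r ~ 1, mitochondrial
    P_lowr       = ramp,                     # RBP, eligible, r < 0.5
    P_border     = base_cyt,                 # fc exactly 2, p exactly 0.05
    P_undetected = base_cyt,                 # missing in one cyt replicate
    P_notrbp     = base_cyt                  # fc ~ 1
  )
  colnames(rna) <- colnames(prot) <- paste0("F", 1:nf)

  oops <- data.frame(
    protein_id = rownames(prot),
    fold_change = c(4, 4, 1.99, 4, 4, 4, 4, 2.0, 4, 1.0),
    p_value =     c(0.01, 0.01, 0.001, 0.06, 0.01, 0.01, 0.01, 0.05,
                    0.01, 0.5),
    stringsAsFactors = FALSE)

  reps <- 3
  cyt <- matrix(80, nrow(prot), reps,
                dimnames = list(rownames(prot), paste0("rep", 1:reps)))
  nuc <- matrix(20, nrow(prot), reps,
                dimnames = list(rownames(prot), paste0("rep", 1:reps)))
  # nuclear-side proteins
  for (p in c("P_good_nuc", "P_mito")) {
    cyt[p, ] <- 20; nuc[p, ] <- 80
  }
  # detected in nucleus only in all reps, >= 60% nuclear in all reps
  cyt["P_wrongcomp", ] <- c(30, 30, 30); nuc["P_wrongcomp", ] <- 70
  # undetected in one cytoplasmic replicate
  cyt["P_undetected", 2] <- 0

  rna_cyt <- matrix(c(90, 85, 88, 10, 12, 9), 2, 3, byrow = TRUE,
                    dimnames = list(rownames(rna), paste0("rep", 1:3)))
  rna_nuc <- matrix(c(10, 15, 12, 90, 88, 91), 2, 3, byrow = TRUE,
                    dimnames = list(rownames(rna), paste0("rep", 1:3)))

  cfg <- gradr_config()
  rna_loc <- localization_table(rna_cyt, rna_nuc, "rna")
  prot_loc <- localization_table(cyt, nuc, "protein")
  ds <- combined_dataset(
    rna_profiles = gradient_matrix(rna, "rna"),
    protein_profiles = gradient_matrix(prot, "protein"),
    oops = oops,
    rna_compartment = call_rna_compartment(rna_loc, cfg),
    protein_elig_cyt = protein_compartment_eligibility(prot_loc,
                                                       "cytoplasmic", cfg),
    protein_elig_nuc = protein_compartment_eligibility(prot_loc,
                                                       "nuclear", cfg),
    mito_list = "P_mito")
  list(ds = ds, cfg = cfg, rna = rna, prot = prot, oops = oops,
       prot_cyt = cyt, prot_nuc = nuc, rna_loc = rna_loc,
       prot_loc = prot_loc)
}

# Toy count table matching the expressed-RNA filter rules.
make_count_fixture <- function() {
  samples <- data.frame(
    sample_id = c("A_r1", "A_r2", "B_r1", "B_r2"),
    condition = c("A", "A", "B", "B"),
    replicate = c("r1", "r2", "r1", "r2"),
    stringsAsFactors = FALSE)
  rpkm <- rbind(
    keep_condA   = c(0.6, 0.7, 0.1, 0.2),  # all reps of A pass
    drop_onerep  = c(0.6, 0.4, 0.6, 0.4),  # one replicate below in each
    drop_lowread = c(5, 5, 5, 5),          # RPKM fine, too few reads
    keep_condB   = c(0.1, 0.1, 2, 3),
    drop_alllow  = c(0.1, 0.2, 0.3, 0.1))
  counts <- rbind(
    keep_condA   = c(50L, 40L, 5L, 5L),
    drop_onerep  = c(50L, 40L, 50L, 40L),
    drop_lowread = c(9L, 8L, 9L, 7L),
    keep_condB   = c(2L, 1L, 30L, 40L),
    drop_alllow  = c(100L, 90L, 80L, 70L))
  colnames(rpkm) <- colnames(counts) <- samples$sample_id
  count_table(counts, rpkm, samples)
}
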