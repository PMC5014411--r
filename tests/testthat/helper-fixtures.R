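# Small handcrafted fixtures shared across test files, plus a cached default
# synthetic study so expensive generation happens once per run.

# Two-gene toy proteome. GENE1 carries two SAP loci (one per tryptic
# segment); GENE2 is an unrelated sequence.
toy_proteome <- function() {
  protein_set(accession = c("P001", "P002"),
              gene = c("GENE1", "GENE2"),
              sequence = c("ACDEFGHIKSTAYVLNWEDRGGFHSTK",
                           "MFWYHSTEEKVLDAGHSIR"))
}

toy_snps <- function() {
  as_snp_table(data.frame(
    rs_id = c("rs1", "rs2"),
    gene = "GENE1", accession = "P001",
    pos = c(3L, 12L), ref_aa = c("D", "A"), alt_aa = c("N", "V"),
    ref_nuc = c("G", "C"), alt_nuc = c("A", "T"),
    count_EUR = c(120, 40), size_EUR = c(379, 379),
    maf_EUR = c(0.18, 0.06),
    count_AFR = c(30, 90), size_AFR = c(246, 246),
    maf_AFR = c(0.07, 0.21),
    stringsAsFactors = FALSE))
}

# panel of 4 individuals at one locus: C/C, C/T, T/T, C/T
toy_panel <- function() {
  population_panel("TOY", data.frame(
    individual_id = paste0("I", 1:4), rs_id = "rs1",
    a1 = c("C", "C", "T", "C"), a2 = c("C", "T", "T", "T"),
    stringsAsFactors = FALSE))
}

# One cached synthetic study per (sensitivity, fpr, decoys, subjects).
.study_cache <- new.env(parent = emptyenv())
cached_study <- function(seed = 7, sensitivity = 1, fpr = 0,
                         decoys = FALSE, n_subjects = 20) {
  key <- paste(seed, sensitivity, fpr, decoys, n_subjects, sep = "_")
  if (is.null(.study_cache[[key]])) {
    cfg <- sim_config(seed = seed, detection_sensitivity = sensitivity,
                      false_positive_rate = fpr, decoys = decoys,
                      n_subjects = n_subjects)
    pr <- simulate_proteome(cfg)
    catalog <- enumerate_gvps(pr$proteome, pr$snps)
    truth <- simulate_subjects(cfg)
    psms <- simulate_detections(truth, catalog, cfg)
    .study_cache[[key]] <- list(config = cfg, proteome = pr$proteome,
                                snps = pr$snps, catalog = catalog,
                                truth = truth, psms = psms)
  }
  .study_cache[[key]]
}

# a minimal passing PSM row for filter tests
toy_psm <- function(peptide, engine = "xtandem", score = -5,
                    obs_mass = NULL, theo_mass = NULL,
                    mods = NA_character_, fragments = NA_character_) {
  m <- peptide_mass(peptide)
  data.frame(subject = "S1", sample = "S1_h", peptide = peptide,
             engine = engine, score = score,
             obs_mass = obs_mass %||% m, theo_mass = theo_mass %||% m,
             mods = mods, fragments = fragments,
             proteins = NA_character_, decoy_rule = NA_character_,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
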