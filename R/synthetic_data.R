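# Residues the generator samples from: canonical minus K/R/P (cleavage
# control) and minus C (mass table simplicity at the fixture level).
SIM_ALPHABET <- c("A", "S", "T", "V", "G", "E", "D", "F", "H", "I", "L",
                  "M", "N", "Q", "W", "Y")

#' Default synthetic nsSNP locus set
#'
#' Twelve loci over eight synthetic trichocyte-keratin-like genes (two genes
#' carry two loci each, exercising within-gene combination counting), with
#' alternative-allele frequencies spanning the common-SNP regime the method
#' targets, and deliberately different frequencies in the two populations so
#' likelihood ratios are informative. All substitutions avoid the
#' chemically confusable pairs.
#'
#' @return data frame with columns `gene`, `rs_id`, `ref_aa`, `alt_aa`,
#'   `ref_nuc`, `alt_nuc`, `af_EUR`, `af_AFR`, `role`.
#' @export
default_sim_loci <- function() {
  data.frame(
    gene = c("KRT31", "KRT32", "KRT32", "KRT33A", "KRT34", "KRT35",
             "KRT81", "KRT81", "KRT83", "KRT86", "JUP", "VSIG8"),
    rs_id = paste0("rs", 101:112),
    ref_aa = c("A", "T", "S", "G", "V", "L", "E", "D", "F", "I", "H", "M"),
    alt_aa = c("V", "M", "L", "E", "A", "V", "G", "A", "L", "V", "Y", "T"),
    ref_nuc = c("C", "C", "T", "G", "T", "C", "A", "A", "T", "A", "C", "A"),
    alt_nuc = c("T", "T", "C", "A", "C", "G", "G", "C", "C", "G", "T", "C"),
    af_EUR = c(0.30, 0.12, 0.25, 0.45, 0.08, 0.20, 0.35, 0.15, 0.05,
               0.40, 0.10, 0.22),
    af_AFR = c(0.08, 0.30, 0.10, 0.20, 0.25, 0.05, 0.15, 0.40, 0.18,
               0.12, 0.35, 0.06),
    role = "standard",
    stringsAsFactors = FALSE)
}

# Extra loci used only to build filter-audit decoys: a rare locus (fails the
# frequency rule), a chemically confusable N->D locus, and a locus whose
# peptide is embedded in a second gene (fails uniqueness).
decoy_sim_loci <- function() {
  data.frame(
    gene = c("KRTAP1", "KRTAP2", "KRTAP3"),
    rs_id = c("rs901", "rs902", "rs903"),
    ref_aa = c("A", "N", "S"),
    alt_aa = c("G", "D", "A"),
    ref_nuc = c("G", "A", "C"),
    alt_nuc = c("A", "G", "A"),
    af_EUR = c(0.001, 0.25, 0.30),
    af_AFR = c(0.001, 0.25, 0.30),
    role = c("rare", "confusable", "shared"),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' The stated world for the synthetic study: a diploid genotype panel under
#' Hardy-Weinberg equilibrium at each locus, subjects drawn from the same
#' law, and a binary peptide-detection process.
#'
#' @param loci locus table as from [default_sim_loci()].
#' @param panel_sizes named vector, population label -> panel size
#'   (default `c(EUR = 400, AFR = 250)`, emulating reference panels of a
#'   few hundred individuals).
#' @param n_subjects number of study subjects (default 20).
#' @param detection_sensitivity per-GVP probability that a carried allele
#'   yields a passing PSM (default 0.9).
#' @param false_positive_rate per-GVP probability of a spurious passing PSM
#'   for an allele the subject lacks (default 0.01).
#' @param seed integer master seed (required).
#' @param decoys include decoy loci and decoy PSMs for filter audits.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(loci = default_sim_loci(),
                       panel_sizes = c(EUR = 400, AFR = 250),
                       n_subjects = 20, detection_sensitivity = 0.9,
                       false_positive_rate = 0.01, seed, decoys = FALSE) {
  stopifnot(!missing(seed), is.numeric(seed),
            detection_sensitivity >= 0, detection_sensitivity <= 1,
            false_positive_rate >= 0, false_positive_rate <= 1,
            all(panel_sizes >= 1), !is.null(names(panel_sizes)))
  af_cols <- grep("^af_", names(loci), value = TRUE)
  stopifnot(length(af_cols) > 0,
            all(unlist(loci[af_cols]) >= 0), all(unlist(loci[af_cols]) <= 1))
  if (decoys) loci <- rbind(loci, decoy_sim_loci())
  if (!"role" %in% names(loci)) loci$role <- "standard"
  structure(list(loci = loci, panel_sizes = panel_sizes,
                 n_subjects = n_subjects,
                 detection_sensitivity = detection_sensitivity,
                 false_positive_rate = false_positive_rate,
                 seed = as.integer(seed), decoys = decoys),
            class = "sim_config")
}

#' Simulate a proteome carrying the configured SAP loci
#'
#' Each gene's sequence is a concatenation of short random tryptic segments
#' (ending in K or R, never followed by P); every locus is planted in the
#' interior of its own segment, so each SAP sits inside a well-formed
#' tryptic peptide. For the `shared` decoy role the SAP-bearing peptide is
#' additionally embedded in a second protein to defeat the uniqueness
#' screen.
#'
#' @param config a [sim_config()].
#' @return list with `proteome` (a [protein_set()]) and `snps` (an
#'   `snp_table` with positions and per-population counts filled in).
#' @export
simulate_proteome <- function(config) {
  loci <- config$loci
  pops <- sub("^af_", "", grep("^af_", names(loci), value = TRUE))
  with_seed(config$seed + 11L, {
    genes <- unique(loci$gene)
    seqs <- character(length(genes))
    acc <- paste0("SYN", formatC(seq_along(genes), width = 3, flag = "0"))
    names(acc) <- genes
    loci$accession <- acc[loci$gene]
    loci$pos <- NA_integer_
    for (gi in seq_along(genes)) {
      g <- genes[gi]
      idx <- which(loci$gene == g)
      n_seg <- max(8L, 2L * length(idx) + 4L)
      segs <- lapply(seq_len(n_seg), function(j) {
        len <- sample(6:11, 1)
        c(sample(SIM_ALPHABET, len, replace = TRUE),
          sample(c("K", "R"), 1))
      })
      # plant each locus mid-segment, in distinct even segments
      seg_for <- seq(2L, by = 2L, length.out = length(idx))
      offset <- 0L
      for (j in seq_len(n_seg)) {
        hit <- which(seg_for == j)
        if (length(hit)) {
          k <- idx[hit]
          at <- max(2L, length(segs[[j]]) %/% 2L)
          segs[[j]][at] <- loci$ref_aa[k]
          loci$pos[k] <- offset + at
        }
        offset <- offset + length(segs[[j]])
      }
      seqs[gi] <- paste(unlist(segs), collapse = "")
    }
    # shared-role loci: copy the SAP-containing 0-missed peptide into the
    # next gene's sequence (appended after its final K/R)
    for (k in which(loci$role == "shared")) {
      host <- match(loci$gene[k], genes)
      other <- if (host < length(genes)) host + 1L else host - 1L
      dg <- digest(seqs[host], 0)
      pep <- dg$peptide[dg$start <= loci$pos[k] & dg$end >= loci$pos[k]]
      seqs[other] <- paste0(seqs[other], pep[1])
    }
    proteome <- protein_set(unname(acc), genes, seqs)
    for (p in pops) {
      q <- loci[[paste0("af_", p)]]
      n <- unname(config$panel_sizes[p])
      loci[[paste0("count_", p)]] <- round(n * (1 - (1 - q)^2))
      loci[[paste0("size_", p)]] <- n
      loci[[paste0("maf_", p)]] <- pmin(q, 1 - q)
    }
    list(proteome = proteome, snps = as_snp_table(loci))
  })
}

.draw_genotypes <- function(ids, loci, af_col, seed) {
  with_seed(seed, {
    rows <- list()
    for (k in seq_len(nrow(loci))) {
      q <- loci[[af_col]][k]
      a1 <- ifelse(stats::runif(length(ids)) < q, loci$alt_nuc[k],
                   loci$ref_nuc[k])
      a2 <- ifelse(stats::runif(length(ids)) < q, loci$alt_nuc[k],
                   loci$ref_nuc[k])
      rows[[k]] <- data.frame(individual_id = ids, rs_id = loci$rs_id[k],
                              a1 = a1, a2 = a2, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Simulate a Hardy-Weinberg genotype panel
#'
#' Each individual's diploid genotype is drawn independently per locus with
#' genotype probabilities (1-q)^2, 2q(1-q), q^2 for alternative-allele
#' frequency q.
#'
#' @param config a [sim_config()].
#' @param population population label (must match an `af_POP` column).
#' @return a [population_panel()].
#' @export
simulate_panel <- function(config, population) {
  af_col <- paste0("af_", population)
  stopifnot(af_col %in% names(config$loci))
  n <- unname(config$panel_sizes[population])
  ids <- paste0(population, "_", formatC(seq_len(n), width = 5, flag = "0"))
  pop_idx <- match(population, names(config$panel_sizes))
  g <- .draw_genotypes(ids, config$loci, af_col,
                       config$seed + 100L + pop_idx)
  population_panel(population, g)
}

#' Simulate study subjects (truth genotypes)
#'
#' Subjects are drawn from the same Hardy-Weinberg law as the panels of the
#' first configured population (they represent members of that population).
#'
#' @param config a [sim_config()].
#' @param population which population the subjects belong to; default the
#'   first `af_POP` column.
#' @return a `truth_genotypes` data frame (all calls `"called"`).
#' @export
simulate_subjects <- function(config, population = NULL) {
  af_cols <- grep("^af_", names(config$loci), value = TRUE)
  population <- population %||% sub("^af_", "", af_cols[1])
  ids <- paste0("S", formatC(seq_len(config$n_subjects), width = 3,
                             flag = "0"))
  g <- .draw_genotypes(ids, config$loci, paste0("af_", population),
                       config$seed + 31L)
  out <- data.frame(subject_id = g$individual_id, rs_id = g$rs_id,
                    a1 = g$a1, a2 = g$a2, status = "called",
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_genotypes", "data.frame")
  out
}

# One representative imputation-grade catalog entry per (gene, rs, allele):
# unique, non-confusable, frequency-passing, single-SAP, fully cleaved.
.representative_entries <- function(catalog, config = filter_config()) {
  maf_cols <- grep("^maf_", names(catalog), value = TRUE)
  freq_ok <- if (length(maf_cols)) {
    m <- as.matrix(catalog[, maf_cols, drop = FALSE])
    apply(m, 1, function(r) any(!is.na(r) & r >= config$freq_threshold))
  } else rep(TRUE, nrow(catalog))
  cand <- catalog[catalog$unique & !catalog$confusable & freq_ok &
                    catalog$n_sap == 1, , drop = FALSE]
  cand <- cand[order(cand$missed_cleavages, nchar(cand$peptide)), ,
               drop = FALSE]
  key <- paste(cand$gene, cand$alleles)
  cand[!duplicated(key), , drop = FALSE]
}

#' Simulate a PSM table from truth genotypes
#'
#' The binary detection model: every allele a subject carries yields a
#' passing PSM with probability `detection_sensitivity`; every catalogued
#' allele the subject lacks yields a spurious passing PSM with probability
#' `false_positive_rate`. Emitted PSMs carry scores and masses that pass
#' all filters. With `config$decoys`, seven additional PSMs are emitted,
#' each crafted to violate exactly one exclusion rule, labelled in the
#' `decoy_rule` column (which the pipeline itself ignores).
#'
#' @param truth a `truth_genotypes` from [simulate_subjects()].
#' @param catalog the `gvp_catalog` for the simulated proteome.
#' @param config a [sim_config()].
#' @return a `psm_table`.
#' @export
simulate_detections <- function(truth, catalog, config) {
  reps <- .representative_entries(catalog)
  subjects <- unique(truth$subject_id)
  truth_key <- paste(truth$subject_id, truth$rs_id)
  with_seed(config$seed + 41L, {
    rows <- list()
    for (s in subjects) {
      for (e in seq_len(nrow(reps))) {
        al <- parse_alleles(reps$alleles[e])
        t_idx <- match(paste(s, al$rs_id[1]), truth_key)
        carried <- !is.na(t_idx) && truth$status[t_idx] == "called" &&
          (truth$a1[t_idx] == al$nuc[1] || truth$a2[t_idx] == al$nuc[1])
        p <- if (carried) config$detection_sensitivity
        else config$false_positive_rate
        if (stats::runif(1) < p) {
          m <- peptide_mass(reps$peptide[e])
          rows[[length(rows) + 1L]] <- data.frame(
            subject = s, sample = paste0(s, "_hair1"),
            peptide = reps$peptide[e], engine = "xtandem", score = -5,
            obs_mass = m, theo_mass = m, mods = NA_character_,
            fragments = NA_character_,
            proteins = reps$accession[e], decoy_rule = NA_character_,
            stringsAsFactors = FALSE)
        }
      }
    }
    psms <- if (length(rows)) do.call(rbind, rows)
    else data.frame(subject = character(0), sample = character(0),
                    peptide = character(0), engine = character(0),
                    score = numeric(0), obs_mass = numeric(0),
                    theo_mass = numeric(0), mods = character(0),
                    fragments = character(0), proteins = character(0),
                    decoy_rule = character(0), stringsAsFactors = FALSE)
    if (config$decoys)
      psms <- rbind(psms, .decoy_psms(catalog, config, subjects[1]))
    rownames(psms) <- NULL
    class(psms) <- c("psm_table", "data.frame")
    psms
  })
}

# Seven PSMs, each violating exactly one exclusion rule.
.decoy_psms <- function(catalog, config, subject) {
  reps <- .representative_entries(catalog)
  loci <- config$loci
  entry_for_role <- function(role) {
    rs <- loci$rs_id[loci$role == role][1]
    hit <- which(vapply(catalog$alleles, function(a)
      rs %in% parse_alleles(a)$rs_id, logical(1)) &
        catalog$n_sap == 1 & catalog$missed_cleavages == 0 &
        catalog$allele_class == "variant")
    catalog[hit[1], , drop = FALSE]
  }
  good <- reps[1, , drop = FALSE]
  mk <- function(entry, rule, score = -5, dmass = 0, mods = NA_character_,
                 fragments = NA_character_) {
    m <- peptide_mass(entry$peptide)
    data.frame(subject = subject, sample = paste0(subject, "_hair1"),
               peptide = entry$peptide, engine = "xtandem", score = score,
               obs_mass = m + dmass, theo_mass = m, mods = mods,
               fragments = fragments, proteins = entry$accession,
               decoy_rule = rule, stringsAsFactors = FALSE)
  }
  frag_entry <- reps[2, , drop = FALSE]
  diag <- diagnostic_ions(frag_entry$alt_peptide, frag_entry$peptide,
                          filter_config()$fragment_tol_da)
  shared <- entry_for_role("shared")
  # a shared-role entry is non-unique whatever its allele class
  if (is.na(shared$unique) || shared$unique) {
    hit <- which(!catalog$unique)
    shared <- catalog[hit[1], , drop = FALSE]
  }
  rbind(mk(good, "score", score = -1),
        mk(good, "precursor_mass", dmass = 0.5),
        mk(entry_for_role("rare"), "frequency"),
        mk(good, "ptm", mods = "2:79.96633:Phospho"),
        mk(entry_for_role("confusable"), "confusable"),
        mk(shared, "uniqueness"),
        mk(frag_entry, "fragment",
           fragments = format(diag[1], digits = 10)))
}

#' Materialise a complete synthetic study on disk
#'
#' Writes every input the pipeline reads: variant-aware proteome FASTA,
#' nsSNP table, per-population genotype panels (both VCF and TSV), truth
#' genotypes, GVP catalog, and the PSM table.
#'
#' @param dir output directory (created if needed).
#' @param config a [sim_config()].
#' @param max_missed missed cleavages for catalog enumeration.
#' @return (invisibly) a list with the in-memory objects and file paths.
#' @export
make_fixtures <- function(dir, config, max_missed = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pr <- simulate_proteome(config)
  catalog <- enumerate_gvps(pr$proteome, pr$snps, max_missed = max_missed)
  truth <- simulate_subjects(config)
  psms <- simulate_detections(truth, catalog, config)
  pops <- names(config$panel_sizes)
  paths <- list(
    proteome = file.path(dir, "proteome.fasta"),
    variant_db = file.path(dir, "variant_db.fasta"),
    snps = file.path(dir, "snps.tsv"),
    catalog = file.path(dir, "catalog.tsv"),
    truth = file.path(dir, "truth.tsv"),
    psms = file.path(dir, "psms.tsv"))
  write_proteome_fasta(pr$proteome, paths$proteome)
  write_proteome_fasta(build_variant_database(pr$proteome, pr$snps),
                       paths$variant_db)
  write_tsv_det(as.data.frame(pr$snps), paths$snps)
  write_catalog(catalog, paths$catalog)
  write_truth_genotypes(truth, paths$truth)
  write_psm_table(psms, paths$psms)
  panels <- list()
  for (p in pops) {
    panels[[p]] <- simulate_panel(config, p)
    paths[[paste0("panel_", p, "_vcf")]] <-
      file.path(dir, paste0("panel_", p, ".vcf"))
    paths[[paste0("panel_", p, "_tsv")]] <-
      file.path(dir, paste0("panel_", p, ".tsv"))
    write_genotype_vcf(panels[[p]], pr$snps,
                       paths[[paste0("panel_", p, "_vcf")]])
    write_genotype_tsv(panels[[p]], paths[[paste0("panel_", p, "_tsv")]])
  }
  invisible(list(proteome = pr$proteome, snps = pr$snps, catalog = catalog,
                 truth = truth, psms = psms, panels = panels,
                 paths = paths, config = config))
}
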