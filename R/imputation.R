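#' Collate filtered detections into per-subject nsSNP profiles
#'
#' Reduces the filtered PSM set to the imputed profile: per subject and
#' gene, the set of distinct (rs ID, allele nucleotide) pairs implied by the
#' detected GVPs. PSM multiplicity is irrelevant — however many spectra
#' support an allele, it contributes a single observation per gene.
#' Multi-SNP peptides contribute all covered alleles jointly.
#'
#' @param detections the `detections` element of [apply_filters()] output
#'   (PSMs joined with their catalog columns, all uniqueness-screened).
#' @param subjects optional character vector of all study subjects, so that
#'   subjects with zero detections still appear (with empty profiles) in
#'   downstream validation.
#' @return data frame of class `subject_profiles` with columns
#'   `subject_id`, `gene`, `rs_id`, `allele`; the full subject roster is
#'   kept in the `"subjects"` attribute.
#' @export
collate_profile <- function(detections, subjects = NULL) {
  if (nrow(detections) && !all(detections$unique))
    stop("detection(s) reference non-unique catalog entries; ",
         "filter upstream", call. = FALSE)
  rows <- list()
  for (i in seq_len(nrow(detections))) {
    al <- parse_alleles(detections$alleles[i])
    rows[[i]] <- data.frame(subject_id = detections$subject[i],
                            gene = detections$gene[i],
                            rs_id = al$rs_id, allele = al$nuc,
                            stringsAsFactors = FALSE)
  }
  prof <- if (length(rows)) do.call(rbind, rows)
  else data.frame(subject_id = character(0), gene = character(0),
                  rs_id = character(0), allele = character(0),
                  stringsAsFactors = FALSE)
  prof <- prof[!duplicated(prof), , drop = FALSE]
  prof <- prof[order(prof$subject_id, prof$gene, prof$rs_id, prof$allele), ,
               drop = FALSE]
  rownames(prof) <- NULL
  attr(prof, "subjects") <- sort(unique(c(subjects, prof$subject_id)))
  class(prof) <- c("subject_profiles", "data.frame")
  prof
}

# Distinct imputable (gene, rs_id, allele) triples in a catalog,
# restricted to unique, non-confusable entries at sufficiently common loci
# (the same gates the filters apply, so the evaluable universe matches
# what the pipeline can ever impute).
catalog_allele_universe <- function(catalog, config = filter_config()) {
  maf_cols <- grep("^maf_", names(catalog), value = TRUE)
  freq_ok <- if (length(maf_cols)) {
    m <- as.matrix(catalog[, maf_cols, drop = FALSE])
    apply(m, 1, function(r) any(!is.na(r) & r >= config$freq_threshold))
  } else rep(TRUE, nrow(catalog))
  keep <- catalog$unique & !catalog$confusable & freq_ok
  rows <- list()
  for (i in which(keep)) {
    al <- parse_alleles(catalog$alleles[i])
    rows[[length(rows) + 1L]] <- data.frame(
      gene = catalog$gene[i], rs_id = al$rs_id, allele = al$nuc,
      stringsAsFactors = FALSE)
  }
  u <- do.call(rbind, rows)
  u <- u[!duplicated(u), , drop = FALSE]
  u[order(u$gene, u$rs_id, u$allele), , drop = FALSE]
}

#' Validate imputed profiles against truth genotypes
#'
#' For every subject with truth data and every imputable GVP allele in the
#' catalog, classifies the (subject, allele) cell: detected and carried ->
#' TP; detected but absent from the genotype -> FP; not detected but
#' carried -> FN; neither -> TN. Cells whose truth call failed (or is
#' missing) are excluded from the evaluable set.
#'
#' @param profiles a `subject_profiles` from [collate_profile()].
#' @param truth a `truth_genotypes` from [read_truth_genotypes()].
#' @param catalog the `gvp_catalog`; defines the imputable allele universe
#'   (unique, non-confusable entries at sufficiently common loci).
#' @param config a [filter_config()]; supplies the frequency gate used to
#'   delimit the universe.
#' @return list of class `gvp_confusion` with elements `per_gvp` (data
#'   frame: gene, rs_id, allele, tp, fp, fn, tn, evaluable) and `overall`
#'   (named totals).
#' @export
classify_calls <- function(profiles, truth, catalog,
                           config = filter_config()) {
  subjects <- attr(profiles, "subjects") %||% unique(profiles$subject_id)
  truth_subjects <- unique(truth$subject_id)
  no_truth <- setdiff(subjects, truth_subjects)
  if (length(no_truth))
    warning("subject(s) missing from truth set, excluded: ",
            paste(no_truth, collapse = ", "), call. = FALSE)
  subjects <- union(intersect(subjects, truth_subjects), truth_subjects)
  universe <- catalog_allele_universe(catalog, config)
  prof_key <- paste(profiles$subject_id, profiles$rs_id, profiles$allele)
  truth_key <- paste(truth$subject_id, truth$rs_id)
  counts <- universe
  counts$tp <- counts$fp <- counts$fn <- counts$tn <- 0L
  for (g in seq_len(nrow(universe))) {
    rs <- universe$rs_id[g]; allele <- universe$allele[g]
    t_idx <- match(paste(subjects, rs), truth_key)
    ok <- !is.na(t_idx) & truth$status[t_idx] == "called"
    present <- ok & (truth$a1[t_idx] == allele | truth$a2[t_idx] == allele)
    detected <- paste(subjects, rs, allele) %in% prof_key
    counts$tp[g] <- sum(ok & detected & present)
    counts$fp[g] <- sum(ok & detected & !present)
    counts$fn[g] <- sum(ok & !detected & present)
    counts$tn[g] <- sum(ok & !detected & !present)
  }
  counts$evaluable <- counts$tp + counts$fp + counts$fn + counts$tn
  counts <- counts[, c("gene", "rs_id", "allele", "tp", "fp", "fn", "tn",
                       "evaluable")]
  overall <- c(tp = sum(counts$tp), fp = sum(counts$fp),
               fn = sum(counts$fn), tn = sum(counts$tn),
               evaluable = sum(counts$evaluable))
  structure(list(per_gvp = counts, overall = overall),
            class = "gvp_confusion")
}

# Percentage metrics with explicit NA (not 0 or 100) on zero denominators.
confusion_metrics <- function(tp, fp, fn) {
  sens <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  ppv <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  fdr <- ifelse(tp + fp > 0, 100 * fp / (tp + fp), NA_real_)
  list(sensitivity = sens, ppv = ppv, fdr = fdr)
}

#' Per-GVP validation metrics table
#'
#' Sensitivity (TP/(TP+FN)), positive predictive value (TP/(TP+FP)) and
#' false discovery rate (FP/(FP+TP)), as percentages, per GVP allele and
#' overall. Zero denominators yield `NA` (undefined), never 0 or 100. When
#' a catalog is supplied rows are sorted by ascending minor allele
#' frequency (minimum across populations).
#'
#' @param confusion a `gvp_confusion` from [classify_calls()].
#' @param catalog optional `gvp_catalog` used to attach and sort by MAF.
#' @return data frame with one row per GVP allele plus an `overall`
#'   attribute (named numeric vector).
#' @export
metrics_table <- function(confusion, catalog = NULL) {
  tab <- confusion$per_gvp
  m <- confusion_metrics(tab$tp, tab$fp, tab$fn)
  tab$sensitivity <- m$sensitivity
  tab$ppv <- m$ppv
  tab$fdr <- m$fdr
  if (!is.null(catalog)) {
    maf_cols <- grep("^maf_", names(catalog), value = TRUE)
    if (length(maf_cols)) {
      idx <- match(tab$rs_id, vapply(seq_len(nrow(catalog)), function(i)
        parse_alleles(catalog$alleles[i])$rs_id[1], character(1)))
      tab$maf <- apply(as.matrix(catalog[idx, maf_cols, drop = FALSE]), 1,
                       min, na.rm = TRUE)
      tab <- tab[order(tab$maf, tab$rs_id, tab$allele), , drop = FALSE]
      rownames(tab) <- NULL
    }
  }
  ov <- as.list(confusion$overall)
  om <- confusion_metrics(ov$tp, ov$fp, ov$fn)
  attr(tab, "overall") <- c(unlist(ov), sensitivity = om$sensitivity,
                            ppv = om$ppv, fdr = om$fdr)
  tab
}

#' Write profiles as a subjects-by-combination 0/1 matrix
#'
#' One column per observed gene-level allele combination (e.g.
#' `KRT32=rs123:T+rs456:C`), one row per subject; a cell is 1 when the
#' subject's imputed profile contains exactly that combination for that
#' gene. At most one combination per gene is observed per subject.
#'
#' @param profiles a `subject_profiles`.
#' @param path output TSV.
#' @export
write_profile_matrix <- function(profiles, path) {
  subjects <- attr(profiles, "subjects") %||% unique(profiles$subject_id)
  combo <- stats::aggregate(
    list(combo = paste0(profiles$rs_id, ":", profiles$allele)),
    by = list(subject_id = profiles$subject_id, gene = profiles$gene),
    FUN = function(v) paste(sort(v), collapse = "+"))
  combo$col <- paste0(combo$gene, "=", combo$combo)
  cols <- sort(unique(combo$col))
  mat <- matrix(0L, nrow = length(subjects), ncol = length(cols),
                dimnames = list(subjects, cols))
  if (nrow(combo))
    mat[cbind(match(combo$subject_id, subjects),
              match(combo$col, cols))] <- 1L
  out <- data.frame(subject_id = subjects, mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write_tsv_det(out, path)
}
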