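#' Filter configuration
#'
#' All exclusion thresholds for candidate GVP detections in one object.
#' Defaults follow standard forensic proteomics practice: X!Tandem PSMs are
#' kept at log10(e) at or below -2, Mascot at expectation at or below 0.05,
#' precursor mass error at or below 0.2 Da (boundary values kept, strict
#' inequalities on the exclusion side), loci with minor allele frequency
#' below 0.4% in every reference population are excluded, biological PTMs
#' (phosphorylation) disqualify an assignment, and fragment spectra are
#' screened for alternative-allele diagnostic ions at 0.02 Da.
#'
#' @param xtandem_loge_max keep X!Tandem PSMs with log10(e) <= this
#'   (default -2).
#' @param mascot_expect_max keep Mascot PSMs with expectation <= this
#'   (default 0.05).
#' @param precursor_tol_da maximum |observed - theoretical| precursor mass
#'   difference, Da (default 0.2).
#' @param freq_threshold minimum MAF (in at least one population) for a
#'   locus to be usable (default 0.004).
#' @param fragment_tol_da fragment-ion match tolerance, Da (default 0.02).
#' @param biological_mods modification-name substrings that mark biological
#'   PTMs (default `"phospho"`); matched case-insensitively. Sample-prep
#'   and artifact modifications (carbamidomethyl, oxidation, deamidation)
#'   must not be listed here.
#' @param exclusion_pairs confusable substitution pairs, see
#'   [confusable_sap_screen()].
#' @return list of class `filter_config`.
#' @export
filter_config <- function(xtandem_loge_max = -2, mascot_expect_max = 0.05,
                          precursor_tol_da = 0.2, freq_threshold = 0.004,
                          fragment_tol_da = 0.02,
                          biological_mods = "phospho",
                          exclusion_pairs = c("M>F", "N>D", "Q>E", "C>S")) {
  stopifnot(precursor_tol_da > 0, fragment_tol_da > 0,
            is.finite(xtandem_loge_max), is.finite(mascot_expect_max))
  structure(list(xtandem_loge_max = xtandem_loge_max,
                 mascot_expect_max = mascot_expect_max,
                 precursor_tol_da = precursor_tol_da,
                 freq_threshold = freq_threshold,
                 fragment_tol_da = fragment_tol_da,
                 biological_mods = biological_mods,
                 exclusion_pairs = exclusion_pairs),
            class = "filter_config")
}

filter_decision <- function(failed = character(0), flags = character(0)) {
  list(passed = length(failed) == 0L, failed_rules = failed, flags = flags)
}

#' Individual exclusion rules
#'
#' Each rule takes one PSM (a one-row slice of a `psm_table`, or a list with
#' the same fields) and/or one catalog entry, and returns a decision list
#' with elements `passed`, `failed_rules` and `flags`. Rules are pure and
#' order-independent; [apply_filters()] is their conjunction.
#'
#' @param psm one PSM record.
#' @param config a [filter_config()].
#' @name filter_rules
NULL

#' @rdname filter_rules
#' @export
score_filter <- function(psm, config = filter_config()) {
  if (is.na(psm$engine) || !psm$engine %in% c("xtandem", "mascot"))
    stop("unknown engine: ", psm$engine, call. = FALSE)
  thr <- if (psm$engine == "xtandem") config$xtandem_loge_max
  else config$mascot_expect_max
  filter_decision(if (psm$score > thr) "score" else character(0))
}

#' @rdname filter_rules
#' @export
precursor_mass_filter <- function(psm, config = filter_config()) {
  filter_decision(
    if (abs(psm$obs_mass - psm$theo_mass) > config$precursor_tol_da)
      "precursor_mass" else character(0))
}

#' @rdname filter_rules
#' @param catalog_entry one row of a `gvp_catalog`.
#' @param populations optional subset of population labels to consider;
#'   default all `maf_*` columns on the entry.
#' @export
frequency_filter <- function(catalog_entry, config = filter_config(),
                             populations = NULL) {
  maf_cols <- grep("^maf_", names(catalog_entry), value = TRUE)
  if (!is.null(populations))
    maf_cols <- intersect(maf_cols, paste0("maf_", populations))
  mafs <- unlist(catalog_entry[maf_cols], use.names = FALSE)
  mafs <- mafs[!is.na(mafs)]
  if (!length(mafs)) return(filter_decision("frequency_missing"))
  filter_decision(
    if (all(mafs < config$freq_threshold)) "frequency" else character(0))
}

#' @rdname filter_rules
#' @export
ptm_filter <- function(psm, config = filter_config()) {
  mods <- parse_mods(psm$mods)
  if (!nrow(mods)) return(filter_decision())
  hit <- vapply(tolower(mods$name), function(nm)
    any(vapply(tolower(config$biological_mods), grepl, logical(1),
               x = nm, fixed = TRUE)), logical(1))
  filter_decision(if (any(hit)) "ptm" else character(0))
}

#' @rdname filter_rules
#' @export
confusable_filter <- function(catalog_entry, config = filter_config()) {
  al <- parse_alleles(catalog_entry$alleles)
  # entry-level annotation computed at catalog build; recheck against the
  # configured pair set so a custom config is honoured
  conf <- isTRUE(catalog_entry$confusable) &&
    any(strsplit(catalog_entry$confusable_pair, ",")[[1]] %in%
          config$exclusion_pairs)
  filter_decision(if (conf) "confusable" else character(0))
}

#' @rdname filter_rules
#' @export
uniqueness_filter <- function(catalog_entry, config = filter_config()) {
  filter_decision(
    if (!isTRUE(catalog_entry$unique)) "uniqueness" else character(0))
}

#' @rdname filter_rules
#' @export
alt_allele_fragment_filter <- function(psm, catalog_entry,
                                       config = filter_config()) {
  frags <- parse_fragments(psm$fragments)
  if (!length(frags))
    return(filter_decision(flags = "fragment_not_evaluated"))
  alt_pep <- catalog_entry$alt_peptide
  if (is.null(alt_pep) || is.na(alt_pep) || !nzchar(alt_pep))
    return(filter_decision(flags = "fragment_not_evaluated"))
  diag <- diagnostic_ions(alt_pep, catalog_entry$peptide,
                          config$fragment_tol_da)
  hit <- any(vapply(frags, function(mz)
    any(abs(diag - mz) <= config$fragment_tol_da), logical(1)))
  filter_decision(if (hit) "fragment" else character(0))
}

FILTER_RULES <- c("score", "precursor_mass", "frequency", "ptm",
                  "confusable", "uniqueness", "fragment")

#' Apply every exclusion rule to a PSM table
#'
#' Joins PSMs to the GVP catalog by peptide sequence and evaluates the
#' conjunction of all exclusion rules. A PSM passes only if no rule fires;
#' every excluded PSM carries the full list of rules it violated. PSMs whose
#' peptide has no catalog entry are set aside (they are not candidate GVP
#' detections) and tallied separately.
#'
#' @param psms a `psm_table`.
#' @param catalog a `gvp_catalog`.
#' @param config a [filter_config()].
#' @param populations optional population subset for the frequency rule.
#' @return list with `detections` (passing PSMs with their catalog columns),
#'   `decisions` (per-PSM audit: `passed`, `failed_rules`, `flags`), and
#'   `audit` (per-rule exclusion counts).
#' @export
apply_filters <- function(psms, catalog, config = filter_config(),
                          populations = NULL) {
  psms <- as.data.frame(psms)
  cat_idx <- match(psms$peptide, catalog$peptide)
  failed <- vector("list", nrow(psms))
  flags <- vector("list", nrow(psms))
  for (i in seq_len(nrow(psms))) {
    psm <- psms[i, ]
    if (is.na(cat_idx[i])) {
      failed[[i]] <- "no_catalog_entry"
      next
    }
    entry <- catalog[cat_idx[i], ]
    dec <- list(score_filter(psm, config),
                precursor_mass_filter(psm, config),
                frequency_filter(entry, config, populations),
                ptm_filter(psm, config),
                confusable_filter(entry, config),
                uniqueness_filter(entry, config),
                alt_allele_fragment_filter(psm, entry, config))
    failed[[i]] <- unlist(lapply(dec, `[[`, "failed_rules"))
    flags[[i]] <- unlist(lapply(dec, `[[`, "flags"))
  }
  passed <- lengths(failed) == 0L
  decisions <- data.frame(
    row = seq_len(nrow(psms)), subject = psms$subject,
    peptide = psms$peptide, passed = passed,
    failed_rules = vapply(failed, paste, character(1), collapse = ","),
    flags = vapply(flags, function(f) paste(f %||% character(0),
                                            collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  all_rules <- c(FILTER_RULES, "frequency_missing", "no_catalog_entry")
  audit <- data.frame(
    rule = all_rules,
    n_failed = vapply(all_rules, function(r)
      sum(vapply(failed, function(f) r %in% f, logical(1))), integer(1)),
    stringsAsFactors = FALSE)
  rownames(audit) <- NULL
  detections <- cbind(psms[passed, , drop = FALSE],
                      catalog[cat_idx[passed],
                              setdiff(names(catalog), names(psms)),
                              drop = FALSE])
  rownames(detections) <- NULL
  list(detections = detections, decisions = decisions, audit = audit)
}
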