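#' Read a peptide-spectrum-match table
#'
#' Tab-separated, one row per PSM. Required columns: `subject`, `sample`,
#' `peptide`, `engine` (`xtandem` or `mascot`), `score`, `obs_mass`,
#' `theo_mass`. Optional: `mods` (semicolon-joined `pos:delta:name`),
#' `fragments` (comma-joined singly charged fragment masses, Da),
#' `proteins` (comma-joined accessions), and a `decoy_rule` pass-through
#' column used only by filter-audit fixtures.
#'
#' Score semantics are engine-specific and never converted: X!Tandem scores
#' are log10 expectation values, Mascot scores linear expectation values.
#'
#' @param path TSV file.
#' @param permissive if `TRUE` (default), rows with unparseable masses are
#'   skipped and reported (with line numbers) in the `"errors"` attribute;
#'   if `FALSE` they are a hard error.
#' @return data frame of class `psm_table`.
#' @export
read_psm_table <- function(path, permissive = TRUE) {
  df <- read_tsv_strict(path, required = c("subject", "sample", "peptide",
                                           "engine", "score", "obs_mass",
                                           "theo_mass"))
  for (cl in c("mods", "fragments", "proteins", "decoy_rule"))
    if (!cl %in% names(df)) df[[cl]] <- NA_character_
  errs <- character(0)
  for (cl in c("score", "obs_mass", "theo_mass")) {
    raw <- df[[cl]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- is.na(num) & !is.na(raw)
    if (any(bad)) {
      msg <- paste0("line ", which(bad) + 1L, ": unparseable ", cl, " '",
                    raw[bad], "'")
      if (!permissive) stop(paste(msg, collapse = "; "), call. = FALSE)
      errs <- c(errs, msg)
    }
    df[[cl]] <- num
  }
  bad_engine <- !df$engine %in% c("xtandem", "mascot")
  if (any(bad_engine))
    stop("unknown engine(s): ", paste(unique(df$engine[bad_engine]),
                                      collapse = ", "), call. = FALSE)
  bad_mass <- is.na(df$obs_mass) | is.na(df$theo_mass) | is.na(df$score) |
    df$obs_mass <= 0 | df$theo_mass <= 0
  if (any(bad_mass)) {
    errs <- c(errs, paste0("line ", which(bad_mass) + 1L,
                           ": invalid mass/score, row skipped"))
    df <- df[!bad_mass, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "errors") <- errs
  class(df) <- c("psm_table", "data.frame")
  df
}

#' @rdname read_psm_table
#' @param psms a `psm_table`.
#' @export
write_psm_table <- function(psms, path) {
  cols <- c("subject", "sample", "peptide", "engine", "score", "obs_mass",
            "theo_mass", "mods", "fragments", "proteins", "decoy_rule")
  df <- as.data.frame(psms)
  for (cl in setdiff(cols, names(df))) df[[cl]] <- NA_character_
  write_tsv_det(df[, cols], path)
}

# Parse a mods field "3:79.96633:Phospho;7:15.99491:Oxidation".
parse_mods <- function(mods) {
  if (is.na(mods) || !nzchar(mods))
    return(data.frame(position = integer(0), delta = numeric(0),
                      name = character(0)))
  parts <- strsplit(strsplit(mods, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[`, character(1), 1)),
             delta = as.numeric(vapply(parts, `[`, character(1), 2)),
             name = vapply(parts, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

parse_fragments <- function(fragments) {
  if (is.na(fragments) || !nzchar(fragments)) return(numeric(0))
  as.numeric(strsplit(fragments, ",", fixed = TRUE)[[1]])
}

#' Construct a population genotype panel
#'
#' @param population_id label, e.g. `"EUR"`.
#' @param genotypes long data frame with columns `individual_id`, `rs_id`,
#'   `a1`, `a2` (single nucleotides, `NA` for missing calls).
#' @return object of class `population_panel`.
#' @export
population_panel <- function(population_id, genotypes) {
  stopifnot(all(c("individual_id", "rs_id", "a1", "a2") %in%
                  names(genotypes)))
  genotypes <- genotypes[order(genotypes$individual_id, genotypes$rs_id), ,
                         drop = FALSE]
  rownames(genotypes) <- NULL
  structure(list(population_id = population_id, genotypes = genotypes),
            class = "population_panel")
}

#' @export
print.population_panel <- function(x, ...) {
  cat("<population_panel> ", x$population_id, ": ",
      length(unique(x$genotypes$individual_id)), " individuals x ",
      length(unique(x$genotypes$rs_id)), " loci\n", sep = "")
  invisible(x)
}

.parse_gt_string <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  parts <- strsplit(gt, "/", fixed = TRUE)
  nall <- lengths(parts)
  if (any(nall != 2 & !gt %in% c(".", "")))
    stop("non-diploid genotype: ", gt[which(nall != 2)[1]], call. = FALSE)
  a1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else ".",
               character(1))
  a2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else ".",
               character(1))
  a1[a1 == "."] <- NA_character_
  a2[a2 == "."] <- NA_character_
  list(a1 = a1, a2 = a2)
}

#' Read a population genotype panel
#'
#' Accepts either a VCF (v4.x, `GT` field, phased or unphased; loci matched
#' by the `ID` column, never by position) or a genotype TSV: first column
#' `individual_id`, one column per rs ID, cells like `C/T` (`./.` or empty
#' for missing). Phase is ignored.
#'
#' @param path VCF (`.vcf`) or TSV file.
#' @param loci optional `snp_table` (or character vector of rs IDs): the
#'   panel is restricted to these loci, and loci absent from the file are
#'   warned about and left uncounted.
#' @param population_id label for the panel; defaults to the file name.
#' @return a [population_panel()].
#' @export
read_genotype_panel <- function(path, loci = NULL,
                                population_id = NULL) {
  population_id <- population_id %||%
    sub("\\.(vcf|tsv|txt)$", "", basename(path))
  rs_wanted <- if (is.null(loci)) NULL
  else if (is.character(loci)) loci else loci$rs_id
  first <- readLines(path, n = 1L)
  if (grepl("^##fileformat=VCF", first)) {
    gt <- VariantAnnotation::readGT(path, nucleotides = TRUE)
    if (anyDuplicated(rownames(gt)))
      stop("duplicated variant IDs in VCF: ",
           rownames(gt)[anyDuplicated(rownames(gt))], call. = FALSE)
    long <- data.frame(
      individual_id = rep(colnames(gt), each = nrow(gt)),
      rs_id = rep(rownames(gt), times = ncol(gt)),
      gt = as.vector(gt), stringsAsFactors = FALSE)
  } else {
    df <- read_tsv_strict(path, required = "individual_id")
    rs_cols <- setdiff(names(df), "individual_id")
    long <- data.frame(
      individual_id = rep(df$individual_id, times = length(rs_cols)),
      rs_id = rep(rs_cols, each = nrow(df)),
      gt = unlist(df[rs_cols], use.names = FALSE), stringsAsFactors = FALSE)
    long$gt[is.na(long$gt)] <- "./."
  }
  if (!is.null(rs_wanted)) {
    absent <- setdiff(rs_wanted, unique(long$rs_id))
    if (length(absent))
      warning("locus/loci absent from ", basename(path), ", uncounted: ",
              paste(absent, collapse = ", "), call. = FALSE)
    long <- long[long$rs_id %in% rs_wanted, , drop = FALSE]
  }
  al <- .parse_gt_string(long$gt)
  population_panel(population_id,
                   data.frame(individual_id = long$individual_id,
                              rs_id = long$rs_id, a1 = al$a1, a2 = al$a2,
                              stringsAsFactors = FALSE))
}

#' Write a genotype panel as TSV (individuals x loci)
#' @param panel a [population_panel()].
#' @param path output file.
#' @export
write_genotype_tsv <- function(panel, path) {
  g <- panel$genotypes
  gt <- ifelse(is.na(g$a1) | is.na(g$a2), "./.", paste0(g$a1, "/", g$a2))
  wide <- stats::reshape(
    data.frame(individual_id = g$individual_id, rs_id = g$rs_id, gt = gt,
               stringsAsFactors = FALSE),
    idvar = "individual_id", timevar = "rs_id", direction = "wide")
  names(wide) <- sub("^gt\\.", "", names(wide))
  wide <- wide[order(wide$individual_id),
               c("individual_id", sort(setdiff(names(wide),
                                               "individual_id")))]
  write_tsv_det(wide, path)
}

#' Write a genotype panel as a minimal VCFv4.2 (GT only)
#'
#' Emits one row per locus with `REF`/`ALT` taken from `loci`; genotypes are
#' coded `0/1` style, missing as `./.`. The output is readable back with
#' [read_genotype_panel()] (which uses a full VCF parser).
#'
#' @param panel a [population_panel()].
#' @param loci an `snp_table` supplying `rs_id`, `ref_nuc`, `alt_nuc`.
#' @param path output file.
#' @export
write_genotype_vcf <- function(panel, loci, path) {
  g <- panel$genotypes
  inds <- sort(unique(g$individual_id))
  rs <- sort(intersect(unique(g$rs_id), loci$rs_id))
  li <- match(rs, loci$rs_id)
  key <- paste(g$individual_id, g$rs_id)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", inds), collapse = "\t"))
  for (k in seq_along(rs)) {
    ref <- loci$ref_nuc[li[k]]; alt <- loci$alt_nuc[li[k]]
    row <- g[match(paste(inds, rs[k]), key), , drop = FALSE]
    code <- function(a) ifelse(is.na(a), ".",
                               ifelse(a == ref, "0",
                                      ifelse(a == alt, "1", NA)))
    c1 <- code(row$a1); c2 <- code(row$a2)
    if (anyNA(c1) || anyNA(c2))
      stop("allele outside {ref, alt} at ", rs[k], call. = FALSE)
    gtstr <- ifelse(c1 == "." | c2 == ".", "./.", paste0(c1, "/", c2))
    lines <- c(lines, paste(c("1", as.character(k * 100L), rs[k], ref, alt,
                              ".", "PASS", ".", "GT", gtstr),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read truth genotypes (e.g. Sanger validation calls)
#'
#' Long TSV with columns `subject_id`, `rs_id`, `genotype`; genotype is
#' `X/Y` (unordered diploid pair), `./.` for missing, or `FAIL` for a failed
#' sequencing determination. Failed and missing calls are retained with
#' their status so downstream validation can exclude them from the
#' evaluable set.
#'
#' @param path TSV file.
#' @param loci optional `snp_table` or rs-ID vector; rows at unknown loci
#'   are dropped with a warning.
#' @return data frame of class `truth_genotypes` with columns `subject_id`,
#'   `rs_id`, `a1`, `a2`, `status` (`"called"` or `"failed"`).
#' @export
read_truth_genotypes <- function(path, loci = NULL) {
  df <- read_tsv_strict(path, required = c("subject_id", "rs_id",
                                           "genotype"))
  if (!is.null(loci)) {
    rs_wanted <- if (is.character(loci)) loci else loci$rs_id
    unknown <- !df$rs_id %in% rs_wanted
    if (any(unknown)) {
      warning("unknown rs ID(s) in truth file ignored: ",
              paste(unique(df$rs_id[unknown]), collapse = ", "),
              call. = FALSE)
      df <- df[!unknown, , drop = FALSE]
    }
  }
  df$genotype[is.na(df$genotype)] <- "./."
  failed <- toupper(df$genotype) == "FAIL" | df$genotype == "./."
  al <- .parse_gt_string(ifelse(failed, "./.", df$genotype))
  out <- data.frame(subject_id = df$subject_id, rs_id = df$rs_id,
                    a1 = al$a1, a2 = al$a2,
                    status = ifelse(failed, "failed", "called"),
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_genotypes", "data.frame")
  out
}

#' @rdname read_truth_genotypes
#' @param truth a `truth_genotypes` data frame.
#' @export
write_truth_genotypes <- function(truth, path) {
  gt <- ifelse(truth$status == "failed", "FAIL",
               paste0(truth$a1, "/", truth$a2))
  write_tsv_det(data.frame(subject_id = truth$subject_id,
                           rs_id = truth$rs_id, genotype = gt,
                           stringsAsFactors = FALSE), path)
}

#' Write results as deterministic JSON
#'
#' Keys are emitted in construction order and numbers at 12 significant
#' digits, so identical inputs give byte-identical files.
#'
#' @param x list or data frame.
#' @param path output file.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 12,
                       pretty = TRUE, na = "null")
  invisible(path)
}
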