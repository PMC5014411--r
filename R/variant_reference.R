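#' Construct a protein set
#'
#' A protein set is a data frame with columns `accession`, `gene` and
#' `sequence` (uppercase canonical amino acids). It is the substrate for
#' variant database construction and in-silico digestion.
#'
#' @param accession character vector of accessions (unique).
#' @param gene gene symbols, one per accession.
#' @param sequence amino-acid strings.
#' @param allow_noncanonical one of `"reject"` (default), `"warn"`, `"allow"`
#'   governing residues outside the canonical 20-letter alphabet
#'   (B/J/O/U/X/Z).
#' @return data frame of class `protein_set`.
#' @export
protein_set <- function(accession, gene, sequence,
                        allow_noncanonical = "reject") {
  stopifnot(length(accession) == length(gene),
            length(gene) == length(sequence))
  if (anyDuplicated(accession))
    stop("duplicated accession(s)", call. = FALSE)
  sequence <- toupper(sequence)
  if (any(!nzchar(sequence))) stop("empty sequence(s)", call. = FALSE)
  assert_canonical_aa(sequence, "protein sequence", allow_noncanonical)
  out <- data.frame(accession = unname(as.character(accession)),
                    gene = unname(as.character(gene)),
                    sequence = unname(sequence), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read a proteome from FASTA
#'
#' Headers are expected as `accession GN=gene`; when the `GN=` tag is absent
#' the gene symbol falls back to the accession (stripped of the `|var`
#' suffix used for variant copies).
#'
#' @param path FASTA file.
#' @inheritParams protein_set
#' @return a [protein_set()].
#' @export
read_proteome_fasta <- function(path, allow_noncanonical = "reject") {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  gene <- ifelse(grepl("GN=", headers),
                 sub("^.*GN=([^ ]+).*$", "\\1", headers),
                 sub("\\|var$", "", accession))
  protein_set(accession, gene, as.character(aa), allow_noncanonical)
}

#' Write a proteome to FASTA
#'
#' @param proteome a [protein_set()].
#' @param path output file.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$sequence)
  names(aa) <- paste0(proteome$accession, " GN=", proteome$gene)
  Biostrings::writeXStringSet(aa, path, width = 60)
  invisible(path)
}

#' Read an nsSNP annotation table
#'
#' Tab-separated, one row per nsSNP locus, with columns `rs_id`, `gene`,
#' `accession`, `pos` (1-based protein residue), `ref_aa`, `alt_aa`,
#' `ref_nuc`, `alt_nuc`, then per population `POP` a pair
#' `count_POP` (alt-allele carrier count), `size_POP` (panel size) and
#' optionally `maf_POP`. When `maf_POP` is absent it is derived from the
#' carrier fraction under Hardy-Weinberg equilibrium
#' (`q = 1 - sqrt(1 - count/size)`).
#'
#' @param path TSV file.
#' @return data frame of class `snp_table` with one `maf_POP` column per
#'   population.
#' @export
read_snp_table <- function(path) {
  df <- read_tsv_strict(path, required = c("rs_id", "gene", "accession",
                                           "pos", "ref_aa", "alt_aa",
                                           "ref_nuc", "alt_nuc"))
  df$pos <- as.integer(df$pos)
  as_snp_table(df)
}

#' @rdname read_snp_table
#' @param df data frame with the columns documented above.
#' @export
as_snp_table <- function(df) {
  pops <- snp_populations(df)
  for (p in pops) {
    mafcol <- paste0("maf_", p)
    if (!mafcol %in% names(df)) {
      carrier <- df[[paste0("count_", p)]] / df[[paste0("size_", p)]]
      q <- 1 - sqrt(pmax(0, 1 - carrier))
      df[[mafcol]] <- pmin(q, 1 - q)
    }
    bad <- !is.na(df[[mafcol]]) & (df[[mafcol]] < 0 | df[[mafcol]] > 1)
    if (any(bad)) stop("MAF outside [0,1] for ", df$rs_id[bad][1],
                       call. = FALSE)
  }
  if (any(df$ref_aa == df$alt_aa))
    stop("ref_aa equals alt_aa for ",
         df$rs_id[df$ref_aa == df$alt_aa][1], call. = FALSE)
  class(df) <- c("snp_table", "data.frame")
  df
}

#' Populations named in an nsSNP table
#' @param snps an `snp_table`.
#' @return character vector of population labels.
#' @export
snp_populations <- function(snps) {
  pops <- sub("^count_", "", grep("^count_", names(snps), value = TRUE))
  if (!length(pops))
    pops <- sub("^maf_", "", grep("^maf_", names(snps), value = TRUE))
  pops
}

# Check every SNP against its reference protein; hard error naming the rs on
# position/residue mismatch.
validate_snps <- function(proteome, snps) {
  idx <- match(snps$accession, proteome$accession)
  if (anyNA(idx))
    stop("SNP(s) reference unknown protein accession: ",
         paste(unique(snps$accession[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  len <- nchar(proteome$sequence)[idx]
  bad <- snps$pos < 1 | snps$pos > len
  if (any(bad))
    stop("protein position out of range for ", snps$rs_id[bad][1],
         call. = FALSE)
  at <- substr(proteome$sequence[idx], snps$pos, snps$pos)
  mism <- at != snps$ref_aa
  if (any(mism))
    stop("reference residue mismatch for ", snps$rs_id[mism][1],
         " (expected ", snps$ref_aa[mism][1], ", found ", at[mism][1], ")",
         call. = FALSE)
  dup <- duplicated(snps[, c("accession", "pos")]) |
    duplicated(snps[, c("accession", "pos")], fromLast = TRUE)
  if (any(dup))
    stop("co-positional SAPs on one protein (",
         paste(unique(snps$rs_id[dup]), collapse = ", "),
         "): cannot coexist in a single variant copy", call. = FALSE)
  invisible(idx)
}

# MAF matrix (loci x populations) from an snp_table.
snp_maf_matrix <- function(snps) {
  pops <- snp_populations(snps)
  m <- sapply(pops, function(p) snps[[paste0("maf_", p)]])
  m <- matrix(m, nrow = nrow(snps),
              dimnames = list(snps$rs_id, pops))
  m
}

# A SAP passes the frequency gate if its MAF reaches the threshold in at
# least one population (either-population semantics).
sap_passes_freq <- function(snps, freq_threshold) {
  m <- snp_maf_matrix(snps)
  if (!ncol(m)) return(rep(TRUE, nrow(snps)))
  apply(m, 1, function(r) any(!is.na(r) & r >= freq_threshold))
}

substitute_saps <- function(sequence, pos, aa) {
  for (k in seq_along(pos)) substr(sequence, pos[k], pos[k]) <- aa[k]
  sequence
}

#' Build a variant-aware protein reference database
#'
#' For every protein with at least one sufficiently common SAP, appends one
#' additional record carrying all passing SAPs simultaneously, accessioned
#' `<accession>|var`. This is the compact "one variant copy per protein"
#' database design: a search engine sees both the reference sequence and a
#' single all-variant sequence instead of a combinatorial expansion.
#'
#' @param proteome a [protein_set()].
#' @param snps an `snp_table` whose entries all reference `proteome`.
#' @param freq_threshold allelic frequency below which (in every population)
#'   a SAP is excluded from the variant copy. Default 0.004.
#' @return a [protein_set()] with the reference records unchanged plus the
#'   variant copies.
#' @export
build_variant_database <- function(proteome, snps, freq_threshold = 0.004) {
  stopifnot(freq_threshold >= 0, freq_threshold <= 1)
  if (nrow(snps) == 0) return(proteome)
  validate_snps(proteome, snps)
  keep <- sap_passes_freq(snps, freq_threshold)
  snps <- snps[keep, , drop = FALSE]
  if (!nrow(snps)) return(proteome)
  var_acc <- character(0); var_gene <- character(0); var_seq <- character(0)
  for (acc in unique(snps$accession)) {
    s <- snps[snps$accession == acc, , drop = FALSE]
    i <- match(acc, proteome$accession)
    var_acc <- c(var_acc, paste0(acc, "|var"))
    var_gene <- c(var_gene, proteome$gene[i])
    var_seq <- c(var_seq,
                 substitute_saps(proteome$sequence[i], s$pos, s$alt_aa))
  }
  out <- rbind(as.data.frame(proteome),
               data.frame(accession = var_acc, gene = var_gene,
                          sequence = var_seq, stringsAsFactors = FALSE))
  class(out) <- c("protein_set", "data.frame")
  out
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine or arginine, suppressed when the next
#' residue is proline, and enumerates all peptides with up to `max_missed`
#' missed cleavages. Output is ordered by start position, then peptide
#' length.
#'
#' @param sequence amino-acid string.
#' @param max_missed maximum number of retained internal cleavage sites
#'   (default 2, a typical search-engine setting).
#' @return data frame with columns `peptide`, `start`, `end` (1-based
#'   inclusive) and `missed_cleavages`.
#' @examples
#' digest("AKRPGFKDE", max_missed = 0)
#' @export
digest <- function(sequence, max_missed = 2) {
  stopifnot(nzchar(sequence), max_missed >= 0)
  n <- nchar(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cut <- which(res[-n] %in% c("K", "R") & res[-1] != "P")
  bounds <- c(0L, cut, n)
  nf <- length(bounds) - 1L
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (i in seq_len(nf)) {
    for (m in 0:max_missed) {
      if (i + m > nf) break
      starts <- c(starts, bounds[i] + 1L)
      ends <- c(ends, bounds[i + m + 1L])
      missed <- c(missed, m)
    }
  }
  data.frame(peptide = substring(sequence, starts, ends),
             start = starts, end = ends, missed_cleavages = missed,
             stringsAsFactors = FALSE)
}

#' Screen a peptide for gene uniqueness
#'
#' A peptide is imputation-grade only if it maps to the products of at most
#' one gene in the search space (a gene's reference sequence and its own
#' variant copy count as one gene). Matching is exact substring matching
#' with isoleucine and leucine distinct; peptides absent from the whole
#' space are reported unique with an empty gene list.
#'
#' @param peptide amino-acid string.
#' @param search_space a [protein_set()] containing reference and variant
#'   records.
#' @return list with `unique` (logical) and `genes` (character vector of
#'   matching gene symbols).
#' @export
uniqueness_screen <- function(peptide, search_space) {
  hit <- grepl(peptide, search_space$sequence, fixed = TRUE)
  genes <- sort(unique(search_space$gene[hit]))
  list(unique = length(genes) <= 1L, genes = genes)
}

#' Screen a SAP for chemical confusability
#'
#' Some amino-acid substitutions are indistinguishable from common chemical
#' modifications or conversions (e.g. deamidation of asparagine to
#' aspartate); such SAPs cannot be attributed to genetics and are excluded.
#'
#' @param ref_aa,alt_aa single residues (the ordered substitution).
#' @param exclusion_pairs character vector of ordered pairs `"X>Y"`; default
#'   `c("M>F", "N>D", "Q>E", "C>S")`.
#' @return `TRUE` if the substitution is confusable (to be excluded).
#' @export
confusable_sap_screen <- function(ref_aa, alt_aa,
                                  exclusion_pairs = c("M>F", "N>D",
                                                      "Q>E", "C>S")) {
  paste0(ref_aa, ">", alt_aa) %in% exclusion_pairs
}

# For one protein, emit catalog rows from one allele-substituted sequence.
.catalog_rows_for_seq <- function(seq, acc, gene, snps_p, max_missed) {
  pep <- digest(seq, max_missed)
  rows <- list()
  for (k in seq_len(nrow(pep))) {
    cov <- which(snps_p$pos >= pep$start[k] & snps_p$pos <= pep$end[k])
    if (!length(cov)) next
    cov <- cov[order(snps_p$pos[cov])]
    res_at <- substr(rep(seq, length(cov)), snps_p$pos[cov], snps_p$pos[cov])
    is_alt <- res_at == snps_p$alt_aa[cov]
    nuc <- ifelse(is_alt, snps_p$alt_nuc[cov], snps_p$ref_nuc[cov])
    rows[[length(rows) + 1L]] <- data.frame(
      peptide = pep$peptide[k], gene = gene, accession = acc,
      start = pep$start[k], end = pep$end[k],
      missed_cleavages = pep$missed_cleavages[k],
      allele_class = if (any(is_alt)) "variant" else "reference",
      rs_ids = paste(snps_p$rs_id[cov], collapse = ","),
      alleles = paste(snps_p$rs_id[cov], nuc, res_at, sep = ":",
                      collapse = ","),
      n_sap = length(cov), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Enumerate genetically variant peptides
#'
#' For every nsSNP allele (reference and alternative) digests the
#' allele-substituted protein sequence and emits every tryptic peptide whose
#' span covers the SAP position. Digestion always operates on the
#' substituted sequence, so SAPs that create or destroy K/R cleavage sites
#' yield allele-specific peptide sets. Peptides covering several catalogued
#' SAPs list all covered loci (combination evidence); an additional
#' all-variant sequence per protein contributes the joint multi-variant
#' peptides.
#'
#' Each entry is annotated with gene uniqueness (against the reference plus
#' variant-copy search space), chemical confusability of its covered SAPs,
#' the minimum population MAF across covered loci, and the peptide produced
#' by the opposite allele (`alt_peptide`, used for diagnostic fragment
#' screening).
#'
#' @inheritParams build_variant_database
#' @param max_missed maximum missed cleavages (default 2).
#' @param exclusion_pairs confusable substitution pairs, see
#'   [confusable_sap_screen()].
#' @return data frame of class `gvp_catalog`.
#' @export
enumerate_gvps <- function(proteome, snps, max_missed = 2,
                           freq_threshold = 0.004,
                           exclusion_pairs = c("M>F", "N>D", "Q>E", "C>S")) {
  validate_snps(proteome, snps)
  pops <- snp_populations(snps)
  all_rows <- list()
  for (acc in unique(snps$accession)) {
    s <- snps[snps$accession == acc, , drop = FALSE]
    i <- match(acc, proteome$accession)
    refseq <- proteome$sequence[i]
    gene <- proteome$gene[i]
    seqs <- list(refseq)
    for (k in seq_len(nrow(s)))
      seqs <- c(seqs, substitute_saps(refseq, s$pos[k], s$alt_aa[k]))
    if (nrow(s) > 1)
      seqs <- c(seqs, substitute_saps(refseq, s$pos, s$alt_aa))
    for (sq in unique(unlist(seqs))) {
      r <- .catalog_rows_for_seq(sq, acc, gene, s, max_missed)
      if (!is.null(r)) {
        # counterpart peptide: flip every covered SAP, re-digest, take the
        # 0-missed peptide covering the first SAP position
        r$alt_peptide <- vapply(seq_len(nrow(r)), function(j) {
          al <- strsplit(strsplit(r$alleles[j], ",", fixed = TRUE)[[1]],
                         ":", fixed = TRUE)
          rs <- vapply(al, `[`, character(1), 1)
          aa <- vapply(al, `[`, character(1), 3)
          m <- match(rs, s$rs_id)
          flip <- ifelse(aa == s$alt_aa[m], s$ref_aa[m], s$alt_aa[m])
          cseq <- substitute_saps(sq, s$pos[m], flip)
          dg <- digest(cseq, 0)
          hit <- which(dg$start <= s$pos[m][1] & dg$end >= s$pos[m][1])
          dg$peptide[hit[1]]
        }, character(1))
        all_rows[[length(all_rows) + 1L]] <- r
      }
    }
  }
  cat <- do.call(rbind, all_rows)
  cat <- cat[!duplicated(cat[, c("accession", "peptide", "start",
                                 "alleles")]), , drop = FALSE]
  cat <- cat[order(cat$gene, cat$accession, cat$start,
                   nchar(cat$peptide), cat$alleles), , drop = FALSE]
  rownames(cat) <- NULL

  search_space <- build_variant_database(proteome, snps, freq_threshold)
  uq <- lapply(cat$peptide, uniqueness_screen, search_space = search_space)
  cat$unique <- vapply(uq, `[[`, logical(1), "unique")
  cat$unique_genes <- vapply(uq, function(u)
    paste(u$genes, collapse = ","), character(1))

  maf_m <- snp_maf_matrix(snps)
  rs_list <- strsplit(cat$rs_ids, ",", fixed = TRUE)
  conf <- lapply(rs_list, function(rr) {
    m <- match(rr, snps$rs_id)
    hit <- confusable_sap_screen(snps$ref_aa[m], snps$alt_aa[m],
                                 exclusion_pairs)
    if (any(hit)) paste0(snps$ref_aa[m][hit], ">", snps$alt_aa[m][hit])
    else character(0)
  })
  cat$confusable <- lengths(conf) > 0L
  cat$confusable_pair <- vapply(conf, paste, character(1), collapse = ",")
  for (p in pops)
    cat[[paste0("maf_", p)]] <- vapply(rs_list, function(rr)
      min(maf_m[match(rr, snps$rs_id), p]), numeric(1))
  class(cat) <- c("gvp_catalog", "data.frame")
  cat
}

#' Write / read a GVP catalog as TSV
#' @param catalog a `gvp_catalog` from [enumerate_gvps()].
#' @param path file path.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv_det(as.data.frame(catalog), path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  df <- read_tsv_strict(path, required = c("peptide", "gene", "accession",
                                           "start", "end",
                                           "missed_cleavages",
                                           "allele_class", "rs_ids",
                                           "alleles"))
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$missed_cleavages <- as.integer(df$missed_cleavages)
  df$n_sap <- as.integer(df$n_sap)
  df$unique <- as.logical(df$unique)
  df$confusable <- as.logical(df$confusable)
  for (cl in c("unique_genes", "confusable_pair"))
    if (cl %in% names(df)) df[[cl]][is.na(df[[cl]])] <- ""
  class(df) <- c("gvp_catalog", "data.frame")
  df
}

# Parse a catalog `alleles` field into a data.frame(rs_id, nuc, aa).
parse_alleles <- function(alleles) {
  parts <- strsplit(strsplit(alleles, ",", fixed = TRUE)[[1]], ":",
                    fixed = TRUE)
  data.frame(rs_id = vapply(parts, `[`, character(1), 1),
             nuc = vapply(parts, `[`, character(1), 2),
             aa = vapply(parts, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}
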