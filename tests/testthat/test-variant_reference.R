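test_that("digest reproduces the stated examples", {
  d0 <- digest("AKRPGFKDE", max_missed = 0)
  expect_identical(d0$peptide, c("AK", "RPGFK", "DE"))
  expect_identical(d0$start, c(1L, 3L, 8L))
  expect_identical(digest("AAAA", max_missed = 3)$peptide, "AAAA")
  d1 <- digest("AKGK", max_missed = 1)
  expect_true(all(c("AKGK", "AK", "GK") %in% d1$peptide))
})

test_that("0-missed peptides concatenate back to the input sequence", {
  set.seed(21)
  for (i in 1:20) {
    s <- random_aa_sequence(sample(10:200, 1))
    d <- digest(s, max_missed = 0)
    expect_identical(paste(d$peptide, collapse = ""), s)
  }
})

test_that("digest equals the brute-force oracle on random sequences", {
  set.seed(22)
  for (i in 1:40) {
    s <- random_aa_sequence(sample(5:200, 1))
    mm <- sample(0:3, 1)
    expect_same_peptide_set(digest(s, mm), oracle_digest(s, mm))
  }
})

test_that("build_variant_database applies all passing SAPs in one copy", {
  prot <- protein_set("P1", "G1", "ACDEFGHIK")
  snp <- as_snp_table(data.frame(
    rs_id = "rsX", gene = "G1", accession = "P1", pos = 3L,
    ref_aa = "D", alt_aa = "N", ref_nuc = "G", alt_nuc = "A",
    count_EUR = 30, size_EUR = 379, maf_EUR = 0.05,
    stringsAsFactors = FALSE))
  db <- build_variant_database(prot, snp, freq_threshold = 0.004)
  expect_identical(db$sequence, c("ACDEFGHIK", "ACNEFGHIK"))
  expect_identical(db$accession[2], "P1|var")

  # below-threshold SAP emits no variant copy
  snp$maf_EUR <- 0.001
  expect_identical(build_variant_database(prot, snp, 0.004), prot)

  # empty SNP list is the identity
  expect_identical(build_variant_database(prot, snp[0, ], 0.004), prot)
})

test_that("variant database size equals proteome + proteins with SAPs", {
  st <- cached_study()
  db <- build_variant_database(st$proteome, st$snps)
  n_with <- length(unique(st$snps$accession[
    gvptools:::sap_passes_freq(st$snps, 0.004)]))
  expect_identical(nrow(db), nrow(st$proteome) + n_with)
})

test_that("SNP/reference inconsistencies are hard errors naming the rs", {
  prot <- protein_set("P1", "G1", "ACDEFGHIK")
  snp <- toy_snps()[1, ]
  snp$accession <- "P1"
  snp$pos <- 4L  # residue E, not D
  expect_error(build_variant_database(prot, snp), "rs1")
  snp$pos <- 99L
  expect_error(build_variant_database(prot, snp), "rs1")
  # co-positional SAPs cannot coexist in one variant copy
  two <- rbind(toy_snps()[1, ], toy_snps()[1, ])
  two$rs_id <- c("rsA", "rsB")
  two$alt_aa <- c("N", "E")
  expect_error(build_variant_database(toy_proteome(), two),
               "co-positional")
})

test_that("enumerate_gvps digests the substituted sequence per allele", {
  st <- cached_study()
  cat <- st$catalog
  seqs <- st$proteome$sequence[match(cat$accession,
                                     st$proteome$accession)]
  for (i in seq_len(nrow(cat))) {
    al <- gvptools:::parse_alleles(cat$alleles[i])
    snp_idx <- match(al$rs_id, st$snps$rs_id)
    sub_seq <- gvptools:::substitute_saps(seqs[i],
                                          st$snps$pos[snp_idx], al$aa)
    expect_identical(substr(sub_seq, cat$start[i], cat$end[i]),
                     cat$peptide[i])
    expect_true(all(st$snps$pos[snp_idx] >= cat$start[i] &
                      st$snps$pos[snp_idx] <= cat$end[i]))
  }
})

test_that("a cleavage-site SAP yields allele-specific peptide sets", {
  # R -> Q at a tryptic boundary: the variant peptide spans the former
  # boundary, the reference peptides terminate at it
  prot <- protein_set("P1", "KRT32", "AAGTRLLDEK")
  snp <- as_snp_table(data.frame(
    rs_id = "rsRQ", gene = "KRT32", accession = "P1", pos = 5L,
    ref_aa = "R", alt_aa = "Q", ref_nuc = "G", alt_nuc = "A",
    count_EUR = 50, size_EUR = 379, maf_EUR = 0.1,
    stringsAsFactors = FALSE))
  cat <- enumerate_gvps(prot, snp, max_missed = 0)
  ref_peps <- cat$peptide[cat$allele_class == "reference"]
  var_peps <- cat$peptide[cat$allele_class == "variant"]
  expect_true("AAGTR" %in% ref_peps)
  expect_true("AAGTQLLDEK" %in% var_peps)
  expect_false(any(var_peps == "AAGTQ"))

  # and the emitted sets match digesting each allele sequence directly
  for (allele in c("reference", "variant")) {
    seq <- if (allele == "reference") "AAGTRLLDEK" else "AAGTQLLDEK"
    d <- oracle_digest(seq, 0)
    d <- d[d$start <= 5 & d$end >= 5, ]
    got <- cat[cat$allele_class == allele, c("peptide", "start", "end",
                                             "missed_cleavages")]
    expect_same_peptide_set(got, d)
  }
})

test_that("peptides covering two SAPs are emitted as combinations", {
  prot <- protein_set("P1", "G1", "AAGTSLLDEKFFK")
  snps <- as_snp_table(data.frame(
    rs_id = c("rsA", "rsB"), gene = "G1", accession = "P1",
    pos = c(4L, 6L), ref_aa = c("T", "L"), alt_aa = c("S", "V"),
    ref_nuc = c("C", "T"), alt_nuc = c("G", "C"),
    count_EUR = c(60, 70), size_EUR = 379, maf_EUR = c(0.1, 0.12),
    stringsAsFactors = FALSE))
  cat <- enumerate_gvps(prot, snps, max_missed = 0)
  both <- cat[cat$n_sap == 2, ]
  expect_true(nrow(both) >= 1)
  expect_true(all(grepl("rsA", both$rs_ids) & grepl("rsB", both$rs_ids)))
  # the double-variant combination exists (from the all-variant sequence)
  combos <- vapply(both$alleles, function(a)
    paste(gvptools:::parse_alleles(a)$aa, collapse = ""), character(1))
  expect_true("SV" %in% combos)  # both alternative residues jointly
})

test_that("uniqueness screen matches an exhaustive substring scan", {
  space <- protein_set(c("P1", "P2", "P2v"),
                       c("KRT81", "KRT86", "KRT86"),
                       c("AAASHARED", "SHAREDKGG", "SHAREDKAA"))
  r <- uniqueness_screen("SHARED", space)
  expect_false(r$unique)
  expect_identical(r$genes, c("KRT81", "KRT86"))
  # present in one gene's records only (reference + variant copy)
  r2 <- uniqueness_screen("SHAREDK", space)
  expect_true(r2$unique)
  expect_identical(r2$genes, "KRT86")
  # absent everywhere: unique with empty gene list
  r3 <- uniqueness_screen("WWWWW", space)
  expect_true(r3$unique)
  expect_length(r3$genes, 0)
  # I and L are distinct in matching
  space2 <- protein_set("P1", "G1", "AAILAA")
  expect_length(uniqueness_screen("AILA", space2)$genes, 1)
  expect_length(uniqueness_screen("ALLA", space2)$genes, 0)
})

test_that("confusable SAP screen uses the ordered default pair set", {
  expect_true(confusable_sap_screen("N", "D"))
  expect_true(confusable_sap_screen("M", "F"))
  expect_true(confusable_sap_screen("Q", "E"))
  expect_true(confusable_sap_screen("C", "S"))
  expect_false(confusable_sap_screen("A", "V"))
  expect_false(confusable_sap_screen("D", "N"))  # ordered, not symmetric
  expect_true(confusable_sap_screen("A", "V", exclusion_pairs = "A>V"))
})

test_that("FASTA and catalog round-trip through disk", {
  st <- cached_study()
  fa <- tempfile(fileext = ".fasta")
  write_proteome_fasta(st$proteome, fa)
  back <- read_proteome_fasta(fa)
  expect_identical(as.data.frame(back), as.data.frame(st$proteome))
  tsv <- tempfile(fileext = ".tsv")
  write_catalog(st$catalog, tsv)
  back2 <- read_catalog(tsv)
  expect_identical(back2$peptide, st$catalog$peptide)
  expect_identical(back2$alleles, st$catalog$alleles)
  expect_equal(back2$maf_EUR, st$catalog$maf_EUR, tolerance = 1e-9)
  expect_identical(back2$unique, st$catalog$unique)
})
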