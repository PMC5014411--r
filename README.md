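# gvptools

Protein-based human identification from shotgun proteomics data.

DNA degrades; protein persists. Hair shaft, bone and tooth proteomes carry
genetic information in the form of single amino acid polymorphisms (SAPs) —
the protein-level image of non-synonymous SNPs (nsSNPs). A tryptic peptide
whose sequence differs between the two alleles of an nsSNP is a
*genetically variant peptide* (GVP): detecting it in an LC-MS/MS dataset
imputes the corresponding nsSNP allele in the donor's genome without any
DNA template. `gvptools` implements the full downstream pipeline for
forensic and bioarchaeological use:

1. **Variant reference construction** — given a reference proteome (FASTA)
   and an nsSNP annotation table, appends to each protein one additional
   sequence carrying all sufficiently common SAPs (`<accession>|var`), and
   enumerates the GVP catalog by in-silico tryptic digestion of each
   allele-substituted sequence (cleavage C-terminal to K/R, suppressed
   before P, configurable missed cleavages). Each catalog entry is screened
   for gene uniqueness and for chemically confusable substitutions
   (M→F, N→D, Q→E, C→S by default).
2. **PSM filtering** — the standard exclusion criteria applied to
   peptide-spectrum matches: engine score (X!Tandem log₁₀(e) ≤ −2, Mascot
   expectation ≤ 0.05), precursor mass error (≤ 0.2 Da), minor allele
   frequency (≥ 0.4% in at least one reference population), biological
   PTMs (phosphorylation), confusable SAPs, gene uniqueness, and
   alternative-allele diagnostic fragment ions (singly charged b/y ladders,
   0.02 Da tolerance).
3. **Profile imputation and validation** — filtered detections are
   collated into per-subject profiles (per gene, the set of detected
   (rs, allele) pairs; one observation per allele per gene regardless of
   PSM multiplicity) and validated against truth genotypes as a TP/FP/FN/TN
   confusion matrix with per-GVP sensitivity, PPV and FDR.
4. **Random-match probability** — per gene, the carrier count x of the
   detected allele combination in a reference panel of size n gives the
   Jeffreys posterior-mean estimate

       p̂ = (x + ½) / (n + 1)

   (non-zero even at x = 0); per-gene estimates are multiplied across genes
   under the product rule (independence between genes, full dependence
   within a gene), with a parametric-bootstrap 90% CI
   (x* ~ Binomial(n, p̂) per gene, 5th/95th percentiles of the resampled
   products) and cross-population likelihood ratios
   L = Pr(profile | pop₁) / Pr(profile | pop₂).
5. **Synthetic data** — Hardy-Weinberg genotype panels, subject genotypes,
   and a binary detection model (per-GVP sensitivity and false-positive
   rate), so every stage is testable end to end with known ground truth.

## Worked example

```r
library(gvptools)

cfg <- sim_config(seed = 101, n_subjects = 10,
                  detection_sensitivity = 0.9, false_positive_rate = 0.01)
pr      <- simulate_proteome(cfg)
catalog <- enumerate_gvps(pr$proteome, pr$snps)
truth   <- simulate_subjects(cfg)
psms    <- simulate_detections(truth, catalog, cfg)

res  <- apply_filters(psms, catalog)
prof <- collate_profile(res$detections, subjects = unique(truth$subject_id))
conf <- classify_calls(prof, truth, catalog)
attr(metrics_table(conf, catalog), "overall")
#>          tp          fp          fn          tn   evaluable sensitivity
#>   137.00000     0.00000    21.00000    82.00000   240.00000    86.70886
#>         ppv         fdr
#>   100.00000     0.00000
```

Of 240 evaluable (subject × GVP allele) cells, 137 detections are all true
(PPV 100%, FDR 0%); 21 carried alleles were missed, matching the
configured 90% detection sensitivity.

```r
panels <- list(EUR = simulate_panel(cfg, "EUR"),
               AFR = simulate_panel(cfg, "AFR"))
ev <- evaluate_profiles(prof, panels, B = 10000, seed = 202)
ev$results[["S001"]][["EUR"]]
#> <profile_probability_result> subject S001 | EUR
#>   Pr(profile|population) = 6.53e-02  90% CI [5.44e-02, 7.61e-02]  (10 genes)

head(ev$summary[ev$summary$population == "AFR",
                c("subject", "overall", "lr_vs_reference", "log10_lr")], 3)
#>   subject  overall lr_vs_reference log10_lr
#> 2    S001 7.60e-03            8.58    0.934
#> 4    S002 2.23e-05           47.29    1.675
#> 6    S003 5.90e-02            1.05    0.020
```

Subject S001's imputed profile occurs with probability 6.5×10⁻² in the
European panel but 7.6×10⁻³ in the African panel: a likelihood ratio of
8.6 in favour of European origin — the biogeographic signal the method
provides.

## Command line

```sh
gvptools simulate --out study --seed 7 --sensitivity 1 --fpr 0
gvptools build-db --proteome study/proteome.fasta --snps study/snps.tsv \
                  --out study/db.fasta --catalog study/catalog.tsv
gvptools filter   --psms study/psms.tsv --catalog study/catalog.tsv \
                  --out study/detections.tsv --audit study/audit.tsv
gvptools impute   --detections study/detections.tsv --out study/profiles.tsv
gvptools validate --profiles study/profiles.tsv --truth study/truth.tsv \
                  --catalog study/catalog.tsv --out study/metrics.tsv
gvptools prob     --profiles study/profiles.tsv --snps study/snps.tsv \
                  --panels EUR=study/panel_EUR.vcf,AFR=study/panel_AFR.tsv \
                  --out study/prob --B 10000 --seed 17
```

Every command writes a `.manifest.json` (options, input MD5 digests, seed,
version). Reruns with the same seed are byte-identical.

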