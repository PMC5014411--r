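---
title: "Imputing nsSNP profiles from genetically variant peptides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing nsSNP profiles from genetically variant peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvptools)
```

# The model

A non-synonymous SNP substitutes one residue in a protein. Tryptic
digestion of that protein therefore yields, at the polymorphic site, one of
two peptide sequences depending on which allele(s) the donor carries. If a
peptide-spectrum-matching engine confidently identifies one of these
genetically variant peptides (GVPs) in a proteomic dataset, the donor's
genome must contain the corresponding allele. Detection is binary evidence
of *carrier status*: a peptide cannot distinguish a heterozygote from a
homozygote, because the proteome of a heterozygote contains both allele
products and the proteome of a homozygote contains one. Every counting
decision in this package follows from that asymmetry.

The pipeline has four stages:

1. **Catalog construction.** For each nsSNP, both allele-substituted
   protein sequences are digested in silico and every peptide whose span
   covers the polymorphic position is catalogued. Digestion always happens
   on the substituted sequence — a SAP that creates or destroys a K/R
   cleavage site changes the peptide set itself, not just one residue, and
   a post-hoc residue swap would get this wrong. Peptides covering several
   catalogued SAPs are emitted as joint combination evidence; an
   all-variant sequence per protein contributes the multi-variant
   combinations.
2. **Filtering.** Candidate detections are excluded on engine score,
   precursor mass error, population frequency, biological PTMs, chemical
   confusability of the substitution, gene uniqueness, and
   alternative-allele diagnostic fragment ions (details below). Filters
   are pure predicates; their conjunction is order-independent and each
   exclusion is attributed to every rule it violates.
3. **Imputation.** Detections collapse to a per-subject profile: per gene,
   the set of distinct (rs, allele) pairs. PSM multiplicity is discarded —
   within a gene, an allele (or allele combination) is observed at most
   once per subject.
4. **Profile statistics.** For each gene, the number of panel individuals
   *carrying* the subject's detected allele combination is x out of n
   complete-case individuals, and the combination probability is the
   Jeffreys posterior mean (x + ½)/(n + 1). Per-gene probabilities are
   multiplied across genes (product rule); uncertainty comes from a
   parametric bootstrap; biogeographic evidence from the ratio of the same
   profile's probability under two population panels.

# Statistical choices

**Carrier counting.** "x individuals with the combination" counts any
individual whose diploid genotype contains every detected allele —
heterozygous or homozygous. This is the only reading consistent with
detection evidence that cannot assert zygosity, and it is conservative: it
yields the larger x, hence the larger (less incriminating) match
probability. Detecting *both* alleles at one rs is heterozygote evidence
and counts only heterozygotes.

**Complete-case panel sizes.** An individual with a missing call at any
locus of a gene's combination is removed from both x and n *for that gene
only*. Shrinking only x would bias probabilities downward.

**Jeffreys estimator.** (x + ½)/(n + 1) is the posterior mean of a
binomial proportion under the Beta(½, ½) prior. Its value over the naive
x/n is behaviour at x = 0: a profile never seen in a 379-individual panel
gets probability 0.5/380 ≈ 1.3 × 10⁻³, not zero — indispensable when
probabilities are multiplied.

**Product rule.** Independence is assumed *between* genes and full
dependence *within* a gene (combinations are counted jointly, which makes
no assumption about within-gene linkage). Trichocyte keratin genes cluster
on chromosomes 12 and 17 within plausible linkage-disequilibrium range, so
between-gene independence is an approximation; no LD correction is
attempted (a deliberate non-goal), and reported probabilities should be
read accordingly.

**Bootstrap.** Per gene, x* ~ Binomial(n, (x + ½)/(n + 1)), re-estimate,
multiply across genes, repeat B = 10,000 times, take the empirical 5th and
95th percentiles (linear interpolation, R quantile type 7) as the 90% CI.
With x = 0 the resampling distribution has an atom at the minimum
(0.5/(n+1))ᴳ, so lower bounds can sit exactly on that point — expected,
not a bug. Products are accumulated in natural-log space; a 40-gene
profile of halves is exactly 2⁻⁴⁰.

**Likelihood ratios** are computed in log10 space and reported both ways.
The `evaluate_profiles()` summary defines `lr_vs_reference` =
Pr(profile | reference panel)/Pr(profile | this panel), the first panel
being the reference, so LR > 1 means the profile is more plausible in the
reference population.

# Filter thresholds

| parameter | default | rationale |
|---|---|---|
| `xtandem_loge_max` | −2 | keep log₁₀(e) ≤ −2. The conventional statement of this criterion ("log(e) < −2" on an exclusion list) inverts X!Tandem semantics, where more negative is better; keep-if-≤ is the only sensible reading. |
| `mascot_expect_max` | 0.05 | linear expectation scale; engines are never cross-converted. |
| `precursor_tol_da` | 0.2 Da | observed vs theoretical precursor mass; strict `>` excludes, so boundary values are kept. |
| `freq_threshold` | 0.004 | minimum MAF in **at least one** reference population. Printed variants of this threshold (0.4% allelic, 0.5% allelic, 0.8% genotype) disagree; one configurable parameter is exposed, applied as exclude-if-below-everywhere. For combination peptides the minimum MAF across covered loci is used: a combination with any rare constituent is excluded. |
| `fragment_tol_da` | 0.02 Da | high-resolution qToF regime; diagnostic-ion matching. |
| `biological_mods` | "phospho" | biological PTMs invalidate an assignment; sample-prep (carbamidomethyl) and artifact mods (oxidation, deamidation) do not — artifact-like conversions are handled by the confusable-SAP screen instead. |
| `exclusion_pairs` | M>F, N>D, Q>E, C>S | ordered substitutions indistinguishable from common chemical conversions; entries covering such a SAP are rejected for both allele classes (the *polymorphism* is unusable, not just one peptide). |

The **uniqueness screen** accepts a peptide only if it occurs in the
products of at most one gene (a gene's reference sequence and its own
variant copy count as one gene); peptides absent from the whole search
space are accepted but flagged. I and L are distinct residues here —
their mass equivalence is an engine-side ambiguity that the engine's own
scoring already absorbs; treating them as equal at the string level would
discard genuinely unique peptides. Pseudogene-derived matches cannot be
excluded at the protein level at all; this is flagged as an intrinsic
limitation, not solved.

The **diagnostic-ion screen** computes singly charged b/y ladders
(monoisotopic residue masses, fixed carbamidomethyl +57.02146 Da on C,
proton 1.00728 Da, water 18.01056 Da) for the detected and the
opposite-allele peptide; ions unique to the opposite allele within
tolerance are diagnostic, and any observed match excludes the PSM. When
the SAP sits on a cleavage site the two ladders have different lengths and
the diagnostic set is simply all non-shared ions. PSMs without a fragment
list pass with an explicit `fragment_not_evaluated` flag rather than
silently.

# The variant database

The search database contains each reference protein plus *one* additional
sequence carrying all SAPs above the frequency threshold simultaneously
(`accession|var`). One combined variant copy rather than a combinatorial
expansion keeps the database compact — large databases cost search
sensitivity. The price is that two above-threshold SAPs at the same
position cannot be represented; this is a hard error rather than a silent
choice. Rare SAPs are excluded from the database (and from the imputable
universe) because a rare genetic explanation for a mass shift is more
likely to be a chemical artifact.

# What the synthetic generator does and does not emulate

`sim_config()` states a world: 12 nsSNP loci in 8 synthetic
trichocyte-keratin-like genes (two genes carry two loci, exercising joint
combination counting), diploid genotypes in Hardy-Weinberg equilibrium at
stated alternative-allele frequencies (0.05–0.5 — the common-SNP regime
the method requires, since rare loci are filtered out by design), panels
of 400/250 individuals (reference panels of a few hundred, the realistic
scale), 20 subjects, and a binary detection process with per-GVP
sensitivity 0.9 and false-positive rate 0.01 by default (detection in real
hair datasets varies widely with protein abundance; 0.9/0.01 represents a
good-quality dataset). Protein sequences are random tryptic segments with
each SAP planted mid-peptide; decoy loci (a rare locus, an N→D confusable
locus, a peptide shared between two genes) plus seven crafted decoy PSMs
exercise every exclusion rule individually.

The generator does **not** emulate: mass spectra or retention times
(detection is binary at the PSM level), within-gene haplotype structure or
between-gene LD (loci are independent), peptide-abundance-dependent
sensitivity, or chemically induced false SAPs. A green end-to-end test
therefore establishes the correctness of the bookkeeping, counting and
statistics — not the real-world error rates of any search engine.

# Numerical and degenerate-input conventions

* Protein positions and peptide spans are 1-based inclusive.
* Boundary filter values (Δ = 0.2 Da, expect = 0.05, log(e) = −2) are kept.
* Zero denominators in sensitivity/PPV/FDR yield `NA` ("undefined"),
  never 0 or 100.
* An empty profile has probability 1 (vacuous product), with a warning.
* Genotype panels are matched to loci by rs ID, never by genomic
  position, to avoid genome-build drift; duplicated VCF IDs are a hard
  error, phase is ignored.
* All table and JSON writers are byte-deterministic (12 significant
  digits, fixed column order); every CLI run writes a manifest with input
  MD5 digests and the seed. Bootstrap seeding saves and restores the
  caller's RNG state.
* Truth genotypes support an explicit failed-determination state; failed
  cells are excluded from the evaluable set of the confusion matrix (the
  treatment of such cells is otherwise underdetermined, and the choice is
  recorded in output metadata via the manifest).

# Known limitations

* No LD/θ-style correction between clustered genes; probabilities are
  product-rule approximations.
* Zygosity is never imputed; profile probabilities are carrier
  probabilities.
* No PSM-level FDR estimation or rescoring — engine output is trusted up
  to the exclusion rules.
* Pseudogene ambiguity is undetectable from protein sequence alone.
* The acceptance battery is property-based (oracle equivalence, coverage,
  recovery); it cannot certify numbers derived from proprietary raw
  datasets that are not distributable.
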