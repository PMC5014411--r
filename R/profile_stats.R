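#' Count carriers of an allele combination in a population panel
#'
#' Carrier counting: an individual counts toward `x` when their diploid
#' genotype contains every allele in the combination (heterozygous or
#' homozygous — peptide detection cannot assert zygosity, so the carrier
#' reading is the conservative, larger-`x` one). The panel size `n` is the
#' number of individuals with complete (non-missing) calls at every locus
#' of the combination, computed per gene.
#'
#' @param panel a [population_panel()].
#' @param combination data frame with columns `rs_id`, `allele` — the
#'   detected alleles within one gene boundary. Detecting both alleles of
#'   one rs (two rows) encodes heterozygote evidence.
#' @return named integer vector `c(x = carriers, n = panel size)`.
#' @export
count_combination <- function(panel, combination) {
  if (!nrow(combination)) stop("empty allele combination", call. = FALSE)
  g <- panel$genotypes
  have <- combination$rs_id %in% g$rs_id
  if (!all(have)) {
    warning("locus/loci absent from panel '", panel$population_id,
            "' dropped from combination: ",
            paste(combination$rs_id[!have], collapse = ", "),
            call. = FALSE)
    combination <- combination[have, , drop = FALSE]
    if (!nrow(combination))
      stop("no combination locus present in panel", call. = FALSE)
  }
  loci <- unique(combination$rs_id)
  inds <- unique(g$individual_id)
  sub <- g[g$rs_id %in% loci, , drop = FALSE]
  key <- paste(sub$individual_id, sub$rs_id)
  complete <- rep(TRUE, length(inds))
  carries <- rep(TRUE, length(inds))
  for (rs in loci) {
    idx <- match(paste(inds, rs), key)
    a1 <- sub$a1[idx]; a2 <- sub$a2[idx]
    ok <- !is.na(idx) & !is.na(a1) & !is.na(a2)
    complete <- complete & ok
    need <- combination$allele[combination$rs_id == rs]
    for (al in need)
      carries <- carries & ok & (a1 == al | a2 == al)
  }
  c(x = sum(carries & complete), n = sum(complete))
}

#' Jeffreys-prior estimate of a population proportion
#'
#' The posterior mean of a binomial proportion under the Beta(1/2, 1/2)
#' (Jeffreys) prior: `(x + 1/2) / (n + 1)`. Strictly inside (0, 1), so a
#' combination never seen in the panel (`x = 0`) still gets a non-zero
#' probability.
#'
#' @param x carrier count(s), `0 <= x <= n`.
#' @param n panel size(s), `n >= 1`.
#' @return numeric vector of probabilities.
#' @examples
#' jeffreys_probability(0, 379)  # 0.5 / 380
#' @export
jeffreys_probability <- function(x, n) {
  if (any(n < 1)) stop("panel size n must be >= 1", call. = FALSE)
  if (any(x < 0 | x > n)) stop("x must satisfy 0 <= x <= n", call. = FALSE)
  (x + 0.5) / (n + 1)
}

#' Product-rule profile probability
#'
#' Multiplies per-gene probabilities under the assumption of full
#' independence between genes (and full dependence within a gene, since
#' combinations are counted jointly). Accumulated in log space so profiles
#' spanning many genes do not underflow.
#'
#' @param p numeric vector of per-gene probabilities in (0, 1].
#' @return the product.
#' @export
profile_probability <- function(p) {
  if (!length(p)) {
    warning("empty profile: vacuous product = 1", call. = FALSE)
    return(1)
  }
  stopifnot(all(p > 0), all(p <= 1))
  exp(sum(log(p)))
}

#' Parametric bootstrap 90% confidence interval for a profile probability
#'
#' For each gene, resamples the carrier count `x* ~ Binomial(n, p_hat)`
#' with `p_hat = (x + 1/2)/(n + 1)`, recomputes the Jeffreys estimate from
#' `x*`, multiplies across genes, and takes the empirical 5th and 95th
#' percentiles (linear interpolation) of the `B` resampled products.
#'
#' @param gene_counts data frame with columns `x` and `n`, one row per gene.
#' @param B number of bootstrap replicates (default 10000).
#' @param seed integer seed; the global RNG state is restored afterwards.
#' @return named numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(gene_counts, B = 10000, seed) {
  stopifnot(B >= 1, nrow(gene_counts) >= 1)
  p_hat <- jeffreys_probability(gene_counts$x, gene_counts$n)
  n <- gene_counts$n
  with_seed(seed, {
    logp <- matrix(0, nrow = B, ncol = length(n))
    for (g in seq_along(n)) {
      xs <- stats::rbinom(B, n[g], p_hat[g])
      logp[, g] <- log((xs + 0.5) / (n[g] + 1))
    }
    tot <- exp(rowSums(logp))
    q <- stats::quantile(tot, c(0.05, 0.95), names = FALSE, type = 7)
    c(lower = q[1], upper = q[2])
  })
}

#' Cross-population likelihood ratio
#'
#' The ratio of one profile's probability under two population panels,
#' computed in log space. Accepts two `profile_probability_result` objects
#' (which must describe the same subject and gene set) or two bare
#' probabilities.
#'
#' @param result_pop1,result_pop2 results from [evaluate_profile()], or
#'   numeric probabilities.
#' @return list with `ratio` and `log10` elements.
#' @export
likelihood_ratio <- function(result_pop1, result_pop2) {
  get_p <- function(r) if (is.numeric(r)) r else r$overall
  if (!is.numeric(result_pop1)) {
    if (!identical(result_pop1$subject_id, result_pop2$subject_id))
      stop("likelihood ratio across different subjects", call. = FALSE)
    g1 <- sort(result_pop1$gene_probabilities$gene)
    g2 <- sort(result_pop2$gene_probabilities$gene)
    if (!identical(g1, g2))
      stop("gene-set mismatch between populations: {",
           paste(g1, collapse = ","), "} vs {",
           paste(g2, collapse = ","), "}", call. = FALSE)
  }
  l10 <- log10(get_p(result_pop1)) - log10(get_p(result_pop2))
  list(ratio = 10^l10, log10 = l10)
}

#' Probability of one subject's imputed profile in one population
#'
#' Per gene, counts carriers of the subject's detected allele combination
#' in the panel, applies the Jeffreys estimator, and combines genes with
#' the product rule; the sampling uncertainty is summarised by a
#' parametric-bootstrap 90% CI.
#'
#' @param profiles a `subject_profiles` (from [collate_profile()]).
#' @param subject_id which subject to evaluate.
#' @param panel a [population_panel()].
#' @param B bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return object of class `profile_probability_result`: a list with
#'   `subject_id`, `population_id`, `gene_probabilities` (gene, x, n,
#'   p_hat), `overall`, `log10_overall`, `ci90`, `B`, `seed`.
#' @export
evaluate_profile <- function(profiles, subject_id, panel, B = 10000, seed) {
  prof <- profiles[profiles$subject_id == subject_id, , drop = FALSE]
  genes <- unique(prof$gene)
  gp <- data.frame(gene = character(0), x = integer(0), n = integer(0),
                   p_hat = numeric(0), stringsAsFactors = FALSE)
  for (g in genes) {
    comb <- prof[prof$gene == g, c("rs_id", "allele")]
    xn <- tryCatch(count_combination(panel, comb),
                   error = function(e) {
                     warning("gene ", g, " dropped for subject ",
                             subject_id, ": ", conditionMessage(e),
                             call. = FALSE)
                     NULL
                   })
    if (is.null(xn) || xn["n"] == 0) next
    gp <- rbind(gp, data.frame(gene = g, x = unname(xn["x"]),
                               n = unname(xn["n"]),
                               p_hat = jeffreys_probability(xn["x"],
                                                            xn["n"]),
                               stringsAsFactors = FALSE))
  }
  overall <- if (nrow(gp)) profile_probability(gp$p_hat) else {
    warning("empty profile for subject ", subject_id, call. = FALSE)
    1
  }
  ci <- if (nrow(gp)) bootstrap_ci(gp[, c("x", "n")], B, seed)
  else c(lower = 1, upper = 1)
  structure(list(subject_id = subject_id,
                 population_id = panel$population_id,
                 gene_probabilities = gp, overall = overall,
                 log10_overall = log10(overall), ci90 = ci, B = B,
                 seed = seed),
            class = "profile_probability_result")
}

#' @export
print.profile_probability_result <- function(x, ...) {
  cat("<profile_probability_result> subject ", x$subject_id, " | ",
      x$population_id, "\n  Pr(profile|population) = ",
      format(x$overall, digits = 3, scientific = TRUE),
      "  90% CI [", format(x$ci90[1], digits = 3, scientific = TRUE), ", ",
      format(x$ci90[2], digits = 3, scientific = TRUE), "]  (",
      nrow(x$gene_probabilities), " genes)\n", sep = "")
  invisible(x)
}

#' Evaluate all subjects against one or more population panels
#'
#' @param profiles a `subject_profiles`.
#' @param panels named list of [population_panel()] objects; the first is
#'   the reference population for likelihood ratios (LR =
#'   Pr(profile|reference) / Pr(profile|population); 1 for the reference
#'   itself).
#' @param B bootstrap replicates per subject/panel.
#' @param seed master integer seed; per-(subject, panel) sub-seeds are
#'   derived deterministically from it.
#' @return list with `results` (nested `profile_probability_result`s,
#'   `results[[subject]][[population]]`) and `summary` (data frame:
#'   subject, population, overall, log10_overall, ci_low, ci_high,
#'   lr_vs_reference, log10_lr).
#' @export
evaluate_profiles <- function(profiles, panels, B = 10000, seed) {
  subjects <- attr(profiles, "subjects") %||% unique(profiles$subject_id)
  subjects <- intersect(subjects, unique(profiles$subject_id))
  if (is.null(names(panels)))
    names(panels) <- vapply(panels, `[[`, character(1), "population_id")
  ref <- names(panels)[1]
  results <- list()
  rows <- list()
  k <- 0L
  for (s in subjects) {
    results[[s]] <- list()
    for (p in names(panels)) {
      k <- k + 1L
      sub_seed <- (as.integer(seed) + 7919L * k) %% 2147483647L
      results[[s]][[p]] <- evaluate_profile(profiles, s, panels[[p]], B,
                                            sub_seed)
    }
    for (p in names(panels)) {
      r <- results[[s]][[p]]
      lr <- likelihood_ratio(results[[s]][[ref]], r)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, population = p, overall = r$overall,
        log10_overall = r$log10_overall,
        ci_low = unname(r$ci90[1]), ci_high = unname(r$ci90[2]),
        lr_vs_reference = lr$ratio, log10_lr = lr$log10,
        stringsAsFactors = FALSE)
    }
  }
  list(results = results, summary = do.call(rbind, rows))
}

#' Serialise evaluation results to JSON
#'
#' @param eval_out output of [evaluate_profiles()].
#' @param path output file.
#' @export
write_probability_json <- function(eval_out, path) {
  payload <- lapply(eval_out$results, function(by_pop)
    lapply(by_pop, function(r)
      list(subject_id = r$subject_id, population_id = r$population_id,
           genes = r$gene_probabilities, overall = r$overall,
           log10_overall = r$log10_overall,
           ci90 = list(lower = unname(r$ci90[1]),
                       upper = unname(r$ci90[2])),
           bootstrap_reps = r$B, seed = r$seed)))
  write_results_json(payload, path)
}
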