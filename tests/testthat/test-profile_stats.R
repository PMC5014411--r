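test_that("jeffreys_probability matches the closed form and bounds", {
  expect_equal(jeffreys_probability(0, 379), 0.5 / 380)
  expect_equal(jeffreys_probability(189, 378), 0.5)
  n <- 17
  expect_lt(jeffreys_probability(n, n), 1)
  expect_gt(jeffreys_probability(0, n), 0)
  # strictly increasing in x at fixed n; x = 0 closed form
  for (n in c(1, 5, 50)) {
    p <- jeffreys_probability(0:n, n)
    expect_true(all(diff(p) > 0))
    expect_equal(p[1], 1 / (2 * (n + 1)))
  }
  expect_error(jeffreys_probability(5, 4), "x must")
  expect_error(jeffreys_probability(0, 0), "n must")
})

test_that("count_combination implements carrier counting", {
  panel <- toy_panel()  # C/C, C/T, T/T, C/T
  expect_identical(count_combination(panel, data.frame(rs_id = "rs1",
                                                       allele = "T")),
                   c(x = 3L, n = 4L))
  # het evidence: both alleles required -> only the two C/T individuals
  het <- data.frame(rs_id = c("rs1", "rs1"), allele = c("C", "T"))
  expect_identical(count_combination(panel, het), c(x = 2L, n = 4L))
  # absent allele
  expect_identical(count_combination(panel, data.frame(rs_id = "rs1",
                                                       allele = "G"))[["x"]],
                   0L)
  expect_error(count_combination(panel, data.frame(rs_id = character(0),
                                                   allele = character(0))),
               "empty")
  expect_warning(
    xn <- count_combination(panel, data.frame(rs_id = c("rs1", "rs9"),
                                              allele = c("T", "A"))),
    "rs9")
  expect_identical(xn, c(x = 3L, n = 4L))
})

test_that("count_combination equals the per-individual oracle", {
  set.seed(41)
  for (i in 1:30) {
    n_loci <- sample(1:4, 1)
    loci <- data.frame(rs_id = paste0("rs", seq_len(n_loci)),
                       ref = "C", alt = "T", stringsAsFactors = FALSE)
    n_ind <- sample(5:60, 1)
    g <- expand.grid(individual_id = paste0("I", seq_len(n_ind)),
                     rs_id = loci$rs_id, stringsAsFactors = FALSE)
    g$a1 <- sample(c("C", "T", NA), nrow(g), replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
    g$a2 <- ifelse(is.na(g$a1), NA,
                   sample(c("C", "T"), nrow(g), replace = TRUE))
    panel <- population_panel("SIM", g)
    k <- sample(n_loci, 1)
    comb <- data.frame(rs_id = loci$rs_id[seq_len(k)],
                       allele = sample(c("C", "T"), k, replace = TRUE))
    expect_identical(count_combination(panel, comb),
                     oracle_count(panel, comb))
  }
})

test_that("profile probability is a log-space product", {
  expect_equal(profile_probability(0.3), 0.3)
  expect_equal(profile_probability(c(0.1, 0.2)), 0.02)
  expect_equal(profile_probability(rep(0.5, 40)), 2^-40)
  expect_gt(profile_probability(rep(1e-6, 40)), 0)  # no premature underflow
  expect_warning(p <- profile_probability(numeric(0)), "vacuous")
  expect_identical(p, 1)
  # adding a gene never increases the overall probability
  set.seed(42)
  for (i in 1:20) {
    p <- runif(sample(2:10, 1))
    expect_lte(profile_probability(p), min(p))
  }
})

test_that("bootstrap CI is seeded, deterministic, and sane", {
  gc1 <- data.frame(x = 500, n = 1000)
  ci <- bootstrap_ci(gc1, B = 10000, seed = 5)
  expect_identical(ci, bootstrap_ci(gc1, B = 10000, seed = 5))
  # at odd small B the percentiles interpolate, so seeds must differ
  expect_false(identical(bootstrap_ci(gc1, B = 101, seed = 5),
                         bootstrap_ci(gc1, B = 101, seed = 6)))
  # brackets the true proportion, shrinks with n
  expect_lt(ci[["lower"]], 0.5)
  expect_gt(ci[["upper"]], 0.5)
  ci_small <- bootstrap_ci(data.frame(x = 50, n = 100), B = 10000,
                           seed = 5)
  expect_lt(diff(unname(ci)), diff(unname(ci_small)))
  # x = 0: when P(x* = 0) > 5%, the lower bound is the degenerate point
  n <- 50
  p0 <- jeffreys_probability(0, n)
  stopifnot((1 - p0)^n > 0.05)
  ci0 <- bootstrap_ci(data.frame(x = 0, n = n), B = 4000, seed = 9)
  expect_equal(ci0[["lower"]], p0)
  # against the closed-form binomial quantile for a single gene
  ciq <- bootstrap_ci(data.frame(x = 300, n = 1000), B = 20000, seed = 3)
  phat <- jeffreys_probability(300, 1000)
  expect_equal(ciq[["lower"]],
               jeffreys_probability(qbinom(0.05, 1000, phat), 1000),
               tolerance = 0.01)
  expect_equal(ciq[["upper"]],
               jeffreys_probability(qbinom(0.95, 1000, phat), 1000),
               tolerance = 0.01)
})

test_that("bootstrap_ci does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(bootstrap_ci(data.frame(x = 3, n = 10), B = 100, seed = 77))
  expect_identical(runif(1), a)
})

test_that("likelihood ratios are reciprocal and unit on identity", {
  expect_equal(likelihood_ratio(0.1, 0.05)$ratio, 2)
  expect_equal(likelihood_ratio(0.1, 0.05)$log10, log10(2))
  l_ab <- likelihood_ratio(0.07, 0.3)
  l_ba <- likelihood_ratio(0.3, 0.07)
  expect_equal(l_ab$ratio * l_ba$ratio, 1)
  expect_equal(likelihood_ratio(0.2, 0.2)$ratio, 1)
})

test_that("likelihood_ratio rejects mismatched subjects or gene sets", {
  prof <- structure(data.frame(subject_id = "S1", gene = c("G1", "G2"),
                               rs_id = c("rs1", "rs2"),
                               allele = c("T", "C"),
                               stringsAsFactors = FALSE),
                    class = c("subject_profiles", "data.frame"))
  attr(prof, "subjects") <- "S1"
  g <- expand.grid(individual_id = paste0("I", 1:20),
                   rs_id = c("rs1", "rs2"), stringsAsFactors = FALSE)
  set.seed(5)
  g$a1 <- sample(c("C", "T"), nrow(g), TRUE)
  g$a2 <- sample(c("C", "T"), nrow(g), TRUE)
  p1 <- population_panel("A", g)
  p2 <- population_panel("B", g[g$rs_id == "rs1", ])  # gene G2 missing
  r1 <- evaluate_profile(prof, "S1", p1, B = 100, seed = 1)
  r2 <- suppressWarnings(evaluate_profile(prof, "S1", p2, B = 100,
                                          seed = 1))
  expect_error(likelihood_ratio(r1, r2), "gene-set mismatch")
  # identical panels give L = 1
  expect_equal(likelihood_ratio(r1, r1)$ratio, 1)
})

test_that("estimates converge to the true product as the panel grows", {
  q <- c(0.2, 0.4)
  carrier <- 2 * q * (1 - q) + q^2
  truep <- prod(carrier)
  loci <- default_sim_loci()[1:2, ]
  loci$af_EUR <- q
  err <- sapply(c(100, 1000, 10000), function(n) {
    cfg <- sim_config(loci = loci, panel_sizes = c(EUR = n),
                      n_subjects = 1, seed = 99)
    panel <- simulate_panel(cfg, "EUR")
    p <- prod(sapply(seq_len(2), function(k) {
      xn <- count_combination(panel,
                              data.frame(rs_id = loci$rs_id[k],
                                         allele = loci$alt_nuc[k]))
      jeffreys_probability(xn[["x"]], xn[["n"]])
    }))
    abs(log(p) - log(truep))
  })
  expect_lt(err[3], 0.05)
  expect_lt(err[3], err[1])
})

test_that("evaluate_profiles wires probabilities, CIs and LRs together", {
  st <- cached_study()
  res <- apply_filters(st$psms, st$catalog)
  prof <- collate_profile(res$detections,
                          subjects = unique(st$truth$subject_id))
  panels <- list(EUR = simulate_panel(st$config, "EUR"),
                 AFR = simulate_panel(st$config, "AFR"))
  ev <- evaluate_profiles(prof, panels, B = 500, seed = 17)
  s <- ev$summary
  expect_true(all(s$ci_low <= s$ci_high))
  expect_true(all(s$overall > 0 & s$overall <= 1))
  expect_true(all(s$lr_vs_reference[s$population == "EUR"] == 1))
  # overall equals the product of the per-gene Jeffreys estimates
  r <- ev$results[[1]][["EUR"]]
  expect_equal(r$overall, prod(r$gene_probabilities$p_hat),
               tolerance = 1e-12)
  # LR column equals the ratio of the stored overall probabilities
  afr <- s[s$population == "AFR", ]
  eur <- s[s$population == "EUR", ]
  expect_equal(afr$lr_vs_reference,
               eur$overall[match(afr$subject, eur$subject)] / afr$overall)
  # deterministic given the master seed
  ev2 <- evaluate_profiles(prof, panels, B = 500, seed = 17)
  expect_identical(ev$summary, ev2$summary)
})
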