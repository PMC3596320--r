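test_that("upstream window extraction covers -100..+1", {
  set.seed(61)
  genome <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                  collapse = "")

  # plus strand at position 101: bases 1..101
  expect_identical(extract_upstream(genome, start = 101, strand = "+"),
                   substr(genome, 1, 101))
  expect_identical(nchar(extract_upstream(genome, 150, "+")), 101L)
  expect_identical(extract_upstream(genome, 150, "+"),
                   substr(genome, 50, 150))

  # minus strand: reverse complement of the corresponding window
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  expect_identical(extract_upstream(genome, 150, "-"),
                   rc(substr(genome, 150, 250)))

  # windows beyond the ends are truncated with a warning
  expect_warning(short <- extract_upstream(genome, 50, "+"), "truncated")
  expect_identical(short, substr(genome, 1, 50))
  expect_error(extract_upstream(genome, 400, "+"), "outside")
})

test_that("CAI weights and geometric mean match hand enumeration", {
  # reference set: Lys codons AAA x1, AAG x4 -> w(AAA) = 0.25, w(AAG) = 1
  ref <- c("AAGAAGAAGAAGAAA")
  w <- cai_weights(ref)
  expect_equal(w$weight[w$codon == "AAA"], 0.25)
  expect_equal(w$weight[w$codon == "AAG"], 1)

  # two codons with w = 0.25 and 1: CAI = sqrt(0.25) = 0.5
  expect_equal(compute_cai("AAAAAG", w), 0.5)
  # gene of only optimal codons: CAI = 1
  expect_equal(compute_cai("AAGAAGAAG", w), 1)

  # enumeration oracle on a larger toy reference set
  ref3 <- c("AAAGGTGGCCTG", "AAGGGTCTGCTG", "GGTGGTAAACTG")
  codons <- unlist(lapply(ref3, function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }))
  counts <- table(codons)
  count_of <- function(cd) {
    if (cd %in% names(counts)) as.numeric(counts[cd]) else 0.5
  }
  syn <- function(cd) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc == gc[[cd]]]
  }
  w_oracle <- function(cd) {
    count_of(cd) / max(vapply(syn(cd), count_of, numeric(1)))
  }
  gene <- "AAAGGCCTGGGT"
  gene_codons <- substring(gene, seq(1, 12, 3), seq(3, 12, 3))
  expected <- geom_mean(vapply(gene_codons, w_oracle, numeric(1)))
  expect_equal(compute_cai(gene, cai_weights(ref3)), expected,
               tolerance = 1e-12)
})

test_that("CAI is invariant to rescaling reference counts", {
  ref <- c("AAGAAGAAGAAGAAA", "GGTGGCCTG")
  w1 <- cai_weights(ref)
  w3 <- cai_weights(rep(ref, 3)) # every count x3
  # genes over codons observed in the reference: CAI unchanged
  gene <- "AAAAAGGGTGGC"
  expect_equal(compute_cai(gene, w1), compute_cai(gene, w3),
               tolerance = 1e-12)
  expect_true(all(w1$weight > 0 & w1$weight <= 1))
  expect_true(all(w3$weight > 0 & w3$weight <= 1))
})

test_that("CDS validation: length and internal stops", {
  expect_error(compute_cai("AAAG", cai_weights("AAA")), "divisible")
  expect_warning(compute_cai("AAATAAAAG", cai_weights("AAAAAG")),
                 "internal stop")
})

test_that("tAI weights follow the wobble-discounted copy-number sums", {
  # all 64 anticodons equally abundant with zero wobble penalty: tAI = 1
  all_ac <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste0,
                  collapse = "")
  equal <- setNames(rep(1, 64), all_ac)
  w_eq <- tai_weights(equal, wobble_penalties = c(gu = 0, ic = 0, ia = 0,
                                                  ug = 0))
  expect_true(all(w_eq$weight == 1))
  expect_equal(compute_tai("TTCAAAGGC", w_eq), 1)

  # 2-tRNA toy system, hand-computed:
  #   W(TTC) = copies(GAA) = 1; W(AAA) = copies(TTT) = 2 = max
  copies <- c(GAA = 1, TTT = 2)
  w <- tai_weights(copies)
  expect_equal(w$weight[w$codon == "TTC"], 0.5)
  expect_equal(w$weight[w$codon == "AAA"], 1)
  #   W(TTT) = (1 - 0.41) * copies(GAA) = 0.59 (G:U wobble only)
  expect_equal(w$weight[w$codon == "TTT"], 0.59 / 2)
  #   W(AAG) = (1 - 0.68) * copies(TTT) = 0.64 (U:G wobble only)
  expect_equal(w$weight[w$codon == "AAG"], 0.64 / 2)

  # gene of one codon type at half-maximal weight: tAI = 0.5
  expect_equal(compute_tai("TTCTTCTTC", w), 0.5)
  # geometric mean over two codon types
  expect_equal(compute_tai("TTCAAA", w), sqrt(0.5 * 1))
  # unreadable codons are excluded with a warning
  expect_warning(t_part <- compute_tai("TTCGGG", w), "excluded")
  expect_equal(t_part, 0.5)
})

test_that("motif counting is overlap-aware and strand-specific", {
  expect_identical(count_motif("AGGAGGAG"), 2L)
  expect_identical(count_motif("ACGTACGT"), 0L)
  expect_identical(count_motif("AGGAGGAGGAG"), 3L)
  # planted motifs in a 101-nt window
  set.seed(62)
  bg <- sample(c("C", "T"), 101, replace = TRUE)
  bg[c(10:14, 40:44, 90:94)] <- c("A", "G", "G", "A", "G")
  expect_identical(count_motif(paste(bg, collapse = "")), 3L)
  # counted on the given strand only: the reverse complement differs
  expect_identical(count_motif("CTCCT"), 0L)
  # RNA alphabet accepted
  expect_identical(count_motif("AGGAGGAG", motif = "AGGAG"), 2L)
})

test_that("GC content excludes ambiguity codes", {
  expect_equal(gc_content(c("GGCC", "ATAT", "ATGC")), c(1, 0, 0.5))
  expect_equal(gc_content("AUGC"), 0.5)
  expect_equal(gc_content("ATGCNN"), 0.5)
  expect_error(gc_content(""), "nchar")
})

test_that("gene_features assembles the covariance-model inputs", {
  cds <- c(gA = "AAGAAGAAG", gB = "AAAAAGGGT")
  up <- c(gA = "AGGAGGAGCCC", gB = "CCCCCCCCCCC")
  dg <- tibble::tibble(gene = c("gA", "gB"), dg = c(-12.3, -4.5))
  f <- gene_features(cds, upstream = up, dg = dg)
  expect_identical(f$gene, c("gA", "gB"))
  expect_identical(f$length, c(9L, 9L))
  expect_identical(f$n_codons[[1]], 3L)
  expect_identical(f$motif_count, c(2L, 0L))
  expect_identical(as.character(f$motif_class), c("2+", "0"))
  expect_equal(f$abs_dg, c(12.3, 4.5))
})

test_that("an exact linear response is recovered with R^2 = 1", {
  set.seed(63)
  d <- tibble::tibble(x = rnorm(60))
  d$y <- 3 + 2 * as.numeric(scale(d$x))
  fit <- suppressWarnings(
    fit_covariance_model(d, response = "y", quantitative = "x",
                         qualitative = character())
  )
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(coef(fit$model)["x"]), 2, tolerance = 1e-8)
  expect_identical(fit$selected_terms, "x")
})

test_that("AIC selection rejects a pure-noise predictor most of the time", {
  # a single null predictor survives AIC with probability P(chisq_1 > 2)
  # ~= 0.157; over seeded replicates the intercept-only model dominates
  set.seed(64)
  picks <- replicate(600, {
    d <- tibble::tibble(x = rnorm(500), y = rnorm(500))
    fit <- fit_covariance_model(d, response = "y", quantitative = "x",
                                qualitative = character())
    length(fit$selected_terms) == 0
  })
  expect_gte(mean(picks), 0.8)
})

test_that("per-term false-retention rate under the null matches theory", {
  set.seed(65)
  kept <- replicate(60, {
    d <- tibble::tibble(x1 = rnorm(400), x2 = rnorm(400), x3 = rnorm(400),
                        y = rnorm(400))
    fit <- fit_covariance_model(d, response = "y",
                                quantitative = c("x1", "x2", "x3"),
                                qualitative = character())
    length(fit$selected_terms)
  })
  # theory: 3 * 0.157 ~= 0.47 terms per replicate
  expect_lt(mean(kept) / 3, 0.25)
})

test_that("selection never raises AIC above the full model", {
  sim <- generate_feature_table(n_genes = 150, seed = 66)
  fit <- fit_covariance_model(sim)
  expect_lte(fit$aic, fit$full_aic)
})

test_that("generative terms and signs are recovered on one replicate", {
  sim <- generate_feature_table(seed = 67)
  fit <- fit_covariance_model(sim)
  expect_true(all(c("ln_mrna", "length", "abs_dg", "cai", "mu_level") %in%
                    fit$selected_terms))
  est <- tidy(fit)
  signs <- sign(est$estimate[match(c("ln_mrna", "length", "abs_dg", "cai"),
                                   est$term)])
  expect_identical(unname(signs), c(-1, -1, 1, 1))
  expect_gt(fit$r_squared, 0.5)
  expect_lt(fit$r_squared, 0.75)
})

test_that("standardization invariance of selection and fit quality", {
  sim <- generate_feature_table(n_genes = 200, seed = 68)
  shifted <- dplyr::mutate(sim, length = length * 1000 + 5e5,
                           cai = cai / 10 + 0.5)
  f1 <- fit_covariance_model(sim)
  f2 <- fit_covariance_model(shifted)
  expect_identical(sort(f1$selected_terms), sort(f2$selected_terms))
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
  expect_equal(f1$aic, f2$aic, tolerance = 1e-8)
})

test_that("rank-deficient candidates are dropped with a report", {
  sim <- generate_feature_table(n_genes = 100, seed = 69)
  sim$dup <- sim$ln_mrna # perfectly collinear
  expect_message(
    fit <- fit_covariance_model(sim, quantitative = c("ln_mrna", "length",
                                                      "dup")),
    "rank-deficient"
  )
  expect_true("dup" %in% fit$dropped_terms)
})

test_that("per-growth-rate models without the growth-rate term", {
  # growth rate as the only driver: within-condition R^2 collapses
  only_mu <- generate_feature_table(n_genes = 200,
                                    coefs = c(ln_mrna = 0), seed = 70)
  r2 <- growth_rate_only_r2(only_mu)
  expect_identical(nrow(r2), 3L)
  expect_true(all(r2$r_squared < 0.05))

  # within-condition signal only: per-condition R^2 matches the pooled fit
  only_gene <- generate_feature_table(
    n_genes = 200, coefs = c(ln_mrna = -0.6),
    mu_effects = c(`0.8` = 0, `0.51` = 0, `0.11` = 0),
    noise_sd = 0.4, seed = 71
  )
  pooled <- fit_covariance_model(only_gene)
  r2g <- growth_rate_only_r2(only_gene)
  expect_true(all(abs(r2g$r_squared - pooled$r_squared) < 0.1))

  # mixed generative model: conditioning away growth rate loses most R^2
  mixed <- generate_feature_table(n_genes = 200, seed = 72)
  pooled_m <- fit_covariance_model(mixed)
  r2m <- growth_rate_only_r2(mixed)
  expect_true(all(r2m$r_squared < pooled_m$r_squared))
})

test_that("tidy and glance expose the covariance fit", {
  sim <- generate_feature_table(n_genes = 150, seed = 73)
  fit <- fit_covariance_model(sim)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in%
                    names(td)))
  gl <- glance(fit)
  expect_identical(gl$n, nrow(fit$data))
  expect_true(gl$r.squared >= 0 && gl$r.squared <= 1)
})
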