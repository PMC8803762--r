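# Ka/Ks estimation, codon alignment, diversity, dating and group contrasts.

test_that("ng86 matches the brute-force enumerator on sampled codon pairs", {
  code <- oracle_codon_table()
  codons <- names(code)[code != "*"]
  set.seed(11)
  pairs <- cbind(sample(codons, 80, replace = TRUE),
                 sample(codons, 80, replace = TRUE))
  for (r in seq_len(nrow(pairs))) {
    est <- ng86(pairs[r, 1], pairs[r, 2])
    ora <- oracle_ng86(pairs[r, 1], pairs[r, 2])
    expect_equal(unname(est$sites["S"]), ora$S, tolerance = 1e-12)
    expect_equal(unname(est$diffs["sd"]), ora$sd, tolerance = 1e-12)
    expect_equal(unname(est$diffs["nd"]), ora$nd, tolerance = 1e-12)
    if (!est$saturated && !is.na(ora$ks)) {
      expect_equal(est$ks, ora$ks, tolerance = 1e-12)
    }
  }
})

test_that("ng86 is symmetric and zero on identical sequences", {
  set.seed(7)
  anc <- paste(sample(names(oracle_codon_table())[oracle_codon_table() != "*"],
                      100, replace = TRUE), collapse = "")
  ident <- ng86(anc, anc)
  expect_equal(ident$ks, 0)
  expect_equal(ident$ka, 0)
  expect_true(is.na(ident$omega))
  for (s in 1:5) {
    pair <- simulate_diverged_pair(anc, 0.3, 0.5, seed = s)
    ab <- ng86(pair$cds_a, pair$cds_b)
    ba <- ng86(pair$cds_b, pair$cds_a)
    expect_equal(ab$ks, ba$ks, tolerance = 1e-12)
    expect_equal(ab$ka, ba$ka, tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction is monotone below saturation", {
  p <- seq(0, 0.74, by = 0.02)
  d <- -0.75 * log(1 - 4 * p / 3)
  est <- vapply(p, function(x) {
    # correction as applied by the estimator path
    nlrevol:::jc_correct(x)
  }, numeric(1))
  expect_equal(est, d)
  expect_true(all(diff(est) > 0))
  expect_true(is.na(nlrevol:::jc_correct(0.75)))
})

test_that("codon_align handles identity, deletions and simulated pairs", {
  cds <- "ATGGCTGAAACTCTTCGT"
  same <- codon_align(cds, cds)
  expect_false(any(same$a == "---" | same$b == "---"))
  expect_identical(same$a, same$b)
  # drop one internal codon -> exactly one gap triple
  del <- paste0(substr(cds, 1, 6), substr(cds, 10, nchar(cds)))
  aln <- codon_align(cds, del)
  expect_equal(sum(aln$b == "---"), 1)
  expect_equal(sum(aln$a == "---"), 0)
  # simulated pairs are indel-free: equal length, no gaps
  anc <- with(list(), {set.seed(2); paste(sample(names(oracle_codon_table())[oracle_codon_table() != "*"], 60, replace = TRUE), collapse = "")})
  pair <- simulate_diverged_pair(anc, 0.2, 0.25, seed = 3)
  aln2 <- codon_align(pair$cds_a, pair$cds_b)
  expect_false(any(aln2$a == "---" | aln2$b == "---"))
  expect_error(codon_align("ATGTAAGCT", cds, id_a = "geneX"), "geneX")
})

test_that("pair classification follows species identity", {
  sp <- c(a1 = "P.persica", a2 = "P.persica", b1 = "P.avium")
  expect_equal(classify_pair("a1", "a2", sp), "paralog")
  expect_equal(classify_pair("a1", "b1", sp), "ortholog")
  expect_error(classify_pair("a1", "zz", sp), "zz")
  sim <- simulate_family_set(tiny_family_config(seed = 4))
  tg <- sim$truth$genes
  ss <- tg[tg$event == "species_specific", ]
  prs <- utils::combn(ss$gene_id, 2)
  types <- apply(prs, 2, function(p) {
    classify_pair(p[1], p[2], stats::setNames(tg$species, tg$gene_id))
  })
  expect_true(all(types == "paralog"))
})

test_that("positive-selection fractions and neutral candidates are counted", {
  res <- positive_selection_fraction(c(rep(2, 3), rep(0.2, 7), NA))
  expect_equal(res$count_gt1, 3)
  expect_equal(res$total, 10)
  expect_equal(res$percent, 30)
  expect_equal(positive_selection_fraction(rep(0.5, 40))$percent, 0)
  expect_true(is.na(positive_selection_fraction(numeric(0))$percent))
  expect_equal(positive_selection_fraction(c(1.005, 0.995, 2, 0.5))$neutral_candidates, 2)
})

test_that("nucleotide diversity equals the pairwise mean", {
  expect_equal(nucleotide_diversity(c(a = "ATGGCT", b = "ATGGCT"))$pi, 0)
  # 3 differences in 300 columns
  set.seed(9)
  base <- paste(sample(names(oracle_codon_table())[oracle_codon_table() != "*"],
                       100, replace = TRUE), collapse = "")
  var1 <- nlrevol:::mutate_positions(base, 3)
  expect_equal(nucleotide_diversity(c(a = base, b = var1))$pi, 3 / 300)
  # 4-member family: mean over the six unordered pairs, computed directly
  fam <- c(g1 = base, g2 = nlrevol:::mutate_positions(base, 5),
           g3 = nlrevol:::mutate_positions(base, 10),
           g4 = nlrevol:::mutate_positions(base, 2))
  prs <- utils::combn(4, 2)
  manual <- mean(apply(prs, 2, function(ij) {
    mean(strsplit(fam[[ij[1]]], "")[[1]] != strsplit(fam[[ij[2]]], "")[[1]])
  }))
  expect_equal(nucleotide_diversity(fam)$pi, manual)
  expect_equal(nucleotide_diversity(rev(fam))$pi, manual)
  expect_true(is.na(nucleotide_diversity(c(x = base))$pi))
})

test_that("duplication dating is linear and rejects negative ks", {
  expect_equal(date_duplication(0), 0)
  expect_equal(date_duplication(0.4), 2 * date_duplication(0.2))
  expect_error(date_duplication(-0.1))
  custom <- dating_params(mu = 1e-8, gen_years = 1)
  expect_equal(date_duplication(0.1, custom), 10)
})

test_that("compare_groups matches the closed-form Welch statistic", {
  a <- c(0.42, 0.51, 0.39, 0.61, 0.55, 0.47)
  b <- c(0.21, 0.33, 0.25, 0.19, 0.3)
  res <- compare_groups(a, b)
  expect_equal(res$t_statistic, oracle_welch_t(a, b), tolerance = 1e-12)
  expect_equal(res$summary$median,
               c(stats::median(a), stats::median(b)))
  same <- compare_groups(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)
  # the TNL-vs-non-TNL direction: clearly shifted groups are significant
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    hi <- stats::rnorm(200, 0.5, 0.1)
    lo <- stats::rnorm(200, 0.2, 0.1)
    hits <- hits + (compare_groups(hi, lo)$p_value < 0.01)
  }
  expect_equal(hits, 20)
})

test_that("ks histogram bins are half-open with detected modes", {
  h <- ks_histogram(rep(0.15, 10))
  expect_equal(which(h$bins$count > 0), 2)
  expect_equal(h$modal_bins, 2)
  empty <- ks_histogram(numeric(0))
  expect_true(all(empty$bins$count == 0))
  expect_length(empty$modal_bins, 0)
  # boundary: 0.2 falls into [0.2, 0.3)
  expect_equal(which(ks_histogram(0.2)$bins$count > 0), 3)
  expect_error(ks_histogram(c(0.5, 1.2)), "max_ks")
})

test_that("family_pair_stats labels, dates and filters within families", {
  sim <- simulate_family_set(tiny_family_config(seed = 12))
  membership <- data.frame(gene_id = sim$truth$genes$gene_id,
                           family_id = sim$truth$genes$family_id)
  stats_df <- family_pair_stats(sim$sequences, membership)
  expect_equal(nrow(stats_df), 2 * choose(4, 2))
  expect_true(all(stats_df$pair_type[stats_df$family_id == "fam01"] == "paralog"))
  expect_true(all(stats_df$ka >= 0 | is.na(stats_df$ka)))
  ok <- !is.na(stats_df$ks)
  expect_equal(stats_df$t_my[ok], date_duplication(stats_df$ks[ok]))
})
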