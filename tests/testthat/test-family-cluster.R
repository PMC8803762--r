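# Pairwise similarity, BLAST table ingestion, threshold clustering.

test_that("pairwise similarity is exact on identical and constructed pairs", {
  set.seed(3)
  s <- nlrevol:::random_cds(100)
  self <- pairwise_similarity(s, s)
  expect_equal(self$identity_pct, 100)
  expect_equal(self$coverage_pct, 100)
  # 30 mismatches scattered over 300 nt, ends intact -> 90 / 100
  v <- strsplit(s, "")[[1]]
  pos <- seq(5, by = 10, length.out = 30)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  other <- paste(v, collapse = "")
  sim <- pairwise_similarity(s, other)
  expect_equal(sim$identity_pct, 90)
  expect_equal(sim$coverage_pct, 100)
  expect_error(pairwise_similarity("", s), "empty")
})

test_that("unrelated sequences fall below every clustering threshold", {
  set.seed(5)
  a <- nlrevol:::random_cds(100)
  b <- nlrevol:::random_cds(100)
  edge <- pairwise_similarity(a, b, "a", "b")
  fams <- build_families(edge, c("a", "b"), 70)
  expect_equal(nrow(fams$families), 2)
})

test_that("BLAST tabular input is deduplicated, merged and validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  row <- function(q, s, pid, len, bits) {
    paste(q, s, pid, len, 0, 0, 1, len, 1, len, "1e-50", bits, sep = "\t")
  }
  writeLines(c(row("a", "a", 100, 300, 500),      # self-hit
               row("a", "b", 85, 300, 400),        # best HSP a->b
               row("a", "b", 99, 50, 100),         # worse HSP, higher identity
               row("b", "a", 83, 290, 380)), path) # reciprocal
  lens <- c(a = 300, b = 310)
  edges <- read_blast_tab(path, lens)
  expect_equal(nrow(edges), 1)
  expect_equal(edges$identity_pct, 85)   # max over merged directions' best HSPs
  expect_equal(edges$coverage_pct, 100)  # 300/300 on the shorter sequence

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(row("a", "b", 85, 300, 400), "a\tb\t85"), bad)
  expect_error(read_blast_tab(bad, lens), "line 2")
  expect_error(read_blast_tab(path, c(a = 300)), "b")
})

test_that("families are strict-threshold connected components", {
  edges <- data.frame(query_id = c("a", "b"), subject_id = c("b", "c"),
                      identity_pct = c(95, 95), coverage_pct = c(95, 95))
  fams <- build_families(edges, c("a", "b", "c"), 90)
  expect_equal(nrow(fams$families), 1)
  expect_equal(sort(fams$membership$gene_id), c("a", "b", "c"))
  # boundary: exactly 70.0 is NOT larger than 70
  bound <- data.frame(query_id = "a", subject_id = "b",
                      identity_pct = 70.0, coverage_pct = 100)
  expect_equal(nrow(build_families(bound, c("a", "b"), 70)$families), 2)
  # no edges -> all singletons
  none <- build_families(bound[0, ], paste0("g", 1:5), 70)
  expect_equal(nrow(none$families), 5)
  expect_true(all(is.na(none$families$avg_identity_pct)))
  expect_error(build_families(bound, c("a"), 70), "outside scope")
})

test_that("clustering equals the brute-force transitive closure on random graphs", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:30, 1)
    genes <- sprintf("g%02d", seq_len(n))
    m <- sample(0:(2 * n), 1)
    edges <- data.frame(query_id = sample(genes, m, replace = TRUE),
                        subject_id = sample(genes, m, replace = TRUE),
                        identity_pct = runif(m, 50, 100),
                        coverage_pct = runif(m, 50, 100))
    edges <- edges[edges$query_id != edges$subject_id, , drop = FALSE]
    level <- sample(c(70, 80, 90), 1)
    fams <- build_families(edges, genes, level)
    got <- unname(lapply(split(fams$membership$gene_id, fams$membership$family_id),
                         sort))
    want <- oracle_components(edges, genes, level)
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(want, paste, "", collapse = ","))
  }
})

test_that("stricter thresholds never increase multi-gene counts", {
  for (s in 1:3) {
    sim <- simulate_family_set(tiny_family_config(seed = 100 + s))
    edges <- similarity_edges(sim$sequences)
    multi <- vapply(c(70, 80, 90), function(lv) {
      fams <- build_families(edges, names(sim$sequences), lv)
      sum(fams$families$n_members[fams$families$n_members >= 2])
    }, numeric(1))
    expect_true(all(diff(multi) <= 0))
    expect_equal(sum(build_families(edges, names(sim$sequences), 70)$families$n_members),
                 length(sim$sequences))
  }
})

test_that("clustering recovers planted families exactly at the loose level", {
  cfg <- sim_config(seed = 77, n_species = 3, n_families = 3,
                    genes_per_family = 3, target_ks = 0.05,
                    event_types = rep("species_specific", 3))
  sim <- simulate_family_set(cfg)
  edges <- similarity_edges(sim$sequences)
  fams <- build_families(edges, names(sim$sequences), 70)
  got <- lapply(split(fams$membership$gene_id, fams$membership$family_id), sort)
  truth <- lapply(split(sim$truth$genes$gene_id, sim$truth$genes$family_id), sort)
  expect_setequal(unname(vapply(got, paste, "", collapse = ",")),
                  unname(vapply(truth, paste, "", collapse = ",")))
})

test_that("family summaries report proportions with two-decimal rounding", {
  edges <- data.frame(query_id = c("spA|g1", "spA|g3"),
                      subject_id = c("spA|g2", "spB|g4"),
                      identity_pct = c(95, 92), coverage_pct = c(95, 95))
  fams <- build_families(edges, c("spA|g1", "spA|g2", "spA|g3", "spB|g4", "spB|g5"),
                        70, "TNL")
  s <- family_summary(list(fams))
  tot <- s[s$species == "Total", ]
  expect_equal(tot$n_multi, 4)
  expect_equal(tot$n_single, 1)
  expect_equal(tot$multi_pct, 80)
  expect_equal(tot$n_families_multi, 2)
  expect_equal(tot$mean_avg_identity, 93.5)
  none <- build_families(edges[0, ], paste0("g", 1:4), 70)
  expect_true(all(family_summary(list(none))$multi_pct == 0))
})
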