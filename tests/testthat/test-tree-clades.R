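# NJ trees, bootstrap supports, Newick I/O and duplicated-clade calls.

test_that("NJ recovers the generating topology from additive distances", {
  # tree ((a,b),(c,d)) with internal branch 2 and tips 1,2,3,4
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["c", "d"] <- d["d", "c"] <- 7
  d["a", "c"] <- d["c", "a"] <- 6
  d["a", "d"] <- d["d", "a"] <- 7
  d["b", "c"] <- d["c", "b"] <- 7
  d["b", "d"] <- d["d", "b"] <- 8
  tr <- nj_tree(d)
  want <- ape::read.tree(text = "((a,b),(c,d));")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(want)), 0,
               ignore_attr = TRUE)
  # larger additive case: distances generated from a random 8-taxon tree
  set.seed(6)
  gen <- ape::rtree(8)
  dm <- ape::cophenetic.phylo(gen)
  expect_equal(ape::dist.topo(ape::unroot(nj_tree(dm)), ape::unroot(gen)), 0,
               ignore_attr = TRUE)
  expect_error(nj_tree(d[1:3, 1:3]), "4")
})

test_that("identical sequences form a zero-length cherry deterministically", {
  set.seed(4)
  base <- nlrevol:::random_cds(80)
  far1 <- nlrevol:::mutate_positions(base, 60)
  far2 <- nlrevol:::mutate_positions(far1, 60)
  aln <- c(t1 = base, t2 = base, t3 = far1, t4 = far2)
  tr1 <- nj_tree(aln)
  tr2 <- nj_tree(aln)
  expect_identical(ape::write.tree(tr1), ape::write.tree(tr2))
  cherry <- ape::getMRCA(tr1, c("t1", "t2"))
  kids <- tr1$edge[tr1$edge[, 1] == cherry, 2]
  expect_setequal(tr1$tip.label[kids], c("t1", "t2"))
  expect_true(all(tr1$edge.length[tr1$edge[, 2] %in% kids] == 0))
  expect_true(all(tr1$edge.length >= 0))
})

test_that("bootstrap supports are deterministic and bounded", {
  sim <- simulate_family_set(tiny_family_config(seed = 31))
  st1 <- bootstrap_support(sim$sequences, n_reps = 50, seed = 9)
  st2 <- bootstrap_support(sim$sequences, n_reps = 50, seed = 9)
  expect_identical(st1$tree$node.label, st2$tree$node.label)
  sup <- suppressWarnings(as.numeric(st1$tree$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  one <- bootstrap_support(sim$sequences, n_reps = 1, seed = 3)
  sup1 <- suppressWarnings(as.numeric(one$tree$node.label))
  expect_true(all(sup1[!is.na(sup1)] %in% c(0, 100)))
})

test_that("well-separated clusters get high between-cluster support", {
  sim <- simulate_family_set(tiny_family_config(seed = 55))
  st <- bootstrap_support(sim$sequences, n_reps = 100, seed = 12)
  tg <- sim$truth$genes
  fam1 <- tg$gene_id[tg$family_id == "fam01"]
  node <- ape::getMRCA(st$tree, fam1)
  sup <- as.numeric(st$tree$node.label[node - length(st$tree$tip.label)])
  expect_gte(sup, 95)
})

test_that("clade calls follow the duplication-evidence definitions", {
  txt <- "(((x1:0.1,x2:0.1,x3:0.1)90:1.0,(x4:0.1,y1:0.1)80:1.0)30:0.5,(y2:0.1,z1:0.1)70:1.5);"
  sp <- c(x1 = "X", x2 = "X", x3 = "X", x4 = "X",
          y1 = "Y", y2 = "Y", z1 = "Z")
  st <- read_newick(txt, species_map = sp)
  calls <- classify_clades(st)
  # {x1,x2,x3}: one species, support 90 -> species-specific with 3 genes
  ss <- calls[calls$call == "species_specific", ]
  expect_equal(nrow(ss), 1)
  expect_equal(ss$n_genes, 3)
  expect_equal(ss$species, "X")
  # {x4,y1}: two species but no within-species pair -> not called
  # {y2,z1}: likewise
  expect_false(any(grepl("y2", calls$genes)))
  expect_equal(nrow(calls), 1)

  # a mixed clade with a duplicated species is lineage-specific
  txt2 <- "((x1:0.1,(x2:0.1,y1:0.1)60:0.2)80:1.0,(z1:0.1,z2:0.1)40:1.0);"
  st2 <- read_newick(txt2, species_map = c(x1 = "X", x2 = "X", y1 = "Y",
                                           z1 = "Z", z2 = "Z"))
  calls2 <- classify_clades(st2)
  expect_equal(calls2$call, "lineage_specific")
  expect_equal(calls2$n_genes, 3)
  # maximality: the nested supported {x2,y1} node is not re-called, and the
  # unsupported {z1,z2} cherry (40) is not called
  expect_equal(nrow(calls2), 1)
})

test_that("calls are maximal, disjoint, and monotone in the support threshold", {
  for (s in 1:5) {
    sim <- simulate_family_set(tiny_family_config(seed = 200 + s))
    st <- bootstrap_support(sim$sequences, n_reps = 50, seed = s)
    genes_called <- character(0)
    n_prev <- Inf
    for (thr in c(0, 30, 50, 70, 90)) {
      calls <- classify_clades(st, min_support = thr)
      n_genes <- sum(calls$n_genes)
      expect_lte(n_genes, length(st$tree$tip.label))
      all_genes <- unlist(strsplit(calls$genes, ";"))
      expect_false(anyDuplicated(all_genes) > 0)
      expect_lte(nrow(calls), n_prev)
      n_prev <- nrow(calls)
    }
  }
})

test_that("newick round-trips supports, lengths and dialects", {
  txt <- "((a:1,b:1)90:1,(c:1,d:1)40:1);"
  st <- read_newick(txt, species_map = c(a = "A", b = "B", c = "C", d = "D"))
  sup <- suppressWarnings(as.numeric(st$tree$node.label))
  expect_setequal(sup[!is.na(sup)], c(90, 40))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(st, path)
  back <- read_newick(path, species_map = c(a = "A", b = "B", c = "C", d = "D"))
  expect_equal(ape::dist.topo(ape::unroot(st$tree), ape::unroot(back$tree)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(suppressWarnings(as.numeric(back$tree$node.label))),
               sort(sup[!is.na(sup)]))
  expect_equal(back$tree$edge.length, st$tree$edge.length, tolerance = 1e-9)

  expect_warning(fr <- read_newick("((a:1,b:1)0.9:1,(c:1,d:1)0.4:1);"),
                 "fraction")
  expect_setequal(suppressWarnings(as.numeric(fr$tree$node.label))[-1],
                  c(90, 40))

  expect_error(read_newick("((a,b),(c,d);"), "position|unclosed")
  expect_error(read_newick("(a,b));"), "position 6")

  # leaf-only tree: nothing to call
  leafy <- read_newick("(a:1,b:1);", species_map = c(a = "A", b = "A"))
  expect_equal(nrow(suppressMessages(classify_clades(leafy))), 0)
})

test_that("duplication proportions use two-decimal half-up percentages", {
  calls <- data.frame(call = c("species_specific", "lineage_specific"),
                      n_genes = c(3, 7))
  p <- duplication_proportions(calls, 20)
  expect_equal(p$percent[p$call == "species_specific"], 15)
  expect_equal(p$percent[p$call == "lineage_specific"], 35)
  p2 <- duplication_proportions(c(species_specific = 0), 50)
  expect_equal(p2$percent, c(0, 0))
})
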