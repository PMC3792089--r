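test_that("simulated trees are ultrametric with mean branch length exactly as set", {
  for (seed in 1:10) {
    set.seed(seed)
    cfg <- sim_config(n_strains = sample(3:20, 1),
                      branching = sample(c("global", "per_lineage"), 1))
    phy <- simulate_tree(cfg)
    expect_equal(mean(phy$edge.length), cfg$avg_branch_length)
    nt <- attr(phy, "node_time")
    expect_lt(diff(range(nt[seq_len(cfg$n_strains)])), 1e-9) # all leaves end together
    # node times are consistent with edge lengths
    idx <- tree_index(phy)
    kids <- setdiff(seq_len(idx$n_node), idx$root)
    expect_equal(nt[kids] - nt[idx$parent[kids]],
                 unname(idx$edge_len[kids]))
  }
})

test_that("a 2-strain tree is a cherry with equal branch lengths", {
  set.seed(3)
  phy <- simulate_tree(sim_config(n_strains = 2))
  expect_equal(length(phy$tip.label), 2L)
  expect_equal(phy$Nnode, 1L)
  expect_equal(phy$edge.length[1], phy$edge.length[2])
})

test_that("zero rates produce no events and identical leaves end-to-end", {
  cfg <- sim_config(n_strains = 6, mutation_rate = 0, hre_rate = 0,
                    error_rate = 0, missing_rate = 0, seed = 11)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$truth), 0L)
  expect_true(all(!is.na(sim$leaf_alleles)))
  expect_equal(max(apply(sim$leaf_alleles, 2, function(x) length(unique(x)))), 1L)
  det <- detect_hre(sim$snp, sim$tree)
  expect_equal(nrow(det$events), 0L)
})

test_that("mutation counts match the Poisson mean of rate x SNPs x length", {
  set.seed(42)
  cfg <- sim_config(n_strains = 5, n_snps = 30, mutation_rate = 0.02,
                    hre_rate = 0)
  tot <- 0; expect_tot <- 0
  for (r in 1:150) {
    tree <- simulate_tree(cfg)
    ev <- simulate_events(tree, cfg)
    tot <- tot + nrow(ev)
    expect_tot <- expect_tot + cfg$mutation_rate * cfg$n_snps * sum(tree$edge.length)
  }
  expect_lt(abs(tot - expect_tot) / sqrt(expect_tot), 4) # ~4 SE
})

test_that("HREs arise only between edges whose time intervals overlap", {
  set.seed(9)
  cfg <- sim_config(n_strains = 8, mutation_rate = 0, hre_rate = 0.05)
  tree <- simulate_tree(cfg)
  ev <- simulate_events(tree, cfg)
  h <- ev[ev$kind == "hre", ]
  expect_gt(nrow(h), 0L)
  nt <- attr(tree, "node_time")
  idx <- tree_index(tree)
  for (r in seq_len(nrow(h))) {
    a <- h$src_node[r]; b <- h$node[r]
    lo <- max(nt[idx$parent[a]], nt[idx$parent[b]])
    hi <- min(nt[a], nt[b])
    expect_true(h$time[r] > lo && h$time[r] < hi)
  }
})

test_that("sequencing error counts match the binomial mean", {
  set.seed(7)
  cfg <- sim_config(n_strains = 10, n_snps = 40, mutation_rate = 0,
                    hre_rate = 0, error_rate = 0.05, missing_rate = 0)
  tot <- 0
  for (r in 1:100) {
    sim <- simulate_dataset(cfg)
    tot <- tot + nrow(sim$error_events)
  }
  expected <- 100 * 10 * 40 * 0.05
  expect_lt(abs(tot - expected) / sqrt(expected * 0.95), 4)
})

test_that("same seed, same data; different seed, different data", {
  cfg <- sim_config(n_strains = 6, seed = 123)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$leaf_alleles, b$leaf_alleles)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
  cfg$seed <- 124
  expect_false(identical(simulate_dataset(cfg)$leaf_alleles, a$leaf_alleles))
})

test_that("nullification rules flag exactly the undetectable events", {
  ev <- data.frame(
    kind = c("mutation", "mutation", "mutation", "hre", "hre", "hre", "hre"),
    time = c(1, 2, 3, 4, 5, 6, 7),
    node = c(9L, 9L, 9L, 9L, 9L, 8L, 8L),
    src_node = c(NA, NA, NA, 7L, 7L, 7L, 7L),
    locus = c(5L, 5L, 9L, NA, NA, NA, NA),
    offset = c(1L, 1L, 1L, NA, NA, NA, NA),
    j1 = c(NA, NA, NA, 10L, 8L, 1L, 2L),
    j2 = c(NA, NA, NA, 15L, 12L, 4L, 3L),
    ndiff = c(NA, NA, NA, 5L, 3L, 1L, 2L),
    loci = NA_character_, stringsAsFactors = FALSE)
  fl <- flag_nullified(ev, hre_overlap = "intersect")
  expect_equal(fl$nullified,
               c(TRUE,   # locus 5 mutated again later on the same branch
                 FALSE,  # the re-mutation survives
                 TRUE,   # locus 9 overwritten by the later HRE [8,12]
                 TRUE,   # [10,15] touched by the later [8,12]
                 FALSE,  # last HRE on branch 9
                 TRUE,   # ndiff = 1: donor ~ recipient, no usable evidence
                 FALSE)) # ndiff = 2 is the detectable boundary
  # containment variant: partial overlap no longer nullifies
  fc <- flag_nullified(ev, hre_overlap = "contain")
  expect_false(fc$nullified[4])
  # union variant: joint coverage by several later HREs counts
  ev2 <- ev[c(4, 5), ]
  ev2$time <- c(1, 2); ev2$j1 <- c(5L, 10L); ev2$j2 <- c(20L, 12L)
  ev2 <- rbind(ev2, transform(ev2[2, ], time = 0.5, j1 = 5L, j2 = 9L))
  rownames(ev2) <- NULL
  fu <- flag_nullified(ev2, hre_overlap = "union")
  expect_true(fu$nullified[3]) # [5,9] covered by [5,20]
  expect_false(fu$nullified[1]) # [5,20] only partially covered later
})

test_that("inversions are off by default, involutive, and origin-symmetric", {
  cfg <- sim_config(n_strains = 5)
  set.seed(2)
  tree <- simulate_tree(cfg)
  expect_equal(nrow(simulate_inversions(tree, cfg)), 0L)

  lay <- 1:10
  inv <- snprecomb:::apply_inversion(lay, center = 0, halfw = 3)
  expect_equal(snprecomb:::apply_inversion(inv, 0, 3), lay)
  # symmetric about the origin: the window wraps the ends equally
  changed <- which(inv != lay)
  expect_setequal(changed, c(1:3, 8:10))

  cfg2 <- sim_config(n_strains = 6, inversions_enabled = TRUE,
                     inversion_rate = 0.05, seed = 5)
  sim <- simulate_dataset(cfg2)
  expect_true(any(sim$truth$kind == "inversion"))
  # the pipeline still runs and every locus still reaches a block
  det <- detect_hre(sim$snp, sim$tree, trace = FALSE)
  expect_true(all(vapply(det$block_set$covered[sim$snp$loci], length, 0L) >= 1L))
})
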