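# node ids under the ape convention for the quartet: tips g1..g4 = 1..4,
# root = 5, anc(g1,g2) = 6, anc(g3,g4) = 7
qidx <- function() tree_index(quartet_tree())

test_that("eligible donors exclude the destination and its descendants", {
  phy <- quartet_tree()
  idx <- qidx()
  anc12 <- idx$parent[1]
  anc34 <- idx$parent[3]
  expect_equal(eligible_sources(phy, anc12), sort(c(idx$root, anc34, 3L, 4L)))
  expect_equal(eligible_sources(phy, 1L), c(2:4, 5:7)[order(c(2:4, 5:7))])
  expect_equal(eligible_sources(phy, idx$root), integer(0))
})

test_that("a block identical along every edge produces no events", {
  A <- allele_matrix("ACGT", "ACGT", "ACGT", "ACGT", "ACGT", "ACGT", "ACGT")
  res <- assign_events(quartet_tree(), A)
  expect_equal(nrow(res$events), 0L)
  expect_equal(res$total_weight, 0)
})

test_that("three leaf mismatches matching a donor become one spanning HRE", {
  # dest g1 carries CCC where its parent (node 6) has AAA; g3 offers CCC
  A <- allele_matrix("CCCA", # g1 (dest)
                     "AAAA", # g2
                     "CCCA", # g3 (donor)
                     "AAAA", # g4
                     "AAAA", # root
                     "AAAA", # anc(g1,g2)
                     "AAAA") # anc(g3,g4)
  res <- assign_events(quartet_tree(), A)
  h <- res$events[res$events$kind == "hre", ]
  g1h <- h[h$dest_node == 1L, ]
  expect_equal(nrow(g1h), 1L)
  expect_equal(c(g1h$j_start, g1h$j_end), c(1L, 3L))
  expect_equal(g1h$source_node, 3L)
  # the donor's own mirror-image HRE is also called: a donor pair
  expect_equal(sort(h$dest_node), c(1L, 3L))
  expect_equal(res$total_weight, 6) # w_x per call, tie against 3 errors each
})

test_that("one isolated internal mismatch is a mutation, never an HRE", {
  # node 7 differs from the root at one SNP; its leaves follow it
  A <- allele_matrix("AAAA", "AAAA", "ACAA", "ACAA",
                     "AAAA", "AAAA", "ACAA")
  res <- assign_events(quartet_tree(), A)
  expect_equal(sort(unique(res$events$kind)), "mutation")
  mu <- res$events
  expect_equal(nrow(mu), 1L)
  expect_equal(mu$dest_node, 7L)
  expect_equal(c(mu$allele_from, mu$allele_to), c("A", "C"))
  expect_equal(res$total_weight, 2)
})

test_that("two adjacent internal mismatches with a donor become one HRE", {
  # node 7 carries CC at SNPs 2-3; leaf g1 offers the same alleles
  A <- allele_matrix("ACCA", "AAAA", "ACCA", "ACCA",
                     "AAAA", "AAAA", "ACCA")
  res <- assign_events(quartet_tree(), A)
  h <- res$events[res$events$kind == "hre" & res$events$dest_node == 7L, ]
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$j_start, h$j_end), c(2L, 3L))
  expect_equal(h$source_node, 1L)
  # g1 itself shows two leaf mismatches: two errors beat one HRE strictly
  e <- res$events[res$events$dest_node == 1L, ]
  expect_equal(e$kind, c("error", "error"))
})

test_that("DP total weight equals exhaustive enumeration on random instances", {
  for (seed in 1:40) {
    set.seed(seed)
    n <- sample(3:4, 1)
    phy <- ape::rtree(n, tip.label = paste0("g", seq_len(n)))
    m <- sample(2:4, 1)
    A <- matrix(sample(c(1:4, NA), (2 * n - 1) * m, replace = TRUE,
                       prob = c(rep(0.225, 4), 0.1)), 2 * n - 1, m)
    A <- fill_internal_na(A, n, 1L)
    for (og in c(TRUE, FALSE)) {
      got <- assign_events(phy, A, outgroup = og)$total_weight
      expect_equal(got, oracle_assign_weight(phy, A, hre_weights(), og),
                   info = paste(seed, og))
    }
  }
})

test_that("the reported weight always equals the sum of emitted event weights", {
  for (seed in 51:70) {
    set.seed(seed)
    n <- sample(3:5, 1)
    phy <- ape::rtree(n, tip.label = paste0("g", seq_len(n)))
    m <- sample(3:6, 1)
    A <- matrix(sample(c(1:4, NA), (2 * n - 1) * m, replace = TRUE,
                       prob = c(rep(0.2, 4), 0.2)), 2 * n - 1, m)
    A <- fill_internal_na(A, n, 2L)
    res <- assign_events(phy, A)
    expect_equal(res$total_weight, sum(res$events$weight), info = seed)
    # one w_x charge per emitted hre event, by construction of the weights
    h <- res$events[res$events$kind == "hre", ]
    expect_equal(sum(h$weight), nrow(h) * hre_weights()$w_x, info = seed)
  }
})

test_that("infinite HRE weights reduce the DP to parsimony-only calls", {
  w_inf <- hre_weights(w_x = Inf)
  for (seed in 81:95) {
    set.seed(seed)
    n <- sample(4:6, 1)
    phy <- ape::rtree(n, tip.label = paste0("g", seq_len(n)))
    m <- 4
    X <- matrix(sample(c(1:4, NA), n * m, replace = TRUE,
                       prob = c(rep(0.22, 4), 0.12)), n, m,
                dimnames = list(phy$tip.label, NULL))
    pars <- infer_internal_alleles(phy, X, w_inf)
    res <- assign_events(phy, pars$alleles, w_inf, outgroup = FALSE)
    expect_equal(res$total_weight, pars$total_weight, info = seed)
    expect_true(all(res$events$kind %in% c("mutation", "error")))
    # and the finite-weight optimum can only be at most as heavy
    res2 <- assign_events(phy, pars$alleles, hre_weights(), outgroup = TRUE)
    expect_lte(res2$total_weight, res$total_weight)
  }
})

test_that("origin tracing is silent without HREs and finds 2- and 3-cycles", {
  idx <- qidx()
  expect_equal(nrow(trace_origins(empty_ev(), idx, 4L)), 0L)

  two <- rbind(hre_ev(6L, 7L, 3L, 5L), hre_ev(7L, 6L, 3L, 5L))
  tr <- trace_origins(two, idx, 6L)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$nodes, "6,7")
  expect_equal(c(tr$j_start, tr$j_end), c(3L, 5L))

  three <- rbind(hre_ev(1L, 3L, 2L, 2L), hre_ev(3L, 7L, 2L, 2L),
                 hre_ev(7L, 1L, 2L, 2L))
  tr3 <- trace_origins(three, idx, 4L)
  expect_equal(nrow(tr3), 1L)
  expect_equal(tr3$nodes, "1,3,7")

  # a non-contiguous SNP range for the same cycle yields two evidence calls
  gap <- rbind(hre_ev(6L, 7L, 1L, 2L), hre_ev(7L, 6L, 1L, 2L),
               hre_ev(6L, 7L, 4L, 5L), hre_ev(7L, 6L, 4L, 5L))
  expect_equal(nrow(trace_origins(gap, idx, 6L)), 2L)
})
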