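test_that("agreement holds for exact substrings and fails on internal rearrangement", {
  snp <- make_snp(list(g1 = 1:3, g2 = c(1L, 3L, 2L)))
  expect_true(agrees(snp, "g1", 1:3))
  expect_false(agrees(snp, "g2", 1:3)) # order differs, no duplications
})

test_that("a locus missing from the genome never breaks agreement", {
  snp <- make_snp(list(g1 = 1:3, g2 = c(1L, 3L)))
  expect_true(agrees(snp, "g2", 1:3))
})

test_that("a match may jump over a contig boundary", {
  snp <- make_snp(list(g1 = 1:4, g2 = list(c(1L, 2L), c(3L, 4L))))
  expect_true(agrees(snp, "g2", 1:4))
  # and across a reversed contig entered from its far end
  snp2 <- make_snp(list(g1 = 1:4, g2 = list(c(1L, 2L), c(-4L, -3L))))
  expect_true(agrees(snp2, "g2", 1:4))
})

test_that("duplicated occurrences may be skipped during matching", {
  # g2 carries an extra copy of locus 2 inside the block span
  snp <- make_snp(list(g1 = 1:3, g2 = c(1L, 2L, 2L, 3L)))
  expect_true(agrees(snp, "g2", 1:3))
  # but a non-duplicated intervening locus is evidence of rearrangement
  snp2 <- make_snp(list(g1 = c(1L, 2L, 3L, 4L), g2 = c(1L, 3L, 2L, 4L)))
  expect_false(agrees(snp2, "g2", c(1L, 2L)))
})

test_that("agreement is invariant under reverse complement of the block", {
  for (seed in 1:25) {
    snp <- random_snp_instance(seed)
    b <- random_block(snp, seed)
    for (g in snp$genomes) {
      expect_equal(agrees(snp, g, b, jump_cap = 10000L),
                   agrees(snp, g, block_revcomp(b), jump_cap = 10000L),
                   info = paste(seed, g))
    }
  }
})

test_that("the matcher agrees with exhaustive concatenation enumeration", {
  for (seed in 1:60) {
    snp <- random_snp_instance(seed)
    b <- random_block(snp, seed)
    for (g in snp$genomes) {
      expect_equal(agrees(snp, g, b, jump_cap = 10000L),
                   oracle_agrees(snp, g, b),
                   info = paste("seed", seed, "genome", g,
                                "block", paste(b, collapse = ",")))
    }
  }
})

test_that("agreement is monotone under contiguous sub-blocks", {
  for (seed in 101:130) {
    snp <- random_snp_instance(seed)
    b <- random_block(snp, seed)
    if (length(b) < 2L) next
    for (g in snp$genomes) {
      if (!agrees(snp, g, b, jump_cap = 10000L)) next
      for (s in seq_len(length(b) - 1L)) {
        expect_true(agrees(snp, g, b[s:(s + 1L)], jump_cap = 10000L),
                    info = paste(seed, g, s))
      }
    }
  }
})

test_that("extension grows a seed to the full block on identical genomes", {
  snp <- make_snp(list(g1 = 1:4, g2 = 1:4))
  b <- extend_block(snp, 2L)
  expect_setequal(abs(b), 1:4)
  expect_true(all(diff(abs(b)) == 1L) || all(diff(abs(b)) == -1L))
})

test_that("extension stops at an inversion breakpoint", {
  snp <- make_snp(list(g1 = c(1L, 2L, 3L, 4L), g2 = c(1L, -3L, -2L, 4L)))
  b <- extend_block(snp, 2L)
  expect_setequal(abs(b), 2:3)
})

test_that("a seed locus present in only one genome can still grow", {
  snp <- make_snp(list(g1 = 1:3, g2 = c(1L, 3L)))
  b <- extend_block(snp, 2L)
  expect_setequal(abs(b), 1:3)
})

test_that("identical genomes yield a single block covering all loci", {
  snp <- make_snp(list(g1 = 1:5, g2 = 1:5, g3 = 1:5))
  bs <- get_blocks(snp)
  expect_equal(length(bs$blocks), 1L)
  expect_equal(bs$increased_snp_count, 5L)
  expect_equal(length(bs$overlap_loci), 0L)
})

test_that("an inversion partitions the genomes into the expected blocks", {
  snp <- make_snp(list(g1 = c(1L, 2L, 3L, 4L), g2 = c(1L, -3L, -2L, 4L)))
  bs <- get_blocks(snp)
  sets <- lapply(bs$blocks, function(b) sort(abs(b)))
  has <- function(x) any(vapply(sets, identical, TRUE, y = x))
  expect_equal(length(sets), 3L)
  expect_true(has(1L))
  expect_true(has(2:3))
  expect_true(has(4L))
  expect_equal(bs$increased_snp_count, 4L)
})

test_that("a locus missing near an inversion endpoint joins two blocks (overlap)", {
  # g1 reads 1 2 3 4 5; g2 inverts (3 4) but locus 3 is absent from g2, so
  # locus 2...: block from the left grows past 2; block from the right pulls
  # the shared neighbour in as well
  snp <- make_snp(list(g1 = c(1L, 2L, 3L, 4L, 5L),
                       g2 = c(1L, 2L, -4L, 5L)))
  bs <- get_blocks(snp)
  expect_gt(length(bs$overlap_loci), 0L)
  expect_equal(bs$increased_snp_count, 5L + length(bs$overlap_loci))
  # every locus is covered by at least one block
  expect_true(all(vapply(bs$covered[snp$loci], length, 0L) >= 1L))
})

test_that("projection keeps block order, complements reverse columns, keeps NA", {
  snp <- make_snp(list(g1 = 1:3, g2 = c(1L, 3L)),
                  alleles = list(g1 = list(c("A", "C", "G")),
                                 g2 = list(c("A", "G"))))
  A <- project_alleles(snp, c(1L, 2L, 3L))
  expect_equal(unname(A["g1", ]), c(1L, 2L, 3L)) # A C G
  expect_true(is.na(A["g2", 2L]))
  # reverse-complemented block: same loci, complemented alleles, reversed order
  Arc <- project_alleles(snp, block_revcomp(c(1L, 2L, 3L)))
  expect_equal(unname(Arc["g1", ]), c(2L, 3L, 4L)) # C G T
  expect_error(project_alleles(snp, c(1L, 9L)), "unknown locus")
})
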