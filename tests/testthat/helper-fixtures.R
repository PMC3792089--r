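# small fixtures shared across tests; everything is built in code

quartet_tree <- function() ape::read.tree(text = "((g1:1,g2:1):1,(g3:1,g4:1):1);")

ladder_tree <- function() ape::read.tree(text = "(g1:1,(g2:1,(g3:1,g4:1):1):1);")

# one-contig genomes given as signed locus vectors; alleles default to 'A'
# (complemented automatically for reverse-strand occurrences on write)
make_snp <- function(layouts, alleles = NULL) {
  rows <- list()
  for (g in names(layouts)) {
    lay <- layouts[[g]]
    if (!is.list(lay)) lay <- list(lay)
    for (ci in seq_along(lay)) {
      v <- lay[[ci]]
      a <- if (is.null(alleles)) rep("A", length(v)) else alleles[[g]][[ci]]
      # `a` is the canonical (forward-strand) base; emit the observed base
      obs <- ifelse(v > 0, a, chartr("ACGT", "TGCA", a))
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = abs(v), genome_id = g, contig_id = paste0("c", ci),
        position = seq_along(v), strand = ifelse(v > 0, "+", "-"),
        allele = obs, stringsAsFactors = FALSE)
    }
  }
  snp_data(do.call(rbind, rows))
}

# full-node allele matrix from base strings ("ACGT", "." = missing),
# rows in node id order (tips first, then root, then internals)
allele_matrix <- function(...) {
  rows <- list(...)
  t(vapply(rows, function(s) {
    x <- strsplit(s, "")[[1]]
    out <- match(x, c("A", "C", "G", "T"))
    out
  }, integer(nchar(rows[[1]]))))
}

# random SNP instance for agreement testing: <=4 genomes, <=8 loci,
# <=2 contigs, <=1 duplicated locus per genome
random_snp_instance <- function(seed) {
  set.seed(seed)
  L <- sample(3:8, 1)
  nG <- sample(2:4, 1)
  layouts <- list()
  for (gi in seq_len(nG)) {
    v <- seq_len(L)
    # random inversion
    if (stats::runif(1) < 0.5) {
      i <- sort(sample.int(L, 2))
      v[i[1]:i[2]] <- -rev(v[i[1]:i[2]])
    }
    # random missing loci
    keep <- stats::runif(L) > 0.2
    if (!any(keep)) keep[1] <- TRUE
    v <- v[keep]
    # at most one duplicated locus, inserted at a random position
    if (length(v) >= 2 && stats::runif(1) < 0.4) {
      d <- sample(v, 1)
      at <- sample.int(length(v) + 1L, 1)
      v <- append(v, d * sample(c(-1, 1), 1), after = at - 1L)
    }
    # split into up to 2 contigs
    if (length(v) >= 2 && stats::runif(1) < 0.5) {
      cut <- sample.int(length(v) - 1L, 1)
      layouts[[paste0("g", gi)]] <- list(v[1:cut], v[(cut + 1):length(v)])
    } else layouts[[paste0("g", gi)]] <- list(v)
  }
  make_snp(layouts)
}

fill_internal_na <- function(A, n, value) {
  rows <- (n + 1L):(2L * n - 1L)
  sub <- A[rows, , drop = FALSE]
  sub[is.na(sub)] <- value
  A[rows, ] <- sub
  A
}

empty_ev <- function() snprecomb:::empty_events()

hre_ev <- function(dest, src, j1, j2) {
  ev <- empty_ev()
  ev[1L, c("kind", "dest_node", "source_node", "j_start", "j_end", "weight")] <-
    list("hre", dest, src, j1, j2, 3)
  ev
}

random_block <- function(snp, seed) {
  set.seed(seed + 7777)
  loci <- snp$loci
  n <- sample.int(min(4L, length(loci)), 1)
  start <- sample.int(length(loci) - n + 1L, 1)
  b <- loci[start:(start + n - 1L)] * sample(c(-1L, 1L), n, replace = TRUE)
  if (stats::runif(1) < 0.5) b <- block_revcomp(b)
  b
}
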