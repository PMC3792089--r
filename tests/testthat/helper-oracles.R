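# independent brute-force oracles; deliberately written with different
# algorithms/data paths than the implementation they check

# --- Definition-style agreement oracle: enumerate every concatenation -------

perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perms(n - 1L)) for (k in seq_len(n))
    out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# can `tgt` be found in the vector cc as a contiguous substring allowing
# insertions of duplicated loci only?
match_with_insertions <- function(cc, tgt, dup) {
  m <- length(tgt)
  walk <- function(pos, ti) {
    # precondition cc[pos] == tgt[ti]
    if (ti == m) return(TRUE)
    q <- pos + 1L
    while (q <= length(cc)) {
      if (cc[q] == tgt[ti + 1L]) {
        if (walk(q, ti + 1L)) return(TRUE)
        if (!(abs(cc[q]) %in% dup)) return(FALSE)
      } else if (!(abs(cc[q]) %in% dup)) return(FALSE)
      q <- q + 1L
    }
    FALSE
  }
  for (s in which(cc == tgt[1L])) if (walk(s, 1L)) return(TRUE)
  FALSE
}

oracle_agrees <- function(snp, genome, block) {
  contigs <- lapply(snp$layouts[[genome]], `[[`, "signed")
  contigs <- contigs[vapply(contigs, length, 0L) > 0L]
  dup <- snp$dup[[genome]]
  pres <- snp$present[genome, ]
  for (tgt0 in list(block, block_revcomp(block))) {
    tgt <- tgt0[pres[abs(tgt0)]]
    if (length(tgt) == 0L) return(TRUE)
    k <- length(contigs)
    for (p in perms(k)) {
      for (mask in 0:(2^k - 1L)) {
        cc <- unlist(lapply(seq_len(k), function(ii) {
          v <- contigs[[p[[ii]]]]
          if (bitwAnd(mask, bitwShiftL(1L, ii - 1L)) > 0L) -rev(v) else v
        }))
        if (match_with_insertions(cc, tgt, dup)) return(TRUE)
      }
    }
  }
  FALSE
}

# --- weighted parsimony oracle: enumerate all internal assignments ----------

oracle_parsimony_weight <- function(phy, leaf_column, weights) {
  n <- length(phy$tip.label)
  parent <- rep(NA_integer_, n + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  internals <- (n + 1L):(n + phy$Nnode)
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    st <- grid[r, ]
    cost <- 0
    for (v in internals) {
      p <- parent[v]
      if (!is.na(p) && st[match(v, internals)] != st[match(p, internals)])
        cost <- cost + weights$w_m
    }
    for (tip in seq_len(n)) {
      obs <- leaf_column[tip]
      if (!is.na(obs) && obs != st[match(parent[tip], internals)])
        cost <- cost + weights$w_e
    }
    best <- min(best, cost)
  }
  best
}

# --- HRE DP oracle: enumerate all per-node donor-state sequences ------------

oracle_assign_weight <- function(phy, alleles, weights, outgroup = TRUE) {
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  parent <- rep(NA_integer_, N)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- which(is.na(parent))
  desc_of <- function(v) {
    out <- integer(0); queue <- v
    while (length(queue)) {
      kids <- phy$edge[phy$edge[, 1] %in% queue, 2]
      out <- c(out, kids); queue <- kids
    }
    out
  }
  m <- ncol(alleles)
  total <- 0
  for (i in setdiff(seq_len(N), root)) {
    srcs <- sort(setdiff(seq_len(N), c(i, desc_of(i))))
    states <- c(0L, srcs, if (outgroup) -1L) # 0 = parent, -1 = out-group
    wsub <- if (i <= n) weights$w_e else weights$w_m
    base <- matrix(0, length(states), m)
    openv <- numeric(length(states))
    for (si in seq_along(states)) {
      s <- states[si]
      if (s == -1L) { base[si, ] <- weights$w_t; openv[si] <- weights$w_o - weights$w_t }
      else {
        ref <- if (s == 0L) alleles[parent[i], ] else alleles[s, ]
        mm <- ref != alleles[i, ]
        mm[is.na(mm)] <- FALSE
        base[si, ] <- mm * wsub
        openv[si] <- if (s == 0L) 0 else weights$w_x
      }
    }
    grid <- as.matrix(expand.grid(rep(list(seq_along(states)), m)))
    cost <- numeric(nrow(grid))
    for (j in seq_len(m)) cost <- cost + base[cbind(grid[, j], j)]
    entered <- cbind(TRUE, grid[, -1, drop = FALSE] != grid[, -m, drop = FALSE])
    for (j in seq_len(m)) {
      e <- entered[, j]
      cost[e] <- cost[e] + openv[grid[e, j]]
    }
    total <- total + min(cost)
  }
  total
}

# descendant tip labels of every node of a rooted phylo, by explicit
# edge-matrix recursion (independent of tree_index)
oracle_clade_sets <- function(phy) {
  n <- length(phy$tip.label)
  N <- n + phy$Nnode
  sets <- vector("list", N)
  for (tip in seq_len(n)) sets[[tip]] <- phy$tip.label[tip]
  repeat {
    done <- TRUE
    for (v in (n + 1L):N) {
      if (!is.null(sets[[v]])) next
      kids <- phy$edge[phy$edge[, 1] == v, 2]
      if (all(!vapply(sets[kids], is.null, TRUE))) {
        sets[[v]] <- sort(unlist(sets[kids]))
      } else done <- FALSE
    }
    if (done) break
  }
  sets
}

as_allele_matrix_chr <- function(x) {
  m <- matrix(match(x, c("A", "C", "G", "T")), nrow = nrow(x),
              dimnames = dimnames(x))
  storage.mode(m) <- "integer"
  m
}

# rooting-by-homoplasy oracle: reroot with phytools on each edge, count loci
# whose allele classes are not all clades
oracle_rooting_counts <- function(un, alleles) {
  vapply(seq_len(nrow(un$edge)), function(e) {
    child <- un$edge[e, 2]
    len <- if (is.null(un$edge.length)) 0 else un$edge.length[e] / 2
    rt <- phytools::reroot(un, child, position = len)
    clades <- oracle_clade_sets(rt)
    bad <- 0L
    for (j in seq_len(ncol(alleles))) {
      col <- alleles[, j]
      obs <- !is.na(col)
      labs <- rownames(alleles)
      ok <- TRUE
      for (a in unique(col[obs])) {
        cls <- sort(labs[obs & col == a])
        # compare against each clade restricted to observed tips
        hit <- any(vapply(clades, function(cl)
          identical(sort(intersect(cl, labs[obs])), cls), TRUE))
        if (!hit) { ok <- FALSE; break }
      }
      if (!ok) bad <- bad + 1L
    }
    bad
  }, 0L)
}
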