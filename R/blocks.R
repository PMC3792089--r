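#' Does a genome agree with a block?
#'
#' A block is an ordered string of signed SNPs; a genome agrees with it when
#' the genome's SNP layout shows no evidence of an inversion inside the block.
#' Formally, after deleting block loci absent from the genome, the remaining
#' signed string (or its full reverse complement) must occur in some
#' concatenation of the genome's contigs -- each contig independently
#' re-orientable, consulted only where the match crosses a contig end (the
#' jump-over-contig step) -- as a contiguous substring into which only
#' duplicated SNPs of the genome may be inserted.
#'
#' The matcher takes a fast path for single-contig genomes without duplicated
#' loci and otherwise runs a depth-first search over duplicate-skip choices
#' and contig-end jumps. Jump enumeration is capped; hitting the cap raises a
#' warning and the test conservatively fails.
#'
#' @param snp a [snp_data] object.
#' @param genome genome id.
#' @param block signed integer vector of locus ids (sign = orientation).
#' @param jump_cap maximum number of jump-over-contig alternatives to try.
#' @param want_witness also return, for each block locus present in the
#'   genome, the matched occurrence (contig index, position, reading
#'   direction).
#' @return logical, or (with `want_witness`) a list with `ok`, `witness`
#'   (m x 3 matrix) and `block_pos` (which block positions the witness rows
#'   correspond to).
#' @export
agrees <- function(snp, genome, block, jump_cap = 64L, want_witness = FALSE) {
  if (length(block) == 0L) stop("empty block")
  ab <- abs(block)
  if (any(ab > snp$max_locus) || !all(snp$is_locus[ab]))
    stop("block references unknown locus")
  if (is.null(snp$layouts[[genome]]) && !genome %in% snp$genomes)
    stop("unknown genome: ", genome)
  pres <- snp$present[genome, ]
  keep <- pres[abs(block)]
  tgt <- block[keep]
  ret <- function(ok, wit = NULL) {
    if (want_witness) list(ok = ok, witness = wit, block_pos = which(keep)) else ok
  }
  if (length(tgt) == 0L)
    return(ret(TRUE, matrix(integer(0), 0, 3)))

  fast <- snp$fast[[genome]]
  if (!is.null(fast)) {
    p <- fast$idx[abs(tgt)]
    v <- fast$val[p]
    if (length(tgt) == 1L) {
      d <- if (v == tgt) 1L else -1L
      return(ret(TRUE, cbind(1L, p, d)))
    }
    if (all(diff(p) == 1L) && all(v == tgt))
      return(ret(TRUE, cbind(1L, p, 1L)))
    if (all(diff(p) == -1L) && all(v == -tgt))
      return(ret(TRUE, cbind(1L, p, -1L)))
    return(ret(FALSE))
  }
  match_block_dfs(snp, genome, tgt, keep, jump_cap, ret)
}

# general matcher: DFS over duplicate skips and contig-end jumps
match_block_dfs <- function(snp, genome, tgt, keep, jump_cap, ret) {
  contigs <- lapply(snp$layouts[[genome]], `[[`, "signed")
  nct <- length(contigs)
  dupv <- rep(FALSE, snp$max_locus)
  dupv[snp$dup[[genome]]] <- TRUE
  m <- length(tgt)
  env <- new.env(parent = emptyenv())
  env$jumps <- 0L
  env$capped <- FALSE

  jump <- function(ti, used, wit) {
    for (c2 in setdiff(seq_len(nct), used)) {
      v2 <- contigs[[c2]]
      for (ent in list(c(1L, 1L), c(length(v2), -1L))) {
        q <- ent[1L]; d <- ent[2L]
        while (q >= 1L && q <= length(v2)) {
          e <- if (d > 0L) v2[q] else -v2[q]
          isdup <- dupv[abs(v2[q])]
          if (e == tgt[ti]) {
            env$jumps <- env$jumps + 1L
            if (env$jumps > jump_cap) { env$capped <- TRUE; return(NULL) }
            res <- dfs(c2, q, d, ti, used, wit)
            if (!is.null(res)) return(res)
            if (!isdup) break
          } else if (!isdup) break
          q <- q + d
        }
        if (env$capped) return(NULL)
      }
    }
    NULL
  }

  dfs <- function(ci, p, d, ti, used, wit) {
    # precondition: contigs[[ci]][p], read with direction d, equals tgt[ti]
    v <- contigs[[ci]]
    repeat {
      wit[ti, ] <- c(ci, p, d)
      if (ti == m) return(wit)
      ti <- ti + 1L
      q <- p + d
      matched <- FALSE
      while (q >= 1L && q <= length(v)) {
        e <- if (d > 0L) v[q] else -v[q]
        isdup <- dupv[abs(v[q])]
        if (e == tgt[ti]) {
          if (isdup) {
            res <- dfs(ci, q, d, ti, used, wit)
            if (!is.null(res) || env$capped) return(res)
            q <- q + d # or treat this duplicated occurrence as an insertion
          } else { matched <- TRUE; p <- q; break }
        } else if (isdup) {
          q <- q + d
        } else return(NULL)
      }
      if (!matched) {
        # walked off the contig end with only duplicated SNPs in between
        return(jump(ti, c(used, ci), wit))
      }
    }
  }

  wit0 <- matrix(NA_integer_, m, 3)
  for (ci in seq_len(nct)) {
    v <- contigs[[ci]]
    hits <- which(abs(v) == abs(tgt[1L]))
    for (p in hits) {
      for (d in c(1L, -1L)) {
        e <- if (d > 0L) v[p] else -v[p]
        if (e == tgt[1L]) {
          res <- dfs(ci, p, d, 1L, integer(0), wit0)
          if (!is.null(res)) return(ret(TRUE, res))
          if (env$capped) {
            warning("jump-over-contig enumeration cap (", jump_cap,
                    ") hit for genome ", genome, "; treating as disagreement")
            return(ret(FALSE))
          }
        }
      }
    }
  }
  ret(FALSE)
}

#' Reverse complement of a block
#' @param block signed integer vector.
#' @export
block_revcomp <- function(block) -rev(block)

# canonical orientation: lexicographically smaller of the two readings,
# ordering signed SNPs by (locus id, then forward < reverse)
canonical_block <- function(block) {
  rc <- block_revcomp(block)
  key <- function(b) 2 * abs(b) + (b < 0)
  a <- key(block); b <- key(rc)
  cmp <- which(a != b)
  if (length(cmp) == 0L || a[cmp[1L]] < b[cmp[1L]]) block else rc
}

#' Grow a maximal block from a seed SNP
#'
#' Greedy extension: starting from a single-SNP block, repeatedly pick a SNP
#' adjacent to the current block end in some genome and append it if every
#' genome still agrees with the extended candidate; when the forward end is
#' exhausted the block is reversed and the other end extended. A candidate
#' that fails stays failed (agreement is monotone under taking contiguous
#' sub-blocks), so each is tested at most once per end.
#'
#' @param snp a [snp_data] object.
#' @param seed locus id present in at least one genome.
#' @param jump_cap passed to [agrees()].
#' @return signed integer vector (canonical orientation).
#' @export
extend_block <- function(snp, seed, jump_cap = 64L) {
  seed <- as.integer(seed)
  if (!seed %in% snp$loci || !any(snp$present[, seed]))
    stop("seed locus absent from all genomes: ", seed)
  B <- seed

  next_candidates <- function(B) {
    out <- integer(0)
    inblock <- abs(B)
    for (g in snp$genomes) {
      w <- agrees(snp, g, B, jump_cap, want_witness = TRUE)
      if (!w$ok || nrow(w$witness) == 0L) next
      last <- w$witness[nrow(w$witness), ]
      v <- snp$layouts[[g]][[last[1L]]]$signed
      q <- last[2L] + last[3L]
      if (q >= 1L && q <= length(v)) {
        cand <- if (last[3L] > 0L) v[q] else -v[q]
        if (!abs(cand) %in% inblock) out <- c(out, cand)
      }
    }
    out[!duplicated(out)]
  }

  for (phase in 1:2) {
    repeat {
      # each round re-proposes candidates adjacent to the current end; every
      # candidate is tested at most once per round, and a round with no
      # successful extension ends the phase
      cands <- next_candidates(B)
      extended <- FALSE
      for (cand in cands) {
        B2 <- c(B, cand)
        ok <- TRUE
        for (g in snp$genomes)
          if (!agrees(snp, g, B2, jump_cap)) { ok <- FALSE; break }
        if (ok) { B <- B2; extended <- TRUE; break }
      }
      if (!extended) break
    }
    B <- block_revcomp(B)
  }
  canonical_block(B)
}

#' Partition all SNPs into locally collinear blocks
#'
#' Iterates genomes in input order and SNP occurrences in layout order; every
#' locus not yet included in a block seeds [extend_block()]. Blocks may
#' overlap (a locus adjacent to an inversion endpoint but missing in some
#' genome, or a duplicated locus, can be pulled into two blocks); the sum of
#' block lengths is the *increased* SNP count.
#'
#' @param snp a [snp_data] object.
#' @param jump_cap passed to [agrees()].
#' @return An object of class `block_set`: list with `blocks` (list of signed
#'   vectors), `covered` (per-locus block ids), `increased_snp_count`, and
#'   `overlap_loci` (loci in more than one block).
#' @export
get_blocks <- function(snp, jump_cap = 64L) {
  if (length(snp$genomes) < 2L) stop("need at least 2 genomes")
  included <- rep(FALSE, snp$max_locus)
  blocks <- list()
  covered <- vector("list", snp$max_locus)
  for (g in snp$genomes) {
    for (ct in snp$layouts[[g]]) {
      for (locus in abs(ct$signed)) {
        if (included[locus]) next
        B <- extend_block(snp, locus, jump_cap)
        blocks[[length(blocks) + 1L]] <- B
        for (l in abs(B)) {
          included[l] <- TRUE
          covered[[l]] <- c(covered[[l]], length(blocks))
        }
      }
    }
  }
  lens <- vapply(blocks, length, 0L)
  structure(list(blocks = blocks,
                 covered = covered,
                 increased_snp_count = sum(lens),
                 overlap_loci = which(vapply(covered, length, 0L) > 1L)),
            class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("block_set: %d blocks, %d SNPs (increased), %d overlapping loci\n",
              length(x$blocks), x$increased_snp_count, length(x$overlap_loci)))
  invisible(x)
}

#' Project leaf alleles onto a block
#'
#' Builds the genomes x m allele matrix of a block in block SNP order:
#' reverse-oriented columns are complemented to the block's reading direction,
#' missing loci stay NA, and for duplicated loci the occurrence selected by
#' the agreement witness supplies the allele.
#'
#' @param snp a [snp_data] object.
#' @param block signed integer vector from [get_blocks()].
#' @param jump_cap passed to [agrees()].
#' @return integer allele matrix (A=1..T=4), rows named by genome.
#' @export
project_alleles <- function(snp, block, jump_cap = 64L) {
  if (any(!abs(block) %in% snp$loci)) stop("block references unknown locus")
  m <- length(block)
  out <- matrix(NA_integer_, length(snp$genomes), m,
                dimnames = list(snp$genomes, NULL))
  for (gi in seq_along(snp$genomes)) {
    g <- snp$genomes[gi]
    row <- snp$allele1[g, abs(block)]
    if (length(intersect(abs(block), snp$dup[[g]])) > 0L) {
      w <- agrees(snp, g, block, jump_cap, want_witness = TRUE)
      if (isTRUE(w$ok) && nrow(w$witness) > 0L) {
        for (k in seq_len(nrow(w$witness))) {
          ct <- snp$layouts[[g]][[w$witness[k, 1L]]]
          row[w$block_pos[k]] <- ct$allele[w$witness[k, 2L]]
        }
      }
    }
    out[gi, ] <- row
  }
  neg <- which(block < 0)
  if (length(neg)) out[, neg] <- complement_allele(out[, neg])
  out
}
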