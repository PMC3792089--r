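#' Infer internal-node alleles by weighted small parsimony
#'
#' Per-locus Sankoff dynamic program over the four nucleotide states: an
#' allele change on the edge into an internal node costs `w_m` (a mutation),
#' while a leaf that disagrees with its parent costs `w_e` (an error; leaves
#' inherit their true state from the parent and pay the error cost locally).
#' Missing leaf alleles contribute zero cost in every state. All columns of a
#' block are solved simultaneously (the columns are independent here; only
#' the HRE dynamic program couples adjacent loci).
#'
#' Backtracking ties are broken by the `tie` policy, then alphabetically.
#' `"subtree"` (default) keeps the state that is optimal for the node's own
#' subtree -- the allele shared by its descendant leaves wins even when
#' changing on the edge above costs the same as paying errors below, which
#' concentrates changes on internal edges the way the detector expects;
#' `"parent"` keeps the parent's state at ties, which minimizes the number
#' of reported internal events by pushing changes down to the leaves. An
#' all-missing column is assigned 'A' everywhere and generates no events.
#'
#' @param phy rooted binary `phylo`, or a prebuilt tree index.
#' @param leaf_alleles integer (A=1..T=4, NA missing) or character matrix,
#'   rows = leaves in tip order (or rownames = tip labels), columns = loci.
#' @param weights an [hre_weights] object.
#' @param tie backtracking tie policy, `"subtree"` or `"parent"` (see above).
#' @return list with `alleles` (full 2n-1 x m integer matrix; leaf rows are
#'   the observations, internal rows the inferred states), `col_weight`
#'   (minimal weight per column) and `total_weight`.
#' @export
infer_internal_alleles <- function(phy, leaf_alleles, weights = hre_weights(),
                                   tie = c("subtree", "parent")) {
  tie <- match.arg(tie)
  idx <- if (inherits(phy, "phylo")) tree_index(phy) else phy
  leaf <- as_allele_matrix(leaf_alleles, idx$labels)
  m <- ncol(leaf)
  if (nrow(leaf) != idx$n_tip) stop("one allele row per leaf required")
  w_m <- weights$w_m; w_e <- weights$w_e

  cost <- vector("list", idx$n_node)
  for (v in idx$postorder) {
    if (idx$is_leaf[v]) {
      C <- matrix(w_e, 4L, m)
      obs <- leaf[v, ]
      j <- which(!is.na(obs))
      if (length(j) < m) C[, setdiff(seq_len(m), j)] <- 0
      C[cbind(obs[j], j)] <- 0
      cost[[v]] <- C
    } else {
      C <- matrix(0, 4L, m)
      for (ch in idx$children[[v]]) {
        Cc <- cost[[ch]]
        if (idx$is_leaf[ch]) {
          C <- C + Cc # leaf state equals the parent's; error cost is local
        } else {
          cm <- pmin(Cc[1L, ], Cc[2L, ], Cc[3L, ], Cc[4L, ]) + w_m
          C <- C + rbind(pmin(Cc[1L, ], cm), pmin(Cc[2L, ], cm),
                         pmin(Cc[3L, ], cm), pmin(Cc[4L, ], cm))
        }
      }
      cost[[v]] <- C
    }
  }
  Croot <- cost[[idx$root]]
  col_weight <- pmin(Croot[1L, ], Croot[2L, ], Croot[3L, ], Croot[4L, ])

  # pre-order backtrack, vectorized across columns
  assign_state <- function(C, prefer) {
    # column-wise argmin with ties to `prefer` (int vector or NULL), then 'A'<..<'T'
    best <- pmin(C[1L, ], C[2L, ], C[3L, ], C[4L, ])
    pick <- max.col(t(-C), ties.method = "first")
    if (!is.null(prefer)) {
      at <- C[cbind(prefer, seq_along(prefer))] <= best
      pick[at] <- prefer[at]
    }
    pick
  }
  alleles <- matrix(NA_integer_, idx$n_node, m)
  alleles[seq_len(idx$n_tip), ] <- leaf
  order_pre <- rev(idx$postorder)
  for (v in order_pre) {
    if (idx$is_leaf[v]) next
    if (v == idx$root) {
      alleles[v, ] <- assign_state(Croot, NULL)
    } else {
      pa <- alleles[idx$parent[v], ]
      C <- cost[[v]] + w_m
      C[cbind(pa, seq_len(m))] <- C[cbind(pa, seq_len(m))] - w_m
      prefer <- if (tie == "parent") pa
        else max.col(t(-cost[[v]]), ties.method = "first")
      alleles[v, ] <- assign_state(C, prefer)
    }
  }
  list(alleles = alleles, col_weight = col_weight,
       total_weight = sum(col_weight))
}

# unit-cost parsimony change count per column (leaves fixed to observations,
# missing leaves unconstrained); used for homoplasy counting
parsimony_changes <- function(idx, leaf) {
  m <- ncol(leaf)
  BIG <- 1e9
  cost <- vector("list", idx$n_node)
  for (v in idx$postorder) {
    if (idx$is_leaf[v]) {
      C <- matrix(BIG, 4L, m)
      obs <- leaf[v, ]
      j <- which(!is.na(obs))
      if (length(j) < m) C[, setdiff(seq_len(m), j)] <- 0
      C[cbind(obs[j], j)] <- 0
      cost[[v]] <- C
    } else {
      C <- matrix(0, 4L, m)
      for (ch in idx$children[[v]]) {
        Cc <- cost[[ch]]
        cm <- pmin(Cc[1L, ], Cc[2L, ], Cc[3L, ], Cc[4L, ]) + 1
        C <- C + rbind(pmin(Cc[1L, ], cm), pmin(Cc[2L, ], cm),
                       pmin(Cc[3L, ], cm), pmin(Cc[4L, ], cm))
      }
      cost[[v]] <- C
    }
  }
  Cr <- cost[[idx$root]]
  ch <- pmin(Cr[1L, ], Cr[2L, ], Cr[3L, ], Cr[4L, ])
  ch[ch >= BIG] <- 0 # columns with no observed allele
  as.integer(round(ch %% BIG))
}
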