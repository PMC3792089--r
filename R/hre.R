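#' Assign mutations, errors and HREs within a block
#'
#' For every non-root node, a dynamic program over the block's SNPs decides,
#' position by position, whether the node's alleles are inherited from its
#' parent (mismatches cost `w_m` on internal nodes, `w_e` on leaves) or from
#' a horizontal donor: any non-descendant node of the tree (one `w_x` charged
#' where the transferred run opens, mismatches against the donor again
#' allowed at mutation/error cost), or an out-group donor outside the tree
#' (affine cost: `w_o` to open, `w_t` per extended SNP, matching any allele).
#' Missing alleles never cost anything on either side. Leaving a run is free:
#' the HRE weight is charged only at its start.
#'
#' Backtracking turns maximal constant-donor runs into `hre` /
#' `outgroup_hre` events and parent-state mismatches into `mutation` (internal
#' node) or `error` (leaf) point events; mismatches against an in-tree donor
#' inside a run are likewise emitted as point events. Cost ties are resolved
#' in favour of the horizontal explanation (out-group first, then in-tree
#' donors by ascending node id, then the parent), so e.g. three adjacent leaf
#' errors tie with one HRE (`w_x = 3 w_e` at default weights) and the HRE is
#' reported.
#'
#' @param phy rooted binary `phylo` or a tree index.
#' @param alleles (2n-1) x m integer allele matrix (leaf rows may contain NA),
#'   e.g. from [infer_internal_alleles()].
#' @param weights an [hre_weights] object. Setting `w_x = Inf` (and
#'   `outgroup = FALSE`) reduces the output to the parsimony-only calls.
#' @param outgroup enable the out-group donor state.
#' @param block optional signed locus vector, used to annotate events with
#'   locus ids.
#' @param block_id block identifier stored in the event table.
#' @return list with `events` (data frame; zero rows if nothing happened) and
#'   `total_weight` (sum of DP optima over nodes; equals the sum of event
#'   weights).
#' @export
assign_events <- function(phy, alleles, weights = hre_weights(),
                          outgroup = TRUE, block = NULL, block_id = 1L) {
  idx <- if (inherits(phy, "phylo")) tree_index(phy) else phy
  m <- ncol(alleles)
  if (nrow(alleles) != idx$n_node)
    stop("allele matrix must have one row per tree node (", idx$n_node, ")")
  if (m < 1L) stop("empty block matrix")
  ev <- vector("list", idx$n_node)
  total <- 0
  for (i in seq_len(idx$n_node)) {
    if (i == idx$root) next
    res <- hre_dp_node(idx, alleles, i, weights, outgroup)
    total <- total + res$weight
    ev[[i]] <- res$events
  }
  events <- do.call(rbind, ev[!vapply(ev, is.null, TRUE)])
  if (is.null(events)) events <- empty_events()
  if (nrow(events) && !is.null(block)) {
    events$locus_start <- abs(block)[events$j_start]
    events$locus_end <- abs(block)[events$j_end]
  }
  if (nrow(events)) events$block_id <- block_id
  rownames(events) <- NULL
  list(events = events, total_weight = total)
}

empty_events <- function() {
  data.frame(kind = character(0), block_id = integer(0),
             dest_node = integer(0), source_node = integer(0),
             j_start = integer(0), j_end = integer(0),
             locus_start = integer(0), locus_end = integer(0),
             allele_from = character(0), allele_to = character(0),
             weight = numeric(0), nodes = character(0),
             stringsAsFactors = FALSE)
}

event_row <- function(kind, dest, src, j1, j2, from, to, weight, nodes = NA) {
  data.frame(kind = kind, block_id = NA_integer_, dest_node = dest,
             source_node = src, j_start = j1, j_end = j2,
             locus_start = NA_integer_, locus_end = NA_integer_,
             allele_from = from, allele_to = to, weight = weight,
             nodes = nodes, stringsAsFactors = FALSE)
}

# the per-destination-node segment DP
hre_dp_node <- function(idx, alleles, i, weights, outgroup) {
  m <- ncol(alleles)
  leafq <- idx$is_leaf[i]
  wsub <- if (leafq) weights$w_e else weights$w_m
  srcs <- sort(setdiff(seq_len(idx$n_node), c(i, idx$desc[[i]])))
  K <- length(srcs)
  og <- isTRUE(outgroup)
  S <- 1L + K + og

  di <- alleles[i, ]
  pa <- alleles[idx$parent[i], ]
  E <- matrix(0, S, m)
  mm <- di != pa
  mm[is.na(mm)] <- FALSE
  E[1L, ] <- mm * wsub
  SA <- alleles[srcs, , drop = FALSE]
  M <- SA != matrix(di, K, m, byrow = TRUE)
  M[is.na(M)] <- FALSE
  E[1L + seq_len(K), ] <- M * wsub

  open <- c(0, rep(weights$w_x, K), if (og) weights$w_o)
  stay_extra <- c(rep(0, 1L + K), if (og) weights$w_t)
  pref <- c(if (og) S, 1L + seq_len(K), 1L) # tie order: out-group, donors, parent

  V <- open + E[, 1L]
  back <- matrix(0L, S, m)
  if (m > 1L) for (j in 2:m) {
    o <- V
    op <- o[pref]
    i1 <- which.min(op); k1 <- pref[i1]; m1 <- op[i1]
    op[i1] <- Inf
    i2 <- which.min(op); k2 <- pref[i2]; m2 <- op[i2]
    ent_base <- rep(m1, S); ent_from <- rep(k1, S)
    ent_base[k1] <- m2; ent_from[k1] <- k2
    stayv <- o + stay_extra + E[, j]
    entv <- ent_base + open + E[, j]
    swap <- entv < stayv # ties prefer staying in the current state
    V <- stayv
    V[swap] <- entv[swap]
    back[swap, j] <- ent_from[swap]
  }
  st <- pref[which.min(V[pref])]
  weight <- V[st]

  states <- integer(m)
  for (j in m:1) {
    states[j] <- st
    if (j > 1L) { b <- back[st, j]; if (b != 0L) st <- b }
  }

  runs <- rle(states)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  point_events <- function(ref, jset, kind) {
    jj <- jset[!is.na(di[jset]) & !is.na(ref[jset]) & di[jset] != ref[jset]]
    if (!length(jj)) return(NULL)
    event_row(kind, i, NA_integer_, jj, jj,
              decode_allele(ref[jj]), decode_allele(di[jj]), wsub)
  }
  kind_pt <- if (leafq) "error" else "mutation"
  pmm <- di != pa
  pmm[is.na(pmm)] <- FALSE
  for (r in seq_along(runs$values)) {
    stv <- runs$values[r]; j1 <- starts[r]; j2 <- ends[r]
    if (stv == 1L) {
      out[[length(out) + 1L]] <- point_events(pa, j1:j2, kind_pt)
    } else if (og && stv == S) {
      out[[length(out) + 1L]] <- event_row(
        "outgroup_hre", i, NA_integer_, j1, j2, NA, NA,
        weights$w_o + (j2 - j1) * weights$w_t)
    } else {
      # report the evidenced extent: the DP may carry a donor state through
      # trailing positions that also match the parent at no cost, but the
      # transferred segment is only supported where the parent disagrees
      core <- which(pmm[j1:j2]) + j1 - 1L
      c1 <- if (length(core)) core[1L] else j1
      c2 <- if (length(core)) core[length(core)] else j2
      k <- srcs[stv - 1L]
      out[[length(out) + 1L]] <- event_row("hre", i, k, c1, c2, NA, NA,
                                           weights$w_x)
      out[[length(out) + 1L]] <- point_events(alleles[k, ], j1:j2, kind_pt)
    }
  }
  out <- out[!vapply(out, is.null, TRUE)]
  list(weight = weight,
       events = if (length(out)) do.call(rbind, out) else NULL)
}

#' Trace allele origins and report inheritance cycles
#'
#' For each node and SNP, the origin of the allele is the HRE donor at the
#' same SNP when the position lies inside a predicted in-tree HRE, and the
#' parent node otherwise. Following origins upward must end at the root (or
#' at a predicted out-group event); a trace that enters a cycle -- two nodes
#' predicted to inherit the same segment from each other, or a longer loop --
#' is itself evidence of an out-group HRE and is reported as one
#' `outgroup_evidence` call per cycle and maximal SNP range.
#'
#' @param events event data frame from [assign_events()].
#' @param phy rooted `phylo` or tree index.
#' @param m number of SNPs in the block.
#' @return data frame of `outgroup_evidence` events (possibly empty), with
#'   the involved nodes in the `nodes` column.
#' @export
trace_origins <- function(events, phy, m) {
  idx <- if (inherits(phy, "phylo")) tree_index(phy) else phy
  base <- idx$parent
  base[idx$root] <- 0L
  hre <- events[events$kind == "hre", , drop = FALSE]
  ogh <- events[events$kind == "outgroup_hre", , drop = FALSE]
  cyc <- list() # key -> list(nodes, js)
  for (j in seq_len(m)) {
    succ <- base
    if (nrow(hre)) {
      inr <- hre$j_start <= j & hre$j_end >= j
      succ[hre$dest_node[inr]] <- hre$source_node[inr]
    }
    if (nrow(ogh)) {
      inr <- ogh$j_start <= j & ogh$j_end >= j
      succ[ogh$dest_node[inr]] <- 0L # out-group: trace terminates
    }
    color <- integer(idx$n_node) # 0 new, 1 on path, 2 done
    for (s in seq_len(idx$n_node)) {
      if (color[s] != 0L) next
      path <- integer(0)
      v <- s
      while (v != 0L && color[v] == 0L) {
        color[v] <- 1L
        path <- c(path, v)
        v <- succ[v]
      }
      if (v != 0L && color[v] == 1L) { # found a new cycle
        cycle <- path[seq(match(v, path), length(path))]
        key <- paste(sort(cycle), collapse = ",")
        if (is.null(cyc[[key]])) cyc[[key]] <- list(nodes = sort(cycle), js = j)
        else cyc[[key]]$js <- c(cyc[[key]]$js, j)
      }
      color[path] <- 2L
    }
  }
  out <- list()
  for (key in names(cyc)) {
    js <- cyc[[key]]$js
    breaks <- c(0L, which(diff(js) > 1L), length(js))
    for (b in seq_len(length(breaks) - 1L)) {
      seg <- js[(breaks[b] + 1L):breaks[b + 1L]]
      out[[length(out) + 1L]] <- event_row(
        "outgroup_evidence", NA_integer_, NA_integer_,
        seg[1L], seg[length(seg)], NA, NA, 0, nodes = key)
    }
  }
  if (length(out)) do.call(rbind, out) else empty_events()
}
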