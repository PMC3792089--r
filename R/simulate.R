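#' Simulation configuration
#'
#' Parameters of the evolutionary simulator. The defaults are the benchmark
#' conditions used throughout the package's evaluation: 40 strains, 50 SNP
#' loci, average branch length 20 time units, mutation rate 1% per SNP per
#' unit branch length, HRE rate 3% per unit branch length per (ordered) pair
#' of coexisting lineages, sequencing error rate 1% and missing rate 10% per
#' SNP per leaf, per-lineage branching, inversions disabled. See the methods
#' vignette for how the default mutation rate, the branching mode and the
#' nullification rule were calibrated against the benchmark baseline.
#'
#' @param n_strains number of leaf genomes (>= 2).
#' @param branching_rate rate of the global lineage-branching event stream;
#'   scale-free because branch lengths are rescaled (see [simulate_tree()]).
#' @param avg_branch_length target mean branch length, time units.
#' @param n_snps number of SNP loci.
#' @param mutation_rate per-SNP per-unit-branch-length mutation rate.
#' @param hre_rate per-unit-time HRE rate for each pair of coexisting edges.
#' @param error_rate per-SNP per-leaf sequencing error probability.
#' @param missing_rate per-SNP per-leaf missing probability.
#' @param inversions_enabled generate inversions (off for the benchmark
#'   regime, which studies HREs within a single block).
#' @param inversion_rate per-unit-branch-length inversion rate (used only
#'   when enabled).
#' @param p_sym probability that an inversion is symmetric about the
#'   replication origin.
#' @param hre_pairs `"ordered"`: each ordered pair of coexisting edges
#'   carries an independent HRE stream at `hre_rate` (donor = first);
#'   `"unordered"`: one stream per unordered pair, direction drawn uniformly.
#' @param branching `"per_lineage"` (default): each extant lineage splits
#'   independently at `branching_rate` (Yule-type growth, homogeneous branch
#'   lengths); `"global"`: a single event stream splits a uniformly chosen
#'   lineage, which produces long pendant branches.
#' @param nullify_rule rule used by [flag_nullified()] for HREs overwritten
#'   by later same-branch HREs; see there.
#' @param seed optional RNG seed applied by [simulate_dataset()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_strains = 40L, branching_rate = 1,
                       avg_branch_length = 20, n_snps = 50L,
                       mutation_rate = 0.01, hre_rate = 0.03,
                       error_rate = 0.01, missing_rate = 0.10,
                       inversions_enabled = FALSE, inversion_rate = 0.01,
                       p_sym = 0.8, hre_pairs = c("ordered", "unordered"),
                       branching = c("per_lineage", "global"),
                       nullify_rule = c("intersect", "union", "contain"),
                       seed = NULL) {
  cfg <- list(n_strains = as.integer(n_strains),
              branching_rate = branching_rate,
              avg_branch_length = avg_branch_length,
              n_snps = as.integer(n_snps), mutation_rate = mutation_rate,
              hre_rate = hre_rate, error_rate = error_rate,
              missing_rate = missing_rate,
              inversions_enabled = isTRUE(inversions_enabled),
              inversion_rate = inversion_rate, p_sym = p_sym,
              hre_pairs = match.arg(hre_pairs),
              branching = match.arg(branching),
              nullify_rule = match.arg(nullify_rule), seed = seed)
  if (cfg$n_strains < 2L) stop("n_strains must be >= 2")
  if (cfg$n_snps < 1L) stop("n_snps must be >= 1")
  rates <- c(cfg$branching_rate, cfg$avg_branch_length, cfg$mutation_rate,
             cfg$hre_rate, cfg$error_rate, cfg$missing_rate,
             cfg$inversion_rate)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (cfg$error_rate > 1 || cfg$missing_rate > 1)
    stop("error/missing rates are probabilities")
  structure(cfg, class = "sim_config")
}

#' Simulate an ultrametric species tree by random lineage branching
#'
#' Starts with a root that splits at time 0; branching events arrive as a
#' single global stream with exponential waiting times, each splitting a
#' uniformly chosen extant lineage. The process stops when the event that
#' would create strain `n+1` is about to occur; all open lineages are then
#' closed as leaves at the stop time, so every root-to-leaf path has equal
#' length (the tree is ultrametric). Branch lengths are finally rescaled so
#' the mean branch length equals `avg_branch_length` exactly, which makes
#' `branching_rate` a free parameter.
#'
#' @param config a [sim_config] object.
#' @return A rooted binary `phylo` (tips `g1..gn`, root = n+1) with a
#'   `node_time` attribute giving each node's (rescaled) time.
#' @export
simulate_tree <- function(config) {
  n <- config$n_strains
  N <- 2L * n - 1L
  parent_of <- rep(NA_integer_, N)
  node_time <- rep(NA_real_, N)
  node_time[n + 1L] <- 0
  t <- 0
  next_int <- n + 2L
  lin_parent <- c(n + 1L, n + 1L)
  per_lineage <- identical(config$branching, "per_lineage")
  while (length(lin_parent) < n) {
    rate <- config$branching_rate * if (per_lineage) length(lin_parent) else 1
    t <- t + stats::rexp(1L, rate)
    k <- sample.int(length(lin_parent), 1L)
    v <- next_int; next_int <- next_int + 1L
    parent_of[v] <- lin_parent[k]
    node_time[v] <- t
    lin_parent <- c(lin_parent[-k], v, v)
  }
  stop_t <- t + stats::rexp(1L, config$branching_rate *
                              if (per_lineage) n else 1)
  parent_of[seq_len(n)] <- lin_parent
  node_time[seq_len(n)] <- stop_t

  len <- node_time - node_time[parent_of]
  scale <- config$avg_branch_length / mean(len[-(n + 1L)])
  node_time <- node_time * scale

  children <- vector("list", N)
  for (v in seq_len(N)) if (!is.na(parent_of[v]))
    children[[parent_of[v]]] <- c(children[[parent_of[v]]], v)
  # cladewise edge matrix: children in depth-first pop order
  ord <- integer(0)
  stack <- n + 1L
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    stack <- c(stack, rev(children[[v]]))
  }
  ord <- ord[ord != n + 1L]
  edge <- cbind(parent_of[ord], ord)
  phy <- structure(list(edge = edge,
                        edge.length = node_time[ord] - node_time[parent_of[ord]],
                        tip.label = paste0("g", seq_len(n)),
                        Nnode = n - 1L),
                   class = "phylo", order = "cladewise")
  attr(phy, "node_time") <- node_time
  phy
}

#' Simulate mutation and HRE event streams on a tree
#'
#' Mutations arrive on each edge as a Poisson process at rate
#' `mutation_rate * n_snps` per unit time (uniform random locus, change to a
#' uniformly random different base). HREs arrive, for each pair of edges
#' whose time intervals overlap, as a Poisson process at rate `hre_rate` over
#' the shared interval (Poisson counts with uniform event times are the same
#' process as the exponential inter-arrival construction). Each HRE's locus
#' range is uniform within a region of shared SNP order and orientation:
#' with inversions disabled that region is the whole locus set and the range
#' is drawn here (length uniform on 1..n_snps, then start uniform); with
#' inversions enabled the homologous regions depend on the lineage layouts
#' at event time, so the range is left NA and resolved by
#' [realize_alleles()].
#'
#' @param tree output of [simulate_tree()].
#' @param config a [sim_config] object.
#' @return data frame of events (kind `mutation`/`hre`) sorted by time, with
#'   destination edge (child node id), donor edge for HREs, locus or locus
#'   range, and the mutation's base offset.
#' @export
simulate_events <- function(tree, config) {
  nt <- attr(tree, "node_time")
  idx <- tree_index(tree)
  kids <- setdiff(seq_len(idx$n_node), idx$root)
  tb <- nt[idx$parent[kids]]
  te <- nt[kids]
  m <- config$n_snps

  ev <- list()
  # mutations
  lam <- config$mutation_rate * m * (te - tb)
  cnt <- stats::rpois(length(kids), lam)
  if (sum(cnt) > 0L) {
    who <- rep(seq_along(kids), cnt)
    ev[[1L]] <- data.frame(
      kind = "mutation", time = stats::runif(sum(cnt), tb[who], te[who]),
      node = kids[who], src_node = NA_integer_,
      locus = sample.int(m, sum(cnt), replace = TRUE),
      offset = sample.int(3L, sum(cnt), replace = TRUE),
      j1 = NA_integer_, j2 = NA_integer_, stringsAsFactors = FALSE)
  }
  # HREs on pairs of coexisting edges
  lo <- outer(tb, tb, pmax)
  hi <- outer(te, te, pmin)
  ov <- hi - lo
  ov[ov < 0] <- 0
  diag(ov) <- 0
  if (config$hre_pairs == "unordered") ov[lower.tri(ov)] <- 0
  cnt <- stats::rpois(length(ov), config$hre_rate * as.vector(ov))
  tot <- sum(cnt)
  if (tot > 0L) {
    cell <- rep(seq_along(cnt), cnt)
    a <- (cell - 1L) %% length(kids) + 1L # row: donor
    b <- (cell - 1L) %/% length(kids) + 1L # col: destination
    if (config$hre_pairs == "unordered") {
      flip <- stats::runif(tot) < 0.5
      tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
    }
    times <- stats::runif(tot, as.vector(lo)[cell], as.vector(hi)[cell])
    if (config$inversions_enabled) {
      j1 <- rep(NA_integer_, tot); j2 <- rep(NA_integer_, tot)
    } else {
      len <- sample.int(m, tot, replace = TRUE)
      j1 <- 1L + floor(stats::runif(tot) * (m - len + 1L))
      j2 <- j1 + len - 1L
    }
    ev[[length(ev) + 1L]] <- data.frame(
      kind = "hre", time = times, node = kids[b], src_node = kids[a],
      locus = NA_integer_, offset = NA_integer_, j1 = j1, j2 = j2,
      stringsAsFactors = FALSE)
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(0), time = numeric(0), node = integer(0),
               src_node = integer(0), locus = integer(0), offset = integer(0),
               j1 = integer(0), j2 = integer(0), stringsAsFactors = FALSE)
  out[order(out$time, out$node, out$kind), , drop = FALSE]
}

#' Simulate replication-origin-biased inversions
#'
#' A simplified generator of the inversion process in circular bacterial
#' chromosomes: each edge carries Poisson(`inversion_rate` x branch length)
#' inversions; an inversion picks a centre (the replication origin, taken as
#' the boundary between the last and first locus, with probability `p_sym`,
#' otherwise uniform on the SNP circle) and a half-width uniform on
#' 1..floor(n_snps/2), and reverses (with orientation flip) that circular
#' window of the lineage's SNP order. Applying the same inversion twice
#' restores the layout.
#'
#' @inheritParams simulate_events
#' @return data frame of `inversion` events (centre and half-width).
#' @export
simulate_inversions <- function(tree, config) {
  if (!config$inversions_enabled)
    return(data.frame(kind = character(0), time = numeric(0), node = integer(0),
                      center = numeric(0), halfw = integer(0),
                      stringsAsFactors = FALSE))
  nt <- attr(tree, "node_time")
  idx <- tree_index(tree)
  kids <- setdiff(seq_len(idx$n_node), idx$root)
  tb <- nt[idx$parent[kids]]
  te <- nt[kids]
  cnt <- stats::rpois(length(kids), config$inversion_rate * (te - tb))
  tot <- sum(cnt)
  if (tot == 0L)
    return(data.frame(kind = character(0), time = numeric(0), node = integer(0),
                      center = numeric(0), halfw = integer(0),
                      stringsAsFactors = FALSE))
  who <- rep(seq_along(kids), cnt)
  m <- config$n_snps
  sym <- stats::runif(tot) < config$p_sym
  # centres live on the boundary circle: 0 = replication origin (between
  # locus m and locus 1), k = boundary after position k
  center <- ifelse(sym, 0, sample.int(m, tot, replace = TRUE) - 1L)
  out <- data.frame(kind = "inversion",
                    time = stats::runif(tot, tb[who], te[who]),
                    node = kids[who], center = center,
                    halfw = sample.int(max(1L, m %/% 2L), tot, replace = TRUE),
                    stringsAsFactors = FALSE)
  out[order(out$time, out$node), , drop = FALSE]
}

# reverse + orientation-flip a circular window of a signed layout
apply_inversion <- function(layout, center, halfw) {
  m <- length(layout)
  pos <- ((center - halfw) : (center + halfw - 1L)) %% m + 1L
  layout[pos] <- -rev(layout[pos])
  layout
}

# maximal collinear shared segments of two signed layouts; returns a list of
# signed locus vectors (reading in `la` order)
shared_segments <- function(la, lb) {
  posb <- rep(NA_integer_, max(abs(c(la, lb))))
  sgnb <- rep(NA_integer_, max(abs(c(la, lb))))
  posb[abs(lb)] <- seq_along(lb)
  sgnb[abs(lb)] <- sign(lb)
  segs <- list()
  cur <- integer(0)
  prev_pos <- NA_integer_; prev_rel <- NA_integer_
  flush <- function() if (length(cur)) segs[[length(segs) + 1L]] <<- cur
  for (i in seq_along(la)) {
    l <- abs(la[i])
    if (is.na(posb[l])) { flush(); cur <- integer(0); prev_pos <- NA; next }
    rel <- sign(la[i]) * sgnb[l] # +1: same orientation in both
    ok <- length(cur) > 0L && !is.na(prev_pos) && rel == prev_rel &&
      posb[l] - prev_pos == prev_rel
    if (!ok) { flush(); cur <- integer(0) }
    cur <- c(cur, la[i])
    prev_pos <- posb[l]; prev_rel <- rel
  }
  flush()
  segs
}

#' Realize allele states down the tree
#'
#' Draws the root alleles uniformly and propagates states down the tree in
#' chronological order, applying mutations, HREs (copying the donor lineage's
#' current alleles over the range at the event time) and, when enabled,
#' inversions to the per-lineage layouts. Finally applies sequencing errors
#' (flip to a random different base) and missing masks independently per leaf
#' and locus. For each HRE the number of donor/recipient differences at
#' application time is recorded (`ndiff`), which [flag_nullified()] uses.
#'
#' @param tree output of [simulate_tree()].
#' @param events combined event data frame ([simulate_events()], plus
#'   [simulate_inversions()] rows if enabled), sorted by time.
#' @param config a [sim_config] object.
#' @return list: `leaf_alleles` (n x m, NA = missing), `true_leaf_alleles`
#'   (before noise), `internal_alleles` ((2n-1) x m truth), `layouts` (per
#'   leaf signed locus order, missing removed), `events` (input plus `ndiff`
#'   and `loci` annotation for layout-resolved HREs), `error_events`,
#'   `missing_events`.
#' @export
realize_alleles <- function(tree, events, config) {
  nt <- attr(tree, "node_time")
  idx <- tree_index(tree)
  n <- idx$n_tip; N <- idx$n_node; m <- config$n_snps
  root <- idx$root
  a0 <- sample.int(4L, m, replace = TRUE)
  cur <- vector("list", N)
  lay <- vector("list", N)
  truth <- matrix(NA_integer_, N, m)
  truth[root, ] <- a0
  for (ch in idx$children[[root]]) { cur[[ch]] <- a0; lay[[ch]] <- seq_len(m) }

  internals <- setdiff((n + 1L):N, root)
  branch <- data.frame(kind = "branch", time = nt[internals], node = internals)
  ek <- events$kind; etime <- events$time; enode <- events$node
  sched <- rbind(data.frame(kind = branch$kind, time = branch$time,
                            node = branch$node, row = NA_integer_),
                 data.frame(kind = ek, time = etime, node = enode,
                            row = seq_along(ek)))
  sched <- sched[order(sched$time, match(sched$kind, c("branch", "inversion",
                                                       "mutation", "hre"))), ]
  ndiff <- rep(NA_integer_, nrow(events))
  loci_str <- rep(NA_character_, nrow(events))
  esrc <- events$src_node; eloc <- events$locus; eoff <- events$offset
  ej1 <- events$j1; ej2 <- events$j2
  ecen <- if ("center" %in% names(events)) events$center else NULL
  ehw <- if ("halfw" %in% names(events)) events$halfw else NULL

  for (s in seq_len(nrow(sched))) {
    kind <- sched$kind[s]; v <- sched$node[s]; r <- sched$row[s]
    if (kind == "branch") {
      truth[v, ] <- cur[[v]]
      for (ch in idx$children[[v]]) { cur[[ch]] <- cur[[v]]; lay[[ch]] <- lay[[v]] }
      cur[v] <- list(NULL); lay[v] <- list(NULL)
    } else if (kind == "mutation") {
      l <- eloc[r]
      cur[[v]][l] <- (cur[[v]][l] - 1L + eoff[r]) %% 4L + 1L
    } else if (kind == "inversion") {
      lay[[v]] <- apply_inversion(lay[[v]], ecen[r], ehw[r])
    } else { # hre
      src <- esrc[r]
      if (is.na(ej1[r])) {
        segs <- shared_segments(lay[[src]], lay[[v]])
        if (length(segs) == 0L) { ndiff[r] <- 0L; next }
        lens <- vapply(segs, length, 0L)
        seg <- segs[[sample.int(length(segs), 1L, prob = lens)]]
        ln <- sample.int(length(seg), 1L)
        st <- 1L + floor(stats::runif(1L) * (length(seg) - ln + 1L))
        loci <- abs(seg[st:(st + ln - 1L)])
        loci_str[r] <- paste(loci, collapse = ",")
      } else {
        loci <- ej1[r]:ej2[r]
      }
      ndiff[r] <- sum(cur[[src]][loci] != cur[[v]][loci])
      cur[[v]][loci] <- cur[[src]][loci]
    }
  }
  true_leaf <- do.call(rbind, cur[seq_len(n)])
  truth[seq_len(n), ] <- true_leaf

  # leaf noise
  err <- matrix(stats::runif(n * m) < config$error_rate, n, m)
  obs <- true_leaf
  if (any(err)) {
    k <- sum(err)
    obs[err] <- (obs[err] - 1L + sample.int(3L, k, replace = TRUE)) %% 4L + 1L
  }
  mis <- matrix(stats::runif(n * m) < config$missing_rate, n, m)
  obs[mis] <- NA_integer_
  we <- which(err, arr.ind = TRUE)
  wm <- which(mis, arr.ind = TRUE)

  layouts <- lapply(seq_len(n), function(tp) {
    l <- lay[[tp]]
    l[!mis[tp, abs(l)]]
  })
  events$ndiff <- ndiff
  events$loci <- loci_str
  list(leaf_alleles = obs, true_leaf_alleles = true_leaf,
       internal_alleles = truth, layouts = layouts, events = events,
       error_events = data.frame(kind = rep("error", nrow(we)),
                                 node = we[, 1L], locus = we[, 2L]),
       missing_events = data.frame(kind = rep("missing", nrow(wm)),
                                   node = wm[, 1L], locus = wm[, 2L]))
}

#' Flag simulated events that leave no detectable evidence
#'
#' Same-branch nullification rules: (a) a mutation is nullified when its
#' locus is hit again by a later mutation, or covered by a later HRE, on the
#' same branch; (b) an HRE is nullified when donor and recipient differed at
#' at most one locus of the range when it was applied (no effect, or
#' indistinguishable from one mutation); (c) an HRE is nullified when a later
#' HRE on the same branch overwrites its entire range. Cross-branch
#' nullification (e.g. a mutation erased independently in both child
#' lineages) is deliberately not identified, so a residue of undetectable
#' events remains in the truth set.
#'
#' @param events realized event data frame (with `ndiff`) from
#'   [realize_alleles()].
#' @param hre_overlap rule (c) variant: `"intersect"` (default) nullifies an
#'   HRE when any later HRE on the same branch touches its range (partial
#'   overwrites scramble the evidence, which is why detection correctness is
#'   judged by overlap); `"union"` when the later HREs on the branch jointly
#'   overwrite the entire range; `"contain"` only when a single later HRE
#'   overwrites the entire range.
#' @return the events with a logical `nullified` column.
#' @export
flag_nullified <- function(events,
                           hre_overlap = c("intersect", "union", "contain")) {
  hre_overlap <- match.arg(hre_overlap)
  nul <- rep(FALSE, nrow(events))
  if (nrow(events) == 0L) { events$nullified <- nul; return(events) }
  hre_loci <- function(r) {
    if (!is.na(events$j1[r])) events$j1[r]:events$j2[r]
    else as.integer(strsplit(events$loci[r], ",")[[1L]])
  }
  for (v in unique(events$node)) {
    rows <- which(events$node == v)
    rows <- rows[order(events$time[rows])]
    mut <- rows[events$kind[rows] == "mutation"]
    hre <- rows[events$kind[rows] == "hre"]
    hloci <- lapply(hre, hre_loci)
    # (a) mutations re-hit or overwritten later on the same branch
    if (length(mut)) {
      nul[mut] <- nul[mut] | duplicated(events$locus[mut], fromLast = TRUE)
      for (i in seq_along(mut)) {
        later <- hre[events$time[hre] > events$time[mut[i]]]
        if (length(later) &&
            any(vapply(hloci[match(later, hre)],
                       function(l) events$locus[mut[i]] %in% l, TRUE)))
          nul[mut[i]] <- TRUE
      }
    }
    # (b) ineffective HREs; (c) HREs fully overwritten later
    if (length(hre)) {
      nul[hre] <- nul[hre] | (!is.na(events$ndiff[hre]) & events$ndiff[hre] <= 1L)
      for (i in seq_along(hre)) {
        li <- hloci[[i]]
        later <- which(vapply(seq_along(hre), function(k)
          events$time[hre[k]] > events$time[hre[i]], TRUE))
        if (!length(later)) next
        hit <- switch(hre_overlap,
          intersect = any(vapply(later, function(k)
            any(li %in% hloci[[k]]), TRUE)),
          union = all(li %in% unlist(hloci[later])),
          contain = any(vapply(later, function(k)
            all(li %in% hloci[[k]]), TRUE)))
        if (hit) nul[hre[i]] <- TRUE
      }
    }
  }
  events$nullified <- nul
  events
}

#' Simulate a complete data set with ground truth
#'
#' Runs tree simulation, event generation (plus inversions when enabled),
#' allele realization and nullified-event flagging, and packages the leaf
#' observations as a [snp_data] object (one contig per genome, positions =
#' layout order, missing loci dropped) ready for [detect_hre()].
#'
#' @param config a [sim_config] object; `config$seed` (if set) seeds the RNG.
#' @return list: `snp` ([snp_data]), `tree` (`phylo` with `node_time`),
#'   `truth` (event table with `nullified`), plus the raw matrices of
#'   [realize_alleles()].
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  tree <- simulate_tree(config)
  events <- simulate_events(tree, config)
  if (config$inversions_enabled) {
    inv <- simulate_inversions(tree, config)
    if (nrow(inv)) {
      inv2 <- data.frame(kind = inv$kind, time = inv$time, node = inv$node,
                         src_node = NA_integer_, locus = NA_integer_,
                         offset = NA_integer_, j1 = NA_integer_,
                         j2 = NA_integer_, center = inv$center,
                         halfw = inv$halfw, stringsAsFactors = FALSE)
      events$center <- NA_real_; events$halfw <- NA_integer_
      events <- rbind(events, inv2)
      events <- events[order(events$time, events$node), , drop = FALSE]
    }
  }
  rz <- realize_alleles(tree, events, config)
  truth <- flag_nullified(rz$events, hre_overlap = config$nullify_rule)

  genomes <- tree$tip.label
  layouts <- lapply(seq_along(genomes), function(tp) {
    sgn <- rz$layouts[[tp]]
    list(list(id = "c1", signed = sgn, pos = seq_along(sgn),
              allele = rz$leaf_alleles[tp, abs(sgn)]))
  })
  names(layouts) <- genomes
  snp <- build_snp_data(genomes, sort(unique(abs(unlist(rz$layouts)))),
                        config$n_snps, layouts)
  c(list(snp = snp, tree = tree, truth = truth, config = config), rz)
}
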