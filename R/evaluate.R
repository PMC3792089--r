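#' Match predicted HREs against simulated truth
#'
#' A predicted in-tree HRE is *correct* when its destination branch (edge
#' into `dest_node`) carries a non-nullified true HRE whose locus set
#' intersects the prediction's locus set; overlap counting is deliberately
#' not bijective (one truth event may validate several predictions and vice
#' versa). Out-group predictions are not matched: the simulator generates no
#' out-group donors.
#'
#' @param predicted event data frame from [detect_hre()] (only `hre` rows
#'   are used).
#' @param truth simulated event table with `nullified` (from
#'   [flag_nullified()]); nullified truth events are discarded before
#'   matching.
#' @param blocks optional list of signed block vectors (indexed by
#'   `block_id`) to translate block-local ranges into locus sets; defaults
#'   to the `locus_start..locus_end` annotation.
#' @return list with logical vectors `pred_correct` and `truth_detected`,
#'   and the filtered truth/prediction tables.
#' @export
match_predictions <- function(predicted, truth, blocks = NULL) {
  pred <- predicted[predicted$kind == "hre", , drop = FALSE]
  tr <- truth[truth$kind == "hre" & !truth$nullified, , drop = FALSE]
  pred_sets <- lapply(seq_len(nrow(pred)), function(i) {
    if (!is.null(blocks)) {
      b <- blocks[[pred$block_id[i]]]
      abs(b[pred$j_start[i]:pred$j_end[i]])
    } else pred$locus_start[i]:pred$locus_end[i]
  })
  truth_sets <- lapply(seq_len(nrow(tr)), function(i) {
    if (!is.na(tr$j1[i])) tr$j1[i]:tr$j2[i]
    else as.integer(strsplit(tr$loci[i], ",")[[1L]])
  })
  pred_correct <- logical(nrow(pred))
  truth_detected <- logical(nrow(tr))
  for (i in seq_len(nrow(pred))) {
    cand <- which(tr$node == pred$dest_node[i])
    for (k in cand) {
      if (any(pred_sets[[i]] %in% truth_sets[[k]])) {
        pred_correct[i] <- TRUE
        truth_detected[k] <- TRUE
      }
    }
  }
  list(pred_correct = pred_correct, truth_detected = truth_detected,
       predicted = pred, truth = tr)
}

#' Recall and precision of HRE detection
#'
#' `recall` = correctly detected true HREs / all non-nullified true HREs;
#' `precision` = correct predictions / all predictions. An empty denominator
#' yields 1 (a run with nothing to find and nothing found is perfect).
#'
#' @param matched output of [match_predictions()], or counts.
#' @param n_truth,n_pred,n_truth_detected,n_pred_correct raw counts,
#'   alternative to `matched`.
#' @return list `recall`, `precision` plus the counts.
#' @export
recall_precision <- function(matched = NULL, n_truth = NULL, n_pred = NULL,
                             n_truth_detected = NULL, n_pred_correct = NULL) {
  if (!is.null(matched)) {
    n_truth <- length(matched$truth_detected)
    n_pred <- length(matched$pred_correct)
    n_truth_detected <- sum(matched$truth_detected)
    n_pred_correct <- sum(matched$pred_correct)
  }
  list(recall = if (n_truth == 0L) 1 else n_truth_detected / n_truth,
       precision = if (n_pred == 0L) 1 else n_pred_correct / n_pred,
       n_truth = n_truth, n_pred = n_pred,
       n_truth_detected = n_truth_detected, n_pred_correct = n_pred_correct)
}

#' Count homoplastic SNP loci
#'
#' A locus is homoplastic when its minimum parsimony change count on the
#' tree exceeds (number of observed alleles - 1), i.e. its allele pattern
#' conflicts with vertical inheritance. Missing alleles are unconstrained;
#' all-missing and invariant loci are never homoplastic.
#'
#' @param phy rooted binary `phylo`.
#' @param leaf_alleles leaf allele matrix (see [infer_internal_alleles()]).
#' @return integer count.
#' @export
count_homoplastic <- function(phy, leaf_alleles) {
  idx <- if (inherits(phy, "phylo")) tree_index(phy) else phy
  leaf <- as_allele_matrix(leaf_alleles, idx$labels)
  ch <- parsimony_changes(idx, leaf)
  k <- apply(leaf, 2L, function(col) length(unique(col[!is.na(col)])))
  sum(k >= 1L & ch > (k - 1L))
}

#' Run a simulation/detection/matching experiment
#'
#' Runs the full pipeline (simulate, detect, match) `reps` times and pools
#' the counts: pooled recall/precision divide summed numerators by summed
#' denominators over replicates (per-replicate means are also reported).
#' Replicate r uses seed `seed + r`, so results are reproducible and
#' individual replicates can be re-run in isolation.
#'
#' @param config a [sim_config] (its `seed` field is ignored here).
#' @param reps number of replicates.
#' @param seed integer base seed.
#' @param weights detection [hre_weights].
#' @param outgroup enable the out-group donor state in detection.
#' @return An `experiment_result`: pooled `recall`/`precision`, per-rep
#'   data frame, and the config.
#' @export
run_experiment <- function(config = sim_config(), reps = 200L, seed = 1L,
                           weights = hre_weights(), outgroup = TRUE) {
  per <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- seed + r
    sim <- simulate_dataset(cfg)
    det <- detect_hre(sim$snp, sim$tree, weights = weights,
                      outgroup = outgroup, trace = FALSE)
    mm <- match_predictions(det$events, sim$truth, det$blocks)
    st <- recall_precision(mm)
    per[[r]] <- data.frame(rep = r, seed = cfg$seed,
                           n_truth = st$n_truth, n_pred = st$n_pred,
                           n_truth_detected = st$n_truth_detected,
                           n_pred_correct = st$n_pred_correct,
                           recall = st$recall, precision = st$precision)
  }
  per <- do.call(rbind, per)
  pooled <- recall_precision(
    n_truth = sum(per$n_truth), n_pred = sum(per$n_pred),
    n_truth_detected = sum(per$n_truth_detected),
    n_pred_correct = sum(per$n_pred_correct))
  structure(list(recall = pooled$recall, precision = pooled$precision,
                 mean_recall = mean(per$recall),
                 mean_precision = mean(per$precision),
                 counts = pooled, per_rep = per, config = config,
                 reps = reps, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "experiment: %d reps | pooled recall %.2f%% (%d/%d) | pooled precision %.2f%% (%d/%d)\n",
    x$reps, 100 * x$recall, x$counts$n_truth_detected, x$counts$n_truth,
    100 * x$precision, x$counts$n_pred_correct, x$counts$n_pred))
  invisible(x)
}

#' Vary one simulator parameter over a grid
#'
#' Reruns [run_experiment()] with one parameter set to each value in turn,
#' all other parameters fixed at `config` -- the design of the accuracy
#' benchmark tables.
#'
#' @param param name of a [sim_config] field.
#' @param values vector of values to try.
#' @inheritParams run_experiment
#' @return data frame with one row per value (pooled recall/precision and
#'   counts).
#' @export
run_grid <- function(param, values, config = sim_config(), reps = 200L,
                     seed = 1L, weights = hre_weights()) {
  if (!param %in% names(config)) stop("unknown simulator parameter: ", param)
  rows <- lapply(seq_along(values), function(i) {
    cfg <- config
    cfg[[param]] <- if (param %in% c("n_strains", "n_snps"))
      as.integer(values[i]) else values[i]
    res <- run_experiment(cfg, reps = reps, seed = seed, weights = weights)
    data.frame(param = param, value = values[i],
               recall = res$recall, precision = res$precision,
               n_truth = res$counts$n_truth, n_pred = res$counts$n_pred)
  })
  do.call(rbind, rows)
}
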