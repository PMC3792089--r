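#' Detect mutations, errors and HREs in a SNP data set
#'
#' The end-to-end detection pipeline: partition the genomes into locally
#' collinear blocks ([get_blocks()]), project leaf alleles onto each block
#' ([project_alleles()]), infer internal-node alleles by weighted parsimony
#' ([infer_internal_alleles()]), run the HRE assignment dynamic program
#' ([assign_events()]) and, optionally, trace allele origins for inheritance
#' cycles ([trace_origins()]).
#'
#' @param snp a [snp_data] object.
#' @param tree rooted binary `phylo` whose tips are the genomes.
#' @param weights an [hre_weights] object.
#' @param outgroup enable the out-group donor state.
#' @param jump_cap jump-over-contig enumeration cap for the block matcher.
#' @param trace run origin tracing (cycle detection) per block.
#' @param tie parsimony backtracking tie policy, see
#'   [infer_internal_alleles()].
#' @return An object of class `hre_detection`: `events` (all blocks),
#'   `blocks` (signed locus vectors), `block_set`, `total_weight`, and a
#'   per-node, per-kind `summary` table.
#' @export
detect_hre <- function(snp, tree, weights = hre_weights(), outgroup = TRUE,
                       jump_cap = 64L, trace = TRUE,
                       tie = c("subtree", "parent")) {
  tie <- match.arg(tie)
  tree <- validate_tree(tree, snp$genomes)
  idx <- tree_index(tree)
  bs <- get_blocks(snp, jump_cap)
  all_events <- list()
  total <- 0
  for (b in seq_along(bs$blocks)) {
    blk <- bs$blocks[[b]]
    A <- project_alleles(snp, blk, jump_cap)
    pars <- infer_internal_alleles(idx, A, weights, tie = tie)
    res <- assign_events(idx, pars$alleles, weights, outgroup = outgroup,
                         block = blk, block_id = b)
    total <- total + res$total_weight
    ev <- res$events
    if (trace && nrow(ev)) {
      tr <- trace_origins(ev, idx, length(blk))
      if (nrow(tr)) {
        tr$block_id <- b
        tr$locus_start <- abs(blk)[tr$j_start]
        tr$locus_end <- abs(blk)[tr$j_end]
        ev <- rbind(ev, tr)
      }
    }
    all_events[[b]] <- ev
  }
  events <- do.call(rbind, all_events)
  if (is.null(events)) events <- empty_events()
  rownames(events) <- NULL
  summary <- if (nrow(events))
    as.data.frame(table(dest_node = events$dest_node, kind = events$kind),
                  stringsAsFactors = FALSE)
  else data.frame(dest_node = character(0), kind = character(0),
                  Freq = integer(0))
  summary <- summary[summary$Freq > 0, , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(events = events, blocks = bs$blocks, block_set = bs,
                 total_weight = total, summary = summary, tree = tree,
                 weights = weights),
            class = "hre_detection")
}

#' @export
print.hre_detection <- function(x, ...) {
  k <- table(factor(x$events$kind, levels = c("mutation", "error", "hre",
                                              "outgroup_hre",
                                              "outgroup_evidence")))
  cat(sprintf("hre_detection: %d blocks, total weight %g\n",
              length(x$blocks), x$total_weight))
  cat(sprintf("  events: %d mutations, %d errors, %d HREs, %d out-group HREs, %d cycle evidences\n",
              k[1L], k[2L], k[3L], k[4L], k[5L]))
  invisible(x)
}

#' Write detection outputs
#'
#' `write_events()` writes the event table as TSV; `write_blocks()` writes
#' one row per block (id, length, signed locus string, overlap flag);
#' `write_summary_json()` writes per-kind and per-node event counts.
#'
#' @param det an `hre_detection` object.
#' @param path output file path.
#' @export
write_events <- function(det, path) {
  utils::write.table(det$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
write_blocks <- function(det, path) {
  bs <- det$block_set
  df <- data.frame(
    block_id = seq_along(bs$blocks),
    length = vapply(bs$blocks, length, 0L),
    snps = vapply(bs$blocks, function(b)
      paste0(ifelse(b < 0, "-", ""), abs(b), collapse = ","), ""),
    overlaps = vapply(bs$blocks, function(b)
      any(abs(b) %in% bs$overlap_loci), TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
write_summary_json <- function(det, path) {
  by_kind <- as.list(table(det$events$kind))
  per_node <- det$summary
  jsonlite::write_json(
    list(n_blocks = length(det$blocks),
         increased_snp_count = det$block_set$increased_snp_count,
         total_weight = det$total_weight,
         events_by_kind = by_kind,
         events_by_node = per_node),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Genomic positions flanking each event
#'
#' Maps every event's first and last locus back to genomic coordinates in
#' each leaf genome (NA where the locus is absent), so predicted regions can
#' be pulled from the assemblies for verification.
#'
#' @param det an `hre_detection` object.
#' @param snp the [snp_data] the detection was run on.
#' @return long data frame: event row id, genome, contig and position of the
#'   first and last locus of the event.
#' @export
event_flank_positions <- function(det, snp) {
  ev <- det$events
  if (nrow(ev) == 0L)
    return(data.frame(event = integer(0), genome = character(0),
                      contig_start = character(0), pos_start = numeric(0),
                      contig_end = character(0), pos_end = numeric(0)))
  find_pos <- function(g, locus) {
    for (ct in snp$layouts[[g]]) {
      hit <- which(abs(ct$signed) == locus)
      if (length(hit)) return(list(ct$id, ct$pos[hit[1L]]))
    }
    list(NA_character_, NA_real_)
  }
  rows <- list()
  for (r in seq_len(nrow(ev))) {
    for (g in snp$genomes) {
      a <- find_pos(g, ev$locus_start[r])
      b <- find_pos(g, ev$locus_end[r])
      rows[[length(rows) + 1L]] <- data.frame(
        event = r, genome = g, contig_start = a[[1L]], pos_start = a[[2L]],
        contig_end = b[[1L]], pos_end = b[[2L]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Command-style entry points
#'
#' Thin wrappers tying the pipeline to files, used by the
#' `inst/scripts/snprecomb` command-line script. `run_detection()` reads a
#' SNP matrix TSV and a Newick tree and writes `events.tsv`, `blocks.tsv`
#' and `summary.json` into `out_dir`; `run_simulation()` writes a simulated
#' `snp.tsv`, `tree.nwk` and `truth.tsv`; `run_evaluation()` writes a
#' benchmark grid `results.tsv`.
#'
#' @param snp_path,tree_path input files.
#' @param out_dir output directory (created if needed).
#' @param weights an [hre_weights] object.
#' @param outgroup,jump_cap passed to [detect_hre()].
#' @return the output directory, invisibly.
#' @export
run_detection <- function(snp_path, tree_path, out_dir,
                          weights = hre_weights(), outgroup = TRUE,
                          jump_cap = 64L) {
  snp <- read_snp_matrix(snp_path)
  tree <- read_tree(tree_path, genomes = snp$genomes)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  det <- detect_hre(snp, tree, weights, outgroup, jump_cap)
  write_events(det, file.path(out_dir, "events.tsv"))
  write_blocks(det, file.path(out_dir, "blocks.tsv"))
  write_summary_json(det, file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

#' @rdname run_detection
#' @param config a [sim_config] object.
#' @param seed RNG seed (overrides `config$seed` when not NULL).
#' @export
run_simulation <- function(config = sim_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_dataset(config)
  write_snp_matrix(sim$snp, file.path(out_dir, "snp.tsv"))
  tr <- sim$tree
  attr(tr, "node_time") <- NULL
  ape::write.tree(tr, file.path(out_dir, "tree.nwk"))
  utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' @rdname run_detection
#' @param param,values simulator parameter grid (see [run_grid()]).
#' @param reps replicates per grid point.
#' @export
run_evaluation <- function(param, values, out_dir, config = sim_config(),
                           reps = 200L, seed = 1L,
                           weights = hre_weights()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_grid(param, values, config, reps, seed, weights)
  utils::write.table(res, file.path(out_dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
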