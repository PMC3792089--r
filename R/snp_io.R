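#' SNP matrix container
#'
#' Builds the internal representation of a SNP matrix from a long-format data
#' frame with one row per SNP occurrence. Each genome becomes an ordered list
#' of contigs, each contig an ordered list of signed SNP occurrences (sign =
#' strand); a locus may be missing from a genome, occur once, or occur several
#' times (a duplicated SNP). Alleles are canonicalized to the locus' forward
#' strand at load time (reverse-strand occurrences are complemented), so rows
#' of the allele matrix are directly comparable across genomes; missingness is
#' preserved, never imputed.
#'
#' @param df data.frame with columns `locus_id` (positive integer),
#'   `genome_id`, `contig_id`, `position` (numeric, strictly increasing within
#'   a contig after sorting), `strand` (`"+"`/`"-"`), `allele` (A/C/G/T).
#' @return An object of class `snp_data`.
#' @export
snp_data <- function(df) {
  need <- c("locus_id", "genome_id", "contig_id", "position", "strand", "allele")
  if (!all(need %in% names(df)))
    stop("SNP table must have columns: ", paste(need, collapse = ", "))
  df$locus_id <- as.integer(df$locus_id)
  if (any(is.na(df$locus_id)) || any(df$locus_id < 1L))
    stop("locus_id must be positive integers")
  bad <- !df$strand %in% c("+", "-")
  if (any(bad)) stop("unknown strand symbol(s): ",
                     paste(unique(df$strand[bad]), collapse = ", "))
  al <- encode_allele(df$allele)
  if (any(is.na(al))) stop("allele outside {A,C,G,T}: ",
                           paste(unique(df$allele[is.na(al)]), collapse = ", "))
  key <- paste(df$genome_id, df$contig_id, df$position)
  if (anyDuplicated(key))
    stop("duplicate (genome, contig, position) rows: ",
         paste(head(unique(key[duplicated(key)]), 3), collapse = "; "))

  genomes <- unique(as.character(df$genome_id))
  loci <- sort(unique(df$locus_id))
  max_locus <- max(loci)
  sgn <- ifelse(df$strand == "+", 1L, -1L)
  canon <- ifelse(sgn == 1L, al, complement_allele(al))

  layouts <- vector("list", length(genomes))
  names(layouts) <- genomes
  for (g in genomes) {
    rows <- which(df$genome_id == g)
    contigs_ids <- unique(as.character(df$contig_id[rows]))
    contigs <- lapply(contigs_ids, function(ct) {
      r <- rows[df$contig_id[rows] == ct]
      r <- r[order(df$position[r])]
      list(id = ct,
           signed = sgn[r] * df$locus_id[r],
           pos = df$position[r],
           allele = as.integer(canon[r]))
    })
    layouts[[g]] <- contigs
  }
  build_snp_data(genomes, loci, max_locus, layouts)
}

# assemble the derived lookup tables shared by snp_data() and the simulator
build_snp_data <- function(genomes, loci, max_locus, layouts) {
  nG <- length(genomes)
  present <- matrix(FALSE, nG, max_locus, dimnames = list(genomes, NULL))
  allele1 <- matrix(NA_integer_, nG, max_locus, dimnames = list(genomes, NULL))
  dup <- vector("list", nG); names(dup) <- genomes
  fast <- vector("list", nG); names(fast) <- genomes
  for (g in genomes) {
    contigs <- layouts[[g]]
    all_loci <- abs(unlist(lapply(contigs, `[[`, "signed")))
    all_alle <- unlist(lapply(contigs, `[[`, "allele"))
    tab <- tabulate(all_loci, max_locus)
    dup[[g]] <- which(tab > 1L)
    present[g, ] <- tab > 0L
    first <- match(seq_len(max_locus), all_loci)
    allele1[g, ] <- all_alle[first]
    if (length(contigs) == 1L && length(dup[[g]]) == 0L) {
      v <- contigs[[1L]]$signed
      idx <- rep(NA_integer_, max_locus)
      idx[abs(v)] <- seq_along(v)
      fast[[g]] <- list(idx = idx, val = v)
    }
  }
  is_locus <- rep(FALSE, max_locus)
  is_locus[loci] <- TRUE
  structure(list(genomes = genomes, loci = loci, max_locus = max_locus,
                 is_locus = is_locus, layouts = layouts, present = present,
                 allele1 = allele1, dup = dup, fast = fast),
            class = "snp_data")
}

#' @export
print.snp_data <- function(x, ...) {
  nc <- vapply(x$layouts, length, 0L)
  cat(sprintf("snp_data: %d genomes, %d loci, %s contig(s) per genome\n",
              length(x$genomes), length(x$loci),
              if (all(nc == 1L)) "1" else paste0(min(nc), "-", max(nc))))
  invisible(x)
}

#' Read / write a SNP matrix TSV
#'
#' The on-disk format is a plain TSV with columns `locus_id`, `genome_id`,
#' `contig_id`, `position`, `strand`, `allele` -- one row per SNP occurrence
#' (reformatted SNP-caller output, e.g. from kSNP). `write_snp_matrix()`
#' inverts `read_snp_matrix()` up to row order: alleles are written back on
#' the strand of the occurrence.
#'
#' @param path file path.
#' @return `read_snp_matrix()`: a [snp_data] object.
#' @export
read_snp_matrix <- function(path) {
  if (!file.exists(path)) stop("SNP matrix file not found: ", path)
  df <- utils::read.delim(path, colClasses = c(
    locus_id = "integer", genome_id = "character", contig_id = "character",
    position = "numeric", strand = "character", allele = "character"))
  snp_data(df)
}

#' @rdname read_snp_matrix
#' @param snp a [snp_data] object.
#' @export
write_snp_matrix <- function(snp, path) {
  rows <- list()
  for (g in snp$genomes) {
    for (ct in snp$layouts[[g]]) {
      s <- sign(ct$signed)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = abs(ct$signed), genome_id = g, contig_id = ct$id,
        position = ct$pos, strand = ifelse(s > 0, "+", "-"),
        allele = decode_allele(ifelse(s > 0, ct$allele,
                                      complement_allele(ct$allele))),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Leaf allele matrix of a SNP data set
#'
#' @param snp a [snp_data] object.
#' @param as_character return bases instead of the internal integer coding.
#' @return genomes x loci matrix (columns named by locus id); missing = NA.
#' @export
snp_alleles <- function(snp, as_character = FALSE) {
  m <- snp$allele1[, snp$loci, drop = FALSE]
  colnames(m) <- snp$loci
  if (as_character) {
    mm <- matrix(decode_allele(m), nrow = nrow(m), dimnames = dimnames(m))
    mm[is.na(m)] <- NA
    mm
  } else m
}
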