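#' Event weight set
#'
#' Constructs and validates the set of event costs used throughout the
#' detection pipeline: `w_m` for a mutation (an allele change on the edge into
#' an internal node), `w_x` for a recombination event whose donor is a node of
#' the species tree, `w_e` for a sequencing error (any disagreement between a
#' leaf and its parent), and the affine out-group pair `w_o` (opening) /
#' `w_t` (per-SNP extension) charged when a dense mismatch run is attributed
#' to a donor outside the tree.
#'
#' The defaults `(2, 3, 1)` are the unique small integers satisfying the
#' calibration rules the detector is built around: two or more adjacent
#' mutations are better explained by one in-tree HRE (`w_x < 2*w_m`), three
#' or more adjacent leaf errors are explained by one HRE with ties resolved
#' toward the HRE (`w_x <= 3*w_e`), while a single mutation or a pair of
#' errors is never promoted to an HRE (`w_x > w_m`, `w_x > 2*w_e`). Errors
#' are always cheaper than mutations (`w_e < w_m`). The out-group defaults
#' `(3, 0.5)` make an out-group call profitable only for runs of at least 6
#' dense mismatches on a leaf (`w_o + (L-1)*w_t < L*w_e`).
#'
#' @param w_m mutation cost (positive).
#' @param w_x in-tree HRE cost (positive).
#' @param w_e error cost (positive).
#' @param w_o out-group HRE opening cost (positive).
#' @param w_t out-group per-SNP extension cost (non-negative).
#' @return An object of class `hre_weights` (a named list).
#' @examples
#' hre_weights()
#' hre_weights(w_m = 2, w_x = 3.5, w_e = 1.5)
#' @export
hre_weights <- function(w_m = 2, w_x = 3, w_e = 1, w_o = 3, w_t = 0.5) {
  w <- list(w_m = w_m, w_x = w_x, w_e = w_e, w_o = w_o, w_t = w_t)
  for (nm in names(w)) {
    if (!is.numeric(w[[nm]]) || length(w[[nm]]) != 1L || is.na(w[[nm]]))
      stop("weight '", nm, "' must be a single number")
  }
  if (any(unlist(w[c("w_m", "w_x", "w_e", "w_o")]) <= 0) || w$w_t < 0)
    stop("weights must be positive (w_t may be zero)")
  check <- function(cond, msg) if (!cond) stop("invalid weights: ", msg, call. = FALSE)
  check(w$w_e < w$w_m, "error weight < mutation weight is required (w_e < w_m)")
  if (is.finite(w$w_x)) {
    check(w$w_x < 2 * w$w_m, "one HRE must beat two mutations (w_x < 2*w_m)")
    check(w$w_x <= 3 * w$w_e, "one HRE must beat (or tie) three errors (w_x <= 3*w_e)")
    check(w$w_x > w$w_m, "one mutation must beat one HRE (w_x > w_m)")
    check(w$w_x > 2 * w$w_e, "two errors must beat one HRE (w_x > 2*w_e)")
  }
  structure(w, class = "hre_weights")
}

#' @export
print.hre_weights <- function(x, ...) {
  cat(sprintf("event weights: w_m=%g  w_x=%g  w_e=%g  w_o=%g  w_t=%g\n",
              x$w_m, x$w_x, x$w_e, x$w_o, x$w_t))
  # smallest leaf mismatch run for which an out-group HRE beats errors
  if (x$w_t < x$w_e) {
    L <- floor((x$w_o - x$w_t) / (x$w_e - x$w_t)) + 1L
    cat(sprintf("out-group call cheaper than errors from %d dense mismatches\n", L))
  }
  invisible(x)
}

# nucleotide coding used internally: A=1 C=2 G=3 T=4, NA = missing
ALLELE_LEVELS <- c("A", "C", "G", "T")

encode_allele <- function(x) {
  out <- match(toupper(x), ALLELE_LEVELS)
  out[x %in% c("", ".", "N", "-", NA)] <- NA_integer_
  out
}

decode_allele <- function(x) {
  out <- ALLELE_LEVELS[x]
  out[is.na(x)] <- "."
  out
}

# complement under the integer coding (A<->T, C<->G)
complement_allele <- function(x) 5L - x
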