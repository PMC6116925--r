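#' Structure-counting matrix
#'
#' Fills the Waterman-Smith counting table `C` in which `C[i, j]` is the
#' number of nested structures the subsequence `i..j` can form:
#' `C[i,j] = C[i,j-1] + sum over complementary k < j - l of
#' C[i,k-1] * C[k+1,j-1]` (empty intervals count 1, `C[i,i] = 1`).
#' Entries are exact arbitrary-precision integers: counts overflow 64-bit
#' arithmetic near length 60 for pairable sequences.
#'
#' @inheritParams validate_structure
#' @return An object of class `count_matrix`: list with `counts` (numeric
#'   matrix, exact while below 2^53), `exact` (decimal strings) and `n`.
#' @examples
#' count_matrix("GGGAAACCC")$counts[1, 9]  # 20
#' @export
count_matrix <- function(seq, cfg = fold_config(), rule = pair_rule()) {
  seq <- rna_seq(seq, concatenated = TRUE)
  res <- count_matrix_bigint(pairable_matrix(seq, rule), as.integer(cfg$min_loop))
  structure(list(counts = res$counts, exact = res$exact, n = seq$n,
                 seq = seq, cfg = cfg, rule = rule),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Counting matrix C for %s (n = %d): |ensemble| = %s\n",
              x$seq$seq, x$n, if (x$n) x$exact[1, x$n] else "1"))
  invisible(x)
}

#' Size of the structure ensemble
#'
#' Returns `C[1, n]`, the total number of nested structures of the sequence
#' (1 for the empty sequence: only the empty structure).
#'
#' @inheritParams count_matrix
#' @param exact if `TRUE` return the exact count as a decimal string,
#'   otherwise a double (exact while below 2^53).
#' @examples
#' count_structures("GAAAC")  # 2
#' @export
count_structures <- function(seq, cfg = fold_config(), rule = pair_rule(),
                             exact = FALSE) {
  seq <- rna_seq(seq, concatenated = TRUE)
  if (seq$n == 0) return(if (exact) "1" else 1)
  cm <- count_matrix(seq, cfg, rule)
  if (exact) cm$exact[1, seq$n] else cm$counts[1, seq$n]
}

#' Asymptotic growth factor of the structure space
#'
#' Specializes the counting recursion to sequence length only (every
#' position pair treated as pairable), `f(m) = f(m-1) +
#' sum_{k=1..m-l-1} f(k-1) * f(m-k-1)` with `f(0) = ... = f(l+1) = 1`, in
#' exact integer arithmetic, and returns the per-nucleotide growth estimate
#' `f(n+1) / f(n)`.  For minimal loop length 3 this converges to about 2.3;
#' without the loop constraint the limit is about 2.62.
#'
#' @param n sequence length at which the ratio is evaluated.
#' @param min_loop minimal loop length `l`.
#' @return `f(n+1) / f(n)` as a double.
#' @examples
#' growth_factor(5)            # 4/2 = 2
#' round(growth_factor(500), 1)  # 2.3
#' @export
growth_factor <- function(n, min_loop = 3) {
  if (!is.numeric(n) || n < 1 || n != round(n))
    stop_input("n must be a positive integer")
  growth_sequence_bigint(as.integer(n), as.integer(min_loop))$ratio
}
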