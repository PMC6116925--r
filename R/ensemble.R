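# Partition function and ensemble probabilities: McCaskill's algorithm
# rephrased for the per-base-pair energy model.  Double precision with an
# explicit sequence-length guard (teaching-scale inputs); overflow is
# detected via the guard rather than silently rescaled.

#' Partition function matrices
#'
#' Computes the split recursion
#' `Qbp[i,j] = Q[i+1,j-1] * q_bp` for admissible `(i,j)` (0 otherwise) and
#' `Q[i,j] = Q[i,j-1] + sum_k Q[i,k-1] * Qbp[k,j]`, with `Q = 1` over empty
#' and length-1 intervals.  The partition function is `Z = Q[1,n]`.  As an
#' internal consistency check the direct single-matrix recursion (the
#' counting recursion with a `q_bp` factor on the pairing case) is evaluated
#' as well and must agree to 1e-12 relative.
#'
#' @inheritParams validate_structure
#' @param model an [energy_model()].
#' @param guard maximal sequence length (default 150); beyond it the
#'   unscaled double-precision arithmetic risks overflow.
#' @return Object of class `partition_matrices`: list with `Q`, `Qbp`, `Z`,
#'   `q_bp` and the inputs.
#' @examples
#' partition_matrices("GAAAC")$Z  # 1 + e
#' @export
partition_matrices <- function(seq, cfg = fold_config(), rule = pair_rule(),
                               model = energy_model(), guard = 150) {
  seq <- rna_seq(seq, concatenated = TRUE)
  n <- seq$n
  if (n > guard)
    stop_guard("sequence length %d exceeds the partition-function guard (%d)",
               n, guard)
  l <- cfg$min_loop
  q_bp <- model$q_bp
  comp <- pairable_matrix(seq, rule)
  Q <- matrix(1, max(n, 1), max(n, 1))
  Qbp <- matrix(0, max(n, 1), max(n, 1))
  Q2 <- matrix(1, max(n, 1), max(n, 1))   # direct one-matrix recursion
  Qget <- function(M, i, j) if (i > j) 1 else M[i, j]
  if (n >= 2) for (span in 1:(n - 1)) for (i in 1:(n - span)) {
    j <- i + span
    if (comp[i, j] && j - i > l) Qbp[i, j] <- Qget(Q, i + 1, j - 1) * q_bp
    v <- Q[i, j - 1]
    v2 <- Q2[i, j - 1]
    hi <- j - l - 1
    if (hi >= i) for (k in i:hi) {
      if (Qbp[k, j] > 0) v <- v + Qget(Q, i, k - 1) * Qbp[k, j]
      if (comp[k, j]) v2 <- v2 + Qget(Q2, i, k - 1) * Qget(Q2, k + 1, j - 1) * q_bp
    }
    Q[i, j] <- v
    Q2[i, j] <- v2
    if (!is.finite(v))
      stop_guard("partition function overflowed at interval (%d,%d)", i, j)
  }
  Z <- if (n) Q[1, n] else 1
  Z2 <- if (n) Q2[1, n] else 1
  if (abs(Z - Z2) > 1e-12 * max(1, abs(Z)))
    stop("internal error: split and direct partition-function recursions disagree")
  structure(list(Q = Q, Qbp = Qbp, Z = Z, q_bp = q_bp,
                 seq = seq, cfg = cfg, rule = rule, model = model),
            class = "partition_matrices")
}

#' @export
print.partition_matrices <- function(x, ...) {
  cat(sprintf("Partition function for %s: Z = %.6f (q_bp = %.6f)\n",
              x$seq$seq, x$Z, x$q_bp))
  invisible(x)
}

#' Boltzmann probability of a single structure
#'
#' `Pr(P) = exp(-E(P)/RT) / Z`.  The energy-minimal structure is always the
#' most probable one.
#'
#' @inheritParams partition_matrices
#' @param pairs the structure.
#' @examples
#' structure_probability(c(1, 5), "GAAAC")  # e / (1 + e)
#' @export
structure_probability <- function(pairs, seq, cfg = fold_config(),
                                  rule = pair_rule(), model = energy_model()) {
  pm <- partition_matrices(seq, cfg, rule, model)
  boltzmann_weight(pairs, model) / pm$Z
}

#' Base-pair and unpaired probabilities of the ensemble
#'
#' Computes `Pr_bp(i,j)` for every admissible pair by the outside recursion:
#' the external term `Q[1,i-1] * Qbp[i,j] * Q[j+1,n] / Z` plus, for every
#' admissible directly-enclosing pair `(p,q)`, the term
#' `Pr_bp(p,q) * q_bp * Q[p+1,i-1] * Qbp[i,j] * Q[j+1,q-1] / Qbp[p,q]`.
#' Pairs are processed in strictly decreasing span order so every enclosing
#' probability is final when used.  Position-wise unpaired probabilities
#' follow as `Pr_u(k) = 1 - sum_i Pr_bp(i,k) - sum_j Pr_bp(k,j)`.
#'
#' @inheritParams partition_matrices
#' @return Object of class `ensemble_stats`: list with `Z`, `pr_bp` (n x n
#'   upper-triangular matrix), `pr_u` (length-n vector), the partition
#'   matrices and the inputs.
#' @examples
#' basepair_probabilities("GAAAC")$pr_bp[1, 5]  # e / (1 + e)
#' @export
basepair_probabilities <- function(seq, cfg = fold_config(),
                                   rule = pair_rule(),
                                   model = energy_model(), guard = 150) {
  pm <- partition_matrices(seq, cfg, rule, model, guard = guard)
  seq <- pm$seq
  n <- seq$n
  Q <- pm$Q; Qbp <- pm$Qbp; Z <- pm$Z; q_bp <- pm$q_bp
  Qget <- function(i, j) if (i > j) 1 else Q[i, j]
  pr <- matrix(0, max(n, 1), max(n, 1))
  ratio <- matrix(0, max(n, 1), max(n, 1))  # pr_bp / Qbp where admissible
  if (n >= 2) {
    adm <- which(Qbp > 0, arr.ind = TRUE)
    if (nrow(adm)) {
      adm <- adm[order(-(adm[, 2] - adm[, 1])), , drop = FALSE]
      for (r in seq_len(nrow(adm))) {
        i <- adm[r, 1]; j <- adm[r, 2]
        v <- Qget(1, i - 1) * Qbp[i, j] * Qget(j + 1, n) / Z
        if (i > 1 && j < n) {
          ps <- 1:(i - 1); qs <- (j + 1):n
          # sum over enclosing (p,q): ratio[p,q] * Q[p+1, i-1] * Q[j+1, q-1]
          a <- vapply(ps, function(p) Qget(p + 1, i - 1), 0)
          b <- vapply(qs, function(q) Qget(j + 1, q - 1), 0)
          v <- v + Qbp[i, j] * q_bp *
            as.numeric(a %*% ratio[ps, qs, drop = FALSE] %*% b)
        }
        pr[i, j] <- v
        ratio[i, j] <- v / Qbp[i, j]
      }
    }
  }
  pr_u <- if (n) 1 - (rowSums(pr) + colSums(pr))[1:n] else numeric(0)
  structure(list(Z = Z, pr_bp = pr[seq_len(max(n, 1)), seq_len(max(n, 1)), drop = FALSE],
                 pr_u = pr_u, ratio = ratio, Q = Q, Qbp = Qbp, q_bp = q_bp,
                 seq = seq, cfg = cfg, rule = pm$rule, model = pm$model),
            class = "ensemble_stats")
}

#' @export
print.ensemble_stats <- function(x, ...) {
  n <- x$seq$n
  cat(sprintf("Ensemble statistics for %s: Z = %.6f\n", x$seq$seq, x$Z))
  bp <- which(x$pr_bp > 0, arr.ind = TRUE)
  if (nrow(bp)) {
    bp <- bp[order(-x$pr_bp[bp]), , drop = FALSE]
    show <- head(seq_len(nrow(bp)), 8)
    for (r in show)
      cat(sprintf("  Pr_bp(%d,%d) = %.6f\n", bp[r, 1], bp[r, 2],
                  x$pr_bp[bp[r, , drop = FALSE]]))
    if (nrow(bp) > length(show)) cat(sprintf("  ... %d more pairs\n",
                                             nrow(bp) - length(show)))
  } else cat("  no admissible base pair\n")
  invisible(x)
}

#' Probability that a region is unpaired (accessibility)
#'
#' `Pr_ss(i,j)` is the ensemble probability that no pair end falls inside
#' `[i, j]`; pairs spanning the region from outside remain allowed.  It is
#' obtained from the outside recursion for `Pr_bp` by substituting 1 (the
#' Boltzmann weight of the enforced single-stranded subsequence) for
#' `Qbp[i,j]`.
#'
#' @inheritParams partition_matrices
#' @param i,j region bounds, `1 <= i <= j <= n`.
#' @param stats optionally a precomputed [basepair_probabilities()] result
#'   for the same sequence and parameters.
#' @examples
#' unpaired_probability("GAAAC", 2, 4)  # 1
#' @export
unpaired_probability <- function(seq, i, j, cfg = fold_config(),
                                 rule = pair_rule(), model = energy_model(),
                                 stats = NULL) {
  if (is.null(stats)) stats <- basepair_probabilities(seq, cfg, rule, model)
  n <- stats$seq$n
  if (i < 1 || j > n || i > j) stop_input("need 1 <= i <= j <= n")
  prss_region(stats, i, j)
}

prss_region <- function(stats, i, j) {
  n <- stats$seq$n
  Q <- stats$Q
  Qget <- function(a, b) if (a > b) 1 else Q[a, b]
  v <- Qget(1, i - 1) * Qget(j + 1, n) / stats$Z
  if (i > 1 && j < n) {
    ps <- 1:(i - 1); qs <- (j + 1):n
    a <- vapply(ps, function(p) Qget(p + 1, i - 1), 0)
    b <- vapply(qs, function(q) Qget(j + 1, q - 1), 0)
    v <- v + stats$q_bp *
      as.numeric(a %*% stats$ratio[ps, qs, drop = FALSE] %*% b)
  }
  v
}

#' Dot-plot of base-pair probabilities
#'
#' Collects all base-pair probabilities above a display floor together with
#' the per-position unpaired probabilities, ready for TSV/JSON export (see
#' [format_dotplot()]) or base-graphics plotting.
#'
#' @param stats an [basepair_probabilities()] result.
#' @param threshold probability floor below which pairs are dropped
#'   (default 1e-6; mirrors the convention that tiny dots are invisible).
#' @return Object of class `rna_dotplot`: list with data frames `bp`
#'   (`i`, `j`, `prob`) and `unpaired` (`k`, `pr_u`).
#' @examples
#' dotplot(basepair_probabilities("GAAAC"))$bp
#' @export
dotplot <- function(stats, threshold = 1e-6) {
  n <- stats$seq$n
  idx <- which(stats$pr_bp > threshold, arr.ind = TRUE)
  bp <- data.frame(i = integer(0), j = integer(0), prob = numeric(0))
  if (nrow(idx)) {
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    bp <- data.frame(i = idx[, 1], j = idx[, 2], prob = stats$pr_bp[idx])
  }
  structure(list(bp = bp,
                 unpaired = data.frame(k = seq_len(n), pr_u = stats$pr_u),
                 n = n, seq = stats$seq, threshold = threshold),
            class = "rna_dotplot")
}

#' @export
print.rna_dotplot <- function(x, ...) {
  cat(sprintf("Dot-plot for %s: %d base-pair record(s) above %g\n",
              x$seq$seq, nrow(x$bp), x$threshold))
  if (nrow(x$bp)) print(x$bp, row.names = FALSE)
  invisible(x)
}

#' @export
plot.rna_dotplot <- function(x, ...) {
  n <- x$n
  graphics::plot(NULL, xlim = c(0.5, n + 0.5), ylim = c(n + 0.5, 0.5),
                 xlab = "j", ylab = "i", asp = 1,
                 main = sprintf("Base-pair probabilities: %s", x$seq$seq), ...)
  graphics::abline(0, -1, col = "grey80")
  if (nrow(x$bp))
    graphics::symbols(x$bp$j, x$bp$i, squares = sqrt(x$bp$prob),
                      inches = FALSE, add = TRUE, bg = "grey30", fg = NA)
  invisible(x)
}
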