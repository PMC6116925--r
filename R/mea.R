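# Maximum expected accuracy folding: structures are scored by the ensemble
# (gamma-weighted base-pair probabilities plus unpaired probabilities of free
# positions) instead of by their own energy.

#' Expected accuracy of a structure
#'
#' `acc(P) = sum over pairs of 2 * gamma * Pr_bp(i,j) + sum over unpaired
#' positions of Pr_u(k)`.  The factor 2 reflects that a pair covers two
#' positions; `gamma` scales pair against unpaired contributions.
#'
#' @param pairs the structure.
#' @param stats an [basepair_probabilities()] result for the same sequence
#'   and parameters.
#' @param gamma non-negative weight (default from the stats' config).
#' @examples
#' s <- basepair_probabilities("GAAAC")
#' accuracy(c(1, 5), s)  # 2 * Pr_bp(1,5) + 3
#' @export
accuracy <- function(pairs, stats, gamma = stats$cfg$gamma) {
  p <- as_pairs(pairs)
  n <- stats$seq$n
  if (nrow(p)) {
    if (max(p) > n) stop_input("pair index exceeds sequence length %d", n)
    adm <- stats$Qbp[p] > 0
    if (!all(adm))
      stop_input("pair (%d,%d) is not admissible for this ensemble",
                 p[!adm, 1][1], p[!adm, 2][1])
  }
  unpaired <- setdiff(seq_len(n), as.vector(p))
  2 * gamma * sum(stats$pr_bp[p]) + sum(stats$pr_u[unpaired])
}

#' MEA dynamic-programming matrix
#'
#' Nussinov-style recursion over expected accuracy:
#' `M[i,j] = max(M[i,j-1] + Pr_u(j), max_k M[i,k-1] + M[k+1,j-1] +
#' 2 * gamma * Pr_bp(k,j))` over admissible `k < j - l`; empty intervals
#' score 0, so `M[1,n]` is the maximal expected accuracy over the ensemble.
#'
#' @inheritParams accuracy
#' @param seq sequence (must match `stats`; taken from `stats` if omitted).
#' @param cfg a [fold_config()] (minimal loop; taken from `stats` if omitted).
#' @param rule a [pair_rule()] (taken from `stats` if omitted).
#' @return Object of class `mea_matrix`: list with `M`, `gamma`, `stats`.
#' @export
mea_matrix <- function(stats, gamma = stats$cfg$gamma, seq = stats$seq,
                       cfg = stats$cfg, rule = stats$rule) {
  seq <- rna_seq(seq, concatenated = TRUE)
  if (seq$seq != stats$seq$seq)
    stop_input("sequence does not match the ensemble statistics")
  n <- seq$n
  l <- cfg$min_loop
  M <- matrix(0, max(n, 1), max(n, 1))
  if (n) for (i in 1:n) M[i, i] <- stats$pr_u[i]
  if (n >= 2) for (span in 1:(n - 1)) for (i in 1:(n - span)) {
    j <- i + span
    best <- M[i, j - 1] + stats$pr_u[j]
    hi <- j - l - 1
    if (hi >= i) for (k in i:hi) if (stats$Qbp[k, j] > 0)
      best <- max(best, mat_get0(M, i, k - 1) + mat_get0(M, k + 1, j - 1) +
                    2 * gamma * stats$pr_bp[k, j])
    M[i, j] <- best
  }
  structure(list(M = M, gamma = gamma, stats = stats, seq = seq,
                 cfg = cfg, rule = rule),
            class = "mea_matrix")
}

#' @export
print.mea_matrix <- function(x, ...) {
  n <- x$seq$n
  cat(sprintf("MEA matrix for %s (gamma = %g): M[1,%d] = %.6f\n",
              x$seq$seq, x$gamma, n, if (n) x$M[1, n] else 0))
  invisible(x)
}

#' Maximum-expected-accuracy structures
#'
#' Computes the ensemble statistics, fills the MEA matrix and enumerates
#' the optimal plus all suboptimal structures whose accuracy lies within
#' `delta` of the optimum, through the shared Wuchty-style enumerator over
#' real-valued scores (case admissibility compared with absolute tolerance
#' 1e-9).
#'
#' @inheritParams partition_matrices
#' @param gamma non-negative weight of pair versus unpaired probabilities.
#' @param delta non-negative absolute accuracy range below the optimum.
#' @param max_structures emission cap.
#' @return List of `traceback_entry` objects (scores are `acc` values),
#'   sorted by score descending; the filled `mea_matrix` is attached as
#'   attribute `"matrix"`.
#' @examples
#' mea_structure("GAAAC")[[1]]$db  # "(...)"
#' @export
mea_structure <- function(seq, cfg = fold_config(), rule = pair_rule(),
                          model = energy_model(), gamma = cfg$gamma,
                          delta = cfg$delta, max_structures = Inf) {
  if (delta < 0) stop_input("delta must be >= 0")
  stats <- basepair_probabilities(seq, cfg, rule, model)
  mm <- mea_matrix(stats, gamma = gamma)
  seq <- mm$seq
  n <- seq$n
  l <- cfg$min_loop
  expand <- function(i, j) {
    cases <- list(list(pair = NULL, ivs = list(c(i, j - 1)),
                       ds = stats$pr_u[j]))
    hi <- j - l - 1
    if (hi >= i) for (k in i:hi) if (stats$Qbp[k, j] > 0)
      cases[[length(cases) + 1L]] <-
        list(pair = c(k, j), ivs = list(c(i, k - 1), c(k + 1, j - 1)),
             ds = 2 * gamma * stats$pr_bp[k, j])
    cases
  }
  opt <- if (n) mm$M[1, n] else 0
  raw <- subopt_enumerate(n, mm$M, expand, threshold = opt - delta,
                          max_structures = max_structures)
  entries <- lapply(raw, function(e) {
    structure(list(pairs = e$pairs, score = e$score,
                   db = render_dotbracket(e$pairs, n), path = NULL),
              class = "traceback_entry")
  })
  entries <- entries[order(-vapply(entries, `[[`, 0, "score"))]
  attr(entries, "matrix") <- mm
  entries
}
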