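# Base-pair maximization (Nussinov) in two recursion variants, optimal
# traceback, and a generic Wuchty-style suboptimal enumerator that is shared
# with the MEA module (real-valued scores).

mat_get0 <- function(M, i, j) if (i > j) 0 else M[i, j]

#' Nussinov score matrix
#'
#' Fills the table `N` in which `N[i, j]` is the maximal number of base
#' pairs formable by subsequence `i..j`.  Two recursion variants are
#' available.  The `"unique"` variant decomposes on the pairing state of the
#' last position (each structure has exactly one derivation):
#' `N[i,j] = max(N[i,j-1], max_k N[i,k-1] + N[k+1,j-1] + 1)` over
#' complementary `k < j - l`.  The `"ambiguous"` variant uses four cases
#' (`i` unpaired; `j` unpaired; pair `(i,j)`; bipartition) and computes the
#' same values but admits several derivations per structure, which
#' duplicates structures under suboptimal enumeration.
#'
#' @inheritParams validate_structure
#' @param variant `"unique"` or `"ambiguous"` (overrides `cfg$variant`).
#' @return Object of class `score_matrix`: list with `N`, `variant`, `seq`,
#'   `cfg`, `rule`.
#' @examples
#' nussinov_matrix("GGGAAACCC")$N[1, 9]  # 3
#' @export
nussinov_matrix <- function(seq, cfg = fold_config(), rule = pair_rule(),
                            variant = cfg$variant) {
  variant <- match.arg(variant, c("unique", "ambiguous"))
  seq <- rna_seq(seq, concatenated = TRUE)
  n <- seq$n
  l <- cfg$min_loop
  comp <- pairable_matrix(seq, rule)
  N <- matrix(0, n, n)
  if (n >= 2) for (span in 1:(n - 1)) for (i in 1:(n - span)) {
    j <- i + span
    if (variant == "unique") {
      best <- N[i, j - 1]
      hi <- j - l - 1
      if (hi >= i) for (k in i:hi) if (comp[k, j])
        best <- max(best, mat_get0(N, i, k - 1) + mat_get0(N, k + 1, j - 1) + 1)
    } else {
      best <- max(mat_get0(N, i + 1, j), N[i, j - 1])
      if (comp[i, j] && i + l < j)
        best <- max(best, mat_get0(N, i + 1, j - 1) + 1)
      if (i + 1 <= j - 2) for (k in (i + 1):(j - 2))
        best <- max(best, N[i, k] + N[k + 1, j])
    }
    N[i, j] <- best
  }
  structure(list(N = N, variant = variant, seq = seq, cfg = cfg, rule = rule),
            class = "score_matrix")
}

#' @rdname nussinov_matrix
#' @export
nussinov_matrix_ambiguous <- function(seq, cfg = fold_config(),
                                      rule = pair_rule()) {
  nussinov_matrix(seq, cfg, rule, variant = "ambiguous")
}

#' @export
print.score_matrix <- function(x, ...) {
  n <- x$seq$n
  cat(sprintf("Nussinov matrix (%s variant) for %s: N[1,%d] = %s\n",
              x$variant, x$seq$seq, n,
              if (n) format(x$N[1, n]) else "0"))
  invisible(x)
}

#' Traceback of one optimal structure
#'
#' Re-derives which recursion case produced each visited cell, starting at
#' `N[1, n]`.  Ties are broken deterministically: cases are evaluated in the
#' order they appear in the recursion (unpaired case first), and within the
#' pairing case the smallest admissible `k` wins.
#'
#' @param seq sequence.
#' @param N a `score_matrix` from [nussinov_matrix()] (computed if missing).
#' @inheritParams validate_structure
#' @return Object of class `traceback_entry`: list with `pairs`, `score`,
#'   `db` (dot-bracket) and `path` (data frame of `(i, j, case, k)` steps).
#' @examples
#' traceback_optimal("GAAAC")$pairs
#' @export
traceback_optimal <- function(seq, N = NULL, cfg = fold_config(),
                              rule = pair_rule()) {
  if (is.null(N)) N <- nussinov_matrix(seq, cfg, rule)
  seq <- N$seq; cfg <- N$cfg; rule <- N$rule
  M <- N$N
  l <- cfg$min_loop
  comp <- pairable_matrix(seq, rule)
  pairs <- list()
  path <- list()
  stack <- if (seq$n >= 1) list(c(1, seq$n)) else list()
  tol <- 1e-9
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    if (i >= j) next
    v <- M[i, j]
    if (v == 0) next
    step <- NULL
    if (N$variant == "unique") {
      if (abs(v - M[i, j - 1]) < tol) {
        step <- list(i = i, j = j, case = "unpaired", k = NA_integer_)
        stack[[length(stack) + 1L]] <- c(i, j - 1)
      } else {
        for (k in i:(j - l - 1)) {
          if (!comp[k, j]) next
          if (abs(v - (mat_get0(M, i, k - 1) + mat_get0(M, k + 1, j - 1) + 1)) < tol) {
            step <- list(i = i, j = j, case = "pair", k = k)
            pairs[[length(pairs) + 1L]] <- c(k, j)
            stack[[length(stack) + 1L]] <- c(i, k - 1)
            stack[[length(stack) + 1L]] <- c(k + 1, j - 1)
            break
          }
        }
      }
    } else {
      if (abs(v - mat_get0(M, i + 1, j)) < tol) {
        step <- list(i = i, j = j, case = "i-unpaired", k = NA_integer_)
        stack[[length(stack) + 1L]] <- c(i + 1, j)
      } else if (abs(v - M[i, j - 1]) < tol) {
        step <- list(i = i, j = j, case = "j-unpaired", k = NA_integer_)
        stack[[length(stack) + 1L]] <- c(i, j - 1)
      } else if (comp[i, j] && i + l < j &&
                 abs(v - (mat_get0(M, i + 1, j - 1) + 1)) < tol) {
        step <- list(i = i, j = j, case = "pair", k = i)
        pairs[[length(pairs) + 1L]] <- c(i, j)
        stack[[length(stack) + 1L]] <- c(i + 1, j - 1)
      } else if (i + 1 <= j - 2) {
        for (k in (i + 1):(j - 2)) {
          if (abs(v - (M[i, k] + M[k + 1, j])) < tol) {
            step <- list(i = i, j = j, case = "bipartition", k = k)
            stack[[length(stack) + 1L]] <- c(i, k)
            stack[[length(stack) + 1L]] <- c(k + 1, j)
            break
          }
        }
      }
    }
    if (is.null(step))
      stop("inconsistent score matrix: no recursion case reproduces N[",
           i, ",", j, "]")
    path[[length(path) + 1L]] <- step
  }
  p <- as_pairs(pairs)
  structure(list(pairs = p,
                 score = if (seq$n) M[1, seq$n] else 0,
                 db = render_dotbracket(p, seq$n),
                 path = do.call(rbind, lapply(path, as.data.frame))),
            class = "traceback_entry")
}

#' @export
print.traceback_entry <- function(x, ...) {
  cat(sprintf("%s  score %.6g  (%d pairs)\n", x$db, x$score, nrow(x$pairs)))
  invisible(x)
}

# Generic Wuchty-style enumerator over partial tracebacks.
#
# Works on a stack of states (remaining intervals, collected pairs, score so
# far); a state is expanded only while its optimistic potential (score so far
# plus the matrix optimum of every remaining interval) stays within
# `threshold`.  `expand(i, j)` returns the recursion cases for one interval:
# list(pairs = NULL or c(k, j), ivs = list of sub-intervals, ds = score delta).
subopt_enumerate <- function(n, M, expand, threshold, tol = 1e-9,
                             max_structures = Inf) {
  out <- list()
  if (n == 0) return(list(list(pairs = as_pairs(NULL), score = 0)))
  pot_of <- function(ivs) {
    s <- 0
    for (iv in ivs) s <- s + mat_get0(M, iv[1], iv[2])
    s
  }
  stack <- list(list(ivs = list(c(1, n)), pairs = list(), g = 0))
  while (length(stack) && length(out) < max_structures) {
    st <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (!length(st$ivs)) {
      out[[length(out) + 1L]] <- list(pairs = as_pairs(st$pairs), score = st$g)
      next
    }
    iv <- st$ivs[[length(st$ivs)]]
    rest <- st$ivs[-length(st$ivs)]
    if (iv[1] > iv[2]) {
      stack[[length(stack) + 1L]] <- list(ivs = rest, pairs = st$pairs, g = st$g)
      next
    }
    rest_pot <- pot_of(rest)
    for (ch in expand(iv[1], iv[2])) {
      ivs2 <- rest
      for (s2 in ch$ivs) if (s2[1] <= s2[2]) ivs2[[length(ivs2) + 1L]] <- s2
      g2 <- st$g + ch$ds
      if (g2 + rest_pot + pot_of(ch$ivs) >= threshold - tol) {
        pairs2 <- st$pairs
        if (!is.null(ch$pair)) pairs2[[length(pairs2) + 1L]] <- ch$pair
        stack[[length(stack) + 1L]] <- list(ivs = ivs2, pairs = pairs2, g = g2)
      }
    }
  }
  out
}

#' Enumerate (sub)optimal structures
#'
#' Wuchty-style enumeration of every structure whose pair count is at least
#' `N[1,n] - delta`, implemented as a work-stack over partial tracebacks
#' (interval lists plus partial structure) rather than call-stack recursion.
#' With the `"unique"` recursion each structure is emitted exactly once;
#' with the `"ambiguous"` recursion the same structure may be derived — and
#' is then reported — multiple times.
#'
#' @inheritParams nussinov_matrix
#' @param delta non-negative score range below the optimum.
#' @param max_structures stop after this many emissions (safety valve for
#'   the ambiguous variant, whose derivation count can explode).
#' @return List of `traceback_entry` objects sorted by score, descending.
#' @examples
#' length(enumerate_suboptimal("GGGAAACCC", delta = 3))  # 20: whole ensemble
#' @export
enumerate_suboptimal <- function(seq, cfg = fold_config(), rule = pair_rule(),
                                 delta = cfg$delta, variant = cfg$variant,
                                 max_structures = Inf) {
  if (delta < 0) stop_input("delta must be >= 0")
  variant <- match.arg(variant, c("unique", "ambiguous"))
  nm <- nussinov_matrix(seq, cfg, rule, variant = variant)
  seq <- nm$seq
  n <- seq$n
  l <- cfg$min_loop
  comp <- pairable_matrix(seq, rule)
  M <- nm$N
  opt <- if (n) M[1, n] else 0
  expand <- if (variant == "unique") {
    function(i, j) {
      cases <- list(list(pair = NULL, ivs = list(c(i, j - 1)), ds = 0))
      hi <- j - l - 1
      if (hi >= i) for (k in i:hi) if (comp[k, j])
        cases[[length(cases) + 1L]] <-
          list(pair = c(k, j), ivs = list(c(i, k - 1), c(k + 1, j - 1)), ds = 1)
      cases
    }
  } else {
    function(i, j) {
      cases <- list(list(pair = NULL, ivs = list(c(i + 1, j)), ds = 0),
                    list(pair = NULL, ivs = list(c(i, j - 1)), ds = 0))
      if (comp[i, j] && i + l < j)
        cases[[length(cases) + 1L]] <-
          list(pair = c(i, j), ivs = list(c(i + 1, j - 1)), ds = 1)
      if (i + 1 <= j - 2) for (k in (i + 1):(j - 2))
        cases[[length(cases) + 1L]] <-
          list(pair = NULL, ivs = list(c(i, k), c(k + 1, j)), ds = 0)
      cases
    }
  }
  raw <- subopt_enumerate(n, M, expand, threshold = opt - delta,
                          max_structures = max_structures)
  entries <- lapply(raw, function(e) {
    structure(list(pairs = e$pairs, score = e$score,
                   db = render_dotbracket(e$pairs, n), path = NULL),
              class = "traceback_entry")
  })
  entries[order(-vapply(entries, `[[`, 0, "score"))]
}

#' Minimum energy under the simplified model
#'
#' For negative `e_bp` the energy-minimal structure is the pair-maximal one,
#' so the minimum of `E(P)` over the ensemble is `N[1,n] * e_bp`.
#'
#' @inheritParams nussinov_matrix
#' @param model an [energy_model()].
#' @examples
#' mfe("GGGAAACCC")  # -3
#' @export
mfe <- function(seq, cfg = fold_config(), rule = pair_rule(),
                model = energy_model()) {
  nm <- nussinov_matrix(seq, cfg, rule, variant = "unique")
  n <- nm$seq$n
  (if (n) nm$N[1, n] else 0) * model$e_bp
}
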