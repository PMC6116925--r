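#' @useDynLib rnakit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames
#' @importFrom utils head tail write.table
NULL

RNA_BASES <- c("A", "C", "G", "U")

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("rnakit_input_error", "error")))
}

stop_guard <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("rnakit_guard_error", "error")))
}

#' RNA sequence object
#'
#' Normalizes and validates an RNA sequence: whitespace is stripped, letters
#' are uppercased and `T` is mapped to `U`.  Residues must come from
#' `{A,C,G,U}`; the linker character `X` is admitted only for concatenated
#' (cofold) sequences.  Positions are 1-based throughout the package.
#'
#' @param x a single character string, or an existing `rna_seq` object
#'   (returned unchanged).
#' @param concatenated logical; set `TRUE` for concatenated duplex sequences
#'   that may contain the non-pairing linker character `X`.
#' @return An object of class `rna_seq` with fields `seq` (string),
#'   `residues` (character vector), `n` (length) and `concatenated`.
#' @examples
#' rna_seq("gaaac")     # normalized to GAAAC
#' rna_seq("GATTACA")   # T is read as U
#' @export
rna_seq <- function(x, concatenated = FALSE) {
  if (inherits(x, "rna_seq")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop_input("an RNA sequence must be a single character string")
  s <- chartr("T", "U", toupper(gsub("[[:space:]]", "", x)))
  res <- if (nzchar(s)) strsplit(s, "", fixed = TRUE)[[1]] else character(0)
  allowed <- c(RNA_BASES, if (concatenated) "X")
  bad <- which(!res %in% allowed)
  if (length(bad))
    stop_input("illegal residue '%s' at position %d (allowed: %s)",
               res[bad[1]], bad[1], paste(allowed, collapse = ","))
  structure(list(seq = s, residues = res, n = length(res),
                 concatenated = concatenated),
            class = "rna_seq")
}

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("RNA sequence (n = %d%s)\n  5'-%s-3'\n", x$n,
              if (x$concatenated) ", concatenated" else "", x$seq))
  invisible(x)
}

#' Base-pair complementarity rule
#'
#' Three rule sets are supported: `"wc-gu"` (Watson-Crick plus the G-U
#' wobble; the default), `"wc"` (Watson-Crick only) and `"any"` (every
#' base-letter combination pairs; this realizes the sequence-independent
#' structure space whose growth rate is about 2.3 per nucleotide).  The
#' linker character `X` never pairs under any rule.
#'
#' @param mode one of `"wc-gu"`, `"wc"`, `"any"`.
#' @return An object of class `pair_rule`.
#' @export
pair_rule <- function(mode = c("wc-gu", "wc", "any")) {
  mode <- match.arg(mode)
  pairs <- switch(mode,
    "wc-gu" = list(c("A", "U"), c("C", "G"), c("G", "U")),
    "wc"    = list(c("A", "U"), c("C", "G")),
    "any"   = {
      p <- list()
      for (a in RNA_BASES) for (b in RNA_BASES)
        if (a <= b) p[[length(p) + 1L]] <- c(a, b)
      p
    })
  keys <- vapply(pairs, function(p) paste(sort(p), collapse = ""), "")
  structure(list(mode = mode, pairs = pairs, keys = keys),
            class = "pair_rule")
}

#' Test base complementarity
#'
#' @param a,b single base letters.
#' @param rule a [pair_rule()].
#' @return `TRUE` iff the unordered pair `{a, b}` is allowed under `rule`.
#'   `X` is never complementary to anything.
#' @examples
#' is_complementary("G", "C")                    # TRUE
#' is_complementary("G", "U", pair_rule("wc"))   # FALSE (wobble excluded)
#' @export
is_complementary <- function(a, b, rule = pair_rule()) {
  if (a == "X" || b == "X") return(FALSE)
  if (rule$mode == "any") return(a %in% RNA_BASES && b %in% RNA_BASES)
  paste(sort(c(a, b)), collapse = "") %in% rule$keys
}

# n x n logical matrix: entry [i, j] TRUE iff residues i and j may pair
# (complementarity only; the minimal-loop constraint is applied by callers)
pairable_matrix <- function(seq, rule = pair_rule()) {
  seq <- rna_seq(seq, concatenated = TRUE)
  n <- seq$n
  m <- matrix(FALSE, n, n)
  if (n == 0) return(m)
  if (rule$mode == "any") {
    ok <- seq$residues %in% RNA_BASES
    m <- outer(ok, ok, `&`)
  } else {
    for (key in rule$keys) {
      a <- substr(key, 1, 1); b <- substr(key, 2, 2)
      ia <- seq$residues == a; ib <- seq$residues == b
      m <- m | outer(ia, ib, `&`) | outer(ib, ia, `&`)
    }
  }
  m
}

#' Simplified per-base-pair energy model
#'
#' Every base pair contributes the same energy `e_bp` (default -1,
#' dimensionless), so a structure with `|P|` pairs has energy `|P| * e_bp`.
#' `rt` is the product of the Boltzmann (or gas) constant and temperature;
#' both are left dimensionless because the model fixes no unit system.  The
#' Boltzmann weight of one pair is `q_bp = exp(-e_bp / rt)`.
#'
#' @param e_bp energy per base pair.
#' @param rt positive temperature factor (k_B*T or R*T).
#' @return An object of class `energy_model` with fields `e_bp`, `rt`, `q_bp`.
#' @export
energy_model <- function(e_bp = -1, rt = 1) {
  if (!is.numeric(rt) || rt <= 0) stop_input("rt must be > 0")
  structure(list(e_bp = e_bp, rt = rt, q_bp = exp(-e_bp / rt)),
            class = "energy_model")
}

#' Folding configuration
#'
#' Bundles the tunable parameters shared by the folding, ensemble, MEA and
#' interaction routines.
#'
#' @param min_loop minimal loop length `l`: a pair `(i, j)` is admissible
#'   only if `j - i > l`, i.e. it encloses at least `l` positions (default 3).
#' @param variant recursion variant for base-pair maximization: `"unique"`
#'   (one derivation per structure) or `"ambiguous"`.
#' @param delta non-negative suboptimal score range.
#' @param gamma non-negative MEA weight for base-pair versus unpaired
#'   probabilities (default 1).
#' @param max_gap maximal distance between consecutive intermolecular base
#'   pairs on either molecule in accessibility-based prediction (default 15;
#'   `Inf` for unbounded).
#' @param linker_length length of the non-pairing linker used by [cofold()]
#'   (default `min_loop + 1`, which guarantees the concatenated sequence ends
#'   may pair).
#' @return An object of class `fold_config`.
#' @export
fold_config <- function(min_loop = 3, variant = c("unique", "ambiguous"),
                        delta = 0, gamma = 1, max_gap = 15,
                        linker_length = min_loop + 1) {
  variant <- match.arg(variant)
  if (min_loop < 0 || min_loop != round(min_loop))
    stop_input("min_loop must be a non-negative integer")
  if (delta < 0) stop_input("delta must be >= 0")
  if (gamma < 0) stop_input("gamma must be >= 0")
  if (!(is.infinite(max_gap) || (max_gap >= 1 && max_gap == round(max_gap))))
    stop_input("max_gap must be a positive integer or Inf")
  if (linker_length < 1 || linker_length != round(linker_length))
    stop_input("linker_length must be a positive integer")
  structure(list(min_loop = min_loop, variant = variant, delta = delta,
                 gamma = gamma, max_gap = max_gap,
                 linker_length = linker_length),
            class = "fold_config")
}

# normalize a structure to a 2-column integer matrix with i < j, sorted by i
as_pairs <- function(p) {
  if (is.null(p) || (is.matrix(p) && nrow(p) == 0) || length(p) == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  if (is.list(p) && !is.matrix(p)) p <- do.call(rbind, p)
  if (is.numeric(p) && !is.matrix(p) && length(p) == 2) p <- matrix(p, 1, 2)
  if (!is.matrix(p) || ncol(p) != 2)
    stop_input("a structure must be a 2-column matrix of (i, j) pairs")
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  storage.mode(p) <- "integer"
  dimnames(p) <- list(NULL, c("i", "j"))
  p
}

#' Validate a secondary structure
#'
#' Checks the four defining constraints of a nested secondary structure:
#' each position in at most one pair, no crossing pairs, complementary ends
#' under the active pair rule, and the minimal-loop constraint `j - i > l`.
#'
#' @param seq sequence ([rna_seq()] or string).
#' @param pairs structure as a 2-column matrix of `(i, j)` pairs (anything
#'   accepted by the internal normalizer: list of pairs, single `c(i, j)`...).
#' @param cfg a [fold_config()].
#' @param rule a [pair_rule()].
#' @return Character vector of human-readable violations; empty if the
#'   structure is valid.  Indices outside `1..n` raise an error.
#' @examples
#' validate_structure("GAAAC", c(1, 5))            # character(0)
#' validate_structure("GAAAC", c(1, 4))            # loop-length violation
#' @export
validate_structure <- function(seq, pairs, cfg = fold_config(),
                               rule = pair_rule()) {
  seq <- rna_seq(seq, concatenated = TRUE)
  p <- as_pairs(pairs)
  if (nrow(p) && (min(p) < 1 || max(p) > seq$n))
    stop_input("pair index out of range 1..%d", seq$n)
  out <- character(0)
  pname <- function(r) sprintf("(%d,%d)", r[1], r[2])
  if (nrow(p) == 0) return(out)
  dup <- p[, 1] == p[, 2]
  if (any(dup))
    out <- c(out, sprintf("self-pair: %s", apply(p[dup, , drop = FALSE], 1, pname)))
  idx <- as.vector(p)
  if (anyDuplicated(idx))
    out <- c(out, sprintf("position %d occurs in more than one pair",
                          unique(idx[duplicated(idx)])))
  if (nrow(p) > 1) {
    for (a in seq_len(nrow(p) - 1)) for (b in (a + 1):nrow(p)) {
      i <- p[a, 1]; j <- p[a, 2]; q1 <- p[b, 1]; q2 <- p[b, 2]
      if (i < q1 && q1 < j && j < q2)
        out <- c(out, sprintf("crossing pairs: %s and %s",
                              pname(p[a, ]), pname(p[b, ])))
    }
  }
  comp <- pairable_matrix(seq, rule)
  for (a in seq_len(nrow(p))) {
    i <- p[a, 1]; j <- p[a, 2]
    if (i == j) next
    if (!comp[i, j])
      out <- c(out, sprintf("non-complementary pair %s: %s-%s",
                            pname(p[a, ]), seq$residues[i], seq$residues[j]))
    if (j - i <= cfg$min_loop)
      out <- c(out, sprintf("loop-length violation at %s: j - i = %d is not > %d",
                            pname(p[a, ]), j - i, cfg$min_loop))
  }
  out
}

#' Structure energy
#'
#' Under the simplified model the energy of a structure is just the number
#' of its pairs times the per-pair energy, `E(P) = |P| * e_bp`.
#'
#' @inheritParams validate_structure
#' @param model an [energy_model()].
#' @return Numeric energy.
#' @export
structure_energy <- function(pairs, model = energy_model()) {
  nrow(as_pairs(pairs)) * model$e_bp
}

#' Boltzmann weight of a structure
#'
#' `exp(-E(P) / RT) = q_bp^|P|`, the product of the individual base-pair
#' weights.
#'
#' @inheritParams structure_energy
#' @return Positive real weight.
#' @export
boltzmann_weight <- function(pairs, model = energy_model()) {
  exp(-structure_energy(pairs, model) / model$rt)
}

#' Parse a dot-bracket string
#'
#' `.` marks an unpaired position, `(` the opening and `)` the closing end
#' of a base pair.  (The extended cofold alphabet with `[]` and `X` is
#' produced by [cofold()] but parsed here as well.)
#'
#' @param s dot-bracket string.
#' @return 2-column integer matrix of pairs, sorted by opening position.
#' @examples
#' parse_dotbracket("((...))")
#' @export
parse_dotbracket <- function(s) {
  if (!is.character(s) || length(s) != 1L)
    stop_input("dot-bracket input must be a single string")
  ch <- if (nzchar(s)) strsplit(s, "", fixed = TRUE)[[1]] else character(0)
  bad <- setdiff(unique(ch), c(".", "(", ")", "[", "]", "X"))
  if (length(bad))
    stop_input("illegal dot-bracket character '%s'", bad[1])
  pairs <- list()
  stacks <- list("(" = integer(0), "[" = integer(0))
  close_of <- c(")" = "(", "]" = "[")
  for (k in seq_along(ch)) {
    c0 <- ch[k]
    if (c0 %in% c("(", "[")) {
      stacks[[c0]] <- c(stacks[[c0]], k)
    } else if (c0 %in% c(")", "]")) {
      op <- close_of[[c0]]
      if (!length(stacks[[op]]))
        stop_input("unbalanced dot-bracket string: unmatched '%s' at position %d",
                   c0, k)
      i <- tail(stacks[[op]], 1)
      stacks[[op]] <- head(stacks[[op]], -1)
      pairs[[length(pairs) + 1L]] <- c(i, k)
    }
  }
  if (length(stacks[["("]]) || length(stacks[["["]]))
    stop_input("unbalanced dot-bracket string: unclosed opening bracket")
  as_pairs(pairs)
}

#' Render a structure as a dot-bracket string
#'
#' @param pairs structure (see [validate_structure()]).
#' @param n sequence length.
#' @return Dot-bracket string of length `n`.
#' @export
render_dotbracket <- function(pairs, n) {
  p <- as_pairs(pairs)
  ch <- rep(".", n)
  if (nrow(p)) {
    if (max(p) > n) stop_input("pair index exceeds sequence length %d", n)
    ch[p[, 1]] <- "("
    ch[p[, 2]] <- ")"
  }
  paste(ch, collapse = "")
}

#' Exhaustively enumerate the structure ensemble
#'
#' Ground-truth oracle: generates every nested secondary structure of the
#' sequence exactly once (including the empty structure) by backtracking on
#' the *first* position of each interval — position `i` is either unpaired
#' or paired with an admissible `k`, splitting the interval into the
#' enclosed part and the part right of `k`.  This is the mirror image of the
#' last-position decomposition used by the dynamic programs it validates.
#'
#' The structure space grows roughly as 2.3^n, so a guard limit on the
#' sequence length bounds the exponential cost.
#'
#' @inheritParams validate_structure
#' @param limit guard on sequence length (default 25); raise deliberately
#'   for longer sequences.
#' @return A list of pair matrices of class `structure_ensemble`.
#' @examples
#' length(enumerate_structures("GGGAAACCC"))  # 20
#' @export
enumerate_structures <- function(seq, cfg = fold_config(),
                                 rule = pair_rule(), limit = 25) {
  seq <- rna_seq(seq, concatenated = TRUE)
  n <- seq$n
  if (n > limit)
    stop_guard("sequence length %d exceeds the enumeration guard (%d)", n, limit)
  l <- cfg$min_loop
  comp <- pairable_matrix(seq, rule)
  memo <- new.env(parent = emptyenv())
  empty <- matrix(integer(0), 0, 2)
  rec <- function(i, j) {
    if (i > j) return(list(empty))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1, j)                       # i unpaired
    if (i + l + 1 <= j) {
      for (k in (i + l + 1):j) {
        if (!comp[i, k]) next
        inner <- rec(i + 1, k - 1)
        outer_ <- rec(k + 1, j)
        for (pi in inner) for (po in outer_)
          out[[length(out) + 1L]] <- rbind(c(i, k), pi, po)
      }
    }
    memo[[key]] <- out
    out
  }
  res <- lapply(rec(1, n), as_pairs)
  structure(res, class = "structure_ensemble",
            seq = seq, cfg = cfg, rule = rule)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  s <- attr(x, "seq")
  cat(sprintf("Structure ensemble of %s: %d structures\n", s$seq, length(x)))
  show <- min(length(x), 10L)
  for (k in seq_len(show))
    cat(sprintf("  %s  (%d pairs)\n", render_dotbracket(x[[k]], s$n),
                nrow(x[[k]])))
  if (length(x) > show) cat(sprintf("  ... %d more\n", length(x) - show))
  invisible(x)
}
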