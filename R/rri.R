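# The three RNA-RNA interaction prediction paradigms under the simplified
# model.  Molecules interact in antiparallel orientation, so the second
# sequence is handled through its reversed view S2rev[j] = S2[m - j + 1];
# all reported coordinates are mapped back to the original 5'->3' numbering
# of both molecules.

#' Duplex of two RNA molecules
#'
#' @param seq1,seq2 the two sequences (strings or [rna_seq()]).
#' @return Object of class `duplex_pair`: `s1`, `s2`, the reversed view
#'   `s2rev`, and lengths `n`, `m`.
#' @export
duplex_pair <- function(seq1, seq2) {
  s1 <- rna_seq(seq1)
  s2 <- rna_seq(seq2)
  if (s1$n == 0 || s2$n == 0) stop_input("both sequences must be non-empty")
  s2rev <- rna_seq(paste(rev(s2$residues), collapse = ""))
  structure(list(s1 = s1, s2 = s2, s2rev = s2rev, n = s1$n, m = s2$n),
            class = "duplex_pair")
}

#' @export
print.duplex_pair <- function(x, ...) {
  cat(sprintf("RNA duplex: S1 (n = %d) 5'-%s-3'  /  S2 (m = %d) 5'-%s-3'\n",
              x$n, x$s1$seq, x$m, x$s2$seq))
  invisible(x)
}

# complementarity between S1 positions and reversed-view S2 positions
duplex_comp <- function(pair, rule = pair_rule()) {
  outer(pair$s1$residues, pair$s2rev$residues,
        Vectorize(function(a, b) is_complementary(a, b, rule)))
}

#' Hybridization-only interaction prediction
#'
#' Maximizes the number of intermolecular base pairs while ignoring all
#' intramolecular structure, via the prefix recursion (a global-alignment
#' scheme with pair scoring and no gap cost):
#' `H[i,j] = max(H[i-1,j-1] + [S1_i pairs S2rev_j], H[i-1,j], H[i,j-1])`
#' with zero initialization.  All distinct optimal intermolecular pair sets
#' are recovered by traceback and reported in original coordinates.
#'
#' @param pair a [duplex_pair()].
#' @param rule a [pair_rule()].
#' @param model an [energy_model()] used only to attach energies
#'   (`count * e_bp`) to the reported interactions.
#' @return List with `H` (the `(n+1) x (m+1)` matrix, row/col 1 are the
#'   zero-initialized borders), `optimum` (`H[n,m]`), and `results`, a list
#'   of `interaction_result` objects.
#' @examples
#' hybrid_only(duplex_pair("CCC", "GGG"))$optimum  # 3
#' @export
hybrid_only <- function(pair, rule = pair_rule(), model = energy_model()) {
  n <- pair$n; m <- pair$m
  comp <- duplex_comp(pair, rule)
  H <- matrix(0, n + 1, m + 1)
  for (i in 1:n) for (j in 1:m)
    H[i + 1, j + 1] <- max(H[i, j] + as.integer(comp[i, j]),
                           H[i, j + 1], H[i + 1, j])
  # all distinct optimal pair sets per cell, memoized and deduplicated
  memo <- new.env(parent = emptyenv())
  sets_at <- function(i, j) {
    if (i == 0 || j == 0) return(list(matrix(integer(0), 0, 2)))
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    v <- H[i + 1, j + 1]
    out <- list()
    if (comp[i, j] && v == H[i, j] + 1)
      out <- c(out, lapply(sets_at(i - 1, j - 1),
                           function(s) rbind(s, c(i, j))))
    if (v == H[i, j + 1]) out <- c(out, sets_at(i - 1, j))
    if (v == H[i + 1, j]) out <- c(out, sets_at(i, j - 1))
    keys <- vapply(out, function(s) paste(s, collapse = ","), "")
    out <- out[!duplicated(keys)]
    memo[[key]] <- out
    out
  }
  sets <- sets_at(n, m)
  results <- lapply(sets, function(s)
    interaction_result_from_pairs(pair, s, energy = nrow(s) * model$e_bp))
  ord <- order(vapply(results, function(r) r$site1[1] %||% n + 1, 0),
               vapply(results, function(r) r$site2[1] %||% m + 1, 0))
  list(H = H, optimum = H[n + 1, m + 1], results = results[ord])
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

# Build an interaction_result from pairs given in (S1 position, reversed-view
# S2 position) space; converts to original 5'->3' coordinates of S2.
interaction_result_from_pairs <- function(pair, rev_pairs, energy,
                                          d = NA_real_, de1 = 0, de2 = 0) {
  m <- pair$m
  if (nrow(rev_pairs)) {
    orig <- cbind(i = rev_pairs[, 1], j = m - rev_pairs[, 2] + 1L)
    orig <- orig[order(orig[, 1]), , drop = FALSE]
    site1 <- range(orig[, 1])
    site2 <- range(orig[, 2])
  } else {
    orig <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j")))
    site1 <- site2 <- c(NA_integer_, NA_integer_)
  }
  structure(list(site1 = site1, site2 = site2, pairs = orig,
                 energy = energy, d = d, de1 = de1, de2 = de2,
                 favorable = is.finite(energy) && energy < 0,
                 pair = pair),
            class = "interaction_result")
}

#' @export
print.interaction_result <- function(x, ...) {
  if (!nrow(x$pairs)) {
    cat("Interaction: none (no intermolecular base pair)\n")
    return(invisible(x))
  }
  cat(sprintf("Interaction: S1[%d..%d] with S2[%d..%d], %d pair(s), energy %.6g%s\n",
              x$site1[1], x$site1[2], x$site2[1], x$site2[2], nrow(x$pairs),
              x$energy, if (x$favorable) " (favorable)" else ""))
  if (!is.na(x$d))
    cat(sprintf("  D = %.6g, deltaE1 = %.6g, deltaE2 = %.6g\n",
                x$d, x$de1, x$de2))
  cat(format_duplex_ascii(x), sep = "\n")
  invisible(x)
}

# Three-line ASCII rendering of the intermolecular pairs:
# S1 5'->3' on top, pairing bars, S2 3'->5' at the bottom.
format_duplex_ascii <- function(x) {
  p <- x$pair
  if (!nrow(x$pairs)) return(character(0))
  i0 <- x$site1[1]; i1 <- x$site1[2]
  # S2 printed 3'->5': original positions descending
  j0 <- x$site2[2]; j1 <- x$site2[1]
  top <- character(0); bar <- character(0); bot <- character(0)
  i <- i0; j <- j0
  paired1 <- x$pairs[, 1]; paired2 <- x$pairs[, 2]
  while (i <= i1 || j >= j1) {
    hit <- which(paired1 == i & paired2 == j)
    if (length(hit)) {
      top <- c(top, p$s1$residues[i]); bar <- c(bar, "|")
      bot <- c(bot, p$s2$residues[j])
      i <- i + 1; j <- j - 1
    } else if (i <= i1 && !(i %in% paired1)) {
      top <- c(top, p$s1$residues[i]); bar <- c(bar, " "); bot <- c(bot, "-")
      i <- i + 1
    } else if (j >= j1 && !(j %in% paired2)) {
      top <- c(top, "-"); bar <- c(bar, " "); bot <- c(bot, p$s2$residues[j])
      j <- j - 1
    } else break
  }
  c(paste0("  5'-", paste(top, collapse = ""), "-3'  S1"),
    paste0("     ", paste(bar, collapse = "")),
    paste0("  3'-", paste(bot, collapse = ""), "-5'  S2"))
}

#' Concatenation-based (cofold) interaction prediction
#'
#' Concatenates `S1 + X^linker + S2` (linker length `min_loop + 1` by
#' default, so the concatenated sequence ends may pair) and runs the unique
#' base-pair-maximization recursion on the hybrid sequence; any pair
#' touching a linker position is inadmissible, and linker-containing loops
#' carry no special energy under the simplified model.  (Sub)optimal hybrid
#' structures are enumerated with the shared Wuchty-style machinery.
#'
#' In the reported dot-bracket strings intramolecular pairs use `()`,
#' intermolecular (linker-spanning) pairs use `[]`, and linker positions
#' are `X`.
#'
#' @inheritParams hybrid_only
#' @param cfg a [fold_config()].
#' @param delta suboptimal score range.
#' @param max_structures emission cap.
#' @return List of `cofold_entry` objects sorted by total pair count,
#'   descending.  Each carries `pairs` (concatenated coordinates), `inter`
#'   (intermolecular pairs in original coordinates of both molecules),
#'   `intra1`, `intra2`, `db`, `score`, `energy`.
#' @examples
#' cofold(duplex_pair("CCC", "CCCGGGGGG"))[[1]]$score  # 4
#' @export
cofold <- function(pair, cfg = fold_config(), rule = pair_rule(),
                   model = energy_model(), delta = cfg$delta,
                   max_structures = Inf) {
  L <- cfg$linker_length
  n1 <- pair$n; n2 <- pair$m
  concat <- rna_seq(paste0(pair$s1$seq, strrep("X", L), pair$s2$seq),
                    concatenated = TRUE)
  entries <- enumerate_suboptimal(concat, cfg, rule, delta = delta,
                                  variant = "unique",
                                  max_structures = max_structures)
  lapply(entries, function(e) {
    p <- e$pairs
    in1 <- p[, 1] <= n1 & p[, 2] <= n1
    in2 <- p[, 1] > n1 + L
    inter <- p[, 1] <= n1 & p[, 2] > n1 + L
    inter_orig <- cbind(i = p[inter, 1],
                        j = p[inter, 2] - n1 - L)
    structure(list(pairs = p,
                   intra1 = p[in1, , drop = FALSE],
                   intra2 = cbind(i = p[in2, 1] - n1 - L,
                                  j = p[in2, 2] - n1 - L),
                   inter = inter_orig,
                   db = render_cofold_db(p, n1, L, n2),
                   score = e$score,
                   energy = e$score * model$e_bp,
                   pair = pair),
              class = "cofold_entry")
  })
}

render_cofold_db <- function(pairs, n1, L, n2) {
  n <- n1 + L + n2
  ch <- rep(".", n)
  ch[(n1 + 1):(n1 + L)] <- "X"
  p <- as_pairs(pairs)
  for (r in seq_len(nrow(p))) {
    i <- p[r, 1]; j <- p[r, 2]
    if (i <= n1 && j > n1 + L) { ch[i] <- "["; ch[j] <- "]" }
    else { ch[i] <- "("; ch[j] <- ")" }
  }
  paste(ch, collapse = "")
}

#' @export
print.cofold_entry <- function(x, ...) {
  cat(sprintf("%s  %d pair(s) (%d intermolecular), energy %.6g\n",
              x$db, nrow(x$pairs), nrow(x$inter), x$energy))
  invisible(x)
}

#' Accessibility (opening) penalties
#'
#' `deltaE[i, j] = -RT * log(Pr_ss(i, j))`: the free energy needed to make
#' the subsequence `i..j` single-stranded, computed on the molecule in
#' isolation.  All penalties are non-negative because `Pr_ss <= 1`.  For
#' the second molecule of a duplex the table is computed on the reversed
#' view (pass `duplex_pair(...)$s2rev`).
#'
#' @inheritParams partition_matrices
#' @return Upper-triangular numeric matrix of penalties (class
#'   `accessibility_penalties`, attribute `stats` holds the ensemble).
#' @examples
#' accessibility_penalties("GAAAC")[1, 1]  # -log(1/(1+e)) ~ 1.313262
#' @export
accessibility_penalties <- function(seq, cfg = fold_config(),
                                    rule = pair_rule(),
                                    model = energy_model()) {
  stats <- basepair_probabilities(seq, cfg, rule, model)
  n <- stats$seq$n
  dE <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    pss <- min(prss_region(stats, i, j), 1)
    if (pss <= 0)
      stop("numeric fault: Pr_ss(", i, ",", j, ") = 0 — the empty structure ",
           "always contributes a positive weight")
    dE[i, j] <- abs(max(-model$rt * log(pss), 0))  # abs() drops IEEE -0
  }
  structure(dE, class = c("accessibility_penalties", "matrix", "array"),
            stats = stats)
}

#' Duplex energy tables
#'
#' Subsequence-based duplex recursion: `D[(i,j) | (k,l)]` is the duplex
#' energy of interacting sites `i..k` on `S1` and `j..l` on the reversed
#' view of `S2`, under the condition that the boundaries form the
#' intermolecular pairs `(i,j)` and `(k,l)`.  Initiation: a single pair
#' costs `e_bp`.  Extension: `e_bp + min over the next pair (p,q)` with
#' `i < p <= k`, `j < q <= l` and both gaps `p - i`, `q - j` bounded by
#' `max_gap`.  All other boundary combinations are `+Inf`.
#'
#' @inheritParams hybrid_only
#' @param max_gap maximal distance between consecutive intermolecular pairs
#'   on either molecule (`Inf` for unbounded).
#' @return Object of class `duplex_tables`: `bp` (data frame of admissible
#'   boundary pairs in reversed-view coordinates), `D` (dense matrix over
#'   boundary-pair indices, left pair x right pair, `Inf` where undefined),
#'   `entries` (data frame of the finite entries: `i`, `j`, `k`, `l`, `d`).
#' @examples
#' duplex_matrix(duplex_pair("CC", "GG"))$entries
#' @export
duplex_matrix <- function(pair, rule = pair_rule(), model = energy_model(),
                          max_gap = 15) {
  comp <- duplex_comp(pair, rule)
  idx <- which(comp, arr.ind = TRUE)
  e_bp <- model$e_bp
  nbp <- nrow(idx)
  if (nbp == 0) {
    return(structure(list(bp = data.frame(i = integer(0), j = integer(0)),
                          D = matrix(numeric(0), 0, 0),
                          entries = data.frame(i = integer(0), j = integer(0),
                                               k = integer(0), l = integer(0),
                                               d = numeric(0)),
                          pair = pair, e_bp = e_bp, max_gap = max_gap),
                     class = "duplex_tables"))
  }
  # left pairs processed in decreasing i (then j): extensions refer to pairs
  # with strictly larger i and j, which are then already filled
  ord <- order(-idx[, 1], -idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  D <- matrix(Inf, nbp, nbp)
  for (b in seq_len(nbp)) {
    k <- idx[b, 1]; l <- idx[b, 2]
    for (a in seq_len(nbp)) {
      i <- idx[a, 1]; j <- idx[a, 2]
      if (i == k && j == l) { D[a, b] <- e_bp; next }
      if (i >= k || j >= l) next
      cand <- which(idx[, 1] > i & idx[, 1] <= k &
                    idx[, 2] > j & idx[, 2] <= l &
                    idx[, 1] - i <= max_gap & idx[, 2] - j <= max_gap)
      if (length(cand)) {
        best <- min(D[cand, b])
        if (is.finite(best)) D[a, b] <- e_bp + best
      }
    }
  }
  fin <- which(is.finite(D), arr.ind = TRUE)
  entries <- data.frame(i = idx[fin[, 1], 1], j = idx[fin[, 1], 2],
                        k = idx[fin[, 2], 1], l = idx[fin[, 2], 2],
                        d = D[fin])
  structure(list(bp = data.frame(i = idx[, 1], j = idx[, 2]),
                 D = D, entries = entries, pair = pair,
                 e_bp = e_bp, max_gap = max_gap),
            class = "duplex_tables")
}

#' @export
print.duplex_tables <- function(x, ...) {
  cat(sprintf("Duplex tables: %d admissible boundary pair(s), %d finite D entr%s\n",
              nrow(x$bp), nrow(x$entries),
              if (nrow(x$entries) == 1) "y" else "ies"))
  invisible(x)
}

#' Accessibility-based interaction prediction
#'
#' Total interaction energies `I = D + deltaE1(i..k) + deltaE2(j..l)` over
#' all boundary combinations: the duplex gain must outweigh the free energy
#' of opening both interaction sites.  Entries below zero mark favorable
#' interactions.  All minimal-energy interactions (or, with
#' `all_favorable = TRUE`, all favorable ones) are reported with their
#' intermolecular pairs recovered by traceback through `D`, site boundaries
#' in the original 5'->3' coordinates of both molecules, and itemized
#' energy terms.
#'
#' @inheritParams cofold
#' @param all_favorable report every interaction with `I < 0` instead of
#'   only the co-optimal ones.
#' @param tol tie tolerance on energies.
#' @return List of `interaction_result` objects sorted lexicographically by
#'   (site1 start, site2 start); empty if no admissible boundary pair
#'   exists.
#' @examples
#' interaction_predict(duplex_pair("C", "G"))[[1]]$energy  # -1
#' @export
interaction_predict <- function(pair, cfg = fold_config(), rule = pair_rule(),
                                model = energy_model(),
                                all_favorable = FALSE, tol = 1e-9) {
  dm <- duplex_matrix(pair, rule, model, max_gap = cfg$max_gap)
  if (!nrow(dm$entries)) return(list())
  dE1 <- accessibility_penalties(pair$s1, cfg, rule, model)
  dE2 <- accessibility_penalties(pair$s2rev, cfg, rule, model)
  ent <- dm$entries
  ent$de1 <- dE1[cbind(ent$i, ent$k)]
  ent$de2 <- dE2[cbind(ent$j, ent$l)]
  ent$I <- ent$d + ent$de1 + ent$de2
  sel <- if (all_favorable) which(ent$I < 0)
         else which(ent$I <= min(ent$I) + tol)
  results <- lapply(sel, function(r) {
    pairs_rev <- duplex_traceback(dm, ent$i[r], ent$j[r], ent$k[r], ent$l[r],
                                  tol = tol)
    res <- interaction_result_from_pairs(pair, pairs_rev, energy = ent$I[r],
                                         d = ent$d[r], de1 = ent$de1[r],
                                         de2 = ent$de2[r])
    res
  })
  ord <- order(vapply(results, function(r) r$site1[1], 0),
               vapply(results, function(r) r$site2[1], 0))
  results[ord]
}

# recover the intermolecular pairs of D[(i,j)|(k,l)] deterministically
# (smallest extension p, then q, at every step)
duplex_traceback <- function(dm, i, j, k, l, tol = 1e-9) {
  idx <- as.matrix(dm$bp)
  id_of <- function(p, q) which(idx[, 1] == p & idx[, 2] == q)[1]
  b <- id_of(k, l)
  pairs <- list()
  p <- i; q <- j
  repeat {
    pairs[[length(pairs) + 1L]] <- c(p, q)
    a <- id_of(p, q)
    if (p == k && q == l) break
    v <- dm$D[a, b]
    cand <- which(idx[, 1] > p & idx[, 1] <= k &
                  idx[, 2] > q & idx[, 2] <= l &
                  idx[, 1] - p <= dm$max_gap & idx[, 2] - q <= dm$max_gap)
    cand <- cand[is.finite(dm$D[cand, b])]
    cand <- cand[abs(dm$e_bp + dm$D[cand, b] - v) < tol]
    if (!length(cand)) stop("inconsistent duplex table during traceback")
    cand <- cand[order(idx[cand, 1], idx[cand, 2])]
    p <- idx[cand[1], 1]; q <- idx[cand[1], 2]
  }
  do.call(rbind, pairs)
}
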