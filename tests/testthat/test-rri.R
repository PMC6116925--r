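test_that("hybridization-only optimum matches hand cases and brute force", {
  expect_equal(hybrid_only(duplex_pair("AAA", "CCC"))$optimum, 0)
  expect_equal(hybrid_only(duplex_pair("CCC", "GGG"))$optimum, 3)
  expect_equal(hybrid_only(duplex_pair("CCC", "CCCGGGGGG"))$optimum, 3)
  for (dp in suite_pairs())
    expect_equal(hybrid_only(dp)$optimum,
                 brute_hybrid_max(dp$s1$seq, dp$s2rev$seq),
                 info = paste(dp$s1$seq, dp$s2$seq))
})

test_that("hybrid matrix is monotone along prefixes and bounded", {
  for (dp in suite_pairs()[1:10]) {
    H <- hybrid_only(dp)$H
    expect_true(all(apply(H, 1, diff) >= 0))
    expect_true(all(apply(H, 2, diff) >= 0))
    expect_lte(H[dp$n + 1, dp$m + 1], min(dp$n, dp$m))
  }
})

test_that("reported intermolecular pair sets are antiparallel-monotone", {
  check_monotone <- function(p) {
    if (nrow(p) < 2) return(TRUE)
    p <- p[order(p[, 1]), , drop = FALSE]
    all(diff(p[, 1]) > 0) && all(diff(p[, 2]) < 0)
  }
  # CCC / CCCGGGGGG: any three of the six Gs, so choose(6, 3) optimal sets
  h <- hybrid_only(duplex_pair("CCC", "CCCGGGGGG"))
  expect_length(h$results, choose(6, 3))
  for (r in h$results) {
    expect_equal(nrow(r$pairs), 3)
    expect_true(check_monotone(r$pairs))
    expect_true(all(r$pairs[, 2] >= 4))  # pairs only with G nucleotides
  }
  for (dp in suite_pairs()[1:10]) {
    for (r in hybrid_only(dp)$results)
      expect_true(check_monotone(r$pairs), info = paste(dp$s1$seq, dp$s2$seq))
    for (r in interaction_predict(dp, all_favorable = TRUE))
      expect_true(check_monotone(r$pairs), info = paste(dp$s1$seq, dp$s2$seq))
  }
})

test_that("cofold folds the linked hybrid without touching the linker", {
  expect_equal(cofold(duplex_pair("AAA", "AAA"))[[1]]$score, 0)
  cf <- cofold(duplex_pair("CCC", "CCCGGGGGG"), delta = 0)
  expect_equal(cf[[1]]$score, 4)
  expect_true(all(vapply(cf, `[[`, 0, "score") == 4))
  # reported optimum: intermolecular pairs confined to the 3'-end Gs of S2
  expect_true(all(cf[[1]]$inter[, 2] %in% 7:9))
  # and some co-optimum uses exactly the three 3'-terminal Gs
  expect_true(any(vapply(cf, function(e)
    nrow(e$inter) == 3 && all(e$inter[, 2] %in% 7:9), TRUE)))
  # linker positions never pair, on the whole pair suite
  for (dp in suite_pairs()[1:10]) {
    n1 <- dp$n; L <- fold_config()$linker_length
    for (e in cofold(dp, delta = 1)) {
      expect_false(any(e$pairs > n1 & e$pairs <= n1 + L),
                   info = paste(dp$s1$seq, dp$s2$seq))
      expect_true(grepl(sprintf("X{%d}", L), e$db))
    }
  }
})

test_that("cofold against a non-pairing partner reduces to single-molecule folding", {
  for (dp in lapply(c("GGGAAACCC", "GGGCAUCCC", "CCGAAACGG"), duplex_pair,
                    seq2 = "AAAA")) {
    expect_equal(cofold(dp)[[1]]$score,
                 nussinov_matrix(dp$s1)$N[1, dp$n], info = dp$s1$seq)
    expect_equal(nrow(cofold(dp)[[1]]$inter), 0)
  }
})

test_that("cofold dot-bracket distinguishes intra- and intermolecular pairs", {
  cf <- cofold(duplex_pair("CCCC", "GGGG"))[[1]]
  expect_equal(cf$db, "[[[[XXXX]]]]")
  expect_equal(nrow(cf$inter), 4)
  top <- cofold(duplex_pair("CCC", "CCCGGGGGG"), delta = 0)[[1]]
  expect_match(top$db, "^[.(\\[]")
  expect_equal(lengths(regmatches(top$db, gregexpr("\\[", top$db))),
               nrow(top$inter))
})

test_that("accessibility penalties are the log-probabilities of opening", {
  expect_equal(accessibility_penalties("G")[1, 1], 0)
  ap <- accessibility_penalties("CCCGGGGGG")
  expect_equal(ap[4, 4], 0)  # G4 has no admissible partner under l = 3
  expect_equal(accessibility_penalties("GAAAC")[1, 1],
               -log(1 / (1 + exp(1))), tolerance = 1e-12)
  for (s in c("CCCGGGGGG", suite_sequences()[1:10])) {
    ap <- accessibility_penalties(s)
    st <- basepair_probabilities(s)
    expect_true(all(ap[upper.tri(ap, diag = TRUE)] >= 0), info = s)
    n <- nchar(s)
    for (i in 1:n) for (j in i:n)
      expect_equal(ap[i, j],
                   -log(min(unpaired_probability(s, i, j, stats = st), 1)),
                   tolerance = 1e-9)
  }
})

test_that("duplex tables follow the initiation/extension recursion", {
  dm <- duplex_matrix(duplex_pair("C", "G"))
  expect_equal(dm$entries$d, -1)
  dm2 <- duplex_matrix(duplex_pair("CC", "GG"))
  full <- dm2$entries[dm2$entries$i == 1 & dm2$entries$j == 1 &
                      dm2$entries$k == 2 & dm2$entries$l == 2, ]
  expect_equal(full$d, -2)
  # with unbounded gaps the best duplex equals the prefix-based optimum
  dm3 <- duplex_matrix(duplex_pair("CCC", "CCCGGGGGG"), max_gap = Inf)
  expect_equal(min(dm3$entries$d), -3)
  for (dp in suite_pairs()) {
    dmx <- duplex_matrix(dp, max_gap = Inf)
    best <- if (nrow(dmx$entries)) max(-dmx$entries$d) else 0
    expect_equal(best, hybrid_only(dp)$optimum,
                 info = paste(dp$s1$seq, dp$s2$seq))
  }
})

test_that("the gap bound prunes distant extensions", {
  # C..C with 20 As in between: both pairs exist, but joining them needs a
  # gap of 21 on S1, beyond the default bound of 15
  dp <- duplex_pair(paste0("C", strrep("A", 20), "C"), "GG")
  unbounded <- duplex_matrix(dp, max_gap = Inf)
  expect_equal(min(unbounded$entries$d), -2)
  bounded <- duplex_matrix(dp, max_gap = 15)
  expect_equal(min(bounded$entries$d), -1)
})

test_that("interaction energies add duplex and opening terms", {
  r <- interaction_predict(duplex_pair("C", "G"))
  expect_length(r, 1)
  expect_equal(r[[1]]$energy, -1)
  expect_true(r[[1]]$favorable)
  expect_equal(r[[1]]$de1, 0)
  expect_equal(r[[1]]$de2, 0)
  expect_length(interaction_predict(duplex_pair("AAA", "AAA")), 0)
  for (dp in suite_pairs()[1:10]) {
    for (r in interaction_predict(dp, all_favorable = TRUE)) {
      expect_gte(r$energy, r$d)             # I >= D entrywise
      expect_gte(r$de1, 0)
      expect_gte(r$de2, 0)
      expect_equal(r$energy, r$d + r$de1 + r$de2, tolerance = 1e-9)
      expect_lt(r$energy, 0)
      expect_equal(nrow(r$pairs), -r$d)     # traceback recovers all pairs
    }
  }
})

test_that("accessibility places the CCC interaction in the loop of CCCGGGGGG", {
  res <- interaction_predict(duplex_pair("CCC", "CCCGGGGGG"))
  expect_gte(length(res), 1)
  for (r in res) {
    # site on S2 sits in the central accessible region, never the
    # 3'-terminal Gs alone (those are blocked by the hairpin stem)
    expect_true(all(r$site2 >= 4 & r$site2 <= 8))
    expect_true(r$favorable)
  }
})

test_that("hybridization-only dominates the other paradigms' pair counts", {
  for (dp in suite_pairs()) {
    h <- hybrid_only(dp)$optimum
    co <- max(vapply(cofold(dp, delta = 0), function(e) nrow(e$inter), 0))
    fav <- interaction_predict(dp, all_favorable = TRUE)
    fav_max <- if (length(fav)) max(vapply(fav, function(r) nrow(r$pairs), 0)) else 0
    expect_gte(h, co)
    expect_gte(h, fav_max)
  }
})
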