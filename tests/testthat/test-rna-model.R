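test_that("sequence normalization and alphabet checks", {
  expect_equal(rna_seq("gaaac")$seq, "GAAAC")
  expect_equal(rna_seq("GATTACA")$seq, "GAUUACA")
  expect_equal(rna_seq("")$n, 0)
  expect_error(rna_seq("GABC"), class = "rnakit_input_error")
  expect_error(rna_seq("CCXGG"), class = "rnakit_input_error")
  expect_equal(rna_seq("CCXGG", concatenated = TRUE)$n, 5)
})

test_that("complementarity rules", {
  expect_true(is_complementary("G", "C", pair_rule("wc-gu")))
  expect_true(is_complementary("G", "U", pair_rule("wc-gu")))
  expect_false(is_complementary("A", "A", pair_rule("wc-gu")))
  expect_false(is_complementary("G", "U", pair_rule("wc")))
  expect_true(is_complementary("A", "A", pair_rule("any")))
  # the linker character never pairs, under any rule
  for (m in c("wc-gu", "wc", "any"))
    expect_false(is_complementary("X", "G", pair_rule(m)))
})

test_that("structure validation reports each broken constraint", {
  expect_length(validate_structure("GAAAC", c(1, 5)), 0)
  expect_match(validate_structure("GAAAC", c(1, 4)), "loop-length",
               all = FALSE)
  expect_match(
    validate_structure("GGGCCCGGGCCC", rbind(c(1, 6), c(4, 9)),
                       fold_config(min_loop = 1)),
    "crossing", all = FALSE)
  expect_match(validate_structure("GAAAC", rbind(c(1, 5), c(1, 5), c(2, 5)),
                                  fold_config(min_loop = 0)),
               "more than one pair", all = FALSE)
  expect_match(validate_structure("AAAAA", c(1, 5)), "non-complementary",
               all = FALSE)
  expect_error(validate_structure("GAAAC", c(1, 6)),
               class = "rnakit_input_error")
})

test_that("structure energy and Boltzmann weight follow the pair count", {
  m <- energy_model()
  expect_equal(structure_energy(NULL, m), 0)
  expect_equal(structure_energy(c(1, 5), m), -1)
  expect_equal(structure_energy(rbind(c(1, 9), c(2, 8), c(3, 7)), m), -3)
  expect_equal(boltzmann_weight(NULL, m), 1)
  expect_equal(boltzmann_weight(c(1, 5), m), exp(1))
  expect_equal(boltzmann_weight(rbind(c(1, 9), c(2, 8)), m), exp(2))
  # configurable model
  m2 <- energy_model(e_bp = -2, rt = 0.5)
  expect_equal(m2$q_bp, exp(4))
  expect_equal(boltzmann_weight(c(1, 5), m2), exp(4))
  expect_error(energy_model(rt = 0), class = "rnakit_input_error")
})

test_that("dot-bracket codec round-trips and rejects malformed input", {
  expect_equal(nrow(parse_dotbracket(".....")), 0)
  expect_equal(parse_dotbracket("(...)"), as_pairs(c(1, 5)),
               ignore_attr = TRUE)
  expect_equal(parse_dotbracket("((...))"), as_pairs(rbind(c(1, 7), c(2, 6))),
               ignore_attr = TRUE)
  expect_error(parse_dotbracket("(.."), class = "rnakit_input_error")
  expect_error(parse_dotbracket("...)"), class = "rnakit_input_error")
  expect_error(parse_dotbracket("(.a.)"), class = "rnakit_input_error")
  # round trip across every enumerated structure of a few suite sequences
  for (s in head(suite_sequences(), 8)) {
    n <- nchar(s)
    for (p in enumerate_structures(s))
      expect_identical(parse_dotbracket(render_dotbracket(p, n)), p)
  }
})

test_that("enumeration oracle matches hand-countable ensembles", {
  expect_length(enumerate_structures("AAAA"), 1)
  gaaac <- enumerate_structures("GAAAC")
  expect_length(gaaac, 2)
  expect_setequal(sapply(gaaac, function(p) render_dotbracket(p, 5)),
                  c(".....", "(...)"))
  # three G and three C positions: order-reversing matchings,
  # sum over k of choose(3, k)^2 = 20
  expect_length(enumerate_structures("GGGAAACCC"), 20)
  expect_equal(sum(choose(3, 0:3)^2), 20)
  # poly-A of any length has exactly the empty structure
  for (n in c(1, 7, 19))
    expect_length(enumerate_structures(strrep("A", n)), 1)
  expect_error(enumerate_structures(strrep("G", 26)),
               class = "rnakit_guard_error")
  expect_length(enumerate_structures(strrep("A", 26), limit = 30), 1)
})

test_that("every enumerated structure is valid and weight-consistent", {
  m <- energy_model()
  for (s in suite_sequences()) {
    for (p in enumerate_structures(s)) {
      expect_length(validate_structure(s, p), 0)
      expect_equal(boltzmann_weight(p, m),
                   exp(-structure_energy(p, m) / m$rt))
    }
  }
})
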