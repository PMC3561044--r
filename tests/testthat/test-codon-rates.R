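test_that("trna_copy_table validates anticodons and copy numbers", {
  tab <- trna_copy_table(c("uuu", "GAT"), c("K", "I"), c(10, 3))
  expect_equal(tab$anticodon, c("UUU", "GAU"))  # case + T->U normalisation
  expect_error(trna_copy_table("UU", "K", 1), "malformed")
  expect_error(trna_copy_table("UUX", "K", 1), "malformed")
  expect_error(trna_copy_table(c("UUU", "UUU"), c("K", "K"), c(1, 1)),
               "duplicate")
  expect_error(trna_copy_table("UUU", "K", -1), "non-negative")
})

test_that("load_trna_table reads a TSV and rejects missing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "anticodon\tamino_acid\tcopy_number",
               "UUU\tK\t10", "GAU\tI\t4"), path)
  tab <- load_trna_table(path)
  expect_s3_class(tab, "trna_copy_table")
  expect_equal(nrow(tab), 2)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("anticodon\tcopies", "UUU\t10"), bad)
  expect_error(load_trna_table(bad), "columns")
})

test_that("pairing factors implement Watson-Crick and wobble rules", {
  pf <- ribotraffic:::.pairing_factor
  rules <- wobble_rules()
  expect_equal(pf("AAA", "UUU", rules), 1)    # all Watson-Crick
  expect_equal(pf("AAG", "UUU", rules), 0.5)  # G:U wobble at position 3
  expect_equal(pf("AAG", "CUU", rules), 1)    # WC G:C at position 3
  expect_equal(pf("AAA", "CUU", rules), 0)    # A:C never pairs
  expect_equal(pf("GAA", "UUU", rules), 0)    # WC required at position 1
  # inosine-like reading by A-starting anticodons: U (WC), C and A
  expect_equal(pf("CUU", "AAG", rules), 1)
  expect_equal(pf("CUC", "AAG", rules), 0.5)
  expect_equal(pf("CUA", "AAG", rules), 0.5)
  expect_equal(pf("CUC", "AAG", wobble_rules(inosine = FALSE)), 0)
  expect_equal(pf("AAG", "UUU", wobble_rules(wobble_penalty = 0.2)), 0.2)
  # extra pairings override matching defaults
  expect_equal(pf("AAG", "UUU", wobble_rules(extra = c("G:U" = 0.9))), 0.9)
  expect_error(wobble_rules(wobble_penalty = 2), "\\[0, 1\\]")
})

test_that("rates sum over all cognate decoding anticodons", {
  # Lys codons in toy_trna (UUU and CUU anticodons, 4 copies each):
  #   AAA <- UUU Watson-Crick only             -> 4
  #   AAG <- UUU wobble (0.5) + CUU WC         -> 6
  rt <- build_rate_table(toy_trna(), wobble_rules(), scaling = 2)
  expect_equal(unname(rt$rates[["AAA"]]), 2 * 4)
  expect_equal(unname(rt$rates[["AAG"]]), 2 * (4 * 0.5 + 4))
})

test_that("cognate restriction excludes near-cognate contributions", {
  # GAA (Glu) is WC-decoded by UUC (Glu, 4 copies). The Asp anticodon
  # AUC also pairs with GAA via inosine-like A:A reading, but crosses
  # amino-acid identity, so it only counts when the restriction is off.
  rt_c <- build_rate_table(toy_trna(), scaling = 1)
  rt_n <- build_rate_table(toy_trna(), scaling = 1, require_cognate = FALSE)
  expect_equal(unname(rt_c$rates[["GAA"]]), 4)
  expect_equal(unname(rt_n$rates[["GAA"]]), 4 + 0.5 * 4)
})

test_that("calibration hits the target usage-weighted mean exactly", {
  rt <- build_rate_table(toy_trna(), wobble_rules(), target_mean = 10)
  expect_equal(mean(rt$rates), 10, tolerance = 1e-12)
  expect_true(all(rt$rates > 0))
  expect_length(rt$rates, 61)
  usage <- setNames(rep(0, 61), sense_codons())
  usage[c("AAA", "GAA")] <- c(3, 1)
  rt2 <- build_rate_table(toy_trna(), wobble_rules(), target_mean = 8,
                          usage = usage)
  expect_equal(unname((3 * rt2$rates[["AAA"]] + rt2$rates[["GAA"]]) / 4), 8,
               tolerance = 1e-12)
})

test_that("scaling is a pure gauge: rates are proportional to it", {
  a <- build_rate_table(toy_trna(), scaling = 1)
  b <- build_rate_table(toy_trna(), scaling = 3.5)
  expect_equal(b$rates, 3.5 * a$rates, tolerance = 1e-12)
})

test_that("rate_profile maps codons, strips the stop, rejects bad ORFs", {
  tab <- rate_table(c(AUG = 5, AAA = 8, GAA = 12))
  p <- rate_profile("AUGAAAGAAUAA", tab, gene_id = "g1")
  expect_s3_class(p, "rate_profile")
  expect_equal(p$codons, c("AUG", "AAA", "GAA"))   # trailing stop stripped
  expect_equal(p$k, c(5, 8, 12))
  # DNA alphabet and lower case are accepted
  p2 <- rate_profile("atgaaagaataa", tab)
  expect_equal(p2$k, p$k)
  expect_error(rate_profile("AAAGAA", tab), "start with AUG")
  expect_error(rate_profile("AUGUAAGAA", tab), "internal stop")
  expect_error(rate_profile("AUGUUU", tab), "missing from rate table")
})

test_that("as_codons handles strings, vectors and bad input", {
  expect_equal(as_codons("AUGGCU"), c("AUG", "GCU"))
  expect_equal(as_codons(c("aug", "gct")), c("AUG", "GCU"))
  expect_error(as_codons("AUGGC"), "divisible by 3")
  expect_error(as_codons(c("AUG", "GX")), "invalid codon")
})

test_that("rate_table rejects non-sense codons and non-positive rates", {
  expect_error(rate_table(c(UAA = 1)), "not sense codons")
  expect_error(rate_table(c(AAA = 0)), "> 0")
  rt <- rate_table(c(AAA = 2), default = 7)
  expect_length(rt$rates, 61)
  expect_equal(unname(rt$rates[["GCU"]]), 7)
})
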