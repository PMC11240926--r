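test_that("AAC counts residues over the full length", {
  v <- aac("AAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  # staphylococcal delta-lysin-like fixture peptide, counted by hand
  v <- aac("MEFVAKLFKFFKDLLGKFLGNN")
  expect_equal(unname(v["F"]), 5 / 22)
  expect_equal(unname(v["K"]), 4 / 22)
  expect_equal(unname(v["L"]), 4 / 22)
  expect_error(aac("AXA"), "invalid residue")
  expect_error(aac(""), "non-empty")
})

test_that("AAC matches the direct-count oracle on random peptides", {
  pep <- random_peptides(50, seed = 21)
  for (s in pep$sequence)
    expect_equal(unname(aac(s)), unname(oracle_aac(s)),
                 tolerance = 1e-14)
})

test_that("CKSAAP reproduces worked pair counts", {
  v <- cksaap("AAAA", k = 0)
  expect_equal(unname(v["AxA"]), 3 / 4)        # 3 pairs, L - k = 4
  expect_equal(sum(v != 0), 1)
  v <- cksaap("ACAC", k = 1)
  expect_equal(unname(v["AxA"]), 1 / 3)
  expect_equal(unname(v["CxC"]), 1 / 3)
  expect_equal(sum(v), 2 / 3)
  # pair-count denominator normalizes to the true pair total
  expect_equal(sum(cksaap("ACAC", 1, denominator = "pair-count")), 1)
  expect_error(cksaap("ACA", k = 2), "L > k \\+ 1")
})

test_that("CKSAAP matches the position-scan oracle for every gap", {
  pep <- random_peptides(20, min_len = 30, max_len = 30, seed = 22)
  for (s in pep$sequence)
    for (k in 0:3) {
      expect_equal(unname(cksaap(s, k)), oracle_cksaap(s, k),
                   tolerance = 1e-14)
      expect_equal(unname(cksaap(s, k, denominator = "pair-count")),
                   oracle_cksaap(s, k, denominator = "pair-count"),
                   tolerance = 1e-14)
    }
})

test_that("CKSAAP block sums follow the chosen denominator", {
  pep <- random_peptides(10, seed = 23)
  for (s in pep$sequence)
    for (k in 0:3) {
      L <- nchar(s)
      expect_equal(sum(cksaap(s, k)), (L - k - 1) / (L - k))
      expect_equal(sum(cksaap(s, k, denominator = "pair-count")), 1)
    }
})

test_that("DPC is CKSAAP at gap zero with 400 dimensions", {
  pep <- random_peptides(5, seed = 24)
  for (s in pep$sequence)
    expect_equal(unname(dpc(s)), unname(cksaap(s, 0)))
  v <- dpc("GLGL")
  expect_equal(length(v), 400)
  expect_equal(unname(v["GL"]), 2 / 4)
  expect_equal(unname(v["LG"]), 1 / 4)
})

test_that("terminal windows slice the right end", {
  s <- "GLPVCGETCVGGTCNTPGCTCSWPVCTRD"
  expect_equal(terminal_window(s, "C", 5), "VCTRD")
  expect_equal(terminal_window(s, "N", 5), "GLPVC")
  expect_equal(terminal_window(s, "N", 100), s)
  expect_equal(terminal_window("ACDEFGHIKL", "N", 10), "ACDEFGHIKL")
})

test_that("encoder specs fix dimension and feature-name order", {
  spec <- encoder_spec()  # AAC + DPC + CKSAAP(1:3)
  nm <- feature_names(spec)
  expect_equal(length(nm), 20 + 400 + 1200)
  expect_equal(nm[1], "AAC:A")
  expect_equal(nm[21], "DPC:AA")
  expect_equal(nm[421], "CKSAAP1:AxA")
  # name order is a pure function of the spec
  expect_equal(feature_names(encoder_spec()), nm)
  # K defaults: 1:3 alongside DPC, 0:3 without
  expect_equal(encoder_spec()$K, 1:3)
  expect_equal(encoder_spec(c("AAC", "CKSAAP"))$K, 0:3)
  expect_equal(encoder_spec("CKSAAP", K = 1)$K, 1L)
  expect_error(encoder_spec("PSSM"), "unknown component")
  expect_error(encoder_spec("CKSAAP", K = 5), "subset of 0:3")
})

test_that("encode concatenates verified blocks in spec order", {
  s <- "MEFVAKLFKFFKDLLGKFLGNN"
  v <- encode(s, encoder_spec())
  expect_equal(length(v), 1620)
  expect_equal(unname(v[1:20]), unname(aac(s)))
  expect_equal(unname(v[421:820]), unname(cksaap(s, 1)))
  # single block equals the raw encoder
  expect_equal(unname(encode("AAAA", encoder_spec("AAC"))),
               unname(aac("AAAA")))
  # SSEC block appended from the supplied states
  v <- encode("GLFDMW", encoder_spec(c("AAC", "SSEC")), ss = "HHHEEC")
  expect_equal(unname(v[21:23]), c(0.5, 1 / 3, 1 / 6))
  expect_error(encode("GLFDMW", encoder_spec(c("AAC", "SSEC"))),
               "SSEC-family")
  expect_error(encode("GLFDMW", encoder_spec(c("AAC", "SSEC")),
                      ss = "HHH"), "length")
})

test_that("encode is a pure function of sequence, ss and spec", {
  pep <- random_peptides(5, seed = 25)
  spec <- encoder_spec(c("AAC", "N-AAC", "C-AAC"))
  m1 <- encode_peptides(pep, spec)
  m2 <- encode_peptides(pep, spec)
  expect_identical(m1, m2)
  expect_equal(dim(m1), c(5, 60))
  expect_equal(rownames(m1), pep$id)
  # terminal blocks equal the encoder applied to the sliced windows
  s <- pep$sequence[1]
  expect_equal(unname(m1[1, 21:40]),
               unname(aac(terminal_window(s, "N", 10))))
  expect_equal(unname(m1[1, 41:60]),
               unname(aac(terminal_window(s, "C", 10))))
})

test_that("SSEC-family set encoding falls back to the propensity stand-in", {
  pep <- random_peptides(4, seed = 26)
  spec <- encoder_spec(c("SSEC", "N-SSEC", "C-SSEC"))
  m <- encode_peptides(pep, spec)
  expect_equal(dim(m), c(4, 9))
  st <- predict_ss_propensity(pep)
  expect_equal(unname(m[2, 1:3]),
               unname(ssec_composition(st[[pep$id[2]]])))
  expect_error(encode_peptides(pep, spec, predict_ss = FALSE),
               "SSEC-family")
})
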