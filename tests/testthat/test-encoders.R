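# Stated toy examples plus oracle agreement on random fragments for each
# encoder; the full 100-fragment oracle sweep lives in test-acceptance.R.

expect_oracle_match <- function(encode, oracle, n = 20, L = 15L) {
  set.seed(101)
  for (i in seq_len(n)) {
    f <- rand_fragment(L)
    expect_equal(unname(encode(f)), unname(oracle(f)), tolerance = 1e-12)
  }
}

test_that("AAC matches its examples and excludes dummies", {
  a <- encode_aac("AAAAA")
  expect_equal(unname(a[["AAC.A"]]), 1)
  expect_equal(sum(a), 1)
  b <- encode_aac("ACACA")
  expect_equal(unname(b[c("AAC.A", "AAC.C")]), c(0.6, 0.4),
               ignore_attr = TRUE)
  d <- encode_aac("AOAOA")
  expect_equal(unname(d[["AAC.A"]]), 1)
  expect_warning(z <- encode_aac("OOO"), "all-dummy")
  expect_equal(sum(z), 0)
  expect_oracle_match(encode_aac, oracle_aac)
})

test_that("DPC has 400 features and the stated fractions", {
  x <- encode_dpc("AAAA")
  expect_length(x, 400L)
  expect_equal(unname(x[["DPC.A.A"]]), 1)
  y <- encode_dpc("ACAC")
  expect_equal(unname(y[c("DPC.A.C", "DPC.C.A")]), c(2 / 3, 1 / 3),
               ignore_attr = TRUE)
  expect_oracle_match(encode_dpc, oracle_dpc)
})

test_that("DDE uses the codon table and matches brute force", {
  # theoretical mean for (A,A) from codon multiplicities
  expect_equal((4 / 61)^2, 0.004299919, tolerance = 1e-6)
  f <- "WWWWKWWWW"  # no dipeptide AA present
  x <- encode_dde(f)
  L <- nchar(f)
  tm <- (4 / 61)^2
  tv <- tm * (1 - tm) / (L - 1)
  expect_equal(unname(x[["DDE.A.A"]]), -tm / sqrt(tv))
  expect_oracle_match(encode_dde, oracle_dde)
})

test_that("EAAC slides a length-5 window fully inside the fragment", {
  x <- encode_eaac("AAAAAAA")
  expect_length(x, 20L * 3L)
  expect_equal(unname(x[paste0("EAAC.w", sprintf("%02d", 1:3), ".A")]),
               rep(1, 3), ignore_attr = TRUE)
  f35 <- paste0(paste0(rep("A", 17), collapse = ""), "K",
                paste0(rep("C", 17), collapse = ""))
  expect_length(encode_eaac(f35), 620L)
  # dummy-free window blocks each sum to 1
  set.seed(5)
  f <- rand_fragment(11, p_dummy = 0)
  x <- encode_eaac(f)
  for (w in 1:7) expect_equal(sum(x[((w - 1) * 20 + 1):(w * 20)]), 1)
  expect_error(encode_eaac("AKA"), "padding|sub-window")
  expect_oracle_match(encode_eaac, oracle_eaac)
})

test_that("EGAAC groups and normalizes per window", {
  x <- encode_egaac("GGGGGGG")
  expect_true(all(x[grep("g1", names(x))] == 1))
  y <- encode_egaac("KRHDE")
  expect_equal(unname(y[c("EGAAC.w01.g3.positive", "EGAAC.w01.g4.negative")]),
               c(0.6, 0.4), ignore_attr = TRUE)
  set.seed(6)
  f <- rand_fragment(11, p_dummy = 0)
  z <- encode_egaac(f)
  for (w in 1:7) expect_equal(sum(z[((w - 1) * 5 + 1):(w * 5)]), 1)
  expect_oracle_match(encode_egaac, oracle_egaac)
})

test_that("BINA one-hot follows the 21-letter convention", {
  a <- encode_bina("A")
  expect_equal(unname(a), c(1, rep(0, 20)))
  o <- encode_bina("O")
  expect_equal(unname(o), c(rep(0, 20), 1))
  set.seed(7)
  f <- rand_fragment(9)
  x <- encode_bina(f)
  blocks <- matrix(x, nrow = 21)
  expect_true(all(colSums(blocks) == 1))
  expect_oracle_match(encode_bina, oracle_bina)
})

test_that("NUM ranks alphabetically and omits the central lysine", {
  f25 <- paste0(paste0(rep("A", 12), collapse = ""), "K",
                paste0(rep("Y", 11), collapse = ""), "O")
  x <- encode_num(f25)
  expect_length(x, 24L)
  expect_equal(unname(x[1]), 1)    # A
  expect_equal(unname(x[13]), 20)  # Y
  expect_equal(unname(x[24]), 21)  # O
  f35 <- paste0(paste0(rep("C", 17), collapse = ""), "K",
                paste0(rep("C", 17), collapse = ""))
  expect_length(encode_num(f35), 34L)
  expect_oracle_match(encode_num, oracle_num)
})

test_that("BLOSUM62 rows come from the bundled matrix", {
  f25 <- paste0(paste0(rep("W", 12), collapse = ""), "K",
                paste0(rep("W", 12), collapse = ""))
  x <- encode_blosum62(f25)
  expect_length(x, 500L)
  expect_equal(unname(x[["BLOSUM62.p01.W"]]), max(diag(blosum62_matrix())))
  d <- encode_blosum62("OKO")
  expect_equal(sum(d[1:20] != 0), 0)
  expect_oracle_match(encode_blosum62, oracle_blosum62)
})

test_that("CKSAAP blocks have 441 features summing to 1", {
  x <- encode_cksaap("AAAA", gaps = 0)
  expect_length(x, 441L)
  expect_equal(unname(x[["CKSAAP.k0.A.A"]]), 1)
  f <- rand_fragment(15)
  full <- encode_cksaap(f)
  expect_length(full, 2205L)
  for (k in 0:4) {
    blk <- full[grep(paste0("^CKSAAP\\.k", k, "\\."), names(full))]
    expect_equal(sum(blk), 1)
  }
  expect_error(encode_cksaap("AKA", gaps = 4), "too short")
  expect_oracle_match(encode_cksaap, oracle_cksaap)
})

test_that("EBGW prefix fractions follow the dichotomy groups", {
  x <- encode_ebgw(paste0(rep("A", 10), collapse = ""))
  expect_equal(unname(x), rep(1, 15))     # A is hydrophobic: in all unions
  y <- encode_ebgw(paste0(rep("K", 10), collapse = ""))
  expect_true(all(y[grep("H1", names(y))] == 0))
  expect_true(all(y[grep("H3", names(y))] == 1))
  set.seed(8)
  for (i in 1:10) {
    z <- encode_ebgw(rand_fragment(sample(9:21, 1)))
    expect_true(all(z >= 0 & z <= 1))
  }
  expect_oracle_match(encode_ebgw, oracle_ebgw)
})

test_that("PWAA closed form and absence hold", {
  f <- paste0(rep("K", 11), collapse = "")
  m <- 5
  x <- encode_pwaa(f)
  expect_equal(unname(x[["PWAA.K"]]), 1 / m)
  expect_equal(unname(x[["PWAA.W"]]), 0)
  expect_error(encode_pwaa("K"), "flanking")
  expect_oracle_match(encode_pwaa, oracle_pwaa)
})

test_that("profile and EBPR encodings match composition oracles", {
  expect_equal(unname(encode_profile("AAC")), c(2 / 3, 2 / 3, 1 / 3))
  set.seed(9)
  f <- paste0(sample(AA20, 12), collapse = "")   # all distinct
  expect_equal(unname(encode_profile(f)), rep(1 / 12, 12))
  expect_equal(unname(encode_ebpr("DEK")), c(2 / 3, 2 / 3, 1 / 3))
  expect_equal(unname(encode_ebpr("AFGIL")), rep(1, 5))
  expect_oracle_match(encode_profile, oracle_profile)
  expect_oracle_match(encode_ebpr, oracle_ebpr)
})

test_that("physicochemical schemes emit the documented shapes", {
  d <- encode_physchem("D", "side_chain")
  expect_equal(unname(d), c(0, 0, 0, 1, 0, 0))
  set.seed(10)
  f <- rand_fragment(9, p_dummy = 0)
  sc <- encode_physchem(f, "side_chain")
  expect_true(all(colSums(matrix(sc, nrow = 6)) == 1))
  expect_length(encode_physchem(f, "reduced_alphabet"), 8L * 9L)
  z <- encode_physchem(f, "zscales")
  expect_length(z, 5L * 9L)
  expect_equal(unname(z[1:5]), unname(ZSCALES[substr(f, 1, 1), ]))
  expect_equal(unname(encode_physchem("O", "zscales")), rep(0, 5))
})

test_that("AAindex encoding is a table lookup", {
  tab <- list(H1 = setNames(seq(0.1, 2, length.out = 20), AA20),
              FLAT = setNames(rep(2, 20), AA20))
  f <- rand_fragment(35)
  x <- encode_aaindex(f, tab, "H1")
  expect_length(x, 35L)
  ch <- strsplit(f, "")[[1]]
  expect_equal(unname(x),
               unname(ifelse(ch == "O", 0, tab$H1[ch])))
  expect_equal(unique(unname(encode_aaindex("ACD", tab, "FLAT"))), 2)
  expect_error(encode_aaindex(f, tab, "NOPE"), "unknown AAindex")
})

test_that("BPB posteriors match manual counts", {
  train <- c("AKC", "AKD", "CKC")
  labels <- c("positive", "positive", "negative")
  st <- fit_bpb(train, labels, alpha = 0)
  x <- encode_bpb(st, "AKC")
  expect_equal(unname(x[1]), 1)        # both positives have A at 1
  expect_length(x, 6L)
  st1 <- fit_bpb(train, labels, alpha = 1)
  x1 <- encode_bpb(st1, "AKC")
  expect_equal(unname(x1[1]), (2 + 1) / (2 + 21))
  expect_equal(unname(x1), unname(oracle_bpb(train, labels, "AKC")))
  expect_error(fit_bpb(train, rep("positive", 3)), "both classes")
  expect_error(encode_bpb(fit_tfidf(train), "AKC"), "fit_bpb")
  set.seed(12)
  corp <- rand_corpus(12)
  st2 <- fit_bpb(corp$fragments, corp$labels)
  for (i in 1:10) {
    q <- rand_fragment(15)
    expect_equal(unname(encode_bpb(st2, q)),
                 unname(oracle_bpb(corp$fragments, corp$labels, q)))
  }
})

test_that("PWM frequencies match the count-matrix oracle", {
  pos <- c("AKC")
  st <- fit_pwm(pos, alpha = 0)
  expect_equal(unname(encode_pwm(st, "AKC")), c(1, 1, 1))
  set.seed(13)
  pos10 <- vapply(1:10, function(i) rand_fragment(9), character(1))
  st2 <- fit_pwm(pos10)
  for (i in 1:5) {
    q <- rand_fragment(9)
    expect_equal(unname(encode_pwm(st2, q)), unname(oracle_pwm(pos10, q)))
  }
  expect_error(fit_pwm(character(0)), "at least one")
})

test_that("KNN feature distances and neighbor votes match brute force", {
  sim <- (blosum62_matrix() - min(blosum62_matrix())) /
    (max(blosum62_matrix()) - min(blosum62_matrix()))
  expect_equal(sim["W", "W"], 1)  # BLOSUM62 max is at (W,W)
  st <- fit_knn_feature(c("WKW", "AKA"), c("positive", "negative"))
  x <- encode_knn(st, "WKW", k_fracs = 0.5)
  expect_equal(unname(x), 1)
  set.seed(14)
  corp <- rand_corpus(50, L = 9)
  st2 <- fit_knn_feature(corp$fragments, corp$labels)
  for (i in 1:10) {
    q <- rand_fragment(9)
    expect_equal(unname(encode_knn(st2, q)),
                 unname(oracle_knn(corp$fragments, corp$labels, q)))
  }
})

test_that("KNN self-exclusion removes the fragment from its own pool", {
  frs <- c("WKW", "WKW", "AKA", "CKC")
  labs <- c("positive", "negative", "negative", "negative")
  st <- fit_knn_feature(frs, labs, ids = sprintf("f%d", 1:4))
  with_self <- encode_knn(st, "WKW", k_fracs = 0.25)
  no_self <- encode_knn(st, "WKW", k_fracs = 0.25, id = "f1")
  expect_equal(unname(with_self), 1)  # finds itself (positive) first
  expect_equal(unname(no_self), 0)    # nearest other is the negative twin
})

test_that("TF-IDF zeroes ubiquitous residues and matches the formula", {
  corpus <- c("AKC", "AKD", "AKY", "AKW")
  st <- fit_tfidf(corpus)
  x <- encode_tfidf(st, "AKA")
  expect_equal(unname(x[["TFIDF.A"]]), 0)   # A in every document
  expect_equal(unname(encode_tfidf(fit_tfidf("AKC"), "AKC")), rep(0, 20))
  set.seed(15)
  corp <- rand_corpus(4, L = 9)
  st2 <- fit_tfidf(corp$fragments)
  for (i in 1:5) {
    q <- rand_fragment(9)
    expect_equal(unname(encode_tfidf(st2, q)),
                 unname(oracle_tfidf(corp$fragments, q)))
  }
})

test_that("TF-CRF blocks coincide on a symmetric corpus and match the oracle", {
  corpus <- c("AKC", "DKY", "AKC", "DKY")
  labels <- c("positive", "positive", "negative", "negative")
  st <- fit_tfcrf(corpus, labels)
  x <- encode_tfcrf(st, "AKY")
  expect_equal(unname(x[1:20]), unname(x[21:40]), tolerance = 1e-5)
  expect_equal(unname(x[["TFCRF.pos.W"]]), 0)   # absent term
  set.seed(16)
  corp <- rand_corpus(6, L = 9)
  st2 <- fit_tfcrf(corp$fragments, corp$labels)
  for (i in 1:5) {
    q <- rand_fragment(9)
    expect_equal(unname(encode_tfcrf(st2, q)),
                 unname(oracle_tfcrf(corp$fragments, corp$labels, q)))
  }
})

test_that("PSSM window encoding looks up the parsed file's entries", {
  prot <- list(id = "P1", sequence = paste0(rep("ACDKY", 8), collapse = ""))
  prof <- generate_pssm(prot, seed = 21)
  x <- encode_pssm_window(prof, center_pos = 4L, half_width = 17L)
  expect_length(x, 700L)
  # positions before the protein start (offsets -17..0 of center 4) are zero
  expect_equal(sum(x[1:(20 * 14)] != 0), 0)
  # first in-range fragment position holds profile row 1
  expect_equal(unname(x[(20 * 14 + 1):(20 * 15)]), unname(prof$scores[1, ]))
  expect_error(encode_pssm_window(prof, 99L, 3L), "outside profile")
  expect_error(encode_pssm_window(NULL, 1L, 3L), "missing")
})

test_that("S-FPSSM clips scores and groups rows by residue", {
  prot <- list(id = "P1", sequence = "ACDKY")
  prof <- generate_pssm(prot, seed = 3)
  prof$scores[1, 1] <- -3
  prof$scores[2, 5] <- 9
  x <- encode_sfpssm(prof, delta = 7)
  expect_length(x, 400L)
  expect_equal(unname(x),
               unname(oracle_sfpssm(prof$scores, prof$row_residues)))
  zero <- prof
  zero$scores[] <- 0
  expect_equal(sum(encode_sfpssm(zero)), 0)
  # clipping: -3 -> 0 contribution, 9 -> 7
  expect_equal(unname(x[["SFPSSM.C.F"]]), 7)
})

test_that("assemble_features concatenates blocks with stable global names", {
  set.seed(17)
  frags <- data.frame(id = sprintf("f%d", 1:6),
                      protein_id = "P1", center_pos = 18:23,
                      residues = vapply(1:6, function(i) rand_fragment(35),
                                        character(1)),
                      label = rep(c("positive", "negative"), 3))
  prot <- list(id = "P1",
               sequence = paste0(sample(AA20, 60, replace = TRUE),
                                 collapse = ""))
  profiles <- list(P1 = generate_pssm(prot, seed = 1))
  fm <- assemble_features(frags, c("eaac", "egaac", "blosum62", "pssm"),
                          profiles = profiles)
  expect_equal(ncol(fm), 620L + 155L + 700L + 700L)
  expect_equal(rownames(fm), frags$id)
  expect_false(anyDuplicated(colnames(fm)) > 0)
  fm2 <- assemble_features(frags, c("eaac", "egaac", "blosum62", "pssm"),
                           profiles = profiles)
  expect_identical(fm, fm2)
  single <- assemble_features(frags, "eaac")
  expect_equal(unname(single[1, ]), unname(encode_eaac(frags$residues[1])))
  expect_error(assemble_features(frags, "bpb"), "fitted state")
})

test_that("fitted encoder states serialize to identical outputs", {
  set.seed(18)
  corp <- rand_corpus(20, L = 11)
  frags <- data.frame(id = sprintf("f%d", 1:20), protein_id = "p",
                      center_pos = 6L, residues = corp$fragments,
                      label = corp$labels)
  states <- fit_encoder_states(c("bpb", "pwm", "knn", "tfidf", "tfcrf"),
                               frags)
  f <- withr::local_tempfile(fileext = ".rds")
  write_encoder_state(states, f)
  states2 <- read_encoder_state(f)
  q <- rand_fragment(11)
  for (s in names(states)) {
    enc <- get(paste0("encode_", if (s == "knn") "knn" else s))
    expect_identical(enc(states[[s]], q), enc(states2[[s]], q))
  }
})

test_that("fitted encoders are leak-free: test labels never influence encodings", {
  set.seed(19)
  tr <- rand_corpus(16, L = 9)
  train <- data.frame(id = sprintf("t%d", 1:16), protein_id = "p",
                      center_pos = 5L, residues = tr$fragments,
                      label = tr$labels)
  te <- rand_corpus(8, L = 9)
  test1 <- data.frame(id = sprintf("e%d", 1:8), protein_id = "p",
                      center_pos = 5L, residues = te$fragments,
                      label = te$labels)
  test2 <- test1
  test2$label <- sample(test2$label)   # permuted held-out labels
  states <- fit_encoder_states(c("bpb", "pwm", "knn", "tfidf", "tfcrf"),
                               train)
  fm1 <- assemble_features(test1, c("bpb", "pwm", "knn", "tfidf", "tfcrf"),
                           states)
  fm2 <- assemble_features(test2, c("bpb", "pwm", "knn", "tfidf", "tfcrf"),
                           states)
  expect_identical(fm1, fm2)
})
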