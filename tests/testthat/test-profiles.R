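test_that("Henikoff weights match hand-evaluated column sums", {
  expect_equal(henikoff_weights("ACDE"), 1)
  expect_equal(henikoff_weights(c("ACDE", "ACDE")), c(0.5, 0.5))
  expect_equal(henikoff_weights(c("AA", "AA", "AC")),
               c(7 / 24, 7 / 24, 10 / 24), tolerance = 1e-12)
  expect_error(henikoff_weights(c("AC", "ACD")), "ragged")
})

test_that("single-sequence profile without pseudocounts is one-hot", {
  p <- build_aa_profile("ACDW", beta = 0)
  expect_equal(nrow(p$prob), 4)
  expect_equal(unname(p$prob[1, "A"]), 1)
  expect_equal(unname(p$prob[4, "W"]), 1)
  expect_equal(sum(p$prob[2, ]), 1)
  expect_equal(p$gap, rep(0, 4))
  expect_equal(p$sequence, "ACDW")
})

test_that("gap probability is the weighted gap fraction in the column", {
  # four rows identical except the gapped column keep equal Henikoff weights
  msa <- c("ACA", "A-A", "A-A", "ACA")
  p <- build_aa_profile(msa, beta = 0)
  expect_equal(p$gap[2], 0.5)
  expect_equal(p$gap[c(1, 3)], c(0, 0))
  # AA probabilities are renormalized independently of the gap mass
  expect_equal(sum(p$prob[2, ]), 1)
})

test_that("master-column convention drops master-gap columns", {
  msa <- c("AC-D", "ACWD")
  p <- build_aa_profile(msa, beta = 0)
  expect_equal(nrow(p$prob), 3)
  expect_equal(p$sequence, "ACD")
})

test_that("pseudocount mixing matches an independent evaluation", {
  # two identical sequences: w = (0.5, 0.5), Neff = 2, f_obs = one-hot
  msa <- c("A", "A")
  p <- build_aa_profile(msa, beta = 10)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- aa_alphabet()
  bg <- aa_background()[aa]
  Pab <- sweep(2^(e$BLOSUM62[aa, aa] / 2), 1, bg, "*")
  Pab <- sweep(Pab, 2, colSums(Pab), "/")
  f_obs <- setNames(as.numeric(aa == "A"), aa)
  expected <- (2 * f_obs + 10 * Pab[, "A"]) / 12
  expected <- expected / sum(expected)
  expect_equal(p$prob[1, ], expected, tolerance = 1e-12)
})

test_that("profile rows are simplexes and row order of homologs is irrelevant", {
  msa <- c("ACDEFG", "AC-EFG", "QCDEFA", "ACDWFG")
  p <- build_aa_profile(msa)
  expect_true(all(abs(rowSums(p$prob) - 1) < 1e-9))
  expect_true(all(p$prob >= 0))
  p2 <- build_aa_profile(msa[c(1, 4, 2, 3)])
  expect_equal(p2$prob, p$prob, tolerance = 1e-12)
  expect_equal(p2$gap, p$gap, tolerance = 1e-12)
})

test_that("larger beta pulls columns toward the pseudocount distribution", {
  msa <- c("A", "A")
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- aa_alphabet()
  pa <- vapply(c(0, 5, 50, 500),
               function(b) build_aa_profile(msa, beta = b)$prob[1, "A"],
               numeric(1))
  expect_true(all(diff(pa) < 0))        # P(A) decreases monotonically
  expect_equal(pa[1], 1)
})

test_that("structural frequency profiles handle members and fallbacks", {
  p1 <- build_pb_profile_from_structures("mmd", eps = 0)
  expect_equal(unname(p1$prob[1, "m"]), 1)
  p2 <- build_pb_profile_from_structures(c("m", "d"), eps = 0)
  expect_equal(unname(p2$prob[1, c("m", "d")]), c(0.5, 0.5))
  pz <- build_pb_profile_from_structures("Z")
  expect_equal(unname(pz$prob[1, ]), rep(1 / 16, 16))
  s1 <- build_sa_profile_from_structures(list(c(3L, 7L)), eps = 0)
  expect_equal(unname(s1$prob[1, "3"]), 1)
  s2 <- build_sa_profile_from_structures(list(1L, 10L), eps = 0)
  expect_equal(unname(s2$prob[1, c("1", "10")]), c(0.5, 0.5))
  sz <- build_sa_profile_from_structures(list(NA_integer_))
  expect_equal(unname(sz$prob[1, ]), rep(0.1, 10))
  # smoothing keeps rows on the simplex
  ps <- build_pb_profile_from_structures(c("mmm", "mdm"), eps = 0.05)
  expect_true(all(abs(rowSums(ps$prob) - 1) < 1e-9))
})

test_that("concat_hybrid enforces matching component lengths", {
  aa <- build_aa_profile(strrep("A", 30), beta = 0)
  pb <- build_pb_profile_from_structures(strrep("m", 30))
  sa <- build_sa_profile_from_structures(list(rep(2L, 30)))
  h <- concat_hybrid(aa, pb, sa, id = "t")
  expect_s3_class(h, "hybrid_profile")
  expect_equal(length(h), 30)
  pb29 <- build_pb_profile_from_structures(strrep("m", 29))
  expect_error(concat_hybrid(aa, pb29, sa), "PB profile has 29")
})

test_that("profile serialization round-trips bit-identically on text", {
  set.seed(3)
  q <- make_toy_query(make_toy_databank(2, 1, 20, seed = 5,
                                        sasa_points = 120),
                      "fold1", seed = 2, sasa_points = 120)$profile
  f <- tempfile(fileext = ".orp")
  write_profile(q, f)
  r <- read_profile(f)
  f2 <- tempfile(fileext = ".orp")
  write_profile(r, f2)
  expect_identical(readLines(f), readLines(f2))
  expect_equal(r$sequence, q$sequence)
  expect_equal(r$aa, q$aa, tolerance = 1e-3)  # written at 6 decimals
})

test_that("malformed profile files raise informative errors", {
  q <- build_query_profile(c("ACDEFGHIKLMNPQRS"))
  f <- tempfile(fileext = ".orp")
  write_profile(q, f)
  lines <- readLines(f)
  bad <- lines
  bad[9] <- paste(strsplit(bad[9], "\t")[[1]][1:10], collapse = "\t")
  fb <- tempfile(); writeLines(bad, fb)
  expect_error(read_profile(fb), "wrong column count.*line 9")
  bad2 <- lines
  bad2[1] <- "#ORP 99"
  fb2 <- tempfile(); writeLines(bad2, fb2)
  expect_error(read_profile(fb2), "unsupported version")
})
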