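uniform_col <- function() list(aa = rep(1 / 20, 20), pb = rep(1 / 16, 16),
                               sa = rep(0.1, 10))

onehot_col <- function(k) {
  c0 <- uniform_col()
  c0$aa <- as.numeric(seq_len(20) == k)
  c0
}

test_that("column score reproduces the closed-form co-emission cases", {
  p <- scoring_params(w_pb = 0, w_sa = 0, aa_bg = rep(1 / 20, 20))
  expect_equal(column_score(uniform_col(), uniform_col(), p), 0,
               tolerance = 1e-12)
  expect_equal(column_score(onehot_col(1), onehot_col(1), p), log2(20),
               tolerance = 1e-12)
  expect_equal(column_score(onehot_col(1), onehot_col(2), p), -10)
})

test_that("column_score_matrix agrees with the scalar column score", {
  set.seed(11)
  q <- random_profile(4); t <- random_profile(3)
  p <- scoring_params()
  S <- column_score_matrix(q, t, p)
  for (i in 1:4) for (j in 1:3) {
    qc <- list(aa = q$aa[i, ], pb = q$pb[i, ], sa = q$sa[i, ])
    tc <- list(aa = t$aa[j, ], pb = t$pb[j, ], sa = t$sa[j, ])
    expect_equal(S[i, j], column_score(qc, tc, p), tolerance = 1e-12)
  }
})

test_that("scoring parameter validation rejects bad inputs", {
  expect_error(scoring_params(gap_open = 0.1, gap_ext = 0.3), "gap_open")
  expect_error(scoring_params(aa_bg = c(0, rep(1, 19))), "zero background")
  expect_error(scoring_params(w_aa = -1), "weights")
})

test_that("gap penalties scale linearly with conservation", {
  prof <- structure(list(gap = c(0, 1, 0.5)), class = "hybrid_profile")
  gp <- gap_penalties(prof, scoring_params())
  expect_equal(gp$open, c(3, 0, 1.5))
  expect_equal(gp$ext, c(0.3, 0, 0.15))
})

test_that("DP optimum equals brute-force enumeration in all three modes", {
  set.seed(97)
  params <- scoring_params()
  for (trial in 1:40) {
    q <- random_profile(sample(1:5, 1))
    t <- random_profile(sample(1:5, 1))
    for (mode in c("gloloc", "local", "global")) {
      expect_equal(align_score(q, t, params, mode = mode),
                   oracle_align_score(q, t, params, mode),
                   tolerance = 1e-9,
                   info = paste(mode, "trial", trial))
    }
  }
})

test_that("traceback score equals the DP optimum and self-hits are perfect", {
  set.seed(5)
  q <- random_profile(12)
  params <- scoring_params(w_corr = 0)
  a <- align_profiles(q, q, params, mode = "global")
  S <- column_score_matrix(q, q, params)
  expect_equal(a$s_raw, sum(diag(S)), tolerance = 1e-9)
  expect_equal(a$identity, 100)
  expect_equal(a$coverage, 100)
  expect_equal(a$columns$q, 1:12)
  expect_equal(a$columns$t, 1:12)
})

test_that("gloloc consumes the template end to end inside a longer query", {
  set.seed(8)
  q <- random_profile(10)
  t <- q
  t$aa <- q$aa[4:7, , drop = FALSE]
  t$pb <- q$pb[4:7, , drop = FALSE]
  t$sa <- q$sa[4:7, , drop = FALSE]
  t$gap <- q$gap[4:7]
  t$sequence <- substr(q$sequence, 4, 7)
  a <- align_profiles(q, t, scoring_params(), mode = "gloloc")
  expect_equal(a$columns$t, 1:4)
  expect_equal(a$columns$q, 4:7)
  expect_equal(unname(a$bounds), c(4, 7, 1, 4))
})

test_that("mode optima are ordered local >= gloloc >= global", {
  set.seed(23)
  params <- scoring_params()
  for (trial in 1:15) {
    q <- random_profile(sample(3:8, 1))
    t <- random_profile(sample(3:8, 1))
    sl <- align_score(q, t, params, mode = "local")
    sg <- align_score(q, t, params, mode = "gloloc")
    sG <- align_score(q, t, params, mode = "global")
    expect_gte(sl, sg - 1e-12)
    expect_gte(sg, sG - 1e-12)
  }
})

test_that("raw score is symmetric in local and global modes", {
  set.seed(31)
  params <- scoring_params()
  for (trial in 1:10) {
    q <- random_profile(sample(3:6, 1))
    t <- random_profile(sample(3:6, 1))
    for (mode in c("local", "global")) {
      expect_equal(align_score(q, t, params, mode = mode),
                   align_score(t, q, params, mode = mode),
                   tolerance = 1e-9)
    }
  }
})

test_that("adding unrelated query flanks never lowers the gloloc score", {
  set.seed(41)
  params <- scoring_params()
  q <- random_profile(6); t <- random_profile(5)
  base <- align_score(q, t, params, mode = "gloloc")
  fl <- random_profile(3)
  ext <- q
  for (f in c("aa", "pb", "sa")) ext[[f]] <- rbind(fl[[f]], q[[f]], fl[[f]])
  ext$gap <- c(fl$gap, q$gap, fl$gap)
  ext$sequence <- paste0(fl$sequence, q$sequence, fl$sequence)
  expect_gte(align_score(ext, t, params, mode = "gloloc"), base - 1e-12)
})

test_that("correlation score matches enumeration and its closed form", {
  expect_equal(correlation_score(5, d = 4), 0)
  expect_equal(correlation_score(rep(1, 5), d = 0), 0)
  expect_equal(correlation_score(rep(1, 5), d = 2), 7)  # 2+2+2+1+0
  s <- c(1.5, -2, 0.5, 3, 1)
  brute <- 0
  for (l in 1:5) for (j in seq_len(min(4, 5 - l)))
    brute <- brute + s[l] * s[l + j]
  expect_equal(correlation_score(s, d = 4), brute, tolerance = 1e-12)
  # constant scores: s^2 * (d(L-d) + d(d-1)/2) for L >= d
  for (sc in c(0.5, 1, 2)) for (L in c(4, 6, 10)) for (d in c(1, 2, 4)) {
    expect_equal(correlation_score(rep(sc, L), d),
                 sc^2 * (d * (L - d) + d * (d - 1) / 2),
                 tolerance = 1e-12, info = paste(sc, L, d))
  }
})

test_that("alignment statistics follow the declared conventions", {
  cols <- data.frame(q = c(2, 3, NA, 4, 5, 6), t = c(1, 2, 3, 4, NA, 5))
  aln <- structure(list(columns = cols), class = "profile_alignment")
  st <- alignment_stats(aln, "AACDEFGHIK", "ACDXF")
  # matched columns: (2,1) A=C? etc: query AACDEFGHIK, template ACDXF
  # pairs: (A,A)=(2,1) id, (C,C)=(3,2) id, (D,X)=(4,4) no, (F,F)=(6,5) id
  expect_equal(st$identity, 100 * 3 / 4)
  expect_equal(st$coverage, 100 * 5 / 10)
  expect_equal(unname(st$bounds), c(2, 6, 1, 5))
  empty <- structure(list(columns = data.frame(q = integer(0),
                                               t = integer(0))),
                     class = "profile_alignment")
  st0 <- alignment_stats(empty, "AAA", "AAA")
  expect_equal(st0$identity, 0)
  expect_equal(st0$coverage, 0)
})
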