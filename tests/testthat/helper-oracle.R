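# Independent brute-force oracle for the profile aligner, plus small random
# profile generators.  The oracle enumerates every monotone set of matched
# column pairs and prices each side's skipped positions as single affine runs
# (with open >= ext >= 0, splitting a run never scores better), so its
# optimum equals the optimum over all gapped alignments.  It shares no code
# with the dynamic-programming recurrences it checks.

oracle_align_score <- function(query, template, params, mode) {
  S <- column_score_matrix(query, template, params)
  pq <- gap_penalties(query, params)
  pt <- gap_penalties(template, params)
  n <- nrow(S); m <- ncol(S)
  run_cost <- function(pen, from, to) {
    if (from > to) return(0)
    pen$open[from] + sum(pen$ext[seq(from + 1, length.out = to - from)])
  }
  score_matching <- function(qs, ts) {
    k <- length(qs)
    if (k == 0) {
      return(switch(mode,
                    local = 0,
                    gloloc = -run_cost(pt, 1, m),
                    global = -run_cost(pq, 1, n) - run_cost(pt, 1, m)))
    }
    sc <- sum(S[cbind(qs, ts)])
    if (k > 1) for (z in seq_len(k - 1)) {
      sc <- sc - run_cost(pq, qs[z] + 1, qs[z + 1] - 1)
      sc <- sc - run_cost(pt, ts[z] + 1, ts[z + 1] - 1)
    }
    if (mode == "global")
      sc <- sc - run_cost(pq, 1, qs[1] - 1) - run_cost(pq, qs[k] + 1, n) -
        run_cost(pt, 1, ts[1] - 1) - run_cost(pt, ts[k] + 1, m)
    if (mode == "gloloc")
      sc <- sc - run_cost(pt, 1, ts[1] - 1) - run_cost(pt, ts[k] + 1, m)
    sc
  }
  best <- score_matching(integer(0), integer(0))
  for (k in seq_len(min(n, m))) {
    qsets <- utils::combn(n, k, simplify = FALSE)
    tsets <- utils::combn(m, k, simplify = FALSE)
    for (qs in qsets) for (ts in tsets)
      best <- max(best, score_matching(qs, ts))
  }
  if (mode == "local") max(best, 0) else best
}

# random probability-simplex rows
random_simplex <- function(L, k) {
  x <- matrix(stats::rexp(L * k), L, k)
  x / rowSums(x)
}

# random hybrid profile of length L (random composition, gap probabilities
# uniform on [0, 0.8], random master sequence)
random_profile <- function(L, id = "rp") {
  aa <- random_simplex(L, 20); colnames(aa) <- aa_alphabet()
  pb <- random_simplex(L, 16); colnames(pb) <- pb_alphabet()
  sa <- random_simplex(L, 10); colnames(sa) <- as.character(1:10)
  structure(list(
    id = id, description = "random",
    sequence = paste(sample(aa_alphabet(), L, replace = TRUE), collapse = ""),
    aa = aa, gap = stats::runif(L, 0, 0.8), pb = pb, sa = sa),
    class = "hybrid_profile")
}
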