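# Profile-profile alignment: hybrid column scoring, position-specific affine
# gap penalties, three-mode dynamic programming with deterministic traceback,
# the clustered-conservation correlation score, and alignment statistics.

#' Scoring parameters for profile-profile alignment
#'
#' @param w_aa,w_pb,w_sa component weights for the amino-acid, Protein Blocks
#'   and solvent-accessibility tracks (defaults 1, 1, 0.5).
#' @param s_min floor on each component's log-odds score, in bits
#'   (default -10); zero co-emission would otherwise give -Inf.
#' @param gap_open,gap_ext base affine gap penalties in bits (defaults 3.0
#'   and 0.3); scaled per position by (1 - gap probability), so
#'   frequently-gapped columns are cheap to gap.
#' @param corr_window sliding-window length d of the correlation score
#'   (default 4).
#' @param w_corr weight of the correlation score in the total (default 0.1).
#' @param mode alignment mode: \code{"gloloc"} (query aligned locally along
#'   the full template, the default), \code{"local"}, or \code{"global"}.
#' @param aa_bg,pb_bg,sa_bg background distributions of the three tracks.
#' @return object of class \code{scoring_params}.
#' @export
scoring_params <- function(w_aa = 1, w_pb = 1, w_sa = 0.5, s_min = -10,
                           gap_open = 3.0, gap_ext = 0.3, corr_window = 4,
                           w_corr = 0.1,
                           mode = c("gloloc", "local", "global"),
                           aa_bg = aa_background(), pb_bg = pb_background(),
                           sa_bg = rep(0.1, 10)) {
  mode <- match.arg(mode)
  if (any(c(w_aa, w_pb, w_sa) < 0)) stop("component weights must be >= 0")
  if (!(gap_open >= gap_ext && gap_ext >= 0))
    stop("need gap_open >= gap_ext >= 0")
  if (corr_window < 0) stop("corr_window must be >= 0")
  for (bg in list(aa_bg, pb_bg, sa_bg))
    if (any(bg <= 0)) stop("zero background entry")
  structure(list(w_aa = w_aa, w_pb = w_pb, w_sa = w_sa, s_min = s_min,
                 gap_open = gap_open, gap_ext = gap_ext,
                 corr_window = corr_window, w_corr = w_corr, mode = mode,
                 aa_bg = aa_bg, pb_bg = pb_bg, sa_bg = sa_bg),
            class = "scoring_params")
}

# one component's co-emission log-odds matrix: log2( Q diag(1/bg) T' ),
# floored at s_min
.coemission <- function(Q, T, bg, s_min) {
  co <- (Q %*% (t(T) / bg))
  pmax(log2(pmax(co, 0)), s_min)
}

#' Column-score matrix between two hybrid profiles
#'
#' Score of aligning query column i to template column j: the weighted sum
#' over the three tracks of the co-emission log-odds
#' \deqn{S = \sum_c w_c \max(S_{min}, \log_2 \sum_a q_c(a) t_c(a) / f_c(a)).}
#'
#' @param query,template \code{hybrid_profile}s.
#' @param params a [scoring_params()].
#' @return numeric matrix, query positions x template positions, in bits.
#' @export
column_score_matrix <- function(query, template, params = scoring_params()) {
  params$w_aa * .coemission(query$aa, template$aa, params$aa_bg, params$s_min) +
  params$w_pb * .coemission(query$pb, template$pb, params$pb_bg, params$s_min) +
  params$w_sa * .coemission(query$sa, template$sa, params$sa_bg, params$s_min)
}

#' Score of a single pair of hybrid columns
#'
#' @param q_col,t_col lists with elements \code{aa}, \code{pb}, \code{sa}
#'   (probability vectors of lengths 20, 16, 10).
#' @param params a [scoring_params()].
#' @return score in bits.
#' @export
column_score <- function(q_col, t_col, params = scoring_params()) {
  comp <- function(q, t, bg, w)
    w * max(log2(max(sum(q * t / bg), 0)), params$s_min)
  comp(q_col$aa, t_col$aa, params$aa_bg, params$w_aa) +
    comp(q_col$pb, t_col$pb, params$pb_bg, params$w_pb) +
    comp(q_col$sa, t_col$sa, params$sa_bg, params$w_sa)
}

#' Position-specific affine gap penalties of a profile
#'
#' Conserved (rarely gapped) columns should accept fewer gaps: penalties are
#' the base costs scaled by (1 - g_i), where g_i is the profile's gap
#' probability at position i.  A gap opposite position i pays the penalty of
#' the position being skipped.
#'
#' @param profile a \code{hybrid_profile} (its \code{gap} field is used;
#'   missing/NULL gap treated as all-zero).
#' @param params a [scoring_params()].
#' @return list with numeric vectors \code{open} and \code{ext}.
#' @export
gap_penalties <- function(profile, params = scoring_params()) {
  g <- profile$gap
  if (is.null(g)) g <- numeric(length(profile))
  list(open = params$gap_open * (1 - g), ext = params$gap_ext * (1 - g))
}

#' Correlation score over per-position alignment scores
#'
#' Rewards clustering of high-scoring columns: the sum over positions l of
#' S_l times the sum of the following scores within a forward window of
#' length d, \deqn{S_{corr} = \sum_l S_l \sum_{j=1}^{\min(d, L-l)} S_{l+j}.}
#'
#' @param s numeric vector of per-position scores (gap columns contribute 0).
#' @param d window length (default 4).
#' @return the correlation score.
#' @export
correlation_score <- function(s, d = 4) {
  L <- length(s)
  if (L < 2 || d < 1) return(0)
  tot <- 0
  for (j in seq_len(min(d, L - 1)))
    tot <- tot + sum(s[seq_len(L - j)] * s[seq_len(L - j) + j])
  tot
}

# DP over three states.  M[i,j]: query i aligned to template j;
# X[i,j]: ends with query i consumed against a gap (gap in template);
# Y[i,j]: ends with template j consumed against a gap (gap in query).
# Gap runs pay open at their first skipped position, ext at the rest, using
# the penalties of the profile being consumed.
.dp_align <- function(S, pq, pt, mode) {
  n <- nrow(S); m <- ncol(S)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  # pointer codes: 0 start, 1 M, 2 X, 3 Y
  Mp <- matrix(0L, n + 1, m + 1)
  Xp <- matrix(0L, n + 1, m + 1)
  Yp <- matrix(0L, n + 1, m + 1)
  free_q_ends <- mode %in% c("gloloc", "local")
  free_t_ends <- mode == "local"
  M[1, 1] <- 0
  if (free_q_ends) M[seq_len(n) + 1, 1] <- 0
  else if (n >= 1) {
    X[2, 1] <- -pq$open[1]; Xp[2, 1] <- 0L
    for (i in seq_len(n - 1) + 1) { X[i + 1, 1] <- X[i, 1] - pq$ext[i]; Xp[i + 1, 1] <- 2L }
  }
  if (free_t_ends) M[1, seq_len(m) + 1] <- 0
  else if (m >= 1) {
    Y[1, 2] <- -pt$open[1]; Yp[1, 2] <- 0L
    for (j in seq_len(m - 1) + 1) { Y[1, j + 1] <- Y[1, j] - pt$ext[j]; Yp[1, j + 1] <- 3L }
  }
  local <- mode == "local"
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      # match step: tie preference match > delete (Y) > insert (X)
      cand <- c(M[i, j], Y[i, j], X[i, j])
      k <- which.max(cand)
      v <- cand[k]
      ptr <- c(1L, 3L, 2L)[k]
      if (local && v < 0) { v <- 0; ptr <- 0L }
      M[i + 1, j + 1] <- S[i, j] + v
      Mp[i + 1, j + 1] <- ptr
      # X: consume query i against a gap (skip query position i); a run
      # opens from M or Y (cost open_q[i]) and extends from X (cost ext_q[i])
      xc <- c(M[i, j + 1] - pq$open[i],
              X[i, j + 1] - pq$ext[i],
              Y[i, j + 1] - pq$open[i])
      kx <- which.max(xc)
      X[i + 1, j + 1] <- xc[kx]
      Xp[i + 1, j + 1] <- c(1L, 2L, 3L)[kx]
      # Y: consume template j against a gap
      yc <- c(M[i + 1, j] - pt$open[j],
              Y[i + 1, j] - pt$ext[j],
              X[i + 1, j] - pt$open[j])
      ky <- which.max(yc)
      Y[i + 1, j + 1] <- yc[ky]
      Yp[i + 1, j + 1] <- c(1L, 3L, 2L)[ky]
    }
  }
  list(M = M, X = X, Y = Y, Mp = Mp, Xp = Xp, Yp = Yp)
}

#' Align two hybrid profiles
#'
#' Affine-gap dynamic programming over match/insert/delete states with
#' position-specific penalties ([gap_penalties()]).  Modes: \code{"global"}
#' consumes both profiles end to end; \code{"local"} is Smith-Waterman
#' (scores clamped at zero, free ends on both sides); \code{"gloloc"} aligns
#' the query locally along the entire length of the template (query flanks
#' free, every template column consumed).  Traceback ties prefer match over
#' delete over insert.  The correlation score is computed on the
#' per-alignment-column scores (gap columns scoring 0) and added with weight
#' \code{w_corr}.
#'
#' @param query,template \code{hybrid_profile}s.
#' @param params a [scoring_params()].
#' @param mode overrides \code{params$mode} if given.
#' @return object of class \code{profile_alignment}: \code{columns}
#'   (data.frame with query/template indices, NA at gaps), \code{s_l}
#'   (per-column scores), \code{s_raw}, \code{s_corr}, \code{total},
#'   \code{bounds}, \code{identity}, \code{coverage}, \code{mode}.
#' @export
align_profiles <- function(query, template, params = scoring_params(),
                           mode = NULL) {
  if (!length(query) || !length(template)) stop("empty profile")
  mode <- mode %||% params$mode
  S <- column_score_matrix(query, template, params)
  pq <- gap_penalties(query, params)
  pt <- gap_penalties(template, params)
  dp <- .dp_align(S, pq, pt, mode)
  n <- length(query); m <- length(template)
  # terminal cell/state per mode
  if (mode == "global") {
    endv <- c(dp$M[n + 1, m + 1], dp$Y[n + 1, m + 1], dp$X[n + 1, m + 1])
    k <- which.max(endv)
    end <- list(i = n, j = m, state = c("M", "Y", "X")[k], score = endv[k])
  } else if (mode == "gloloc") {
    colM <- dp$M[, m + 1]; colY <- dp$Y[, m + 1]
    vals <- pmax(colM, colY)
    i <- which.max(vals) - 1L
    st <- if (colM[i + 1] >= colY[i + 1]) "M" else "Y"
    end <- list(i = i, j = m, state = st, score = vals[i + 1])
  } else {
    best <- max(0, max(dp$M))
    if (best <= 0) {
      end <- list(i = 0L, j = 0L, state = "0", score = 0)
    } else {
      idx <- which(dp$M == best, arr.ind = TRUE)[1, ]
      end <- list(i = idx[1] - 1L, j = idx[2] - 1L, state = "M", score = best)
    }
  }
  # traceback
  qi <- integer(0); tj <- integer(0)
  i <- end$i; j <- end$j; st <- end$state
  while (st != "0") {
    if (st == "M") {
      qi <- c(i, qi); tj <- c(j, tj)
      p <- dp$Mp[i + 1, j + 1]
      i <- i - 1; j <- j - 1
      st <- c("0", "M", "X", "Y")[p + 1]
      if (st == "M" && (i == 0 || j == 0)) st <- "0"  # border init = free start
    } else if (st == "X") {
      qi <- c(i, qi); tj <- c(NA, tj)
      p <- dp$Xp[i + 1, j + 1]
      i <- i - 1
      st <- c("0", "M", "X", "Y")[p + 1]
      if (st == "M" && (i == 0 || j == 0)) st <- "0"
    } else if (st == "Y") {
      qi <- c(NA, qi); tj <- c(j, tj)
      p <- dp$Yp[i + 1, j + 1]
      j <- j - 1
      st <- c("0", "M", "X", "Y")[p + 1]
      if (st == "M" && (i == 0 || j == 0)) st <- "0"
    } else break
  }
  cols <- data.frame(q = qi, t = tj)
  s_l <- ifelse(!is.na(qi) & !is.na(tj), S[cbind(qi, tj)], 0)
  s_corr <- correlation_score(s_l, params$corr_window)
  res <- structure(list(
    columns = cols, s_l = s_l, s_raw = end$score, s_corr = s_corr,
    total = end$score + params$w_corr * s_corr, mode = mode,
    query_id = query$id, template_id = template$id), class = "profile_alignment")
  st2 <- alignment_stats(res, query$sequence, template$sequence)
  res$identity <- st2$identity
  res$coverage <- 100 * sum(!is.na(qi)) / n
  res$bounds <- st2$bounds
  res
}

#' Score-only optimal alignment score (no traceback)
#'
#' @inheritParams align_profiles
#' @return the optimal raw alignment score in bits.
#' @export
align_score <- function(query, template, params = scoring_params(),
                        mode = NULL) {
  mode <- mode %||% params$mode
  S <- column_score_matrix(query, template, params)
  dp <- .dp_align(S, gap_penalties(query, params),
                  gap_penalties(template, params), mode)
  n <- length(query); m <- length(template)
  if (mode == "global") max(dp$M[n + 1, m + 1], dp$X[n + 1, m + 1], dp$Y[n + 1, m + 1])
  else if (mode == "gloloc") max(dp$M[, m + 1], dp$Y[, m + 1])
  else max(0, dp$M)
}

#' Identity, coverage and bounds of an alignment
#'
#' Identity: identical residue pairs over aligned (gap-free) columns, in
#' percent; coverage: aligned query positions over the query length; bounds:
#' 1-based inclusive start/end on query and template.  An empty alignment
#' reports zero identity and coverage.
#'
#' @param aln a \code{profile_alignment}.
#' @param query_seq,template_seq master sequences (single strings).
#' @return list with \code{identity}, \code{coverage}, \code{bounds}.
#' @export
alignment_stats <- function(aln, query_seq, template_seq) {
  cols <- aln$columns
  mt <- which(!is.na(cols$q) & !is.na(cols$t))
  qpos <- cols$q[!is.na(cols$q)]
  if (!length(mt)) {
    return(list(identity = 0, coverage = 0,
                bounds = c(q_start = 0L, q_end = 0L,
                           t_start = 0L, t_end = 0L)))
  }
  qc <- strsplit(query_seq, "")[[1]][cols$q[mt]]
  tc <- strsplit(template_seq, "")[[1]][cols$t[mt]]
  ident <- 100 * sum(qc == tc) / length(mt)
  cov <- 100 * length(qpos) / nchar(query_seq)
  list(identity = ident, coverage = cov,
       bounds = c(q_start = min(cols$q, na.rm = TRUE),
                  q_end = max(cols$q, na.rm = TRUE),
                  t_start = min(cols$t, na.rm = TRUE),
                  t_end = max(cols$t, na.rm = TRUE)))
}

#' @export
print.profile_alignment <- function(x, ...) {
  b <- x$bounds
  cat(sprintf(
    "profile_alignment [%s] %s vs %s: total %.2f (raw %.2f, corr %.2f)\n",
    x$mode, x$query_id, x$template_id, x$total, x$s_raw, x$s_corr))
  cat(sprintf("  query %d-%d, template %d-%d, identity %.1f%%, coverage %.1f%%\n",
              b["q_start"], b["q_end"], b["t_start"], b["t_end"],
              x$identity, x$coverage))
  invisible(x)
}
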