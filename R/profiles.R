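# Profile construction: Henikoff sequence weighting, amino-acid profiles with
# substitution-matrix pseudocounts, structural (PB / SA) frequency profiles,
# hybrid concatenation and text serialization.

.pkg_cache <- new.env(parent = emptyenv())

# normalize an MSA given as strings or matrix into an uppercase character
# matrix with '-' for gaps ('.' accepted as gap on input)
.msa_matrix <- function(msa) {
  if (is.character(msa) && !is.matrix(msa)) {
    if (!length(msa)) stop("empty MSA")
    w <- nchar(msa)
    if (length(unique(w)) != 1) stop("ragged MSA: rows differ in length")
    msa <- do.call(rbind, strsplit(toupper(msa), ""))
  }
  msa[msa == "."] <- "-"
  msa
}

#' Henikoff position-based sequence weights
#'
#' Each sequence accumulates 1/(r * s) over the alignment columns, where r is
#' the number of distinct symbols in the column and s the multiplicity of the
#' sequence's own symbol; gap characters count as a symbol type in mixed
#' columns and all-gap columns are skipped.  Weights are normalized to sum
#' to one.
#'
#' @param msa character vector of equal-length aligned sequences, or a
#'   character matrix (rows = sequences).
#' @return numeric vector of per-sequence weights summing to 1.
#' @export
henikoff_weights <- function(msa) {
  m <- .msa_matrix(msa)
  n <- nrow(m)
  w <- numeric(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    if (all(col == "-")) next
    tab <- table(col)
    r <- length(tab)
    w <- w + 1 / (r * as.numeric(tab[col]))
  }
  if (sum(w) == 0) w <- rep(1, n)
  w / sum(w)
}

# BLOSUM62 conditional probabilities P(a | b), reconstructed from the
# half-bit score matrix via P(a|b) proportional to bg(a) * 2^(S(a,b)/2)
.blosum_conditional <- function() {
  if (!is.null(.pkg_cache$blosum_cond)) return(.pkg_cache$blosum_cond)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- aa_alphabet()
  S <- e$BLOSUM62[aa, aa]
  bg <- aa_background()[aa]
  P <- sweep(2^(S / 2), 1, bg, "*")      # rows: a, cols: b
  P <- sweep(P, 2, colSums(P), "/")
  .pkg_cache$blosum_cond <- P
  P
}

#' Amino-acid profile from a multiple sequence alignment
#'
#' Columns where the master sequence is gapped are dropped, so the profile
#' lives in master (query) coordinates.  Observed frequencies use Henikoff
#' weights; \code{X} residues contribute the background composition.  The
#' observed distribution is mixed with BLOSUM62 conditional pseudocounts,
#' \deqn{p' = (N_{eff} f_{obs} + \beta f_{pc}) / (N_{eff} + \beta),}
#' with effective sequence count N_eff = 1 / sum(w_i^2).  The per-column gap
#' probability (weighted gap fraction) is stored beside the amino-acid
#' simplex, which is renormalized to one on its own.
#'
#' @param msa aligned sequences (character vector or matrix).
#' @param master_index 1-based row of the master/query sequence (default 1).
#' @param beta pseudocount admixture weight (default 10; 0 disables).
#' @return object of class \code{aa_profile}: list with \code{prob}
#'   (L x 20 matrix), \code{gap} (length-L vector), \code{sequence} (master,
#'   degapped).
#' @export
build_aa_profile <- function(msa, master_index = 1, beta = 10) {
  m <- .msa_matrix(msa)
  if (master_index < 1 || master_index > nrow(m))
    stop("master index out of range")
  master <- m[master_index, ]
  keep <- which(master != "-")
  if (!length(keep)) stop("master sequence is all gaps")
  w <- henikoff_weights(m)
  neff <- 1 / sum(w^2)
  aa <- aa_alphabet()
  bg <- aa_background()[aa]
  P <- .blosum_conditional()
  L <- length(keep)
  prob <- matrix(0, L, 20, dimnames = list(NULL, aa))
  gap <- numeric(L)
  for (l in seq_len(L)) {
    col <- m[, keep[l]]
    gap[l] <- sum(w[col == "-"])
    f <- setNames(numeric(20), aa)
    for (s in seq_len(nrow(m))) {
      ch <- col[s]
      if (ch == "-") next
      if (ch %in% aa) f[ch] <- f[ch] + w[s]
      else f <- f + w[s] * bg            # 'X' and other unknowns
    }
    if (sum(f) == 0) f <- bg else f <- f / sum(f)
    if (beta > 0) {
      fpc <- as.numeric(P %*% f)
      f <- (neff * f + beta * fpc) / (neff + beta)
    }
    prob[l, ] <- f / sum(f)
  }
  structure(list(prob = prob, gap = gap,
                 sequence = paste(master[keep], collapse = "")),
            class = "aa_profile")
}

# shared builder for PB / SA structural frequency profiles
.struct_profile <- function(aligned_states, master_index, n_states, labels,
                            eps) {
  if (!length(aligned_states)) stop("no member states")
  len <- unique(vapply(aligned_states, length, integer(1)))
  if (length(len) != 1) stop("length mismatch between aligned member states")
  master <- aligned_states[[master_index]]
  keep <- which(!vapply(master, function(x) identical(x, "-"), logical(1)))
  if (!length(keep)) stop("master row is all gaps")
  L <- length(keep)
  prob <- matrix(0, L, n_states, dimnames = list(NULL, labels))
  for (l in seq_len(L)) {
    cnt <- setNames(numeric(n_states), labels)
    for (s in aligned_states) {
      v <- s[[keep[l]]]
      if (!is.na(v) && v %in% labels) cnt[as.character(v)] <- cnt[as.character(v)] + 1
    }
    tot <- sum(cnt)
    if (tot == 0) prob[l, ] <- 1 / n_states
    else prob[l, ] <- (1 - eps) * cnt / tot + eps / n_states
  }
  prob
}

#' Protein Blocks profile from aligned member PB strings
#'
#' Per-column frequencies of the 16 PB letters over family members mapped
#' onto the family alignment, with uniform smoothing weight \code{eps};
#' columns carrying only undefined (\code{Z}) or gap evidence are uniform
#' 1/16.  Columns where the master is gapped are dropped.
#'
#' @param aligned_pb character vector of aligned PB strings ('-' at gap
#'   columns, \code{Z} for unassignable positions).
#' @param master_index 1-based master row (default 1).
#' @param eps smoothing weight toward uniform (default 0.05).
#' @return object of class \code{pb_profile} with \code{prob} (L x 16).
#' @export
build_pb_profile_from_structures <- function(aligned_pb, master_index = 1,
                                             eps = 0.05) {
  rows <- lapply(aligned_pb, function(s) strsplit(s, "")[[1]])
  prob <- .struct_profile(rows, master_index, 16, pb_alphabet(), eps)
  structure(list(prob = prob), class = "pb_profile")
}

#' Solvent-accessibility profile from aligned member class sequences
#'
#' As [build_pb_profile_from_structures()] with the ten accessibility
#' classes; undefined columns fall back to uniform 1/10.
#'
#' @param aligned_sa list of integer vectors aligned to the family alignment
#'   (classes 1..10, \code{NA} at gaps/undefined), or character vectors where
#'   \code{"-"} marks a gap.
#' @param master_index 1-based master row (default 1).
#' @param eps smoothing weight (default 0.05).
#' @return object of class \code{sa_profile} with \code{prob} (L x 10).
#' @export
build_sa_profile_from_structures <- function(aligned_sa, master_index = 1,
                                             eps = 0.05) {
  rows <- lapply(aligned_sa, function(s) {
    v <- as.list(s)
    lapply(v, function(x) if (identical(x, "-")) "-" else
      if (is.na(suppressWarnings(as.integer(x)))) NA else as.integer(x))
  })
  prob <- .struct_profile(rows, master_index, 10, as.character(1:10), eps)
  structure(list(prob = prob), class = "sa_profile")
}

#' Concatenate component profiles into a hybrid profile
#'
#' @param aa an \code{aa_profile}.
#' @param pb a \code{pb_profile}.
#' @param sa an \code{sa_profile}.
#' @param id,description metadata strings.
#' @return object of class \code{hybrid_profile}: fields \code{id},
#'   \code{description}, \code{sequence}, \code{aa} (L x 20), \code{gap}
#'   (L), \code{pb} (L x 16), \code{sa} (L x 10).
#' @export
concat_hybrid <- function(aa, pb, sa, id = "query", description = "") {
  for (comp in list(aa = aa, pb = pb, sa = sa))
    if (!nrow(comp$prob)) stop("empty profile")
  L <- nrow(aa$prob)
  if (nrow(pb$prob) != L)
    stop("length mismatch: PB profile has ", nrow(pb$prob),
         " positions, AA profile has ", L)
  if (nrow(sa$prob) != L)
    stop("length mismatch: SA profile has ", nrow(sa$prob),
         " positions, AA profile has ", L)
  structure(list(id = id, description = description,
                 sequence = aa$sequence, aa = aa$prob, gap = aa$gap,
                 pb = pb$prob, sa = sa$prob),
            class = "hybrid_profile")
}

#' @export
length.hybrid_profile <- function(x) nrow(x$aa)

#' @export
print.hybrid_profile <- function(x, ...) {
  cat("hybrid_profile '", x$id, "': ", length(x),
      " positions (20 AA + gap | 16 PB | 10 SA)\n", sep = "")
  invisible(x)
}

#' Build a query hybrid profile
#'
#' Assembles the searchable object for a query: the amino-acid track from its
#' MSA, and structural tracks either from per-residue PB / SA state strings
#' (e.g. an external predictor's one-best output, smoothed), from
#' ready-made probability matrices, or — when no structural information is
#' available — uniform distributions, which score neutrally against any
#' template under the background used here.
#'
#' @param msa aligned sequences, master first (or see \code{master_index}).
#' @param pb PB string of the master, L x 16 probability matrix, or NULL.
#' @param sa integer vector of SA classes, L x 10 matrix, or NULL.
#' @param master_index master row in the MSA.
#' @param beta pseudocount weight for the AA track.
#' @param eps smoothing for state-string structural tracks.
#' @param id,description metadata.
#' @return a [concat_hybrid()] \code{hybrid_profile}.
#' @export
build_query_profile <- function(msa, pb = NULL, sa = NULL, master_index = 1,
                                beta = 10, eps = 0.05, id = "query",
                                description = "") {
  aa <- build_aa_profile(msa, master_index = master_index, beta = beta)
  L <- nrow(aa$prob)
  pbp <- if (is.null(pb)) {
    structure(list(prob = matrix(1 / 16, L, 16,
                                 dimnames = list(NULL, pb_alphabet()))),
              class = "pb_profile")
  } else if (is.matrix(pb)) {
    structure(list(prob = pb), class = "pb_profile")
  } else build_pb_profile_from_structures(pb, eps = eps)
  sap <- if (is.null(sa)) {
    structure(list(prob = matrix(0.1, L, 10,
                                 dimnames = list(NULL, as.character(1:10)))),
              class = "sa_profile")
  } else if (is.matrix(sa)) {
    structure(list(prob = sa), class = "sa_profile")
  } else build_sa_profile_from_structures(list(sa), eps = eps)
  concat_hybrid(aa, pbp, sap, id = id, description = description)
}
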