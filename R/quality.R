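# Model-quality utilities: sequence-permutation decoys, decoy-based z-score,
# the four-band quality classification, and per-residue score smoothing.

#' Random sequence-permutation decoy
#'
#' Uniformly random permutation of the residue labels of a sequence,
#' deterministic for a given seed; callers rescore decoys themselves.
#'
#' @param sequence single string or character vector of residues.
#' @param seed integer seed.
#' @return decoy of the same type as the input.
#' @export
permute_sequence_decoy <- function(sequence, seed) {
  as_string <- length(sequence) == 1 && nchar(sequence[1]) > 1
  ch <- if (as_string) strsplit(sequence, "")[[1]] else sequence
  perm <- .with_seed(seed, sample.int(length(ch)))
  out <- ch[perm]
  if (as_string) paste(out, collapse = "") else out
}

#' z-score of a model score against decoys
#'
#' z = (model - mean(decoys)) / sd(decoys), with the n-1 standard deviation;
#' for energy-like scores, lower (more negative) z means a better model.
#'
#' @param model_score numeric scalar.
#' @param decoy_scores numeric vector of at least two, not all equal,
#'   decoy scores (conventionally 50).
#' @return the z-score.
#' @export
zscore_from_decoys <- function(model_score, decoy_scores) {
  if (length(decoy_scores) < 2) stop("need at least 2 decoy scores")
  s <- stats::sd(decoy_scores)
  if (s == 0) stop("decoy scores have zero variance")
  (model_score - mean(decoy_scores)) / s
}

#' Classify model quality from a decoy z-score
#'
#' Bands: z > -1 poor; -2 <= z <= -1 medium; -4 <= z < -2 reliable;
#' z < -4 native-like.  Boundary values are assigned to the better
#' (lower-energy) class.
#'
#' @param z z-score from [zscore_from_decoys()].
#' @return one of \code{"poor"}, \code{"medium"}, \code{"reliable"},
#'   \code{"native-like"}.
#' @export
classify_quality <- function(z) {
  if (z < -4) "native-like"
  else if (z <= -2) "reliable"
  else if (z <= -1) "medium"
  else "poor"
}

#' Sliding-window mean of per-residue scores
#'
#' Centred moving mean with the window truncated at the chain ends (no
#' padding); output length equals input length.
#'
#' @param values numeric vector of per-residue scores.
#' @param window window length (default 15).
#' @return smoothed numeric vector.
#' @export
smooth_scores <- function(values, window = 15) {
  n <- length(values)
  half <- (window - 1) %/% 2
  up <- window - 1 - half                # even windows extend one more ahead
  vapply(seq_len(n), function(i)
    mean(values[max(1, i - half):min(n, i + up)]), numeric(1))
}

#' Full quality report for a model
#'
#' @param model_score global model score (energy-like; lower is better).
#' @param decoy_scores decoy score vector (conventionally 50 values).
#' @param per_residue optional per-residue score vector to smooth.
#' @param window smoothing window (default 15).
#' @return list with \code{global}, \code{z}, \code{category},
#'   \code{smoothed} (NULL without per-residue scores), and the
#'   pseudo-energy \code{threshold} 0 above which local quality is poor.
#' @export
quality_report <- function(model_score, decoy_scores, per_residue = NULL,
                           window = 15) {
  z <- zscore_from_decoys(model_score, decoy_scores)
  list(global = model_score, z = z, category = classify_quality(z),
       smoothed = if (!is.null(per_residue))
         smooth_scores(per_residue, window),
       threshold = 0)
}

# evaluate expr with a local RNG seeded at `seed`, restoring caller state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
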