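# Deterministic synthetic fixtures: ideal-geometry toy backbones realizing
# prescribed dihedrals or Protein Blocks strings, mutated MSAs, and toy fold
# databanks, so every module is testable without external data.

# ideal peptide geometry (Engh-Huber-like averages), Angstrom / degrees
.GEO <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231,
             ca_cb = 1.530, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
             ang_c_n_ca = 121.7, ang_ca_c_o = 120.8, ang_c_ca_cb = 110.1,
             tor_n_c_ca_cb = 122.6, omega = 180)

#' Build a toy backbone from per-residue dihedrals
#'
#' Grows an N/CA/C/O (+CB except glycine) chain by internal-coordinate
#' placement with ideal bond lengths and angles and the requested phi/psi;
#' omega is fixed at 180 degrees.  The construction is purely arithmetic and
#' bit-reproducible.
#'
#' @param segments data.frame (or list of triples) with columns \code{phi},
#'   \code{psi}, \code{length}: each segment contributes \code{length}
#'   residues with those dihedrals.
#' @param sequence optional one-letter sequence (single string); default
#'   poly-alanine.
#' @param id chain id.
#' @return a [structure_chain()].
#' @export
make_backbone <- function(segments, sequence = NULL, id = "toy") {
  if (!is.data.frame(segments))
    segments <- do.call(rbind, lapply(segments, function(s)
      data.frame(phi = s[1], psi = s[2], length = s[3])))
  phi <- rep(segments$phi, segments$length)
  psi <- rep(segments$psi, segments$length)
  .backbone_from_dihedrals(phi, psi, sequence = sequence, id = id)
}

.backbone_from_dihedrals <- function(phi, psi, sequence = NULL, id = "toy") {
  n <- length(phi)
  if (n < 1) stop("empty segment plan")
  if (is.null(sequence)) sequence <- strrep("A", n)
  seqv <- strsplit(sequence, "")[[1]]
  if (length(seqv) != n) stop("sequence length != residue count")
  g <- .GEO
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(g$n_ca, 0, 0)
  C[[1]] <- .place_atom(c(0, 1, 0), N[[1]], CA[[1]], g$ca_c,
                        g$ang_n_ca_c, 55)   # arbitrary rigid-body orientation
  for (i in seq_len(n - 1)) {
    N[[i + 1]] <- .place_atom(N[[i]], CA[[i]], C[[i]], g$c_n,
                              g$ang_ca_c_n, psi[i])
    CA[[i + 1]] <- .place_atom(CA[[i]], C[[i]], N[[i + 1]], g$n_ca,
                               g$ang_c_n_ca, g$omega)
    C[[i + 1]] <- .place_atom(C[[i]], N[[i + 1]], CA[[i + 1]], g$ca_c,
                              g$ang_n_ca_c, phi[i + 1])
  }
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    O <- .place_atom(N[[i]], CA[[i]], C[[i]], g$c_o, g$ang_ca_c_o,
                     (if (i < n) psi[i] else 180) + 180)
    a <- rbind(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O)
    if (seqv[i] != "G") {
      CB <- .place_atom(N[[i]], C[[i]], CA[[i]], g$ca_cb, g$ang_c_ca_cb,
                        g$tor_n_c_ca_cb)
      a <- rbind(a, CB = CB)
    }
    atoms[[i]] <- a
  }
  structure_chain(seqv, atoms, id = id)
}

#' Build a toy backbone realizing a Protein Blocks string
#'
#' Uses the central phi/psi of each requested block's reference window as the
#' per-residue dihedrals, so [assign_pb()] on the result returns the
#' requested letters at internal positions away from block junctions.
#'
#' @param pb_string string over \code{a..p}.
#' @param sequence optional sequence (default poly-alanine).
#' @param refs reference table, default [pb_reference_angles()].
#' @param id chain id.
#' @return a [structure_chain()].
#' @export
make_pb_backbone <- function(pb_string, sequence = NULL,
                             refs = pb_reference_angles(), id = "toy") {
  ch <- strsplit(pb_string, "")[[1]]
  bad <- setdiff(ch, rownames(refs))
  if (length(bad)) stop("not a PB letter: ", paste(unique(bad), collapse = ","))
  .backbone_from_dihedrals(refs[ch, "phi0"], refs[ch, "psi0"],
                           sequence = sequence, id = id)
}

#' Random protein-like sequence
#'
#' Residues drawn from the background amino-acid composition.
#'
#' @param n length.
#' @param seed integer seed.
#' @return single string.
#' @export
random_sequence <- function(n, seed) {
  bg <- aa_background()
  .with_seed(seed, paste(sample(names(bg), n, replace = TRUE, prob = bg),
                         collapse = ""))
}

# substitutions at `rate` (uniform over the 19 alternatives); deletions open
# with probability indel_rate per site and extend geometrically (p = 0.5)
.mutate_row <- function(master, rate, indel_rate) {
  ch <- strsplit(master, "")[[1]]
  n <- length(ch)
  aa <- aa_alphabet()
  sub <- which(stats::runif(n) < rate)
  for (i in sub) ch[i] <- sample(setdiff(aa, ch[i]), 1)
  if (indel_rate > 0) {
    i <- 1
    while (i <= n) {
      if (stats::runif(1) < indel_rate) {
        len <- stats::rgeom(1, 0.5) + 1
        ch[i:min(n, i + len - 1)] <- "-"
        i <- i + len
      }
      i <- i + 1
    }
  }
  paste(ch, collapse = "")
}

#' Mutated alignment rows from a master sequence
#'
#' Each returned row is the master with independent per-site substitutions at
#' the given rate and geometric-length deletions at the indel rate; rows keep
#' the master's length, so prepending the master gives a gapped aligned-FASTA
#' style MSA.  Deterministic per seed.
#'
#' @param master single master sequence string.
#' @param n_rows number of mutated rows.
#' @param rate per-site substitution probability in [0,1].
#' @param indel_rate per-site deletion-opening probability (default 0).
#' @param seed integer seed.
#' @return character vector of \code{n_rows} aligned rows.
#' @export
mutate_msa <- function(master, n_rows, rate, indel_rate = 0, seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  .with_seed(seed, vapply(seq_len(n_rows), function(k)
    .mutate_row(master, rate, indel_rate), character(1)))
}

# random segment plan of PB letters totalling `length` positions
.random_pb_plan <- function(len) {
  plan <- list()
  tot <- 0
  while (tot < len) {
    l <- sample(3:7, 1)
    plan[[length(plan) + 1]] <- c(letter = sample(pb_alphabet(), 1),
                                  length = min(l, len - tot))
    tot <- tot + l
  }
  plan
}

.plan_to_string <- function(plan)
  paste(unlist(lapply(plan, function(s)
    strrep(s[["letter"]], as.integer(s[["length"]])))), collapse = "")

.hamming <- function(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Deterministic toy fold databank
#'
#' Generates \code{n_folds} distinct Protein Blocks segment plans (pairwise
#' Hamming-separated by at least 30 percent of the length), realizes each
#' member as an ideal-geometry backbone carrying a sequence mutated from the
#' fold master, and builds one template record per member via
#' [build_databank()].  A fold map for benchmark evaluation is returned with
#' the databank.
#'
#' @param n_folds number of folds (default 5).
#' @param members_per_fold members per fold (default 2).
#' @param length residues per structure (default 40).
#' @param seed integer seed.
#' @param mutation_rate within-fold sequence divergence (default 0.3).
#' @param dir optional directory: if given the databank is also written there.
#' @param sasa_points SASA quadrature points (default 960).
#' @return list with \code{databank} (a \code{template_databank}),
#'   \code{folds} (named vector record id -> fold id), \code{specs} (per
#'   fold: \code{pb}, \code{master_seq}), and \code{seed}.
#' @export
make_toy_databank <- function(n_folds = 5, members_per_fold = 2, length = 40,
                              seed = 1, mutation_rate = 0.3, dir = NULL,
                              sasa_points = 960) {
  if (length < 15) stop("toy structures need at least 15 residues")
  gen <- .with_seed(seed, {
    pbs <- character(0)
    for (tries in 1:500) {
      cand <- .plan_to_string(.random_pb_plan(length))
      if (all(!length(pbs) | vapply(pbs, function(p)
        .hamming(p, cand) >= 0.3 * length, logical(1))))
        pbs <- c(pbs, cand)
      if (base::length(pbs) == n_folds) break
    }
    if (base::length(pbs) < n_folds)
      stop("could not generate separated fold plans")
    masters <- vapply(seq_len(n_folds), function(f)
      paste(sample(names(aa_background()), length, replace = TRUE,
                   prob = aa_background()), collapse = ""), character(1))
    members <- list()
    for (f in seq_len(n_folds)) {
      for (k in seq_len(members_per_fold)) {
        seqk <- if (k == 1) masters[f]
                else .mutate_row(masters[f], mutation_rate, 0)
        members[[paste0("F", f, "_", k)]] <-
          list(fold = paste0("fold", f), pb = pbs[f], sequence = seqk)
      }
    }
    list(pbs = pbs, masters = masters, members = members)
  })
  families <- lapply(names(gen$members), function(id) {
    m <- gen$members[[id]]
    list(id = id, description = paste0("toy ", m$fold),
         members = list(make_pb_backbone(m$pb, sequence = m$sequence,
                                         id = id)))
  })
  db <- build_databank(families, sasa_points = sasa_points)
  folds <- vapply(gen$members, function(m) m$fold, character(1))
  specs <- lapply(seq_len(n_folds), function(f)
    list(pb = gen$pbs[f], master_seq = gen$masters[f]))
  names(specs) <- paste0("fold", seq_len(n_folds))
  if (!is.null(dir)) write_databank(db, dir)
  list(databank = db, folds = folds, specs = specs, seed = seed)
}

#' Held-out toy query for a fold
#'
#' Simulates a new member of a fold: a sequence mutated from the fold master
#' is placed on the fold's backbone; the query hybrid profile combines an
#' amino-acid profile from a mutated MSA of that sequence with the PB and SA
#' tracks assigned from the held-out structure (standing in for an external
#' structural predictor).
#'
#' @param toydb result of [make_toy_databank()].
#' @param fold fold id (e.g. \code{"fold1"}).
#' @param seed integer seed.
#' @param mutation_rate divergence of the held-out member and of its MSA rows
#'   (default 0.3).
#' @param n_msa MSA rows generated around the query (default 8).
#' @param indel_rate deletion rate in the MSA rows (default 0.05).
#' @param sasa_points SASA quadrature points.
#' @return list with \code{profile} (a \code{hybrid_profile}), \code{fold},
#'   \code{sequence}, \code{pb}, \code{sa}.
#' @export
make_toy_query <- function(toydb, fold, seed = 1, mutation_rate = 0.3,
                           n_msa = 8, indel_rate = 0.05, sasa_points = 960) {
  spec <- toydb$specs[[fold]]
  if (is.null(spec)) stop("unknown fold: ", fold)
  qseq <- .with_seed(seed, .mutate_row(spec$master_seq, mutation_rate, 0))
  chain <- make_pb_backbone(spec$pb, sequence = qseq, id = paste0(fold, "_q"))
  qpb <- chain_pb(chain)
  qsa <- chain_sa_class(chain, n_points = sasa_points)
  msa <- c(qseq, mutate_msa(qseq, n_msa, mutation_rate, indel_rate,
                            seed = seed + 104729L))
  prof <- build_query_profile(msa, pb = qpb, sa = qsa,
                              id = paste0(fold, "_query"))
  list(profile = prof, fold = fold, sequence = qseq, pb = qpb, sa = qsa)
}
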