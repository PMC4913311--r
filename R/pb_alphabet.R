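# Protein Blocks assignment: backbone dihedrals, angular distance, and the
# 16-letter structural alphabet with its 3-state secondary-structure mapping.

#' Backbone phi/psi dihedrals of a chain
#'
#' phi(i) = torsion C(i-1), N(i), CA(i), C(i); psi(i) = torsion N(i), CA(i),
#' C(i), N(i+1).  An angle is \code{NA} when any contributing atom is absent,
#' at the chain termini, or across a chain break (consecutive C--N distance
#' above \code{break_dist}).
#'
#' @param chain a [structure_chain()].
#' @param break_dist chain-break threshold on the peptide C(i)-N(i+1) distance
#'   in Angstrom (default 2.5).
#' @return data.frame with columns \code{phi}, \code{psi} (degrees, \code{NA}
#'   when undefined), one row per residue.
#' @export
backbone_dihedrals <- function(chain, break_dist = 2.5) {
  if (!inherits(chain, "structure_chain")) stop("not a structure_chain")
  n <- length(chain)
  if (n == 0) stop("empty structure")
  N <- lapply(seq_len(n), .atom_xyz, chain = chain, name = "N")
  CA <- lapply(seq_len(n), .atom_xyz, chain = chain, name = "CA")
  C <- lapply(seq_len(n), .atom_xyz, chain = chain, name = "C")
  linked <- rep(FALSE, n)                # linked[i]: peptide bond i -> i+1 ok
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      if (!is.null(C[[i]]) && !is.null(N[[i + 1]])) {
        d <- sqrt(sum((C[[i]] - N[[i + 1]])^2))
        linked[i] <- d <= break_dist
      }
    }
  }
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && linked[i - 1] &&
        !is.null(C[[i - 1]]) && !is.null(N[[i]]) &&
        !is.null(CA[[i]]) && !is.null(C[[i]]))
      phi[i] <- dihedral_angle(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
    if (i < n && linked[i] &&
        !is.null(N[[i]]) && !is.null(CA[[i]]) &&
        !is.null(C[[i]]) && !is.null(N[[i + 1]]))
      psi[i] <- dihedral_angle(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
  }
  data.frame(phi = phi, psi = psi)
}

#' Root mean square deviation on angular values
#'
#' Distance between two 8-angle dihedral windows:
#' sqrt(mean of squared angular differences), each difference wrapped to
#' [0, 180] degrees.  This is the distance used to assign the nearest
#' Protein Block.
#'
#' @param a,b numeric vectors of 8 angles in degrees.
#' @return distance in degrees (0 to 180).
#' @export
rmsda <- function(a, b) {
  if (length(a) != 8 || length(b) != 8)
    stop("rmsda expects two 8-angle windows")
  if (anyNA(a) || anyNA(b)) stop("incomplete window")
  sqrt(mean(.wrap_delta(a, b)^2))
}

#' Assign Protein Blocks from backbone dihedrals
#'
#' Each residue i with a complete pentapeptide window of eight dihedrals
#' (psi(i-2), phi(i-1), psi(i-1), phi(i), psi(i), phi(i+1), psi(i+1),
#' phi(i+2)) is assigned the block with minimal [rmsda()] to its reference
#' window; ties break to the alphabetically first letter.  The first and last
#' two residues, and any window touching an undefined dihedral, are \code{Z}.
#'
#' @param dihedrals data.frame from [backbone_dihedrals()] (columns
#'   \code{phi}, \code{psi}).
#' @param refs reference table, default [pb_reference_angles()].
#' @return single string over \code{a..p} and \code{Z}, same length as the
#'   chain.
#' @export
assign_pb <- function(dihedrals, refs = pb_reference_angles()) {
  n <- nrow(dihedrals)
  if (is.null(n) || n == 0) stop("empty dihedral series")
  out <- rep("Z", n)
  lab <- rownames(refs)
  for (i in seq_len(n)) {
    if (i < 3 || i > n - 2) next
    w <- c(dihedrals$psi[i - 2], dihedrals$phi[i - 1], dihedrals$psi[i - 1],
           dihedrals$phi[i], dihedrals$psi[i],
           dihedrals$phi[i + 1], dihedrals$psi[i + 1], dihedrals$phi[i + 2])
    if (anyNA(w)) next
    d <- sqrt(rowMeans(.wrap_delta(refs, matrix(w, nrow = nrow(refs),
                                                ncol = 8, byrow = TRUE))^2))
    out[i] <- lab[which.min(d)]          # which.min takes the first = lowest letter
  }
  paste(out, collapse = "")
}

#' Map a Protein Block letter to a 3-state secondary structure
#'
#' Helix: central helix \code{m} plus the helix N/C-cap transitions
#' \code{f,k,l,n,o,p}; strand: central strand \code{d} plus caps
#' \code{b,c,e}; coil/turn: \code{a,g,h,i,j}; \code{Z} maps to \code{"-"}.
#'
#' @param pb character vector of PB letters (elements may be multi-letter
#'   strings, which are mapped per character).
#' @return character of the same shape over \code{H}, \code{E}, \code{C},
#'   \code{-}.
#' @export
pb_to_ss <- function(pb) {
  map <- c(m = "H", f = "H", k = "H", l = "H", n = "H", o = "H", p = "H",
           d = "E", b = "E", c = "E", e = "E",
           a = "C", g = "C", h = "C", i = "C", j = "C",
           Z = "-", "-" = "-")
  one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    bad <- setdiff(ch, names(map))
    if (length(bad)) stop("unknown PB letter: ", paste(bad, collapse = ","))
    paste(map[ch], collapse = "")
  }
  vapply(pb, one, character(1), USE.NAMES = FALSE)
}

#' Assign Protein Blocks directly from a chain
#'
#' Convenience composition of [backbone_dihedrals()] and [assign_pb()].
#'
#' @inheritParams backbone_dihedrals
#' @param refs reference table, default [pb_reference_angles()].
#' @return PB string (see [assign_pb()]).
#' @export
chain_pb <- function(chain, refs = pb_reference_angles(), break_dist = 2.5) {
  assign_pb(backbone_dihedrals(chain, break_dist = break_dist), refs = refs)
}
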