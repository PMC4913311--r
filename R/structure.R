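# Ordered-residue chain container and PDB ingestion.

#' Construct a structure chain
#'
#' A \code{structure_chain} is an ordered list of residues with named heavy
#' (and optionally hydrogen) atom coordinates; it is the source object for
#' Protein Blocks assignment and solvent accessibility.
#'
#' @param sequence one-letter residue codes (character vector or single
#'   string); \code{"X"} for non-standard residues.
#' @param atoms list (one entry per residue) of numeric matrices with rownames
#'   giving atom names (\code{N}, \code{CA}, \code{C}, \code{O}, \code{CB},
#'   ...) and three columns x, y, z.
#' @param resno optional author residue numbers (default 1..n).
#' @param id chain identifier string.
#' @return object of class \code{structure_chain}.
#' @export
structure_chain <- function(sequence, atoms, resno = NULL, id = "chain") {
  if (length(sequence) == 1 && nchar(sequence[1]) > 1)
    sequence <- strsplit(sequence, "")[[1]]
  n <- length(sequence)
  if (n == 0) stop("empty structure")
  if (length(atoms) != n)
    stop("atoms list length (", length(atoms), ") != sequence length (", n, ")")
  if (is.null(resno)) resno <- seq_len(n)
  structure(list(id = id, sequence = toupper(sequence),
                 atoms = atoms, resno = resno),
            class = "structure_chain")
}

#' @export
length.structure_chain <- function(x) length(x$sequence)

#' @export
print.structure_chain <- function(x, ...) {
  cat("structure_chain '", x$id, "': ", length(x), " residues\n", sep = "")
  cat(" sequence: ", paste(x$sequence, collapse = ""), "\n", sep = "")
  invisible(x)
}

#' One-letter sequence of a chain
#' @param chain a \code{structure_chain}.
#' @return single string.
#' @export
chain_sequence <- function(chain) paste(chain$sequence, collapse = "")

# coordinates of one named atom of residue i, or NULL if absent
.atom_xyz <- function(chain, i, name) {
  if (i < 1 || i > length(chain)) return(NULL)
  a <- chain$atoms[[i]]
  if (is.null(a) || !(name %in% rownames(a))) return(NULL)
  as.numeric(a[name, ])
}

#' Read one chain of a PDB file
#'
#' Thin wrapper over \code{bio3d::read.pdb}: keeps ATOM records of the first
#' model for the requested chain, resolves alternate locations by highest
#' occupancy (ties to the first conformer), and maps non-standard residues to
#' \code{"X"} while keeping whatever backbone atoms they carry.
#'
#' @param file path to a PDB-format file.
#' @param chain chain identifier (default \code{"A"}; \code{NA} takes the
#'   first chain present).
#' @return a [structure_chain()].
#' @export
read_pdb_chain <- function(file, chain = "A") {
  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.na(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records for chain '", chain, "' in ", file)
  ins <- if ("insert" %in% names(at)) ifelse(is.na(at$insert), "", at$insert) else ""
  key <- paste(at$resno, ins, sep = "|")
  ukey <- unique(key)
  occ <- if ("o" %in% names(at)) ifelse(is.na(at$o), 1, at$o) else rep(1, nrow(at))
  seqv <- character(length(ukey))
  atoms <- vector("list", length(ukey))
  resno <- integer(length(ukey))
  for (r in seq_along(ukey)) {
    rows <- which(key == ukey[r])
    res3 <- toupper(at$resid[rows[1]])
    seqv[r] <- if (res3 %in% names(.aa3to1)) .aa3to1[[res3]] else "X"
    resno[r] <- at$resno[rows[1]]
    nm <- at$elety[rows]
    # highest-occupancy conformer per atom name
    keep <- vapply(unique(nm), function(x) {
      cand <- rows[nm == x]
      cand[which.max(occ[cand])]
    }, integer(1))
    xyz <- cbind(at$x[keep], at$y[keep], at$z[keep])
    rownames(xyz) <- unique(nm)
    atoms[[r]] <- xyz
  }
  structure_chain(seqv, atoms, resno = resno,
                  id = paste0(basename(file), "_", chain))
}

#' Write a chain as a minimal PDB file
#'
#' Emits standard fixed-format ATOM records (single chain, single model);
#' suitable for feeding toy structures to [read_pdb_chain()] or external
#' tools.
#'
#' @param chain a [structure_chain()].
#' @param file output path.
#' @param chain_id one-character chain identifier (default "A").
#' @return \code{file}, invisibly.
#' @export
write_chain_pdb <- function(chain, file, chain_id = "A") {
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(length(chain))) {
    a <- chain$atoms[[i]]
    res3 <- if (chain$sequence[i] %in% names(.aa1to3))
      .aa1to3[[chain$sequence[i]]] else "UNK"
    for (k in seq_len(nrow(a))) {
      serial <- serial + 1L
      nm <- rownames(a)[k]
      nmf <- if (nchar(nm) < 4) sprintf(" %-3s", nm) else nm
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nmf, res3, chain_id, chain$resno[i],
        a[k, 1], a[k, 2], a[k, 3], 1.0, 0.0, .atom_element(nm)))
    }
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}
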