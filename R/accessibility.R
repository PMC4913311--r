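# Solvent accessibility: deterministic Shrake-Rupley SASA, relative
# accessibility against per-residue maxima, and ten-class discretization.

#' Van der Waals radii used for SASA
#'
#' Bondi (1964) element radii; unlisted elements fall back to 1.70 Angstrom.
#' @return named numeric vector (Angstrom).
#' @export
vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20, SE = 1.90)
}

#' Maximum accessible surface area per residue type
#'
#' Reference maxima used to turn absolute SASA into relative accessibility.
#' \code{"hubbard"} (default) are the Gly-X-Gly tripeptide totals of Hubbard &
#' Thornton (1993), the normalization used by NACCESS; \code{"tien"} are the
#' theoretical maxima of Tien et al. (2013).
#'
#' @param scale \code{"hubbard"} or \code{"tien"}.
#' @return named numeric vector over the 20 one-letter codes (Angstrom^2).
#' @export
max_asa_table <- function(scale = c("hubbard", "tien")) {
  scale <- match.arg(scale)
  if (scale == "hubbard")
    c(A = 107.95, R = 238.76, N = 143.94, D = 140.39, C = 134.28,
      Q = 178.50, E = 172.25, G = 80.10, H = 182.88, I = 175.12,
      L = 178.63, K = 200.81, M = 194.15, F = 199.48, P = 136.13,
      S = 116.50, T = 139.27, W = 249.36, Y = 212.76, V = 151.44)
  else
    c(A = 129, R = 274, N = 195, D = 193, C = 167,
      Q = 225, E = 223, G = 104, H = 224, I = 197,
      L = 201, K = 236, M = 224, F = 240, P = 159,
      S = 155, T = 172, W = 285, Y = 263, V = 174)
}

# deterministic unit-sphere point set (golden-section / Fibonacci lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (3 - sqrt(5)) * (i - 0.5)
  cbind(r * cos(th), r * sin(th), z)
}

#' Solvent accessible surface area of arbitrary spheres
#'
#' Shrake-Rupley quadrature on a deterministic golden-section lattice: the
#' accessible area of sphere k is 4*pi*(r_k+probe)^2 times the fraction of
#' its test points not inside any other probe-expanded sphere.
#'
#' @param centers numeric matrix (n x 3) of sphere centres.
#' @param radii numeric vector of n van der Waals radii.
#' @param probe probe radius in Angstrom (default 1.4, a water molecule).
#' @param n_points lattice points per sphere (default 960).
#' @return numeric vector of per-sphere accessible areas (Angstrom^2).
#' @export
sphere_sasa <- function(centers, radii, probe = 1.4, n_points = 960) {
  centers <- as.matrix(centers)
  n <- nrow(centers)
  if (n == 0) stop("no atoms")
  if (length(radii) != n) stop("radii length mismatch")
  pts <- .sphere_points(n_points)
  er <- radii + probe
  out <- numeric(n)
  for (k in seq_len(n)) {
    dk <- sqrt(colSums((t(centers) - centers[k, ])^2))
    nb <- which(dk < er[k] + er & seq_len(n) != k)
    p <- pts * er[k]
    p <- sweep(p, 2, centers[k, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      d2 <- (p[, 1] - centers[j, 1])^2 + (p[, 2] - centers[j, 2])^2 +
            (p[, 3] - centers[j, 3])^2
      acc <- acc & d2 >= er[j]^2
      if (!any(acc)) break
    }
    out[k] <- 4 * pi * er[k]^2 * sum(acc) / n_points
  }
  out
}

#' Per-residue solvent accessibility of a chain
#'
#' Computes heavy-atom Shrake-Rupley SASA, sums it per residue, normalizes by
#' the residue-type maximum ([max_asa_table()]) and discretizes into ten
#' classes with [sa_class()].  Unknown residue types are normalized by the
#' glycine maximum with a warning.
#'
#' @param chain a [structure_chain()].
#' @param probe probe radius (Angstrom).
#' @param n_points quadrature points per atom.
#' @param scale max-ASA normalization table (see [max_asa_table()]).
#' @return data.frame with columns \code{resno}, \code{residue},
#'   \code{abs_sasa}, \code{rel_acc}, \code{sa_class}.
#' @export
residue_sasa <- function(chain, probe = 1.4, n_points = 960,
                         scale = "hubbard") {
  if (!inherits(chain, "structure_chain")) stop("not a structure_chain")
  cen <- list(); rad <- list(); ridx <- list()
  radii <- vdw_radii()
  for (i in seq_len(length(chain))) {
    a <- chain$atoms[[i]]
    if (is.null(a) || nrow(a) == 0) next
    el <- .atom_element(rownames(a))
    heavy <- el != "H"
    if (!any(heavy)) next
    cen[[length(cen) + 1]] <- a[heavy, , drop = FALSE]
    r <- radii[el[heavy]]
    r[is.na(r)] <- 1.70
    rad[[length(rad) + 1]] <- r
    ridx[[length(ridx) + 1]] <- rep(i, sum(heavy))
  }
  if (!length(cen)) stop("no atoms")
  centers <- do.call(rbind, cen)
  area <- sphere_sasa(centers, unlist(rad), probe = probe,
                      n_points = n_points)
  per_res <- vapply(seq_len(length(chain)),
                    function(i) sum(area[unlist(ridx) == i]), numeric(1))
  rel <- vapply(seq_len(length(chain)), function(i)
    relative_accessibility(per_res[i], chain$sequence[i], scale = scale),
    numeric(1))
  data.frame(resno = chain$resno, residue = chain$sequence,
             abs_sasa = per_res, rel_acc = rel,
             sa_class = vapply(rel, sa_class, integer(1)))
}

# element symbol from a PDB atom name ("CA" -> C, "OG1" -> O, "SE" kept)
.atom_element <- function(name) {
  nm <- toupper(trimws(name))
  el <- substr(nm, 1, 1)
  el[nm == "SE" | substr(nm, 1, 2) == "SE"] <- "SE"
  el[grepl("^[0-9]", el)] <- substr(sub("^[0-9]+", "", nm[grepl("^[0-9]", el)]), 1, 1)
  el
}

#' Relative accessibility of one residue
#'
#' @param abs_sasa absolute SASA in Angstrom^2.
#' @param residue_type one-letter amino-acid code.
#' @param scale max-ASA table (see [max_asa_table()]).
#' @return percent of the residue-type maximum (can exceed 100 for extended
#'   termini; not clamped here).
#' @export
relative_accessibility <- function(abs_sasa, residue_type,
                                   scale = "hubbard") {
  tab <- max_asa_table(scale)
  residue_type <- toupper(residue_type)
  if (!residue_type %in% names(tab)) {
    warning("unknown residue type '", residue_type,
            "'; normalizing by glycine maximum")
    residue_type <- "G"
  }
  100 * abs_sasa / tab[[residue_type]]
}

#' Discretize relative accessibility into ten classes
#'
#' Equal-width 10 percent bins on [0, 100], clamped above: class 1 is fully
#' buried, class 10 fully exposed.
#'
#' @param rel_acc relative accessibility in percent (>= 0).
#' @return integer class in 1..10.
#' @export
sa_class <- function(rel_acc) {
  if (is.na(rel_acc) || rel_acc < 0) stop("negative relative accessibility")
  as.integer(min(floor(rel_acc / 10), 9) + 1)
}

#' Per-residue SA classes of a chain
#'
#' @inheritParams residue_sasa
#' @return integer vector of classes 1..10, one per residue.
#' @export
chain_sa_class <- function(chain, probe = 1.4, n_points = 960,
                           scale = "hubbard") {
  residue_sasa(chain, probe = probe, n_points = n_points,
               scale = scale)$sa_class
}
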