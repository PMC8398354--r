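# Kier molecular flexibility index.
#
# Built from the first two alpha-modified kappa shape indices:
#   kappa1 = (A + alpha) (A + alpha - 1)^2 / (P1 + alpha)^2
#   kappa2 = (A + alpha - 1) (A + alpha - 2)^2 / (P2 + alpha)^2
# with A the heavy-atom count, P1 the bond count, P2 the number of distinct
# two-bond paths, and alpha = sum_i (r_i / r_Csp3 - 1) over heavy atoms using
# hybridisation-dependent covalent radii (aromatic atoms treated as sp2).
# The flexibility index is kappa1 * kappa2 / A.

# Kier's covalent radii (Angstrom) by element and hybridisation
.kier_radius <- c(
  "C.sp3" = 0.77, "C.sp2" = 0.67, "C.sp" = 0.60,
  "N.sp3" = 0.74, "N.sp2" = 0.62, "N.sp" = 0.55,
  "O.sp3" = 0.74, "O.sp2" = 0.62,
  "F.sp3" = 0.72, "Cl.sp3" = 0.99, "Br.sp3" = 1.14, "I.sp3" = 1.33,
  "S.sp3" = 1.04, "S.sp2" = 0.94, "P.sp3" = 1.10
)

kier_alpha <- function(mol) {
  hyb <- atom_hybridisation(mol)
  key <- paste0(mol$atoms$element, ".", hyb)
  # elements tabulated only as sp3 (halogens) and sp heteroatoms fall back
  miss <- !key %in% names(.kier_radius)
  key[miss] <- paste0(mol$atoms$element[miss], ".sp3")
  still <- !key %in% names(.kier_radius)
  key[still] <- sub("\\.sp3$", ".sp2", key[still])
  r <- .kier_radius[key]
  if (anyNA(r))
    stop("no Kier radius for element(s): ",
         paste(unique(mol$atoms$element[is.na(r)]), collapse = ", "), call. = FALSE)
  sum(r / 0.77 - 1)
}

# number of distinct two-bond paths
count_p2 <- function(mol) {
  sum(mol$atoms$degree * (mol$atoms$degree - 1) / 2)
}

#' Kier molecular flexibility index
#'
#' @param mol A `mol_graph` or SMILES string.
#' @return Non-negative flexibility index; 0 (with a warning) for degenerate
#'   molecules with fewer than three heavy atoms or no two-bond path.
#' @export
#' @examples
#' kier_flex(parse_smiles("CCC"))   # propane: exactly 2
kier_flex <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "mol_graph"))
  A <- nrow(mol$atoms)
  P1 <- nrow(mol$bonds)
  P2 <- count_p2(mol)
  if (A < 3 || P2 == 0) {
    warning("molecule too small for the Kier flexibility index; returning 0")
    return(0)
  }
  alpha <- kier_alpha(mol)
  k1 <- (A + alpha) * (A + alpha - 1)^2 / (P1 + alpha)^2
  k2 <- (A + alpha - 1) * (A + alpha - 2)^2 / (P2 + alpha)^2
  k1 * k2 / A
}
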