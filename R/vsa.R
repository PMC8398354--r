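# Approximate per-atom van der Waals surface areas (VSA).
#
# Labute-style 2D approximation: each heavy atom is a sphere of its van der
# Waals radius; for every bonded neighbour a spherical cap is subtracted,
# with the cap height computed from an ideal (tabulated) bond length clamped
# to the geometrically admissible range.  Implicit hydrogens contribute their
# own capped spheres, folded into the heavy atom they sit on.  Radii follow
# Labute's connection-table approximation so that descriptor magnitudes are
# on the scale expected by the activity equation (hundreds of Angstrom^2 for
# a drug-sized molecule).

# van der Waals radii (Angstrom), Labute's table
.vdw_radius <- c(H = 1.485, C = 1.950, N = 1.950, O = 1.779, F = 1.496,
                 Cl = 2.044, Br = 2.166, I = 2.358, S = 2.185, P = 2.287,
                 B = 2.048)

# single-bond covalent radii (Angstrom), fallback for untabulated pairs
.cov_radius <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                 Cl = 1.02, Br = 1.20, I = 1.39, S = 1.05, P = 1.07, B = 0.84)

# ideal bond lengths (Angstrom) for common element pairs; key "A-B-order"
# with elements sorted alphabetically, order in {1, 2, 3, a}
.bond_length <- c(
  "C-C-1" = 1.54, "C-C-2" = 1.34, "C-C-3" = 1.20, "C-C-a" = 1.40,
  "C-H-1" = 1.09, "C-N-1" = 1.47, "C-N-2" = 1.28, "C-N-3" = 1.16,
  "C-N-a" = 1.34, "C-O-1" = 1.43, "C-O-2" = 1.21, "C-O-a" = 1.36,
  "C-S-1" = 1.81, "C-S-2" = 1.60, "C-S-a" = 1.74,
  "C-F-1" = 1.35, "C-Cl-1" = 1.77, "Br-C-1" = 1.94, "C-I-1" = 2.14,
  "H-N-1" = 1.01, "H-O-1" = 0.96, "H-S-1" = 1.34,
  "N-N-1" = 1.45, "N-N-2" = 1.25, "N-N-a" = 1.32,
  "N-O-1" = 1.40, "N-O-2" = 1.21, "N-O-a" = 1.28,
  "N-S-1" = 1.71, "N-S-2" = 1.54, "N-S-a" = 1.62,
  "O-O-1" = 1.48, "O-S-1" = 1.57, "O-S-2" = 1.45,
  "C-P-1" = 1.84, "O-P-1" = 1.63, "O-P-2" = 1.50
)

# contraction applied to covalent-radius sums when a pair is untabulated
.order_scale <- c(`1` = 1.00, `2` = 0.87, `3` = 0.78, a = 0.93)

ideal_bond_length <- function(el1, el2, order, aromatic) {
  otok <- if (aromatic) "a" else as.character(order)
  pair <- sort(c(el1, el2))
  key <- paste(pair[1], pair[2], otok, sep = "-")
  if (key %in% names(.bond_length)) return(.bond_length[[key]])
  unname((.cov_radius[el1] + .cov_radius[el2]) * .order_scale[[otok]])
}

# area of the spherical cap cut from a sphere of radius R by a neighbour of
# radius r at distance d (d clamped to the admissible range)
cap_area <- function(R, r, d) {
  d <- pmin(pmax(d, abs(R - r) + 1e-6), R + r)
  2 * pi * R * (R - d / 2 - (R^2 - r^2) / (2 * d))
}

#' Per-atom approximate van der Waals surface areas
#'
#' @param mol A `mol_graph`.
#' @return Numeric vector (Angstrom^2), one entry per heavy atom, implicit
#'   hydrogens folded in; every entry is non-negative.
#' @export
atom_vsa <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  el <- mol$atoms$element
  R <- .vdw_radius[el]
  if (anyNA(R))
    stop("no van der Waals radius for element(s): ",
         paste(unique(el[is.na(R)]), collapse = ", "), call. = FALSE)
  n <- nrow(mol$atoms)
  area <- 4 * pi * R^2
  for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$a1[b]; j <- mol$bonds$a2[b]
    d <- ideal_bond_length(el[i], el[j], mol$bonds$order[b], mol$bonds$aromatic[b])
    area[i] <- area[i] - cap_area(R[i], R[j], d)
    area[j] <- area[j] - cap_area(R[j], R[i], d)
  }
  # implicit hydrogens: subtract their caps from the heavy atom and add the
  # hydrogens' own capped spheres
  rH <- .vdw_radius[["H"]]
  for (i in seq_len(n)) {
    k <- mol$atoms$nH[i]
    if (k == 0) next
    dH <- ideal_bond_length(el[i], "H", 1L, FALSE)
    area[i] <- area[i] - k * cap_area(R[i], rH, dH) +
      k * max(0, 4 * pi * rH^2 - cap_area(rH, R[i], dH))
  }
  pmax(unname(area), 0)
}
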