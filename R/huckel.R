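# Hueckel pi bond orders over conjugated subsystems.
#
# Pi atoms are atoms carrying a double or triple bond plus lone-pair donor
# heteroatoms (N/O/S with only single bonds) directly attached to such an
# atom.  Each connected subsystem gets a simple Hueckel matrix: diagonal
# elements h (in units of beta, alpha = 0) and off-diagonal k parameters by
# element pair, lowest orbitals filled with the subsystem's pi electrons
# (fractional occupation across a degenerate frontier shell), and bond order
# p_uv = sum_k n_k c_uk c_vk.  The second pi bond of a triple bond lies in an
# orthogonal plane and is added as a localised p = 1.

# Coulomb parameter h by element and number of contributed electrons
# (van-Catledge style values; carbon defines the zero)
.huckel_h <- c("C.1" = 0, "C.2" = 0,
               "N.1" = 0.51, "N.2" = 1.37,
               "O.1" = 0.97, "O.2" = 2.09,
               "S.1" = 0.46, "S.2" = 1.11,
               "P.1" = 0.19, "P.2" = 0.75)

# resonance parameter k by unordered element pair (beta units)
.huckel_k <- c("C-C" = 1.00, "C-N" = 0.95, "C-O" = 0.95, "C-S" = 0.69,
               "N-N" = 0.85, "N-O" = 0.80, "O-O" = 0.60,
               "N-S" = 0.60, "O-S" = 0.55, "C-P" = 0.77)

huckel_k_par <- function(e1, e2) {
  key <- paste(sort(c(e1, e2)), collapse = "-")
  if (key %in% names(.huckel_k)) .huckel_k[[key]] else 0.7
}

# electrons contributed by pi atom i (donor = atom without multiple bond)
pi_electrons <- function(el, charge, is_donor) {
  if (is_donor) {
    n <- 2L
  } else {
    n <- 1L
  }
  # a positive charge empties, a negative charge fills, the p orbital
  n <- n - ifelse(is_donor, 0L, charge)
  max(0L, min(2L, n))
}

#' Hueckel pi systems and bond orders
#'
#' @param mol A `mol_graph`.
#' @return List with `p` (numeric vector, one pi bond order per bond of the
#'   molecule, 0 for sigma-only bonds), `systems` (list of atom index
#'   vectors, one per conjugated subsystem) and `electrons` (pi electron
#'   count per subsystem).
#' @export
pi_bond_orders <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  n <- nrow(mol$atoms)
  bonds <- mol$bonds
  el <- mol$atoms$element
  has_multiple <- logical(n)
  for (b in seq_len(nrow(bonds))) if (bonds$order[b] >= 2) {
    has_multiple[bonds$a1[b]] <- TRUE
    has_multiple[bonds$a2[b]] <- TRUE
  }
  # lone-pair donors: N/O/S with only single bonds, non-positive charge,
  # adjacent to a multiple-bond atom
  nbrs <- adjacency_list(n, bonds$a1, bonds$a2)
  donor <- logical(n)
  for (i in seq_len(n)) {
    if (has_multiple[i]) next
    if (!el[i] %in% c("N", "O", "S", "P")) next
    if (mol$atoms$charge[i] > 0) next
    if (any(has_multiple[nbrs[[i]]])) donor[i] <- TRUE
  }
  in_pi <- has_multiple | donor
  p <- numeric(nrow(bonds))
  systems <- list(); electrons <- integer(0)
  if (!any(in_pi))
    return(list(p = p, systems = systems, electrons = electrons))
  # connected components of the pi subgraph
  idx <- which(in_pi)
  sel <- bonds$a1 %in% idx & bonds$a2 %in% idx
  sub_map <- integer(n); sub_map[idx] <- seq_along(idx)
  comp <- graph_components(length(idx), sub_map[bonds$a1[sel]], sub_map[bonds$a2[sel]])
  for (cid in unique(comp)) {
    atoms_sub <- idx[comp == cid]
    m <- length(atoms_sub)
    pos <- integer(n); pos[atoms_sub] <- seq_len(m)
    bsel <- which(bonds$a1 %in% atoms_sub & bonds$a2 %in% atoms_sub)
    n_el <- 0L
    H <- matrix(0, m, m)
    for (a in atoms_sub) {
      key <- paste0(el[a], ".", if (donor[a]) 2 else 1)
      h <- if (key %in% names(.huckel_h)) .huckel_h[[key]] else 0
      H[pos[a], pos[a]] <- h
      n_el <- n_el + pi_electrons(el[a], mol$atoms$charge[a], donor[a])
    }
    if (m == 1 || length(bsel) == 0) next
    for (b in bsel) {
      i <- pos[bonds$a1[b]]; j <- pos[bonds$a2[b]]
      k <- huckel_k_par(el[bonds$a1[b]], el[bonds$a2[b]])
      H[i, j] <- k; H[j, i] <- k
    }
    eig <- eigen(H, symmetric = TRUE)
    # orbitals sorted by decreasing eigenvalue = increasing energy in
    # alpha + x beta convention (beta < 0): fill from the largest x down
    occ <- fill_orbitals(eig$values, n_el)
    for (b in bsel) {
      i <- pos[bonds$a1[b]]; j <- pos[bonds$a2[b]]
      p[b] <- sum(occ * eig$vectors[i, ] * eig$vectors[j, ])
    }
    # orthogonal second pi bond of any triple bond in the subsystem
    p[bsel][bonds$order[bsel] == 3] <- p[bsel][bonds$order[bsel] == 3] + 1
    systems[[length(systems) + 1L]] <- atoms_sub
    electrons <- c(electrons, n_el)
  }
  # isolated triple bonds between atoms that ended in single-atom systems
  p[bonds$order == 3 & p == 0] <- 2
  list(p = p, systems = systems, electrons = electrons)
}

# occupation numbers for n_el electrons over orbitals with eigenvalues ev
# (descending ev = ascending energy); degenerate frontier shells are filled
# fractionally and flagged with a warning (open shell)
fill_orbitals <- function(ev, n_el) {
  ord <- order(ev, decreasing = TRUE)
  occ <- numeric(length(ev))
  remaining <- n_el
  i <- 1
  while (remaining > 0 && i <= length(ev)) {
    shell_pos <- which(abs(ev[ord] - ev[ord[i]]) < 1e-9)
    shell_pos <- shell_pos[shell_pos >= i]
    shell <- ord[shell_pos]
    cap <- 2 * length(shell)
    take <- min(remaining, cap)
    if (take < cap && length(shell) > 1)
      warning("open-shell pi system: fractional occupation of a degenerate frontier shell")
    occ[shell] <- take / length(shell)
    remaining <- remaining - take
    i <- i + length(shell)
  }
  occ
}

#' Sum of log(1 + pi bond order) over all bonds
#'
#' The pi-bond-order descriptor of the activity equation, computed from the
#' Hueckel bond orders under the natural-log convention (configurable).
#'
#' @param mol A `mol_graph` or SMILES string.
#' @param base Logarithm base; `exp(1)` (natural log, the default) or any
#'   positive base.
#' @return Non-negative descriptor value; exactly 0 for saturated molecules.
#' @export
h_log_pbo <- function(mol, base = exp(1)) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  pb <- pi_bond_orders(mol)
  sum(log(1 + pb$p, base = base))
}
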