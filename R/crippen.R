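# Wildman-Crippen atomic logP contributions.
#
# Each heavy atom is assigned to one atom class by a first-match-wins walk
# over the published ordered class table (Wildman & Crippen 1999); the class
# contribution values are the published constants.  Implicit hydrogens use
# the H classes and are folded into the heavy atom carrying them, so the
# per-atom vector sums to the molecular Crippen logP and is the quantity
# binned by the SlogP_VSA descriptors.

.crippen_logp <- c(
  C1 = 0.1441, C2 = 0, C3 = -0.2035, C4 = -0.2051, C5 = -0.2783,
  C6 = 0.1551, C7 = 0.0017, C8 = 0.08452, C9 = -0.1444, C10 = -0.0516,
  C11 = 0.1193, C12 = -0.0967, C13 = -0.5443, C14 = 0, C15 = 0.245,
  C16 = 0.198, C17 = 0, C18 = 0.1581, C19 = 0.2955, C20 = 0.2713,
  C21 = 0.136, C22 = 0.4619, C23 = 0.5437, C24 = 0.1893, C25 = -0.8186,
  C26 = 0.264, C27 = 0.2148, CS = 0.08129,
  H1 = 0.123, H2 = -0.2677, H3 = 0.2142, H4 = 0.298, HS = 0.1125,
  N1 = -1.019, N2 = -0.7096, N3 = -1.027, N4 = -0.5188, N5 = 0.08387,
  N6 = 0.1836, N7 = -0.3187, N8 = -0.4458, N9 = 0.01508, N10 = -1.95,
  N11 = -0.3239, N12 = -1.119, N13 = -0.3396, N14 = 0.2887, NS = -0.4806,
  O1 = 0.1552, O2 = -0.2893, O3 = -0.0684, O4 = -0.4195, O5 = 0.0335,
  O6 = -0.3339, O7 = -1.189, O8 = 0.1788, O9 = -0.1526, O10 = 0.1129,
  O11 = 0.4833, O12 = -1.326, OS = -0.1188,
  F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857, Hal = -2.996,
  P = 0.8612, S1 = 0.6482, S2 = -0.0024, S3 = 0.6237, Me1 = -0.3808
)

# neighbourhood context used by the class predicates
crippen_context <- function(g) {
  n <- nrow(g$atoms)
  nbr <- adjacency_list(n, g$bonds$a1, g$bonds$a2)
  dbl <- vector("list", n); trp <- vector("list", n); arom_nbr <- vector("list", n)
  for (b in seq_len(nrow(g$bonds))) {
    i <- g$bonds$a1[b]; j <- g$bonds$a2[b]
    if (g$bonds$order[b] == 2) { dbl[[i]] <- c(dbl[[i]], j); dbl[[j]] <- c(dbl[[j]], i) }
    if (g$bonds$order[b] == 3) { trp[[i]] <- c(trp[[i]], j); trp[[j]] <- c(trp[[j]], i) }
    if (g$bonds$aromatic[b]) { arom_nbr[[i]] <- c(arom_nbr[[i]], j)
                               arom_nbr[[j]] <- c(arom_nbr[[j]], i) }
  }
  list(nbr = nbr, dbl = dbl, trp = trp, arom_nbr = arom_nbr)
}

# class of one carbon atom
crippen_type_C <- function(g, ctx, i) {
  a <- g$atoms; el <- a$element
  nbrs <- ctx$nbr[[i]]; dbl <- ctx$dbl[[i]]; trp <- ctx$trp[[i]]
  het <- c("N", "O", "P", "S", "F", "Cl", "Br", "I")
  if (a$aromatic[i]) {
    nbr_out <- setdiff(nbrs, ctx$arom_nbr[[i]])        # non-ring attachments
    out_el <- el[nbr_out]; out_arom <- a$aromatic[nbr_out]
    if (a$nH[i] == 0 && length(nbr_out) &&
        any(!out_arom & !out_el %in% c("C", het))) return("C13")
    if (any(out_el == "F")) return("C14")
    if (any(out_el == "Cl")) return("C15")
    if (any(out_el == "Br")) return("C16")
    if (any(out_el == "I")) return("C17")
    if (a$nH[i] >= 1) return("C18")
    if (length(ctx$arom_nbr[[i]]) >= 3) return("C19")
    if (length(nbr_out) && any(out_arom)) return("C20")
    if (length(dbl) && any(!dbl %in% ctx$arom_nbr[[i]])) return("C25")
    if (any(out_el == "C")) return("C21")
    if (any(out_el == "N")) return("C22")
    if (any(out_el == "O")) return("C23")
    if (any(out_el == "S")) return("C24")
    return("CS")
  }
  if (length(trp)) return("C7")
  if (length(dbl)) {
    d_el <- el[dbl]; d_arom <- a$aromatic[dbl]
    if (any(d_el != "C" & !d_arom)) return("C5")       # C=O, C=N, ...
    if (any(d_arom)) return("C26")                     # C=c exocyclic
    if (any(a$aromatic[nbrs])) return("C26")           # vinyl on a ring
    return("C6")
  }
  # saturated carbon
  nbr_el <- el[nbrs]; nbr_arom <- a$aromatic[nbrs]
  if (all(nbr_el == "C" & !nbr_arom)) return(if (a$nH[i] >= 2 || a$degree[i] <= 1) "C1" else "C2")
  if (any(nbr_el %in% het & !nbr_arom) && !any(nbr_arom))
    return(if (a$nH[i] >= 2) "C3" else "C4")
  if (any(nbr_arom)) {
    if (a$nH[i] == 3) return(if (all(el[nbrs[nbr_arom]] == "C")) "C8" else "C9")
    if (a$nH[i] == 2) return("C10")
    if (a$nH[i] == 1) return("C11")
    return("C12")
  }
  if (any(!nbr_el %in% c("C", "N", "O", "P", "S", "F", "Cl", "Br", "I"))) return("C27")
  "CS"
}

crippen_type_N <- function(g, ctx, i) {
  a <- g$atoms
  nbrs <- ctx$nbr[[i]]; dbl <- ctx$dbl[[i]]; trp <- ctx$trp[[i]]
  if (a$aromatic[i]) return(if (a$charge[i] > 0) "N12" else "N11")
  if (a$charge[i] > 0) return(if (a$nH[i] >= 1) "N10" else "N13")
  if (a$charge[i] < 0) return("N14")
  if (length(trp)) return("N9")
  if (length(dbl)) return(if (a$nH[i] >= 1) "N5" else "N6")
  has_ar <- any(a$aromatic[nbrs])
  if (a$nH[i] >= 2) return(if (has_ar) "N3" else "N1")
  if (a$nH[i] == 1) return(if (has_ar) "N4" else "N2")
  if (has_ar) "N8" else "N7"
}

crippen_type_O <- function(g, ctx, i) {
  a <- g$atoms; el <- a$element
  nbrs <- ctx$nbr[[i]]; dbl <- ctx$dbl[[i]]
  if (a$aromatic[i]) return("O1")
  if (a$charge[i] < 0) {
    if (any(el[nbrs] %in% c("N", "O"))) return("O5")
    if (any(el[nbrs] == "S")) return("O6")
    cn <- nbrs[el[nbrs] == "C"]
    if (length(cn) && any(el[ctx$dbl[[cn[1]]]] == "O")) return("O12")
    return("O7")
  }
  if (length(dbl)) {
    p <- dbl[1]
    if (el[p] %in% c("N", "O")) return("O5")
    if (el[p] == "S") return("O6")
    if (a$aromatic[p]) return("O8")
    others <- setdiff(ctx$nbr[[p]], i)
    o_el <- el[others]; o_arom <- a$aromatic[others]
    if (length(others) && all(o_el != "C")) return("O11")
    if (any(o_arom)) return("O10")
    return("O9")
  }
  if (a$nH[i] >= 1) return("O2")
  if (any(a$aromatic[nbrs])) return("O4")
  if (length(nbrs) >= 2) return("O3")
  "OS"
}

crippen_type_S <- function(g, ctx, i) {
  a <- g$atoms
  if (a$aromatic[i]) return("S3")
  if (a$charge[i] != 0) return("S2")
  if (length(ctx$dbl[[i]]) && any(a$element[ctx$dbl[[i]]] %in% c("N", "O", "P", "S")))
    return("S2")
  "S1"
}

# class of the implicit hydrogens on heavy atom i
crippen_type_H <- function(g, ctx, i) {
  el <- g$atoms$element[i]
  if (el == "C") return("H1")
  if (el == "N") return("H3")
  if (el == "O") {
    cn <- ctx$nbr[[i]][g$atoms$element[ctx$nbr[[i]]] == "C"]
    if (length(cn) && length(ctx$dbl[[cn[1]]])) return("H4")   # acid-like O-H
    if (any(g$atoms$element[ctx$nbr[[i]]] == "N")) return("H3")
    return("H2")
  }
  if (el %in% c("S", "P")) return("H2")
  "HS"
}

#' Wildman-Crippen atom classes and logP contributions
#'
#' @param mol A `mol_graph`.
#' @return Tibble with one row per heavy atom: `type` (atom class), `logp`
#'   (class value), `logp_h` (implicit-hydrogen contribution folded in) and
#'   `contrib = logp + logp_h`.  `sum(contrib)` is the molecular Crippen
#'   logP.  Atoms outside the class tables fall to the element wildcard
#'   class with a warning.
#' @export
crippen_contribs <- function(mol) {
  stopifnot(inherits(mol, "mol_graph"))
  ctx <- crippen_context(mol)
  n <- nrow(mol$atoms)
  type <- character(n); hv <- numeric(n)
  for (i in seq_len(n)) {
    el <- mol$atoms$element[i]
    type[i] <- switch(el,
      C = crippen_type_C(mol, ctx, i),
      N = crippen_type_N(mol, ctx, i),
      O = crippen_type_O(mol, ctx, i),
      S = crippen_type_S(mol, ctx, i),
      F = "F", Cl = "Cl", Br = "Br", I = "I", P = "P",
      H = "HS",
      { warning(sprintf("atom %d (%s) matches no Crippen class; wildcard used",
                        i, el)); "Me1" })
    if (mol$atoms$nH[i] > 0)
      hv[i] <- mol$atoms$nH[i] * .crippen_logp[[crippen_type_H(mol, ctx, i)]]
  }
  tibble::tibble(
    atom = seq_len(n),
    element = mol$atoms$element,
    type = type,
    logp = unname(.crippen_logp[type]),
    logp_h = hv,
    contrib = unname(.crippen_logp[type]) + hv
  )
}

# SlogP_VSA bin edges on the per-atom Crippen contribution (MOE numbering:
# bin k collects contributions in (edge[k], edge[k+1]])
.slogp_bin_edges <- c(-Inf, -0.4, -0.2, 0, 0.1, 0.15, 0.20, 0.25, 0.30, 0.40, Inf)

#' VSA partitioned by Crippen logP contribution (SlogP_VSA bin family)
#'
#' Sums the approximate van der Waals surface area of atoms whose
#' Wildman-Crippen logP contribution falls in each of ten fixed intervals.
#' Bin 7 — contribution in (0.25, 0.30] — is the `SlogP_VSA7` descriptor of
#' the activity equation; the whole family is exposed because its sum equals
#' the total molecular VSA, a conservation property used in the tests.
#'
#' @param mol A `mol_graph`.
#' @return Named numeric vector `SlogP_VSA0` ... `SlogP_VSA9` (Angstrom^2).
#' @export
slogp_vsa_bins <- function(mol) {
  vsa <- atom_vsa(mol)
  contrib <- crippen_contribs(mol)$contrib
  bin <- cut(contrib, .slogp_bin_edges, labels = FALSE, right = TRUE)
  out <- numeric(10)
  for (k in seq_len(10)) out[k] <- sum(vsa[bin == k])
  names(out) <- paste0("SlogP_VSA", 0:9)
  out
}
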