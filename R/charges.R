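# Gasteiger-Marsili PEOE partial charges.
#
# Partial equalisation of orbital electronegativities: electronegativity is a
# quadratic function chi(q) = a + b q + c q^2 of the atomic charge; each
# iteration moves charge across every bond towards the more electronegative
# atom, damped by (1/2)^k at iteration k.  Implicit hydrogens take part as
# virtual atoms and their final charges are folded back into the heavy atom
# that carries them.

# a, b, c parameters by element and hybridisation (Gasteiger & Marsili 1980)
.peoe_params <- list(
  "H"     = c(7.17, 6.24, -0.56),
  "C.sp3" = c(7.98, 9.18, 1.88),
  "C.sp2" = c(8.79, 9.32, 1.51),
  "C.sp"  = c(10.39, 9.45, 0.73),
  "N.sp3" = c(11.54, 10.82, 1.36),
  "N.sp2" = c(12.87, 11.15, 0.85),
  "N.sp"  = c(15.68, 11.70, -0.27),
  "O.sp3" = c(14.18, 12.92, 1.39),
  "O.sp2" = c(17.07, 13.79, 0.47),
  "F"     = c(14.66, 13.85, 2.31),
  "Cl"    = c(11.00, 9.69, 1.35),
  "Br"    = c(10.08, 8.47, 1.16),
  "I"     = c(9.90, 7.96, 0.96),
  "S.sp3" = c(10.14, 9.13, 1.38),
  "S.sp2" = c(10.14, 9.13, 1.38),
  "P.sp3" = c(8.90, 8.24, 0.96)
)

peoe_key <- function(element, hyb) {
  key <- ifelse(element %in% c("H", "F", "Cl", "Br", "I"),
                element, paste0(element, ".", hyb))
  # sp heteroatoms fall back to sp2 parameters where no sp set exists
  miss <- !key %in% names(.peoe_params)
  key[miss] <- sub("\\.sp$", ".sp2", key[miss])
  key
}

#' Gasteiger-Marsili PEOE partial charges
#'
#' @param mol A `mol_graph`.
#' @param n_iter Number of damped equalisation cycles (default 8).
#' @param damping Per-cycle damping factor (default 0.5).
#' @param fold_h If `TRUE` (default) the charges of implicit hydrogens are
#'   added to their heavy atom, so the vector sums to the molecule's total
#'   formal charge over heavy atoms alone.
#' @return Numeric charge vector, one entry per heavy atom (elementary
#'   charge units).
#' @export
peoe_charges <- function(mol, n_iter = 8L, damping = 0.5, fold_h = TRUE) {
  stopifnot(inherits(mol, "mol_graph"))
  hyb <- atom_hybridisation(mol)
  n_heavy <- nrow(mol$atoms)
  el <- mol$atoms$element
  # expand virtual hydrogen atoms
  h_owner <- rep(seq_len(n_heavy), mol$atoms$nH)
  el_all <- c(el, rep("H", length(h_owner)))
  hyb_all <- c(hyb, rep("sp3", length(h_owner)))
  key <- peoe_key(el_all, hyb_all)
  bad <- !key %in% names(.peoe_params)
  if (any(bad))
    stop("no PEOE electronegativity parameters for: ",
         paste(unique(el_all[bad]), collapse = ", "), call. = FALSE)
  par <- do.call(rbind, .peoe_params[key])
  a1 <- c(mol$bonds$a1, n_heavy + seq_along(h_owner))
  a2 <- c(mol$bonds$a2, h_owner)
  q <- c(as.numeric(mol$atoms$charge), numeric(length(h_owner)))
  # chi+ of the cation limit, used as the normalising denominator; hydrogen
  # uses the conventional 20.02
  chi_plus <- rowSums(par)
  chi_plus[el_all == "H"] <- 20.02
  for (it in seq_len(n_iter)) {
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q^2
    dq <- numeric(length(q))
    f <- damping^it
    for (b in seq_along(a1)) {
      i <- a1[b]; j <- a2[b]
      if (chi[i] == chi[j]) next
      if (chi[j] > chi[i]) {
        t <- (chi[j] - chi[i]) / chi_plus[i] * f
        dq[i] <- dq[i] + t; dq[j] <- dq[j] - t
      } else {
        t <- (chi[i] - chi[j]) / chi_plus[j] * f
        dq[j] <- dq[j] + t; dq[i] <- dq[i] - t
      }
    }
    q <- q + dq
  }
  if (fold_h && length(h_owner)) {
    qh <- q[n_heavy + seq_along(h_owner)]
    for (k in seq_along(h_owner)) q[h_owner[k]] <- q[h_owner[k]] + qh[k]
  }
  q[seq_len(n_heavy)]
}
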