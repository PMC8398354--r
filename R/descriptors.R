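# The five-descriptor vector of the activity equation and the tabular
# featurisation interface.

#' Per-atom property contributions
#'
#' The atomic quantities behind the VSA-partitioned descriptors: approximate
#' van der Waals surface area, PEOE partial charge (implicit hydrogens folded
#' in), Wildman-Crippen logP contribution, and hydrogen-bond donor/acceptor/
#' polar flags.  A "polar" atom is one that is simultaneously donor and
#' acceptor (e.g. hydroxyl oxygen, amine N-H nitrogen).
#'
#' @param mol A `mol_graph` or SMILES string.
#' @return Tibble with one row per heavy atom: `element`, `vsa`, `charge`,
#'   `crippen`, `donor_flag`, `acceptor_flag`, `polar_flag`.
#' @export
atom_contributions <- function(mol) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "mol_graph"))
  a <- mol$atoms
  n <- nrow(a)
  ctx <- crippen_context(mol)
  # donors: N or O bearing at least one hydrogen
  donor <- a$element %in% c("N", "O") & a$nH > 0
  # acceptors: any non-positive O; N with an available lone pair (rules out
  # amide and nitro N, pyrrole-type aromatic N and quaternary N)
  acceptor <- logical(n)
  for (i in seq_len(n)) {
    el <- a$element[i]
    if (a$charge[i] > 0) next
    if (el == "O") { acceptor[i] <- TRUE; next }
    if (el != "N") next
    if (a$aromatic[i] && (a$nH[i] > 0 || a$degree[i] >= 3)) next   # pyrrole-type
    if (any(a$element[ctx$dbl[[i]]] == "O")) next                  # nitroso/nitro
    carbonyl <- any(vapply(ctx$nbr[[i]], function(j) {
      a$element[j] == "C" && any(a$element[ctx$dbl[[j]]] == "O")
    }, logical(1)))
    if (carbonyl) next                                             # amide
    if (a$degree[i] + a$nH[i] > 3) next
    acceptor[i] <- TRUE
  }
  tibble::tibble(
    atom = seq_len(n),
    element = a$element,
    vsa = atom_vsa(mol),
    charge = peoe_charges(mol),
    crippen = crippen_contribs(mol)$contrib,
    donor_flag = donor,
    acceptor_flag = acceptor,
    polar_flag = donor & acceptor
  )
}

#' Compute the five model descriptors for one molecule
#'
#' * `h_log_pbo` — sum of log(1 + Hueckel pi bond order) over all bonds;
#' * `kier_flex` — Kier molecular flexibility index;
#' * `q_vsa_hyd` — VSA of hydrophobic atoms (|PEOE charge| <= `hyd_threshold`);
#' * `slogp_vsa7` — VSA of atoms with Crippen logP contribution in (0.25, 0.30];
#' * `vsa_pol` — VSA of polar (donor-and-acceptor) atoms.
#'
#' @param mol A `mol_graph` or SMILES string.
#' @param log_base Base of the logarithm in `h_log_pbo` (default natural).
#' @param hyd_threshold Absolute-charge cutoff separating hydrophobic from
#'   polarised atoms (default 0.2).
#' @return One-row tibble with the five descriptor columns.
#' @export
#' @examples
#' compute_descriptors("CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21")  # diazepam
compute_descriptors <- function(mol, log_base = exp(1), hyd_threshold = 0.2) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "mol_graph"))
  ac <- atom_contributions(mol)
  tibble::tibble(
    h_log_pbo = h_log_pbo(mol, base = log_base),
    kier_flex = suppressWarnings(kier_flex(mol)),
    q_vsa_hyd = sum(ac$vsa[abs(ac$charge) <= hyd_threshold]),
    slogp_vsa7 = sum(ac$vsa[ac$crippen > 0.25 & ac$crippen <= 0.30]),
    vsa_pol = sum(ac$vsa[ac$polar_flag])
  )
}

#' Names of the five model descriptors
#' @return Character vector of descriptor column names.
#' @export
descriptor_names <- function() {
  c("h_log_pbo", "kier_flex", "q_vsa_hyd", "slogp_vsa7", "vsa_pol")
}

# ---- molecule cache ---------------------------------------------------------

.mol_cache <- new.env(parent = emptyenv())

# parse + descriptors (+ lazily computed fingerprint), memoised on the input
# SMILES string and the descriptor parameters
cached_molecule <- function(smiles, log_base = exp(1), hyd_threshold = 0.2,
                            nbits = 2048L, max_len = 7L) {
  key <- paste(smiles, log_base, hyd_threshold, nbits, max_len, sep = "|")
  hit <- .mol_cache[[key]]
  if (!is.null(hit)) return(hit)
  g <- parse_smiles(smiles)
  val <- new.env(parent = emptyenv())
  val$graph <- g
  val$desc <- compute_descriptors(g, log_base = log_base,
                                  hyd_threshold = hyd_threshold)
  # fingerprints are costlier than descriptors; compute on first access
  delayedAssign("fp", fingerprint(g, nbits = nbits, max_len = max_len),
                assign.env = val)
  assign(key, val, envir = .mol_cache)
  val
}

#' Clear the internal molecule cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_molecule_cache <- function() {
  n <- length(ls(.mol_cache))
  rm(list = ls(.mol_cache), envir = .mol_cache)
  invisible(n)
}

#' Featurise a table of molecules
#'
#' Parses every SMILES, computes the five model descriptors and appends them
#' as columns.  Rows whose SMILES cannot be parsed are dropped with a
#' warning naming the offending records.
#'
#' @param data Data frame with at least a SMILES column.
#' @param smiles_col Name of the SMILES column (default `"smiles"`).
#' @param log_base,hyd_threshold Descriptor parameters, see
#'   [compute_descriptors()].
#' @return The input as a tibble with columns `h_log_pbo`, `kier_flex`,
#'   `q_vsa_hyd`, `slogp_vsa7`, `vsa_pol` appended and an attribute
#'   `"parse_failures"` listing dropped records.
#' @export
#' @examples
#' library(tibble)
#' featurize(tibble(id = "diazepam",
#'                  smiles = "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21"))
featurize <- function(data, smiles_col = "smiles",
                      log_base = exp(1), hyd_threshold = 0.2) {
  stopifnot(is.data.frame(data), smiles_col %in% names(data))
  smiles <- data[[smiles_col]]
  rows <- vector("list", length(smiles))
  failed <- character(0)
  for (i in seq_along(smiles)) {
    rows[[i]] <- tryCatch(
      cached_molecule(smiles[i], log_base, hyd_threshold)$desc,
      error = function(e) {
        failed <<- c(failed, sprintf("row %d (%s): %s", i, smiles[i],
                                     conditionMessage(e)))
        NULL
      })
  }
  keep <- !vapply(rows, is.null, logical(1))
  if (any(!keep))
    warning("dropped ", sum(!keep), " unparseable record(s):\n  ",
            paste(failed, collapse = "\n  "))
  out <- dplyr::bind_cols(tibble::as_tibble(data[keep, , drop = FALSE]),
                          dplyr::bind_rows(rows[keep]))
  attr(out, "parse_failures") <- failed
  out
}
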