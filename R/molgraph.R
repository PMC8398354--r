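# Molecular graph construction from SMILES.
#
# SMILES parsing and canonicalisation are delegated to Open Babel (via
# ChemmineOB/ChemmineR); the molblock it returns is kekulised, so aromaticity
# is re-perceived here with an explicit Hueckel 4n+2 ring rule that is applied
# uniformly to every molecule.  Stereochemistry is discarded throughout: all
# descriptors are two-dimensional.

# default valence used for implicit-hydrogen assignment; charge adjusts it
# (N+ -> 4, O- -> 1, ...).  S and P may exceed these (sulfone, phosphate);
# implicit H is floored at zero so hypervalent atoms simply get no hydrogens.
.default_valence <- c(
  C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
  F = 1, Cl = 1, Br = 1, I = 1, H = 1
)

# old-style molfile charge codes (atom block field 5)
.molfile_charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                     `5` = -1, `6` = -2, `7` = -3)

#' Canonicalise SMILES strings
#'
#' Converts SMILES to Open Babel canonical form.  Multi-fragment inputs
#' (dot-separated) are reduced to their largest covalent fragment first, so
#' counter-ions and solvates never reach the descriptor code.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES (`NA` where parsing failed).
#' @export
#' @examples
#' canonical_smiles(c("OCC", "CCO"))   # same molecule, one spelling
canonical_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    s <- largest_fragment_smiles(s)
    if (is.na(s)) return(NA_character_)
    out <- ob_convert(s, "CAN")
    if (is.na(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Single-molecule Open Babel conversion; returns NA on failure.
ob_convert <- function(smiles, to = "CAN") {
  res <- tryCatch(
    ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\tmol\n")),
    error = function(e) NA_character_
  )
  if (length(res) != 1 || is.na(res) || !nzchar(trimws(res))) return(NA_character_)
  if (to == "CAN") {
    line <- strsplit(trimws(res), "[\t ]")[[1]][1]
    if (!nzchar(line)) return(NA_character_)
    return(line)
  }
  res
}

# Pick the largest dot-separated fragment (by heavy-atom count estimated
# lexically); ties keep the first.  Returns NA for empty input.
largest_fragment_smiles <- function(smiles) {
  smiles <- trimws(smiles)
  if (!nzchar(smiles)) return(NA_character_)
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) return(NA_character_)
  if (length(parts) == 1) return(parts)
  counts <- vapply(parts, count_heavy_tokens, numeric(1))
  parts[which.max(counts)]
}

# Lexical heavy-atom count (used only to rank fragments).
count_heavy_tokens <- function(s) {
  s <- gsub("\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]", "", s)      # explicit-H atoms
  toks <- gregexpr("Cl|Br|Si|Se|As|[BCNOPSFI]|\\b|[bcnops]", s)[[1]]
  m <- regmatches(s, gregexpr("Cl|Br|Si|Se|As|[BCNOPSFIbcnops]", s))[[1]]
  length(m)
}

# Cheap lexical check so parse failures can point at the offending position.
# Returns NULL if nothing obviously wrong, else list(pos, msg).
smiles_lint <- function(s) {
  chars <- strsplit(s, "")[[1]]
  depth <- 0L; in_brk <- FALSE
  ok <- "[]()=#:/\\%.+-@0123456789BCNOPSFIbcnopsilrHeKaguAdTtWmZhXyVf*"
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "[") { if (in_brk) return(list(pos = i, msg = "nested '['")); in_brk <- TRUE }
    else if (ch == "]") { if (!in_brk) return(list(pos = i, msg = "unmatched ']'")); in_brk <- FALSE }
    else if (ch == "(") depth <- depth + 1L
    else if (ch == ")") { depth <- depth - 1L
      if (depth < 0) return(list(pos = i, msg = "unmatched ')'")) }
    if (!grepl(ch, ok, fixed = TRUE))
      return(list(pos = i, msg = sprintf("invalid character '%s'", ch)))
  }
  if (in_brk) return(list(pos = length(chars), msg = "unclosed '['"))
  if (depth != 0) return(list(pos = length(chars), msg = "unclosed '('"))
  NULL
}

#' Parse a SMILES string into a molecular graph
#'
#' Builds a sanitised heavy-atom graph: the largest covalent fragment is kept,
#' implicit hydrogens are assigned from standard valences, aromaticity is
#' perceived with a Hueckel 4n+2 ring rule, and stereochemistry is discarded.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `mol_graph`: a list with `atoms` (data frame of
#'   element, formal charge, aromatic flag, implicit hydrogen count, degree,
#'   ring membership), `bonds` (data frame of endpoint indices, integer order,
#'   aromatic flag) and `smiles` (canonical SMILES of the kept fragment).
#' @export
#' @examples
#' mol <- parse_smiles("c1ccccc1")   # benzene
#' nrow(mol$atoms)
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  if (!nzchar(trimws(smiles))) stop("empty SMILES string", call. = FALSE)
  frag <- largest_fragment_smiles(smiles)
  lint <- smiles_lint(frag)
  if (!is.null(lint))
    stop(sprintf("cannot parse SMILES '%s': %s at position %d",
                 smiles, lint$msg, lint$pos), call. = FALSE)
  can <- ob_convert(frag, "CAN")
  if (is.na(can))
    stop(sprintf("cannot parse SMILES '%s'", smiles), call. = FALSE)
  sdf <- ob_convert(can, "SDF")
  if (is.na(sdf))
    stop(sprintf("cannot parse SMILES '%s'", smiles), call. = FALSE)
  g <- molblock_to_graph(sdf)
  if (nrow(g$atoms) == 0)
    stop(sprintf("SMILES '%s' describes an empty molecule", smiles), call. = FALSE)
  g$smiles <- can
  g
}

# Convert a V2000 molblock string (single record) to a mol_graph.
molblock_to_graph <- function(sdftext) {
  lines <- strsplit(sdftext, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[seq_len(n_atoms) + 4]
  element <- trimws(substr(atom_lines, 32, 34))
  chg_code <- as.integer(substr(atom_lines, 37, 39))
  charge <- unname(.molfile_charge[as.character(chg_code)])
  charge[is.na(charge)] <- 0
  # M CHG lines override the old-style codes
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  for (cl in chg_lines) {
    flds <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "\\s+")[[1]])
    k <- flds[1]
    for (j in seq_len(k)) charge[flds[2 * j]] <- flds[2 * j + 1]
  }
  if (n_bonds > 0) {
    bond_lines <- lines[seq_len(n_bonds) + 4 + n_atoms]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    order <- as.integer(substr(bond_lines, 7, 9))
  } else {
    a1 <- a2 <- order <- integer(0)
  }
  # fold explicit hydrogens into their heavy neighbour
  extra_h <- integer(n_atoms)
  is_h <- element == "H"
  if (any(is_h)) {
    for (b in seq_along(a1)) {
      if (is_h[a1[b]] && !is_h[a2[b]]) extra_h[a2[b]] <- extra_h[a2[b]] + 1L
      if (is_h[a2[b]] && !is_h[a1[b]]) extra_h[a1[b]] <- extra_h[a1[b]] + 1L
    }
    keep <- which(!is_h)
    remap <- integer(n_atoms); remap[keep] <- seq_along(keep)
    sel <- !is_h[a1] & !is_h[a2]
    a1 <- remap[a1[sel]]; a2 <- remap[a2[sel]]; order <- order[sel]
    element <- element[keep]; charge <- charge[keep]; extra_h <- extra_h[keep]
    n_atoms <- length(keep)
  }
  # keep the largest connected component (fragment selection safety net)
  comp <- graph_components(n_atoms, a1, a2)
  if (length(unique(comp)) > 1) {
    main <- as.integer(names(which.max(table(comp))))
    keep <- which(comp == main)
    remap <- integer(n_atoms); remap[keep] <- seq_along(keep)
    sel <- comp[a1] == main
    a1 <- remap[a1[sel]]; a2 <- remap[a2[sel]]; order <- order[sel]
    element <- element[keep]; charge <- charge[keep]; extra_h <- extra_h[keep]
    n_atoms <- length(keep)
  }
  bond_sum <- numeric(n_atoms); degree <- integer(n_atoms)
  for (b in seq_along(a1)) {
    bond_sum[a1[b]] <- bond_sum[a1[b]] + order[b]
    bond_sum[a2[b]] <- bond_sum[a2[b]] + order[b]
    degree[a1[b]] <- degree[a1[b]] + 1L
    degree[a2[b]] <- degree[a2[b]] + 1L
  }
  val <- unname(.default_valence[element])
  if (anyNA(val))
    stop("unsupported element(s): ",
         paste(unique(element[is.na(val)]), collapse = ", "), call. = FALSE)
  adj_val <- ifelse(element == "C", val - abs(charge), val + charge)
  nH <- pmax(0L, as.integer(adj_val - bond_sum)) + extra_h
  atoms <- data.frame(element = element, charge = as.integer(charge),
                      aromatic = FALSE, nH = as.integer(nH),
                      degree = degree, in_ring = FALSE,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a1 = a1, a2 = a2, order = order,
                      aromatic = logical(length(a1)))
  g <- structure(list(atoms = atoms, bonds = bonds, smiles = NA_character_),
                 class = "mol_graph")
  perceive_aromaticity(g)
}

# connected components by breadth-first search
graph_components <- function(n, a1, a2) {
  comp <- integer(n); cur <- 0L
  nbrs <- adjacency_list(n, a1, a2)
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in nbrs[[v]]) if (comp[w] == 0L) { comp[w] <- cur; queue <- c(queue, w) }
    }
  }
  comp
}

adjacency_list <- function(n, a1, a2) {
  nbrs <- vector("list", n)
  for (b in seq_along(a1)) {
    nbrs[[a1[b]]] <- c(nbrs[[a1[b]]], a2[b])
    nbrs[[a2[b]]] <- c(nbrs[[a2[b]]], a1[b])
  }
  nbrs
}

# enumerate simple cycles of length 5 or 6 (candidate aromatic rings)
find_rings <- function(g, sizes = 5:6) {
  n <- nrow(g$atoms)
  nbrs <- adjacency_list(n, g$bonds$a1, g$bonds$a2)
  rings <- list()
  seen <- character(0)
  maxlen <- max(sizes)
  dfs <- function(path) {
    v <- path[length(path)]
    for (w in nbrs[[v]]) {
      if (w == path[1] && length(path) %in% sizes) {
        key <- paste(sort(path), collapse = "-")
        if (!key %in% seen) { seen <<- c(seen, key); rings[[length(rings) + 1L]] <<- path }
      } else if (!w %in% path && length(path) < maxlen && w > path[1]) {
        dfs(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) dfs(s)
  rings
}

# Hueckel 4n+2 aromatic perception on the kekulised graph.  An atom in a
# candidate ring contributes 1 pi electron if it carries a double bond inside
# the ring, 2 if it is a lone-pair donor (N/O/S with only single bonds), and
# disqualifies the ring otherwise (sp3 carbon, exocyclic-only double bond).
perceive_aromaticity <- function(g) {
  bonds <- g$bonds
  n <- nrow(g$atoms)
  dbl_partner <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    if (bonds$order[b] >= 2) {
      dbl_partner[[bonds$a1[b]]] <- c(dbl_partner[[bonds$a1[b]]], bonds$a2[b])
      dbl_partner[[bonds$a2[b]]] <- c(dbl_partner[[bonds$a2[b]]], bonds$a1[b])
    }
  }
  rings <- find_rings(g)
  bond_key <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
  for (ring in rings) {
    g$atoms$in_ring[ring] <- TRUE
    k <- length(ring)
    pi_e <- integer(k); ok <- TRUE
    for (j in seq_len(k)) {
      a <- ring[j]
      el <- g$atoms$element[a]
      partners <- dbl_partner[[a]]
      if (length(partners) && any(partners %in% ring)) {
        pi_e[j] <- 1L
      } else if (length(partners)) {
        ok <- FALSE; break            # exocyclic double bond (e.g. quinone C)
      } else if (el %in% c("N", "O", "S") && g$atoms$charge[a] <= 0) {
        pi_e[j] <- 2L                 # lone-pair donor (pyrrole N, furan O, thiophene S)
      } else {
        ok <- FALSE; break            # saturated atom breaks conjugation
      }
    }
    if (ok && sum(pi_e) %% 4 == 2) {
      g$atoms$aromatic[ring] <- TRUE
      ring_pairs <- paste(pmin(ring, c(ring[-1], ring[1])),
                          pmax(ring, c(ring[-1], ring[1])))
      g$bonds$aromatic[bond_key %in% ring_pairs] <- TRUE
    }
  }
  g
}

# simple hybridisation assignment from the kekulised bond orders
atom_hybridisation <- function(g) {
  n <- nrow(g$atoms)
  n_dbl <- integer(n); n_trp <- integer(n)
  for (b in seq_len(nrow(g$bonds))) {
    o <- g$bonds$order[b]
    if (o == 2) { n_dbl[g$bonds$a1[b]] <- n_dbl[g$bonds$a1[b]] + 1L
                  n_dbl[g$bonds$a2[b]] <- n_dbl[g$bonds$a2[b]] + 1L }
    if (o == 3) { n_trp[g$bonds$a1[b]] <- n_trp[g$bonds$a1[b]] + 1L
                  n_trp[g$bonds$a2[b]] <- n_trp[g$bonds$a2[b]] + 1L }
  }
  hyb <- rep("sp3", n)
  hyb[n_dbl >= 1 | g$atoms$aromatic] <- "sp2"
  hyb[n_trp >= 1 | n_dbl >= 2] <- "sp"
  hyb
}

#' @export
print.mol_graph <- function(x, ...) {
  n_arom <- sum(x$atoms$aromatic)
  cat(sprintf("<mol_graph> %s\n  %d heavy atoms (%d aromatic), %d bonds\n",
              x$smiles, nrow(x$atoms), n_arom, nrow(x$bonds)))
  invisible(x)
}
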