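# Hashed linear-path fingerprints and Tanimoto similarity.
#
# Every simple path of 0..7 bonds is encoded as a string of element symbols
# (with aromatic and charge marks) alternating with bond orders, read in its
# lexicographically smaller direction so the encoding is independent of atom
# numbering, and hashed onto a fixed-length bit set.

#' Compute a hashed linear-path fingerprint
#'
#' Enumerates all simple linear paths up to `max_len` bonds and hashes each
#' canonical path string onto an `nbits`-bit vector.  Deterministic for a
#' given molecule regardless of how its SMILES was written.
#'
#' @param mol A `mol_graph` (from [parse_smiles()]) or a SMILES string.
#' @param nbits Fingerprint length in bits (default 2048).
#' @param max_len Maximum path length in bonds (default 7).
#' @return Integer vector of set bit positions (sorted, zero-based) with
#'   attributes `nbits`; class `mol_fp`.
#' @export
#' @examples
#' fp <- fingerprint("c1ccccc1")
#' length(fp) >= 1
fingerprint <- function(mol, nbits = 2048L, max_len = 7L) {
  if (is.character(mol)) mol <- parse_smiles(mol)
  stopifnot(inherits(mol, "mol_graph"))
  hashes <- enumerate_path_hashes(mol, max_len)
  bits <- sort(unique(as.integer(hashes %% nbits)))
  structure(bits, nbits = as.integer(nbits), class = "mol_fp")
}

# Numeric token codes for atoms (element, aromatic flag, charge) and bonds
# (order / aromatic), and the hash modulus.  The modulus is below 2^26 so all
# products stay exactly representable in double arithmetic.
.fp_modulus <- 67108859
.fp_radix <- 131

# canonical hash of every simple path up to max_len bonds: each path is read
# as an alternating atom/bond token sequence; forward and reverse rolling
# hashes are maintained incrementally and the smaller of the two at emission
# is the direction-independent path code
enumerate_path_hashes <- function(g, max_len) {
  n <- nrow(g$atoms)
  nbrs <- adjacency_list(n, g$bonds$a1, g$bonds$a2)
  m <- .fp_modulus; rad <- .fp_radix
  # atom token codes
  atok <- (match(g$atoms$element, c("C", "N", "O", "S", "F", "Cl", "Br", "I",
                                    "P", "B", "H")) * 8 +
           as.integer(g$atoms$aromatic) * 4 + (g$atoms$charge %% 4)) %% m
  # bond token lookup as a dense matrix (molecular graphs are small)
  btok_m <- matrix(0, n, n)
  bcode <- ifelse(g$bonds$aromatic, 5L, g$bonds$order)
  for (b in seq_len(nrow(g$bonds))) {
    btok_m[g$bonds$a1[b], g$bonds$a2[b]] <- bcode[b]
    btok_m[g$bonds$a2[b], g$bonds$a1[b]] <- bcode[b]
  }
  rad2 <- (rad * rad) %% m
  pow <- numeric(max_len + 2)        # rad2^k mod m
  pow[1] <- 1
  for (k in seq_len(max_len + 1)) pow[k + 1] <- (pow[k] * rad2) %% m
  out <- numeric(0)
  # depth-first extension keeping fwd/rev hashes incrementally; a path of k
  # atoms has 2k-1 tokens:
  #   fwd(new) = fwd * rad^2 + bond * rad + atom
  #   rev(new) = (atom * rad + bond) * rad^(2k-3) + rev(old)
  dfs <- function(path, fwd, rev_) {
    out[length(out) + 1L] <<- min(fwd, rev_)
    if (length(path) > max_len) return()
    v <- path[length(path)]
    k <- length(path) + 1L
    sh <- (pow[k - 1] * rad) %% m            # rad^(2k-3)
    for (w in nbrs[[v]]) {
      if (w %in% path) next
      bt <- btok_m[v, w]
      f2 <- (fwd * rad2 + bt * rad + atok[w]) %% m
      r2 <- (((atok[w] * rad + bt) %% m) * sh + rev_) %% m
      dfs(c(path, w), f2, r2)
    }
  }
  for (s in seq_len(n)) dfs(s, atok[s], atok[s])
  unique(out)
}

#' Tanimoto similarity between two fingerprints
#'
#' @param a,b Fingerprints from [fingerprint()] (same `nbits`).
#' @return Similarity |a n b| / |a u b| in `[0, 1]`; two empty fingerprints
#'   give 0 with a warning.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "mol_fp"), inherits(b, "mol_fp"))
  if (!identical(attr(a, "nbits"), attr(b, "nbits")))
    stop("fingerprints have different lengths", call. = FALSE)
  u <- length(union(a, b))
  if (u == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  length(intersect(a, b)) / u
}

#' Average Tanimoto similarity of one molecule against a pool
#'
#' The arithmetic mean of the pairwise Tanimoto coefficients between `target`
#' and every fingerprint in `pool`.  Used both for dataset curation and for
#' the applicability domain.  If `target` itself is present in the pool
#' (identical bit set) exactly one copy is excluded, so a molecule is never
#' compared with itself.
#'
#' @param target A `mol_fp`.
#' @param pool List of `mol_fp`.
#' @return Mean similarity in `[0, 1]`.
#' @export
average_tc <- function(target, pool) {
  stopifnot(inherits(target, "mol_fp"), is.list(pool))
  self <- which(vapply(pool, identical, logical(1), y = target))
  if (length(self)) pool <- pool[-self[1]]
  if (length(pool) == 0) stop("similarity pool is empty", call. = FALSE)
  mean(vapply(pool, function(f) tanimoto(target, f), numeric(1)))
}

# all-pairs average Tc for a list of fingerprints (each vs all others)
average_tc_matrixwise <- function(fps) {
  n <- length(fps)
  if (n < 2) stop("need at least two fingerprints", call. = FALSE)
  sim <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- tanimoto(fps[[i]], fps[[j]])
    sim[i, j] <- s; sim[j, i] <- s
  }
  (rowSums(sim) - 1) / (n - 1)
}
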