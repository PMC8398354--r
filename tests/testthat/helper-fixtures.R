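# shared fixtures and small constructors

DIAZEPAM <- "CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21"
ALPRAZOLAM <- "Cc1nnc2n1-c1ccc(Cl)cc1C(=NC2)c1ccccc1"
OXAZEPAM <- "OC1N=C(c2ccccc2)c2cc(Cl)ccc2NC1=O"
HEXANE <- "CCCCCC"

# a fingerprint object with explicitly chosen bits
make_fp <- function(bits, nbits = 2048L) {
  structure(sort(as.integer(bits)), nbits = as.integer(nbits),
            class = "mol_fp")
}

# ten classic benzodiazepine congeners (for curation/domain tests)
BZD_TEN <- c(
  DIAZEPAM, OXAZEPAM,
  "O=C1CN=C(c2ccccc2)c2cc(Cl)ccc2N1",           # nordiazepam
  "O=C1CN=C(c2ccccc2)c2cc([N+](=O)[O-])ccc2N1", # nitrazepam
  "O=C1CN=C(c2ccccc2F)c2cc(Cl)ccc2N1",          # norflurazepam-like
  "CN1C(=O)CN=C(c2ccccc2F)c2cc(Cl)ccc21",       # flu-analogue
  "O=C1CN=C(c2ccccc2Cl)c2cc(Br)ccc2N1",         # phenazepam-like
  "CCN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21",       # N1-ethyl analogue
  "OC1N=C(c2ccccc2Cl)c2cc(Cl)ccc2NC1=O",        # lorazepam-like
  "CN1C(=O)C(O)N=C(c2ccccc2)c2cc(Cl)ccc21"      # temazepam-like
)

# random numeric regression problem with planted coefficients
make_regression <- function(n, beta, sigma = 0, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- as.vector(X %*% beta) + rnorm(n, 0, sigma)
  list(X = X, y = y)
}

# train-mode libraries are costly to optimise; share them across test files
.shared_libs <- new.env(parent = emptyenv())
shared_train_lib <- function(n, seed = 1) {
  key <- paste(n, seed)
  if (is.null(.shared_libs[[key]]))
    .shared_libs[[key]] <- generate_library(n, seed = seed)
  .shared_libs[[key]]
}
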