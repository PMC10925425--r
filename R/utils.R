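## Internal geometry / bookkeeping helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

## Cross-distance matrix between two (n x 3) coordinate matrices.
cross_dist <- function(a, b) {
  a <- matrix(as.numeric(a), ncol = 3)
  b <- matrix(as.numeric(b), ncol = 3)
  ## |a - b|^2 = |a|^2 + |b|^2 - 2 a.b, guarded against tiny negatives
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vcross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

vnorm <- function(u) sqrt(sum(u^2))

## Element symbol from a PDB atom name when the element column is blank.
## Atom names like "NH1", "OD1", "CA", "N1N", "1HB" resolve to their leading
## alphabetic character after stripping digits/primes.
element_from_name <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", toupper(atom_name))
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("FE", "ZN", "MG", "MN", "CA", "NA", "CL", "BR", "SE"),
                two, substr(nm, 1, 1))
  ## "CA" as an atom name is almost always an alpha carbon in protein residues;
  ## callers pass the residue context when the calcium ion matters.
  ifelse(toupper(atom_name) == "CA", "C", out)
}

WATER_NAMES <- c("HOH", "WAT", "DOD")

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = "|")
}

is_heavy <- function(atoms) !(atoms$element %in% c("H", "D"))

stop2 <- function(...) stop(..., call. = FALSE)
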