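# Independent oracles and random-fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Signed torsion via projection onto the plane normal to the central bond
# (no atan2 on the package's intermediate vectors; different construction).
oracle_dihedral <- function(p1, p2, p3, p4) {
  b2 <- p3 - p2
  bhat <- b2 / sqrt(sum(b2^2))
  proj <- function(v) v - sum(v * bhat) * bhat
  u1 <- proj(p1 - p2)
  u2 <- proj(p4 - p3)
  x <- sum(u1 * u2)
  cr <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  ang <- atan2(sum(cr * bhat), x) * 180 / pi
  if (ang <= -180) ang + 360 else ang
}

# Horn's quaternion method for optimal rigid superposition RMSD.
oracle_quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(A, B)
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lambda <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lambda) / nrow(A)
  sqrt(max(msd, 0))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

apply_rigid <- function(model, R = random_rotation(), t = rnorm(3, sd = 5)) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R) +
    matrix(t, nrow(model$atoms), 3, byrow = TRUE)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]; model$atoms$z <- xyz[, 3]
  model
}

# Random structure fixture: n atoms scattered in a box, random chains,
# residues of 1-4 atoms, elements biased toward protein composition.
random_structure <- function(n = 200, box = 20) {
  resno <- cumsum(runif(n) < 0.4) + 1L
  chain <- sample(c("A", "B"), n, replace = TRUE)
  resid <- ifelse(runif(n) < 0.1, "HOH", "ALA")
  element <- ifelse(resid == "HOH", "O",
                    sample(c("C", "N", "O", "S"), n, replace = TRUE,
                           prob = c(0.55, 0.2, 0.2, 0.05)))
  atoms <- data.frame(
    eleno = seq_len(n), chain = chain, resno = resno, insert = "",
    resid = resid,
    elety = paste0(element, seq_len(n) %% 10), element = element,
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    o = 1, alt = "", is_water = resid == "HOH",
    is_hetero = resid == "HOH", stringsAsFactors = FALSE)
  remodelkit:::new_structure_model(atoms, source_id = "random-fixture")
}

# O(n^2) residue-shell enumeration.
oracle_shell <- function(model, center_atoms, cutoff) {
  a <- model$atoms
  a <- a[!(a$element %in% c("H", "D")), ]
  ca <- center_atoms[!(center_atoms$element %in% c("H", "D")), ]
  ck <- unique(paste(ca$chain, ca$resno, ca$insert))
  hits <- character(0)
  for (i in seq_len(nrow(a))) {
    k <- paste(a$chain[i], a$resno[i], a$insert[i])
    if (k %in% ck) next
    for (j in seq_len(nrow(ca))) {
      d <- sqrt((a$x[i] - ca$x[j])^2 + (a$y[i] - ca$y[j])^2 +
                  (a$z[i] - ca$z[j])^2)
      if (d <= cutoff) { hits <- c(hits, k); break }
    }
  }
  sort(unique(hits))
}

# O(n^2) polar-contact enumeration across two selections.
oracle_polar_contacts <- function(sa, sb, cutoff) {
  polar <- c("N", "O", "S")
  keys <- character(0)
  for (i in seq_len(nrow(sa))) {
    if (!(sa$element[i] %in% polar)) next
    for (j in seq_len(nrow(sb))) {
      if (!(sb$element[j] %in% polar)) next
      if (sa$eleno[i] == sb$eleno[j]) next
      d <- sqrt((sa$x[i] - sb$x[j])^2 + (sa$y[i] - sb$y[j])^2 +
                  (sa$z[i] - sb$z[j])^2)
      if (d <= cutoff)
        keys <- c(keys, paste(min(sa$eleno[i], sb$eleno[j]),
                              max(sa$eleno[i], sb$eleno[j])))
    }
  }
  sort(unique(keys))
}

standard_peptides <- function() {
  data.frame(start = c(210L, 240L, 257L), end = c(216L, 253L, 267L),
             sequence = c("LGWTKPI", "ACDEFGHIKLMNQR", "STVWYACDEFG"),
             stringsAsFactors = FALSE)
}
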