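# Independent oracles used across the suite. These deliberately share no
# code with the package implementations they check.

# Exhaustive affine-gap local alignment (Gotoh recursion), scoring a gap
# of length L as gap_open + L * gap_extend.
sw_oracle <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  Iy <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Quaternion-based optimal superposition rmsd (Horn's method): the
# largest eigenvalue of the 4x4 key matrix gives the optimal residual.
quaternion_rmsd <- function(A, B) {
  A0 <- scale(A, scale = FALSE); B0 <- scale(B, scale = FALSE)
  S <- crossprod(B0, A0)
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2], S[3,1]-S[1,3], S[1,2]-S[2,1],
    S[2,3]-S[3,2], S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1], S[3,1]+S[1,3],
    S[3,1]-S[1,3], S[1,2]+S[2,1], -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1], S[3,1]+S[1,3], S[2,3]+S[3,2], -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(A0^2) + sum(B0^2) - 2 * lam)) / nrow(A))
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  sum_i <- ch2(rowSums(tab)); sum_j <- ch2(colSums(tab))
  n2 <- ch2(sum(tab))
  expected <- sum_i * sum_j / n2
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# Random protein over the 20 standard residues.
random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                 "R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}

# Three diverged families with known membership, for clustering checks.
three_family_set <- function(sub_rate, sizes = c(40, 30, 30), seed) {
  fams <- lapply(seq_along(sizes), function(k)
    make_family(160 + 5 * k, n = sizes[k], sub_rate = sub_rate,
                seed = seed * 100 + k)$members)
  seqs <- unlist(lapply(seq_along(fams), function(k)
    setNames(fams[[k]], sprintf("f%d_%02d", k, seq_along(fams[[k]])))))
  truth <- rep(seq_along(sizes), sizes)
  list(sequences = seqs, truth = truth)
}

# Minimal hand-built PDB text for C-alpha fixtures.
pdb_atom_line <- function(serial, elety, resid, chain, resno, x, y, z,
                          occ = 1, alt = " ") {
  paste0("ATOM  ", formatC(serial, width = 5), "  ",
         formatC(elety, width = -3), alt, formatC(resid, width = -3),
         " ", chain, formatC(resno, width = 4), "    ",
         formatC(x, width = 8, format = "f", digits = 3),
         formatC(y, width = 8, format = "f", digits = 3),
         formatC(z, width = 8, format = "f", digits = 3),
         formatC(occ, width = 6, format = "f", digits = 2),
         formatC(0, width = 6, format = "f", digits = 2),
         "           C")
}

write_toy_pdb <- function(path, lines) {
  writeLines(c(lines, "END"), path)
  path
}
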