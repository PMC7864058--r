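# independent oracles and small fixture builders used across test files

# brute-force trace of the three-pass trimmed threshold
bf_threshold <- function(v) {
  v <- v[is.finite(v)]
  for (pass in 1:2) {
    m <- mean(v); s <- if (length(v) > 1) sd(v) else 0
    v <- v[v >= m - s & v <= m + s]
    stopifnot(length(v) > 0)
  }
  m3 <- mean(v)
  std3 <- if (length(v) > 1) sd(v) else 0
  list(m3 = m3, std3 = std3, upper = m3 + 2 * std3, lower = m3 - 2 * std3,
       n_core = length(v))
}

# naive average-linkage 2-cluster partition via the full pairwise matrix
naive_linkage_2cluster <- function(values) {
  hc <- stats::hclust(stats::dist(values), method = "average")
  stats::cutree(hc, k = 2)
}

# do two label vectors describe the same partition into two groups?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# apply a random rigid transform (rotation + translation) to every frame
rigid_transform_frames <- function(frames) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 20)
  xyz <- frames$xyz
  out <- xyz
  n_at <- frames$n_atoms
  for (f in seq_len(frames$n_frames)) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    m <- m %*% t(q) + matrix(shift, n_at, 3, byrow = TRUE)
    out[f, ] <- as.vector(t(m))
  }
  frame_series(out, frames$frame_interval_ps)
}

# hand-built two-residue peptide PDB with a backbone N-H donor and C=O
# acceptor, plus an optional second model; returns the file path
write_toy_peptide_pdb <- function(path, second_model = FALSE) {
  atom_line <- function(no, name, res, resno, x, y, z, ele)
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            no, name, res, resno, x, y, z, ele)
  model <- function(dz) c(
    atom_line(1, "N",  "ALA", 1, 0.0, 0.0, 0.0 + dz, "N"),
    atom_line(2, "H",  "ALA", 1, 0.0, 0.0, -1.0 + dz, "H"),
    atom_line(3, "CA", "ALA", 1, 1.5, 0.0, 0.0 + dz, "C"),
    atom_line(4, "C",  "ALA", 1, 2.5, 1.1, 0.0 + dz, "C"),
    atom_line(5, "O",  "ALA", 1, 3.7, 1.0, 0.0 + dz, "O"),
    atom_line(6, "N",  "GLY", 2, 2.0, 2.3, 0.0 + dz, "N"),
    atom_line(7, "H",  "GLY", 2, 1.0, 2.3, 0.0 + dz, "H"),
    atom_line(8, "CA", "GLY", 2, 2.8, 3.5, 0.0 + dz, "C"))
  lines <- c("MODEL     1", model(0), "ENDMDL")
  if (second_model) lines <- c(lines, "MODEL     2", model(2.5), "ENDMDL")
  writeLines(c(lines, "END"), path)
  path
}

# Cramer-Rao lower bound on the rate variance for I(t) = I0 exp(-R t)
# with iid Gaussian noise sigma
cr_sigma_rate <- function(delays, i0, rate, sigma) {
  f <- exp(-rate * delays)
  jac <- cbind(f, -i0 * delays * f)          # d/dI0, d/dR
  v <- sigma^2 * solve(crossprod(jac))
  sqrt(v[2, 2])
}
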