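# Shared fixtures, built in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

protein_tbl <- function(id, sequence) tibble::tibble(id = id, sequence = sequence)

# brute-force unordered adjacent-pair tally, independent of the package
brute_pair_tally <- function(residues) {
  ch <- strsplit(residues, "")[[1]]
  m <- matrix(0L, 20L, 20L, dimnames = list(AA20, AA20))
  for (i in seq_len(length(ch) - 1L)) {
    a <- ch[i]; b <- ch[i + 1L]
    m[a, b] <- m[a, b] + 1L
    if (a != b) m[b, a] <- m[b, a] + 1L
  }
  m
}

# independent dihedral via the projection ("praxeolitic") formula
brute_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- p3 - p2; b2 <- p4 - p3
  b1u <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1u) * b1u
  w <- b2 - sum(b2 * b1u) * b1u
  x <- sum(v * w)
  cr <- c(b1u[2] * v[3] - b1u[3] * v[2],
          b1u[3] * v[1] - b1u[1] * v[3],
          b1u[1] * v[2] - b1u[2] * v[1])
  y <- sum(cr * w)
  ang <- atan2(y, x) * 180 / pi
  ((ang + 180) %% 360) - 180
}

random_rotation <- function(seed) {
  set.seed(seed)
  q <- matrix(rnorm(9), 3, 3)
  qr_q <- qr.Q(qr(q))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

small_dataset <- function(n_proteins = 15, seed = 7) {
  generate_dataset(synth_config(n_proteins = n_proteins, seed = seed))
}
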