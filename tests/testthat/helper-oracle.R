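# Independent brute-force reference implementation of the shape descriptors.
# Deliberately written with explicit scalar loops and no shared code with the
# package, so agreement between the two is evidence of correctness rather
# than of shared bugs.

oracle_ref_points <- function(coords) {
  n <- nrow(coords)
  ctd <- c(0, 0, 0)
  for (i in seq_len(n)) ctd <- ctd + coords[i, ]
  ctd <- ctd / n
  d <- numeric(n)
  for (i in seq_len(n))
    d[i] <- sqrt(sum((coords[i, ] - ctd)^2))
  i_cst <- 1; i_fct <- 1
  for (i in seq_len(n)) {
    if (d[i] < d[i_cst]) i_cst <- i
    if (d[i] > d[i_fct]) i_fct <- i
  }
  d2 <- numeric(n)
  for (i in seq_len(n))
    d2[i] <- sqrt(sum((coords[i, ] - coords[i_fct, ])^2))
  i_ftf <- 1
  for (i in seq_len(n)) if (d2[i] > d2[i_ftf]) i_ftf <- i
  list(ctd, coords[i_cst, ], coords[i_fct, ], coords[i_ftf, ])
}

oracle_triple <- function(d) {
  n <- length(d)
  mu <- 0
  for (x in d) mu <- mu + x
  mu <- mu / n
  v <- 0; m3 <- 0
  for (x in d) {
    v <- v + (x - mu)^2
    m3 <- m3 + (x - mu)^3
  }
  v <- v / n; m3 <- m3 / n
  # same degenerate-zero rule as the method definition: third moments at
  # rounding-noise scale relative to sigma^3 are exactly zero
  if (abs(m3) <= 1e-12 * sqrt(v)^3) m3 <- 0
  kappa <- if (m3 >= 0) m3^(1 / 3) else -((-m3)^(1 / 3))
  c(mu, sqrt(v), kappa)
}

oracle_block <- function(coords, refs) {
  out <- numeric(0)
  for (p in refs) {
    d <- numeric(nrow(coords))
    for (i in seq_len(nrow(coords)))
      d[i] <- sqrt(sum((coords[i, ] - p)^2))
    out <- c(out, oracle_triple(d))
  }
  out
}

oracle_usrcat <- function(coords, subsets) {
  refs <- oracle_ref_points(coords)
  v <- oracle_block(coords, refs)
  for (nm in c("hydrophobic", "aromatic", "acceptor", "donor")) {
    idx <- subsets[[nm]]
    v <- c(v, if (length(idx) == 0) rep(0, 12)
             else oracle_block(coords[idx, , drop = FALSE], refs))
  }
  v
}

# uniform random proper rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d) %*% diag(sign(diag(qr.R(qr_d))))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_cloud <- function(n) matrix(rnorm(n * 3, sd = 2), ncol = 3)

random_subsets <- function(n) {
  pick <- function() {
    k <- sample(0:n, 1)
    if (k == 0) integer() else sample.int(n, k)
  }
  pharmacophore_subsets(pick(), pick(), pick(), pick(), n_atoms = n)
}

fixture_path <- function(f) system.file("extdata", f, package = "usrcatkit")

.paste_m <- function() paste0("m", 1:60)
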