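# Independent brute-force oracles used across tests. Each re-derives the
# target quantity from first principles, never calling the implementation
# it checks.

# High-density SASA oracle: 10k-point spherical lattice (rotated away
# from any axis-aligned set), plain double loop over all atom pairs.
oracle_sasa <- function(model, probe = 1.4, n = 10000L) {
  a <- model$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- a$radius + probe
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  th <- sqrt(n * pi) * asin(z)          # spherical Fibonacci-like lattice
  u <- cbind(cos(th) * sqrt(1 - z^2), sin(th) * sqrt(1 - z^2), z)
  ang <- c(0.3, 0.7, 1.1)               # fixed arbitrary rotation
  rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  u <- u %*% rx %*% rz
  per_atom <- vapply(seq_len(nrow(a)), function(i) {
    pts <- u * r[i] + matrix(xyz[i, ], n, 3L, byrow = TRUE)
    acc <- rep(TRUE, n)
    for (j in seq_len(nrow(a))) {
      if (j == i) next
      acc <- acc & rowSums((pts - matrix(xyz[j, ], n, 3L, byrow = TRUE))^2) >
        r[j]^2
    }
    4 * pi * r[i]^2 * mean(acc)
  }, numeric(1))
  tapply(per_atom, a$residue, sum)
}

# EC by explicit per-column counting.
oracle_ec <- function(aln) {
  rows <- strsplit(unname(aln$sequences), "")
  ref <- rows[[match(aln$reference_id, names(aln$sequences))]]
  out <- numeric(0)
  pos <- 0L
  for (col in seq_along(ref)) {
    if (ref[col] %in% c("-", ".")) next
    pos <- pos + 1L
    n_id <- sum(vapply(rows, function(rw) rw[col] == ref[col], logical(1)))
    out[as.character(pos)] <- n_id / length(rows)
  }
  out
}

# Nearest-neighbour classification by explicit distance sort.
oracle_knn <- function(train_x, train_y, query_x, k) {
  d <- apply(train_x, 1L, function(tr) sqrt(sum((tr - query_x)^2)))
  nn <- order(d)[seq_len(k)]
  votes <- table(train_y[nn])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) top else train_y[nn[1L]]
}

# RMSF straight from the definition (no superposition).
oracle_rmsf <- function(ens) {
  nf <- dim(ens)[1]
  vapply(seq_len(dim(ens)[2]), function(i) {
    xyz <- ens[, i, , drop = TRUE]
    mu <- colMeans(xyz)
    sqrt(mean(rowSums(sweep(xyz, 2, mu)^2)))
  }, numeric(1))
}

# DCCM by explicit double loop.
oracle_dccm <- function(ens) {
  nres <- dim(ens)[2]
  dev <- lapply(seq_len(nres), function(i) {
    xyz <- ens[, i, , drop = TRUE]
    sweep(xyz, 2, colMeans(xyz))
  })
  m <- matrix(0, nres, nres)
  for (i in seq_len(nres)) {
    for (j in seq_len(nres)) {
      num <- mean(rowSums(dev[[i]] * dev[[j]]))
      den <- sqrt(mean(rowSums(dev[[i]]^2)) * mean(rowSums(dev[[j]]^2)))
      m[i, j] <- num / den
    }
  }
  m
}

# A small curated-variant table exercised by several tests.
toy_variant_table <- function() {
  data.frame(
    protein_change = c("T93M", "p.Arg404Cys", "E288K", "V126I", "A41V",
                       "R352W", "G410S", "L99P"),
    clinical_significance = c("pathogenic", "likely_pathogenic", "uncertain",
                              "uncertain", "uncertain", "pathogenic",
                              "benign", "likely_pathogenic"),
    af_exac  = c(1e-3, 2e-4, 5e-4, 1e-4, 3e-5, 1e-6, 4e-4, 2e-3),
    af_1000g = c(0, 0, 0, 1e-3, 0, 0, 5e-4, 0),
    af_esp   = c(1e-3, 0, 0, 0, 2e-4, 0, 1e-4, 5e-4),
    n_female = c(30L, 5L, 60L, 40L, 2L, 1L, 20L, 80L),
    n_male   = c(25L, 3L, 55L, 30L, 1L, 0L, 35L, 60L),
    stringsAsFactors = FALSE)
}
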