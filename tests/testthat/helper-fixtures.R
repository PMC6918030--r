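# Shared fixture builders. Everything is generated in code under a fixed
# seed; no stored binary data.

# Random n x p data matrix
rand_matrix <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# Random PSD kernel of full rank (Wishart-style)
rand_psd <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(rnorm(n * (n + 2)), n)
  tcrossprod(a) / (n + 2)
}

# Small count table with some zeros
toy_counts <- function(seed = 42, n = 6, p = 5) {
  set.seed(seed)
  m <- matrix(rpois(n * p, lambda = 8), n, p)
  m[1, 2] <- 0
  count_table(m,
              sample_ids = sprintf("S%02d", seq_len(n)),
              variable_ids = sprintf("taxon%02d", seq_len(p)))
}

# Independent brute-force patristic distances: sum edge lengths along the
# node path between each pair of tips (never calls cophenetic).
patristic_oracle <- function(tree) {
  ntip <- length(tree$tip.label)
  edge_len <- function(a, b) {
    hit <- (tree$edge[, 1] == a & tree$edge[, 2] == b) |
      (tree$edge[, 1] == b & tree$edge[, 2] == a)
    tree$edge.length[which(hit)]
  }
  d <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip - 1)) {
    for (j in (i + 1):ntip) {
      path <- ape::nodepath(tree, i, j)
      len <- sum(vapply(seq_len(length(path) - 1), function(k) {
        edge_len(path[k], path[k + 1])
      }, numeric(1)))
      d[i, j] <- d[j, i] <- len
    }
  }
  d
}

# Reference design: synthetic kernel with the published leading spectrum
# and the planted weights that invert the AMD ordering.
contrast_fixture <- function(seed = 1, n = 45, p = 50, q = 27) {
  sk <- synthesize_kernel(n, contrast_spectrum(q), seed = seed)
  design <- simulation_design(sk$kernel, sk$basis, contrast_weights(q),
                              p = p, seed = seed + 1000)
  list(kernel = sk$kernel, basis = sk$basis, design = design)
}

# Largest principal angle between the column spans of two M-orthonormal
# bases, via the sine (projection-residual) formula, which is stable for
# small angles where the cosine route loses half the digits.
max_principal_angle <- function(V1, V2, M = NULL) {
  mm <- function(x) if (is.null(M)) x else M %*% x
  res <- V1 - V2 %*% crossprod(V2, mm(V1))
  s2 <- max(eigen(crossprod(res, mm(res)), symmetric = TRUE,
                  only.values = TRUE)$values, 0)
  asin(min(1, sqrt(s2)))
}
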