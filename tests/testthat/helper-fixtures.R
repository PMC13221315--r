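# Shared fixtures, built in code.

# Exactly consistent comparison matrix a_ij = w_i / w_j for a weight vector.
consistent_matrix <- function(w, raw = FALSE) {
  comparison_matrix(outer(w, w, `/`), names(w), raw = raw)
}

# Small 2-domain / 5-indicator hierarchy for cheap structural tests.
tiny_hierarchy <- function() {
  hierarchy_spec(
    domains = data.frame(id = c("d1", "d2"),
                         label = c("First domain", "Second domain")),
    indicators = data.frame(
      code = c("W1.1", "W1.2", "W2.1", "W2.2", "W2.3"),
      domain_id = c("d1", "d1", "d2", "d2", "d2"),
      label = paste("indicator", 1:5)))
}

# One fully specified judgment set on the tiny hierarchy.
tiny_judgment <- function(id = "p1", group = "Regulators",
                          a12 = 3, s1 = c(W1.1 = 100, W1.2 = 50),
                          s2 = c(W2.1 = 100, W2.2 = 80, W2.3 = 40)) {
  h <- tiny_hierarchy()
  m <- comparison_matrix(rbind(c(1, a12), c(1 / a12, 1)),
                         c("d1", "d2"), raw = TRUE)
  judgment_set(id, group, m,
               list(swing_table("d1", s1), swing_table("d2", s2)), h)
}

# Random positive reciprocal matrix of order n (off the Saaty scale).
random_reciprocal <- function(n) {
  A <- matrix(1, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      A[i, j] <- exp(rnorm(1L, 0, 1))
      A[j, i] <- 1 / A[i, j]
    }
  }
  comparison_matrix(A, paste0("e", seq_len(n)))
}

# Independent dense eigen-solver oracle (LAPACK), never the implementation.
eigen_oracle <- function(m) {
  e <- eigen(unclass(m))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  list(weights = v / sum(v), lambda_max = Re(e$values[i]))
}

# Brute-force Kruskal-Wallis H with tie correction, from first principles.
kw_oracle <- function(samples) {
  x <- unlist(samples, use.names = FALSE)
  g <- rep(seq_along(samples), lengths(samples))
  r <- rank(x)
  N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / corr
}
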