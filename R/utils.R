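`%||%` <- function(x, y) if (is.null(x)) y else x

# log(sum(exp(x))) along rows of a matrix, guarded against underflow
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# Gauss-Hermite nodes/weights rescaled for a standard-normal integrand:
# sum(w * f(x)) approximates E[f(Z)], Z ~ N(0, 1).
gh_normal <- function(n = 61L) {
  gh <- pracma::gaussHermite(n)
  list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
}

round6 <- function(x) {
  if (is.numeric(x)) round(x, 6) else x
}

# fixed 6-decimal float formatting shared by all tabular writers
write_table6 <- function(df, path) {
  df[] <- lapply(df, round6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
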