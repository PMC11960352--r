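# Independent oracles and small fixture builders shared across test files.
# The oracles are deliberately naive (double loops, explicit normal
# equations) so they share no code path with the package implementation.

# Pearson correlation straight from the definition, accumulator loop
oracle_pearson <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# brute-force MSN: double loop over region pairs
oracle_msn <- function(fm) {
  n <- nrow(fm)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) out[i, j] <- oracle_pearson(fm[i, ], fm[j, ])
    }
  }
  out
}

# OLS group t via explicit normal equations (X'X)^-1 X'y
oracle_ols_t <- function(X, y, coef_idx = 2L) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  tval <- beta[coef_idx] / sqrt(s2 * xtx_inv[coef_idx, coef_idx])
  list(t = as.numeric(tval), df = df,
       p = 2 * pt(-abs(tval), df = df))
}

# pooled-variance two-sample t (case minus control)
oracle_pooled_t <- function(case, control) {
  n1 <- length(case); n2 <- length(control)
  sp2 <- ((n1 - 1) * var(case) + (n2 - 1) * var(control)) / (n1 + n2 - 2)
  (mean(case) - mean(control)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# small all-left parcellation with exactly unit centroids
toy_parcellation <- function(n = 6, seed = 1) {
  make_parcellation(n, 0, seed = seed)
}

rand_features <- function(n_regions, n_features = 5, seed = 1,
                          ids = sprintf("r%02d", seq_len(n_regions))) {
  set.seed(seed)
  matrix(rnorm(n_regions * n_features), nrow = n_regions,
         dimnames = list(ids, paste0("f", seq_len(n_features))))
}

# minimal manifest for GLM tests
toy_manifest <- function(n_case, n_control, seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             group = c(rep("case", n_case), rep("control", n_control)),
             age = round(runif(n, 18, 60)),
             sex = sample(c("female", "male"), n, replace = TRUE),
             etiv = rnorm(n, 1.5e6, 1e5),
             stringsAsFactors = FALSE)
}

write_parcellation_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
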