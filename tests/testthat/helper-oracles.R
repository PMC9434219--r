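# Independent oracles and fixture builders shared across tests.
# Oracles are deliberately naive (loops, direct formulas, a separate
# ADMM solver) so they share no code path with the implementation.

rand_geno <- function(n, p, seed = 1, maf = NULL) {
  withr::with_seed(seed, {
    if (is.null(maf)) maf <- runif(p, 0.05, 0.5)
    g <- sapply(maf, function(q) rbinom(n, 2, q))
    dimnames(g) <- list(sprintf("s%03d", seq_len(n)),
                       sprintf("m%04d", seq_len(p)))
    g
  })
}

punch_holes <- function(g, rate, seed = 1) {
  withr::with_seed(seed, {
    g[matrix(runif(length(g)) < rate, nrow(g))] <- NA
    g
  })
}

# Brute-force marker filter: per-column loops, explicit allele counts.
oracle_filter_markers <- function(g, maf_min = 0.05, callrate_min = 0.95) {
  keep <- logical(ncol(g))
  reason <- character(ncol(g))
  for (j in seq_len(ncol(g))) {
    col <- g[, j]
    obs <- col[!is.na(col)]
    cr <- length(obs) / length(col)
    if (cr < callrate_min) { reason[j] <- "callrate"; next }
    af <- if (length(obs)) sum(obs) / (2 * length(obs)) else 0
    maf <- min(af, 1 - af)
    if (maf < maf_min) { reason[j] <- "maf"; next }
    keep[j] <- TRUE
  }
  list(keep = colnames(g)[keep],
       removed = data.frame(id = colnames(g)[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

oracle_filter_samples <- function(g, max_missing = 0.10,
                                  matched_ids = rownames(g)) {
  keep <- logical(nrow(g))
  reason <- character(nrow(g))
  for (i in seq_len(nrow(g))) {
    miss <- sum(is.na(g[i, ])) / ncol(g)
    if (miss > max_missing) { reason[i] <- "missingness"; next }
    if (!rownames(g)[i] %in% matched_ids) { reason[i] <- "unmatched"; next }
    keep[i] <- TRUE
  }
  list(keep = rownames(g)[keep],
       removed = data.frame(id = rownames(g)[!keep],
                            reason = reason[!keep],
                            stringsAsFactors = FALSE))
}

# ADMM solver for min tr(S Omega) - log|Omega| + lambda ||Omega||_1
# (penalty on every entry), independent of the package's G-ISTA path.
oracle_glasso_admm <- function(S, lambda, rho = 1, iters = 500) {
  t <- ncol(S)
  Z <- diag(t); U <- matrix(0, t, t)
  soft <- function(x, g) sign(x) * pmax(abs(x) - g, 0)
  for (i in seq_len(iters)) {
    es <- eigen(rho * (Z - U) - S, symmetric = TRUE)
    theta_d <- (es$values + sqrt(es$values^2 + 4 * rho)) / (2 * rho)
    Theta <- es$vectors %*% (theta_d * t(es$vectors))
    Z_new <- soft(Theta + U, lambda / rho)
    U <- U + Theta - Z_new
    if (max(abs(Z_new - Z)) < 1e-10 && max(abs(Theta - Z_new)) < 1e-8) {
      Z <- Z_new
      break
    }
    Z <- Z_new
  }
  (Z + t(Z)) / 2
}

# Direct-formula two-sample Hotelling T2.
oracle_hotelling <- function(a, b) {
  n1 <- nrow(a); n2 <- nrow(b); p <- ncol(a)
  m1 <- colMeans(a); m2 <- colMeans(b)
  S1 <- cov(a); S2 <- cov(b)
  Sp <- ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) *
    t(m1 - m2) %*% solve(Sp) %*% (m1 - m2)
  f <- as.numeric(t2) * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  p_val <- pf(f, p, n1 + n2 - p - 1, lower.tail = FALSE)
  list(statistic = as.numeric(t2), p_value = p_val)
}

# Toy setting block straight from matrices.
toy_block <- function(X, Y, source = "chlf", setting = "S2",
                      X_test = NULL, Y_test = NULL) {
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%03d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%02d", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- sprintf("y%02d", seq_len(ncol(Y)))
  rownames(Y) <- rownames(X)
  phenogp:::new_setting_block(setting, source, X, Y, X_test, Y_test)
}
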