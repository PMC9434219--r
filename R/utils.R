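# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's RNG stream. With `seed = NULL` the expression runs
#' on the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-seed from a base seed and a stream index,
# kept within the 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1000003 + as.double(index) * 7919) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

# Column standardization used by the penalized fits. Constant columns get
# scale 1 so they survive (their coefficient is then exactly zero).
standardize_columns <- function(X, center = TRUE, scale = TRUE) {
  ctr <- if (center) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, ctr, "-")
  scl <- if (scale) {
    s <- sqrt(colMeans(Xc^2))
    s[s < 1e-12] <- 1
    s
  } else rep(1, ncol(X))
  Xs <- sweep(Xc, 2, scl, "/")
  list(X = Xs, center = ctr, scale = scl)
}

apply_standardization <- function(X, center, scale) {
  sweep(sweep(X, 2, center, "-"), 2, scale, "/")
}

as_response_matrix <- function(Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1, dimnames = list(names(Y), "y"))
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  storage.mode(Y) <- "double"
  Y
}

as_design_matrix <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  assert_that(all(is.finite(X)), "design matrix contains non-finite values")
  X
}
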