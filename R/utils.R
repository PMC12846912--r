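#' @useDynLib glottocoevo, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dgamma dnorm runif rnorm rbinom rexp rgamma rlnorm
#'   median quantile setNames kmeans cor.test pnorm qnorm plogis nlminb sd
#' @importFrom utils read.csv write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

gc_log <- function(...) {
  message(sprintf("[glottocoevo] %s", sprintf(...)))
}

#' Deterministically split a master seed into a stage seed
#'
#' Hashes an id string and a stage label together with the master seed so
#' that per-universal, per-stage analyses are reproducible and independent
#' of execution order. Result is a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param id character identifier (e.g. a universal id).
#' @param stage character stage label.
#' @return a single integer seed.
#' @export
split_seed <- function(master, id, stage = "") {
  txt <- paste0(id, "::", stage)
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(txt)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h %% 2147483562) + 1L
}

## run an expression under a local RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Repair a nearly positive-semidefinite matrix
#'
#' Clips eigenvalues below a tolerance to zero and reassembles the matrix;
#' used on covariance matrices whose numerical eigenvalues dip slightly
#' negative.
#'
#' @param m symmetric matrix.
#' @param tol eigenvalues below `-tol` trigger the repair; smaller negative
#'   values are clipped silently.
#' @return a symmetric positive-semidefinite matrix.
#' @export
nearest_psd <- function(m, tol = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    if (min(e$values) >= 0) return(m)
  }
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  dimnames(out) <- dimnames(m)
  (out + t(out)) / 2
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
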