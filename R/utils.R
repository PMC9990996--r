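## Internal numerical helpers shared across the package.

#' Two-sided normal-tail p-value
#'
#' Converts a z-score to a two-sided p-value, \eqn{p = 2\Phi(-|z|)}.
#' Computation is done in log space so that extreme z-scores do not
#' underflow to exact zero before the final exponentiation; the result is
#' floored at the smallest positive normalized double.
#'
#' @param z numeric vector of z-scores (finite).
#' @return numeric vector of p-values in (0, 1].
#' @examples
#' twoSidedP(0)         # 1
#' twoSidedP(1.959964)  # ~0.05
#' twoSidedP(40) > 0    # TRUE
#' @export
twoSidedP <- function(z) {
  stopifnot(is.numeric(z), all(is.finite(z)))
  lp <- log(2) + stats::pnorm(-abs(z), log.p = TRUE)
  p <- exp(pmin(lp, 0))
  pmax(p, .Machine$double.xmin)
}

## log(sum(exp(x))) without overflow; -Inf-safe
.logSumExp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## log(exp(a) - exp(b)) for a >= b, clamped to -Inf when the difference
## is non-positive (cancellation guard)
.logDiffExp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

## Signed log-space sum: terms are sign_i * exp(logabs_i).
## Returns c(logabs, sign) of the total; sign 0 when the total cancels.
.signedLogSum <- function(logabs, signs) {
  keep <- is.finite(logabs) | logabs > -Inf
  logabs <- logabs[keep]
  signs <- signs[keep]
  if (length(logabs) == 0L) return(c(-Inf, 0))
  m <- max(logabs)
  if (!is.finite(m)) return(c(-Inf, 0))
  s <- sum(signs * exp(logabs - m))
  if (s == 0) return(c(-Inf, 0))
  c(m + log(abs(s)), sign(s))
}

## Draw one MVN(mu, R) vector given U = chol(R) (upper triangular,
## R = t(U) %*% U). Kept separate so callers can cache the factorization.
.mvnDraw <- function(mu, cholU) {
  mu + drop(crossprod(cholU, stats::rnorm(length(mu))))
}

## Cache of Cholesky factors for AR(1) LD matrices keyed by (m, rho):
## the simulator draws thousands of regions with identical LD during
## calibration runs and the factorization dominates otherwise.
.cholCache <- new.env(parent = emptyenv())

.ar1Chol <- function(m, rho) {
  key <- paste0(m, "_", format(rho, digits = 17))
  got <- get0(key, envir = .cholCache, inherits = FALSE)
  if (!is.null(got)) return(got)
  U <- chol(.ar1Matrix(m, rho))
  assign(key, U, envir = .cholCache)
  U
}

.ar1Matrix <- function(m, rho) {
  if (rho == 0) return(diag(m))
  rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

.complementAllele <- function(a) {
  c(A = "T", C = "G", G = "C", T = "A")[a]
}

.isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

## Deterministic ordering used wherever ties in p must be broken:
## ascending p, then descending |z| (p can tie at the underflow floor
## while beta/se still ranks; beta and se are authoritative), then
## position, then variant id.
.orderByP <- function(p, pos, id, zabs = numeric(length(p))) {
  order(p, -zabs, pos, id, method = "radix")
}
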