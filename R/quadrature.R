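# Fixed-order Gauss-Legendre rules, used as the fast vectorised quadrature
# backend for the validity sweeps.  Nodes come from the Golub-Welsch
# eigenvalue construction and are cached per order.

.fcsrd_env <- new.env(parent = emptyenv())

#' Gauss-Legendre nodes and weights on [-1, 1]
#'
#' @param n rule order (number of nodes).
#' @return list with `nodes` and `weights`, exact for polynomials of
#'   degree 2n - 1.
#' @keywords internal
#' @noRd
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  cached <- .fcsrd_env[[key]]
  if (!is.null(cached)) return(cached)
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)          # Jacobi matrix off-diagonal
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  ord <- order(nodes)
  out <- list(nodes = nodes[ord], weights = weights[ord])
  .fcsrd_env[[key]] <- out
  out
}

# Integrate f (vectorised) over [a, b] with an n-point Gauss-Legendre rule.
gl_integrate <- function(f, a, b, n = 160L) {
  gl <- gauss_legendre(n)
  h <- (b - a) / 2
  x <- a + h * (gl$nodes + 1)
  h * sum(gl$weights * f(x))
}
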