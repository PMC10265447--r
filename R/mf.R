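# Classical masked matrix factorization by alternating ridge least squares.
# This is the linear special case of the ER model (one relation, identity
# activations, inner-product scoring) and serves as the linear-limit
# reference oracle in tests.

#' Masked matrix factorization oracle (alternating least squares)
#'
#' Minimizes `sum_observed (Y - U V)^2 + lambda (||U||_F^2 + ||V||_F^2)` by
#' alternating exact ridge solves for `U` (n x rank) and `V` (rank x m).
#' The objective is non-increasing across sweeps.
#'
#' @param Y Dense numeric matrix.
#' @param mask Logical matrix of observed cells (default: non-`NA` entries
#'   of `Y`).
#' @param rank Factorization rank, `1 <= rank <= min(dim(Y))`.
#' @param lambda Ridge weight `lambda >= 0`.
#' @param iters Number of alternating sweeps.
#' @param seed Seed for the factor initialization.
#' @return List with `U`, `V`, `objective` (final value) and `trace`
#'   (objective after every sweep).
#' @export
mf_oracle <- function(Y, mask = NULL, rank, lambda = 0, iters = 50, seed = 1L) {
  Y <- as.matrix(Y)
  if (is.null(mask)) mask <- !is.na(Y)
  mask <- as.matrix(mask)
  stopifnot(identical(dim(mask), dim(Y)))
  if (rank < 1 || rank > min(dim(Y))) stop("rank must be in [1, min(dim(Y))]")
  if (iters < 1) stop("iters must be >= 1")
  if (!any(mask)) stop("empty observation mask")
  n <- nrow(Y)
  m <- ncol(Y)
  U <- with_seed(seed, matrix(rnorm(n * rank, sd = 0.5), n, rank))
  V <- with_seed(seed + 1L, matrix(rnorm(rank * m, sd = 0.5), rank, m))
  ridge <- diag(lambda, rank)
  obj <- function() {
    R <- (Y - U %*% V)[mask]
    sum(R * R) + lambda * (sum(U * U) + sum(V * V))
  }
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    for (i in seq_len(n)) {
      o <- mask[i, ]
      if (!any(o)) next
      Vo <- V[, o, drop = FALSE]
      U[i, ] <- solve(tcrossprod(Vo) + ridge, Vo %*% Y[i, o])
    }
    for (j in seq_len(m)) {
      o <- mask[, j]
      if (!any(o)) next
      Uo <- U[o, , drop = FALSE]
      V[, j] <- solve(crossprod(Uo) + ridge, crossprod(Uo, Y[o, j]))
    }
    trace[it] <- obj()
  }
  list(U = U, V = V, objective = trace[iters], trace = trace)
}

#' Penalized reconstruction objective of a factor pair
#'
#' Convenience for comparing a fitted linear model against [mf_oracle()]:
#' `sum_observed (Y - U V)^2 + lambda (||U||_F^2 + ||V||_F^2)`.
#'
#' @inheritParams mf_oracle
#' @param U,V Factor matrices (`n x rank`, `rank x m`).
#' @return Scalar objective value.
#' @export
mf_objective <- function(Y, mask, U, V, lambda = 0) {
  R <- (Y - U %*% V)[mask]
  sum(R * R) + lambda * (sum(U * U) + sum(V * V))
}
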