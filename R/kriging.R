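#' Precomputed search context
#'
#' The search algorithms evaluate the two log-determinant criteria for
#' thousands of designs drawn from the same candidate set. The context
#' caches the full candidate-candidate correlation matrix, its parameter
#' derivatives, the trend basis and the rook neighbourhood in the layout the
#' compiled evaluators expect, so each design evaluation only indexes
#' submatrices.
#'
#' @param model an `ekModel`.
#' @param cands an `ekCandidates` design space.
#' @return An object of class `ekContext`.
#' @export
ekContext <- function(model, cands) {
  Cq <- correlationMatrix(cands$coords, model$kernel)
  dCq <- kernelDerivatives(cands$coords, model$kernel)
  Fq <- trendBasis(cands$coords, model$trend)
  maxdeg <- if (is.null(cands$neighbours)) 0L else
    max(0L, vapply(cands$neighbours, length, integer(1)))
  neigh <- matrix(-1L, cands$n_sites, max(maxdeg, 1L))
  if (!is.null(cands$neighbours)) {
    for (i in seq_len(cands$n_sites)) {
      nb <- cands$neighbours[[i]]
      if (length(nb)) neigh[i, seq_along(nb)] <- as.integer(nb - 1L)
    }
  }
  structure(list(model = model, cands = cands,
                 C = Cq, dC = dCq, F = Fq, neigh = neigh,
                 s = length(dCq), p = ncol(Fq)),
            class = "ekContext")
}

#' @export
print.ekContext <- function(x, ...) {
  cat("Search context:", x$cands$n_sites, "candidates,",
      x$s, "covariance parameter(s), trend rank", x$p, "\n")
  invisible(x)
}

# Universal-kriging solve for a design given by coordinates, vectorized over
# prediction sites. Returns weights, normalized variance rho2 and, when
# deriv = TRUE, the weight-derivative matrices per covariance parameter.
.ukCore <- function(model, des_coords, pred_coords, deriv = FALSE) {
  kernel <- model$kernel
  C <- correlationMatrix(des_coords, kernel)
  Ci <- chol2inv(chol(C))
  Fm <- trendBasis(des_coords, model$trend)
  p <- ncol(Fm)
  if (qr(Fm)$rank < p) stop("trend basis rank-deficient on this design")
  K <- .corrFromDist(.anisoDist(des_coords, pred_coords, kernel), kernel)
  Fp <- t(trendBasis(pred_coords, model$trend))       # p x m
  G <- crossprod(Fm, Ci %*% Fm)
  Gi <- solve(G)
  A <- Ci %*% K
  B <- Fp - crossprod(Fm, A)
  GiB <- Gi %*% B
  W <- A + Ci %*% Fm %*% GiB
  rho2 <- 1 - colSums(K * A) + colSums(B * GiB)
  out <- list(w = W, rho2 = pmax(rho2, 0), C = C, Ci = Ci, G = G, Gi = Gi)
  if (deriv) {
    dC <- kernelDerivatives(des_coords, kernel)
    dK <- .crossDerivatives(des_coords, pred_coords, kernel)
    dW <- vector("list", length(dC))
    names(dW) <- names(dC)
    for (k in seq_along(dC)) {
      P <- -Ci %*% dC[[k]] %*% Ci                     # d(C^-1)/dnu_k
      dA <- P %*% K + Ci %*% dK[[k]]
      dB <- -crossprod(Fm, dA)
      dGi <- -Gi %*% crossprod(Fm, P %*% Fm) %*% Gi
      dW[[k]] <- dA + P %*% Fm %*% GiB + Ci %*% Fm %*% (dGi %*% B + Gi %*% dB)
    }
    out$dw <- dW
  }
  out
}

#' Universal-kriging predictor weights and normalized variance
#'
#' Returns the BLUP weight vector
#' `w = C^-1 c(x) + C^-1 F (F'C^-1F)^-1 (f(x) - F'C^-1 c(x))` and the
#' normalized kriging variance
#' `rho2 = 1 - c'C^-1 c + (f - F'C^-1 c)'(F'C^-1F)^-1 (f - F'C^-1 c)`.
#' At a design site `w` is a coordinate basis vector and `rho2 = 0`
#' (interpolation); unbiasedness `w'F = f(x)'` holds for every x.
#'
#' @param x coordinate vector of the prediction site.
#' @param des an `ekDesign` (or coordinate matrix).
#' @param model an `ekModel`.
#' @return A list with elements `w` (n-vector) and `rho2` (scalar).
#' @examples
#' g <- candidateGrid(5)
#' m <- gpModel(expKernel(7))
#' d <- design(g, c(1, 5, 13, 21, 25))
#' krigingWeights(c(0.5, 0.5), d, m)
#' @export
krigingWeights <- function(x, des, model) {
  coords <- if (inherits(des, "ekDesign")) des$coords else as.matrix(des)
  sol <- .ukCore(model, coords, rbind(x))
  list(w = unname(drop(sol$w)), rho2 = unname(drop(sol$rho2)))
}

#' Simulate Gaussian-field realizations over a candidate set
#'
#' Draws `n_real` independent realizations of `f(x)'beta + eps(x)` with
#' `cov(eps) = sigma2 * C` over all candidate sites, via a Cholesky
#' factorization of the model covariance. Fully reproducible given `seed`.
#'
#' @param cands an `ekCandidates`.
#' @param model an `ekModel`.
#' @param n_real number of realizations.
#' @param seed integer RNG seed.
#' @param beta trend coefficient vector (default all zero).
#' @return An `n_real` x Q matrix, one realization per row.
#' @export
simulateField <- function(cands, model, n_real, seed, beta = NULL) {
  Cq <- correlationMatrix(cands$coords, model$kernel)
  L <- tryCatch(chol(model$sigma2 * Cq),
                error = function(e) stop("model covariance not positive definite: ",
                                         conditionMessage(e)))
  Fq <- trendBasis(cands$coords, model$trend)
  if (is.null(beta)) beta <- rep(0, ncol(Fq))
  mu <- drop(Fq %*% beta)
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_real * cands$n_sites), n_real, cands$n_sites)
  sweep(Z %*% L, 2, mu, "+")
}
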