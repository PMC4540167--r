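#' Fisher-information bundle of a design
#'
#' For the Gaussian linear model with trend basis F and correlation C(nu),
#' the information carried by a design splits into a trend block
#' `M_beta = (1/sigma2) F'C^-1 F` and a covariance-parameter block with
#' entries `M_nu[k,l] = tr(C^-1 dC/dnu_k C^-1 dC/dnu_l) / 2`. The asymptotic
#' covariance of the covariance-parameter estimator is
#' `V_nu = (M_nu - t t'/(2n))^-1` with `t_k = tr(C^-1 dC/dnu_k)` when
#' `sigma2` is estimated jointly, or `M_nu^-1` when it is known; either way
#' `V_nu` does not depend on `sigma2`.
#'
#' @param des an `ekDesign` (or coordinate matrix).
#' @param model an `ekModel`; the `sigma2_known` flag selects the `V_nu` form.
#' @return An object of class `ekInfo` with elements `M_beta`, `M_nu`, `t`,
#'   `V_nu`, `log_det_beta`, `log_det_nu`, `n` and `sigma2_known`.
#' @examples
#' g <- candidateGrid(5)
#' m <- gpModel(expKernel(7))
#' informationBundle(design(g, c(1, 7, 13, 19, 25)), m)
#' @export
informationBundle <- function(des, model) {
  coords <- if (inherits(des, "ekDesign")) des$coords else as.matrix(des)
  n <- nrow(coords)
  C <- correlationMatrix(coords, model$kernel)
  Ci <- chol2inv(chol(C))
  Fm <- trendBasis(coords, model$trend)
  M_beta <- crossprod(Fm, Ci %*% Fm) / model$sigma2
  dC <- kernelDerivatives(coords, model$kernel)
  s <- length(dC)
  A <- lapply(dC, function(D) Ci %*% D)
  M_nu <- matrix(0, s, s, dimnames = list(names(dC), names(dC)))
  for (k in seq_len(s)) for (l in k:s) {
    M_nu[k, l] <- M_nu[l, k] <- 0.5 * sum(A[[k]] * t(A[[l]]))
  }
  tvec <- vapply(A, function(M) sum(diag(M)), numeric(1))
  S <- if (model$sigma2_known) M_nu else M_nu - tcrossprod(tvec) / (2 * n)
  V_nu <- tryCatch(solve(S), error = function(e)
    stop("covariance-parameter information is singular for this design ",
         "(n may be too small to identify the correlation parameters)"))
  ldb <- determinant(M_beta, logarithm = TRUE)
  ldn <- determinant(M_nu, logarithm = TRUE)
  structure(list(M_beta = M_beta, M_nu = M_nu, t = tvec, V_nu = V_nu,
                 log_det_beta = if (ldb$sign > 0) as.numeric(ldb$modulus) else -Inf,
                 log_det_nu = if (ldn$sign > 0) as.numeric(ldn$modulus) else -Inf,
                 n = n, sigma2_known = model$sigma2_known),
            class = "ekInfo")
}

#' @export
print.ekInfo <- function(x, ...) {
  cat("Information bundle (n =", x$n, "):\n")
  cat("  log det M_beta =", x$log_det_beta,
      "  log det M_nu =", x$log_det_nu, "\n")
  cat("  V_nu (sigma2", if (x$sigma2_known) "known" else "estimated", "):\n")
  print(x$V_nu)
  invisible(x)
}

#' Export an information bundle to JSON
#'
#' Matrices are written row-major together with the log-determinants and the
#' `sigma2_known` flag, as an audit trail of criterion evaluations.
#'
#' @param info an `ekInfo` object.
#' @param path output path.
#' @export
writeBundleJson <- function(info, path) {
  jsonlite::write_json(list(
    n = info$n,
    sigma2_known = info$sigma2_known,
    M_beta = as.vector(t(info$M_beta)),
    M_nu = as.vector(t(info$M_nu)),
    t = as.vector(info$t),
    V_nu = as.vector(t(info$V_nu)),
    log_det_beta = info$log_det_beta,
    log_det_nu = info$log_det_nu), path, auto_unbox = TRUE, digits = NA)
}

#' Compound D-optimality criterion
#'
#' The convex combination
#' `J_alpha = alpha * log det M_beta + (1 - alpha) * log det M_nu`,
#' to be maximized. Designs maximizing `J_alpha` for some weight lie on the
#' upper convex hull of the attainable set in the two-criterion plane, which
#' is why a grid of `alpha` values samples the Pareto front. Values of
#' `alpha` below 0.5 overweight the covariance block and are rarely useful.
#' Returns `-Inf` for designs with singular information.
#'
#' @param des an `ekDesign`.
#' @param model an `ekModel`.
#' @param alpha weight in [0, 1].
#' @param normalize if `TRUE`, scale the two log-determinants by 1/p and 1/s.
#' @return The criterion value (scalar).
#' @export
jAlpha <- function(des, model, alpha, normalize = FALSE) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  coords <- if (inherits(des, "ekDesign")) des$coords else as.matrix(des)
  ld <- tryCatch({
    C <- correlationMatrix(coords, model$kernel)
    Ci <- chol2inv(chol(C))
    Fm <- trendBasis(coords, model$trend)
    M_beta <- crossprod(Fm, Ci %*% Fm) / model$sigma2
    dC <- kernelDerivatives(coords, model$kernel)
    A <- lapply(dC, function(D) Ci %*% D)
    s <- length(A)
    M_nu <- matrix(0, s, s)
    for (k in seq_len(s)) for (l in k:s)
      M_nu[k, l] <- M_nu[l, k] <- 0.5 * sum(A[[k]] * t(A[[l]]))
    db <- determinant(M_beta, logarithm = TRUE)
    dn <- determinant(M_nu, logarithm = TRUE)
    c(if (db$sign > 0) as.numeric(db$modulus) else -Inf,
      if (dn$sign > 0) as.numeric(dn$modulus) else -Inf,
      ncol(Fm), s)
  }, error = function(e) c(-Inf, -Inf, 1, 1))   # singular -> -Inf sentinel
  ldb <- ld[1]; ldn <- ld[2]
  if (normalize) { ldb <- ldb / ld[3]; ldn <- ldn / ld[4] }
  if (alpha == 1) return(ldb)       # avoid 0 * -Inf
  if (alpha == 0) return(ldn)
  if (!is.finite(ldb) || !is.finite(ldn)) return(-Inf)
  alpha * ldb + (1 - alpha) * ldn
}
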