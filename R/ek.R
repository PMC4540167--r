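#' Derivatives of the kriging weights in the covariance parameters
#'
#' Differentiates the universal-kriging weight vector `w(x; nu)` implicitly
#' through `C` and `c(x)`, using the analytic kernel derivatives where
#' available. The differentiated unbiasedness constraint `(dw/dnu_k)'F = 0`
#' holds for every parameter, and all derivatives vanish when `x` is a
#' design site (there `w` is constant in `nu`).
#'
#' @inheritParams krigingWeights
#' @return An n x s matrix, one column per covariance parameter.
#' @export
weightDerivatives <- function(x, des, model) {
  coords <- if (inherits(des, "ekDesign")) des$coords else as.matrix(des)
  sol <- .ukCore(model, coords, rbind(x), deriv = TRUE)
  out <- vapply(sol$dw, drop, numeric(nrow(coords)))
  matrix(out, nrow = nrow(coords), dimnames = list(NULL, names(sol$dw)))
}

# Corrected-variance profile over a set of prediction sites.
.ekProfile <- function(model, des_coords, pred_coords) {
  sol <- .ukCore(model, des_coords, pred_coords, deriv = TRUE)
  V <- .vnu(model, des_coords)
  s <- length(sol$dw)
  corr <- 0
  for (k in seq_len(s)) {
    Cdwk <- sol$C %*% sol$dw[[k]]
    for (l in seq_len(s)) corr <- corr + V[k, l] * colSums(sol$dw[[l]] * Cdwk)
  }
  model$sigma2 * (sol$rho2 + pmax(corr, 0))
}

# V_nu only (avoids the full bundle on the hot path).
.vnu <- function(model, coords) {
  n <- nrow(coords)
  C <- correlationMatrix(coords, model$kernel)
  Ci <- chol2inv(chol(C))
  dC <- kernelDerivatives(coords, model$kernel)
  s <- length(dC)
  A <- lapply(dC, function(D) Ci %*% D)
  M <- matrix(0, s, s)
  for (k in seq_len(s)) for (l in k:s)
    M[k, l] <- M[l, k] <- 0.5 * sum(A[[k]] * t(A[[l]]))
  if (!model$sigma2_known) {
    tvec <- vapply(A, function(X) sum(diag(X)), numeric(1))
    M <- M - tcrossprod(tvec) / (2 * n)
  }
  solve(M)
}

#' Corrected (empirical-kriging) prediction variance at a site
#'
#' The kriging variance plus the first-order correction for plug-in
#' estimation of the covariance parameters:
#' `sigma2 * (rho2(x) + tr(V_nu W(x)))` with
#' `W[k,l](x) = (dw/dnu_k)' C (dw/dnu_l)`. The correction is non-negative,
#' so the corrected variance dominates the classical one everywhere, and
#' both vanish at design sites.
#'
#' @inheritParams krigingWeights
#' @return The corrected prediction variance (scalar).
#' @export
ekVariance <- function(x, des, model) {
  coords <- if (inherits(des, "ekDesign")) des$coords else as.matrix(des)
  drop(.ekProfile(model, coords, rbind(x)))
}

#' Empirical-kriging design criterion
#'
#' Maximum of the corrected prediction variance over the prediction set
#' (by default the whole candidate set). Ties in the maximum are broken by
#' the first site in candidate-file order, making the evaluation
#' bit-reproducible.
#'
#' @param des an `ekDesign` (or a coordinate matrix for designs that are not
#'   restricted to the candidate set).
#' @param model an `ekModel`.
#' @param cands the `ekCandidates` space whose sites are predicted.
#' @param prediction optional `ekCandidates` overriding the prediction set.
#' @param per_site if `TRUE`, also return the per-site decomposition.
#' @return An object of class `ekEval`: list with `value`, `argmax_site`
#'   (index into the prediction set), `argmax_coords` and optionally
#'   `per_site` (data frame with rho2, correction and total per site).
#' @examples
#' g <- candidateGrid(7)
#' m <- gpModel(expKernel(7))
#' d <- design(g, c(1, 4, 25, 46, 49))
#' mek(d, m, g)$value
#' @export
mek <- function(des, model, cands, prediction = NULL, per_site = FALSE) {
  coords <- if (inherits(des, "ekDesign")) des$coords else as.matrix(des)
  pred <- if (is.null(prediction)) cands else prediction
  ek <- .ekProfile(model, coords, pred$coords)
  arg <- which.max(ek)            # which.max returns the first maximum
  out <- list(value = ek[arg], argmax_site = arg,
              argmax_coords = pred$coords[arg, ])
  if (per_site) {
    sol <- .ukCore(model, coords, pred$coords)
    out$per_site <- data.frame(x = pred$coords[, 1], y = pred$coords[, 2],
                               rho2 = sol$rho2,
                               correction = ek / model$sigma2 - sol$rho2,
                               total = ek)
  }
  class(out) <- "ekEval"
  out
}

#' @export
print.ekEval <- function(x, ...) {
  cat("M_EK =", x$value, "at site", x$argmax_site,
      "(", paste(round(x$argmax_coords, 4), collapse = ", "), ")\n")
  invisible(x)
}

#' Relative EK efficiency of two designs
#'
#' `mek(des_b) / mek(des_a)`: at most 1 when `des_b` is the reference
#' optimum, and `ekEfficiency(a, b) * ekEfficiency(b, a) = 1`.
#'
#' @param des_a,des_b `ekDesign` objects (or coordinate matrices).
#' @inheritParams mek
#' @return The efficiency ratio (scalar).
#' @export
ekEfficiency <- function(des_a, des_b, model, cands, prediction = NULL) {
  mek(des_b, model, cands, prediction)$value /
    mek(des_a, model, cands, prediction)$value
}
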