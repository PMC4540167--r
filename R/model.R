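#' Correlation kernels
#'
#' Two stationary correlation families are supported. The exponential kernel
#' is `c(h) = exp(-nu * h)` with inverse-range `nu > 0`. The Matern kernel
#' uses the geoR parametrization
#' `c(h) = (2^(kappa-1) Gamma(kappa))^-1 (h/phi)^kappa K_kappa(h/phi)` with
#' range `phi > 0` and smoothness `kappa > 0`; for `kappa = 5/2` the closed
#' form `(1 + u + u^2/3) exp(-u)`, `u = h/phi`, is used. Geometric anisotropy
#' rotates the plane by `angle` and stretches the second rotated coordinate
#' by `ratio >= 1` before distances are taken.
#'
#' @param nu inverse range of the exponential kernel (positive).
#' @param phi range of the Matern kernel (positive).
#' @param kappa smoothness of the Matern kernel (positive).
#' @param angle,ratio geometric anisotropy: rotation angle in radians and
#'   stretch ratio (identity by default).
#' @return A list of class `ekKernel` describing the kernel.
#' @examples
#' k <- expKernel(7)
#' kernelCorrelation(c(0, 0), c(1, 0), k)   # exp(-7)
#' @export
expKernel <- function(nu, angle = 0, ratio = 1) {
  if (nu <= 0) stop("exponential kernel needs nu > 0")
  if (ratio < 1) stop("anisotropy ratio must be >= 1")
  structure(list(family = "exponential", params = c(nu = nu),
                 angle = angle, ratio = ratio),
            class = "ekKernel")
}

#' @rdname expKernel
#' @export
maternKernel <- function(phi, kappa = 5 / 2, angle = 0, ratio = 1) {
  if (phi <= 0 || kappa <= 0) stop("Matern kernel needs phi > 0 and kappa > 0")
  if (ratio < 1) stop("anisotropy ratio must be >= 1")
  structure(list(family = "matern", params = c(phi = phi, kappa = kappa),
                 angle = angle, ratio = ratio),
            class = "ekKernel")
}

#' @export
print.ekKernel <- function(x, ...) {
  cat(x$family, "kernel:", paste(names(x$params), signif(x$params, 6),
                                 sep = " = ", collapse = ", "), "\n")
  if (x$angle != 0 || x$ratio != 1)
    cat("  anisotropy: angle", x$angle, "ratio", x$ratio, "\n")
  invisible(x)
}

#' Anisotropy coordinate transform
#'
#' Rotates 2-d coordinates by `angle` and multiplies the second rotated
#' coordinate by `ratio` (geoR `coords.aniso` convention); isotropic
#' correlation applied to transformed coordinates yields geometric
#' anisotropy. Identity when `angle = 0, ratio = 1`.
#'
#' @param x numeric 2-vector or matrix with 2 columns.
#' @inheritParams expKernel
#' @return Transformed coordinates, same shape as `x`.
#' @export
anisotropyTransform <- function(x, angle, ratio) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, 1) else as.matrix(x)
  if (ncol(xm) != 2) stop("anisotropy transform is only defined for d = 2")
  R <- matrix(c(cos(angle), -sin(angle), sin(angle), cos(angle)), 2, 2,
              byrow = TRUE)
  out <- xm %*% t(R)
  out[, 2] <- out[, 2] * ratio
  if (vec) drop(out) else out
}

.anisoDist <- function(a, b, kernel) {
  if (kernel$angle != 0 || kernel$ratio != 1) {
    a <- anisotropyTransform(a, kernel$angle, kernel$ratio)
    b <- anisotropyTransform(b, kernel$angle, kernel$ratio)
  }
  a <- if (is.null(dim(a))) matrix(a, 1) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, 1) else as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

.corrFromDist <- function(h, kernel) {
  switch(kernel$family,
    exponential = exp(-kernel$params[["nu"]] * h),
    matern = {
      phi <- kernel$params[["phi"]]; kappa <- kernel$params[["kappa"]]
      u <- h / phi
      if (isTRUE(all.equal(kappa, 2.5))) {
        (1 + u + u^2 / 3) * exp(-u)
      } else {
        out <- ifelse(u == 0, 1,
                      u^kappa * besselK(u, kappa) / (2^(kappa - 1) * gamma(kappa)))
        # besselK underflows for large u; the correlation is then 0
        out[!is.finite(out)] <- 0
        out
      }
    },
    stop("unsupported kernel family"))
}

#' Kernel correlation between two sites
#'
#' @param x,y coordinate vectors of the two sites (same dimension).
#' @param kernel an `ekKernel`.
#' @return The correlation, a value in (0, 1].
#' @export
kernelCorrelation <- function(x, y, kernel) {
  if (length(x) != length(y)) stop("x and y must have the same dimension")
  drop(.corrFromDist(.anisoDist(rbind(x), rbind(y), kernel), kernel))
}

#' Correlation matrix of a set of sites
#'
#' Symmetric with unit diagonal; positive definite for the supported kernels
#' on distinct sites. If the condition estimate exceeds 1e12 a small diagonal
#' jitter (1e-10 times the mean diagonal) is added and a warning raised.
#'
#' @param coords matrix of site coordinates (or an `ekDesign`).
#' @param kernel an `ekKernel`.
#' @param jitter logical; add jitter when near-singular (default `TRUE`).
#' @return The n x n correlation matrix.
#' @export
correlationMatrix <- function(coords, kernel, jitter = TRUE) {
  if (inherits(coords, "ekDesign")) coords <- coords$coords
  coords <- as.matrix(coords)
  if (anyDuplicated(coords)) stop("duplicate sites give a singular correlation matrix")
  C <- .corrFromDist(.anisoDist(coords, coords, kernel), kernel)
  diag(C) <- 1
  if (jitter) {
    rc <- tryCatch(rcond(C), error = function(e) 0)
    if (rc < 1e-12) {
      warning("correlation matrix near-singular (rcond ", signif(rc, 3),
              "); adding diagonal jitter")
      diag(C) <- diag(C) + 1e-10 * mean(diag(C))
    }
  }
  C
}

.FD_REL_STEP <- 1e-5
.FD_ABS_FLOOR <- 1e-8

#' Derivatives of the correlation matrix in the covariance parameters
#'
#' Analytic for the exponential inverse-range (`dC/dnu = -h * C`) and for the
#' Matern 5/2 range; central finite differences (relative step 1e-5, floor
#' 1e-8) for any other parameter. Diagonals are exactly zero since
#' `c(x, x) = 1` for all parameter values.
#'
#' @inheritParams correlationMatrix
#' @return A named list of n x n matrices, one per covariance parameter.
#' @export
kernelDerivatives <- function(coords, kernel) {
  if (inherits(coords, "ekDesign")) coords <- coords$coords
  coords <- as.matrix(coords)
  h <- .anisoDist(coords, coords, kernel)
  C <- .corrFromDist(h, kernel); diag(C) <- 1
  out <- list()
  if (kernel$family == "exponential") {
    out$nu <- -h * C
  } else if (kernel$family == "matern" &&
             isTRUE(all.equal(kernel$params[["kappa"]], 2.5))) {
    phi <- kernel$params[["phi"]]
    u <- h / phi
    # d/dphi [(1+u+u^2/3) e^-u] with du/dphi = -u/phi
    out$phi <- (u / phi) * (u / 3) * (1 + u) * exp(-u)
    out$kappa <- NULL
  } else {
    for (pn in names(kernel$params)) {
      v <- kernel$params[[pn]]
      st <- max(.FD_REL_STEP * abs(v), .FD_ABS_FLOOR)
      kp <- kernel; kp$params[[pn]] <- v + st
      km <- kernel; km$params[[pn]] <- v - st
      if (km$params[[pn]] <= 0) { km$params[[pn]] <- v; st <- st }  # one-sided floor
      d <- (.corrFromDist(h, kp) - .corrFromDist(h, km)) /
           (kp$params[[pn]] - km$params[[pn]])
      diag(d) <- 0
      out[[pn]] <- d
    }
  }
  for (k in seq_along(out)) diag(out[[k]]) <- 0
  out
}

# Cross-correlation derivative matrices between two site sets (no unit
# diagonal to zero out); same analytic/FD split as kernelDerivatives.
.crossDerivatives <- function(a, b, kernel) {
  h <- .anisoDist(a, b, kernel)
  if (kernel$family == "exponential") {
    list(nu = -h * .corrFromDist(h, kernel))
  } else if (kernel$family == "matern" &&
             isTRUE(all.equal(kernel$params[["kappa"]], 2.5))) {
    phi <- kernel$params[["phi"]]
    u <- h / phi
    list(phi = (u / phi) * (u / 3) * (1 + u) * exp(-u))
  } else {
    out <- list()
    for (pn in names(kernel$params)) {
      v <- kernel$params[[pn]]
      st <- max(.FD_REL_STEP * abs(v), .FD_ABS_FLOOR)
      kp <- kernel; kp$params[[pn]] <- v + st
      km <- kernel; km$params[[pn]] <- v - st
      out[[pn]] <- (.corrFromDist(h, kp) - .corrFromDist(h, km)) / (2 * st)
    }
    out
  }
}

#' Gaussian-process model specification
#'
#' Couples a trend basis, a correlation kernel and a process variance. The
#' trend is either `"constant"` (p = 1) or `"linear"` (1, x, y; p = 3).
#' `sigma2_known` selects the form of the covariance-parameter covariance
#' `V_nu`: when `FALSE` (default) the Schur-complement form
#' `(M_nu - t t' / (2n))^-1` accounting for joint estimation of `sigma2`,
#' when `TRUE` simply `M_nu^-1`.
#'
#' @param kernel an `ekKernel`.
#' @param trend `"constant"` or `"linear"`.
#' @param sigma2 process variance (positive).
#' @param sigma2_known logical flag, see Details.
#' @return An object of class `ekModel`.
#' @examples
#' m <- gpModel(expKernel(7), trend = "constant", sigma2 = 1)
#' @export
gpModel <- function(kernel, trend = c("constant", "linear"), sigma2 = 1,
                    sigma2_known = FALSE) {
  trend <- match.arg(trend)
  if (sigma2 <= 0) stop("sigma2 must be positive")
  stopifnot(inherits(kernel, "ekKernel"))
  structure(list(kernel = kernel, trend = trend, sigma2 = sigma2,
                 sigma2_known = isTRUE(sigma2_known)),
            class = "ekModel")
}

#' @export
print.ekModel <- function(x, ...) {
  cat("Gaussian-process model: trend =", x$trend,
      " sigma2 =", x$sigma2,
      if (x$sigma2_known) "(known)" else "(estimated)", "\n  ")
  print(x$kernel)
  invisible(x)
}

#' Trend basis evaluated at sites
#'
#' @param coords matrix of site coordinates.
#' @param trend `"constant"` or `"linear"`.
#' @return The n x p basis matrix F with rows f(x_i)'.
#' @export
trendBasis <- function(coords, trend) {
  coords <- as.matrix(coords)
  switch(trend,
    constant = matrix(1, nrow(coords), 1),
    linear = cbind(1, coords),
    stop("unsupported trend"))
}

#' Read a model specification from YAML or JSON
#'
#' The file must contain fields `family` (`exponential` or `matern`),
#' the kernel parameters (`nu`, or `phi` and `kappa`), optional `angle`,
#' `ratio`, plus `trend`, `sigma2` and optional `sigma2_known`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return An `ekModel`.
#' @export
readModelSpec <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  kern <- switch(spec$family,
    exponential = expKernel(spec$nu,
                            angle = spec$angle %||% 0, ratio = spec$ratio %||% 1),
    matern = maternKernel(spec$phi, kappa = spec$kappa %||% 2.5,
                          angle = spec$angle %||% 0, ratio = spec$ratio %||% 1),
    stop("unsupported kernel family in model spec"))
  gpModel(kern, trend = spec$trend %||% "constant",
          sigma2 = spec$sigma2 %||% 1,
          sigma2_known = isTRUE(spec$sigma2_known))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
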