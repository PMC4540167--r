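#' Numerical tie tolerance for criterion comparisons
#'
#' Criterion values that differ by less than this tolerance are treated as
#' equal by the dominance filter and the convex hull. Exact duplicates arise
#' whenever a design configuration has a nontrivial symmetry group (all its
#' images share both log-determinants), and floating-point evaluation breaks
#' such ties inconsistently at the last bits; comparisons are therefore made
#' modulo the customary numerical tolerance `sqrt(.Machine$double.eps)`.
#' @keywords internal
.CRIT_TOL <- sqrt(.Machine$double.eps)

#' Non-dominated (Pareto) filter in the two-criterion plane
#'
#' Both coordinates are maximized. A point is dominated when some other
#' point is at least as good in both coordinates and strictly better in one,
#' with comparisons made modulo the numerical tie tolerance; exact ties in
#' both coordinates are mutually non-dominating and all retained (duplicate
#' criterion pairs are common, see [.CRIT_TOL]).
#'
#' @param points data frame with columns `c_beta`, `c_nu` and optionally
#'   `design_id` (defaults to the row number).
#' @param tol tie tolerance (default [.CRIT_TOL]).
#' @return An object of class `ekFront`: the non-dominated subset of
#'   `points` with a logical column `on_hull` initialized to `NA` (set by
#'   [upperConvexHull()]).
#' @examples
#' pts <- data.frame(c_beta = c(0, 1, 2), c_nu = c(2, 1, 0))
#' nondominatedFilter(pts)        # all three are non-dominated
#' @export
nondominatedFilter <- function(points, tol = .CRIT_TOL) {
  points <- as.data.frame(points)
  if (nrow(points) == 0) stop("empty point set")
  if (is.null(points$design_id)) points$design_id <- seq_len(nrow(points))
  keep <- .nondominatedKeep(points$c_beta, points$c_nu, tol)
  front <- points[keep, , drop = FALSE]
  front$on_hull <- NA
  rownames(front) <- NULL
  class(front) <- c("ekFront", "data.frame")
  front
}

# A point p is dominated iff either
#   (A) some q with c_beta_q >= c_beta_p - tol has c_nu_q > c_nu_p + tol, or
#   (B) some q with c_beta_q >  c_beta_p + tol has c_nu_q >= c_nu_p - tol.
# Both are suffix-maximum queries on c_nu after sorting by c_beta, so the
# filter runs in O(N log N); it also supports incremental insertion simply by
# re-filtering the retained set plus the new point.
.nondominatedKeep <- function(cb, cn, tol = .CRIT_TOL) {
  N <- length(cb)
  o <- order(cb)
  cbs <- cb[o]; cns <- cn[o]
  sufmax <- c(rev(cummax(rev(cns))), -Inf)  # sufmax[i] = max c_nu over cbs[i..N]
  a <- findInterval(cbs - tol, cbs, left.open = TRUE) + 1L  # first cbs >= cbs_p - tol
  b <- findInterval(cbs + tol, cbs) + 1L                    # first cbs >  cbs_p + tol
  domA <- sufmax[pmin(a, N + 1L)] > cns + tol
  domB <- sufmax[pmin(b, N + 1L)] >= cns - tol
  keep <- logical(N)
  keep[o] <- !(domA | domB)
  keep
}

#' Upper convex hull of a Pareto front
#'
#' Flags the points of a non-dominated front that lie on the upper-right
#' convex hull — exactly those attainable by maximizing some convex
#' combination of the two criteria. Both coordinate-wise maxima are always
#' included. Collinear interior points are excluded by default (strict
#' hull); duplicates of a hull vertex count once.
#'
#' @param front an `ekFront` from [nondominatedFilter()].
#' @param include_collinear if `TRUE`, keep points lying on hull edges.
#' @param tol tie tolerance for the turn test.
#' @return The same front with `on_hull` filled in.
#' @export
upperConvexHull <- function(front, include_collinear = FALSE, tol = .CRIT_TOL) {
  stopifnot(inherits(front, "ekFront"))
  hull <- .hullIndices(front$c_beta, front$c_nu, front$design_id,
                       include_collinear = include_collinear, tol = tol)
  front$on_hull <- seq_len(nrow(front)) %in% hull
  front
}

# Monotone-chain upper hull on points sorted by (c_beta, c_nu, design_id).
# The turn test is exact (no tolerance): points tied in criterion space to a
# hull vertex are then retained alongside it, mirroring the dominance
# filter's keep-all-ties rule.
.hullIndices <- function(cb, cn, id = seq_along(cb),
                         include_collinear = FALSE, tol = .CRIT_TOL) {
  o <- order(cb, cn, id)
  cbs <- cb[o]; cns <- cn[o]
  st <- integer(0)
  cross <- function(a, b, c)
    (cbs[b] - cbs[a]) * (cns[c] - cns[a]) - (cns[b] - cns[a]) * (cbs[c] - cbs[a])
  for (i in seq_along(cbs)) {
    while (length(st) >= 2L) {
      cr <- cross(st[length(st) - 1L], st[length(st)], i)
      pop <- if (include_collinear) cr > 0 else cr >= 0
      if (!pop) break
      st <- st[-length(st)]
    }
    st <- c(st, i)
  }
  o[st]
}

#' @export
print.ekFront <- function(x, ...) {
  cat("Pareto front:", nrow(x), "non-dominated point(s)")
  if (!all(is.na(x$on_hull))) cat(";", sum(x$on_hull), "on the convex hull")
  cat("\n")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Write a Pareto front to CSV
#'
#' @param front an `ekFront`.
#' @param path output path; columns `c_beta`, `c_nu`, `on_hull`, `design_id`.
#' @export
writeFront <- function(front, path) {
  utils::write.csv(front[, c("c_beta", "c_nu", "on_hull", "design_id")],
                   path, row.names = FALSE)
}
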