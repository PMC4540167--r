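# Shared fixtures, built once per test run.
# The reference configuration: constant trend, unit process variance,
# exponential correlation with inverse range 7, a 25 x 25 candidate grid on
# the unit square, and the 7-point maximin/minimax Latin hypercube start.
.fx <- new.env()

fxModel <- function(...) gpModel(expKernel(7), ...)

fxGrid <- function() {
  if (is.null(.fx$grid)) .fx$grid <- candidateGrid(25)
  .fx$grid
}

fxLh <- function() {
  if (is.null(.fx$lh)) .fx$lh <- maximinLh(7, cands = fxGrid())
  .fx$lh
}

fxCtx <- function() {
  if (is.null(.fx$ctx)) .fx$ctx <- ekContext(fxModel(), fxGrid())
  .fx$ctx
}

fxSmallGrid <- function(m = 6) candidateGrid(m)

randomDesign <- function(cands, n, seed) {
  set.seed(seed)
  design(cands, sample.int(cands$n_sites, n), provenance = "random")
}

# Independent double-loop dominance oracle (maximization, weak dominance
# with one strict inequality, comparisons modulo tol).
bruteForceNondominated <- function(cb, cn, tol = sqrt(.Machine$double.eps)) {
  keep <- logical(length(cb))
  for (p in seq_along(cb)) {
    dom <- (cb >= cb[p] - tol) & (cn >= cn[p] - tol) &
      ((cb > cb[p] + tol) | (cn > cn[p] + tol))
    keep[p] <- !any(dom)
  }
  keep
}

# All n-subsets of 1..Q as rows (small instances only).
allDesigns <- function(Q, n) t(utils::combn(Q, n))
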