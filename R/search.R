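#' Criterion points of a set of designs
#'
#' Computes the pair (log det M_beta, log det M_nu) for each design, the
#' coordinates in which Pareto filtering and the compound criterion operate.
#'
#' @param designs list of `ekDesign` objects, or an integer matrix with one
#'   design's candidate indices per row.
#' @param model an `ekModel`.
#' @param cands the `ekCandidates` the indices refer to.
#' @param ctx optional precomputed [ekContext()].
#' @return Data frame with columns `c_beta`, `c_nu`, `design_id`.
#' @export
criterionPoints <- function(designs, model, cands, ctx = NULL) {
  if (is.null(ctx)) ctx <- ekContext(model, cands)
  M <- if (is.matrix(designs)) designs else
    do.call(rbind, lapply(designs, function(d) d$idx))
  out <- critPairBatchCpp(M - 1L, ctx$C, ctx$dC, ctx$F, model$sigma2)
  data.frame(c_beta = unname(out[, 1]), c_nu = unname(out[, 2]),
             design_id = seq_len(nrow(M)))
}

#' Simulated-annealing configuration
#'
#' @param T0 initial temperature (> 0).
#' @param r geometric cooling factor in (0, 1).
#' @param Nmax iteration cap (>= 1).
#' @param seed integer RNG seed.
#' @return A list of class `saConfig`.
#' @export
saConfig <- function(T0 = 0.6, r = 0.93, Nmax = 5000, seed = 1) {
  if (T0 <= 0 || r <= 0 || r >= 1 || Nmax < 1) stop("invalid SA configuration")
  structure(list(T0 = T0, r = r, Nmax = as.integer(Nmax),
                 seed = as.integer(seed)), class = "saConfig")
}

#' Compound-criterion objective bound to a search context
#'
#' Packages `J_alpha` evaluation over a fixed model and candidate set so the
#' search algorithms can use the compiled evaluator. The returned object is
#' also callable as an ordinary objective on `ekDesign` objects.
#'
#' @inheritParams jAlpha
#' @param cands the `ekCandidates` design space.
#' @param ctx optional precomputed [ekContext()].
#' @return A function of class `ekJalphaObjective` mapping a design (or an
#'   index vector) to the criterion value.
#' @export
jAlphaObjective <- function(model, cands, alpha, ctx = NULL) {
  if (is.null(ctx)) ctx <- ekContext(model, cands)
  f <- function(des) {
    idx <- if (inherits(des, "ekDesign")) des$idx else as.integer(des)
    pr <- critPairCpp(idx - 1L, ctx$C, ctx$dC, ctx$F, model$sigma2)
    if (alpha >= 1) return(pr[[1]])
    if (alpha <= 0) return(pr[[2]])
    if (!all(is.finite(pr))) return(-Inf)
    alpha * pr[[1]] + (1 - alpha) * pr[[2]]
  }
  attr(f, "ctx") <- ctx
  attr(f, "alpha") <- alpha
  class(f) <- c("ekJalphaObjective", "function")
  f
}

#' Rook-clique local search
#'
#' Scans the design sites in order, tentatively replacing each by each of
#' its rook (N/S/W/E) neighbours not already in the design, keeping any
#' strict improvement of the objective immediately, and repeats until a full
#' pass yields no improvement. The objective never decreases, and the search
#' terminates because strictly increasing moves over a finite design space
#' cannot cycle.
#'
#' @param des starting `ekDesign`.
#' @param objective function mapping a design to the (maximized) criterion;
#'   an [jAlphaObjective()] dispatches to the compiled evaluator.
#' @param cands `ekCandidates` with a neighbourhood structure.
#' @return The locally optimal `ekDesign`.
#' @export
localOptimize <- function(des, objective, cands) {
  if (is.null(cands$neighbours)) stop("candidate set has no neighbourhood structure")
  if (inherits(objective, "ekJalphaObjective")) {
    ctx <- attr(objective, "ctx")
    out <- localOptCpp(des$idx - 1L, ctx$C, ctx$dC, ctx$F,
                       ctx$model$sigma2, ctx$neigh, attr(objective, "alpha"))
    return(design(cands, out$idx + 1L, provenance = "local_opt"))
  }
  idx <- des$idx
  J <- objective(design(cands, idx, "local_opt"))
  repeat {
    improved <- FALSE
    for (i in seq_along(idx)) {
      for (y in cands$neighbours[[idx[i]]]) {
        if (y %in% idx) next
        trial <- idx; trial[i] <- y
        Jt <- objective(design(cands, trial, "local_opt"))
        if (Jt > J) { idx <- trial; J <- Jt; improved <- TRUE; break }
      }
    }
    if (!improved) break
  }
  design(cands, idx, provenance = "local_opt")
}

#' Simulated annealing over a design criterion
#'
#' Maximizes the objective by the scheme: uniform random initial design (or
#' a supplied one, typically space-filling); proposals replacing two random
#' design points by two uniform draws from the remaining candidates; rook
#' local search on each proposal; Metropolis acceptance of worse moves with
#' probability `exp((e' - e)/T)`; geometric cooling `T <- r T` applied only
#' at iterations where the state did not change; best-visited tracking.
#'
#' @param objective objective to maximize (an [jAlphaObjective()] runs
#'   compiled; any other function runs the reference R loop).
#' @param cands `ekCandidates` with neighbourhood structure.
#' @param n design size.
#' @param config an [saConfig()].
#' @param init optional initial `ekDesign`.
#' @return An object of class `ekSearchResult` with the best design, its
#'   value, counters, the iteration trace and the configuration echo.
#' @export
saOptimize <- function(objective, cands, n, config, init = NULL) {
  stopifnot(inherits(config, "saConfig"))
  if (n >= cands$n_sites) stop("design size must be below the candidate count")
  set.seed(config$seed)
  if (inherits(objective, "ekJalphaObjective")) {
    ctx <- attr(objective, "ctx")
    out <- saCpp(ctx$C, ctx$dC, ctx$F, ctx$model$sigma2, ctx$neigh,
                 n, attr(objective, "alpha"), config$T0, config$r,
                 config$Nmax, if (is.null(init)) integer(0) else init$idx - 1L,
                 trace = TRUE)
    best <- design(cands, out$best + 1L, provenance = "sa")
    res <- list(best_design = best, best_value = out$best_value,
                counters = c(iterations = config$Nmax,
                             j_evaluations = out$j_evaluations,
                             accepted = out$accepted,
                             ek_evaluations = 0),
                trace = data.frame(iteration = seq_len(config$Nmax),
                                   value = out$trace[, 1],
                                   accepted = out$trace[, 2] == 1,
                                   best = out$trace[, 3],
                                   temperature = out$trace[, 4]),
                config = config, seed = config$seed)
    class(res) <- "ekSearchResult"
    return(res)
  }
  .saReference(objective, cands, n, config, init)
}

# Plain-R mirror of the annealing scheme for arbitrary objectives.
.saReference <- function(objective, cands, n, config, init) {
  Q <- cands$n_sites
  cur <- if (is.null(init)) sort(sample.int(Q, n)) else init$idx
  e_cur <- objective(design(cands, cur, "sa"))
  best <- cur; e_best <- e_cur
  Temp <- config$T0
  tr <- matrix(NA_real_, config$Nmax, 4)
  accepted <- 0L
  for (k in seq_len(config$Nmax)) {
    pos <- sample.int(n, 2)
    new_pts <- sample(setdiff(seq_len(Q), cur), 2)
    cand <- cur; cand[pos] <- new_pts
    cand <- localOptimize(design(cands, cand, "sa"), objective, cands)$idx
    e_cand <- objective(design(cands, cand, "sa"))
    if (e_cand > e_best) { e_best <- e_cand; best <- cand }
    accept <- e_cand > e_cur || stats::runif(1) < exp((e_cand - e_cur) / Temp)
    changed <- FALSE
    if (accept) {
      changed <- !setequal(cand, cur)
      cur <- cand; e_cur <- e_cand
      accepted <- accepted + 1L
    }
    if (!changed) Temp <- Temp * config$r
    tr[k, ] <- c(e_cand, accept, e_best, Temp)
  }
  res <- list(best_design = design(cands, best, provenance = "sa"),
              best_value = e_best,
              counters = c(iterations = config$Nmax, j_evaluations = NA,
                           accepted = accepted, ek_evaluations = 0),
              trace = data.frame(iteration = seq_len(config$Nmax),
                                 value = tr[, 1], accepted = tr[, 2] == 1,
                                 best = tr[, 3], temperature = tr[, 4]),
              config = config, seed = config$seed)
  class(res) <- "ekSearchResult"
  res
}

#' @export
print.ekSearchResult <- function(x, ...) {
  cat("Search result: best value", x$best_value, "\n")
  cat("  counters:", paste(names(x$counters), x$counters, sep = " = ",
                           collapse = ", "), "\n")
  print(x$best_design)
  invisible(x)
}

#' Pareto-front sampling by annealing over an alpha grid
#'
#' Runs one annealing search per weight in `alpha_grid`, maps the returned
#' designs to their criterion points, filters to the non-dominated set, and
#' collapses designs occupying the same Pareto point: distinct designs with
#' criterion values within `point_tol` (symmetric images of one optimum, or
#' runs converged to the same hull vertex) represent a single point on the
#' Pareto surface. The expensive EK criterion is then evaluated once per
#' distinct Pareto point, and the EK-minimizing design returned.
#'
#' @param model an `ekModel`.
#' @param cands `ekCandidates` with neighbourhood structure.
#' @param n design size.
#' @param alpha_grid weights in [0.5, 1].
#' @param config an [saConfig()]; run `i` uses seed `config$seed + i - 1`.
#' @param init optional initial `ekDesign` shared by all runs (a
#'   space-filling design is the recommended start).
#' @param prediction optional prediction set for the EK evaluation.
#' @param point_tol resolution at which two criterion points coincide; well
#'   below the separation of distinct Pareto points, above annealing
#'   convergence scatter.
#' @return A list with `points` (data frame of distinct Pareto points with
#'   their EK values), `designs` (one representative `ekDesign` per point),
#'   `front` (the `ekFront` before collapsing), `selected` (an
#'   `ekSearchResult` for the EK-minimizing design) and `per_alpha` values.
#' @export
paretoSampleSA <- function(model, cands, n, alpha_grid, config, init = NULL,
                           prediction = NULL, point_tol = 1e-4) {
  if (any(alpha_grid < 0 | alpha_grid > 1)) stop("alpha values must lie in [0, 1]")
  ctx <- ekContext(model, cands)
  runs <- vector("list", length(alpha_grid))
  for (i in seq_along(alpha_grid)) {
    obj <- jAlphaObjective(model, cands, alpha_grid[i], ctx = ctx)
    cfg <- config; cfg$seed <- config$seed + i - 1L
    runs[[i]] <- saOptimize(obj, cands, n, cfg, init = init)
  }
  designs <- lapply(runs, function(r) r$best_design)
  keys <- vapply(designs, function(d) paste(sort(d$idx), collapse = ","),
                 character(1))
  uniq <- !duplicated(keys)
  designs <- designs[uniq]
  pts <- criterionPoints(designs, model, cands, ctx = ctx)
  front <- nondominatedFilter(pts)
  grp <- .clusterPoints(front$c_beta, front$c_nu, point_tol)
  reps <- front$design_id[!duplicated(grp)]
  rep_designs <- designs[reps]
  mek_vals <- vapply(rep_designs, function(d)
    mek(d, model, cands, prediction)$value, numeric(1))
  points <- data.frame(c_beta = front$c_beta[!duplicated(grp)],
                       c_nu = front$c_nu[!duplicated(grp)],
                       mek = mek_vals)
  sel <- which.min(mek_vals)
  selected <- list(best_design = rep_designs[[sel]],
                   best_value = mek_vals[sel],
                   counters = c(iterations = length(alpha_grid) * config$Nmax,
                                j_evaluations = sum(vapply(runs, function(r)
                                  r$counters[["j_evaluations"]], numeric(1))),
                                ek_evaluations = length(rep_designs)),
                   trace = points,
                   config = config, seed = config$seed)
  class(selected) <- "ekSearchResult"
  list(points = points, designs = rep_designs, front = front,
       selected = selected,
       per_alpha = data.frame(alpha = alpha_grid,
                              value = vapply(runs, function(r) r$best_value,
                                             numeric(1))))
}

# Greedy single-linkage grouping of criterion points: sorted by c_beta,
# chain together consecutive points within tol in both coordinates.
.clusterPoints <- function(cb, cn, tol) {
  o <- order(cb, cn)
  grp <- integer(length(cb))
  g <- 0L
  for (i in seq_along(o)) {
    if (i == 1L || abs(cb[o[i]] - cb[o[i - 1L]]) > tol ||
        abs(cn[o[i]] - cn[o[i - 1L]]) > tol) g <- g + 1L
    grp[o[i]] <- g
  }
  grp
}

#' Simplified exchange algorithm with Pareto-restricted EK evaluation
#'
#' Starting from `xi0`, iteration k enumerates all single-point exchanges
#' (`n (Q-n)` at the first iteration, `(n-1)(Q-n)` afterwards — the point
#' swapped in at the previous iteration is not exchanged back), computes the
#' two log-determinant criteria for each, restricts to the non-dominated set
#' (`restrict = "front"`) or to its upper convex hull (`restrict = "hull"`),
#' evaluates the EK criterion on the restricted set only, and moves to the
#' best exchange if it strictly improves, stopping otherwise. EK evaluations
#' are counted over every scan including the final non-improving one, plus
#' the initial evaluation of `xi0`.
#'
#' @param xi0 initial `ekDesign` (typically space-filling).
#' @param model an `ekModel`.
#' @param cands the `ekCandidates` design space.
#' @param restrict `"front"` or `"hull"`.
#' @param prediction optional prediction set for the EK criterion.
#' @param ctx optional precomputed [ekContext()].
#' @param verbose print per-scan progress.
#' @return An `ekSearchResult`; `counters` reports `iterations` (design
#'   updates), `scans`, `ek_evaluations` and `j_evaluations` (criterion
#'   pairs), and `trace` holds one row per scan.
#' @export
exchangeSearch <- function(xi0, model, cands, restrict = c("front", "hull"),
                           prediction = NULL, ctx = NULL, verbose = FALSE) {
  restrict <- match.arg(restrict)
  if (any(xi0$idx > cands$n_sites)) stop("initial design outside candidate set")
  if (is.null(ctx)) ctx <- ekContext(model, cands)
  Q <- cands$n_sites
  n <- length(xi0$idx)
  cur <- xi0$idx
  mek_cur <- mek(design(cands, cur, "exchange"), model, cands, prediction)$value
  ek_evals <- 1L
  j_evals <- 0L
  updates <- 0L; scans <- 0L
  last_pos <- NA_integer_
  tr <- list()
  repeat {
    outs <- setdiff(seq_len(Q), cur)
    pos_set <- seq_len(n)
    if (!is.na(last_pos)) pos_set <- setdiff(pos_set, last_pos)
    cand_pos <- rep(pos_set, each = length(outs))
    cand_new <- rep(outs, times = length(pos_set))
    designs <- matrix(cur, length(cand_pos), n, byrow = TRUE)
    designs[cbind(seq_along(cand_pos), cand_pos)] <- cand_new
    pts <- criterionPoints(designs, model, cands, ctx = ctx)
    j_evals <- j_evals + nrow(designs)
    front <- nondominatedFilter(pts)
    sel <- front$design_id
    if (restrict == "hull") {
      front <- upperConvexHull(front)
      sel <- front$design_id[front$on_hull]
    }
    vals <- vapply(sel, function(s)
      mek(design(cands, designs[s, ], "exchange"), model, cands,
          prediction)$value, numeric(1))
    ek_evals <- ek_evals + length(sel)
    scans <- scans + 1L
    bi <- which.min(vals)
    tr[[scans]] <- data.frame(scan = scans, candidates = nrow(designs),
                              nondominated = nrow(front),
                              evaluated = length(sel),
                              best_mek = vals[bi], current_mek = mek_cur)
    if (verbose)
      message(sprintf("scan %d: %d candidates, %d evaluated, best %.6f (current %.6f)",
                      scans, nrow(designs), length(sel), vals[bi], mek_cur))
    if (vals[bi] >= mek_cur) break
    mek_cur <- vals[bi]
    last_pos <- cand_pos[sel[bi]]
    cur[last_pos] <- cand_new[sel[bi]]
    updates <- updates + 1L
  }
  res <- list(best_design = design(cands, cur, provenance = "exchange"),
              best_value = mek_cur,
              counters = c(iterations = updates, scans = scans,
                           ek_evaluations = ek_evals,
                           j_evaluations = j_evals),
              trace = do.call(rbind, tr),
              config = list(restrict = restrict), seed = NA_integer_)
  class(res) <- "ekSearchResult"
  res
}

#' Greedy sequential design augmentation
#'
#' Starting from `xi0`, repeatedly appends the candidate site maximizing the
#' classical kriging variance (`strategy = "S1"`) or the corrected
#' empirical-kriging variance (`strategy = "S2"`), recomputing all
#' quantities after each addition.
#'
#' @param xi0 initial `ekDesign`.
#' @param model an `ekModel`.
#' @param cands the `ekCandidates` space (also the prediction set).
#' @param strategy `"S1"` (kriging variance) or `"S2"` (corrected variance).
#' @param k_max number of points to add.
#' @return List of `ekDesign`s of sizes n0, n0+1, ..., n0+k_max.
#' @export
greedyAugment <- function(xi0, model, cands, strategy = c("S1", "S2"), k_max) {
  strategy <- match.arg(strategy)
  if (k_max > cands$n_sites - length(xi0$idx))
    stop("k_max exceeds the number of available candidate sites")
  out <- vector("list", k_max + 1)
  out[[1]] <- xi0
  cur <- xi0$idx
  for (k in seq_len(k_max)) {
    coords <- cands$coords[cur, , drop = FALSE]
    score <- if (strategy == "S1")
      .ukCore(model, coords, cands$coords)$rho2
    else
      .ekProfile(model, coords, cands$coords)
    score[cur] <- -Inf
    cur <- c(cur, which.max(score))
    out[[k + 1]] <- design(cands, cur, provenance = paste0("greedy_", strategy))
  }
  out
}

#' Exhaustive maximin/minimax Latin hypercube design
#'
#' Enumerates all `n!` Latin hypercube designs on the levels
#' `{i/(n-1)}` in `[0,1]^2`, keeps those maximizing the minimum pairwise
#' distance, and breaks ties by minimizing the maximum distance from any
#' site of the reference grid to the design (minimax), then by lexicographic
#' permutation order. Exhaustive search is capped at `n <= 9`.
#'
#' @param n design size (2..9).
#' @param m_per_axis reference grid resolution for the minimax tie-break;
#'   also the grid the returned design indexes into.
#' @param cands optional `ekCandidates` to attach the design to (must
#'   contain the Lh levels); defaults to `candidateGrid(m_per_axis)`.
#' @return An `ekDesign` on `cands`.
#' @examples
#' d <- maximinLh(7)        # the classical 7-point maximin/minimax Lh design
#' @export
maximinLh <- function(n, m_per_axis = 25, cands = NULL) {
  if (n > 9) stop("exhaustive search capped at n = 9; use a heuristic for larger n")
  if (n < 2) stop("need n >= 2")
  if (is.null(cands)) cands <- candidateGrid(m_per_axis)
  lev <- (seq_len(n) - 1) / (n - 1)
  gx <- cands$coords[, 1]; gy <- cands$coords[, 2]
  best_min <- -Inf; best_mmx <- Inf; best_pts <- NULL
  perm <- seq_len(n)
  repeat {
    pts <- cbind(lev, lev[perm])
    mind <- min(stats::dist(pts))
    if (mind > best_min + 1e-12) {
      best_min <- mind
      best_mmx <- .minimaxDist(pts, gx, gy)
      best_pts <- pts
    } else if (mind > best_min - 1e-12) {
      mmx <- .minimaxDist(pts, gx, gy)
      if (mmx < best_mmx - 1e-12) { best_mmx <- mmx; best_pts <- pts }
    }
    perm <- .nextPermutation(perm)
    if (is.null(perm)) break
  }
  designFromCoords(cands, best_pts, provenance = "maximin_lh")
}

.minimaxDist <- function(pts, gx, gy) {
  d2 <- outer(gx, pts[, 1], "-")^2 + outer(gy, pts[, 2], "-")^2
  sqrt(max(apply(d2, 1, min)))
}

# Next lexicographic permutation, or NULL after the last one.
.nextPermutation <- function(p) {
  n <- length(p)
  i <- n - 1L
  while (i >= 1L && p[i] >= p[i + 1L]) i <- i - 1L
  if (i < 1L) return(NULL)
  j <- n
  while (p[j] <= p[i]) j <- j - 1L
  tmp <- p[i]; p[i] <- p[j]; p[j] <- tmp
  p[(i + 1L):n] <- rev(p[(i + 1L):n])
  p
}

#' Randomly perturbed Latin hypercube design
#'
#' A uniform-random Latin hypercube on the levels `{i/(n-1)}` with
#' independent Gaussian jitter of standard deviation `sd` added to every
#' coordinate and truncation to `[0, 1]`. These designs are generally off
#' the candidate grid; they serve as a realistic random-design law for
#' criterion scatter and baseline studies.
#'
#' @param n design size.
#' @param sd jitter standard deviation (`0` gives an exact random Lh).
#' @param seed integer RNG seed; if `NULL` the current RNG state is used.
#' @return An n x 2 coordinate matrix.
#' @export
perturbedLhSample <- function(n, sd = 0.1, seed = NULL) {
  if (sd < 0) stop("sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  lev <- (seq_len(n) - 1) / (n - 1)
  pts <- cbind(lev, lev[sample.int(n)])
  pts <- pts + matrix(stats::rnorm(2 * n, 0, sd), n, 2)
  pmin(pmax(pts, 0), 1)
}
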