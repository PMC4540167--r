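#' Extrapolation-error study on simulated fields
#'
#' Simulates `n_real` field realizations over the candidate set and, for
#' each design, predicts every site from the design-site values by
#' universal kriging with the generating parameters. Reports the maximum
#' squared extrapolation error over the grid per realization and the
#' empirical mean-square error summaries. Plug-in re-estimation of the
#' covariance parameters per realization is deliberately not performed;
#' predictions use the generating model.
#'
#' @param designs named list of `ekDesign` objects.
#' @param model an `ekModel`.
#' @param cands the `ekCandidates` grid (design space and prediction set).
#' @param n_real number of simulated realizations.
#' @param seed integer RNG seed.
#' @return A list of class `ekEvaluationReport`: `per_realization` (data
#'   frame with columns realization, design, E_j) and `summaries` (data
#'   frame with median E_j and the empirical maximum mean-square error per
#'   design).
#' @export
fieldEval <- function(designs, model, cands, n_real, seed) {
  if (is.null(names(designs)))
    names(designs) <- paste0("design_", seq_along(designs))
  Yr <- simulateField(cands, model, n_real, seed)
  per <- list(); summ <- list()
  for (nm in names(designs)) {
    d <- designs[[nm]]
    if (any(d$idx > cands$n_sites)) stop("design site outside the grid")
    W <- .ukCore(model, d$coords, cands$coords)$w      # n x Q weights
    Err <- Yr[, d$idx, drop = FALSE] %*% W - Yr
    E_j <- apply(Err^2, 1, max)
    mse <- colMeans(Err^2)
    per[[nm]] <- data.frame(realization = seq_len(n_real), design = nm,
                            E_j = E_j)
    summ[[nm]] <- data.frame(design = nm, median_Ej = stats::median(E_j),
                             max_mse = max(mse))
  }
  structure(list(per_realization = do.call(rbind, per),
                 summaries = do.call(rbind, summ)),
            class = "ekEvaluationReport")
}

#' @export
print.ekEvaluationReport <- function(x, ...) {
  cat("Field-evaluation report over",
      max(x$per_realization$realization), "realizations:\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Random-design baseline study for the EK criterion
#'
#' Draws `n_sets` sets of `set_size` random designs (perturbed Latin
#' hypercubes), records the minimum EK value within each set — the best one
#' would achieve with the same number of expensive evaluations spent on
#' random designs — and locates a reference design's EK value within that
#' empirical distribution.
#'
#' @param model an `ekModel`.
#' @param cands the `ekCandidates` prediction grid.
#' @param n design size.
#' @param n_sets number of random sets.
#' @param set_size designs per set.
#' @param seed integer RNG seed.
#' @param reference optional `ekDesign` (or coordinates) to compare.
#' @param sd jitter standard deviation of the random-design law.
#' @return A list with `minima` (length `n_sets`), `reference_value` and
#'   `fraction_beaten` (share of sets whose best random design is worse than
#'   the reference), the latter two `NULL` without a reference.
#' @export
randomBaselineStudy <- function(model, cands, n, n_sets, set_size, seed,
                                reference = NULL, sd = 0.1) {
  set.seed(seed)
  minima <- numeric(n_sets)
  for (i in seq_len(n_sets)) {
    vals <- vapply(seq_len(set_size), function(j)
      mek(perturbedLhSample(n, sd), model, cands)$value, numeric(1))
    minima[i] <- min(vals)
  }
  out <- list(minima = minima, reference_value = NULL, fraction_beaten = NULL)
  if (!is.null(reference)) {
    out$reference_value <- mek(reference, model, cands)$value
    out$fraction_beaten <- mean(minima > out$reference_value)
  }
  out
}

#' Criterion scatter study over random designs
#'
#' Evaluates, for a sample of perturbed-Lh random designs, the two
#' log-determinant criteria, the compound criterion at weight `alpha`, and
#' the EK criterion, together with the rank correlation between `-J_alpha`
#' and EK. Useful for checking the antagonism of the two estimation
#' criteria and how well the compound criterion tracks the EK objective.
#'
#' @param model an `ekModel`.
#' @param cands the `ekCandidates` prediction grid.
#' @param n design size.
#' @param n_designs number of random designs.
#' @param sd jitter standard deviation.
#' @param seed integer RNG seed.
#' @param alpha compound-criterion weight.
#' @return A list with `table` (data frame: c_beta, c_nu, j_alpha, mek) and
#'   `rank_correlation` (Spearman correlation of -j_alpha with mek).
#' @export
scatterStudy <- function(model, cands, n, n_designs, sd = 0.1, seed = 1,
                         alpha = 0.75) {
  set.seed(seed)
  rows <- vector("list", n_designs)
  for (i in seq_len(n_designs)) {
    pts <- perturbedLhSample(n, sd)
    info <- informationBundle(pts, model)
    m <- mek(pts, model, cands)$value
    rows[[i]] <- data.frame(c_beta = info$log_det_beta,
                            c_nu = info$log_det_nu,
                            j_alpha = alpha * info$log_det_beta +
                              (1 - alpha) * info$log_det_nu,
                            mek = m)
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       rank_correlation = stats::cor(-tab$j_alpha, tab$mek,
                                     method = "spearman"))
}

#' Synthetic bay-shaped candidate grid
#'
#' A 21 x 21 grid with a synthetic non-convex coastline mask, emulating the
#' geometry of a coastal monitoring region (an open sea area indented by a
#' land mass in the south-east corner and a peninsula in the north). This
#' is a synthetic stand-in: the mask is generated from simple geometric
#' predicates, not from any real bathymetry.
#'
#' @param m grid resolution per axis.
#' @return An `ekCandidates` with the masked sites removed.
#' @export
syntheticBayCandidates <- function(m = 21) {
  candidateGrid(m, mask = function(x, y) {
    land_se <- x > 0.55 && y < 0.35 && (x - 0.55) > 0.8 * y   # SE land wedge
    peninsula <- y > 0.8 && x > 0.35 && x < 0.6               # N peninsula
    !(land_se || peninsula)
  })
}

#' Write a self-describing search-result JSON
#'
#' Records the design, criterion value, counters, configuration echo, seed
#' and package version — enough to re-run the search bit-identically.
#'
#' @param result an `ekSearchResult`.
#' @param path output path.
#' @export
writeResultJson <- function(result, path) {
  jsonlite::write_json(list(
    package = "ekdesign",
    version = as.character(utils::packageVersion("ekdesign")),
    best_value = result$best_value,
    design = list(idx = result$best_design$idx,
                  x = result$best_design$coords[, 1],
                  y = result$best_design$coords[, 2],
                  provenance = result$best_design$provenance),
    counters = as.list(result$counters),
    config = unclass(result$config),
    seed = result$seed), path, auto_unbox = TRUE, digits = NA)
}
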