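#' Candidate sets of design sites
#'
#' A candidate set is the finite design space: the sites from which designs
#' are drawn and, by default, also the prediction set over which the
#' empirical-kriging criterion is maximized. Regular grids carry a rook
#' (North/South/West/East) neighbourhood used by the local search; arbitrary
#' point lists have an empty neighbourhood.
#'
#' @param coords numeric matrix (Q x d) of site coordinates.
#' @param neighbours optional list of integer vectors, `neighbours[[i]]`
#'   giving the indices of the sites adjacent to site `i`. Must be symmetric.
#' @param grid optional list with elements `m`, `lo`, `hi` recording that the
#'   set is a regular grid (set by [candidateGrid()]).
#' @return An object of class `ekCandidates`: a list with elements `coords`,
#'   `neighbours`, `grid` and `n_sites`.
#' @seealso [candidateGrid()], [readCandidates()]
#' @export
candidateSet <- function(coords, neighbours = NULL, grid = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (anyNA(coords) || any(!is.finite(coords)))
    stop("candidate coordinates must be finite")
  if (anyDuplicated(coords))
    stop("candidate sites must be distinct")
  if (!is.null(neighbours)) {
    if (length(neighbours) != nrow(coords))
      stop("neighbourhood must have one entry per site")
    for (i in seq_along(neighbours)) {
      nb <- neighbours[[i]]
      if (any(nb < 1L | nb > nrow(coords)))
        stop("neighbour index out of range")
      for (j in nb) if (!(i %in% neighbours[[j]]))
        stop("neighbourhood is not symmetric")
    }
  }
  structure(list(coords = coords,
                 neighbours = neighbours,
                 grid = grid,
                 n_sites = nrow(coords)),
            class = "ekCandidates")
}

#' Regular grid candidate set
#'
#' Builds the closed m x m grid with coordinates `{lo + i*(hi-lo)/(m-1)}` for
#' `i = 0, ..., m-1` on each axis, together with its rook neighbourhood.
#' Sites are ordered with the first axis varying fastest; this order fixes
#' all first-index tie-breaks downstream.
#'
#' @param m number of levels per axis (at least 2).
#' @param lo,hi endpoints of each axis.
#' @param mask optional logical vector of length m^2 (in site order) or a
#'   predicate `function(x, y)` returning `TRUE` for admissible sites;
#'   masked-out sites are dropped and the neighbourhood restricted, which is
#'   how non-convex monitoring regions are represented.
#' @return An `ekCandidates` object.
#' @examples
#' g <- candidateGrid(5)
#' g$n_sites
#' @export
candidateGrid <- function(m, lo = 0, hi = 1, mask = NULL) {
  if (m < 2) stop("grid needs at least 2 levels per axis")
  lev <- lo + (seq_len(m) - 1L) * (hi - lo) / (m - 1L)
  coords <- as.matrix(expand.grid(x = lev, y = lev, KEEP.OUT.ATTRS = FALSE))
  dimnames(coords) <- list(NULL, c("x", "y"))
  keep <- rep(TRUE, nrow(coords))
  if (!is.null(mask)) {
    keep <- if (is.function(mask)) {
      vapply(seq_len(nrow(coords)),
             function(i) isTRUE(mask(coords[i, 1], coords[i, 2])), logical(1))
    } else as.logical(mask)
    if (length(keep) != nrow(coords)) stop("mask length must equal m^2")
  }
  idx_map <- cumsum(keep)                    # old index -> new index
  nb <- vector("list", sum(keep))
  for (i in seq_len(nrow(coords))) {
    if (!keep[i]) next
    ix <- (i - 1L) %% m           # 0-based position on first axis
    iy <- (i - 1L) %/% m
    cand <- integer(0)
    if (ix > 0L)      cand <- c(cand, i - 1L)
    if (ix < m - 1L)  cand <- c(cand, i + 1L)
    if (iy > 0L)      cand <- c(cand, i - m)
    if (iy < m - 1L)  cand <- c(cand, i + m)
    nb[[idx_map[i]]] <- idx_map[cand[keep[cand]]]
  }
  candidateSet(coords[keep, , drop = FALSE], neighbours = nb,
               grid = list(m = m, lo = lo, hi = hi))
}

#' @export
print.ekCandidates <- function(x, ...) {
  cat("Candidate set:", x$n_sites, "sites in", ncol(x$coords), "dimensions\n")
  if (!is.null(x$grid))
    cat("  regular", x$grid$m, "x", x$grid$m, "grid on [",
        x$grid$lo, ",", x$grid$hi, "] with rook neighbourhood\n")
  invisible(x)
}

#' Read a candidate set from CSV or a JSON grid specification
#'
#' CSV files must have columns `x`, `y` and optionally a logical/0-1 column
#' `mask`. JSON files must contain an object like
#' `{"type": "grid", "m": 25, "lo": 0, "hi": 1}`.
#'
#' @param path file path; format chosen by extension (`.json` else CSV).
#' @return An `ekCandidates` object.
#' @export
readCandidates <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    spec <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!identical(spec$type, "grid"))
      stop("JSON candidate spec must have type = \"grid\"")
    return(candidateGrid(spec$m,
                         lo = if (is.null(spec$lo)) 0 else spec$lo,
                         hi = if (is.null(spec$hi)) 1 else spec$hi))
  }
  tab <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(tab)))
    stop("candidate CSV needs columns x and y")
  coords <- as.matrix(tab[, c("x", "y")])
  if ("mask" %in% names(tab)) coords <- coords[as.logical(tab$mask), , drop = FALSE]
  candidateSet(coords)
}

#' Write a candidate set to CSV
#'
#' @param cands an `ekCandidates` object.
#' @param path output file path.
#' @export
writeCandidates <- function(cands, path) {
  utils::write.csv(data.frame(x = cands$coords[, 1], y = cands$coords[, 2]),
                   path, row.names = FALSE)
}

#' Designs: ordered subsets of a candidate set
#'
#' A design is an ordered set of distinct sites, stored as integer indices
#' into a candidate set. Site order is significant only for bookkeeping and
#' tie-breaking; the criteria themselves are permutation invariant.
#'
#' @param cands an `ekCandidates` object.
#' @param idx integer vector of distinct candidate indices (length >= 2).
#' @param provenance short tag recording how the design arose.
#' @return An object of class `ekDesign`: a list with `idx`, `coords` and
#'   `provenance`.
#' @examples
#' g <- candidateGrid(5)
#' d <- design(g, c(1, 13, 25))
#' @export
design <- function(cands, idx, provenance = "user") {
  idx <- as.integer(idx)
  if (length(idx) < 2) stop("designs need at least 2 sites")
  if (anyDuplicated(idx)) stop("designs may not contain replicated sites")
  if (any(idx < 1L | idx > cands$n_sites)) stop("design site outside candidate set")
  structure(list(idx = idx,
                 coords = cands$coords[idx, , drop = FALSE],
                 provenance = provenance),
            class = "ekDesign")
}

#' Match free coordinates to candidate sites
#'
#' @param cands an `ekCandidates` object.
#' @param coords matrix of coordinates, one row per site; each must coincide
#'   with a candidate site to within `tol`.
#' @param tol matching tolerance on squared distance.
#' @inheritParams design
#' @return An `ekDesign` object.
#' @export
designFromCoords <- function(cands, coords, provenance = "user", tol = 1e-9) {
  coords <- as.matrix(coords)
  idx <- integer(nrow(coords))
  for (i in seq_len(nrow(coords))) {
    d2 <- rowSums((cands$coords - matrix(coords[i, ], cands$n_sites,
                                         ncol(coords), byrow = TRUE))^2)
    j <- which.min(d2)
    if (d2[j] > tol) stop("coordinate row ", i, " does not match any candidate site")
    idx[i] <- j
  }
  design(cands, idx, provenance)
}

#' @export
print.ekDesign <- function(x, ...) {
  cat("Design with", length(x$idx), "sites (", x$provenance, ")\n")
  print(round(x$coords, 4))
  invisible(x)
}

#' Read / write designs as CSV (columns x, y)
#'
#' @param cands an `ekCandidates` object the sites must belong to.
#' @param path file path.
#' @return `readDesign` returns an `ekDesign`; `writeDesign` is called for
#'   its side effect.
#' @export
readDesign <- function(cands, path) {
  tab <- utils::read.csv(path)
  designFromCoords(cands, as.matrix(tab[, c("x", "y")]), provenance = "file")
}

#' @rdname readDesign
#' @param des an `ekDesign` object.
#' @export
writeDesign <- function(des, path) {
  utils::write.csv(data.frame(x = des$coords[, 1], y = des$coords[, 2]),
                   path, row.names = FALSE)
}
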