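# Least-cost landscape connectivity: resistance = 1 - suitability, and the
# minimum accumulated-cost path between two range borders over an
# 8-connected grid (ArcGIS cost-distance convention).

#' Resistance raster from habitat suitability
#'
#' Cellwise \code{1 - LV}; nodata propagates.
#'
#' @param suit suitability raster with values in [0, 1].
#' @return an \code{asc_raster} of resistances.
#' @export
resistance_raster <- function(suit) {
  v <- suit$values
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("suitability values must lie in [0, 1]")
  raster_grid(1 - v, suit$xllcorner, suit$yllcorner, suit$cellsize,
              suit$nodata_value)
}

# map (row, col) cells to vertex ids of the lattice graph (column-major)
cell_vertex <- function(cells, nr) (cells[, 2] - 1L) * nr + cells[, 1]

grid_graph <- function(res, neighborhood = 8) {
  v <- res$values
  nr <- nrow(v); nc <- ncol(v)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (neighborhood == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  from <- to <- integer(0); w <- numeric(0)
  for (o in offs) {
    rows <- seq_len(nr - o[1])
    cols <- if (o[2] >= 0) seq_len(nc - o[2]) else seq(1L - o[2], nc)
    a <- as.matrix(expand.grid(row = rows, col = cols))
    b <- cbind(a[, 1] + o[1], a[, 2] + o[2])
    ra <- v[a]; rb <- v[b]
    ok <- !is.na(ra) & !is.na(rb)
    if (!any(ok)) next
    mult <- if (all(o != 0)) sqrt(2) else 1
    from <- c(from, cell_vertex(a[ok, , drop = FALSE], nr))
    to <- c(to, cell_vertex(b[ok, , drop = FALSE], nr))
    w <- c(w, (ra[ok] + rb[ok]) / 2 * mult)
  }
  g <- igraph::make_empty_graph(nr * nc, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, c(rbind(from, to)), weight = w)
  g
}

#' Least-cost path between source and target cell sets
#'
#' Dijkstra shortest path on the 4- or 8-connected grid graph; the cost
#' of a move is the mean resistance of the two cells times 1 (orthogonal)
#' or sqrt(2) (diagonal), so accumulated costs are dimensionless
#' (resistance x cell steps).  The minimum is taken over all
#' source-target pairs.
#'
#' @param res resistance raster (\code{asc_raster}; \code{NA} cells are
#'   barriers).
#' @param sources,targets cell sets: data.frames/matrices with columns
#'   \code{row}, \code{col}.
#' @param neighborhood 8 (default) or 4.
#' @return list: \code{cost} (Inf if unreachable), \code{path} (matrix of
#'   row/col cells along one optimal path, or NULL), \code{reachable}.
#' @export
least_cost_path <- function(res, sources, targets, neighborhood = 8) {
  stopifnot(neighborhood %in% c(4, 8))
  src <- cells_df_to_matrix(sources)
  tgt <- cells_df_to_matrix(targets)
  if (nrow(src) == 0L || nrow(tgt) == 0L)
    stop("source and target sets must be non-empty")
  v <- res$values
  inside <- function(m) all(m[, 1] >= 1 & m[, 1] <= nrow(v) &
                            m[, 2] >= 1 & m[, 2] <= ncol(v))
  if (!inside(src) || !inside(tgt)) stop("cells outside the grid")
  if (anyNA(v[src]) || anyNA(v[tgt]))
    stop("source/target cells on nodata")
  g <- grid_graph(res, neighborhood)
  nr <- nrow(v)
  sv <- cell_vertex(src, nr); tv <- cell_vertex(tgt, nr)
  dm <- igraph::distances(g, v = sv, to = tv, algorithm = "dijkstra")
  if (!any(is.finite(dm)))
    return(list(cost = Inf, path = NULL, reachable = FALSE))
  best <- which(dm == min(dm), arr.ind = TRUE)[1, ]
  sp <- igraph::shortest_paths(g, from = sv[best[1]], to = tv[best[2]],
                               algorithm = "dijkstra")$vpath[[1]]
  ids <- as.integer(sp)
  path <- cbind(row = (ids - 1L) %% nr + 1L, col = (ids - 1L) %/% nr + 1L)
  list(cost = min(dm), path = path, reachable = TRUE)
}

#' Gap connectivity report across two climate scenarios
#'
#' Builds resistance surfaces from the two suitability rasters, computes
#' the least-cost cost between the range borders under each, and pairs
#' this with the paired t comparison of gap suitability
#' (\code{\link{compare_gap_suitability}}).
#'
#' @param suit_current,suit_lgm suitability rasters sharing one header.
#' @param gap_mask logical matrix of gap cells.
#' @param sources,targets border cell sets (row/col).
#' @param neighborhood passed to \code{\link{least_cost_path}}.
#' @return list: \code{cost_current}, \code{cost_lgm},
#'   \code{path_current}, \code{path_lgm}, \code{gap_t} (the paired
#'   test), \code{verdict}.
#' @export
gap_connectivity_report <- function(suit_current, suit_lgm, gap_mask,
                                    sources, targets, neighborhood = 8) {
  if (!same_header(suit_current, suit_lgm))
    stop("suitability rasters do not share one header")
  lc_cur <- least_cost_path(resistance_raster(suit_current), sources,
                            targets, neighborhood)
  lc_lgm <- least_cost_path(resistance_raster(suit_lgm), sources,
                            targets, neighborhood)
  tt <- compare_gap_suitability(suit_current, suit_lgm, gap_mask)
  verdict <- if (!lc_lgm$reachable || lc_lgm$cost > lc_cur$cost)
    "gap at least as resistant at the LGM: consistent with a persistent barrier"
  else
    "gap less resistant at the LGM: no support for a persistent barrier"
  list(cost_current = lc_cur$cost, cost_lgm = lc_lgm$cost,
       path_current = lc_cur$path, path_lgm = lc_lgm$path,
       gap_t = tt, verdict = verdict)
}
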