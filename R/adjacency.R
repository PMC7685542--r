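#' Areal adjacency graph
#'
#' An `adjacency_graph` holds the neighbourhood structure of a set of areal
#' units (sub-counties): the number of areas, a de-duplicated set of
#' unordered neighbour pairs, per-area neighbour counts, and a deterministic
#' connected-component labelling. It is the structure underpinning the
#' intrinsic conditional autoregressive (ICAR) prior on the structured
#' spatial effect.
#'
#' Areas are always referred to by 1-based integer index; when a graph is
#' read from files carrying area identifiers, areas are ordered
#' lexicographically by id and that ordering is fixed from then on.
#'
#' @param pairs two-column matrix (or list of length-2 vectors) of area
#'   indices in `1..n_areas`; order within a pair is ignored and duplicate
#'   pairs are collapsed.
#' @param n_areas positive integer number of areal units.
#' @param area_ids optional character vector of area identifiers (length
#'   `n_areas`); defaults to `"A001"...` style labels.
#'
#' @return An object of class `adjacency_graph`: a list with elements
#'   `n_areas`, `edges` (m x 2 integer matrix, `edges[,1] < edges[,2]`),
#'   `degree` (integer vector), `component` (integer component label per
#'   area, numbered by smallest member index), `n_components`, `neighbours`
#'   (list of integer vectors) and `area_ids`.
#' @examples
#' g <- graph_from_edge_list(rbind(c(1, 2), c(2, 3)), n_areas = 3)
#' g$degree  # 1 2 1
#' @export
graph_from_edge_list <- function(pairs, n_areas, area_ids = NULL) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || length(pairs) == 0L) {
    pairs <- matrix(integer(), ncol = 2L)
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns", call. = FALSE)
  n_areas <- as.integer(n_areas)
  if (is.na(n_areas) || n_areas < 1L) stop("`n_areas` must be a positive integer", call. = FALSE)
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) > 0L) {
    if (anyNA(pairs) || any(pairs < 1L) || any(pairs > n_areas)) {
      stop("area index out of range [1, ", n_areas, "] in edge list", call. = FALSE)
    }
    if (any(pairs[, 1L] == pairs[, 2L])) {
      stop("self-edges are not allowed in an areal adjacency graph", call. = FALSE)
    }
    pairs <- cbind(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
    dimnames(pairs) <- NULL
    pairs <- unique(pairs)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  }
  nbr <- vector("list", n_areas)
  for (k in seq_len(n_areas)) nbr[[k]] <- integer()
  if (nrow(pairs) > 0L) {
    for (e in seq_len(nrow(pairs))) {
      i <- pairs[e, 1L]; j <- pairs[e, 2L]
      nbr[[i]] <- c(nbr[[i]], j)
      nbr[[j]] <- c(nbr[[j]], i)
    }
    nbr <- lapply(nbr, sort)
  }
  deg <- vapply(nbr, length, integer(1))
  comp <- .graph_components(nbr, n_areas)
  if (is.null(area_ids)) {
    area_ids <- sprintf("A%03d", seq_len(n_areas))
  } else {
    if (length(area_ids) != n_areas) stop("`area_ids` length must equal `n_areas`", call. = FALSE)
    area_ids <- as.character(area_ids)
  }
  structure(
    list(
      n_areas = n_areas,
      edges = pairs,
      degree = deg,
      neighbours = nbr,
      component = comp,
      n_components = max(comp),
      area_ids = area_ids
    ),
    class = "adjacency_graph"
  )
}

# Deterministic connected components by breadth-first search from the
# smallest unvisited index; labels are 1, 2, ... in order of discovery.
.graph_components <- function(nbr, n) {
  comp <- integer(n)
  lab <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    comp[s] <- lab
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      for (j in nbr[[cur]]) {
        if (comp[j] == 0L) {
          comp[j] <- lab
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("<adjacency_graph> ", x$n_areas, " areas, ", nrow(x$edges), " edges, ",
      x$n_components, " component(s)\n", sep = "")
  invisible(x)
}

#' Queen-contiguity graph from a GeoJSON FeatureCollection
#'
#' Two areas are neighbours when their polygon boundaries share at least one
#' point (queen contiguity, so a corner touch counts). Coordinates are
#' compared after rounding to `digits` decimal places, the usual snapping
#' rule for contiguity building. Features are ordered lexicographically by
#' their `area_id` property, which fixes the area indexing used everywhere
#' downstream.
#'
#' @param path path to a GeoJSON file containing a `FeatureCollection` of
#'   `Polygon`/`MultiPolygon` features, each with an `area_id` property.
#' @param digits coordinate rounding used when matching shared vertices.
#' @return An [graph_from_edge_list()] `adjacency_graph`.
#' @export
graph_from_polygons <- function(path, digits = 8) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- gj$features
  if (length(feats) == 0L) stop("GeoJSON contains zero features", call. = FALSE)
  ids <- vapply(feats, function(f) {
    id <- f$properties$area_id
    if (is.null(id)) stop("every feature needs an `area_id` property", call. = FALSE)
    as.character(id)
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate `area_id` values in GeoJSON", call. = FALSE)
  ord <- order(ids)
  feats <- feats[ord]
  ids <- ids[ord]
  n <- length(feats)

  vertex_keys <- function(f) {
    geom <- f$geometry
    if (is.null(geom) || is.null(geom$type)) stop("feature without geometry", call. = FALSE)
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    keys <- character(0)
    for (ring in rings) {
      for (pt in ring) {
        x <- as.numeric(pt[[1L]]); y <- as.numeric(pt[[2L]])
        if (!is.finite(x) || !is.finite(y)) stop("non-finite coordinate in geometry", call. = FALSE)
        keys <- c(keys, paste0(round(x, digits), "_", round(y, digits)))
      }
    }
    unique(keys)
  }

  keys <- lapply(feats, vertex_keys)
  # invert: vertex -> areas touching it
  all_keys <- unlist(keys, use.names = FALSE)
  owner <- rep.int(seq_len(n), vapply(keys, length, integer(1)))
  by_vertex <- split(owner, all_keys)
  pairs <- matrix(integer(), ncol = 2L)
  touch <- by_vertex[vapply(by_vertex, length, integer(1)) > 1L]
  if (length(touch)) {
    pl <- lapply(touch, function(a) {
      a <- sort(unique(a))
      if (length(a) < 2L) return(NULL)
      t(utils::combn(a, 2L))
    })
    pl <- pl[!vapply(pl, is.null, logical(1))]
    if (length(pl)) pairs <- unique(do.call(rbind, pl))
  }
  graph_from_edge_list(pairs, n_areas = n, area_ids = ids)
}

#' Read an adjacency structure from an edge-list CSV or a GAL file
#'
#' The CSV form has two columns, `area_id_a` and `area_id_b`, one neighbour
#' pair per row. The GAL form is the classic neighbour-file layout: a header
#' line whose last-but-one token is the number of areas, then for each area a
#' line `id k` followed by a line of `k` neighbour ids. In both cases area
#' ids are arbitrary strings and indexing is fixed lexicographically.
#'
#' @param path file path.
#' @param format `"csv"`, `"gal"`, or `"auto"` (by file extension).
#' @return An `adjacency_graph`.
#' @export
read_adjacency <- function(path, format = c("auto", "csv", "gal")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gal$", path, ignore.case = TRUE)) "gal" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("area_id_a", "area_id_b")
    if (!all(need %in% names(df))) {
      stop("adjacency CSV needs columns area_id_a, area_id_b", call. = FALSE)
    }
    ids <- sort(unique(c(as.character(df$area_id_a), as.character(df$area_id_b))))
    idx <- stats::setNames(seq_along(ids), ids)
    pairs <- cbind(idx[as.character(df$area_id_a)], idx[as.character(df$area_id_b)])
    graph_from_edge_list(pairs, n_areas = length(ids), area_ids = ids)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
    n <- as.integer(if (length(hdr) >= 2L) hdr[[2L]] else hdr[[1L]])
    if (is.na(n) || n < 1L) stop("cannot parse GAL header", call. = FALSE)
    ids <- character(n)
    nb_raw <- vector("list", n)
    k <- 2L
    for (a in seq_len(n)) {
      rec <- strsplit(trimws(lines[[k]]), "\\s+")[[1L]]
      ids[[a]] <- rec[[1L]]
      deg <- as.integer(rec[[2L]])
      if (is.na(deg)) stop("cannot parse GAL record for area ", rec[[1L]], call. = FALSE)
      nb_raw[[a]] <- if (deg > 0L) strsplit(trimws(lines[[k + 1L]]), "\\s+")[[1L]] else character(0)
      k <- k + (if (deg > 0L) 2L else 1L)
    }
    ord <- order(ids)
    ids_sorted <- ids[ord]
    idx <- stats::setNames(seq_along(ids_sorted), ids_sorted)
    pairs <- matrix(integer(), ncol = 2L)
    pl <- list()
    for (a in seq_len(n)) {
      me <- idx[[ids[[a]]]]
      for (nbid in nb_raw[[a]]) {
        if (!nbid %in% names(idx)) stop("GAL neighbour id not declared: ", nbid, call. = FALSE)
        pl[[length(pl) + 1L]] <- c(me, idx[[nbid]])
      }
    }
    if (length(pl)) pairs <- do.call(rbind, pl)
    graph_from_edge_list(pairs, n_areas = n, area_ids = ids_sorted)
  }
}

#' Write an adjacency graph as an edge-list CSV
#'
#' @param graph an `adjacency_graph`.
#' @param path output path.
#' @export
write_adjacency <- function(graph, path) {
  df <- data.frame(
    area_id_a = graph$area_ids[graph$edges[, 1L]],
    area_id_b = graph$area_ids[graph$edges[, 2L]],
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' ICAR joint log density (kernel plus rank-deficient normalising term)
#'
#' Evaluates, up to an additive constant not involving `u` or `tau`,
#' \deqn{\frac{n - c}{2}\log\tau \;-\; \frac{\tau}{2}\sum_{i \sim j}(u_i - u_j)^2,}
#' where the sum runs over unordered neighbour pairs and `c` is the number
#' of connected components (isolated areas each count as a component, so the
#' exponent is the rank of the graph Laplacian). The density is improper:
#' flat along per-component constant shifts of `u`.
#'
#' @param u numeric vector of structured spatial effects, one per area.
#' @param tau positive ICAR precision.
#' @param graph an `adjacency_graph`.
#' @return log density (scalar).
#' @export
icar_log_density <- function(u, tau, graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (length(u) != graph$n_areas) {
    stop("length(u) must equal graph$n_areas", call. = FALSE)
  }
  if (!is.finite(tau) || tau <= 0) stop("`tau` must be positive", call. = FALSE)
  S <- 0
  if (nrow(graph$edges) > 0L) {
    d <- u[graph$edges[, 1L]] - u[graph$edges[, 2L]]
    S <- sum(d^2)
  }
  rank <- graph$n_areas - graph$n_components
  rank / 2 * log(tau) - tau / 2 * S
}

#' ICAR full conditional of one area's structured effect
#'
#' Given the neighbours' current values, the ICAR full conditional of
#' `u[i]` is Gaussian with mean the neighbour average and precision
#' `tau * m_i` where `m_i` is the neighbour count.
#'
#' @inheritParams icar_log_density
#' @param i area index (1-based).
#' @return list with `mean` and `precision`.
#' @export
icar_full_conditional <- function(u, i, tau, graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (length(u) != graph$n_areas) stop("length(u) must equal graph$n_areas", call. = FALSE)
  i <- as.integer(i)
  if (is.na(i) || i < 1L || i > graph$n_areas) stop("area index out of range", call. = FALSE)
  m <- graph$degree[[i]]
  if (m == 0L) {
    stop(structure(
      class = c("anaemap_island_error", "error", "condition"),
      list(message = paste0("area ", i, " has no neighbours; the island policy applies ",
                            "(structured effect fixed at zero)"),
           call = sys.call(-1))
    ))
  }
  list(mean = mean(u[graph$neighbours[[i]]]), precision = tau * m)
}

#' Regular lattice adjacency (rook contiguity on a grid)
#'
#' Utility used by the synthetic generator: `nr x nc` grid, areas numbered
#' row-major, horizontally/vertically adjacent cells are neighbours.
#'
#' @param nr,nc grid dimensions.
#' @return An `adjacency_graph` with `nr * nc` areas.
#' @export
grid_graph <- function(nr, nc) {
  nr <- as.integer(nr); nc <- as.integer(nc)
  if (nr < 1L || nc < 1L) stop("grid dimensions must be positive", call. = FALSE)
  idx <- function(r, c) (r - 1L) * nc + c
  pl <- list()
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (c < nc) pl[[length(pl) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
      if (r < nr) pl[[length(pl) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
    }
  }
  pairs <- if (length(pl)) do.call(rbind, pl) else matrix(integer(), ncol = 2L)
  graph_from_edge_list(pairs, n_areas = nr * nc)
}
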