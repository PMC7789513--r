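#' Build an adjacency structure from a binary contiguity matrix
#'
#' The spatial prior machinery works off a symmetric binary contiguity
#' matrix W with zero diagonal: `W[i, j] = 1` when areas i and j are
#' neighbours.  The conditional mean of an ICAR effect at area i is the
#' average over its `m_i = sum_j W[i, j]` neighbours and its conditional
#' variance is `sigma2 / m_i`, so every area must have at least one
#' neighbour unless `allow_islands = TRUE`.
#'
#' @param W symmetric binary N x N matrix, zero diagonal; rownames taken as
#'   area ids when present.
#' @param area_ids optional character vector of area ids (length N).
#' @param allow_islands keep areas with no neighbours instead of erroring.
#' @return an object of class `adjacency`: list with `W`, `area_ids`,
#'   `neighbor_counts`, `neighbors` (list of integer index vectors),
#'   `components` (connected-component label per area).
#' @export
adjacency_structure <- function(W, area_ids = NULL, allow_islands = FALSE) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (ncol(W) != n) stop("W must be square")
  if (!all(W %in% c(0, 1))) stop("W entries must be 0 or 1")
  if (any(diag(W) != 0)) stop("W must have a zero diagonal")
  if (!isTRUE(all.equal(W, t(W)))) stop("W must be symmetric")
  storage.mode(W) <- "double"
  if (is.null(area_ids)) area_ids <- rownames(W)
  if (is.null(area_ids)) area_ids <- as.character(seq_len(n))
  if (length(area_ids) != n) stop("area_ids length must match W")
  dimnames(W) <- list(area_ids, area_ids)
  m <- rowSums(W)
  if (!allow_islands && any(m == 0)) {
    stop("island area(s) with no neighbours: ",
         paste(area_ids[m == 0], collapse = ", "),
         " (set allow_islands = TRUE to keep them)")
  }
  nb <- lapply(seq_len(n), function(i) which(W[i, ] == 1))
  structure(list(W = W, area_ids = area_ids,
                 neighbor_counts = as.integer(m),
                 neighbors = nb,
                 components = graph_components(nb, n)),
            class = "adjacency")
}

# connected components by breadth-first search over the neighbour lists
graph_components <- function(nb, n) {
  comp <- integer(n)
  label <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    label <- label + 1L
    queue <- start
    comp[start] <- label
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in nb[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- label
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' Adjacency from an edge list
#'
#' Edges are undirected: each pair is symmetrized and duplicates collapse.
#'
#' @param area_ids character vector of all area ids (defines N and order;
#'   sorted lexicographically to match panel ordering).
#' @param edges two-column matrix or data frame of area-id pairs.
#' @param allow_islands passed to [adjacency_structure()].
#' @return an `adjacency` object.
#' @export
adjacency_from_edges <- function(area_ids, edges, allow_islands = FALSE) {
  area_ids <- sort(as.character(area_ids))
  n <- length(area_ids)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must have two columns")
  from <- as.character(edges[, 1L]); to <- as.character(edges[, 2L])
  unknown <- setdiff(c(from, to), area_ids)
  if (length(unknown) > 0L) {
    stop("unknown area id(s) in edge list: ", paste(unknown, collapse = ", "))
  }
  if (any(from == to)) {
    stop("self-loop edge for area ", from[which(from == to)[1L]])
  }
  W <- matrix(0, n, n, dimnames = list(area_ids, area_ids))
  W[cbind(match(from, area_ids), match(to, area_ids))] <- 1
  W <- pmax(W, t(W))
  adjacency_structure(W, area_ids, allow_islands = allow_islands)
}

#' Read an edge-list CSV (`from_id,to_id`) into an adjacency structure
#' @param path CSV path with header `from_id,to_id`.
#' @param area_ids optional full id set (areas absent from any edge are
#'   islands); defaults to the ids appearing in the file.
#' @param allow_islands passed through.
#' @return an `adjacency` object.
#' @export
read_edges <- function(path, area_ids = NULL, allow_islands = FALSE) {
  if (!file.exists(path)) stop("edge file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(area_ids)) area_ids <- unique(c(df[[1L]], df[[2L]]))
  adjacency_from_edges(area_ids, df[, 1:2], allow_islands = allow_islands)
}

#' Write an adjacency structure as an edge-list CSV
#' @param adj an `adjacency` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(adj, path) {
  stopifnot(inherits(adj, "adjacency"))
  idx <- which(upper.tri(adj$W) & adj$W == 1, arr.ind = TRUE)
  df <- data.frame(from_id = adj$area_ids[idx[, 1L]],
                   to_id = adj$area_ids[idx[, 2L]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Contiguity from GeoJSON polygons
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features (with
#' an `area_id` property) and derives contiguity from shared boundary
#' vertices: two areas are queen neighbours when their boundaries share at
#' least one vertex (after snapping coordinates to `tol`), and rook
#' neighbours when they share a whole boundary segment (two consecutive
#' vertices).  This vertex-based rule is exact for tessellations whose
#' shared boundaries carry matching vertices (regular grids, shared-border
#' administrative layers); boundaries digitized with non-matching vertex
#' chains should be pre-snapped or supplied as an edge list instead.
#'
#' @param path GeoJSON file path.
#' @param contiguity `"queen"` (any shared boundary point) or `"rook"`
#'   (shared boundary segment).
#' @param id_property feature property holding the area id.
#' @param tol coordinate snapping tolerance.
#' @param allow_islands passed to [adjacency_structure()].
#' @return an `adjacency` object.
#' @export
adjacency_from_geojson <- function(path, contiguity = c("queen", "rook"),
                                   id_property = "area_id", tol = 1e-8,
                                   allow_islands = FALSE) {
  contiguity <- match.arg(contiguity)
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  ids <- character(0)
  verts <- list()   # per feature: matrix of snapped vertices
  segs <- list()    # per feature: character keys of boundary segments
  for (f in gj$features) {
    id <- f$properties[[id_property]]
    if (is.null(id)) stop("feature missing property '", id_property, "'")
    geom <- f$geometry
    if (is.null(geom$type) || !geom$type %in% c("Polygon", "MultiPolygon")) {
      stop("area ", id, ": geometry must be Polygon or MultiPolygon")
    }
    polys <- if (geom$type == "Polygon") list(geom$coordinates) else
      geom$coordinates
    vv <- NULL; ss <- character(0)
    for (poly in polys) {
      for (ring in poly) {
        pts <- do.call(rbind, lapply(ring, function(p) {
          c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))
        }))
        if (nrow(pts) < 4L) stop("area ", id, ": degenerate ring")
        pts <- round(pts / tol) * tol
        vv <- rbind(vv, pts)
        vkey <- paste(pts[, 1L], pts[, 2L], sep = ",")
        # consecutive-vertex segments, direction-normalized
        a <- vkey[-length(vkey)]; b <- vkey[-1L]
        ss <- c(ss, ifelse(a < b, paste(a, b, sep = "|"),
                           paste(b, a, sep = "|")))
      }
    }
    ids <- c(ids, as.character(id))
    verts[[length(verts) + 1L]] <-
      unique(paste(vv[, 1L], vv[, 2L], sep = ","))
    segs[[length(segs) + 1L]] <- unique(ss)
  }
  if (anyDuplicated(ids)) stop("duplicate area ids in GeoJSON")
  ord <- order(ids)
  ids <- ids[ord]; verts <- verts[ord]; segs <- segs[ord]
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      touch <- if (contiguity == "queen") {
        length(intersect(verts[[i]], verts[[j]])) > 0L
      } else {
        length(intersect(segs[[i]], segs[[j]])) > 0L
      }
      if (touch) W[i, j] <- W[j, i] <- 1
    }
  }
  adjacency_structure(W, ids, allow_islands = allow_islands)
}

#' Read / write WinBUGS-style adjacency lists
#'
#' Legacy disease-mapping scripts exchange adjacency as the three arrays
#' `num` (neighbour count per area), `adj` (concatenated neighbour indices)
#' and `sumNumNeigh`.  The text format accepted here is a plain file with
#' lines `num: 3 2 ...` and `adj: 2 3 ...` (whitespace-separated integers);
#' `sumNumNeigh` is validated when present.
#'
#' @param path file path.
#' @param area_ids optional ids for the N areas (defaults to "1".."N").
#' @return an `adjacency` object.
#' @export
read_winbugs_adjacency <- function(path, area_ids = NULL) {
  if (!file.exists(path)) stop("adjacency file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  grab <- function(name) {
    m <- regmatches(txt, regexpr(paste0(name, "\\s*:\\s*[0-9 \\t\\n]+"), txt))
    if (length(m) == 0L) return(NULL)
    as.integer(strsplit(sub(paste0(name, "\\s*:\\s*"), "", m), "\\s+")[[1L]])
  }
  num <- grab("num"); adj <- grab("adj")
  if (is.null(num) || is.null(adj)) stop("file must contain 'num:' and 'adj:' arrays")
  if (sum(num) != length(adj)) stop("sum(num) != length(adj)")
  snn <- grab("sumNumNeigh")
  if (!is.null(snn) && snn[1L] != sum(num)) stop("sumNumNeigh mismatch")
  n <- length(num)
  if (is.null(area_ids)) area_ids <- as.character(seq_len(n))
  W <- matrix(0, n, n, dimnames = list(area_ids, area_ids))
  pos <- 0L
  for (i in seq_len(n)) {
    js <- adj[pos + seq_len(num[i])]; pos <- pos + num[i]
    W[i, js] <- 1
  }
  if (!isTRUE(all.equal(W, t(W)))) stop("adjacency list is not symmetric")
  adjacency_structure(W, area_ids)
}

#' @rdname read_winbugs_adjacency
#' @param adj an `adjacency` object (for writing).
#' @export
write_winbugs_adjacency <- function(adj, path) {
  stopifnot(inherits(adj, "adjacency"))
  num <- adj$neighbor_counts
  adj_vec <- unlist(adj$neighbors)
  lines <- c(paste("num:", paste(num, collapse = " ")),
             paste("adj:", paste(adj_vec, collapse = " ")),
             paste("sumNumNeigh:", sum(num)))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.adjacency <- function(x, ...) {
  n <- length(x$area_ids)
  cat(sprintf("Adjacency structure: %d areas, %d edges, %d connected component(s)\n",
              n, sum(x$W) / 2, max(x$components)))
  cat(sprintf("  neighbour counts: min %d, median %g, max %d\n",
              min(x$neighbor_counts), stats::median(x$neighbor_counts),
              max(x$neighbor_counts)))
  invisible(x)
}
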