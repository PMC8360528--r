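#' Construct a validated triangle mesh
#'
#' Builds a \code{triangle_mesh} object from a vertex table and a face
#' table, enforcing the invariants every downstream routine relies on:
#' triangular faces with valid, non-repeated indices, a consistent
#' counter-clockwise orientation, manifoldness, and disk topology
#' (Euler characteristic \eqn{V - E + F = 1} with exactly one boundary
#' loop). Degenerate (near zero-area) faces are rejected.
#'
#' @param vertices numeric matrix, one row per vertex, 2 or 3 columns.
#' @param faces integer matrix, one row per face, 3 columns of 1-based
#'   vertex indices.
#' @param check_disk logical; if \code{TRUE} (default) require disk
#'   topology and a single boundary loop.
#' @param area_eps degenerate-face threshold as a fraction of the mean
#'   face area.
#' @return An object of class \code{triangle_mesh}: a list with
#'   \code{vertices}, \code{faces} (consistently oriented, CCW for planar
#'   meshes) and \code{boundary_loop} (ordered vertex indices; for CCW
#'   faces the loop runs counter-clockwise with the interior on its left).
#' @export
triangle_mesh <- function(vertices, faces, check_disk = TRUE, area_eps = 1e-12) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L)
    stop("non-triangular face: faces must have exactly 3 vertices")
  nv <- nrow(vertices)
  if (!(ncol(vertices) %in% c(2L, 3L)))
    stop("vertices must have 2 or 3 coordinate columns")
  if (any(faces < 1L) || any(faces > nv))
    stop("face index out of range: every face index must be a valid vertex index")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]))
    stop("degenerate face: repeated vertex index within a face")

  a <- face_areas(vertices, faces)
  if (any(a < area_eps * mean(a)))
    stop(sprintf("degenerate face: %d face(s) with area below %g of the mean (faces %s)",
                 sum(a < area_eps * mean(a)), area_eps,
                 paste(utils::head(which(a < area_eps * mean(a)), 5), collapse = ", ")))

  faces <- orient_faces(vertices, faces)
  bl <- boundary_loops(faces)
  if (check_disk) {
    ne <- nrow(mesh_edges(faces))
    chi <- nv - ne + nrow(faces)
    if (length(bl) != 1L)
      stop(sprintf("not a disk: found %d boundary loops (lengths %s)",
                   length(bl), paste(vapply(bl, length, 1L), collapse = ", ")))
    if (chi != 1L)
      stop(sprintf("not a disk: Euler characteristic V - E + F = %d (expected 1)", chi))
  }
  structure(list(vertices = vertices, faces = faces,
                 boundary_loop = if (length(bl)) bl[[1]] else integer(0)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, boundary loop of %d vertices (%dD)\n",
              nrow(x$vertices), nrow(x$faces), length(x$boundary_loop), ncol(x$vertices)))
  invisible(x)
}

# unsigned face areas, 2D or 3D
face_areas <- function(vertices, faces) {
  p1 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - p1
  e2 <- vertices[faces[, 3], , drop = FALSE] - p1
  if (ncol(vertices) == 2L) {
    abs(e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  } else {
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
}

#' Signed areas of faces under a 2D embedding
#'
#' @param coords numeric n x 2 matrix (or complex vector) of per-vertex
#'   2D positions.
#' @param faces integer face matrix.
#' @return numeric vector of signed areas (positive = counter-clockwise).
#' @export
signed_areas <- function(coords, faces) {
  coords <- as_coord_matrix(coords)
  p1 <- coords[faces[, 1], , drop = FALSE]
  p2 <- coords[faces[, 2], , drop = FALSE]
  p3 <- coords[faces[, 3], , drop = FALSE]
  ((p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
   (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])) / 2
}

# accept complex vectors or n x 2 matrices everywhere 2D coordinates occur
as_coord_matrix <- function(x) {
  if (is.complex(x)) return(cbind(Re(x), Im(x)))
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("2D coordinates required (n x 2 matrix or complex vector)")
  x
}

as_complex_coords <- function(x) {
  if (is.complex(x)) return(x)
  x <- as.matrix(x)
  complex(real = x[, 1], imaginary = x[, 2])
}

# undirected edge list (2-column, sorted within row, unique)
mesh_edges <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

# Make face orientation globally consistent by region growing over the
# face-adjacency graph; for 2D meshes additionally flip everything so the
# total signed area is positive (counter-clockwise convention).
orient_faces <- function(vertices, faces) {
  nf <- nrow(faces)
  # directed half-edge table: face id + directed edge
  he <- data.frame(f = rep(seq_len(nf), 3L),
                   a = c(faces[, 1], faces[, 2], faces[, 3]),
                   b = c(faces[, 2], faces[, 3], faces[, 1]))
  ekey <- paste(pmin(he$a, he$b), pmax(he$a, he$b))
  ef <- split(seq_len(nrow(he)), ekey)
  if (any(vapply(ef, length, 1L) > 2L))
    stop("non-manifold mesh: an edge is shared by more than two faces")
  # adjacency with relative-orientation flag: same directed edge twice => one
  # face must flip
  adj <- vector("list", nf)
  for (ii in ef) {
    if (length(ii) == 2L) {
      f1 <- he$f[ii[1]]; f2 <- he$f[ii[2]]
      same_dir <- he$a[ii[1]] == he$a[ii[2]]  # both traverse edge identically
      adj[[f1]] <- rbind(adj[[f1]], c(f2, same_dir))
      adj[[f2]] <- rbind(adj[[f2]], c(f1, same_dir))
    }
  }
  flip <- rep(NA, nf)
  for (seed in seq_len(nf)) {
    if (!is.na(flip[seed])) next
    flip[seed] <- FALSE
    queue <- seed
    while (length(queue)) {
      f <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[f]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        g <- nb[r, 1]; same <- nb[r, 2] == 1
        want <- if (same) !flip[f] else flip[f]
        if (is.na(flip[g])) {
          flip[g] <- want
          queue <- c(queue, g)
        } else if (flip[g] != want) {
          stop("mesh is not orientable")
        }
      }
    }
  }
  faces[flip, c(2, 3)] <- faces[flip, c(3, 2)]
  if (ncol(vertices) == 2L && sum(signed_areas(vertices, faces)) < 0)
    faces[, c(2, 3)] <- faces[, c(3, 2)]
  faces
}

# ordered boundary loops following face orientation (directed boundary
# half-edges; for CCW faces each loop is traversed with the interior on
# the left)
boundary_loops <- function(faces) {
  he <- cbind(c(faces[, 1], faces[, 2], faces[, 3]),
              c(faces[, 2], faces[, 3], faces[, 1]))
  ekey <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(ekey)
  bdry <- he[cnt[ekey] == 1L, , drop = FALSE]
  if (nrow(bdry) == 0L) return(list())
  nxt <- stats::setNames(bdry[, 2], as.character(bdry[, 1]))
  if (anyDuplicated(bdry[, 1]))
    stop("non-manifold boundary: a vertex starts two boundary edges")
  seen <- rep(FALSE, nrow(bdry))
  names(seen) <- as.character(bdry[, 1])
  loops <- list()
  for (s in as.character(bdry[, 1])) {
    if (seen[s]) next
    loop <- integer(0)
    v <- s
    repeat {
      seen[v] <- TRUE
      loop <- c(loop, as.integer(v))
      v <- as.character(nxt[[v]])
      if (identical(v, s)) break
      if (is.null(nxt[[v]])) stop("open boundary chain: boundary is not a closed loop")
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

#' Count flipped faces between two 2D embeddings of a mesh
#'
#' A face is flipped when its signed area in the target embedding has the
#' opposite sign to its signed area in the source (parametric) embedding,
#' i.e. the mapping reverses its orientation. Faces that are degenerate in
#' the source (area within \code{tol} of zero) are flagged separately and
#' never counted as flipped.
#'
#' @param param per-vertex source 2D coordinates (n x 2 matrix or complex).
#' @param mapped per-vertex target 2D coordinates.
#' @param faces integer face matrix.
#' @param tol absolute tolerance below which a source face counts as
#'   degenerate.
#' @return list with \code{count}, logical per-face \code{flipped}, and
#'   logical per-face \code{degenerate}.
#' @export
count_flipped <- function(param, mapped, faces, tol = 0) {
  sa_src <- signed_areas(param, faces)
  sa_dst <- signed_areas(mapped, faces)
  degen <- abs(sa_src) <= tol
  flipped <- (sa_src * sa_dst < 0) & !degen
  list(count = sum(flipped), flipped = flipped, degenerate = degen)
}

#' Extract a geodesic disk patch around a center vertex
#'
#' Keeps every vertex whose graph-geodesic distance (Dijkstra on the edge
#' graph, weighted by Euclidean edge length) to \code{center} is at most
#' \code{radius}, restricted to faces whose three corners all survive, and
#' then to the connected component containing the center. The result must
#' be a disk; extra boundary loops (holes) raise an error.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param center vertex index.
#' @param radius geodesic radius in mesh length units.
#' @return a \code{triangle_mesh} for the patch, with attribute
#'   \code{vertex_map} giving original vertex indices.
#' @export
cut_geodesic_disk <- function(mesh, center, radius) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (radius <= 0) stop("radius must be positive")
  nv <- nrow(mesh$vertices)
  if (center < 1 || center > nv) stop("center is not a valid vertex index")
  d <- geodesic_distances(mesh, center)
  keep <- which(d <= radius)
  fkeep <- mesh$faces[rowSums(matrix(mesh$faces %in% keep, ncol = 3)) == 3L, , drop = FALSE]
  if (nrow(fkeep) == 0L)
    stop("empty patch: no face has all three vertices within the requested radius")
  # component containing center, on the kept faces
  g <- igraph::graph_from_edgelist(mesh_edges(fkeep), directed = FALSE)
  comp <- igraph::components(g)$membership
  if (length(comp) < center || is.na(comp[center]))
    stop("empty patch: center vertex has no surviving incident face")
  vkeep <- sort(which(comp == comp[center]))
  fkeep <- fkeep[rowSums(matrix(fkeep %in% vkeep, ncol = 3)) == 3L, , drop = FALSE]
  remap <- integer(nv); remap[vkeep] <- seq_along(vkeep)
  sub <- triangle_mesh(mesh$vertices[vkeep, , drop = FALSE],
                       matrix(remap[fkeep], ncol = 3L))
  attr(sub, "vertex_map") <- vkeep
  sub
}

#' Graph-geodesic distances from a source vertex
#'
#' Dijkstra shortest paths on the mesh edge graph with Euclidean edge
#' lengths as weights.
#'
#' @param mesh a \code{triangle_mesh}.
#' @param from source vertex index.
#' @return numeric vector of distances to every vertex.
#' @export
geodesic_distances <- function(mesh, from) {
  e <- mesh_edges(mesh$faces)
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  as.numeric(igraph::distances(g, v = from, weights = w))
}
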