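#' Tetrahedral mesh container
#'
#' A `tet_mesh` bundles node coordinates (mm), 4-node tetrahedral
#' connectivity, a per-element tissue label and named node sets.
#' Node and element indices are 1-based throughout the package and
#' converted to the 0-based convention only at the VTK file boundary.
#'
#' @param nodes numeric matrix, one row per node, columns x, y, z (mm).
#' @param elems integer matrix, one row per element, 4 node indices with
#'   consistent positive orientation (volume > 0).
#' @param tissue character vector, one label per element, drawn from
#'   `cortical`, `trabecular`, `suture`, `tooth`, `pulp`, `pdl`.
#' @param node_sets named list of integer vectors of node indices.
#' @param param optional matrix of flat ("parametric") node coordinates
#'   kept alongside arched/distorted geometry; used for region labelling
#'   and site snapping.
#' @param check validate invariants (positive volumes, label domain,
#'   index bounds)? Default `TRUE`.
#'
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, elems, tissue = NULL, node_sets = list(),
                     param = NULL, check = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  colnames(nodes) <- c("x", "y", "z")
  elems <- as.matrix(elems)
  storage.mode(elems) <- "integer"
  if (ncol(nodes) != 3L) abort("`nodes` must have 3 columns (x, y, z)")
  if (ncol(elems) != 4L) abort("`elems` must have 4 columns (tet4 connectivity)")
  if (is.null(tissue)) tissue <- rep("cortical", nrow(elems))
  tissue <- as.character(tissue)
  mesh <- structure(
    list(nodes = nodes, elems = elems, tissue = tissue,
         node_sets = node_sets, param = param),
    class = "tet_mesh"
  )
  if (check) validate_tet_mesh(mesh)
  mesh
}

validate_tet_mesh <- function(mesh) {
  n <- nrow(mesh$nodes)
  if (any(mesh$elems < 1L) || any(mesh$elems > n))
    abort("element connectivity references node indices out of range")
  if (length(mesh$tissue) != nrow(mesh$elems))
    abort("`tissue` must have one label per element")
  bad <- setdiff(unique(mesh$tissue), TISSUE_LEVELS)
  if (length(bad))
    abort(paste0("unknown tissue label(s): ", paste(bad, collapse = ", ")))
  v <- tet_volumes(mesh)
  if (any(v <= 0)) {
    abort(paste0("non-positive element volume in element(s): ",
                 paste(head(which(v <= 0), 5L), collapse = ", ")))
  }
  for (nm in names(mesh$node_sets)) {
    s <- mesh$node_sets[[nm]]
    if (length(s) == 0L) abort(paste0("node set '", nm, "' is empty"))
    if (any(s < 1L) || any(s > n))
      abort(paste0("node set '", nm, "' references invalid node indices"))
  }
  invisible(mesh)
}

#' Signed tetrahedron volumes
#'
#' @param mesh a `tet_mesh`, or a node coordinate matrix if `elems` given.
#' @param elems optional connectivity matrix when `mesh` is a matrix.
#' @return numeric vector of volumes (mm^3), positive for well-oriented tets.
#' @export
tet_volumes <- function(mesh, elems = NULL) {
  if (inherits(mesh, "tet_mesh")) {
    nodes <- mesh$nodes; elems <- mesh$elems
  } else {
    nodes <- mesh
  }
  a <- nodes[elems[, 2L], , drop = FALSE] - nodes[elems[, 1L], , drop = FALSE]
  b <- nodes[elems[, 3L], , drop = FALSE] - nodes[elems[, 1L], , drop = FALSE]
  c_ <- nodes[elems[, 4L], , drop = FALSE] - nodes[elems[, 1L], , drop = FALSE]
  ## scalar triple product a . (b x c) / 6
  (a[, 1L] * (b[, 2L] * c_[, 3L] - b[, 3L] * c_[, 2L]) +
   a[, 2L] * (b[, 3L] * c_[, 1L] - b[, 1L] * c_[, 3L]) +
   a[, 3L] * (b[, 1L] * c_[, 2L] - b[, 2L] * c_[, 1L])) / 6
}

#' Element centroids
#' @param mesh a `tet_mesh`.
#' @param space `"geom"` for actual coordinates, `"param"` for the flat
#'   parametric coordinates when present.
#' @return numeric matrix, one row per element.
#' @export
element_centroids <- function(mesh, space = c("geom", "param")) {
  space <- match.arg(space)
  nodes <- if (space == "param" && !is.null(mesh$param)) mesh$param else mesh$nodes
  (nodes[mesh$elems[, 1L], , drop = FALSE] +
   nodes[mesh$elems[, 2L], , drop = FALSE] +
   nodes[mesh$elems[, 3L], , drop = FALSE] +
   nodes[mesh$elems[, 4L], , drop = FALSE]) / 4
}

## The four faces of each tet, as a (4m) x 3 matrix of node triples plus
## the owning element index. Face node order is outward for positive tets.
tet_faces <- function(elems) {
  f <- rbind(elems[, c(1L, 3L, 2L), drop = FALSE],
             elems[, c(1L, 2L, 4L), drop = FALSE],
             elems[, c(2L, 3L, 4L), drop = FALSE],
             elems[, c(1L, 4L, 3L), drop = FALSE])
  list(faces = f, elem = rep.int(seq_len(nrow(elems)), 4L))
}

## Encode sorted node triples into a single double key (safe for < 2^17 nodes:
## max key ~ n^3 < 2^53).
face_keys <- function(faces, n_nodes) {
  ## branch-free 3-way sort of each node triple
  a <- faces[, 1L]; b <- faces[, 2L]; c_ <- faces[, 3L]
  lo <- pmin(a, b, c_); hi <- pmax(a, b, c_)
  mid <- a + b + c_ - lo - hi
  as.numeric(lo) + as.numeric(mid) * n_nodes + as.numeric(hi) * n_nodes^2
}

#' Boundary (surface) triangles of a mesh
#'
#' A triangular face is on the surface iff it belongs to exactly one
#' tetrahedron; every interior face must be shared by exactly two.
#'
#' @param mesh a `tet_mesh`.
#' @return list with `faces` (matrix of node triples, outward-ordered) and
#'   `elem` (owning element index per face).
#' @export
surface_faces <- function(mesh) {
  tf <- tet_faces(mesh$elems)
  key <- face_keys(tf$faces, nrow(mesh$nodes))
  cnt <- table_counts(key)
  once <- cnt$count[match(key, cnt$key)] == 1L
  list(faces = tf$faces[once, , drop = FALSE], elem = tf$elem[once])
}

## counts of a numeric key vector without string coercion
table_counts <- function(key) {
  o <- order(key)
  k <- key[o]
  new_grp <- c(TRUE, k[-1L] != k[-length(k)])
  grp_id <- cumsum(new_grp)
  list(key = k[new_grp], count = tabulate(grp_id))
}

#' Surface node indices
#' @param mesh a `tet_mesh`.
#' @return sorted integer vector of node indices lying on boundary faces.
#' @export
surface_nodes <- function(mesh) {
  sort(unique(as.vector(surface_faces(mesh)$faces)))
}

#' Check that every interior face is shared by exactly two tets
#' @param mesh a `tet_mesh`.
#' @return `TRUE` invisibly, or an error describing the defect.
#' @export
check_conformity <- function(mesh) {
  tf <- tet_faces(mesh$elems)
  key <- face_keys(tf$faces, nrow(mesh$nodes))
  cnt <- table_counts(key)
  if (any(cnt$count > 2L))
    abort("non-conforming mesh: a face is shared by more than two tets")
  invisible(TRUE)
}

#' Is the mesh a single connected component?
#' @param mesh a `tet_mesh`.
#' @return logical scalar.
#' @export
is_connected <- function(mesh) {
  e <- mesh$elems
  edges <- rbind(cbind(e[, 1L], e[, 2L]),
                 cbind(e[, 1L], e[, 3L]),
                 cbind(e[, 1L], e[, 4L]))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(mesh$nodes) - igraph::vcount(g)))
  igraph::count_components(g) == 1L
}

#' Nearest mesh node to a point
#'
#' Snapping is done in parametric (flat) coordinates when available, so
#' that anatomical landmarks survive arching and distortion. Ties break
#' to the lowest node index.
#'
#' @param mesh a `tet_mesh`.
#' @param point numeric length-3.
#' @param candidates optional subset of node indices to search.
#' @return integer node index.
#' @export
snap_node <- function(mesh, point, candidates = NULL) {
  nodes <- if (!is.null(mesh$param)) mesh$param else mesh$nodes
  idx <- candidates %||% seq_len(nrow(nodes))
  d2 <- (nodes[idx, 1L] - point[1L])^2 + (nodes[idx, 2L] - point[2L])^2 +
    (nodes[idx, 3L] - point[3L])^2
  idx[which.min(d2)]
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("<tet_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$elems),
      " tet4 elements\n", sep = "")
  tab <- table(factor(x$tissue, levels = TISSUE_LEVELS))
  tab <- tab[tab > 0]
  cat("  tissues: ",
      paste0(names(tab), " (", as.integer(tab), ")", collapse = ", "), "\n",
      sep = "")
  if (length(x$node_sets))
    cat("  node sets: ", paste(names(x$node_sets), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Nodes of a mesh as a tibble
#' @param mesh a `tet_mesh`.
#' @return tibble with columns `node`, `x`, `y`, `z`.
#' @export
tidy_nodes <- function(mesh) {
  tibble(node = seq_len(nrow(mesh$nodes)),
         x = mesh$nodes[, 1L], y = mesh$nodes[, 2L], z = mesh$nodes[, 3L])
}

#' Elements of a mesh as a tibble
#' @param mesh a `tet_mesh`.
#' @return tibble with connectivity, tissue label and volume per element.
#' @export
tidy_elements <- function(mesh) {
  tibble(element = seq_len(nrow(mesh$elems)),
         n1 = mesh$elems[, 1L], n2 = mesh$elems[, 2L],
         n3 = mesh$elems[, 3L], n4 = mesh$elems[, 4L],
         tissue = mesh$tissue,
         volume = tet_volumes(mesh))
}

#' Relabel suture elements as cortical bone
#'
#' Produces the "fused" geometry interpretation: same mesh, with every
#' suture element re-written to cortical. Used to cross-check the fused
#' material variant, which must give a bit-identical stiffness matrix.
#'
#' @param mesh a `tet_mesh`.
#' @return a `tet_mesh` with no suture-labelled elements.
#' @export
relabel_sutures_cortical <- function(mesh) {
  mesh$tissue[mesh$tissue == "suture"] <- "cortical"
  mesh
}
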