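## Legacy ASCII VTK unstructured-grid I/O. Hand-written because no
## pre-installed R package speaks this format; the writer emits 9
## significant digits so a write/read round trip preserves values to
## well under 1e-6 relative.

fmt_num <- function(x) formatC(x, format = "g", digits = 9)

#' Write a mesh and result fields to a legacy ASCII VTK file
#'
#' Emits a `DATASET UNSTRUCTURED_GRID` with the tetrahedral connectivity
#' (VTK cell type 10, 0-based indices on disk), the tissue label as an
#' integer cell array, any per-element scalar fields as `CELL_DATA` and
#' any per-node scalars/vectors as `POINT_DATA`. Node sets are encoded
#' as 0/1 integer point masks named `set_<name>`.
#'
#' @param mesh a `tet_mesh`.
#' @param path output file path.
#' @param cell_data named list of numeric vectors (one value per
#'   element). `NA` values are written as 0 with a companion
#'   `<name>_defined` mask.
#' @param point_data named list of numeric vectors (length n) or
#'   matrices (n x 3, written as VECTORS).
#' @param include_sets write node sets as point masks? Default `TRUE`.
#' @param title dataset title line.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(mesh, path, cell_data = list(), point_data = list(),
                       include_sets = TRUE, title = "suturefe phantom") {
  n <- nrow(mesh$nodes); m <- nrow(mesh$elems)
  for (nm in names(cell_data))
    if (length(cell_data[[nm]]) != m)
      abort(paste0("cell_data '", nm, "' is not sized to the mesh"))
  con <- tryCatch(suppressWarnings(file(path, open = "w")),
                  error = function(e) abort(paste0("cannot write '", path, "'")))
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# vtk DataFile Version 3.0", title, "ASCII", "DATASET UNSTRUCTURED_GRID")
  w(paste("POINTS", n, "double"))
  w(paste(fmt_num(mesh$nodes[, 1L]), fmt_num(mesh$nodes[, 2L]),
          fmt_num(mesh$nodes[, 3L])))
  w(paste("CELLS", m, 5L * m))
  e0 <- mesh$elems - 1L
  w(paste(4L, e0[, 1L], e0[, 2L], e0[, 3L], e0[, 4L]))
  w(paste("CELL_TYPES", m))
  w(as.character(rep(10L, m)))

  w(paste("CELL_DATA", m))
  w("SCALARS tissue int 1", "LOOKUP_TABLE default")
  w(as.character(match(mesh$tissue, TISSUE_LEVELS) - 1L))
  for (nm in names(cell_data)) {
    v <- cell_data[[nm]]
    if (anyNA(v)) {
      w(paste("SCALARS", paste0(nm, "_defined"), "int 1"), "LOOKUP_TABLE default")
      w(as.character(as.integer(!is.na(v))))
      v[is.na(v)] <- 0
    }
    w(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default")
    w(fmt_num(v))
  }

  masks <- list()
  if (include_sets) {
    for (nm in names(mesh$node_sets)) {
      mask <- integer(n)
      mask[mesh$node_sets[[nm]]] <- 1L
      masks[[paste0("set_", nm)]] <- mask
    }
  }
  if (length(point_data) || length(masks)) {
    w(paste("POINT_DATA", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        if (nrow(v) != n || ncol(v) != 3L)
          abort(paste0("point_data '", nm, "' must be n x 3"))
        w(paste("VECTORS", nm, "double"))
        w(paste(fmt_num(v[, 1L]), fmt_num(v[, 2L]), fmt_num(v[, 3L])))
      } else {
        if (length(v) != n)
          abort(paste0("point_data '", nm, "' is not sized to the mesh"))
        w(paste("SCALARS", nm, "double 1"), "LOOKUP_TABLE default")
        w(fmt_num(v))
      }
    }
    for (nm in names(masks)) {
      w(paste("SCALARS", nm, "int 1"), "LOOKUP_TABLE default")
      w(as.character(masks[[nm]]))
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK unstructured grid
#'
#' Minimal reader for the files [export_vtk()] writes (and any
#' tet-only legacy ASCII unstructured grid): points, tet cells, scalar
#' and vector cell/point data. Node-set masks (`set_*`) are decoded
#' back into node sets.
#'
#' @param path VTK file path.
#' @return list with `mesh` (a `tet_mesh`), `cell_data` and
#'   `point_data` (named lists).
#' @export
read_vtk <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "",
               skip = 4L)
  pos <- 1L
  peek <- function() toks[pos]
  take <- function(k = 1L) {
    out <- toks[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  expect <- function(word) {
    got <- take()
    if (!identical(toupper(got), word))
      abort(paste0("VTK parse error: expected ", word, ", got ", got))
  }
  expect("POINTS")
  n <- as.integer(take()); take()       # dtype
  pts <- matrix(as.numeric(take(3L * n)), ncol = 3L, byrow = TRUE)
  expect("CELLS")
  m <- as.integer(take()); take()       # total ints
  cells <- matrix(as.integer(take(5L * m)), ncol = 5L, byrow = TRUE)
  if (any(cells[, 1L] != 4L)) abort("only tet4 cells are supported")
  elems <- cells[, 2:5, drop = FALSE] + 1L
  expect("CELL_TYPES")
  take(1L + m)
  cell_data <- list(); point_data <- list(); sets <- list()
  tissue <- NULL
  section <- NULL
  while (pos <= length(toks)) {
    kw <- toupper(peek())
    if (kw %in% c("CELL_DATA", "POINT_DATA")) {
      section <- kw
      take(2L)
    } else if (kw == "SCALARS") {
      take()
      nm <- take(); take()                     # dtype
      if (grepl("^[0-9]+$", peek())) take()    # optional numComp
      expect("LOOKUP_TABLE"); take()
      len <- if (section == "CELL_DATA") m else n
      vals <- as.numeric(take(len))
      if (nm == "tissue") {
        tissue <- TISSUE_LEVELS[as.integer(vals) + 1L]
      } else if (startsWith(nm, "set_")) {
        sets[[substring(nm, 5L)]] <- which(vals != 0)
      } else if (section == "CELL_DATA") {
        cell_data[[nm]] <- vals
      } else {
        point_data[[nm]] <- vals
      }
    } else if (kw == "VECTORS") {
      take()
      nm <- take(); take()
      len <- if (section == "CELL_DATA") m else n
      point_data[[nm]] <- matrix(as.numeric(take(3L * len)), ncol = 3L,
                                 byrow = TRUE)
    } else {
      abort(paste0("VTK parse error: unexpected token ", peek()))
    }
  }
  mesh <- tet_mesh(pts, elems, tissue = tissue, node_sets = sets,
                   check = FALSE)
  list(mesh = mesh, cell_data = cell_data, point_data = point_data)
}
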