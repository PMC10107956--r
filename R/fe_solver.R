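#' Single-element stiffness matrix of a linear tetrahedron
#'
#' Constant-strain TET4 stiffness `K_e = V * B' D B` with the isotropic
#' elasticity matrix D built from the Lame parameters. DOF ordering is
#' node-major: (n1x, n1y, n1z, n2x, ...). The result is symmetric
#' positive semi-definite with exactly six zero eigenvalues (the rigid
#' modes).
#'
#' @param coords 4 x 3 node coordinate matrix (mm).
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 12 x 12 stiffness matrix (N/mm).
#' @export
element_stiffness_tet4 <- function(coords, E, nu) {
  coords <- as.matrix(coords)
  J <- coords[2:4, ] - matrix(coords[1L, ], 3L, 3L, byrow = TRUE)
  detJ <- det(J)
  V <- detJ / 6
  if (V <= 0) abort("degenerate tetrahedron (volume <= 0)")
  M <- solve(J)                       # columns are grad N2, grad N3, grad N4
  g <- cbind(-rowSums(M), M)          # 3 x 4, column a = grad N_a
  B <- matrix(0, 6L, 12L)
  for (a in 1:4) {
    c0 <- 3L * (a - 1L)
    bx <- g[1L, a]; by <- g[2L, a]; bz <- g[3L, a]
    B[1L, c0 + 1L] <- bx
    B[2L, c0 + 2L] <- by
    B[3L, c0 + 3L] <- bz
    B[4L, c0 + 1L] <- by; B[4L, c0 + 2L] <- bx
    B[5L, c0 + 2L] <- bz; B[5L, c0 + 3L] <- by
    B[6L, c0 + 1L] <- bz; B[6L, c0 + 3L] <- bx
  }
  lp <- lame_parameters(E, nu)
  D <- matrix(0, 6L, 6L)
  D[1:3, 1:3] <- lp$lambda
  diag(D)[1:3] <- lp$lambda + 2 * lp$mu
  diag(D)[4:6] <- lp$mu
  V * crossprod(B, D %*% B)
}

## Per-element shape-function gradients and volumes, vectorised.
## Returns gx, gy, gz as m x 4 matrices (column a = component of grad N_a)
## with grad N1 computed as the exact negative sum of the others, so that
## partition of unity holds to the last bit.
shape_gradients <- function(mesh) {
  nodes <- mesh$nodes; elems <- mesh$elems
  p1 <- nodes[elems[, 1L], , drop = FALSE]
  e2 <- nodes[elems[, 2L], , drop = FALSE] - p1
  e3 <- nodes[elems[, 3L], , drop = FALSE] - p1
  e4 <- nodes[elems[, 4L], , drop = FALSE] - p1
  cr <- function(a, b) cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
                             a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
                             a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
  c34 <- cr(e3, e4)
  detJ <- rowSums(e2 * c34)           # 6V
  if (any(detJ <= 0)) abort("degenerate element in mesh (volume <= 0)")
  g2 <- c34 / detJ
  g3 <- cr(e4, e2) / detJ
  g4 <- cr(e2, e3) / detJ
  g1 <- -(g2 + g3 + g4)
  list(gx = cbind(g1[, 1L], g2[, 1L], g3[, 1L], g4[, 1L]),
       gy = cbind(g1[, 2L], g2[, 2L], g3[, 2L], g4[, 2L]),
       gz = cbind(g1[, 3L], g2[, 3L], g3[, 3L], g4[, 3L]),
       volume = detJ / 6)
}

#' Assemble the global sparse stiffness matrix
#'
#' Sums the per-element TET4 stiffness contributions into a symmetric
#' sparse matrix of size `3 * n_nodes`, with per-element Lame parameters
#' looked up from the tissue label. Uses the closed-form isotropic
#' entry `K[(a,i),(b,j)] = V (lambda g_ai g_bj + mu g_aj g_bi +
#' delta_ij mu g_a . g_b)`, vectorised over elements.
#'
#' @param mesh a labelled `tet_mesh`.
#' @param materials a `material_table`.
#' @return a `dsCMatrix` stiffness (N/mm).
#' @export
assemble_stiffness <- function(mesh, materials) {
  idx <- match(mesh$tissue, materials$tissue)
  if (anyNA(idx)) {
    missing_lab <- unique(mesh$tissue[is.na(idx)])
    abort(paste0("no material for tissue label(s): ",
                 paste(missing_lab, collapse = ", ")))
  }
  lp <- lame_parameters(materials$E[idx], materials$nu[idx])
  sg <- shape_gradients(mesh)
  g <- list(sg$gx, sg$gy, sg$gz)      # g[[i]][, a] = (grad N_a)_i
  V <- sg$volume
  lamV <- lp$lambda * V
  muV <- lp$mu * V
  m <- nrow(mesh$elems)
  n_trip <- 144L * m
  ii <- integer(n_trip); jj <- integer(n_trip); xx <- numeric(n_trip)
  pos <- 0L
  dof <- function(a, i) 3L * (mesh$elems[, a] - 1L) + i
  for (a in 1:4) for (b in 1:4) {
    dot_ab <- sg$gx[, a] * sg$gx[, b] + sg$gy[, a] * sg$gy[, b] +
      sg$gz[, a] * sg$gz[, b]
    for (i in 1:3) {
      ga_i <- g[[i]][, a]
      for (j in 1:3) {
        val <- lamV * ga_i * g[[j]][, b] + muV * g[[j]][, a] * g[[i]][, b]
        if (i == j) val <- val + muV * dot_ab
        rng <- pos + seq_len(m)
        ii[rng] <- dof(a, i)
        jj[rng] <- dof(b, j)
        xx[rng] <- val
        pos <- pos + m
      }
    }
  }
  ndof <- 3L * nrow(mesh$nodes)
  K <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(ndof, ndof))
  forceSymmetric(K)
}

#' Load case: nodal forces and displacement constraints
#'
#' Encodes one bite scenario for the solver: point forces plus
#' single-DOF or all-DOF zero-displacement constraints (non-zero
#' prescribed values are supported for verification problems such as
#' the patch test). A DOF may not be both loaded and constrained.
#'
#' @param name load case name (`incisor_bilateral`, `molar_unilateral`
#'   or `custom`).
#' @param loads tibble with columns `node`, `fx`, `fy`, `fz` (N);
#'   duplicate nodes are summed.
#' @param fixed tibble with columns `node`, `axis` (`"x"`, `"y"`, `"z"`)
#'   and optional `value` (mm, default 0).
#' @return object of class `load_case`.
#' @export
load_case <- function(name, loads, fixed) {
  loads <- as_tibble(loads)
  fixed <- as_tibble(fixed)
  if (!all(c("node", "fx", "fy", "fz") %in% names(loads)))
    abort("`loads` needs columns node, fx, fy, fz")
  if (!all(c("node", "axis") %in% names(fixed)))
    abort("`fixed` needs columns node, axis")
  if (!"value" %in% names(fixed)) fixed$value <- 0
  ax <- match(fixed$axis, c("x", "y", "z"))
  if (anyNA(ax)) abort("constraint axis must be one of 'x', 'y', 'z'")
  fixed$axis_id <- ax
  if (anyDuplicated(cbind(fixed$node, ax)))
    abort("duplicate constraint on the same node and axis")
  load_dofs <- c(
    3L * (loads$node - 1L)[abs(loads$fx) > 0] + 1L,
    3L * (loads$node - 1L)[abs(loads$fy) > 0] + 2L,
    3L * (loads$node - 1L)[abs(loads$fz) > 0] + 3L
  )
  if (length(intersect(load_dofs, 3L * (fixed$node - 1L) + ax)))
    abort("a DOF cannot be both loaded and constrained")
  structure(list(name = name, loads = loads, fixed = fixed),
            class = "load_case")
}

#' Solve the static linear-elastic problem
#'
#' Eliminates constrained DOFs (row/column reduction, honouring any
#' prescribed values), factorises the reduced symmetric system with a
#' sparse Cholesky decomposition and recovers reactions at every
#' constrained DOF as `(K u - f)` there. Deterministic and seedless.
#'
#' @param mesh a labelled `tet_mesh`.
#' @param materials a `material_table`.
#' @param loadcase a [load_case()].
#' @param K optional pre-assembled stiffness (reused across load cases).
#' @return object of class `fe_solution`: displacement matrix `u`
#'   (n x 3, mm), `reactions` tibble (N), solver `residual`, and the
#'   assembled force vector.
#' @export
fe_solve <- function(mesh, materials, loadcase, K = NULL) {
  if (is.null(K)) K <- assemble_stiffness(mesh, materials)
  ndof <- 3L * nrow(mesh$nodes)
  f <- numeric(ndof)
  ld <- loadcase$loads
  for (i in 1:3) {
    col <- c("fx", "fy", "fz")[i]
    dofs <- 3L * (ld$node - 1L) + i
    add <- rowsum(ld[[col]], dofs)
    f[as.integer(rownames(add))] <- f[as.integer(rownames(add))] + add[, 1L]
  }
  fixed_dof <- 3L * (loadcase$fixed$node - 1L) + loadcase$fixed$axis_id
  u_fix <- loadcase$fixed$value
  free <- setdiff(seq_len(ndof), fixed_dof)
  K_ff <- forceSymmetric(K[free, free])
  rhs <- f[free]
  if (any(u_fix != 0))
    rhs <- rhs - as.numeric(K[free, fixed_dof, drop = FALSE] %*% u_fix)
  ch <- tryCatch(
    suppressWarnings(Cholesky(K_ff, LDL = FALSE, perm = TRUE)),
    error = function(e) abort(paste0(
      "reduced stiffness is not positive definite (", conditionMessage(e),
      "); the constraint set likely leaves rigid-body modes"))
  )
  u_free <- as.numeric(solve(ch, rhs))
  rnorm_ <- sqrt(sum((as.numeric(K_ff %*% u_free) - rhs)^2))
  fnorm <- sqrt(sum(rhs^2))
  residual <- if (fnorm > 0) rnorm_ / fnorm else rnorm_
  if (fnorm > 0 && residual > 1e-8)
    warn(paste0("solver residual ", format(residual, digits = 3),
                " exceeds 1e-8"))
  u <- numeric(ndof)
  u[free] <- u_free
  u[fixed_dof] <- u_fix
  r_all <- as.numeric(K %*% u) - f
  reactions <- tibble(node = loadcase$fixed$node,
                      axis = loadcase$fixed$axis,
                      value = r_all[fixed_dof])
  structure(list(u = matrix(u, ncol = 3L, byrow = TRUE),
                 reactions = reactions, residual = residual,
                 loadcase = loadcase$name, f = f),
            class = "fe_solution")
}

#' Recover element strains from a displacement field
#'
#' Constant strain per TET4: the symmetric displacement gradient built
#' from relative nodal displacements, which makes rigid translations
#' produce exactly zero strain and is exact for any globally linear
#' displacement field.
#'
#' @param mesh a `tet_mesh`.
#' @param u displacement matrix (n x 3, mm) or an `fe_solution`.
#' @return object of class `strain_field`: matrix m x 6 with columns
#'   `exx`, `eyy`, `ezz`, `exy`, `exz`, `eyz` (tensor shear components,
#'   dimensionless), with element volumes attached.
#' @export
recover_strains <- function(mesh, u) {
  if (inherits(u, "fe_solution")) u <- u$u
  sg <- shape_gradients(mesh)
  e <- mesh$elems
  d2 <- u[e[, 2L], , drop = FALSE] - u[e[, 1L], , drop = FALSE]
  d3 <- u[e[, 3L], , drop = FALSE] - u[e[, 1L], , drop = FALSE]
  d4 <- u[e[, 4L], , drop = FALSE] - u[e[, 1L], , drop = FALSE]
  ## H_ij = sum_a (grad N_a)_i * d_a_j over a = 2..4
  H <- function(i, j) {
    gi <- list(sg$gx, sg$gy, sg$gz)[[i]]
    gi[, 2L] * list(d2, d3, d4)[[1L]][, j] +
      gi[, 3L] * list(d2, d3, d4)[[2L]][, j] +
      gi[, 4L] * list(d2, d3, d4)[[3L]][, j]
  }
  eps <- cbind(
    exx = H(1L, 1L),
    eyy = H(2L, 2L),
    ezz = H(3L, 3L),
    exy = (H(1L, 2L) + H(2L, 1L)) / 2,
    exz = (H(1L, 3L) + H(3L, 1L)) / 2,
    eyz = (H(2L, 3L) + H(3L, 2L)) / 2
  )
  structure(eps, class = "strain_field", volume = sg$volume)
}

#' Equivalent nodal loads of a uniform surface traction
#'
#' Finds the boundary triangles whose three nodes all belong to the
#' given node set and lumps `traction * area / 3` onto each of their
#' nodes — the consistent load vector for linear triangles under
#' constant traction.
#'
#' @param mesh a `tet_mesh`.
#' @param face_nodes node indices spanning the loaded surface patch.
#' @param traction traction vector (N/mm^2 = MPa), length 3.
#' @return tibble of nodal loads `node`, `fx`, `fy`, `fz` (N).
#' @export
traction_loads <- function(mesh, face_nodes, traction) {
  sf <- surface_faces(mesh)
  keep <- matrix(sf$faces %in% face_nodes, ncol = 3L)
  tri <- sf$faces[rowSums(keep) == 3L, , drop = FALSE]
  if (nrow(tri) == 0L) abort("no boundary triangles span `face_nodes`")
  p1 <- mesh$nodes[tri[, 1L], , drop = FALSE]
  e1 <- mesh$nodes[tri[, 2L], , drop = FALSE] - p1
  e2 <- mesh$nodes[tri[, 3L], , drop = FALSE] - p1
  cr <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  area <- sqrt(rowSums(cr^2)) / 2
  w <- rep(area / 3, 3L)
  nd <- as.vector(tri)
  agg <- rowsum(cbind(w * traction[1L], w * traction[2L], w * traction[3L]), nd)
  tibble(node = as.integer(rownames(agg)),
         fx = agg[, 1L], fy = agg[, 2L], fz = agg[, 3L])
}

#' @export
print.fe_solution <- function(x, ...) {
  cat("<fe_solution> load case:", x$loadcase, "\n")
  cat("  nodes:", nrow(x$u), " residual:", format(x$residual, digits = 3), "\n")
  cat("  max |u|:", format(max(abs(x$u)), digits = 5), "mm\n")
  invisible(x)
}

#' Broom-style tidiers for FE solutions
#'
#' `tidy()` returns the reaction forces (one row per constrained DOF);
#' `glance()` returns a one-row model summary.
#'
#' @param x an `fe_solution`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy fe_solution
#' @export
tidy.fe_solution <- function(x, ...) x$reactions

#' @rdname tidy.fe_solution
#' @method glance fe_solution
#' @export
glance.fe_solution <- function(x, ...) {
  tibble(loadcase = x$loadcase,
         n_nodes = nrow(x$u),
         n_constrained = nrow(x$reactions),
         residual = x$residual,
         max_displacement = max(abs(x$u)),
         total_applied_force = sum(abs(x$f)))
}
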