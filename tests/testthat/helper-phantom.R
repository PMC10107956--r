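## Shared fixtures, built once per test run and cached.
.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

## Coarse 30x16x4-cell phantom (1 mm in-plane cells, ~11.5k tets): full
## tissue topology, too coarse for 1 mm^2 gauge patches.
coarse_spec <- function() {
  default_phantom_spec(
    nx = 30, ny = 16, nz = 4,
    pegs = list(tooth_peg(2.5, 5.5, pdl_thickness = 1),
                tooth_peg(2.5, 9.5, pdl_thickness = 1),
                tooth_peg(7, 4.5, pdl_thickness = 1),
                tooth_peg(7, 10.5, pdl_thickness = 1)))
}

coarse_mesh <- function() memo("coarse_mesh", build_phantom(coarse_spec()))

## Thin phantom (0.5 mm in-plane cells, nz = 2, ~21.6k tets): fine enough
## in-plane for gauges, cheap enough for pipeline tests.
thin_spec <- function() default_phantom_spec(nz = 2)

thin_report <- function() {
  memo("thin_report", {
    cfg <- validate_config(list(phantom = list(nz = 2)))
    run_experiment(cfg)
  })
}

## bar mesh helpers for closed-form solutions: an nx x ny x nz grid over
## an L x W x t bar, all cortical, no sutures/pegs
bar_mesh <- function(L, W, t, nx, ny, nz, distortion = 0, seed = 1) {
  spec <- phantom_spec(L = L, W = W, t = t, nx = nx, ny = ny, nz = nz,
                       distortion = distortion, seed = seed)
  mesh <- hex_to_tets(build_hex_grid(spec))
  mesh$tissue <- rep("cortical", nrow(mesh$elems))
  mesh
}

plane_nodes <- function(mesh, axis, value, tol = 1e-9) {
  which(abs(mesh$param[, axis] - value) < tol)
}

## Independent single-element stiffness oracle: finite-difference Hessian
## of the strain energy U(u) = V/2 (lambda tr(e)^2 + 2 mu e:e), with the
## element strain obtained by fitting the affine interpolant of the four
## nodal displacements (no B matrix, no elasticity matrix shared with the
## implementation).
oracle_stiffness_tet4 <- function(coords, E, nu, h = 1e-5) {
  lambda <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  V <- abs(det(cbind(coords[2:4, ] - rep(coords[1, ], each = 3)))) / 6
  energy <- function(uvec) {
    u <- matrix(uvec, ncol = 3, byrow = TRUE)
    A <- cbind(1, coords)              # affine fit u(x) = c + G x
    G <- solve(A, u)[2:4, ]            # 3 x 3 gradient (d u_j / d x_i)
    eps <- (G + t(G)) / 2
    V / 2 * (lambda * sum(diag(eps))^2 + 2 * mu * sum(eps^2))
  }
  K <- matrix(0, 12, 12)
  for (i in 1:12) for (j in i:12) {
    ei <- ej <- numeric(12)
    ei[i] <- h; ej[j] <- h
    K[i, j] <- K[j, i] <-
      (energy(ei + ej) - energy(ei - ej) - energy(ej - ei) + energy(-ei - ej)) /
      (4 * h^2)
  }
  K
}

## Independent legacy-VTK parser: line-oriented, sharing no code with
## read_vtk(); returns points, connectivity and names of data arrays.
naive_vtk_parse <- function(path) {
  lines <- readLines(path)
  grab <- function(pattern) grep(pattern, lines)
  np <- as.integer(strsplit(lines[grab("^POINTS ")], " ")[[1]][2])
  pstart <- grab("^POINTS ") + 1
  nums <- as.numeric(unlist(strsplit(trimws(
    lines[pstart:(grab("^CELLS ") - 1)]), "[ ]+")))
  pts <- matrix(nums[seq_len(3 * np)], ncol = 3, byrow = TRUE)
  nc <- as.integer(strsplit(lines[grab("^CELLS ")], " ")[[1]][2])
  cstart <- grab("^CELLS ") + 1
  cnums <- as.integer(unlist(strsplit(trimws(
    lines[cstart:(grab("^CELL_TYPES") - 1)]), "[ ]+")))
  cells <- matrix(cnums, ncol = 5, byrow = TRUE)
  arrays <- sub("^(SCALARS|VECTORS) ([^ ]+) .*$", "\\2",
                lines[grab("^(SCALARS|VECTORS) ")])
  list(points = pts, cells = cells[, 2:5] + 1L, arrays = arrays)
}

## equilibrium check: sum of applied loads plus reactions, per axis
equilibrium_gap <- function(solution) {
  f_tot <- colSums(matrix(solution$f, ncol = 3, byrow = TRUE))
  r <- solution$reactions
  r_tot <- vapply(c("x", "y", "z"),
                  function(a) sum(r$value[r$axis == a]), numeric(1))
  abs(f_tot + r_tot)
}
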