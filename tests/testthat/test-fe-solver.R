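test_that("element stiffness has the rigid-body null space and SPD structure", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  K <- element_stiffness_tet4(coords, E = 19920, nu = 0.3)
  expect_equal(K, t(K), tolerance = 1e-12)
  ## uniform translations and infinitesimal rotations cost no energy
  for (u in list(rep(c(1, 0, 0), 4), rep(c(0, 1, 0), 4), rep(c(0, 0, 1), 4))) {
    expect_lt(max(abs(K %*% u)), 1e-9)
  }
  Wrot <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 0), 3, 3, byrow = TRUE)
  u_rot <- as.vector(t(coords %*% t(Wrot)))
  expect_lt(max(abs(K %*% u_rot)), 1e-9)
  ## exactly 6 (near-)zero eigenvalues, the rest positive
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-6 * max(ev)), 6)
  expect_true(all(ev > -1e-6 * max(ev)))
  expect_error(element_stiffness_tet4(coords[c(1, 3, 2, 4), ], 1, 0.3),
               "degenerate")
})

test_that("element stiffness matches an independent energy-Hessian oracle", {
  ## unit reference tet at nu = 0, plus a random distorted tet
  coords_ref <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  K <- element_stiffness_tet4(coords_ref, E = 1, nu = 0)
  K_o <- oracle_stiffness_tet4(coords_ref, E = 1, nu = 0)
  expect_equal(K, K_o, tolerance = 1e-6)
  set.seed(5)
  coords_r <- coords_ref + matrix(runif(12, -0.2, 0.2), 4, 3)
  if (det(rbind(coords_r[2, ] - coords_r[1, ], coords_r[3, ] - coords_r[1, ],
                coords_r[4, ] - coords_r[1, ])) < 0)
    coords_r <- coords_r[c(1, 3, 2, 4), ]
  K_r <- element_stiffness_tet4(coords_r, E = 19920, nu = 0.3)
  K_ro <- oracle_stiffness_tet4(coords_r, E = 19920, nu = 0.3)
  expect_equal(K_r, K_ro, tolerance = 1e-5)
})

test_that("assembly is consistent with per-element stiffness and symmetric", {
  ## two disconnected tets give a block-diagonal matrix matching the
  ## element matrices
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(5, 5, 5), c(6, 5, 5), c(5, 6, 5), c(5, 5, 6))
  elems <- rbind(1:4, 5:8)
  mesh <- tet_mesh(nodes, elems, tissue = c("cortical", "suture"))
  tab <- default_material_table()
  K <- as.matrix(assemble_stiffness(mesh, tab))
  expect_equal(K[1:12, 13:24], matrix(0, 12, 12))
  expect_equal(K[1:12, 1:12],
               unname(element_stiffness_tet4(nodes[1:4, ], 19920, 0.3)),
               tolerance = 1e-9)
  expect_equal(K[13:24, 13:24],
               unname(element_stiffness_tet4(nodes[5:8, ], 20, 0.49)),
               tolerance = 1e-9)
  ## symmetry on a real phantom assembly
  Kp <- assemble_stiffness(coarse_mesh(), tab)
  expect_lt(max(abs(Kp - Matrix::t(Kp))), 1e-9 * max(abs(Kp)))
  ## missing material label is reported by name
  tab_bad <- tab[tab$tissue != "suture", ]
  expect_error(assemble_stiffness(mesh, tab_bad), "suture")
})

test_that("solver reproduces closed-form axial extension", {
  ## end-loaded bar, 100 x 10 x 10 mm: u_tip = PL/(EA) under uniform
  ## tension with symmetry constraints that admit the exact solution
  mesh <- bar_mesh(100, 10, 10, 20, 2, 2)
  tab <- default_material_table()
  P <- 10
  loads <- traction_loads(mesh, plane_nodes(mesh, 1, 100),
                          c(P / 100, 0, 0))
  fixed <- dplyr::bind_rows(
    tibble::tibble(node = plane_nodes(mesh, 1, 0), axis = "x"),
    tibble::tibble(node = plane_nodes(mesh, 2, 0), axis = "y"),
    tibble::tibble(node = plane_nodes(mesh, 3, 0), axis = "z"))
  sol <- fe_solve(mesh, tab, load_case("custom", loads, fixed))
  tip <- plane_nodes(mesh, 1, 100)
  expect_equal(sol$u[tip, 1], rep(P * 100 / (19920 * 100), length(tip)),
               tolerance = 1e-6)
  ## zero loads give zero displacements and reactions
  sol0 <- fe_solve(mesh, tab,
                   load_case("custom", loads[0, ], fixed))
  expect_equal(max(abs(sol0$u)), 0)
  expect_equal(max(abs(sol0$reactions$value)), 0)
})

test_that("applied forces and reactions balance on phantom solves", {
  m <- coarse_mesh()
  tab <- default_material_table()
  ml <- build_muscle_loads(m, default_muscles(coarse_spec()))
  for (case in c("incisor_bilateral", "molar_unilateral")) {
    sol <- fe_solve(m, tab, build_load_case(m, case, ml$loads))
    expect_lt(max(equilibrium_gap(sol)), 1e-8 * sum(abs(sol$f)))
    expect_lt(sol$residual, 1e-8)
  }
})

test_that("linearity: scaling loads scales the whole solution", {
  m <- coarse_mesh()
  tab <- default_material_table()
  ml <- build_muscle_loads(m, default_muscles(coarse_spec()))
  lc1 <- build_load_case(m, "incisor_bilateral", ml$loads)
  loads3 <- ml$loads
  loads3[, c("fx", "fy", "fz")] <- 3 * loads3[, c("fx", "fy", "fz")]
  lc3 <- build_load_case(m, "incisor_bilateral", loads3)
  K <- assemble_stiffness(m, tab)
  s1 <- fe_solve(m, tab, lc1, K = K)
  s3 <- fe_solve(m, tab, lc3, K = K)
  expect_equal(s3$u, 3 * s1$u, tolerance = 1e-10)
  expect_equal(s3$reactions$value, 3 * s1$reactions$value, tolerance = 1e-10)
  e1 <- recover_strains(m, s1)
  e3 <- recover_strains(m, s3)
  expect_equal(unclass(e3), 3 * unclass(e1), tolerance = 1e-10)
})

test_that("strain recovery is exact for linear displacement fields", {
  m <- coarse_mesh()
  n <- nrow(m$nodes)
  ## rigid translation: identically zero strain
  u_t <- matrix(rep(c(0.3, -0.2, 0.1), each = n), ncol = 3)
  expect_lt(max(abs(unclass(recover_strains(m, u_t)))), 1e-12)
  ## uniaxial stretch u_x = 0.001 x: 1000 microstrain in xx only
  u_s <- cbind(0.001 * m$nodes[, 1], 0, 0)
  eps <- unclass(recover_strains(m, u_s)) * 1e6
  expect_equal(unname(eps[, 1]), rep(1000, nrow(eps)), tolerance = 1e-9)
  expect_lt(max(abs(eps[, 2:6])), 1e-6)
  ## symmetric shear u_x = a y, u_y = a x: tensor shear exy = 500 ue
  u_g <- cbind(0.0005 * m$nodes[, 2], 0.0005 * m$nodes[, 1], 0)
  eps_g <- unclass(recover_strains(m, u_g)) * 1e6
  expect_equal(unname(eps_g[, 4]), rep(500, nrow(eps_g)), tolerance = 1e-9)
  expect_lt(max(abs(eps_g[, c(1:3, 5:6)])), 1e-6)
})

test_that("under-constrained systems are diagnosed", {
  mesh <- bar_mesh(10, 5, 5, 4, 2, 2)
  tab <- default_material_table()
  loads <- tibble::tibble(node = 1L, fx = 0, fy = 0, fz = -1)
  ## single fully fixed node leaves rotational rigid modes
  fixed <- tibble::tibble(node = rep(2L, 3), axis = c("x", "y", "z"))
  expect_error(fe_solve(mesh, tab, load_case("custom", loads, fixed)),
               "rigid-body|positive definite")
  expect_error(load_case("custom",
                         tibble::tibble(node = 2L, fx = 1, fy = 0, fz = 0),
                         fixed),
               "both loaded and constrained")
})
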