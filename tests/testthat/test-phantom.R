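test_that("hex grid has the expected lattice structure", {
  g1 <- build_hex_grid(phantom_spec(L = 1, W = 1, t = 1, nx = 2, ny = 2, nz = 2))
  expect_equal(nrow(g1$nodes), 27)
  expect_equal(nrow(g1$hexes), 8)

  g2 <- build_hex_grid(phantom_spec(L = 2, W = 1, t = 1, nx = 2, ny = 2, nz = 2))
  expect_equal(nrow(g2$nodes), 27)

  ## flat limit: all z-levels are parallel planes
  g3 <- build_hex_grid(phantom_spec(L = 4, W = 3, t = 2, nx = 4, ny = 3, nz = 2,
                                    curvature = 0))
  expect_equal(sort(unique(g3$nodes[, 3])), c(0, 1, 2))

  expect_error(phantom_spec(L = -1, W = 1, t = 1, nx = 2, ny = 2, nz = 2),
               "positive")
  expect_error(phantom_spec(L = 1, W = 1, t = 1, nx = 1, ny = 2, nz = 2),
               ">= 2")
})

test_that("hex-to-tet subdivision conserves volume and conforms", {
  ## single cells: 6 tets per hex, volumes sum to the cell volume
  g <- build_hex_grid(phantom_spec(L = 1, W = 1, t = 1, nx = 2, ny = 2, nz = 2))
  m <- hex_to_tets(g)
  expect_equal(nrow(m$elems), 48)
  expect_equal(sum(tet_volumes(m)), 1, tolerance = 1e-14)
  expect_equal(sum(tet_volumes(m)[1:6]), 0.125, tolerance = 1e-14)
  expect_false(any(duplicated(apply(m$elems, 1, function(r)
    paste(sort(r), collapse = "-")))))
  check_conformity(m)

  ## arched grid: per-cell tet volumes match the convex cell volume
  ## computed independently by the divergence theorem
  ga <- build_hex_grid(phantom_spec(L = 10, W = 8, t = 2, nx = 5, ny = 4,
                                    nz = 2, curvature = 0.8))
  ma <- hex_to_tets(ga)
  hex_volume_divergence <- function(corners) {
    ## surface integral of x . n / 3 over the 12 boundary triangles,
    ## using the same corner split as the face diagonals (lowest-to-
    ## highest corner), oriented outward
    quads <- list(c(1, 3, 4, 2), c(5, 6, 8, 7), c(1, 2, 6, 5),
                  c(3, 7, 8, 4), c(1, 5, 7, 3), c(2, 4, 8, 6))
    v <- 0
    for (q in quads) {
      p <- corners[q, ]
      for (tri in list(p[c(1, 2, 3), ], p[c(1, 3, 4), ])) {
        n <- pracma_cross(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
        v <- v + sum((tri[1, ] + tri[2, ] + tri[3, ]) / 3 * n) / 6
      }
    }
    v
  }
  pracma_cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                   a[3] * b[1] - a[1] * b[3],
                                   a[1] * b[2] - a[2] * b[1])
  vt <- tet_volumes(ma)
  for (cell in c(1L, 7L, 20L)) {
    corners <- ga$nodes[ga$hexes[cell, ], ]
    expect_equal(sum(vt[(6 * (cell - 1) + 1):(6 * cell)]),
                 abs(hex_volume_divergence(corners)),
                 tolerance = 1e-12)
  }
})

test_that("region labelling follows band geometry and patency", {
  ## straight band of width 0.4 on a 0.2 mm grid: exactly 2 cells wide
  spec <- phantom_spec(L = 4, W = 4, t = 0.4, nx = 20, ny = 20, nz = 2,
                       sutures = list(suture_band("longitudinal", offset = 2,
                                                  width = 0.4)))
  m <- label_regions(hex_to_tets(build_hex_grid(spec)), spec)
  cen <- element_centroids(m, space = "param")
  sut_y <- unique(round(cen[m$tissue == "suture", 2], 9))
  expect_equal(sort(unique(findInterval(sut_y, seq(0, 4, by = 0.2)))),
               c(10, 11))                       # two cell columns
  expect_true(all(abs(cen[m$tissue == "suture", 2] - 2) <= 0.2))

  ## patent = FALSE: no suture elements at all
  spec_f <- phantom_spec(L = 4, W = 4, t = 0.4, nx = 20, ny = 20, nz = 2,
                         sutures = list(suture_band("longitudinal", offset = 2,
                                                    width = 0.4,
                                                    patent = FALSE)))
  m_f <- label_regions(hex_to_tets(build_hex_grid(spec_f)), spec_f)
  expect_equal(sum(m_f$tissue == "suture"), 0)

  ## interdigitation adds suture elements on a fixed 40x20x4 grid
  base <- list(L = 20, W = 10, t = 2, nx = 40, ny = 20, nz = 4)
  straight <- do.call(phantom_spec, c(base, list(sutures = list(
    suture_band("longitudinal", offset = 5, width = 0.5)))))
  wiggly <- do.call(phantom_spec, c(base, list(sutures = list(
    suture_band("longitudinal", offset = 5, width = 0.5,
                amplitude = 2, wavelength = 4)))))
  n_straight <- sum(label_regions(hex_to_tets(build_hex_grid(straight)),
                                  straight)$tissue == "suture")
  n_wiggly <- sum(label_regions(hex_to_tets(build_hex_grid(wiggly)),
                                wiggly)$tissue == "suture")
  expect_gt(n_wiggly, n_straight)
})

test_that("suture element count is monotone in width and amplitude", {
  base <- list(L = 20, W = 10, t = 2, nx = 40, ny = 20, nz = 2)
  count <- function(w, A) {
    spec <- do.call(phantom_spec, c(base, list(sutures = list(
      suture_band("longitudinal", offset = 5, width = w,
                  amplitude = A, wavelength = 4)))))
    sum(label_regions(hex_to_tets(build_hex_grid(spec)), spec)$tissue ==
          "suture")
  }
  widths <- vapply(c(0.3, 0.6, 1.2, 2), count, numeric(1), A = 0)
  expect_true(all(diff(widths) >= 0))
  amps <- vapply(c(0, 0.5, 1, 2), function(A) count(1, A), numeric(1))
  expect_true(all(diff(amps) >= 0))
})

test_that("default phantom satisfies the mesh invariants", {
  m <- coarse_mesh()
  spec <- coarse_spec()
  ## deterministic rebuild is bit-identical
  m2 <- build_phantom(spec)
  expect_identical(m$nodes, m2$nodes)
  expect_identical(m$elems, m2$elems)
  expect_identical(m$tissue, m2$tissue)
  expect_identical(m$node_sets, m2$node_sets)
  ## volume conservation against the analytic plate volume
  expect_equal(sum(tet_volumes(m)), spec$L * spec$W * spec$t,
               tolerance = 1e-10)
  ## single connected component, conforming interior faces
  expect_true(is_connected(m))
  check_conformity(m)
  ## every element has exactly one valid label
  expect_true(all(m$tissue %in% c("cortical", "trabecular", "suture",
                                  "tooth", "pulp", "pdl")))
  expect_setequal(unique(m$tissue),
                  c("cortical", "trabecular", "suture", "tooth", "pulp", "pdl"))
})

test_that("node sets mirror the constraint and gauge scheme", {
  m <- coarse_mesh()
  expect_length(m$node_sets$incisor_left, 1)
  expect_length(m$node_sets$incisor_right, 1)
  expect_length(m$node_sets$molar_left, 1)
  expect_length(m$node_sets$tmj_working, 1)
  ## PB-analog gauge is >= 3 mm from every suture element centroid
  pb <- m$param[m$node_sets$gauge_pb, 1:2]
  sut <- element_centroids(m, space = "param")[m$tissue == "suture", 1:2]
  expect_gte(sqrt(min((sut[, 1] - pb[1])^2 + (sut[, 2] - pb[2])^2)), 3)
  ## bone surface sets are disjoint from suture-interior nodes and from
  ## each other; their union is the bone-only part of the surface
  bone_sets <- m$node_sets[grep("^bone_", names(m$node_sets))]
  expect_length(bone_sets, 6)
  all_bone <- unlist(bone_sets)
  sut_nodes <- unique(as.vector(m$elems[m$tissue == "suture", ]))
  expect_length(intersect(all_bone, sut_nodes), 0)
  soft <- unique(as.vector(m$elems[!m$tissue %in% c("cortical", "trabecular"), ]))
  expect_setequal(unique(all_bone), setdiff(surface_nodes(m), soft))
  ## gauge sites impossible => error (sutures covering the plate)
  spec_all_sut <- phantom_spec(L = 8, W = 8, t = 2, nx = 8, ny = 8, nz = 2,
                               sutures = list(suture_band("longitudinal",
                                                          offset = 4,
                                                          width = 7.9)))
  msh <- label_regions(hex_to_tets(build_hex_grid(spec_all_sut)), spec_all_sut)
  expect_error(make_node_sets(msh, spec_all_sut), "PB-analog")
})
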