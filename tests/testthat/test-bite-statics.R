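## simple lever scenario: joint at origin-side, bite anterior
lever_scenario <- function(muscle_fz = -10, muscle_x = 70, lateral = FALSE) {
  bite_scenario(
    bite_point = c(0, 5, 0),
    tmj_working = c(100, 0, 0), tmj_balancing = c(100, 10, 0),
    muscle_forces = tibble::tibble(x = muscle_x, y = 5, z = 0,
                                   fx = 0, fy = 0, fz = muscle_fz),
    laterality = if (lateral) "unilateral" else "bilateral")
}

test_that("bilateral lever balance matches the moment-arm closed form", {
  ## 10 N at 30 mm anterior of the joint, bite at 100 mm: 10 * 30 / 100
  sol <- solve_bilateral_bite(lever_scenario(muscle_fz = -10, muscle_x = 70))
  expect_equal(sol$bite_force, 3, tolerance = 1e-12)
  expect_lt(sol$residual, 1e-9)
  ## muscle collocated with the bite point: full transfer, no joint load
  sol_c <- solve_bilateral_bite(lever_scenario(muscle_fz = -10, muscle_x = 0))
  expect_equal(sol_c$bite_force, 10, tolerance = 1e-12)
  expect_equal(sol_c$working_reaction + sol_c$balancing_reaction,
               c(0, 0, 0), tolerance = 1e-12)
  ## linearity in the muscle forces
  sol2 <- solve_bilateral_bite(lever_scenario(muscle_fz = -20, muscle_x = 70))
  expect_equal(sol2$bite_force, 2 * sol$bite_force, tolerance = 1e-12)
})

test_that("unilateral solver reduces to the bilateral one under symmetry", {
  mf <- tibble::tibble(x = c(70, 70), y = c(2, 8), z = c(1, 1),
                       fx = c(0.5, 0.5), fy = c(1, -1), fz = c(-6, -6))
  sc_uni <- bite_scenario(c(10, 5, 0), tmj_working = c(100, 0, 0),
                          tmj_balancing = c(100, 10, 0), muscle_forces = mf,
                          laterality = "unilateral")
  sc_bi <- bite_scenario(c(10, 5, 0), tmj_working = c(100, 0, 0),
                         tmj_balancing = c(100, 10, 0), muscle_forces = mf,
                         laterality = "bilateral")
  expect_equal(solve_unilateral_bite(sc_uni)$bite_force,
               solve_bilateral_bite(sc_bi)$bite_force, tolerance = 1e-10)
  ## zero muscles give an all-zero solution
  sc0 <- bite_scenario(c(10, 5, 0), tmj_working = c(100, 0, 0),
                       tmj_balancing = c(100, 10, 0),
                       muscle_forces = mf[0, ], laterality = "unilateral")
  sol0 <- solve_unilateral_bite(sc0)
  expect_equal(sol0$bite_force, 0)
  expect_equal(sol0$balancing_reaction, c(0, 0, 0))
})

test_that("unilateral 6x6 solution matches a pseudo-inverse oracle", {
  set.seed(7)
  for (k in 1:5) {
    mf <- tibble::tibble(x = runif(4, 40, 90), y = runif(4, 0, 10),
                         z = runif(4, -3, 3), fx = runif(4, -2, 2),
                         fy = runif(4, -2, 2), fz = runif(4, -10, -1))
    sc <- bite_scenario(c(10, 4, -2), tmj_working = c(100, 0, 0),
                        tmj_balancing = c(100, 10, 0), muscle_forces = mf,
                        laterality = "unilateral")
    sol <- solve_unilateral_bite(sc)
    ## independent route: least squares via SVD pseudo-inverse on the
    ## same equilibrium equations, assembled separately
    f_res <- c(sum(mf$fx), sum(mf$fy), sum(mf$fz))
    m_res <- c(sum(mf$y * mf$fz - mf$z * mf$fy),
               sum(mf$z * mf$fx - mf$x * mf$fz),
               sum(mf$x * mf$fy - mf$y * mf$fx))
    unit_wrench <- function(f, r) c(f, c(r[2] * f[3] - r[3] * f[2],
                                         r[3] * f[1] - r[1] * f[3],
                                         r[1] * f[2] - r[2] * f[1]))
    A <- cbind(unit_wrench(c(0, 0, 1), c(10, 4, -2)),
               unit_wrench(c(1, 0, 0), c(100, 10, 0)),
               unit_wrench(c(0, 1, 0), c(100, 10, 0)),
               unit_wrench(c(0, 0, 1), c(100, 10, 0)),
               unit_wrench(c(1, 0, 0), c(100, 0, 0)),
               unit_wrench(c(0, 0, 1), c(100, 0, 0)))
    sv <- svd(A)
    q <- sv$v %*% (crossprod(sv$u, -c(f_res, m_res)) / sv$d)
    expect_equal(sol$bite_force, q[1], tolerance = 1e-10)
    expect_equal(sol$balancing_reaction, q[2:4], tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_equal(sol$working_reaction[c(1, 3)], q[5:6], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("returned solutions balance forces and moments about any pivot", {
  set.seed(11)
  mf <- tibble::tibble(x = runif(6, 30, 90), y = runif(6, 0, 10),
                       z = runif(6, -2, 2), fx = runif(6, -3, 3),
                       fy = runif(6, -3, 3), fz = runif(6, -8, -2))
  sc <- bite_scenario(c(5, 5, 0), tmj_working = c(100, 0, 0),
                      tmj_balancing = c(100, 10, 0), muscle_forces = mf,
                      laterality = "unilateral")
  sol <- solve_unilateral_bite(sc)
  pts <- rbind(c(5, 5, 0), c(100, 0, 0), c(100, 10, 0))
  forces <- rbind(as.matrix(mf[, c("fx", "fy", "fz")]),
                  sol$bite_force * c(0, 0, 1),
                  sol$working_reaction, sol$balancing_reaction)
  pos <- rbind(as.matrix(mf[, c("x", "y", "z")]), pts)
  expect_lt(max(abs(colSums(forces))), 1e-10)
  for (pivot in list(c(0, 0, 0), c(13, -7, 22), c(-5, 100, 1))) {
    r <- sweep(pos, 2, pivot)
    mom <- c(sum(r[, 2] * forces[, 3] - r[, 3] * forces[, 2]),
             sum(r[, 3] * forces[, 1] - r[, 1] * forces[, 3]),
             sum(r[, 1] * forces[, 2] - r[, 2] * forces[, 1]))
    expect_lt(max(abs(mom)), 1e-9)
  }
})

test_that("degenerate bite geometry is rejected", {
  ## bite point on the joint axis: moment arm vanishes
  sc <- bite_scenario(c(100, 5, 0), tmj_working = c(100, 0, 0),
                      tmj_balancing = c(100, 10, 0),
                      muscle_forces = tibble::tibble(x = 50, y = 5, z = 0,
                                                     fx = 0, fy = 0, fz = -1),
                      laterality = "bilateral")
  expect_error(solve_bilateral_bite(sc), "singular")
  expect_error(bite_scenario(c(0, 0, 0), bite_dir = c(0, 0, 2),
                             tmj_working = c(1, 0, 0),
                             tmj_balancing = c(1, 1, 0),
                             muscle_forces = tibble::tibble(
                               x = 0, y = 0, z = 0, fx = 0, fy = 0, fz = 1)),
               "unit-norm")
})
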