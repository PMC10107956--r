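#' Static bite scenario
#'
#' Rigid-body description of a maximal static bite: the full set of
#' applied muscle nodal forces, the bite point with its (unit) bite
#' direction, and the two TMJ reaction points. Solving the scenario
#' predicts the bite force and joint reactions that balance the muscle
#' system — the determinate desk-scale analog of a multibody bite
#' simulation, and an independent cross-check of the FE reactions,
#' since the unknown reaction components mirror the FE constraint DOFs.
#'
#' @param bite_point numeric length-3 (mm).
#' @param bite_dir unit bite direction; default vertical `(0, 0, 1)`.
#' @param tmj_working,tmj_balancing TMJ points (mm). For unilateral
#'   biting the working side is the biting side.
#' @param muscle_forces tibble/data frame with columns `x`, `y`, `z`
#'   (application point, mm) and `fx`, `fy`, `fz` (N).
#' @param laterality `"bilateral"` or `"unilateral"`.
#' @return object of class `bite_scenario`.
#' @export
bite_scenario <- function(bite_point, bite_dir = c(0, 0, 1),
                          tmj_working, tmj_balancing, muscle_forces,
                          laterality = c("bilateral", "unilateral")) {
  laterality <- match.arg(laterality)
  bite_dir <- as.numeric(bite_dir)
  nrm <- sqrt(sum(bite_dir^2))
  if (abs(nrm - 1) > 1e-9) abort("bite direction must be unit-norm")
  mf <- as_tibble(muscle_forces)
  need <- c("x", "y", "z", "fx", "fy", "fz")
  if (!all(need %in% names(mf)))
    abort("muscle_forces needs columns x, y, z, fx, fy, fz")
  structure(list(bite_point = as.numeric(bite_point), bite_dir = bite_dir,
                 tmj_working = as.numeric(tmj_working),
                 tmj_balancing = as.numeric(tmj_balancing),
                 muscle_forces = mf, laterality = laterality),
            class = "bite_scenario")
}

## net force and moment (about origin) of the applied muscle system
muscle_resultant <- function(mf) {
  f <- c(sum(mf$fx), sum(mf$fy), sum(mf$fz))
  m <- c(sum(mf$y * mf$fz - mf$z * mf$fy),
         sum(mf$z * mf$fx - mf$x * mf$fz),
         sum(mf$x * mf$fy - mf$y * mf$fx))
  list(force = f, moment = m)
}

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

new_bite_solution <- function(bite_force, working, balancing, residual,
                              laterality) {
  structure(list(bite_force = bite_force, working_reaction = working,
                 balancing_reaction = balancing, residual = residual,
                 laterality = laterality),
            class = "bite_solution")
}

#' Solve a bilateral (symmetric) bite
#'
#' For a scenario symmetric about the sagittal plane with a vertical
#' bite direction, the out-of-plane equations vanish and the
#' sagittal-plane equilibrium (forces in x and z, moment about y)
#' determines the total vertical bite force and the joint reaction
#' (x and z components, acting at the midpoint of the two TMJ points).
#'
#' @param scenario a [bite_scenario()].
#' @return a `bite_solution`; `working_reaction` and
#'   `balancing_reaction` each carry half the joint reaction.
#' @export
solve_bilateral_bite <- function(scenario) {
  if (abs(abs(scenario$bite_dir[3L]) - 1) > 1e-9)
    abort("bilateral solver assumes a vertical bite direction")
  res <- muscle_resultant(scenario$muscle_forces)
  jp <- (scenario$tmj_working + scenario$tmj_balancing) / 2
  bp <- scenario$bite_point
  ## unknowns q = (b, Rx, Rz): bite force along +z, joint reaction x/z
  ## Fx: Rx = -sum Fx
  ## Fz: b + Rz = -sum Fz
  ## My: -x_b * b + (z_j * Rx - x_j * Rz) = -My_muscle
  A <- rbind(c(0, 1, 0),
             c(1, 0, 1),
             c(-bp[1L], jp[3L], -jp[1L]))
  rhs <- c(-res$force[1L], -res$force[3L], -res$moment[2L])
  if (abs(det(A)) < 1e-12 * max(abs(A), 1))
    abort("singular bilateral bite geometry (bite point on the joint axis)")
  q <- solve(A, rhs)
  resid <- max(abs(A %*% q - rhs)) / max(1e-30, sum(abs(res$force)))
  half <- c(q[2L], 0, q[3L]) / 2
  new_bite_solution(q[1L], working = half, balancing = half,
                    residual = resid, laterality = "bilateral")
}

#' Solve a unilateral bite
#'
#' Full 3D rigid equilibrium with the unknown set mirroring the FE
#' constraint scheme: vertical bite force at the bite point (1), full
#' 3-component reaction at the balancing-side TMJ (3), and an
#' anterior-posterior plus dorsoventral reaction at the working-side
#' TMJ (2, mediolateral left free). Six equations, six unknowns.
#'
#' @param scenario a [bite_scenario()].
#' @return a `bite_solution`.
#' @export
solve_unilateral_bite <- function(scenario) {
  res <- muscle_resultant(scenario$muscle_forces)
  bp <- scenario$bite_point
  wp <- scenario$tmj_working
  bl <- scenario$tmj_balancing
  d <- scenario$bite_dir
  ## unknowns q = (b, Bx, By, Bz, Wx, Wz)
  cols <- list(
    list(f = d,          r = bp),
    list(f = c(1, 0, 0), r = bl),
    list(f = c(0, 1, 0), r = bl),
    list(f = c(0, 0, 1), r = bl),
    list(f = c(1, 0, 0), r = wp),
    list(f = c(0, 0, 1), r = wp)
  )
  A <- matrix(0, 6L, 6L)
  for (j in seq_along(cols)) {
    A[1:3, j] <- cols[[j]]$f
    A[4:6, j] <- cross3(cols[[j]]$r, cols[[j]]$f)
  }
  rhs <- c(-res$force, -res$moment)
  rc <- rcond(A)
  if (rc < 1e-12)
    abort(paste0("rank-deficient bite geometry (reciprocal condition number ",
                 format(rc, digits = 3), ")"))
  q <- solve(A, rhs)
  scale <- max(1e-30, sum(abs(res$force)) + sum(abs(res$moment)))
  resid <- max(abs(A %*% q - rhs)) / scale
  new_bite_solution(q[1L],
                    working = c(q[5L], 0, q[6L]),
                    balancing = q[2:4],
                    residual = resid, laterality = "unilateral")
}

#' @export
print.bite_solution <- function(x, ...) {
  cat("<bite_solution> (", x$laterality, ")\n", sep = "")
  cat("  bite force:", format(x$bite_force, digits = 6), "N\n")
  cat("  working TMJ reaction: ",
      paste(format(x$working_reaction, digits = 4), collapse = ", "), "\n")
  cat("  balancing TMJ reaction: ",
      paste(format(x$balancing_reaction, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn solve_unilateral_bite tidy method: one row per predicted
#'   quantity (bite force and reaction components).
#' @param x a `bite_solution`.
#' @param ... unused.
#' @method tidy bite_solution
#' @export
tidy.bite_solution <- function(x, ...) {
  tibble(
    quantity = c("bite_force", "working_rx", "working_rz",
                 "balancing_rx", "balancing_ry", "balancing_rz"),
    value = c(x$bite_force, x$working_reaction[1L], x$working_reaction[3L],
              x$balancing_reaction)
  )
}
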