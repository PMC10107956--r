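#' Muscle architecture specification
#'
#' Architecture (wet mass, mean pennation angle, mean resting fibre
#' length) determines the physiological cross-sectional area and hence
#' the maximal isometric force; geometry (origin node set, insertion
#' point, optional wrap polyline) determines how that force is applied
#' to the mesh. Parallel-fibred muscles record pennation 0.
#'
#' @param name muscle name.
#' @param mass wet mass (g), > 0.
#' @param pennation mean pennation angle (degrees), in `[0, 90)`.
#' @param fibre_length mean resting fibre length (cm), > 0.
#' @param density muscle fibre density (g cm^-3), default 1.06.
#' @param stress constant muscle stress sigma_m (N cm^-2), default 25.
#' @param n_strands number of discretization strands (>= 1).
#' @param origin_set name of the origin node set on the mesh.
#' @param insertion insertion point, numeric length-3 (mm).
#' @param wrap optional wrap polyline: matrix of via points (mm), >= 2
#'   rows, ordered proximal (cranial anchor) to distal.
#' @return object of class `muscle_spec`.
#' @export
muscle_spec <- function(name, mass, pennation = 0, fibre_length,
                        density = 1.06, stress = 25, n_strands = 1L,
                        origin_set = NULL, insertion = NULL, wrap = NULL) {
  if (mass <= 0 || fibre_length <= 0)
    abort("muscle mass and fibre length must be positive")
  if (pennation < 0 || pennation >= 90)
    abort("pennation must lie in [0, 90) degrees")
  if (n_strands < 1L) abort("n_strands must be >= 1")
  if (!is.null(wrap)) {
    wrap <- as.matrix(wrap)
    if (nrow(wrap) < 2L) abort("wrap polyline needs at least 2 points")
  }
  structure(list(name = name, mass = mass, pennation = pennation,
                 fibre_length = fibre_length, density = density,
                 stress = stress, n_strands = as.integer(n_strands),
                 origin_set = origin_set, insertion = insertion,
                 wrap = wrap),
            class = "muscle_spec")
}

#' Physiological cross-sectional area
#'
#' `PCSA = mass * cos(pennation) / (fibre_length * density)`, with mass
#' in g, fibre length in cm and density in g cm^-3, giving cm^2.
#'
#' @param spec a [muscle_spec()], or a numeric mass when the remaining
#'   arguments are supplied directly.
#' @param pennation,fibre_length,density used when `spec` is numeric.
#' @return PCSA in cm^2.
#' @export
compute_pcsa <- function(spec, pennation = 0, fibre_length = NULL,
                         density = 1.06) {
  if (inherits(spec, "muscle_spec")) {
    mass <- spec$mass; pennation <- spec$pennation
    fibre_length <- spec$fibre_length; density <- spec$density
  } else {
    mass <- spec
  }
  if (is.null(fibre_length) || any(fibre_length <= 0) || any(density <= 0))
    abort("fibre_length and density must be positive")
  mass * cos(pennation * pi / 180) / (fibre_length * density)
}

#' Maximal isometric muscle force
#'
#' PCSA multiplied by a constant muscle stress (default 25 N cm^-2).
#'
#' @param pcsa physiological cross-sectional area (cm^2), >= 0.
#' @param stress muscle stress (N cm^-2).
#' @return force in N.
#' @export
max_isometric_force <- function(pcsa, stress = 25) {
  if (any(pcsa < 0)) abort("pcsa must be non-negative")
  pcsa * stress
}

#' Discretize a muscle into equal-force strands
#'
#' The maximal isometric force is divided equally over `n_strands`
#' strands; each strand applies its share at an origin node, directed
#' toward the insertion point. Origin nodes are picked deterministically,
#' evenly spaced by index over the (sorted) origin set.
#'
#' @param mesh a `tet_mesh` holding the origin node set.
#' @param spec a [muscle_spec()] with `origin_set` and `insertion`.
#' @param f_max total force (N); computed from the architecture when
#'   omitted.
#' @return tibble of strand loads: `muscle`, `node`, `fx`, `fy`, `fz`.
#' @export
discretize_strands <- function(mesh, spec, f_max = NULL) {
  origin <- mesh$node_sets[[spec$origin_set]]
  if (is.null(origin) || length(origin) == 0L)
    abort(paste0("origin node set '", spec$origin_set, "' is empty or missing"))
  if (length(origin) < spec$n_strands)
    abort("origin set has fewer candidate nodes than n_strands")
  if (is.null(f_max))
    f_max <- max_isometric_force(compute_pcsa(spec), spec$stress)
  origin <- sort(origin)
  pick <- origin[unique(round(seq(1L, length(origin),
                                  length.out = spec$n_strands)))]
  ## rounding can merge indices on tiny sets; spread deterministically
  while (length(pick) < spec$n_strands)
    pick <- sort(unique(c(pick, setdiff(origin, pick)[1L])))
  per <- f_max / spec$n_strands
  p <- mesh$nodes[pick, , drop = FALSE]
  d <- matrix(rep(spec$insertion, each = length(pick)), ncol = 3L) - p
  len <- sqrt(rowSums(d^2))
  if (any(len < 1e-12)) abort("strand origin coincides with insertion point")
  u <- d / len
  tibble(muscle = spec$name, node = pick,
         fx = per * u[, 1L], fy = per * u[, 2L], fz = per * u[, 3L])
}

#' Nodal forces of a frictionless wrapped muscle path
#'
#' Treats the wrapped muscle as an inextensible frictionless string
#' under tension T laid over via points snapped to mesh nodes. Each
#' interior via point i receives `T * (t_out - t_in)` (the string
#' pressing on the bend); the most distal node receives the full tension
#' pulling back along its incoming segment (`-T * t_in`); the proximal
#' anchor receives `+T * t_out`. The emitted force system is internally
#' balanced: it sums to the zero vector and carries zero net moment.
#' Negative tension is clamped to 0 (tension-only elements).
#'
#' @param mesh a `tet_mesh`; via points are snapped to its nodes.
#' @param polyline matrix of via points (mm), ordered proximal to
#'   distal, >= 2 rows.
#' @param tension string tension T (N).
#' @param name label for the output rows.
#' @return tibble of nodal loads: `muscle`, `node`, `fx`, `fy`, `fz`.
#' @export
wrapped_path_nodal_forces <- function(mesh, polyline, tension,
                                      name = "wrap") {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) abort("wrap polyline needs at least 2 points")
  tension <- max(0, tension)
  nodes <- vapply(seq_len(nrow(polyline)),
                  function(i) snap_node(mesh, polyline[i, ]), integer(1))
  if (anyDuplicated(nodes))
    abort("wrap polyline snaps onto a zero-length segment (duplicate node)")
  p <- mesh$nodes[nodes, , drop = FALSE]
  seg <- diff(p)
  len <- sqrt(rowSums(seg^2))
  if (any(len < 1e-12)) abort("wrap polyline contains a zero-length segment")
  t_hat <- seg / len
  k <- length(nodes)
  f <- matrix(0, nrow = k, ncol = 3L)
  f[1L, ] <- tension * t_hat[1L, ]
  if (k > 2L)
    f[2:(k - 1L), ] <- tension * (t_hat[-1L, , drop = FALSE] -
                                    t_hat[-(k - 1L), , drop = FALSE])
  f[k, ] <- -tension * t_hat[k - 1L, ]
  tibble(muscle = name, node = nodes,
         fx = f[, 1L], fy = f[, 2L], fz = f[, 3L])
}

#' Read a muscle architecture table from CSV
#'
#' Expected columns: `name`, `mass_g`, `pennation_deg`,
#' `fibre_length_cm`, `n_strands`, `wrap` (logical).
#'
#' @param path CSV file path.
#' @return tibble with one row per muscle plus derived `pcsa_cm2` and
#'   `f_max_n` columns.
#' @export
read_muscle_csv <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("name", "mass_g", "pennation_deg", "fibre_length_cm",
            "n_strands", "wrap")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    abort(paste0("muscle CSV missing column(s): ", paste(miss, collapse = ", ")))
  tab$pcsa_cm2 <- compute_pcsa(tab$mass_g, tab$pennation_deg,
                               tab$fibre_length_cm)
  tab$f_max_n <- max_isometric_force(tab$pcsa_cm2)
  tab
}
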