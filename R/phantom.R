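#' Suture band definition
#'
#' A suture band is a soft-tissue strip splitting the phantom plate into
#' "bones". Longitudinal bands run along the x (anterior-posterior) axis
#' with centreline `y = offset + amplitude * sin(2*pi*x / wavelength)`;
#' transverse bands run along y with the axes swapped. A sinusoidal
#' centreline models marginal interdigitation; `amplitude = 0` gives a
#' straight suture. A non-patent band is skipped entirely during
#' labelling, yielding a fused (all-bone) region.
#'
#' @param axis `"longitudinal"` or `"transverse"`.
#' @param offset centreline position (mm) across the band's running axis.
#' @param width band width w (mm), minimum 0.2 mm.
#' @param amplitude interdigitation amplitude A (mm).
#' @param wavelength interdigitation wavelength (mm); required > 0 when
#'   `amplitude > 0`.
#' @param patent logical; `FALSE` marks an already-ossified band.
#' @return object of class `suture_band`.
#' @export
suture_band <- function(axis = c("longitudinal", "transverse"), offset,
                        width, amplitude = 0, wavelength = 1, patent = TRUE) {
  axis <- match.arg(axis)
  if (width < 0.2) abort("suture width must be >= 0.2 mm")
  if (amplitude > 0 && wavelength <= 0)
    abort("wavelength must be > 0 when amplitude > 0")
  structure(list(axis = axis, offset = offset, width = width,
                 amplitude = amplitude, wavelength = wavelength,
                 patent = isTRUE(patent)),
            class = "suture_band")
}

#' Tooth peg definition
#'
#' A tooth peg is a vertical cylinder rooted in the ventral (z = 0)
#' surface of the plate: a pulp core, a dentine/enamel shell, and a thin
#' periodontal-ligament (PDL) sleeve separating the tooth from the
#' alveolar bone. The bite constraint node sits at the peg tip centre on
#' the ventral surface.
#'
#' @param x,y peg axis position (mm).
#' @param radius tooth radius (mm).
#' @param length peg length from the ventral surface upward (mm).
#' @param pdl_thickness PDL sleeve thickness (mm); default 0.2 mm.
#'   Must be at least one cell size on the chosen grid.
#' @param pulp_radius pulp core radius (mm); default `radius / 3`.
#' @return object of class `tooth_peg`.
#' @export
tooth_peg <- function(x, y, radius = 0.75, length = 3,
                      pdl_thickness = 0.2, pulp_radius = radius / 3) {
  if (radius <= 0 || length <= 0 || pdl_thickness <= 0)
    abort("peg radius, length and pdl_thickness must be positive")
  structure(list(x = x, y = y, radius = radius, length = length,
                 pdl_thickness = pdl_thickness, pulp_radius = pulp_radius),
            class = "tooth_peg")
}

#' Skull-phantom specification
#'
#' The phantom is an L x W x t plate (optionally bent into an arch about
#' the longitudinal axis), meshed on a structured hex grid that is split
#' into tetrahedra. Suture bands, tooth pegs with PDL sleeves and a
#' trabecular mid-thickness core give it the tissue topology of a
#' multi-region cranial model: near-suture and far-from-suture sites,
#' anterior (incisor) and posterior (molar) bite points.
#'
#' Coordinates: x longitudinal (anterior -> posterior), y transverse,
#' z dorsoventral ("vertical"); units mm.
#'
#' @param L,W,t plate length, width, thickness (mm).
#' @param nx,ny,nz hex-grid resolution (>= 2 per axis).
#' @param sutures list of [suture_band()] objects.
#' @param pegs list of [tooth_peg()] objects.
#' @param trabecular_fraction fraction of thickness occupied by the
#'   trabecular mid-layer inside bones (0 disables it).
#' @param curvature total arch angle (radians) about the longitudinal
#'   axis; 0 = flat plate.
#' @param distortion interior-node jitter as a fraction of cell size
#'   (0 = structured grid); used for patch-test style meshes.
#' @param seed integer seed for the jitter.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(L = 30, W = 15, t = 4, nx = 60, ny = 30, nz = 8,
                         sutures = list(), pegs = list(),
                         trabecular_fraction = 0, curvature = 0,
                         distortion = 0, seed = 1L) {
  if (L <= 0 || W <= 0 || t <= 0) abort("plate dimensions must be positive")
  if (nx < 2 || ny < 2 || nz < 2) abort("grid resolutions must be >= 2")
  if (trabecular_fraction < 0 || trabecular_fraction >= 1)
    abort("trabecular_fraction must be in [0, 1)")
  if (distortion < 0 || distortion >= 0.5)
    abort("distortion must be in [0, 0.5) to keep tets positive")
  cell <- c(L / nx, W / ny, t / nz)
  for (s in sutures) {
    if (!inherits(s, "suture_band")) abort("`sutures` must contain suture_band objects")
    half <- s$width / 2 + s$amplitude
    lim <- if (s$axis == "longitudinal") W else L
    if (s$offset - half < 0 || s$offset + half > lim)
      abort("suture band extends outside the plate")
  }
  for (p in pegs) {
    if (!inherits(p, "tooth_peg")) abort("`pegs` must contain tooth_peg objects")
    if (p$pdl_thickness < max(cell[1:2]) - 1e-9)
      abort("PDL thickness must be >= one in-plane cell size on this grid")
  }
  structure(list(L = L, W = W, t = t, nx = as.integer(nx),
                 ny = as.integer(ny), nz = as.integer(nz),
                 sutures = sutures, pegs = pegs,
                 trabecular_fraction = trabecular_fraction,
                 curvature = curvature, distortion = distortion,
                 seed = as.integer(seed), cell = cell),
            class = "phantom_spec")
}

#' Default skull-phantom specification
#'
#' A 30 x 15 x 4 mm plate at 0.5 mm cell size (~86k tetrahedra): one
#' interdigitated longitudinal "sagittal" band, two straight transverse
#' "coronal"/"lambdoid" bands, two anterior incisor pegs and two
#' posterior molar pegs (0.5 mm PDL sleeves, one cell on this grid), and
#' a trabecular mid-core occupying 40% of the thickness inside bones.
#'
#' @param ... overrides passed to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
default_phantom_spec <- function(...) {
  defaults <- list(
    L = 30, W = 15, t = 4, nx = 60, ny = 30, nz = 8,
    sutures = list(
      suture_band("longitudinal", offset = 7.5, width = 1,
                  amplitude = 1, wavelength = 3),
      suture_band("transverse", offset = 10, width = 1),
      suture_band("transverse", offset = 20, width = 1)
    ),
    pegs = list(
      tooth_peg(x = 2.5, y = 5.5, pdl_thickness = 0.5),
      tooth_peg(x = 2.5, y = 9.5, pdl_thickness = 0.5),
      tooth_peg(x = 7,   y = 4.5, pdl_thickness = 0.5),
      tooth_peg(x = 7,   y = 10.5, pdl_thickness = 0.5)
    ),
    trabecular_fraction = 0.4,
    curvature = 0, distortion = 0, seed = 1L
  )
  dots <- list(...)
  defaults[names(dots)] <- dots
  do.call(phantom_spec, defaults)
}

#' Build the structured hex grid of a phantom
#'
#' Lays out an (nx+1)(ny+1)(nz+1) node lattice over the flat plate, then
#' optionally bends it into an arch about the longitudinal axis and
#' jitters interior nodes. The flat coordinates are kept as `param` so
#' that region labelling and landmark snapping stay well defined on
#' deformed geometry.
#'
#' @param spec a [phantom_spec()].
#' @return list with `nodes` (deformed), `param` (flat), `hexes`
#'   (n_cells x 8 connectivity, vertex order binary (dx, dy, dz)), grid
#'   resolutions and cell sizes.
#' @export
build_hex_grid <- function(spec) {
  nx <- spec$nx; ny <- spec$ny; nz <- spec$nz
  xs <- seq(0, spec$L, length.out = nx + 1L)
  ys <- seq(0, spec$W, length.out = ny + 1L)
  zs <- seq(0, spec$t, length.out = nz + 1L)
  ## node id = 1 + i + (nx+1)*j + (nx+1)*(ny+1)*k for 0-based (i,j,k)
  param <- as.matrix(expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE))
  nid <- function(i, j, k) 1L + i + (nx + 1L) * j + (nx + 1L) * (ny + 1L) * k
  ijk <- as.matrix(expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L),
                               k = 0:(nz - 1L), KEEP.OUT.ATTRS = FALSE))
  corners <- cbind(
    nid(ijk[, 1L],      ijk[, 2L],      ijk[, 3L]),
    nid(ijk[, 1L] + 1L, ijk[, 2L],      ijk[, 3L]),
    nid(ijk[, 1L],      ijk[, 2L] + 1L, ijk[, 3L]),
    nid(ijk[, 1L] + 1L, ijk[, 2L] + 1L, ijk[, 3L]),
    nid(ijk[, 1L],      ijk[, 2L],      ijk[, 3L] + 1L),
    nid(ijk[, 1L] + 1L, ijk[, 2L],      ijk[, 3L] + 1L),
    nid(ijk[, 1L],      ijk[, 2L] + 1L, ijk[, 3L] + 1L),
    nid(ijk[, 1L] + 1L, ijk[, 2L] + 1L, ijk[, 3L] + 1L)
  )
  nodes <- param
  if (spec$curvature > 0) {
    ## isometric bend of the mid-surface about the x axis
    R <- spec$W / spec$curvature
    phi <- spec$curvature * (param[, 2L] - spec$W / 2) / spec$W
    r <- R + (param[, 3L] - spec$t / 2)
    nodes[, 2L] <- spec$W / 2 + r * sin(phi)
    nodes[, 3L] <- spec$t / 2 - R + r * cos(phi)
  }
  if (spec$distortion > 0) {
    set.seed(spec$seed)
    interior <- param[, 1L] > 0 & param[, 1L] < spec$L &
      param[, 2L] > 0 & param[, 2L] < spec$W &
      param[, 3L] > 0 & param[, 3L] < spec$t
    n_int <- sum(interior)
    jit <- matrix(stats::runif(3L * n_int, -1, 1), ncol = 3L)
    jit <- jit * rep(spec$distortion * spec$cell, each = n_int)
    nodes[interior, ] <- nodes[interior, ] + jit
  }
  dimnames(nodes) <- list(NULL, c("x", "y", "z"))
  dimnames(param) <- list(NULL, c("x", "y", "z"))
  list(nodes = nodes, param = param, hexes = corners,
       nx = nx, ny = ny, nz = nz, cell = spec$cell)
}

## Freudenthal 6-tet subdivision around the main diagonal c000 -> c111.
## The same pattern in every cell produces conforming face triangulations,
## because each face diagonal always joins the locally lowest and highest
## corner of that face. Orderings below are positively oriented for an
## axis-aligned cell.
FREUDENTHAL <- list(
  c(1L, 2L, 4L, 8L),   # x, y, z
  c(1L, 2L, 8L, 6L),   # x, z, y
  c(1L, 4L, 3L, 8L),   # y, x, z
  c(1L, 3L, 7L, 8L),   # y, z, x  (reordered for positive volume)
  c(1L, 6L, 8L, 5L),   # z, x, y
  c(1L, 8L, 7L, 5L)    # z, y, x
)

#' Split a hex grid into tetrahedra
#'
#' Each hex cell is split into 6 tetrahedra sharing the cell's main
#' diagonal (Freudenthal subdivision). Neighbouring cells receive
#' conforming face triangulations, and the 6 tet volumes sum exactly to
#' the (possibly deformed) cell volume.
#'
#' @param grid output of [build_hex_grid()].
#' @return a [tet_mesh()] (unlabelled: all cortical).
#' @export
hex_to_tets <- function(grid) {
  m <- nrow(grid$hexes)
  elems <- matrix(0L, nrow = 6L * m, ncol = 4L)
  for (p in seq_along(FREUDENTHAL)) {
    pat <- FREUDENTHAL[[p]]
    rows <- seq.int(p, by = 6L, length.out = m)
    elems[rows, ] <- grid$hexes[, pat, drop = FALSE]
  }
  v <- tet_volumes(grid$nodes, elems)
  if (any(v <= 0)) {
    bad_cell <- unique((which(v <= 0) - 1L) %/% 6L + 1L)
    abort(paste0("inverted hex cell(s) after deformation: ",
                 paste(head(bad_cell, 5L), collapse = ", ")))
  }
  tet_mesh(grid$nodes, elems, param = grid$param, check = FALSE)
}

## distance of points (px, py) from a band's centreline in the flat
## parametric plane: true Euclidean distance to the (finely sampled)
## sinusoidal curve, so interdigitated bands keep a constant thickness
## measured perpendicular to their path. A straight band (A = 0)
## reduces exactly to the offset-line distance.
band_distance <- function(band, x, y, run_length = max(x, y)) {
  if (band$amplitude == 0) {
    return(if (band$axis == "longitudinal") abs(y - band$offset)
           else abs(x - band$offset))
  }
  if (band$axis == "transverse") {
    tmp <- x; x <- y; y <- tmp            # swap axes: run along x below
  }
  ds <- band$wavelength / 64
  s <- seq(-ds, run_length + ds, by = ds)
  cx <- s
  cy <- band$offset + band$amplitude * sin(2 * pi * s / band$wavelength)
  sqrt(min_dist2_to_segments(x, y, cx, cy))
}

## squared distance from points (x, y) to the polyline with vertices
## (cx, cy), exact per segment, blockwise over points
min_dist2_to_segments <- function(x, y, cx, cy) {
  n <- length(x)
  out <- rep(Inf, n)
  ax <- cx[-length(cx)]; ay <- cy[-length(cy)]
  bx <- cx[-1L]; by <- cy[-1L]
  ux <- bx - ax; uy <- by - ay
  uu <- ux^2 + uy^2
  block <- max(1L, floor(2e6 / length(ax)))
  for (s0 in seq(1L, n, by = block)) {
    idx <- s0:min(n, s0 + block - 1L)
    dx <- outer(x[idx], ax, "-")
    dy <- outer(y[idx], ay, "-")
    t_ <- sweep(dx, 2L, ux, "*") + sweep(dy, 2L, uy, "*")
    t_ <- pmin(pmax(sweep(t_, 2L, uu, "/"), 0), 1)
    d2 <- (dx - sweep(t_, 2L, ux, "*"))^2 + (dy - sweep(t_, 2L, uy, "*"))^2
    rmin <- d2[cbind(seq_along(idx), max.col(-d2, ties.method = "first"))]
    out[idx] <- pmin(out[idx], rmin)
  }
  out
}

#' Assign tissue labels to phantom elements
#'
#' Rule-based replacement for manual segmentation: each element is
#' labelled from its centroid position (in flat parametric coordinates)
#' with precedence tooth > pulp > pdl > suture > trabecular > cortical.
#' A centroid within `width/2` of a patent band centreline is suture;
#' peg membership is radial (pulp core, tooth shell, PDL sleeve over a
#' limited length from the ventral surface); the trabecular core is a
#' mid-thickness layer kept one cell clear of suture bands and pegs.
#'
#' @param mesh unlabelled `tet_mesh` from [hex_to_tets()].
#' @param spec the [phantom_spec()].
#' @return the mesh with `tissue` filled in; deterministic given `spec`.
#' @export
label_regions <- function(mesh, spec) {
  cen <- element_centroids(mesh, space = "param")
  x <- cen[, 1L]; y <- cen[, 2L]; z <- cen[, 3L]
  m <- length(x)
  lab <- rep("cortical", m)

  ## trabecular mid-core (lowest precedence above cortical)
  if (spec$trabecular_fraction > 0) {
    core <- abs(z - spec$t / 2) <= spec$trabecular_fraction * spec$t / 2
    clear <- rep(TRUE, m)
    margin <- max(spec$cell[1:2])
    for (b in spec$sutures) {
      if (!b$patent) next
      run <- if (b$axis == "longitudinal") spec$L else spec$W
      clear <- clear & band_distance(b, x, y, run) > b$width / 2 + margin
    }
    for (p in spec$pegs) {
      r <- sqrt((x - p$x)^2 + (y - p$y)^2)
      clear <- clear & r > p$radius + p$pdl_thickness + margin
    }
    lab[core & clear] <- "trabecular"
  }

  for (b in spec$sutures) {
    if (!b$patent) next
    run <- if (b$axis == "longitudinal") spec$L else spec$W
    lab[band_distance(b, x, y, run) <= b$width / 2] <- "suture"
  }

  for (p in spec$pegs) {
    r <- sqrt((x - p$x)^2 + (y - p$y)^2)
    in_len <- z <= p$length
    lab[in_len & r <= p$radius + p$pdl_thickness] <- "pdl"
    lab[in_len & r <= p$radius] <- "tooth"
    lab[in_len & r <= p$pulp_radius] <- "pulp"
  }

  mesh$tissue <- lab
  mesh
}

## bone region id (1..6 on the default topology) of flat points; regions
## are the rectangles between transverse band offsets crossed with the
## two sides of the longitudinal band. Returns NA inside no bone (never
## happens: regions tile the plate).
bone_regions <- function(spec) {
  tr <- sort(vapply(Filter(function(b) b$axis == "transverse", spec$sutures),
                    function(b) b$offset, numeric(1)))
  lo <- vapply(Filter(function(b) b$axis == "longitudinal", spec$sutures),
               function(b) b$offset, numeric(1))
  xb <- c(0, tr, spec$L)
  yb <- c(0, sort(lo), spec$W)
  list(xb = xb, yb = yb)
}

bone_name <- function(ix, iy, nx_reg, ny_reg) {
  xnm <- if (nx_reg == 3L) c("frontal", "parietal", "occipital")[ix]
    else paste0("x", ix)
  ynm <- if (ny_reg == 2L) c("left", "right")[iy] else paste0("y", iy)
  paste0("bone_", xnm, "_", ynm)
}

#' Construct the named node sets of a phantom
#'
#' Builds the constraint/attachment/measurement sites the analysis uses:
#' single-node bite sets at the ventral tips of the incisor and molar
#' pegs; single-node TMJ sets at the posterior ventral corners; lateral
#' muscle attachment patches; virtual gauge sites (IFS-analog on a
#' transverse band, SGS-analog on the longitudinal band, PB-analog on
#' bone >= 3 mm from any suture element); and per-bone surface node sets
#' (surface nodes touching no suture element, grouped by the bone
#' regions between bands).
#'
#' @param mesh labelled `tet_mesh`.
#' @param spec the [phantom_spec()].
#' @return the mesh with `node_sets` populated.
#' @export
make_node_sets <- function(mesh, spec) {
  par <- mesh$param %||% mesh$nodes
  sets <- list()

  pegs <- spec$pegs
  if (length(pegs) >= 4L) {
    ## pegs sorted anterior first, then left (low y) before right
    ord <- order(vapply(pegs, `[[`, numeric(1), "x"),
                 vapply(pegs, `[[`, numeric(1), "y"))
    pegs <- pegs[ord]
    sets$incisor_left  <- snap_node(mesh, c(pegs[[1L]]$x, pegs[[1L]]$y, 0))
    sets$incisor_right <- snap_node(mesh, c(pegs[[2L]]$x, pegs[[2L]]$y, 0))
    sets$molar_left    <- snap_node(mesh, c(pegs[[3L]]$x, pegs[[3L]]$y, 0))
    sets$molar_right   <- snap_node(mesh, c(pegs[[4L]]$x, pegs[[4L]]$y, 0))
  }
  sets$tmj_working   <- snap_node(mesh, c(spec$L, 0, spec$t / 2))
  sets$tmj_balancing <- snap_node(mesh, c(spec$L, spec$W, spec$t / 2))

  surf <- surface_nodes(mesh)
  ## lateral attachment patches on the side faces, posterior of the molars
  side_l <- surf[abs(par[surf, 2L]) < 1e-9 &
                   par[surf, 1L] >= 11 / 30 * spec$L &
                   par[surf, 1L] <= 19 / 30 * spec$L &
                   par[surf, 3L] >= spec$t / 2]
  side_r <- surf[abs(par[surf, 2L] - spec$W) < 1e-9 &
                   par[surf, 1L] >= 11 / 30 * spec$L &
                   par[surf, 1L] <= 19 / 30 * spec$L &
                   par[surf, 3L] >= spec$t / 2]
  if (length(side_l)) sets$muscle_attach_left <- side_l
  if (length(side_r)) sets$muscle_attach_right <- side_r

  ## gauge sites on the dorsal surface
  reg <- bone_regions(spec)
  tr_bands <- Filter(function(b) b$axis == "transverse" && b$patent, spec$sutures)
  lo_bands <- Filter(function(b) b$axis == "longitudinal" && b$patent, spec$sutures)
  top <- surf[abs(par[surf, 3L] - spec$t) < 1e-9]
  if (length(tr_bands)) {
    b <- tr_bands[[1L]]
    sets$gauge_ifs <- snap_node(mesh, c(b$offset, spec$W / 4, spec$t),
                                candidates = top)
  }
  if (length(lo_bands)) {
    b <- lo_bands[[1L]]
    xg <- spec$L / 2
    yg <- b$offset + b$amplitude * sin(2 * pi * xg / b$wavelength)
    sets$gauge_sgs <- snap_node(mesh, c(xg, yg, spec$t), candidates = top)
  }
  ## PB-analog: dorsal bone node maximally far from sutures; must be
  ## >= 3 mm from every suture element centroid
  sut_cen <- element_centroids(mesh, space = "param")[mesh$tissue == "suture", ,
                                                      drop = FALSE]
  if (nrow(sut_cen)) {
    cand <- top
    d2min <- min_dist2_to_points(par[cand, 1:2, drop = FALSE],
                                 sut_cen[, 1:2, drop = FALSE])
    best <- cand[which.max(d2min)]
    if (sqrt(max(d2min)) < 3)
      abort("no PB-analog gauge site >= 3 mm from sutures exists on this phantom")
    sets$gauge_pb <- best
  }

  ## per-bone surface sets: surface nodes adjacent only to bone tissue
  ## (suture-, tooth-, pulp- and pdl-adjacent nodes are not bone surface)
  soft <- unique(as.vector(mesh$elems[!mesh$tissue %in% c("cortical", "trabecular"),
                                      , drop = FALSE]))
  bone_surf <- setdiff(surf, soft)
  xb <- reg$xb; yb <- reg$yb
  for (ix in seq_len(length(xb) - 1L)) {
    for (iy in seq_len(length(yb) - 1L)) {
      inb <- bone_surf[par[bone_surf, 1L] >= xb[ix] & par[bone_surf, 1L] <= xb[ix + 1L] &
                         par[bone_surf, 2L] >= yb[iy] & par[bone_surf, 2L] <= yb[iy + 1L]]
      if (length(inb))
        sets[[bone_name(ix, iy, length(xb) - 1L, length(yb) - 1L)]] <- inb
    }
  }
  mesh$node_sets <- sets
  mesh
}

## squared distance from each row of `pts` (n x 2) to its nearest row of
## `ref` (m x 2), blockwise to bound memory
min_dist2_to_points <- function(pts, ref) {
  n <- nrow(pts)
  out <- rep(Inf, n)
  block <- max(1L, floor(2e6 / max(1L, nrow(ref))))
  for (s in seq(1L, n, by = block)) {
    idx <- s:min(n, s + block - 1L)
    d2 <- outer(pts[idx, 1L], ref[, 1L], "-")^2 +
      outer(pts[idx, 2L], ref[, 2L], "-")^2
    rmin <- d2[cbind(seq_along(idx), max.col(-d2, ties.method = "first"))]
    out[idx] <- pmin(out[idx], rmin)
  }
  out
}

#' Build a complete labelled phantom mesh
#'
#' Convenience wrapper: hex grid, tet subdivision, tissue labelling and
#' node sets in one call. Bit-deterministic given the spec.
#'
#' @param spec a [phantom_spec()]; default [default_phantom_spec()].
#' @return a labelled `tet_mesh` with node sets.
#' @export
build_phantom <- function(spec = default_phantom_spec()) {
  grid <- build_hex_grid(spec)
  mesh <- hex_to_tets(grid)
  mesh <- label_regions(mesh, spec)
  mesh <- make_node_sets(mesh, spec)
  mesh$spec <- spec
  validate_tet_mesh(mesh)
  mesh
}
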