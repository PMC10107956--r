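## Closed-form eigenvalues of symmetric 3x3 tensors (Cardano /
## trigonometric form), vectorised over rows of an m x 6 component
## matrix (exx, eyy, ezz, exy, exz, eyz). Returns descending columns.
sym3_eigenvalues <- function(eps) {
  exx <- eps[, 1L]; eyy <- eps[, 2L]; ezz <- eps[, 3L]
  exy <- eps[, 4L]; exz <- eps[, 5L]; eyz <- eps[, 6L]
  q <- (exx + eyy + ezz) / 3
  p2 <- (exx - q)^2 + (eyy - q)^2 + (ezz - q)^2 +
    2 * (exy^2 + exz^2 + eyz^2)
  p <- sqrt(p2 / 6)
  iso <- p <= .Machine$double.eps * pmax(abs(q), 1e-300)
  ps <- ifelse(iso, 1, p)             # avoid 0/0; isotropic handled below
  b11 <- (exx - q) / ps; b22 <- (eyy - q) / ps; b33 <- (ezz - q) / ps
  b12 <- exy / ps; b13 <- exz / ps; b23 <- eyz / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(1, pmax(-1, detB / 2))
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[iso] <- q[iso]; e2[iso] <- q[iso]; e3[iso] <- q[iso]
  cbind(e1 = e1, e2 = e2, e3 = e3)
}

#' Principal strains of a symmetric tensor
#'
#' Eigenvalues of a symmetric 3x3 strain tensor, sorted descending:
#' the first principal strain is the most tensile, the third the most
#' compressive.
#'
#' @param tensor symmetric 3x3 matrix (asymmetry beyond 1e-9 relative is
#'   rejected).
#' @return numeric length-3 `(e1, e2, e3)` in the units of the input.
#' @export
principal_strains <- function(tensor) {
  tensor <- as.matrix(tensor)
  scale <- max(abs(tensor), 1e-300)
  if (max(abs(tensor - t(tensor))) > 1e-9 * scale)
    abort("strain tensor is not symmetric")
  ev <- sym3_eigenvalues(cbind(tensor[1L, 1L], tensor[2L, 2L], tensor[3L, 3L],
                               (tensor[1L, 2L] + tensor[2L, 1L]) / 2,
                               (tensor[1L, 3L] + tensor[3L, 1L]) / 2,
                               (tensor[2L, 3L] + tensor[3L, 2L]) / 2))
  c(e1 = unname(ev[1L, 1L]), e2 = unname(ev[1L, 2L]),
    e3 = unname(ev[1L, 3L]))
}

#' Dominance ratio |e1 / e3|
#'
#' Classifies the local strain regime: ratio > 1 means tension
#' dominates, < 1 compression. When the compressive strain is below the
#' floor (1e-3 microstrain by default) the ratio is undefined and
#' `NA` is returned — a tension-dominated, degenerate-divisor sentinel.
#'
#' @param e1,e3 principal strains (microstrain), vectorised.
#' @param floor smallest `|e3|` treated as a valid divisor.
#' @return numeric vector of ratios, `NA` where undefined.
#' @export
dominance_ratio <- function(e1, e3, floor = 1e-3) {
  out <- abs(e1) / abs(e3)
  out[abs(e3) < floor] <- NA_real_
  out
}

#' Per-element and nodal principal strain field
#'
#' Converts a raw strain field to microstrain, decomposes every element
#' tensor into principal strains, computes the |e1:e3| dominance ratio,
#' and volume-weight-averages e1 and e3 onto the nodes (needed for
#' surface-node summaries and virtual gauges).
#'
#' @param mesh the `tet_mesh` the field was computed on.
#' @param strains a `strain_field` from [recover_strains()].
#' @return a tibble of class `principal_field` with columns `element`,
#'   `e1`, `e2`, `e3` (microstrain), `ratio`, `tension_dominated`;
#'   the nodal companion field is in `attr(, "nodal")` (tibble with
#'   `node`, `e1`, `e3`).
#' @export
principal_field <- function(mesh, strains) {
  eps_ue <- unclass(strains) * 1e6
  ev <- sym3_eigenvalues(eps_ue)
  ratio <- dominance_ratio(ev[, 1L], ev[, 3L])
  out <- tibble(element = seq_len(nrow(ev)),
                e1 = ev[, 1L], e2 = ev[, 2L], e3 = ev[, 3L],
                ratio = ratio,
                tension_dominated = is.na(ratio))
  V <- attr(strains, "volume")
  idx <- as.vector(mesh$elems)
  w <- rep(V, 4L)
  den <- rowsum(w, idx)
  nodal <- tibble(
    node = as.integer(rownames(den)),
    e1 = rowsum(w * rep(ev[, 1L], 4L), idx)[, 1L] / den[, 1L],
    e3 = rowsum(w * rep(ev[, 3L], 4L), idx)[, 1L] / den[, 1L]
  )
  structure(out, class = c("principal_field", class(out)),
            nodal = nodal, n_nodes = nrow(mesh$nodes))
}

#' Nodal principal strain field
#' @param field a `principal_field`.
#' @return tibble with `node`, `e1`, `e3` (microstrain).
#' @export
nodal_field <- function(field) attr(field, "nodal")

#' Sutured-vs-fused difference fields
#'
#' Per element and per principal component: the absolute difference
#' `|eps|_fused - |eps|_sutured` (positive where strain is higher when
#' sutures are absent/fused, negative where sutures elevate strain) and
#' the relative difference with the sutured magnitude as denominator,
#' floored at 1 microstrain.
#'
#' @param field_fused,field_sutured `principal_field`s computed on the
#'   identical mesh (the variants differ only in the material table).
#' @param floor denominator floor (microstrain).
#' @return tibble with `element`, `d_abs_e1`, `d_rel_e1`, `d_abs_e3`,
#'   `d_rel_e3`.
#' @export
difference_fields <- function(field_fused, field_sutured, floor = 1) {
  if (nrow(field_fused) != nrow(field_sutured) ||
      !identical(attr(field_fused, "n_nodes"), attr(field_sutured, "n_nodes")))
    abort("difference fields require the two variants of the same mesh")
  d_abs_e1 <- abs(field_fused$e1) - abs(field_sutured$e1)
  d_abs_e3 <- abs(field_fused$e3) - abs(field_sutured$e3)
  tibble(element = field_sutured$element,
         d_abs_e1 = d_abs_e1,
         d_rel_e1 = d_abs_e1 / pmax(abs(field_sutured$e1), floor),
         d_abs_e3 = d_abs_e3,
         d_rel_e3 = d_abs_e3 / pmax(abs(field_sutured$e3), floor))
}

#' Virtual strain gauge reading
#'
#' Averages the nodal principal strain field over a surface patch of
#' about 1 mm^2 (the footprint of a rosette strain gauge) centred on a
#' named gauge site. The patch is the set of surface nodes within the
#' disc radius `sqrt(area / pi)` of the site node, measured in flat
#' parametric coordinates.
#'
#' @param mesh a `tet_mesh` with gauge sites in its node sets.
#' @param field a `principal_field` (its nodal companion is used).
#' @param site gauge-site node-set name (e.g. `"gauge_ifs"`,
#'   `"gauge_sgs"`, `"gauge_pb"`).
#' @param area target patch area (mm^2), default 1.
#' @return one-row tibble: `site`, `n_nodes`, `area`, `e1_mean`,
#'   `e1_sd`, `e3_mean`, `e3_sd` (microstrain).
#' @export
virtual_gauge <- function(mesh, field, site, area = 1) {
  centre <- mesh$node_sets[[site]]
  if (is.null(centre) || length(centre) == 0L)
    abort(paste0("gauge site '", site, "' is missing or empty"))
  centre <- centre[1L]
  par <- mesh$param %||% mesh$nodes
  surf <- surface_nodes(mesh)
  r <- sqrt(area / pi)
  d2 <- rowSums((par[surf, , drop = FALSE] -
                   matrix(par[centre, ], length(surf), 3L, byrow = TRUE))^2)
  patch <- surf[d2 <= r^2]
  if (length(patch) < 3L)
    abort("gauge patch has fewer than 3 nodes; refine the mesh")
  nod <- nodal_field(field)
  vals <- nod[match(patch, nod$node), ]
  tibble(site = site, n_nodes = length(patch), area = area,
         e1_mean = mean(vals$e1), e1_sd = sd(vals$e1),
         e3_mean = mean(vals$e3), e3_sd = sd(vals$e3))
}

#' Per-bone surface strain summary
#'
#' Mean and SD of the nodal principal strains over each bone's surface
#' node set (surface nodes touching no suture element, grouped by the
#' bone regions between suture bands).
#'
#' @param mesh a `tet_mesh` with `bone_*` node sets.
#' @param field a `principal_field`.
#' @param bones bone set names; default all `bone_*` sets.
#' @return tibble: `bone`, `n_nodes`, `e1_mean`, `e1_sd`, `e3_mean`,
#'   `e3_sd` (microstrain).
#' @export
bone_surface_summary <- function(mesh, field, bones = NULL) {
  if (is.null(bones))
    bones <- grep("^bone_", names(mesh$node_sets), value = TRUE)
  if (length(bones) == 0L) abort("no bone surface sets on this mesh")
  nod <- nodal_field(field)
  rows <- lapply(bones, function(b) {
    s <- mesh$node_sets[[b]]
    if (is.null(s) || length(s) == 0L)
      abort(paste0("bone surface set '", b, "' is missing or empty"))
    vals <- nod[match(s, nod$node), ]
    tibble(bone = b, n_nodes = length(s),
           e1_mean = mean(vals$e1), e1_sd = sd(vals$e1),
           e3_mean = mean(vals$e3), e3_sd = sd(vals$e3))
  })
  dplyr::bind_rows(rows)
}

#' Suture-vs-adjacent-bone strain contrast
#'
#' Mean first principal strain inside suture elements against the mean
#' over bone elements whose centroids lie within `margin` of the nearest
#' suture element centroid — the headline "strain amplification inside
#' sutures" summary.
#'
#' @param mesh a labelled `tet_mesh`.
#' @param field a `principal_field`.
#' @param margin adjacency distance (mm), default 1.
#' @return one-row tibble: `suture_mean_e1`, `near_bone_mean_e1`,
#'   `amplification`, element counts.
#' @export
suture_amplification <- function(mesh, field, margin = 1) {
  cen <- element_centroids(mesh, space = "param")
  is_sut <- mesh$tissue == "suture"
  if (!any(is_sut)) abort("phantom has no suture elements")
  is_bone <- mesh$tissue %in% c("cortical", "trabecular")
  d2 <- min_dist2_to_points(cen[is_bone, 1:2, drop = FALSE],
                            cen[is_sut, 1:2, drop = FALSE])
  near <- which(is_bone)[d2 <= margin^2]
  sut_mean <- mean(field$e1[is_sut])
  near_mean <- mean(field$e1[near])
  tibble(suture_mean_e1 = sut_mean, near_bone_mean_e1 = near_mean,
         amplification = sut_mean / near_mean,
         n_suture = sum(is_sut), n_near_bone = length(near))
}
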