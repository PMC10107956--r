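#' Tissue material table
#'
#' All tissues are idealised as homogeneous, linear-elastic and
#' isotropic: each label maps to a Young's modulus E (MPa) and a
#' Poisson's ratio nu. Together with mm lengths this gives a consistent
#' mm-N-MPa unit system (forces in N, stresses in MPa).
#'
#' @param values tibble or data frame with columns `tissue`, `E`, `nu`.
#' @param variant `"sutured"` (patent sutures keep their soft-tissue
#'   properties) or `"fused"` (sutures take cortical bone properties).
#' @return a tibble of class `material_table` with columns `tissue`,
#'   `E`, `nu` and a `variant` attribute.
#' @export
material_table <- function(values, variant = "sutured") {
  tab <- as_tibble(values)[, c("tissue", "E", "nu")]
  if (!setequal(tab$tissue, TISSUE_LEVELS))
    abort("material table must contain exactly the six tissue labels")
  if (any(tab$E <= 0)) abort("Young's moduli must be positive")
  if (any(tab$nu < 0 | tab$nu >= 0.5))
    abort("Poisson's ratios must lie in [0, 0.5)")
  tab <- tab[match(TISSUE_LEVELS, tab$tissue), ]
  structure(tab, class = c("material_table", class(tab)), variant = variant)
}

#' Default tissue properties
#'
#' Nano-indentation-derived linear-elastic constants for the six cranial
#' tissues: cortical bone E = 19920 MPa (nu = 0.3), trabecular bone
#' 56 MPa (0.3), PDL 50 MPa (0.49), suture 20 MPa (0.49), tooth
#' (combined dentine/enamel, assigned enamel) 62370 MPa (0.33), pulp
#' 2 MPa (0.45).
#'
#' @param overrides optional named list `list(tissue = list(E =, nu =))`
#'   applied on top of the defaults.
#' @return a `material_table`, variant `"sutured"`.
#' @export
default_material_table <- function(overrides = NULL) {
  tab <- tibble(
    tissue = c("cortical", "trabecular", "suture", "tooth", "pulp", "pdl"),
    E = c(19920, 56, 20, 62370, 2, 50),
    nu = c(0.3, 0.3, 0.49, 0.33, 0.45, 0.49)
  )
  for (nm in names(overrides)) {
    i <- match(nm, tab$tissue)
    if (is.na(i)) abort(paste0("material override for unknown tissue '", nm, "'"))
    ov <- overrides[[nm]]
    if (!is.null(ov$E)) tab$E[i] <- ov$E
    if (!is.null(ov$nu)) tab$nu[i] <- ov$nu
  }
  material_table(tab, variant = "sutured")
}

#' Apply the sutured/fused experimental variant
#'
#' The fused variant simulates complete suture ossification by assigning
#' the cortical-bone properties to the suture entry; every other entry
#' is untouched. `"sutured"` returns the table unchanged. The operation
#' is idempotent.
#'
#' @param table a `material_table`.
#' @param variant `"sutured"` or `"fused"`.
#' @return a `material_table` with the `variant` attribute updated.
#' @export
apply_variant <- function(table, variant = c("sutured", "fused")) {
  variant <- match.arg(variant)
  if (variant == "fused") {
    i <- match("suture", table$tissue)
    j <- match("cortical", table$tissue)
    table$E[i] <- table$E[j]
    table$nu[i] <- table$nu[j]
  }
  attr(table, "variant") <- variant
  table
}

#' Lame parameters from engineering constants
#'
#' Standard isotropic conversion: `mu = E / (2 (1 + nu))`,
#' `lambda = E nu / ((1 + nu)(1 - 2 nu))`. The incompressible limit
#' nu = 0.5 is rejected.
#'
#' @param E Young's modulus (MPa), > 0.
#' @param nu Poisson's ratio, in (-1, 0.5).
#' @return named list with `lambda` and `mu` (MPa); vectorised over
#'   `E`/`nu`.
#' @export
lame_parameters <- function(E, nu) {
  if (any(E <= 0)) abort("E must be positive")
  if (any(nu <= -1 | nu >= 0.5))
    abort("nu must lie in (-1, 0.5); nu = 0.5 (incompressible) is unsupported")
  list(lambda = E * nu / ((1 + nu) * (1 - 2 * nu)),
       mu = E / (2 * (1 + nu)))
}

#' @export
print.material_table <- function(x, ...) {
  cat("<material_table> variant:", attr(x, "variant"), "\n")
  NextMethod()
}
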