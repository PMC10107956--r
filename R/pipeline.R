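#' Default phantom muscle set
#'
#' Two muscle groups per side, placed as fractions of the plate
#' dimensions so they scale with the phantom: a "masseter-analog" direct
#' strand group originating on the lateral attachment patch and pulling
#' ventrally toward an insertion below the plate, and a
#' "temporalis-analog" frictionless wrap anchored near the midline,
#' bending over the lateral edge to a distal point on the side face
#' (the bend presses the vault down and inward, loading the sagittal
#' band). Architecture values are config inputs, not anatomy: defaults
#' are rat-scale placeholders sized so total muscle force is a few tens
#' of newtons.
#'
#' @param spec the [phantom_spec()] the muscles attach to.
#' @param architecture optional tibble overriding the architecture
#'   columns (`name`, `mass_g`, `pennation_deg`, `fibre_length_cm`,
#'   `n_strands`, `wrap`); names must end in `_left`/`_right`.
#' @return list of [muscle_spec()] objects.
#' @export
default_muscles <- function(spec, architecture = NULL) {
  arch <- architecture %||% tibble(
    name = c("masseter_left", "masseter_right",
             "temporalis_left", "temporalis_right"),
    mass_g = c(1.3, 1.3, 0.9, 0.9),
    pennation_deg = c(15, 15, 0, 0),
    fibre_length_cm = c(1.0, 1.0, 1.2, 1.2),
    n_strands = c(4L, 4L, 1L, 1L),
    wrap = c(FALSE, FALSE, TRUE, TRUE)
  )
  L <- spec$L; W <- spec$W; t <- spec$t
  geom <- function(name, wrap) {
    left <- grepl("_left$", name)
    if (!left && !grepl("_right$", name))
      abort(paste0("muscle name '", name, "' must end in _left or _right"))
    yy <- function(y_left) if (left) y_left else W - y_left
    if (wrap) {
      list(origin_set = NULL, insertion = NULL,
           wrap = rbind(c(16 / 30 * L, yy(11 / 30 * W), t),
                        c(16 / 30 * L, yy(0), t),
                        c(16 / 30 * L, yy(0), 3 / 8 * t)))
    } else {
      list(origin_set = paste0("muscle_attach_", if (left) "left" else "right"),
           insertion = c(13 / 30 * L, yy(-4 / 15 * W), -3 * t),
           wrap = NULL)
    }
  }
  lapply(seq_len(nrow(arch)), function(i) {
    g <- geom(arch$name[i], isTRUE(arch$wrap[i]))
    muscle_spec(name = arch$name[i], mass = arch$mass_g[i],
                pennation = arch$pennation_deg[i],
                fibre_length = arch$fibre_length_cm[i],
                n_strands = arch$n_strands[i],
                origin_set = g$origin_set, insertion = g$insertion,
                wrap = g$wrap)
  })
}

#' Assemble all muscle nodal loads on a phantom
#'
#' Runs the architecture -> PCSA -> maximal force chain for every
#' muscle, then distributes forces as direct strands or wrapped-path
#' nodal forces.
#'
#' @param mesh a labelled `tet_mesh` with node sets.
#' @param muscles list of [muscle_spec()]s.
#' @return list with `loads` (tibble `muscle`, `node`, `fx`, `fy`,
#'   `fz`) and `forces` (per-muscle tibble with `pcsa_cm2`, `f_max_n`).
#' @export
build_muscle_loads <- function(mesh, muscles) {
  forces <- dplyr::bind_rows(lapply(muscles, function(ms) {
    pcsa <- compute_pcsa(ms)
    tibble(muscle = ms$name, pcsa_cm2 = pcsa,
           f_max_n = max_isometric_force(pcsa, ms$stress),
           wrapped = !is.null(ms$wrap))
  }))
  loads <- dplyr::bind_rows(lapply(seq_along(muscles), function(i) {
    ms <- muscles[[i]]
    if (!is.null(ms$wrap)) {
      wrapped_path_nodal_forces(mesh, ms$wrap, tension = forces$f_max_n[i],
                                name = ms$name)
    } else {
      discretize_strands(mesh, ms, f_max = forces$f_max_n[i])
    }
  }))
  list(loads = loads, forces = forces)
}

## constraint scheme shared by both load cases: balancing TMJ clamped in
## all three directions, working TMJ in anterior-posterior (x) and
## dorsoventral (z) only
tmj_constraints <- function(mesh) {
  dplyr::bind_rows(
    tibble(node = rep(mesh$node_sets$tmj_balancing, 3L),
           axis = c("x", "y", "z")),
    tibble(node = rep(mesh$node_sets$tmj_working, 2L),
           axis = c("x", "z"))
  )
}

#' Build a named bite load case on a phantom
#'
#' `incisor_bilateral` constrains the vertical DOF of one node on each
#' incisor peg tip; `molar_unilateral` constrains the vertical DOF at
#' the left (working-side) molar tip. Both add the TMJ scheme: the
#' balancing-side node clamped in all three directions, the
#' working-side node in the anterior-posterior and dorsoventral
#' directions.
#'
#' @param mesh a labelled `tet_mesh` with node sets.
#' @param name `"incisor_bilateral"` or `"molar_unilateral"`.
#' @param loads muscle load tibble from [build_muscle_loads()].
#' @return a [load_case()].
#' @export
build_load_case <- function(mesh, name = c("incisor_bilateral",
                                           "molar_unilateral"), loads) {
  name <- match.arg(name)
  bite_fixed <- if (name == "incisor_bilateral") {
    tibble(node = c(mesh$node_sets$incisor_left, mesh$node_sets$incisor_right),
           axis = "z")
  } else {
    tibble(node = mesh$node_sets$molar_left, axis = "z")
  }
  load_case(name, loads = loads,
            fixed = dplyr::bind_rows(bite_fixed, tmj_constraints(mesh)))
}

## rigid-body scenario mirroring a load case, using actual node positions
scenario_from_case <- function(mesh, name, loads) {
  mf <- tibble(x = mesh$nodes[loads$node, 1L],
               y = mesh$nodes[loads$node, 2L],
               z = mesh$nodes[loads$node, 3L],
               fx = loads$fx, fy = loads$fy, fz = loads$fz)
  wp <- mesh$nodes[mesh$node_sets$tmj_working, ]
  bp <- mesh$nodes[mesh$node_sets$tmj_balancing, ]
  if (name == "incisor_bilateral") {
    bite <- (mesh$nodes[mesh$node_sets$incisor_left, ] +
               mesh$nodes[mesh$node_sets$incisor_right, ]) / 2
    bite_scenario(bite, tmj_working = wp, tmj_balancing = bp,
                  muscle_forces = mf, laterality = "bilateral")
  } else {
    bite_scenario(mesh$nodes[mesh$node_sets$molar_left, ],
                  tmj_working = wp, tmj_balancing = bp,
                  muscle_forces = mf, laterality = "unilateral")
  }
}

## vertical bite reaction recovered at the constrained bite node(s)
fe_bite_reaction <- function(mesh, solution, name) {
  bite_nodes <- if (name == "incisor_bilateral") {
    c(mesh$node_sets$incisor_left, mesh$node_sets$incisor_right)
  } else {
    mesh$node_sets$molar_left
  }
  r <- solution$reactions
  sum(r$value[r$node %in% bite_nodes & r$axis == "z"])
}

#' Run the full sutured-vs-fused experiment
#'
#' For every requested load case, runs the sutured and the fused
#' material variant on the identical phantom mesh (two FE analyses per
#' loading case), cross-checks the FE bite reaction against the rigid
#' statics prediction, post-processes principal strain fields (virtual
#' gauges, per-bone surface summaries, difference fields) and
#' optionally writes VTK/CSV/JSON artifacts. Fully deterministic given
#' the configuration.
#'
#' @param config a validated configuration from [validate_config()], or
#'   `NULL` for the full default experiment.
#' @param out_dir output directory (overrides the config); `NULL`
#'   writes nothing.
#' @return a `run_report` object.
#' @export
run_experiment <- function(config = NULL, out_dir = NULL) {
  config <- config %||% validate_config(NULL)
  out_dir <- out_dir %||% config$out_dir
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) abort(paste0(
      "experiment stage '", what, "' failed: ", conditionMessage(e))))
  }
  mesh <- stage("phantom", build_phantom(config$spec))
  sutured <- stage("materials",
                   default_material_table(config$material_overrides))
  fused <- apply_variant(sutured, "fused")
  muscles <- stage("muscles", default_muscles(config$spec, config$architecture))
  ml <- stage("muscle_loads", build_muscle_loads(mesh, muscles))
  K <- list(sutured = stage("assembly", assemble_stiffness(mesh, sutured)),
            fused = stage("assembly", assemble_stiffness(mesh, fused)))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  cases <- list()
  for (case_name in config$load_cases) {
    lc <- stage("load_case", build_load_case(mesh, case_name, ml$loads))
    sc <- scenario_from_case(mesh, case_name, ml$loads)
    statics <- stage("bite_statics", if (case_name == "incisor_bilateral")
      solve_bilateral_bite(sc) else solve_unilateral_bite(sc))
    variants <- list()
    for (variant in c("sutured", "fused")) {
      tab <- if (variant == "sutured") sutured else fused
      sol <- stage("fe_solve", fe_solve(mesh, tab, lc, K = K[[variant]]))
      pf <- stage("strain_post",
                  principal_field(mesh, recover_strains(mesh, sol)))
      gauges <- dplyr::bind_rows(lapply(
        grep("^gauge_", names(mesh$node_sets), value = TRUE),
        function(s) virtual_gauge(mesh, pf, s)))
      variants[[variant]] <- list(
        solution = sol, field = pf,
        bite_reaction_n = fe_bite_reaction(mesh, sol, case_name),
        gauges = gauges,
        bones = bone_surface_summary(mesh, pf),
        amplification = if (any(mesh$tissue == "suture"))
          suture_amplification(mesh, pf))
    }
    diffs <- difference_fields(variants$fused$field, variants$sutured$field)
    files <- character()
    if (!is.null(out_dir)) {
      for (variant in c("sutured", "fused")) {
        v <- variants[[variant]]
        fp <- file.path(out_dir, paste0(case_name, "_", variant, ".vtk"))
        export_vtk(
          mesh, fp,
          cell_data = list(e1 = v$field$e1, e3 = v$field$e3,
                           dominance = v$field$ratio,
                           d_abs_e1 = diffs$d_abs_e1,
                           d_rel_e1 = diffs$d_rel_e1,
                           d_abs_e3 = diffs$d_abs_e3,
                           d_rel_e3 = diffs$d_rel_e3),
          point_data = list(displacement = v$solution$u,
                            e1_nodal = full_nodal(v$field, nrow(mesh$nodes), "e1"),
                            e3_nodal = full_nodal(v$field, nrow(mesh$nodes), "e3")),
          title = paste("suturefe", case_name, variant))
        files <- c(files, fp)
      }
    }
    cases[[case_name]] <- list(
      statics_bite_n = statics$bite_force,
      statics = statics,
      sutured = strip_heavy(variants$sutured),
      fused = strip_heavy(variants$fused),
      diff_extrema = list(
        d_abs_e1 = range(diffs$d_abs_e1), d_abs_e3 = range(diffs$d_abs_e3),
        d_rel_e1 = range(diffs$d_rel_e1), d_rel_e3 = range(diffs$d_rel_e3)),
      files = files,
      fields = list(sutured = variants$sutured$field,
                    fused = variants$fused$field, diffs = diffs))
  }

  report <- structure(
    list(config = config_echo(config),
         version = as.character(utils::packageVersion("suturefe")),
         muscle_forces = ml$forces,
         cases = cases,
         mesh = mesh),
    class = "run_report")
  if (!is.null(out_dir)) write_report_files(report, out_dir)
  report
}

full_nodal <- function(field, n, col) {
  out <- numeric(n)
  nod <- nodal_field(field)
  out[nod$node] <- nod[[col]]
  out
}

strip_heavy <- function(v) {
  list(bite_reaction_n = v$bite_reaction_n, gauges = v$gauges,
       bones = v$bones, amplification = v$amplification,
       residual = v$solution$residual,
       max_displacement_mm = max(abs(v$solution$u)),
       reactions = v$solution$reactions)
}

config_echo <- function(config) {
  sp <- config$spec
  list(phantom = list(L = sp$L, W = sp$W, t = sp$t, nx = sp$nx, ny = sp$ny,
                      nz = sp$nz, curvature = sp$curvature,
                      trabecular_fraction = sp$trabecular_fraction,
                      distortion = sp$distortion, seed = sp$seed,
                      n_sutures = length(sp$sutures), n_pegs = length(sp$pegs)),
       material_overrides = config$material_overrides,
       load_cases = config$load_cases,
       element_order = config$element_order,
       seed = config$seed)
}

write_report_files <- function(report, out_dir) {
  gauges <- dplyr::bind_rows(lapply(names(report$cases), function(cn) {
    dplyr::bind_rows(lapply(c("sutured", "fused"), function(vn) {
      g <- report$cases[[cn]][[vn]]$gauges
      g$load_case <- cn; g$variant <- vn
      g
    }))
  }))
  readr::write_csv(gauges, file.path(out_dir, "gauges.csv"))
  bones <- dplyr::bind_rows(lapply(names(report$cases), function(cn) {
    dplyr::bind_rows(lapply(c("sutured", "fused"), function(vn) {
      b <- report$cases[[cn]][[vn]]$bones
      b$load_case <- cn; b$variant <- vn
      b
    }))
  }))
  summary_tab <- dplyr::bind_rows(lapply(names(report$cases), function(cn) {
    cs <- report$cases[[cn]]
    tibble(load_case = cn,
           statics_bite_n = cs$statics_bite_n,
           fe_bite_sutured_n = cs$sutured$bite_reaction_n,
           fe_bite_fused_n = cs$fused$bite_reaction_n,
           amplification_sutured = cs$sutured$amplification$amplification %||%
             NA_real_)
  }))
  readr::write_csv(bones, file.path(out_dir, "summary_bones.csv"))
  readr::write_csv(summary_tab, file.path(out_dir, "summary.csv"))
  json <- list(config = report$config, version = report$version,
               cases = lapply(report$cases, function(cs) {
                 list(statics_bite_n = cs$statics_bite_n,
                      fe_bite_sutured_n = cs$sutured$bite_reaction_n,
                      fe_bite_fused_n = cs$fused$bite_reaction_n,
                      diff_extrema = cs$diff_extrema,
                      files = basename(cs$files))
               }))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> suturefe", x$version, "\n")
  for (cn in names(x$cases)) {
    cs <- x$cases[[cn]]
    cat("  ", cn, ": statics bite ", format(cs$statics_bite_n, digits = 5),
        " N; FE bite sutured ", format(cs$sutured$bite_reaction_n, digits = 5),
        " N, fused ", format(cs$fused$bite_reaction_n, digits = 5), " N\n",
        sep = "")
    if (!is.null(cs$sutured$amplification))
      cat("    suture strain amplification (sutured): ",
          format(cs$sutured$amplification$amplification, digits = 4), "x\n",
          sep = "")
  }
  invisible(x)
}

#' @describeIn run_experiment tidy method: gauge readings across cases
#'   and variants, one row per (load case, variant, site).
#' @param x a `run_report`.
#' @param ... unused.
#' @method tidy run_report
#' @export
tidy.run_report <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$cases), function(cn) {
    dplyr::bind_rows(lapply(c("sutured", "fused"), function(vn) {
      g <- x$cases[[cn]][[vn]]$gauges
      dplyr::bind_cols(tibble(load_case = cn, variant = vn), g)
    }))
  }))
}

#' Validate and complete a run configuration
#'
#' Accepts a YAML file path, a raw list, or `NULL` (all defaults), and
#' returns a fully populated `run_config`. Unknown keys and invalid
#' values are rejected with the offending field named. `element_order`
#' `"tet10"` is recognised but not implemented in this build.
#'
#' @param raw YAML path, list or `NULL`.
#' @return object of class `run_config`.
#' @export
validate_config <- function(raw = NULL) {
  cfg <- if (is.null(raw)) list()
  else if (is.character(raw)) yaml::read_yaml(raw)
  else if (is.list(raw)) raw
  else abort("config must be a YAML path, a list or NULL")
  cfg <- cfg %||% list()
  known <- c("phantom", "materials", "muscles", "load_cases",
             "element_order", "out_dir", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))

  seed <- as.integer(cfg$seed %||% 1L)
  ph <- cfg$phantom %||% list()
  known_ph <- c("L", "W", "t", "nx", "ny", "nz", "curvature", "distortion",
                "trabecular_fraction", "sutures", "pegs")
  unknown <- setdiff(names(ph), known_ph)
  if (length(unknown))
    abort(paste0("unknown phantom key(s): ", paste(unknown, collapse = ", ")))
  if (!is.null(ph$sutures))
    ph$sutures <- lapply(ph$sutures, function(s) do.call(suture_band, s))
  if (!is.null(ph$pegs))
    ph$pegs <- lapply(ph$pegs, function(p) do.call(tooth_peg, p))
  spec <- do.call(default_phantom_spec, c(ph, list(seed = seed)))

  overrides <- cfg$materials
  if (!is.null(overrides)) default_material_table(overrides)  # validates

  architecture <- NULL
  if (!is.null(cfg$muscles)) {
    if (is.character(cfg$muscles)) {
      if (!file.exists(cfg$muscles))
        abort(paste0("muscle CSV not found: ", cfg$muscles))
      architecture <- read_muscle_csv(cfg$muscles)
    } else {
      architecture <- dplyr::bind_rows(lapply(cfg$muscles, as_tibble))
    }
  }

  load_cases <- if ("load_cases" %in% names(cfg)) unlist(cfg$load_cases)
    else c("incisor_bilateral", "molar_unilateral")
  if (length(load_cases) == 0L) abort("at least one load case is required")
  bad <- setdiff(load_cases, c("incisor_bilateral", "molar_unilateral"))
  if (length(bad))
    abort(paste0("unknown load case(s): ", paste(bad, collapse = ", ")))

  element_order <- cfg$element_order %||% "tet4"
  if (identical(element_order, "tet10"))
    abort("element_order 'tet10' is not implemented in this build; use 'tet4'")
  if (!identical(element_order, "tet4"))
    abort("element_order must be 'tet4'")

  structure(list(spec = spec, material_overrides = overrides,
                 architecture = architecture, load_cases = load_cases,
                 element_order = element_order,
                 out_dir = cfg$out_dir, seed = seed),
            class = "run_config")
}
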