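# Parameter registry for the intima plaque model.
#
# Unit system is fixed package-wide to g, cm, day. Lipid levels given in mg/dL
# at the user interface are converted with 1 mg/dL = 1e-5 g cm^-3.

MGDL_TO_GCM3 <- 1e-5

# name, default, unit, group, positive-required
.param_registry <- function() {
  tribble_ <- function(...) {
    m <- matrix(c(...), ncol = 5, byrow = TRUE)
    tibble::tibble(
      name = m[, 1],
      value = as.numeric(m[, 2]),
      unit = m[, 3],
      group = m[, 4],
      description = m[, 5]
    )
  }
  tribble_(
    # -- oxidation kinetics -------------------------------------------------
    "k_L",      2.35e-4, "cm3/g/day", "reaction", "oxidation rate LDL + radical -> ox-LDL",
    "k_H",      5.29e-6, "cm3/g/day", "reaction", "oxidation rate HDL + radical -> ox-HDL",
    "lam_ox",   10,      "g/cm3/day", "production", "ox-LDL ingestion capacity of macrophages",
    # -- diffusion ----------------------------------------------------------
    "D_L",      29.89,   "cm2/day",   "diffusion", "LDL diffusivity",
    "D_H",      3.93,    "cm2/day",   "diffusion", "HDL diffusivity",
    "D_Lox",    29.89,   "cm2/day",   "diffusion", "ox-LDL diffusivity",
    "D_r",      0.205,   "cm2/day",   "diffusion", "free-radical diffusivity",
    "D_M",      8.64e-7, "cm2/day",   "diffusion", "macrophage diffusivity",
    "D_T",      8.64e-7, "cm2/day",   "diffusion", "T-cell diffusivity",
    "D_S",      8.64e-7, "cm2/day",   "diffusion", "SMC diffusivity",
    "D_F",      8.64e-7, "cm2/day",   "diffusion", "foam-cell diffusivity",
    "D_P",      17.28,   "cm2/day",   "diffusion", "MCP-1 diffusivity",
    "D_Ig",     1.08e2,  "cm2/day",   "diffusion", "IFN-gamma diffusivity",
    "D_I12",    1.08e2,  "cm2/day",   "diffusion", "IL-12 diffusivity",
    "D_G",      8.64e-2, "cm2/day",   "diffusion", "PDGF diffusivity",
    "D_Q",      4.32e-2, "cm2/day",   "diffusion", "MMP diffusivity",
    "D_Qr",     4.32e-2, "cm2/day",   "diffusion", "TIMP diffusivity",
    # -- production / activation -------------------------------------------
    "lam_MIg",  0.005,   "1/day",     "production", "macrophage activation by IFN-gamma",
    "lam_P",    8.65e-10,"g/cm3/day", "production", "MCP-1 production by endothelium",
    "lam_TI12", 1e6,     "1/day",     "production", "T-cell activation by IL-12",
    "lam_IgT",  0.066,   "1/day",     "production", "IFN-gamma production by T cells",
    "lam_I12M", 3e-7,    "g/cm3/day", "production", "IL-12 production by macrophages",
    "lam_I12F", 1e-7,    "g/cm3/day", "production", "IL-12 production by foam cells",
    "lam_GM",   0.1,     "1/day",     "production", "PDGF production by macrophages",
    "lam_GF",   0.033,   "1/day",     "production", "PDGF production by foam cells",
    "lam_GS",   0.5,     "1/day",     "production", "PDGF production by SMCs",
    "lam_QS",   3e-4,    "1/day",     "production", "MMP production by SMCs",
    "lam_QrS",  3e-5,    "1/day",     "production", "TIMP production by SMCs",
    "lam_QrM",  6e-5,    "1/day",     "production", "TIMP production by macrophages",
    "lam_rho",  0.432,   "1/day",     "production", "ECM remodeling rate",
    "lam_F",    0.12,    "1/day",     "production", "foam-cell activation (conversion) rate",
    # -- death / degradation ------------------------------------------------
    "d_M",      0.015,   "1/day",     "degradation", "macrophage death rate",
    "d_P",      1.73,    "1/day",     "degradation", "MCP-1 degradation rate",
    "d_T",      0.33,    "1/day",     "degradation", "T-cell death rate",
    "d_Ig",     0.69,    "1/day",     "degradation", "IFN-gamma degradation rate",
    "d_S",      0.86,    "1/day",     "degradation", "SMC death rate",
    "d_I12",    1.188,   "1/day",     "degradation", "IL-12 degradation rate",
    "d_G",      3.84,    "1/day",     "degradation", "PDGF degradation rate",
    "d_Q",      4.32,    "1/day",     "degradation", "MMP degradation rate",
    "d_Qr",     21.6,    "1/day",     "degradation", "TIMP degradation rate",
    "d_rhoQ",   2.59e7,  "cm3/g/day", "degradation", "ECM degradation rate by MMP",
    "d_F",      0.03,    "1/day",     "degradation", "foam-cell death rate",
    "d_r",      0.02,    "1/day",     "degradation", "free-radical quench rate (reconstruction)",
    # -- binding ------------------------------------------------------------
    "k_QQr",    4.98e8,  "cm3/g/day", "binding", "binding rate of MMP to TIMP",
    "k_QrQ",    1.04e9,  "cm3/g/day", "binding", "binding rate of TIMP to MMP",
    # -- chemotaxis / haptotaxis -------------------------------------------
    "chi_P",    10,      "cm5/g/day", "chemotaxis", "SMC chemotactic sensitivity to MCP-1",
    "chi_G",    10,      "cm5/g/day", "chemotaxis", "SMC chemotactic sensitivity to PDGF",
    "chi_rho",  1e-3,    "cm5/g/day", "chemotaxis", "SMC haptotactic sensitivity to ECM",
    # -- sources and boundary concentrations -------------------------------
    "r0",       0.26,    "g/cm3/day", "source", "free-radical source in the intima",
    "L0",       1.3e-3,  "g/cm3",     "boundary", "blood LDL concentration (130 mg/dL)",
    "H0",       5e-4,    "g/cm3",     "boundary", "blood HDL concentration (50 mg/dL)",
    "M0",       5e-5,    "g/cm3",     "boundary", "blood monocyte/macrophage density",
    "T0",       1e-3,    "g/cm3",     "boundary", "blood T-cell density",
    "S0",       6e-3,    "g/cm3",     "boundary", "SMC density in the media",
    "rho0",     1,       "g/cm3",     "boundary", "reference (packed) ECM density",
    "P0",       3e-10,   "g/cm3",     "boundary", "blood MCP-1 concentration",
    "G0",       1.5e-8,  "g/cm3",     "boundary", "blood PDGF concentration",
    # -- influx rates -------------------------------------------------------
    "beta_L",   1.0,     "1/cm",      "influx", "influx rate of LDL into the intima",
    "beta_H",   1.0,     "1/cm",      "influx", "influx rate of HDL into the intima",
    "beta_M",   0.2,     "1/cm",      "influx", "influx rate of macrophages into the intima",
    "beta_T",   0.05,    "1/cm",      "influx", "influx rate of T cells into the intima",
    "beta_S",   0.2,     "1/cm",      "influx", "influx rate of SMCs from the media",
    # -- saturation constants ----------------------------------------------
    "K_Lox",    0.5,     "g/cm3",     "saturation", "ox-LDL saturation (MCP-1 production, ingestion)",
    "K_M",      2.5e-5,  "g/cm3",     "saturation", "macrophage saturation (T-cell activation, IL-12)",
    "K_F",      2.5e-5,  "g/cm3",     "saturation", "foam-cell saturation (IL-12 production)",
    "K_Ig_act", 1e-11,   "g/cm3",     "saturation", "IFN-gamma saturation (macrophage activation)",
    "K_Ig_I12", 7e-11,   "g/cm3",     "saturation", "IFN-gamma saturation (IL-12 production)",
    "C_tot",    1,       "g/cm3",     "closure", "total cell + ECM density",
    # -- reconstruction closures (see methods vignette) ---------------------
    "s_lip",    1e-3,    "cm2/day",   "closure", "endothelial permeability scale for lipoproteins",
    "s_cell",   2.5e-4,  "cm2/day",   "closure", "transmigration permeability scale for cells",
    "a_M",      10,      "-",         "closure", "ox-LDL enhancement amplitude of monocyte influx",
    "K_MLox",   4e-4,    "g/cm3",     "closure", "ox-LDL scale of the monocyte influx enhancement",
    "K_actLox", 5e-5,    "g/cm3",     "closure", "ox-LDL half-saturation of macrophage activation",
    "H_ref",    4.5e-4,    "g/cm3",     "closure", "HDL scale of the anti-inflammatory damping",
    "n_H",      4,       "-",         "closure", "Hill exponent of the HDL damping",
    "delta_T",  0.0376,    "-",         "closure", "implicit MHC-II/IL-10 attenuation of T-cell activation",
    "w_ecm",    0.01,    "-",         "closure", "weight of the ECM turnover term in the pressure source",
    "gamma_adh",1e-9,    "sigma*cm",  "closure", "adhesion (surface tension) coefficient, sigma = gamma*kappa"
  )
}

#' Default model parameters
#'
#' Returns the full set of model constants in the package unit system
#' (g, cm, day): oxidation kinetics, diffusivities, production and
#' death/degradation rates, MMP-TIMP binding rates, chemotaxis coefficients,
#' boundary concentrations, influx rates, saturation constants, and the
#' documented reconstruction closures (see the methods vignette).
#'
#' @param as_tibble if `TRUE`, return the registry tibble with units, group
#'   and description columns; otherwise a named list of values.
#' @return A named list (default) or a tibble with columns `name`, `value`,
#'   `unit`, `group`, `description`.
#' @examples
#' p <- default_parameters()
#' p$k_L
#' @export
default_parameters <- function(as_tibble = FALSE) {
  reg <- .param_registry()
  if (as_tibble) return(reg)
  structure(as.list(stats::setNames(reg$value, reg$name)),
            class = "plaque_parameters")
}

#' Load parameters from a configuration
#'
#' Overlays user overrides on the defaults. Overrides may be a named list or a
#' path to a YAML file with a flat `parameters:` mapping. Unknown names and
#' non-positive values for positivity-constrained parameters are errors
#' (fail-closed).
#'
#' @param config named list of overrides, or a YAML file path, or `NULL`.
#' @return A `plaque_parameters` list.
#' @examples
#' p <- load_parameters(list(L0 = 1.9e-3, H0 = 4e-4))
#' @export
load_parameters <- function(config = NULL) {
  p <- default_parameters()
  if (is.null(config)) return(p)
  if (is.character(config) && length(config) == 1) {
    doc <- yaml::read_yaml(config)
    config <- if (!is.null(doc$parameters)) doc$parameters else doc
  }
  stopifnot(is.list(config))
  if (length(config) == 0) return(p)
  nm <- names(config)
  if (is.null(nm) || any(nm == "")) {
    stop("parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(nm, names(p))
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in nm) {
    v <- as.numeric(config[[k]])
    if (length(v) != 1 || !is.finite(v)) {
      stop("parameter '", k, "' must be a single finite number", call. = FALSE)
    }
    p[[k]] <- v
  }
  viol <- validate_parameters(p)
  hard <- viol[grepl("positive", viol)]
  if (length(hard) > 0) stop(paste(hard, collapse = "; "), call. = FALSE)
  p
}

# parameters that may legitimately be zero
.zero_ok <- c("a_M", "w_ecm", "n_H")

#' Validate a parameter set
#'
#' Checks the structural invariants of the model constants: strict positivity
#' of rates, diffusivities and saturations; the LDL oxidation rate exceeding
#' the HDL one (LDL is the preferred radical substrate); and the single shared
#' diffusivity for all cell species.
#'
#' @param p a `plaque_parameters` list.
#' @return Character vector of violations; empty when all invariants hold.
#' @examples
#' validate_parameters(default_parameters())
#' @export
validate_parameters <- function(p) {
  viol <- character(0)
  reg <- .param_registry()
  for (i in seq_len(nrow(reg))) {
    nmi <- reg$name[i]
    v <- p[[nmi]]
    if (is.null(v) || !is.finite(v)) {
      viol <- c(viol, paste0("parameter '", nmi, "' missing or non-finite"))
      next
    }
    if (!(nmi %in% .zero_ok) && v <= 0) {
      viol <- c(viol, paste0("parameter '", nmi, "' must be strictly positive"))
    }
  }
  if (is.finite(p$k_L) && is.finite(p$k_H) && p$k_L <= p$k_H) {
    viol <- c(viol, "k_L must exceed k_H (LDL oxidizes faster than HDL)")
  }
  cellD <- c(p$D_M, p$D_T, p$D_S, p$D_F)
  if (all(is.finite(cellD)) && diff(range(cellD)) > 0) {
    viol <- c(viol, "cell diffusivities D_M, D_T, D_S, D_F must be equal")
  }
  viol
}

#' Convert a per-molar rate to a mass-action rate
#'
#' Converts a binding/reaction rate expressed per molar per second to the
#' package's mass-action units (cm^3 g^-1 day^-1) for a species of molecular
#' weight `MW` (kDa): multiply by 86400 s/day and 1000 cm^3/L, divide by the
#' molar mass in g/mol (kDa * 1000).
#'
#' @param k_molar rate in 1/(M s).
#' @param MW molecular weight in kDa.
#' @return Rate in cm^3 g^-1 day^-1.
#' @examples
#' molar_to_mass_rate(3e5, 52)  # MMP-scale binding rate
#' @export
molar_to_mass_rate <- function(k_molar, MW) {
  stopifnot(all(k_molar >= 0))
  if (any(MW <= 0)) stop("MW must be positive", call. = FALSE)
  k_molar * 86400 * 1000 / (MW * 1000)
}

#' Invert [molar_to_mass_rate()]
#' @param k_mass rate in cm^3 g^-1 day^-1.
#' @param MW molecular weight in kDa.
#' @return Rate in 1/(M s).
#' @export
mass_to_molar_rate <- function(k_mass, MW) {
  stopifnot(all(k_mass >= 0))
  if (any(MW <= 0)) stop("MW must be positive", call. = FALSE)
  k_mass * (MW * 1000) / (86400 * 1000)
}

# tabulated protein diffusivities (cm2/day) and molecular weights (kDa)
.diffusion_table <- function() {
  tibble::tibble(
    species = c("LDL", "HDL", "oxLDL", "radical", "MCP1", "IFNg", "IL12",
                "PDGF", "MMP", "TIMP"),
    MW = c(549, 105, 549, 0.51, 8.9, 17, 70, 35, 52, 25),
    D = c(29.89, 3.93, 29.89, 0.205, 17.28, 108, 108, 0.0864, 0.0432, 0.0432)
  )
}

#' Protein diffusivity by molecular weight
#'
#' In `"tabulated"` mode returns the canonical diffusivity of a named species.
#' In `"estimated"` mode applies the accessible-surface-area scaling
#' `D = K * A(MW)` with `A(MW) = 6.3 * MW^0.73` (the empirical area law for
#' monomeric globular proteins) and `K` pinned so that the free radical entry
#' (MW 0.51 kDa, a glucose-sized molecule) reproduces its tabulated value.
#' The estimated mode is strictly increasing in MW; it is provided for
#' provenance and does not overwrite tabulated defaults.
#'
#' @param species species name (tabulated mode), one of the tabulated set.
#' @param MW molecular weight in kDa (estimated mode).
#' @param mode `"tabulated"` or `"estimated"`.
#' @return Diffusivity in cm^2/day.
#' @examples
#' area_scaled_diffusion("LDL")
#' area_scaled_diffusion(MW = 52, mode = "estimated")
#' @export
area_scaled_diffusion <- function(species = NULL, MW = NULL,
                                  mode = c("tabulated", "estimated")) {
  mode <- match.arg(mode)
  tab <- .diffusion_table()
  if (mode == "tabulated") {
    if (is.null(species) || !all(species %in% tab$species)) {
      stop("unknown species in tabulated mode", call. = FALSE)
    }
    return(tab$D[match(species, tab$species)])
  }
  if (is.null(MW) || any(MW <= 0)) stop("MW must be positive", call. = FALSE)
  area <- function(mw) 6.3 * (mw * 1000)^0.73   # Angstrom^2, MW in kDa
  K <- tab$D[tab$species == "radical"] / area(tab$MW[tab$species == "radical"])
  K * area(MW)
}

#' Sensitivity-analysis parameter ranges
#'
#' The 22 parameters screened in the global sensitivity analysis: the 15
#' production/activation rates, the 5 boundary influx rates, and the blood
#' lipid levels `L0` and `H0`. Ranges follow the halving/doubling convention
#' around the baseline except where a specific range is tabulated.
#'
#' @param p baseline parameters (defaults used when `NULL`).
#' @return Tibble with columns `name`, `lower`, `baseline`, `upper`, `unit`.
#' @examples
#' sensitivity_ranges()
#' @export
sensitivity_ranges <- function(p = NULL) {
  if (is.null(p)) p <- default_parameters()
  reg <- .param_registry()
  prod_names <- reg$name[reg$group == "production"]
  infl_names <- reg$name[reg$group == "influx"]
  nm <- c(prod_names, infl_names, "L0", "H0")
  base <- vapply(nm, function(k) p[[k]], numeric(1))
  lower <- base / 2
  upper <- base * 2
  # tabulated ranges that differ from the halving/doubling convention
  set_rng <- function(k, lo, hi) {
    i <- match(k, nm)
    lower[i] <<- lo; upper[i] <<- hi
  }
  set_rng("lam_MIg", 0.002, 0.01)
  set_rng("lam_rho", 0.266, 0.864)
  set_rng("L0", 7e-4, 1.9e-3)
  set_rng("H0", 4e-4, 6e-4)
  unit <- reg$unit[match(nm, reg$name)]
  tibble::tibble(name = nm, lower = unname(lower), baseline = unname(base),
                 upper = unname(upper), unit = unit)
}

#' Write the default parameter table as CSV
#'
#' @param path output file path.
#' @return The path, invisibly.
#' @export
dump_default_parameters <- function(path) {
  utils::write.csv(default_parameters(as_tibble = TRUE), path,
                   row.names = FALSE)
  invisible(path)
}

#' Convert lipid levels between mg/dL and g/cm^3
#' @param x numeric vector.
#' @return Converted vector.
#' @export
mgdl_to_gcm3 <- function(x) x * MGDL_TO_GCM3

#' @rdname mgdl_to_gcm3
#' @export
gcm3_to_mgdl <- function(x) x / MGDL_TO_GCM3
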