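## Gibbs-Thomson critical-radius theory for ice embryos.

# Avogadro's number, 1/mol
.N_A <- 6.02214076e23

.water_model_presets <- list(
  real = list(
    name = "real", M_w = 0.018, sigma = 29.1e-3, L = 6.02e3,
    rho_i = 917, T0 = 273.15),
  tip4p = list(
    name = "tip4p", M_w = 0.018, sigma = 23e-3, L = 4.4e3,
    rho_i = 944, T0 = 230.5)
)

#' Thermophysical parameters of a water model
#'
#' Bundles the constants entering the Gibbs-Thomson relation for one water
#' model: molecular weight, ice-water interfacial energy, latent heat of
#' fusion, ice density and melting temperature. Two presets are built in:
#' `"real"` (experimental water/ice values) and `"tip4p"` (the TIP4P model,
#' whose melting point is 230.5 K).
#'
#' @param name Preset name (`"real"` or `"tip4p"`), or an arbitrary label
#'   when all other arguments are supplied for a custom model.
#' @param M_w Molecular weight of water, kg/mol.
#' @param sigma Ice-water interfacial energy, J/m^2.
#' @param L Latent heat of fusion, J/mol.
#' @param rho_i Density of ice, kg/m^3.
#' @param T0 Melting temperature at atmospheric pressure, K.
#' @return An object of class `water_model` (a named list of the five
#'   constants plus the label).
#' @examples
#' water_model("real")
#' water_model("mymodel", M_w = 0.018, sigma = 25e-3, L = 5e3,
#'             rho_i = 930, T0 = 250)
#' @export
water_model <- function(name = "real", M_w = NULL, sigma = NULL, L = NULL,
                        rho_i = NULL, T0 = NULL) {
  custom <- !is.null(M_w) || !is.null(sigma) || !is.null(L) ||
    !is.null(rho_i) || !is.null(T0)
  if (!custom) {
    key <- tolower(name)
    if (!key %in% names(.water_model_presets))
      stop("unknown water model preset '", name, "'; available: ",
           paste(names(.water_model_presets), collapse = ", "))
    wm <- .water_model_presets[[key]]
  } else {
    vals <- list(M_w = M_w, sigma = sigma, L = L, rho_i = rho_i, T0 = T0)
    missing <- names(vals)[vapply(vals, is.null, logical(1))]
    if (length(missing))
      stop("custom water model requires all constants; missing: ",
           paste(missing, collapse = ", "))
    wm <- c(list(name = name), vals)
  }
  with(wm, {
    if (any(c(M_w, sigma, L, rho_i, T0) <= 0))
      stop("all water-model constants must be strictly positive")
    if (T0 < 150 || T0 > 400)
      stop("melting temperature T0 = ", T0, " K outside plausible [150, 400] K")
  })
  structure(wm, class = "water_model")
}

#' Load named water models from a YAML configuration file
#'
#' Reads a `water_models:` section mapping model names to the five
#' thermophysical constants (`M_w`, `sigma`, `L`, `rho_i`, `T0`).
#'
#' @param path Path to a YAML file.
#' @return A named list of [water_model()] objects.
#' @export
read_water_models <- function(path) {
  cfg <- yaml::read_yaml(path)
  sec <- cfg$water_models
  if (is.null(sec)) stop("no 'water_models' section in ", path)
  out <- lapply(names(sec), function(nm) {
    p <- sec[[nm]]
    water_model(nm, M_w = p$M_w, sigma = p$sigma, L = p$L,
                rho_i = p$rho_i, T0 = p$T0)
  })
  names(out) <- names(sec)
  out
}

#' @export
print.water_model <- function(x, ...) {
  cat(sprintf("Water model '%s'\n", x$name))
  cat(sprintf("  M_w   %-10g kg/mol\n", x$M_w))
  cat(sprintf("  sigma %-10g J/m^2\n", x$sigma))
  cat(sprintf("  L     %-10g J/mol\n", x$L))
  cat(sprintf("  rho_i %-10g kg/m^3\n", x$rho_i))
  cat(sprintf("  T0    %-10g K\n", x$T0))
  invisible(x)
}

#' Gibbs-Thomson critical radius of an ice embryo
#'
#' Radius at which an ice embryo of the given geometry is in equilibrium
#' with supercooled liquid water:
#' \deqn{R = A_g M_w \sigma T_0 / (L \rho_i (T_0 - T_r))}
#' with geometry constant \eqn{A_g = 2} for a sphere and 1 for a cylinder.
#' Crystals smaller than `R` melt; larger ones grow. Adsorbed AFPs exploit
#' this by forcing the growth front into curvatures below the critical
#' radius.
#'
#' @param params A [water_model()].
#' @param supercooling Supercooling `T0 - T_r` in K; must be positive and
#'   less than `T0`.
#' @param geometry `"spherical"` or `"cylindrical"`.
#' @return An object of class `critical_radius` with elements `R_m` and
#'   `R_angstrom` (the radius in metres and angstroms), `geometry`, `A_g`,
#'   `supercooling`, `params`, and for spheres `volume` (A^3) and
#'   `n_waters` (molecule count) of the embryo.
#' @examples
#' critical_radius(water_model("real"), supercooling = 1, "spherical")
#' critical_radius(water_model("tip4p"), supercooling = 5, "cylindrical")
#' @export
critical_radius <- function(params, supercooling,
                            geometry = c("spherical", "cylindrical")) {
  stopifnot(inherits(params, "water_model"))
  geometry <- match.arg(geometry)
  if (!is.numeric(supercooling) || length(supercooling) != 1 ||
      !is.finite(supercooling))
    stop("supercooling must be a finite number")
  if (supercooling <= 0)
    stop("supercooling must be > 0: the equilibrium radius is undefined ",
         "at or above the melting point")
  if (supercooling >= params$T0)
    stop("supercooling of ", supercooling, " K is >= T0 = ", params$T0, " K")
  A_g <- if (geometry == "spherical") 2 else 1
  R_m <- A_g * params$M_w * params$sigma * params$T0 /
    (params$L * params$rho_i * supercooling)
  out <- list(R_m = R_m, R_angstrom = R_m * 1e10, geometry = geometry,
              A_g = A_g, supercooling = supercooling, params = params)
  if (geometry == "spherical") {
    emb <- embryo_size(out$R_angstrom, params)
    out$volume <- emb$volume
    out$n_waters <- emb$n_waters
  }
  structure(out, class = "critical_radius")
}

#' Volume and molecule count of a spherical ice embryo
#'
#' @param R Radius in angstroms, `>= 0`.
#' @param params A [water_model()] supplying the ice density and molecular
#'   weight used for the molecule count.
#' @return List with `volume` (A^3) and `n_waters` (count, not rounded).
#' @examples
#' embryo_size(518, water_model("real"))
#' @export
embryo_size <- function(R, params) {
  stopifnot(inherits(params, "water_model"))
  if (!is.numeric(R) || length(R) != 1 || !is.finite(R))
    stop("R must be a finite number")
  if (R < 0) stop("embryo radius must be >= 0")
  volume <- 4 / 3 * pi * R^3                    # A^3
  mass <- volume * 1e-30 * params$rho_i         # kg
  n_waters <- mass / params$M_w * .N_A
  list(volume = volume, n_waters = n_waters)
}

#' @export
print.critical_radius <- function(x, ...) {
  cat(sprintf("Gibbs-Thomson critical radius (%s, %s water model)\n",
              x$geometry, x$params$name))
  cat(sprintf("  supercooling  %g K\n", x$supercooling))
  cat(sprintf("  R             %s m  (%s Angstrom)\n",
              signif(x$R_m, 3), signif(x$R_angstrom, 3)))
  if (x$geometry == "spherical") {
    cat(sprintf("  embryo volume %s A^3\n", signif(x$volume, 3)))
    cat(sprintf("  molecules     %s\n", signif(x$n_waters, 2)))
  }
  invisible(x)
}

#' Compare a fitted ice-front radius with Gibbs-Thomson theory
#'
#' @param fitted_radius Fitted front curvature radius, angstroms.
#' @param params A [water_model()].
#' @param supercooling Supercooling in K.
#' @param geometry Geometry of the theoretical radius (default cylindrical,
#'   matching a front pinned between periodic adsorption sites).
#' @return List of class `gibbs_thomson_comparison` with the fitted and
#'   theoretical radii (angstroms) and their dimensionless `ratio`.
#' @examples
#' compare_gibbs_thomson(46, water_model("tip4p"), supercooling = 5)
#' @export
compare_gibbs_thomson <- function(fitted_radius, params, supercooling,
                                  geometry = "cylindrical") {
  if (inherits(fitted_radius, "cylinder_fit")) {
    if (!fitted_radius$finite)
      stop("front profile has no finite curvature; nothing to compare")
    fitted_radius <- fitted_radius$radius
  }
  if (!is.numeric(fitted_radius) || !is.finite(fitted_radius) ||
      fitted_radius <= 0)
    stop("fitted_radius must be a positive finite number (in angstroms)")
  theory <- critical_radius(params, supercooling, geometry)
  structure(list(fitted_radius = fitted_radius,
                 theoretical_radius = theory$R_angstrom,
                 ratio = fitted_radius / theory$R_angstrom,
                 geometry = geometry, supercooling = supercooling,
                 params = params),
            class = "gibbs_thomson_comparison")
}

#' @export
print.gibbs_thomson_comparison <- function(x, ...) {
  cat("Fitted front radius vs Gibbs-Thomson theory\n")
  cat(sprintf("  fitted      %.1f A\n", x$fitted_radius))
  cat(sprintf("  theoretical %.1f A (%s, %s, dT = %g K)\n",
              x$theoretical_radius, x$params$name, x$geometry,
              x$supercooling))
  cat(sprintf("  ratio       %.3f\n", x$ratio))
  invisible(x)
}
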