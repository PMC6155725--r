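#' Generalized Guinier-Porod parameter set
#'
#' One scatterer component of the generalized Guinier-Porod model
#' (Hammouda's empirical unification of the Guinier and Porod regimes).
#' The scattered intensity is piecewise:
#' \deqn{I(q) = I_0\, q^{-s} \exp\!\big(-q^2 R_g^2/(3-s)\big), \quad q \le q_1}
#' \deqn{I(q) = D\, q^{-d}, \quad q \ge q_1}
#' where the crossover \eqn{q_1} and the Porod prefactor \eqn{D} are fixed
#' by requiring the two branches to agree in value and logarithmic slope
#' at \eqn{q_1} (see [ggp_crossover()] and [ggp_porod_prefactor()]).
#'
#' @param i0 Forward intensity I(0), arbitrary units, > 0.
#' @param rg Radius of gyration, nm, > 0.
#' @param d Porod exponent (high-q power-law slope), dimensionless;
#'   must exceed `s`. d = 4 for sharp interfaces.
#' @param s Dimensionality parameter: 0 for globular (sphere-like)
#'   scatterers, 1 for rods, 2 for lamellae; must satisfy 0 <= s < 3.
#' @return An object of class `ggp_params`.
#' @export
#' @examples
#' p <- ggp_params(i0 = 1, rg = 1.6, d = 4, s = 0)
#' ggp_crossover(p)   # sqrt(6)/1.6
ggp_params <- function(i0, rg, d = 4, s = 0) {
  if (!(i0 > 0)) stop("`i0` must be > 0", call. = FALSE)
  if (!(rg > 0)) stop("`rg` must be > 0", call. = FALSE)
  if (!(s >= 0 && s < 3))
    stop("`s` must satisfy 0 <= s < 3", call. = FALSE)
  if (!(d > s)) stop("`d` must exceed `s`", call. = FALSE)
  structure(list(i0 = i0, rg = rg, d = d, s = s), class = "ggp_params")
}

#' @export
print.ggp_params <- function(x, ...) {
  cat(sprintf("<ggp_params> I0 = %.4g, Rg = %.4g nm, d = %.3g, s = %.3g (q1 = %.4g nm^-1)\n",
              x$i0, x$rg, x$d, x$s, ggp_crossover(x)))
  invisible(x)
}

#' Porod power-law parameter set
#'
#' A pure power law I(q) = D q^-d with no Guinier rollover, used for
#' scatterers whose size exceeds the instrument window (here, the
#' low-q "shoulder" from microfibril bundles > 50 nm).
#'
#' @param prefactor Porod prefactor D, a.u. nm^-d, > 0.
#' @param d Power-law exponent; defaults to 4 (sharp interfaces). Must
#'   lie in (0, `d_max`].
#' @param d_max Configurable upper bound on `d`.
#' @return An object of class `porod_params`.
#' @export
porod_params <- function(prefactor, d = 4, d_max = 4) {
  if (!(prefactor > 0)) stop("`prefactor` must be > 0", call. = FALSE)
  if (!(d > 0 && d <= d_max))
    stop(sprintf("`d` must lie in (0, %g]", d_max), call. = FALSE)
  structure(list(prefactor = prefactor, d = d), class = "porod_params")
}

#' @export
print.porod_params <- function(x, ...) {
  cat(sprintf("<porod_params> D = %.4g, d = %.3g\n", x$prefactor, x$d))
  invisible(x)
}

#' Debye-Bueche parameter set
#'
#' I(q) = A / (1 + xi^2 q^2)^2 — scattering from long-range density
#' inhomogeneities in gels; `xi` is the correlation length.
#'
#' @param amplitude Forward intensity A, a.u., > 0.
#' @param xi Correlation length, nm, > 0.
#' @return An object of class `db_params`.
#' @export
db_params <- function(amplitude, xi) {
  if (!(amplitude > 0)) stop("`amplitude` must be > 0", call. = FALSE)
  if (!(xi > 0)) stop("`xi` must be > 0", call. = FALSE)
  structure(list(amplitude = amplitude, xi = xi), class = "db_params")
}

#' Ornstein-Zernike parameter set
#'
#' I(q) = A / (1 + xi^2 q^2) — thermal concentration fluctuations of
#' polymer chains; `xi` is the correlation length.
#'
#' @inheritParams db_params
#' @return An object of class `oz_params`.
#' @export
oz_params <- function(amplitude, xi) {
  if (!(amplitude > 0)) stop("`amplitude` must be > 0", call. = FALSE)
  if (!(xi > 0)) stop("`xi` must be > 0", call. = FALSE)
  structure(list(amplitude = amplitude, xi = xi), class = "oz_params")
}

#' @export
print.db_params <- function(x, ...) {
  cat(sprintf("<db_params> A = %.4g, xi = %.4g nm\n", x$amplitude, x$xi))
  invisible(x)
}

#' @export
print.oz_params <- function(x, ...) {
  cat(sprintf("<oz_params> A = %.4g, xi = %.4g nm\n", x$amplitude, x$xi))
  invisible(x)
}

#' Composite scattering model
#'
#' An additive model for one profile: zero or more generalized
#' Guinier-Porod components, an optional pure-Porod shoulder, and an
#' optional flat background. Component intensities are summed.
#'
#' @param ggp A list of [ggp_params()] objects (possibly empty).
#' @param porod An optional [porod_params()] shoulder.
#' @param background Optional flat background, a.u., >= 0 (`NULL` for
#'   none).
#' @return An object of class `saxs_composite`.
#' @export
composite_model <- function(ggp = list(), porod = NULL, background = NULL) {
  if (inherits(ggp, "ggp_params")) ggp <- list(ggp)
  if (!all(vapply(ggp, inherits, logical(1), "ggp_params")))
    stop("`ggp` must be a list of ggp_params", call. = FALSE)
  if (!is.null(porod) && !inherits(porod, "porod_params"))
    stop("`porod` must be porod_params or NULL", call. = FALSE)
  if (!is.null(background) && !(is.numeric(background) && background >= 0))
    stop("`background` must be a nonnegative number or NULL", call. = FALSE)
  if (length(ggp) == 0 && is.null(porod) && is.null(background))
    stop("composite model needs at least one component", call. = FALSE)
  structure(list(ggp = ggp, porod = porod, background = background),
            class = "saxs_composite")
}

#' @export
print.saxs_composite <- function(x, ...) {
  cat(sprintf("<saxs_composite> %d GGP component(s)%s%s\n",
              length(x$ggp),
              if (!is.null(x$porod)) " + Porod shoulder" else "",
              if (!is.null(x$background)) " + flat background" else ""))
  for (g in x$ggp) print(g)
  if (!is.null(x$porod)) print(x$porod)
  if (!is.null(x$background)) cat(sprintf("  background = %.4g a.u.\n", x$background))
  invisible(x)
}

#' Guinier-Porod crossover momentum transfer
#'
#' The q at which the Guinier and Porod branches of the generalized
#' Guinier-Porod model meet with matching value and log-slope:
#' \deqn{q_1 = \frac{1}{R_g}\sqrt{\frac{(d-s)(3-s)}{2}}}
#'
#' @param params A [ggp_params()] object.
#' @return Crossover q1 in nm^-1 (strictly positive).
#' @export
ggp_crossover <- function(params) {
  stopifnot(inherits(params, "ggp_params"))
  with(params, sqrt((d - s) * (3 - s) / 2) / rg)
}

#' Porod prefactor of a generalized Guinier-Porod component
#'
#' The prefactor D that makes the power-law branch continuous with the
#' Guinier branch at the crossover:
#' \deqn{D = I_0\, q_1^{\,d-s} \exp\!\big(-q_1^2 R_g^2/(3-s)\big)}
#'
#' @param params A [ggp_params()] object.
#' @return Prefactor D in a.u. nm^-d.
#' @export
ggp_porod_prefactor <- function(params) {
  q1 <- ggp_crossover(params)
  with(params, i0 * q1^(d - s) * exp(-q1^2 * rg^2 / (3 - s)))
}

#' Generalized Guinier-Porod intensity
#'
#' Evaluates the piecewise model of [ggp_params()] on a q grid. Both
#' branches agree in value and logarithmic slope at the crossover
#' [ggp_crossover()].
#'
#' @param params A [ggp_params()] object.
#' @param q Numeric vector of momentum transfer, nm^-1, all > 0.
#' @return Intensities in arbitrary units.
#' @export
ggp_intensity <- function(params, q) {
  stopifnot(inherits(params, "ggp_params"))
  if (any(q <= 0)) stop("q must be strictly positive", call. = FALSE)
  q1 <- ggp_crossover(params)
  D <- ggp_porod_prefactor(params)
  out <- numeric(length(q))
  lo <- q <= q1
  out[lo] <- params$i0 * q[lo]^(-params$s) *
    exp(-q[lo]^2 * params$rg^2 / (3 - params$s))
  out[!lo] <- D * q[!lo]^(-params$d)
  out
}

#' Porod power-law intensity
#'
#' @param params A [porod_params()] object.
#' @param q Numeric vector, nm^-1, all > 0.
#' @return `prefactor * q^-d`.
#' @export
porod_intensity <- function(params, q) {
  stopifnot(inherits(params, "porod_params"))
  if (any(q <= 0)) stop("q must be strictly positive", call. = FALSE)
  params$prefactor * q^(-params$d)
}

#' Debye-Bueche intensity
#'
#' @param params A [db_params()] object.
#' @param q Numeric vector, nm^-1, all >= 0.
#' @return `A / (1 + xi^2 q^2)^2`.
#' @export
debye_bueche_intensity <- function(params, q) {
  stopifnot(inherits(params, "db_params"))
  if (any(q < 0)) stop("q must be nonnegative", call. = FALSE)
  params$amplitude / (1 + params$xi^2 * q^2)^2
}

#' Ornstein-Zernike intensity
#'
#' @param params An [oz_params()] object.
#' @param q Numeric vector, nm^-1, all >= 0.
#' @return `A / (1 + xi^2 q^2)`.
#' @export
ornstein_zernike_intensity <- function(params, q) {
  stopifnot(inherits(params, "oz_params"))
  if (any(q < 0)) stop("q must be nonnegative", call. = FALSE)
  params$amplitude / (1 + params$xi^2 * q^2)
}

#' Composite model intensity
#'
#' Elementwise sum of all component intensities plus any flat
#' background.
#'
#' @param model A [composite_model()].
#' @param q Numeric vector, nm^-1, all > 0.
#' @return Intensities in arbitrary units.
#' @export
composite_intensity <- function(model, q) {
  stopifnot(inherits(model, "saxs_composite"))
  out <- numeric(length(q))
  for (g in model$ggp) out <- out + ggp_intensity(g, q)
  if (!is.null(model$porod)) out <- out + porod_intensity(model$porod, q)
  if (!is.null(model$background)) out <- out + model$background
  out
}

#' Equivalent-sphere diameter from a radius of gyration
#'
#' For a uniform sphere of radius R, R^2 = (5/3) Rg^2; the diameter is
#' therefore 2 sqrt(5/3) Rg.
#'
#' @param rg Radius of gyration, nm, >= 0 (vectorized).
#' @return Sphere diameter 2R in nm.
#' @export
#' @examples
#' sphere_diameter(1.6)   # 4.13 nm, the microfibril-like aggregate
sphere_diameter <- function(rg) {
  if (any(rg < 0, na.rm = TRUE)) stop("`rg` must be nonnegative", call. = FALSE)
  2 * sqrt(5 / 3) * rg
}

#' Kratky-plot peak position of a Guinier-Porod component
#'
#' The argmax over q of q^2 I(q). On the Guinier branch with s < 2 the
#' maximum has the closed form
#' \deqn{q^* = \frac{1}{R_g}\sqrt{\frac{(2-s)(3-s)}{2}},}
#' which reduces to sqrt(3)/Rg for globular scatterers (s = 0). The
#' closed form applies whenever q* < q1 (always true when d > 2);
#' otherwise the peak is located numerically on a dense grid.
#'
#' @param params A [ggp_params()] object with s < 2.
#' @param q_range Search window (nm^-1) for the numeric fallback.
#' @param n_grid Grid size for the numeric fallback.
#' @return Peak position q* in nm^-1.
#' @export
kratky_peak_q <- function(params, q_range = c(1e-3, 1e2), n_grid = 1e5) {
  stopifnot(inherits(params, "ggp_params"))
  if (params$s >= 2)
    stop("no Kratky peak in the Guinier branch for s >= 2", call. = FALSE)
  q_star <- sqrt((2 - params$s) * (3 - params$s) / 2) / params$rg
  q1 <- ggp_crossover(params)
  if (q_star < q1) return(q_star)
  # peak sits at the branch boundary region: locate numerically
  qs <- exp(seq(log(q_range[1]), log(q_range[2]), length.out = n_grid))
  k <- qs^2 * ggp_intensity(params, qs)
  i <- which.max(k)
  if (i == 1 || i == n_grid)
    stop("no interior Kratky maximum on the evaluated range", call. = FALSE)
  qs[i]
}

#' Serialize model parameters to a flat key-value list
#'
#' Flattens a composite (or correlation-length) model into the key
#' scheme `i0`, `rg`, `d`, `s` per GGP section, `D`/`d` for the
#' shoulder, `A`/`xi` for correlation models and `background`.
#'
#' @param model A [composite_model()], [db_params()] or [oz_params()].
#' @return A named list of named numeric lists, one per component
#'   (`ggp1`, `ggp2`, ..., `porod`, `background`; or `debye_bueche` /
#'   `ornstein_zernike`).
#' @export
model_to_config <- function(model) {
  if (inherits(model, "db_params"))
    return(list(debye_bueche = list(A = model$amplitude, xi = model$xi)))
  if (inherits(model, "oz_params"))
    return(list(ornstein_zernike = list(A = model$amplitude, xi = model$xi)))
  stopifnot(inherits(model, "saxs_composite"))
  out <- list()
  for (k in seq_along(model$ggp)) {
    g <- model$ggp[[k]]
    out[[paste0("ggp", k)]] <-
      list(i0 = g$i0, rg = g$rg, d = g$d, s = g$s)
  }
  if (!is.null(model$porod))
    out$porod <- list(D = model$porod$prefactor, d = model$porod$d)
  if (!is.null(model$background))
    out$background <- list(background = model$background)
  out
}

#' Rebuild a model from its flat key-value form
#'
#' Inverse of [model_to_config()].
#'
#' @param config A list as produced by [model_to_config()].
#' @return The reconstructed model object.
#' @export
model_from_config <- function(config) {
  nm <- names(config)
  if (identical(nm, "debye_bueche"))
    return(db_params(config[[1]]$A, config[[1]]$xi))
  if (identical(nm, "ornstein_zernike"))
    return(oz_params(config[[1]]$A, config[[1]]$xi))
  ggp <- lapply(config[grepl("^ggp", nm)], function(x)
    ggp_params(x$i0, x$rg, x$d, x$s))
  porod <- if ("porod" %in% nm)
    porod_params(config$porod$D, config$porod$d, d_max = 4.5) else NULL
  bg <- if ("background" %in% nm) config$background$background else NULL
  composite_model(ggp = unname(ggp), porod = porod, background = bg)
}
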