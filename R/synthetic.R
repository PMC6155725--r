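#' Instrument configuration for simulated measurements
#'
#' Describes the q grid of a laboratory SAXS camera. Defaults mirror a
#' Cu K-alpha pinhole setup with a 700 mm sample-detector distance:
#' q = 0.142-2.844 nm^-1, wavelength 0.154 nm.
#'
#' @param q_min,q_max Grid limits, nm^-1; 0 < q_min < q_max.
#' @param n_points Number of grid points, >= 8 (default 256).
#' @param spacing `"linear"` or `"log"` (geometric) spacing.
#' @param wavelength Source wavelength in nm; metadata only.
#' @return An object of class `instrument_config`.
#' @export
instrument_config <- function(q_min = 0.142, q_max = 2.844, n_points = 256,
                              spacing = c("linear", "log"),
                              wavelength = 0.154) {
  spacing <- match.arg(spacing)
  if (!(q_min > 0 && q_min < q_max))
    stop("need 0 < q_min < q_max", call. = FALSE)
  if (n_points < 8) stop("`n_points` must be >= 8", call. = FALSE)
  structure(list(q_min = q_min, q_max = q_max, n_points = as.integer(n_points),
                 spacing = spacing, wavelength = wavelength),
            class = "instrument_config")
}

#' @export
print.instrument_config <- function(x, ...) {
  cat(sprintf("<instrument_config> q = %g-%g nm^-1, %d points (%s), lambda = %g nm\n",
              x$q_min, x$q_max, x$n_points, x$spacing, x$wavelength))
  invisible(x)
}

#' Noise model for simulated profiles
#'
#' @param kind `"multiplicative_gaussian"` (default): each intensity is
#'   multiplied by `1 + level * N(0,1)`, i.e. `level` is the relative
#'   standard deviation. `"poisson_count"`: intensities are scaled so the
#'   curve maximum corresponds to `level` expected counts, Poisson
#'   sampled, and rescaled.
#' @param level Relative sd (gaussian; default 0.02, a typical
#'   laboratory-source figure) or expected counts at the maximum
#'   (poisson). Must be > 0.
#' @param seed Integer RNG seed; identical seeds reproduce identical
#'   profiles bit-for-bit.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("multiplicative_gaussian", "poisson_count"),
                        level = 0.02, seed = 1L) {
  kind <- match.arg(kind)
  if (!(level > 0)) stop("`level` must be > 0", call. = FALSE)
  structure(list(kind = kind, level = level, seed = as.integer(seed)),
            class = "noise_model")
}

#' Build the instrument q grid
#'
#' @param config An [instrument_config()].
#' @return Strictly increasing numeric vector of `n_points` values
#'   spanning `[q_min, q_max]` inclusive.
#' @export
make_q_grid <- function(config = instrument_config()) {
  stopifnot(inherits(config, "instrument_config"))
  with(config, switch(spacing,
    linear = seq(q_min, q_max, length.out = n_points),
    log = exp(seq(log(q_min), log(q_max), length.out = n_points))
  ))
}

model_curve <- function(model, q) {
  if (inherits(model, "saxs_composite")) composite_intensity(model, q)
  else if (inherits(model, "db_params")) debye_bueche_intensity(model, q)
  else if (inherits(model, "oz_params")) ornstein_zernike_intensity(model, q)
  else stop("unsupported model class: ", paste(class(model), collapse = "/"),
            call. = FALSE)
}

# Run `expr` under a local RNG seeded with `seed`, restoring global state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a noisy scattering profile from a model
#'
#' Evaluates a composite, Debye-Bueche or Ornstein-Zernike model on the
#' instrument grid and applies the noise model. The `sigma` column holds
#' the true per-point standard deviation of the noise process, and the
#' seed is recorded in the profile label.
#'
#' @param model A [composite_model()], [db_params()] or [oz_params()].
#' @param config An [instrument_config()].
#' @param noise A [noise_model()], or `NULL` for a noise-free curve.
#' @param label Sample label; defaults to a seed-stamped tag.
#' @param concentration Optional concentration metadata, mol %.
#' @return A [saxs_profile()].
#' @export
simulate_profile <- function(model, config = instrument_config(),
                             noise = noise_model(), label = NULL,
                             concentration = NULL) {
  q <- make_q_grid(config)
  mu <- model_curve(model, q)
  if (is.null(noise)) {
    return(saxs_profile(q, mu, NULL,
                        label = if (is.null(label)) "noise-free" else label,
                        concentration = concentration))
  }
  stopifnot(inherits(noise, "noise_model"))
  if (noise$kind == "multiplicative_gaussian") {
    sd_true <- noise$level * abs(mu)
    i <- with_seed(noise$seed, mu * (1 + noise$level * stats::rnorm(length(q))))
  } else {
    scale <- noise$level / max(mu)
    counts <- with_seed(noise$seed, stats::rpois(length(q), lambda = mu * scale))
    i <- counts / scale
    sd_true <- sqrt(mu * scale) / scale
  }
  sd_true <- pmax(sd_true, 1e-12 * max(abs(mu)))  # keep sigma strictly positive
  saxs_profile(q, i, sd_true,
               label = if (is.null(label))
                 sprintf("sim seed=%d", noise$seed) else label,
               concentration = concentration)
}

#' Reference parameter table for the cellulose/ionic-liquid series
#'
#' Fitted generalized Guinier-Porod parameters for cellulose dissolved
#' in 1-ethyl-3-methylimidazolium acetate at 30-80 mol % (glucose unit /
#' (glucose unit + ion pair)): radius of gyration, Porod exponent and
#' dimensionality parameter for the large (subscript 1) and small
#' (subscript 2) aggregates, and the shoulder exponent `ds`. Rows below
#' 50 mol % have no resolvable small aggregate or shoulder (`NA`).
#'
#' @return A data.frame with columns `concentration`, `rg1`, `d1`, `s1`,
#'   `rg2`, `d2`, `s2`, `ds`.
#' @export
reference_series_params <- function() {
  data.frame(
    concentration = c(30, 35, 40, 50, 60, 70, 80),
    rg1 = c(7.9, 7.5, 7.1, 5.5, 5.9, 4.9, 4.7),
    d1  = c(4.0, 3.8, 3.9, 3.0, 4.0, 3.6, 3.8),
    s1  = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.1, 0.1),
    rg2 = c(NA,  NA,  NA,  1.6, 1.6, 1.6, 1.5),
    d2  = c(NA,  NA,  NA,  3.5, 4.0, 4.0, 4.0),
    s2  = c(NA,  NA,  NA,  0.0, 0.1, 0.1, 0.1),
    ds  = c(NA,  NA,  NA,  4.0, 4.0, 4.0, 4.0)
  )
}

#' Build the composite model for one reference concentration
#'
#' Assembles the [composite_model()] for a row of
#' [reference_series_params()]: one generalized Guinier-Porod component
#' below 50 mol %, two components plus a Porod shoulder at 50-80 mol %.
#' Forward intensities are not reported in the reference table, so they
#' are supplied here: defaults are `i0_large = 1`, `i0_small = 0.5`, and
#' a shoulder prefactor chosen so the shoulder contributes
#' `shoulder_fraction` of the total intensity at `q_min`.
#'
#' @param concentration One of 30, 35, 40, 50, 60, 70, 80 (mol %).
#' @param i0_large,i0_small Forward intensities of the two aggregates,
#'   a.u.
#' @param shoulder_fraction Fraction of total intensity at `q_min`
#'   contributed by the shoulder (default 0.2).
#' @param config An [instrument_config()] supplying `q_min`.
#' @return A [composite_model()].
#' @export
reference_model <- function(concentration, i0_large = 1.0, i0_small = 0.5,
                            shoulder_fraction = 0.2,
                            config = instrument_config()) {
  tab <- reference_series_params()
  row <- tab[tab$concentration == concentration, ]
  if (nrow(row) != 1)
    stop("unknown concentration ", concentration, "; valid rows: ",
         paste(tab$concentration, collapse = ", "), call. = FALSE)
  ggp <- list(ggp_params(i0_large, row$rg1, row$d1, row$s1))
  porod <- NULL
  if (!is.na(row$rg2)) {
    ggp <- c(ggp, list(ggp_params(i0_small, row$rg2, row$d2, row$s2)))
    rest <- composite_intensity(composite_model(ggp = ggp), config$q_min)
    # shoulder/(shoulder + rest) = f  =>  shoulder = f/(1-f) * rest
    pref <- shoulder_fraction / (1 - shoulder_fraction) * rest *
      config$q_min^row$ds
    porod <- porod_params(pref, row$ds)
  }
  composite_model(ggp = ggp, porod = porod)
}

#' Simulate the full concentration series with replicates
#'
#' Generates seeded noisy profiles for every requested concentration of
#' the reference series: three replicates above 40 mol % (where sample
#' inhomogeneity warrants replicate spots) and one otherwise. Replicate
#' seeds are derived deterministically from `noise$seed`.
#'
#' @param concentrations Subset of the reference concentrations; default
#'   all seven.
#' @param noise A [noise_model()]; its seed is the series base seed.
#' @param config An [instrument_config()].
#' @param ... Passed to [reference_model()] (amplitudes, shoulder
#'   fraction).
#' @return A named list (names = concentrations) of lists of replicate
#'   [saxs_profile()]s.
#' @export
simulate_reference_series <- function(concentrations = c(30, 35, 40, 50, 60, 70, 80),
                                      noise = noise_model(),
                                      config = instrument_config(), ...) {
  tab <- reference_series_params()
  bad <- setdiff(concentrations, tab$concentration)
  if (length(bad) > 0)
    stop("unknown concentration(s) ", paste(bad, collapse = ", "),
         "; valid rows: ", paste(tab$concentration, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (k in seq_along(concentrations)) {
    conc <- concentrations[k]
    model <- reference_model(conc, config = config, ...)
    n_rep <- if (conc > 40) 3L else 1L
    reps <- lapply(seq_len(n_rep), function(r) {
      nm <- noise_model(noise$kind, noise$level,
                        seed = noise$seed + 100L * k + r)
      simulate_profile(model, config, nm,
                       label = sprintf("%g mol%% rep %d", conc, r),
                       concentration = conc)
    })
    out[[as.character(conc)]] <- reps
  }
  out
}

#' Simulate an instrument background curve
#'
#' A smooth low-amplitude stand-in for cell-window (Kapton) scattering:
#' a constant plus a weak inverse-q power law, with noise, for
#' exercising [subtract_background()].
#'
#' @param config An [instrument_config()].
#' @param noise A [noise_model()] or `NULL`.
#' @param amplitude Overall amplitude scale, a.u.; 0 gives a zero curve.
#' @return A [saxs_profile()] labelled as background. For
#'   `amplitude = 0` the intensities are exactly zero and no noise or
#'   sigma is attached (a degenerate but valid stand-in).
#' @export
simulate_background <- function(config = instrument_config(),
                                noise = noise_model(), amplitude = 0.05) {
  q <- make_q_grid(config)
  if (amplitude == 0)
    return(saxs_profile(q, rep(0, length(q)), label = "background"))
  mu <- amplitude * (0.5 + 0.5 * (config$q_min / q)^0.7)
  if (is.null(noise))
    return(saxs_profile(q, mu, NULL, label = "background"))
  stopifnot(noise$kind == "multiplicative_gaussian" ||
            noise$kind == "poisson_count")
  if (noise$kind == "multiplicative_gaussian") {
    sd_true <- noise$level * mu
    i <- with_seed(noise$seed, mu * (1 + noise$level * stats::rnorm(length(q))))
  } else {
    scale <- noise$level / max(mu)
    counts <- with_seed(noise$seed, stats::rpois(length(q), lambda = mu * scale))
    i <- counts / scale
    sd_true <- pmax(sqrt(mu * scale) / scale, 1e-12 * max(mu))
  }
  saxs_profile(q, i, sd_true, label = "background")
}
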