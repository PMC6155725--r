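# Weighted bounded nonlinear least squares on top of stats::nlminb, with
# covariance from a finite-difference Jacobian at the optimum. Amplitude-
# and length-type parameters are optimized on a log scale for conditioning;
# the covariance is evaluated in the original units.

PENALTY <- 1e12

# --- parameter vector <-> composite model -------------------------------

composite_par_spec <- function(model, d_max = 4.5, s_max = 2.99,
                               rg_bounds = c(0.1, 50),
                               shoulder_d_bounds = c(3 + 1e-9, 4)) {
  rows <- list()
  add <- function(name, value, lower, upper, log) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, value = value, lower = lower, upper = upper, log = log,
      stringsAsFactors = FALSE)
  }
  for (k in seq_along(model$ggp)) {
    g <- model$ggp[[k]]
    pre <- paste0("ggp", k, ".")
    add(paste0(pre, "i0"), g$i0, 1e-10, 1e10, TRUE)
    add(paste0(pre, "rg"), g$rg, rg_bounds[1], rg_bounds[2], TRUE)
    add(paste0(pre, "d"),  g$d, 1e-3, d_max, FALSE)
    add(paste0(pre, "s"),  g$s, 0, s_max, FALSE)
  }
  if (!is.null(model$porod)) {
    add("porod.D", model$porod$prefactor, 1e-12, 1e10, TRUE)
    add("porod.d", model$porod$d, shoulder_d_bounds[1], shoulder_d_bounds[2],
        FALSE)
  }
  if (!is.null(model$background))
    add("background", model$background, 0, 1e10, FALSE)
  do.call(rbind, rows)
}

composite_from_par <- function(par, template) {
  ggp <- lapply(seq_along(template$ggp), function(k) {
    pre <- paste0("ggp", k, ".")
    list(i0 = par[[paste0(pre, "i0")]], rg = par[[paste0(pre, "rg")]],
         d = par[[paste0(pre, "d")]], s = par[[paste0(pre, "s")]])
  })
  porod <- if (!is.null(template$porod))
    list(prefactor = par[["porod.D"]], d = par[["porod.d"]]) else NULL
  bg <- if (!is.null(template$background)) par[["background"]] else NULL
  list(ggp = ggp, porod = porod, background = bg)
}

# Raw composite evaluation tolerating invalid (d <= s, s >= 3) parameter
# combinations during optimization: returns NULL there so the caller can
# apply a penalty.
composite_eval_raw <- function(pl, q) {
  out <- numeric(length(q))
  for (g in pl$ggp) {
    if (!(g$d > g$s) || !(g$s < 3) || !(g$rg > 0) || !(g$i0 > 0)) return(NULL)
    q1 <- sqrt((g$d - g$s) * (3 - g$s) / 2) / g$rg
    D <- g$i0 * q1^(g$d - g$s) * exp(-q1^2 * g$rg^2 / (3 - g$s))
    lo <- q <= q1
    v <- numeric(length(q))
    v[lo] <- g$i0 * q[lo]^(-g$s) * exp(-q[lo]^2 * g$rg^2 / (3 - g$s))
    v[!lo] <- D * q[!lo]^(-g$d)
    out <- out + v
  }
  if (!is.null(pl$porod)) out <- out + pl$porod$prefactor * q^(-pl$porod$d)
  if (!is.null(pl$background)) out <- out + pl$background
  out
}

pl_to_model <- function(pl) {
  composite_model(
    ggp = lapply(pl$ggp, function(g) ggp_params(g$i0, g$rg, g$d, g$s)),
    porod = if (!is.null(pl$porod))
      porod_params(pl$porod$prefactor, pl$porod$d, d_max = 4.5) else NULL,
    background = pl$background)
}

# --- generic bounded weighted NLS engine --------------------------------

fd_jacobian <- function(resid_fn, par) {
  r0 <- resid_fn(par)
  J <- matrix(NA_real_, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- max(1e-6 * abs(par[j]), 1e-9)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (resid_fn(pp) - resid_fn(pm)) / (2 * h)
  }
  J
}

# resid_fn(full named par vector) -> weighted residual vector (or NULL for
# invalid parameters). spec: data.frame(name, value, lower, upper, log).
wnls <- function(resid_fn, spec, fixed = character(), multistart = 1,
                 seed = 1L, max_iter = 1000, rel_tol = 1e-12) {
  free <- !(spec$name %in% fixed)
  if (!any(free)) stop("no free parameters", call. = FALSE)
  full_par <- stats::setNames(spec$value, spec$name)
  to_opt <- function(v) ifelse(spec$log[free], log(v), v)
  from_opt <- function(x) ifelse(spec$log[free], exp(x), x)
  obj <- function(x) {
    p <- full_par
    p[free] <- from_opt(x)
    r <- resid_fn(p)
    if (is.null(r) || any(!is.finite(r))) return(PENALTY)
    sum(r^2)
  }
  lower <- ifelse(spec$log[free], log(pmax(spec$lower[free], 1e-300)),
                  spec$lower[free])
  upper <- ifelse(spec$log[free], log(spec$upper[free]), spec$upper[free])
  pick_best <- function(cands) {
    objs <- vapply(cands, `[[`, numeric(1), "objective")
    conv <- vapply(cands, `[[`, numeric(1), "convergence")
    # lowest objective wins; among near-ties prefer a clean convergence code
    tie <- objs <= min(objs) * (1 + 1e-9) + 1e-300
    idx <- which(tie)[order(conv[tie])][1]
    cands[[idx]]
  }
  run_nlminb <- function(x0, tol, iters) {
    x0 <- pmin(pmax(x0, lower), upper)
    stats::nlminb(x0, obj, lower = lower, upper = upper,
                  control = list(iter.max = iters, eval.max = 4 * iters,
                                 rel.tol = tol))
  }
  x_init <- to_opt(spec$value[free])
  starts <- list(x_init)
  if (multistart > 1) {
    jit <- with_seed(seed, lapply(seq_len(multistart - 1), function(i)
      x_init + stats::rnorm(length(x_init), sd = 0.1)))
    starts <- c(starts, jit)
  }
  # coarse pass over all starts, then a tight polish (with one confirming
  # restart) of the best candidate only
  coarse <- lapply(starts, run_nlminb, tol = 1e-8,
                   iters = min(max_iter, 300))
  best0 <- pick_best(coarse)
  polished <- list(best0)
  x_cur <- best0$par
  for (i in 1:3) {
    fit_i <- run_nlminb(x_cur, rel_tol, max_iter)
    polished <- c(polished, list(fit_i))
    x_cur <- fit_i$par
  }
  best <- pick_best(polished)
  par_hat <- full_par
  par_hat[free] <- from_opt(best$par)
  r <- resid_fn(par_hat)
  n <- length(r); p <- sum(free)
  ssr <- sum(r^2)
  # Gauss-Newton polish in original units: quadratic convergence near the
  # optimum takes the solution past the FD-gradient noise floor of nlminb
  resid_orig <- function(v) {
    pp <- par_hat; pp[free] <- v
    out <- resid_fn(pp)
    if (is.null(out) || any(!is.finite(out))) rep(PENALTY, n) else out
  }
  for (it in 1:3) {
    J <- tryCatch(fd_jacobian(resid_orig, par_hat[free]),
                  error = function(e) NULL)
    if (is.null(J) || any(!is.finite(J))) break
    step <- tryCatch(qr.solve(J, r), error = function(e) NULL)
    if (is.null(step)) break
    cand <- pmin(pmax(par_hat[free] - step, spec$lower[free]),
                 spec$upper[free])
    r_cand <- resid_orig(cand)
    if (sum(r_cand^2) < ssr) {
      par_hat[free] <- cand
      r <- r_cand
      ssr <- sum(r^2)
    } else break
  }
  chi2_red <- if (n > p) ssr / (n - p) else NA_real_
  # covariance in ORIGINAL units via FD Jacobian of the weighted residuals
  resid_free <- function(v) {
    pp <- par_hat
    pp[free] <- v
    out <- resid_fn(pp)
    if (is.null(out)) rep(PENALTY, n) else out
  }
  stderr <- stats::setNames(rep(NA_real_, length(full_par)), spec$name)
  cov_ok <- FALSE
  opt_ok <- FALSE
  if (n > p) {
    J <- tryCatch(fd_jacobian(resid_free, par_hat[free]), error = function(e) NULL)
    if (!is.null(J) && all(is.finite(J))) {
      JTJ <- crossprod(J)
      cv <- tryCatch(solve(JTJ) * max(chi2_red, 0), error = function(e) NULL)
      if (!is.null(cv)) {
        dg <- diag(cv)
        dg[dg < 0] <- NA_real_
        stderr[free] <- sqrt(dg)
        cov_ok <- TRUE
      }
      # first-order optimality with bounds: the projected gradient should be
      # orthogonal to the residual (small cosine) at a genuine optimum. This
      # rescues nlminb's "singular/false convergence" codes, which flag flat
      # directions and over-tight tolerances, not failure to minimize.
      g <- drop(crossprod(J, r))
      at_lo <- par_hat[free] <= spec$lower[free] +
        1e-10 * pmax(1, abs(spec$lower[free]))
      at_hi <- par_hat[free] >= spec$upper[free] -
        1e-10 * pmax(1, abs(spec$upper[free]))
      viol <- abs(g)
      viol[at_lo] <- pmax(-g[at_lo], 0)   # only an inward pull counts
      viol[at_hi] <- pmax(g[at_hi], 0)
      denom <- sqrt(colSums(J^2)) * sqrt(ssr)
      cosang <- ifelse(denom > 0, viol / denom, 0)
      opt_ok <- max(cosang) < 1e-3
      # at machine-zero residuals the gradient direction is rounding noise
      # and the cosine test is meaningless; compare the residual rms to the
      # function scale implied by the Jacobian instead
      scale_r <- abs(J) %*% abs(par_hat[free])
      if (sqrt(mean(r^2)) <= 1e-10 * max(sqrt(mean(scale_r^2)), 1e-300))
        opt_ok <- TRUE
    }
  }
  converged <- best$convergence == 0 || opt_ok
  list(par = par_hat, stderr = stderr, ssr = ssr, chi2_reduced = chi2_red,
       n = n, n_free = p, converged = converged,
       message = best$message, cov_ok = cov_ok)
}

profile_weights <- function(profile) {
  if (is.null(profile$sigma)) rep(1, length(profile$q)) else 1 / profile$sigma
}

new_saxs_fit <- function(kind, model, engine, profile, fitted, extra = list()) {
  structure(c(list(
    kind = kind, model = model,
    par = engine$par, stderr = engine$stderr,
    chi2_reduced = engine$chi2_reduced,
    residuals = profile$intensity - fitted,
    n_free = engine$n_free, converged = engine$converged,
    message = engine$message,
    fit_window = range(profile$q), n_points = length(profile$q),
    data = profile), extra), class = "saxs_fit")
}

#' @export
print.saxs_fit <- function(x, ...) {
  cat(sprintf("<saxs_fit> %s model, %d points in q = %.3g-%.3g nm^-1\n",
              x$kind, x$n_points, x$fit_window[1], x$fit_window[2]))
  cat(sprintf("  reduced chi^2 = %.4g, %d free parameter(s), converged: %s\n",
              x$chi2_reduced, x$n_free, x$converged))
  est <- x$par
  se <- x$stderr[names(est)]
  for (nm in names(est))
    cat(sprintf("  %-10s %.5g%s\n", nm, est[[nm]],
                if (is.finite(se[[nm]])) sprintf(" +/- %.3g", se[[nm]]) else ""))
  invisible(x)
}

#' Coefficients of a scattering model fit
#' @param object A `saxs_fit`.
#' @param ... Unused.
#' @return Named numeric vector of parameter estimates.
#' @export
coef.saxs_fit <- function(object, ...) object$par

# --- Kratky-based initialization ----------------------------------------

running_mean <- function(x, k) {
  if (k < 2) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

find_local_maxima <- function(y, order = 3) {
  n <- length(y)
  idx <- integer(0)
  for (i in seq((order + 1), (n - order))) {
    win <- y[(i - order):(i + order)]
    if (y[i] == max(win) && y[i] > min(win)) idx <- c(idx, i)
  }
  # collapse plateaus / adjacent hits
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > order)]
  idx
}

#' Initialize a composite model from Kratky-plot peaks
#'
#' Automates the visual procedure of reading aggregate sizes off a
#' Kratky plot. Extraction is greedy: the strongest local maximum of the
#' smoothed q^2 I(q) curve at position q* is inverted to a radius of
#' gyration via the globular-scatterer relation Rg = sqrt(3)/q* and to a
#' forward intensity via I0 = K(q*) Rg^2 e / 3 (d = 4, s = 0 seeds);
#' that component's Kratky contribution is then subtracted and the
#' search repeats, so a weaker peak riding on the flank of a stronger
#' one is still found. If the smoothed Kratky curve rises toward the
#' lowest q, a Porod shoulder (d = 4) is seeded from the residual low-q
#' intensity.
#'
#' @param profile A [saxs_profile()].
#' @param n_components Maximum number of Guinier-Porod components to
#'   seed (1 or 2 in this study). Fewer are returned, with a notice, if
#'   fewer peaks are found.
#' @param smooth_window Running-mean window (points) applied to the
#'   Kratky curve before peak picking.
#' @param prominence Minimum peak height, as a fraction of the original
#'   smoothed Kratky range, for a maximum to count as a component.
#' @return A [composite_model()]. A peak-free profile yields a model
#'   with zero components and a flat background at the median intensity.
#' @export
initialize_from_kratky <- function(profile, n_components = 2,
                                   smooth_window = 7, prominence = 0.05) {
  stopifnot(is_saxs_profile(profile))
  kr <- kratky_transform(profile)
  ks <- running_mean(kr$kratky, smooth_window)
  span <- max(ks) - min(ks)
  ord <- max(3, length(ks) %/% 50)
  resid <- ks
  ggp <- list()
  while (length(ggp) < n_components && span > 0) {
    idx <- find_local_maxima(running_mean(resid, smooth_window), order = ord)
    idx <- idx[resid[idx] > prominence * span]
    if (length(idx) == 0) break
    i <- idx[which.max(resid[idx])]
    q_star <- kr$q[i]
    rg <- sqrt(3) / q_star
    i0 <- max(resid[i] * rg^2 * exp(1) / 3, 1e-8)
    g <- ggp_params(i0 = i0, rg = rg, d = 4, s = 0)
    ggp <- c(ggp, list(g))
    resid <- resid - kr$q^2 * ggp_intensity(g, kr$q)
  }
  if (length(ggp) < n_components)
    message("initialize_from_kratky: found ", length(ggp),
            " peak(s), fewer than the ", n_components, " requested")
  # order seeds by descending rg, matching the reporting convention
  if (length(ggp) > 1)
    ggp <- ggp[order(vapply(ggp, `[[`, numeric(1), "rg"), decreasing = TRUE)]
  # shoulder: smoothed Kratky rising toward q_min beyond seeded components
  porod <- NULL
  head_n <- max(3, ord)
  seeded_k <- ks - resid
  rises <- (resid[1] > resid[head_n] && resid[1] > 0.02 * span) ||
    (length(ggp) == 0 && ks[1] > ks[head_n])
  if (rises) {
    seeded <- if (length(ggp) > 0)
      composite_intensity(composite_model(ggp = ggp), profile$q[1]) else 0
    resid0 <- profile$intensity[1] - seeded
    D0 <- max(resid0, 0.05 * abs(profile$intensity[1])) * profile$q[1]^4
    porod <- porod_params(D0, 4)
  }
  if (length(ggp) == 0 && is.null(porod)) {
    message("initialize_from_kratky: no peaks found; returning flat background model")
    return(composite_model(background = max(stats::median(profile$intensity), 1e-10)))
  }
  composite_model(ggp = ggp, porod = porod)
}

# --- model fits ----------------------------------------------------------

#' Fit a composite Guinier-Porod model to a profile
#'
#' Weighted nonlinear least squares in intensity space: minimizes
#' sum of w_i (I_obs - I_model)^2 with w_i = 1/sigma_i^2 when the
#' profile carries uncertainties, else 1. The crossover q1 of every
#' Guinier-Porod component is recomputed from the current (Rg, d, s) at
#' each evaluation. Standard errors come from the covariance of the
#' linearized problem at the optimum, scaled by the reduced chi^2 — the
#' conventional "nonlinear regression" uncertainty.
#'
#' A seeded random multistart (jitter around the initialization)
#' mitigates local minima; the best final objective wins, so the result
#' is deterministic for fixed `seed`.
#'
#' @param profile A [saxs_profile()].
#' @param init A [composite_model()] initialization, e.g. from
#'   [initialize_from_kratky()]; must lie within the bounds.
#' @param fixed Character vector of parameter names to hold at their
#'   initial values (names as in the fit output, e.g. `"ggp1.s"`,
#'   `"porod.d"`).
#' @param rg_bounds,d_max,s_max,shoulder_d_bounds Box bounds: Rg in
#'   `[0.1, 50]` nm (instrument window), GGP exponent d <= 4.5,
#'   dimensionality s in `[0, 2.99]`, shoulder exponent in `(3, 4]`.
#'   The coupled constraint d > s is enforced by penalty.
#' @param multistart Number of optimizer starts (default 5).
#' @param seed Seed for the multistart jitter.
#' @param max_iter Iteration cap per start; non-convergence is reported
#'   via `converged = FALSE`, not an error.
#' @return A `saxs_fit` object: fitted model (components ordered by
#'   descending Rg), estimates `par`, `stderr`, `chi2_reduced`,
#'   `residuals`, `n_free`, `converged`, `fit_window`.
#' @export
fit_composite <- function(profile, init = initialize_from_kratky(profile),
                          fixed = character(), rg_bounds = c(0.1, 50),
                          d_max = 4.5, s_max = 2.99,
                          shoulder_d_bounds = c(3 + 1e-9, 4),
                          multistart = 5, seed = 1L, max_iter = 1000) {
  stopifnot(is_saxs_profile(profile), inherits(init, "saxs_composite"))
  spec <- composite_par_spec(init, d_max = d_max, s_max = s_max,
                             rg_bounds = rg_bounds,
                             shoulder_d_bounds = shoulder_d_bounds)
  w <- profile_weights(profile)
  q <- profile$q
  iobs <- profile$intensity
  resid_fn <- function(par) {
    pl <- composite_from_par(par, init)
    mu <- composite_eval_raw(pl, q)
    if (is.null(mu)) return(NULL)
    w * (iobs - mu)
  }
  eng <- wnls(resid_fn, spec, fixed = fixed, multistart = multistart,
              seed = seed, max_iter = max_iter)
  pl <- composite_from_par(eng$par, init)
  model <- pl_to_model(pl)
  # canonical ordering: subscript 1 = largest Rg
  if (length(model$ggp) > 1) {
    ord <- order(vapply(model$ggp, `[[`, numeric(1), "rg"), decreasing = TRUE)
    if (!identical(ord, seq_along(model$ggp))) {
      model$ggp <- model$ggp[ord]
      eng <- relabel_ggp(eng, ord)
    }
  }
  fitted <- composite_intensity(model, q)
  new_saxs_fit("composite", model, eng, profile, fitted)
}

relabel_ggp <- function(eng, ord) {
  nm <- names(eng$par)
  new_nm <- nm
  for (new_k in seq_along(ord)) {
    old_pre <- paste0("ggp", ord[new_k], ".")
    hit <- startsWith(nm, old_pre)
    new_nm[hit] <- sub(old_pre, paste0("ggp", new_k, "."), nm[hit], fixed = TRUE)
  }
  names(eng$par) <- new_nm
  names(eng$stderr) <- new_nm
  # ggp blocks first in numeric order, keeping i0/rg/d/s field order
  suffix <- sub("^ggp[0-9]+\\.", "", new_nm)
  field <- match(suffix, c("i0", "rg", "d", "s"), nomatch = 9L)
  block <- ifelse(startsWith(new_nm, "ggp"), sub("\\..*$", "", new_nm), "zzz")
  ord2 <- order(block, field)
  eng$par <- eng$par[ord2]
  eng$stderr <- eng$stderr[ord2]
  eng
}

#' Fit the Debye-Bueche model
#'
#' Fits I(q) = A/(1 + xi^2 q^2)^2 by weighted nonlinear least squares,
#' and also reports the classical linearized diagnostic: I^(-1/2) is
#' linear in q^2 with slope xi^2/sqrt(A) and intercept 1/sqrt(A), fitted
#' by ordinary regression on the points with positive intensity. The
#' linearized estimates initialize the nonlinear fit and are returned in
#' `$linearized` for cross-checking.
#'
#' @param profile A [saxs_profile()].
#' @param window Optional `c(qmin, qmax)` fit window, nm^-1; default the
#'   full profile.
#' @param multistart,seed,max_iter As in [fit_composite()].
#' @return A `saxs_fit` with parameters `A` and `xi`, plus
#'   `$linearized = list(A, xi, slope, intercept)`.
#' @export
fit_debye_bueche <- function(profile, window = NULL, multistart = 3,
                             seed = 1L, max_iter = 1000) {
  stopifnot(is_saxs_profile(profile))
  if (!is.null(window)) profile <- restrict_q(profile, window[1], window[2])
  if (length(profile$q) < 5)
    stop("insufficient data: need >= 5 points in the fit window", call. = FALSE)
  lin <- db_linearized(profile)
  spec <- data.frame(name = c("A", "xi"),
                     value = c(lin$A, lin$xi),
                     lower = c(1e-10, 0.01), upper = c(1e10, 1e3),
                     log = c(TRUE, TRUE), stringsAsFactors = FALSE)
  w <- profile_weights(profile)
  resid_fn <- function(par)
    w * (profile$intensity - par[["A"]] / (1 + par[["xi"]]^2 * profile$q^2)^2)
  eng <- wnls(resid_fn, spec, multistart = multistart, seed = seed,
              max_iter = max_iter)
  model <- db_params(eng$par[["A"]], eng$par[["xi"]])
  fitted <- debye_bueche_intensity(model, profile$q)
  new_saxs_fit("debye_bueche", model, eng, profile, fitted,
               extra = list(linearized = lin))
}

db_linearized <- function(profile) {
  ok <- profile$intensity > 0
  if (sum(ok) < 3) return(list(A = max(profile$intensity, 1), xi = 1,
                               slope = NA_real_, intercept = NA_real_))
  y <- profile$intensity[ok]^(-0.5)
  x <- profile$q[ok]^2
  fit <- stats::lm(y ~ x)
  b0 <- stats::coef(fit)[[1]]
  b1 <- stats::coef(fit)[[2]]
  if (b0 <= 0 || b1 <= 0)
    return(list(A = max(profile$intensity), xi = 1,
                slope = b1, intercept = b0))
  list(A = 1 / b0^2, xi = sqrt(b1 / b0), slope = b1, intercept = b0)
}

#' Fit the sum of Debye-Bueche and Ornstein-Zernike models
#'
#' Fits the 4-parameter sum A_db/(1 + xi_db^2 q^2)^2 +
#' A_oz/(1 + xi_oz^2 q^2), intended for comparison against the
#' Debye-Bueche model alone via [compare_models()]: gel profiles with a
#' long-range inhomogeneity plus chain-fluctuation scattering need both
#' terms, simpler profiles do not.
#'
#' @inheritParams fit_debye_bueche
#' @return A `saxs_fit` with parameters `A_db`, `xi_db`, `A_oz`,
#'   `xi_oz`.
#' @export
fit_db_plus_oz <- function(profile, window = NULL, multistart = 5,
                           seed = 1L, max_iter = 1000) {
  stopifnot(is_saxs_profile(profile))
  if (!is.null(window)) profile <- restrict_q(profile, window[1], window[2])
  if (length(profile$q) < 5)
    stop("insufficient data: need >= 5 points in the fit window", call. = FALSE)
  lin <- db_linearized(profile)
  spec <- data.frame(
    name = c("A_db", "xi_db", "A_oz", "xi_oz"),
    value = c(0.9 * lin$A, lin$xi, 0.1 * lin$A, 0.5 * lin$xi),
    lower = c(1e-10, 0.01, 1e-10, 0.01),
    upper = c(1e10, 1e3, 1e10, 1e3),
    log = c(TRUE, TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  w <- profile_weights(profile)
  resid_fn <- function(par)
    w * (profile$intensity -
           par[["A_db"]] / (1 + par[["xi_db"]]^2 * profile$q^2)^2 -
           par[["A_oz"]] / (1 + par[["xi_oz"]]^2 * profile$q^2))
  eng <- wnls(resid_fn, spec, multistart = multistart, seed = seed,
              max_iter = max_iter)
  model <- list(db = db_params(eng$par[["A_db"]], eng$par[["xi_db"]]),
                oz = oz_params(eng$par[["A_oz"]], eng$par[["xi_oz"]]))
  fitted <- debye_bueche_intensity(model$db, profile$q) +
    ornstein_zernike_intensity(model$oz, profile$q)
  new_saxs_fit("db_plus_oz", model, eng, profile, fitted)
}

#' Rank competing fits of the same profile
#'
#' Ranks fits by reduced chi^2 (ties broken toward fewer free
#' parameters) and applies a parsimony rule: a more complex model is
#' flagged "not required" unless its reduced chi^2 improves on the best
#' simpler model by more than `threshold` (relative, default 5%). The
#' selected model is the simplest one that no more complex model beats
#' by the threshold.
#'
#' @param fits A list of `saxs_fit` objects over the same data and
#'   window.
#' @param threshold Relative reduced-chi^2 improvement required to
#'   justify extra parameters.
#' @return A list with `ranking` (data.frame: kind, n_free,
#'   chi2_reduced, required), `selected` (index into `fits`) and the
#'   selected fit in `$best`.
#' @export
compare_models <- function(fits, threshold = 0.05) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "saxs_fit")))
  win <- fits[[1]]$fit_window
  np <- fits[[1]]$n_points
  for (f in fits[-1])
    if (!isTRUE(all.equal(f$fit_window, win)) || f$n_points != np)
      stop("fits cover different data/windows; comparison is not meaningful",
           call. = FALSE)
  kind <- vapply(fits, `[[`, character(1), "kind")
  nf <- vapply(fits, `[[`, numeric(1), "n_free")
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2_reduced")
  rank_ord <- order(chi2, nf)
  # selection: walk models by increasing complexity; accept a more complex
  # one only on a > threshold relative improvement
  cplx_ord <- order(nf, chi2)
  sel <- cplx_ord[1]
  required <- rep(TRUE, length(fits))
  if (length(fits) > 1) {
    for (i in cplx_ord[-1]) {
      if (chi2[i] < (1 - threshold) * chi2[sel]) {
        sel <- i
      } else {
        required[i] <- FALSE
      }
    }
  }
  list(
    ranking = data.frame(kind = kind, n_free = nf, chi2_reduced = chi2,
                         required = required,
                         stringsAsFactors = FALSE)[rank_ord, ],
    selected = sel,
    best = fits[[sel]]
  )
}
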