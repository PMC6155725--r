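# Concentration-series orchestration: per-concentration composite fits,
# equivalent-sphere sizing, and the normalized forward-intensity ratio.

REPORT_COLS <- c("concentration",
                 "Rg1", "Rg1_sd", "d1", "d1_sd", "s1", "s1_sd",
                 "Rg2", "Rg2_sd", "d2", "d2_sd", "s2", "s2_sd",
                 "ds", "ds_sd", "D_large_nm", "D_small_nm", "I2I1_norm")

#' Default component plan for a concentration
#'
#' The model composition used when none is configured: a single
#' Guinier-Porod component below 50 mol %, two components plus a Porod
#' shoulder at 50 mol % and above — the composition under which the
#' reference concentration series was analysed.
#'
#' @param concentration Concentration in mol %.
#' @return List with `n_ggp` (1 or 2) and `shoulder` (logical).
#' @export
default_component_plan <- function(concentration) {
  if (concentration >= 50) list(n_ggp = 2, shoulder = TRUE)
  else list(n_ggp = 1, shoulder = FALSE)
}

#' Forward-intensity ratio of the two aggregates
#'
#' The ratio I2(0)/I1(0) of the small aggregate's forward intensity to
#' the large aggregate's, from a composite fit with two Guinier-Porod
#' components (components are ordered by descending Rg, so component 1
#' is the large aggregate).
#'
#' @param fit A `saxs_fit` from [fit_composite()].
#' @return The dimensionless ratio, or `NA` when the fit has fewer than
#'   two components.
#' @export
intensity_ratio <- function(fit) {
  stopifnot(inherits(fit, "saxs_fit"))
  if (fit$kind != "composite" || length(fit$model$ggp) < 2) return(NA_real_)
  fit$model$ggp[[2]]$i0 / fit$model$ggp[[1]]$i0
}

ensure_plan <- function(init, plan, profile) {
  # reconcile the Kratky initialization with the configured composition
  if (length(init$ggp) > plan$n_ggp) {
    keep <- order(vapply(init$ggp, `[[`, numeric(1), "i0"),
                  decreasing = TRUE)[seq_len(plan$n_ggp)]
    init$ggp <- init$ggp[sort(keep)]
  }
  if (plan$shoulder && is.null(init$porod)) {
    D0 <- max(0.05 * abs(profile$intensity[1]), 1e-8) * profile$q[1]^4
    init$porod <- porod_params(D0, 4)
  }
  if (!plan$shoulder) init$porod <- NULL
  if (length(init$ggp) == 0 && is.null(init$porod) && is.null(init$background))
    init$background <- max(stats::median(profile$intensity), 1e-10)
  composite_model(ggp = init$ggp, porod = init$porod,
                  background = init$background)
}

#' Analyse a concentration series of scattering profiles
#'
#' Runs the full per-concentration workflow — Kratky initialization,
#' composite fit, equivalent-sphere sizing, forward-intensity ratio —
#' and assembles a report in the conventional table layout (subscript 1
#' = large aggregate, 2 = small aggregate, s = shoulder). Ratios are
#' normalized by the series maximum. A profile that fails to fit flags
#' its row and the series continues.
#'
#' @param profiles Named list: names are concentrations in mol %, values
#'   are [saxs_profile()] objects or lists of replicate profiles (which
#'   are averaged first).
#' @param plan_fn Function(concentration) -> list(n_ggp, shoulder);
#'   default [default_component_plan()].
#' @param fixed,multistart,seed,max_iter Passed to [fit_composite()].
#' @return An object of class `saxs_series`: `rows` (data.frame, one
#'   row per concentration, ascending; columns `r REPORT_COLS` plus
#'   `fitted`), `normalization` (description of the ratio convention)
#'   and `fits` (the underlying `saxs_fit` objects).
#' @export
analyze_series <- function(profiles, plan_fn = default_component_plan,
                           fixed = character(), multistart = 5, seed = 1L,
                           max_iter = 1000) {
  if (length(profiles) == 0) stop("empty profile map", call. = FALSE)
  concs <- suppressWarnings(as.numeric(names(profiles)))
  if (any(is.na(concs)))
    stop("profile map names must be numeric concentrations (mol %)",
         call. = FALSE)
  ord <- order(concs)
  concs <- concs[ord]
  profiles <- profiles[ord]
  rows <- list()
  fits <- list()
  for (k in seq_along(profiles)) {
    p <- profiles[[k]]
    if (is.list(p) && !is_saxs_profile(p)) p <- average_profiles(p)
    plan <- plan_fn(concs[k])
    row <- as.list(stats::setNames(rep(NA_real_, length(REPORT_COLS)),
                                   REPORT_COLS))
    row$concentration <- concs[k]
    fit <- tryCatch({
      init <- ensure_plan(initialize_from_kratky(p, plan$n_ggp), plan, p)
      fit_composite(p, init, fixed = fixed, multistart = multistart,
                    seed = seed, max_iter = max_iter)
    }, error = function(e) {
      warning("concentration ", concs[k], " failed to fit: ",
              conditionMessage(e), call. = FALSE)
      NULL
    })
    fits[[as.character(concs[k])]] <- fit
    row$fitted <- !is.null(fit)
    if (!is.null(fit)) {
      g <- fit$model$ggp
      se <- fit$stderr
      if (length(g) >= 1) {
        row$Rg1 <- g[[1]]$rg;  row$Rg1_sd <- se[["ggp1.rg"]]
        row$d1 <- g[[1]]$d;    row$d1_sd <- se[["ggp1.d"]]
        row$s1 <- g[[1]]$s;    row$s1_sd <- se[["ggp1.s"]]
        row$D_large_nm <- sphere_diameter(g[[1]]$rg)
      }
      if (length(g) >= 2) {
        row$Rg2 <- g[[2]]$rg;  row$Rg2_sd <- se[["ggp2.rg"]]
        row$d2 <- g[[2]]$d;    row$d2_sd <- se[["ggp2.d"]]
        row$s2 <- g[[2]]$s;    row$s2_sd <- se[["ggp2.s"]]
        row$D_small_nm <- sphere_diameter(g[[2]]$rg)
        row$I2I1_norm <- intensity_ratio(fit)  # normalized below
      }
      if (!is.null(fit$model$porod)) {
        row$ds <- fit$model$porod$d
        row$ds_sd <- se[["porod.d"]]
      }
    }
    rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  if (any(is.finite(rows$I2I1_norm))) {
    rows$I2I1_norm <- rows$I2I1_norm / max(rows$I2I1_norm, na.rm = TRUE)
  }
  structure(list(rows = rows,
                 normalization = "I2(0)/I1(0) divided by the series maximum",
                 fits = fits),
            class = "saxs_series")
}

#' @export
print.saxs_series <- function(x, ...) {
  cat(sprintf("<saxs_series> %d concentration(s), %d fitted\n",
              nrow(x$rows), sum(x$rows$fitted)))
  show <- x$rows[, c("concentration", "Rg1", "Rg2", "D_large_nm",
                     "D_small_nm", "I2I1_norm")]
  print(format(show, digits = 3), row.names = FALSE)
  cat("  ratio normalization:", x$normalization, "\n")
  invisible(x)
}

#' Export a series report
#'
#' CSV output has exactly the columns `concentration, Rg1, Rg1_sd, d1,
#' d1_sd, s1, s1_sd, Rg2, Rg2_sd, d2, d2_sd, s2, s2_sd, ds, ds_sd,
#' D_large_nm, D_small_nm, I2I1_norm`, with missing values rendered
#' `n/a`. JSON output serializes the rows and the normalization
#' convention and round-trips through [read_report()].
#'
#' @param report A `saxs_series` from [analyze_series()].
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
export_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "saxs_series"))
  d <- report$rows[, REPORT_COLS]
  if (format == "csv") {
    chr <- as.data.frame(lapply(d, function(col) {
      out <- ifelse(is.finite(col),
                    trimws(formatC(col, format = "g", digits = 10)), "n/a")
      out
    }), stringsAsFactors = FALSE)
    ok <- tryCatch({
      utils::write.table(chr, path, sep = ",", quote = FALSE,
                         row.names = FALSE, col.names = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write report to ", path, call. = FALSE)
  } else {
    jsonlite::write_json(list(rows = d, normalization = report$normalization),
                         path, dataframe = "columns", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read back a JSON series report
#'
#' @param path Path written by [export_report()] with `format = "json"`.
#' @return A `saxs_series` (without the per-fit objects).
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- as.data.frame(obj$rows)[, REPORT_COLS]
  rows[] <- lapply(rows, as.numeric)
  rows$fitted <- is.finite(rows$Rg1)
  structure(list(rows = rows, normalization = obj$normalization,
                 fits = list()),
            class = "saxs_series")
}
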