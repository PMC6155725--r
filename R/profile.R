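#' One-dimensional scattering profile
#'
#' Constructs a `saxs_profile`, the package's container for an
#' azimuthally-averaged 1-D scattering curve: a momentum-transfer grid `q`
#' (nm^-1), intensities `intensity` (arbitrary units) and optional
#' per-point uncertainties `sigma`. Rows are sorted by ascending `q`;
#' non-finite rows are rejected.
#'
#' @param q Numeric vector of momentum transfer values, nm^-1. Must be
#'   strictly positive; duplicates are not allowed.
#' @param intensity Numeric vector of scattered intensities, arbitrary
#'   units, same length as `q`. Negative values are permitted (they arise
#'   legitimately from background subtraction).
#' @param sigma Optional numeric vector of intensity standard deviations,
#'   same length and units as `intensity`, all strictly positive.
#' @param label Free-text sample identifier.
#' @param concentration Optional cellulose mole fraction in mol %,
#'   defined as glucose unit / (glucose unit + ionic-liquid ion pair).
#' @return An object of class `saxs_profile`: a list with elements `q`,
#'   `intensity`, `sigma` (possibly `NULL`), `label`, `concentration`.
#' @export
#' @examples
#' p <- saxs_profile(q = c(0.2, 0.4), intensity = c(10, 5))
#' p$q
saxs_profile <- function(q, intensity, sigma = NULL, label = "",
                         concentration = NULL) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("`q` and `intensity` must have the same length", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("`sigma` must have the same length as `q`", call. = FALSE)
  }
  if (any(!is.finite(q)) || any(!is.finite(intensity)))
    stop("`q` and `intensity` must be finite", call. = FALSE)
  if (any(q <= 0))
    stop("all q values must be strictly positive", call. = FALSE)
  if (anyDuplicated(q))
    stop("duplicate q values are not allowed", call. = FALSE)
  if (is.unsorted(q)) {
    ord <- order(q)
    q <- q[ord]
    intensity <- intensity[ord]
    if (!is.null(sigma)) sigma <- sigma[ord]
    message("saxs_profile: q was not ascending; rows re-sorted")
  }
  if (!is.null(sigma) && any(sigma <= 0))
    stop("all sigma values must be strictly positive", call. = FALSE)
  structure(
    list(q = q, intensity = intensity, sigma = sigma,
         label = as.character(label), concentration = concentration),
    class = "saxs_profile"
  )
}

#' @export
print.saxs_profile <- function(x, ...) {
  cat("<saxs_profile>", if (nzchar(x$label)) x$label else "(unlabelled)", "\n")
  cat(sprintf("  %d points, q = %.4g-%.4g nm^-1\n",
              length(x$q), min(x$q), max(x$q)))
  cat(sprintf("  intensity range: %.4g-%.4g a.u.%s\n",
              min(x$intensity), max(x$intensity),
              if (is.null(x$sigma)) " (no uncertainties)" else ""))
  if (!is.null(x$concentration))
    cat(sprintf("  concentration: %g mol %%\n", x$concentration))
  invisible(x)
}

#' @export
length.saxs_profile <- function(x) length(x$q)

#' @export
as.data.frame.saxs_profile <- function(x, ...) {
  d <- data.frame(q = x$q, intensity = x$intensity)
  if (!is.null(x$sigma)) d$sigma <- x$sigma
  d
}

is_saxs_profile <- function(x) inherits(x, "saxs_profile")

#' Read a columnar scattering profile file
#'
#' Reads the de-facto ".dat" 1-D SAXS convention: whitespace- or
#' comma-delimited numeric columns (q, I and optionally sigma), with
#' lines starting with `#` treated as comments. Rows with non-positive q
#' are dropped with a warning giving the count.
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"` (default: use a third column as sigma
#'   when present), `"two_column"` (ignore any third column) or
#'   `"three_column"` (require a sigma column).
#' @param label,concentration Passed to [saxs_profile()]; `label`
#'   defaults to the file's base name.
#' @return A [saxs_profile()].
#' @export
read_profile <- function(path, dialect = c("auto", "two_column", "three_column"),
                         label = NULL, concentration = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0)
    stop("insufficient data in ", path, ": no data rows", call. = FALSE)
  fields <- strsplit(trimws(body), "[,[:space:]]+")
  ncols <- lengths(fields)
  bad <- which(ncols < 2)
  if (length(bad) > 0)
    stop(sprintf("cannot parse %s: line %d ('%s') has fewer than 2 fields",
                 path, lineno[bad[1]], body[bad[1]]), call. = FALSE)
  vals <- lapply(fields, function(f) suppressWarnings(as.numeric(f)))
  badnum <- which(vapply(vals, function(v) any(is.na(v[1:2])), logical(1)))
  if (length(badnum) > 0)
    stop(sprintf("cannot parse %s: line %d ('%s') is not numeric",
                 path, lineno[badnum[1]], body[badnum[1]]), call. = FALSE)
  q <- vapply(vals, `[`, numeric(1), 1L)
  i <- vapply(vals, `[`, numeric(1), 2L)
  has3 <- all(ncols >= 3)
  sigma <- NULL
  if (dialect == "three_column" && !has3)
    stop("dialect 'three_column' requires 3 columns in ", path, call. = FALSE)
  if (has3 && dialect != "two_column")
    sigma <- vapply(vals, `[`, numeric(1), 3L)
  drop <- !is.finite(q) | q <= 0
  if (any(drop)) {
    warning(sum(drop), " row(s) with non-positive q dropped from ", path,
            call. = FALSE)
    q <- q[!drop]; i <- i[!drop]
    if (!is.null(sigma)) sigma <- sigma[!drop]
  }
  if (length(q) < 2)
    stop("insufficient data in ", path, ": fewer than 2 usable rows",
         call. = FALSE)
  saxs_profile(q, i, sigma,
               label = if (is.null(label)) basename(path) else label,
               concentration = concentration)
}

#' Write a scattering profile to a columnar text file
#'
#' Writes the same 2- or 3-column whitespace-delimited format that
#' [read_profile()] reads, with a `#` header line.
#'
#' @param profile A [saxs_profile()].
#' @param path Output path.
#' @param digits Significant digits for the printed values.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, digits = 10) {
  stopifnot(is_saxs_profile(profile))
  d <- as.data.frame(profile)
  hdr <- paste0("# ", profile$label,
                if (is.null(profile$sigma)) "\n# q_nm^-1 intensity"
                else "\n# q_nm^-1 intensity sigma")
  rows <- do.call(paste, c(lapply(d, signif, digits = digits), sep = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Convert a profile's q grid from inverse Angstrom to inverse nanometre
#'
#' Most public SAXS data files carry q in A^-1; the package's canonical
#' unit is nm^-1 (1 A^-1 = 10 nm^-1). This converter makes the unit
#' change explicit rather than silent.
#'
#' @param profile A [saxs_profile()] whose q is in A^-1.
#' @return The profile with q multiplied by 10.
#' @export
convert_q_angstrom_to_nm <- function(profile) {
  stopifnot(is_saxs_profile(profile))
  saxs_profile(profile$q * 10, profile$intensity, profile$sigma,
               label = profile$label, concentration = profile$concentration)
}

grids_match <- function(a, b, rtol = 1e-9) {
  length(a) == length(b) && all(abs(a - b) <= rtol * pmax(abs(a), abs(b)))
}

#' Subtract a background profile
#'
#' Computes `sample - scale * background` pointwise, the standard
#' treatment of cell/window scattering (e.g. Kapton film backgrounds).
#' Negative resulting intensities are retained, not clipped: downstream
#' fitting is weighted and clipping would bias it. Uncertainties, when
#' both profiles carry them, combine in quadrature.
#'
#' @param sample,background [saxs_profile()] objects on the same q grid
#'   (relative tolerance 1e-9), unless `interpolate = TRUE`.
#' @param scale Nonnegative scale factor applied to the background.
#' @param interpolate If `TRUE`, linearly interpolate the background onto
#'   the sample grid instead of requiring identical grids.
#' @return A [saxs_profile()] with the sample's metadata.
#' @export
subtract_background <- function(sample, background, scale = 1,
                                interpolate = FALSE) {
  stopifnot(is_saxs_profile(sample), is_saxs_profile(background))
  if (!is.numeric(scale) || length(scale) != 1 || scale < 0)
    stop("`scale` must be a single nonnegative number", call. = FALSE)
  if (grids_match(sample$q, background$q)) {
    bg_i <- background$intensity
    bg_s <- background$sigma
  } else if (interpolate) {
    bg_i <- stats::approx(background$q, background$intensity,
                          xout = sample$q, rule = 2)$y
    bg_s <- if (is.null(background$sigma)) NULL else
      stats::approx(background$q, background$sigma,
                    xout = sample$q, rule = 2)$y
  } else {
    stop("q grids differ; pass interpolate = TRUE to allow interpolation",
         call. = FALSE)
  }
  out_i <- sample$intensity - scale * bg_i
  n_neg <- sum(out_i < 0)
  if (n_neg > 0)
    message("subtract_background: ", n_neg,
            " negative intensities retained after subtraction")
  out_s <- if (!is.null(sample$sigma) && !is.null(bg_s))
    sqrt(sample$sigma^2 + (scale * bg_s)^2) else sample$sigma
  saxs_profile(sample$q, out_i, out_s,
               label = sample$label, concentration = sample$concentration)
}

#' Average replicate profiles
#'
#' Pointwise arithmetic mean of replicate measurements on a common q
#' grid. With two or more replicates and no input uncertainties, the
#' standard error of the mean (sample sd / sqrt(n)) is reported as
#' `sigma`; when the inputs carry uncertainties these are propagated
#' instead (sigma_mean = sqrt(sum sigma_i^2) / n).
#'
#' @param profiles A list of [saxs_profile()] objects with identical q
#'   grids.
#' @return A [saxs_profile()].
#' @export
average_profiles <- function(profiles) {
  if (!is.list(profiles) || length(profiles) == 0 ||
      !all(vapply(profiles, is_saxs_profile, logical(1))))
    stop("`profiles` must be a non-empty list of saxs_profile objects",
         call. = FALSE)
  q0 <- profiles[[1]]$q
  for (p in profiles[-1])
    if (!grids_match(q0, p$q))
      stop("q grids differ between replicates", call. = FALSE)
  n <- length(profiles)
  im <- vapply(profiles, `[[`, numeric(length(q0)), "intensity")
  im <- matrix(im, nrow = length(q0))
  mean_i <- rowMeans(im)
  have_sigma <- !vapply(profiles, function(p) is.null(p$sigma), logical(1))
  if (all(have_sigma)) {
    sm <- matrix(vapply(profiles, `[[`, numeric(length(q0)), "sigma"),
                 nrow = length(q0))
    sigma <- sqrt(rowSums(sm^2)) / n
  } else if (n >= 2) {
    sigma <- apply(im, 1, stats::sd) / sqrt(n)
    if (any(sigma <= 0)) sigma <- NULL  # degenerate identical replicates
  } else {
    sigma <- profiles[[1]]$sigma
  }
  saxs_profile(q0, mean_i, sigma,
               label = profiles[[1]]$label,
               concentration = profiles[[1]]$concentration)
}

#' Kratky transform of a profile
#'
#' Returns the Kratky representation q^2 * I(q) versus q, in which
#' scattering from compact nanostructures appears as a peak while a
#' q^-2 power law is flattened.
#'
#' @param profile A [saxs_profile()].
#' @return An object of class `kratky_profile`: list with `q` (nm^-1)
#'   and `kratky` (q^2 I, nm^-2 a.u.), same length and grid as the
#'   source.
#' @export
kratky_transform <- function(profile) {
  stopifnot(is_saxs_profile(profile))
  structure(list(q = profile$q, kratky = profile$q^2 * profile$intensity),
            class = "kratky_profile")
}

#' @export
print.kratky_profile <- function(x, ...) {
  cat(sprintf("<kratky_profile> %d points, q = %.4g-%.4g nm^-1\n",
              length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Restrict a profile to a q window
#'
#' @param profile A [saxs_profile()].
#' @param qmin,qmax Window bounds in nm^-1, inclusive; `qmin < qmax`.
#' @return The subset profile; metadata preserved. Errors if the window
#'   contains no points.
#' @export
restrict_q <- function(profile, qmin, qmax) {
  stopifnot(is_saxs_profile(profile))
  if (!(qmin < qmax)) stop("`qmin` must be < `qmax`", call. = FALSE)
  keep <- profile$q >= qmin & profile$q <= qmax
  if (!any(keep))
    stop(sprintf("no points in q window [%g, %g]", qmin, qmax), call. = FALSE)
  saxs_profile(profile$q[keep], profile$intensity[keep],
               if (is.null(profile$sigma)) NULL else profile$sigma[keep],
               label = profile$label, concentration = profile$concentration)
}
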