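## Umbrella-integration estimation of a potential of mean force (PMF)
## along a scalar reaction coordinate xi (here: centre-of-mass distance
## between two residues, in Angstrom), from harmonically biased samples.

# Boltzmann constant in kcal/mol/K
KB_KCAL <- 0.0019872041

#' A harmonically biased sampling window
#'
#' @param center Window centre `xi_c` (Angstrom).
#' @param spring Harmonic spring constant K (kcal/mol/A^2); the bias is
#'   `w(xi) = K/2 (xi - xi_c)^2`.
#' @param samples Numeric vector of sampled reaction-coordinate values
#'   (Angstrom); at least 2.
#' @param temperature Simulation temperature (K), default 300.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, spring, samples, temperature = 300) {
  if (!(spring > 0)) stop("spring constant must be > 0", call. = FALSE)
  if (!(temperature > 0)) stop("temperature must be > 0", call. = FALSE)
  if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite", call. = FALSE)
  }
  structure(list(center = center, spring = spring,
                 samples = as.numeric(samples), temperature = temperature),
            class = "umbrella_window")
}

#' Burn-in-trimmed sample statistics of a window
#'
#' Discards the first `burn_in_fraction` of the samples (in order; sample
#' order stands in for simulation time) and returns the mean and unbiased
#' variance of the remainder.  The default 0.4 mirrors a protocol that
#' keeps the last 3 ns of 5-ns windows.
#'
#' @param window An `umbrella_window`.
#' @param burn_in_fraction Fraction in \[0, 1) discarded from the front.
#' @return An object of class `window_statistics` with `mean`, `variance`,
#'   `count`.
#' @export
window_statistics <- function(window, burn_in_fraction = 0.4) {
  stopifnot(inherits(window, "umbrella_window"))
  if (!(burn_in_fraction >= 0 && burn_in_fraction < 1)) {
    stop("burn_in_fraction must be in [0, 1)", call. = FALSE)
  }
  x <- window$samples
  drop <- floor(burn_in_fraction * length(x))
  x <- x[(drop + 1L):length(x)]
  if (length(x) < 2L) stop("fewer than 2 samples remain after burn-in",
                           call. = FALSE)
  v <- stats::var(x)
  if (v == 0) stop("zero sample variance in window; cannot estimate PMF derivative",
                   call. = FALSE)
  structure(list(mean = mean(x), variance = v, count = length(x)),
            class = "window_statistics")
}

#' Unbiased PMF derivative from one window (umbrella integration)
#'
#' Under the normal approximation to the biased sampling distribution, the
#' derivative of the unbiased PMF estimated from window i is
#' `dA/dxi = (1/beta) (xi - mean_i) / var_i - K (xi - center_i)`, where
#' `beta = 1/(kB T)`.  The per-window offset constants of the underlying
#' free-energy matching cancel in this derivative formulation and never
#' enter the computation.
#'
#' @param stats A `window_statistics`.
#' @param window The `umbrella_window` the statistics came from.
#' @param xi Reaction-coordinate value(s) at which to evaluate (Angstrom).
#' @return `dA/dxi` in kcal/mol/A, same length as `xi`.
#' @export
unbiased_derivative <- function(stats, window, xi) {
  stopifnot(inherits(stats, "window_statistics"),
            inherits(window, "umbrella_window"))
  kT <- KB_KCAL * window$temperature
  kT * (xi - stats$mean) / stats$variance - window$spring * (xi - window$center)
}

#' Combine windows and integrate to a PMF profile
#'
#' At each grid point the per-window derivative estimates are averaged
#' with weights proportional to `n_i` times the normal density of window
#' i's biased sample distribution at that point (Kaestner-Thiel
#' combination), then integrated by the trapezoidal rule and pinned to
#' zero at the largest grid value (the separated state).
#'
#' @param windows List of `umbrella_window` (>= 1) sharing a temperature.
#' @param grid_spacing Grid step in Angstrom (default 0.05).
#' @param burn_in_fraction Passed to [window_statistics()].
#' @param grid_range Optional `c(lo, hi)`; default spans the window
#'   centres.
#' @return An object of class `pmf_profile`: `grid`, `values` (kcal/mol,
#'   zero at the last grid point), `reference`, `temperature`.
#' @export
combine_and_integrate <- function(windows, grid_spacing = 0.05,
                                  burn_in_fraction = 0.4,
                                  grid_range = NULL) {
  if (length(windows) < 1L) stop("need at least one window", call. = FALSE)
  stopifnot(all(vapply(windows, inherits, logical(1), "umbrella_window")))
  temps <- vapply(windows, `[[`, numeric(1), "temperature")
  if (diff(range(temps)) > 1e-9) {
    stop("windows have differing temperatures", call. = FALSE)
  }
  stats <- lapply(windows, window_statistics,
                  burn_in_fraction = burn_in_fraction)
  centers <- vapply(windows, `[[`, numeric(1), "center")
  if (is.null(grid_range)) grid_range <- range(centers)
  grid <- seq(grid_range[1L], grid_range[2L], by = grid_spacing)
  if (grid[length(grid)] < grid_range[2L]) grid <- c(grid, grid_range[2L])

  means <- vapply(stats, `[[`, numeric(1), "mean")
  vars <- vapply(stats, `[[`, numeric(1), "variance")
  ns <- vapply(stats, `[[`, numeric(1), "count")
  sds <- sqrt(vars)

  # weight matrix: rows = windows, cols = grid points
  w <- vapply(grid, function(x) ns * stats::dnorm(x, means, sds), numeric(length(windows)))
  w <- matrix(w, nrow = length(windows))
  totw <- colSums(w)
  gap <- which(totw < .Machine$double.xmin * 1e10)
  if (length(gap) > 0L) {
    stop(sprintf(
      "coverage gap: no window has appreciable weight on [%.3f, %.3f] A",
      min(grid[gap]), max(grid[gap])), call. = FALSE)
  }

  dv <- vapply(seq_along(grid), function(g) {
    x <- grid[g]
    d <- vapply(seq_along(windows), function(i) {
      unbiased_derivative(stats[[i]], windows[[i]], x)
    }, numeric(1))
    sum(w[, g] * d) / totw[g]
  }, numeric(1))

  A <- c(0, cumsum((dv[-1L] + dv[-length(dv)]) / 2 * diff(grid)))
  A <- A - A[length(A)]
  structure(list(grid = grid, values = A, reference = grid[length(grid)],
                 temperature = temps[1L]),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat(sprintf("PMF profile: %d points on [%.2f, %.2f] A, min %.3f kcal/mol at %.2f A (A = 0 at %.2f A)\n",
              length(x$grid), min(x$grid), max(x$grid), min(x$values),
              x$grid[which.min(x$values)], x$reference))
  invisible(x)
}

#' Pairwise binding free energy from a PMF profile
#'
#' `min_minus_reference` (default) reads the well depth: the minimum of
#' `A(xi)` relative to the dissociated reference where `A = 0`.
#' `boltzmann_bound_state` instead Boltzmann-integrates
#' `exp(-beta A)` over the bound region (`xi <= bound_cutoff`) and over
#' the unbound remainder and returns `-(1/beta) ln(Z_bound / Z_unbound)`.
#'
#' @param profile A `pmf_profile`.
#' @param convention `"min_minus_reference"` or `"boltzmann_bound_state"`.
#' @param bound_cutoff Bound-region cutoff (Angstrom) for the Boltzmann
#'   convention; default is the midpoint of the grid.
#' @return An object of class `binding_free_energy` with `value`
#'   (kcal/mol) and `convention`.  A profile whose minimum sits at the
#'   reference has no bound state; the value is 0 with a warning.
#' @export
binding_free_energy <- function(profile,
                                convention = c("min_minus_reference",
                                               "boltzmann_bound_state"),
                                bound_cutoff = NULL) {
  convention <- match.arg(convention)
  stopifnot(inherits(profile, "pmf_profile"))
  g <- profile$grid; A <- profile$values
  kT <- KB_KCAL * profile$temperature
  if (min(A) >= A[length(A)] - .Machine$double.eps * 100) {
    warning("profile has no well below the reference; no bound state (value 0)")
    return(structure(list(value = 0, convention = convention),
                     class = "binding_free_energy"))
  }
  if (convention == "min_minus_reference") {
    val <- min(A)
  } else {
    if (is.null(bound_cutoff)) bound_cutoff <- mean(range(g))
    trapz <- function(x, y) sum((y[-1L] + y[-length(y)]) / 2 * diff(x))
    inb <- g <= bound_cutoff
    if (sum(inb) < 2L || sum(!inb) < 2L) {
      stop("bound_cutoff leaves fewer than 2 grid points on one side",
           call. = FALSE)
    }
    zb <- trapz(g[inb], exp(-A[inb] / kT))
    zu <- trapz(g[!inb], exp(-A[!inb] / kT))
    val <- -kT * log(zb / zu)
  }
  structure(list(value = val, convention = convention),
            class = "binding_free_energy")
}

#' Draw biased reaction-coordinate samples from a known PMF
#'
#' Synthetic stand-in for a biased simulation: samples are drawn from the
#' density proportional to `exp(-beta (A(xi) + K/2 (xi - xi_c)^2))` by
#' inverse-CDF lookup on a fine grid (trapezoidal cumulative, so the CDF
#' is second-order accurate; a one-sided Riemann cumulative would bias
#' every sample by half a grid cell, which stiff springs amplify into a
#' visible PMF drift).  Deterministic given `seed`.
#'
#' @param true_pmf Function `A(xi)` in kcal/mol, finite on the support.
#' @param center,spring Window centre (A) and spring constant
#'   (kcal/mol/A^2).
#' @param n Number of samples.
#' @param seed Integer RNG seed.
#' @param temperature Temperature (K), default 300.
#' @param support Sampling support `c(lo, hi)`; default
#'   `center +- (8 sd + 0.1)` with `sd = sqrt(kT/K)`, which keeps the
#'   inverse-CDF grid fine relative to the biased distribution's width
#'   even for very stiff springs.
#' @param grid_points Resolution of the inverse-CDF grid.
#' @return An `umbrella_window` carrying the samples.
#' @export
simulate_biased_samples <- function(true_pmf, center, spring, n, seed,
                                    temperature = 300, support = NULL,
                                    grid_points = 8001L) {
  if (!(spring > 0)) stop("spring constant must be > 0", call. = FALSE)
  kT <- KB_KCAL * temperature
  if (is.null(support)) {
    half <- 8 * sqrt(kT / spring) + 0.1
    support <- c(center - half, center + half)
  }
  g <- seq(support[1L], support[2L], length.out = grid_points)
  logd <- -(true_pmf(g) + spring / 2 * (g - center)^2) / kT
  if (anyNA(logd)) stop("true_pmf returned non-finite values on the support",
                        call. = FALSE)
  d <- exp(logd - max(logd))
  if (max(d) == 0 || all(d < .Machine$double.xmin)) {
    stop("biased density numerically zero everywhere on the support",
         call. = FALSE)
  }
  cdf <- c(0, cumsum((d[-1L] + d[-length(d)]) / 2 * diff(g)))
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)  # strictly increasing knots for inversion
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  u <- stats::runif(n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  samples <- stats::approx(cdf[keep], g[keep], xout = u, rule = 2)$y
  umbrella_window(center = center, spring = spring, samples = samples,
                  temperature = temperature)
}

#' Write / read window sample files
#'
#' Plain-text window format: `#` metadata lines (`center`, `spring`,
#' `temperature`, `units`), then one sampled xi value per line.  A
#' manifest is a text file listing one window file path per line
#' (relative paths resolved against the manifest's directory).
#'
#' @param window An `umbrella_window`.
#' @param path Output file.
#' @return `path` (write) or an `umbrella_window` / list of them (read),
#'   invisibly for writers.
#' @export
write_window_file <- function(window, path) {
  stopifnot(inherits(window, "umbrella_window"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# center: %.17g", window$center),
               sprintf("# spring: %.17g", window$spring),
               sprintf("# temperature: %.17g", window$temperature),
               "# units: Angstrom, kcal/mol/A^2, K"), con)
  writeLines(sprintf("%.17g", window$samples), con)
  invisible(path)
}

#' @rdname write_window_file
#' @export
read_window_file <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getval <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (length(hit) == 0L) stop(sprintf("window file %s lacks '%s' metadata",
                                        path, key), call. = FALSE)
    as.numeric(trimws(sub(sprintf("^#\\s*%s:", key), "", hit[1L])))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  samples <- as.numeric(body)
  if (anyNA(samples)) stop("non-numeric sample line in ", path, call. = FALSE)
  umbrella_window(center = getval("center"), spring = getval("spring"),
                  samples = samples, temperature = getval("temperature"))
}

#' @rdname write_window_file
#' @param manifest_path Manifest file listing window files.
#' @export
read_window_manifest <- function(manifest_path) {
  lines <- readLines(manifest_path)
  lines <- trimws(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  if (length(lines) == 0L) stop("empty window manifest", call. = FALSE)
  base <- dirname(manifest_path)
  lapply(lines, function(p) {
    full <- if (file.exists(p)) p else file.path(base, p)
    read_window_file(full)
  })
}

#' Write a PMF profile as a two-column TSV
#'
#' @param profile A `pmf_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pmf_profile <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# temperature: %g K", profile$temperature),
               sprintf("# reference: %g A", profile$reference),
               "xi\tA"), con)
  writeLines(sprintf("%.10g\t%.10g", profile$grid, profile$values), con)
  invisible(path)
}
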