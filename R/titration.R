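## One-to-one binding model for fluorescence-anisotropy titrations:
## a labelled species A at fixed total concentration c_A is titrated with
## B; the observed anisotropy is the population-weighted mix of the free
## (r_A) and bound (r_AB) anisotropies, with the complex concentration
## given by the exact quadratic solution of the 1:1 equilibrium.

#' Equilibrium complex concentration of a 1:1 binding
#'
#' Solves `(c_A - c_AB)(c_B - c_AB) = K_D c_AB` for the physical root.
#' Evaluated in the cancellation-free form
#' `c_AB = 2 c_A c_B / (s + sqrt(s^2 - 4 c_A c_B))`, `s = c_A + c_B + K_D`,
#' which is algebraically identical to the textbook
#' `(s - sqrt(s^2 - 4 c_A c_B)) / 2` but loses no precision when
#' `K_D >> c_A, c_B`.
#'
#' @param c_A,c_B Total concentrations of the labelled species and the
#'   titrant (molar, >= 0); vectors recycle.
#' @param K_D Dissociation constant (molar, >= 0).
#' @return Complex concentration(s) `c_AB`, bounded by
#'   `0 <= c_AB <= min(c_A, c_B)`.
#' @export
complex_concentration <- function(c_A, c_B, K_D) {
  if (any(c_A < 0) || any(c_B < 0) || any(K_D < 0)) {
    stop("concentrations and K_D must be non-negative", call. = FALSE)
  }
  s <- c_A + c_B + K_D
  disc <- s^2 - 4 * c_A * c_B
  disc[disc < 0] <- 0  # guard tiny negative round-off at K_D = 0, c_A = c_B
  denom <- s + sqrt(disc)
  out <- ifelse(denom > 0, 2 * c_A * c_B / denom, 0)
  pmin(out, pmin(c_A, c_B))
}

#' Parameters of the 1:1 anisotropy binding model
#'
#' @param r_A Anisotropy of the free labelled species (dimensionless).
#' @param r_AB Anisotropy of the complex (dimensionless).
#' @param K_D Dissociation constant (molar, >= 0).
#' @param c_A Total labelled-species concentration (molar, > 0).
#' @return An object of class `binding_parameters`.
#' @export
binding_parameters <- function(r_A, r_AB, K_D, c_A) {
  if (!(K_D >= 0)) stop("K_D must be >= 0", call. = FALSE)
  if (!(c_A > 0)) stop("c_A must be > 0", call. = FALSE)
  structure(list(r_A = r_A, r_AB = r_AB, K_D = K_D, c_A = c_A),
            class = "binding_parameters")
}

#' Predicted anisotropy at a titrant concentration
#'
#' `r_obs = r_A (c_A - c_AB)/c_A + r_AB c_AB/c_A`, with `c_AB` from
#' [complex_concentration()]; always bounded between `r_A` and `r_AB`.
#'
#' @param params A `binding_parameters`.
#' @param c_B Titrant concentration(s) (molar).
#' @return Predicted anisotropies, same length as `c_B`.
#' @export
predicted_anisotropy <- function(params, c_B) {
  stopifnot(inherits(params, "binding_parameters"))
  f <- complex_concentration(params$c_A, c_B, params$K_D) / params$c_A
  params$r_A * (1 - f) + params$r_AB * f
}

#' Simulate a titration curve
#'
#' Forward model plus optional i.i.d. Gaussian noise on the anisotropy;
#' deterministic given `seed`.
#'
#' @param params A `binding_parameters`.
#' @param c_B_series Ascending titrant concentrations (molar).
#' @param noise_sd Gaussian noise standard deviation on r_obs (0 = exact).
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return An object of class `titration_curve`: `c_B`, `r_obs`,
#'   `noise_sd`, `c_A`.
#' @export
simulate_titration <- function(params, c_B_series, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(params, "binding_parameters"))
  c_B <- sort(as.numeric(c_B_series))
  r <- predicted_anisotropy(params, c_B)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("seed required for noisy simulation", call. = FALSE)
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    r <- r + stats::rnorm(length(r), sd = noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  structure(list(c_B = c_B, r_obs = r, noise_sd = noise_sd, c_A = params$c_A),
            class = "titration_curve")
}

#' Fit the 1:1 binding model to a titration curve
#'
#' Least-squares fit of `(r_A, r_AB, K_D)` at fixed, known `c_A`
#' (floating the label concentration would destroy identifiability when
#' `c_A << K_D`).  `K_D` is fitted on the log scale, which enforces
#' positivity; its standard error is mapped back by the delta method.
#' Default initial values: `r_A` from the first point, `r_AB` from the
#' last, `K_D` from the titrant concentration nearest half-signal.
#'
#' @param curve A `titration_curve` (or list with `c_B`, `r_obs`).
#' @param c_A Total labelled concentration (molar); defaults to the
#'   curve's own `c_A` when present.
#' @param init Optional `binding_parameters` supplying starting values.
#' @return An object of class `fit_result`: `estimates` (named vector
#'   r_A, r_AB, K_D), `se` (standard errors on the same scale), `rss`,
#'   `converged`, `fit` (the underlying `nls` object).
#' @export
fit_titration <- function(curve, c_A = curve$c_A, init = NULL) {
  c_B <- as.numeric(curve$c_B)
  r_obs <- as.numeric(curve$r_obs)
  if (length(c_B) != length(r_obs)) stop("c_B and r_obs lengths differ",
                                         call. = FALSE)
  if (is.null(c_A)) stop("c_A must be supplied", call. = FALSE)
  if (length(c_B) < 4L) {
    warning("fewer than 4 titration points; fit may be unreliable")
  }
  span <- diff(range(r_obs))
  if (span < 1e-6) {
    stop("flat titration curve (r_A ~ r_AB): parameters not identifiable",
         call. = FALSE)
  }
  if (is.null(init)) {
    half <- r_obs[1L] + span / 2 * sign(r_obs[length(r_obs)] - r_obs[1L])
    kd0 <- c_B[which.min(abs(r_obs - half))]
    if (!(kd0 > 0)) kd0 <- max(c_B[c_B > 0][1L], c_A)
    init <- binding_parameters(r_A = r_obs[1L], r_AB = r_obs[length(r_obs)],
                               K_D = kd0, c_A = c_A)
  }
  df <- data.frame(c_B = c_B, r_obs = r_obs)
  model <- function(r_A, r_AB, logK, c_B) {
    f <- complex_concentration(c_A, c_B, exp(logK)) / c_A
    r_A * (1 - f) + r_AB * f
  }
  fit <- minpack.lm::nlsLM(
    r_obs ~ model(r_A, r_AB, logK, c_B),
    data = df,
    start = list(r_A = init$r_A, r_AB = init$r_AB, logK = log(init$K_D)),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                         ptol = 1e-15))
  co <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3L))
  names(se) <- names(co)
  kd <- exp(co[["logK"]])
  estimates <- c(r_A = co[["r_A"]], r_AB = co[["r_AB"]], K_D = kd)
  ses <- c(r_A = se[["r_A"]], r_AB = se[["r_AB"]],
           K_D = kd * se[["logK"]])  # delta method for exp(logK)
  structure(list(estimates = estimates, se = ses,
                 rss = sum(stats::residuals(fit)^2),
                 converged = fit$convInfo$isConv %||% TRUE,
                 fit = fit),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  e <- x$estimates; s <- x$se
  cat(sprintf("1:1 binding fit: K_D = %.3g +/- %.2g M, r_A = %.4f +/- %.2g, r_AB = %.4f +/- %.2g (RSS %.3g)\n",
              e[["K_D"]], s[["K_D"]], e[["r_A"]], s[["r_A"]],
              e[["r_AB"]], s[["r_AB"]], x$rss))
  invisible(x)
}

#' Read / write titration TSV files
#'
#' Two tab-separated columns (`c_B` in molar, `r_obs`), with `#` metadata
#' lines; `# c_A:` records the labelled-species concentration.
#'
#' @param curve A `titration_curve`.
#' @param path File path.
#' @return `path` (write) / a `titration_curve` (read).
#' @export
write_titration <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# c_A: %.17g", curve$c_A),
               sprintf("# noise_sd: %.17g", curve$noise_sd %||% 0),
               "c_B\tr_obs"), con)
  writeLines(sprintf("%.17g\t%.17g", curve$c_B, curve$r_obs), con)
  invisible(path)
}

#' @rdname write_titration
#' @export
read_titration <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  c_A <- NULL
  hit <- grep("^#\\s*c_A:", meta, value = TRUE)
  if (length(hit) > 0L) c_A <- as.numeric(trimws(sub("^#\\s*c_A:", "", hit[1L])))
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  body <- body[!grepl("^c_B", body)]  # header row
  parts <- strsplit(body, "\t", fixed = TRUE)
  c_B <- as.numeric(vapply(parts, `[[`, character(1), 1L))
  r_obs <- as.numeric(vapply(parts, `[[`, character(1), 2L))
  if (anyNA(c_B) || anyNA(r_obs)) stop("non-numeric titration row in ", path,
                                       call. = FALSE)
  structure(list(c_B = c_B, r_obs = r_obs, noise_sd = NA_real_, c_A = c_A),
            class = "titration_curve")
}
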