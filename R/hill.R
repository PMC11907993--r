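# Hill-equation fitting of fraction-bound binding titrations.

#' Hill binding model
#'
#' Fraction bound as a function of protein concentration:
#' `Y = Bmax * X^h / (Kd^h + X^h)`, with `Bmax` the maximum response (in
#' (0, 1]), `Kd` the dissociation constant (> 0, same units as `X`) and `h`
#' the Hill coefficient (> 0). `Y(0) = 0`, `Y(Kd) = Bmax / 2` for any `h`,
#' and `Y` increases towards `Bmax`.
#'
#' @param x Concentrations (>= 0).
#' @param bmax,kd,h Model parameters.
#' @return Numeric vector of responses.
#' @examples
#' hill_model(238, bmax = 1, kd = 238, h = 1)  # 0.5 at half-saturation
#' @export
hill_model <- function(x, bmax, kd, h) {
  if (kd <= 0) stop("Kd must be > 0", call. = FALSE)
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  if (bmax <= 0 || bmax > 1) stop("Bmax must be in (0, 1]", call. = FALSE)
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  xh <- x^h
  ifelse(x == 0, 0, bmax * xh / (kd^h + xh))
}

.hill_failed <- function(data, reason) {
  structure(list(coefficients = c(Bmax = NA_real_, Kd = NA_real_,
                                  h = NA_real_),
                 se = c(Bmax = NA_real_, Kd = NA_real_, h = NA_real_),
                 rss = NA_real_, converged = FALSE, flags = reason,
                 n = nrow(data), data = data, fit = NULL),
            class = "hill_fit")
}

#' Fit the Hill model to a binding curve
#'
#' Constrained nonlinear least squares (Levenberg-Marquardt with box
#' bounds): `Bmax` in (0, 1], `Kd > 0`, `h > 0`, so reported parameters and
#' standard errors live on the natural scale. Replicates, if present, are
#' fitted jointly by stacking points. Initialization: `Bmax0 = max(Y)`
#' clipped to (0, 1], `Kd0` = the concentration whose response is closest
#' to `Bmax0 / 2`, `h0 = 1`.
#'
#' @param curve data.frame with columns `concentration` and
#'   `fraction_bound` (and optionally `replicate`). Responses must lie in
#'   `[-0.05, 1.05]` (small quantification noise is tolerated); at least 4
#'   distinct concentrations are required.
#' @param init Optional named list/vector overriding the starting values
#'   (`Bmax`, `Kd`, `h`).
#' @return An object of class `hill_fit` with `coefficients` (Bmax, Kd, h),
#'   `se`, `rss`, `converged` and `flags`. Non-convergence yields a flagged
#'   result with `NA` parameters, never fabricated values. A fitted `Kd`
#'   beyond 10x the largest tested concentration is flagged
#'   `"kd_extrapolated"`; `h` pinned at its lower bound is flagged
#'   `"h_at_bound"`.
#' @examples
#' curve <- simulate_binding_curve(0.9, 300, 1.2,
#'                                 concentrations = c(10, 30, 100, 300,
#'                                                    1000, 3000),
#'                                 noise_sd = 0)
#' fit_hill(curve)
#' @export
fit_hill <- function(curve, init = NULL) {
  stopifnot(is.data.frame(curve),
            all(c("concentration", "fraction_bound") %in% names(curve)))
  x <- curve$concentration
  y <- curve$fraction_bound
  if (any(x < 0)) stop("concentrations must be >= 0", call. = FALSE)
  if (any(y < -0.05 | y > 1.05)) {
    stop("fraction_bound outside [-0.05, 1.05]", call. = FALSE)
  }
  if (length(unique(x)) < 4L) {
    stop("need >= 4 distinct concentrations", call. = FALSE)
  }
  if (all(abs(y) < 1e-12)) stop("no binding signal", call. = FALSE)

  bmax0 <- min(max(max(y), 1e-3), 1)
  kd0 <- x[which.min(abs(y - bmax0 / 2))]
  if (kd0 <= 0) kd0 <- min(x[x > 0])
  lower <- c(bmax = 1e-6, kd = 1e-9, h = 1e-3)
  upper <- c(bmax = 1, kd = Inf, h = Inf)
  # deterministic multi-start over the Hill slope: a single h0 can strand
  # the optimizer at the Bmax bound on steep curves
  starts <- lapply(c(0.5, 1, 2), function(h0) {
    list(bmax = bmax0, kd = kd0, h = h0)
  })
  if (!is.null(init)) {
    init <- as.list(init)
    names(init) <- tolower(names(init))
    user <- starts[[2]]
    for (nm in intersect(names(init), names(user))) user[[nm]] <- init[[nm]]
    starts <- c(list(user), starts)
  }
  fit <- NULL
  last_error <- NULL
  for (start in starts) {
    cand <- tryCatch(
      minpack.lm::nlsLM(
        fraction_bound ~ bmax * concentration^h / (kd^h + concentration^h),
        data = curve, start = start, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = identity)
    if (inherits(cand, "error")) {
      last_error <- cand
      next
    }
    if (is.null(fit) ||
        sum(stats::residuals(cand)^2) < sum(stats::residuals(fit)^2)) {
      fit <- cand
    }
  }
  if (is.null(fit)) {
    return(.hill_failed(curve, paste0("no_convergence: ",
                                      conditionMessage(last_error))))
  }
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3))
  flags <- character(0)
  if (est[["kd"]] > 10 * max(x)) {
    flags <- c(flags, "kd_extrapolated")
    warning("fitted Kd is more than 10x the largest tested concentration",
            call. = FALSE)
  }
  if (est[["h"]] <= lower[["h"]] * 1.001) {
    flags <- c(flags, "h_at_bound")
    warning("Hill coefficient pinned at its lower bound", call. = FALSE)
  }
  structure(list(
    coefficients = c(Bmax = unname(est[["bmax"]]), Kd = unname(est[["kd"]]),
                     h = unname(est[["h"]])),
    se = c(Bmax = unname(se[1]), Kd = unname(se[2]), h = unname(se[3])),
    rss = sum(stats::residuals(fit)^2),
    converged = fit$convInfo$isConv,
    flags = if (length(flags)) flags else "ok",
    n = nrow(curve), data = curve, fit = fit),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_fit> not converged:", x$flags, "\n")
    return(invisible(x))
  }
  co <- x$coefficients
  cat(sprintf(
    "<hill_fit> Bmax = %.3f +/- %.3f, Kd = %.4g +/- %.3g, h = %.2f +/- %.2f\n",
    co["Bmax"], x$se["Bmax"], co["Kd"], x$se["Kd"], co["h"], x$se["h"]))
  cat(sprintf("  n = %d points, RSS = %.4g, cooperativity: %s\n", x$n, x$rss,
              classify_cooperativity(co["h"])))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) object$coefficients

#' Qualitative cooperativity band of a Hill coefficient
#'
#' Interpretive thresholds (not fitted): `h < 1.3` weak positive
#' cooperativity, `h >= 1.5` moderate positive, in between intermediate.
#'
#' @param h Hill coefficient(s).
#' @return Character vector of band names.
#' @export
classify_cooperativity <- function(h) {
  ifelse(h < 1.3, "weak_positive",
         ifelse(h >= 1.5, "moderate_positive", "intermediate"))
}

#' Plot a Hill fit
#'
#' Points on a log-concentration axis with the fitted curve overlaid.
#'
#' @param x A `hill_fit` object.
#' @param ... Passed to [plot()].
#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data
  plot(d$concentration, d$fraction_bound, log = "x",
       xlab = "concentration", ylab = "fraction bound", ...)
  if (x$converged) {
    co <- x$coefficients
    xs <- exp(seq(log(min(d$concentration[d$concentration > 0])),
                  log(max(d$concentration)), length.out = 200))
    graphics::lines(xs, hill_model(xs, co["Bmax"], co["Kd"], co["h"]))
  }
  invisible(x)
}
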