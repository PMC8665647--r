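#' Standard-curve model families
#'
#' Forward models map concentration (pg/mL, well scale) to median
#' fluorescence intensity. The four-parameter logistic (4PL) is
#' `mfi(x) = d + (a - d) / (1 + (x / c)^(-b))` with lower asymptote `d`,
#' upper asymptote `a`, inflection concentration `c` and slope `b` (`b > 0`
#' gives a response increasing in concentration). The five-parameter
#' logistic (5PL) raises the denominator to an asymmetry power `g`. The
#' exponential family is a power law, `log10(mfi) = alpha + beta * log10(x)`,
#' used when the sigmoid families fail or are not supported by the data.
#'
#' @param family One of `"logistic4"`, `"logistic5"`, `"exponential"`.
#' @param params Named numeric vector of coefficients
#'   (`a`, `d`, `c`, `b`[, `g`] or `alpha`, `beta`).
#' @param fit_sse Sum of squared residuals on the log10(MFI) scale.
#' @param n Number of standard points used in the fit.
#' @return An object of class `curve_model`.
#' @export
curve_model <- function(family, params, fit_sse = NA_real_, n = NA_integer_) {
  family <- match.arg(family, c("logistic4", "logistic5", "exponential"))
  params <- unlist(params)
  if (!all(is.finite(params))) abort("Curve parameters must be finite.")
  structure(
    list(family = family, params = params, fit_sse = fit_sse, n = n),
    class = "curve_model"
  )
}

#' @export
print.curve_model <- function(x, ...) {
  cat(
    "<curve_model ", x$family, "> ",
    paste(names(x$params), signif(x$params, 4), sep = "=", collapse = " "),
    "  sse=", signif(x$fit_sse, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Evaluate a standard-curve model
#'
#' @param model A `curve_model`.
#' @param conc Concentrations (pg/mL, well scale), strictly positive.
#' @return Predicted MFI.
#' @export
curve_forward <- function(model, conc) {
  p <- model$params
  switch(model$family,
    logistic4 = p[["d"]] + (p[["a"]] - p[["d"]]) / (1 + (conc / p[["c"]])^(-p[["b"]])),
    logistic5 = p[["d"]] + (p[["a"]] - p[["d"]]) /
      (1 + (conc / p[["c"]])^(-p[["b"]]))^p[["g"]],
    exponential = 10^(p[["alpha"]] + p[["beta"]] * log10(conc))
  )
}

#' Invert a standard-curve model
#'
#' Maps MFI back to concentration. For the logistic families values at or
#' beyond the asymptotes are mapped to 0 / `Inf` (increasing response; the
#' mirror for a decreasing response with `b < 0`), so censoring rules can be
#' applied downstream rather than erroring here.
#'
#' @param model A `curve_model`.
#' @param mfi Observed MFI values.
#' @return Concentrations (pg/mL, well scale).
#' @export
curve_inverse <- function(model, mfi) {
  p <- model$params
  if (model$family == "exponential") {
    return(10^((log10(mfi) - p[["alpha"]]) / p[["beta"]]))
  }
  a <- p[["a"]]; d <- p[["d"]]; cc <- p[["c"]]; b <- p[["b"]]
  g <- if (model$family == "logistic5") p[["g"]] else 1
  lo <- min(a, d); hi <- max(a, d)
  increasing <- xor(a > d, b < 0) # response rises with conc?
  out <- rep(NA_real_, length(mfi))
  # ratio r = (x/c)^(-b) solves ((a-d)/(y-d))^(1/g) - 1
  inside <- mfi > lo & mfi < hi
  r <- ((a - d) / (mfi[inside] - d))^(1 / g) - 1
  out[inside] <- cc * r^(-1 / b)
  out[mfi <= lo] <- if (increasing) 0 else Inf
  out[mfi >= hi] <- if (increasing) Inf else 0
  out
}

# least-squares objective is on log10(MFI); shared by fit + AIC
curve_rss <- function(model, conc, mfi) {
  pred <- curve_forward(model, conc)
  if (any(!is.finite(pred)) || any(pred <= 0)) return(Inf)
  sum((log10(mfi) - log10(pred))^2)
}

# AIC on gaussian log10(MFI) residuals; k = n_params + 1 (sigma).
# RSS is floored so that two numerically-perfect fits tie and the
# parameter penalty decides (a noiseless 4PL must not lose to a 5PL on
# machine-epsilon residual differences).
curve_aic <- function(rss, n, n_params, rss_floor = n * 1e-20) {
  rss <- max(rss, rss_floor)
  n * log(rss / n) + 2 * (n_params + 1)
}

fit_logistic_family <- function(conc, mfi, family, seed = 1L) {
  five <- family == "logistic5"
  y <- log10(mfi)
  d0 <- max(min(mfi) * 0.9, 1e-6)
  a0 <- max(mfi) * 1.1
  # slope/inflection starts from the logit-linearization of the response
  frac <- pmin(pmax((mfi - d0) / (a0 - d0), 1e-4), 1 - 1e-4)
  z <- log(frac / (1 - frac))
  lf <- lm(z ~ log(conc))
  b0 <- unname(coef(lf)[2])
  if (!is.finite(b0) || abs(b0) < 1e-3) b0 <- sign(b0 + 1e-12) * 0.5
  c0 <- exp(-unname(coef(lf)[1]) / b0)
  if (!is.finite(c0) || c0 <= 0) c0 <- exp(mean(log(conc)))
  starts <- list(c(a = a0, d = d0, c = c0, b = b0))
  # when the ladder never reaches the lower plateau, 0.9*min(mfi) badly
  # overestimates d: offer a near-zero floor as a second basin
  starts[[2]] <- c(a = a0, d = 0.02 * min(mfi), c = c0, b = b0)
  if (five) {
    starts[[1]] <- c(starts[[1]], g = 1)
    starts[[2]] <- c(starts[[2]], g = 1)
  }
  # jittered restarts (used when the data-driven starts fail),
  # deterministic given `seed` and invisible to the caller's RNG stream
  jit <- with_preserved_seed(seed, matrix(rnorm(12, 0, 0.4), nrow = 4))
  for (j in 1:3) {
    s <- starts[[1 + j %% 2]]
    s[["c"]] <- s[["c"]] * exp(jit[j, 1])
    s[["b"]] <- s[["b"]] * exp(jit[j, 2] * 0.5)
    s[["d"]] <- s[["d"]] * exp(jit[j, 3])
    if (five) s[["g"]] <- exp(jit[j + 1, 3] * 0.5)
    starts[[j + 2]] <- s
  }
  # optimize on log-scale parameters (positivity for free, and the
  # Levenberg-Marquardt steps are far better conditioned than with raw
  # asymptotes in the tens of thousands next to a unit slope)
  to_log <- function(s) {
    out <- c(la = log(s[["a"]]), ld = log(max(s[["d"]], 1e-9)),
      lc = log(s[["c"]]), b = s[["b"]])
    if (five) out <- c(out, lg = log(s[["g"]]))
    out
  }
  from_log <- function(q) {
    out <- c(a = exp(q[["la"]]), d = exp(q[["ld"]]), c = exp(q[["lc"]]), b = q[["b"]])
    if (five) out <- c(out, g = exp(q[["lg"]]))
    out
  }
  lower <- c(la = -Inf, ld = -Inf, lc = -Inf, b = -50)
  upper <- c(la = Inf, ld = Inf, lc = Inf, b = 50)
  if (five) {
    lower <- c(lower, lg = log(1e-3))
    upper <- c(upper, lg = log(50))
  }
  resid_fn <- function(q) {
    p <- from_log(setNames(q, names(lower)))
    pred <- p[["d"]] + (p[["a"]] - p[["d"]]) /
      (1 + (conc / p[["c"]])^(-p[["b"]]))^(if (five) p[["g"]] else 1)
    if (any(!is.finite(pred)) || any(pred <= 0)) {
      return(rep(1e6, length(conc)))
    }
    y - log10(pred)
  }
  rss_null <- sum((y - mean(y))^2)
  best <- NULL
  for (i in seq_along(starts)) {
    s <- starts[[i]]
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nls.lm(
        par = to_log(s), fn = resid_fn, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          maxiter = 300, ftol = 1e-12, ptol = 1e-10
        )
      )),
      error = function(e) NULL
    )
    if (is.null(fit) || any(!is.finite(fit$par))) next
    m <- curve_model(family, from_log(setNames(fit$par, names(lower))))
    rss <- curve_rss(m, conc, mfi)
    if (!is.finite(rss)) next
    if (is.null(best) || rss < best$fit_sse) {
      best <- m
      best$fit_sse <- rss
    }
    # once both data-driven starts have run, a fit explaining > 99.9% of
    # the response variance has found the sigmoid; the jittered restarts
    # are for harder geometries only
    if (i >= 2 && best$fit_sse < 1e-3 * rss_null) break
  }
  if (!is.null(best)) best$n <- length(conc)
  best
}

fit_exponential_family <- function(conc, mfi) {
  f <- lm(log10(mfi) ~ log10(conc))
  m <- curve_model("exponential",
    c(alpha = unname(coef(f)[1]), beta = unname(coef(f)[2]))
  )
  m$fit_sse <- sum(f$residuals^2)
  m$n <- length(conc)
  m
}

#' Fit a standard curve with model selection
#'
#' Fits each requested family to a dilution series by least squares on
#' log10(MFI) and returns the family with the lowest AIC (set
#' `criterion = "sse"` to select on raw residual sum of squares instead).
#' Logistic fits use Levenberg-Marquardt with data-driven starts plus
#' seeded jittered restarts.
#'
#' @param standards Data frame with columns `expected_conc` (> 0, well
#'   scale) and `mfi`; blank rows (`expected_conc == 0`) are ignored here.
#' @param families Character vector of families to try.
#' @param criterion `"aic"` (default) or `"sse"`.
#' @param seed Seed for the jittered restarts.
#' @return A `curve_model`.
#' @export
#' @examples
#' m0 <- curve_model("logistic4", c(a = 30000, d = 50, c = 100, b = 1))
#' std <- data.frame(expected_conc = 10^seq(-1, 4, length.out = 8))
#' std$mfi <- curve_forward(m0, std$expected_conc)
#' fit <- fit_standard_curve(std)
#' fit$family
fit_standard_curve <- function(standards,
                               families = c("logistic4", "logistic5", "exponential"),
                               criterion = c("aic", "sse"),
                               seed = 1L) {
  criterion <- match.arg(criterion)
  std <- standards[standards$expected_conc > 0, , drop = FALSE]
  conc <- std$expected_conc
  mfi <- std$mfi
  if (length(conc) < 5) abort("Need at least 5 positive standard points.")
  if (diff(range(log10(conc))) < 2) {
    abort("Standards must span at least 2 orders of magnitude.")
  }
  if (sd(log10(mfi)) < 1e-8) {
    abort("Standards are flat (no MFI response): cannot fit a curve.",
      class = "ontokine_fit_error"
    )
  }
  n_params <- c(logistic4 = 4, logistic5 = 5, exponential = 2)
  fits <- list()
  for (fam in families) {
    f <- switch(fam,
      logistic4 = fit_logistic_family(conc, mfi, "logistic4", seed),
      logistic5 = fit_logistic_family(conc, mfi, "logistic5", seed),
      exponential = fit_exponential_family(conc, mfi)
    )
    if (!is.null(f) && is.finite(f$fit_sse)) fits[[fam]] <- f
  }
  if (!length(fits)) {
    abort("No curve family converged for this dilution series.",
      class = "ontokine_fit_error"
    )
  }
  score <- map_dbl(fits, function(f) {
    if (criterion == "sse") f$fit_sse
    else curve_aic(f$fit_sse, f$n, n_params[[f$family]])
  })
  fits[[which.min(score)]]
}

#' Detection and quantification limits for a fitted curve
#'
#' The lower limit of detection (LLD) is the concentration at the mean blank
#' MFI plus three blank standard deviations; the upper limit of detection
#' (ULD) is the concentration at 95% of the fitted asymptote span. The
#' quantification limits (LLOQ/ULOQ) are the outermost standard
#' concentrations whose back-calculated recovery
#' (inverse-curve(MFI)/expected) first falls within 70-130% when sweeping
#' inward from the extremes. The ordering `lld <= lloq < uloq <= uld` is
#' enforced by widening the detection limits if necessary. All limits are on
#' the well (diluted) concentration scale.
#'
#' @param model A `curve_model`.
#' @param blanks Numeric vector of replicate blank MFIs (>= 2 unless
#'   `sd` is irrelevant; a single blank is accepted with `sd = 0`).
#' @param standards Data frame with `expected_conc` (> 0) and `mfi`.
#' @param recovery Length-2 acceptable recovery window (default `c(0.7, 1.3)`).
#' @return Named list `lld`, `uld`, `lloq`, `uloq`.
#' @export
estimate_limits <- function(model, blanks, standards, recovery = c(0.7, 1.3)) {
  std <- standards[standards$expected_conc > 0, , drop = FALSE]
  std <- std[order(std$expected_conc), , drop = FALSE]
  expected <- std$expected_conc
  back <- curve_inverse(model, std$mfi)
  rec <- back / expected
  ok <- is.finite(rec) & rec >= recovery[1] & rec <= recovery[2]
  if (!any(ok)) {
    abort("No standard back-calculates within the recovery window.",
      class = "ontokine_limits_error"
    )
  }
  lloq <- expected[which(ok)[1]]
  uloq <- expected[rev(which(ok))[1]]
  if (lloq >= uloq) {
    abort("Quantification range is degenerate (lloq >= uloq).",
      class = "ontokine_limits_error"
    )
  }

  mb <- mean(blanks)
  sb <- if (length(blanks) >= 2) sd(blanks) else 0
  y_lld <- mb + 3 * sb
  if (model$family == "exponential") {
    lld <- curve_inverse(model, y_lld)
    uld <- max(expected)
  } else {
    p <- model$params
    lo <- min(p[["a"]], p[["d"]]); hi <- max(p[["a"]], p[["d"]])
    increasing <- xor(p[["a"]] > p[["d"]], p[["b"]] < 0)
    if (increasing && y_lld >= hi) {
      abort("Blank mean + 3 SD exceeds the curve range: analyte unquantifiable.",
        class = "ontokine_limits_error"
      )
    }
    lld <- curve_inverse(model, y_lld)
    if (!is.finite(lld)) lld <- 0 # blank signal at/below the asymptote
    y95 <- if (increasing) lo + 0.95 * (hi - lo) else hi - 0.95 * (hi - lo)
    uld <- curve_inverse(model, y95)
  }
  lld <- min(lld, lloq)
  uld <- max(uld, uloq)
  list(lld = lld, uld = uld, lloq = lloq, uloq = uloq)
}
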