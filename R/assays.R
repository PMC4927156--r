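#' @title Downstream assay models
#' @description Quantitative models for follow-up assays: MIC calling from
#'   2-fold broth-microdilution OD series, single/double exponential-decay
#'   fits of translation-inhibition kinetics with AICc model selection,
#'   and the quadratic ligand-depletion binding isotherm for
#'   protein-ligand titrations.
#' @name assay_models
NULL

#' Call the MIC from a broth-microdilution series
#'
#' ODs are normalized as `(OD - blank) / (control - blank)`; scanning the
#' 2-fold dilution series from the lowest concentration upward, the MIC is
#' the first concentration at which the normalized density falls strictly
#' below `threshold` (default 10% of the no-drug control). If no
#' concentration qualifies the result is right-censored ("> max tested").
#' Growth recovery at concentrations above the first crossing (paradoxical
#' wells) is reported as a warning; the first crossing still defines the
#' MIC. The call is invariant to affine rescaling of all ODs.
#'
#' @param concentration Drug concentrations (2-fold series; any order).
#' @param od Raw OD per concentration.
#' @param blank Blank (no-cells) OD.
#' @param control No-drug control OD; must exceed `blank`.
#' @param threshold Normalized-density threshold (0.10).
#' @return A list of class `mic_call`: `mic` (concentration, or `Inf` if
#'   censored), `censored`, `label` (e.g. `"50"` or `"> 100"`),
#'   `normalized` (named vector in concentration order), `threshold`.
#' @export
call_mic <- function(concentration, od, blank, control, threshold = 0.10) {
  if (length(concentration) != length(od))
    stop("concentration and od lengths differ")
  if (control - blank <= 0) stop("control OD must exceed blank OD")
  if (any(od < 0)) stop("ODs must be >= 0")
  o <- order(concentration)
  conc <- concentration[o]
  ratio <- conc[-1] / conc[-length(conc)]
  if (any(abs(ratio - 2) > 1e-9 * 2))
    stop("concentrations must form a 2-fold dilution series")
  norm <- (od[o] - blank) / (control - blank)
  names(norm) <- format(conc, trim = TRUE)
  below <- norm < threshold
  if (!any(below)) {
    out <- list(mic = Inf, censored = TRUE,
                label = paste(">", format(max(conc), trim = TRUE)),
                normalized = norm, threshold = threshold)
  } else {
    first <- which(below)[1]
    if (any(!below[seq_along(below) > first]))
      warning("growth recovery above the MIC (paradoxical wells); first crossing used")
    out <- list(mic = conc[first], censored = FALSE,
                label = format(conc[first], trim = TRUE),
                normalized = norm, threshold = threshold)
  }
  class(out) <- "mic_call"
  out
}

#' @export
print.mic_call <- function(x, ...) {
  cat(sprintf("MIC: %s (normalized density < %g%%)\n", x$label,
              100 * x$threshold))
  invisible(x)
}

aicc_from_rss <- function(rss, n, k) {
  # k model parameters + 1 for the error variance
  p <- k + 1
  corr <- if (n - p - 1 > 0) 2 * p * (p + 1) / (n - p - 1) else Inf
  n * log(rss / n) + 2 * p + corr
}

decay_formula <- function(model) {
  if (model == "single") y ~ A * exp(-k * t) + C
  else y ~ A1 * exp(-k1 * t) + A2 * exp(-k2 * t) + C
}

decay_starts <- function(model, t, y, n_starts) {
  y_rng <- max(y) - min(y)
  t_rng <- max(max(t) - min(t), 1e-6)
  k0 <- 2 / t_rng
  base <- if (model == "single") {
    list(A = max(y_rng, 1e-3), k = k0, C = max(min(y), 0))
  } else {
    list(A1 = max(y_rng, 1e-3) / 2, k1 = 4 * k0,
         A2 = max(y_rng, 1e-3) / 2, k2 = k0 / 4, C = max(min(y), 0))
  }
  starts <- list(base)
  if (n_starts > 1L) {
    for (i in seq_len(n_starts - 1L)) {
      jit <- lapply(base, function(v) v * stats::runif(1, 0.2, 3) + 1e-8)
      starts[[i + 1L]] <- jit
    }
  }
  starts
}

#' Fit an exponential-decay model to an inhibition time course
#'
#' Models the decline of a normalized activity (e.g. pulse-label
#' incorporation relative to a pre-treatment reference) after drug
#' addition. Single: `y(t) = A exp(-k t) + C`; double:
#' `y(t) = A1 exp(-k1 t) + A2 exp(-k2 t) + C`, all parameters
#' constrained non-negative and rates ordered `k1 > k2` by convention.
#' Fitting is nonlinear least squares ([minpack.lm::nlsLM]) with seeded
#' multi-start; the best converged start (lowest residual sum of squares)
#' wins.
#'
#' @param t Time points (e.g. minutes after drug addition), strictly
#'   increasing.
#' @param y Activity at each time point; if `reference` is given `y` is
#'   divided by it first.
#' @param model `"single"` or `"double"`.
#' @param reference Optional pre-treatment reference count (> 0).
#' @param n_starts Number of optimizer starts (>= 5 recommended).
#' @param seed Seed for the start jitter.
#' @return An object of class `decay_fit`: `coefficients`, `model`,
#'   `rss`, `aicc`, `fitted.values`, `residuals`, `data`.
#' @export
fit_decay <- function(t, y, model = c("single", "double"),
                      reference = NULL, n_starts = 5L, seed = 1L) {
  model <- match.arg(model)
  if (any(diff(t) <= 0)) stop("time points must be strictly increasing")
  if (!is.null(reference)) {
    if (reference <= 0) stop("reference count must be > 0")
    y <- y / reference
  }
  min_pts <- if (model == "single") 4L else 6L
  if (length(t) < min_pts)
    stop(sprintf("%s-exponential fit needs >= %d points", model, min_pts))

  dat <- data.frame(t = t, y = y)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  starts <- decay_starts(model, t, y, n_starts)
  lower <- stats::setNames(rep(0, length(starts[[1]])), names(starts[[1]]))

  best_cf <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        decay_formula(model), data = dat, start = st, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) {
        best_cf <- stats::coef(fit)
        best_rss <- rss
      }
    }
  }
  # flat (no-decay) candidate, evaluated in closed form: the optimizer's
  # Jacobian is singular on constant traces
  flat_cf <- if (model == "single") c(A = 0, k = 0, C = mean(y))
    else c(A1 = 0, k1 = 1, A2 = 0, k2 = 0, C = mean(y))
  flat_rss <- sum((y - mean(y))^2)
  if (flat_rss < best_rss) {
    best_cf <- flat_cf
    best_rss <- flat_rss
  }
  if (is.null(best_cf))
    stop(sprintf("decay fit failed to converge from %d starts (best residual: %s)",
                 length(starts), format(best_rss)))

  cf <- best_cf
  if (model == "double" && cf[["k1"]] < cf[["k2"]]) {
    cf <- c(A1 = cf[["A2"]], k1 = cf[["k2"]],
            A2 = cf[["A1"]], k2 = cf[["k1"]], C = cf[["C"]])
  }
  k_par <- length(cf)
  fitted <- predict_decay(cf, model, t)
  structure(list(
    coefficients = cf, model = model, rss = best_rss,
    aicc = aicc_from_rss(max(best_rss, 1e-300), length(t), k_par),
    fitted.values = fitted, residuals = y - fitted, data = dat
  ), class = "decay_fit")
}

predict_decay <- function(cf, model, t) {
  if (model == "single") cf[["A"]] * exp(-cf[["k"]] * t) + cf[["C"]]
  else cf[["A1"]] * exp(-cf[["k1"]] * t) +
    cf[["A2"]] * exp(-cf[["k2"]] * t) + cf[["C"]]
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s-exponential decay fit\n", x$model))
  print(signif(x$coefficients, digits))
  cat(sprintf("RSS = %.4g, AICc = %.4g (n = %d)\n", x$rss, x$aicc,
              nrow(x$data)))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...) object$coefficients

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$t else newdata$t
  predict_decay(object$coefficients, object$model, t)
}

#' @export
residuals.decay_fit <- function(object, ...) object$residuals

#' @export
fitted.decay_fit <- function(object, ...) object$fitted.values

#' @export
plot.decay_fit <- function(x, ...) {
  plot(x$data$t, x$data$y, xlab = "time", ylab = "normalized activity", ...)
  tt <- seq(min(x$data$t), max(x$data$t), length.out = 200)
  graphics::lines(tt, predict(x, data.frame(t = tt)))
  invisible(x)
}

#' Select between single and double exponential decay
#'
#' Fits both models and keeps the one with lower AICc, with a parsimony
#' tie-break: when the AICc difference is below `delta_tie` (2 by
#' default, the conventional "indistinguishable" band) the single
#' exponential wins. With fewer than 6 points only the single model is
#' fit.
#'
#' @param t,y,reference,n_starts,seed As in [fit_decay()].
#' @param delta_tie AICc difference below which the simpler model is
#'   preferred.
#' @return A list of class `decay_selection`: `model` (`"single"` or
#'   `"double"`), `delta_aicc` (AICc(double) - AICc(single)), `single`,
#'   `double` (the fits; `double` may be `NULL`), `fit` (the selected
#'   one).
#' @export
select_decay_model <- function(t, y, reference = NULL, n_starts = 5L,
                               seed = 1L, delta_tie = 2) {
  single <- fit_decay(t, y, "single", reference = reference,
                      n_starts = n_starts, seed = seed)
  if (length(t) < 6L) {
    out <- list(model = "single", delta_aicc = NA_real_, single = single,
                double = NULL, fit = single)
    class(out) <- "decay_selection"
    return(out)
  }
  double <- fit_decay(t, y, "double", reference = reference,
                      n_starts = n_starts, seed = seed)
  delta <- double$aicc - single$aicc
  model <- if (delta < -delta_tie) "double" else "single"
  out <- list(model = model, delta_aicc = delta, single = single,
              double = double,
              fit = if (model == "single") single else double)
  class(out) <- "decay_selection"
  out
}

#' @export
print.decay_selection <- function(x, ...) {
  cat(sprintf("selected model: %s (AICc(double) - AICc(single) = %s)\n",
              x$model, format(signif(x$delta_aicc, 4))))
  invisible(x)
}

#' Fit the quadratic ligand-depletion binding model
#'
#' For a 1:1 equilibrium where protein and ligand concentrations are
#' comparable (so free ligand cannot be approximated by total ligand),
#' the measured signal follows
#' \deqn{F(L) = \Delta F_{max} \frac{(P + L + K_d) -
#'   \sqrt{(P + L + K_d)^2 - 4 P L}}{2 P}}
#' with `P` the total protein concentration, `L` the total ligand
#' concentration and `Kd` the dissociation constant. In the dilute limit
#' (`P << Kd`) this reduces to the hyperbola
#' `dFmax * L / (L + Kd)`. The half-maximal effective ligand
#' concentration under this model is `Kd + P/2`.
#'
#' @param L Total ligand concentrations (>= 0, strictly increasing), in
#'   the same units as `Kd`.
#' @param F_obs Normalized signal change per titration point.
#' @param P Total protein concentration (> 0, same units).
#' @param n_starts Optimizer starts.
#' @param seed Seed for start jitter.
#' @return An object of class `binding_fit`: `coefficients` (`Kd`,
#'   `dFmax`), `ec50` (= Kd + P/2), `P`, `rss`, `fitted.values`,
#'   `residuals`, `data`.
#' @export
fit_binding <- function(L, F_obs, P, n_starts = 5L, seed = 1L) {
  if (P <= 0) stop("protein concentration P must be > 0")
  if (length(L) < 5L) stop("need >= 5 titration points")
  if (any(L < 0) || any(diff(L) <= 0))
    stop("L must be >= 0 and strictly increasing")
  if (all(F_obs == 0)) stop("all-zero signal; nothing to fit")

  model_fun <- function(L, Kd, dFmax) {
    disc <- (P + L + Kd)^2 - 4 * P * L
    if (any(disc < 0)) {
      warning("negative discriminant clamped to 0")
      disc <- pmax(disc, 0)
    }
    dFmax * ((P + L + Kd) - sqrt(disc)) / (2 * P)
  }

  dat <- data.frame(L = L, F_obs = F_obs)
  # crude initial guesses: amplitude from the top of the curve, Kd from
  # the half-rise point
  dF0 <- max(F_obs)
  half <- L[which.min(abs(F_obs - dF0 / 2))]
  base <- list(Kd = max(half, L[L > 0][1] / 10), dFmax = max(dF0, 1e-6))

  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  starts <- list(base)
  for (i in seq_len(max(n_starts - 1L, 0L)))
    starts[[i + 1L]] <- lapply(base, function(v)
      v * stats::runif(1, 0.1, 10) + 1e-10)

  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        F_obs ~ model_fun(L, Kd, dFmax), data = dat, start = st,
        lower = c(Kd = 1e-12, dFmax = 1e-12),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) {
        best <- fit
        best_rss <- rss
      }
    }
  }
  if (is.null(best)) stop("binding fit failed to converge")

  cf <- stats::coef(best)
  fitted <- model_fun(L, cf[["Kd"]], cf[["dFmax"]])
  structure(list(
    coefficients = cf, ec50 = cf[["Kd"]] + P / 2, P = P, rss = best_rss,
    fitted.values = fitted, residuals = F_obs - fitted, data = dat
  ), class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, digits = 4, ...) {
  cat("ligand-depletion binding fit\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("EC50 (half-maximal ligand) = %.4g; P = %.4g; RSS = %.4g\n",
              x$ec50, x$P, x$rss))
  invisible(x)
}

#' @export
coef.binding_fit <- function(object, ...) object$coefficients

#' @export
predict.binding_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$L else newdata$L
  cf <- object$coefficients
  P <- object$P
  disc <- pmax((P + L + cf[["Kd"]])^2 - 4 * P * L, 0)
  cf[["dFmax"]] * ((P + L + cf[["Kd"]]) - sqrt(disc)) / (2 * P)
}

#' @export
residuals.binding_fit <- function(object, ...) object$residuals

#' @export
fitted.binding_fit <- function(object, ...) object$fitted.values

#' @export
plot.binding_fit <- function(x, ...) {
  plot(x$data$L, x$data$F_obs, xlab = "total ligand", ylab = "signal", ...)
  LL <- seq(min(x$data$L), max(x$data$L), length.out = 200)
  graphics::lines(LL, predict(x, data.frame(L = LL)))
  invisible(x)
}
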