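#' Hill-type product inhibition model
#'
#' Reaction velocity in the presence of the inhibitory product:
#' `V = V0 / (1 + (cdG / Ki)^h)`, where `V0` is the uninhibited velocity,
#' `Ki` the inhibitory constant (the product concentration giving
#' half-maximal inhibition) and `h` the Hill coefficient. Strictly
#' decreasing in `cdG` for `h > 0`, with `V(0) = V0` and `V(Ki) = V0/2`.
#'
#' @param cdG Product (c-di-GMP) concentration, micromolar; non-negative.
#' @param V0 Uninhibited velocity (any consistent rate unit).
#' @param Ki Inhibitory constant, micromolar; > 0.
#' @param h Hill coefficient; > 0.
#' @return Velocity, same units as `V0`.
#' @examples
#' eval_inhibition(0, 1, 15, 1.8)    # 1
#' eval_inhibition(15, 1, 15, 1.8)   # 0.5
#' @export
eval_inhibition <- function(cdG, V0, Ki, h) {
  if (any(cdG < 0)) stop("'cdG' must be non-negative")
  if (V0 <= 0 || Ki <= 0 || h <= 0) stop("V0, Ki and h must be > 0")
  V0 / (1 + (cdG / Ki)^h)
}

#' One-site specific binding model
#'
#' Equilibrium response `R = Rmax * C / (KD + C)`: non-cooperative binding
#' to a single site, strictly increasing in `C` with asymptote `Rmax` and
#' half-saturation at `C = KD`.
#'
#' @param conc Ligand concentration, micromolar; non-negative.
#' @param Rmax Maximal response (e.g. interferometric wavelength shift).
#' @param KD Dissociation constant, micromolar; > 0.
#' @return Response, same units as `Rmax`.
#' @export
eval_binding <- function(conc, Rmax, KD) {
  if (any(conc < 0)) stop("'conc' must be non-negative")
  if (Rmax <= 0 || KD <= 0) stop("Rmax and KD must be > 0")
  Rmax * conc / (KD + conc)
}

kinetics_fit_object <- function(fit, data, model, flags) {
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(est)))
  df <- stats::df.residual(fit)
  tq <- stats::qt(0.975, df)
  ci <- cbind(lower = est - tq * se, upper = est + tq * se)
  structure(
    list(model = model, coefficients = est, se = se, ci = ci,
         vcov = tryCatch(vcov(fit), error = function(e) NULL),
         residual_sd = sqrt(sum(stats::residuals(fit)^2) / df),
         df_residual = df, flags = flags, data = data, fit = fit),
    class = c(paste0(model, "_fit"), "kinetics_fit")
  )
}

#' Fit the Hill inhibition model to velocity data
#'
#' Nonlinear least squares (Levenberg-Marquardt, bounded below at zero) of
#' `V = V0 / (1 + (cdG/Ki)^h)`. Starting values: `V0` from the maximal
#' observed velocity, `Ki` from the concentration nearest half-maximal
#' velocity, `h = 1`. A fit whose `Ki` lands more than 10-fold above the
#' highest tested concentration is flagged `"unconstrained"`: the data do
#' not reach into the inhibited regime and the parameter is not
#' identifiable.
#'
#' @param data Data.frame with columns `cdG` (micromolar) and `velocity`;
#'   needs at least 4 distinct concentrations including (near-)zero.
#' @return An object of class `c("inhibition_fit", "kinetics_fit")` with
#'   coefficients `V0`, `Ki`, `h`, standard errors, 95 percent confidence
#'   intervals, residual SD and flags. Supports `print()`, `summary()`,
#'   `coef()`, `predict()`, `confint()`, `vcov()`, `residuals()`, `plot()`.
#' @export
fit_inhibition <- function(data) {
  stopifnot(all(c("cdG", "velocity") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("cdG", "velocity")]), ]
  concs <- sort(unique(data$cdG))
  if (length(concs) < 4L) stop("need at least 4 distinct concentrations")
  if (min(concs) > 0.01 * max(concs)) {
    stop("need a zero or near-zero concentration to anchor V0")
  }
  v0_start <- max(data$velocity)
  half <- v0_start / 2
  mean_v <- tapply(data$velocity, data$cdG, mean)
  ki_start <- as.numeric(names(mean_v))[which.min(abs(mean_v - half))]
  if (ki_start <= 0) ki_start <- stats::median(concs[concs > 0])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      velocity ~ V0 / (1 + (cdG / Ki)^h), data = data,
      start = list(V0 = v0_start, Ki = ki_start, h = 1),
      lower = c(V0 = 1e-12, Ki = 1e-12, h = 1e-3),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("inhibition fit failed to converge: ",
                             conditionMessage(e))
  )
  flags <- character(0)
  if (coef(fit)[["Ki"]] > 10 * max(concs)) flags <- c(flags, "unconstrained")
  kinetics_fit_object(fit, data, "inhibition", flags)
}

#' Fit the one-site binding model to equilibrium responses
#'
#' Nonlinear least squares of `R = Rmax * C / (KD + C)`, optionally with a
#' linear nonspecific term `+ ns * C` (off by default). Starting values:
#' `Rmax` from the maximal response, `KD` from the concentration nearest
#' half-maximal response. Flags `"unconstrained"` when `KD` exceeds ten
#' times the highest tested concentration.
#'
#' @param data Data.frame with columns `conc` (micromolar) and `response`;
#'   needs at least 3 distinct concentrations.
#' @param nonspecific Include a linear nonspecific-binding term.
#' @return An object of class `c("binding_fit", "kinetics_fit")`; see
#'   [fit_inhibition()] for the contents.
#' @export
fit_binding <- function(data, nonspecific = FALSE) {
  stopifnot(all(c("conc", "response") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("conc", "response")]), ]
  concs <- sort(unique(data$conc))
  if (length(concs) < 3L) stop("need at least 3 distinct concentrations")
  rmax_start <- max(data$response)
  mean_r <- tapply(data$response, data$conc, mean)
  kd_start <- as.numeric(names(mean_r))[which.min(abs(mean_r - rmax_start / 2))]
  if (kd_start <= 0) kd_start <- stats::median(concs[concs > 0])
  form <- if (nonspecific) {
    response ~ Rmax * conc / (KD + conc) + ns * conc
  } else {
    response ~ Rmax * conc / (KD + conc)
  }
  start <- list(Rmax = rmax_start, KD = kd_start)
  lower <- c(Rmax = 1e-12, KD = 1e-12)
  if (nonspecific) {
    start$ns <- 0
    lower <- c(lower, ns = -Inf)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = data, start = start, lower = lower,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("binding fit failed to converge: ",
                             conditionMessage(e))
  )
  flags <- character(0)
  if (coef(fit)[["KD"]] > 10 * max(concs)) flags <- c(flags, "unconstrained")
  kinetics_fit_object(fit, data, "binding", flags)
}

#' @export
print.kinetics_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<%s fit> (n = %d)\n", x$model, nrow(x$data)))
  tab <- cbind(estimate = x$coefficients, se = x$se, x$ci)
  print(round(tab, digits))
  cat(sprintf("residual SD: %.4g on %d df\n", x$residual_sd, x$df_residual))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.kinetics_fit <- function(object, ...) {
  print(object, ...)
  invisible(object)
}

#' @export
coef.kinetics_fit <- function(object, ...) object$coefficients

#' @export
vcov.kinetics_fit <- function(object, ...) object$vcov

#' @export
confint.kinetics_fit <- function(object, parm, level = 0.95, ...) {
  tq <- stats::qt(1 - (1 - level) / 2, object$df_residual)
  ci <- cbind(object$coefficients - tq * object$se,
              object$coefficients + tq * object$se)
  colnames(ci) <- sprintf("%.1f %%", 100 * c((1 - level) / 2, 1 - (1 - level) / 2))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
residuals.kinetics_fit <- function(object, ...) stats::residuals(object$fit)

#' @export
predict.kinetics_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(stats::predict(object$fit))
  stats::predict(object$fit, newdata = newdata)
}

#' @export
plot.kinetics_fit <- function(x, ...) {
  if (x$model == "inhibition") {
    xs <- x$data$cdG; ys <- x$data$velocity
    xlab <- "c-di-GMP (µM)"; ylab <- "velocity"
    newdata <- function(g) data.frame(cdG = g)
  } else {
    xs <- x$data$conc; ys <- x$data$response
    xlab <- "concentration (µM)"; ylab <- "response"
    newdata <- function(g) data.frame(conc = g)
  }
  plot(xs, ys, xlab = xlab, ylab = ylab, pch = 16,
       main = sprintf("%s fit", x$model), ...)
  grid_x <- seq(min(xs), max(xs), length.out = 200)
  lines(grid_x, predict(x, newdata(grid_x)), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Relative enzymatic activity from pyrophosphate-release progress curves
#'
#' Product synthesis is followed through the coupled release of inorganic
#' pyrophosphate, read as an absorbance change over the reaction window.
#' Each sample's activity is the blank-subtracted absorbance change
#' (`endpoint` mode: last minus first point; `slope` mode: initial linear
#' slope over `slope_window_s`), averaged over replicates and reported
#' relative to the mean of the reference sample.
#'
#' @param curves Data.frame with columns `sample`, `replicate`, `time_s`,
#'   `a360` and `blank` (matched no-enzyme absorbance series).
#' @param reference Sample id to normalize against.
#' @param mode `"endpoint"` (default) or `"slope"`.
#' @param slope_window_s Initial window for slope mode, seconds.
#' @return A list: `per_replicate` (data.frame with raw and relative
#'   activity) and `summary` (per-sample mean relative activity).
#' @export
relative_dgc_activity <- function(curves, reference, mode = c("endpoint", "slope"),
                                  slope_window_s = 600) {
  mode <- match.arg(mode)
  need <- c("sample", "replicate", "time_s", "a360", "blank")
  if (!all(need %in% names(curves))) {
    stop("curves must have columns: ", paste(need, collapse = ", "))
  }
  if (any(is.na(curves$blank))) stop("missing blank series")
  if (!reference %in% curves$sample) stop("reference sample not found")
  one <- function(d) {
    d <- d[order(d$time_s), ]
    y <- d$a360 - d$blank
    if (mode == "endpoint") {
      y[length(y)] - y[1]
    } else {
      w <- d$time_s <= d$time_s[1] + slope_window_s
      unname(coef(stats::lm(y[w] ~ d$time_s[w]))[2]) * 3600
    }
  }
  per <- do.call(rbind, lapply(
    split(curves, list(curves$sample, curves$replicate), drop = TRUE),
    function(d) data.frame(sample = d$sample[1], replicate = d$replicate[1],
                           activity = one(d))))
  ref_mean <- mean(per$activity[per$sample == reference])
  if (ref_mean == 0) stop("reference sample has zero mean activity")
  per$relative <- per$activity / ref_mean
  summ <- stats::aggregate(relative ~ sample, per, mean)
  rownames(per) <- NULL
  list(per_replicate = per, summary = summ)
}
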