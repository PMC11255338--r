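#' Simulate a kinetics dataset from known parameters
#'
#' Generates replicate measurements `y = f(x) * (1 + e)`, `e ~ N(0,
#' noise_sd)`, from either the Hill inhibition model
#' ([eval_inhibition()]; `true_params` = `V0`, `Ki`, `h`) or the one-site
#' binding model ([eval_binding()]; `true_params` = `Rmax`, `KD`).
#'
#' @param model `"inhibition"` or `"binding"`.
#' @param true_params Named list/vector of generating parameters.
#' @param x_values Concentration grid, micromolar.
#' @param replicates Replicates per concentration.
#' @param noise_sd Relative (multiplicative) noise SD.
#' @param seed Integer seed.
#' @return Data.frame with columns `cdG`/`velocity` (inhibition) or
#'   `conc`/`response` (binding), plus `replicate`.
#' @export
make_kinetics_dataset <- function(model = c("inhibition", "binding"),
                                  true_params = list(V0 = 1, Ki = 15, h = 1.8),
                                  x_values = c(0, 1, 3, 10, 30, 100, 300, 1000),
                                  replicates = 3L, noise_sd = 0.05,
                                  seed = 1L) {
  model <- match.arg(model)
  if (any(x_values < 0)) stop("concentrations must be non-negative")
  if (replicates < 1L) stop("need at least one replicate")
  stopif_neg(noise_sd, "noise_sd")
  p <- as.list(true_params)
  y0 <- if (model == "inhibition") {
    eval_inhibition(x_values, p$V0, p$Ki, p$h)
  } else {
    eval_binding(x_values, p$Rmax, p$KD)
  }
  with_seed(seed, {
    out <- do.call(rbind, lapply(seq_len(replicates), function(r) {
      y <- y0 * (1 + stats::rnorm(length(y0), 0, noise_sd))
      data.frame(x = x_values, y = y, replicate = r)
    }))
    names(out)[1:2] <- if (model == "inhibition") c("cdG", "velocity") else
      c("conc", "response")
    out
  })
}

#' Sample cell ages from the steady-state age distribution
#'
#' In a steady-state exponentially growing population the cell-age density
#' is `f(a) = (2 log(2) / Td) * 2^(-a/Td)` on `[0, Td]`: young cells are
#' twice as frequent as cells about to divide. Sampling uses the inverse
#' CDF `a = -Td * log2(1 - u/2)`.
#'
#' The fraction of cells within the final `w` minutes before division is
#' `2^(w/Td) - 1`, which links a division-site marker's residence time to
#' the fraction of marker-positive cells in an unsynchronized snapshot.
#'
#' @param n Number of cells.
#' @param doubling_time Population doubling time `Td`, minutes.
#' @param seed Integer seed (optional).
#' @return Numeric vector of ages in `[0, Td]`, minutes.
#' @export
sample_population_ages <- function(n, doubling_time, seed = NULL) {
  if (n < 1) stop("'n' must be >= 1")
  if (doubling_time <= 0) stop("'doubling_time' must be > 0")
  with_seed(seed, {
    u <- stats::runif(n)
    -doubling_time * log2(1 - u / 2)
  })
}
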