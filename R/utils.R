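#' Median absolute deviation (raw, unscaled)
#'
#' The robust spread statistic used throughout the package:
#' `median(|x_i - median(x)|)`. Unlike [stats::mad()], no consistency
#' constant is applied, so the value is on the same scale as the data and
#' matches the convention of reporting population summaries as median +/- MAD.
#'
#' @param x Numeric vector with at least one non-missing value.
#' @param na.rm Drop `NA`s before computing (default `FALSE`).
#' @return A single number, same units as `x`.
#' @examples
#' mad_raw(c(1, 2, 3))   # 1
#' mad_raw(c(1, 1, 1, 9))  # 0: the median deviation ignores one outlier
#' @export
mad_raw <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) stop("mad_raw() needs at least one value")
  stats::median(abs(x - stats::median(x)))
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mean +/- sd specification used by several generator parameters
check_mean_sd <- function(x, name) {
  if (!is.numeric(x) || length(x) != 2L || any(is.na(x)) || x[2] < 0) {
    stop(sprintf("'%s' must be c(mean, sd) with sd >= 0", name))
  }
  x
}

stopif_neg <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be non-negative", name))
  }
  x
}

um_to_px <- function(um, pixel_size_um) um / pixel_size_um

# Mean and SD of a normal(mu, sigma) truncated to (0, Inf).
truncnorm0_moments <- function(mu, sigma) {
  a <- -mu / sigma
  lam <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parameters (mu, sigma) of the zero-truncated normal whose realized mean
# and SD equal the targets, so that configured timing distributions are the
# distributions of the observable (truncated) quantities themselves.
match_truncnorm0 <- function(mean, sd) {
  if (sd == 0) return(c(mean, 0))
  obj <- function(p) {
    mm <- truncnorm0_moments(p[1], exp(p[2]))
    (mm["mean"] - mean)^2 + (mm["sd"] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(fit$par[1], exp(fit$par[2]))
}

# Truncated-at-zero normal sampler used for all timing distributions.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x > 0])
  }
  out[seq_len(n)]
}

# Pixel sets are integer matrices with columns (row, col), 1-based.
as_pixel_matrix <- function(px) {
  px <- as.matrix(px)
  storage.mode(px) <- "integer"
  colnames(px) <- c("row", "col")
  px
}

# Connected components of a pixel set; returns integer component id per row.
# 4-connectivity is the default for cluster calling: compact genuine clusters
# survive it while diagonal chains of isolated noise pixels do not.
label_components <- function(px, connectivity = 4L) {
  n <- nrow(px)
  if (n == 0L) return(integer(0))
  key <- paste(px[, 1], px[, 2])
  idx <- stats::setNames(seq_len(n), key)
  off <- if (connectivity == 4L) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    o <- cbind(rep(-1:1, each = 3), rep(-1:1, 3))
    o[!(o[, 1] == 0 & o[, 2] == 0), , drop = FALSE]
  }
  edges <- integer(0)
  for (k in seq_len(nrow(off))) {
    nb <- paste(px[, 1] + off[k, 1], px[, 2] + off[k, 2])
    hit <- idx[nb]
    ok <- !is.na(hit)
    if (any(ok)) edges <- c(edges, rbind(which(ok), unname(hit[ok])))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  igraph::components(g)$membership
}

# Binary dilation of a logical matrix by a (2r+1) square structuring element.
dilate_mask <- function(m, r = 1L) {
  if (r <= 0) return(m)
  out <- m
  nr <- nrow(m); nc <- ncol(m)
  for (dr in -r:r) {
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    rt <- max(1, 1 - dr):min(nr, nr - dr)
    for (dc in -r:r) {
      if (dr == 0 && dc == 0) next
      cs <- max(1, 1 + dc):min(nc, nc + dc)
      ct <- max(1, 1 - dc):min(nc, nc - dc)
      out[rt, ct] <- out[rt, ct] | m[rs, cs]
    }
  }
  out
}
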