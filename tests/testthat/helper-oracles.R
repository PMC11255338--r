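# Independent oracles used to pin expected values.

# Brute-force geodesic distances on a pixel set: iterative relaxation
# (Bellman-Ford style) over the same documented 16-neighbourhood chamfer
# moves, independent of the package's graph-based implementation.
oracle_geodesic <- function(px, from) {
  n <- nrow(px)
  d <- rep(Inf, n)
  d[from] <- 0
  key <- paste(px[, 1], px[, 2])
  idx <- setNames(seq_len(n), key)
  moves <- rbind(expand.grid(dr = -1:1, dc = -1:1),
                 data.frame(dr = c(1, 1, -1, -1, 2, 2, -2, -2),
                            dc = c(2, -2, 2, -2, 1, -1, 1, -1)))
  moves <- moves[!(moves$dr == 0 & moves$dc == 0), ]
  nbs <- lapply(seq_len(n), function(i) {
    out <- list()
    for (k in seq_len(nrow(moves))) {
      j <- idx[paste(px[i, 1] + moves$dr[k], px[i, 2] + moves$dc[k])]
      if (!is.na(j)) {
        out[[length(out) + 1]] <- c(j, sqrt(moves$dr[k]^2 + moves$dc[k]^2))
      }
    }
    out
  })
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (nb in nbs[[i]]) {
        if (d[i] + nb[2] < d[nb[1]] - 1e-12) {
          d[nb[1]] <- d[i] + nb[2]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  d
}

# Rectangle pixel set (rows x cols), 1-based coordinates.
rect_pixels <- function(nrow, ncol) {
  as.matrix(expand.grid(row = seq_len(nrow), col = seq_len(ncol)))
}

# A rectangular synthetic cell embedded in an image, with a deterministic
# +/-1 cytoplasmic texture so the threshold SD is non-zero.
make_rect_cell <- function(nrow_cell = 8, ncol_cell = 40, base = 100,
                           pad = 3) {
  img <- matrix(0, nrow_cell + 2 * pad, ncol_cell + 2 * pad)
  mask <- matrix(0L, nrow(img), ncol(img))
  rows <- pad + seq_len(nrow_cell)
  cols <- pad + seq_len(ncol_cell)
  mask[rows, cols] <- 1L
  tex <- outer(seq_len(nrow_cell), seq_len(ncol_cell),
               function(r, c) ifelse((r + c) %% 2 == 0, -1, 1))
  img[rows, cols] <- base + tex
  list(image = img, mask = mask)
}

# Rotate a pixel set by `deg` about its centroid and re-round to a grid.
rotate_pixels <- function(px, deg) {
  th <- deg * pi / 180
  ctr <- colMeans(px)
  r <- px[, 1] - ctr[1]; c <- px[, 2] - ctr[2]
  out <- cbind(round(ctr[1] + r * cos(th) - c * sin(th)) + 30,
               round(ctr[2] + r * sin(th) + c * cos(th)) + 30)
  unique(out)
}

# Fill holes introduced by rotation rounding: add any empty pixel with
# 4 or more filled 4/8-neighbours.
fill_holes <- function(px) {
  key <- paste(px[, 1], px[, 2])
  cand <- unique(do.call(rbind, lapply(list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0)),
    function(o) cbind(px[, 1] + o[1], px[, 2] + o[2]))))
  cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% key), , drop = FALSE]
  nfull <- sapply(seq_len(nrow(cand)), function(i) {
    sum(paste(rep(cand[i, 1], 8) + rep(-1:1, 3)[-5],
              rep(cand[i, 2], 8) + rep(-1:1, each = 3)[-5]) %in% key)
  })
  rbind(px, cand[nfull >= 6, , drop = FALSE])
}

scene_noiseless <- function(..., seed = 1) {
  make_snapshot_scene(scene_params(..., noise_gaussian_sd = 0,
                                   poisson_scaling = Inf, seed = seed))
}
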