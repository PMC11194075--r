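# Independent brute-force oracles and tiny fixture builders. Everything here
# is deliberately naive (double loops, explicit flood) so that the optimized
# implementations are checked against first-principles definitions.

# strip Projection2D attributes down to a plain matrix
as_mat <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = dim(m))
  m
}

disc_offsets <- function(r) {
  k <- expand.grid(dy = -r:r, dx = -r:r)
  k[k$dy^2 + k$dx^2 <= r^2, ]
}

# grayscale erosion-then-dilation opening, in-bounds neighborhood only
brute_opening <- function(m, r) {
  off <- disc_offsets(r)
  ny <- nrow(m); nx <- ncol(m)
  er <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ys <- i + off$dy; xs <- j + off$dx
    inb <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
    er[i, j] <- min(m[cbind(ys[inb], xs[inb])])
  }
  di <- matrix(0, ny, nx)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    ys <- i + off$dy; xs <- j + off$dx
    inb <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
    di[i, j] <- max(er[cbind(ys[inb], xs[inb])])
  }
  di
}

brute_tophat <- function(m, r) pmax(m - brute_opening(m, r), 0)

# 8-connected labelling by repeated flood (naive)
brute_label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nxt <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dy in -1:1) for (dx in -1:1) {
        a <- p[1] + dy; b <- p[2] + dx
        if (a < 1 || a > ny || b < 1 || b > nx) next
        if (mask[a, b] && lab[a, b] == 0) {
          lab[a, b] <- nxt
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
  }
  lab
}

# prominence by explicit threshold descent: for a local maximum at `pos`
# with height h, the merge level is the highest threshold v < h at which the
# 8-connected component of {pixels >= v} containing `pos` holds a strictly
# higher pixel; prominence = h - v (or h - min(image) if never merged).
brute_prominence <- function(m, pos) {
  h <- m[pos[1], pos[2]]
  lv <- sort(unique(as.numeric(m)), decreasing = TRUE)
  for (v in lv[lv < h]) {
    lab <- brute_label8(m >= v)
    comp <- lab == lab[pos[1], pos[2]]
    if (max(m[comp]) > h) return(h - v)
  }
  h - min(m)
}

# all strict 8-neighborhood local maxima of a tie-free image
brute_local_maxima <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- NULL
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    nb <- m[max(1, i - 1):min(ny, i + 1), max(1, j - 1):min(nx, j + 1)]
    if (sum(nb >= m[i, j]) == 1) out <- rbind(out, c(i, j))
  }
  out
}

# faster accept/reject oracle: a local maximum of height h has prominence
# >= prom iff h - min(image) >= prom and the 8-component of {m >= v*}
# containing it holds no strictly higher pixel, where v* is the smallest
# image value exceeding h - prom (one labelling per candidate)
oracle_peak_accepted <- function(m, pos, prom) {
  h <- m[pos[1], pos[2]]
  if (h - min(m) < prom) return(FALSE)
  v <- min(m[m > h - prom])
  lab <- brute_label8(m >= v)
  comp <- lab == lab[pos[1], pos[2]]
  max(m[comp]) <= h
}

oracle_maxima_fast <- function(m, prom) {
  cand <- brute_local_maxima(m)
  keep <- NULL
  for (k in seq_len(NROW(cand)))
    if (oracle_peak_accepted(m, cand[k, ], prom))
      keep <- rbind(keep, cand[k, ])
  if (is.null(keep)) return(matrix(integer(0), 0, 2))
  keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
}

brute_maxima_with_prominence <- function(m, prom) {
  cand <- brute_local_maxima(m)
  keep <- NULL
  for (k in seq_len(NROW(cand))) {
    if (brute_prominence(m, cand[k, ]) >= prom)
      keep <- rbind(keep, cand[k, ])
  }
  if (is.null(keep)) return(matrix(integer(0), 0, 2))
  keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
}

# all-pairs mask-intersection colocalization oracle
brute_coloc <- function(a, b) {
  out <- NULL
  for (la in a$objects$label) for (lb in b$objects$label) {
    ov <- sum(a$labels == la & b$labels == lb)
    if (ov >= 1) out <- rbind(out, data.frame(
      channel_a_label = la, channel_b_label = lb, overlap_area_px = ov))
  }
  if (is.null(out))
    return(data.frame(channel_a_label = integer(),
                      channel_b_label = integer(),
                      overlap_area_px = integer()))
  out[order(out$channel_a_label, out$channel_b_label), , drop = FALSE]
}

# smooth tie-free random test image: white noise plus a few Gaussian bumps
random_smooth_image <- function(ny = 32, nx = 32, n_bumps = 4,
                                noise_sd = 0.05) {
  m <- matrix(rnorm(ny * nx, 0, noise_sd), ny, nx)
  for (b in seq_len(n_bumps)) {
    yc <- runif(1, 4, ny - 3); xc <- runif(1, 4, nx - 3)
    s <- runif(1, 1, 2.5); a <- runif(1, 0.5, 2)
    m <- m + a * exp(-(outer((1:ny - yc)^2, (1:nx - xc)^2, "+")) / (2 * s^2))
  }
  m
}

# a FociSet built from a label matrix (for colocalization tests)
foci_from_labels <- function(lab, channel_role = "custom") {
  labs <- sort(unique(lab[lab > 0]))
  objects <- do.call(rbind, lapply(labs, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    data.frame(label = l, y = mean(idx[, 1]), x = mean(idx[, 2]),
               area_px = nrow(idx), peak_intensity = 1,
               peak_y = idx[1, 1], peak_x = idx[1, 2])
  }))
  if (is.null(objects))
    objects <- data.frame(label = integer(), y = numeric(), x = numeric(),
                          area_px = integer(), peak_intensity = numeric(),
                          peak_y = integer(), peak_x = integer())
  foci_set(channel_role, objects, lab)
}

# random non-overlapping-ish blobs as a label image
random_label_image <- function(ny = 40, nx = 40, n_obj = 8,
                               max_r = 3) {
  lab <- matrix(0L, ny, nx)
  for (l in seq_len(n_obj)) {
    yc <- sample(seq_len(ny), 1); xc <- sample(seq_len(nx), 1)
    r <- sample(seq_len(max_r), 1)
    ys <- pmax(1, yc - r):pmin(ny, yc + r)
    xs <- pmax(1, xc - r):pmin(nx, xc + r)
    for (i in ys) for (j in xs)
      if ((i - yc)^2 + (j - xc)^2 <= r^2 && lab[i, j] == 0L)
        lab[i, j] <- l
  }
  # relabel consecutively in case an object was fully overwritten
  labs <- sort(unique(lab[lab > 0]))
  out <- matrix(0L, ny, nx)
  for (k in seq_along(labs)) out[lab == labs[k]] <- k
  out
}

# small, fast simulation config for tests (defaults overridable)
test_config <- function(...) {
  args <- list(n_cells = 4, image_shape_px = c(224, 224),
               telomere_count_mean = 20, free_pml_mean = 5)
  args <- utils::modifyList(args, list(...))
  do.call(simulation_config, args)
}
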