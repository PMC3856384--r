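# Independent brute-force oracles for the image primitives.  These are
# written directly from the mathematical definitions (Minkowski sums,
# sliding windows as explicit shifts, exhaustive threshold scans) and share
# no code with the package implementations.

# Shift an array by an integer offset, padding with `fill`.
shift_arr <- function(a, off, fill) {
  d <- dim(a)
  out <- array(fill, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    i <- seq_len(d[ax])
    keep <- i - off[ax] >= 1 & i - off[ax] <= d[ax]
    dst[[ax]] <- i[keep]
    src[[ax]] <- i[keep] - off[ax]
  }
  if (any(lengths(dst) == 0)) return(out)
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

ball_offs_oracle <- function(r, sp) {
  m <- ceiling(r / sp)
  off <- as.matrix(expand.grid(-m[1]:m[1], -m[2]:m[2], -m[3]:m[3]))
  off[(off[, 1] * sp[1])^2 + (off[, 2] * sp[2])^2 +
        (off[, 3] * sp[3])^2 <= r^2 + 1e-9, , drop = FALSE]
}

box_offs_oracle <- function(h) {
  as.matrix(expand.grid(-h[1]:h[1], -h[2]:h[2], -h[3]:h[3]))
}

# Minkowski erosion/dilation of a logical array by an explicit offset set;
# out-of-grid counts as background for dilation and foreground for erosion
# (the adjoint boundary pair).
oracle_binary <- function(m, offs, op) {
  acc <- NULL
  for (i in seq_len(nrow(offs))) {
    s <- if (op == "dilate") shift_arr(m, offs[i, ], FALSE) else
      shift_arr(m, -offs[i, ], TRUE)
    acc <- if (is.null(acc)) s else if (op == "dilate") acc | s else acc & s
  }
  acc
}

# Grayscale min/max over an offset footprint, out-of-grid ignored.
oracle_gray <- function(v, offs, do_max) {
  acc <- array(if (do_max) -Inf else Inf, dim(v))
  for (i in seq_len(nrow(offs))) {
    s <- shift_arr(v, offs[i, ], if (do_max) -Inf else Inf)
    acc <- if (do_max) pmax(acc, s) else pmin(acc, s)
  }
  acc
}

# Truncated-window box mean via shifted sums and counts.
oracle_box_mean <- function(v, h) {
  offs <- box_offs_oracle(h)
  s <- array(0, dim(v)); n <- array(0, dim(v))
  ones <- array(1, dim(v))
  for (i in seq_len(nrow(offs))) {
    s <- s + shift_arr(v, offs[i, ], 0)
    n <- n + shift_arr(ones, offs[i, ], 0)
  }
  s / n
}

oracle_masked_mean <- function(v, m, h) {
  offs <- box_offs_oracle(h)
  s <- array(0, dim(v)); n <- array(0, dim(v))
  for (i in seq_len(nrow(offs))) {
    s <- s + shift_arr(v * m, offs[i, ], 0)
    n <- n + shift_arr(m + 0, offs[i, ], 0)
  }
  out <- array(0, dim(v))
  out[n > 0] <- s[n > 0] / n[n > 0]
  out
}

# Exhaustive scan over histogram bin edges for the Otsu threshold.
oracle_otsu <- function(vals, bins = 128L) {
  lo <- min(vals); hi <- max(vals)
  breaks <- seq(lo, hi, length.out = bins + 1L)
  bi <- findInterval(vals, breaks, all.inside = TRUE)
  mid <- (breaks[-1] + breaks[-(bins + 1L)]) / 2
  vc <- mid[bi]
  best <- -Inf; best_t <- NA_real_
  for (k in seq_len(bins - 1L)) {
    in0 <- bi <= k
    n0 <- sum(in0); n1 <- length(vals) - n0
    if (n0 == 0 || n1 == 0) next
    bcv <- n0 * n1 * (mean(vc[in0]) - mean(vc[!in0]))^2
    if (bcv > best) { best <- bcv; best_t <- breaks[k + 1L] }
  }
  best_t
}

# 6-connected flood labelling in plain R.
oracle_label <- function(m) {
  d <- dim(m)
  lab <- array(0L, d)
  nxt <- 0L
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
              c(0, 0, -1), c(0, 0, 1))
  idx <- which(m)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      pc <- arrayInd(p, d)
      for (o in seq_len(6)) {
        q <- pc + nb[o, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
        if (m[qi] && lab[qi] == 0L) {
          lab[qi] <- nxt
          queue <- c(queue, qi)
        }
      }
    }
  }
  lab
}

# Separable truncated Gaussian written independently (explicit kernel,
# renormalized at borders), matching the package's stated convention.
oracle_gauss1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  R <- ceiling(3.5 * sigma)
  w <- exp(-0.5 * ((-R:R) / sigma)^2)
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - R):min(n, i + R)
    wk <- w[j - i + R + 1]
    out[i] <- sum(wk * x[j]) / sum(wk)
  }
  out
}

oracle_gauss <- function(v, sigma_vox) {
  d <- dim(v)
  out <- v
  for (i in seq_len(d[2])) for (k in seq_len(d[3]))
    out[, i, k] <- oracle_gauss1d(out[, i, k], sigma_vox[1])
  for (i in seq_len(d[1])) for (k in seq_len(d[3]))
    out[i, , k] <- oracle_gauss1d(out[i, , k], sigma_vox[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2]))
    out[i, j, ] <- oracle_gauss1d(out[i, j, ], sigma_vox[3])
  out
}

rand_dims <- function(max_side = 16L, min_side = 5L) {
  sample(min_side:max_side, 3L, replace = TRUE)
}

rand_vol <- function(d, spacing = c(1, 1, 1)) {
  vol3(array(runif(prod(d)), d), spacing)
}

rand_mask <- function(d, p = 0.5, spacing = c(1, 1, 1)) {
  mask3(array(runif(prod(d)) < p, d), spacing)
}
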