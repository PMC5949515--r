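# Small fixtures and independent brute-force oracles used across the suite.

# compact group spec for fast unit tests: 256 px fields (0.0041 mm^2)
tiny_spec <- function(genotype = "control", age_months = 8L, ...) {
  default_group_spec(genotype, age_months,
                     n_mice = 2L, slices_per_mouse = 1L,
                     fields_per_region = c(left_ventricle = 2L),
                     field_px = 256L, ...)
}

# constant-channel field builder
const_field <- function(hoechst = 300, fitc = 1000, cy3 = 1000, n = 32,
                        pixel_size_um = 0.25) {
  m <- function(v) matrix(as.integer(v), n, n)
  ist_field(m(hoechst), m(fitc), m(cy3), pixel_size_um)
}

# paint a filled disc of value into a matrix (row/col 0-based center)
disc_into <- function(mat, cx, cy, r, value) {
  for (row in seq_len(nrow(mat))) {
    for (col in seq_len(ncol(mat))) {
      if (((col - 1) - cx)^2 + ((row - 1) - cy)^2 <= r^2) {
        mat[row, col] <- value
      }
    }
  }
  mat
}

# exhaustive-search Otsu oracle: same 256-bin min-max binning contract,
# criterion evaluated cut by cut with an explicit loop
otsu_oracle <- function(px, n_bins = 256L) {
  rng <- range(px)
  bw <- (rng[2] - rng[1]) / n_bins
  idx <- pmin(floor((px - rng[1]) / bw), n_bins - 1)
  h <- as.numeric(tabulate(idx + 1L, nbins = n_bins))
  mids <- rng[1] + (seq_len(n_bins) - 0.5) * bw
  best_k <- NA_integer_; best <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    w0 <- sum(h[1:k]); w1 <- sum(h[(k + 1):n_bins])
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:k] * mids[1:k]) / w0
    mu1 <- sum(h[(k + 1):n_bins] * mids[(k + 1):n_bins]) / w1
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_k <- k }   # strict: lowest tie wins
  }
  rng[1] + best_k * bw
}

# breadth-first connected-component labeling oracle (small masks only)
flood_label <- function(mask, eight = TRUE) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (eight) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  }
  cur <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && lab[r, c] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(r, c), 1)
      lab[r, c] <- cur
      while (nrow(queue) > 0L) {
        p <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
        for (k in seq_len(nrow(nb))) {
          rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
          if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
              mask[rr, cc] && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue <- rbind(queue, c(rr, cc))
          }
        }
      }
    }
  }
  lab
}

# full-enumeration two-sided Mann-Whitney oracle; U computed from pairwise
# comparisons (not from rank sums, to stay independent of the implementation)
mw_enum_oracle <- function(x, y) {
  u_of <- function(a, b) {
    u <- 0
    for (ai in a) for (bj in b) {
      u <- u + (ai > bj) + 0.5 * (ai == bj)
    }
    u
  }
  pool <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pool), n1)
  u_obs <- u_of(x, y)
  u_all <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# type-7 quantile oracle by sort-and-index arithmetic
quantile7_oracle <- function(x, p) {
  s <- sort(x); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  val <- s[lo]
  if (lo < n) val <- val + (h - lo) * (s[lo + 1] - s[lo])
  val
}
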