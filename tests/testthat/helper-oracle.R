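# Independent brute-force references, written directly from the operator
# definitions with explicit loops. They share no code with the package
# internals and serve as oracles for the morphological and contour-update
# operations.

oracle_segment <- function(len, angle) {
  half <- (len - 1) %/% 2
  step <- switch(as.character(angle %% 180),
                 "0" = c(0, 1), "45" = c(-1, 1),
                 "90" = c(1, 0), "135" = c(1, 1))
  t(vapply(-half:half, function(k) step * k, numeric(2)))
}

# min/max over the element at each pixel, out-of-grid offsets ignored
oracle_reduce <- function(m, offsets, op) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- c()
    for (i in seq_len(nrow(offsets))) {
      rr <- r + offsets[i, 1]; cc <- c + offsets[i, 2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        vals <- c(vals, m[rr, cc])
    }
    out[r, c] <- if (op == "min") min(vals) else max(vals)
  }
  out
}

oracle_sup_inf <- function(u, segments) {
  eroded <- lapply(segments, function(s) oracle_reduce(u, s, "min"))
  Reduce(pmax, eroded)
}

oracle_inf_sup <- function(u, segments) {
  dilated <- lapply(segments, function(s) oracle_reduce(u, s, "max"))
  Reduce(pmin, dilated)
}

oracle_si_is <- function(u, segments, mu = 1) {
  for (i in seq_len(mu)) u <- oracle_sup_inf(oracle_inf_sup(u, segments), segments)
  u
}

oracle_k3_segments <- function()
  lapply(c(0, 45, 90, 135), function(a) oracle_segment(3, a))

oracle_k15_segments <- function()
  lapply(c(0, 45, 90, 135), function(a) oracle_segment(15, a))

oracle_cross <- function() rbind(c(0, 0), c(-1, 0), c(1, 0), c(0, -1), c(0, 1))

# central-difference contour indicator with replicated edges
oracle_contour <- function(u) {
  nr <- nrow(u); nc <- ncol(u)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dr <- u[min(r + 1, nr), c] - u[max(r - 1, 1), c]
    dc <- u[r, min(c + 1, nc)] - u[r, max(c - 1, 1)]
    out[r, c] <- dr != 0 || dc != 0
  }
  out
}

# one full contour update: region means, balloon dilation, sign test on the
# pre-balloon contour, then smoothing
oracle_macwe_step <- function(u, img, segments, nu = 1, mu = 1,
                              lambda1 = 1, lambda2 = 1) {
  c1 <- mean(img[u == 1]); c2 <- mean(img[u == 0])
  contour <- oracle_contour(u)
  u1 <- if (nu > 0) oracle_reduce(u, oracle_cross(), "max")
        else if (nu < 0) oracle_reduce(u, oracle_cross(), "min") else u
  for (r in seq_len(nrow(u))) for (c in seq_len(ncol(u))) {
    if (contour[r, c]) {
      f <- lambda1 * (img[r, c] - c1)^2 - lambda2 * (img[r, c] - c2)^2
      if (f < 0) u1[r, c] <- 1 else if (f > 0) u1[r, c] <- 0
    }
  }
  oracle_si_is(u1, segments, mu)
}

# brute-force grayscale opening-then-closing over a disk
oracle_open_close <- function(m, radius) {
  g <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  disk <- as.matrix(g[g$dr^2 + g$dc^2 <= radius^2, ])
  opened <- oracle_reduce(oracle_reduce(m, disk, "min"), disk, "max")
  oracle_reduce(oracle_reduce(opened, disk, "max"), disk, "min")
}

random_mask <- function(n, p = 0.5) matrix(rbinom(n * n, 1, p), n, n)
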