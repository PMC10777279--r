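# Independent brute-force oracles. These deliberately avoid the package's
# code paths: plain per-pixel loops and direct enumeration.

random_mask <- function(h, w, p = 0.3) {
  matrix(runif(h * w) < p, h, w)
}

# per-pixel tally + threshold, scalar loops only
oracle_majority <- function(masks, threshold = 0.5) {
  h <- nrow(masks[[1]])
  w <- ncol(masks[[1]])
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      votes <- 0
      for (m in masks) votes <- votes + (m[i, j] == TRUE)
      out[i, j] <- votes / length(masks) >= threshold
    }
  }
  out
}

oracle_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      na <- na + a[i, j]
      nb <- nb + b[i, j]
      inter <- inter + (a[i, j] && b[i, j])
    }
  }
  if (na + nb == 0) 1 else 2 * inter / (na + nb)
}

oracle_sae <- function(pred, gt, skin) {
  abs(100 * sum(pred) / sum(skin) - 100 * sum(gt) / sum(skin))
}

# Mann-Whitney by pair counting and full enumeration over group labelings
oracle_mwu <- function(a, b) {
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y) u <- u + (xi > yj) + 0.5 * (xi == yj)
    u
  }
  U <- u_of(a, b)
  pooled <- c(a, b)
  na <- length(a)
  combos <- utils::combn(length(pooled), na)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p <- 2 * min(mean(us <= U + 1e-9), mean(us >= U - 1e-9))
  list(U = U, p_value = min(1, p))
}

# ray-casting point-in-polygon (even-odd), one point at a time
oracle_point_in_polygon <- function(py, px, loop) {
  n <- nrow(loop)
  inside <- FALSE
  for (a in seq_len(n)) {
    b <- if (a == n) 1 else a + 1
    y1 <- loop[a, 1]; x1 <- loop[a, 2]
    y2 <- loop[b, 1]; x2 <- loop[b, 2]
    if ((y1 <= py) != (y2 <= py)) {
      xc <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (xc <= px) inside <- !inside
    }
  }
  inside
}
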