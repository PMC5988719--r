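# Independent brute-force oracles. These deliberately avoid the code paths
# of the implementations they check: enumeration instead of dynamic
# programming, per-pixel loops instead of vectorized shifts.

# Two-sided exact rank-sum p by exhaustive enumeration of all
# choose(n, n1) assignments of the pooled mid-ranks to group 1.
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x)
  rk <- rank(c(x, y))
  sums <- combn(rk, n1, sum)
  s_obs <- sum(rk[seq_len(n1)])
  tol <- 1e-9
  p_le <- mean(sums <= s_obs + tol)
  p_ge <- mean(sums >= s_obs - tol)
  min(1, 2 * min(p_le, p_ge))
}

# Two-sided Fisher p from the explicit factorial formula, enumerating
# every table with the observed margins (no dhyper).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- sum(tab)
  lp <- function(aa) {
    lfactorial(r1) + lfactorial(r2) + lfactorial(c1) + lfactorial(c2) -
      lfactorial(n) - lfactorial(aa) - lfactorial(r1 - aa) -
      lfactorial(c1 - aa) - lfactorial(n - r1 - c1 + aa)
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lp(ks))
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Grayscale opening with a ball structuring element by per-pixel loops.
oracle_opening <- function(img, radius, height = radius) {
  h <- nrow(img); w <- ncol(img)
  r <- floor(radius)
  z <- function(dy, dx) (height / radius) * sqrt(max(radius^2 - dy^2 - dx^2, 0))
  in_disk <- function(dy, dx) dy^2 + dx^2 <= radius^2
  er <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    m <- Inf
    for (dy in -r:r) for (dx in -r:r) {
      if (!in_disk(dy, dx)) next
      ii <- i + dy; jj <- j + dx
      if (ii < 1 || ii > h || jj < 1 || jj > w) next
      m <- min(m, img[ii, jj] - z(dy, dx))
    }
    er[i, j] <- m
  }
  di <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    m <- -Inf
    for (dy in -r:r) for (dx in -r:r) {
      if (!in_disk(dy, dx)) next
      ii <- i - dy; jj <- j - dx
      if (ii < 1 || ii > h || jj < 1 || jj > w) next
      m <- max(m, er[ii, jj] + z(dy, dx))
    }
    di[i, j] <- m
  }
  di
}

# Mean filter with a disk neighborhood by per-pixel loops.
oracle_mean_disk <- function(img, radius) {
  h <- nrow(img); w <- ncol(img)
  r <- floor(radius)
  out <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    acc <- 0; cnt <- 0
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 > radius^2) next
      ii <- i + dy; jj <- j + dx
      if (ii < 1 || ii > h || jj < 1 || jj > w) next
      acc <- acc + img[ii, jj]; cnt <- cnt + 1
    }
    out[i, j] <- acc / cnt
  }
  out
}

# Build a single-frame image_stack from a matrix.
stack1 <- function(img, dt = 1) {
  arr <- array(0, dim = c(1, nrow(img), ncol(img)))
  arr[1, , ] <- img
  image_stack(arr, frame_interval = dt)
}

# Hand-built event_set for arithmetic tests.
make_event_set <- function(times, amps = rep(1, length(times)),
                           duration = 10, baseline = 0) {
  structure(list(event_times = times, event_amplitudes = amps,
                 sigma = 1, baseline = baseline, threshold_multiplier = 2,
                 duration = duration),
            class = "event_set")
}

# Sequence-level agreement between ground-truth and detected boundary
# events: fraction of positions (per larva, in order) where origin and
# outcome both match, over the longer of the two lists.
event_agreement <- function(gt, ev) {
  agree <- 0; tot <- 0
  for (id in unique(c(gt$larva_id, ev$larva_id))) {
    g <- gt[gt$larva_id == id, , drop = FALSE]
    d <- ev[ev$larva_id == id, , drop = FALSE]
    k <- min(nrow(g), nrow(d))
    tot <- tot + max(nrow(g), nrow(d))
    if (k > 0) {
      agree <- agree + sum(g$outcome[seq_len(k)] == d$outcome[seq_len(k)] &
                           g$origin_side[seq_len(k)] == d$origin_side[seq_len(k)])
    }
  }
  if (tot == 0) return(NA_real_)
  agree / tot
}
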