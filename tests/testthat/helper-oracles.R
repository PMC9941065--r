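# Independent oracles used across the suite. These deliberately avoid
# the code paths they check.

# Upper-tail hypergeometric probability by exhaustive enumeration over
# draw outcomes: P(X >= k) for X ~ Hypergeometric(N, K, n).
enum_hyper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  js <- k:min(K, n)
  js <- js[n - js <= N - K]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Pooled two-sample t statistic, written out longhand.
pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# Naive grayscale reconstruction by iterated 8-neighbour dilation under
# the mask, run to the fixed point. Slow; for small fixtures only.
naive_reconstruct <- function(marker, mask) {
  J <- pmin(marker, mask)
  nr <- nrow(J); nc <- ncol(J)
  repeat {
    D <- J
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      S <- matrix(-Inf, nr, nc)
      yr <- seq_len(nr) - dy; xr <- seq_len(nc) - dx
      oky <- yr >= 1 & yr <= nr; okx <- xr >= 1 & xr <= nc
      S[which(oky), which(okx)] <- J[yr[oky], xr[okx], drop = FALSE]
      D <- pmax(D, S)
    }
    Jn <- pmin(D, mask)
    if (all(Jn == J)) return(J)
    J <- Jn
  }
}

# Greedy matching of detections to ground-truth spots: a detection
# matches a truth spot when its centroid lies within that spot's radius.
match_detections <- function(records, truth) {
  tp <- 0L
  used <- rep(FALSE, nrow(records))
  for (i in seq_len(nrow(truth))) {
    d <- sqrt((records$x - truth$x[i])^2 + (records$y - truth$y[i])^2)
    j <- which(!used & d <= truth$radiusPx[i])
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(tp = tp, fp = nrow(records) - tp, fn = nrow(truth) - tp)
}

f1_from_counts <- function(m) {
  prec <- m[["tp"]] / max(m[["tp"]] + m[["fp"]], 1)
  rec <- m[["tp"]] / max(m[["tp"]] + m[["fn"]], 1)
  if (prec + rec == 0) return(0)
  2 * prec * rec / (prec + rec)
}

# Point-in-ellipse test for ground-truth geometry checks.
inside_ellipse <- function(px, py, nucleus) {
  dx <- px - nucleus$x; dy <- py - nucleus$y
  u <- dx * cos(nucleus$thetaRad) + dy * sin(nucleus$thetaRad)
  v <- -dx * sin(nucleus$thetaRad) + dy * cos(nucleus$thetaRad)
  (u / nucleus$semiMajorPx)^2 + (v / nucleus$semiMinorPx)^2 <= 1
}
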