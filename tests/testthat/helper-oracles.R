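## Independent reference implementations used to check the package
## against first principles. These are deliberately brute-force and
## share no code with the implementation under test.

## Exact soft-margin linear SVM by KKT active-set enumeration.
## Solves min 1/2 |w|^2 + C sum xi  s.t.  y_i (w.x_i + b) >= 1 - xi_i
## for <= ~8 points by enumerating, for every assignment of points to
## {alpha = 0, 0 < alpha < C, alpha = C}, the linear KKT system of the
## dual, keeping feasible solutions and returning the best.
svmQPOracle <- function(x, y, C = 1) {
  n <- nrow(x)
  yy <- ifelse(as.character(y) == "A", 1, -1)
  K <- x %*% t(x)
  best <- NULL
  states <- expand.grid(rep(list(0:2), n))   # 0 = zero, 1 = free, 2 = at C
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    Fr <- which(st == 1L); U <- which(st == 2L)
    if (!length(Fr)) next                    # need free SVs to pin b
    alpha <- numeric(n); alpha[U] <- C
    ## KKT: for i in F, y_i f(x_i) = 1; plus sum alpha_i y_i = 0
    A <- rbind(cbind(outer(yy[Fr], yy[Fr]) * K[Fr, Fr, drop = FALSE],
                     yy[Fr]),
               c(yy[Fr], 0))
    rhs <- c(1 - yy[Fr] * (K[Fr, U, drop = FALSE] %*% (C * yy[U]))[, 1L],
             -C * sum(yy[U]))
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    alpha[Fr] <- sol[seq_along(Fr)]
    b <- sol[length(sol)]
    tol <- 1e-9
    if (any(alpha[Fr] < -tol) || any(alpha[Fr] > C + tol)) next
    f <- (K %*% (alpha * yy))[, 1L] + b
    m <- yy * f
    Z <- which(st == 0L)
    if (any(m[Z] < 1 - 1e-7) || any(m[U] > 1 + 1e-7)) next
    obj <- sum(alpha) - 0.5 * sum((alpha * yy) * (K %*% (alpha * yy)))
    if (is.null(best) || obj > best$obj + 1e-12)
      best <- list(alpha = alpha, b = b, obj = obj,
                   w = drop(t(x) %*% (alpha * yy)))
  }
  best
}

## Exact Wilcoxon signed-rank two-sided p by enumerating all 2^n sign
## assignments (matches the R convention: one tail doubled, capped at 1).
wilcoxonEnumOracle <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 15, !anyDuplicated(abs(d)))
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Vdist <- signs %*% rk
  mu <- n * (n + 1) / 4
  p1 <- if (V > mu) mean(Vdist >= V) else mean(Vdist <= V)
  list(V = V, p = min(1, 2 * p1))
}

## Mean band PSD from a raw periodogram (Welch-style oracle, no
## wavelets): mean periodogram ordinate over the band's frequency range.
welchBandPower <- function(x, fs, bands) {
  n <- length(x)
  pg <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) * fs / n
  sapply(seq_len(nrow(bands)), function(b)
    mean(pg[f >= bands$lo[b] & f <= bands$hi[b]]))
}

## Direct (time-domain) complex Morlet convolution with zero extension.
directMorletPower <- function(x, f0, fs, ratio = 7) {
  w <- morletWavelet(f0, fs, ratio)
  L <- (length(w) - 1L) %/% 2L
  n <- length(x)
  xp <- c(numeric(L), x, numeric(L))
  out <- complex(n)
  for (t in seq_len(n))
    out[t] <- sum(w * xp[t + (2L * L):0L])  # sum_k w(k) x(t - k)
  Mod(out)^2
}
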