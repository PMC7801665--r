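# Small FFT helpers shared by the map-correlation code.

fft2 <- function(m, inverse = FALSE) {
  res <- t(stats::mvfft(t(stats::mvfft(m, inverse = inverse)),
                        inverse = inverse))
  if (inverse) res / length(m) else res
}

# Full 2-D linear convolution via zero-padded FFT, size (na+nb-1) per dim.
conv2_full <- function(a, b) {
  nr <- nrow(a) + nrow(b) - 1L
  nc <- ncol(a) + ncol(b) - 1L
  pa <- matrix(0, nr, nc); pa[seq_len(nrow(a)), seq_len(ncol(a))] <- a
  pb <- matrix(0, nr, nc); pb[seq_len(nrow(b)), seq_len(ncol(b))] <- b
  Re(fft2(fft2(pa) * fft2(pb), inverse = TRUE))
}

rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]

# Circular (wrap) cross-correlation c[du,dv] = sum_ij a[i,j] b[i+du, j+dv]
# (indices mod n), centered with zero offset at index floor(n/2)+1.
xcorr2_wrap <- function(a, b) {
  cc <- Re(fft2(Conj(fft2(a)) * fft2(b), inverse = TRUE))
  si <- floor(nrow(cc) / 2)
  sj <- floor(ncol(cc) / 2)
  cc[c((si + 1):nrow(cc), seq_len(si)), c((sj + 1):ncol(cc), seq_len(sj))]
}

# Bilinear interpolation of matrix values at fractional indices (xi, yi),
# 1-based. Points outside the grid return NA.
bilinear <- function(m, xi, yi) {
  nr <- nrow(m); nc <- ncol(m)
  out <- rep(NA_real_, length(xi))
  ok <- xi >= 1 & xi <= nr & yi >= 1 & yi <= nc
  x <- xi[ok]; y <- yi[ok]
  x0 <- pmin(floor(x), nr - 1L); y0 <- pmin(floor(y), nc - 1L)
  fx <- x - x0; fy <- y - y0
  v <- (1 - fx) * (1 - fy) * m[cbind(x0, y0)] +
    fx * (1 - fy) * m[cbind(x0 + 1, y0)] +
    (1 - fx) * fy * m[cbind(x0, y0 + 1)] +
    fx * fy * m[cbind(x0 + 1, y0 + 1)]
  out[ok] <- v
  out
}
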