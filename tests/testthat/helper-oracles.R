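# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths.

# per-pixel double-loop blue mask: manual RGB -> HSV conversion
oracle_blue_mask <- function(img, band = c(200, 260), min_s = 0.25,
                             min_v = 0.15) {
  d <- dim(img)[1:2]
  out <- matrix(FALSE, d[1], d[2])
  for (x in seq_len(d[1])) {
    for (y in seq_len(d[2])) {
      r <- img[x, y, 1]; g <- img[x, y, 2]; b <- img[x, y, 3]
      mx <- max(r, g, b); mn <- min(r, g, b); c <- mx - mn
      v <- mx
      s <- if (mx > 0) c / mx else 0
      h <- if (c == 0) 0
      else if (mx == r) 60 * (((g - b) / c) %% 6)
      else if (mx == g) 60 * ((b - r) / c + 2)
      else 60 * ((r - g) / c + 4)
      inband <- if (band[1] <= band[2]) h >= band[1] && h <= band[2]
                else h >= band[1] || h <= band[2]
      out[x, y] <- inband && s >= min_s && v >= min_v
    }
  }
  out
}

# per-pixel double-loop residue count over a half-open rectangle
oracle_residue_count <- function(mask, x0, y0, x1, y1) {
  cnt <- 0
  for (x in (x0 + 1):x1) {
    for (y in (y0 + 1):y1) {
      if (as.numeric(mask[x, y]) > 0.5) cnt <- cnt + 1
    }
  }
  cnt
}

# two-sided Fisher p by direct hypergeometric enumeration over all tables
# with the observed margins (point-probability rule)
oracle_fisher_p <- function(tp, fp, fn, tn) {
  r1 <- tp + fp; c1 <- tp + fn; n <- tp + fp + fn + tn
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  a_all <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(a_all, c1, n - c1, r1)
  p_obs <- stats::dhyper(tp, c1, n - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Cohen's kappa through the agreement (not disagreement) formulation
oracle_kappa <- function(m, weights = "none") {
  n <- sum(m); k <- nrow(m); idx <- seq_len(k)
  wd <- switch(weights,
               none = 1 * outer(idx, idx, `!=`),
               linear = abs(outer(idx, idx, `-`)),
               quadratic = outer(idx, idx, `-`)^2)
  wa <- 1 - wd / max(wd)
  p <- m / n
  pe <- outer(rowSums(p), colSums(p))
  po_w <- sum(wa * p); pe_w <- sum(wa * pe)
  (po_w - pe_w) / (1 - pe_w)
}

# uniform colour image helper
solid_image <- function(r, g, b, w = 32, h = 32) {
  EBImage::Image(c(matrix(r, w, h), matrix(g, w, h), matrix(b, w, h)),
                 dim = c(w, h, 3), colormode = "Color")
}

# image from HSV scalars/matrices (independent of the package's helper)
hsv_image <- function(hue, s, v, w = 10, h = 10) {
  hex <- grDevices::hsv(hue / 360, s, v)
  m <- grDevices::col2rgb(hex)[, 1] / 255
  solid_image(m[1], m[2], m[3], w, h)
}

# Shannon entropy of an 8-bit-quantized channel
channel_entropy <- function(x) {
  tab <- tabulate(pmin(floor(as.numeric(x) * 256), 255) + 1, nbins = 256)
  p <- tab[tab > 0] / sum(tab)
  -sum(p * log2(p))
}
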