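# Independent scalar transcription of the four signal statistics, used as
# the oracle against the vectorised implementation. Kept deliberately
# separate from the package code path.

oracle_stats <- function(a, b, c, d, z = 1.96, z_ebgm = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  out <- list()

  if (min(a, b, c, d) > 0) {
    or <- (a / b) * (d / c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    out$ror <- or
    out$ror_lower <- exp(log(or) - z * se)
    out$ror_upper <- exp(log(or) + z * se)
  } else {
    out$ror <- out$ror_lower <- out$ror_upper <- NA_real_
  }

  if ((a + b) > 0 && c > 0 && (c + d) > 0) {
    out$prr <- (a / (a + b)) * ((c + d) / c)
    if (a > 0) {
      se_p <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
      out$prr_lower <- exp(log(out$prr) - z * se_p)
      out$prr_upper <- exp(log(out$prr) + z * se_p)
    } else {
      out$prr_lower <- out$prr_upper <- NA_real_
    }
  } else {
    out$prr <- out$prr_lower <- out$prr_upper <- NA_real_
  }
  if ((a + b) > 0 && (c + d) > 0 && (a + c) > 0 && (b + d) > 0) {
    out$chisq <- (a * d - b * c)^2 * N /
      ((a + b) * (c + d) * (a + c) * (b + d))
  } else {
    out$chisq <- NA_real_
  }

  gam <- (N + 2)^2 / ((a + b + 1) * (a + c + 1))
  out$gamma <- gam
  out$eic <- log((a + 1) * (N + 2)^2 /
                   ((N + gam) * (a + b + 1) * (a + c + 1))) / log(2)
  out$vic <- (1 / log(2))^2 * (
    (b + c + d + gam - 1) / ((a + 1) * (N + gam + 1)) +
    (c + d + 1) / ((a + b + 1) * (N + 3)) +
    (b + d + 1) / ((a + c + 1) * (N + 3))
  )
  out$ic025 <- out$eic - 2 * sqrt(out$vic)

  if ((a + b) > 0 && (a + c) > 0) {
    out$ebgm <- a * N / ((a + c) * (a + b))
    if (min(a, b, c, d) > 0) {
      se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
      out$ebgm05 <- exp(log(out$ebgm) - z_ebgm * se)
    } else {
      out$ebgm05 <- NA_real_
    }
  } else {
    out$ebgm <- out$ebgm05 <- NA_real_
  }
  out
}

rel_err <- function(x, y) {
  ifelse(is.na(x) & is.na(y), 0,
         abs(x - y) / pmax(abs(y), .Machine$double.eps))
}
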