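# Classical IIR band-pass design from analog prototypes.
#
# The three comparator families are built the textbook way: analog
# low-pass prototype in zero-pole-gain form, low-pass -> band-pass
# transform with edge prewarping, bilinear transform, then pairing into
# second-order sections. No external DSP library is used; the elliptic
# prototype uses Landen/Gauss transformations of the Jacobi elliptic
# functions.

# ---- complex helpers (base R lacks complex asin up front on doubles) ----

casin <- function(z) {
  z <- as.complex(z)
  -1i * log(1i * z + sqrt(1 - z^2))
}

# ---- Jacobi elliptic machinery (descending Landen sequence) ----

# sequence of descending moduli k_1, k_2, ... from k_0 = k
landen_seq <- function(k, tol = .Machine$double.eps) {
  v <- numeric(0)
  while (k > tol && length(v) < 60L) {
    k <- (k / (1 + sqrt(1 - k^2)))^2
    v <- c(v, k)
  }
  v
}

# ascending recurrence shared by cd and sn
ell_ascend <- function(w, v) {
  for (vi in rev(v)) w <- (1 + vi) * w / (1 + vi * w^2)
  w
}

# Jacobi cd(u*K, k) and sn(u*K, k) with u in units of the quarter period
ell_cd <- function(u, k) ell_ascend(cos(u * pi / 2), landen_seq(k))
ell_sn <- function(u, k) ell_ascend(sin(u * pi / 2), landen_seq(k))

# inverse sn: returns u (in quarter-period units) with sn(u*K, k) = w
ell_asn <- function(w, k) {
  v <- landen_seq(k)
  kprev <- c(k, v[-length(v)])
  w <- as.complex(w)
  for (n in seq_along(v)) {
    w <- 2 * w / ((1 + v[n]) * (1 + sqrt(1 - kprev[n]^2 * w^2)))
  }
  2 / pi * casin(w)
}

# exact degree equation: modulus k achieving integer degree n at
# discrimination k1 = eps_p / eps_s
ellip_degree_modulus <- function(n, k1) {
  L <- floor(n / 2)
  kc <- sqrt(1 - k1^2)
  ui <- (2 * seq_len(L) - 1) / n
  kp <- kc^n * prod(Re(ell_sn(ui, kc)))^4
  sqrt(1 - kp^2)
}

# ---- analog low-pass prototypes (cutoff 1 rad/s), zpk form ----

butter_prototype <- function(n) {
  theta <- pi * (2 * seq_len(n) - 1) / (2 * n)
  p <- complex(real = -sin(theta), imaginary = cos(theta))
  list(z = complex(0), p = p, k = 1)
}

cheby1_prototype <- function(n, rp_db) {
  eps <- sqrt(10^(rp_db / 10) - 1)
  mu <- asinh(1 / eps) / n
  theta <- pi * (2 * seq_len(n) - 1) / (2 * n)
  p <- complex(real = -sinh(mu) * sin(theta),
               imaginary = cosh(mu) * cos(theta))
  k <- Re(prod(-p))
  if (n %% 2 == 0) k <- k / sqrt(1 + eps^2)
  list(z = complex(0), p = p, k = k)
}

ellip_prototype <- function(n, rp_db, rs_db) {
  ep <- sqrt(10^(rp_db / 10) - 1)
  es <- sqrt(10^(rs_db / 10) - 1)
  k1 <- ep / es
  k <- ellip_degree_modulus(n, k1)
  L <- floor(n / 2)
  r <- n %% 2
  ui <- (2 * seq_len(L) - 1) / n
  zeta <- Re(ell_cd(ui, k))
  z <- 1i / (k * zeta)
  z <- c(z, Conj(z))
  v0 <- Re(-1i * ell_asn(1i / ep, k1) / n)
  pc <- 1i * ell_cd(as.complex(ui - 1i * v0), k)
  p <- c(pc, Conj(pc))
  if (r == 1) p <- c(p, Re(1i * ell_sn(as.complex(1i * v0), k)))
  H0 <- if (r == 1) 1 else 10^(-rp_db / 20)
  kg <- H0 * Re(prod(-p) / prod(-z))
  list(z = z, p = p, k = kg)
}

# ---- frequency transforms ----

# analog low-pass (cutoff 1) -> analog band-pass centered wo, width bw
lp_to_bp_zpk <- function(zpk, wo, bw) {
  z <- zpk$z; p <- zpk$p
  degree <- length(p) - length(z)
  z <- z * bw / 2
  p <- p * bw / 2
  z_bp <- c(z + sqrt(as.complex(z^2 - wo^2)),
            z - sqrt(as.complex(z^2 - wo^2)))
  p_bp <- c(p + sqrt(as.complex(p^2 - wo^2)),
            p - sqrt(as.complex(p^2 - wo^2)))
  z_bp <- c(z_bp, rep(0 + 0i, degree))
  list(z = z_bp, p = p_bp, k = zpk$k * bw^degree)
}

# analog -> digital, matched at prewarped frequencies
bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  z <- zpk$z; p <- zpk$p
  degree <- length(p) - length(z)
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, degree))
  kd <- zpk$k * Re(prod(fs2 - z) / prod(fs2 - p))
  list(z = zd, p = pd, k = kd)
}

# ---- zpk -> second-order sections ----

# split a set of roots into conjugate pairs (and paired reals)
conj_pair_groups <- function(r, tol = 1e-8) {
  re <- r[abs(Im(r)) <= tol * pmax(1, abs(r))]
  cx <- r[abs(Im(r)) > tol * pmax(1, abs(r))]
  cx_up <- cx[Im(cx) > 0]
  cx_up <- cx_up[order(-Mod(cx_up))]
  groups <- lapply(cx_up, function(q) c(q, Conj(q)))
  re <- sort(Re(re))
  while (length(re) >= 2) {
    groups <- c(groups, list(as.complex(re[1:2])))
    re <- re[-(1:2)]
  }
  if (length(re) == 1) groups <- c(groups, list(as.complex(re[1])))
  groups
}

poly_from_roots <- function(r) {
  coef <- c(1 + 0i)
  for (ri in r) coef <- c(coef, 0) - c(0, coef * ri)
  Re(coef)
}

# Pair pole groups (ordered worst-conditioned first, i.e. closest to the
# unit circle) with the nearest remaining zero group. Any pairing yields
# the same overall transfer function; this one keeps sections well
# scaled numerically.
zpk_to_sos <- function(zpk) {
  pg <- conj_pair_groups(zpk$p)
  zg <- conj_pair_groups(zpk$z)
  pg <- pg[order(-sapply(pg, function(g) max(Mod(g))))]
  sos <- matrix(0, nrow = length(pg), ncol = 6)
  for (i in seq_along(pg)) {
    pp <- pg[[i]]
    if (length(zg) > 0) {
      d <- sapply(zg, function(g) Mod(g[1] - pp[1]))
      j <- which.min(d)
      zz <- zg[[j]]
      zg <- zg[-j]
    } else zz <- complex(0)
    b <- poly_from_roots(zz)
    a <- poly_from_roots(pp)
    b <- c(b, rep(0, 3 - length(b)))
    a <- c(a, rep(0, 3 - length(a)))
    sos[i, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * zpk$k
  sos
}

# ---- public design surface ----

#' IIR band-pass design specification
#'
#' Parameters of a classical band-pass design: the family, the prototype
#' order as passed to the design routine (a band-pass of order `n` has
#' `2n` poles), the pass band, the sampling rate, and — where the family
#' uses them — the passband ripple `rp_db` and minimum stopband
#' attenuation `rs_db` in dB.
#'
#' @param family one of `"butterworth"`, `"chebyshev1"`, `"elliptic"`.
#' @param order prototype order (the conventional "fourth-order" = 4).
#' @param band a [band_spec()].
#' @param fs sampling rate in Hz.
#' @param rp_db passband ripple in dB (chebyshev1, elliptic).
#' @param rs_db minimum stopband attenuation in dB (elliptic).
#' @return An object of class `iir_design_spec`.
#' @examples
#' iir_design_spec("chebyshev1", 4, band_spec(0.5, 50), fs = 512, rp_db = 0.5)
#' @export
iir_design_spec <- function(family = c("butterworth", "chebyshev1", "elliptic"),
                            order, band, fs, rp_db = NULL, rs_db = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(band, "band_spec"))
  if (order < 1 || order != round(order)) stop("`order` must be a positive integer")
  check_band_vs_fs(band, fs)
  if (band$f_lo <= 0) stop("lower band edge must be > 0")
  if (family %in% c("chebyshev1", "elliptic")) {
    if (is.null(rp_db) || rp_db <= 0) stop("`rp_db` > 0 required for ", family)
  }
  if (family == "elliptic") {
    if (is.null(rs_db) || rs_db <= rp_db)
      stop("`rs_db` > `rp_db` required for elliptic designs")
  }
  structure(list(family = family, order = as.integer(order), band = band,
                 fs = as.numeric(fs), rp_db = rp_db, rs_db = rs_db),
            class = "iir_design_spec")
}

#' Design a classical IIR band-pass filter in second-order sections
#'
#' Builds the analog low-pass prototype of the requested family
#' (Butterworth maximally flat, Chebyshev Type I equiripple passband,
#' elliptic equiripple in both bands), transforms it to a band-pass with
#' bilinear-prewarped edges, and realizes it as a cascade of
#' second-order sections.
#'
#' @param spec an [iir_design_spec()].
#' @return An object of class `designed_filter` with elements `sos`
#'   (matrix, one section per row, columns `b0 b1 b2 a0 a1 a2` with
#'   `a0 = 1`) and `spec`.
#' @examples
#' filt <- design_iir(iir_design_spec("butterworth", 4,
#'                                    band_spec(0.5, 50), fs = 512))
#' filter_is_stable(filt)
#' @export
design_iir <- function(spec) {
  stopifnot(inherits(spec, "iir_design_spec"))
  proto <- switch(spec$family,
    butterworth = butter_prototype(spec$order),
    chebyshev1  = cheby1_prototype(spec$order, spec$rp_db),
    elliptic    = ellip_prototype(spec$order, spec$rp_db, spec$rs_db))
  fs <- spec$fs
  # prewarp the band edges so the digital response hits them exactly
  wl <- 2 * fs * tan(pi * spec$band$f_lo / fs)
  wh <- 2 * fs * tan(pi * spec$band$f_hi / fs)
  bp <- lp_to_bp_zpk(proto, wo = sqrt(wl * wh), bw = wh - wl)
  dig <- bilinear_zpk(bp, fs)
  sos <- zpk_to_sos(dig)
  filt <- structure(list(sos = sos, spec = spec), class = "designed_filter")
  if (!filter_is_stable(filt))
    stop("numerically unstable design: pole on or outside the unit circle")
  filt
}

#' @export
print.designed_filter <- function(x, ...) {
  s <- x$spec
  extras <- c(if (!is.null(s$rp_db)) sprintf("Rp=%g dB", s$rp_db),
              if (!is.null(s$rs_db)) sprintf("Rs=%g dB", s$rs_db))
  cat(sprintf("<designed_filter> %s order %d, band [%g, %g] Hz @ %g Hz%s (%d sections)\n",
              s$family, s$order, s$band$f_lo, s$band$f_hi, s$fs,
              if (length(extras)) paste0(", ", paste(extras, collapse = ", ")) else "",
              nrow(x$sos)))
  invisible(x)
}

#' @rdname design_iir
#' @param filt a `designed_filter`.
#' @export
filter_is_stable <- function(filt) {
  all(apply(filt$sos, 1, function(s) {
    r <- polyroot(rev(s[4:6]))
    all(Mod(r) < 1)
  }))
}

#' Magnitude response of a designed filter
#'
#' Evaluates the second-order-section cascade transfer function on the
#' unit circle at the requested frequencies and returns the magnitude in
#' dB. Exact zeros are clamped to a floor of -300 dB.
#'
#' @param filt a `designed_filter`.
#' @param freqs frequencies in Hz, within `[0, fs/2]`.
#' @return Numeric vector of `20*log10(|H(f)|)` values.
#' @export
frequency_response <- function(filt, freqs) {
  stopifnot(inherits(filt, "designed_filter"))
  fs <- filt$spec$fs
  if (any(freqs < 0 | freqs > fs / 2))
    stop("`freqs` must lie within [0, fs/2]")
  H <- sos_response_complex(filt$sos, freqs, fs)
  mag <- Mod(H)
  db <- ifelse(mag <= 10^(-300 / 20), -300, 20 * log10(mag))
  pmax(db, -300)
}

sos_response_complex <- function(sos, freqs, fs) {
  w <- 2 * pi * freqs / fs
  e1 <- exp(-1i * w)
  e2 <- exp(-2i * w)
  H <- rep(1 + 0i, length(freqs))
  for (i in seq_len(nrow(sos))) {
    num <- sos[i, 1] + sos[i, 2] * e1 + sos[i, 3] * e2
    den <- sos[i, 4] + sos[i, 5] * e1 + sos[i, 6] * e2
    H <- H * num / den
  }
  H
}

#' Measure realized passband ripple and stopband attenuation
#'
#' Characterizes a band-pass design from its realized response:
#' peak-to-peak magnitude variation (dB) on a dense grid inside the
#' design band, and the minimum attenuation among stopband ripple
#' maxima. For equiripple-stopband designs (elliptic) the stopband on
#' each side starts at the first frequency, moving away from the band,
#' where attenuation first reaches the design's `rs_db` target; for
#' monotone-stopband families the attenuation at half the lower edge and
#' twice the upper edge is reported instead.
#'
#' @param filt a `designed_filter` from [design_iir()].
#' @param n_grid grid density for the search.
#' @return A list with `passband_ripple_db` and
#'   `min_stopband_attenuation_db`.
#' @export
measure_ripple_and_attenuation <- function(filt, n_grid = 8192L) {
  stopifnot(inherits(filt, "designed_filter"))
  s <- filt$spec
  fpass <- seq(s$band$f_lo, s$band$f_hi, length.out = n_grid)
  db_pass <- frequency_response(filt, fpass)
  # peak-to-peak variation between the outermost in-band local maxima:
  # for equiripple families this is exactly Rp; a maximally flat design,
  # whose only in-band structure is the monotone fall towards the -3 dB
  # edges, reports ~0 rather than 3 dB.
  n <- length(db_pass)
  pk <- which(db_pass[2:(n - 1)] >= db_pass[1:(n - 2)] &
              db_pass[2:(n - 1)] >= db_pass[3:n]) + 1L
  ripple <- if (length(pk) >= 2) {
    core <- db_pass[min(pk):max(pk)]
    max(db_pass) - min(core)
  } else 0

  if (!is.null(s$rs_db)) {
    att <- c(stopband_side_attenuation(filt, side = "low", n_grid = n_grid),
             stopband_side_attenuation(filt, side = "high", n_grid = n_grid))
    min_att <- min(att)
  } else {
    probes <- c(s$band$f_lo / 2, min(2 * s$band$f_hi, s$fs / 2 * 0.999))
    min_att <- min(-frequency_response(filt, probes))
  }
  list(passband_ripple_db = ripple, min_stopband_attenuation_db = min_att)
}

# attenuation at every stopband ripple maximum on one side of the band
stopband_side_attenuation <- function(filt, side, n_grid = 8192L) {
  s <- filt$spec
  rs <- s$rs_db
  if (side == "low") {
    f <- seq(s$band$f_lo / 1000, s$band$f_lo, length.out = n_grid)
    db <- frequency_response(filt, f)
    # last crossing of -rs walking up towards the band edge
    cross <- which(db <= -rs)
    if (!length(cross)) return(-max(db))
    region <- seq_len(max(cross))
  } else {
    f <- seq(s$band$f_hi, s$fs / 2 * 0.9999, length.out = n_grid)
    db <- frequency_response(filt, f)
    cross <- which(db <= -rs)
    if (!length(cross)) return(-max(db))
    region <- min(cross):length(f)
  }
  dbr <- db[region]
  # local maxima of the magnitude within the stopband region (ripple peaks)
  n <- length(dbr)
  if (n < 3) return(-max(dbr))
  peak <- which(dbr[2:(n - 1)] >= dbr[1:(n - 2)] &
                dbr[2:(n - 1)] >= dbr[3:n]) + 1L
  if (!length(peak)) return(-max(dbr))
  -max(dbr[peak])
}

#' Export / import a designed filter as a delimited coefficient table
#'
#' One second-order section per row, columns `b0 b1 b2 a0 a1 a2`,
#' written in full double precision for cross-implementation checks.
#'
#' @param filt a `designed_filter`.
#' @param path output file path.
#' @export
write_sos <- function(filt, path) {
  stopifnot(inherits(filt, "designed_filter"))
  df <- as.data.frame(filt$sos)
  names(df) <- c("b0", "b1", "b2", "a0", "a1", "a2")
  utils::write.table(format(df, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sos
#' @param path path to a table written by [write_sos()].
#' @return `read_sos` returns the SOS coefficient matrix.
#' @export
read_sos <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  as.matrix(df[, c("b0", "b1", "b2", "a0", "a1", "a2")])
}
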