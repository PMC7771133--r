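#' Equal-width segment partition of the visible range
#'
#' For a viewer with `n_receptors` photoreceptor types the visible range
#' (lambda1, lambda2) is divided into n + 1 equally sized segments with
#' boundaries lambda_i = lambda1 + i * (lambda2 - lambda1) / (n + 1). For the
#' trichromatic case (n = 3) the four segments are conventionally labelled
#' B, G, Y, R.
#'
#' @param lambda1,lambda2 visible-range endpoints in nm; defaults 300-700
#'   (bee-relevant range)
#' @param n_receptors number of photoreceptor types, integer >= 2
#' @return object of class `segment_partition` with fields `lambda1`,
#'   `lambda2`, `n`, and the boundary vector `boundaries` (length n + 2)
#' @export
segment_partition <- function(lambda1 = 300, lambda2 = 700, n_receptors = 3) {
  if (!(lambda1 < lambda2)) stop("lambda1 must be < lambda2", call. = FALSE)
  n <- as.integer(n_receptors)
  if (n < 2L) stop("n_receptors must be >= 2", call. = FALSE)
  b <- lambda1 + (0:(n + 1L)) * (lambda2 - lambda1) / (n + 1L)
  structure(list(lambda1 = lambda1, lambda2 = lambda2, n = n, boundaries = b),
            class = "segment_partition")
}

#' @export
print.segment_partition <- function(x, ...) {
  cat(sprintf("<segment_partition> %g-%g nm, n = %d (%d segments at %s nm)\n",
              x$lambda1, x$lambda2, x$n, x$n + 1L,
              paste(format(x$boundaries), collapse = ", ")))
  invisible(x)
}

same_partition <- function(a, b) {
  a$n == b$n && isTRUE(all.equal(c(a$lambda1, a$lambda2), c(b$lambda1, b$lambda2)))
}

#' Brightness of a radiance spectrum over a wavelength segment
#'
#' Total photon flux over `[a, b)`: the plain sum of L(lambda) over grid
#' sample points, with NO bin-width weighting. This matches the original
#' segment classification convention in which the brightness coordinate X3
#' depends on the binning (the same green-leaf radiance gives X3 around five
#' times larger at 1 nm than at 5 nm bins); the NSC achromatic coordinate
#' beta/beta_m cancels this dependence. The interval is half-open on the
#' right so that adjacent segments count every sample exactly once;
#' `include_right = TRUE` closes it (used for the final segment of a
#' partition, and the default when `b` is the last grid sample).
#'
#' @param l radiance [spectrum()]
#' @param a,b segment endpoints in nm, `a < b`, within the spectrum range
#' @param include_right count a sample at exactly `b`? Default: only when `b`
#'   is the spectrum's final sample point
#' @return brightness (photon-flux sum, units of L summed over samples)
#' @export
brightness <- function(l, a, b, include_right = NULL) {
  stopifnot(inherits(l, "spectrum"))
  if (l$kind == "reflectance") {
    stop("brightness is defined for radiance (or illuminant) spectra; multiply by an illuminant first",
         call. = FALSE)
  }
  if (!(a < b)) stop("need a < b", call. = FALSE)
  wl <- l$wl
  if (a < wl[1L] - 1e-9 || b > wl[length(wl)] + 1e-9) {
    stop("segment extends beyond spectrum range", call. = FALSE)
  }
  if (is.null(include_right)) include_right <- abs(b - wl[length(wl)]) < 1e-9
  keep <- wl >= a - 1e-9 & (if (include_right) wl <= b + 1e-9 else wl < b - 1e-9)
  if (!any(keep)) stop("empty segment: no grid samples in [a, b)", call. = FALSE)
  sum(l$values[keep])
}

#' White-standard brightness of an illuminant
#'
#' The maximum brightness attainable under illuminant D: with R(lambda) = 1
#' the radiance equals D itself, so beta_m is the brightness of D over the
#' partition range. Used to normalize the NSC achromatic coordinate.
#'
#' @param d illuminant [spectrum()]
#' @param p [segment_partition()] within the illuminant range
#' @return beta_m, the white-standard brightness
#' @export
white_standard_brightness <- function(d, p) {
  stopifnot(inherits(d, "spectrum"), inherits(p, "segment_partition"))
  if (d$kind != "illuminant") stop("d must be an illuminant spectrum", call. = FALSE)
  l <- spectrum(d$wl, d$values, "radiance", name = d$name)
  brightness(l, p$lambda1, p$lambda2,
             include_right = TRUE)
}

#' Relative segment brightnesses
#'
#' Summarizes a radiance spectrum as the fraction of its total brightness
#' falling in each of the n + 1 partition segments: S_i = beta(lambda_{i-1},
#' lambda_i) / beta(lambda1, lambda2). The S_i are non-negative and sum to 1.
#' An all-black spectrum (zero total brightness) has undefined chromatic
#' coordinates and is an error.
#'
#' @param l radiance [spectrum()] covering the partition range
#' @param p [segment_partition()]
#' @return object of class `segment_brightness`: fields `S` (length n + 1,
#'   named B/G/Y/R when n = 3), `beta` (total brightness), `beta_m`
#'   (white-standard brightness, `NA` until an illuminant is supplied, see
#'   [nsc_locus()]), and `partition`
#' @export
segment_relative_brightness <- function(l, p) {
  stopifnot(inherits(l, "spectrum"), inherits(p, "segment_partition"))
  bounds <- p$boundaries
  k <- p$n + 1L
  seg <- numeric(k)
  for (i in seq_len(k)) {
    seg[i] <- brightness(l, bounds[i], bounds[i + 1L],
                         include_right = (i == k))
  }
  beta <- sum(seg)
  if (beta <= 0) {
    stop("zero total brightness: undefined chromatic coordinates", call. = FALSE)
  }
  S <- seg / beta
  if (p$n == 3L) names(S) <- c("B", "G", "Y", "R")
  structure(list(S = S, beta = beta, beta_m = NA_real_, partition = p),
            class = "segment_brightness")
}

#' @export
print.segment_brightness <- function(x, ...) {
  cat("<segment_brightness> S =", paste(format(x$S, digits = 4), collapse = " "),
      sprintf(" beta = %.6g, beta_m = %s\n", x$beta, format(x$beta_m)))
  invisible(x)
}

#' Endler's segment classification locus
#'
#' Maps a 4-segment relative-brightness vector (B, G, Y, R) to polar
#' coordinates: chroma X1 = sqrt((R-G)^2 + (Y-B)^2), hue angle X2 by a
#' three-branch arcsine rule (branching on R >= G and Y >= B, the corrected
#' formulation rather than the original PASCAL-implementation arcsine), and
#' brightness X3 = beta. Defined for the trichromatic case only. At the
#' achromatic point (X1 = 0) the hue is undefined; X2 is set to 0 and flagged
#' via the `hue_defined` field.
#'
#' @param sb [segment_relative_brightness()] result with n = 3
#' @return object of class `endler_locus`: `X1` chroma, `X2` hue (radians),
#'   `X3` brightness, `hue_defined` logical, `partition`
#' @export
endler_locus <- function(sb) {
  stopifnot(inherits(sb, "segment_brightness"))
  if (sb$partition$n != 3L) {
    stop("segment classification defined for trichromatic case (n = 3)", call. = FALSE)
  }
  S <- sb$S
  B <- S[[1L]]; G <- S[[2L]]; Y <- S[[3L]]; R <- S[[4L]]
  X1 <- sqrt((R - G)^2 + (Y - B)^2)
  hue_defined <- X1 > 0
  if (!hue_defined) {
    X2 <- 0
  } else {
    t <- (Y - B) / X1
    t <- max(-1, min(1, t))  # clamp rounding noise
    X2 <- if (R >= G && Y >= B) asin(t)
          else if (R >= G) asin(t) + 2 * pi
          else pi - asin(t)
  }
  structure(list(X1 = X1, X2 = X2, X3 = sb$beta, hue_defined = hue_defined,
                 partition = sb$partition),
            class = "endler_locus")
}

#' @export
print.endler_locus <- function(x, ...) {
  cat(sprintf("<endler_locus> X1 (chroma) = %.5g, X2 (hue) = %.5g rad%s, X3 (brightness) = %.6g\n",
              x$X1, x$X2, if (x$hue_defined) "" else " [hue undefined]", x$X3))
  invisible(x)
}

#' Chromatic distance between segment classification loci
#'
#' The loci are polar, so the Euclidean distance in the underlying chromatic
#' plane follows the law of cosines rather than the Pythagorean rule:
#' sqrt(X1a^2 + X1b^2 - 2 X1a X1b cos(X2a - X2b)). Identical to the Cartesian
#' distance between the corresponding (Z1, Z2) pairs.
#'
#' @param a,b [endler_locus()] objects on the same partition
#' @return chromatic distance (dimensionless)
#' @export
endler_chromatic_distance <- function(a, b) {
  stopifnot(inherits(a, "endler_locus"), inherits(b, "endler_locus"))
  d2 <- a$X1^2 + b$X1^2 - 2 * a$X1 * b$X1 * cos(a$X2 - b$X2)
  sqrt(max(d2, 0))
}

#' Achromatic (brightness) distance between segment classification loci
#'
#' In the original scheme the brightness difference is reported separately
#' from the chromatic distance: |X3a - X3b|. Note X3 is a raw photon-flux sum
#' and therefore bin-width dependent; compare only loci computed on one grid.
#'
#' @param a,b [endler_locus()] objects
#' @return |X3a - X3b|
#' @export
endler_achromatic_distance <- function(a, b) {
  stopifnot(inherits(a, "endler_locus"), inherits(b, "endler_locus"))
  abs(a$X3 - b$X3)
}

nsc_variants <- c("standard", "normalized")

#' NSC locus of a radiance spectrum
#'
#' The normalized segment classification coordinates. With n + 1 relative
#' segment brightnesses S_1..S_{n+1}, the n - 1 chromatic coordinates are
#' Z_i = S_{i+2} - S_i (differences of next-but-one segments, approximating
#' color-opponent mechanisms), and the achromatic coordinate is Z_n =
#' beta / beta_m, brightness relative to the white standard under the same
#' illuminant, bounded in (0, 1] for reflectances <= 1. For n = 3 this gives
#' Z1 = Y - B, Z2 = R - G, Z3 = beta/beta_m; chromatic coordinate i compares
#' the segments flanking receptor pair (i, i+1), so Z1 tracks the M-vs-S and
#' Z2 the L-vs-M opponent mechanism. (Trichromatic treatments often list
#' R - G first; that is a coordinate permutation with identical distances.)
#'
#' The `"normalized"` variant rescales each chromatic coordinate by its
#' segment-pair total, Z_i = 2 (S_{i+2} - S_i) / (S_{i+2} + S_i), bounding it
#' in \[-2, 2\]. This removes dependence on the relative brightness of the two
#' segments, at the cost of magnifying irrelevant differences when the
#' denominator is small; a near-zero denominator (< 1e-9) is an error naming
#' the offending coordinate.
#'
#' @param l radiance [spectrum()]
#' @param d illuminant [spectrum()] defining the white standard (same grid
#'   convention as `l`)
#' @param p [segment_partition()]
#' @param variant `"standard"` (default) or `"normalized"`
#' @return object of class `nsc_locus`: `Z` (length n, last entry achromatic),
#'   `variant`, `partition`, `illum_id` (fingerprint of the illuminant; loci
#'   under different illuminants are not comparable and [nsc_distance()]
#'   refuses them)
#' @export
nsc_locus <- function(l, d, p = segment_partition(),
                      variant = c("standard", "normalized")) {
  variant <- match.arg(variant)
  stopifnot(inherits(d, "spectrum"))
  sb <- segment_relative_brightness(l, p)
  beta_m <- white_standard_brightness(d, p)
  if (beta_m < sb$beta - 1e-9 * beta_m) {
    warning("beta exceeds white-standard brightness (reflectance > 1 somewhere?)",
            call. = FALSE)
  }
  sb$beta_m <- beta_m
  z <- nsc_coordinates(sb, variant)
  structure(list(Z = z, variant = variant, partition = p,
                 illum_id = illum_fingerprint(d), name = l$name),
            class = "nsc_locus")
}

# chromatic + achromatic coordinates from a segment_brightness with beta_m set
nsc_coordinates <- function(sb, variant) {
  S <- unname(sb$S)
  n <- sb$partition$n
  i <- seq_len(n - 1L)
  if (variant == "standard") {
    zc <- S[i + 2L] - S[i]
  } else {
    den <- S[i + 2L] + S[i]
    bad <- which(den < 1e-9)
    if (length(bad)) {
      stop(sprintf(
        "normalized variant undefined: denominator S_%d + S_%d below 1e-9 for chromatic coordinate Z%d",
        bad[1L] + 2L, bad[1L], bad[1L]), call. = FALSE)
    }
    zc <- 2 * (S[i + 2L] - S[i]) / den
  }
  if (is.na(sb$beta_m)) stop("beta_m not set; supply an illuminant", call. = FALSE)
  c(zc, sb$beta / sb$beta_m)
}

illum_fingerprint <- function(d) {
  paste0(d$wl[1L], ":", d$wl[length(d$wl)], ":",
         format(sum(d$values), digits = 15), ":",
         format(sum(d$values * d$wl), digits = 15))
}

#' @export
print.nsc_locus <- function(x, ...) {
  cat(sprintf("<nsc_locus:%s>%s Z = (%s)\n", x$variant,
              if (is.null(x$name)) "" else paste0(" '", x$name, "'"),
              paste(format(x$Z, digits = 5), collapse = ", ")))
  invisible(x)
}

#' NSC distance between two loci
#'
#' Euclidean distance over the chromatic coordinates plus an alpha-weighted
#' achromatic term: sqrt(sum_i (Z_ai - Z_bi)^2 + alpha (Z_an - Z_bn)^2).
#' `alpha = 1` (default) is the proposed NSC model; `alpha = 0` discards
#' brightness and recovers the chromatic part of the original segment
#' classification scheme. Loci must share variant, partition, and illuminant.
#'
#' @param a,b [nsc_locus()] objects
#' @param alpha achromatic weight >= 0 (default 1)
#' @return distance (dimensionless)
#' @export
nsc_distance <- function(a, b, alpha = 1) {
  stopifnot(inherits(a, "nsc_locus"), inherits(b, "nsc_locus"))
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (a$variant != b$variant) {
    stop("mismatched NSC variants: ", a$variant, " vs ", b$variant, call. = FALSE)
  }
  if (!same_partition(a$partition, b$partition)) {
    stop("mismatched segment partitions", call. = FALSE)
  }
  if (!identical(a$illum_id, b$illum_id)) {
    stop("loci computed under different illuminants are not comparable",
         call. = FALSE)
  }
  n <- length(a$Z)
  dz <- a$Z - b$Z
  sqrt(sum(dz[-n]^2) + alpha * dz[n]^2)
}

#' Pairwise NSC distance matrix
#'
#' Convenience wrapper applying [nsc_distance()] to every pair of a list of
#' loci.
#'
#' @param loci named list of [nsc_locus()] objects
#' @param alpha achromatic weight, see [nsc_distance()]
#' @return symmetric matrix of distances
#' @export
nsc_distance_matrix <- function(loci, alpha = 1) {
  k <- length(loci)
  m <- matrix(0, k, k, dimnames = list(names(loci), names(loci)))
  if (k < 2L) return(m)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      m[i, j] <- m[j, i] <- nsc_distance(loci[[i]], loci[[j]], alpha)
    }
  }
  m
}
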