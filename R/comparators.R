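#' Photoreceptor excitations from rectangular sensitivities
#'
#' A deliberately rough approximation tying the segment scheme to receptor
#' physiology: for a trichromat with evenly spaced receptor peaks and
#' rectangular (box) sensitivity curves spanning two adjacent segments each,
#' with linear transduction, the excitations are E_S = B + G, E_M = G + Y,
#' E_L = Y + R. Under this approximation the opponent differences are exactly
#' the NSC chromatic coordinates: E_L - E_M = R - G = Z1 and E_M - E_S =
#' Y - B = Z2.
#'
#' @param sb [segment_relative_brightness()] result with n = 3 (four segments)
#' @return object of class `excitations`: numeric `E` named (E_S, E_M, E_L)
#' @export
rect_excitations <- function(sb) {
  stopifnot(inherits(sb, "segment_brightness"))
  if (length(sb$S) != 4L) {
    stop("rectangular excitation approximation needs exactly 4 segments (n = 3)",
         call. = FALSE)
  }
  S <- unname(sb$S)
  excitations(c(S[1L] + S[2L], S[2L] + S[3L], S[3L] + S[4L]))
}

#' Photoreceptor excitation vector
#'
#' @param E non-negative numeric vector of excitations, ordered from shortest
#'   to longest peak wavelength (E_S, E_M, E_L for a trichromat)
#' @return object of class `excitations`
#' @export
excitations <- function(E) {
  E <- as.numeric(E)
  if (anyNA(E)) stop("NA excitations", call. = FALSE)
  if (any(E < 0)) stop("excitations must be non-negative", call. = FALSE)
  if (length(E) == 3L) names(E) <- c("E_S", "E_M", "E_L")
  structure(list(E = E), class = "excitations")
}

#' @export
print.excitations <- function(x, ...) {
  cat("<excitations>", paste(format(x$E, digits = 5), collapse = " "), "\n")
  invisible(x)
}

#' Color-opponent mechanism
#'
#' A linear combination M(E) = sum(c_i E_i) qualifies as a color-opponent
#' mechanism only if its coefficients sum to zero, so that uniform excitation
#' produces no signal. Returns a callable mechanism.
#'
#' @param coef coefficient vector, must sum to 0 (tolerance 1e-12 relative to
#'   coefficient magnitude)
#' @return object of class `opponent_mechanism`; call it on an
#'   [excitations()] object or bare numeric vector
#' @examples
#' m <- make_opponent(c(-9.86, 7.70, 2.16))
#' m(excitations(c(1, 1, 1))) # 0
#' @export
make_opponent <- function(coef) {
  coef <- as.numeric(coef)
  scale <- max(abs(coef), 1)
  if (abs(sum(coef)) > 1e-12 * scale) {
    stop("not color-opponent: coefficients must sum to zero", call. = FALSE)
  }
  f <- function(e) {
    E <- if (inherits(e, "excitations")) e$E else as.numeric(e)
    if (length(E) != length(coef)) {
      stop("excitation length does not match mechanism", call. = FALSE)
    }
    sum(coef * E)
  }
  structure(f, coef = coef, class = c("opponent_mechanism", "function"))
}

as_excitation_vector <- function(e, n = 3L) {
  E <- if (inherits(e, "excitations")) e$E else as.numeric(e)
  if (length(E) != n) stop(sprintf("need %d excitations", n), call. = FALSE)
  unname(E)
}

# Backhaus color-opponent coding coefficients (honeybee)
.coc_A <- c(-9.86, 7.70, 2.16)
.coc_B <- c(-5.17, 20.25, -15.08)

#' Color-opponent coding (COC) locus and distance
#'
#' The honeybee color-opponent coding model places each color at
#' (A, B) = (-9.86 E_S + 7.70 E_M + 2.16 E_L,
#'           -5.17 E_S + 20.25 E_M - 15.08 E_L)
#' and measures perceptual difference with the city-block metric
#' |dA| + |dB|. Both coefficient rows sum to zero, so equal excitations map
#' to the origin.
#'
#' @param e [excitations()] (3 receptor types)
#' @return `coc_locus`: object of class `coc_locus` with fields `A`, `B`
#' @export
coc_locus <- function(e) {
  E <- as_excitation_vector(e)
  structure(list(A = sum(.coc_A * E), B = sum(.coc_B * E)),
            class = "coc_locus")
}

#' @rdname coc_locus
#' @param a,b `coc_locus` objects
#' @return `coc_distance`: city-block distance |dA| + |dB|
#' @export
coc_distance <- function(a, b) {
  stopifnot(inherits(a, "coc_locus"), inherits(b, "coc_locus"))
  abs(a$A - b$A) + abs(a$B - b$B)
}

#' Color hexagon locus and distance
#'
#' The color hexagon model for trichromatic Hymenoptera uses the opponent
#' pair X = sqrt(3) (E_L - E_S) / 2, Y = E_M - (E_S + E_L) / 2 and Euclidean
#' distance in hexagon units. (Some flattened renderings of the X equation
#' drop the radical and read "3 (E_L - E_S) / 2"; the sqrt(3) form of the
#' original hexagon model is implemented here.)
#'
#' @param e [excitations()] (3 receptor types)
#' @return `hexagon_locus`: object of class `hexagon_locus` with fields `X`, `Y`
#' @export
hexagon_locus <- function(e) {
  E <- as_excitation_vector(e)
  structure(list(X = sqrt(3) * (E[3L] - E[1L]) / 2,
                 Y = E[2L] - 0.5 * (E[1L] + E[3L])),
            class = "hexagon_locus")
}

#' @rdname hexagon_locus
#' @param a,b `hexagon_locus` objects
#' @return `hexagon_distance`: Euclidean distance in hexagon units
#' @export
hexagon_distance <- function(a, b) {
  stopifnot(inherits(a, "hexagon_locus"), inherits(b, "hexagon_locus"))
  sqrt((a$X - b$X)^2 + (a$Y - b$Y)^2)
}

#' Receptor-noise-limited model parameters
#'
#' The receptor-noise-limited (RN) locus coordinates depend on four positive
#' species-specific constants derived from receptor noise levels. No defaults
#' are provided: they must come from the species under study.
#'
#' @param A,B,a,b positive reals
#' @return object of class `rn_params`
#' @export
rn_params <- function(A, B, a, b) {
  vals <- c(A = A, B = B, a = a, b = b)
  if (anyNA(vals) || length(vals) != 4L) {
    stop("missing RN parameters: supply A, B, a, b", call. = FALSE)
  }
  if (any(vals <= 0)) stop("RN parameters must be positive", call. = FALSE)
  structure(as.list(vals), class = "rn_params")
}

#' Receptor-noise-limited locus and distance
#'
#' Trichromatic RN loci: X = A (E_L - E_M), Y = B (E_S - (a E_L + b E_M)),
#' with Euclidean distance. The model is often applied to log-transformed
#' excitations ("logarithmic version"); apply the transform to E before
#' calling, e.g. `rn_locus(excitations(log(E)), p)` — the locus itself is
#' always linear in whatever excitations it is given. Note X is proportional
#' to the NSC Z1 coordinate under the rectangular-sensitivity approximation.
#'
#' @param e [excitations()] (3 receptor types)
#' @param p [rn_params()]
#' @return `rn_locus`: object of class `rn_locus` with fields `X`, `Y`
#' @export
rn_locus <- function(e, p) {
  if (missing(p) || !inherits(p, "rn_params")) {
    stop("missing RN parameters: supply rn_params(A, B, a, b)", call. = FALSE)
  }
  E <- as_excitation_vector(e)
  structure(list(X = p$A * (E[3L] - E[2L]),
                 Y = p$B * (E[1L] - (p$a * E[3L] + p$b * E[2L]))),
            class = "rn_locus")
}

#' @rdname rn_locus
#' @param a,b `rn_locus` objects
#' @return `rn_distance`: Euclidean distance
#' @export
rn_distance <- function(a, b) {
  stopifnot(inherits(a, "rn_locus"), inherits(b, "rn_locus"))
  sqrt((a$X - b$X)^2 + (a$Y - b$Y)^2)
}
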