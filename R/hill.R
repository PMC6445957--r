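#' Hill-type transcription rate with basal activity
#'
#' Transcription of a gene activated by a modifier `mod` follows
#' \deqn{v = V_{max} \left(\frac{1}{a} + \left(1 - \frac{1}{a}\right)
#'   \frac{mod^h}{mod^h + M_0^h}\right)}
#' so that transcription never stops completely: with no activator the rate is
#' the basal rate \eqn{V_{max}/a}, and upon full activation it saturates at
#' \eqn{V_{max}}. `a` is the fold increase in transcription upon activation,
#' `m0` the modifier amount at half-activation and `h` the Hill exponent
#' (default 2).
#'
#' @param mod Modifier (activator) amount, particles per cell, `>= 0`.
#' @param vmax Maximal transcription rate, particles per hour, `>= 0`.
#' @param a Fold activation, `>= 1`. `a = 1` gives a constant rate `vmax`.
#' @param m0 Half-activation amount, `> 0`.
#' @param h Hill exponent, `> 0`.
#' @return Transcription rate in particles/h, bounded in `[vmax/a, vmax]` and
#'   monotone nondecreasing in `mod`. Vectorised over `mod`.
#' @seealso [hill_repression()] for the mirrored decreasing form.
#' @examples
#' hill_transcription(0, vmax = 10, a = 5, m0 = 1)   # basal rate 2
#' hill_transcription(1, vmax = 10, a = 5, m0 = 1)   # half-activation: 6
#' @export
hill_transcription <- function(mod, vmax, a, m0, h = 2) {
  check_hill_args(mod, vmax, a, m0, h)
  mh <- mod^h
  vmax * (1 / a + (1 - 1 / a) * mh / (mh + m0^h))
}

#' Hill-type transcription rate under repression
#'
#' Decreasing mirror of [hill_transcription()]: with no repressor the gene is
#' transcribed at `vmax`; a saturating repressor reduces the rate to the floor
#' `vmax / a`. The two forms share the same parameters and bounds, so basal
#' and maximal rates remain interpretable in both directions of regulation.
#'
#' @inheritParams hill_transcription
#' @param mod Repressor amount, `>= 0`.
#' @return Rate in particles/h, bounded in `[vmax/a, vmax]`, monotone
#'   nonincreasing in `mod`.
#' @examples
#' hill_repression(0, vmax = 10, a = 5, m0 = 1)    # unrepressed: 10
#' hill_repression(1e9, vmax = 10, a = 5, m0 = 1)  # floor ~ 2
#' @export
hill_repression <- function(mod, vmax, a, m0, h = 2) {
  check_hill_args(mod, vmax, a, m0, h)
  mh <- m0^h
  vmax * (1 / a + (1 - 1 / a) * mh / (mod^h + mh))
}

check_hill_args <- function(mod, vmax, a, m0, h) {
  if (any(!is.finite(mod)) || any(mod < 0)) {
    stop("modifier amount must be finite and >= 0", call. = FALSE)
  }
  if (!is.finite(vmax) || vmax < 0) stop("vmax must be >= 0", call. = FALSE)
  if (!is.finite(a) || a < 1) stop("fold activation a must be >= 1", call. = FALSE)
  if (!is.finite(m0) || m0 <= 0) stop("m0 must be > 0", call. = FALSE)
  if (!is.finite(h) || h <= 0) stop("h must be > 0", call. = FALSE)
  invisible(TRUE)
}
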