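#' @title Two-rater agreement result
#'
#' @description S4 record of a Cohen's kappa computation between two
#' binary raters: the label vectors, observed and chance-expected
#' agreement, kappa, its interpretation band, and a flag for degenerate
#' (constant-rater) inputs.
#'
#' @slot labelsA,labelsB the two 0/1 label vectors.
#' @slot pObserved observed agreement in `[0, 1]`.
#' @slot pExpected chance-expected agreement in `[0, 1]`.
#' @slot kappa Cohen's kappa in `[-1, 1]`.
#' @slot band interpretation band (see [interpretKappa()]).
#' @slot degenerate `TRUE` when both raters are constant.
#' @export
setClass("AgreementResult",
  representation(labelsA = "integer", labelsB = "integer",
                 pObserved = "numeric", pExpected = "numeric",
                 kappa = "numeric", band = "character",
                 degenerate = "logical"),
  validity = function(object) {
    msgs <- character()
    if (length(object@labelsA) != length(object@labelsB))
      msgs <- c(msgs, "label vectors must have equal length")
    if (!isProb(object@pObserved)) msgs <- c(msgs, "pObserved must be in [0, 1]")
    if (!isProb(object@pExpected)) msgs <- c(msgs, "pExpected must be in [0, 1]")
    if (!is.finite(object@kappa) || abs(object@kappa) > 1 + 1e-12)
      msgs <- c(msgs, "kappa must be in [-1, 1]")
    if (length(msgs)) msgs else TRUE
  })

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf("AgreementResult: n = %d, po = %.4f, pe = %.4f\n",
              length(object@labelsA), object@pObserved, object@pExpected))
  cat(sprintf("  kappa = %.4f (%s)%s\n", object@kappa, object@band,
              if (object@degenerate) " [degenerate: constant raters]" else ""))
})

#' @describeIn AgreementResult-class Cohen's kappa value.
#' @param x an `AgreementResult`.
#' @export
kappaValue <- function(x) { stopIfNot(is(x, "AgreementResult"), "not an AgreementResult"); x@kappa }

#' @describeIn AgreementResult-class interpretation band.
#' @export
agreementBand <- function(x) { stopIfNot(is(x, "AgreementResult"), "not an AgreementResult"); x@band }

#' @describeIn AgreementResult-class observed agreement.
#' @export
observedAgreement <- function(x) { stopIfNot(is(x, "AgreementResult"), "not an AgreementResult"); x@pObserved }

#' @describeIn AgreementResult-class chance-expected agreement.
#' @export
expectedAgreement <- function(x) { stopIfNot(is(x, "AgreementResult"), "not an AgreementResult"); x@pExpected }

#' @describeIn AgreementResult-class degenerate-input flag.
#' @export
isDegenerate <- function(x) { stopIfNot(is(x, "AgreementResult"), "not an AgreementResult"); x@degenerate }

#' Binarize an engagement percentage at the 50% threshold
#'
#' A session (or child) counts as engaged when its engagement percentage
#' is 50% or above; the threshold is inclusive.
#'
#' @param percent numeric vector of percentages in `[0, 100]`.
#' @return an integer vector of labels (1 = engaged, 0 = not engaged).
#' @examples
#' binarizeEngagement(c(84, 14, 41, 15, 9))  # 1 0 0 0 0
#' binarizeEngagement(50)                    # inclusive threshold -> 1
#' @export
binarizeEngagement <- function(percent) {
  stopIfNot(is.numeric(percent) && length(percent) >= 1,
            "percent must be numeric")
  if (any(!is.finite(percent)) || any(percent < 0 | percent > 100)) {
    stop("percentages must be finite and in [0, 100]", call. = FALSE)
  }
  as.integer(percent >= 50)
}

coerceBinary <- function(x, what) {
  if (is.factor(x)) x <- x == levels(x)[2]
  if (is.logical(x)) x <- as.integer(x)
  stopIfNot(is.numeric(x) && all(x %in% c(0, 1)),
            sprintf("%s must be binary (0/1, logical, or 2-level factor)", what))
  as.integer(x)
}

#' Cohen's kappa between two binary raters
#'
#' Standard two-rater kappa from the 2x2 contingency table:
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po` and
#' chance-expected agreement `pe` from the marginal label rates.
#' Degenerate inputs, which small studies hit easily, are defined
#' explicitly rather than erroring: when both raters are constant and
#' identical (`pe = 1`), kappa is 1; when both are constant but different,
#' the formula yields 0; both cases carry `degenerate = TRUE`.
#'
#' @param a,b equal-length binary label vectors (length >= 2).
#' @return an [AgreementResult-class].
#' @examples
#' r <- cohenKappa(c(1, 0, 0, 0, 0), c(1, 0, 0, 0, 0))
#' kappaValue(r)       # 1
#' agreementBand(r)    # "almost_perfect"
#' @export
cohenKappa <- function(a, b) {
  a <- coerceBinary(a, "a")
  b <- coerceBinary(b, "b")
  n <- length(a)
  stopIfNot(n == length(b), "label vectors must have equal length")
  stopIfNot(n >= 2, "at least two paired labels are required")
  po <- mean(a == b)
  pA1 <- mean(a); pB1 <- mean(b)
  pe <- pA1 * pB1 + (1 - pA1) * (1 - pB1)
  degenerate <- (pA1 %in% c(0, 1)) && (pB1 %in% c(0, 1))
  kappa <- if (pe >= 1) 1 else (po - pe) / (1 - pe)
  new("AgreementResult", labelsA = a, labelsB = b,
      pObserved = po, pExpected = pe, kappa = kappa,
      band = interpretKappa(kappa), degenerate = degenerate)
}

#' Interpret a kappa value on the standard agreement bands
#'
#' Bands: kappa <= 0 `no_agreement`; 0.01-0.20 `slight`; 0.21-0.40 `fair`;
#' 0.41-0.60 `moderate`; 0.61-0.80 `substantial`; 0.81-1.00
#' `almost_perfect`. Values in (0, 0.01), which the printed bands leave
#' unassigned, map to `slight` by continuity; comparisons use the
#' unrounded kappa.
#'
#' @param kappa numeric kappa values in `[-1, 1]`.
#' @return a character vector of band names.
#' @examples
#' interpretKappa(c(0.10, 0.50, -0.30))
#' @export
interpretKappa <- function(kappa) {
  stopIfNot(is.numeric(kappa) && all(is.finite(kappa)),
            "kappa must be numeric and finite")
  if (any(kappa < -1 - 1e-12 | kappa > 1 + 1e-12)) {
    stop("kappa must be in [-1, 1]", call. = FALSE)
  }
  vapply(kappa, function(k) {
    if (k <= 0) "no_agreement"
    else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else "almost_perfect"
  }, character(1))
}
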