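## Shared constants and small numeric helpers.

## Proton mass convention used throughout: ion m/z = neutral monoisotopic
## mass + 1.00728 Da (electron mass ignored; the resulting bias is < 8 ppm
## below m/z 80, well inside every tolerance used here).
.PROTON_MASS <- 1.00728

## Monoisotopic atomic masses (Da), CODATA/IUPAC values.
.ATOMIC_MASSES <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  F  = 18.99840322,
  Cl = 34.96885268,
  Na = 22.9897692809,
  Br = 78.9183371
)

#' Monoisotopic atomic masses
#'
#' Named vector of monoisotopic masses (Da) for the elements supported by
#' [enumerateFormulas()]: C, H, N, O, P, S, F, Cl, Na, Br.
#'
#' @return Named numeric vector of masses in Da.
#' @export
#' @examples
#' atomicMasses()[["C"]]
atomicMasses <- function() .ATOMIC_MASSES

#' Monoisotopic mass of an elemental composition
#'
#' @param counts Named integer vector of element counts, e.g.
#'   `c(C = 5, H = 8)`.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' formulaMass(c(C = 5, H = 8)) # isoprene
formulaMass <- function(counts) {
  counts <- counts[counts != 0]
  if (length(counts) == 0L) return(0)
  bad <- setdiff(names(counts), names(.ATOMIC_MASSES))
  if (length(bad)) stop("unknown element(s): ", paste(bad, collapse = ", "))
  sum(.ATOMIC_MASSES[names(counts)] * counts)
}

#' Mass-dependent alignment tolerance
#'
#' Linear interpolation of the absolute m/z tolerance used for cross-sample
#' feature alignment and calibrant matching, from `tolLow` Da at `mzLow` to
#' `tolHigh` Da at `mzHigh` (clamped outside that range). The endpoints
#' approximate constant relative resolution across the acquisition range.
#'
#' @param mz Numeric vector of m/z values (Da).
#' @param tolLow,tolHigh Tolerances (Da) at the low and high anchor masses.
#' @param mzLow,mzHigh Anchor masses (Da).
#' @return Numeric vector of tolerances (Da).
#' @export
#' @examples
#' massTolerance(c(42, 363.5, 685))
massTolerance <- function(mz, tolLow = 0.015, tolHigh = 0.4,
                          mzLow = 42, mzHigh = 685) {
  frac <- (pmin(pmax(mz, mzLow), mzHigh) - mzLow) / (mzHigh - mzLow)
  tolLow + frac * (tolHigh - tolLow)
}

## ppm error convention: (theoretical - measured) / theoretical * 1e6, signed.
.ppmError <- function(theoretical, measured) {
  (theoretical - measured) / theoretical * 1e6
}

## Local maxima over a +/- k neighbourhood; the first index of a plateau
## counts as the maximum, but a maximum must rise above at least one
## neighbour (an all-flat window is not a peak). Differences below a small
## relative tolerance count as ties, so numerically flat segments (e.g.
## smoothing round-off) do not spawn spurious peaks.
.localMaxima <- function(x, k = 2L) {
  n <- length(x)
  out <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - k); hi <- min(n, i + k)
    w <- x[lo:hi]
    tol <- 1e-8 * max(abs(w), 1e-300)
    if (x[i] < max(w) - tol) next
    if (!any(w < x[i] - tol)) next           # flat window: no peak
    before <- if (i > lo) x[lo:(i - 1L)] else numeric(0)
    if (any(before >= x[i] - tol)) next      # plateau: first index only
    out[i] <- TRUE
  }
  out
}

## Savitzky-Golay smoothing with a guard for short vectors.
.sgSmooth <- function(x, window = 5L, order = 2L) {
  if (length(x) < window || window < 3L) return(x)
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}
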