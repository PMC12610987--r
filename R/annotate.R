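## Chemical hypothesis generation for aligned features: neutral masses,
## library matching, exhaustive elemental-composition enumeration, and
## isotopologue flagging. All annotations are hypotheses; structural
## confirmation (e.g. targeted MS/MS) is outside this package's scope.

#' Neutral mass of a protonated ion
#'
#' All ions are assumed singly protonated; the neutral monoisotopic mass is
#' `m/z - 1.00728` Da (electron mass ignored).
#'
#' @param mz Ion m/z (Da), vectorized.
#' @return Neutral mass (Da).
#' @export
#' @examples
#' neutralMass(79.054)
neutralMass <- function(mz) {
  if (any(mz <= .PROTON_MASS))
    stop("domain error: m/z must exceed the proton mass (1.00728 Da)")
  mz - .PROTON_MASS
}

#' Bundled VOC reference library
#'
#' Small curated table of exhaled-breath compounds (name, formula, neutral
#' monoisotopic mass computed from atomic masses). Users may supply their
#' own two-column table to [matchLibrary()].
#'
#' @return Data frame with columns `name`, `formula`, `neutral_mass`.
#' @export
defaultVOCLibrary <- function() {
  read.csv(system.file("extdata", "voc_library.csv", package = "breathVOC",
                       mustWork = TRUE), stringsAsFactors = FALSE)
}

.candidateFrame <- function(featureMz, neutralMass, kind, nameOrFormula,
                            theoreticalMz, errorPpm) {
  data.frame(feature_mz = featureMz, neutral_mass = neutralMass,
             kind = kind, name_or_formula = nameOrFormula,
             theoretical_mz = theoreticalMz, error_ppm = errorPpm,
             stringsAsFactors = FALSE)
}

#' Match a feature against a compound library
#'
#' Assumes protonation: each library entry's theoretical ion mass is its
#' neutral mass + 1.00728 Da. Entries within `tolPpm` of the observed m/z
#' are returned sorted by absolute ppm error (signed convention:
#' `(theoretical - measured) / theoretical * 1e6`).
#'
#' @param mz Observed feature m/z (Da).
#' @param library Data frame with columns `name` and `neutral_mass`
#'   (default [defaultVOCLibrary()]).
#' @param tolPpm Match tolerance in ppm (default 200).
#' @return Data frame of annotation candidates (possibly zero rows) with
#'   columns `feature_mz`, `neutral_mass`, `kind`, `name_or_formula`,
#'   `theoretical_mz`, `error_ppm`.
#' @export
#' @examples
#' matchLibrary(77.059)
matchLibrary <- function(mz, library = defaultVOCLibrary(), tolPpm = 200) {
  stopifnot(length(mz) == 1L, nrow(library) > 0L)
  theo <- library$neutral_mass + .PROTON_MASS
  ppm <- .ppmError(theo, mz)
  keep <- abs(ppm) <= tolPpm
  out <- .candidateFrame(mz, neutralMass(mz), "library_match",
                         library$name, theo, ppm)[keep, , drop = FALSE]
  out <- out[order(abs(out$error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.formulaString <- function(counts) {
  counts <- counts[counts > 0]
  ## Hill order: C, H, then alphabetical
  ord <- c("C", "H", sort(setdiff(names(counts), c("C", "H"))))
  ord <- ord[ord %in% names(counts)]
  paste0(vapply(ord, function(e)
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]]), character(1)),
    collapse = "")
}

## Chemical plausibility: ring-plus-double-bond equivalents >= 0 and
## integer (even-electron neutral species); H + monovalent substituents
## bounded by 2C + 2 + N; Na only as a substituent on a carbon skeleton.
.isPlausible <- function(cnt) {
  x <- cnt[["F"]] + cnt[["Cl"]] + cnt[["Br"]] + cnt[["Na"]]
  rdbe <- cnt[["C"]] + 1 - (cnt[["H"]] + x) / 2 +
    (cnt[["N"]] + cnt[["P"]]) / 2
  if (rdbe < 0) return(FALSE)
  if (abs(rdbe - round(rdbe)) > 1e-9) return(FALSE)
  if (cnt[["H"]] + x > 2 * cnt[["C"]] + 2 + cnt[["N"]]) return(FALSE)
  if (cnt[["Na"]] > 0 && cnt[["C"]] == 0) return(FALSE)
  sum(cnt) >= 1
}

#' Exhaustively enumerate elemental compositions for a neutral mass
#'
#' Depth-first search over bounded element counts with mass-window pruning,
#' followed by a chemical plausibility filter (RDBE >= 0 and integer,
#' `H + halogens + Na <= 2C + 2 + N`, Na only on a carbon skeleton).
#' Candidates are returned sorted by absolute ppm error; results at a
#' tighter tolerance are always a subset of results at a looser one.
#'
#' @param mass Target neutral monoisotopic mass (Da).
#' @param elements Elements to consider, a subset of
#'   C, H, N, O, P, S, F, Cl, Na, Br (default CHNOPS).
#' @param tolPpm Tolerance in ppm (default 10; the working range is 5-10).
#' @param maxCounts Named integer vector of per-element count ceilings. By
#'   default each ceiling is derived from the target mass
#'   (`floor(mass / element mass)`), which keeps the search bounded; an
#'   explicit non-finite ceiling is a config error.
#' @return Data frame of candidates in the [matchLibrary()] layout with
#'   `kind = "formula"` and `name_or_formula` in Hill notation.
#' @export
#' @examples
#' enumerateFormulas(68.0626, tolPpm = 10)  # includes C5H8 (isoprene)
enumerateFormulas <- function(mass, elements = c("C", "H", "N", "O", "P",
                                                 "S"),
                              tolPpm = 10, maxCounts = NULL) {
  stopifnot(mass > 0)
  elements <- match.arg(elements, names(.ATOMIC_MASSES),
                        several.ok = TRUE)
  if (is.null(maxCounts)) {
    maxCounts <- setNames(
      pmax(floor(mass * (1 + tolPpm * 1e-6) / .ATOMIC_MASSES[elements]), 0L),
      elements)
  }
  if (any(!is.finite(maxCounts)))
    stop("config error: max_counts must be finite for every element")
  missing <- setdiff(elements, names(maxCounts))
  if (length(missing))
    stop("config error: max_counts missing for element(s): ",
         paste(missing, collapse = ", "))
  lo <- mass * (1 - tolPpm * 1e-6)
  hi <- mass * (1 + tolPpm * 1e-6)

  ## heaviest elements first so pruning bites early
  searchOrder <- elements[order(.ATOMIC_MASSES[elements],
                                decreasing = TRUE)]
  results <- list()
  counts <- setNames(integer(length(.ATOMIC_MASSES)),
                     names(.ATOMIC_MASSES))
  minMass <- min(.ATOMIC_MASSES[elements])
  recurse <- function(depth, acc) {
    if (acc > hi) return()
    if (depth > length(searchOrder)) {
      if (acc >= lo && .isPlausible(counts)) {
        cnt <- counts
        results[[length(results) + 1L]] <<- list(counts = cnt, mass = acc)
      }
      return()
    }
    el <- searchOrder[depth]
    m <- .ATOMIC_MASSES[[el]]
    for (k in 0:min(maxCounts[[el]], floor((hi - acc) / m))) {
      counts[[el]] <<- k
      recurse(depth + 1L, acc + k * m)
    }
    counts[[el]] <<- 0L
  }
  recurse(1L, 0)

  if (!length(results))
    return(.candidateFrame(numeric(0), numeric(0), character(0),
                           character(0), numeric(0), numeric(0)))
  masses <- vapply(results, `[[`, numeric(1), "mass")
  formulas <- vapply(results, function(r) .formulaString(r$counts),
                     character(1))
  ppm <- .ppmError(masses, mass)
  out <- .candidateFrame(mass + .PROTON_MASS, mass, "formula", formulas,
                         masses + .PROTON_MASS, ppm)
  out <- out[order(abs(out$error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag likely 13C isotopologue features
#'
#' A feature B is flagged as the first 13C isotopologue of a lighter feature
#' A iff (a) `mz_B - mz_A` lies within `tol` Da of the 13C-12C mass
#' difference (1.00336 Da) and (b) the median intensity ratio B/A across
#' samples is consistent with natural 13C abundance (0.0107 per carbon) for
#' some plausible carbon count, i.e. `ratio / 0.0107` lies between 0.5 and
#' `floor(neutral mass / 12) + 0.5`.
#'
#' @param fm A normalized [BreathFeatureSet-class].
#' @param deltaMass Isotopic mass shift (default 1.00336 Da).
#' @param tol Mass-shift tolerance in Da (default 0.003).
#' @param c13Abundance Natural 13C fraction per carbon (default 0.0107).
#' @return Data frame of candidates (`kind = "isotopologue"`); zero rows if
#'   none.
#' @export
flagIsotopologues <- function(fm, deltaMass = 1.00336, tol = 0.003,
                              c13Abundance = 0.0107) {
  stopifnot(is(fm, "BreathFeatureSet"))
  if (!isNormalized(fm))
    stop("flagIsotopologues() expects a normalized feature matrix")
  mzs <- featureMz(fm)
  m <- SummarizedExperiment::assay(fm, "intensity")
  out <- list()
  for (a in seq_along(mzs)) {
    bCand <- which(abs(mzs - mzs[a] - deltaMass) <= tol)
    for (b in bCand) {
      ok <- m[a, ] > 0
      if (!any(ok)) next
      ratio <- median(m[b, ok] / m[a, ok])
      cMax <- max(1, floor(neutralMass(mzs[a]) / .ATOMIC_MASSES[["C"]]))
      nHat <- ratio / c13Abundance
      if (nHat < 0.5 || nHat > cMax + 0.5) next
      expected <- mzs[a] + deltaMass
      out[[length(out) + 1L]] <- .candidateFrame(
        mzs[b], neutralMass(mzs[b]), "isotopologue",
        sprintf("13C isotopologue of m/z %.4f (ratio %.4f, ~%d C)",
                mzs[a], ratio, round(nHat)),
        expected, .ppmError(expected, mzs[b]))
    }
  }
  if (!length(out))
    return(.candidateFrame(numeric(0), numeric(0), character(0),
                           character(0), numeric(0), numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
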