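#' @importFrom stats lm coef residuals setNames
#' @importFrom Biostrings matchPattern
NULL

#' A densitometry band measurement
#'
#' Intensity is in arbitrary densitometry units; ethidium bromide signal
#' is proportional to the mass of double-stranded DNA, so dividing by the
#' product length in bp converts intensity to a molar signal.
#'
#' @param label band label.
#' @param intensity non-negative intensity.
#' @param lengthBp PCR product length in bp (>= 1).
#' @return a list with class `BandMeasurement`.
#' @export
bandMeasurement <- function(label, intensity, lengthBp) {
  intensity <- as.numeric(intensity); lengthBp <- as.integer(lengthBp)
  if (is.na(intensity) || intensity < 0)
    stop("intensity must be >= 0", call. = FALSE)
  if (is.na(lengthBp) || lengthBp < 1L)
    stop("lengthBp must be >= 1", call. = FALSE)
  structure(list(label = as.character(label), intensity = intensity,
                 lengthBp = lengthBp), class = "BandMeasurement")
}

#' Percent exon skipping from gel band intensities
#'
#' Implements the molar-corrected densitometry formula
#' `100 * exclusion / (inclusion + exclusion)` where each band's signal is
#' first divided by its product length in bp. The length division is the
#' ethidium-bromide correction: EtBr fluorescence scales with DNA mass, so
#' equal molar amounts of a long inclusion product and a short exclusion
#' product give unequal raw intensities.
#'
#' @param inclusion,exclusion [bandMeasurement()] objects for the
#'   exon-inclusion and exon-exclusion products.
#' @return percent exon skipping (0-100).
#' @examples
#' percentSkipping(bandMeasurement("incl", 2000, 400),
#'                 bandMeasurement("excl", 500, 200))  # 33.33
#' @export
percentSkipping <- function(inclusion, exclusion) {
  stopifnot(inherits(inclusion, "BandMeasurement"),
            inherits(exclusion, "BandMeasurement"))
  mIncl <- inclusion$intensity / inclusion$lengthBp
  mExcl <- exclusion$intensity / exclusion$lengthBp
  if (mIncl + mExcl == 0)
    stop("percent skipping undefined: both band intensities are zero",
         call. = FALSE)
  100 * mExcl / (mIncl + mExcl)
}

#' @rdname percentSkipping
#' @param intensities,lengthsBp numeric vectors describing all bands in a
#'   lane (e.g. full-length, single-skip and double-skip products).
#' @return `bandPercentages`: the molar percent of each band; the two-band
#'   case reduces to `percentSkipping`.
#' @export
bandPercentages <- function(intensities, lengthsBp) {
  stopifnot(length(intensities) == length(lengthsBp),
            all(intensities >= 0), all(lengthsBp >= 1))
  m <- intensities / lengthsBp
  if (sum(m) == 0)
    stop("band percentages undefined: all intensities are zero",
         call. = FALSE)
  100 * m / sum(m)
}

#' Fit a qPCR relative standard curve
#'
#' Least-squares fit of `ct = slope * log10(quantity) + intercept` over a
#' dilution series, the relative standard curve method. A valid
#' amplification gives a negative slope (about -3.32 at 100% efficiency).
#'
#' @param quantity known input quantities (> 0, at least two distinct).
#' @param ct observed threshold cycles.
#' @return a list with class `StandardCurve`: `slope`, `intercept`,
#'   `residuals`.
#' @export
fitStandardCurve <- function(quantity, ct) {
  stopifnot(length(quantity) == length(ct), length(quantity) >= 2L,
            all(quantity > 0))
  if (length(unique(quantity)) < 2L)
    stop("standard curve needs at least two distinct quantities",
         call. = FALSE)
  fit <- lm(ct ~ log10(quantity))
  curve <- structure(list(slope = unname(coef(fit)[2L]),
                          intercept = unname(coef(fit)[1L]),
                          residuals = unname(residuals(fit))),
                     class = "StandardCurve")
  if (curve$slope >= 0)
    warning("standard curve slope is non-negative; ",
            "check the dilution series")
  curve
}

#' Quantify an unknown from its Ct via the standard curve
#'
#' Inverts the fitted curve, `quantity = 10^((ct - intercept)/slope)`, and
#' divides by the normalizer quantity (e.g. a total-RNA measurement used
#' as loading control).
#'
#' @param ct threshold cycle(s) of the unknown(s).
#' @param curve a [fitStandardCurve()] result (or any list with `slope`
#'   and `intercept`).
#' @param normalizerQuantity positive scalar to normalize by (default 1).
#' @return relative quantity, same length as `ct`.
#' @export
quantifyCt <- function(ct, curve, normalizerQuantity = 1) {
  if (curve$slope == 0)
    stop("standard curve slope is zero; cannot invert", call. = FALSE)
  stopifnot(normalizerQuantity > 0)
  10^((ct - curve$intercept) / curve$slope) / normalizerQuantity
}

#' Map 5' RACE clones to a cleavage-site histogram
#'
#' Each adapter-trimmed clone sequence is anchored by exact match of its
#' first `minAnchor` nucleotides against the transcript: a unique match
#' calls a cleavage site at the clone's 5' end; no match leaves the clone
#' unmapped and multiple matches leave it ambiguous. Exact anchoring (not
#' alignment) is appropriate for Sanger-confirmed clones.
#'
#' @param clones a named character vector or [Biostrings::DNAStringSet]
#'   of clone sequences (adapter already trimmed).
#' @param mature a [MatureTranscript-class] (or `DNAString`/character) to
#'   map against.
#' @param minAnchor anchor length in nt (>= 10; default 15).
#' @return a list with `histogram` (named integer vector, mRNA position ->
#'   clone count), `calls` (per-clone position, `NA` if uncalled), and the
#'   counts `mapped`, `unmapped`, `ambiguous`, `skipped`, `total`.
#'   `mapped + unmapped + ambiguous + skipped == total`.
#' @export
mapRaceClones <- function(clones, mature, minAnchor = 15L) {
  minAnchor <- as.integer(minAnchor)
  if (minAnchor < 10L)
    stop("minAnchor must be >= 10 nt for reliable exact anchoring",
         call. = FALSE)
  target <- if (is(mature, "MatureTranscript")) mature@sequence
            else Biostrings::DNAString(as.character(mature))
  if (is(clones, "DNAStringSet")) clones <- as.character(clones)
  if (is.null(names(clones)))
    names(clones) <- sprintf("clone%d", seq_along(clones))
  calls <- setNames(rep(NA_integer_, length(clones)), names(clones))
  status <- setNames(character(length(clones)), names(clones))
  for (i in seq_along(clones)) {
    cl <- toupper(clones[[i]])
    if (nchar(cl) < minAnchor) {
      warning("clone '", names(clones)[i], "' shorter than minAnchor (",
              minAnchor, " nt); skipped")
      status[i] <- "skipped"
      next
    }
    anchor <- substr(cl, 1L, minAnchor)
    pos <- start(matchPattern(anchor, target))
    if (length(pos) == 1L) {
      calls[i] <- pos
      status[i] <- "mapped"
    } else if (length(pos) == 0L) {
      status[i] <- "unmapped"
    } else {
      status[i] <- "ambiguous"
    }
  }
  called <- sort(calls[!is.na(calls)])
  tab <- table(called)
  histogram <- setNames(as.integer(tab), names(tab))
  list(histogram = histogram, calls = calls,
       mapped = sum(status == "mapped"),
       unmapped = sum(status == "unmapped"),
       ambiguous = sum(status == "ambiguous"),
       skipped = sum(status == "skipped"),
       total = length(clones))
}
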