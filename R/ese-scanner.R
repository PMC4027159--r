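#' @importFrom IRanges IRanges
NULL

#' Position weight matrix for exonic splicing enhancer motifs
#'
#' A plain additive PWM: the score of a window is the sum over positions
#' of the weight of the base observed there, and windows scoring at or
#' above `threshold` are reported. No background model or log-odds
#' preprocessing is applied; matrices such as the SR-protein consensus
#' motifs used by ESE prediction servers are supplied by the user in
#' whatever scale their thresholds are calibrated to.
#'
#' @param name motif name.
#' @param weights a 4 x width numeric matrix with rownames `A,C,G,T`.
#' @param threshold minimum reported score.
#' @return a list with class `Pwm`.
#' @export
pwm <- function(name, weights, threshold) {
  weights <- as.matrix(weights)
  if (nrow(weights) != 4L || !setequal(rownames(weights), DNA_BASES))
    stop("weights must be a 4 x width matrix with rownames A,C,G,T",
         call. = FALSE)
  weights <- weights[DNA_BASES, , drop = FALSE]
  if (ncol(weights) < 1L) stop("PWM width must be >= 1", call. = FALSE)
  if (any(!is.finite(weights)) || !is.finite(threshold))
    stop("weights and threshold must be finite", call. = FALSE)
  structure(list(name = as.character(name), width = ncol(weights),
                 weights = weights, threshold = as.numeric(threshold)),
            class = "Pwm")
}

#' Read and write PWM files
#'
#' The file format is tab-separated, one block per motif, blocks separated
#' by blank lines. The first line of a block carries the motif name and
#' threshold; the next four lines are labeled `A`, `C`, `G`, `T` and carry
#' one weight per motif position. Lines starting with `#` are comments.
#'
#' \preformatted{
#' SYN_SR1	6.0
#' A	1.0	0.0	-0.5	...
#' C	...
#' G	...
#' T	...
#' }
#'
#' @param path file path.
#' @return `readPwm`: a named list of `Pwm` objects.
#' @export
readPwm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  blocks <- split(lines, cumsum(!nzchar(trimws(lines))))
  blocks <- lapply(blocks, function(b) b[nzchar(trimws(b))])
  blocks <- blocks[lengths(blocks) > 0L]
  out <- list()
  for (b in blocks) {
    head <- strsplit(b[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(head) != 2L)
      stop("malformed PWM header line: '", b[[1L]],
           "' (expected name<TAB>threshold)", call. = FALSE)
    name <- head[1L]; threshold <- as.numeric(head[2L])
    rows <- lapply(b[-1L], function(l) strsplit(l, "\t", fixed = TRUE)[[1L]])
    labels <- vapply(rows, `[`, character(1), 1L)
    if (!setequal(labels, DNA_BASES))
      stop("PWM '", name, "' must have exactly the rows A, C, G, T (got ",
           paste(labels, collapse = ","), ")", call. = FALSE)
    widths <- vapply(rows, length, integer(1)) - 1L
    if (length(unique(widths)) != 1L)
      stop("PWM '", name, "' has ragged row widths", call. = FALSE)
    w <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
    rownames(w) <- labels
    out[[name]] <- pwm(name, w, threshold)
  }
  if (!length(out)) stop("no PWM blocks found in '", path, "'",
                         call. = FALSE)
  out
}

#' @rdname readPwm
#' @param pwms a list of `Pwm` objects.
#' @export
writePwm <- function(pwms, path) {
  if (inherits(pwms, "Pwm")) pwms <- list(pwms)
  chunks <- vapply(pwms, function(p) {
    rows <- vapply(DNA_BASES, function(b)
      paste(c(b, format(p$weights[b, ], trim = TRUE)), collapse = "\t"),
      character(1))
    paste(c(paste(p$name, format(p$threshold, trim = TRUE), sep = "\t"),
            rows), collapse = "\n")
  }, character(1))
  writeLines(paste(chunks, collapse = "\n\n"), path)
  invisible(path)
}

#' Scan a sequence with a PWM
#'
#' Slides the matrix along the sense strand (splicing enhancers act on the
#' pre-mRNA sense sequence) and reports every window whose additive score
#' reaches the matrix threshold. Windows containing `N` are skipped; a
#' single warning reports how many.
#'
#' @param seq a DNA character string (or `DNAString`).
#' @param x a `Pwm` or a list of them.
#' @return a `data.frame` with columns `pwmName`, `start` (1-based window
#'   start), `width`, `score`, sorted by `start` within each motif.
#' @export
scanPwm <- function(seq, x) {
  if (inherits(x, "Pwm")) x <- list(x)
  if (is(seq, "DNAString")) seq <- as.character(seq)
  checkDna(seq, what = "scanPwm input")
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_BASES)  # NA for N
  n <- length(chars)
  out <- lapply(x, function(p) {
    w <- p$width
    if (n < w)
      stop("sequence (", n, " nt) shorter than PWM '", p$name, "' width ",
           w, call. = FALSE)
    nWin <- n - w + 1L
    scores <- numeric(nWin)
    for (i in seq_len(w))
      scores <- scores + p$weights[cbind(idx[i:(i + nWin - 1L)], i)]
    skipped <- sum(is.na(scores))
    if (skipped)
      warning(skipped, " window(s) containing N skipped for PWM '",
              p$name, "'")
    hit <- which(!is.na(scores) & scores >= p$threshold)
    data.frame(pwmName = rep(p$name, length(hit)), start = hit,
               width = rep(w, length(hit)), score = scores[hit],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  df[order(match(df$pwmName, vapply(x, `[[`, character(1), "name")),
           df$start), , drop = FALSE]
}

#' Annotate ASO candidates with the ESE motifs they cover
#'
#' For each candidate, counts the motif hits whose interval intersects the
#' candidate's exonic footprint (interval intersection, so a hit merely
#' touching the candidate's boundary does not count). An ASO that covers
#' predicted SR-protein enhancer motifs is a plausible splice blocker even
#' when it does not span a splice site.
#'
#' @param candidates a `GRanges` from [tileAso()].
#' @param hits a `data.frame` from [scanPwm()] with exon-relative
#'   coordinates (1-based within the scanned exon).
#' @param exonInterval the exon's genomic [IRanges::IRanges] (length 1),
#'   used to place the hits genomically.
#' @return a `data.frame` with columns `id`, `eseHits` (count) and
#'   `motifs` (comma-joined motif names).
#' @export
annotateOverlaps <- function(candidates, hits, exonInterval) {
  stopifnot(length(exonInterval) == 1L)
  exS <- start(exonInterval); exE <- end(exonInterval)
  hitR <- if (nrow(hits)) IRanges(exS + hits$start - 1L,
                                  width = hits$width) else IRanges()
  n <- length(candidates)
  ids <- candidates$id
  counts <- integer(n); motifs <- character(n)
  for (k in seq_len(n)) {
    # exonic footprint of the candidate
    fs <- max(start(candidates)[k], exS)
    fe <- min(end(candidates)[k], exE)
    if (fs > fe || !length(hitR)) { motifs[k] <- ""; next }
    ov <- start(hitR) <= fe & end(hitR) >= fs
    counts[k] <- sum(ov)
    motifs[k] <- paste(hits$pwmName[ov], collapse = ",")
  }
  data.frame(id = ids, eseHits = counts, motifs = motifs,
             stringsAsFactors = FALSE)
}
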