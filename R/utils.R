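# internal helpers shared across modules

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

# label used in reports and isoform ids
eventLabel <- function(event) {
  if (is.null(event)) return("reference")
  if (is(event, "SkipEvent"))
    return(paste0("skip_e", paste(event@exonIndices, collapse = "+")))
  if (is(event, "CrypticSpliceEvent"))
    return(sprintf("cryptic_%s_e%d_%d", event@side, event@exonIndex,
                   event@newBoundary))
  if (is(event, "RetentionEvent"))
    return(sprintf("retain_i%d", event@intronIndex))
  stop("unknown event class: ", class(event))
}

# validate a character DNA string; name appears in the error
checkDna <- function(x, what = "sequence", allowN = TRUE) {
  stopifnot(is.character(x), length(x) == 1L)
  alphabet <- if (allowN) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", x)
  if (nzchar(bad))
    stop(sprintf("%s contains characters outside {%s}: '%s'",
                 what, paste(strsplit(alphabet, "")[[1]], collapse = ","),
                 substr(bad, 1L, 10L)), call. = FALSE)
  invisible(x)
}

# random DNA of length n from the current RNG stream
randomDna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# n random sense codons, none of them a stop; rejection sampling per codon
nonStopCodons <- function(n) {
  if (n <= 0L) return("")
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = "")
      if (!cod %in% STOP_CODONS) break
    }
    out[i] <- cod
  }
  paste(out, collapse = "")
}

# positions (1-based, relative to `from`) of in-frame stop codons in a
# character sequence; used by fixture construction, independent of scanOrf
frameStops <- function(seq, from) {
  n <- nchar(seq)
  if (from > n - 2L) return(integer())
  starts <- seq.int(from, n - 2L, by = 3L)
  cods <- substring(seq, starts, starts + 2L)
  starts[cods %in% STOP_CODONS]
}
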