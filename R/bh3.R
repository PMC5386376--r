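# BH3 motif scanning. The motif is modelled as the fixed spacing of the
# four conserved hydrophobic positions plus the invariant acidic residue
# observed across Bcl-2 family BH3 domains: with h1 at offset 0, h2 at
# +4 (the conserved leucine), h3 at +7, the Asp/Glu at +9 and h4 at +11 -
# the spacing exemplified by V71/L75/F78/Asp80/V82 of a Bak-like BH3.

.BH3_OFFSETS <- c(h1 = 0L, h2 = 4L, h3 = 7L, acid = 9L, h4 = 11L)
.BH3_SPAN <- 12L
.HYDROPHOBIC <- c("A", "I", "L", "M", "F", "V", "W", "Y")

#' Default BH3 position weights
#'
#' +2 for any hydrophobic at h1/h3/h4; +3 for Leu (else +1 for another
#' hydrophobic) at h2; +3 for Asp (+2 for Glu) at the acid position.
#' The maximum score is 12; the default acceptance threshold is 10, set
#' so canonical BH3 sequences pass and featureless sequences do not.
#'
#' @return named list of scoring weights.
#' @export
bh3Weights <- function() {
  list(hydrophobic = 2, leuBonus = 3, otherH2 = 1, asp = 3, glu = 2)
}

.scoreWindow <- function(chars, start, w) {
  p <- setNames(chars[start + .BH3_OFFSETS], names(.BH3_OFFSETS))
  s <- 0
  s <- s + w$hydrophobic * sum(p[c("h1", "h3", "h4")] %in% .HYDROPHOBIC)
  s <- s + if (p[["h2"]] == "L") w$leuBonus
           else if (p[["h2"]] %in% .HYDROPHOBIC) w$otherH2 else 0
  s <- s + if (p[["acid"]] == "D") w$asp
           else if (p[["acid"]] == "E") w$glu else 0
  s
}

#' Scan a protein sequence for BH3 motifs
#'
#' Slides the fixed BH3 spacing template over the sequence, scores every
#' placement with \code{\link{bh3Weights}}, and returns non-overlapping
#' hits with score >= \code{minScore}, best first (ties resolved
#' leftmost). Coordinates are 1-based and inclusive; unknown residues
#' ("X") score zero at any template position.
#'
#' @param sequence amino-acid string (lowercase accepted).
#' @param id sequence identifier carried into the result.
#' @param minScore acceptance threshold (default 10).
#' @param weights scoring weights, see \code{\link{bh3Weights}}.
#' @return data.frame with one row per hit: id, start, end, score, the
#'   h1-h4 positions, the conserved acid and conserved Leu (= h2)
#'   positions.
#' @examples
#' s <- makeBH3Sequence(71)
#' scanBH3(s)
#' @export
scanBH3 <- function(sequence, id = "seq", minScore = 10,
                    weights = bh3Weights()) {
  empty <- data.frame(id = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      h1 = integer(0), h2 = integer(0), h3 = integer(0),
                      h4 = integer(0), acid = integer(0),
                      leu = integer(0), stringsAsFactors = FALSE)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < .BH3_SPAN) {
    warning("sequence '", id, "' is shorter than the BH3 template (",
            .BH3_SPAN, " residues)", call. = FALSE)
    return(empty)
  }
  starts <- seq_len(n - .BH3_SPAN + 1L)
  scores <- vapply(starts, function(s) .scoreWindow(chars, s, weights),
                   numeric(1))
  cand <- starts[scores >= minScore]
  if (!length(cand)) return(empty)
  cand <- cand[order(-scores[cand], cand)]
  taken <- rep(FALSE, n)
  keep <- integer(0)
  for (s in cand) {
    span <- s:(s + .BH3_SPAN - 1L)
    if (!any(taken[span])) { taken[span] <- TRUE; keep <- c(keep, s) }
  }
  data.frame(id = id, start = keep, end = keep + .BH3_SPAN - 1L,
             score = scores[keep],
             h1 = keep + .BH3_OFFSETS[["h1"]],
             h2 = keep + .BH3_OFFSETS[["h2"]],
             h3 = keep + .BH3_OFFSETS[["h3"]],
             h4 = keep + .BH3_OFFSETS[["h4"]],
             acid = keep + .BH3_OFFSETS[["acid"]],
             leu = keep + .BH3_OFFSETS[["h2"]],
             stringsAsFactors = FALSE)
}

#' Scan a FASTA file or AAStringSet for BH3 motifs
#'
#' @param x path to a FASTA file or a \code{Biostrings::AAStringSet}.
#' @param ... passed to \code{\link{scanBH3}}.
#' @return data.frame of hits across all sequences.
#' @export
scanBH3Set <- function(x, ...) {
  if (is.character(x)) x <- Biostrings::readAAStringSet(x)
  hits <- lapply(names(x), function(nm)
    scanBH3(as.character(x[[nm]]), id = nm, ...))
  do.call(rbind, hits)
}

#' Peptide window around a BH3 hit
#'
#' Returns a window of the given length placed so that the template's h1
#' sits at window position 10, matching how a 28-mer spanning residues
#' 62-89 frames a motif with h1 at residue 71 (nine residues of
#' N-terminal context). Windows reaching beyond the sequence are
#' truncated with a warning.
#'
#' @param sequence amino-acid string.
#' @param hit single-row data.frame from \code{\link{scanBH3}}.
#' @param length window length (default 28; 26 is a common synthetic
#'   peptide length).
#' @return list with \code{sequence}, \code{start}, \code{end}
#'   (1-based, inclusive, within the input sequence).
#' @export
peptideWindow <- function(sequence, hit, length = 28L) {
  n <- nchar(sequence)
  .stopIfNot(hit$h1 >= 1 && hit$end <= n, "hit lies outside the sequence")
  start <- hit$h1 - 9L
  end <- start + length - 1L
  if (start < 1L || end > n) {
    warning("window truncated at sequence bounds", call. = FALSE)
    start <- max(1L, start); end <- min(n, end)
  }
  list(sequence = substr(sequence, start, end), start = start, end = end)
}
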