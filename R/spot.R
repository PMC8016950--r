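# Overlapping-peptide SPOT arrays: tiling design, positive-spot calling,
# minimal common motif extraction and localization.

#' Design an overlapping-peptide tiling
#'
#' Windows of `window` residues starting at `region[1]`, `region[1] + step`,
#' ...; by default every full window fitting inside the region (for a
#' 112-residue region at window 8 / step 2 that is 53 spots). `max_spots`
#' truncates the series, matching array layouts that stop short of full
#' coverage.
#'
#' @param antigen_seq antigen sequence string.
#' @param window peptide length (default 8).
#' @param step start-to-start offset in residues (default 2).
#' @param region inclusive 1-based residue range (default whole sequence).
#' @param max_spots optional truncation of the spot count.
#' @return object of class `spot_array`: data.frame `peptides` (index, start,
#'   sequence) plus fields `window`, `step`, `region`; intensities are `NULL`
#'   until measured or simulated.
#' @examples
#' arr <- tile_peptides(hgal3_nd_sequence())
#' nrow(arr$peptides)
#' @export
tile_peptides <- function(antigen_seq, window = 8, step = 2,
                          region = c(1, nchar(antigen_seq)), max_spots = NULL) {
  stopifnot(step >= 1, step <= window)
  L <- nchar(antigen_seq)
  if (region[1] < 1 || region[2] > L) stop("region outside sequence bounds")
  rlen <- region[2] - region[1] + 1
  if (window > rlen) stop("window longer than region")
  starts <- seq(region[1], region[2] - window + 1, by = step)
  if (!is.null(max_spots)) starts <- starts[seq_len(min(max_spots, length(starts)))]
  peptides <- data.frame(
    index = seq_along(starts), start = starts,
    sequence = substring(antigen_seq, starts, starts + window - 1),
    stringsAsFactors = FALSE)
  structure(list(peptides = peptides, window = window, step = step,
                 region = region, intensities = NULL),
            class = "spot_array")
}

#' @export
print.spot_array <- function(x, ...) {
  cat(sprintf("SPOT array: %d x %d-mer peptides, step %d, region %d-%d%s\n",
              nrow(x$peptides), x$window, x$step, x$region[1], x$region[2],
              if (is.null(x$intensities)) "" else " (with intensities)"))
  invisible(x)
}

#' Call positive spots from normalized intensities
#'
#' @param array a [tile_peptides()] array carrying `intensities` (max-
#'   normalized to 1).
#' @param threshold positivity threshold on the normalized scale
#'   (default 0.5).
#' @return integer vector of positive spot indices, ascending.
#' @export
call_positive_spots <- function(array, threshold = 0.5) {
  stopifnot(inherits(array, "spot_array"))
  if (is.null(array$intensities)) stop("array has no intensities")
  stopifnot(length(array$intensities) == nrow(array$peptides))
  sort(array$peptides$index[array$intensities >= threshold])
}

# all distinct substrings of a string (including itself), by length descending
.all_substrings <- function(s) {
  n <- nchar(s)
  out <- unlist(lapply(seq_len(n), function(len) {
    substring(s, seq_len(n - len + 1), seq_len(n - len + 1) + len - 1)
  }))
  unique(out)
}

#' Minimal common epitope motif of positive spots
#'
#' The longest string occurring in every positive peptide; among equal-length
#' candidates, the one occurring earliest in the lowest-index positive
#' peptide. An empty motif (no common substring) is allowed and reported with
#' `sequence = ""`.
#'
#' @param array a [tile_peptides()] array.
#' @param positive integer vector of positive spot indices.
#' @return object of class `epitope_motif`: `sequence`, `support` (the spot
#'   indices), `occurrences` (start positions of the motif within the
#'   antigen region covered by the array, 1-based).
#' @export
minimal_common_motif <- function(array, positive) {
  stopifnot(inherits(array, "spot_array"), length(positive) >= 1)
  positive <- sort(positive)
  peps <- array$peptides$sequence[match(positive, array$peptides$index)]
  if (anyNA(peps)) stop("positive index outside the array")
  first <- peps[1]
  n <- nchar(first)
  motif <- ""
  found <- FALSE
  for (len in seq(n, 1)) {
    starts <- seq_len(n - len + 1)
    for (st in starts) {  # earliest occurrence in the lowest-index peptide
      cand <- substr(first, st, st + len - 1)
      if (all(vapply(peps, function(p) grepl(cand, p, fixed = TRUE), TRUE))) {
        motif <- cand
        found <- TRUE
        break
      }
    }
    if (found) break
  }
  occurrences <- integer(0)
  if (nzchar(motif)) {
    cov <- .covered_sequence(array)
    occurrences <- locate_motif(cov$seq, motif)$positions + cov$offset
  }
  structure(list(sequence = motif, support = positive,
                 occurrences = occurrences),
            class = "epitope_motif")
}

# reconstruct the antigen stretch covered by the array (overlap-consistent
# tilings only); returns the sequence and the offset such that antigen
# position = string position + offset
.covered_sequence <- function(array) {
  p <- array$peptides
  lo <- min(p$start)
  hi <- max(p$start) + array$window - 1
  chars <- rep(NA_character_, hi - lo + 1)
  for (i in seq_len(nrow(p))) {
    idx <- (p$start[i] - lo + 1):(p$start[i] - lo + array$window)
    chars[idx] <- strsplit(p$sequence[i], "")[[1]]
  }
  list(seq = paste(chars, collapse = ""), offset = lo - 1L)
}

#' @export
print.epitope_motif <- function(x, ...) {
  if (nzchar(x$sequence)) {
    cat(sprintf("Epitope motif '%s' (length %d), supported by spots %s\n",
                x$sequence, nchar(x$sequence),
                paste(x$support, collapse = ", ")))
  } else {
    cat("No common motif among spots", paste(x$support, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Locate a motif on the antigen
#'
#' All (possibly overlapping) occurrences, 1-based.
#'
#' @param antigen_seq sequence string.
#' @param motif nonempty motif string.
#' @return list with `positions` (integer starts) and `count`.
#' @examples
#' locate_motif(hgal3_nd_sequence(), "APPGAY")
#' @export
locate_motif <- function(antigen_seq, motif) {
  if (!nzchar(motif)) stop("motif must be nonempty")
  m <- gregexpr(paste0("(?=", motif, ")"), antigen_seq, perl = TRUE)[[1]]
  pos <- as.integer(m[m > 0])
  list(positions = pos, count = length(pos))
}
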