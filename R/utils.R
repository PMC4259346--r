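#' Reverse-complement DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] for plain
#' character vectors, which is how sequences travel through this package.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAGCTT"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Random DNA sequence
#'
#' @param n Length in bp.
#' @return A single DNA string of length `n`.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Stable per-stage / per-unit seed stream derived from the root seed, kept
## below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stage, unit = 0L) {
  offsets <- c(
    reference = 11L, clones = 20011L, rnaseq = 40009L, qpcr = 60013L,
    hic = 80021L, junctions = 100003L, dna = 120011L, fixtures = 140009L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) + off + 104729 * as.numeric(unit)) %% 2147483647)
}

## Weighted pool-adjacent-violators fit, non-increasing in the given order.
## stats::isoreg() has no weights, so the handful of lines live here.
pav_nonincreasing <- function(y, w) {
  stopifnot(length(y) == length(w), all(w > 0))
  n <- length(y)
  if (n == 0) return(numeric(0))
  vals <- y
  wts <- w
  idx <- as.list(seq_len(n))
  i <- 1L
  while (i < length(vals)) {
    if (vals[i] < vals[i + 1]) {
      merged <- (vals[i] * wts[i] + vals[i + 1] * wts[i + 1]) / (wts[i] + wts[i + 1])
      vals[i] <- merged
      wts[i] <- wts[i] + wts[i + 1]
      idx[[i]] <- c(idx[[i]], idx[[i + 1]])
      vals <- vals[-(i + 1)]
      wts <- wts[-(i + 1)]
      idx[[i + 1]] <- NULL
      i <- max(1L, i - 1L)
    } else {
      i <- i + 1L
    }
  }
  out <- numeric(n)
  for (b in seq_along(vals)) out[idx[[b]]] <- vals[b]
  out
}

first_or_na <- function(x) if (length(x)) x[[1]] else NA
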