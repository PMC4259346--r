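#' Digest a chromosome into restriction fragments
#'
#' Fragments run between successive occurrences of the restriction site
#' (HindIII, `AAGCTT`, by default), with boundaries at the site start, plus
#' the two chromosome-end fragments. The fragments tile the chromosome: their
#' lengths sum to the chromosome length. A sequence without any site yields
#' a single fragment.
#'
#' @param sequence Chromosome DNA string.
#' @param site Restriction-site motif (default HindIII).
#' @param chrom Chromosome name recorded in the output.
#' @return Tibble `fragment_id, chrom, start, end, mid` (1-based closed
#'   intervals).
#' @export
#' @examples
#' digest_fragments("NNAAGCTTNN")
digest_fragments <- function(sequence, site = "AAGCTT", chrom = "chr") {
  if (!nchar(sequence)) abort("`sequence` must be non-empty.")
  hits <- Biostrings::matchPattern(site, Biostrings::DNAString(sequence))
  cut <- BiocGenerics::start(hits)
  starts <- c(1L, cut)
  ends <- c(cut - 1L, nchar(sequence))
  tibble(
    fragment_id = sprintf("F%04d", seq_along(starts)),
    chrom = chrom,
    start = as.integer(starts),
    end = as.integer(ends),
    mid = (as.integer(starts) + as.integer(ends)) / 2
  )
}

#' Observed anchor contact profile
#'
#' Sums contact counts with one end in the anchor fragment, keyed by the
#' partner fragment; fragments never seen in the table get observed 0.
#'
#' @param contacts Tibble `frag_i, frag_j, count`.
#' @param fragments Fragment tibble from [digest_fragments()].
#' @param anchor Anchor fragment id.
#' @return The fragment tibble plus `distance` (midpoint to midpoint, bp)
#'   and `observed`, anchor row excluded.
#' @export
anchor_profile <- function(contacts, fragments, anchor) {
  if (!anchor %in% fragments$fragment_id) {
    abort(paste0("anchor fragment not found: ", anchor))
  }
  contacts <- as_tibble(contacts)
  inc <- contacts[contacts$frag_i == anchor | contacts$frag_j == anchor, ]
  partner <- ifelse(inc$frag_i == anchor, inc$frag_j, inc$frag_i)
  obs <- tapply(inc$count, partner, sum)
  mid_a <- fragments$mid[fragments$fragment_id == anchor]
  out <- fragments[fragments$fragment_id != anchor, ]
  out$distance <- abs(out$mid - mid_a)
  out$observed <- as.integer(ifelse(is.na(obs[out$fragment_id]), 0,
                                    obs[out$fragment_id]))
  out
}

#' Distance-decay expected model for an anchor profile
#'
#' Fragments are binned by log distance to the anchor; each fragment's
#' expected count is its bin's leave-one-out mean, smoothed to be
#' non-increasing with distance by a weighted pool-adjacent-violators fit.
#' Leaving the fragment itself out keeps a genuine loop spike from inflating
#' its own expectation.
#'
#' @param profile Output of [anchor_profile()].
#' @param n_bins Number of log-distance bins (default 20; profiles with
#'   fewer fragments than bins are rejected).
#' @return `profile` with an `expected` column.
#' @export
expected_model <- function(profile, n_bins = 20L) {
  n <- nrow(profile)
  if (n < n_bins) abort("need at least `n_bins` fragments to fit the decay.")
  if (all(profile$observed == 0)) abort("all-zero profile: nothing to fit.")
  ld <- log10(profile$distance)
  ## quantile bins: equal fragment occupancy, so near-anchor bins are not
  ## starved of data by the log-distance skew
  brk <- unique(stats::quantile(ld, probs = seq(0, 1, length.out = n_bins + 1L)))
  bin <- cut(ld, breaks = brk, include.lowest = TRUE, labels = FALSE)
  bins <- sort(unique(bin))
  bkey <- as.character(bins)
  bin_sum <- tapply(profile$observed, bin, sum)[bkey]
  bin_n <- tapply(rep(1L, n), bin, sum)[bkey]
  bin_ldsum <- tapply(ld, bin, sum)[bkey]

  expected <- numeric(n)
  for (i in seq_len(n)) {
    s <- as.numeric(bin_sum)
    m <- as.numeric(bin_n)
    dsum <- as.numeric(bin_ldsum)
    b <- match(bin[i], bins)
    s[b] <- s[b] - profile$observed[i]
    m[b] <- m[b] - 1L
    dsum[b] <- dsum[b] - ld[i]
    keep <- m > 0
    means <- pmax(s[keep] / m[keep], 1e-8)
    ctr <- dsum[keep] / m[keep]
    ord <- order(ctr)
    fit <- pav_nonincreasing(means[ord], m[keep][ord])
    ## log-log interpolation between bin centres tracks the decay within
    ## and beyond the bin grid (clamped at the ends)
    expected[i] <- if (length(fit) == 1L) fit else {
      exp(stats::approx(ctr[ord], log(fit), xout = ld[i], rule = 2,
                        ties = "ordered")$y)
    }
  }
  profile$expected <- pmax(expected, 1e-8)
  profile
}

#' Flag significantly looping fragments
#'
#' Per-fragment upper Poisson tail `P(X >= observed | mean = expected)` with
#' Benjamini-Hochberg correction across fragments; a fragment is looping
#' when its adjusted tail probability falls below `fdr`.
#'
#' @param profile Output of [expected_model()].
#' @param fdr Nominal false-discovery rate (default 0.05).
#' @return An object of class `loop_profile`: the profile tibble with
#'   `p_value`, `p_adj` and `looping` columns.
#' @export
call_loops <- function(profile, fdr = 0.05) {
  if (!"expected" %in% names(profile)) abort("run `expected_model()` first.")
  p <- ppois(profile$observed - 1L, profile$expected, lower.tail = FALSE)
  profile$p_value <- p
  profile$p_adj <- p.adjust(p, method = "BH")
  profile$looping <- profile$p_adj < fdr
  class(profile) <- c("loop_profile", class(profile))
  profile
}

#' Anchor loop profile in one call
#'
#' Convenience wrapper chaining [anchor_profile()], [expected_model()] and
#' [call_loops()].
#'
#' @param contacts,fragments,anchor See [anchor_profile()].
#' @param n_bins,fdr See [expected_model()] and [call_loops()].
#' @return A `loop_profile` tibble; the anchor id is kept in the
#'   `"anchor"` attribute.
#' @export
profile_loops <- function(contacts, fragments, anchor, n_bins = 20L, fdr = 0.05) {
  out <- anchor_profile(contacts, fragments, anchor) |>
    expected_model(n_bins = n_bins) |>
    call_loops(fdr = fdr)
  attr(out, "anchor") <- anchor
  out
}
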