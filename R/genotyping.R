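#' Deletion-spanning PCR screen
#'
#' A clone is product-positive when any junction amplicon is short enough to
#' amplify (default cap 3 kb): the un-deleted span is far beyond the
#' polymerase's practical range, so a product implies at least one deleted
#' (or inverted) allele.
#'
#' @param amplicons Junction amplicons (tibble with `clone_id` and
#'   `length`), e.g. from [simulate_junctions()].
#' @param clone_ids All screened clones (so product-negative clones appear
#'   in the output).
#' @param max_amplifiable Longest amplifiable product in bp (default 3000).
#' @return Tibble `clone_id, product_detected, approx_length` (`NA` length
#'   when no product).
#' @export
pcr_screen <- function(amplicons, clone_ids, max_amplifiable = 3000L) {
  amplicons <- as_tibble(amplicons)
  ok <- amplicons[amplicons$length <= max_amplifiable, ]
  tibble(
    clone_id = clone_ids,
    product_detected = clone_ids %in% ok$clone_id,
    approx_length = vapply(clone_ids, function(cl) {
      len <- ok$length[ok$clone_id == cl]
      if (length(len)) as.integer(min(len)) else NA_integer_
    }, integer(1), USE.NAMES = FALSE)
  )
}

#' Relative DNA copy number by the delta-delta-Ct method
#'
#' Per clone, `dCt = mean Ct(target) - mean Ct(control)`; against the
#' wild-type reference clone, `ddCt = dCt_clone - dCt_WT` and
#' `copy_number = 2 * 2^(-ddCt)`, so the reference clone reads exactly 2.
#' Clones whose target wells are all missing (no amplification) get copy
#' number 0. The statistic is invariant to any constant Ct offset applied
#' to all wells of a clone.
#'
#' @param ct Ct table `clone_id, well, assay, ct` with `assay` in
#'   `{"target", "control"}`; `NA` Ct encodes no amplification.
#' @param wt_clone Reference clone id (must have complete target and
#'   control data).
#' @param aggregate Well aggregation function (default mean of the
#'   replicates).
#' @return Tibble `clone_id, delta_ct, copy_number`.
#' @export
ddct_copy_number <- function(ct, wt_clone, aggregate = mean) {
  ct <- as_tibble(ct)
  if (!wt_clone %in% ct$clone_id) abort("`wt_clone` absent from the Ct table.")
  if (!all(c("target", "control") %in% ct$assay)) {
    abort("the Ct table needs both 'target' and 'control' assays; control wells are missing.")
  }
  agg <- ct |>
    group_by(.data$clone_id, .data$assay) |>
    summarise(
      all_missing = all(is.na(.data$ct)),
      m = if (all(is.na(.data$ct))) NA_real_ else aggregate(.data$ct[!is.na(.data$ct)]),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(names_from = "assay", values_from = c("m", "all_missing"))
  if (any(agg$all_missing_control)) {
    abort("missing control wells; the assay cannot be normalised.")
  }
  wt <- agg[agg$clone_id == wt_clone, ]
  if (wt$all_missing_target) abort("the reference clone must have target data.")
  dct_wt <- wt$m_target - wt$m_control
  agg |>
    mutate(
      delta_ct = .data$m_target - .data$m_control,
      copy_number = ifelse(.data$all_missing_target, 0,
                           2 * 2^(-(.data$delta_ct - dct_wt)))
    ) |>
    select("clone_id", "delta_ct", "copy_number")
}

#' Classify a clone genotype from its relative copy number
#'
#' Class boundaries default to the midpoints between the ideal copy numbers
#' 0, 1 and 2: below 0.5 is biallelic, `[0.5, 1.5)` monoallelic, 1.5 and
#' above wild type.
#'
#' @param copy_number Numeric vector of relative copy numbers (WT = 2).
#' @param thresholds Length-2 boundaries `c(biallelic|monoallelic,
#'   monoallelic|WT)`.
#' @return Character vector in `{"biallelic", "monoallelic", "WT"}`.
#' @export
classify_genotype <- function(copy_number, thresholds = c(0.5, 1.5)) {
  if (any(copy_number < 0)) abort("copy numbers must be >= 0.")
  dplyr::case_when(
    copy_number >= thresholds[2] ~ "WT",
    copy_number >= thresholds[1] ~ "monoallelic",
    TRUE ~ "biallelic"
  )
}

#' Identify the targeted allele from a junction amplicon
#'
#' The 3' end of the junction amplicon is the downstream cut-site flank, so
#' diagnostic SNP positions have a fixed offset from the amplicon end
#' regardless of the NHEJ scar at the fusion point. Bases at the diagnostic
#' positions are compared to both haplotypes and the allele is called by
#' majority vote; ties are `ambiguous`.
#'
#' @param amplicon_seq Amplicon DNA string.
#' @param ref The `diploid_reference` (provides the diagnostic SNPs and the
#'   amplicon flank geometry).
#' @return `"CAST"`, `"129"` or `"ambiguous"`.
#' @export
call_junction_allele <- function(amplicon_seq, ref) {
  flank <- ref$amplicon_flank
  diag <- ref$variants[ref$variants$id %in% ref$diagnostic &
                         ref$variants$pos > ref$enhancer$end, ]
  if (!nrow(diag)) abort("no diagnostic variants in the downstream flank.")
  amp_end_pos <- ref$enhancer$end + flank[["right"]]
  n <- nchar(amplicon_seq)
  off <- amp_end_pos - diag$pos       # offset from the amplicon 3' end
  if (any(n - off < 1)) {
    abort("amplicon does not align to the downstream flank.")
  }
  base <- substring(amplicon_seq, n - off, n - off)
  v_cast <- sum(base == diag$ref)
  v_129 <- sum(base == diag$alt)
  if (v_cast > v_129) "CAST" else if (v_129 > v_cast) "129" else "ambiguous"
}

#' Allelic deletion frequency of a screen
#'
#' `(monoallelic + 2 * biallelic) / (2 * total clones)`: the fraction of
#' all screened alleles carrying the deletion, evaluated in exact rational
#' arithmetic.
#'
#' @param n_mono,n_bi,n_total Clone tallies.
#' @return The deletion frequency as a fraction in `[0, 1]`.
#' @export
#' @examples
#' deletion_frequency(6, 2, 16)  # 0.3125
deletion_frequency <- function(n_mono, n_bi, n_total) {
  if (n_total == 0) abort("`n_total` must be positive.")
  if (any(c(n_mono, n_bi, n_total) < 0) || n_mono + n_bi > n_total) {
    abort("clone tallies are inconsistent.")
  }
  num <- as.integer(n_mono) + 2L * as.integer(n_bi)
  den <- 2L * as.integer(n_total)
  num / den
}

#' Genotype a panel of clones end to end
#'
#' Combines the PCR screen, delta-delta-Ct copy number classification and
#' junction-SNP allele identification into one call table.
#'
#' @param ct Ct table.
#' @param amplicons Junction amplicon tibble (`clone_id, allele, seq,
#'   length`).
#' @param ref The `diploid_reference`.
#' @param wt_clone Reference clone for the ddCt normalisation.
#' @param clone_ids Clones screened (default: all in `ct`).
#' @param thresholds Copy-number class boundaries.
#' @return An object of class `genotype_calls`: tibble `clone_id,
#'   product_detected, copy_number, call, deleted_allele`.
#' @export
genotype_clones <- function(ct, amplicons, ref, wt_clone,
                            clone_ids = NULL, thresholds = c(0.5, 1.5)) {
  clone_ids <- clone_ids %||% unique(ct$clone_id)
  screen <- pcr_screen(amplicons, clone_ids)
  cn <- ddct_copy_number(ct, wt_clone)
  out <- left_join(screen, cn, by = "clone_id") |>
    mutate(call = classify_genotype(.data$copy_number, thresholds))
  out$deleted_allele <- vapply(seq_len(nrow(out)), function(i) {
    if (out$call[i] == "WT") return("none")
    if (out$call[i] == "biallelic") return("both")
    amps <- amplicons[amplicons$clone_id == out$clone_id[i], ]
    if (!nrow(amps)) return(NA_character_)
    calls <- vapply(amps$seq, call_junction_allele, character(1), ref = ref,
                    USE.NAMES = FALSE)
    calls <- unique(calls[calls != "ambiguous"])
    if (length(calls) == 1) calls else NA_character_
  }, character(1))
  class(out) <- c("genotype_calls", class(out))
  out
}
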