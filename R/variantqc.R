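#' Enumerate dummy reads across a variant
#'
#' Generates every full-length window from each haplotype whose span overlaps
#' the variant site: for a SNP mid-chromosome that is exactly `read_length`
#' reads per haplotype; for indels, every start position overlapping the
#' variant's affected span on that haplotype (which differs between
#' haplotypes by the indel length). Windows that would run past a chromosome
#' end are dropped, so edge variants yield fewer reads.
#'
#' @param variant A variant id, or a one-row tibble with `chrom, pos, ref,
#'   alt`.
#' @param ref A `diploid_reference`.
#' @param read_length Window size in bp.
#' @return Tibble `seq, haplotype, chrom, start` (`start` in that
#'   haplotype's own frame).
#' @export
generate_dummy_reads <- function(variant, ref, read_length) {
  if (is.character(variant)) {
    variant <- ref$variants[ref$variants$id == variant, ]
    if (!nrow(variant)) abort("unknown variant id.")
  }
  v <- as_tibble(variant)
  spans <- list(
    CAST = c(v$pos, v$pos + nchar(v$ref) - 1L),
    `129` = {
      pb <- hapb_pos(ref, v$chrom, v$pos)
      c(pb, pb + nchar(v$alt) - 1L)
    }
  )
  out <- lapply(c("CAST", "129"), function(h) {
    hap <- ref$haplotypes[[h]][[v$chrom]]
    len <- nchar(hap)
    if (read_length > len) abort("`read_length` exceeds the chromosome length.")
    sp <- spans[[h]]
    s <- seq.int(max(1L, sp[1] - read_length + 1L),
                 min(sp[2], len - read_length + 1L))
    if (length(s) == 0 || s[1] > s[length(s)]) {
      return(tibble(seq = character(0), haplotype = character(0),
                    chrom = character(0), start = integer(0)))
    }
    tibble(seq = substring(hap, s, s + read_length - 1L), haplotype = h,
           chrom = v$chrom, start = as.integer(s))
  })
  bind_rows(out)
}

#' Exact-match read mapper over the combined diploid index
#'
#' Returns a mapper closure for use with [assess_mapping_bias()]: given read
#' sequences it reports, per read, the total number of exact occurrences
#' across both haplotypes' chromosomes on both strands. A read with exactly
#' one occurrence maps uniquely (and, for a read extracted from the genome,
#' necessarily to its true locus). Any aligner honouring the same contract
#' (a placement count per read) can be plugged in instead.
#'
#' @param ref A `diploid_reference`.
#' @return `function(seqs)` returning an integer vector of placement counts.
#' @export
exact_match_mapper <- function(ref) {
  subject <- Biostrings::DNAStringSet(
    c(unname(ref$haplotypes$CAST), unname(ref$haplotypes$`129`))
  )
  function(seqs) {
    n <- length(seqs)
    hits <- integer(n)
    for (w in unique(nchar(seqs))) {
      ix <- which(nchar(seqs) == w)
      count_set <- function(patterns) {
        if (length(patterns) >= 10L && w >= 10L) {
          pd <- Biostrings::PDict(patterns)
          rowSums(Biostrings::vcountPDict(pd, subject))
        } else {
          vapply(patterns, function(p) {
            sum(Biostrings::vcountPattern(p, subject))
          }, integer(1), USE.NAMES = FALSE)
        }
      }
      hits[ix] <- count_set(Biostrings::DNAStringSet(seqs[ix])) +
        count_set(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[ix])))
    }
    hits
  }
}

#' Assess mapping bias of one variant's dummy reads
#'
#' A dummy read counts toward its haplotype's mapped tally iff it places
#' uniquely in the combined diploid index (a unique placement is necessarily
#' the read's true locus, since the read was lifted from there). The bias
#' score is `|m_CAST - m_129| / max(m_CAST, m_129)`, or 1 when no read maps
#' uniquely.
#'
#' @param reads Dummy-read tibble from [generate_dummy_reads()].
#' @param mapper A mapper closure, e.g. [exact_match_mapper()].
#' @return One-row tibble `n_dummy_CAST, n_dummy_129, m_CAST, m_129,
#'   bias_score`.
#' @export
assess_mapping_bias <- function(reads, mapper) {
  if (!nrow(reads)) abort("empty dummy-read set.")
  hits <- mapper(reads$seq)
  unique_hit <- hits == 1L
  m <- tapply(unique_hit, reads$haplotype, sum)
  m_cast <- as.integer(m["CAST"] %||% 0L)
  m_129 <- as.integer(m["129"] %||% 0L)
  m_cast <- ifelse(is.na(m_cast), 0L, m_cast)
  m_129 <- ifelse(is.na(m_129), 0L, m_129)
  top <- max(m_cast, m_129)
  tibble(
    n_dummy_CAST = sum(reads$haplotype == "CAST"),
    n_dummy_129 = sum(reads$haplotype == "129"),
    m_CAST = m_cast, m_129 = m_129,
    bias_score = if (top > 0) abs(m_cast - m_129) / top else 1
  )
}

#' Mapping-bias report for every variant
#'
#' Batch driver: enumerates dummy reads for all variants, maps them in one
#' pass, and scores each variant with [assess_mapping_bias()]'s rule.
#'
#' @param ref A `diploid_reference`.
#' @param read_length Dummy-read length.
#' @param mapper A mapper closure (default: exact-match over `ref`).
#' @param variants Optional subset of variant ids.
#' @return Tibble `id, kind, n_dummy_CAST, n_dummy_129, m_CAST, m_129,
#'   bias_score`.
#' @export
qc_mapping_bias <- function(ref, read_length,
                            mapper = exact_match_mapper(ref),
                            variants = NULL) {
  vt <- ref$variants
  if (!is.null(variants)) vt <- vt[vt$id %in% variants, ]
  all_reads <- lapply(seq_len(nrow(vt)), function(i) {
    rd <- generate_dummy_reads(vt[i, ], ref, read_length)
    rd$id <- vt$id[i]
    rd
  })
  reads <- bind_rows(all_reads)
  reads$unique_hit <- mapper(reads$seq) == 1L
  agg <- reads |>
    group_by(.data$id) |>
    summarise(
      n_dummy_CAST = sum(.data$haplotype == "CAST"),
      n_dummy_129 = sum(.data$haplotype == "129"),
      m_CAST = sum(.data$unique_hit & .data$haplotype == "CAST"),
      m_129 = sum(.data$unique_hit & .data$haplotype == "129"),
      .groups = "drop"
    ) |>
    mutate(bias_score = ifelse(
      pmax(.data$m_CAST, .data$m_129) > 0,
      abs(.data$m_CAST - .data$m_129) / pmax(.data$m_CAST, .data$m_129), 1
    ))
  left_join(vt[, c("id", "kind")], agg, by = "id")
}

#' Flag variants with dummy-read mapping bias
#'
#' SNPs with bias strictly above `snp_thresh` (default 5%) and indels
#' strictly above `indel_thresh` (default 10%) get the `mapping_bias` flag.
#'
#' @param variants A variant table (see [variant_table()]).
#' @param report Bias report from [qc_mapping_bias()].
#' @param snp_thresh,indel_thresh Strict thresholds per variant kind.
#' @return The variant table with `mapping_bias`, `bias_score` and `usable`
#'   updated.
#' @export
filter_mapping_bias <- function(variants, report, snp_thresh = 0.05,
                                indel_thresh = 0.10) {
  if (!all(variants$id %in% report$id)) {
    abort("`report` must cover every variant.")
  }
  score <- report$bias_score[match(variants$id, report$id)]
  variants$bias_score <- score
  variants$mapping_bias <- ifelse(variants$kind == "SNP",
                                  score > snp_thresh, score > indel_thresh)
  refresh_usable(variants)
}

## exact two-sided binomial p at p0 = 0.5 (the symmetric case has a closed
## two-tail form: fold the more extreme tail)
binom_p_balanced <- function(x, n) {
  if (n == 0) return(NA_real_)
  lo <- min(x, n - x)
  min(1, 2 * pbinom(lo, n, 0.5) - stats::dbinom(lo, n, 0.5))
}

#' Copy-number-balance filter on genomic-DNA allele counts
#'
#' Two-sided exact binomial test of each variant's DNA allele counts against
#' an equal 50/50 split, Benjamini-Hochberg corrected across variants;
#' variants rejected at `fdr` get the `cnv_bias` flag. Zero-depth variants
#' cannot be tested and get `poor_het` instead.
#'
#' @param variants A variant table.
#' @param dna_counts Tibble `id, count_CAST, count_129`.
#' @param fdr Nominal FDR (default 0.05).
#' @return The variant table with flags updated.
#' @export
cnv_balance_filter <- function(variants, dna_counts, fdr = 0.05) {
  m <- match(variants$id, dna_counts$id)
  a <- dna_counts$count_CAST[m]
  b <- dna_counts$count_129[m]
  n <- a + b
  p <- vapply(seq_along(a), function(i) binom_p_balanced(a[i], n[i]), numeric(1))
  tested <- !is.na(p)
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  variants$cnv_bias <- variants$cnv_bias | (tested & p_adj < fdr)
  variants$poor_het <- variants$poor_het | !tested
  refresh_usable(variants)
}

#' Heterozygous-call quality filter
#'
#' One-sided exact binomial test that the minor-allele fraction of the DNA
#' counts is at least `min_minor_frac`: the p-value is
#' `P(X <= minor | n, min_minor_frac)`, Benjamini-Hochberg corrected;
#' rejection of heterozygosity at `fdr` sets the `poor_het` flag.
#'
#' @inheritParams cnv_balance_filter
#' @param min_minor_frac Minimum credible minor-allele fraction for a true
#'   heterozygous site (default 0.15).
#' @return The variant table with flags updated.
#' @export
het_quality_filter <- function(variants, dna_counts, fdr = 0.05,
                               min_minor_frac = 0.15) {
  m <- match(variants$id, dna_counts$id)
  a <- dna_counts$count_CAST[m]
  b <- dna_counts$count_129[m]
  n <- a + b
  minor <- pmin(a, b)
  p <- ifelse(n > 0, pbinom(minor, n, min_minor_frac), NA_real_)
  tested <- !is.na(p)
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  variants$poor_het <- variants$poor_het | (tested & p_adj < fdr) | !tested
  refresh_usable(variants)
}

refresh_usable <- function(variants) {
  variants$usable <- !(variants$mapping_bias | variants$cnv_bias |
                         variants$poor_het)
  variants
}

#' Run the full variant-QC battery
#'
#' Chains the dummy-read mapping-bias assessment, the copy-number-balance
#' test and the heterozygosity filter, and reports how many variants each
#' rule removed.
#'
#' @param ref A `diploid_reference`.
#' @param dna_counts Genomic-DNA allele counts (see [simulate_dna_counts()]).
#' @param read_length Dummy-read length.
#' @param mapper Mapper closure (default exact match over `ref`).
#' @param snp_thresh,indel_thresh,fdr,min_minor_frac Filter parameters.
#' @param quiet Suppress the per-filter audit messages.
#' @return A variant table with `bias_score`, the three QC flags, and
#'   `usable`.
#' @export
variant_qc <- function(ref, dna_counts, read_length,
                       mapper = exact_match_mapper(ref),
                       snp_thresh = 0.05, indel_thresh = 0.10,
                       fdr = 0.05, min_minor_frac = 0.15, quiet = FALSE) {
  vt <- variant_table(ref)
  report <- qc_mapping_bias(ref, read_length, mapper)
  vt <- filter_mapping_bias(vt, report, snp_thresh, indel_thresh)
  n1 <- sum(vt$mapping_bias)
  vt <- cnv_balance_filter(vt, dna_counts, fdr)
  n2 <- sum(vt$cnv_bias)
  vt <- het_quality_filter(vt, dna_counts, fdr, min_minor_frac)
  n3 <- sum(vt$poor_het)
  if (!quiet) {
    message(sprintf(
      "variant QC: %d variants; flagged %d mapping-bias, %d CNV-bias, %d poor-het; %d usable",
      nrow(vt), n1, n2, n3, sum(vt$usable)
    ))
  }
  vt
}
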