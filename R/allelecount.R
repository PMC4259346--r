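#' Assign reads to parental alleles at usable variants
#'
#' Each read is compared to both haplotypes at every usable variant it
#' overlaps. At a SNP the read's base votes for CAST when it equals the REF
#' allele and for 129 when it equals the ALT allele; a base matching neither
#' haplotype (sequencing error) is ignored. A read overlapping a usable
#' indel is compared as a whole window against both haplotype sequences and
#' votes for the single haplotype it matches exactly (no vote when it
#' matches both or neither). The final call is a majority vote across
#' variants; ties and reads with no informative site are `unassigned`.
#'
#' @param reads Read placement tibble with columns `read_id, clone_id,
#'   chrom, start, strand, seq` (`start` 1-based in the CAST frame, `seq` on
#'   the transcript strand as sequenced).
#' @param variants A variant table; only rows with `usable = TRUE` are
#'   consulted.
#' @param ref The `diploid_reference` (needed to window-match indels).
#' @return `reads` with an `allele` column in `{"CAST", "129",
#'   "unassigned"}`.
#' @export
assign_reads <- function(reads, variants, ref) {
  reads <- as_tibble(reads)
  if (!nrow(reads)) {
    reads$allele <- character(0)
    return(reads)
  }
  use <- variants[variants$usable, ]
  reads$.len <- nchar(reads$seq)
  ## genomic-forward copy of each read for base comparisons
  fwd <- reads$seq
  neg <- reads$strand == "-"
  fwd[neg] <- revcomp(fwd[neg])

  votes_cast <- integer(nrow(reads))
  votes_129 <- integer(nrow(reads))

  snps <- use[use$kind == "SNP", ]
  for (chrom in unique(reads$chrom)) {
    rix <- which(reads$chrom == chrom)
    vs <- snps[snps$chrom == chrom, ]
    if (!nrow(vs) || !length(rix)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(reads$start[rix], reads$start[rix] + reads$.len[rix] - 1L),
      IRanges::IRanges(vs$pos, vs$pos)
    )
    if (!length(ov)) next
    ri <- rix[S4Vectors::queryHits(ov)]
    vi <- S4Vectors::subjectHits(ov)
    off <- vs$pos[vi] - reads$start[ri] + 1L
    base <- substring(fwd[ri], off, off)
    is_cast <- base == vs$ref[vi]
    is_129 <- base == vs$alt[vi]
    votes_cast <- votes_cast + tabulate(ri[is_cast], nbins = nrow(reads))
    votes_129 <- votes_129 + tabulate(ri[is_129], nbins = nrow(reads))
  }

  indels <- use[use$kind == "indel", ]
  if (nrow(indels)) {
    for (chrom in unique(indels$chrom)) {
      rix <- which(reads$chrom == chrom)
      vs <- indels[indels$chrom == chrom, ]
      if (!length(rix)) next
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(reads$start[rix], reads$start[rix] + reads$.len[rix] - 1L),
        IRanges::IRanges(vs$pos, vs$pos + nchar(vs$ref) - 1L)
      )
      for (k in seq_along(ov)) {
        i <- rix[S4Vectors::queryHits(ov)[k]]
        s <- reads$start[i]
        e <- s + reads$.len[i] - 1L
        win_a <- substring(ref$haplotypes$CAST[[chrom]], s, e)
        sb <- hapb_pos(ref, chrom, s)
        win_b <- substring(ref$haplotypes$`129`[[chrom]], sb, sb + reads$.len[i] - 1L)
        hit_a <- fwd[i] == win_a
        hit_b <- fwd[i] == win_b
        if (hit_a && !hit_b) votes_cast[i] <- votes_cast[i] + 1L
        if (hit_b && !hit_a) votes_129[i] <- votes_129[i] + 1L
      }
    }
  }

  reads$allele <- dplyr::case_when(
    votes_cast > votes_129 ~ "CAST",
    votes_129 > votes_cast ~ "129",
    TRUE ~ "unassigned"
  )
  reads$.len <- NULL
  reads
}

#' Aggregate allele-assigned reads into a per-gene count matrix
#'
#' Reads are attributed to genes by strand-aware interval overlap: a read is
#' counted for the gene whose annotated strand matches the read's strand; a
#' read compatible with two genes on both strands is dropped from gene
#' counting (with a message). Totals are conserved: for every gene,
#' `c_CAST + c_129 + c_unassigned` equals the number of reads counted for
#' it.
#'
#' @param reads Output of [assign_reads()] (needs `clone_id`, `chrom`,
#'   `start`, `strand`, `seq`, `allele`).
#' @param genes Gene tibble (`gene, chrom, start, end, strand`).
#' @return An allele count matrix: tibble `gene, clone_id, c_CAST, c_129,
#'   c_unassigned, total`, one row per gene and clone (zero rows filled in).
#' @export
count_by_gene <- function(reads, genes) {
  reads <- as_tibble(reads)
  genes <- as_tibble(genes)
  clone_ids <- unique(reads$clone_id)
  if (!nrow(reads)) clone_ids <- character(0)

  hits <- NULL
  if (nrow(reads)) {
    rl <- nchar(reads$seq)
    per_chrom <- lapply(unique(reads$chrom), function(chrom) {
      rix <- which(reads$chrom == chrom)
      g <- genes[genes$chrom == chrom, ]
      if (!nrow(g)) return(NULL)
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(reads$start[rix], reads$start[rix] + rl[rix] - 1L),
        IRanges::IRanges(g$start, g$end)
      )
      if (!length(ov)) return(NULL)
      tibble(read = rix[S4Vectors::queryHits(ov)],
             gene = g$gene[S4Vectors::subjectHits(ov)],
             strand_ok = reads$strand[rix[S4Vectors::queryHits(ov)]] ==
               g$strand[S4Vectors::subjectHits(ov)])
    })
    hits <- bind_rows(per_chrom)
  }
  counted <- NULL
  if (!is.null(hits) && nrow(hits)) {
    hits <- hits[hits$strand_ok, ]
    multi <- hits |>
      dplyr::count(.data$read) |>
      filter(.data$n > 1)
    if (nrow(multi)) {
      message(sprintf("%d reads matched two genes on strand; dropped from gene counts",
                      nrow(multi)))
      hits <- hits[!hits$read %in% multi$read, ]
    }
    counted <- tibble(
      gene = hits$gene,
      clone_id = reads$clone_id[hits$read],
      allele = reads$allele[hits$read]
    ) |>
      group_by(.data$gene, .data$clone_id) |>
      summarise(
        c_CAST = sum(.data$allele == "CAST"),
        c_129 = sum(.data$allele == "129"),
        c_unassigned = sum(.data$allele == "unassigned"),
        .groups = "drop"
      )
  }
  grid <- tidyr::expand_grid(gene = genes$gene, clone_id = clone_ids)
  out <- left_join(grid, counted %||% tibble(gene = character(0),
                                             clone_id = character(0),
                                             c_CAST = integer(0),
                                             c_129 = integer(0),
                                             c_unassigned = integer(0)),
                   by = c("gene", "clone_id")) |>
    mutate(across(c("c_CAST", "c_129", "c_unassigned"),
                  ~ ifelse(is.na(.x), 0L, as.integer(.x)))) |>
    mutate(total = .data$c_CAST + .data$c_129 + .data$c_unassigned)
  out
}

#' Allele-specificity statistic
#'
#' Per gene and clone, `s = log2((c_CAST + pseudo) / (c_129 + pseudo))` with
#' a pseudo-count of 10: positive values mean CAST-specific expression,
#' negative 129-specific; the pseudo-count keeps silent genes at 0 and
#' prevents division by zero. The pseudo-count is applied only here, never
#' to the stored counts.
#'
#' @param counts An allele count matrix from [count_by_gene()].
#' @param pseudo Pseudo-count (default 10).
#' @return Tibble `gene, clone_id, c_CAST, c_129, specificity`, of class
#'   `allele_specificity`.
#' @export
allele_specificity <- function(counts, pseudo = 10) {
  out <- counts |>
    mutate(specificity = log2((.data$c_CAST + pseudo) / (.data$c_129 + pseudo))) |>
    select("gene", "clone_id", "c_CAST", "c_129", "specificity")
  class(out) <- c("allele_specificity", class(out))
  out
}

#' Knockout-allele to intact-allele expression ratio
#'
#' For monoallelic deletion clones, the ratio of the focal gene's
#' allele-assigned read count on the deleted allele to the count on the
#' intact allele, averaged across clones. This is the statistic whose value
#' near 0.07 demonstrates that the enhancer acts almost exclusively in cis.
#'
#' @param counts Allele count matrix.
#' @param genotypes Tibble with `clone_id` and either `true_label` (from the
#'   simulator) or `call` + `deleted_allele` (from the genotyping module);
#'   only monoallelic clones are used.
#' @param focal_gene Name of the focal gene (default `"focal"`).
#' @param per_clone Return the per-clone table instead of the mean.
#' @return The mean deleted:intact ratio (or a per-clone tibble).
#' @export
knockout_allele_ratio <- function(counts, genotypes, focal_gene = "focal",
                                  per_clone = FALSE) {
  genotypes <- as_tibble(genotypes)
  if ("true_label" %in% names(genotypes)) {
    mono <- genotypes |>
      filter(grepl("^monoallelic", .data$true_label)) |>
      mutate(deleted_allele = ifelse(.data$true_label == "monoallelic_CAST",
                                     "CAST", "129"))
  } else {
    mono <- filter(genotypes, .data$call == "monoallelic",
                   .data$deleted_allele %in% c("CAST", "129"))
  }
  if (!nrow(mono)) abort("no monoallelic clones in `genotypes`.")
  tab <- counts |>
    filter(.data$gene == focal_gene, .data$clone_id %in% mono$clone_id) |>
    left_join(mono[, c("clone_id", "deleted_allele")], by = "clone_id") |>
    mutate(
      deleted = ifelse(.data$deleted_allele == "CAST", .data$c_CAST, .data$c_129),
      intact = ifelse(.data$deleted_allele == "CAST", .data$c_129, .data$c_CAST)
    ) |>
    select("clone_id", "deleted_allele", "deleted", "intact")
  if (any(tab$intact == 0)) {
    abort("intact-allele count is zero for at least one clone; ratio undefined.")
  }
  tab$ratio <- tab$deleted / tab$intact
  if (per_clone) tab else mean(tab$ratio)
}
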