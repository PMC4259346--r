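#' Simulate the qPCR copy-number genotyping assay
#'
#' Emits triplicate wells for the target assay (primers inside the enhancer)
#' and the control assay (a two-copy control interval on another chromosome).
#' Each well's Ct is `ct0 - log2(copies) + Normal(0, ct_sd)`; alleles whose
#' enhancer interior is deleted (or replaced by the junction inversion
#' insert) contribute no template, and a clone with zero intact copies gets
#' the no-amplification sentinel `NA` in its target wells.
#'
#' @param clone_set A `clone_set`.
#' @param ref The `diploid_reference`.
#' @param config A [sim_config()]; `ct_sd`, `ct0_target`, `ct0_control` are
#'   used.
#' @param replicates Wells per assay (default 3, "in triplicate").
#' @return A Ct table: tibble `clone_id, well, assay, ct` with
#'   `assay` in `{"target", "control"}`.
#' @export
simulate_qpcr <- function(clone_set, ref, config, replicates = 3L) {
  withr::local_seed(derive_seed(config$seed, "qpcr"))
  clones <- clone_set$clones
  rows <- lapply(seq_len(nrow(clones)), function(i) {
    copies <- sum(c(clones$status_CAST[i], clones$status_129[i]) == "intact")
    ct_t <- if (copies == 0) {
      rep(NA_real_, replicates)
    } else {
      config$ct0_target - log2(copies) + rnorm(replicates, 0, config$ct_sd)
    }
    ct_c <- config$ct0_control - log2(2) + rnorm(replicates, 0, config$ct_sd)
    tibble(
      clone_id = clones$clone_id[i],
      well = rep(seq_len(replicates), 2L),
      assay = rep(c("target", "control"), each = replicates),
      ct = c(ct_t, ct_c)
    )
  })
  bind_rows(rows)
}

#' Simulate genomic-DNA allele counts at every variant
#'
#' Balanced binomial sampling at Poisson depth, the input expected by the
#' copy-number-balance and heterozygosity QC filters.
#'
#' @param ref A `diploid_reference`.
#' @param config A [sim_config()]; `dna_depth` is the mean depth.
#' @return Tibble `id, count_CAST, count_129`, one row per variant.
#' @export
simulate_dna_counts <- function(ref, config) {
  withr::local_seed(derive_seed(config$seed, "dna"))
  n <- nrow(ref$variants)
  depth <- rpois(n, config$dna_depth)
  a <- rbinom(n, depth, 0.5)
  tibble(id = ref$variants$id, count_CAST = a, count_129 = depth - a)
}

#' Simulate an anchor-fragment contact profile
#'
#' The focal chromosome (CAST haplotype) is digested at HindIII sites
#' (`AAGCTT`); anchor-to-fragment contact counts are Poisson with mean
#' proportional to `distance^(-hic_decay_exponent)` (midpoint to midpoint),
#' scaled so the profile totals `hic_total_reads` in expectation. Fragments
#' overlapping the enhancer get their mean multiplied by `loop_enrichment`
#' (the planted loop). The anchor is the fragment containing the focal
#' gene's TSS.
#'
#' @param ref A `diploid_reference`.
#' @param config A [sim_config()].
#' @return A list of class `hic_sim`: `fragments` (tibble from
#'   [digest_fragments()]), `contacts` (tibble `frag_i, frag_j, count` with
#'   one end in the anchor) and `anchor` (fragment id).
#' @export
simulate_hic <- function(ref, config) {
  withr::local_seed(derive_seed(config$seed, "hic"))
  chrom <- ref$enhancer$chrom
  frags <- digest_fragments(ref$haplotypes$CAST[[chrom]], chrom = chrom)
  if (nrow(frags) < 2) {
    abort("no restriction site in the focal chromosome; cannot build a profile.")
  }
  fg <- ref$genes[ref$genes$role == "focal", ]
  tss <- if (fg$strand == "+") fg$start else fg$end
  anchor <- frags$fragment_id[frags$start <= tss & tss <= frags$end]
  mid_a <- frags$mid[frags$fragment_id == anchor]

  part <- frags[frags$fragment_id != anchor, ]
  d <- abs(part$mid - mid_a)
  w <- d^(-config$hic_decay_exponent)
  loop <- part$start <= ref$enhancer$end & ref$enhancer$start <= part$end
  w[loop] <- w[loop] * config$loop_enrichment
  mu <- config$hic_total_reads * w / sum(w)
  counts <- rpois(length(mu), mu)
  structure(list(
    fragments = frags,
    contacts = tibble(frag_i = anchor, frag_j = part$fragment_id,
                      count = counts),
    anchor = anchor
  ), class = "hic_sim")
}

#' Simulate deletion-spanning junction amplicons
#'
#' For every deleted or inverted allele, returns the PCR product of primers
#' flanking the cut sites: `amplicon_flank["left"]` bases upstream of the
#' 5' cut plus `amplicon_flank["right"]` bases downstream of the 3' cut from
#' that allele's haplotype, carrying the clone's junction indel (and, for
#' inverted alleles, the reverse-complemented insert, which lengthens the
#' product). Intact alleles yield no amplicon: the un-deleted span is the
#' full-length enhancer region, beyond what the screen's PCR can amplify.
#'
#' @param clone_set A `clone_set`.
#' @param ref The `diploid_reference`.
#' @param config A [sim_config()].
#' @return Tibble `clone_id, allele, amplicon_id, seq, length` (zero rows
#'   for a roster of intact clones).
#' @export
simulate_junctions <- function(clone_set, ref, config) {
  flank <- ref$amplicon_flank
  chrom <- ref$enhancer$chrom
  diag <- ref$variants[ref$variants$id %in% ref$diagnostic, ]
  n_right <- sum(diag$pos > ref$enhancer$end &
                   diag$pos <= ref$enhancer$end + flank[["right"]] - 25L)
  if (n_right < 2) {
    abort(paste0("fewer than two diagnostic SNPs in the right amplicon flank; ",
                 "rebuild the reference with diagnostic SNPs planted there."))
  }
  clones <- clone_set$clones
  rows <- list()
  for (i in seq_len(nrow(clones))) {
    for (a in c("CAST", "129")) {
      st <- if (a == "CAST") clones$status_CAST[i] else clones$status_129[i]
      if (st == "intact") next
      k <- if (a == "CAST") clones$edit_CAST[i] else clones$edit_129[i]
      ins <- if (a == "CAST") clones$insert_CAST[i] else clones$insert_129[i]
      hap <- ref$haplotypes[[a]][[chrom]]
      if (a == "CAST") {
        s <- ref$enhancer$start
        e <- ref$enhancer$end
      } else {
        s <- hapb_pos(ref, chrom, ref$enhancer$start)
        e <- hapb_pos(ref, chrom, ref$enhancer$end + 1L) - 1L
      }
      eat_l <- if (k < 0) ceiling(abs(k) / 2) else 0L
      eat_r <- if (k < 0) abs(k) - eat_l else 0L
      left <- substring(hap, s - flank[["left"]], s - 1L - eat_l)
      right <- substring(hap, e + 1L + eat_r, e + flank[["right"]])
      amp <- paste0(left, ins, right)
      rows[[length(rows) + 1L]] <- tibble(
        clone_id = clones$clone_id[i], allele = a,
        amplicon_id = sprintf("%s_%s_junction", clones$clone_id[i], a),
        seq = amp, length = nchar(amp)
      )
    }
  }
  if (!length(rows)) {
    return(tibble(clone_id = character(0), allele = character(0),
                  amplicon_id = character(0), seq = character(0),
                  length = integer(0)))
  }
  bind_rows(rows)
}
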