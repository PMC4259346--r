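#' Simulation configuration for the synthetic hybrid-ESC deletion experiment
#'
#' Bundles every tunable of the synthetic experiment generator. The defaults
#' describe the study conditions the analysis modules are meant to operate
#' under: an F1 hybrid (CAST x 129) ESC line, a 13-kb-class super-enhancer
#' deletion scaled down to a desk-size genome, a ~7% residual cis activity of
#' the focal gene on a deleted allele, strand-specific 100-bp reads, and
#' distance-decaying restriction-fragment contacts with a planted
#' promoter-enhancer loop.
#'
#' @param seed Integer root seed; every stage derives its own stream from it.
#' @param chrom_length Length (bp) of the focal chromosome carrying the focal
#'   gene and the enhancer.
#' @param control_chrom_length Length (bp) of the second chromosome carrying
#'   the copy-number control interval and the bulk of the gene panel.
#' @param read_length RNA-seq / dummy read length in bp (>= 25).
#' @param n_reads_per_clone Expected number of RNA-seq reads per clone.
#' @param snp_density Planted variants per kb.
#' @param indel_fraction Fraction of intergenic variants planted as indels
#'   (genic variants are always SNPs so reads never straddle an indel).
#' @param cis_residual Fraction of focal-gene expression retained on an allele
#'   whose enhancer is deleted (default 0.07).
#' @param trans_down_factor,trans_up_factor Fold applied to down-/up-signature
#'   genes on both alleles in biallelic deletion clones; monoallelic clones
#'   get the geometric mean of this factor and 1.
#' @param nb_dispersion Residual per-gene negative-binomial dispersion across
#'   clones after the shared clone-level factor (counts are gamma-Poisson with
#'   the gamma factor shared by the two alleles of a gene).
#' @param clone_factor_sd Log-sd of the global per-clone expression factor
#'   (cancels under library-size normalisation).
#' @param ct_sd Per-well qPCR Ct noise SD (cycles).
#' @param ct0_target,ct0_control Baseline Ct of the target / control assay for
#'   a single template copy (primer constants).
#' @param hic_decay_exponent Power of the contact distance decay.
#' @param loop_enrichment Fold enrichment of anchor contacts at fragments
#'   overlapping the enhancer.
#' @param hic_total_reads Expected total anchor-incident contact pairs.
#' @param enhancer_length Enhancer length in bp.
#' @param enhancer_offset Distance (bp) from the focal gene end to the
#'   enhancer (the scaled-down analogue of "100 kb downstream").
#' @param inversion_insert_bp Length of the enhancer-edge segment reinserted
#'   in reverse complement at the junction of an inverted allele.
#' @param junction_indel_p Geometric(p) parameter for junction indel lengths.
#' @param dna_depth Mean genomic-DNA read depth per variant for the
#'   copy-number / heterozygosity QC input.
#' @param seq_error Uniform per-base substitution rate applied to reads.
#' @param n_neutral_genes,n_down_genes,n_up_genes Panel sizes (neutral genes
#'   include six on the focal chromosome).
#' @param amplicon_flank Named integer vector `c(left=, right=)`: bases of
#'   flank either side of the cut sites carried by the junction amplicon.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$cis_residual
sim_config <- function(seed = 1L,
                       chrom_length = 200000L,
                       control_chrom_length = 170000L,
                       read_length = 100L,
                       n_reads_per_clone = 200000L,
                       snp_density = 5,
                       indel_fraction = 0.1,
                       cis_residual = 0.07,
                       trans_down_factor = 0.15,
                       trans_up_factor = 6,
                       nb_dispersion = 0.005,
                       clone_factor_sd = 0.1,
                       ct_sd = 0.15,
                       ct0_target = 24,
                       ct0_control = 23,
                       hic_decay_exponent = 1,
                       loop_enrichment = 5,
                       hic_total_reads = 20000L,
                       enhancer_length = 1300L,
                       enhancer_offset = 20000L,
                       inversion_insert_bp = 250L,
                       junction_indel_p = 0.3,
                       dna_depth = 60L,
                       seq_error = 0,
                       n_neutral_genes = 46L,
                       n_down_genes = 10L,
                       n_up_genes = 10L,
                       amplicon_flank = c(left = 200L, right = 220L)) {
  cfg <- list(
    seed = as.integer(seed),
    chrom_length = as.integer(chrom_length),
    control_chrom_length = as.integer(control_chrom_length),
    read_length = as.integer(read_length),
    n_reads_per_clone = as.integer(n_reads_per_clone),
    snp_density = snp_density,
    indel_fraction = indel_fraction,
    cis_residual = cis_residual,
    trans_down_factor = trans_down_factor,
    trans_up_factor = trans_up_factor,
    nb_dispersion = nb_dispersion,
    clone_factor_sd = clone_factor_sd,
    ct_sd = ct_sd,
    ct0_target = ct0_target,
    ct0_control = ct0_control,
    hic_decay_exponent = hic_decay_exponent,
    loop_enrichment = loop_enrichment,
    hic_total_reads = as.integer(hic_total_reads),
    enhancer_length = as.integer(enhancer_length),
    enhancer_offset = as.integer(enhancer_offset),
    inversion_insert_bp = as.integer(inversion_insert_bp),
    junction_indel_p = junction_indel_p,
    dna_depth = as.integer(dna_depth),
    seq_error = seq_error,
    n_neutral_genes = as.integer(n_neutral_genes),
    n_down_genes = as.integer(n_down_genes),
    n_up_genes = as.integer(n_up_genes),
    amplicon_flank = c(left = as.integer(amplicon_flank[["left"]]),
                       right = as.integer(amplicon_flank[["right"]]))
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$cis_residual < 0 || cfg$cis_residual > 1) {
    abort("`cis_residual` must lie in [0, 1].")
  }
  if (cfg$read_length < 25) abort("`read_length` must be >= 25 bp.")
  counts <- c(cfg$n_reads_per_clone, cfg$hic_total_reads, cfg$dna_depth,
              cfg$n_neutral_genes, cfg$n_down_genes, cfg$n_up_genes)
  if (any(counts < 0)) abort("all counts in the configuration must be >= 0.")
  if (cfg$snp_density < 0) abort("`snp_density` must be >= 0.")
  if (cfg$trans_down_factor <= 0 || cfg$trans_up_factor <= 0) {
    abort("trans factors must be positive.")
  }
  if (cfg$nb_dispersion < 0) abort("`nb_dispersion` must be >= 0.")
  if (cfg$ct_sd < 0) abort("`ct_sd` must be >= 0.")
  if (cfg$seq_error < 0 || cfg$seq_error > 1) abort("`seq_error` must lie in [0, 1].")
  if (cfg$junction_indel_p <= 0 || cfg$junction_indel_p > 1) {
    abort("`junction_indel_p` must lie in (0, 1].")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, "\n")
  cat("  focal chromosome:", x$chrom_length, "bp; control chromosome:",
      x$control_chrom_length, "bp\n")
  cat("  enhancer:", x$enhancer_length, "bp,", x$enhancer_offset,
      "bp downstream of the focal gene\n")
  cat("  cis residual:", x$cis_residual, "; reads/clone:", x$n_reads_per_clone,
      "x", x$read_length, "bp\n")
  invisible(x)
}
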