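# Small study-shaped configurations and hand-built references shared by the
# test files. Fixtures are generated in code; nothing is read from disk.

tiny_cfg <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed, chrom_length = 60000, control_chrom_length = 60000,
    enhancer_offset = 4000, n_reads_per_clone = 20000,
    n_neutral_genes = 10, n_down_genes = 3, n_up_genes = 3,
    hic_total_reads = 5000
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# cache the tiny reference: several files only need it read-only
tiny_ref_cache <- new.env(parent = emptyenv())
tiny_ref <- function() {
  if (is.null(tiny_ref_cache$ref)) {
    tiny_ref_cache$ref <- build_reference(tiny_cfg())
  }
  tiny_ref_cache$ref
}

# Hand-built single-chromosome diploid reference with explicit variants.
# hap_b is derived from hap_a by substituting ALT alleles (positions given
# in the CAST frame), mirroring the package's phasing convention but coded
# independently of build_reference().
toy_reference <- function(hap_a, variants, genes = NULL, seed = 99,
                          chrom = "chrT") {
  variants <- variants[order(variants$pos), ]
  hap_b <- hap_a
  for (i in rev(seq_len(nrow(variants)))) {  # right to left keeps positions valid
    p <- variants$pos[i]
    hap_b <- paste0(
      substring(hap_b, 1, p - 1),
      variants$alt[i],
      substring(hap_b, p + nchar(variants$ref[i]), nchar(hap_b))
    )
  }
  variants$chrom <- chrom
  variants$id <- sprintf("t%03d", seq_len(nrow(variants)))
  variants$kind <- ifelse(nchar(variants$ref) == nchar(variants$alt),
                          "SNP", "indel")
  if (is.null(genes)) {
    genes <- tibble::tibble(
      gene = "focal", chrom = chrom, start = 1L,
      end = nchar(hap_a), strand = "+", length_bp = nchar(hap_a),
      role = "focal", base_expression = 100
    )
  }
  new_reference(
    haplotypes = list(CAST = setNames(hap_a, chrom),
                      `129` = setNames(hap_b, chrom)),
    variants = variants[, c("id", "chrom", "pos", "ref", "alt", "kind")],
    genes = genes,
    enhancer = NULL
  )
}

rand_seq <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# brute-force window enumeration used as the dummy-read oracle
enumerate_windows <- function(hap, span_start, span_end, rl) {
  len <- nchar(hap)
  s <- seq.int(max(1L, span_start - rl + 1L), min(span_end, len - rl + 1L))
  if (!length(s) || s[1] > s[length(s)]) return(character(0))
  substring(hap, s, s + rl - 1L)
}
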