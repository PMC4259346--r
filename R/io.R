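#' Read and write the standard flat formats used by the pipeline
#'
#' Sequences travel as FASTA/FASTQ via Biostrings; variants as VCF 4.2 with
#' the CAST haplotype as the REF frame and phased `0|1` genotypes (QC flags
#' in FILTER); intervals as BED6 (0-based half-open); tables as TSV.
#'
#' @param seqs Named character vector of sequences.
#' @param path File path.
#' @name io
NULL

#' @rdname io
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname io
#' @param reads Read tibble with `read_id` and `seq`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  )
  invisible(path)
}

#' @rdname io
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(x), seq = unname(as.character(x)))
}

#' Write a variant table as VCF
#'
#' Flags, when present, are written to FILTER as `MAPBIAS`/`CNVBIAS`/
#' `POORHET` (`PASS` otherwise); the variant kind goes to INFO. Genotypes
#' are phased `0|1` with CAST as the REF haplotype.
#'
#' @param variants Variant tibble (optionally with QC flag columns).
#' @param path Output path.
#' @param contigs Optional named vector of contig lengths for the header.
#' @export
write_variants_vcf <- function(variants, path, contigs = NULL) {
  v <- as_tibble(variants)
  filter_col <- if ("mapping_bias" %in% names(v)) {
    vapply(seq_len(nrow(v)), function(i) {
      f <- c("MAPBIAS", "CNVBIAS", "POORHET")[c(v$mapping_bias[i],
                                                v$cnv_bias[i], v$poor_het[i])]
      if (length(f)) paste(f, collapse = ";") else "PASS"
    }, character(1))
  } else rep("PASS", nrow(v))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=crisprase",
    if (!is.null(contigs)) {
      sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs)
    },
    "##INFO=<ID=KIND,Number=1,Type=String,Description=\"SNP or indel\">",
    "##FILTER=<ID=MAPBIAS,Description=\"Dummy-read mapping bias\">",
    "##FILTER=<ID=CNVBIAS,Description=\"Allelic copy-number imbalance\">",
    "##FILTER=<ID=POORHET,Description=\"Poor heterozygous call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tF1hybrid"
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t%s\tKIND=%s\tGT\t0|1",
                  v$chrom, v$pos, v$id, v$ref, v$alt, filter_col, v$kind)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF written by [write_variants_vcf()]
#'
#' Uses vcfR; FILTER flags are mapped back onto the QC columns.
#'
#' @param path VCF path.
#' @return A variant tibble with QC flag columns.
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("reading VCF requires the vcfR package.")
  }
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(x@fix, stringsAsFactors = FALSE)
  flt <- fix$FILTER
  tibble(
    id = fix$ID,
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    kind = sub("^KIND=", "", fix$INFO),
    mapping_bias = grepl("MAPBIAS", flt),
    cnv_bias = grepl("CNVBIAS", flt),
    poor_het = grepl("POORHET", flt),
    usable = flt %in% c("PASS", ".")
  )
}

#' @rdname io
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally a
#'   name column (`gene` or `fragment_id`) and `strand`.
#' @export
write_bed <- function(intervals, path) {
  iv <- as_tibble(intervals)
  pick <- function(col, default) if (col %in% names(iv)) iv[[col]] else default
  name <- pick("gene", pick("fragment_id", rep(".", nrow(iv))))
  strand <- pick("strand", rep(".", nrow(iv)))
  readr::write_tsv(
    tibble(chrom = iv$chrom, start = iv$start - 1L, end = iv$end,
           name = name, score = 0L, strand = strand),
    path, col_names = FALSE
  )
  invisible(path)
}
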