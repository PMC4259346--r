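#' Construct a diploid reference object
#'
#' Low-level constructor for the container describing the two phased
#' haplotypes of a hybrid cell line. The "CAST" haplotype is the reference
#' frame (VCF REF); the "129" haplotype carries the ALT allele of every
#' variant. Most users will call [build_reference()], which assembles a
#' complete synthetic reference; this constructor exists so that tests and
#' advanced callers can build small references by hand.
#'
#' @param haplotypes Named list with elements `CAST` and `129`, each a named
#'   character vector of chromosome sequences.
#' @param variants Tibble with columns `id`, `chrom`, `pos` (1-based, CAST
#'   frame), `ref`, `alt`, `kind` (`"SNP"` or `"indel"`).
#' @param genes Tibble with columns `gene`, `chrom`, `start`, `end`, `strand`,
#'   `length_bp`, `role`, `base_expression`.
#' @param enhancer,control_interval,domain One-row tibbles with `chrom`,
#'   `start`, `end` (1-based closed).
#' @param diagnostic Character vector of variant ids flagged as
#'   allele-diagnostic for junction genotyping (must be SNPs in the amplicon
#'   flanks).
#' @param amplicon_flank Named integer vector `c(left=, right=)` of flank
#'   sizes carried by junction amplicons.
#' @return An object of class `diploid_reference`.
#' @export
new_reference <- function(haplotypes, variants, genes, enhancer,
                          control_interval = NULL, domain = NULL,
                          diagnostic = character(0),
                          amplicon_flank = c(left = 200L, right = 220L)) {
  stopifnot(is.list(haplotypes), setequal(names(haplotypes), c("CAST", "129")))
  if (!identical(names(haplotypes$CAST), names(haplotypes$`129`))) {
    abort("both haplotypes must carry the same chromosome names.")
  }
  variants <- as_tibble(variants)
  genes <- as_tibble(genes)
  chrom_len <- vapply(haplotypes$CAST, nchar, integer(1))
  if (nrow(variants)) {
    end_pos <- variants$pos + nchar(variants$ref) - 1L
    if (any(variants$pos < 1L | end_pos > chrom_len[variants$chrom])) {
      abort("every variant must lie within its chromosome bounds.")
    }
  }
  if (nrow(genes)) {
    focal <- genes$role == "focal"
    if (sum(focal) != 1L) abort("exactly one gene must have role 'focal'.")
    fg <- genes[focal, ]
    if (!is.null(enhancer) &&
        fg$chrom == enhancer$chrom &&
        fg$start <= enhancer$end && enhancer$start <= fg$end) {
      abort("the enhancer interval must not overlap the focal gene body.")
    }
  }
  ref <- structure(
    list(
      haplotypes = haplotypes,
      variants = variants,
      genes = genes,
      enhancer = if (is.null(enhancer)) NULL else as_tibble(enhancer),
      control_interval = if (is.null(control_interval)) NULL else as_tibble(control_interval),
      domain = if (is.null(domain)) NULL else as_tibble(domain),
      diagnostic = diagnostic,
      amplicon_flank = amplicon_flank,
      chrom_lengths = chrom_len
    ),
    class = "diploid_reference"
  )
  if (!is.null(ref$domain) && nrow(genes)) {
    fg <- genes[genes$role == "focal", ]
    tss <- if (fg$strand == "+") fg$start else fg$end
    in_domain <- function(chrom, a, b) {
      chrom == ref$domain$chrom && a >= ref$domain$start && b <= ref$domain$end
    }
    if (!in_domain(fg$chrom, tss, tss) ||
        !in_domain(ref$enhancer$chrom, ref$enhancer$start, ref$enhancer$end)) {
      abort("the focal promoter and the enhancer must lie in the declared domain.")
    }
  }
  ref
}

#' @export
print.diploid_reference <- function(x, ...) {
  cat("<diploid_reference>\n")
  cat("  chromosomes:",
      paste(sprintf("%s (%d bp)", names(x$chrom_lengths), x$chrom_lengths),
            collapse = ", "), "\n")
  cat("  variants:", nrow(x$variants),
      sprintf("(%d SNP / %d indel)", sum(x$variants$kind == "SNP"),
              sum(x$variants$kind == "indel")), "\n")
  cat("  genes:", nrow(x$genes), "\n")
  if (!is.null(x$enhancer)) {
    cat("  enhancer:", sprintf("%s:%d-%d", x$enhancer$chrom, x$enhancer$start,
                               x$enhancer$end), "\n")
  }
  invisible(x)
}

#' Build a synthetic diploid hybrid reference
#'
#' Generates a two-chromosome diploid genome emulating an F1 hybrid (CAST x
#' 129) ESC line at desk scale: the focal chromosome carries the focal gene,
#' six neutral genes and a distal enhancer downstream of the focal gene; the
#' control chromosome carries the copy-number control interval (the "Gapdh
#' intron 1" analogue) and the rest of the gene panel. Variants (phased
#' SNPs/indels) are planted at the configured density; two diagnostic SNPs
#' are always planted in the right junction-amplicon flank and one in the
#' left, so that junction sequencing can identify the targeted allele.
#'
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A `diploid_reference`.
#' @export
#' @examples
#' ref <- build_reference(sim_config(seed = 1, chrom_length = 50000,
#'   control_chrom_length = 40000, enhancer_offset = 4000,
#'   n_neutral_genes = 8, n_down_genes = 2, n_up_genes = 2))
#' ref
build_reference <- function(config) {
  validate_sim_config(config)
  withr::local_seed(derive_seed(config$seed, "reference"))
  L3 <- config$chrom_length
  L6 <- config$control_chrom_length
  rl <- config$read_length
  flank <- config$amplicon_flank

  seq3 <- random_dna(L3)
  seq6 <- random_dna(L6)

  ## --- gene panel ------------------------------------------------------
  focal_len <- 2000L
  focal_start <- as.integer(floor(0.3 * L3)) + 1L
  focal_end <- focal_start + focal_len - 1L
  enh_start <- focal_end + config$enhancer_offset + 1L
  enh_end <- enh_start + config$enhancer_length - 1L
  if (enh_end + flank[["right"]] + 200L > L3) {
    abort("focal chromosome too short for the requested enhancer layout.")
  }

  n_chr3_neutral <- min(6L, config$n_neutral_genes)
  neutral3_start <- as.integer(floor(c(0.025, 0.1, 0.2, 0.6, 0.75, 0.9) * L3)) + 1L
  neutral3_start <- neutral3_start[seq_len(n_chr3_neutral)]
  genes3 <- tibble(
    gene = c("focal", sprintf("neu_%02d", seq_len(n_chr3_neutral))),
    chrom = "chr3",
    start = c(focal_start, neutral3_start),
    end = c(focal_end, neutral3_start + 2000L - 1L),
    strand = c("+", rep_len(c("+", "-"), n_chr3_neutral)),
    role = c("focal", rep("neutral", n_chr3_neutral))
  )
  if (any(genes3$end > L3 - rl)) {
    abort("focal chromosome too short for the gene layout.")
  }
  ## genes must not collide with each other or the enhancer/amplicon window
  ivs <- genes3[order(genes3$start), ]
  if (any(diff(ivs$start) < 2100L) ||
      any(ivs$start <= enh_end + flank[["right"]] + 60L &
          ivs$end >= enh_start - flank[["left"]] - 60L)) {
    abort("gene layout collides with itself or the enhancer; enlarge the chromosome.")
  }

  n_chr6_neutral <- config$n_neutral_genes - n_chr3_neutral
  roles6 <- sample(c("control",
                     rep("signature_down", config$n_down_genes),
                     rep("signature_up", config$n_up_genes),
                     rep("neutral", n_chr6_neutral)))
  n6 <- length(roles6)
  len6 <- sample(seq(1000L, 3000L, by = 100L), n6, replace = TRUE)
  start6 <- 3000L + cumsum(c(0L, head(len6, -1) + 300L)) + 1L
  end6 <- start6 + len6 - 1L
  if (max(end6) > L6 - rl) {
    abort("control chromosome too short for the gene panel; enlarge it.")
  }
  name6 <- character(n6)
  name6[roles6 == "control"] <- "ctrl"
  name6[roles6 == "signature_down"] <- sprintf("down_%02d", seq_len(config$n_down_genes))
  name6[roles6 == "signature_up"] <- sprintf("up_%02d", seq_len(config$n_up_genes))
  name6[roles6 == "neutral"] <- sprintf("neu_%02d", n_chr3_neutral + seq_len(n_chr6_neutral))
  genes6 <- tibble(
    gene = name6, chrom = "chr6", start = start6, end = end6,
    strand = rep_len(c("+", "-"), n6), role = roles6
  )

  genes <- bind_rows(genes3, genes6)
  genes$length_bp <- genes$end - genes$start + 1L
  genes$base_expression <- dplyr::case_when(
    genes$role == "focal" ~ 150,
    genes$role == "control" ~ 400,
    genes$role == "signature_down" ~ rlnorm(nrow(genes), log(60), 0.3),
    genes$role == "signature_up" ~ rlnorm(nrow(genes), log(30), 0.3),
    TRUE ~ rlnorm(nrow(genes), log(100), 0.5)
  )
  if (any(genes$length_bp < 200L)) abort("gene lengths must be >= 200 bp.")

  ## --- variants --------------------------------------------------------
  seqs <- list(chr3 = seq3, chr6 = seq6)
  lens <- c(chr3 = L3, chr6 = L6)

  ## diagnostic SNPs around the enhancer cut sites, planted whenever the
  ## genome carries variants at all (snp_density = 0 means two identical
  ## haplotypes, diagnostics included)
  if (config$snp_density > 0) {
    diag_pos <- c(enh_start - 80L, enh_end + 60L, enh_end + 120L)
    diag_tbl <- tibble(chrom = "chr3", pos = diag_pos, kind = "SNP",
                       diagnostic = TRUE)
  } else {
    diag_pos <- integer(0)
    diag_tbl <- tibble(chrom = character(0), pos = integer(0),
                       kind = character(0), diagnostic = logical(0))
  }

  amp_zone <- c(enh_start - flank[["left"]] - 60L, enh_end + flank[["right"]] + 60L)
  draw_positions <- function(chrom) {
    len <- lens[[chrom]]
    lo <- rl + 1L
    hi <- len - rl
    n <- rpois(1, (len / 1000) * config$snp_density)
    if (n > (hi - lo) / 16) {
      abort("`snp_density` too high: planted variants would collide.")
    }
    pos <- sort(sample(lo:hi, n))
    if (!length(pos)) return(integer(0))
    pos <- pos[c(TRUE, diff(pos) >= 8L)]
    if (chrom == "chr3") {
      pos <- pos[!vapply(pos, function(p) any(abs(p - diag_pos) < 8L), logical(1))]
    }
    pos
  }

  var_list <- lapply(c("chr3", "chr6"), function(chrom) {
    pos <- draw_positions(chrom)
    if (!length(pos)) {
      return(tibble(chrom = character(0), pos = integer(0), kind = character(0),
                    diagnostic = logical(0)))
    }
    g <- genes[genes$chrom == chrom, ]
    genic <- vapply(pos, function(p) any(p >= g$start - 4L & p <= g$end + 4L),
                    logical(1))
    in_amp <- chrom == "chr3" & pos >= amp_zone[1] & pos <= amp_zone[2]
    kind <- ifelse(!genic & !in_amp & runif(length(pos)) < config$indel_fraction,
                   "indel", "SNP")
    tibble(chrom = chrom, pos = pos, kind = kind, diagnostic = FALSE)
  })
  variants <- bind_rows(c(list(diag_tbl), var_list))
  variants <- variants[order(variants$chrom, variants$pos), ]

  base_at <- function(chrom, pos, n = 1L) {
    vapply(seq_along(chrom), function(i) {
      substring(seqs[[chrom[i]]], pos[i], pos[i] + n - 1L)
    }, character(1))
  }
  other_base <- function(b) {
    vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
           character(1), USE.NAMES = FALSE)
  }
  n_var <- nrow(variants)
  ref_al <- character(n_var)
  alt_al <- character(n_var)
  is_snp <- variants$kind == "SNP"
  ref_al[is_snp] <- base_at(variants$chrom, variants$pos)[is_snp]
  alt_al[is_snp] <- other_base(ref_al[is_snp])
  for (i in which(!is_snp)) {
    dlen <- sample(1:3, 1)
    if (runif(1) < 0.5) { # deletion on the 129 haplotype
      ref_al[i] <- base_at(variants$chrom[i], variants$pos[i], dlen + 1L)
      alt_al[i] <- substring(ref_al[i], 1L, 1L)
    } else {             # insertion on the 129 haplotype
      ref_al[i] <- base_at(variants$chrom[i], variants$pos[i])
      alt_al[i] <- paste0(ref_al[i], random_dna(dlen))
    }
  }
  variants$ref <- ref_al
  variants$alt <- alt_al
  variants$id <- sprintf("v%05d", seq_len(n_var))
  diagnostic_ids <- variants$id[variants$diagnostic]
  variants <- variants[, c("id", "chrom", "pos", "ref", "alt", "kind")]

  hap_b <- vapply(names(seqs), function(chrom) {
    apply_variants(seqs[[chrom]], variants[variants$chrom == chrom, ])
  }, character(1))

  new_reference(
    haplotypes = list(CAST = unlist(seqs), `129` = hap_b),
    variants = variants,
    genes = genes[, c("gene", "chrom", "start", "end", "strand", "length_bp",
                      "role", "base_expression")],
    enhancer = tibble(chrom = "chr3", start = enh_start, end = enh_end),
    control_interval = tibble(chrom = "chr6", start = 1001L, end = 1600L),
    domain = tibble(chrom = "chr3",
                    start = max(1L, focal_start - 5000L),
                    end = min(L3, enh_end + 5000L)),
    diagnostic = diagnostic_ids,
    amplicon_flank = flank
  )
}

## Substitute ALT alleles into a reference chromosome string.
apply_variants <- function(seq, vars) {
  if (!nrow(vars)) return(seq)
  vars <- vars[order(vars$pos), ]
  pieces <- character(2L * nrow(vars) + 1L)
  cursor <- 1L
  for (i in seq_len(nrow(vars))) {
    p <- vars$pos[i]
    pieces[2L * i - 1L] <- substring(seq, cursor, p - 1L)
    pieces[2L * i] <- vars$alt[i]
    cursor <- p + nchar(vars$ref[i])
  }
  pieces[2L * nrow(vars) + 1L] <- substring(seq, cursor, nchar(seq))
  paste(pieces, collapse = "")
}

#' Project a CAST-frame position onto the 129 haplotype
#'
#' Positions are shifted by the cumulative length difference of all indels
#' strictly upstream. The position itself must not fall inside an indel span.
#'
#' @param ref A `diploid_reference`.
#' @param chrom Chromosome name.
#' @param pos Integer vector of 1-based CAST-frame positions.
#' @return Integer vector of 129-frame positions.
#' @export
hapb_pos <- function(ref, chrom, pos) {
  v <- ref$variants
  v <- v[v$chrom == chrom & v$kind == "indel", ]
  if (!nrow(v)) return(as.integer(pos))
  delta <- nchar(v$alt) - nchar(v$ref)
  vapply(pos, function(p) {
    as.integer(p + sum(delta[v$pos + nchar(v$ref) - 1L < p]))
  }, integer(1))
}

#' Extract a gene's genomic-forward sequence from one haplotype
#'
#' @param ref A `diploid_reference`.
#' @param gene Gene name.
#' @param allele `"CAST"` or `"129"`.
#' @return A DNA string (forward genomic orientation).
#' @export
gene_sequence <- function(ref, gene, allele = c("CAST", "129")) {
  allele <- match.arg(allele)
  g <- ref$genes[ref$genes$gene == gene, ]
  if (!nrow(g)) abort(paste0("unknown gene: ", gene))
  if (allele == "CAST") {
    substring(ref$haplotypes$CAST[[g$chrom]], g$start, g$end)
  } else {
    s <- hapb_pos(ref, g$chrom, g$start)
    substring(ref$haplotypes$`129`[[g$chrom]], s, s + g$length_bp - 1L)
  }
}

#' Variant table with QC flag columns
#'
#' Returns the reference's variants with the three QC flags
#' (`mapping_bias`, `cnv_bias`, `poor_het`) initialised to `FALSE` and
#' `usable = TRUE`; the `variant QC` functions fill them in.
#'
#' @param ref A `diploid_reference`.
#' @return A tibble, one row per variant.
#' @export
variant_table <- function(ref) {
  mutate(ref$variants, mapping_bias = FALSE, cnv_bias = FALSE,
         poor_het = FALSE, usable = TRUE)
}
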