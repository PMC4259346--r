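#' Run the full synthetic experiment end to end
#'
#' Orchestrates every stage from one configuration: reference and clone
#' simulation, genomic-DNA variant QC, per-clone RNA-seq simulation with
#' allele assignment and gene counting, FPKM and signature calling, qPCR
#' genotyping with the deletion-frequency statistic, and the Hi-C anchor
#' loop profile. All randomness flows from `config$seed`, so a rerun with
#' the same configuration reproduces the result exactly.
#'
#' Reads are simulated, assigned and counted one clone at a time so the
#' peak memory stays modest even at deep read counts.
#'
#' @param config A [sim_config()].
#' @param roster Clone roster (default [default_roster()], the 16-clone
#'   screen).
#' @param outdir Optional directory; when given, the main tables and
#'   sequence files are written there and their checksums recorded in the
#'   manifest.
#' @param quiet Suppress stage progress messages.
#' @return An object of class `ase_experiment`: a list with the fitted
#'   tables (`variant_table`, `counts`, `expr`, `specificity`,
#'   `signatures`, `genotypes`, `loops`), the simulated truth (`ref`,
#'   `clones`), headline `metrics`, and a reproducibility `manifest`.
#' @export
run_experiment <- function(config = sim_config(), roster = default_roster(),
                           outdir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  say("stage 1/6: reference and clones")
  ref <- clock("reference", build_reference(config))
  cs <- clock("clones", simulate_clones(ref, roster, config))
  clones <- cs$clones

  say("stage 2/6: variant QC")
  dna <- simulate_dna_counts(ref, config)
  vt <- clock("variantqc", variant_qc(ref, dna, config$read_length,
                                      quiet = quiet))

  say("stage 3/6: RNA-seq, allele assignment, counting")
  counts <- clock("rnaseq", {
    per_clone <- lapply(clones$clone_id, function(cid) {
      sim <- simulate_rnaseq(cs, ref, config, clone_ids = cid)
      assigned <- assign_reads(sim$reads, vt, ref)
      count_by_gene(assigned, ref$genes)
    })
    bind_rows(per_clone)
  })

  say("stage 4/6: expression and signatures")
  expr <- fpkm(
    counts |> select("gene", "clone_id", count = "total"),
    ref$genes
  )
  spec_tbl <- allele_specificity(counts)
  wt_id <- clones$clone_id[clones$true_label == "WT"][1]
  bi_id <- first_or_na(clones$clone_id[clones$true_label == "biallelic"])
  sig <- NULL
  if (!is.na(wt_id) && !is.na(bi_id)) {
    sig <- call_signature(expr, wt_clone = wt_id, mut_clone = bi_id)
  }

  say("stage 5/6: genotyping")
  ct <- simulate_qpcr(cs, ref, config)
  junc <- simulate_junctions(cs, ref, config)
  geno <- clock("genotyping",
                genotype_clones(ct, junc, ref, wt_clone = wt_id,
                                clone_ids = clones$clone_id))
  delfreq <- deletion_frequency(sum(geno$call == "monoallelic"),
                                sum(geno$call == "biallelic"),
                                nrow(geno))

  say("stage 6/6: contact profile and loop calling")
  hic <- simulate_hic(ref, config)
  n_bins <- min(20L, max(4L, nrow(hic$fragments) %/% 3L))
  loops <- clock("loopcall",
                 profile_loops(hic$contacts, hic$fragments, hic$anchor,
                               n_bins = n_bins))

  focal_fpkm <- expr |>
    filter(.data$gene == "focal") |>
    left_join(clones[, c("clone_id", "true_label")], by = "clone_id")
  mean_fpkm <- function(label) {
    x <- focal_fpkm$fpkm[grepl(label, focal_fpkm$true_label)]
    if (length(x)) mean(x) else NA_real_
  }
  f_wt <- mean_fpkm("^WT$")
  kr <- tryCatch(knockout_allele_ratio(counts, clones), error = function(e) NA_real_)

  metrics <- list(
    deletion_frequency = delfreq,
    n_product_positive = sum(geno$product_detected),
    n_biallelic_called = sum(geno$call == "biallelic"),
    n_monoallelic_called = sum(geno$call == "monoallelic"),
    knockout_allele_ratio = kr,
    wt_copy_number = geno$copy_number[geno$clone_id == wt_id],
    reduction_biallelic = 100 * (1 - mean_fpkm("^biallelic$") / f_wt),
    reduction_monoallelic = 100 * (1 - mean_fpkm("^monoallelic") / f_wt),
    n_signature_up = if (is.null(sig)) NA_integer_ else sum(sig$signature == "up"),
    n_signature_down = if (is.null(sig)) NA_integer_ else sum(sig$signature == "down"),
    n_loops = sum(loops$looping),
    loop_hits_enhancer = any(
      loops$looping &
        loops$start <= ref$enhancer$end & ref$enhancer$start <= loops$end
    ),
    n_usable_variants = sum(vt$usable)
  )

  out <- structure(list(
    config = config, ref = ref, clones = clones, variant_table = vt,
    counts = counts, expr = expr, specificity = spec_tbl, signatures = sig,
    ct = ct, genotypes = geno, loops = loops,
    metrics = metrics,
    manifest = list(
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      metrics_hash = rlang::hash(metrics),
      timings = timings,
      files = NULL
    )
  ), class = "ase_experiment")

  if (!is.null(outdir)) out <- write_experiment(out, outdir)
  out
}

write_experiment <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_fasta(x$ref$haplotypes$CAST, p("haplotype_CAST.fa"))
  write_fasta(x$ref$haplotypes$`129`, p("haplotype_129.fa"))
  write_variants_vcf(x$variant_table, p("variants.vcf"),
                     contigs = x$ref$chrom_lengths)
  write_bed(x$ref$genes, p("genes.bed"))
  readr::write_tsv(x$counts, p("allele_counts.tsv"))
  readr::write_tsv(x$expr, p("fpkm.tsv"))
  readr::write_tsv(x$ct, p("ct_table.tsv"))
  readr::write_tsv(as_tibble(x$genotypes), p("genotype_calls.tsv"))
  readr::write_tsv(as_tibble(x$loops), p("loop_profile.tsv"))
  files <- list.files(outdir, full.names = TRUE)
  x$manifest$files <- tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  x
}

#' @export
print.ase_experiment <- function(x, ...) {
  m <- x$metrics
  cat("<ase_experiment>", nrow(x$clones), "clones, seed", x$config$seed, "\n")
  cat(sprintf("  deletion frequency:     %.4f\n", m$deletion_frequency))
  cat(sprintf("  product-positive:       %d/%d\n", m$n_product_positive,
              nrow(x$clones)))
  cat(sprintf("  genotypes called:       %d biallelic, %d monoallelic\n",
              m$n_biallelic_called, m$n_monoallelic_called))
  cat(sprintf("  knockout/intact ratio:  %.3f\n", m$knockout_allele_ratio))
  cat(sprintf("  focal reduction:        %.1f%% (biallelic), %.1f%% (monoallelic)\n",
              m$reduction_biallelic, m$reduction_monoallelic))
  cat(sprintf("  signatures:             %d up, %d down\n",
              m$n_signature_up, m$n_signature_down))
  cat(sprintf("  looping fragments:      %d (enhancer hit: %s)\n",
              m$n_loops, m$loop_hits_enhancer))
  invisible(x)
}

#' Write a small frozen fixture set
#'
#' Generates a miniature experiment (short chromosomes, shallow reads) and
#' writes every input format the analysis modules consume: haplotype FASTA
#' pair, phased VCF, gene/enhancer BED, a FASTQ sample with its ground-truth
#' tag table, the Ct table, junction amplicon FASTA and the fragment contact
#' table, plus a JSON manifest with checksums. Regenerates byte-identically
#' from the pinned seed.
#'
#' @param outdir Output directory (created if needed).
#' @param config Optional [sim_config()]; defaults to a small fixture
#'   configuration with seed 20140101.
#' @return The manifest, invisibly.
#' @export
make_fixtures <- function(outdir, config = NULL) {
  config <- config %||% sim_config(
    seed = 20140101, chrom_length = 60000, control_chrom_length = 60000,
    enhancer_offset = 4000, n_reads_per_clone = 5000,
    n_neutral_genes = 10, n_down_genes = 3, n_up_genes = 3,
    hic_total_reads = 5000
  )
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  ref <- build_reference(config)
  roster <- tibble(clone_id = c("WT01", "M01"),
                   true_label = c("WT", "monoallelic_129"))
  cs <- simulate_clones(ref, roster, config)
  sim <- simulate_rnaseq(cs, ref, config)
  ct <- simulate_qpcr(cs, ref, config)
  junc <- simulate_junctions(cs, ref, config)
  hic <- simulate_hic(ref, config)

  write_fasta(ref$haplotypes$CAST, p("haplotype_CAST.fa"))
  write_fasta(ref$haplotypes$`129`, p("haplotype_129.fa"))
  write_variants_vcf(ref$variants, p("variants.vcf"),
                     contigs = ref$chrom_lengths)
  write_bed(ref$genes, p("genes.bed"))
  write_bed(ref$enhancer, p("enhancer.bed"))
  write_fastq(sim$reads, p("reads.fastq"))
  readr::write_tsv(sim$reads |> select(-"seq"), p("read_truth.tsv"))
  readr::write_tsv(ct, p("ct_table.tsv"))
  write_fasta(setNames(junc$seq, junc$amplicon_id), p("junctions.fa"))
  readr::write_tsv(hic$contacts, p("contacts.tsv"))
  write_bed(hic$fragments, p("fragments.bed"))

  files <- list.files(outdir, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    n_reads = nrow(sim$reads),
    n_variants = nrow(ref$variants),
    anchor = hic$anchor,
    files = lapply(files, function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
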