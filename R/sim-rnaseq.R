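#' Simulate strand-specific allele-tagged RNA-seq reads for deletion clones
#'
#' Implements the generative model of the synthetic experiment. For gene `g`
#' and allele `h` in a clone the expected read count is
#' `mu(g, h) = depth * base_expression(g) * allele_factor(g, h)`, where the
#' allele factor is the cis residual for the focal gene on a deleted (or
#' inverted) allele and 1 otherwise, and trans factors apply to signature
#' genes on both alleles, scaled by deletion dosage (full effect in biallelic
#' clones, the geometric mean of full and none in monoallelic clones).
#' Counts are gamma-Poisson: a per-(gene, clone) gamma factor with variance
#' `nb_dispersion` is shared by the two alleles (so counts are marginally
#' negative binomial but allelic ratios stay Poisson-limited, as in a real
#' hybrid line), on top of a global lognormal clone factor. Reads are
#' `read_length`-bp substrings of the correct haplotype's transcript,
#' reported on the transcript strand (dUTP protocol).
#'
#' @param clone_set A `clone_set` from [simulate_clones()].
#' @param ref The `diploid_reference`.
#' @param config A [sim_config()].
#' @param clone_ids Clones to simulate (default: all in the set).
#' @param emit_reads If `FALSE`, only the ground-truth count table is
#'   generated (fast path for expression-level analyses).
#' @return An object of class `rna_sim`: list with `reads` (tibble
#'   `read_id, clone_id, chrom, start, strand, seq, gene_true, allele_true`,
#'   where `start` is the 1-based CAST-frame start of the genomic-forward
#'   window; `NULL` when `emit_reads = FALSE`) and `counts` (tibble
#'   `clone_id, gene, allele, mu, count`).
#' @export
simulate_rnaseq <- function(clone_set, ref, config, clone_ids = NULL,
                            emit_reads = TRUE) {
  genes <- ref$genes
  if (any(genes$length_bp < config$read_length)) {
    abort("every gene must be at least `read_length` bp long.")
  }
  clones <- clone_set$clones
  if (is.null(clone_ids)) clone_ids <- clones$clone_id
  rl <- config$read_length
  disp <- config$nb_dispersion

  ## haplotype transcript templates (genomic-forward), fixed across clones
  tpl <- list(
    CAST = setNames(vapply(genes$gene, gene_sequence, character(1), ref = ref,
                           allele = "CAST"), genes$gene),
    `129` = setNames(vapply(genes$gene, gene_sequence, character(1), ref = ref,
                            allele = "129"), genes$gene)
  )
  depth <- config$n_reads_per_clone / sum(2 * genes$base_expression)

  read_list <- list()
  count_list <- list()
  for (cid in clone_ids) {
    row <- clones[clones$clone_id == cid, ]
    if (!nrow(row)) abort(paste0("unknown clone: ", cid))
    withr::local_seed(derive_seed(config$seed, "rnaseq",
                                  match(cid, clones$clone_id)))
    dose <- switch(row$true_label, WT = 0, biallelic = 1, 0.5)
    theta_clone <- if (config$clone_factor_sd > 0) {
      rlnorm(1, 0, config$clone_factor_sd)
    } else 1
    theta_gene <- if (disp > 0) {
      rgamma(nrow(genes), shape = 1 / disp, rate = 1 / disp)
    } else rep(1, nrow(genes))

    grid <- tidyr::expand_grid(gene_ix = seq_len(nrow(genes)),
                               allele = c("CAST", "129"))
    grid$gene <- genes$gene[grid$gene_ix]
    role <- genes$role[grid$gene_ix]
    status <- ifelse(grid$allele == "CAST", row$status_CAST, row$status_129)
    factor <- rep(1, nrow(grid))
    factor[role == "focal" & status != "intact"] <- config$cis_residual
    factor[role == "signature_down"] <- config$trans_down_factor^dose
    factor[role == "signature_up"] <- config$trans_up_factor^dose
    mu <- depth * genes$base_expression[grid$gene_ix] * factor *
      theta_clone * theta_gene[grid$gene_ix]
    count <- rpois(nrow(grid), mu)
    count_list[[cid]] <- tibble(clone_id = cid, gene = grid$gene,
                                allele = grid$allele, mu = mu, count = count)

    if (!emit_reads) next
    per <- lapply(which(count > 0), function(j) {
      g <- genes[grid$gene_ix[j], ]
      n <- count[j]
      starts <- sample.int(g$length_bp - rl + 1L, n, replace = TRUE)
      window <- substring(tpl[[grid$allele[j]]][[g$gene]], starts, starts + rl - 1L)
      tibble(
        clone_id = cid, chrom = g$chrom, start = g$start + starts - 1L,
        strand = g$strand,
        seq = if (g$strand == "-") revcomp(window) else window,
        gene_true = g$gene, allele_true = grid$allele[j]
      )
    })
    rd <- bind_rows(per)
    if (config$seq_error > 0 && nrow(rd)) rd$seq <- mutate_bases(rd$seq, config$seq_error)
    rd$read_id <- sprintf("%s_r%06d", cid, seq_len(nrow(rd)))
    read_list[[cid]] <- rd[, c("read_id", "clone_id", "chrom", "start",
                               "strand", "seq", "gene_true", "allele_true")]
  }
  structure(list(
    reads = if (emit_reads) bind_rows(read_list) else NULL,
    counts = bind_rows(count_list)
  ), class = "rna_sim")
}

## uniform substitution errors
mutate_bases <- function(seqs, rate) {
  n_mut <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_mut > 0)
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), n_mut[i])
    for (p in pos) {
      old <- substring(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  seqs
}

#' Per-clone library sizes of a simulated read set
#'
#' @param sim An `rna_sim`.
#' @return Tibble `clone_id`, `library_size` (total simulated reads).
#' @export
library_sizes <- function(sim) {
  sim$counts |>
    group_by(.data$clone_id) |>
    summarise(library_size = sum(.data$count), .groups = "drop")
}

#' @export
print.rna_sim <- function(x, ...) {
  cat("<rna_sim>", length(unique(x$counts$clone_id)), "clones,",
      sum(x$counts$count), "reads",
      if (is.null(x$reads)) "(counts only)" else "", "\n")
  invisible(x)
}
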