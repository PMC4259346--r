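cfg <- tiny_cfg()
ref <- tiny_ref()

# micro reference with two SNPs inside one gene for hand-built reads
micro <- local({
  hap <- rand_seq(1000, 55)
  vars <- tibble::tibble(
    pos = c(200L, 300L),
    ref = substring(hap, c(200, 300), c(200, 300)),
    alt = NA_character_
  )
  vars$alt <- vapply(vars$ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                     character(1))
  genes <- tibble::tibble(gene = "g1", chrom = "chrT", start = 101L, end = 400L,
                          strand = "+", length_bp = 300L, role = "focal",
                          base_expression = 100)
  toy_reference(hap, vars, genes = genes)
})
micro_vt <- variant_table(micro)

micro_read <- function(start, len, hap = "CAST", seq = NULL) {
  s <- if (is.null(seq)) {
    substring(micro$haplotypes[[hap]][["chrT"]], start, start + len - 1L)
  } else seq
  tibble::tibble(read_id = "r1", clone_id = "c1", chrom = "chrT",
                 start = start, strand = "+", seq = s)
}

test_that("single-SNP reads vote for their haplotype; conflicts are unassigned", {
  expect_identical(assign_reads(micro_read(180, 50, "CAST"), micro_vt, micro)$allele,
                   "CAST")
  expect_identical(assign_reads(micro_read(180, 50, "129"), micro_vt, micro)$allele,
                   "129")
  ## chimeric read spanning both SNPs, one base from each haplotype
  chim <- substring(micro$haplotypes$CAST[["chrT"]], 180, 329)
  off <- 300 - 180 + 1
  substr(chim, off, off) <- micro$variants$alt[2]
  expect_identical(assign_reads(micro_read(180, 150, seq = chim), micro_vt,
                                micro)$allele, "unassigned")
  ## a base matching neither haplotype is ignored -> no informative site left
  err <- substring(micro$haplotypes$CAST[["chrT"]], 180, 229)
  bad <- setdiff(c("A", "C", "G", "T"),
                 c(micro$variants$ref[1], micro$variants$alt[1]))[1]
  substr(err, 21, 21) <- bad  # position 200
  expect_identical(assign_reads(micro_read(180, 50, seq = err), micro_vt,
                                micro)$allele, "unassigned")
  ## reads overlapping no variant are unassigned
  expect_identical(assign_reads(micro_read(101, 50, "CAST"), micro_vt,
                                micro)$allele, "unassigned")
})

test_that("indel-spanning windows are matched exactly against one haplotype", {
  hap <- rand_seq(600, 56)
  vars <- tibble::tibble(pos = 300L, ref = substring(hap, 300, 303),
                         alt = substring(hap, 300, 300))  # 3-bp deletion
  genes <- tibble::tibble(gene = "g1", chrom = "chrT", start = 101L, end = 500L,
                          strand = "+", length_bp = 400L, role = "focal",
                          base_expression = 100)
  toy <- toy_reference(hap, vars, genes = genes)
  vt <- variant_table(toy)
  read_a <- tibble::tibble(read_id = "a", clone_id = "c", chrom = "chrT",
                           start = 280L, strand = "+",
                           seq = substring(toy$haplotypes$CAST[["chrT"]], 280, 329))
  ## a 129-origin window, reported at its CAST-frame start
  sb <- hapb_pos(toy, "chrT", 280L)
  read_b <- tibble::tibble(read_id = "b", clone_id = "c", chrom = "chrT",
                           start = 280L, strand = "+",
                           seq = substring(toy$haplotypes$`129`[["chrT"]], sb, sb + 49L))
  out <- assign_reads(dplyr::bind_rows(read_a, read_b), vt, toy)
  expect_identical(out$allele, c("CAST", "129"))
})

test_that("assignment is perfect on error-free simulated reads", {
  cs <- simulate_clones(ref, c("WT", "monoallelic_129"), cfg)
  sim <- simulate_rnaseq(cs, ref, cfg)
  asn <- assign_reads(sim$reads, variant_table(ref), ref)
  called <- asn[asn$allele != "unassigned", ]
  expect_gt(nrow(called) / nrow(asn), 0.3)   # plenty of informative reads
  expect_identical(sum(called$allele != called$allele_true), 0L)
})

test_that("gene counting is conservative and symmetric for wild type", {
  cs <- simulate_clones(ref, "WT", cfg)
  sim <- simulate_rnaseq(cs, ref, cfg)
  asn <- assign_reads(sim$reads, variant_table(ref), ref)
  cm <- count_by_gene(asn, ref$genes)
  expect_identical(sum(cm$total), nrow(sim$reads))
  expect_true(all(cm$total == cm$c_CAST + cm$c_129 + cm$c_unassigned))
  expressed <- cm[cm$total > 200, ]
  expect_true(all(abs(expressed$c_CAST - expressed$c_129) /
                    (expressed$c_CAST + expressed$c_129) < 0.35))
})

test_that("count bookkeeping handles crafted assignments and empty input", {
  reads <- tibble::tibble(
    read_id = sprintf("r%03d", 1:107), clone_id = "c1", chrom = "chrT",
    start = 150L, strand = "+", seq = strrep("A", 50),
    allele = c(rep("CAST", 100), rep("129", 7))
  )
  genes <- tibble::tibble(gene = "g1", chrom = "chrT", start = 101L,
                          end = 400L, strand = "+")
  cm <- count_by_gene(reads, genes)
  expect_identical(cm$c_CAST, 100L)
  expect_identical(cm$c_129, 7L)
  empty <- count_by_gene(reads[0, ], genes)
  expect_identical(nrow(empty), 0L)
  expect_identical(sum(empty$total), 0L)
})

test_that("allele specificity uses the pseudo-count and is antisymmetric", {
  cm <- tibble::tibble(gene = c("a", "b"), clone_id = "c1",
                       c_CAST = c(0L, 90L), c_129 = c(0L, 0L),
                       c_unassigned = 0L, total = c(0L, 90L))
  s <- allele_specificity(cm)
  expect_identical(s$specificity[1], 0)
  expect_equal(s$specificity[2], log2(100 / 10), tolerance = 1e-12)
  withr::with_seed(21, {
    cm2 <- tibble::tibble(gene = sprintf("g%d", 1:30), clone_id = "c",
                          c_CAST = rpois(30, 50), c_129 = rpois(30, 50),
                          c_unassigned = 0L)
    cm2$total <- cm2$c_CAST + cm2$c_129
    swapped <- dplyr::mutate(cm2, tmp = c_CAST, c_CAST = c_129, c_129 = tmp)
    expect_equal(allele_specificity(cm2)$specificity,
                 -allele_specificity(swapped)$specificity)
  })
})

test_that("only the focal gene is allele-specific in monoallelic clones", {
  cs <- simulate_clones(ref, tibble::tibble(
    clone_id = c("M9", "MC"),
    true_label = c("monoallelic_129", "monoallelic_CAST")
  ), cfg)
  sim <- simulate_rnaseq(cs, ref, cfg)
  asn <- assign_reads(sim$reads, variant_table(ref), ref)
  cm <- count_by_gene(asn, ref$genes)
  s <- allele_specificity(cm)
  focal <- s[s$gene == "focal", ]
  expect_gt(focal$specificity[focal$clone_id == "M9"], 1.5)   # CAST-specific
  expect_lt(focal$specificity[focal$clone_id == "MC"], -1.5)  # 129-specific
  other <- s[s$gene != "focal" & (s$c_CAST + s$c_129) > 100, ]
  expect_true(all(abs(other$specificity) < 1))
})

test_that("the knockout:intact ratio is recovered across cis residuals", {
  genotypes <- tibble::tibble(clone_id = c("M1", "M2"),
                              true_label = "monoallelic_129")
  for (eps in c(0, 0.07, 0.5, 1)) {
    cfg_eps <- tiny_cfg(seed = 300 + round(100 * eps), cis_residual = eps,
                        n_reads_per_clone = 50000)
    ref_eps <- build_reference(cfg_eps)
    cs <- simulate_clones(ref_eps, genotypes, cfg_eps)
    sim <- simulate_rnaseq(cs, ref_eps, cfg_eps)
    asn <- assign_reads(sim$reads, variant_table(ref_eps), ref_eps)
    cm <- count_by_gene(asn, ref_eps$genes)
    per <- knockout_allele_ratio(cm, genotypes, per_clone = TRUE)
    est <- mean(per$ratio)
    mc_se <- sqrt(sum(1 / pmax(per$deleted, 1) + 1 / per$intact)) / nrow(per) *
      max(eps, 0.02)
    expect_lt(abs(est - eps), 0.01 + 4 * mc_se)
  }
})

test_that("ratio bookkeeping: crafted counts, equality, and undefined cases", {
  cm <- tibble::tibble(gene = "focal", clone_id = c("M1", "M2"),
                       c_CAST = c(100L, 40L), c_129 = c(7L, 40L),
                       c_unassigned = 0L, total = c(107L, 80L))
  g1 <- tibble::tibble(clone_id = "M1", true_label = "monoallelic_129")
  expect_equal(knockout_allele_ratio(cm, g1), 0.07)
  g2 <- tibble::tibble(clone_id = "M2", true_label = "monoallelic_129")
  expect_equal(knockout_allele_ratio(cm, g2), 1)
  cm0 <- dplyr::mutate(cm, c_129 = c(0L, 0L))
  g3 <- tibble::tibble(clone_id = "M1", true_label = "monoallelic_CAST")
  expect_error(knockout_allele_ratio(cm0, g3), "undefined|zero")
  expect_error(knockout_allele_ratio(cm, g1[0, ]), "monoallelic")
})

test_that("mapping-bias filtering restores allele balance at a repeat SNP", {
  ## gene with two SNPs; SNP1 sits inside a duplicated 300-bp segment whose
  ## second copy matches the CAST sequence, so CAST reads over SNP1 multimap
  d <- rand_seq(300, 91)
  gene_seq <- paste0(substring(d, 1, 150), rand_seq(300, 92),
                     substring(d, 151, 300))
  hap <- paste0(rand_seq(100, 93), substring(d, 1, 150), rand_seq(300, 92),
                substring(d, 151, 300), rand_seq(60, 94), d, rand_seq(100, 95))
  # gene occupies [101, 700]; SNP1 at 175 (inside first half of d), SNP2 at 400
  vars <- tibble::tibble(
    pos = c(175L, 400L),
    ref = substring(hap, c(175, 400), c(175, 400)), alt = NA_character_
  )
  vars$alt <- vapply(vars$ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                     character(1))
  genes <- tibble::tibble(gene = "g1", chrom = "chrT", start = 101L, end = 700L,
                          strand = "+", length_bp = 600L, role = "focal",
                          base_expression = 100)
  toy <- toy_reference(hap, vars, genes = genes)
  rl <- 50L
  starts <- 101:(700 - rl + 1)
  reads <- dplyr::bind_rows(lapply(c("CAST", "129"), function(h) {
    s0 <- if (h == "129") hapb_pos(toy, "chrT", starts) else starts
    tibble::tibble(
      read_id = sprintf("%s_%d", h, starts), clone_id = "c1", chrom = "chrT",
      start = starts, strand = "+",
      seq = substring(toy$haplotypes[[h]][["chrT"]], s0, s0 + rl - 1L)
    )
  }))
  ## emulate unique-placement mapping: multimapping reads are lost
  mapper <- exact_match_mapper(toy)
  kept <- reads[mapper(reads$seq) == 1L, ]
  naive <- allele_specificity(count_by_gene(
    assign_reads(kept, variant_table(toy), toy), genes))
  expect_lt(naive$specificity, -0.3)  # 129-skewed without QC
  dna <- tibble::tibble(id = toy$variants$id, count_CAST = 50L, count_129 = 50L)
  vt <- variant_qc(toy, dna, rl, quiet = TRUE)
  expect_false(vt$usable[vt$id == "t001"])
  expect_true(vt$usable[vt$id == "t002"])
  qc <- allele_specificity(count_by_gene(assign_reads(kept, vt, toy), genes))
  expect_lt(abs(qc$specificity), 0.15)
})
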