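cfg <- tiny_cfg()
ref <- tiny_ref()
cs16 <- simulate_clones(ref, default_roster(), cfg)

test_that("noiseless qPCR reproduces the one-cycle-per-doubling geometry", {
  cfg0 <- tiny_cfg(ct_sd = 0)
  ct <- simulate_qpcr(cs16, ref, cfg0)
  wt <- ct[ct$clone_id == "WT01", ]
  expect_equal(unique(wt$ct[wt$assay == "target"]), cfg0$ct0_target - 1)
  expect_equal(unique(wt$ct[wt$assay == "control"]), cfg0$ct0_control - 1)
  mono <- ct[ct$clone_id == "M01", ]
  ## one lost copy = exactly one extra cycle
  expect_equal(unique(mono$ct[mono$assay == "target"]) -
                 unique(wt$ct[wt$assay == "target"]), 1)
  bi <- ct[ct$clone_id == "B01", ]
  expect_true(all(is.na(bi$ct[bi$assay == "target"])))
  expect_false(anyNA(bi$ct[bi$assay == "control"]))
})

test_that("ddCt copy numbers: reference at exactly 2, mono at 1, missing at 0", {
  cfg0 <- tiny_cfg(ct_sd = 0)
  ct <- simulate_qpcr(cs16, ref, cfg0)
  cn <- ddct_copy_number(ct, "WT01")
  expect_identical(cn$copy_number[cn$clone_id == "WT01"], 2)
  expect_equal(cn$copy_number[cn$clone_id == "M01"], 1)
  expect_identical(cn$copy_number[cn$clone_id == "B01"], 0)
  expect_error(ddct_copy_number(ct[ct$assay == "target", ], "WT01"), "control")
})

test_that("ddCt is invariant to a constant per-clone Ct offset", {
  ct <- simulate_qpcr(cs16, ref, cfg)
  shifted <- dplyr::mutate(ct, ct = ct + ifelse(clone_id == "M02", 1.7, 0))
  expect_equal(ddct_copy_number(ct, "WT01")$copy_number,
               ddct_copy_number(shifted, "WT01")$copy_number)
})

test_that("copy-number classification uses the midpoint bands", {
  expect_identical(classify_genotype(c(2, 1.02, 0.3, 1.5, 0.5, 1.49)),
                   c("WT", "monoallelic", "biallelic", "WT", "monoallelic",
                     "monoallelic"))
  expect_error(classify_genotype(-0.1), ">= 0")
})

test_that("junction amplicons exist only for edited alleles with the right geometry", {
  expect_identical(nrow(simulate_junctions(
    simulate_clones(ref, "WT", cfg), ref, cfg)), 0L)
  roster <- tibble::tibble(clone_id = "M1", true_label = "monoallelic_129",
                           junction_edit = 0L)
  cs <- simulate_clones(ref, roster, cfg)
  amp <- simulate_junctions(cs, ref, cfg)
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$allele, "129")
  expect_identical(amp$length,
                   unname(ref$amplicon_flank[["left"]] + ref$amplicon_flank[["right"]]))
  ## diagnostic bases in the amplicon come from the 129 haplotype
  diag <- ref$variants[ref$variants$id %in% ref$diagnostic &
                         ref$variants$pos > ref$enhancer$end, ]
  off <- ref$enhancer$end + ref$amplicon_flank[["right"]] - diag$pos
  bases <- substring(amp$seq, nchar(amp$seq) - off, nchar(amp$seq) - off)
  expect_identical(bases, diag$alt)
  ## an inversion lengthens the product
  inv <- simulate_junctions(simulate_clones(ref, tibble::tibble(
    clone_id = "H1", true_label = "monoallelic_129", inverted_allele = "129",
    junction_edit = 0L
  ), cfg), ref, cfg)
  expect_identical(inv$length, amp$length + cfg$inversion_insert_bp)
})

test_that("junction-SNP calls identify the targeted allele, ties are ambiguous", {
  junc <- simulate_junctions(cs16, ref, cfg)
  mono <- cs16$clones[grepl("^monoallelic", cs16$clones$true_label), ]
  calls <- vapply(mono$clone_id, function(cl) {
    call_junction_allele(junc$seq[junc$clone_id == cl][1], ref)
  }, character(1))
  expect_identical(sum(calls == "129"), 5L)
  expect_identical(sum(calls == "CAST"), 1L)
  ## chimeric amplicon with one diagnostic base from each haplotype
  amp <- junc$seq[junc$clone_id == "M06"][1]  # CAST-origin amplicon
  diag <- ref$variants[ref$variants$id %in% ref$diagnostic &
                         ref$variants$pos > ref$enhancer$end, ]
  off <- ref$enhancer$end + ref$amplicon_flank[["right"]] - diag$pos[1]
  substr(amp, nchar(amp) - off, nchar(amp) - off) <- diag$alt[1]
  expect_identical(call_junction_allele(amp, ref), "ambiguous")
  expect_error(call_junction_allele("ACGT", ref), "align")
})

test_that("the PCR screen flags every clone with at least one edited allele", {
  junc <- simulate_junctions(cs16, ref, cfg)
  screen <- pcr_screen(junc, cs16$clones$clone_id)
  expect_identical(sum(screen$product_detected), 8L)
  hits <- screen$clone_id[screen$product_detected]
  expect_setequal(hits,
                  cs16$clones$clone_id[cs16$clones$true_label != "WT"])
  expect_true(all(is.na(screen$approx_length[!screen$product_detected])))
  expect_true(all(screen$approx_length[screen$product_detected] < 800))
})

test_that("deletion frequency is exact rational arithmetic with guards", {
  expect_identical(deletion_frequency(6, 2, 16), 0.3125)
  expect_identical(deletion_frequency(0, 0, 16), 0)
  expect_identical(deletion_frequency(0, 5, 5), 1)
  expect_error(deletion_frequency(1, 0, 0), "positive")
  expect_error(deletion_frequency(10, 8, 16), "inconsistent")
  expect_error(deletion_frequency(-1, 0, 16), "inconsistent")
})

test_that("end-to-end genotype recovery is exact at low Ct noise", {
  truth <- c(WT = "WT", monoallelic_129 = "monoallelic",
             monoallelic_CAST = "monoallelic", biallelic = "biallelic")
  junc <- simulate_junctions(cs16, ref, cfg)
  for (s in 1:50) {
    cfg_s <- tiny_cfg(seed = 2000 + s, ct_sd = 0.05)
    ct <- simulate_qpcr(cs16, ref, cfg_s)
    cn <- ddct_copy_number(ct, "WT01")
    call <- classify_genotype(cn$copy_number)
    ok <- identical(unname(truth[cs16$clones$true_label[
      match(cn$clone_id, cs16$clones$clone_id)]]), call)
    if (!ok) {
      fail(sprintf("genotype recovery failed at seed %d", 2000 + s))
      break
    }
  }
  succeed()
})

test_that("recovery stays accurate at the screen's working Ct noise", {
  truth <- c(WT = "WT", monoallelic_129 = "monoallelic",
             monoallelic_CAST = "monoallelic", biallelic = "biallelic")
  wrong <- 0; total <- 0
  for (s in 1:50) {
    cfg_s <- tiny_cfg(seed = 4000 + s, ct_sd = 0.15)
    ct <- simulate_qpcr(cs16, ref, cfg_s)
    cn <- ddct_copy_number(ct, "WT01")
    call <- classify_genotype(cn$copy_number)
    expected <- unname(truth[cs16$clones$true_label[
      match(cn$clone_id, cs16$clones$clone_id)]])
    wrong <- wrong + sum(call != expected)
    total <- total + length(call)
  }
  expect_lte(wrong / total, 0.02)
})

test_that("the combined genotyper reproduces the screen's genotype table", {
  ct <- simulate_qpcr(cs16, ref, tiny_cfg(ct_sd = 0))
  junc <- simulate_junctions(cs16, ref, cfg)
  geno <- genotype_clones(ct, junc, ref, wt_clone = "WT01")
  expect_identical(sum(geno$call == "biallelic"), 2L)
  expect_identical(sum(geno$call == "monoallelic"), 6L)
  expect_identical(sum(geno$deleted_allele == "129"), 5L)
  expect_identical(sum(geno$deleted_allele == "CAST"), 1L)
  g <- glance(geno)
  expect_identical(g$deletion_frequency, 0.3125)
  td <- tidy(geno)
  expect_identical(nrow(td), 16L)
})
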