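# Toy single-chromosome diploid: a mid SNP, an edge SNP and a 3-bp deletion
toy_vqc <- local({
  hap <- rand_seq(400, 31)
  vars <- tibble::tibble(
    pos = c(5L, 200L, 300L),
    ref = c(substring(hap, 5, 5), substring(hap, 200, 200),
            substring(hap, 300, 303)),
    alt = c("X", "X", substring(hap, 300, 300))
  )
  # pick SNP alts different from the reference base
  vars$alt[1] <- setdiff(c("A", "C", "G", "T"), vars$ref[1])[1]
  vars$alt[2] <- setdiff(c("A", "C", "G", "T"), vars$ref[2])[1]
  toy_reference(hap, vars)
})

test_that("dummy-read enumeration equals brute-force window enumeration", {
  rl <- 50L
  for (vid in toy_vqc$variants$id) {
    v <- toy_vqc$variants[toy_vqc$variants$id == vid, ]
    rd <- generate_dummy_reads(v, toy_vqc, rl)
    for (h in c("CAST", "129")) {
      hap <- toy_vqc$haplotypes[[h]][["chrT"]]
      allele_len <- if (h == "CAST") nchar(v$ref) else nchar(v$alt)
      span_start <- if (h == "CAST") v$pos else hapb_pos(toy_vqc, "chrT", v$pos)
      oracle <- enumerate_windows(hap, span_start,
                                  span_start + allele_len - 1L, rl)
      expect_identical(sort(rd$seq[rd$haplotype == h]), sort(oracle))
    }
  }
})

test_that("dummy-read counts follow the affected span", {
  rl <- 50L
  mid <- generate_dummy_reads("t002", toy_vqc, rl)
  expect_identical(nrow(mid), 2L * rl)
  edge <- generate_dummy_reads("t001", toy_vqc, rl)
  expect_identical(sum(edge$haplotype == "CAST"), 5L)  # starts 1..5 only
  del <- generate_dummy_reads("t003", toy_vqc, rl)
  expect_identical(sum(del$haplotype == "CAST") - sum(del$haplotype == "129"),
                   3L)  # 4-bp REF span vs 1-bp ALT span
  expect_error(generate_dummy_reads("t002", toy_vqc, 1000L), "chromosome")
})

test_that("mapping-bias scores follow the unique-and-correct rule", {
  rl <- 50L
  rd <- generate_dummy_reads("t002", toy_vqc, rl)
  all_unique <- assess_mapping_bias(rd, exact_match_mapper(toy_vqc))
  expect_identical(all_unique$bias_score, 0)
  expect_identical(all_unique$m_CAST, rl)
  # mock mapper: 7 of the 129 reads fail to map uniquely
  mock <- function(seqs) {
    hit <- rep(1L, length(seqs))
    hit[rd$haplotype == "129"][1:7] <- 2L
    hit
  }
  biased <- assess_mapping_bias(rd, mock)
  expect_equal(biased$bias_score, 7 / 50)
  expect_error(assess_mapping_bias(rd[0, ], exact_match_mapper(toy_vqc)),
               "empty")
})

test_that("a variant inside a perfect repeat is fully biased and flagged", {
  d <- rand_seq(200, 77)
  hap <- paste0(rand_seq(100, 78), d, rand_seq(80, 79), d, rand_seq(100, 80))
  pos <- 100L + 100L  # centre of the first copy of d
  refb <- substring(hap, pos, pos)
  vars <- tibble::tibble(pos = pos, ref = refb,
                         alt = setdiff(c("A", "C", "G", "T"), refb)[1])
  toy <- toy_reference(hap, vars)
  rep_rd <- generate_dummy_reads("t001", toy, 50L)
  rep_bias <- assess_mapping_bias(rep_rd, exact_match_mapper(toy))
  expect_identical(rep_bias$m_CAST, 0L)   # CAST windows recur in the repeat
  expect_identical(rep_bias$m_129, 50L)   # ALT windows are unique
  expect_identical(rep_bias$bias_score, 1)
  vt <- filter_mapping_bias(variant_table(toy),
                            dplyr::mutate(rep_bias, id = "t001", kind = "SNP"))
  expect_true(vt$mapping_bias)
  expect_false(vt$usable)
})

test_that("bias thresholds are strict and kind-specific", {
  vt <- variant_table(toy_vqc)[rep(1, 4), ]
  vt$id <- sprintf("x%d", 1:4)
  vt$kind <- c("SNP", "SNP", "indel", "indel")
  report <- tibble::tibble(id = vt$id, bias_score = c(0.05, 0.051, 0.10, 0.101))
  out <- filter_mapping_bias(vt, report)
  expect_identical(out$mapping_bias, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("raising the SNP threshold never flags more variants", {
  withr::with_seed(4, {
    vt <- variant_table(toy_vqc)[rep(1, 50), ]
    vt$id <- sprintf("s%02d", 1:50)
    vt$kind <- "SNP"
    report <- tibble::tibble(id = vt$id, bias_score = runif(50, 0, 0.2))
    n_flagged <- vapply(seq(0, 0.2, by = 0.01), function(th) {
      sum(filter_mapping_bias(vt, report, snp_thresh = th)$mapping_bias)
    }, numeric(1))
    expect_true(all(diff(n_flagged) <= 0))
  })
})

test_that("a collision-free genome yields zero mapping-bias flags", {
  cfg <- tiny_cfg(chrom_length = 30000, control_chrom_length = 30000,
                  enhancer_offset = 3000, snp_density = 2)
  ref <- build_reference(cfg)
  report <- qc_mapping_bias(ref, cfg$read_length)
  ## SNP windows are fully haplotype-specific; indels concede only the one
  ## shared window ending at the anchor base, far below threshold
  expect_true(all(report$bias_score[report$kind == "SNP"] == 0))
  expect_true(all(report$bias_score[report$kind == "indel"] < 0.05))
  vt <- filter_mapping_bias(variant_table(ref), report)
  expect_identical(sum(vt$mapping_bias), 0L)
})

test_that("the balance test matches the closed-form binomial and flags extremes", {
  vt <- variant_table(toy_vqc)
  counts <- tibble::tibble(id = vt$id,
                           count_CAST = c(50L, 100L, 55L),
                           count_129 = c(50L, 0L, 45L))
  expect_equal(crisprase:::binom_p_balanced(50, 100), 1)
  expect_equal(crisprase:::binom_p_balanced(0, 100), 2 * 0.5^100)
  out <- cnv_balance_filter(vt, counts, fdr = 0.05)
  expect_identical(out$cnv_bias, c(FALSE, TRUE, FALSE))
})

test_that("the balance test recovers planted imbalanced variants at 5% FDR", {
  hit9 <- 0
  false_rates <- numeric(5)
  for (s in 1:5) {
    withr::with_seed(1000 + s, {
      n_bal <- 300
      depth <- rpois(n_bal + 10, 100)
      a <- c(rbinom(n_bal, depth[1:n_bal], 0.5),
             rbinom(10, depth[n_bal + 1:10], 0.9))
      counts <- tibble::tibble(id = sprintf("v%03d", 1:(n_bal + 10)),
                               count_CAST = a, count_129 = depth - a)
      vt <- tibble::tibble(id = counts$id, chrom = "chrT", pos = 1L,
                           ref = "A", alt = "G", kind = "SNP",
                           mapping_bias = FALSE, cnv_bias = FALSE,
                           poor_het = FALSE, usable = TRUE)
      out <- cnv_balance_filter(vt, counts)
      hit9 <- hit9 + (sum(out$cnv_bias[n_bal + 1:10]) >= 9)
      false_rates[s] <- mean(out$cnv_bias[1:n_bal])
    })
  }
  expect_gte(hit9, 4)                 # planted 90/10 variants nearly always caught
  expect_lte(mean(false_rates), 0.05) # balanced variants respect the FDR
})

test_that("the heterozygosity filter keeps honest hets and drops skewed calls", {
  vt <- variant_table(toy_vqc)
  counts <- tibble::tibble(id = vt$id,
                           count_CAST = c(50L, 100L, 8L),
                           count_129 = c(50L, 1L, 6L))
  out <- het_quality_filter(vt, counts)
  expect_identical(out$poor_het, c(FALSE, TRUE, FALSE))
  expect_identical(out$usable, c(TRUE, FALSE, TRUE))
  # zero-depth variants cannot be validated as heterozygous
  zero <- het_quality_filter(vt, tibble::tibble(id = vt$id,
                                                count_CAST = c(0L, 10L, 10L),
                                                count_129 = c(0L, 10L, 10L)))
  expect_true(zero$poor_het[1])
})

test_that("Benjamini-Hochberg agrees with a sort-based step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n)
    out[o] <- pmin(adj, 1)
    out
  }
  withr::with_seed(9, {
    for (i in 1:20) {
      p <- runif(sample(5:200, 1))^sample(1:3, 1)
      expect_equal(p.adjust(p, method = "BH"), bh_oracle(p))
    }
  })
})
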