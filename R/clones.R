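#' Default clone roster of the synthetic deletion screen
#'
#' Sixteen clones mirroring the genotype spectrum of a double-CRISPR
#' enhancer-deletion screen in a hybrid line: eight wild-type clones, two
#' biallelic deletions, five monoallelic deletions on the 129 allele (one of
#' which carries a short junction inversion instead of a clean fusion) and
#' one monoallelic deletion on the CAST allele.
#'
#' @return A tibble with columns `clone_id`, `true_label` and
#'   `inverted_allele` (`NA` or the allele carrying the inversion).
#' @export
#' @examples
#' default_roster()
default_roster <- function() {
  tibble(
    clone_id = c(sprintf("WT%02d", 1:8), "B01", "B02",
                 sprintf("M%02d", 1:6)),
    true_label = c(rep("WT", 8), rep("biallelic", 2),
                   rep("monoallelic_129", 5), "monoallelic_CAST"),
    inverted_allele = c(rep(NA_character_, 14), "129", NA_character_)
  )
}

clone_labels <- c("WT", "monoallelic_CAST", "monoallelic_129", "biallelic")

#' Simulate CRISPR deletion clones
#'
#' For each roster entry the enhancer interval is excised from the deleted
#' allele(s) and a small NHEJ junction indel (geometric length,
#' deletion-biased 2:1 over insertion, capped at 50 bp) is applied at the
#' fusion point. An inverted allele additionally carries a short segment from
#' the enhancer's 5' edge reinserted in reverse complement at the junction,
#' which lengthens the junction amplicon while still removing the enhancer
#' interior (so its qPCR copy number reads as deleted).
#'
#' @param ref A `diploid_reference`.
#' @param roster Character vector of labels among `"WT"`,
#'   `"monoallelic_CAST"`, `"monoallelic_129"`, `"biallelic"`, or a tibble
#'   as returned by [default_roster()]; an optional `junction_edit` column
#'   (signed bp, applied to every edited allele of that clone) pins the NHEJ
#'   scar for testing.
#' @param config A [sim_config()].
#' @return An object of class `clone_set`: a list with `clones` (tibble of
#'   per-allele status and junction edits) and `genomes` (per clone, the
#'   edited focal-chromosome sequence of each haplotype).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, chrom_length = 60000, control_chrom_length = 60000,
#'   enhancer_offset = 4000, n_neutral_genes = 8, n_down_genes = 2, n_up_genes = 2)
#' ref <- build_reference(cfg)
#' cs <- simulate_clones(ref, c("WT", "biallelic"), cfg)
#' cs$clones
simulate_clones <- function(ref, roster, config) {
  if (is.character(roster)) {
    roster <- tibble(
      clone_id = sprintf("C%02d", seq_along(roster)),
      true_label = roster,
      inverted_allele = NA_character_
    )
  }
  roster <- as_tibble(roster)
  if (!nrow(roster)) abort("`roster` must contain at least one clone.")
  if (!all(roster$true_label %in% clone_labels)) {
    abort("unknown clone label in `roster`.")
  }
  if (!"inverted_allele" %in% names(roster)) roster$inverted_allele <- NA_character_
  withr::local_seed(derive_seed(config$seed, "clones"))

  chrom <- ref$enhancer$chrom
  draw_edit <- function() {
    len <- min(rgeom(1, config$junction_indel_p), 50L)
    if (len == 0L) return(0L)
    if (runif(1) < 2 / 3) -len else len
  }

  status_for <- function(label, allele, inverted_allele) {
    deleted <- switch(label,
      WT = character(0),
      monoallelic_CAST = "CAST",
      monoallelic_129 = "129",
      biallelic = c("CAST", "129")
    )
    if (!allele %in% deleted) return("intact")
    if (!is.na(inverted_allele) && inverted_allele == allele) "inverted" else "deleted"
  }

  rows <- list()
  genomes <- list()
  for (i in seq_len(nrow(roster))) {
    cl <- roster[i, ]
    alleles <- c("CAST", "129")
    st <- vapply(alleles, function(a) status_for(cl$true_label, a, cl$inverted_allele),
                 character(1))
    edit <- setNames(rep(NA_integer_, 2), alleles)
    ins <- setNames(rep(NA_character_, 2), alleles)
    gnm <- list()
    for (a in alleles) {
      if (st[[a]] == "intact") {
        gnm[[a]] <- ref$haplotypes[[a]][[chrom]]
        next
      }
      k <- if ("junction_edit" %in% names(cl)) as.integer(cl$junction_edit) else draw_edit()
      edit[[a]] <- k
      ins_seq <- if (k > 0) random_dna(k) else ""
      if (st[[a]] == "inverted") {
        hap <- ref$haplotypes[[a]][[chrom]]
        es <- if (a == "CAST") ref$enhancer$start else hapb_pos(ref, chrom, ref$enhancer$start)
        inv <- revcomp(substring(hap, es, es + config$inversion_insert_bp - 1L))
        ins_seq <- paste0(inv, ins_seq)
      }
      ins[[a]] <- ins_seq
      gnm[[a]] <- excise_enhancer(ref, a, k, ins_seq)
    }
    rows[[i]] <- tibble(
      clone_id = cl$clone_id, true_label = cl$true_label,
      status_CAST = st[["CAST"]], status_129 = st[["129"]],
      edit_CAST = edit[["CAST"]], edit_129 = edit[["129"]],
      insert_CAST = ins[["CAST"]], insert_129 = ins[["129"]]
    )
    genomes[[cl$clone_id]] <- gnm
  }
  structure(list(clones = bind_rows(rows), genomes = genomes,
                 chrom = chrom),
            class = "clone_set")
}

## Excise the enhancer from one haplotype's focal chromosome and apply the
## junction edit: a net deletion eats ceil/floor halves either side of the
## fusion point; a net insertion (or the inversion insert) goes in between.
excise_enhancer <- function(ref, allele, edit, ins_seq) {
  chrom <- ref$enhancer$chrom
  hap <- ref$haplotypes[[allele]][[chrom]]
  if (allele == "CAST") {
    s <- ref$enhancer$start
    e <- ref$enhancer$end
  } else {
    s <- hapb_pos(ref, chrom, ref$enhancer$start)
    e <- hapb_pos(ref, chrom, ref$enhancer$end + 1L) - 1L
  }
  pre <- substring(hap, 1L, s - 1L)
  post <- substring(hap, e + 1L, nchar(hap))
  if (edit < 0) {
    eat_l <- ceiling(abs(edit) / 2)
    eat_r <- abs(edit) - eat_l
    pre <- substring(pre, 1L, nchar(pre) - eat_l)
    post <- substring(post, eat_r + 1L, nchar(post))
  }
  paste0(pre, ins_seq, post)
}

#' @export
print.clone_set <- function(x, ...) {
  cat("<clone_set>", nrow(x$clones), "clones\n")
  print(dplyr::count(x$clones, .data$true_label))
  invisible(x)
}

#' Full genome of one clone allele
#'
#' Returns the clone's chromosome sequences for one haplotype (the edited
#' focal chromosome plus the unedited remainder of that haplotype).
#'
#' @param clone_set A `clone_set`.
#' @param ref The `diploid_reference` the clones were simulated from.
#' @param clone_id Clone identifier.
#' @param allele `"CAST"` or `"129"`.
#' @return Named character vector of chromosome sequences.
#' @export
clone_genome <- function(clone_set, ref, clone_id, allele = c("CAST", "129")) {
  allele <- match.arg(allele)
  gnm <- ref$haplotypes[[allele]]
  gnm[[clone_set$chrom]] <- clone_set$genomes[[clone_id]][[allele]]
  gnm
}
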