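#' FPKM from raw counts
#'
#' `FPKM = count * 1e9 / (length_bp * mapped_reads)`. Library sizes default
#' to the per-clone total of the supplied counts; FPKM is invariant under a
#' common rescaling of counts and library size.
#'
#' @param counts Tidy count tibble `gene, clone_id, count`.
#' @param genes Gene tibble with `gene` and `length_bp`.
#' @param library_sizes Optional tibble `clone_id, library_size`; defaults
#'   to column sums of `counts`.
#' @return Tibble `gene, clone_id, count, fpkm`.
#' @export
fpkm <- function(counts, genes, library_sizes = NULL) {
  counts <- as_tibble(counts)
  genes <- as_tibble(genes)
  if (any(genes$length_bp <= 0)) abort("gene lengths must be positive.")
  if (is.null(library_sizes)) {
    library_sizes <- counts |>
      group_by(.data$clone_id) |>
      summarise(library_size = sum(.data$count), .groups = "drop")
  }
  if (any(library_sizes$library_size <= 0)) {
    abort("library sizes must be positive.")
  }
  counts |>
    left_join(genes[, c("gene", "length_bp")], by = "gene") |>
    left_join(library_sizes, by = "clone_id") |>
    mutate(fpkm = .data$count * 1e9 / (.data$length_bp * .data$library_size)) |>
    select("gene", "clone_id", "count", "fpkm")
}

#' Call up/down signature genes between two clones
#'
#' A pseudo-count of 4 is added to every FPKM and genes changing at least
#' `fold`-fold are called: up when
#' `(FPKM_mut + pseudo) / (FPKM_wt + pseudo) >= fold`, down when the ratio
#' is `<= 1/fold` (the boundary counts as a call). Comparing single clones
#' without replicates mirrors the screen design this models; pass
#' pre-averaged FPKM columns for a replicate-mean comparison.
#'
#' @param expr FPKM tibble from [fpkm()].
#' @param wt_clone,mut_clone Clone ids to compare.
#' @param pseudo FPKM pseudo-count (default 4).
#' @param fold Fold-change cutoff (default 3).
#' @return An object of class `signature_calls`: tibble `gene, fpkm_wt,
#'   fpkm_mut, fold_change, signature` with `signature` in
#'   `{"up", "down", "none"}`.
#' @export
call_signature <- function(expr, wt_clone, mut_clone, pseudo = 4, fold = 3) {
  w <- expr[expr$clone_id == wt_clone, c("gene", "fpkm")]
  m <- expr[expr$clone_id == mut_clone, c("gene", "fpkm")]
  if (!nrow(w) || !nrow(m)) abort("both clones must be present in `expr`.")
  out <- left_join(rename(w, fpkm_wt = "fpkm"), rename(m, fpkm_mut = "fpkm"),
                   by = "gene") |>
    mutate(
      fold_change = (.data$fpkm_mut + pseudo) / (.data$fpkm_wt + pseudo),
      signature = dplyr::case_when(
        .data$fold_change >= fold ~ "up",
        .data$fold_change <= 1 / fold ~ "down",
        TRUE ~ "none"
      )
    )
  attr(out, "wt_clone") <- wt_clone
  attr(out, "mut_clone") <- mut_clone
  class(out) <- c("signature_calls", class(out))
  out
}

new_enrichment_result <- function(fields) {
  structure(fields, class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result>", x$description, "\n")
  cat(sprintf("  %d/%d vs %d/%d, p = %.3g\n",
              x$k_down_bound, x$n_down, x$k_up_bound, x$n_up, x$p_value))
  invisible(x)
}

#' Promoter-binding enrichment between signature directions
#'
#' Tests whether factor binding at promoters is unequally distributed
#' between the down- and up-regulated signature lists: the bound fraction of
#' the down list is compared against the pooled bound fraction of both lists
#' with a two-sided exact binomial test.
#'
#' @param down_genes,up_genes Character vectors of signature genes.
#' @param bound_genes Character vector of genes with factor binding at the
#'   promoter.
#' @return An `enrichment_result` with counts and the two-sided p-value.
#' @export
promoter_binding_enrichment <- function(down_genes, up_genes, bound_genes) {
  if (!length(down_genes) || !length(up_genes)) {
    abort("both signature lists must be non-empty.")
  }
  k_down <- sum(down_genes %in% bound_genes)
  k_up <- sum(up_genes %in% bound_genes)
  n_down <- length(down_genes)
  n_up <- length(up_genes)
  p0 <- (k_down + k_up) / (n_down + n_up)
  p <- binom.test(k_down, n_down, p = p0, alternative = "two.sided")$p.value
  new_enrichment_result(list(
    description = "promoter binding: down vs pooled signature fraction",
    k_down_bound = k_down, n_down = n_down,
    k_up_bound = k_up, n_up = n_up,
    p0 = p0, p_value = p
  ))
}

#' Directional overlap test between two gene signatures
#'
#' For each directional quadrant (A-up vs B-up, A-up vs B-down, ...) the
#' observed overlap is tested against the chance expectation
#' `|A| * |B| / universe` with an upper binomial tail
#' (`P(X >= overlap | |A|, |B|/U)`): small p-values mean the two signatures
#' share more genes in that direction pair than expected.
#'
#' @param sig_a,sig_b Named lists with character vectors `up` and `down`.
#' @param universe Number of genes in the testable universe.
#' @return Tibble `quadrant, n_a, n_b, overlap, expected, p_value`.
#' @export
signature_overlap_test <- function(sig_a, sig_b, universe) {
  all_genes <- unique(c(sig_a$up, sig_a$down, sig_b$up, sig_b$down))
  if (universe < length(all_genes)) {
    abort("`universe` is smaller than the union of the gene lists.")
  }
  quad <- tidyr::expand_grid(a = c("up", "down"), b = c("up", "down"))
  rows <- lapply(seq_len(nrow(quad)), function(i) {
    ga <- sig_a[[quad$a[i]]]
    gb <- sig_b[[quad$b[i]]]
    k <- sum(ga %in% gb)
    p_chance <- length(gb) / universe
    p <- if (length(ga)) {
      pbinom(k - 1L, length(ga), p_chance, lower.tail = FALSE)
    } else NA_real_
    tibble(
      quadrant = paste0("A_", quad$a[i], ":B_", quad$b[i]),
      n_a = length(ga), n_b = length(gb), overlap = k,
      expected = length(ga) * length(gb) / universe, p_value = p
    )
  })
  bind_rows(rows)
}
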