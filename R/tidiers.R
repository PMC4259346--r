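#' Tidy a fitted experiment into a per-clone summary
#'
#' One row per clone: the true simulated genotype, the genotyping call and
#' copy number, the focal gene's FPKM and its allele-specificity value.
#'
#' @param x An `ase_experiment` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble with one row per clone.
#' @export
tidy.ase_experiment <- function(x, ...) {
  focal <- x$expr |>
    filter(.data$gene == "focal") |>
    select("clone_id", focal_fpkm = "fpkm")
  spec <- x$specificity |>
    filter(.data$gene == "focal") |>
    select("clone_id", focal_specificity = "specificity")
  x$clones |>
    select("clone_id", "true_label") |>
    left_join(as_tibble(x$genotypes) |>
                select("clone_id", "product_detected", "copy_number", "call",
                       "deleted_allele"),
              by = "clone_id") |>
    left_join(focal, by = "clone_id") |>
    left_join(spec, by = "clone_id")
}

#' One-row summary of a fitted experiment
#'
#' @inheritParams tidy.ase_experiment
#' @return A one-row tibble of the headline metrics.
#' @export
glance.ase_experiment <- function(x, ...) {
  as_tibble(x$metrics[c(
    "deletion_frequency", "n_product_positive", "n_biallelic_called",
    "n_monoallelic_called", "knockout_allele_ratio", "wt_copy_number",
    "reduction_biallelic", "reduction_monoallelic", "n_signature_up",
    "n_signature_down", "n_loops", "n_usable_variants"
  )])
}

#' @export
tidy.loop_profile <- function(x, ...) {
  as_tibble(x)[, c("fragment_id", "chrom", "start", "end", "distance",
                   "observed", "expected", "p_value", "p_adj", "looping")]
}

#' @export
glance.loop_profile <- function(x, ...) {
  tibble(
    anchor = attr(x, "anchor") %||% NA_character_,
    n_fragments = nrow(x),
    n_looping = sum(x$looping),
    total_contacts = sum(x$observed)
  )
}

#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(
    k_down_bound = x$k_down_bound, n_down = x$n_down,
    k_up_bound = x$k_up_bound, n_up = x$n_up,
    null_fraction = x$p0, p.value = x$p_value
  )
}

#' @export
glance.enrichment_result <- function(x, ...) tidy(x)

#' @export
tidy.signature_calls <- function(x, ...) as_tibble(x)

#' @export
glance.signature_calls <- function(x, ...) {
  tibble(
    wt_clone = attr(x, "wt_clone"),
    mut_clone = attr(x, "mut_clone"),
    n_up = sum(x$signature == "up"),
    n_down = sum(x$signature == "down"),
    n_tested = nrow(x)
  )
}

#' @export
tidy.genotype_calls <- function(x, ...) as_tibble(x)

#' @export
glance.genotype_calls <- function(x, ...) {
  tibble(
    n_clones = nrow(x),
    n_product_positive = sum(x$product_detected),
    n_wt = sum(x$call == "WT"),
    n_monoallelic = sum(x$call == "monoallelic"),
    n_biallelic = sum(x$call == "biallelic"),
    deletion_frequency = deletion_frequency(
      sum(x$call == "monoallelic"), sum(x$call == "biallelic"), nrow(x)
    )
  )
}
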