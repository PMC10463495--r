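# Post-hoc evidence screens on per-gene result tables: free-ratio dN/dS
# curation, positively-selected-gene intersection, and differential-
# expression thresholds with a cross-region direction summary.  All filters
# are pure, idempotent functions of their tables.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(what, ": missing column(s) ", paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Curate free-ratio dN/dS estimates
#'
#' Removes genes whose per-branch codon-model estimates are unreliable: a
#' record is dropped when `dS > 1`, when the inferred nonsynonymous site
#' count exceeds the sequence length (`N > sequence_length`), when
#' `N + S_sites >= sequence_length + 50`, or when either expected
#' substitution count is below one (`N * dN < 1` or `S_sites * dS < 1`).
#' Every removed record carries all the reasons that apply.
#'
#' @param records Data frame with columns `gene`, `dN`, `dS`, `N`,
#'   `S_sites`, `sequence_length`.
#' @return A list with `kept` (tibble), `removed` (tibble with a `reason`
#'   column, `;`-separated), and `mean_dnds` (mean `dN/dS` of kept genes,
#'   `NA` if none or if any kept gene has `dS = 0`-safe division handled by
#'   dropping non-finite ratios).
#' @export
#' @examples
#' tab <- tibble::tibble(gene = c("g1", "g2"), dN = c(0.05, 0.2),
#'                       dS = c(0.5, 1.2), N = c(400, 400),
#'                       S_sites = c(200, 200), sequence_length = c(700, 700))
#' curate_dnds(tab)$removed
curate_dnds <- function(records) {
  records <- tibble::as_tibble(records)
  require_columns(records, c("gene", "dN", "dS", "N", "S_sites", "sequence_length"),
                  "curate_dnds")
  reasons <- cbind(
    `dS>1` = records$dS > 1,
    `N>length` = records$N > records$sequence_length,
    `N+S>=length+50` = records$N + records$S_sites >= records$sequence_length + 50,
    `N*dN<1` = records$N * records$dN < 1,
    `S*dS<1` = records$S_sites * records$dS < 1
  )
  drop <- rowSums(reasons) > 0
  removed <- records[drop, , drop = FALSE]
  removed$reason <- apply(reasons[drop, , drop = FALSE], 1, function(r)
    paste(colnames(reasons)[r], collapse = ";"))
  kept <- records[!drop, , drop = FALSE]
  ratio <- kept$dN / kept$dS
  list(
    kept = kept,
    removed = removed,
    mean_dnds = if (nrow(kept) == 0) NA_real_ else mean(ratio[is.finite(ratio)])
  )
}

#' Intersect positive-selection screens
#'
#' A gene is a final positively selected gene (PSG) only when both codon
#' frameworks agree: the branch-site likelihood-ratio test is significant
#' (`lrt_fdr_paml < 0.05`) with at least one site at Bayes-empirical-Bayes
#' posterior above 0.95 (`beb_max_posterior > 0.95`), and the
#' multi-nucleotide-aware test is also significant (`lrt_fdr_hyphy < 0.05`).
#' All comparisons are strict, as stated by the screen.
#'
#' @param records Data frame with columns `gene`, `lrt_fdr_paml`,
#'   `beb_max_posterior`, `lrt_fdr_hyphy`; gene ids must be unique.
#' @return Tibble of retained genes, sorted by `gene`.
#' @export
intersect_psgs <- function(records) {
  records <- tibble::as_tibble(records)
  require_columns(records, c("gene", "lrt_fdr_paml", "beb_max_posterior", "lrt_fdr_hyphy"),
                  "intersect_psgs")
  if (anyDuplicated(records$gene)) {
    stop("intersect_psgs: duplicate gene ids", call. = FALSE)
  }
  kept <- dplyr::filter(records,
                        .data$lrt_fdr_paml < 0.05,
                        .data$beb_max_posterior > 0.95,
                        .data$lrt_fdr_hyphy < 0.05)
  dplyr::arrange(kept, .data$gene)
}

DEG_REGIONS <- c("FB", "MB", "HB")

#' Filter differentially expressed genes
#'
#' Keeps records with `fdr <= 0.05`, `basemean >= 10`, and absolute effect
#' size `|log2fc| >= 0.3` (the effect-size threshold is applied to the
#' magnitude since both up- and down-regulated genes are reported).  All
#' comparisons are inclusive.
#'
#' @param records Data frame with columns `gene`, `region` (one of FB, MB,
#'   HB), `fdr`, `basemean`, `log2fc`.
#' @return Tibble of retained records with an added `direction` column
#'   (`"up"`/`"down"`).
#' @export
filter_degs <- function(records) {
  records <- tibble::as_tibble(records)
  require_columns(records, c("gene", "region", "fdr", "basemean", "log2fc"),
                  "filter_degs")
  bad <- setdiff(unique(records$region), DEG_REGIONS)
  if (length(bad) > 0) {
    stop("filter_degs: unknown region label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  kept <- dplyr::filter(records,
                        .data$fdr <= 0.05,
                        .data$basemean >= 10,
                        abs(.data$log2fc) >= 0.3)
  dplyr::mutate(kept, direction = ifelse(.data$log2fc < 0, "down", "up"))
}

#' Summarise expression-change direction across brain regions
#'
#' Takes the filtered DEG records of all regions, forms the union of genes
#' that are differentially expressed in at least one region, and reports the
#' fraction whose expression change is downward in *every region where they
#' are a DEG*.  Because "consistently down across all regions" can also be
#' read as requiring DEG status in all regions, that stricter count is
#' reported alongside.
#'
#' @param degs Filtered DEG tibble (output of [filter_degs()], any number of
#'   regions bound together).
#' @return One-row tibble: `n_union`, `n_down_consistent`,
#'   `pct_down_consistent`, `n_deg_all_regions_down`,
#'   `pct_deg_all_regions_down` (percentages of `n_union`; `NA` when the
#'   union is empty).
#' @export
summarize_deg_direction <- function(degs) {
  degs <- tibble::as_tibble(degs)
  require_columns(degs, c("gene", "region", "direction"), "summarize_deg_direction")
  per_gene <- dplyr::summarise(
    dplyr::group_by(degs, .data$gene),
    n_regions = dplyr::n_distinct(.data$region),
    all_down = all(.data$direction == "down"),
    .groups = "drop"
  )
  n_union <- nrow(per_gene)
  n_down <- sum(per_gene$all_down)
  n_strict <- sum(per_gene$all_down & per_gene$n_regions == length(DEG_REGIONS))
  tibble::tibble(
    n_union = n_union,
    n_down_consistent = n_down,
    pct_down_consistent = if (n_union == 0) NA_real_ else 100 * n_down / n_union,
    n_deg_all_regions_down = n_strict,
    pct_deg_all_regions_down = if (n_union == 0) NA_real_ else 100 * n_strict / n_union
  )
}
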