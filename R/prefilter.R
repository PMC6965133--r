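#' Taxonomy-based ASV prefilter
#'
#' Removes, ahead of decontamination, the ASVs a 16S pipeline cannot use:
#' (i) ASVs with no domain-level assignment (`unassigned`); (ii) ASVs
#' assigned to a domain but not to any phylum, or whose lineage carries a
#' mitochondrial token — these are mostly host mitochondrial reads
#' (`unclassified_bacteria`); (iii) ASVs whose lineage contains a
#' chloroplast token (`chloroplast`). Rules are applied in that order and
#' the first match wins, so every removed ASV has exactly one recorded
#' reason.
#'
#' @param table ASV table.
#' @param taxonomy Taxonomy map covering every ASV in `table`.
#' @return The filtered table, with a [prefilter_report()] attached as the
#'   `"prefilter"` attribute.
#' @export
taxonomy_prefilter <- function(table, taxonomy) {
  ranks <- taxonomy_ranks(taxonomy)
  ids <- asv_ids(table)
  missing <- setdiff(ids, ranks$asv_id)
  if (length(missing)) {
    abort(paste0("ASVs missing from taxonomy: ",
                 paste(head(missing, 10), collapse = ", ")))
  }
  ranks <- ranks[match(ids, ranks$asv_id), ]
  lineage <- taxonomy$lineage[match(ids, taxonomy$asv_id)]
  lineage[is.na(lineage)] <- ""

  unassigned <- is.na(ranks$domain)
  mito <- stringr::str_detect(lineage, stringr::regex("mitochondri",
                                                      ignore_case = TRUE))
  unclassified <- !unassigned & (is.na(ranks$phylum) | mito)
  chloro <- stringr::str_detect(lineage, stringr::regex("chloroplast",
                                                        ignore_case = TRUE))
  chloro <- !unassigned & !unclassified & chloro

  reason <- rep(NA_character_, length(ids))
  reason[chloro] <- "chloroplast"
  reason[unclassified] <- "unclassified_bacteria"
  reason[unassigned] <- "unassigned"

  drop <- !is.na(reason)
  removed <- tibble::tibble(asv_id = ids[drop], reason = reason[drop])
  out <- table[, c("sample_id", ids[!drop]), drop = FALSE]
  attr(out, "prefilter") <- new_prefilter_report(table, out, removed,
                                                list(rule = "taxonomy"))
  out
}

#' Minimum dataset-wide count filter
#'
#' Drops ASVs detected fewer than `min_total` times across the entire
#' dataset (all samples in `table`, negative controls included). The
#' inequality is strict: an ASV totalling exactly `min_total` reads is
#' retained.
#'
#' @param table ASV table.
#' @param min_total Minimum dataset-wide read count (default 10).
#' @return The filtered table with a `"prefilter"` report attribute.
#' @export
min_total_count_filter <- function(table, min_total = 10) {
  if (min_total < 1) abort("`min_total` must be >= 1.")
  m <- asv_matrix(table)
  tot <- colSums(m)
  drop <- tot < min_total
  removed <- tibble::tibble(asv_id = colnames(m)[drop],
                            reason = "min_total_count")
  out <- table[, c("sample_id", colnames(m)[!drop]), drop = FALSE]
  attr(out, "prefilter") <- new_prefilter_report(
    table, out, removed, list(rule = "min_total_count", min_total = min_total))
  out
}

#' Exclude samples with too few accepted reads
#'
#' After decontamination, samples whose accepted read total falls below
#' `min_reads` carry too little signal for composition analysis and are
#' excluded. Negative controls are exempt: their (tiny) post-filter totals
#' are a reported quality metric, not analysed communities.
#'
#' @param table ASV table (intended: the decontaminated table).
#' @param metadata Sample metadata; used only to exempt controls. `NULL`
#'   treats every sample as a non-control.
#' @param min_reads Read threshold (default 1500); strictly-below samples
#'   are excluded.
#' @return Filtered table; attribute `"excluded_samples"` lists the dropped
#'   sample ids.
#' @export
exclude_low_read_samples <- function(table, metadata = NULL, min_reads = 1500) {
  m <- asv_matrix(table)
  depth <- rowSums(m)
  exempt <- rep(FALSE, nrow(m))
  if (!is.null(metadata)) {
    ct <- metadata$control_type[match(rownames(m), metadata$sample_id)]
    exempt <- !is.na(ct) & ct != "none"
  }
  drop <- depth < min_reads & !exempt
  out <- table[!drop, , drop = FALSE]
  attr(out, "excluded_samples") <- rownames(m)[drop]
  out
}

new_prefilter_report <- function(before, after, removed, params) {
  pre <- rowSums(asv_matrix(before))
  post <- rowSums(asv_matrix(after))
  structure(
    list(
      removed_asvs = removed,
      reads_removed_per_sample = tibble::tibble(
        sample_id = names(pre),
        reads_removed = unname(pre - post[names(pre)])
      ),
      params = params
    ),
    class = "prefilter_report"
  )
}

#' Retrieve a prefilter report
#'
#' @param table A table returned by [taxonomy_prefilter()] or
#'   [min_total_count_filter()].
#' @return A `prefilter_report` (removed ASVs with reasons, reads removed
#'   per sample, parameters), or `NULL` if none is attached.
#' @export
prefilter_report <- function(table) attr(table, "prefilter")

#' @export
print.prefilter_report <- function(x, ...) {
  cat("Prefilter (", x$params$rule, "): ", nrow(x$removed_asvs),
      " ASVs removed, ", sum(x$reads_removed_per_sample$reads_removed),
      " reads\n", sep = "")
  invisible(x)
}

#' @export
tidy.prefilter_report <- function(x, ...) x$removed_asvs

#' Write a prefilter report to disk
#'
#' Emits the removed-ASV table as TSV and the parameters as JSON.
#'
#' @param report A `prefilter_report`.
#' @param tsv,json Output paths (either may be `NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_prefilter_report <- function(report, tsv = NULL, json = NULL) {
  if (!is.null(tsv)) readr::write_tsv(report$removed_asvs, tsv, progress = FALSE)
  if (!is.null(json)) {
    jsonlite::write_json(report$params, json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}
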