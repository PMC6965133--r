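#' Taxonomy maps
#'
#' A taxonomy map is a two-column tibble (`asv_id`, `lineage`) giving each
#' ASV an ordered lineage string from domain down to species. Both
#' SILVA-style strings (`D_0__Bacteria;D_1__Firmicutes;...`) and plain
#' semicolon-delimited strings (`Bacteria;Firmicutes;...`) are accepted;
#' deep ranks may be missing or empty (unassigned).
#'
#' `taxonomy_ranks()` parses lineages into one column per canonical rank
#' (domain, phylum, class, order, family, genus, species); unassigned ranks
#' are `NA`.
#'
#' @param path Two-column TSV with header `asv_id`, `lineage`.
#' @param taxonomy Taxonomy map tibble.
#' @return `read_taxonomy()`: the taxonomy tibble. `taxonomy_ranks()`: a
#'   tibble `asv_id` + seven rank columns.
#' @export
read_taxonomy <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("asv_id", "lineage") %in% names(tab))) {
    abort("Taxonomy file must have columns `asv_id` and `lineage`.")
  }
  tab$lineage[is.na(tab$lineage)] <- ""
  tibble::as_tibble(tab[, c("asv_id", "lineage")])
}

#' @rdname read_taxonomy
#' @export
write_taxonomy <- function(taxonomy, path) {
  readr::write_tsv(taxonomy, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_taxonomy
#' @export
taxonomy_ranks <- function(taxonomy) {
  if (!all(c("asv_id", "lineage") %in% names(taxonomy))) {
    abort("Taxonomy map must have columns `asv_id` and `lineage`.")
  }
  lin <- as.character(taxonomy$lineage)
  lin[is.na(lin)] <- ""
  parts <- stringr::str_split(lin, ";")
  parsed <- purrr::map(parts, function(p) {
    p <- stringr::str_trim(p)
    # strip SILVA "D_k__" prefixes
    p <- stringr::str_replace(p, "^[Dd]_?[0-9]+__", "")
    out <- rep(NA_character_, length(.RANKS))
    n <- min(length(p), length(.RANKS))
    out[seq_len(n)] <- p[seq_len(n)]
    out[out == ""] <- NA_character_
    out
  })
  mat <- do.call(rbind, parsed)
  colnames(mat) <- .RANKS
  dplyr::bind_cols(tibble::tibble(asv_id = taxonomy$asv_id),
                   tibble::as_tibble(mat))
}

#' Sample metadata
#'
#' Per-sample annotations: `sample_id`, `group` (e.g. foal_0h, mare_feces,
#' control_field), `control_type` (none, pcr, instrument or field),
#' `animal_id`, and `dyad_id` linking a foal to its dam (`NA` for controls).
#' `validate_sample_metadata()` checks the structural invariants, and — when
#' an ASV table is supplied — that every sample in the table has exactly one
#' metadata row.
#'
#' @param path Metadata TSV with the five columns above.
#' @param metadata Metadata tibble.
#' @param table Optional ASV table to cross-check sample coverage against.
#' @return `read_sample_metadata()`: the metadata tibble;
#'   `validate_sample_metadata()`: `metadata`, invisibly.
#' @export
read_sample_metadata <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_sample_metadata(tibble::as_tibble(tab))
  tibble::as_tibble(tab)
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(metadata, path) {
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_sample_metadata
#' @export
validate_sample_metadata <- function(metadata, table = NULL) {
  need <- c("sample_id", "group", "control_type", "animal_id", "dyad_id")
  missing <- setdiff(need, names(metadata))
  if (length(missing)) {
    abort(paste0("Metadata is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(metadata$sample_id)) {
    abort("Metadata sample ids must be unique.")
  }
  bad <- setdiff(unique(metadata$control_type), .CONTROL_TYPES)
  if (length(bad)) {
    abort(paste0("Unknown control_type value(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(table)) {
    uncovered <- setdiff(sample_ids(table), metadata$sample_id)
    if (length(uncovered)) {
      abort(paste0("Samples without metadata: ",
                   paste(head(uncovered, 10), collapse = ", "),
                   if (length(uncovered) > 10) ", ..."))
    }
  }
  invisible(metadata)
}

# sample ids of one control type
control_samples <- function(metadata, type) {
  metadata$sample_id[metadata$control_type == type]
}

# non-control group labels, in metadata order
animal_groups <- function(metadata) {
  unique(metadata$group[metadata$control_type == "none"])
}
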