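#' ASV count tables
#'
#' An ASV table is a wide tibble: a `sample_id` character column followed by
#' one numeric column per amplicon sequence variant (ASV), holding
#' non-negative integer read counts. It is the single substrate every stage
#' of the package transforms. `validate_asv_table()` checks the invariants
#' (unique ids, non-negative integral counts) and returns its input
#' invisibly, so it can sit inside a pipe.
#'
#' @param table ASV table (tibble: `sample_id` + one count column per ASV).
#' @return `validate_asv_table()` returns `table` invisibly; it throws on
#'   violation.
#' @export
validate_asv_table <- function(table) {
  if (!is.data.frame(table)) {
    abort("An ASV table must be a data frame.")
  }
  if (!identical(names(table)[1], "sample_id")) {
    abort("The first column of an ASV table must be `sample_id`.")
  }
  if (anyDuplicated(table$sample_id)) {
    dup <- unique(table$sample_id[duplicated(table$sample_id)])
    abort(paste0("Duplicate sample ids: ", paste(dup, collapse = ", ")))
  }
  ids <- asv_ids(table)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("Duplicate ASV ids: ", paste(dup, collapse = ", ")))
  }
  m <- asv_matrix(table)
  if (length(m)) {
    bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8,
                 arr.ind = TRUE)
    if (nrow(bad)) {
      abort(paste0(
        "Counts must be non-negative integers; offending cell: sample `",
        rownames(m)[bad[1, 1]], "`, ASV `", colnames(m)[bad[1, 2]],
        "` = ", m[bad[1, 1], bad[1, 2]]
      ))
    }
  }
  invisible(table)
}

#' @rdname validate_asv_table
#' @export
asv_ids <- function(table) setdiff(names(table), "sample_id")

#' @rdname validate_asv_table
#' @export
sample_ids <- function(table) table$sample_id

# numeric matrix (samples x ASVs) with dimnames; the workhorse view
asv_matrix <- function(table) {
  m <- as.matrix(table[, setdiff(names(table), "sample_id"), drop = FALSE])
  if (!is.numeric(m) && length(m)) {
    # locate the first non-numeric cell for a useful message
    for (j in setdiff(names(table), "sample_id")) {
      v <- suppressWarnings(as.numeric(table[[j]]))
      if (anyNA(v) && !anyNA(table[[j]])) {
        i <- which(is.na(v))[1]
        abort(paste0("Malformed numeric cell: sample `",
                     table$sample_id[i], "`, ASV `", j, "` = `",
                     table[[j]][i], "`"))
      }
    }
    abort("ASV table contains non-numeric count columns.")
  }
  storage.mode(m) <- "double"
  rownames(m) <- table$sample_id
  m
}

# inverse of asv_matrix()
as_asv_table <- function(m) {
  tibble::as_tibble(cbind(
    tibble::tibble(sample_id = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  ))
}

#' Read and write ASV count tables
#'
#' Supports two on-disk layouts: tab-separated text (by convention ASVs as
#' rows and samples as columns, as QIIME-style feature tables are exported;
#' the transposed layout is accepted via `orientation`) and BIOM JSON
#' (read/written through the biomformat package). Round-trips are lossless:
#' counts, sample order and ASV order are preserved exactly.
#'
#' With `orientation = "auto"` the TSV reader inspects the header corner
#' cell: `sample_id` means samples-as-rows, anything else (e.g. `asv_id`,
#' `#OTU ID`) means ASVs-as-rows.
#'
#' @param path File to read or write.
#' @param format `"tsv"` or `"biom-json"`; `"auto"` picks by file extension
#'   (`.biom`/`.json` vs anything else).
#' @param orientation TSV layout: `"asvs_as_rows"`, `"samples_as_rows"` or
#'   (reading only) `"auto"`.
#' @param table ASV table to write.
#' @return `read_asv_table()` returns a validated ASV table tibble;
#'   `write_asv_table()` returns `path` invisibly.
#' @examples
#' tbl <- tibble::tibble(sample_id = c("s1", "s2"), asv1 = c(3, 0), asv2 = c(1, 9))
#' f <- tempfile(fileext = ".tsv")
#' write_asv_table(tbl, f)
#' identical(read_asv_table(f), tbl)
#' @export
read_asv_table <- function(path, format = c("auto", "tsv", "biom-json"),
                           orientation = c("auto", "asvs_as_rows",
                                           "samples_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(biom|json)$", path)) "biom-json" else "tsv"
  }
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("Package `biomformat` is required to read BIOM files.")
    }
    b <- biomformat::read_biom(path)
    m <- t(as.matrix(biomformat::biom_data(b)))  # biom stores ASVs as rows
    tbl <- as_asv_table(m)
    return(validate_asv_table(tbl))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, name_repair = "minimal")
  if (ncol(raw) < 1) abort("Empty table.")
  corner <- names(raw)[1]
  if (orientation == "auto") {
    orientation <- if (identical(corner, "sample_id"))
      "samples_as_rows" else "asvs_as_rows"
  }
  num <- lapply(names(raw)[-1], function(j) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad)) {
      abort(paste0("Malformed numeric cell at row `", raw[[1]][bad[1]],
                   "`, column `", j, "`: `", raw[[j]][bad[1]], "`"))
    }
    v
  })
  m <- do.call(cbind, c(num, list(deparse.level = 0)))
  if (is.null(m)) m <- matrix(numeric(), nrow = nrow(raw), ncol = 0)
  rownames(m) <- raw[[1]]
  colnames(m) <- names(raw)[-1]
  if (orientation == "asvs_as_rows") m <- t(m)
  validate_asv_table(as_asv_table(m))
}

#' @rdname read_asv_table
#' @export
write_asv_table <- function(table, path, format = c("auto", "tsv", "biom-json"),
                            orientation = c("asvs_as_rows", "samples_as_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  validate_asv_table(table)
  if (format == "auto") {
    format <- if (grepl("\\.(biom|json)$", path)) "biom-json" else "tsv"
  }
  m <- asv_matrix(table)
  if (format == "biom-json") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("Package `biomformat` is required to write BIOM files.")
    }
    b <- biomformat::make_biom(t(m))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  if (orientation == "asvs_as_rows") {
    out <- tibble::as_tibble(t(m), .name_repair = "minimal")
    out <- dplyr::bind_cols(tibble::tibble(asv_id = colnames(m)), out)
  } else {
    out <- table
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its read depth. Samples with zero depth
#' carry no compositional information; their rows are left all-zero and
#' their ids recorded in the `zero_depth_samples` attribute.
#'
#' @param table ASV table.
#' @return Tibble of the same shape with per-sample proportions; attribute
#'   `zero_depth_samples` lists flagged samples.
#' @export
relative_abundance <- function(table) {
  m <- asv_matrix(table)
  depth <- rowSums(m)
  zero <- rownames(m)[depth == 0]
  scale <- ifelse(depth > 0, depth, 1)
  out <- as_asv_table(m / scale)
  attr(out, "zero_depth_samples") <- zero
  out
}

#' ASV prevalence within a sample subset
#'
#' Prevalence of an ASV is the proportion of samples in which it is
#' detected (at least `min_reads` reads). Expressing it as a proportion, not
#' a raw sample count, keeps groups of different sizes comparable — the
#' decontamination rule compares animal groups against control groups of a
#' different size. Zero-depth samples are dropped from the denominator.
#'
#' @param table ASV table.
#' @param samples Sample ids defining the subset; `NULL` means all samples.
#' @param min_reads Detection threshold (default 1 read).
#' @return Tibble with columns `asv_id`, `prevalence`.
#' @export
prevalence <- function(table, samples = NULL, min_reads = 1) {
  m <- asv_matrix(table)
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(m))
    if (length(missing)) {
      abort(paste0("Unknown sample ids: ", paste(missing, collapse = ", ")))
    }
    m <- m[samples, , drop = FALSE]
  }
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) == 0) {
    abort("No samples with nonzero depth in the requested subset.")
  }
  tibble::tibble(
    asv_id = colnames(m),
    prevalence = unname(colMeans(m >= min_reads))
  )
}

#' Mean relative abundance within a sample subset
#'
#' Mean over the subset's nonzero-depth samples of each ASV's within-sample
#' proportion (zeros included for samples lacking the ASV).
#'
#' @inheritParams prevalence
#' @return Tibble with columns `asv_id`, `mean_rel_abundance`.
#' @export
mean_relative_abundance <- function(table, samples = NULL) {
  m <- asv_matrix(table)
  if (!is.null(samples)) m <- m[intersect(samples, rownames(m)), , drop = FALSE]
  m <- m[rowSums(m) > 0, , drop = FALSE]
  if (nrow(m) == 0) {
    abort("No samples with nonzero depth in the requested subset.")
  }
  tibble::tibble(
    asv_id = colnames(m),
    mean_rel_abundance = unname(colMeans(m / rowSums(m)))
  )
}

#' Aggregate an ASV table at a taxonomic rank
#'
#' Sums counts over ASVs that share the named rank (e.g. all ASVs of one
#' phylum). ASVs unassigned at that rank are pooled into an `"unassigned"`
#' bucket, so per-sample read totals are conserved exactly.
#'
#' @param table ASV table.
#' @param taxonomy Taxonomy map (see [read_taxonomy()]).
#' @param rank One of domain, phylum, class, order, family, genus, species.
#' @return ASV-table-shaped tibble whose columns are taxon names.
#' @export
aggregate_by_rank <- function(table, taxonomy, rank = "phylum") {
  rank <- match.arg(rank, .RANKS)
  ranks <- taxonomy_ranks(taxonomy)
  ids <- asv_ids(table)
  missing <- setdiff(ids, ranks$asv_id)
  if (length(missing)) {
    abort(paste0("ASVs missing from taxonomy: ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) ", ..."))
  }
  lab <- ranks[[rank]][match(ids, ranks$asv_id)]
  lab[is.na(lab) | lab == ""] <- "unassigned"
  m <- asv_matrix(table)
  agg <- t(rowsum(t(m), group = lab))
  as_asv_table(agg)
}
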