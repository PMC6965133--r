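#' ASVs present in a set of samples
#'
#' "Present" means at least one read; `min_animals` requires detection in
#' at least that many of the named samples, the rule used for group-level
#' Venn comparisons (per-dyad analyses use the default of 1, since each
#' animal contributes a single sample).
#'
#' @param table ASV table.
#' @param samples Sample ids to scan.
#' @param min_animals Minimum number of samples an ASV must appear in.
#' @return Character vector of ASV ids.
#' @export
presence_set <- function(table, samples, min_animals = 1) {
  if (min_animals < 1) abort("`min_animals` must be >= 1.")
  missing <- setdiff(samples, sample_ids(table))
  if (length(missing)) {
    abort(paste0("Unknown sample ids: ", paste(missing, collapse = ", ")))
  }
  m <- asv_matrix(table[table$sample_id %in% samples, , drop = FALSE])
  colnames(m)[colSums(m >= 1) >= min_animals]
}

#' Per-dyad shared-ASV percentages
#'
#' For every mare-foal dyad with a foal sample in `foal_group` and a dam
#' sample in `source_group`, computes the percentage of the foal's ASVs
#' also detected in its own dam's sample. The denominator is always the
#' foal's ASV set — the question is what fraction of the newborn community
#' the maternal compartment can account for, so the relation is
#' deliberately asymmetric. Dyads missing either sample are skipped and
#' recorded in the `skipped_dyads` attribute.
#'
#' @param table ASV table (decontaminated).
#' @param metadata Sample metadata with `dyad_id` links.
#' @param foal_group Group label of the foal samples (e.g. `"foal_0h"`).
#' @param source_group Group label of the dam compartment (e.g.
#'   `"mare_feces"`).
#' @return Tibble with one row per complete dyad: `dyad_id`, `foal_sample`,
#'   `dam_sample`, `n_foal_asvs`, `n_shared`, `shared_pct` (`NA` when the
#'   foal sample has no ASVs). Attributes `mean` and `sd` hold the group
#'   mean and standard deviation of `shared_pct`.
#' @export
dyad_shared_fraction <- function(table, metadata, foal_group, source_group) {
  validate_sample_metadata(metadata)
  foal <- metadata[metadata$group == foal_group &
                     metadata$sample_id %in% sample_ids(table), ]
  dam <- metadata[metadata$group == source_group &
                    metadata$sample_id %in% sample_ids(table), ]
  dyads <- unique(stats::na.omit(c(foal$dyad_id, dam$dyad_id)))
  rows <- list()
  skipped <- character(0)
  for (d in dyads) {
    fs <- foal$sample_id[!is.na(foal$dyad_id) & foal$dyad_id == d]
    ds <- dam$sample_id[!is.na(dam$dyad_id) & dam$dyad_id == d]
    if (length(fs) != 1 || length(ds) != 1) {
      skipped <- c(skipped, d)
      next
    }
    fset <- presence_set(table, fs)
    dset <- presence_set(table, ds)
    n_shared <- length(intersect(fset, dset))
    rows[[d]] <- tibble::tibble(
      dyad_id = d, foal_sample = fs, dam_sample = ds,
      n_foal_asvs = length(fset), n_shared = n_shared,
      shared_pct = if (length(fset)) 100 * n_shared / length(fset) else NA_real_
    )
  }
  if (length(rows) == 0) {
    abort(paste0("No complete dyads between `", foal_group, "` and `",
                 source_group, "`."))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "mean") <- mean(out$shared_pct, na.rm = TRUE)
  attr(out, "sd") <- sd(out$shared_pct, na.rm = TRUE)
  attr(out, "skipped_dyads") <- skipped
  out
}

#' Venn partition of 2-4 labelled ASV sets
#'
#' Exact counts for every region of the set-intersection lattice (the
#' numbers a Venn diagram displays). Regions are disjoint, so counts sum to
#' the size of the union.
#'
#' @param sets Named list of 2-4 character vectors (ASV id sets).
#' @return A `venn_partition`: tibble with one logical membership column
#'   per set plus `count`, only non-empty regions included. Attribute
#'   `labels` holds the set names.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 4) {
    abort("`sets` must be a named list of 2-4 ASV id sets.")
  }
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("Every set must be named.")
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0) {
    member <- matrix(logical(0), ncol = length(sets),
                     dimnames = list(NULL, names(sets)))
  }
  if (is.vector(member)) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, names(sets)))
  key <- apply(member, 1, paste, collapse = "/")
  regions <- unique(key)
  out <- purrr::map_dfr(regions, function(k) {
    i <- which(key == k)[1]
    row <- tibble::as_tibble(as.list(member[i, ]))
    row$count <- sum(key == k)
    row
  })
  structure(out[order(-rowSums(as.matrix(out[names(sets)]))), ],
            class = c("venn_partition", class(out)),
            labels = names(sets))
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("Venn partition of sets: ",
      paste(attr(x, "labels"), collapse = ", "),
      " (union = ", sum(x$count), ")\n", sep = "")
  NextMethod()
}

#' Write a Venn partition as JSON
#'
#' Region labels are `&`-joined set names (e.g. `"foal_0h&mare_feces"`).
#'
#' @param venn A `venn_partition`.
#' @param path Output JSON path.
#' @return `venn`, invisibly.
#' @export
write_venn_json <- function(venn, path) {
  labels <- attr(venn, "labels")
  region <- apply(as.matrix(venn[labels]), 1, function(b) {
    paste(labels[b], collapse = "&")
  })
  jsonlite::write_json(as.list(setNames(venn$count, region)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(venn)
}

#' How much of the foal community do maternal sources explain?
#'
#' Two complementary summaries of source coverage: (1) of all ASVs detected
#' in any foal of `foal_group`, the percentage found in the union of the
#' source groups' ASVs; (2) per foal sample, the share of its reads carried
#' by those source-shared ASVs — an abundance-weighted view, since a few
#' shared ASVs can dominate a newborn community.
#'
#' @param table ASV table.
#' @param metadata Sample metadata.
#' @param foal_group Foal group label.
#' @param source_groups Character vector of source group labels.
#' @param min_animals Detection threshold for the group-level ASV unions.
#' @return List with `pct_asvs_in_sources` (scalar percentage), `per_foal`
#'   (tibble `sample_id`, `pct_reads_on_shared`), and `mean`/`sd` of the
#'   per-foal percentages.
#' @export
reads_explained <- function(table, metadata, foal_group, source_groups,
                            min_animals = 1) {
  validate_sample_metadata(metadata)
  foal_samples <- intersect(
    metadata$sample_id[metadata$group == foal_group],
    sample_ids(table)
  )
  source_samples <- intersect(
    metadata$sample_id[metadata$group %in% source_groups],
    sample_ids(table)
  )
  if (length(foal_samples) == 0 || length(source_samples) == 0) {
    abort("Foal and source groups must both contain samples.")
  }
  foal_union <- presence_set(table, foal_samples, min_animals)
  source_union <- presence_set(table, source_samples, min_animals)
  shared <- intersect(foal_union, source_union)
  pct_asvs <- if (length(foal_union)) {
    100 * length(shared) / length(foal_union)
  } else NA_real_

  m <- asv_matrix(table[table$sample_id %in% foal_samples, , drop = FALSE])
  depth <- rowSums(m)
  on_shared <- if (length(shared)) {
    rowSums(m[, intersect(colnames(m), shared), drop = FALSE])
  } else rep(0, nrow(m))
  per_foal <- tibble::tibble(
    sample_id = rownames(m),
    pct_reads_on_shared = unname(ifelse(depth > 0, 100 * on_shared / depth,
                                        NA_real_))
  )
  list(
    pct_asvs_in_sources = pct_asvs,
    per_foal = per_foal,
    mean = mean(per_foal$pct_reads_on_shared, na.rm = TRUE),
    sd = sd(per_foal$pct_reads_on_shared, na.rm = TRUE)
  )
}
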