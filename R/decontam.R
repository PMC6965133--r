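#' Prevalence and abundance profile of the negative controls
#'
#' For each filtering control type (instrument and field), computes every
#' ASV's prevalence (proportion of that type's controls detecting it) and
#' mean relative abundance (mean of per-control proportions, zeros included
#' where the ASV is absent). These are the reference quantities the
#' decontamination rule compares sample groups against. PCR no-template
#' controls are not part of the rule and are ignored here.
#'
#' @param table ASV table containing the control samples.
#' @param metadata Sample metadata identifying control types.
#' @return Tibble with columns `asv_id`, `prev_instrument`, `mra_instrument`,
#'   `prev_field`, `mra_field`; attribute `n_controls` gives the number of
#'   controls of each type used.
#' @export
build_control_profile <- function(table, metadata) {
  validate_sample_metadata(metadata)
  profile <- tibble::tibble(asv_id = asv_ids(table))
  n_controls <- c(instrument = 0L, field = 0L)
  for (type in c("instrument", "field")) {
    ids <- intersect(control_samples(metadata, type), sample_ids(table))
    if (length(ids) == 0) {
      abort(paste0("No ", type, " controls found in the table."))
    }
    m <- asv_matrix(table[table$sample_id %in% ids, , drop = FALSE])
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) == 0) {
      abort(paste0("All ", type, " controls have zero depth."))
    }
    n_controls[type] <- nrow(m)
    profile[[paste0("prev_", type)]] <- unname(colMeans(m >= 1))
    profile[[paste0("mra_", type)]] <- unname(colMeans(m / rowSums(m)))
  }
  attr(profile, "n_controls") <- n_controls
  profile
}

#' Classify one or more ASVs against the control profile
#'
#' The decontamination criterion, applied within one sample group: an ASV
#' is flagged as a probable contaminant when its prevalence among the
#' group's samples is at most `prev_factor` times its prevalence in the
#' negative controls AND its mean relative abundance is at most
#' `abund_factor` times its mean relative abundance in the controls. Both
#' comparisons are inclusive (ties flag) and are evaluated multiplicatively,
#' so zero-valued control entries never divide. With
#' `control_combine = "or"` (default) satisfying either control type
#' suffices for each criterion — equivalently each group quantity is
#' compared against the maximum over the two control types; `"and"` demands
#' both types, i.e. comparison against the minimum.
#'
#' An ASV absent from both control types (all four control entries zero)
#' but present in the group can never satisfy the prevalence criterion, so
#' it is always kept.
#'
#' All arguments are vectorised over ASVs.
#'
#' @param prev_group,mra_group Group prevalence and mean relative abundance.
#' @param prev_instrument,prev_field,mra_instrument,mra_field Control
#'   profile entries (see [build_control_profile()]).
#' @param prev_factor,abund_factor Rule multipliers; defaults 2 and 10.
#' @param control_combine `"or"` (default) or `"and"`.
#' @return Tibble with logical columns `prev_flag`, `abund_flag`, `removed`.
#' @export
classify_asv <- function(prev_group, mra_group,
                         prev_instrument, prev_field,
                         mra_instrument, mra_field,
                         prev_factor = 2, abund_factor = 10,
                         control_combine = c("or", "and")) {
  control_combine <- match.arg(control_combine)
  vals <- list(prev_group, mra_group, prev_instrument, prev_field,
               mra_instrument, mra_field)
  rng <- range(unlist(vals))
  if (rng[1] < 0 || rng[2] > 1) {
    abort("Prevalences and mean relative abundances must lie in [0, 1].")
  }
  if (prev_factor < 0 || abund_factor < 0) {
    abort("`prev_factor` and `abund_factor` must be non-negative.")
  }
  comb <- if (control_combine == "or") pmax else pmin
  prev_flag <- prev_group <= prev_factor * comb(prev_instrument, prev_field)
  abund_flag <- mra_group <= abund_factor * comb(mra_instrument, mra_field)
  tibble::tibble(prev_flag = prev_flag, abund_flag = abund_flag,
                 removed = prev_flag & abund_flag)
}

#' Control-informed decontamination of an ASV table
#'
#' Applies the dual prevalence/abundance criterion (see [classify_asv()])
#' to each non-control sample group independently: within a group, every
#' ASV detected there is classified against the instrument- and
#' field-control profile, and flagged ASVs have their counts zeroed in that
#' group's samples only. A taxon that is a genuine community member in one
#' group (say, a gut organism ubiquitous in adult feces) therefore survives
#' there even while the same ASV is purged from a low-biomass group where
#' its pattern matches the controls.
#'
#' The retained ASV universe is the union of the per-group retained sets;
#' control samples are re-tabulated over that universe (not themselves
#' filtered), which leaves them small nonzero read totals — a useful
#' post-filter quality readout.
#'
#' @param table Prefiltered ASV table containing animal and control samples.
#' @param metadata Sample metadata covering every sample.
#' @inheritParams classify_asv
#' @return An object of class `asv_decontam` with components
#'   \describe{
#'     \item{table}{decontaminated ASV table (all samples x retained universe)}
#'     \item{decisions}{per-ASV-per-group decision records with all six
#'       comparison quantities and flags}
#'     \item{sample_summary}{per-sample accepted/rejected read counts}
#'     \item{group_summary}{per-group reads and ASVs removed/kept}
#'     \item{profile}{the control profile used}
#'     \item{params}{rule parameters}
#'   }
#'   Use [tidy()] for decisions, [glance()] for a one-row overview,
#'   [autoplot()] for an accepted/rejected reads barplot and
#'   [decontaminated()] for the filtered table.
#' @export
decontaminate <- function(table, metadata, prev_factor = 2, abund_factor = 10,
                          control_combine = c("or", "and")) {
  control_combine <- match.arg(control_combine)
  validate_asv_table(table)
  validate_sample_metadata(metadata, table)
  profile <- build_control_profile(table, metadata)
  m <- asv_matrix(table)
  ids <- colnames(m)
  groups <- animal_groups(metadata)

  decisions <- vector("list", length(groups))
  out <- m
  retained <- character(0)
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    gs <- metadata$sample_id[metadata$group == g & metadata$control_type == "none"]
    gs <- intersect(gs, rownames(m))
    eff <- gs[rowSums(m[gs, , drop = FALSE]) > 0]
    if (length(eff) == 0) {
      abort(paste0("Group `", g, "` has no samples with nonzero depth."))
    }
    sub <- m[eff, , drop = FALSE]
    prev_g <- colMeans(sub >= 1)
    mra_g <- colMeans(sub / rowSums(sub))
    present <- prev_g > 0
    cls <- classify_asv(prev_g[present], mra_g[present],
                        profile$prev_instrument[present],
                        profile$prev_field[present],
                        profile$mra_instrument[present],
                        profile$mra_field[present],
                        prev_factor, abund_factor, control_combine)
    dec <- tibble::tibble(
      group = g,
      asv_id = ids[present],
      prev_group = unname(prev_g[present]),
      mra_group = unname(mra_g[present]),
      prev_instrument = profile$prev_instrument[present],
      prev_field = profile$prev_field[present],
      mra_instrument = profile$mra_instrument[present],
      mra_field = profile$mra_field[present]
    )
    decisions[[gi]] <- dplyr::bind_cols(dec, cls)
    rem_ids <- ids[present][cls$removed]
    out[gs, rem_ids] <- 0
    retained <- union(retained, ids[present][!cls$removed])
  }
  decisions <- dplyr::bind_rows(decisions)
  retained <- ids[ids %in% retained]  # keep original column order

  out <- out[, retained, drop = FALSE]
  out_tbl <- as_asv_table(out)

  depth_before <- rowSums(m)
  depth_after <- rowSums(out)
  grp <- metadata$group[match(rownames(m), metadata$sample_id)]
  sample_summary <- tibble::tibble(
    sample_id = rownames(m),
    group = grp,
    control_type = metadata$control_type[match(rownames(m), metadata$sample_id)],
    reads_kept = unname(depth_after),
    reads_removed = unname(depth_before - depth_after),
    pct_reads_removed = ifelse(depth_before > 0,
                               100 * (depth_before - depth_after) / depth_before,
                               NA_real_)
  )

  asv_stats <- decisions |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(asvs_removed = sum(.data$removed),
                     asvs_kept = sum(!.data$removed), .groups = "drop")
  group_summary <- sample_summary |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      mean_sample_pct_removed = mean(.data$pct_reads_removed, na.rm = TRUE),
      sd_sample_pct_removed = sd(.data$pct_reads_removed, na.rm = TRUE),
      reads_removed = sum(.data$reads_removed),
      reads_kept = sum(.data$reads_kept),
      pct_reads_removed = 100 * .data$reads_removed /
        (.data$reads_removed + .data$reads_kept),
      .groups = "drop"
    ) |>
    dplyr::left_join(asv_stats, by = "group")

  structure(
    list(table = out_tbl, decisions = decisions,
         sample_summary = sample_summary, group_summary = group_summary,
         profile = profile, raw = table, metadata = metadata,
         params = list(prev_factor = prev_factor, abund_factor = abund_factor,
                       control_combine = control_combine)),
    class = "asv_decontam"
  )
}

#' @rdname decontaminate
#' @param fit An `asv_decontam` object.
#' @export
decontaminated <- function(fit) fit$table

#' @export
print.asv_decontam <- function(x, ...) {
  n_rem <- sum(x$decisions$removed)
  cat("Control-informed decontamination (prev <= ", x$params$prev_factor,
      "x, abundance <= ", x$params$abund_factor, "x, controls combined by `",
      x$params$control_combine, "`)\n", sep = "")
  cat("  ", length(asv_ids(x$raw)), " ASVs in, ", length(asv_ids(x$table)),
      " retained; ", n_rem, " group-local removal decisions\n", sep = "")
  print(x$group_summary)
  invisible(x)
}

#' @export
tidy.asv_decontam <- function(x, ...) x$decisions

#' @export
glance.asv_decontam <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$raw),
    n_asvs_in = length(asv_ids(x$raw)),
    n_asvs_retained = length(asv_ids(x$table)),
    n_removal_decisions = sum(x$decisions$removed),
    total_reads_removed = sum(x$sample_summary$reads_removed),
    pct_reads_removed = 100 * sum(x$sample_summary$reads_removed) /
      sum(x$sample_summary$reads_kept + x$sample_summary$reads_removed),
    prev_factor = x$params$prev_factor,
    abund_factor = x$params$abund_factor,
    control_combine = x$params$control_combine
  )
}

#' @export
autoplot.asv_decontam <- function(object, ...) {
  d <- object$sample_summary |>
    tidyr::pivot_longer(c("reads_kept", "reads_removed"),
                        names_to = "fate", values_to = "reads") |>
    dplyr::mutate(fate = ifelse(.data$fate == "reads_kept",
                                "accepted", "rejected"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sample_id, y = .data$reads,
                                  fill = .data$fate)) +
    ggplot2::geom_col() +
    ggplot2::facet_grid(~group, scales = "free_x", space = "free_x") +
    ggplot2::scale_fill_manual(values = c(accepted = "#2166ac",
                                          rejected = "#ef8a62")) +
    ggplot2::labs(x = NULL, y = "reads", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Percentage of a taxon's reads removed by decontamination
#'
#' Read-level accounting for one taxon (e.g. the genus Ralstonia, a
#' signature reagent contaminant): of all reads carried by ASVs classified
#' to the taxon within the scoped groups, what percentage did the filter
#' remove? Useful both to confirm contaminant purging and to verify that
#' plausibly genuine taxa (typical intestinal genera) were left intact.
#'
#' @param fit An `asv_decontam` object.
#' @param taxonomy Taxonomy map.
#' @param rank Canonical rank of the taxon (default `"genus"`).
#' @param name Taxon name at that rank.
#' @param groups Group labels to scope to; `NULL` means all non-control
#'   groups.
#' @return A percentage in \[0, 100\], or `NA` (with a warning) when the
#'   taxon has no reads in scope.
#' @export
taxon_removal_rollup <- function(fit, taxonomy, name, rank = "genus",
                                 groups = NULL) {
  ranks <- taxonomy_ranks(taxonomy)
  rank <- match.arg(rank, .RANKS)
  taxon_asvs <- ranks$asv_id[!is.na(ranks[[rank]]) & ranks[[rank]] == name]
  if (length(taxon_asvs) == 0) {
    abort(paste0("Taxon not found in taxonomy: ", rank, " `", name, "`"))
  }
  md <- fit$metadata
  if (is.null(groups)) groups <- animal_groups(md)
  scope_samples <- md$sample_id[md$group %in% groups & md$control_type == "none"]
  m <- asv_matrix(fit$raw)
  scope_samples <- intersect(scope_samples, rownames(m))
  cols <- intersect(taxon_asvs, colnames(m))
  total <- if (length(cols)) sum(m[scope_samples, cols]) else 0
  if (total == 0) {
    warn(paste0("Taxon ", rank, " `", name, "` has no reads in scope; ",
                "removal percentage is undefined."))
    return(NA_real_)
  }
  removed <- 0
  for (g in intersect(groups, animal_groups(md))) {
    gs <- intersect(md$sample_id[md$group == g & md$control_type == "none"],
                    rownames(m))
    dec <- fit$decisions[fit$decisions$group == g & fit$decisions$removed, ]
    rem_ids <- intersect(dec$asv_id, cols)
    if (length(rem_ids)) removed <- removed + sum(m[gs, rem_ids])
  }
  100 * removed / total
}

#' Write decontamination reports to disk
#'
#' @param fit An `asv_decontam` object.
#' @param decisions_tsv,summary_tsv,params_json Output paths (`NULL` skips).
#' @return `fit`, invisibly.
#' @export
write_decontam_report <- function(fit, decisions_tsv = NULL,
                                  summary_tsv = NULL, params_json = NULL) {
  if (!is.null(decisions_tsv)) {
    readr::write_tsv(fit$decisions, decisions_tsv, progress = FALSE)
  }
  if (!is.null(summary_tsv)) {
    readr::write_tsv(fit$group_summary, summary_tsv, progress = FALSE)
  }
  if (!is.null(params_json)) {
    jsonlite::write_json(fit$params, params_json, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(fit)
}
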