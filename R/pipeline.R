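#' Run the full decontamination and analysis pipeline
#'
#' Orchestrates prefilter -> decontamination -> sample exclusion ->
#' aggregation/diversity -> dam-foal sharing -> statistics from a single
#' plain-text (YAML) configuration, writing every report plus a
#' machine-readable run manifest to an output directory. Each stage's
#' read/ASV bookkeeping is recorded; a failure in one stage leaves the
#' completed stages' outputs on disk and marks the failed stage in the
#' manifest.
#'
#' The configuration either points at input files
#' (`inputs: {counts, taxonomy, metadata[, qpcr], format}`) or asks for a
#' synthetic dataset (`simulate: {seed}`). Every analysis threshold is a
#' named parameter with the conventional default: `prefilter.min_total`
#' (10), `samples.min_reads` (1500), `decontam.prev_factor` (2),
#' `decontam.abund_factor` (10), `decontam.control_combine` ("or"),
#' `analysis.venn_min_animals` (2).
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @param output_dir Output directory (created if needed); overrides the
#'   config's `output_dir`.
#' @return The run manifest (named list, also written as
#'   `manifest.json`), invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  defaults <- list(
    prefilter = list(min_total = 10),
    decontam = list(prev_factor = 2, abund_factor = 10,
                    control_combine = "or"),
    samples = list(min_reads = 1500),
    analysis = list(
      foal_groups = c("foal_0h", "foal_24h", "foal_7d"),
      source_groups = c("mare_feces", "mare_vagina", "mare_mouth"),
      venn_min_animals = 2, qpcr_group = "foal_0h", qpcr_control = "field"
    )
  )
  for (sec in names(defaults)) {
    cfg[[sec]] <- modifyList(defaults[[sec]], cfg[[sec]] %||% list())
  }
  out_dir <- output_dir %||% cfg$output_dir %||%
    abort("No output directory given (argument or config `output_dir`).")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("asvdecon")),
    parameters = cfg[c("prefilter", "decontam", "samples", "analysis")],
    stages = list()
  )
  state <- new.env(parent = emptyenv())

  record <- function(name, table) {
    m <- asv_matrix(table)
    manifest$stages[[name]] <<- c(
      manifest$stages[[name]],
      list(status = "ok", n_samples = nrow(m), n_asvs = ncol(m),
           total_reads = sum(m))
    )
  }
  run_stage <- function(name, fun) {
    ok <- TRUE
    tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      ok <<- FALSE
    })
    ok
  }
  finish <- function(status) {
    manifest$status <- status
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  }

  # ---- load / simulate ----------------------------------------------------
  ok <- run_stage("load", function() {
    if (!is.null(cfg$simulate)) {
      sim <- simulate_dataset(
        config = cfg$simulate$config %||% sim_config(),
        seed = cfg$simulate$seed %||% 1
      )
      state$table <- sim$table
      state$taxonomy <- sim$taxonomy
      state$metadata <- sim$metadata
      state$qpcr <- sim$qpcr
      manifest$inputs <<- list(simulated = TRUE,
                               seed = cfg$simulate$seed %||% 1)
    } else {
      inp <- cfg$inputs
      need <- c("counts", "taxonomy", "metadata")
      missing <- need[vapply(inp[need], is.null, logical(1))]
      if (length(missing)) {
        abort(paste0("Config `inputs` is missing: ",
                     paste(missing, collapse = ", ")))
      }
      for (p in unlist(inp[need])) {
        if (!file.exists(p)) abort(paste0("Input file not found: ", p))
      }
      state$table <- read_asv_table(inp$counts,
                                    format = inp$format %||% "auto")
      state$taxonomy <- read_taxonomy(inp$taxonomy)
      state$metadata <- read_sample_metadata(inp$metadata)
      if (!is.null(inp$qpcr)) {
        state$qpcr <- readr::read_tsv(inp$qpcr, show_col_types = FALSE)
      }
      manifest$inputs <<- lapply(inp[need], function(p) {
        list(path = p, md5 = unname(tools::md5sum(p)))
      })
    }
    validate_sample_metadata(state$metadata, state$table)
    record("load", state$table)
  })
  if (!ok) return(finish("failed"))

  # ---- prefilter ----------------------------------------------------------
  ok <- run_stage("prefilter", function() {
    t1 <- taxonomy_prefilter(state$table, state$taxonomy)
    rep1 <- prefilter_report(t1)
    t2 <- min_total_count_filter(t1, min_total = cfg$prefilter$min_total)
    rep2 <- prefilter_report(t2)
    removed <- dplyr::bind_rows(rep1$removed_asvs, rep2$removed_asvs)
    readr::write_tsv(removed, file.path(out_dir, "prefilter_removed.tsv"),
                     progress = FALSE)
    jsonlite::write_json(list(min_total = cfg$prefilter$min_total),
                         file.path(out_dir, "prefilter_params.json"),
                         auto_unbox = TRUE)
    state$table <- t2
    record("prefilter", state$table)
  })
  if (!ok) return(finish("failed"))

  # ---- decontaminate ------------------------------------------------------
  ok <- run_stage("decontam", function() {
    fit <- decontaminate(state$table, state$metadata,
                         prev_factor = cfg$decontam$prev_factor,
                         abund_factor = cfg$decontam$abund_factor,
                         control_combine = cfg$decontam$control_combine)
    write_decontam_report(
      fit,
      decisions_tsv = file.path(out_dir, "decontam_decisions.tsv"),
      summary_tsv = file.path(out_dir, "decontam_group_summary.tsv"),
      params_json = file.path(out_dir, "decontam_params.json")
    )
    state$fit <- fit
    state$table <- decontaminated(fit)
    record("decontam", state$table)
  })
  if (!ok) return(finish("failed"))

  # ---- sample exclusion ---------------------------------------------------
  ok <- run_stage("exclude_samples", function() {
    t <- exclude_low_read_samples(state$table, state$metadata,
                                  min_reads = cfg$samples$min_reads)
    writeLines(attr(t, "excluded_samples"),
               file.path(out_dir, "excluded_samples.txt"))
    state$table <- t
    write_asv_table(t, file.path(out_dir, "decontaminated_table.tsv"))
    record("exclude_samples", state$table)
  })
  if (!ok) return(finish("failed"))

  # ---- analysis -----------------------------------------------------------
  ok <- run_stage("analysis", function() {
    an <- cfg$analysis
    md <- state$metadata
    tbl <- state$table
    animal <- md$sample_id[md$control_type == "none" &
                             md$sample_id %in% sample_ids(tbl)]
    atbl <- tbl[tbl$sample_id %in% animal, , drop = FALSE]

    # phylum-level mean relative abundances per group
    phy <- aggregate_by_rank(atbl, state$taxonomy, "phylum")
    ra <- relative_abundance(phy)
    phy_long <- ra |>
      tidyr::pivot_longer(-"sample_id", names_to = "phylum",
                          values_to = "rel_abundance") |>
      dplyr::left_join(md[, c("sample_id", "group")], by = "sample_id") |>
      dplyr::group_by(.data$group, .data$phylum) |>
      dplyr::summarise(mean_rel_abundance = mean(.data$rel_abundance),
                       sd_rel_abundance = sd(.data$rel_abundance),
                       .groups = "drop")
    readr::write_tsv(phy_long, file.path(out_dir, "phylum_relabund.tsv"),
                     progress = FALSE)

    # diversity
    div <- sample_shannon(atbl) |>
      dplyr::left_join(md[, c("sample_id", "group")], by = "sample_id")
    readr::write_tsv(div, file.path(out_dir, "shannon.tsv"), progress = FALSE)
    foal_div <- div[div$group %in% an$foal_groups, ]
    tests <- list()
    if (length(unique(foal_div$group)) >= 2) {
      kw <- kruskal_wallis(foal_div, .data$shannon, .data$group)
      nem <- nemenyi_allpairs(foal_div, .data$shannon, .data$group)
      tests$diversity <- dplyr::bind_rows(
        dplyr::mutate(kw, test = "kruskal_wallis", group1 = NA, group2 = NA),
        dplyr::mutate(nem, test = "nemenyi_allpairs")
      )
    }

    # dam-foal sharing
    sharing <- list()
    sharing_tests <- list()
    for (fg in an$foal_groups) {
      per_source <- list()
      for (sg in an$source_groups) {
        rec <- tryCatch(
          dyad_shared_fraction(tbl, md, fg, sg),
          error = function(e) NULL
        )
        if (is.null(rec)) next
        per_source[[sg]] <- dplyr::mutate(rec, foal_group = fg,
                                          source_group = sg)
      }
      if (length(per_source) == 0) next
      sharing[[fg]] <- dplyr::bind_rows(per_source)
      if (length(per_source) >= 2) {
        wide <- sharing[[fg]] |>
          dplyr::select("dyad_id", "source_group", "shared_pct") |>
          tidyr::pivot_wider(names_from = "source_group",
                             values_from = "shared_pct") |>
          tidyr::drop_na()
        if (nrow(wide) >= 2) {
          y <- as.matrix(wide[, -1])
          fr <- friedman_blocked(y)
          nb <- nemenyi_blocked(y)
          sharing_tests[[fg]] <- dplyr::bind_rows(
            dplyr::mutate(fr, test = "friedman", foal_group = fg),
            dplyr::mutate(nb, test = "nemenyi_blocked", foal_group = fg)
          )
        }
      }
    }
    if (length(sharing)) {
      readr::write_tsv(dplyr::bind_rows(sharing),
                       file.path(out_dir, "sharing.tsv"), progress = FALSE)
    }
    if (length(sharing_tests)) {
      tests$sharing <- dplyr::bind_rows(sharing_tests)
    }

    # group-level Venn partitions and reads-explained summaries
    explained <- list()
    for (fg in an$foal_groups) {
      fg_samples <- intersect(md$sample_id[md$group == fg], sample_ids(tbl))
      if (length(fg_samples) == 0) next
      sets <- c(
        setNames(list(presence_set(tbl, fg_samples, an$venn_min_animals)), fg),
        lapply(setNames(an$source_groups, an$source_groups), function(sg) {
          presence_set(tbl,
                       intersect(md$sample_id[md$group == sg],
                                 sample_ids(tbl)),
                       an$venn_min_animals)
        })
      )
      write_venn_json(venn_partition(sets),
                      file.path(out_dir, paste0("venn_", fg, ".json")))
      re <- reads_explained(tbl, md, fg, an$source_groups, min_animals = 1)
      explained[[fg]] <- tibble::tibble(
        foal_group = fg,
        pct_asvs_in_sources = re$pct_asvs_in_sources,
        mean_pct_reads_on_shared = re$mean,
        sd_pct_reads_on_shared = re$sd
      )
    }
    if (length(explained)) {
      readr::write_tsv(dplyr::bind_rows(explained),
                       file.path(out_dir, "reads_explained.tsv"),
                       progress = FALSE)
    }

    # qPCR comparison: newborns vs field controls
    if (!is.null(state$qpcr)) {
      q <- state$qpcr
      newborn <- q$copies[q$sample_id %in%
                            md$sample_id[md$group == an$qpcr_group]]
      ctrl <- q$copies[q$sample_id %in%
                         md$sample_id[md$control_type == an$qpcr_control]]
      if (length(newborn) && length(ctrl)) {
        tests$qpcr <- dplyr::mutate(mann_whitney(newborn, ctrl),
                                    test = "mann_whitney_qpcr")
      }
    }
    if (length(tests)) {
      readr::write_tsv(dplyr::bind_rows(tests),
                       file.path(out_dir, "stats.tsv"), progress = FALSE)
    }
    record("analysis", state$table)
  })
  finish(if (ok) "ok" else "failed")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
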