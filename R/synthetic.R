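#' Configuration for the synthetic mare-foal study generator
#'
#' Encodes the study design the generator emulates: mare-foal dyads
#' sampled at three foal time points (rectum at 0 h, 24 h, 7 d) and three
#' dam compartments (feces, vagina, mouth), with PCR, instrument and field
#' negative controls. Bacterial biomass spans roughly 1e3 (meconium) to
#' 1e11 (adult feces) 16S copies per sample, while reagent contamination is
#' a fixed additive copy load per extraction — which is exactly what makes
#' low-biomass samples contaminant-dominated and high-biomass samples
#' essentially clean.
#'
#' @param n_dyads Number of mare-foal pairs (default 14).
#' @param biomass_range Named list of `c(lo, hi)` 16S-copy ranges per
#'   group; samples draw biomass log-uniformly within their group's range.
#' @param richness Named vector: number of true-community ASVs per sample
#'   group.
#' @param profile_sdlog Named vector: log-normal sdlog of true ASV
#'   abundances per group (larger = more dominance, lower diversity).
#' @param contaminant_load Reagent contaminant 16S copies added to every
#'   animal, instrument and field extraction (default 4e3).
#' @param pcr_load Contaminant copies in no-template PCR controls.
#' @param env_load Extra environmental copies in field controls.
#' @param n_contaminant_asvs,n_env_asvs Pool sizes.
#' @param transmission Named list (one entry per foal group) of named
#'   vectors: fraction of the foal's ASV richness seeded from each dam
#'   compartment; the remainder comes from a foal-age-specific novel pool.
#' @param n_controls Named vector: controls per type.
#' @param depth_mean,depth_sd,depth_min Sequencing depth distribution
#'   (truncated normal, reads per sample).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(
    n_dyads = 14,
    biomass_range = list(
      foal_0h = c(1e3, 1e5), foal_24h = c(1e8, 1e10), foal_7d = c(1e9, 1e11),
      mare_feces = c(1e8, 1e11), mare_vagina = c(1e8, 1e11),
      mare_mouth = c(1e8, 1e11)
    ),
    richness = c(foal_0h = 80, foal_24h = 30, foal_7d = 90,
                 mare_feces = 350, mare_vagina = 90, mare_mouth = 25),
    profile_sdlog = c(foal_0h = 1.2, foal_24h = 2.5, foal_7d = 1.5,
                      mare_feces = 0.9, mare_vagina = 2, mare_mouth = 2.5),
    contaminant_load = 4e3,
    pcr_load = 1e3,
    env_load = 700,
    n_contaminant_asvs = 40,
    n_env_asvs = 10,
    transmission = list(
      foal_0h = c(mare_feces = 0.09, mare_vagina = 0.04, mare_mouth = 0.003),
      foal_24h = c(mare_feces = 0.02, mare_vagina = 0.05, mare_mouth = 0.015),
      foal_7d = c(mare_feces = 0.033, mare_vagina = 0.028, mare_mouth = 0.013)
    ),
    n_controls = c(pcr = 3, instrument = 6, field = 6),
    depth_mean = 6e4, depth_sd = 1e4, depth_min = 2e3) {
  cfg <- structure(
    list(n_dyads = n_dyads, biomass_range = biomass_range,
         richness = richness, profile_sdlog = profile_sdlog,
         contaminant_load = contaminant_load, pcr_load = pcr_load,
         env_load = env_load, n_contaminant_asvs = n_contaminant_asvs,
         n_env_asvs = n_env_asvs, transmission = transmission,
         n_controls = n_controls, depth_mean = depth_mean,
         depth_sd = depth_sd, depth_min = depth_min),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  problems <- character(0)
  if (config$n_dyads < 1) problems <- c(problems, "n_dyads must be >= 1")
  groups <- names(config$biomass_range)
  if (!setequal(names(config$richness), groups)) {
    problems <- c(problems, "richness must name the same groups as biomass_range")
  }
  for (g in groups) {
    r <- config$biomass_range[[g]]
    if (length(r) != 2 || any(r <= 0) || r[1] > r[2]) {
      problems <- c(problems, paste0("invalid biomass range for ", g))
    }
  }
  if (any(config$richness < 1)) problems <- c(problems, "richness must be >= 1")
  for (g in names(config$transmission)) {
    f <- config$transmission[[g]]
    if (any(f < 0) || any(f > 1) || sum(f) > 1) {
      problems <- c(problems,
                    paste0("transmission fractions for ", g,
                           " must lie in [0,1] and sum to <= 1"))
    }
  }
  if (any(config$n_controls < 1)) {
    problems <- c(problems, "need at least one control of each type")
  }
  if (config$contaminant_load < 0 || config$pcr_load < 0 ||
      config$env_load < 0) {
    problems <- c(problems, "loads must be non-negative")
  }
  if (config$depth_min < 1 || config$depth_mean <= 0) {
    problems <- c(problems, "depth parameters must be positive")
  }
  if (length(problems)) {
    abort(paste0("Invalid sim_config:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  invisible(config)
}

# small taxonomic lexicon so taxon-level rollups are exercisable
.CONTAM_GENERA <- c("Ralstonia", "Ralstonia", "Ralstonia", "Methylobacterium",
                    "Burkholderia", "Bradyrhizobium", "Pseudomonas",
                    "Acinetobacter")
.ENV_GENERA <- c("Sphingomonas", "Massilia", "Deinococcus")
.POOL_GENERA <- list(
  mare_feces = c("Lachnospiraceae_uc", "Ruminococcus", "Rikenellaceae_RC9",
                 "Treponema", "Fibrobacter", "Prevotella", "Clostridium",
                 "Streptococcus", "Bacteroidales_RF16"),
  mare_vagina = c("Corynebacterium", "Porphyromonas", "Campylobacter",
                  "Helcococcus", "Streptococcus", "Peptoniphilus",
                  "Anaerococcus", "Oceanivirga"),
  mare_mouth = c("Gemella", "Streptococcus", "Moraxella", "Enterococcus",
                 "Pasteurellaceae_uc"),
  foal_0h = c("Staphylococcus", "Lactobacillus", "Bacillus", "Streptococcus",
              "Corynebacterium", "Sphingomonas"),
  foal_24h = c("Escherichia_Shigella", "Clostridium", "Streptococcus",
               "Bacteroides", "Epulopiscium"),
  foal_7d = c("Bacteroides", "Fusobacterium", "Tyzzerella", "Streptococcus",
              "Lactobacillus", "Akkermansia")
)
.GENUS_PHYLUM <- c(
  Ralstonia = "Proteobacteria", Methylobacterium = "Proteobacteria",
  Burkholderia = "Proteobacteria", Bradyrhizobium = "Proteobacteria",
  Pseudomonas = "Proteobacteria", Acinetobacter = "Proteobacteria",
  Sphingomonas = "Proteobacteria", Massilia = "Proteobacteria",
  Deinococcus = "Deinococcus-Thermus", Lachnospiraceae_uc = "Firmicutes",
  Ruminococcus = "Firmicutes", Rikenellaceae_RC9 = "Bacteroidetes",
  Treponema = "Spirochaetes", Fibrobacter = "Fibrobacteres",
  Prevotella = "Bacteroidetes", Clostridium = "Firmicutes",
  Streptococcus = "Firmicutes", Bacteroidales_RF16 = "Bacteroidetes",
  Corynebacterium = "Actinobacteria", Porphyromonas = "Bacteroidetes",
  Campylobacter = "Epsilonbacteraeota", Helcococcus = "Firmicutes",
  Peptoniphilus = "Firmicutes", Anaerococcus = "Firmicutes",
  Oceanivirga = "Fusobacteria", Gemella = "Firmicutes",
  Moraxella = "Proteobacteria", Enterococcus = "Firmicutes",
  Pasteurellaceae_uc = "Proteobacteria", Staphylococcus = "Firmicutes",
  Lactobacillus = "Firmicutes", Bacillus = "Firmicutes",
  Escherichia_Shigella = "Proteobacteria", Bacteroides = "Bacteroidetes",
  Epulopiscium = "Firmicutes", Fusobacterium = "Fusobacteria",
  Tyzzerella = "Firmicutes", Akkermansia = "Verrucomicrobia"
)

make_lineage <- function(genus) {
  phylum <- .GENUS_PHYLUM[genus]
  phylum[is.na(phylum)] <- "Firmicutes"
  paste("Bacteria", phylum, "c_uc", "o_uc", "f_uc", genus, "", sep = ";")
}

#' Generate a synthetic contaminated mare-foal amplicon dataset
#'
#' Builds a complete dataset with known ground truth: per-group true
#' communities (log-normal abundances; foal communities seeded from the
#' paired dam's compartments at the configured transmission fractions plus
#' an age-specific novel pool), a shared reagent-contaminant pool added to
#' every extraction at a fixed copy load, field controls carrying an extra
#' trace environmental pool, multinomial read sampling at a drawn depth,
#' and a qPCR-style total copy-number readout per sample. Deterministic
#' given `(config, seed)`.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return List of class `asv_simulation`:
#'   \describe{
#'     \item{table}{ASV count table (animal samples + controls)}
#'     \item{metadata}{sample metadata with dyad links and control types}
#'     \item{taxonomy}{taxonomy map over all generated ASVs}
#'     \item{truth}{ground truth: `asv_labels` (true_community/contaminant),
#'       `sample_biomass`, `transmission` (which dam compartment seeded
#'       which foal ASV), and the config}
#'     \item{qpcr}{per-sample 16S copy-number readouts}
#'   }
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1) {
  validate_sim_config(config)
  set.seed(seed)
  foal_groups <- names(config$transmission)
  mare_groups <- setdiff(names(config$biomass_range), foal_groups)
  dyads <- sprintf("dyad%02d", seq_len(config$n_dyads))

  # --- ASV pools ----------------------------------------------------------
  pool_ids <- list()
  pool_genus <- list()
  mk_pool <- function(prefix, n, genera) {
    ids <- sprintf("ASV_%s%03d", prefix, seq_len(n))
    list(ids = ids, genus = sample(genera, n, replace = TRUE))
  }
  contam <- mk_pool("C", config$n_contaminant_asvs, .CONTAM_GENERA)
  env <- mk_pool("E", config$n_env_asvs, .ENV_GENERA)
  for (g in mare_groups) {
    p <- mk_pool(toupper(substr(sub("mare_", "", g), 1, 1)),
                 config$richness[[g]], .POOL_GENERA[[g]])
    pool_ids[[g]] <- p$ids
    pool_genus[[g]] <- p$genus
  }
  # novel pools: ASVs a foal does not inherit from its dam
  novel_size <- pmax(2 * config$richness[foal_groups], 20)
  for (i in seq_along(foal_groups)) {
    g <- foal_groups[i]
    p <- mk_pool(paste0("N", i), novel_size[[g]], .POOL_GENERA[[g]])
    pool_ids[[g]] <- p$ids
    pool_genus[[g]] <- p$genus
  }
  all_ids <- c(contam$ids, env$ids, unlist(pool_ids, use.names = FALSE))
  all_genus <- c(contam$genus, env$genus, unlist(pool_genus, use.names = FALSE))
  taxonomy <- tibble::tibble(asv_id = all_ids,
                             lineage = make_lineage(all_genus))

  contam_base <- stats::rlnorm(length(contam$ids), 0, 1.5)
  env_base <- stats::rlnorm(length(env$ids), 0, 1)
  mare_base <- lapply(mare_groups, function(g) {
    stats::rlnorm(config$richness[[g]], 0, config$profile_sdlog[[g]])
  })
  names(mare_base) <- mare_groups

  # --- per-animal true profiles ------------------------------------------
  # each mare carries a subset of its group pool with individual jitter
  mare_profiles <- list()
  for (g in mare_groups) {
    for (d in dyads) {
      present <- stats::runif(config$richness[[g]]) < 0.8
      if (!any(present)) present[1] <- TRUE
      w <- mare_base[[g]] * stats::rlnorm(config$richness[[g]], 0, 0.7)
      w[!present] <- 0
      mare_profiles[[paste(g, d)]] <- setNames(w, pool_ids[[g]])
    }
  }

  transmission_rows <- list()
  foal_profiles <- list()
  for (g in foal_groups) {
    rich <- config$richness[[g]]
    frac <- config$transmission[[g]]
    for (d in dyads) {
      picked <- character(0)
      src <- character(0)
      for (sg in names(frac)) {
        dam_set <- names(which(mare_profiles[[paste(sg, d)]] > 0))
        k <- min(round(frac[[sg]] * rich), length(dam_set))
        take <- sample(dam_set, k)
        picked <- c(picked, take)
        src <- c(src, rep(sg, k))
      }
      picked_u <- !duplicated(picked)
      picked <- picked[picked_u]; src <- src[picked_u]
      n_novel <- max(rich - length(picked), 0)
      novel <- sample(pool_ids[[g]], n_novel)
      asvs <- c(picked, novel)
      w <- stats::rlnorm(length(asvs), 0, config$profile_sdlog[[g]])
      foal_profiles[[paste(g, d)]] <- setNames(w, asvs)
      transmission_rows[[paste(g, d)]] <- tibble::tibble(
        dyad_id = d, foal_group = g, asv_id = asvs,
        source = c(src, rep("novel", n_novel))
      )
    }
  }

  # --- samples ------------------------------------------------------------
  draw_depth <- function() {
    max(config$depth_min, round(rnorm(1, config$depth_mean, config$depth_sd)))
  }
  draw_biomass <- function(g) {
    r <- log10(config$biomass_range[[g]])
    10^runif(1, r[1], r[2])
  }
  samples <- list()
  meta_rows <- list()
  biomass_rows <- list()
  qpcr_rows <- list()

  add_sample <- function(sid, group, control_type, animal, dyad,
                         true_profile, load, env_mix = FALSE) {
    copies <- numeric(length(all_ids))
    names(copies) <- all_ids
    biomass <- 0
    if (!is.null(true_profile)) {
      biomass <- draw_biomass(group)
      copies[names(true_profile)] <- biomass * true_profile / sum(true_profile)
    }
    cw <- contam_base * stats::rlnorm(length(contam_base), 0, 0.5)
    copies[contam$ids] <- copies[contam$ids] + load * cw / sum(cw)
    if (env_mix && config$env_load > 0) {
      ew <- env_base * stats::rlnorm(length(env_base), 0, 0.5)
      copies[env$ids] <- copies[env$ids] + config$env_load * ew / sum(ew)
    }
    depth <- draw_depth()
    counts <- if (sum(copies) > 0) {
      rmultinom(1, depth, copies / sum(copies))[, 1]
    } else {
      setNames(numeric(length(copies)), names(copies))  # nothing to amplify
    }
    samples[[sid]] <<- counts
    meta_rows[[sid]] <<- tibble::tibble(
      sample_id = sid, group = group, control_type = control_type,
      animal_id = animal, dyad_id = dyad
    )
    total_copies <- biomass + load + if (env_mix) config$env_load else 0
    biomass_rows[[sid]] <<- tibble::tibble(
      sample_id = sid, biomass = biomass, contaminant_load = load)
    qpcr_rows[[sid]] <<- tibble::tibble(
      sample_id = sid,
      copies = total_copies * stats::rlnorm(1, 0, 0.25))
  }

  for (d in seq_along(dyads)) {
    dy <- dyads[d]
    for (g in foal_groups) {
      add_sample(sprintf("%s_%s", g, dy), g, "none",
                 sprintf("foal%02d", d), dy,
                 foal_profiles[[paste(g, dy)]], config$contaminant_load)
    }
    for (g in mare_groups) {
      add_sample(sprintf("%s_%s", g, dy), g, "none",
                 sprintf("mare%02d", d), dy,
                 mare_profiles[[paste(g, dy)]], config$contaminant_load)
    }
  }
  for (type in names(config$n_controls)) {
    for (i in seq_len(config$n_controls[[type]])) {
      load <- switch(type, pcr = config$pcr_load, config$contaminant_load)
      add_sample(sprintf("control_%s_%02d", type, i),
                 paste0("control_", type), type, NA_character_,
                 NA_character_, NULL, load, env_mix = type == "field")
    }
  }

  m <- do.call(rbind, samples)
  rownames(m) <- names(samples)
  colnames(m) <- all_ids
  table <- as_asv_table(m)
  metadata <- dplyr::bind_rows(meta_rows)

  truth <- list(
    asv_labels = tibble::tibble(
      asv_id = all_ids,
      label = ifelse(all_ids %in% c(contam$ids, env$ids),
                     "contaminant", "true_community")
    ),
    sample_biomass = dplyr::bind_rows(biomass_rows),
    transmission = dplyr::bind_rows(transmission_rows),
    config = config, seed = seed
  )
  structure(
    list(table = table, metadata = metadata, taxonomy = taxonomy,
         truth = truth, qpcr = dplyr::bind_rows(qpcr_rows)),
    class = "asv_simulation"
  )
}

#' @export
print.asv_simulation <- function(x, ...) {
  cat("Synthetic mare-foal amplicon dataset: ", nrow(x$table), " samples x ",
      length(asv_ids(x$table)), " ASVs (seed ", x$truth$seed, ")\n", sep = "")
  invisible(x)
}

#' Confusion summary of a decontamination run against generator truth
#'
#' Read- and ASV-level sensitivity and specificity per sample group:
#' sensitivity is the fraction of contaminant-labelled reads (ASVs) the
#' filter removed, specificity the fraction of true-community reads (ASVs)
#' it kept.
#'
#' @param fit An `asv_decontam` object fitted to a simulated table.
#' @param truth The `truth` component of [simulate_dataset()] output.
#' @return Tibble with one row per non-control group.
#' @export
truth_confusion <- function(fit, truth) {
  labels <- truth$asv_labels
  contam_ids <- labels$asv_id[labels$label == "contaminant"]
  md <- fit$metadata
  m <- asv_matrix(fit$raw)
  purrr::map_dfr(animal_groups(md), function(g) {
    gs <- intersect(md$sample_id[md$group == g & md$control_type == "none"],
                    rownames(m))
    sub <- m[gs, , drop = FALSE]
    dec <- fit$decisions[fit$decisions$group == g, ]
    removed_ids <- dec$asv_id[dec$removed]
    is_contam <- colnames(sub) %in% contam_ids
    is_removed <- colnames(sub) %in% removed_ids
    contam_reads <- sum(sub[, is_contam, drop = FALSE])
    contam_removed <- sum(sub[, is_contam & is_removed, drop = FALSE])
    true_reads <- sum(sub[, !is_contam, drop = FALSE])
    true_removed <- sum(sub[, !is_contam & is_removed, drop = FALSE])
    present <- colSums(sub) > 0
    n_contam_asv <- sum(present & is_contam)
    n_true_asv <- sum(present & !is_contam)
    tibble::tibble(
      group = g,
      contaminant_reads = contam_reads,
      sensitivity_reads = ifelse(contam_reads > 0,
                                 contam_removed / contam_reads, NA_real_),
      true_reads = true_reads,
      specificity_reads = ifelse(true_reads > 0,
                                 1 - true_removed / true_reads, NA_real_),
      sensitivity_asvs = ifelse(n_contam_asv > 0,
                                sum(present & is_contam & is_removed) /
                                  n_contam_asv, NA_real_),
      specificity_asvs = ifelse(n_true_asv > 0,
                                1 - sum(present & !is_contam & is_removed) /
                                  n_true_asv, NA_real_)
    )
  })
}
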