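# Fixture builders and independent brute-force oracles used across tests.
# Oracles are written as plain loops, sharing no code with the package.

tbl_from_matrix <- function(m) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(as.data.frame(m)))
}

rand_table <- function(n_samples, n_asvs, seed, lambda = 5, p_zero = 0.6) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_asvs, lambda) *
                rbinom(n_samples * n_asvs, 1, 1 - p_zero),
              n_samples, n_asvs,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("a%03d", seq_len(n_asvs))))
  tbl_from_matrix(m)
}

# metadata for a table whose samples are assigned round-robin to
# `n_groups` animal groups plus instrument/field controls
rand_metadata <- function(table, n_groups = 2, n_instrument = 2, n_field = 2) {
  ids <- table$sample_id
  n <- length(ids)
  stopifnot(n > n_instrument + n_field)
  n_animal <- n - n_instrument - n_field
  group <- c(paste0("g", rep_len(seq_len(n_groups), n_animal)),
             rep("ctl_instrument", n_instrument),
             rep("ctl_field", n_field))
  tibble::tibble(
    sample_id = ids,
    group = group,
    control_type = c(rep("none", n_animal),
                     rep("instrument", n_instrument),
                     rep("field", n_field)),
    animal_id = ifelse(group %in% c("ctl_instrument", "ctl_field"),
                       NA_character_, paste0("an", seq_len(n))),
    dyad_id = NA_character_
  )
}

# order-insensitive matrix view for round-trip comparisons
asv_matrix_public <- function(tbl) {
  m <- as.matrix(tbl[, -1]); rownames(m) <- tbl$sample_id
  m[order(rownames(m)), order(colnames(m))]
}

# --- brute-force oracles --------------------------------------------------

bf_prevalence <- function(m, samples) {
  keep <- character(0)
  for (s in samples) if (sum(m[s, ]) > 0) keep <- c(keep, s)
  out <- numeric(ncol(m))
  for (a in seq_len(ncol(m))) {
    hit <- 0
    for (s in keep) if (m[s, a] >= 1) hit <- hit + 1
    out[a] <- hit / length(keep)
  }
  names(out) <- colnames(m)
  out
}

bf_mra <- function(m, samples) {
  keep <- character(0)
  for (s in samples) if (sum(m[s, ]) > 0) keep <- c(keep, s)
  out <- numeric(ncol(m))
  for (a in seq_len(ncol(m))) {
    acc <- 0
    for (s in keep) acc <- acc + m[s, a] / sum(m[s, ])
    out[a] <- acc / length(keep)
  }
  names(out) <- colnames(m)
  out
}

# per-group per-ASV removal decisions, independent of the package path
bf_decontam <- function(m, meta, prev_factor = 2, abund_factor = 10,
                        combine = "or") {
  instr <- meta$sample_id[meta$control_type == "instrument"]
  field <- meta$sample_id[meta$control_type == "field"]
  prev_i <- bf_prevalence(m, instr); mra_i <- bf_mra(m, instr)
  prev_f <- bf_prevalence(m, field); mra_f <- bf_mra(m, field)
  groups <- unique(meta$group[meta$control_type == "none"])
  rows <- list()
  for (g in groups) {
    gs <- meta$sample_id[meta$group == g & meta$control_type == "none"]
    prev_g <- bf_prevalence(m, gs); mra_g <- bf_mra(m, gs)
    for (a in colnames(m)) {
      if (prev_g[a] == 0) next
      if (combine == "or") {
        pflag <- prev_g[a] <= prev_factor * prev_i[a] ||
          prev_g[a] <= prev_factor * prev_f[a]
        aflag <- mra_g[a] <= abund_factor * mra_i[a] ||
          mra_g[a] <= abund_factor * mra_f[a]
      } else {
        pflag <- prev_g[a] <= prev_factor * prev_i[a] &&
          prev_g[a] <= prev_factor * prev_f[a]
        aflag <- mra_g[a] <= abund_factor * mra_i[a] &&
          mra_g[a] <= abund_factor * mra_f[a]
      }
      rows[[paste(g, a)]] <- data.frame(group = g, asv_id = a,
                                        removed = pflag && aflag)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$asv_id), ]
}

# metadata for the simple two-group + controls hand fixtures
hand_metadata <- function(animal = c("g1" = 4, "g2" = 4),
                          n_instrument = 3, n_field = 3) {
  ids <- c(unlist(lapply(names(animal), function(g) {
    paste0(g, "_s", seq_len(animal[[g]]))
  })), paste0("instr_", seq_len(n_instrument)),
  paste0("field_", seq_len(n_field)))
  tibble::tibble(
    sample_id = ids,
    group = c(rep(names(animal), animal),
              rep("ctl_instrument", n_instrument),
              rep("ctl_field", n_field)),
    control_type = c(rep("none", sum(animal)),
                     rep("instrument", n_instrument),
                     rep("field", n_field)),
    animal_id = paste0("an", seq_along(ids)),
    dyad_id = NA_character_
  )
}
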