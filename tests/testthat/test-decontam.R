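test_that("control profile matches forced arithmetic and brute force", {
  md <- hand_metadata(animal = c(g1 = 2), n_instrument = 6, n_field = 3)
  n <- nrow(md)
  m <- matrix(0, n, 3, dimnames = list(md$sample_id, c("a1", "a2", "a3")))
  m[, "a3"] <- 1                                   # keeps depth nonzero
  instr <- md$sample_id[md$control_type == "instrument"]
  m[instr[1:3], "a1"] <- 2                         # 3 of 6 instrument controls
  prof <- build_control_profile(tbl_from_matrix(m), md)
  expect_equal(prof$prev_instrument[prof$asv_id == "a1"], 0.5)
  expect_equal(prof$prev_field[prof$asv_id == "a1"], 0)
  expect_equal(prof$mra_field[prof$asv_id == "a2"], 0)

  tbl <- rand_table(9, 15, seed = 31)
  md2 <- rand_metadata(tbl, n_groups = 1, n_instrument = 3, n_field = 2)
  prof2 <- build_control_profile(tbl, md2)
  m2 <- as.matrix(tbl[, -1]); rownames(m2) <- tbl$sample_id
  expect_equal(prof2$prev_instrument,
               unname(bf_prevalence(m2, md2$sample_id[md2$control_type == "instrument"])),
               tolerance = 1e-12)
  expect_equal(prof2$mra_field,
               unname(bf_mra(m2, md2$sample_id[md2$control_type == "field"])),
               tolerance = 1e-12)

  md_miss <- md[md$control_type != "field", ]
  expect_error(
    build_control_profile(tbl_from_matrix(m[md_miss$sample_id, ]), md_miss),
    "field")
})

test_that("classification keeps control-absent ASVs and removes at the boundary", {
  # present in the group, absent from every control: never removed
  keep <- classify_asv(0.8, 0.5, 0, 0, 0, 0)
  expect_false(keep$prev_flag)
  expect_false(keep$removed)

  # equality on both criteria flags (inclusive rule)
  eq <- classify_asv(0.5, 1e-4, 0.5, 0, 1e-4, 0)
  expect_true(eq$removed)

  # exactly 2x field prevalence and 10x field abundance: still removed
  boundary <- classify_asv(prev_group = 0.6, mra_group = 0.02,
                           prev_instrument = 0, prev_field = 0.3,
                           mra_instrument = 0, mra_field = 0.002)
  expect_true(boundary$prev_flag)
  expect_true(boundary$abund_flag)
  expect_true(boundary$removed)
  # one epsilon above either multiple survives
  above <- classify_asv(0.6 + 1e-9, 0.02, 0, 0.3, 0, 0.002)
  expect_false(above$removed)

  expect_error(classify_asv(1.2, 0.5, 0, 0, 0, 0), "\\[0, 1\\]")
})

test_that("the 'and' control combination compares against the stricter type", {
  # passes vs field only: removed under OR, kept under AND
  res_or <- classify_asv(0.5, 0.01, 0.05, 0.4, 0.0001, 0.005,
                         control_combine = "or")
  res_and <- classify_asv(0.5, 0.01, 0.05, 0.4, 0.0001, 0.005,
                          control_combine = "and")
  expect_true(res_or$removed)
  expect_false(res_and$removed)
})

test_that("decontamination is group-local: removal in one group spares another", {
  md <- hand_metadata(animal = c(foal = 11, feces = 14),
                      n_instrument = 6, n_field = 6)
  asvs <- c("reagent", "gut1", "gut2", "kitasv")
  m <- matrix(0, nrow(md), 4, dimnames = list(md$sample_id, asvs))
  ctl <- md$sample_id[md$control_type != "none"]
  instr <- md$sample_id[md$control_type == "instrument"]
  m[ctl, "kitasv"] <- 10                         # keeps control depth nonzero
  m[instr[1:2], "reagent"] <- 300                # prev_instrument 1/3
  foal <- md$sample_id[md$group == "foal"]
  feces <- md$sample_id[md$group == "feces"]
  m[foal, "gut1"] <- 50                          # keeps foal depth up
  m[foal[1:2], "reagent"] <- 25                  # 2/11 foals <= 2 x 1/3
  m[feces, "reagent"] <- 40                      # 14/14 adults > 2 x 1/3
  m[feces, "gut1"] <- 900
  m[feces, "gut2"] <- 60
  fit <- decontaminate(tbl_from_matrix(m), md)
  dec <- tidy(fit)
  removed_foal <- dec$asv_id[dec$group == "foal" & dec$removed]
  removed_feces <- dec$asv_id[dec$group == "feces" & dec$removed]
  expect_true("reagent" %in% removed_foal)
  expect_false("reagent" %in% removed_feces)     # prev 1.0 > 2x controls
  expect_false("gut1" %in% c(removed_foal, removed_feces))

  out <- decontaminated(fit)
  mo <- as.matrix(out[, -1]); rownames(mo) <- out$sample_id
  expect_true(all(mo[foal, "reagent"] == 0))     # zeroed only in foal group
  expect_true(all(mo[feces, "reagent"] == 40))
  # controls are re-tabulated over the retained universe, not zeroed:
  # reagent stays in the universe (kept in feces) so control reads survive
  expect_equal(mo[ctl, "reagent"], m[ctl, "reagent"])
})

test_that("decisions are invariant to permuting counts in other groups", {
  tbl <- rand_table(12, 25, seed = 77)
  md <- rand_metadata(tbl, n_groups = 2, n_instrument = 2, n_field = 2)
  fit1 <- decontaminate(tbl, md)
  g2 <- md$sample_id[md$group == "g2"]
  m <- as.matrix(tbl[, -1]); rownames(m) <- tbl$sample_id
  set.seed(1); m[g2, ] <- m[sample(g2), ] * 3    # permute + rescale g2
  fit2 <- decontaminate(tbl_from_matrix(m), md)
  d1 <- dplyr::filter(tidy(fit1), group == "g1")
  d2 <- dplyr::filter(tidy(fit2), group == "g1")
  expect_equal(d1, d2)
})

test_that("raising either factor never shrinks the removed set", {
  for (seed in 1:10) {
    tbl <- rand_table(10, 30, seed = seed)
    md <- rand_metadata(tbl, n_groups = 2, n_instrument = 2, n_field = 2)
    base <- tidy(decontaminate(tbl, md))
    for (params in list(c(4, 10), c(2, 50), c(10, 100))) {
      more <- tidy(decontaminate(tbl, md, prev_factor = params[1],
                                 abund_factor = params[2]))
      joined <- dplyr::inner_join(
        base[c("group", "asv_id", "removed")],
        more[c("group", "asv_id", "removed")],
        by = c("group", "asv_id"), suffix = c("_base", "_more"))
      expect_true(all(joined$removed_more | !joined$removed_base))
    }
  }
})

test_that("an ASV absent from all controls is never removed anywhere", {
  for (seed in 1:20) {
    tbl <- rand_table(10, 30, seed = seed + 100)
    md <- rand_metadata(tbl, n_groups = 3, n_instrument = 2, n_field = 2)
    fit <- decontaminate(tbl, md)
    dec <- tidy(fit)
    safe <- dec$prev_instrument == 0 & dec$prev_field == 0 &
      dec$mra_instrument == 0 & dec$mra_field == 0
    expect_false(any(dec$removed[safe]))
  }
})

test_that("taxon removal rollup matches brute-force read accounting", {
  sim <- simulate_dataset(seed = 2)
  tbl <- min_total_count_filter(taxonomy_prefilter(sim$table, sim$taxonomy), 10)
  fit <- decontaminate(tbl, sim$metadata)
  tax <- sim$taxonomy

  # brute force: reads of Ralstonia ASVs removed across animal groups
  ranks <- taxonomy_ranks(tax)
  ral <- ranks$asv_id[!is.na(ranks$genus) & ranks$genus == "Ralstonia"]
  m <- as.matrix(fit$raw[, -1]); rownames(m) <- fit$raw$sample_id
  md <- sim$metadata
  total <- 0; removed <- 0
  for (g in unique(md$group[md$control_type == "none"])) {
    gs <- md$sample_id[md$group == g & md$control_type == "none"]
    dec <- fit$decisions[fit$decisions$group == g, ]
    for (a in intersect(ral, colnames(m))) {
      reads <- sum(m[gs, a])
      total <- total + reads
      was_removed <- a %in% dec$asv_id[dec$removed]
      if (was_removed) removed <- removed + reads
    }
  }
  skip_if(total == 0)
  expect_equal(taxon_removal_rollup(fit, tax, "Ralstonia"),
               100 * removed / total, tolerance = 1e-12)

  expect_warning(
    out <- taxon_removal_rollup(fit, tax, "Ralstonia",
                                groups = character(0)),
    "undefined")
  expect_true(is.na(out))
})

test_that("per-group summary percentages reconcile exactly", {
  sim <- simulate_dataset(seed = 3)
  fit <- decontaminate(sim$table, sim$metadata)
  gs <- fit$group_summary
  expect_equal(gs$pct_reads_removed,
               100 * gs$reads_removed / (gs$reads_removed + gs$reads_kept))
  g <- glance(fit)
  expect_equal(g$total_reads_removed, sum(gs$reads_removed))
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
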