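test_that("panel generation is reproducible with the stated moments", {
  spec <- panel_spec(n_genes = 691)
  p1 <- generate_panel(spec, seed = 5)
  expect_identical(p1, generate_panel(spec, seed = 5))
  expect_equal(nrow(p1), 691)
  big <- generate_panel(panel_spec(10000, intolerance_mean = -0.5,
                                   intolerance_sd = 2, pubweight_mean = 8),
                        seed = 3)
  # 3 standard errors of the mean at n = 1e4
  expect_lt(abs(mean(big$intolerance) + 0.5), 3 * 2 / sqrt(1e4))
  expect_lt(abs(mean(big$pubweight) - 8), 3 * 8 / sqrt(1e4))
  expect_true(all(big$pubweight >= 0))
})

test_that("center cohorts honor the requested composition", {
  panel <- generate_panel(panel_spec(20), 1)
  co <- generate_center_cohort(center_spec("skewed", 42, 14, seed = 3), panel)
  expect_equal(sum(co$labels), 42)
  expect_equal(length(co$labels), 56)
  expect_equal(dim(co$tensor), c(56, 11, 20))
  expect_identical(generate_center_cohort(center_spec("skewed", 42, 14, seed = 3), panel)$tensor,
                   co$tensor)
})

test_that("null cohorts are exchangeable: t-statistics are calibrated", {
  panel <- generate_panel(panel_spec(200), 2)
  co <- generate_center_cohort(center_spec("null", 50, 50, seed = 8), panel)
  burden <- apply(co$tensor[, 1:9, ], c(1, 3), sum)  # sample x gene totals
  pvals <- vapply(seq_len(200), function(g)
    stats::t.test(burden[co$labels == 1, g], burden[co$labels == 0, g])$p.value, 0)
  # ~5% of 200 null genes beyond the 5% critical value (binomial 99.9% band)
  expect_gte(sum(pvals < 0.05), 1)
  expect_lte(sum(pvals < 0.05), 25)
})

test_that("planted signal raises case burden on signal genes", {
  panel <- generate_panel(panel_spec(30), 4)
  sig <- 1:10
  co <- generate_center_cohort(
    center_spec("sig", 50, 50, signal_genes = sig, effect_size = 3, seed = 5),
    panel)
  burden <- apply(co$tensor[, 1:9, sig], 1, sum)
  tt <- stats::t.test(burden[co$labels == 1], burden[co$labels == 0],
                      alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})

test_that("batch factors shift class counts center-wide", {
  panel <- generate_panel(panel_spec(40), 6)
  batch <- c(3, rep(1, 8))  # triple the exonic rate
  plain <- generate_center_cohort(center_spec("p", 30, 30, seed = 7), panel)
  shifted <- generate_center_cohort(
    center_spec("s", 30, 30, batch_factor = batch, seed = 7), panel)
  ratio <- mean(shifted$tensor[, 1, ]) / mean(plain$tensor[, 1, ])
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 3.5)
  other <- mean(shifted$tensor[, 8, ]) / mean(plain$tensor[, 8, ])
  expect_lt(abs(other - 1), 0.1)
  # label-confounded mode shifts cases only
  conf <- generate_center_cohort(
    center_spec("c", 30, 30, batch_factor = batch,
                confound_with_label = TRUE, seed = 7), panel)
  r_case <- mean(conf$tensor[conf$labels == 1, 1, ]) /
    mean(plain$tensor[plain$labels == 1, 1, ])
  r_ctrl <- mean(conf$tensor[conf$labels == 0, 1, ]) /
    mean(plain$tensor[plain$labels == 0, 1, ])
  expect_gt(r_case, 2.5)
  expect_lt(abs(r_ctrl - 1), 0.1)
})

test_that("emitted variant records re-encode to the identical tensor", {
  panel <- generate_panel(panel_spec(6), 3)
  co <- generate_center_cohort(
    center_spec("rt", 3, 3, signal_genes = 1:2, effect_size = 2, seed = 4),
    panel, emit_variants = TRUE)
  vl <- attr(co, "variants")
  re <- encode_cohort(vl, co$labels, panel, center_id = co$center_id)
  expect_equal(re$tensor, co$tensor)
  # and through on-disk Annovar-style tables
  dir <- withr::local_tempdir()
  paths <- write_annovar_tables(vl, dir)
  back <- lapply(paths, read_annovar_table)
  re2 <- encode_cohort(back, co$labels, panel)
  expect_equal(re2$tensor, co$tensor)
})

test_that("random and stratified splits partition the cohort", {
  co <- tiny_cohort(10, 10, n_genes = 4, seed = 5)
  folds <- split_stratified(co, 5, seed = 1)
  expect_length(folds, 5)
  for (f in folds) {
    expect_equal(sum(f$labels), 2)
    expect_equal(sum(f$labels == 0), 2)
  }
  rnd <- split_random(co, 3, seed = 2)
  ids <- sort(unlist(lapply(rnd, `[[`, "sample_ids")))
  expect_equal(ids, sort(co$sample_ids))
  expect_equal(sum(vapply(rnd, n_samples, 0L)), 20L)
  expect_error(split_random(co, 21, seed = 1), "n_folds")
})

test_that("233 samples split into 31 folds of size 7 or 8", {
  panel <- generate_panel(panel_spec(5), 1)
  co <- generate_center_cohort(center_spec("pool", 157, 76, seed = 2), panel)
  for (splitter in list(split_random, split_stratified)) {
    folds <- splitter(co, 31, seed = 3)
    sizes <- vapply(folds, n_samples, 0L)
    expect_true(all(sizes %in% c(7L, 8L)))
    expect_equal(sum(sizes), 233L)
  }
  # stratified folds keep case counts within 1 of 157/31
  folds <- split_stratified(co, 31, seed = 3)
  cases <- vapply(folds, function(f) sum(f$labels), 0L)
  expect_true(all(abs(cases - 157 / 31) <= 1))
})

test_that("held-out AUC is non-decreasing in planted effect size", {
  aucs <- vapply(c(1, 2, 3), function(eff) {
    panel <- generate_panel(panel_spec(20), 9)
    mean(vapply(1:2, function(sd) {
      tr <- generate_center_cohort(
        center_spec("tr", 25, 25, signal_genes = 1:5, effect_size = eff,
                    seed = sd), panel)
      te <- generate_center_cohort(
        center_spec("te", 25, 25, signal_genes = 1:5, effect_size = eff,
                    seed = sd + 50), panel)
      cfg <- model_config(n_genes = 20, epochs = 60, seed = sd)
      fit <- train_local(init_model(cfg), tr, cfg)
      auc(te$labels, predict_proba(fit$model, te))
    }, 0))
  }, 0)
  expect_lte(abs(aucs[1] - 0.5), 0.25)  # null hovers near chance
  expect_gte(aucs[3], aucs[1])
  expect_gte(aucs[3], 0.8)
})
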