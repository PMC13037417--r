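test_that("panel construction enforces disjoint roles and a reference", {
  expect_error(panel_config("a", character(0)), "reference")
  expect_error(panel_config(c("a", "b"), "a"), "overlap")
  pan <- panel_config(c("a", "b"), "r", controls = "spike")
  expect_equal(pan$controls, "spike")
})

test_that("delta-CT subtracts the mean of determined references per sample", {
  ct <- make_ct(sample_id = rep("s1", 3), group = "case",
                assay_id = c("t", "r1", "r2"), ct = c(25, 20, 22))
  d <- delta_ct(ct, panel_config("t", c("r1", "r2")))
  expect_equal(d$dct, 4)
  # single reference degenerates to a plain difference
  d1 <- delta_ct(ct, panel_config("t", "r1"))
  expect_equal(d1$dct, 5)
  # an undetermined reference is dropped from the mean
  ct2 <- ct; ct2$undetermined[ct2$assay_id == "r2"] <- TRUE
  d2 <- delta_ct(ct2, panel_config("t", c("r1", "r2")))
  expect_equal(d2$dct, 5)
  # a sample with no determined reference is dropped, by name
  ct3 <- ct; ct3$undetermined[ct3$assay_id %in% c("r1", "r2")] <- TRUE
  expect_warning(d3 <- delta_ct(ct3, panel_config("t", c("r1", "r2"))),
                 "s1")
  expect_equal(nrow(d3), 0)
})

test_that("technical replicates are averaged before delta-CT", {
  ct <- make_ct(sample_id = rep("s1", 4), group = "case",
                assay_id = c("t", "t", "r", "r"), ct = c(24, 26, 20, 20))
  d <- delta_ct(ct, panel_config("t", "r"))
  expect_equal(d$dct, 5)
})

test_that("delta-delta-CT follows the 2^(-ddCT) formula and sign conventions", {
  ct <- make_ct(
    sample_id = rep(c("c1", "c2", "n1", "n2"), each = 2),
    group = rep(c("case", "case", "control", "control"), each = 2),
    assay_id = rep(c("t", "r"), 4),
    ct = c(23, 20, 23, 20, 25, 20, 25, 20))
  res <- ddct_quantify(delta_ct(ct, panel_config("t", "r")))
  expect_equal(res$ddct, -2)
  expect_equal(res$fold_change, 4)
  expect_equal(res$fold_regulation, 4)
  # equal group means -> FC = FR = 1
  ct0 <- ct; ct0$ct[c(1, 3)] <- 25
  res0 <- ddct_quantify(delta_ct(ct0, panel_config("t", "r")))
  expect_equal(res0$ddct, 0)
  expect_equal(res0$fold_change, 1)
  expect_equal(res0$fold_regulation, 1)
})

test_that("fold regulation matches the published down-regulation convention", {
  expect_equal(fold_regulation(0.3774), -1 / 0.3774)
  expect_equal(round(fold_regulation(0.3774), 2), -2.65)
  expect_equal(fold_regulation(2.5), 2.5)
  expect_equal(fold_regulation(1), 1)
})

test_that("fold regulation and fold change round-trip on |FR| >= 1", {
  # -1 is excluded: FC = 1 maps to FR = +1, so -1 is never produced
  frs <- c(-8.2, -2.65, 1, 1.5, 4.31, 11.31)
  expect_equal(fold_regulation(fold_change_from_fr(frs)), frs)
  fcs <- c(0.1, 0.3774, 1, 2.24, 5.76)
  expect_equal(fold_change_from_fr(fold_regulation(fcs)), fcs)
})

test_that("volcano classification applies the 2-fold and 0.05 thresholds", {
  res <- data.frame(fold_regulation = c(2.24, -4.54, 1.5, 2.5, -2, 2),
                    p = c(0.007977, 0.000001, 0.01, 0.2, 0.049, 0.05))
  expect_equal(classify_volcano(res),
               c("up", "down", "ns", "ns", "down", "ns"))
})

test_that("swapping group labels negates ddCT and mirrors fold regulation", {
  set.seed(5)
  ct <- make_ct(sample_id = rep(paste0("s", 1:8), each = 2),
                group = rep(rep(c("case", "control"), each = 4), each = 2),
                assay_id = rep(c("t", "r"), 8),
                ct = c(rbind(rnorm(8, c(24, 24, 24, 24, 26, 26, 26, 26), 0.3),
                             rnorm(8, 20, 0.1))))
  pan <- panel_config("t", "r")
  a <- ddct_quantify(delta_ct(ct, pan))
  swapped <- ct
  swapped$group <- ifelse(ct$group == "case", "control", "case")
  b <- ddct_quantify(delta_ct(swapped, pan))
  expect_equal(b$ddct, -a$ddct)
  expect_equal(b$fold_regulation, -a$fold_regulation, tolerance = 1e-9)
  expect_equal(b$p, a$p, tolerance = 1e-9)
})

test_that("insufficient samples yield a flagged NA p-value", {
  ct <- make_ct(sample_id = rep(c("c1", "n1", "n2"), each = 2),
                group = rep(c("case", "control", "control"), each = 2),
                assay_id = rep(c("t", "r"), 3),
                ct = c(23, 20, 25, 20, 25.5, 20))
  expect_warning(res <- ddct_quantify(delta_ct(ct, panel_config("t", "r"))),
                 "<2 usable")
  expect_true(is.na(res$p))
  expect_equal(res$class, "ns")
})

test_that("a planted 4-fold difference is recovered end to end", {
  fcs <- numeric(0)
  for (s in 1:10) {
    cfg <- sim_config(n_mirnas = 50, n_case = 6, n_control = 6,
                      frac_de = 0.02, lfc_range = c(2, 2), n_stable = 3,
                      ct_noise_sd = 0.25, seed = s)
    sim <- simulate_counts(cfg)
    tr <- sim$truth
    target <- tr$mirna_id[tr$is_de][1]
    pan <- panel_config(target, tr$mirna_id[tr$is_stable])
    ct <- simulate_ct(tr, cfg, pan)
    res <- ddct_quantify(delta_ct(ct, pan))
    fc <- res$fold_change
    if (tr$true_log2fc[tr$mirna_id == target] < 0) fc <- 1 / fc
    fcs <- c(fcs, fc)
  }
  expect_true(all(fcs > 3 & fcs < 5.3))
})
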