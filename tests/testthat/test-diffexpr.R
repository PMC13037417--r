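toy_counts <- function() {
  m <- matrix(c(100, 200, 300,
                200, 400, 600,
                120, 210, 330,
                90, 190, 310) , nrow = 3,
              dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  count_matrix(m, c(s1 = "case", s2 = "case", s3 = "control", s4 = "control"))
}

test_that("cpm matches its definition and normalization identities", {
  m <- matrix(c(500, 999500, 2, 999998), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(cpm(m)["a", "s1"], 500)
  x <- toy_counts()
  expect_equal(unname(colSums(cpm(x))), rep(1e6, 4))
  doubled <- x$counts; doubled[, 1] <- doubled[, 1] * 2L
  expect_equal(cpm(doubled)[, 1], cpm(x)[, 1])
  zero <- x$counts; zero[, 2] <- 0L
  expect_error(cpm(zero), "s2")
})

test_that("size factors follow median-of-ratios on hand-computed cases", {
  # columns proportional 1:2:4 -> factors 0.5, 1, 2 after geomean rescaling
  m <- matrix(c(1, 2, 3, 2, 4, 6, 4, 8, 12), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  expect_equal(unname(size_factors(m)), c(0.5, 1, 2))
  expect_equal(unname(size_factors(m[, c(1, 1, 1)] + 0)), rep(1, 3))
  # non-proportional 3x3: independent recomputation of the definition
  m2 <- matrix(c(4, 10, 20, 8, 10, 10, 16, 40, 5), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  geo <- apply(m2, 1, function(r) prod(r)^(1 / 3))
  raw <- apply(m2, 2, function(cl) stats::median(cl / geo))
  expect_equal(unname(size_factors(m2)), unname(raw / prod(raw)^(1 / 3)))
  allzero <- matrix(c(0, 1, 1, 0, 0, 2), 2,
                    dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_error(size_factors(allzero), "filter")
})

test_that("BH adjustment reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 6)), rep(0.2, 6))
  expect_error(bh_adjust(c(0.1, 1.3)), "\\[0, 1\\]")
  # brute-force enumeration over all permutations of random 5-vectors
  set.seed(1)
  for (rep in 1:5) {
    p <- round(stats::runif(5), 3)
    perms <- matrix(unlist(combinat_perms(5)), ncol = 5, byrow = TRUE)
    for (i in seq_len(nrow(perms))) {
      q <- p[perms[i, ]]
      expect_equal(bh_adjust(q), bh_bruteforce(q))
    }
  }
})

test_that("the DE test is calibrated under the null and finds planted effects", {
  sim <- simulate_counts(sim_config(n_mirnas = 400, n_case = 6,
                                    n_control = 6, frac_de = 0, n_stable = 0,
                                    seed = 2))
  de <- de_test(sim$counts)
  expect_lt(abs(mean(de$log2fc)), 0.1)
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_lte(sum(de$call != "ns"), 2)

  sim2 <- simulate_counts(sim_config(n_mirnas = 150, n_case = 6,
                                     n_control = 6, frac_de = 0.1,
                                     lfc_range = c(2, 2), dispersion = 0.01,
                                     n_stable = 0, seed = 3))
  de2 <- de_test(sim2$counts)
  up_true <- sim2$truth$is_de & sim2$truth$true_log2fc > 0
  expect_false(any(de2$call[up_true] == "down"))
  called <- sim2$truth$is_de & de2$call != "ns"
  expect_gt(mean(called[sim2$truth$is_de]), 0.8)
  expect_lt(abs(mean(abs(de2$log2fc[called])) - 2), 0.5)
})

test_that("Wald and permutation p-values agree in rank order", {
  sim <- simulate_counts(sim_config(n_mirnas = 40, n_case = 5, n_control = 5,
                                    frac_de = 0.25, dispersion = 0.05,
                                    n_stable = 0, seed = 4))
  w <- de_test(sim$counts, method = "wald")
  set.seed(1)
  p <- de_test(sim$counts, method = "permutation", n_perm = 500)
  expect_gt(stats::cor(w$p, p$p, method = "spearman"), 0.9)
  expect_error(de_test(sim$counts, method = "bayes"))
  expect_warning(de_test(sim$counts, method = "permutation", n_perm = 50),
                 "100")
})

test_that("candidate ranking composes |log2FC| and FDR ranks deterministically", {
  de <- structure(
    data.frame(mirna_id = c("a", "b", "c", "d", "e"),
               base_mean = 100,
               log2fc = c(3, 2, 4, 1.5, 2.5),
               p = c(1e-4, 1e-4, 5e-4, 5e-5, 1e-3),
               fdr = c(0.001, 0.001, 0.005, 0.0005, 0.01),
               call = "up", stringsAsFactors = FALSE),
    class = c("mirde", "data.frame"))
  # hand-computed composite ranks: a 2.25, c 2.5, d 3, b 3.25, e 4
  expect_equal(rank_candidates(de, 5), c("a", "c", "d", "b", "e"))
  expect_equal(rank_candidates(de, 2), c("a", "c"))
  # equal fdr, |log2fc| 3 vs 2 -> the larger change ranks first
  de2 <- de[de$mirna_id %in% c("a", "b"), ]
  class(de2) <- class(de)
  expect_equal(rank_candidates(de2, 2), c("a", "b"))
  expect_warning(out <- rank_candidates(de, 10), "returning all")
  expect_length(out, 5)
})
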