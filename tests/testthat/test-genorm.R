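prop_matrix <- function() {
  base <- c(1, 2, 4, 8, 3, 5)
  rbind(g1 = base, g2 = 3 * base, g3 = 0.5 * base)
}

test_that("perfectly proportional genes have M exactly zero", {
  m <- genorm_m(prop_matrix())
  expect_equal(unname(m), c(0, 0, 0))
})

test_that("M matches the brute-force pairwise-sd oracle", {
  set.seed(7)
  expr <- 2^matrix(rnorm(12, 5, 0.4), 3, 4,
                   dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  expect_equal(genorm_m(expr), genorm_m_bruteforce(expr))
  expect_error(genorm_m(expr - 2^6), "positive")
})

test_that("log-noise added to one gene raises its M in expectation", {
  set.seed(42)
  worse <- 0L
  for (i in 1:50) {
    expr <- 2^matrix(rnorm(20, 6, 0.1), 4, 5,
                     dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
    m0 <- genorm_m(expr)["g1"]
    noisy <- expr
    noisy["g1", ] <- noisy["g1", ] * 2^rnorm(5, 0, 0.5)
    worse <- worse + (genorm_m(noisy)["g1"] > m0)
  }
  expect_gt(worse, 45)
})

test_that("iterative exclusion removes the noisy gene first", {
  set.seed(3)
  expr <- rbind(stable1 = 2^rnorm(6, 5, 0.02),
                stable2 = 2^rnorm(6, 7, 0.02),
                noisy = 2^rnorm(6, 6, 1.5))
  r <- rank_by_stability(expr)
  expect_equal(sort(r$gene[r$rank == 1]), c("stable1", "stable2"))
  expect_equal(r$gene[r$rank == max(r$rank)], "noisy")
})

test_that("ranking of proportional genes is a pure lexicographic tie-break", {
  # power-of-two entries give exact log2s, so the tie is exact
  base <- c(1, 2, 4, 8)
  expr <- rbind(g3 = base / 2, g1 = base, g2 = 4 * base)
  r <- rank_by_stability(expr)
  expect_equal(r$gene, c("g1", "g2", "g3"))
  expect_equal(r$rank, c(1L, 1L, 2L))
})

test_that("ranking agrees with exhaustive recomputation on a 4-gene input", {
  set.seed(11)
  expr <- 2^matrix(rnorm(24, 5, c(0.05, 0.1, 0.4, 0.9)), 4, 6,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  # oracle: recompute the removal sequence with the brute-force M
  remaining <- expr; removal <- character(0)
  while (nrow(remaining) > 2) {
    m <- genorm_m_bruteforce(remaining)
    worst <- names(which.max(m))
    removal <- c(removal, worst)
    remaining <- remaining[setdiff(rownames(remaining), worst), ]
  }
  r <- rank_by_stability(expr)
  expect_equal(sort(r$gene[r$rank == 1]), sort(rownames(remaining)))
  expect_equal(rev(r$gene[r$rank > 1]), removal)
})

test_that("the V curve matches the geometric-mean oracle and flags V = 0 cases", {
  set.seed(13)
  expr <- 2^matrix(rnorm(24, 5, 0.3), 4, 6,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  ranking <- paste0("g", 1:4)
  pv <- pairwise_variation(expr, ranking)
  expect_equal(unname(pv$v_curve), v_curve_bruteforce(expr, ranking),
               tolerance = 1e-10)
  # gene n+1 proportional to NF_n -> V(n, n+1) = 0
  nf2 <- sqrt(expr["g1", ] * expr["g2", ])
  expr0 <- rbind(expr[1:2, ], g3 = 2 * nf2, g4 = expr["g4", ])
  pv0 <- pairwise_variation(expr0, paste0("g", 1:4))
  expect_equal(unname(pv0$v_curve["V2/3"]), 0)
})

test_that("the V threshold is strict and falls back to all genes with a warning", {
  # three stable genes: V(2,3) far below 0.15 -> two references suffice
  set.seed(19)
  expr <- 2^matrix(rnorm(18, 5, 0.01), 3, 6,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:6)))
  expect_equal(genorm(expr)$recommended_n, 2L)
  # V just above the cut is not accepted; just below is
  eps <- 1e-6
  mk <- function(target_v) {
    d <- target_v * sqrt(2) * 3           # sd(c(0, d)/3) = target_v
    rbind(g1 = c(1, 1), g2 = c(1, 1), g3 = 2^c(0, d))
  }
  above <- suppressWarnings(pairwise_variation(mk(0.15 + eps),
                                               paste0("g", 1:3)))
  expect_equal(above$recommended_n, 3L)
  below <- pairwise_variation(mk(0.15 - eps), paste0("g", 1:3))
  expect_equal(below$recommended_n, 2L)
  expect_warning(pairwise_variation(mk(0.2), paste0("g", 1:3)), "recommending")
})

test_that("M is invariant to per-sample scaling and gene relabeling", {
  set.seed(23)
  for (i in 1:10) {
    expr <- 2^matrix(rnorm(30, 5, 0.5), 5, 6,
                     dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    scaled <- sweep(expr, 2, runif(6, 0.1, 10), "*")
    expect_equal(genorm_m(scaled), genorm_m(expr), tolerance = 1e-9)
    perm <- sample(5)
    expect_equal(genorm_m(expr[perm, ]), genorm_m(expr)[perm])
  }
})

test_that("implementation equals brute force on random matrices up to 5 x 6", {
  set.seed(29)
  for (G in 3:5) for (S in c(3, 6)) for (rep in 1:3) {
    expr <- matrix(stats::runif(G * S, 0.5, 100), G, S,
                   dimnames = list(paste0("g", 1:G), paste0("s", 1:S)))
    expect_equal(genorm_m(expr), genorm_m_bruteforce(expr))
    r <- rank_by_stability(expr)
    ord <- r$gene[order(r$rank, r$gene)]
    pv <- suppressWarnings(pairwise_variation(expr, ord))
    expect_equal(unname(pv$v_curve), v_curve_bruteforce(expr, ord),
                 tolerance = 1e-9)
  }
})

test_that("CT tables convert to 2^(-CT) quantities with replicate averaging", {
  ct <- make_ct(sample_id = c("s1", "s1", "s1", "s2", "s2"),
                group = "case",
                assay_id = c("a", "a", "b", "a", "b"),
                ct = c(20, 22, 25, 21, 25))
  q <- ct_to_expression(ct)
  expect_equal(q["a", "s1"], mean(2^-c(20, 22)))
  expect_equal(q["b", "s2"], 2^-25)
})
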