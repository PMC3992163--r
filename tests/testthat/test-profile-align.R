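test_that("self-alignment is perfect: Ne = NQ, zero RMSD, zero diversity", {
  p <- profile_from_values(c(3.2, 4.1, 5.6, 4.4, 3.9))
  al <- alignProfiles(p, p)
  expect_equal(al@ne, 5L)
  expect_equal(al@ladRmsd, 0)
  expect_equal(al@ladDiv, 0)
  expect_equal(alignedPairs(al)[, 1], alignedPairs(al)[, 2])
})

test_that("a small perturbation keeps the pairing and shows up in the RMSD", {
  q <- profile_from_values(c(1, 2, 3))
  s <- profile_from_values(c(1, 2, 3.1), id = "fix2:A")
  al <- alignProfiles(q, s)
  expect_equal(unname(alignedPairs(al)), cbind(1:3, 1:3), ignore_attr = TRUE)
  expect_equal(al@ladRmsd, sqrt(0.01 / 3))
})

test_that("profiles with incompatible metadata refuse to align", {
  q <- profile_from_values(1:4, metric = "ED")
  s <- profile_from_values(1:4, metric = "GD", id = "fix2:A")
  expect_error(alignProfiles(q, s), "metric mismatch")
  s2 <- profile_from_values(1:4, window = 11, id = "fix2:A")
  expect_error(alignProfiles(q, s2), "window mismatch")
})

test_that("profiles too different to align return an empty alignment, not an error", {
  q <- profile_from_values(c(1, 1.2, 1.1))
  s <- profile_from_values(c(50, 60, 70), id = "fix2:A")
  al <- alignProfiles(q, s)
  expect_equal(al@ne, 0L)
  expect_equal(al@ladDiv, 1)
})

test_that("the DP alignment matches exhaustive enumeration on short profiles", {
  set.seed(101)
  for (k in 1:60) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    a <- runif(n, 0, 4); b <- runif(m, 0, 4)
    al <- alignProfiles(profile_from_values(a),
                        profile_from_values(b, id = "fix2:A"))
    expect_equal(al@score, bf_local_align_score(a, b), tolerance = 1e-9)
    expect_equal(score_from_pairs(a, b, alignedPairs(al)), al@score,
                 tolerance = 1e-9)
  }
})

test_that("LAD_div follows its closed form at the published worked points", {
  # Ne = 0 -> 1; perfect match -> 0
  expect_equal(ladDiv(0, 0, 50, 50), 1)
  expect_equal(ladDiv(50, 0, 50, 50), 0)
  # ED-parameter worked value: RMSD 0.173, full coverage -> 0.0004 at 4 d.p.
  expect_equal(round(ladDiv(100, 0.173, 100, 100, D = 1, alpha = 4.5), 4),
               0.0004)
  # GD-parameter companion value (RMSD 0.454, LAD_div 0.02) is consistent
  # with near-complete coverage: the implied Ne/mean lies just below 1
  cov_gd <- (1 - 0.02) * (1 + (0.454 / 1.1)^5)
  expect_gt(cov_gd, 0.9)
  expect_lte(cov_gd, 1)
  # dissimilar-pair example: LAD_div 0.955 at RMSD 1.601 implies ~42% coverage
  cov <- (1 - 0.955) * (1 + (1.601 / 1)^4.5)
  expect_equal(cov, 0.42, tolerance = 0.01)
  expect_equal(ladDiv(cov * 100, 1.601, 100, 100, D = 1, alpha = 4.5), 0.955,
               tolerance = 1e-3)
  expect_error(ladDiv(10, 1, 0, 0), "zero")
  expect_error(ladDiv(80, 1, 50, 50), "exceeds")
})

test_that("LAD_div stays in [0,1] and is monotone in RMSD and coverage", {
  rmsd <- seq(0, 10, length.out = 1000)
  d <- ladDiv(40, rmsd, 50, 50)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(diff(d) >= 0))            # non-decreasing in RMSD
  ne <- seq(0, 50, length.out = 1000)
  d2 <- vapply(ne, function(k) ladDiv(k, 0.8, 50, 50), numeric(1))
  expect_true(all(diff(d2) <= 0))           # non-increasing in Ne
})

test_that("Struct_div follows its closed form", {
  expect_equal(structDiv(0, 30, 50, 50), 0)
  expect_equal(structDiv(2, 50, 100, 100), 2 / 0.5^1.5)   # 5.6569
  expect_equal(round(structDiv(2, 50, 100, 100), 4), 5.6569)
  expect_equal(structDiv(1.7, 80, 80, 80), 1.7)           # Ne = mean -> rmsd
  expect_identical(structDiv(2, 0, 50, 50), Inf)
})

test_that("alignment diversity is symmetric for generic profiles", {
  set.seed(17)
  for (k in 1:10) {
    a <- runif(sample(5:15, 1), 2, 8)
    b <- runif(sample(5:15, 1), 2, 8)
    d1 <- alignProfiles(profile_from_values(a),
                        profile_from_values(b, id = "o:A"))@ladDiv
    d2 <- alignProfiles(profile_from_values(b, id = "o:A"),
                        profile_from_values(a))@ladDiv
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("the (D, alpha) grid search covers 1800 combinations and ties go first", {
  pairs <- data.frame(ne = c(90, 85), lad_rmsd = c(0.2, 0.3),
                      nq = 100, ns = 100)
  # degenerate tuning: identical positives and negatives keep the objective
  # flat, so the tie rule must return the first grid point
  fit <- tuneDiversityParams(pairs, pairs)
  expect_equal(fit$evaluated, 1800L)
  expect_equal(fit$D, 0.1)
  expect_equal(fit$alpha, 1)
  expect_error(tuneDiversityParams(pairs[0, ], pairs), "non-empty")
})

test_that("well-separated synthetic pairs are recovered almost perfectly", {
  train <- makeLabeledPairs(120, 120, seed = 7)
  fit <- tuneDiversityParams(train[train$label == "pos", ],
                             train[train$label == "neg", ])
  held <- makeLabeledPairs(120, 120, seed = 8)
  div <- vapply(seq_len(nrow(held)), function(i)
    ladDiv(held$ne[i], held$lad_rmsd[i], held$nq[i], held$ns[i],
           D = fit$D, alpha = fit$alpha), numeric(1))
  acc <- mean(ifelse(held$label == "pos", div < 0.5, div >= 0.5))
  expect_gte(acc, 0.95)
})
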