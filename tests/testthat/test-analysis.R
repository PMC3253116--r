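test_that("group selection uses strict inequalities and drops missing genes", {
  tbl <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    sense_avg = c(0.9, 1.1, 0.9, 1.0, NA),
                    antisense_avg = c(0.6, 0.6, 0.5, 0.6, 0.6))
  sel <- select_high_antisense_low_sense(tbl, analysis_config())
  expect_equal(sel, "a")  # b fails sense<1, c fails antisense>0.5, d at bound
  empty <- tbl[0, ]
  expect_equal(length(select_high_antisense_low_sense(empty)), 0L)
})

test_that("differential selection is strict and antisymmetric", {
  tbl <- function(s) data.frame(gene_id = c("a", "b", "c"),
                                sense_avg = s, antisense_avg = 0)
  A <- tbl(c(2.01, 2.00, 0.0)); B <- tbl(c(1.0, 1.0, 1.0))
  expect_equal(differential_sense(A, B, 1), "a")  # 1.01 in, 1.00 out
  up <- differential_sense(A, B, 1)
  down <- differential_sense(B, A, 1)
  expect_length(intersect(up, down), 0L)
  A2 <- A[1:2, ]
  expect_warning(differential_sense(A2, B, 1), "intersection")
})

test_that("new-antisense selection applies the ratio on stored values", {
  t0 <- data.frame(gene_id = c("a", "b", "c"),
                   sense_avg = 0, antisense_avg = c(0.4, 1.0, -0.2))
  t1 <- data.frame(gene_id = c("a", "b", "c"),
                   sense_avg = 0, antisense_avg = c(1.0, 1.5, 0.2))
  sel <- select_new_antisense(t0, t1, analysis_config())
  expect_true("a" %in% sel)        # 1.0 / 0.4 = 2.5 > 2
  expect_false("b" %in% sel)       # 1.5 / 1.0 < 2
  expect_true("c" %in% sel)        # floored denominator 0.05: 0.2/0.05 > 2
  sel2 <- select_new_antisense(t0, t1, analysis_config(), exclude = "a")
  expect_false("a" %in% sel2)
})

test_that("delta correlation matches closed forms and flags degeneracy", {
  n <- 40
  set.seed(401)
  base <- data.frame(gene_id = sprintf("g%02d", 1:n),
                     sense_avg = rnorm(n), antisense_avg = rnorm(n))
  d <- rnorm(n)
  t1 <- base
  t1$sense_avg <- base$sense_avg + d
  t1$antisense_avg <- base$antisense_avg - d
  expect_equal(delta_correlation(base, t1), -1)
  expect_warning(r0 <- delta_correlation(base, base), "zero variance")
  expect_true(is.na(r0))
  expect_error(delta_correlation(base[1:2, ], t1[1:2, ]), "fewer than 3")

  # planted rho recovered within the Fisher-z sampling bound at n = 2000
  set.seed(402)
  m <- 2000
  z1 <- rnorm(m); z2 <- rnorm(m)
  rho <- -0.4
  big0 <- data.frame(gene_id = sprintf("g%04d", 1:m), sense_avg = 0,
                     antisense_avg = 0)
  big1 <- data.frame(gene_id = big0$gene_id, sense_avg = z1,
                     antisense_avg = rho * z1 + sqrt(1 - rho^2) * z2)
  expect_equal(delta_correlation(big0, big1), rho, tolerance = 0.05 / 0.4)
})

test_that("induction status is a strict-positive-delta rule, shift invariant", {
  mk <- function(v, s4, s6) list(
    veg = data.frame(gene_id = "g", sense_avg = v, antisense_avg = 0),
    m4 = data.frame(gene_id = "g", sense_avg = s4, antisense_avg = 0),
    m6 = data.frame(gene_id = "g", sense_avg = s6, antisense_avg = 0))
  t <- mk(1, 0.8, 0.9)   # deltas (-0.2, -0.1): not induced
  expect_false(meiotic_induction_status(t$veg, t$m4, t$m6)$induced)
  t <- mk(1, 0.8, 1.1)   # deltas (-0.2, +0.1): induced
  expect_true(meiotic_induction_status(t$veg, t$m4, t$m6)$induced)
  # adding a constant to all three samples leaves the deltas unchanged
  t2 <- mk(1 + 5, 0.8 + 5, 1.1 + 5)
  expect_equal(meiotic_induction_status(t$veg, t$m4, t$m6)$induced,
               meiotic_induction_status(t2$veg, t2$m4, t2$m6)$induced)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # N = 10, K = 5, n = 4, k = 4: C(5,4) C(5,0) / C(10,4) = 5/210
  universe <- sprintf("u%02d", 1:10)
  annotated <- universe[1:5]
  selection <- universe[1:4]
  res <- hypergeometric_enrichment(selection, annotated, universe)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  # full enumeration over all C(10,4) draws
  draws <- utils::combn(10, 4)
  tail4 <- mean(colSums(draws <= 5) >= 4)
  expect_equal(res$p_value, tail4, tolerance = 1e-12)

  # selection within annotated = universe: k = n, p = 1
  res2 <- hypergeometric_enrichment(universe[1:3], universe, universe)
  expect_equal(res2$p_value, 1)
  expect_error(hypergeometric_enrichment("a", "a", character()), "empty")

  # p decreases as the overlap k grows at fixed margins
  ps <- vapply(1:4, function(k) {
    sel <- c(annotated[seq_len(k)], universe[6:(9 - k + 1)])
    hypergeometric_enrichment(sel, annotated, universe)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("log-space enrichment p agrees with the direct density sum", {
  set.seed(403)
  for (rep in 1:20) {
    N <- sample(20:200, 1); K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    kr <- max(0L, n - (N - K)):min(n, K)
    k <- kr[sample.int(length(kr), 1)]
    universe <- sprintf("u%03d", seq_len(N))
    annotated <- universe[seq_len(K)]
    selection <- c(annotated[seq_len(k)],
                   setdiff(universe, annotated)[seq_len(n - k)])
    res <- hypergeometric_enrichment(selection, annotated, universe)
    direct <- sum(dhyper(k:min(n, K), K, N - K, n))
    if (direct > 0)
      expect_equal(res$p_value, direct, tolerance = 1e-10)
  }
})
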