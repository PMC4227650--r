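test_that("relative expression follows the efficiency-power ratio", {
  expect_equal(relative_expression(25, 25), 1)
  expect_equal(relative_expression(20, 30), 1024)
  # efficiency-corrected case against direct arithmetic
  expect_equal(relative_expression(20, 22, 1.9, 2.0), 2.0^22 / 1.9^20)
  # replicate Cts averaged before exponentiation
  expect_equal(relative_expression(c(19, 21), c(29, 31)), 1024)
  # identity holds for any valid ct/efficiency
  for (e in c(1.8, 1.95, 2)) {
    for (ct in c(15, 25, 35)) expect_equal(relative_expression(ct, ct, e, e), 1)
  }
  expect_error(relative_expression(20, 30, eff_target = 2.5),
               class = "promscreen_usage_error")
  expect_error(relative_expression(20, 30, eff_ref = 1),
               class = "promscreen_usage_error")
  expect_error(relative_expression(-1, 30), class = "promscreen_usage_error")
})

test_that("Ct tables summarise to per-sample folds versus the reference", {
  ct <- tibble::tibble(
    sample_id = rep(c("s1", "s2"), each = 4),
    target_id = rep(c("tgt", "tgt", "ref", "ref"), 2),
    ct = c(20, 20, 30, 30, 25, 27, 28, 28),
    efficiency = 2
  )
  out <- relative_expression_table(ct, "ref")
  expect_equal(out$fold[out$sample_id == "s1"], 1024)
  expect_equal(out$fold[out$sample_id == "s2"], 2^(28 - 26))
  expect_error(relative_expression_table(ct, "nonesuch"),
               class = "promscreen_usage_error")
})

test_that("geNORM M is zero for proportional genes and matches the hand example", {
  q <- rbind(A = c(1, 2, 4, 8), B = c(2, 4, 8, 16))
  res <- genorm_m(q)
  expect_equal(res$M, c(0, 0))

  q3 <- rbind(A = c(1, 2, 4, 8), B = c(2, 4, 8, 16), C = c(1, 1, 1, 1))
  res3 <- genorm_m(q3)
  expect_equal(res3$M[res3$gene_id == "A"], sd(0:3) / 2, tolerance = 1e-12)
  expect_equal(res3$M[res3$gene_id == "B"], sd(0:3) / 2, tolerance = 1e-12)
  expect_equal(res3$M[res3$gene_id == "C"], sd(0:3), tolerance = 1e-12)

  expect_error(genorm_m(q3[1, , drop = FALSE]), class = "promscreen_usage_error")
  expect_error(genorm_m(q3[, 1, drop = FALSE]), class = "promscreen_usage_error")
  q3[1, 1] <- 0
  expect_error(genorm_m(q3), class = "promscreen_usage_error")
})

test_that("geNORM M matches the brute-force pairwise oracle on random grids", {
  set.seed(101)
  for (i in 1:10) {
    q <- matrix(2^rnorm(40, 0, 1.5), 5, 8,
                dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:8)))
    res <- genorm_m(q)
    expect_equal(res$M, unname(oracle_genorm(q)[res$gene_id]),
                 tolerance = 1e-9)
  }
})

test_that("geNORM M is invariant to per-sample scaling and gene order", {
  set.seed(33)
  q <- matrix(2^rnorm(40, 0, 1), 5, 8,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:8)))
  base <- genorm_m(q)
  scaled <- sweep(q, 2, runif(8, 0.1, 10), `*`)
  expect_equal(genorm_m(scaled)$M, base$M, tolerance = 1e-12)
  perm <- sample(5)
  permuted <- genorm_m(q[perm, ])
  expect_equal(permuted$M[match(base$gene_id, permuted$gene_id)], base$M,
               tolerance = 1e-12)
})

test_that("a simulated stable reference clears the conventional M < 0.5 bar", {
  q <- withr::with_seed(19, {
    n <- 10
    rbind(ref1 = 2^rnorm(n, 0, 0.1), ref2 = 2^rnorm(n, 0, 0.1),
          ref3 = 2^rnorm(n, 0, 0.1))
  })
  expect_true(all(genorm_m(q)$M < 0.5))
})

test_that("iterative geNORM exclusion drops the least stable gene first", {
  q <- rbind(A = c(1, 2, 4, 8), B = c(2, 4, 8, 16), C = c(1, 1, 1, 1),
             D = c(1.1, 2.1, 3.9, 8.2))
  rk <- genorm_rank(q)
  expect_equal(rk$gene_id[1], "C")
  expect_equal(sum(is.na(rk$order_excluded)), 2L)
})

test_that("copy-number windows call absent, single and multi insertions", {
  out <- copy_number_call(c(0.63, 0, 2.1, 0.5))
  expect_equal(out$call, c("single", "absent", "multi", "single"))
  expect_false(any(out$indeterminate))
  expect_warning(ind <- copy_number_call(0.15), "indeterminate")
  expect_equal(ind$call, "single")
  expect_true(ind$indeterminate)
  expect_error(copy_number_call(-0.1), class = "promscreen_usage_error")
})

test_that("transformation efficiency normalizes to control and applies the 30-fold workability rule", {
  rec <- tibble::tibble(construct_id = c("ctrl", "same", "hsp18like", "half"),
                        n_fertile = c(10, 10, 1, 5),
                        n_calli = c(100, 100, 400, 50))
  out <- transformation_efficiency(rec, "ctrl")
  expect_equal(out$normalized_efficiency[out$construct_id == "ctrl"], 100)
  expect_equal(out$normalized_efficiency[out$construct_id == "same"], 100)
  expect_true(out$workable[out$construct_id == "same"])
  # 5/50 vs control 10/100 -> 100%
  expect_equal(out$normalized_efficiency[out$construct_id == "half"], 100)
  # 1/400 is 2.5% of control: below 100/30, not workable
  expect_equal(out$normalized_efficiency[out$construct_id == "hsp18like"], 2.5)
  expect_false(out$workable[out$construct_id == "hsp18like"])

  expect_error(transformation_efficiency(rec, "missing"),
               class = "promscreen_usage_error")
  bad <- rec; bad$n_calli[2] <- 0
  expect_error(transformation_efficiency(bad, "ctrl"),
               class = "promscreen_usage_error")
})
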