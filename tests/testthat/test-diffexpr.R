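test_that("RPM normalisation and fold change follow their definitions", {
  expect_equal(rpm(0, 1e6), 0)
  expect_equal(rpm(1e6, 1e6), 1e6)
  expect_equal(rpm(100, 1e6), 100)
  expect_error(rpm(1, 0), "positive")

  expect_equal(log2_fold_change(100, 100), 0)
  expect_equal(log2_fold_change(400, 100), 2)
  expect_equal(log2_fold_change(100, 400),
               -log2_fold_change(400, 100))  # antisymmetry
  # zero counts hit the pseudo-value only inside the fold change
  expect_equal(log2_fold_change(0, 0), 0)
  expect_equal(log2_fold_change(10.24, 0), log2(10.24 / 0.01))
})

test_that("exact-test pmf matches hand values and the closed form", {
  expect_equal(ac_pmf(0, 0, 1e6, 1e6), 0.5)
  expect_equal(ac_pmf(1, 1, 1e6, 1e6), 0.25)
  # closed form at a 2:1 ratio, evaluated directly
  x <- 5; y <- 10; N1 <- 1e6; N2 <- 2e6; r <- N2 / N1
  direct <- r^y * factorial(x + y) / (factorial(x) * factorial(y)) /
    (1 + r)^(x + y + 1)
  expect_equal(ac_pmf(x, y, N1, N2), direct, tolerance = 1e-12)
  expect_error(ac_pmf(-1, 0, 1, 1))
})

test_that("pmf sums to one and coincides with the binomial at equal depths", {
  for (x in c(0, 1, 5, 50)) {
    for (r in c(0.5, 1, 2)) {
      s <- sum(ac_pmf(x, 0:5000, 1e6, r * 1e6))
      expect_equal(s, 1, tolerance = 1e-9)
    }
    # with N1 = N2 the conditional law is Binomial(x+y, 1/2) renormalised:
    # P(y | x) = C(x+y, y) / 2^(x+y+1) = dbinom(y, x+y, 1/2) / 2
    y <- 0:20
    expect_equal(ac_pmf(x, y, 1e6, 1e6), dbinom(y, x + y, 0.5) / 2,
                 tolerance = 1e-12)
  }
})

test_that("tail sums satisfy the C + D identity and symmetry", {
  # at x = y with equal depths the lower tail is exactly 1/2 (a binomial
  # median identity), so the two-sided p-value caps at 1
  for (x in c(3, 7, 25)) {
    res <- ac_pvalue(x, x, 1e6, 1e6)
    expect_equal(res$C, 0.5, tolerance = 1e-12)
    expect_equal(res$D, 0.5 + ac_pmf(x, x, 1e6, 1e6), tolerance = 1e-10)
    expect_equal(res$p_value, 1)
  }
  res <- ac_pvalue(7, 7, 1e6, 1e6)
  expect_equal(res$p_value, min(1, 2 * min(res$C, res$D)))
  for (x in c(0, 3, 40)) {
    for (y in c(0, 5, 60)) {
      r <- ac_pvalue(x, y, 1e6, 2e6)
      expect_equal(r$C + r$D - ac_pmf(x, y, 1e6, 2e6), 1, tolerance = 1e-10)
    }
  }
  # y = 0 boundary: D = 1 and C = P(0 | x)
  b <- ac_pvalue(12, 0, 1e6, 1e6)
  expect_equal(b$D, 1)
  expect_equal(b$C, ac_pmf(12, 0, 1e6, 1e6), tolerance = 1e-12)
})

test_that("p-values are monotone along either tail", {
  x <- 50
  N <- 1e6
  ys <- 0:200
  p <- ac_pvalue(x, ys, N, N)$p_value
  peak <- which.max(p)
  expect_true(all(diff(p[1:peak]) >= -1e-12))
  expect_true(all(diff(p[peak:length(p)]) <= 1e-12))
})

test_that("independent nbinom identity reproduces the tails", {
  # the conditional law is NegBinomial(size = x + 1, prob = N1/(N1+N2));
  # this closed-form identity is an independent cross-check, not the
  # implementation route
  for (r in c(0.5, 1, 2)) {
    for (x in c(0, 4, 33)) {
      got <- ac_pvalue(x, 0:80, 1e6, r * 1e6)
      expect_equal(got$C, pnbinom(0:80, x + 1, 1 / (1 + r)),
                   tolerance = 1e-10)
      expect_equal(got$D,
                   c(1, pnbinom(0:79, x + 1, 1 / (1 + r),
                                lower.tail = FALSE)),
                   tolerance = 1e-8)
    }
  }
})

test_that("DE calling gates on both p-value and fold change", {
  res <- data.frame(
    mirna_id = c("a", "b", "c", "d"),
    p_value = c(0.04, 0.005, 0.2, 0.004),
    log2fc = c(0.8, -1.5, 2.0, 1.2)
  )
  de <- call_de(res)
  expect_equal(unname(de$tally["n_de"]), 2)        # b and d
  expect_false(de$results$de_flag[1])              # fold-change gate
  expect_true(de$results$sig_flag[2])
  expect_equal(de$results$direction[2], "down")
  expect_equal(unname(de$tally["n_sig_up"]), 1)
  expect_equal(unname(de$tally["n_de"]),
               unname(de$tally["n_up"] + de$tally["n_down"]))
})

test_that("ac_test assembles a coherent expression table", {
  tab <- ac_test(c("m1", "m2"), c(50, 0), c(5, 7), 1e6, 2e6)
  expect_equal(tab$rpm_treated, c(50, 0))
  expect_equal(tab$rpm_control, c(2.5, 3.5))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_equal(tab$log2fc[2], log2(0.01 / 3.5))
  swap <- ac_test(c("m1"), 5, 50, 2e6, 1e6)
  direct <- ac_test(c("m1"), 50, 5, 1e6, 2e6)
  expect_equal(swap$log2fc, -direct$log2fc)
})

test_that("type-I error with the fold-change gate stays at the nominal level", {
  set.seed(77)
  n_flagged <- 0
  n_tot <- 0
  for (rep in 1:5) {
    mu <- 10^runif(300, 0.7, 3.3)
    cnt <- simulate_counts(mu, lfc = 0, dispersion = 0.02)
    res <- ac_test(paste0("m", 1:300), cnt$count_treated, cnt$count_control,
                   sum(cnt$count_treated) * 20, sum(cnt$count_control) * 20)
    de <- call_de(res)
    n_flagged <- n_flagged + de$tally["n_de"]
    n_tot <- n_tot + 300
  }
  expect_lt(n_flagged / n_tot, 0.07)
})
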