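# Statistical primitives against closed forms and brute-force oracles.

test_that("Fisher's exact test matches closed forms", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)
  # both extreme tables: p = 2 / C(20, 10)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10), 2 / choose(20, 10),
               tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact_2x2(0, 0, 3, 4), "degenerate")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  # includes the stratified carrier table with a = 18, b = 14, c = 7, d = 27
  expect_equal(fisher_exact_2x2(18, 14, 7, 27), fisher_enum_oracle(18, 14, 7, 27),
               tolerance = 1e-10)
  withr::with_seed(101, {
    for (i in 1:200) {
      repeat {
        n <- sample(4:60, 1)
        cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
        tab <- matrix(cells, 2, byrow = TRUE)
        if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) break
      }
      expect_equal(
        fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4]),
        fisher_enum_oracle(cells[1], cells[2], cells[3], cells[4]),
        tolerance = 1e-9
      )
    }
  })
})

test_that("Mann-Whitney exact path equals label enumeration", {
  expect_equal(mann_whitney_u(c(1, 2), c(3, 4))$p_value, 1 / 3)
  withr::with_seed(55, {
    for (i in 1:60) {
      n <- sample(2:6, 1)
      m <- sample(2:6, 1)
      repeat {
        x <- round(runif(n, 0, 100), 3)
        y <- round(runif(m, 0, 100), 3)
        if (!anyDuplicated(c(x, y))) break
      }
      got <- mann_whitney_u(x, y)
      expect_equal(got$method, "exact")
      expect_equal(got$p_value, mw_enum_oracle(x, y), tolerance = 1e-12)
    }
  })
})

test_that("Mann-Whitney tie-corrected approximation gives p = 1 for identical samples", {
  x <- c(1, 2, 2, 3, 5, 5, 6, 7, 8, 9)
  got <- mann_whitney_u(x, x)
  expect_equal(got$method, "normal_approx")
  expect_equal(got$p_value, 1)
  # cross-check the approximation against the base implementation
  y <- c(2, 3, 3, 4, 8, 9, 10, 11, 12, 15)
  ref <- suppressWarnings(
    stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  )
  expect_equal(mann_whitney_u(x, y)$p_value, ref, tolerance = 1e-10)
  expect_error(mann_whitney_u(numeric(0), x), "non-empty")
})

test_that("Spearman correlation handles monotone and degenerate inputs", {
  x <- 1:10
  expect_equal(spearman_rho(x, x^2)$rho, 1)
  expect_equal(spearman_rho(x, -x^3)$rho, -1)
  expect_warning(res <- spearman_rho(c(1, 2, 3), c(5, 5, 5)), "zero rank")
  expect_true(is.na(res$rho))
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("Spearman rho and p match the t-approximation reference", {
  withr::with_seed(77, {
    for (i in 1:25) {
      n <- sample(5:40, 1)
      x <- rnorm(n)
      y <- 0.5 * x + rnorm(n)
      got <- spearman_rho(x, y)
      ref <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE)
      )
      expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-10)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-8)
    }
  })
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  withr::with_seed(78, {
    x <- rexp(20)
    y <- rnorm(20)
    base <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(log(x), y)$rho, base)
    expect_equal(spearman_rho(x, exp(y))$rho, base)
    expect_equal(spearman_rho(rank(x), y^3)$rho, base)
  })
})

test_that("BH adjustment honours the declared family size", {
  expect_equal(bh_adjust(0.02, m = 1), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), m = 5),
               rep(0.05, 5))
  # family larger than the supplied vector inflates each adjusted p
  expect_equal(bh_adjust(c(0.01, 0.04), m = 8), c(0.08, 0.16))
  expect_error(bh_adjust(c(0.1, 0.2), m = 1), "at least")
  expect_error(bh_adjust(1.2), "\\[0, 1\\]")
})

test_that("BH step-up equals the quadratic-time reference", {
  withr::with_seed(202, {
    for (i in 1:100) {
      k <- sample(1:12, 1)
      p <- round(runif(k), 4)
      m <- k + sample(0:4, 1)
      expect_equal(bh_adjust(p, m = m), bh_quad_oracle(p, m), tolerance = 1e-12)
    }
  })
})

test_that("BH adjustment never decreases p, preserves ranks, and fixes constants", {
  withr::with_seed(203, {
    p <- runif(10)
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    # order of evidence is preserved
    expect_true(all(diff(adj[order(p)]) >= 0))
    # the smallest p at rank 1 is scaled by the full family size when that
    # bound is binding
    p2 <- c(0.001, 0.5, 0.6, 0.7)
    expect_equal(bh_adjust(p2)[1], 4 * 0.001)
    # constant vectors are the fixed points of the step-up map
    flat <- bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), m = 5)
    expect_equal(bh_adjust(flat, m = 5), flat)
  })
})

test_that("logistic OR recovers the null and respects age centring", {
  withr::with_seed(301, {
    dat <- simulate_association(500, or = 1, base_rate = 0.3)
    fit <- logistic_or(dat)
    expect_true(fit$ci_lo <= 1 && 1 <= fit$ci_hi)
    expect_false(fit$ci_unbounded)
    # centring age leaves the LOY coefficient identical to the raw fit
    raw <- stats::glm(carrier ~ loy + age + I(age^2), binomial(), data = dat)
    expect_equal(fit$log_or, unname(coef(raw)[["loyTRUE"]]), tolerance = 1e-6)
  })
})

test_that("complete separation is flagged, and Firth tames it", {
  dat <- tibble::tibble(
    carrier = rep(c(TRUE, FALSE), each = 12),
    loy = rep(c(TRUE, FALSE), each = 12),
    age = rep(seq(70, 92, length.out = 12), 2)
  )
  fit <- logistic_or(dat)
  expect_true(fit$ci_unbounded)
  firth <- logistic_or(dat, firth = TRUE)
  expect_false(firth$ci_unbounded)
  expect_true(is.finite(firth$or) && firth$or > 1)
  expect_error(
    logistic_or(dat %>% dplyr::mutate(carrier = TRUE)),
    "non-carrier"
  )
})

test_that("Firth fit matches plain ML closely on well-behaved data", {
  withr::with_seed(302, {
    dat <- simulate_association(2000, or = 3, base_rate = 0.25)
    ml <- logistic_or(dat)
    fi <- logistic_or(dat, firth = TRUE)
    expect_equal(fi$log_or, ml$log_or, tolerance = 0.05)
  })
})
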