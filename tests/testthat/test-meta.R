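test_that("mean difference and its variance follow the two-arm formula", {
  eff <- mean_difference(64.22, 12, 31, 50.73, 14, 30)
  expect_equal(eff$md, 13.49)
  expect_equal(eff$variance, 12^2 / 31 + 14^2 / 30)
  expect_equal(eff$variance, 11.178, tolerance = 1e-3)

  expect_equal(mean_difference(10, 2, 5, 10, 2, 5)$md, 0)

  expect_error(mean_difference(10, 0, 5, 12, 0, 5),
               "degenerate", class = "sctbias_domain_error")
})

test_that("fixed-effect pooling matches hand-computed cases", {
  # md {0, 1, 2}, all variance 1: pooled 1, Q = 2 = df, I^2 truncates to 0
  fit <- pool_fixed(tibble::tibble(md = c(0, 1, 2), variance = 1))
  expect_equal(fit$pooled_md, 1)
  expect_equal(fit$q, 2)
  expect_equal(fit$df, 2L)
  expect_equal(fit$i_squared, 0)

  # two identical studies: no heterogeneity at all
  fit2 <- pool_fixed(tibble::tibble(md = c(3, 3), variance = c(2, 2)))
  expect_equal(fit2$q, 0)
  expect_equal(fit2$i_squared, 0)
  expect_equal(fit2$pooled_md, 3)

  # weights are inverse variances and sum to 1 / pooled_se^2
  fit3 <- pool_fixed(tibble::tibble(md = c(1, 4, -2), variance = c(0.5, 2, 4)))
  expect_equal(fit3$studies$weight, 1 / c(0.5, 2, 4))
  expect_equal(sum(fit3$studies$weight), 1 / fit3$pooled_se^2)
  expect_gte(fit3$pooled_md, min(c(1, 4, -2)))
  expect_lte(fit3$pooled_md, max(c(1, 4, -2)))

  expect_error(pool_fixed(tibble::tibble(md = 1, variance = 1)),
               class = "sctbias_domain_error")
  expect_error(pool_fixed(tibble::tibble(md = c(1, 2), variance = c(1, 0))),
               class = "sctbias_domain_error")
})

test_that("I^2 formula, truncation branch, and domain checks", {
  expect_equal(i_squared(6.895, 2), 100 * 4.895 / 6.895)
  expect_equal(round(i_squared(6.895, 2)), 71)
  expect_equal(i_squared(2, 2), 0)
  expect_equal(i_squared(0.004, 2), 0)
  expect_equal(i_squared(0, 5), 0)
  expect_error(i_squared(-1, 2), class = "sctbias_domain_error")
  expect_error(i_squared(3, 0), class = "sctbias_domain_error")

  withr::with_seed(8, {
    q <- rexp(100, 1 / 3)
    i2 <- i_squared(q, 2)
    expect_true(all(i2 >= 0 & i2 < 100))
  })
})

test_that("pooling is invariant to study order and effect sign, equivariant to scale", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      k <- sample(2:6, 1)
      md <- rnorm(k, sd = 4)
      v <- rexp(k, 1 / 2) + 0.1
      base <- pool_fixed(tibble::tibble(md = md, variance = v))

      perm <- sample(k)
      fitp <- pool_fixed(tibble::tibble(md = md[perm], variance = v[perm]))
      expect_equal(fitp$pooled_md, base$pooled_md)
      expect_equal(fitp$q, base$q)
      expect_equal(fitp$i_squared, base$i_squared)

      fitn <- pool_fixed(tibble::tibble(md = -md, variance = v))
      expect_equal(fitn$pooled_md, -base$pooled_md)
      expect_equal(fitn$q, base$q)
      expect_equal(fitn$i_squared, base$i_squared)

      c_scale <- runif(1, 0.2, 5)
      fits <- pool_fixed(tibble::tibble(md = c_scale * md,
                                        variance = c_scale^2 * v))
      expect_equal(fits$pooled_md, c_scale * base$pooled_md)
      expect_equal(fits$i_squared, base$i_squared)
    }
  })
})

test_that("pooling agrees with an independent direct-summation oracle", {
  withr::with_seed(33, {
    for (rep in 1:40) {
      k <- sample(2:6, 1)
      md <- rnorm(k, sd = 3)
      v <- rexp(k) + 0.05
      fit <- pool_fixed(tibble::tibble(md = md, variance = v))
      ref <- oracle_pool(md, v)
      expect_equal(fit$pooled_md, ref$pooled_md, tolerance = 1e-10)
      expect_equal(fit$pooled_se, ref$pooled_se, tolerance = 1e-10)
      expect_equal(fit$q, ref$q, tolerance = 1e-10)
      expect_equal(fit$i_squared, ref$i_squared, tolerance = 1e-10)
    }
  })
})

test_that("pooling agrees with metafor's fixed-effect fit", {
  skip_if_not_installed("metafor")
  withr::with_seed(55, {
    for (rep in 1:10) {
      k <- sample(2:6, 1)
      md <- rnorm(k, sd = 3)
      v <- rexp(k) + 0.05
      fit <- pool_fixed(tibble::tibble(md = md, variance = v))
      ref <- metafor::rma(yi = md, vi = v, method = "FE")
      expect_equal(fit$pooled_md, as.numeric(ref$beta), tolerance = 1e-8)
      expect_equal(fit$pooled_se, as.numeric(ref$se), tolerance = 1e-8)
      expect_equal(fit$q, as.numeric(ref$QE), tolerance = 1e-8)
      expect_equal(fit$i_squared, as.numeric(ref$I2), tolerance = 1e-6)
    }
  })
})

test_that("tidy and glance views expose the fit as tibbles", {
  fit <- pool_fixed(tibble::tibble(study_id = c("a", "b", "c"),
                                   md = c(0, 1, 2), variance = 1))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$study_id, c("a", "b", "c"))
  expect_equal(td$weight_pct, rep(100 / 3, 3))

  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$pooled_md, 1)
  expect_equal(gl$k, 3)

  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
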