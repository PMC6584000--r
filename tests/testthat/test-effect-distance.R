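# Independent oracle: solve f(d) = f(far) + q (f(near) - f(far)) by uniroot
# on log10 d, without reusing the package's bisection.
ed_oracle <- function(beta0, beta1, transform, q, d_near = 0.19, d_far = 34.8) {
  f <- function(t) invert_transform(beta0 + beta1 * t, transform)
  tn <- log10(d_near); tf <- log10(d_far)
  target <- f(tf) + q * (f(tn) - f(tf))
  10^stats::uniroot(function(t) f(t) - target, c(tn, tf),
                    tol = 1e-12)$root
}

test_that("identity-transform effect distances follow the closed-form geometry", {
  # independent of the coefficients, by construction
  expect_equal(ed_point(0, -1, "identity", 0.1), 20.66792, tolerance = 1e-6)
  expect_equal(ed_point(5, -0.01, "identity", 0.1), 20.66792,
               tolerance = 1e-6)
  expect_equal(ed_point(0, -1, "identity", 0.5), 2.571381, tolerance = 1e-6)
  expect_equal(ed_point(0, -1, "identity", 0.5),
               sqrt(0.19 * 34.8), tolerance = 1e-9)   # log-midpoint
  for (q in c(0.05, 0.1, 0.5, 0.9))
    expect_equal(ed_point(2, -3, "identity", q),
                 ed_oracle(2, -3, "identity", q), tolerance = 1e-6)
})

test_that("bisection matches a dense grid search for the logit transform", {
  tgrid <- seq(log10(0.19), log10(34.8), length.out = 1e6)
  f <- invert_transform(0 - 2 * tgrid, "logit")
  target <- f[length(f)] + 0.1 * (f[1] - f[length(f)])
  d_grid <- 10^tgrid[which.min(abs(f - target))]
  expect_lt(abs(ed_point(0, -2, "logit", 0.1) - d_grid), 1e-4)
  expect_equal(ed_point(0, -2, "logit", 0.1), ed_oracle(0, -2, "logit", 0.1),
               tolerance = 1e-9)
})

test_that("closed forms and bisection agree over random parameter draws", {
  set.seed(31)
  for (i in 1:50) {
    b0 <- runif(1, -2, 2)
    b1 <- -exp(runif(1, log(0.2), log(3)))
    q <- runif(1, 0.05, 0.95)
    for (tr in c("identity", "log10", "logit"))
      expect_equal(ed_point(b0, b1, tr, q), ed_oracle(b0, b1, tr, q),
                   tolerance = 1e-6)
  }
})

test_that("effect distances respect endpoint limits and handle rising metrics", {
  expect_equal(ed_point(0, -1, "logit", 1 - 1e-9), 0.19, tolerance = 1e-6)
  expect_equal(ed_point(0, -1, "logit", 1e-9), 34.8, tolerance = 1e-6)
  # a light-like metric rises with distance; the definition is symmetric
  ed_up <- ed_point(1, 0.8, "sqrt", 0.1)
  expect_true(ed_up > 0.19 && ed_up < 34.8)
  expect_equal(ed_up, ed_oracle(1, 0.8, "sqrt", 0.1), tolerance = 1e-6)
  expect_error(ed_point(0, 0, "identity", 0.1), "undefined")
  expect_error(ed_point(0, -1, "identity", 1.2), "strictly between")
})

test_that("effect distances live on the back-transformed scale", {
  # on the transformed scale every metric would collapse to the identity
  # geometry; the natural-scale definition makes EDs coefficient-specific
  ed_id <- ed_point(0, -2, "identity", 0.5)
  ed_lg <- ed_point(0, -2, "logit", 0.5)
  ed_lg2 <- ed_point(1.5, -2, "logit", 0.5)
  expect_gt(abs(ed_lg - ed_id), 0.05)
  expect_gt(abs(ed_lg2 - ed_lg), 0.05)
})

test_that("posterior effect distances summarise per-draw inversions", {
  draws <- cbind(beta0 = rep(0.5, 400), beta1 = rep(-1.2, 400))
  res <- ed_posterior(draws, 0.1, transform = "logit", metric = "depo_index")
  expect_equal(res$ci95_km[1], res$ci95_km[2])            # width 0
  expect_equal(res$ed_km, ed_point(0.5, -1.2, "logit", 0.1))
  expect_equal(res$n_clipped, 0)

  # plug-in oracle from a near-degenerate fit
  sites <- simulate_sites(17, 0.19, 34.8)
  d <- rep(sites$distance_km, each = 2)
  y <- 0.5 - 1.2 * log10(d) + rnorm(length(d), 0, 1e-4)
  fit <- fit_decay(y, d, spec = quick_spec("logit", seed = 12))
  res2 <- ed_posterior(fit, 0.1)
  expect_lt(abs(res2$ed_km - ed_point(0.5, -1.2, "logit", 0.1)) /
              res2$ed_km, 0.01)

  # wrong-sign draws are clipped and counted, not dropped
  mix <- cbind(beta0 = rep(0, 400), beta1 = c(rep(-1, 360), rep(1, 40)))
  res3 <- ed_posterior(mix, 0.1, transform = "logit")
  expect_equal(res3$n_clipped, 40)
  expect_equal(res3$n_draws, 400)
  flat <- cbind(beta0 = rep(0, 10), beta1 = c(rep(1e-14, 6), rep(-1, 4)))
  expect_error(ed_posterior(flat, 0.1, transform = "logit"),
               "no gradient|not estimable")
})

test_that("widening residual noise widens the posterior ED interval on average", {
  sites <- simulate_sites(17, 0.19, 34.8)
  d <- sites$distance_km
  widths <- sapply(c(0.05, 0.6), function(sig) {
    mean(sapply(1:4, function(r) {
      set.seed(300 + r)
      y <- 0 - 0.8 * log10(d) + rnorm(length(d), 0, sig)
      fit <- fit_decay(y, d, spec = quick_spec("logit", seed = 400 + r))
      ci <- ed_posterior(fit, 0.1)$ci95_km
      diff(ci)
    }))
  })
  expect_lt(widths[1], widths[2])
})

test_that("the ED table is one row per metric with ED10 >= ED50", {
  draws <- cbind(beta0 = rnorm(300, 0, 0.1), beta1 = rnorm(300, -1.5, 0.1))
  res <- list(ed_posterior(draws, 0.1, transform = "logit", metric = "ssc"),
              ed_posterior(draws, 0.5, transform = "logit", metric = "ssc"))
  tab <- ed_table(res)
  expect_equal(nrow(tab), 1)
  expect_named(tab, c("metric", "ed10_km", "ed10_ci95", "ed50_km",
                      "ed50_ci95"))
  expect_gt(tab$ed10_km, tab$ed50_km)
  expect_error(ed_table(list()), "no effect-distance results")
})
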