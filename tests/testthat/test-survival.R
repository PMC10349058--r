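test_that("Kaplan-Meier matches the product-limit oracle", {
  # no events: flat curve, median undefined
  km0 <- kaplanMeier(c(3, 5, 9), c(0, 0, 0))
  expect_true(all(km0$curve$survival == 1))
  expect_true(is.na(km0$median))

  km1 <- kaplanMeier(c(2, 4, 6, 8), c(1, 0, 0, 0))
  expect_equal(km1$curve$survival[km1$curve$time == 2], 0.75)

  time <- c(1, 2, 2, 3, 5, 6)
  event <- c(1, 1, 0, 1, 0, 1)
  km <- kaplanMeier(time, event)
  orc <- oracleKm(time, event)
  got <- km$curve[km$curve$n_event > 0, c("time", "survival")]
  expect_equal(got$time, orc$time)
  expect_equal(got$survival, orc$survival, tolerance = 1e-12)
  expect_true(all(diff(km$curve$survival) <= 1e-12))
  expect_error(kaplanMeier(c(0, 1), c(1, 1)), "positive")
})

test_that("log-rank equals the risk-table oracle and honours df", {
  time <- c(1, 2, 3, 4, 6, 1.5, 2.5, 5, 7, 9)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  group <- rep(c("a", "b"), each = 5)
  res <- logrankTest(time, event, group)
  expect_equal(unname(res$statistic), oracleLogrank2(time, event, group),
               tolerance = 1e-9)

  dup <- logrankTest(rep(time, 2), rep(event, 2),
                     rep(c("a", "b", "c", "c"), each = 5))
  expect_equal(dup$details$df, 2)

  same <- logrankTest(c(time, time), c(event, event),
                      rep(c("g1", "g2"), each = 10))
  expect_lt(same$statistic, 1e-9)
  expect_equal(same$p.value, 1)
  expect_error(logrankTest(c(1, 2), c(0, 0), c("a", "b")), "event")
})

test_that("trend test reduces to log-rank for 2 groups and is order-symmetric", {
  set.seed(20)
  time <- rexp(30, rep(c(0.05, 0.15), each = 15))
  event <- rbinom(30, 1, 0.8)
  time <- pmax(time, 0.01)
  group <- rep(c("lo", "hi"), each = 15)
  if (sum(event) == 0) event[1] <- 1
  tr <- logrankTrend(time, event, factor(group, c("lo", "hi")))
  lr <- logrankTest(time, event, group)
  expect_equal(tr$statistic, unname(lr$statistic), tolerance = 1e-9)

  g3 <- factor(rep(c("a", "b", "c"), each = 10))
  t3 <- rexp(30, c(rep(0.05, 10), rep(0.1, 10), rep(0.2, 10)))
  e3 <- rbinom(30, 1, 0.9)
  fwd <- logrankTrend(t3, e3, g3)
  rev <- logrankTrend(t3, e3, factor(as.character(g3), c("c", "b", "a")))
  expect_equal(fwd$p.value, rev$p.value, tolerance = 1e-9)
  expect_equal(fwd$details$direction, -rev$details$direction)
})

test_that("trend test is better powered than pooling extremes", {
  set.seed(30)
  hit_trend <- hit_pool <- 0
  for (i in 1:100) {
    n <- 20
    g <- rep(1:3, each = n)
    h <- c(0.04, 0.08, 0.16)[g]
    t_ev <- rexp(3 * n, h)
    cens <- runif(3 * n, 0, 40)
    time <- pmin(t_ev, cens); event <- as.integer(t_ev <= cens)
    p_tr <- logrankTrend(time, event, factor(g))$p.value
    keep <- g != 2
    p_po <- logrankTest(time[keep], event[keep], g[keep])$p.value
    hit_trend <- hit_trend + (p_tr < 0.05)
    hit_pool <- hit_pool + (p_po < 0.05)
  }
  expect_gte(hit_trend, hit_pool)
})

test_that("Cox coefficient matches the closed-form toy solution", {
  # risk sets give dlogL/dbeta = 0 at exp(beta) = 1/sqrt(2)
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 0), x = c(1, 0, 1))
  fit <- coxFit(d, "x")
  expect_equal(fit$terms$coef, -log(2) / 2, tolerance = 1e-6)
  expect_equal(fit$terms$hr, exp(fit$terms$coef), tolerance = 1e-9)
  expect_true(fit$converged)
  expect_error(coxFit(data.frame(time = 1:4, event = c(1, 1, 0, 0),
                                 x = 1), "x"), "constant")
})

test_that("Cox is honest about null covariates and separation", {
  set.seed(31)
  coefs <- replicate(40, {
    d <- data.frame(time = rexp(60, 0.1), event = rbinom(60, 1, 0.7),
                    x = rbinom(60, 1, 0.5))
    coxFit(d, "x")$terms$coef
  })
  expect_lt(abs(mean(coefs)), 0.15)

  sep <- data.frame(time = c(1, 2, 3, 10, 11, 12),
                    event = c(1, 1, 1, 1, 1, 1),
                    x = c(1, 1, 1, 0, 0, 0))
  fit <- coxFit(sep, "x")
  expect_false(fit$converged)
})

test_that("stepwise selection applies the screen and elimination rules", {
  set.seed(32)
  n <- 300
  x_signal <- rbinom(n, 1, 0.4)
  x_noise <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.05 * exp(log(2.5) * x_signal))
  cens <- runif(n, 0, 40)
  d <- data.frame(time = pmin(t_ev, cens),
                  event = as.integer(t_ev <= cens),
                  score_high = x_signal, junk = x_noise,
                  pure_noise = rnorm(n))
  sw <- stepwiseCox(d, c("score_high", "junk", "pure_noise"))
  expect_true("score_high" %in% sw$selected)
  expect_false("junk" %in% sw$selected && "pure_noise" %in% sw$selected)
  # screened-out candidates never enter the multivariable stage, so they
  # cannot appear among the backward-elimination steps either
  uni <- sw$univariable
  expect_false(any(uni$term[!uni$admitted] %in% sw$trace$removed))
  expect_false(any(uni$term[!uni$admitted] %in% sw$selected))
  if (!is.null(sw$final))
    expect_true(all(vapply(sw$selected, function(v)
      cfAneuploidy:::termPvalue(sw$final, v), numeric(1)) < 0.05))
})

test_that("stepwise returns a null model when nothing passes the screen", {
  set.seed(33)
  d <- data.frame(time = rexp(80, 0.1), event = rbinom(80, 1, 0.7),
                  a = rnorm(80), b = rbinom(80, 1, 0.5))
  # force a no-signal screen by shuffling outcome relative to covariates
  sw <- stepwiseCox(d, c("a", "b"), enter_p = 1e-6)
  expect_null(sw$final)
  expect_length(sw$selected, 0)
  expect_s3_class(sw$univariable, "data.frame")
})

test_that("multi-level factors are screened as whole terms", {
  set.seed(34)
  n <- 200
  ps <- factor(sample(0:2, n, TRUE))
  t_ev <- rexp(n, 0.05 * exp(0.6 * (ps == "2")))
  cens <- runif(n, 0, 40)
  d <- data.frame(time = pmin(t_ev, cens),
                  event = as.integer(t_ev <= cens), who_ps = ps)
  fit <- coxFit(d, "who_ps")
  expect_equal(nrow(fit$terms), 2)  # ref level 0, coefficients for 1 and 2
  p <- cfAneuploidy:::termPvalue(fit, "who_ps")
  expect_true(p >= 0 && p <= 1)
})
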