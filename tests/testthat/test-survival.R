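# Hand-coded product-limit, log-rank and Efron partial-likelihood oracles
# keep the delegated estimators honest.

km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    at_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  tibble::tibble(time = ts, survival = out)
}

test_that("KM estimate matches the product-limit oracle", {
  # single subject with an event at 5
  km1 <- km_estimate(5, 1)
  expect_equal(km1$survival, 0)
  expect_equal(km1$time, 5)

  # all censored: S stays 1
  km2 <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km2$survival == 1))

  # 10-record worked set with ties and censoring
  time <- c(2, 3, 3, 5, 7, 7, 8, 10, 12, 14)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1, 0, 1)
  km <- km_estimate(time, event)
  oracle <- km_oracle(time, event)
  got <- km$survival[km$n_event > 0]
  expect_equal(got, oracle$survival, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 1e-12))

  expect_error(km_estimate(c(-1, 2), c(1, 1)), ">= 0")
})

logrank_oracle <- function(time, event, group) {
  # standard O-E / V chi-squared over event times, two groups
  g <- unique(group)
  ts <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (tt in ts) {
    n <- sum(time >= tt)
    n1 <- sum(time >= tt & group == g[1])
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g[1])
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

test_that("log-rank test matches the risk-table oracle and is label-symmetric", {
  time <- c(3, 5, 7, 9, 11, 13, 4, 6, 8, 10, 12, 14)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0, 1, 1, 1, 0)
  group <- rep(c("a", "b"), each = 6)
  lr <- logrank_test(time, event, group)
  expect_equal(lr$chi2, logrank_oracle(time, event, group), tolerance = 1e-10)
  lr2 <- logrank_test(time, event, ifelse(group == "a", "b", "a"))
  expect_equal(lr$chi2, lr2$chi2, tolerance = 1e-12)
  expect_equal(lr$p, lr2$p, tolerance = 1e-12)

  # two identical groups (duplicated records) give chi2 ~ 0
  lr3 <- logrank_test(rep(time[1:6], 2), rep(event[1:6], 2), rep(c("a", "b"), each = 6))
  expect_lt(lr3$chi2, 1e-10)

  expect_error(logrank_test(time, event, rep("a", 12)), "2 groups")
})

test_that("kaplan scan handles degenerate input and monotone transforms", {
  set.seed(61)
  n <- 40
  time <- rexp(n, 0.05); event <- rbinom(n, 1, 0.7)
  expr0 <- rep(3, n)
  res0 <- kaplan_scan(expr0, time, event)
  expect_true(is.na(res0$best_cutoff))
  expect_equal(res0$n_cutoffs_tested, 0L)

  expr <- rnorm(n)
  a <- kaplan_scan(expr, time, event)
  b <- kaplan_scan(exp(expr), time, event)   # monotone transform
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
  expect_equal(a$logrank_chi2, b$logrank_chi2, tolerance = 1e-12)
  expect_equal(a$n_cutoffs_tested, b$n_cutoffs_tested)
  expect_equal(a$p_bonferroni, min(1, a$p_raw * a$n_cutoffs_tested))

  expect_error(kaplan_scan(expr, time, rep(0, n)), "no events")
})

test_that("kaplan scan finds a programmed hazard gene", {
  set.seed(71)
  n <- 196
  hits <- 0; n_rep <- 25
  for (i in seq_len(n_rep)) {
    expr <- rnorm(n)
    time <- rexp(n, rate = exp(0.8 * expr) / 50)
    cens <- runif(n) < 0.3
    obs <- ifelse(cens, runif(n) * time, time)
    res <- kaplan_scan(expr, obs, as.integer(!cens))
    hits <- hits + (res$p_bonferroni < 0.05 && res$direction == 1)
  }
  expect_gte(hits / n_rep, 0.8)
})

efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (tt in unique(time[event == 1])) {
    D <- which(time == tt & event == 1)
    R <- which(time >= tt)
    d <- length(D)
    sum_r <- sum(exp(beta * x[R]))
    sum_d <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in 0:(d - 1)) ll <- ll - log(sum_r - (l / d) * sum_d)
  }
  ll
}

test_that("Cox fit matches a brute-force Efron partial likelihood with ties", {
  time <- c(4, 4, 6, 6, 8, 10, 12, 12)
  event <- c(1, 1, 1, 0, 1, 1, 1, 1)
  x <- c(1, 0, 1, 1, 0, 1, 0, 0)
  fit <- cox_fit(data.frame(time = time, event = event, x = x), "x")
  beta_oracle <- optimize(function(b) -efron_loglik(b, time, event, x),
                          c(-5, 5), tol = 1e-10)$minimum
  expect_equal(fit$table$beta, beta_oracle, tolerance = 1e-6)
  expect_equal(fit$loglik, efron_loglik(fit$table$beta, time, event, x),
               tolerance = 1e-8)

  # identical groups: beta ~ 0
  t2 <- rep(c(3, 5, 7, 9), 2); e2 <- rep(c(1, 1, 0, 1), 2)
  x2 <- rep(c(0, 1), each = 4)
  suppressWarnings(fit2 <- cox_fit(data.frame(time = t2, event = e2, x = x2), "x"))
  expect_lt(abs(fit2$table$beta), 1e-8)

  # sign flips under group label swap
  set.seed(81)
  d <- data.frame(x = rbinom(60, 1, 0.5))
  d$time <- rexp(60, exp(0.7 * d$x) / 20); d$event <- 1
  f_a <- cox_fit(d, "x")
  d2 <- d; d2$x <- 1 - d2$x
  f_b <- cox_fit(d2, "x")
  expect_equal(f_a$table$beta, -f_b$table$beta, tolerance = 1e-6)
})

test_that("Cox recovers a true hazard ratio of 2", {
  hrs <- vapply(1:50, function(s) {
    set.seed(200 + s)
    x <- rbinom(400, 1, 0.5)
    time <- rexp(400, rate = exp(log(2) * x) / 30)
    cens <- runif(400) < 0.2
    obs <- ifelse(cens, runif(400) * time, time)
    cox_fit(data.frame(time = obs, event = as.integer(!cens), x = x), "x")$table$HR
  }, numeric(1))
  expect_gt(mean(hrs), 1.8)
  expect_lt(mean(hrs), 2.2)
})

test_that("metagene construction pools risk-concordant scan hits", {
  scan_up <- tibble::tibble(gene = c("u1", "u2", "u3"),
                            p_bonferroni = c(0.01, 0.2, 0.03),
                            direction = c(1, 1, -1))
  scan_down <- tibble::tibble(gene = c("d1", "d2"),
                              p_bonferroni = c(0.04, NA),
                              direction = c(-1, -1))
  mg <- build_metagene(scan_up, scan_down)
  expect_equal(mg$unfavorable, "u1")
  expect_equal(mg$favorable, "d1")

  empty <- build_metagene(dplyr::mutate(scan_up, p_bonferroni = 0.9),
                          dplyr::mutate(scan_down, p_bonferroni = 0.9))
  expect_length(empty$unfavorable, 0)

  # score of a one-gene set is that gene's z-score
  m <- random_expr(5, 8, seed = 91)
  sc <- metagene_score(m, rownames(m)[1])
  z <- (m[1, ] - mean(m[1, ])) / sd(m[1, ])
  expect_equal(sc, z, tolerance = 1e-12)
})

test_that("association tests pick Fisher for sparse tables and match enumeration", {
  ann <- data.frame(a = rep(c("x", "y"), each = 20),
                    b = rep(c("u", "v"), 20))
  out <- association_tests(ann, list(c("a", "b")))
  expect_equal(out$test, "chisq")
  expect_equal(out$p, 1, tolerance = 1e-12)

  # Fisher on a sparse 2x2 equals the exact hypergeometric enumeration
  sp <- data.frame(a = rep(c("x", "y"), c(10, 6)),
                   b = c(rep("u", 8), rep("v", 2), rep("u", 1), rep("v", 5)))
  out2 <- association_tests(sp, list(c("a", "b")))
  expect_equal(out2$test, "fisher")
  tab <- table(sp$a, sp$b)
  # enumerate all tables with the observed margins
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_exact <- sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
  expect_equal(out2$p, p_exact, tolerance = 1e-10)

  # transpose symmetry
  out3 <- association_tests(sp, list(c("b", "a")))
  expect_equal(out2$p, out3$p, tolerance = 1e-12)

  expect_error(association_tests(data.frame(a = "x", b = c("u")),
                                 list(c("a", "b"))), "single level")
})
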