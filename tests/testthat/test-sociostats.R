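test_that("performance adjustment removes planted session trends and is idempotent", {
  set.seed(28)
  n_id <- 20; n_sess <- 12
  d <- data.frame(individual_id = rep(seq_len(n_id), each = n_sess),
                  session_index = rep(seq_len(n_sess), n_id),
                  day_gap = sample(1:3, n_id * n_sess, TRUE))
  # planted linear trend in session index
  d$score <- 0.5 + 0.02 * d$session_index + rnorm(nrow(d), 0, 0.05)
  a <- adjust_performance(d)
  expect_lt(abs(cor(a$adjusted, a$session_index)), 0.05)
  # grand means are preserved per individual
  m_raw <- tapply(a$score, a$individual_id, mean)
  m_adj <- tapply(a$adjusted, a$individual_id, mean)
  expect_equal(unname(m_adj), unname(m_raw), tolerance = 1e-10)
  # idempotence
  d2 <- a; d2$score <- a$adjusted
  a2 <- adjust_performance(d2)
  expect_lt(max(abs(a2$adjusted - a$adjusted)), 1e-10)
  # constant scores pass through
  dc <- d; dc$score <- 0.4
  expect_equal(adjust_performance(dc)$adjusted, rep(0.4, nrow(dc)))
  expect_error(adjust_performance(d[d$session_index < 3, ]), ">= 3")
})

test_that("the opponent F-test reduces to one-way repeated ANOVA and the textbook formula", {
  set.seed(29)
  n_id <- 12
  d <- expand.grid(individual_id = seq_len(n_id),
                   opponent = c("RB", "OTOM", "ITOM"))
  d$species <- "sp1"
  d$score <- rnorm(nrow(d), 0.5, 0.1) +
    rep(c(0, -0.05, -0.08), each = n_id)
  r <- effects_regression(d)
  # direct repeated-measures ANOVA of the same data
  a <- summary(stats::aov(score ~ factor(individual_id) + opponent, data = d))
  f_direct <- a[[1]]["opponent", "F value"]
  expect_equal(r$opponent$F, f_direct, tolerance = 1e-8)
  expect_equal(r$opponent$df1, 2)
  # textbook nested-SSR arithmetic on a fixed small design
  y <- c(1, 2, 3, 2, 5, 7)
  g <- factor(c("a", "a", "b", "b", "c", "c"))
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(unlist(lapply(split(y, g), function(v) (v - mean(v))^2)))
  f_hand <- ((rss0 - rss1) / 2) / (rss1 / 3)
  ft <- tomassay:::nested_f(lm(y ~ 1), lm(y ~ g))
  expect_equal(ft$F, f_hand, tolerance = 1e-12)
  expect_equal(ft$p, pf(f_hand, 2, 3, lower.tail = FALSE))
})

test_that("the opponent F-test has calibrated type-I error under the null", {
  set.seed(30)
  n_sim <- 400
  n_id <- 35
  d0 <- expand.grid(individual_id = seq_len(n_id),
                    opponent = c("RB", "OTOM", "ITOM"))
  d0$species <- rep(rep(paste0("sp", 1:7), each = 5), 3)
  rej <- 0L
  for (i in seq_len(n_sim)) {
    d0$score <- rnorm(nrow(d0))
    r <- effects_regression(d0)
    if (r$opponent$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / n_sim, 0.02)
  expect_lte(rej / n_sim, 0.09)
})

test_that("a planted opponent effect is detected with high power", {
  set.seed(31)
  n_id <- 35
  d <- expand.grid(individual_id = seq_len(n_id),
                   opponent = c("RB", "OTOM", "ITOM"))
  d$species <- rep(rep(paste0("sp", 1:7), each = 5), 3)
  hits <- 0L
  for (i in 1:30) {
    d$score <- rnorm(nrow(d)) + (d$opponent == "RB") * 1
    if (effects_regression(d)$opponent$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.9)
})

test_that("Sobel test matches its formula and detects a mediation chain", {
  set.seed(32)
  x <- rnorm(300); m <- 0.6 * x + rnorm(300, 0, 0.4)
  y <- 0.5 * m + rnorm(300, 0, 0.4)
  s <- sobel_mediation(x, m, y)
  expect_equal(s$z,
               s$a * s$b / sqrt(s$a^2 * s$se_b^2 + s$b^2 * s$se_a^2),
               tolerance = 1e-12)
  expect_lt(s$p, 1e-4)
  # hand arithmetic of the formula at fixed values
  z_hand <- (0.5 * 0.4) / sqrt(0.5^2 * 0.1^2 + 0.4^2 * 0.1^2)
  expect_equal(z_hand, 0.2 / sqrt(0.0025 + 0.0016), tolerance = 1e-12)
  expect_equal(round(z_hand, 3), 3.123)
  expect_error(sobel_mediation(rep(1, 20), rnorm(20), rnorm(20)),
               "zero-variance")
})

test_that("Sobel p-values are conservative-to-uniform under the null", {
  set.seed(33)
  n_sim <- 500
  p <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    x <- rnorm(40); m <- rnorm(40); y <- 0.4 * m + rnorm(40)
    p[i] <- sobel_mediation(x, m, y)$p
  }
  # under H0 (x independent of mediator) the Sobel test must not
  # over-reject; rejection at 5% should be at or below nominal
  expect_lte(mean(p < 0.05), 0.07)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("species-feature regression reproduces the direct Pearson formula", {
  feats <- species_features()
  set.seed(34)
  pt <- data.frame(species = feats$species,
                   ptom = plogis(scale(log(feats$ecv_cm3)) + rnorm(7, 0, 0.3)))
  out <- species_feature_regression(pt, feats,
                                    include = c("ecv_cm3", "group_size"))
  r_hand <- cor(log(feats$ecv_cm3), pt$ptom)
  expect_equal(out$pairwise$r[out$pairwise$feature == "ecv_cm3"], r_hand,
               tolerance = 1e-10)
  expect_false(any(out$pairwise$degenerate))
  expect_true(all(c("ecv_cm3", "group_size") %in%
                    rownames(out$regression$coefficients)))
  # constant pToM across species is flagged degenerate
  pt0 <- data.frame(species = feats$species, ptom = 0.5)
  out0 <- species_feature_regression(pt0, feats, include = "ecv_cm3")
  expect_true(all(out0$pairwise$degenerate))
  expect_null(out0$regression)
})
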