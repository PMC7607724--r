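test_that("every within-subject F equals the corresponding paired t squared", {
  set.seed(41)
  for (rep in 1:50) {
    tab <- random_table(n = sample(3:12, 1))
    a <- rmanova_2x2(tab)
    m <- as.matrix(tab[c("LA_high", "HA_high", "LA_low", "HA_low")])
    d_c <- (m[, 3] + m[, 4]) / 2 - (m[, 1] + m[, 2]) / 2
    d_a <- (m[, 2] + m[, 4]) / 2 - (m[, 1] + m[, 3]) / 2
    d_i <- (m[, 4] - m[, 3]) - (m[, 2] - m[, 1])
    for (k in 1:3) {
      tt <- t.test(list(d_c, d_a, d_i)[[k]])
      expect_equal(a$F[k], unname(tt$statistic)^2, tolerance = 1e-10)
      expect_equal(a$p[k], tt$p.value, tolerance = 1e-10)
      expect_identical(a$df_den[k], nrow(tab) - 1L)
    }
  }
})

test_that("rmANOVA matches the aov error-stratum oracle", {
  set.seed(42)
  for (rep in 1:5) {
    tab <- random_table(n = 7)
    long <- table_to_long(tab)
    fit <- summary(aov(y ~ clarity * ambiguity +
                         Error(subject / (clarity * ambiguity)), data = long))
    get_f <- function(stratum, term) {
      s <- fit[[paste0("Error: subject:", stratum)]][[1]]
      s[trimws(rownames(s)) == term, "F value"]
    }
    a <- rmanova_2x2(tab)
    expect_equal(a$F[a$effect == "Clarity"], get_f("clarity", "clarity"),
                 tolerance = 1e-8)
    expect_equal(a$F[a$effect == "Ambiguity"], get_f("ambiguity", "ambiguity"),
                 tolerance = 1e-8)
    expect_equal(a$F[a$effect == "Clarity:Ambiguity"],
                 get_f("clarity:ambiguity", "clarity:ambiguity"),
                 tolerance = 1e-8)
  }
})

test_that("degenerate no-variance tables yield F = 0, p = 1 with a warning", {
  tab <- make_table(matrix(5, nrow = 4, ncol = 4))
  w <- capture_warnings(a <- rmanova_2x2(tab))
  expect_length(w, 3)
  expect_match(w, "zero variance", all = TRUE)
  expect_true(all(a$F == 0))
  expect_true(all(a$p == 1))
  expect_true(all(a$partial_eta_sq == 0))
})

test_that("partial eta squared is invariant to per-participant offsets", {
  set.seed(43)
  tab <- random_table(6)
  shifted <- tab
  offs <- rnorm(6, sd = 10)
  for (cl in c("LA_high", "HA_high", "LA_low", "HA_low"))
    shifted[[cl]] <- shifted[[cl]] + offs
  expect_equal(rmanova_2x2(tab)$partial_eta_sq,
               rmanova_2x2(shifted)$partial_eta_sq, tolerance = 1e-10)
})

test_that("simple effects equal the paired t squared on the two cells", {
  set.seed(44)
  tab <- random_table(9)
  se <- simple_effect(tab, "clarity", "low_snr")
  tt <- t.test(tab$HA_low, tab$LA_low, paired = TRUE)
  expect_equal(se$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(se$p, tt$p.value, tolerance = 1e-10)

  se2 <- simple_effect(tab, "ambiguity", "HA")
  tt2 <- t.test(tab$HA_low, tab$HA_high, paired = TRUE)
  expect_equal(se2$F, unname(tt2$statistic)^2, tolerance = 1e-10)

  # identical cells -> F = 0 (with a degenerate-variance warning)
  tab0 <- tab
  tab0$HA_low <- tab0$LA_low
  expect_warning(se0 <- simple_effect(tab0, "clarity", "low_snr"),
                 "zero variance")
  expect_equal(se0$F, 0)
})

test_that("the pooled split-plot matches the aov oracle for balanced groups", {
  set.seed(45)
  t1 <- random_table(6)
  t2 <- random_table(6)
  t2$participant <- sub("P", "Q", t2$participant)
  res <- pooled_mixed_anova(list(t1, t2))
  expect_identical(res$df_den, rep(10L, 7))

  long <- rbind(cbind(table_to_long(t1), group = "e1"),
                cbind(table_to_long(t2), group = "e2"))
  long$group <- factor(long$group)
  fit <- summary(aov(y ~ group * clarity * ambiguity +
                       Error(subject / (clarity * ambiguity)), data = long))
  pick <- function(stratum, term) {
    s <- fit[[stratum]][[1]]
    s[trimws(rownames(s)) == term, "F value"]
  }
  expect_equal(res$F[res$effect == "Experiment"],
               pick("Error: subject", "group"), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "Clarity"],
               pick("Error: subject:clarity", "clarity"), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "Clarity:Experiment"],
               pick("Error: subject:clarity", "group:clarity"),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "Ambiguity"],
               pick("Error: subject:ambiguity", "ambiguity"), tolerance = 1e-8)
  expect_equal(res$F[res$effect == "Ambiguity:Experiment"],
               pick("Error: subject:ambiguity", "group:ambiguity"),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "Clarity:Ambiguity"],
               pick("Error: subject:clarity:ambiguity", "clarity:ambiguity"),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "Clarity:Ambiguity:Experiment"],
               pick("Error: subject:clarity:ambiguity",
                    "group:clarity:ambiguity"), tolerance = 1e-8)
})

test_that("identical groups produce a null Experiment effect", {
  set.seed(46)
  t1 <- random_table(5)
  t2 <- t1
  t2$participant <- sub("P", "Q", t2$participant)
  res <- pooled_mixed_anova(list(t1, t2))
  expect_equal(res$F[res$effect == "Experiment"], 0, tolerance = 1e-20)
  expect_error(pooled_mixed_anova(list(t1, t2, t1)), "two groups")
})

test_that("effect-magnitude contrast is a one-sample t squared and is symmetric", {
  set.seed(47)
  tab <- random_table(10)
  m <- as.matrix(tab[c("LA_high", "HA_high", "LA_low", "HA_low")])
  d_c <- (m[, 3] + m[, 4]) / 2 - (m[, 1] + m[, 2]) / 2
  d_a <- (m[, 2] + m[, 4]) / 2 - (m[, 1] + m[, 3]) / 2
  res <- effect_magnitude_contrast(tab)
  tt <- t.test(d_c - d_a)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_identical(res$df_den, 9L)

  # swapping the roles of the factors flips the sign but not F
  swapped <- make_table(m[, c(1, 3, 2, 4)])
  res_sw <- effect_magnitude_contrast(swapped)
  expect_equal(res_sw$F, res$F, tolerance = 1e-10)

  # equal per-participant effects -> F = 0
  tab0 <- make_table(cbind(0, m[, 2] - m[, 1], m[, 2] - m[, 1], 0) +
                       rnorm(10))
  m0 <- as.matrix(tab0[c("LA_high", "HA_high", "LA_low", "HA_low")])
  dc0 <- (m0[, 3] + m0[, 4]) / 2 - (m0[, 1] + m0[, 2]) / 2
  da0 <- (m0[, 2] + m0[, 4]) / 2 - (m0[, 1] + m0[, 3]) / 2
  expect_equal(dc0, da0, tolerance = 1e-12)
  expect_warning(r0 <- effect_magnitude_contrast(tab0), "zero variance")
  expect_equal(r0$F, 0)

  # pooling two experiments: df = total participants - 1
  res2 <- effect_magnitude_contrast(list(tab, random_table(8)))
  expect_identical(res2$df_den, 17L)
})

test_that("partial correlation residualizes out the covariate", {
  set.seed(48)
  x <- rnorm(30)
  pc <- partial_correlation(x, x + 1, rep(c(0, 1), 15))
  expect_equal(pc$r, 1, tolerance = 1e-9)
  expect_lt(pc$p, 1e-12)

  # both variables shifted by group: raw r large, partial r near zero
  g <- rep(c(0, 1), each = 40)
  x2 <- rnorm(80) + 5 * g
  y2 <- rnorm(80) + 5 * g
  raw_r <- cor(x2, y2)
  pc2 <- partial_correlation(x2, y2, g)
  rx <- residuals(lm(x2 ~ g)); ry <- residuals(lm(y2 ~ g))
  expect_equal(pc2$r, cor(rx, ry), tolerance = 1e-10)
  expect_gt(raw_r, abs(pc2$r))

  # df bookkeeping matches the n - 3 rule (73 participants -> 70)
  pc3 <- partial_correlation(rnorm(73), rnorm(73),
                             c(rep(1, 38), rep(2, 35)))
  expect_identical(pc3$df, 70)
  expect_error(partial_correlation(rnorm(10), rnorm(10), rep(1, 10)),
               "constant")
})
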