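make_factorial <- function(seed, treatment_shift = 0, interaction_shifts = NULL,
                           n = 5, sd = 0.3, genotypes = paste0("G", 1:4)) {
  set.seed(seed)
  grid <- expand.grid(replicate = seq_len(n), treatment = c("control", "drought"),
                      genotype = genotypes, stringsAsFactors = FALSE)
  mu <- 28 + ifelse(grid$treatment == "drought", treatment_shift, 0)
  if (!is.null(interaction_shifts)) {
    mu <- mu + ifelse(grid$treatment == "drought",
                      interaction_shifts[match(grid$genotype, genotypes)], 0)
  }
  grid$y <- mu + stats::rnorm(nrow(grid), 0, sd)
  grid
}

test_that("Cochran's C flags an inflated cell variance and passes homogeneous ones", {
  set.seed(5)
  g <- rep(letters[1:4], each = 10)
  y <- stats::rnorm(40)
  expect_gt(cochran_c_test(y, g)$p.value, 0.05)
  y[g == "d"] <- stats::rnorm(10, 0, 6)
  expect_lt(cochran_c_test(y, g)$p.value, 0.05)
  expect_equal(cochran_c_test(rep(1, 8), rep(1:2, each = 4))$p.value, 1)
})

test_that("a pure treatment effect routes comparisons between treatments", {
  d <- make_factorial(31, treatment_shift = 3)
  a <- factorial_analysis(d, "y")
  expect_equal(a$routing, "compare_between_treatments")
  expect_lt(a$anova_table$p[a$anova_table$term == "treatment"], 0.05)
  expect_named(a$letters, paste0("G", 1:4))
  # every genotype separates control from drought at this effect size
  for (lt in a$letters) expect_false(lt["control"] == lt["drought"])
})

test_that("genotype-specific drought offsets route comparisons within treatments", {
  d <- make_factorial(32, interaction_shifts = c(5, 3, 1, 1))
  a <- suppressWarnings(factorial_analysis(d, "y"))  # assumption-check warnings are incidental here
  expect_equal(a$routing, "compare_within_treatment")
  expect_lt(a$anova_table$p[a$anova_table$term == "treatment:genotype"], 0.05)
  expect_named(a$letters, c("control", "drought"))
  expect_gt(length(unique(a$letters$drought)), 1)   # genotypes split under drought
  expect_equal(length(unique(a$letters$control)), 1) # identical under control
})

test_that("an all-constant response yields no significance and one shared letter", {
  d <- make_factorial(33, sd = 0)
  d$y <- 30
  a <- suppressWarnings(factorial_analysis(d, "y"))  # perfect-fit F warnings from aov
  expect_false(a$significant)
  for (lt in a$letters) expect_true(all(lt == "a"))
})

test_that("studentized-range p-values agree with TukeyHSD on a one-way fit", {
  set.seed(41)
  df <- data.frame(g = rep(letters[1:4], each = 6),
                   y = stats::rnorm(24) + rep(c(0, 0.5, 1, 3), each = 6))
  fit <- stats::aov(y ~ g, data = df)
  hsd <- stats::TukeyHSD(fit)$g
  at <- summary(fit)[[1]]
  pm <- canopytherm:::tukey_pairwise_p(tapply(df$y, df$g, mean),
                                       tapply(df$y, df$g, length),
                                       at$`Mean Sq`[2], at$Df[2])
  for (row in rownames(hsd)) {
    pair <- strsplit(row, "-")[[1]]
    expect_equal(pm[pair[1], pair[2]], hsd[row, "p adj"], tolerance = 1e-8)
  }
})

test_that("compact letters follow the pairwise significance structure", {
  allsig <- matrix(0.01, 3, 3); diag(allsig) <- 1
  expect_equal(unname(compact_letters(allsig)), c("a", "b", "c"))
  nosig <- matrix(0.9, 3, 3); diag(nosig) <- 1
  expect_equal(unname(compact_letters(nosig)), c("a", "a", "a"))
  onesig <- matrix(0.9, 3, 3); diag(onesig) <- 1
  onesig[1, 3] <- onesig[3, 1] <- 0.01
  expect_equal(unname(compact_letters(onesig)), c("a", "ab", "b"))
})

test_that("letter displays are valid and minimal for up to six groups", {
  for (g in 2:6) for (rep in 1:8) {
    p <- random_p_matrix(g, seed = 100 * g + rep)
    lt <- compact_letters(p, 0.05)
    expect_true(cld_valid(lt, p, 0.05),
                label = sprintf("validity g=%d rep=%d", g, rep))
    n_letters <- length(unique(unlist(strsplit(lt, ""))))
    expect_equal(n_letters, cld_min_letters(p, 0.05),
                 label = sprintf("minimality g=%d rep=%d", g, rep))
  }
})

test_that("correlation coefficients map to the printed interpretation bands", {
  expect_equal(interpret_r(0.6), "moderate positive")
  expect_equal(interpret_r(c(0.1, 0.3, 0.45, 0.5, 0.7, 0.9, 1)),
               c("negligible positive", "low positive", "low positive",
                 "moderate positive", "high positive", "very high positive",
                 "very high positive"))
  expect_equal(interpret_r(-0.75), "high negative")
  expect_true(is.na(interpret_r(NA)))
})

test_that("the Pearson report matches exact and simulated relationships", {
  x <- 1:30
  df <- data.frame(x = x, y = 2 * x, z = stats::rnorm(30))
  rp <- pearson_report(df, c("x", "y", "z"))
  expect_equal(rp$r_matrix["x", "y"], 1)
  expect_equal(rp$interpretation_matrix["x", "y"], "very high positive")
  expect_true(all(diag(rp$r_matrix) == 1))
  expect_equal(rp$r_matrix, t(rp$r_matrix))
  # zero-variance column: undefined correlation, warned
  df$c0 <- 5
  expect_warning(rp0 <- pearson_report(df, c("x", "c0")), "zero variance")
  expect_true(is.na(rp0$r_matrix["x", "c0"]))
  # bivariate normal, true rho = 0.8, n = 40: small-sample bias region
  set.seed(55)
  rs <- replicate(500, {
    u <- stats::rnorm(40); v <- 0.8 * u + sqrt(1 - 0.64) * stats::rnorm(40)
    stats::cor(u, v)
  })
  expect_lt(abs(mean(rs) - 0.79), 0.05)
  expect_gt(mean(abs(rs) >= 0.7 & abs(rs) < 0.9), 0.5)  # "high" in the majority
})

test_that("Pearson r is affine invariant and sign flips under negation", {
  set.seed(66)
  df <- data.frame(a = stats::rnorm(25))
  df$b <- df$a + stats::rnorm(25, 0, 0.5)
  r0 <- pearson_report(df, c("a", "b"))$r_matrix["a", "b"]
  df$b2 <- 3 * df$b + 7
  df$b3 <- -df$b
  rp <- pearson_report(df, c("a", "b2", "b3"))
  expect_equal(rp$r_matrix["a", "b2"], r0)
  expect_equal(rp$r_matrix["a", "b3"], -r0)
})
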