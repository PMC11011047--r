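# Expands per-class counts into a score vector.
scores_from_counts <- function(n0, n1, n2) rep(0:2, c(n0, n1, n2))

test_that("prevalence percentages reconstruct the published table from counts", {
  ref <- reference_prevalence()
  rec <- as.data.frame(lapply(seq_len(nrow(ref)), function(i) {
    v <- rep(NA_integer_, max(ref$N))
    v[seq_len(ref$N[i])] <- scores_from_counts(ref$n0[i], ref$n1[i], ref$n2[i])
    v
  }))
  names(rec) <- ref$trait
  pt <- prevalence_table(rec, traits = ref$trait)
  expect_identical(pt$N, ref$N)
  expect_identical(pt$pct0, ref$pct0)
  expect_identical(pt$pct1, ref$pct1)
  expect_identical(pt$pct2, ref$pct2)
  expect_identical(pt$pct12, ref$pct12)
  ## internal consistency
  expect_identical(pt$n0 + pt$n1 + pt$n2, pt$N)
  expect_true(all(abs(pt$pct12_raw - pt$pct12) < 0.02))
})

test_that("prevalence handles degenerate and stratified inputs", {
  rec <- data.frame(t1 = c(0L, 0L, 0L, NA), g = c("a", "a", "b", "b"))
  pt <- prevalence_table(rec, traits = "t1")
  expect_identical(pt$pct0, 100)
  expect_identical(pt$pct12, 0)
  expect_identical(pt$N, 3L)   # missing excluded

  expect_warning(prevalence_table(data.frame(t1 = NA_integer_, t2 = c(1L, 2L)),
                                  traits = c("t1", "t2")), "omitted")
  expect_error(prevalence_table(rec, traits = "zz"), "no such trait")

  ## stratified counts sum to the overall counts
  set.seed(1)
  rec2 <- data.frame(t1 = sample(c(0:2, NA), 300, TRUE),
                     appraiser = sample(c("1", "2", "3"), 300, TRUE))
  by <- prevalence_by_factor(rec2, "appraiser", traits = "t1")
  expect_identical(Reduce(`+`, lapply(by, function(x) x$n12)),
                   prevalence_table(rec2, "t1")$n12)
  expect_error(prevalence_by_factor(rec2, "nope"), "unknown factor")

  ## a single-level factor reproduces the overall table
  rec2$one <- "x"
  expect_identical(prevalence_by_factor(rec2, "one", traits = "t1")$x,
                   prevalence_table(rec2, "t1"))
})

test_that("a severity-shifted appraiser shows the highest prevalence", {
  set.seed(2)
  n <- 3000
  appr <- sample(c("1", "2", "3"), n, TRUE)
  lat <- rnorm(n) + 0.8 * (appr == "2")
  rec <- data.frame(appraiser = appr, t1_latent = lat)
  rec <- discretize_to_classes(rec, list(t1 = c(0.5, 1.8)))
  by <- prevalence_by_factor(rec, "appraiser", traits = "t1")
  p12 <- vapply(by, function(x) x$pct12, numeric(1))
  expect_identical(names(which.max(p12)), "2")
})

test_that("two-class multinomial logit matches the logistic-regression oracle", {
  set.seed(3)
  n <- 500
  g <- sample(c("male", "female"), n, TRUE)
  a <- sample(c("1", "2", "3"), n, TRUE)
  eta <- -0.3 + 0.8 * (g == "female") + 0.5 * (a == "2")
  y <- rbinom(n, 1, plogis(eta))
  rec <- data.frame(t1 = y, gender = g, appraiser = a)
  expect_warning(fit <- fit_multinomial_logit(rec, "t1", factors = c("gender", "appraiser")),
                 "collapsed")
  orc <- stats::glm(y ~ factor(g) + factor(a), family = stats::binomial())
  expect_lt(max(abs(as.numeric(fit$coef) - unname(stats::coef(orc)))), 1e-6)
  ## LR p-value vs drop-one oracle
  orc0 <- stats::glm(y ~ factor(a), family = stats::binomial())
  p_or <- stats::pchisq(orc0$deviance - orc$deviance, 1, lower.tail = FALSE)
  expect_lt(abs(fit$p_values[["gender"]] - p_or), 1e-6)
})

test_that("three-class fit: LR stats are invariant and separation is flagged", {
  set.seed(4)
  n <- 600
  g <- sample(c("male", "female"), n, TRUE)
  bp <- sample(c("<=2000", "2001-2010", ">2010"), n, TRUE)
  pr <- cbind(1, exp(0.5 * (g == "female")), exp(-0.3 * (g == "female")))
  y <- vapply(seq_len(n), function(i) sample(0:2, 1, prob = pr[i, ]), numeric(1))
  rec <- data.frame(t1 = y, gender = g, birth_period = bp)
  f1 <- fit_multinomial_logit(rec, "t1", factors = c("gender", "birth_period"))
  expect_true(all(f1$lr_stats >= 0))
  expect_identical(unname(f1$df), c(2, 4))
  ## invariant to factor level ordering (relabelled levels)
  rec2 <- rec
  rec2$gender <- factor(rec2$gender, levels = c("female", "male"))
  f2 <- fit_multinomial_logit(rec2, "t1", factors = c("gender", "birth_period"))
  expect_equal(unname(f1$lr_stats), unname(f2$lr_stats), tolerance = 1e-6)

  ## two observed classes collapse with a warning
  rec3 <- rec[rec$t1 < 2, ]
  expect_warning(fit_multinomial_logit(rec3, "t1", factors = "gender"), "collapsed")

  ## separation: one level always class 2
  rec4 <- rec
  rec4$gender <- as.character(rec4$gender)
  rec4$t1[rec4$birth_period == ">2010"] <- 2
  expect_warning(fit_multinomial_logit(rec4, "t1", factors = c("gender", "birth_period")),
                 "separation")
})

test_that("gait comparison: letters, two-group t equivalence, small classes", {
  ## identical values: one letter everywhere
  rec <- data.frame(t1 = rep(0:2, each = 10), walk = 5)
  f <- fit_gait_glm(rec, "t1", "walk")
  expect_true(all(f$table$letters == "a"))

  ## two groups: Tukey p equals the pooled two-sample t p
  set.seed(5)
  rec2 <- data.frame(t1 = rep(0:1, c(12, 9)), trot = c(rnorm(12, 5), rnorm(9, 5.7)))
  f2 <- fit_gait_glm(rec2, "t1", "trot")
  tt <- stats::t.test(trot ~ t1, rec2, var.equal = TRUE)
  expect_lt(abs(f2$pairwise["0", "1"] - tt$p.value), 1e-10)

  ## class with n < 2 keeps its mean but is excluded from pairwise tests
  rec3 <- data.frame(t1 = c(rep(0, 10), rep(1, 10), 2),
                     trot = c(rnorm(10, 6), rnorm(10, 5), 3.2))
  f3 <- fit_gait_glm(rec3, "t1", "trot")
  expect_identical(f3$table$n[f3$table$class == 2], 1)
  expect_identical(f3$table$letters[f3$table$class == 2], "")
  expect_identical(f3$table$mean[f3$table$class == 2], 3.2)

  ## letter partition invariant under class relabelling (letter names may
  ## differ; sharing structure may not)
  set.seed(6)
  v <- c(rnorm(40, 5), rnorm(40, 5.1), rnorm(40, 3))
  cl <- rep(0:2, each = 40)
  fa <- fit_gait_glm(data.frame(t1 = cl, walk = v), "t1", "walk")
  fb <- fit_gait_glm(data.frame(t1 = 2 - cl, walk = v), "t1", "walk")
  shares <- function(lets) {
    outer(seq_along(lets), seq_along(lets), Vectorize(function(i, j)
      any(strsplit(lets[i], "")[[1]] %in% strsplit(lets[j], "")[[1]])))
  }
  expect_identical(shares(fa$table$letters),
                   shares(rev(fb$table$letters)))
})

test_that("an injected trot depression in class 2 earns a distinct letter", {
  ## study-shaped group sizes (~ closed-hock row), depression of 0.8 points
  hits <- 0
  set.seed(7)
  for (r in 1:100) {
    n <- c(175, 231, 67)
    cl <- rep(0:2, n)
    trot <- rnorm(sum(n), mean = 5.7, sd = 1.2) - 0.8 * (cl == 2)
    f <- fit_gait_glm(data.frame(t1 = cl, trot = trot), "t1", "trot")
    lets <- f$table$letters
    others <- strsplit(paste0(lets[1], lets[2]), "")[[1]]
    if (!any(strsplit(lets[3], "")[[1]] %in% others)) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
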