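test_that("gene level sums both arms of the included read types", {
  rec <- rbind(
    toyRecords(arm = "5p", counts = c("0|0" = 7)),
    toyRecords(arm = "3p", counts = c("0|0" = 1)))
  expect_equal(geneLevel(rec)$rpm, 8)
  expect_equal(geneLevel(rec)$log2_level, log2(9))

  # ambiguous-source reads contribute nothing
  amb <- within(toyRecords(counts = c("0|0" = 100)), {
    allele <- "AMBIG"; source <- "ambiguous"
  })
  expect_equal(geneLevel(rbind(rec, amb))$rpm, 8)
  expect_equal(geneLevel(amb)$rpm, 0)

  # mutated (snps-source) and exclusive reads add linearly
  mut <- toyRecords(counts = c("0|0" = 5), alleles = "MUT")
  expect_equal(geneLevel(rbind(rec, mut))$rpm, 13)
})

test_that("cohort engine: t, z and the IQR outlier rule", {
  wt <- c(1, 2, 3, 4, 5)
  r <- cohortCompare(wt, 10)
  tstat <- (mean(wt) - 10) / (sd(wt) / sqrt(5))
  expect_equal(r$t_p, 2 * pt(-abs(tstat), df = 4))
  expect_equal(r$z, (10 - 3) / sd(wt))
  expect_true(r$outlier)

  # mutated value at the cohort mean: nothing significant
  r <- cohortCompare(wt, 3)
  expect_equal(r$z, 0)
  expect_equal(r$z_p, 1)
  expect_equal(r$t_p, 1)
  expect_false(r$outlier)

  # outlier rule arithmetic: Q1=2, Q3=4 -> fence at 4 + 1.5*2 = 7
  wt2 <- c(1, 2, 2, 3, 4, 4, 5)
  q <- quantile(wt2, c(.25, .75), names = FALSE)
  expect_equal(q, c(2, 4))
  expect_true(cohortCompare(wt2, 7.1)$outlier)
  expect_false(cohortCompare(wt2, 6.9)$outlier)

  expect_equal(cohortCompare(c(1, 2), 5)$flag, "cohort_too_small")
  expect_equal(cohortCompare(c(2, 2, 2, 2), 5)$flag, "degenerate_cohort")
})

test_that("t and z agree in sign; |z| is affine-invariant", {
  set.seed(9)
  for (i in 1:20) {
    wt <- rnorm(10)
    mv <- rnorm(1, sd = 2)
    r <- cohortCompare(wt, mv)
    tstat <- (mean(wt) - mv) / (sd(wt) / sqrt(10))
    expect_equal(sign(r$z), -sign(tstat))
    a <- runif(1, 0.5, 3)
    b <- rnorm(1)
    r2 <- cohortCompare(a * wt + b, a * mv + b)
    expect_equal(abs(r2$z), abs(r$z))
    expect_equal(r2$t_p, r$t_p)
  }
})

test_that("profile distance is an L1 metric bounded by 2", {
  p <- c(a = 0.5, b = 0.5, c = 0)
  q <- c(a = 1, b = 0, c = 0)
  expect_equal(profileDistance(p, p), 0)
  expect_equal(profileDistance(p, q), 1)
  expect_equal(profileDistance(c(a = 1, b = 0), c(a = 0, b = 1)), 2)
  expect_error(profileDistance(p, c(x = 1, y = 0, z = 0)), "label sets")

  set.seed(31)
  for (i in 1:30) {
    x <- randomProfile(); y <- randomProfile(); z <- randomProfile()
    expect_equal(profileDistance(x, y), profileDistance(y, x))
    expect_lte(profileDistance(x, y),
               profileDistance(x, z) + profileDistance(z, y) + 1e-12)
    expect_gte(profileDistance(x, y), 0)
    expect_lte(profileDistance(x, y), 2)
    # maximum only on disjoint support
    if (any(x > 1e-6 & y > 1e-6))
      expect_lt(profileDistance(x, y), 2)
  }
  # ClassProfile objects work directly
  cp <- buildProfile(toyRecords(counts = c("0|0" = 1)), "ten")
  cq <- buildProfile(toyRecords(counts = c("0|-" = 1)), "ten")
  expect_equal(profileDistance(cp, cq), 2)
})

test_that("strand balance: log ratio with pseudocount, antisymmetric", {
  expect_equal(strandBalance(100, 100), 0)
  expect_equal(strandBalance(1023, 0), 10)
  set.seed(2)
  for (i in 1:20) {
    x <- sample(0:5000, 2)
    expect_equal(strandBalance(x[1], x[2]), -strandBalance(x[2], x[1]))
  }
})

test_that("cohort level calls follow the four-way rule", {
  set.seed(101)
  wt_rpm <- rlnorm(50, log(500), 0.4)
  # mutated sample at the cohort's (geometric) center: ns
  r <- runExp3(list(list(wt_rpm = wt_rpm, mut_rpm = exp(mean(log(wt_rpm))))))
  expect_equal(r$call, "ns")
  # 64-fold drop: decrease with log2fc around -6
  r <- runExp3(list(list(wt_rpm = wt_rpm, mut_rpm = 500 / 64)))
  expect_equal(r$call, "decrease")
  expect_lt(r$log2fc, -4)
  # large z but |log2fc| < 1 stays ns
  tight <- rep(c(99.9, 100.1), 25)
  r <- runExp3(list(list(wt_rpm = tight, mut_rpm = 150)))
  expect_equal(r$call, "ns")
})

test_that("profile-distance calls: identical cohorts are ns, shifts called", {
  labs <- classLabels("ten")
  base <- c(0.5, 0.2, 0.1, 0.05, 0.05, 0.03, 0.03, 0.02, 0.01, 0.01)
  names(base) <- labs
  same <- matrix(base, nrow = 10, ncol = 10, byrow = TRUE,
                 dimnames = list(NULL, labs))
  r <- runExp4(list(list(wt_profiles = same, mut_profile = base)))
  # all distances zero: degenerate cohort, never a call
  expect_false(r$call)

  set.seed(55)
  noisy <- t(replicate(30, {
    p <- rgamma(10, base * 400); p / sum(p)
  }))
  colnames(noisy) <- labs
  shifted <- base
  shifted["0|0"] <- base["0|0"] - 0.4
  shifted["+|0"] <- base["+|0"] + 0.4
  r <- runExp4(list(list(wt_profiles = noisy, mut_profile = shifted)))
  expect_true(r$call)
  # the injected 40%-mass shift has L1 distance near 2 * 0.4
  expect_equal(r$distance, sum(abs(shifted - colMeans(noisy))))
  expect_gt(r$distance, 0.6)
})

test_that("strand-balance calls respect the 10-point effect rule", {
  set.seed(8)
  # tiny cohort noise so that z is huge for any shift
  wt <- cbind(round(rnorm(40, 9000, 30)), round(rnorm(40, 1000, 30)))
  # a 5-point shift: hugely significant but below the effect threshold
  r <- runExp5(list(list(wt_counts = wt, mut_counts = c(8500, 1500))))
  expect_lt(r$z_p, 1e-6)
  expect_false(r$call)
  expect_lt(abs(r$delta_f5p), 10)
  # a 35-point shift is called
  r <- runExp5(list(list(wt_counts = wt, mut_counts = c(5500, 4500))))
  expect_true(r$call)
  # low-coverage wild-type samples are dropped from the cohort
  wt2 <- rbind(wt, c(10, 5))
  r2 <- runExp5(list(list(wt_counts = wt2, mut_counts = c(5500, 4500))))
  expect_equal(r2$n_wt, 40L)
})

test_that("functional roll-up flags mutations called in any experiment", {
  calls <- list(
    exp1 = data.frame(mutation_id = c("M1", "M2"),
                      call = c("decrease", "ns")),
    exp4 = data.frame(mutation_id = c("M2", "M2", "M3"),
                      call = c(FALSE, TRUE, FALSE)))
  out <- functionalCalls(calls)
  expect_equal(out$functional[match(c("M1", "M2", "M3"), out$mutation_id)],
               c(TRUE, TRUE, FALSE))
})
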