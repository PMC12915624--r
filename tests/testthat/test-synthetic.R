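test_that("RNA mutant fraction follows the mixing formula", {
  expect_equal(rnaMutantFraction(0.5, 1), 0.5)
  expect_equal(rnaMutantFraction(0.3, 0), 0)      # silenced allele
  expect_equal(rnaMutantFraction(1, 1 / 64), 1)   # homozygous stays pure
  expect_equal(rnaMutantFraction(0.19, 2.5),
               0.19 * 2.5 / (0.81 + 0.19 * 2.5))
})

test_that("identical seeds give byte-identical cohorts", {
  cfg <- simulationConfig(n_wt_samples = 6, n_genes = 2)
  eff <- list(effectSpec("M1", "SIMG001", "MS1", vaf_dna = 0.4,
                         level_multiplier = 0.25))
  s1 <- simulateCohort(cfg, eff, seed = 99)
  s2 <- simulateCohort(cfg, eff, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeCohort(s1, d1)
  writeCohort(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  s3 <- simulateCohort(cfg, eff, seed = 100)
  expect_false(identical(s1$isomirs, s3$isomirs))
})

test_that("effects referencing unknown genes fail hard", {
  cfg <- simulationConfig(n_wt_samples = 3, n_genes = 1)
  expect_error(simulateCohort(cfg, list(effectSpec("M1", "NOPE", "MS1")),
                              seed = 1), "unknown gene")
})

test_that("empirical RNA allele fraction converges to the mixing formula", {
  cfg <- simulationConfig(n_wt_samples = 3, n_genes = 1,
                          expr_meanlog = log(50000),
                          expr_sdlog_gene = 0, expr_sdlog_sample = 0,
                          ambiguous_rate = 0)
  for (vaf in c(0.25, 0.5)) for (lam in c(1, 4)) {
    sim <- simulateCohort(cfg, list(
      effectSpec("M1", "SIMG001", "MS1", vaf_dna = vaf,
                 level_multiplier = lam)), seed = 17)
    rec <- sim$isomirs[sim$isomirs$sample_id == "MS1" &
                         sim$isomirs$source != "ambiguous", ]
    obs <- sum(rec$count[rec$allele == "MUT"]) / sum(rec$count)
    expect_gt(sum(rec$count), 1e5)   # law-of-large-numbers regime
    expect_lt(abs(obs - rnaMutantFraction(vaf, lam)), 0.01)
  }
})

test_that("wild-type class fractions converge to the Dirichlet template", {
  template <- c(0.4, 0.15, 0.12, 0.08, 0.07, 0.06, 0.05, 0.03, 0.02, 0.02)
  cfg <- simulationConfig(n_wt_samples = 40, n_genes = 1,
                          class_template = template,
                          expr_meanlog = log(5000), expr_sdlog_gene = 0,
                          ambiguous_rate = 0)
  sim <- simulateCohort(cfg, seed = 23)
  rec <- sim$isomirs[sim$isomirs$arm == "5p", ]
  p <- buildProfile(rec, "ten")
  expect_equal(unname(fractions(p)), template, tolerance = 0.02)
})

test_that("a class shift moves exactly the stated mass at the allele level", {
  shift <- list(from = "0|0", to = "-|0", mass = 0.3)
  cfg <- simulationConfig(n_wt_samples = 3, n_genes = 1,
                          expr_meanlog = log(50000), expr_sdlog_gene = 0,
                          expr_sdlog_sample = 0,
                          class_concentration = 1e7,  # freeze sampling noise
                          ambiguous_rate = 0)
  sim <- simulateCohort(cfg, list(
    effectSpec("M1", "SIMG001", "MS1", vaf_dna = 0.5,
               class_shift = shift)), seed = 29)
  rec <- sim$isomirs[sim$isomirs$sample_id == "MS1" &
                       sim$isomirs$arm == "5p", ]
  p_wt <- fractions(buildProfile(rec[rec$allele == "WT", ], "ten"))
  p_mut <- fractions(buildProfile(rec[rec$allele == "MUT", ], "ten"))
  # closed form: moving 0.3 of mass gives an L1 distance of 2 * 0.3
  expect_equal(sum(abs(p_wt - p_mut)), 0.6, tolerance = 0.02)
  expect_equal(unname(p_wt["0|0"] - p_mut["0|0"]), 0.3, tolerance = 0.02)
})

test_that("strand shift sets the mutant allele's 5p fraction", {
  cfg <- simulationConfig(n_wt_samples = 3, n_genes = 1,
                          expr_meanlog = log(50000), expr_sdlog_gene = 0,
                          expr_sdlog_sample = 0, f5p_mean = 0.95,
                          f5p_concentration = 1e7, ambiguous_rate = 0)
  sim <- simulateCohort(cfg, list(
    effectSpec("M1", "SIMG001", "MS1", vaf_dna = 0.5,
               strand_shift = 0.3)), seed = 31)
  rec <- sim$isomirs[sim$isomirs$sample_id == "MS1", ]
  f5p_mut <- sum(rec$count[rec$allele == "MUT" & rec$arm == "5p"]) /
    sum(rec$count[rec$allele == "MUT"])
  f5p_wt <- sum(rec$count[rec$allele == "WT" & rec$arm == "5p"]) /
    sum(rec$count[rec$allele == "WT"])
  expect_equal(f5p_mut, 0.3, tolerance = 0.02)
  expect_equal(f5p_wt, 0.95, tolerance = 0.02)
})

test_that("the emitted tables are valid inputs for the readers", {
  cfg <- simulationConfig(n_wt_samples = 5, n_genes = 2)
  sim <- simulateCohort(cfg, list(effectSpec("M1", "SIMG002", "MS1")),
                        seed = 37)
  dir <- withr::local_tempdir()
  writeCohort(sim, dir)
  rec <- readIsomirTable(file.path(dir, "isomirs.tsv"))
  expect_equal(nrow(rec), nrow(sim$isomirs))
  mut <- readMutationTable(file.path(dir, "mutations.tsv"))
  expect_equal(mut$mutation_id, "M1")
  parsed <- parseMutations(mut, sim$annotations)
  expect_true(is.na(parsed$parse_error))
  expect_equal(parsed$subregion, "seed3p")
})
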