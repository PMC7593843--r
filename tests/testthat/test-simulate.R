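panel <- load_snp_panel()

test_that("genotypes follow Hardy-Weinberg expectations", {
  g <- simulate_genotypes(10000, panel, mafs = rep(0.5, 43), ld_r2 = 0,
                          seed = 1)
  means <- colMeans(g$dosages)
  # Binomial(2, 0.5) mean 1, SE of the column mean ~ 0.007
  expect_true(all(abs(means - 1) < 0.03))
  expect_true(all(g$dosages %in% 0:2))
  expect_equal(colnames(g$dosages), panel$rsid)

  # homozygote frequency ~ maf^2 within 3 binomial SEs at n = 50,000
  maf <- 0.3
  g2 <- simulate_genotypes(50000, panel[1:5, ], mafs = rep(maf, 5),
                           seed = 2)
  hom <- colMeans(g2$dosages == 2)
  se <- sqrt(maf^2 * (1 - maf^2) / 50000)
  expect_true(all(abs(hom - maf^2) < 3 * se))

  # degenerate cases
  g0 <- simulate_genotypes(100, panel[1:3, ], mafs = rep(0, 3), seed = 3)
  expect_true(all(g0$dosages == 0))
  expect_error(simulate_genotypes(100, panel[0, ], seed = 1), "empty panel")
})

test_that("the linkage block is correlated as requested", {
  in_block <- which(!is.na(panel$ld_group))
  g1 <- simulate_genotypes(4000, panel, ld_r2 = 1, seed = 4)
  block <- g1$dosages[, in_block]
  expect_true(all(block == block[, 1]))  # perfectly correlated

  g2 <- simulate_genotypes(20000, panel, ld_r2 = 0.8, seed = 5)
  cors <- cor(g2$dosages[, in_block])
  off <- cors[upper.tri(cors)]
  expect_true(all(abs(off^2 - 0.8) < 0.08))
  # SNPs outside the block stay essentially uncorrelated
  out <- cor(g2$dosages[, -in_block])
  expect_lt(max(abs(out[upper.tri(out)])), 0.05)
})

test_that("continuous dosages stay in [0,2] and track the genotypes", {
  g <- simulate_genotypes(2000, panel, seed = 6, continuous = TRUE)
  expect_true(all(g$dosages >= 0 & g$dosages <= 2))
  expect_false(all(g$dosages %in% 0:2))
})

test_that("solve_intercept hits the target prevalence", {
  g <- simulate_genotypes(1000, panel, seed = 7)
  # all effects zero: closed-form logit
  expect_equal(solve_intercept(rep(0, 43), g, 0.1), qlogis(0.1),
               tolerance = 1e-8)
  expect_equal(solve_intercept(rep(0, 43), g, 0.5), 0, tolerance = 1e-8)
  expect_error(solve_intercept(c(Inf, rep(0, 42)), g, 0.1), "non-finite")

  # planted effects, large n: realized case fraction near target
  g5 <- simulate_genotypes(1e5, panel, seed = 8)
  truth <- simulation_truth(g5, panel,
                            planted_rsids = panel$rsid[c(1, 10, 20)],
                            planted_or = c(3, 0.5, 2),
                            target_prevalence = 0.1)
  y <- simulate_outcome(g5, truth, seed = 9)
  expect_lt(abs(mean(y) - 0.1), 0.005)
})

test_that("outcomes are null when no effect is planted and recover planted ORs", {
  g <- simulate_genotypes(1e5, panel, seed = 5)
  truth0 <- simulation_truth(g, panel, target_prevalence = 0.1)
  y0 <- simulate_outcome(g, truth0, seed = 6)
  cors <- abs(cor(g$dosages, y0))
  expect_true(all(cors < 4 / sqrt(1e5)))  # within sampling noise of zero

  truth3 <- simulation_truth(g, panel, planted_rsids = "rs342442",
                             planted_or = 3, target_prevalence = 0.1)
  y3 <- simulate_outcome(g, truth3, seed = 8)
  fit <- fit_univariate(g$dosages[, "rs342442"], y3)
  expect_lt(abs(fit$log_or - log(3)), 0.1)

  # fixed seed reproduces the label vector bit for bit
  expect_identical(simulate_outcome(g, truth3, seed = 8), y3)
})

test_that("longitudinal records invert to the input labels at zero rates", {
  for (ep in c("rectal_bleeding", "urinary_frequency", "nocturia")) {
    for (policy in c("exclude", "recode_control")) {
      spec <- endpoint_spec(ep, baseline_policy = policy)
      set.seed(20)
      labels <- rbinom(400, 1, 0.12)
      records <- simulate_longitudinal(labels, spec, seed = 21)
      derived <- derive_labels(records, spec)
      expect_identical(as.integer(derived$status == "case"), labels)
      expect_false(any(derived$status == "excluded"))
    }
  }
  # baseline-prevalent non-worsening controls survive recoding
  spec_rc <- endpoint_spec("nocturia", baseline_policy = "recode_control")
  labels <- rep(c(1L, 0L), c(30, 270))
  records <- simulate_longitudinal(labels, spec_rc,
                                   baseline_prevalent_rate = 0.3, seed = 22)
  derived <- derive_labels(records, spec_rc)
  expect_identical(as.integer(derived$status == "case"), labels)
  expect_gt(sum(records$base >= spec_rc$grade_threshold), 0)

  # degenerate inputs
  all_ctrl <- derive_labels(
    simulate_longitudinal(rep(0L, 50), endpoint_spec("haematuria"), seed = 1),
    endpoint_spec("haematuria"))
  expect_equal(prevalence(all_ctrl), 0)
  bleeding <- endpoint_spec("rectal_bleeding")
  all_hem <- derive_labels(
    simulate_longitudinal(rep(c(1L, 0L), 25), bleeding,
                          exclusion_rates = list(hemorrhoids = 1), seed = 2),
    bleeding)
  expect_true(all(all_hem$status == "excluded"))
})

test_that("generators are pure functions of parameters and seed", {
  a <- simulate_genotypes(500, panel, seed = 31)
  b <- simulate_genotypes(500, panel, seed = 31)
  expect_identical(a$dosages, b$dosages)
  spec <- endpoint_spec("nocturia")
  r1 <- simulate_longitudinal(rep(c(1L, 0L), 50), spec, seed = 32)
  r2 <- simulate_longitudinal(rep(c(1L, 0L), 50), spec, seed = 32)
  expect_identical(r1, r2)
  c1 <- simulate_cohort(300, panel, spec, target_prevalence = 0.15, seed = 33)
  c2 <- simulate_cohort(300, panel, spec, target_prevalence = 0.15, seed = 33)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$genotypes$dosages, c2$genotypes$dosages)
})

test_that("genotype tables round-trip through TSV and VCF dosage files", {
  g <- simulate_genotypes(40, panel, seed = 44)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, tsv)
  back <- read_genotypes(tsv)
  expect_equal(back$dosages, g$dosages, ignore_attr = TRUE)
  expect_equal(back$rsids, g$rsids)
  expect_equal(back$patient_ids, g$patient_ids)

  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_dosage(g, vcf)
  vback <- read_vcf_dosage(vcf)
  expect_equal(vback$dosages[g$patient_ids, g$rsids], g$dosages,
               ignore_attr = TRUE)
})
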