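test_that("packaged panel has 43 unique SNPs with printed effects", {
  panel <- load_snp_panel()
  expect_equal(nrow(panel), 43)
  expect_false(anyDuplicated(panel$rsid) > 0)
  expect_true(all(panel$effect > 0))

  entry <- panel[panel$rsid == "rs10519410", ]
  expect_equal(as.character(entry$endpoint), "rectal_bleeding")
  expect_equal(entry$effect, 3.7)

  # the six correlated overall-toxicity SNPs share one linkage group
  expect_equal(sum(!is.na(panel$ld_group)), 6)
  expect_setequal(panel$rsid[!is.na(panel$ld_group)],
                  c("rs10497203", "rs7582141", "rs6432512",
                    "rs264651", "rs264588", "rs264631"))
})

test_that("malformed panels are rejected", {
  panel <- load_snp_panel()
  tmp <- withr::local_tempfile(fileext = ".tsv")

  dup <- rbind(panel[1, ], panel)
  dup$endpoint <- as.character(dup$endpoint)
  dup$effect_type <- ifelse(dup$effect_is_hazard_ratio, "HR", "OR")
  write.table(dup[, c("rsid", "endpoint", "effect", "effect_type", "p",
                      "ld_group", "ref")],
              tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_snp_panel(tmp), "duplicate rsid")

  bad <- read.delim(system.file("extdata", "snp_panel.tsv",
                                package = "dsaeselect"))
  bad$effect[3] <- "not-a-number"
  write.table(bad, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_snp_panel(tmp), "malformed effect")
})

test_that("endpoint specs carry the published grade thresholds", {
  specs <- endpoint_specs()
  thresholds <- vapply(specs, function(s) s$grade_threshold, integer(1))
  expect_equal(thresholds,
               c(rectal_bleeding = 1L, urinary_frequency = 2L,
                 haematuria = 1L, nocturia = 2L, decreased_stream = 1L))
  expect_true(specs$rectal_bleeding$exclude_hemorrhoids)
  expect_false(specs$rectal_bleeding$urinary)
  expect_true(all(vapply(specs[-1], function(s) s$urinary, logical(1))))
  expect_error(endpoint_spec("proctitis"), "unknown endpoint")
})

test_that("derive_labels applies case, baseline and exclusion rules", {
  bleed <- endpoint_spec("rectal_bleeding", baseline_policy = "recode_control")
  records <- rbind(
    rec("case_m12", base = 0, m12 = 1, m24 = 0),
    rec("recoded_control", base = 1, m12 = 1, m24 = 1),
    rec("hemorrhoid", base = 0, m12 = 2, m24 = 2, hemorrhoids = TRUE),
    rec("cvd", base = 0, m12 = 2, m24 = 2, cvd = TRUE),
    rec("plain_control", base = 0, m12 = 0, m24 = 0),
    rec("no_fu", base = 0, m12 = NA, m24 = NA),
    rec("worsened", base = 1, m12 = 3, m24 = 0)
  )
  labels <- derive_labels(records, bleed)
  got <- setNames(as.character(labels$status), labels$patient_id)
  expect_equal(got[["case_m12"]], "case")
  expect_equal(got[["recoded_control"]], "control")
  expect_equal(got[["hemorrhoid"]], "excluded")
  expect_equal(got[["cvd"]], "excluded")
  expect_equal(got[["plain_control"]], "control")
  expect_equal(got[["no_fu"]], "excluded")
  # baseline-prevalent but worsened beyond the threshold: a case here
  expect_equal(got[["worsened"]], "case")
  reasons <- setNames(labels$exclusion_reason, labels$patient_id)
  expect_equal(reasons[["hemorrhoid"]], "hemorrhoids_baseline")
  expect_equal(reasons[["cvd"]], "collagen_vascular_disease")
  expect_equal(reasons[["no_fu"]], "no_followup")

  # under the exclude policy baseline-prevalent patients are dropped
  labels_ex <- derive_labels(records, endpoint_spec("rectal_bleeding"))
  got_ex <- setNames(as.character(labels_ex$status), labels_ex$patient_id)
  expect_equal(got_ex[["recoded_control"]], "excluded")
  expect_equal(got_ex[["worsened"]], "excluded")

  # urinary endpoints exclude TURB / antimuscarinic patients
  freq <- endpoint_spec("urinary_frequency")
  turb_rec <- rbind(rec("t", m12 = 3, turb = TRUE),
                    rec("a", m12 = 3, antimuscarinic = TRUE))
  lab_freq <- derive_labels(turb_rec, freq)
  expect_true(all(lab_freq$status == "excluded"))
  # ...but rectal bleeding does not
  lab_bleed <- derive_labels(turb_rec, endpoint_spec("rectal_bleeding"))
  expect_true(all(lab_bleed$status == "case"))
})

test_that("labels partition the cohort and are monotone in the threshold", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 200
    records <- tibble::tibble(
      patient_id = sprintf("P%03d", 1:n),
      base = sample(c(0:3, NA), n, replace = TRUE),
      m12 = sample(c(0:4, NA), n, replace = TRUE),
      m24 = sample(c(0:4, NA), n, replace = TRUE),
      hemorrhoids = runif(n) < 0.05, turb = runif(n) < 0.05,
      antimuscarinic = runif(n) < 0.05, cvd = runif(n) < 0.03
    )
    for (policy in c("exclude", "recode_control")) {
      specs <- lapply(1:3, function(T) {
        s <- endpoint_spec("nocturia", baseline_policy = policy)
        s$grade_threshold <- T
        s
      })
      labs <- lapply(specs, function(s) derive_labels(records, s))
      for (l in labs) {
        expect_equal(sum(table(l$status)), n)                  # partition
        expect_true(all(!is.na(l$exclusion_reason[l$status == "excluded"])))
        expect_true(all(is.na(l$exclusion_reason[l$status != "excluded"])))
      }
      # raising T never converts a control into a case
      for (k in 1:2) {
        was_control <- labs[[k]]$status == "control"
        expect_false(any(labs[[k + 1]]$status[was_control] == "case"))
      }
    }
    # the two baseline policies agree wherever baseline grade < T
    s_ex <- endpoint_spec("nocturia", baseline_policy = "exclude")
    s_rc <- endpoint_spec("nocturia", baseline_policy = "recode_control")
    l_ex <- derive_labels(records, s_ex)
    l_rc <- derive_labels(records, s_rc)
    low_base <- is.na(records$base) | records$base < s_ex$grade_threshold
    expect_equal(l_ex$status[low_base], l_rc$status[low_base])
  }
})

test_that("prevalence arithmetic and formatting", {
  spec <- endpoint_spec("rectal_bleeding")
  records <- make_count_cohort(spec, 160, 1206, n_excluded = 12)
  labels <- derive_labels(records, spec)
  expect_equal(as.vector(table(labels$status)[c("case", "control")]),
               c(160, 1206))
  expect_equal(prevalence(labels), 160 / 1366)
  expect_equal(format_prevalence(prevalence(labels)), "11.7%")

  none <- derive_labels(make_count_cohort(spec, 0, 50), spec)
  expect_equal(prevalence(none), 0)
  all_cases <- derive_labels(make_count_cohort(spec, 30, 0), spec)
  expect_equal(prevalence(all_cases), 1)

  excluded_only <- derive_labels(rec("only", cvd = TRUE), spec)
  expect_error(prevalence(excluded_only), "prevalence undefined")
})

test_that("phenotype files round-trip through the documented layout", {
  spec <- endpoint_spec("nocturia")
  records <- simulate_longitudinal(rep(c(1L, 0L), c(5, 20)), spec,
                                   exclusion_rates = list(turb = 0.2),
                                   seed = 4)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(records, tmp, endpoint = "nocturia")
  back <- read_phenotypes(tmp, endpoint = "nocturia")
  expect_equal(back$m12, records$m12)
  expect_equal(back$turb, records$turb)
  expect_error(read_phenotypes(tmp, endpoint = "haematuria"),
               "missing columns")
})
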