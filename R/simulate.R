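#' Simulate additive genotype dosages under Hardy-Weinberg equilibrium
#'
#' Draws an N x J matrix of additive genotypes (0/1/2 copies of the effect
#' allele), one column per panel SNP. Columns are independent
#' Binomial(2, maf) draws except within a declared linkage group, whose
#' members copy alleles from a shared pair of latent haplotypes: each of a
#' patient's two alleles at a group SNP equals the corresponding latent
#' allele with probability `ld_r2^(1/4)` and is an independent
#' Bernoulli(maf) draw otherwise, giving pairwise genotype correlation of
#' about `sqrt(ld_r2)` (squared correlation `ld_r2`). Group members share the
#' group MAF so the marginal Hardy-Weinberg distribution is preserved.
#'
#' @param n Number of patients (>= 2).
#' @param panel Panel tibble from [load_snp_panel()]; column order of the
#'   result follows the panel.
#' @param maf_range Interval the per-SNP minor-allele frequencies are drawn
#'   from (uniform), default `c(0.05, 0.5)`.
#' @param ld_r2 Target squared correlation within the linkage group, in
#'   \[0,1\].
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param mafs Optional explicit per-SNP MAF vector overriding `maf_range`.
#' @param continuous If `TRUE`, jitter integer genotypes with N(0, 0.1)
#'   noise truncated to \[0,2\], emulating imputed dosages.
#' @return A list of class `genotype_matrix`: `dosages` (N x J matrix,
#'   rsID column names), `rsids`, `patient_ids`, `mafs`, `ld_r2`, `seed`.
#' @export
simulate_genotypes <- function(n, panel, maf_range = c(0.05, 0.5),
                               ld_r2 = 0.9, seed = 1L, mafs = NULL,
                               continuous = FALSE) {
  if (nrow(panel) == 0) stop("empty panel")
  stopifnot(n >= 2, ld_r2 >= 0, ld_r2 <= 1)
  J <- nrow(panel)
  set.seed(seed)
  if (is.null(mafs)) {
    mafs <- runif(J, maf_range[1], maf_range[2])
  }
  stopifnot(length(mafs) == J, all(mafs >= 0 & mafs <= 0.5))
  names(mafs) <- panel$rsid

  groups <- split(seq_len(J), panel$ld_group)
  for (g in groups) {
    if (length(g) > 1) mafs[g] <- mean(mafs[g])  # shared MAF within block
  }

  G <- matrix(0L, n, J, dimnames = list(NULL, panel$rsid))
  in_group <- !is.na(panel$ld_group)
  for (j in which(!in_group)) {
    G[, j] <- rbinom(n, 2L, mafs[j])
  }
  q <- ld_r2^(1 / 4)  # per-allele copy probability
  for (g in groups) {
    if (length(g) < 2) {
      for (j in g) G[, j] <- rbinom(n, 2L, mafs[j])
      next
    }
    maf_g <- mafs[g[1]]
    h1 <- rbinom(n, 1L, maf_g)
    h2 <- rbinom(n, 1L, maf_g)
    for (j in g) {
      copy1 <- rbinom(n, 1L, q) == 1L
      copy2 <- rbinom(n, 1L, q) == 1L
      a1 <- ifelse(copy1, h1, rbinom(n, 1L, maf_g))
      a2 <- ifelse(copy2, h2, rbinom(n, 1L, maf_g))
      G[, j] <- a1 + a2
    }
  }
  if (continuous) {
    G <- G + matrix(rnorm(n * J, 0, 0.1), n, J)
    G[G < 0] <- 0
    G[G > 2] <- 2
    colnames(G) <- panel$rsid
  }
  structure(list(
    dosages = G,
    rsids = panel$rsid,
    patient_ids = sprintf("P%05d", seq_len(n)),
    mafs = mafs,
    ld_r2 = ld_r2,
    seed = seed
  ), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$dosages), "patients x",
      ncol(x$dosages), "SNPs\n")
  cat("  MAF range:", sprintf("%.3f-%.3f", min(x$mafs), max(x$mafs)),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Solve the logistic intercept for a target outcome prevalence
#'
#' Finds the intercept b0 such that the population mean of
#' `plogis(b0 + X %*% effects)` over the supplied genotypes equals the
#' target case prevalence, by monotone one-dimensional root finding.
#'
#' @param effects Per-SNP log odds ratios (0 for null SNPs), length J.
#' @param genotypes A `genotype_matrix`.
#' @param target_prevalence Target case fraction in (0,1).
#' @return The intercept, accurate to 1e-6 in realised prevalence.
#' @export
#' @examples
#' # with all effects zero the solution is the logit of the target:
#' # solve_intercept(rep(0, J), g, 0.1) ~= qlogis(0.1) = -2.197
solve_intercept <- function(effects, genotypes, target_prevalence) {
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  if (any(!is.finite(effects))) stop("non-finite effects")
  eta <- drop(genotypes$dosages %*% effects)
  f <- function(b0) mean(plogis(b0 + eta)) - target_prevalence
  uniroot(f, lower = qlogis(target_prevalence) - max(abs(eta)) - 1,
          upper = qlogis(target_prevalence) + max(abs(eta)) + 1,
          tol = 1e-10)$root
}

#' Assemble the generative truth for an additive-logistic outcome model
#'
#' Plants log odds ratios on a chosen subset of panel SNPs and solves the
#' intercept for the requested prevalence on the supplied genotypes.
#'
#' @param genotypes A `genotype_matrix`.
#' @param panel Panel tibble aligned with the genotype columns.
#' @param planted_rsids Character vector of SNPs carrying effects (default
#'   none).
#' @param planted_or Odds ratios for the planted SNPs (recycled; values in
#'   the panel's printed range, e.g. 2.5-3.5, give paper-plausible signal).
#' @param target_prevalence Case fraction in (0,1), default 0.1.
#' @param seed Integer recorded for downstream label draws.
#' @return A list of class `simulation_truth`: `planted_effects` (named
#'   length-J log-OR vector), `intercept`, `target_prevalence`, `mafs`,
#'   `ld_r2`, `seed`.
#' @export
simulation_truth <- function(genotypes, panel, planted_rsids = character(),
                             planted_or = numeric(), target_prevalence = 0.1,
                             seed = 1L) {
  stopifnot(all(planted_rsids %in% panel$rsid))
  effects <- setNames(rep(0, nrow(panel)), panel$rsid)
  if (length(planted_rsids) > 0) {
    effects[planted_rsids] <- log(rep_len(planted_or, length(planted_rsids)))
  }
  structure(list(
    planted_effects = effects,
    intercept = solve_intercept(effects, genotypes, target_prevalence),
    target_prevalence = target_prevalence,
    mafs = genotypes$mafs,
    ld_r2 = genotypes$ld_r2,
    seed = seed
  ), class = "simulation_truth")
}

#' Draw binary toxicity outcomes from the additive-logistic model
#'
#' @param genotypes A `genotype_matrix`.
#' @param truth A `simulation_truth` whose intercept was solved for these
#'   genotypes.
#' @param seed Integer seed (defaults to `truth$seed`).
#' @return Integer 0/1 vector of length N (1 = toxicity / "unhealthy").
#' @export
simulate_outcome <- function(genotypes, truth, seed = truth$seed) {
  p <- plogis(truth$intercept +
                drop(genotypes$dosages %*% truth$planted_effects))
  set.seed(seed)
  rbinom(length(p), 1L, p)
}

#' Simulate longitudinal grade trajectories consistent with binary labels
#'
#' Builds per-patient CTCAE-style grade records (baseline, 12 and 24
#' months) such that applying [derive_labels()] with the same endpoint
#' specification recovers the input labels exactly when all exclusion rates
#' are zero. Cases get at least one follow-up grade at or above the
#' threshold; controls stay below it. A configurable fraction of controls is
#' made baseline-prevalent but non-worsening (these remain controls under
#' `baseline_policy = "recode_control"` but are excluded under
#' `"exclude"`). Exclusion flags are then drawn independently at the given
#' rates on top.
#'
#' @param labels Binary 0/1 vector (1 = case).
#' @param spec An [endpoint_spec()].
#' @param exclusion_rates Named list with any of `hemorrhoids`, `turb`,
#'   `antimuscarinic`, `cvd` (Bernoulli flag rates, default all 0).
#' @param baseline_prevalent_rate Fraction of controls given a baseline
#'   grade at or above the threshold (default 0; only meaningful with
#'   `recode_control`).
#' @param seed Integer seed.
#' @param patient_ids Optional ids, default `P00001...`.
#' @return Tibble of toxicity records for [derive_labels()].
#' @export
simulate_longitudinal <- function(labels, spec,
                                  exclusion_rates = list(),
                                  baseline_prevalent_rate = 0,
                                  seed = 1L, patient_ids = NULL) {
  stopifnot(all(labels %in% c(0L, 1L)))
  rates <- modifyList(
    list(hemorrhoids = 0, turb = 0, antimuscarinic = 0, cvd = 0),
    exclusion_rates)
  stopifnot(all(unlist(rates) >= 0), all(unlist(rates) <= 1))
  n <- length(labels)
  T <- spec$grade_threshold
  set.seed(seed)
  # uniform integer draw on lo..hi that is safe for single-value ranges
  rint <- function(lo, hi, m) lo + sample.int(hi - lo + 1L, m, replace = TRUE) - 1L

  base <- rint(0L, T - 1L, n)
  m12 <- integer(n)
  m24 <- integer(n)

  case <- labels == 1L
  # cases: one visit forced to reach the threshold, the other free in 0..4
  hit24 <- sample(c(TRUE, FALSE), n, replace = TRUE)
  hi <- rint(T, 4L, n)
  free <- rint(0L, 4L, n)
  m12[case] <- ifelse(hit24[case], free[case], hi[case])
  m24[case] <- ifelse(hit24[case], hi[case], free[case])
  # controls: follow-up strictly below the threshold
  lo12 <- rint(0L, T - 1L, n)
  lo24 <- rint(0L, T - 1L, n)
  m12[!case] <- lo12[!case]
  m24[!case] <- lo24[!case]

  if (baseline_prevalent_rate > 0) {
    # baseline-prevalent, non-worsening controls: follow-up grades <= T
    bp <- !case & runif(n) < baseline_prevalent_rate
    base[bp] <- rint(T, 4L, sum(bp))
    m12[bp] <- rint(0L, T, sum(bp))
    m24[bp] <- rint(0L, T, sum(bp))
  }

  tibble::tibble(
    patient_id = if (is.null(patient_ids)) sprintf("P%05d", seq_len(n)) else patient_ids,
    base = base, m12 = m12, m24 = m24,
    hemorrhoids = runif(n) < rates$hemorrhoids,
    turb = runif(n) < rates$turb,
    antimuscarinic = runif(n) < rates$antimuscarinic,
    cvd = runif(n) < rates$cvd
  )
}

#' Simulate a complete radiogenomic cohort
#'
#' Convenience wrapper chaining [simulate_genotypes()],
#' [simulation_truth()], [simulate_outcome()] and
#' [simulate_longitudinal()] with sub-seeds derived deterministically from
#' one seed.
#'
#' @inheritParams simulate_genotypes
#' @inheritParams simulation_truth
#' @param spec Endpoint specification for the grade trajectories.
#' @param exclusion_rates Passed to [simulate_longitudinal()].
#' @return List with `genotypes`, `truth`, `labels` (0/1), `records`,
#'   `spec`.
#' @export
simulate_cohort <- function(n, panel, spec,
                            planted_rsids = character(),
                            planted_or = numeric(),
                            target_prevalence = 0.1,
                            maf_range = c(0.05, 0.5), ld_r2 = 0.9,
                            exclusion_rates = list(), seed = 1L) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 3L)
  genotypes <- simulate_genotypes(n, panel, maf_range = maf_range,
                                  ld_r2 = ld_r2, seed = sub[1])
  truth <- simulation_truth(genotypes, panel,
                            planted_rsids = planted_rsids,
                            planted_or = planted_or,
                            target_prevalence = target_prevalence,
                            seed = sub[2])
  labels <- simulate_outcome(genotypes, truth)
  records <- simulate_longitudinal(labels, spec,
                                   exclusion_rates = exclusion_rates,
                                   seed = sub[3],
                                   patient_ids = genotypes$patient_ids)
  list(genotypes = genotypes, truth = truth, labels = labels,
       records = records, spec = spec)
}

#' Write / read genotype dosage tables
#'
#' Plain TSV with a `patient_id` column followed by one column per rsID.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path File path.
#' @return `path` (writer, invisibly) or a `genotype_matrix` (reader; `mafs`
#'   are recomputed as empirical allele frequencies).
#' @export
write_genotypes <- function(genotypes, path) {
  out <- data.frame(patient_id = genotypes$patient_ids,
                    genotypes$dosages, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  raw <- read.delim(path, check.names = FALSE)
  ids <- as.character(raw$patient_id)
  G <- as.matrix(raw[, setdiff(names(raw), "patient_id"), drop = FALSE])
  if (any(G < 0 | G > 2, na.rm = TRUE)) stop("dosages must lie in [0,2]")
  structure(list(dosages = G, rsids = colnames(G), patient_ids = ids,
                 mafs = colMeans(G) / 2, ld_r2 = NA_real_, seed = NA_integer_),
            class = "genotype_matrix")
}

#' Write / read dosages as VCF with a DS FORMAT field
#'
#' Minimal VCF 4.2 interoperability: one record per SNP with placeholder
#' coordinates and a per-sample dosage (`DS`) value; the reader (requires
#' the suggested `vcfR` package) recovers the patient x SNP dosage matrix.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path File path (`.vcf`, uncompressed).
#' @return `path` (writer, invisibly) or a `genotype_matrix` (reader).
#' @export
write_vcf_dosage <- function(genotypes, path) {
  G <- genotypes$dosages
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=dsaeselect",
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Additive dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$patient_ids), collapse = "\t")
  ), con)
  for (j in seq_len(ncol(G))) {
    writeLines(paste(c("1", j, genotypes$rsids[j], "A", "G", ".", "PASS",
                       ".", "DS", format(G[, j], trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_vcf_dosage
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF dosages requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  G <- t(ds)  # samples x SNPs
  if (any(G < 0 | G > 2, na.rm = TRUE)) stop("dosages must lie in [0,2]")
  structure(list(dosages = G, rsids = colnames(G),
                 patient_ids = rownames(G),
                 mafs = colMeans(G) / 2, ld_r2 = NA_real_,
                 seed = NA_integer_),
            class = "genotype_matrix")
}
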