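#' Load the packaged literature SNP panel
#'
#' Reads the panel of 43 candidate SNPs previously reported as associated
#' with late toxicity after prostate radiotherapy, together with the endpoint
#' each was reported for, the printed effect size (odds ratio, or hazard
#' ratio for three entries), the reported p-value where available, and the
#' linkage-disequilibrium group label shared by the six highly correlated
#' overall-toxicity SNPs.
#'
#' @param path Path to a panel TSV with columns
#'   `rsid, endpoint, effect, effect_type, p, ld_group, ref`. Defaults to the
#'   fixture shipped with the package.
#' @return A [tibble::tibble] with one row per SNP and columns `rsid`,
#'   `endpoint` (factor over the five symptom endpoints plus `overall_STAT`),
#'   `effect` (positive numeric), `effect_is_hazard_ratio` (logical), `p`
#'   (numeric, `NA` where unreported), `ld_group` (character or `NA`), `ref`
#'   (citation key).
#' @export
#' @examples
#' panel <- load_snp_panel()
#' nrow(panel) # 43
load_snp_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "snp_panel.tsv", package = "dsaeselect",
                        mustWork = TRUE)
  }
  raw <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("rsid", "endpoint", "effect", "effect_type", "p", "ld_group", "ref")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("panel file is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(raw$rsid)) {
    dup <- unique(raw$rsid[duplicated(raw$rsid)])
    stop("duplicate rsid in panel: ", paste(dup, collapse = ", "))
  }
  effect <- suppressWarnings(as.numeric(raw$effect))
  if (anyNA(effect) || any(effect <= 0)) {
    stop("malformed effect column: effects must be positive numbers")
  }
  bad_ep <- setdiff(unique(raw$endpoint), panel_endpoints())
  if (length(bad_ep) > 0) {
    stop("unknown endpoint in panel: ", paste(bad_ep, collapse = ", "))
  }
  tibble::tibble(
    rsid = raw$rsid,
    endpoint = factor(raw$endpoint, levels = panel_endpoints()),
    effect = effect,
    effect_is_hazard_ratio = raw$effect_type == "HR",
    p = suppressWarnings(as.numeric(raw$p)),
    ld_group = as.character(raw$ld_group),
    ref = raw$ref
  )
}

#' Endpoint names recognised in a SNP panel
#' @return Character vector of the five symptom endpoints plus the composite
#'   overall-toxicity (STAT) label.
#' @export
panel_endpoints <- function() {
  c("rectal_bleeding", "urinary_frequency", "decreased_stream",
    "haematuria", "nocturia", "overall_STAT")
}

#' Late-toxicity endpoint definitions
#'
#' Each endpoint is a grade threshold applied to ordinal symptom grades at
#' the 12- and 24-month follow-up visits, plus the exclusion rules that go
#' with it: patients with collagen vascular disease are always excluded;
#' urinary endpoints exclude patients with transurethral bladder resection or
#' on antimuscarinic drugs; rectal bleeding excludes patients with baseline
#' haemorrhoids. `baseline_policy` governs patients already at or above the
#' threshold before radiotherapy: `"exclude"` drops them, `"recode_control"`
#' keeps them as controls unless a follow-up grade exceeds the threshold.
#'
#' @param name One of `"rectal_bleeding"`, `"urinary_frequency"`,
#'   `"haematuria"`, `"nocturia"`, `"decreased_stream"`.
#' @param baseline_policy `"exclude"` (default) or `"recode_control"`.
#' @return An object of class `endpoint_spec`: a list with fields `name`,
#'   `grade_threshold`, `urinary`, `exclude_hemorrhoids`, `baseline_policy`.
#' @export
#' @examples
#' endpoint_spec("rectal_bleeding")$grade_threshold # 1
#' endpoint_spec("nocturia")$grade_threshold        # 2
endpoint_spec <- function(name, baseline_policy = c("exclude", "recode_control")) {
  baseline_policy <- match.arg(baseline_policy)
  defs <- list(
    rectal_bleeding   = list(grade_threshold = 1L, urinary = FALSE, exclude_hemorrhoids = TRUE),
    urinary_frequency = list(grade_threshold = 2L, urinary = TRUE,  exclude_hemorrhoids = FALSE),
    haematuria        = list(grade_threshold = 1L, urinary = TRUE,  exclude_hemorrhoids = FALSE),
    nocturia          = list(grade_threshold = 2L, urinary = TRUE,  exclude_hemorrhoids = FALSE),
    decreased_stream  = list(grade_threshold = 1L, urinary = TRUE,  exclude_hemorrhoids = FALSE)
  )
  if (!name %in% names(defs)) {
    stop("unknown endpoint: ", name, " (expected one of ",
         paste(names(defs), collapse = ", "), ")")
  }
  spec <- c(list(name = name), defs[[name]], list(baseline_policy = baseline_policy))
  structure(spec, class = "endpoint_spec")
}

#' @export
print.endpoint_spec <- function(x, ...) {
  cat("Endpoint:", x$name, "\n")
  cat("  case if grade >=", x$grade_threshold, "at 12 or 24 months\n")
  cat("  urinary confounder exclusions:", x$urinary, "\n")
  cat("  haemorrhoid exclusion:", x$exclude_hemorrhoids, "\n")
  cat("  baseline-prevalent policy:", x$baseline_policy, "\n")
  invisible(x)
}

#' All five shipped endpoint specifications
#' @inheritParams endpoint_spec
#' @return Named list of `endpoint_spec` objects.
#' @export
endpoint_specs <- function(baseline_policy = "exclude") {
  eps <- c("rectal_bleeding", "urinary_frequency", "haematuria",
           "nocturia", "decreased_stream")
  setNames(lapply(eps, endpoint_spec, baseline_policy = baseline_policy), eps)
}

#' Derive case/control/excluded endpoint labels from toxicity records
#'
#' Applies an endpoint definition to per-patient grade trajectories.
#' Exclusions, in order of precedence: collagen vascular disease (always);
#' transurethral bladder resection or antimuscarinic use (urinary endpoints);
#' baseline haemorrhoids (rectal bleeding); no follow-up grades at all;
#' baseline grade at or above the threshold when `baseline_policy` is
#' `"exclude"`. Among the remaining patients, a case is a patient whose
#' maximum available follow-up grade reaches the threshold — or, for
#' baseline-prevalent patients kept under `"recode_control"`, strictly
#' exceeds it (a non-worsening trajectory does not count as the endpoint).
#'
#' @param records A data frame of toxicity records: columns `patient_id`,
#'   `base`, `m12`, `m24` (ordinal grades 0-4, `NA` for missing) and logical
#'   flags `hemorrhoids`, `turb`, `antimuscarinic`, `cvd`. See
#'   [read_phenotypes()] for the on-disk layout.
#' @param spec An [endpoint_spec()].
#' @return A tibble with columns `patient_id`, `status` (factor
#'   case/control/excluded) and `exclusion_reason` (`NA` unless excluded).
#' @export
derive_labels <- function(records, spec) {
  stopifnot(inherits(spec, "endpoint_spec"))
  records <- as.data.frame(records)
  needed <- c("patient_id", "base", "m12", "m24",
              "hemorrhoids", "turb", "antimuscarinic", "cvd")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  grades <- as.matrix(records[, c("base", "m12", "m24")])
  if (any(grades < 0 | grades > 4, na.rm = TRUE)) {
    stop("grades must be in 0..4 or NA")
  }
  n <- nrow(records)
  T <- spec$grade_threshold
  status <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  excl <- function(idx, why) {
    hit <- idx & is.na(status)
    status[hit] <<- "excluded"
    reason[hit] <<- why
  }
  as_flag <- function(x) !is.na(x) & as.logical(x)

  excl(as_flag(records$cvd), "collagen_vascular_disease")
  if (isTRUE(spec$urinary)) {
    excl(as_flag(records$turb), "turb")
    excl(as_flag(records$antimuscarinic), "antimuscarinic")
  }
  if (isTRUE(spec$exclude_hemorrhoids)) {
    excl(as_flag(records$hemorrhoids), "hemorrhoids_baseline")
  }
  fu <- grades[, c("m12", "m24"), drop = FALSE]
  no_fu <- rowSums(!is.na(fu)) == 0
  excl(no_fu, "no_followup")

  base_prev <- !is.na(grades[, "base"]) & grades[, "base"] >= T
  if (spec$baseline_policy == "exclude") {
    excl(base_prev, "baseline_prevalent")
  }

  open <- is.na(status)
  max_fu <- suppressWarnings(apply(fu, 1, max, na.rm = TRUE))
  is_case <- ifelse(base_prev, max_fu > T, max_fu >= T)
  status[open] <- ifelse(is_case[open], "case", "control")

  tibble::tibble(
    patient_id = records$patient_id,
    status = factor(status, levels = c("case", "control", "excluded")),
    exclusion_reason = reason
  )
}

#' Endpoint prevalence among evaluable patients
#'
#' @param labels Output of [derive_labels()].
#' @return Fraction of cases among non-excluded patients.
#' @export
#' @examples
#' # 160 cases out of 1,366 evaluable patients -> 0.117..., printed "11.7%"
prevalence <- function(labels) {
  tab <- table(labels$status)
  n_cases <- tab[["case"]]
  n_eval <- n_cases + tab[["control"]]
  if (n_eval == 0) stop("no non-excluded patients; prevalence undefined")
  n_cases / n_eval
}

#' Format a prevalence as a percentage with one decimal
#' @param p Fraction in \[0,1\].
#' @return Character like `"11.7%"`.
#' @export
format_prevalence <- function(p) sprintf("%.1f%%", 100 * p)

#' Read a phenotype table of longitudinal toxicity records
#'
#' Expects one row per patient with columns `patient_id`,
#' `<symptom>_base`, `<symptom>_m12`, `<symptom>_m24` for the endpoint's
#' symptom, and flags `hemorrhoids`, `turb`, `antimuscarinic`, `cvd`
#' (0/1 or TRUE/FALSE). Missing grades are empty fields.
#'
#' @param path CSV or TSV file (delimiter inferred from extension; `.csv`
#'   means comma, anything else tab).
#' @param endpoint Endpoint/symptom name selecting the grade columns.
#' @return A tibble in the layout expected by [derive_labels()].
#' @export
read_phenotypes <- function(path, endpoint) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  cols <- paste0(endpoint, c("_base", "_m12", "_m24"))
  needed <- c("patient_id", cols, "hemorrhoids", "turb", "antimuscarinic", "cvd")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("phenotype file is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  tibble::tibble(
    patient_id = as.character(raw$patient_id),
    base = as.integer(raw[[cols[1]]]),
    m12 = as.integer(raw[[cols[2]]]),
    m24 = as.integer(raw[[cols[3]]]),
    hemorrhoids = as.logical(raw$hemorrhoids),
    turb = as.logical(raw$turb),
    antimuscarinic = as.logical(raw$antimuscarinic),
    cvd = as.logical(raw$cvd)
  )
}

#' Write toxicity records to a phenotype TSV
#'
#' Inverse of [read_phenotypes()]: prefixes the grade columns with the
#' endpoint name so several endpoints can later share one file layout.
#'
#' @param records Records as produced by [simulate_longitudinal()].
#' @param path Output file path.
#' @param endpoint Symptom name used as the column prefix.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path, endpoint) {
  out <- data.frame(
    patient_id = records$patient_id,
    base = records$base, m12 = records$m12, m24 = records$m24,
    hemorrhoids = as.integer(records$hemorrhoids),
    turb = as.integer(records$turb),
    antimuscarinic = as.integer(records$antimuscarinic),
    cvd = as.integer(records$cvd)
  )
  names(out)[2:4] <- paste0(endpoint, c("_base", "_m12", "_m24"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}
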