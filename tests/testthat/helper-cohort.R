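# shared fixtures, built in code

# one toxicity record row
rec <- function(id = "P1", base = 0, m12 = 0, m24 = 0,
                hemorrhoids = FALSE, turb = FALSE,
                antimuscarinic = FALSE, cvd = FALSE) {
  tibble::tibble(patient_id = id, base = base, m12 = m12, m24 = m24,
                 hemorrhoids = hemorrhoids, turb = turb,
                 antimuscarinic = antimuscarinic, cvd = cvd)
}

# a cohort whose derived labels have exactly the requested counts
make_count_cohort <- function(spec, n_cases, n_controls, n_excluded = 0) {
  labels <- rep(c(1L, 0L), c(n_cases, n_controls))
  records <- simulate_longitudinal(labels, spec, seed = 99)
  if (n_excluded > 0) {
    extra <- simulate_longitudinal(rep(0L, n_excluded), spec, seed = 100)
    extra$patient_id <- paste0("X", seq_len(n_excluded))
    extra$cvd <- TRUE
    records <- rbind(records, extra)
  }
  records
}

# small fast architecture for tests that only need *a* working autoencoder
small_spec <- function(J = 8, epochs = 30) {
  network_spec(J, encoder_widths = c(6L, 4L),
               encoder_activations = c("tanh", "sigmoid"),
               epochs = epochs)
}

# hand-rolled linear-interpolation percentile (independent of stats::quantile)
brute_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(s[lo])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# build a replicate_errors object directly from per-class mean matrices
manual_replicate_errors <- function(unhealthy, healthy, rsids = NULL) {
  structure(list(unhealthy = unhealthy, healthy = healthy,
                 rsids = rsids %||% paste0("snp", seq_len(ncol(unhealthy))),
                 S = 1L, B = nrow(unhealthy),
                 replicate_seeds = seq_len(nrow(unhealthy)),
                 master_seed = 0L),
            class = "replicate_errors")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
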