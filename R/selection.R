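#' Split a cohort into a healthy-only training set and a balanced test set
#'
#' Samples, without replacement, S healthy patients where S is the number of
#' unhealthy patients; these plus all unhealthy patients form the test set
#' (2S rows), and every remaining healthy patient forms the training set.
#' The method presumes class imbalance: it is an error for unhealthy
#' patients to be at least as numerous as healthy ones.
#'
#' @param labels Binary 0/1 vector (1 = unhealthy/toxicity).
#' @param seed Integer seed; the split is a pure function of it.
#' @return List with integer index vectors `train` (healthy only) and
#'   `test` (all unhealthy plus S sampled healthy), and `S`.
#' @export
#' @examples
#' sp <- resample_split(rep(c(0, 1), c(100, 20)), seed = 1)
#' length(sp$train) # 80
#' length(sp$test)  # 40
resample_split <- function(labels, seed = 1L) {
  stopifnot(all(labels %in% c(0L, 1L)))
  healthy <- which(labels == 0L)
  unhealthy <- which(labels == 1L)
  S <- length(unhealthy)
  if (S < 1) stop("no unhealthy patients")
  if (S >= length(healthy)) {
    stop("method presumes imbalance: need more healthy (", length(healthy),
         ") than unhealthy (", S, ") patients")
  }
  set.seed(seed)
  test_healthy <- sample(healthy, S)
  list(train = sort(setdiff(healthy, test_healthy)),
       test = sort(c(unhealthy, test_healthy)),
       S = S)
}

#' Replicate sampling-training-testing and per-class mean errors
#'
#' For each of B replicates: draw a fresh healthy/test split, train a fresh
#' autoencoder on the (scaled) healthy training rows, compute the
#' reconstruction-error matrix on the balanced test set, and reduce it to
#' two J-vectors — the per-feature mean over unhealthy test rows and over
#' healthy test rows. Replicate seeds are derived deterministically from
#' `master_seed` (one counter-based draw per replicate), so the whole
#' procedure is reproducible end to end.
#'
#' @param X Input matrix on the network scale (e.g. [scale_dosages()]
#'   output), rows = patients.
#' @param labels Binary 0/1 vector aligned with the rows of `X`.
#' @param network_spec A [network_spec()] with `input_width == ncol(X)`.
#' @param B Number of replicates (default 50).
#' @param master_seed Integer master seed.
#' @param reconstruct_fn Optional function `(X_train, X_test) -> Xhat_test`
#'   replacing autoencoder training, e.g. for oracle tests; the default
#'   trains a fresh DSAE per replicate.
#' @return Object of class `replicate_errors`: `unhealthy` and `healthy`
#'   (B x J matrices of per-class per-feature mean reconstruction errors),
#'   `rsids`, `S`, `B`, `replicate_seeds`, `master_seed`.
#' @export
run_replicates <- function(X, labels, network_spec, B = 50L,
                           master_seed = 1L, reconstruct_fn = NULL) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(labels), B >= 1)
  J <- ncol(X)
  set.seed(master_seed)
  replicate_seeds <- sample.int(.Machine$integer.max - 1L, B)
  unhealthy_means <- matrix(NA_real_, B, J)
  healthy_means <- matrix(NA_real_, B, J)
  for (b in seq_len(B)) {
    sp <- resample_split(labels, seed = replicate_seeds[b])
    X_test <- X[sp$test, , drop = FALSE]
    if (is.null(reconstruct_fn)) {
      model <- dsae_fit(X[sp$train, , drop = FALSE], network_spec,
                        seed = replicate_seeds[b])
      R <- reconstruction_errors(model, X_test)
    } else {
      R <- squared_residuals(X_test, reconstruct_fn(X[sp$train, , drop = FALSE],
                                                    X_test))
    }
    is_unhealthy <- labels[sp$test] == 1L
    unhealthy_means[b, ] <- colMeans(R[is_unhealthy, , drop = FALSE])
    healthy_means[b, ] <- colMeans(R[!is_unhealthy, , drop = FALSE])
  }
  structure(list(unhealthy = unhealthy_means, healthy = healthy_means,
                 rsids = colnames(X), S = sum(labels == 1L), B = as.integer(B),
                 replicate_seeds = replicate_seeds,
                 master_seed = master_seed),
            class = "replicate_errors")
}

#' @export
print.replicate_errors <- function(x, ...) {
  cat("Replicate reconstruction errors:", x$B, "replicates x",
      ncol(x$unhealthy), "features (S =", x$S, ")\n")
  invisible(x)
}

#' Aggregate replicate class means into the per-SNP delta profile
#'
#' The two per-class vectors are averaged across replicates with equal
#' weight per replicate, then subtracted elementwise: delta = mean unhealthy
#' reconstruction error minus mean healthy reconstruction error, per
#' feature. Features where patients with toxicity sit far from the learned
#' pattern of normal radiosensitivity receive large positive deltas.
#'
#' @param rep A `replicate_errors` object.
#' @return Object of class `delta_profile`: `delta` (named length-J
#'   vector), `unhealthy_mean`, `healthy_mean`, `rsids`, `B`.
#' @export
delta_profile <- function(rep) {
  stopifnot(inherits(rep, "replicate_errors"))
  unhealthy_mean <- colMeans(rep$unhealthy)
  healthy_mean <- colMeans(rep$healthy)
  delta <- unhealthy_mean - healthy_mean
  names(delta) <- rep$rsids
  structure(list(delta = delta, unhealthy_mean = unhealthy_mean,
                 healthy_mean = healthy_mean, rsids = rep$rsids, B = rep$B),
            class = "delta_profile")
}

#' @export
print.delta_profile <- function(x, ...) {
  cat("Delta profile over", length(x$delta), "features (B =", x$B, ")\n")
  print(summary(x$delta))
  invisible(x)
}

#' Percentile-tier SNP selection from a delta profile
#'
#' Thresholds are the 70th, 80th, 90th and 95th percentiles of the J delta
#' values (linear-interpolation quantiles); a SNP enters a tier when its
#' delta is strictly greater than the threshold, so tiers are nested by
#' construction and a constant delta profile selects nothing. Tier
#' membership maps to the literature effect-size vocabulary: above the 70th
#' percentile small (OR < 2), above the 80th moderate (OR ~ 2), above the
#' 90th or 95th large (OR > 2).
#'
#' @param delta A `delta_profile`.
#' @param percentiles Increasing percentile thresholds, default
#'   `c(70, 80, 90, 95)`.
#' @param panel Optional panel tibble ([load_snp_panel()]) to cross-reference
#'   literature endpoint and effect.
#' @param endpoint Optional endpoint name of the analysis, used to flag SNPs
#'   identified for the endpoint they were originally reported for.
#' @return A tibble of class `selection_report` with one row per SNP:
#'   `rsid`, `delta`, logical columns `p70`, `p80`, `p90`, `p95` (strictly
#'   above each threshold), `tier` (highest tier or `"none"`),
#'   `effect_label`, `identified` (above the lowest threshold), and, when a
#'   panel is given, `literature_endpoint`, `literature_effect`,
#'   `identified_for_this_endpoint`. Percentile thresholds are attached as
#'   attribute `thresholds`.
#' @export
tier_select <- function(delta, percentiles = c(70, 80, 90, 95),
                        panel = NULL, endpoint = NULL) {
  stopifnot(inherits(delta, "delta_profile"),
            all(diff(percentiles) > 0), all(percentiles > 0),
            all(percentiles < 100))
  d <- delta$delta
  if (any(!is.finite(d))) stop("delta profile contains non-finite values")
  thr <- quantile(d, percentiles / 100, type = 7, names = FALSE)
  names(thr) <- paste0("p", percentiles)
  member <- vapply(thr, function(t) d > t, logical(length(d)))
  if (max(d) == min(d)) {
    warning("constant delta profile: all tiers empty")
  }
  tier_names <- colnames(member)
  highest <- apply(member, 1, function(m) {
    if (!any(m)) "none" else tier_names[max(which(m))]
  })
  label_map <- c(none = "none", p70 = "small", p80 = "moderate",
                 p90 = "large", p95 = "large")
  out <- tibble::tibble(
    rsid = if (is.null(delta$rsids)) sprintf("snp%02d", seq_along(d)) else delta$rsids,
    delta = unname(d)
  )
  for (tn in tier_names) out[[tn]] <- unname(member[, tn])
  out$tier <- factor(highest, levels = c("none", tier_names))
  out$effect_label <- factor(
    unname(label_map[ifelse(highest %in% names(label_map), highest, "large")]),
    levels = c("none", "small", "moderate", "large"))
  out$identified <- unname(member[, 1])
  if (!is.null(panel)) {
    idx <- match(out$rsid, panel$rsid)
    out$literature_endpoint <- as.character(panel$endpoint)[idx]
    out$literature_effect <- panel$effect[idx]
    if (!is.null(endpoint)) {
      out$identified_for_this_endpoint <-
        out$identified & !is.na(out$literature_endpoint) &
        out$literature_endpoint == endpoint
    }
  }
  attr(out, "thresholds") <- thr
  class(out) <- c("selection_report", class(out))
  out
}

#' Write a selection report to TSV
#' @param report A `selection_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  out <- as.data.frame(report)
  logi <- vapply(out, is.logical, logical(1))
  out[logi] <- lapply(out[logi], as.integer)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Validation-matrix view of a selection report
#'
#' One row per SNP, one column per percentile tier, each cell either
#' `"Identified"` or `"Not validated"` — the layout used to report which
#' literature SNPs the autoencoder confirms at each effect-size tier.
#'
#' @param report A `selection_report`.
#' @return A tibble with `rsid` and one character column per tier.
#' @export
validation_matrix <- function(report) {
  tiers <- grep("^p[0-9]+$", names(report), value = TRUE)
  out <- tibble::tibble(rsid = report$rsid)
  for (tn in tiers) {
    out[[tn]] <- ifelse(report[[tn]], "Identified", "Not validated")
  }
  out
}
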