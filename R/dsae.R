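#' Specify a deep sparse autoencoder
#'
#' The default architecture is the one used for SNP-panel validation: an
#' input of `input_width` nodes (one per SNP), encoder layers of 40 and 30
#' nodes with hyperbolic-tangent activations, a 20-node innermost code layer
#' with a sigmoid activation (so an L1 activity penalty on the code is
#' nonnegative and bounded), and a decoder mirroring the encoder (30, 40,
#' tanh) with a linear output layer. Training minimises the mean per-sample
#' squared reconstruction error plus `lambda` times the batch-mean L1 norm
#' of the code activations, by Adam.
#'
#' @param input_width Number of input features J (>= 1).
#' @param encoder_widths Hidden widths down to and including the code layer.
#' @param encoder_activations One of `"tanh"`, `"sigmoid"`, `"linear"` per
#'   encoder layer.
#' @param decoder_widths Hidden widths of the decoder (output layer is added
#'   automatically); must mirror the encoder ("specular").
#' @param decoder_activations Activations for the decoder hidden layers; the
#'   output layer is linear.
#' @param lambda Nonnegative sparsity weight (default 1e-4; the method's
#'   rankings are insensitive to the 1e-4 vs 1e-5 choice, both are
#'   exercised in the test-suite).
#' @param epochs Training epochs (default 400).
#' @param learning_rate Adam step size (default 0.001; other Adam
#'   parameters at their conventional defaults).
#' @param batch_size Mini-batch size; `Inf` (default) trains full-batch,
#'   appropriate for cohort-sized (~1,000 row) training sets.
#' @return Object of class `dsae_spec`.
#' @export
#' @examples
#' spec <- network_spec(43)
#' n_parameters(spec) # 7243
network_spec <- function(input_width,
                         encoder_widths = c(40L, 30L, 20L),
                         encoder_activations = c("tanh", "tanh", "sigmoid"),
                         decoder_widths = rev(encoder_widths[-length(encoder_widths)]),
                         decoder_activations = rep("tanh", length(decoder_widths)),
                         lambda = 1e-4, epochs = 400L,
                         learning_rate = 0.001, batch_size = Inf) {
  if (input_width < 1) stop("input_width must be >= 1")
  stopifnot(all(encoder_widths > 0), all(decoder_widths > 0), lambda >= 0,
            epochs >= 1, learning_rate > 0,
            length(encoder_activations) == length(encoder_widths),
            length(decoder_activations) == length(decoder_widths))
  if (!identical(as.integer(decoder_widths),
                 as.integer(rev(encoder_widths[-length(encoder_widths)])))) {
    stop("decoder_widths must mirror the encoder widths")
  }
  ok <- c("tanh", "sigmoid", "linear")
  stopifnot(all(encoder_activations %in% ok), all(decoder_activations %in% ok))
  structure(list(
    input_width = as.integer(input_width),
    encoder_widths = as.integer(encoder_widths),
    encoder_activations = encoder_activations,
    decoder_widths = as.integer(decoder_widths),
    decoder_activations = decoder_activations,
    lambda = lambda,
    epochs = as.integer(epochs),
    learning_rate = learning_rate,
    batch_size = batch_size
  ), class = "dsae_spec")
}

#' @export
print.dsae_spec <- function(x, ...) {
  cat("Deep sparse autoencoder spec\n")
  cat("  layers:", paste(c(x$input_width, x$encoder_widths, x$decoder_widths,
                           x$input_width), collapse = " -> "), "\n")
  cat("  code width:", x$encoder_widths[length(x$encoder_widths)],
      " lambda:", x$lambda, "\n")
  cat("  epochs:", x$epochs, " lr:", x$learning_rate,
      " batch:", ifelse(is.finite(x$batch_size), x$batch_size, "full"), "\n")
  invisible(x)
}

# per-layer (input, output, activation) triples including the linear output
.layer_plan <- function(spec) {
  widths <- c(spec$input_width, spec$encoder_widths, spec$decoder_widths,
              spec$input_width)
  acts <- c(spec$encoder_activations, spec$decoder_activations, "linear")
  list(fan_in = widths[-length(widths)], fan_out = widths[-1], act = acts)
}

.act_code <- function(a) c(linear = 0L, tanh = 1L, sigmoid = 2L)[a]

#' Total number of trainable parameters
#' @param spec A [network_spec()].
#' @return Integer count of weights plus biases over all layers.
#' @export
n_parameters <- function(spec) {
  p <- .layer_plan(spec)
  sum(p$fan_in * p$fan_out + p$fan_out)
}

#' Initialise an untrained autoencoder
#'
#' Weights get fan-balanced (Glorot-style) uniform draws on
#' `+/- sqrt(6 / (fan_in + fan_out))`; biases start at zero. Initialisation
#' is bit-reproducible under `seed`.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed.
#' @return Object of class `dsae_model` with fields `spec`, `weights`,
#'   `biases`, `trained`, `loss_trace`, `seed`.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "dsae_spec"))
  p <- .layer_plan(spec)
  set.seed(seed)
  weights <- vector("list", length(p$act))
  biases <- vector("list", length(p$act))
  for (l in seq_along(p$act)) {
    lim <- sqrt(6 / (p$fan_in[l] + p$fan_out[l]))
    weights[[l]] <- matrix(runif(p$fan_in[l] * p$fan_out[l], -lim, lim),
                           p$fan_in[l], p$fan_out[l])
    biases[[l]] <- rep(0, p$fan_out[l])
  }
  structure(list(spec = spec, weights = weights, biases = biases,
                 trained = FALSE, loss_trace = NULL, seed = seed),
            class = "dsae_model")
}

#' @export
print.dsae_model <- function(x, ...) {
  print(x$spec)
  cat(if (x$trained) "  trained" else "  untrained",
      "|", n_parameters(x$spec), "parameters\n")
  if (x$trained) {
    cat("  final training loss:",
        format(x$loss_trace[length(x$loss_trace)]), "\n")
  }
  invisible(x)
}

#' Train a deep sparse autoencoder
#'
#' Minimises the mean per-sample squared reconstruction error
#' `||x - xhat||^2` plus `lambda` times the batch-mean L1 norm of the code
#' activations, by Adam, for `spec$epochs` epochs. Inputs must already be on
#' the input scale convention (see [scale_dosages()]); column scaling is
#' fixed, never data-dependent, so train and test sets are scaled
#' identically by construction.
#'
#' @param model Untrained `dsae_model` from [build_network()].
#' @param X_train Numeric matrix, rows = patients, columns matching
#'   `spec$input_width`.
#' @return The trained `dsae_model`, with `loss_trace` of length
#'   `spec$epochs` (per-epoch total training loss).
#' @export
train_dsae <- function(model, X_train) {
  stopifnot(inherits(model, "dsae_model"))
  X_train <- as.matrix(X_train)
  if (nrow(X_train) == 0) stop("empty training set")
  if (ncol(X_train) != model$spec$input_width) {
    stop("X_train has ", ncol(X_train), " columns; spec expects ",
         model$spec$input_width)
  }
  if (any(!is.finite(X_train))) stop("non-finite values in X_train")
  spec <- model$spec
  p <- .layer_plan(spec)
  bs <- if (is.finite(spec$batch_size)) as.integer(spec$batch_size)
        else nrow(X_train)
  fit <- cpp_train_dsae(X_train, model$weights, model$biases,
                        as.integer(.act_code(p$act)), spec$lambda,
                        length(spec$encoder_widths), spec$epochs,
                        spec$learning_rate, bs)
  model$weights <- fit$weights
  model$biases <- fit$biases
  model$loss_trace <- as.numeric(fit$loss_trace)
  model$trained <- TRUE
  model
}

#' Convenience: initialise and train in one call
#' @inheritParams train_dsae
#' @param spec A [network_spec()].
#' @param seed Integer seed for the weight initialisation.
#' @return Trained `dsae_model`.
#' @export
dsae_fit <- function(X_train, spec, seed = 1L) {
  train_dsae(build_network(spec, seed = seed), X_train)
}

.check_width <- function(model, X) {
  if (ncol(X) != model$spec$input_width) {
    stop("input has ", ncol(X), " columns; model expects ",
         model$spec$input_width)
  }
}

#' Reconstruct inputs through the autoencoder
#' @param model A `dsae_model`.
#' @param X Matrix on the input scale.
#' @return Matrix of reconstructions, same shape as `X`.
#' @export
reconstruct <- function(model, X) {
  X <- as.matrix(X)
  .check_width(model, X)
  p <- .layer_plan(model$spec)
  out <- cpp_forward(X, model$weights, model$biases,
                     as.integer(.act_code(p$act)), length(p$act))
  dimnames(out) <- dimnames(X)
  out
}

#' Innermost code-layer activations
#' @inheritParams reconstruct
#' @return Matrix of code activations (sigmoid outputs in (0,1) under the
#'   default spec), rows aligned with `X`.
#' @export
encode <- function(model, X) {
  X <- as.matrix(X)
  .check_width(model, X)
  p <- .layer_plan(model$spec)
  cpp_forward(X, model$weights, model$biases,
              as.integer(.act_code(p$act)),
              length(model$spec$encoder_widths))
}

#' Per-feature squared residuals between inputs and reconstructions
#' @param X,Xhat Conformable numeric matrices.
#' @return Matrix of `(X - Xhat)^2`, elementwise.
#' @export
squared_residuals <- function(X, Xhat) {
  stopifnot(all(dim(X) == dim(Xhat)))
  (as.matrix(X) - as.matrix(Xhat))^2
}

#' Reconstruction-error matrix on a test set
#'
#' The per-patient, per-feature squared deviation between input and
#' reconstruction: `r_ij = (x_ij - xhat_ij)^2`. Shape is preserved, so a
#' class-balanced test set of 2S patients over J SNPs yields a 2S x J
#' matrix.
#'
#' @inheritParams reconstruct
#' @return Nonnegative matrix with the shape of `X`.
#' @export
reconstruction_errors <- function(model, X) {
  squared_residuals(as.matrix(X), reconstruct(model, X))
}

#' Scale additive dosages to the network input convention
#'
#' Dosages in \[0,2\] are halved to \[0,1\]. The constant is fixed (not
#' estimated from data) so train and test scaling always agree.
#'
#' @param G Dosage matrix or `genotype_matrix`.
#' @return Numeric matrix in \[0,1\].
#' @export
scale_dosages <- function(G) {
  if (inherits(G, "genotype_matrix")) G <- G$dosages
  as.matrix(G) / 2
}

#' Serialise / restore a model as portable JSON
#'
#' The container stores the spec plus per-layer shape-annotated weight and
#' bias arrays as plain JSON; nothing framework-specific.
#'
#' @param model A `dsae_model`.
#' @param path File path (`.json`).
#' @return `path` (writer, invisibly) or a `dsae_model` (reader).
#' @export
write_dsae <- function(model, path) {
  spec_out <- unclass(model$spec)
  if (!is.finite(spec_out$batch_size)) spec_out$batch_size <- NULL
  payload <- list(
    spec = spec_out,
    layers = lapply(seq_along(model$weights), function(l) list(
      shape = dim(model$weights[[l]]),
      weights = as.numeric(model$weights[[l]]),
      bias = as.numeric(model$biases[[l]])
    )),
    trained = model$trained,
    loss_trace = model$loss_trace,
    seed = model$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_dsae
#' @export
read_dsae <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- payload$spec
  spec <- network_spec(sp$input_width, sp$encoder_widths,
                       sp$encoder_activations, sp$decoder_widths,
                       sp$decoder_activations, sp$lambda, sp$epochs,
                       sp$learning_rate,
                       if (is.null(sp$batch_size)) Inf else sp$batch_size)
  layers <- payload$layers
  weights <- lapply(seq_len(nrow(layers)), function(l) {
    matrix(layers$weights[[l]], layers$shape[[l]][1], layers$shape[[l]][2])
  })
  biases <- lapply(seq_len(nrow(layers)), function(l) layers$bias[[l]])
  structure(list(spec = spec, weights = weights, biases = biases,
                 trained = isTRUE(payload$trained),
                 loss_trace = payload$loss_trace,
                 seed = payload$seed),
            class = "dsae_model")
}
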