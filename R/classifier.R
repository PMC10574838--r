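#' Configuration of the utility classifier
#'
#' A small dense network used as the arbiter of synthetic-data utility:
#' hidden widths 64, 32, 16, 8 with 20% dropout after each, a 2-unit
#' softmax head (3,402 trainable parameters on the 9-channel input), Adam
#' at learning rate 0.001, batch size 64, 250 epochs. The classifier is
#' deliberately not tuned: the evaluation targets the data, not the model.
#'
#' @param layer_widths dense widths ending in the 2-unit output.
#' @param dropout rate applied after each hidden layer.
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs training epochs.
#' @param seed integer seed.
#' @return an object of class `"classifier_config"`.
#' @export
classifier_config <- function(layer_widths = c(64L, 32L, 16L, 8L, 2L),
                              dropout = 0.2, learning_rate = 0.001,
                              batch_size = 64L, epochs = 250L, seed = 1L) {
  layer_widths <- as.integer(layer_widths)
  if (layer_widths[length(layer_widths)] != 2L)
    stop("the output layer must have width 2 (binary classification)")
  if (learning_rate <= 0 || batch_size < 1L || epochs < 1L)
    stop("hyperparameters must be positive")
  structure(list(layer_widths = layer_widths, dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "classifier_config")
}

#' Build the (untrained) utility classifier network
#'
#' @param cfg a [classifier_config()].
#' @param input_dim feature dimension (9 for the gait channels).
#' @return a `"fog_network"` with a softmax head; rows of its output sum
#'   to 1.
#' @export
build_classifier <- function(cfg = classifier_config(), input_dim = 9L) {
  stopifnot(inherits(cfg, "classifier_config"))
  k <- length(cfg$layer_widths)
  mlp_init(mlp_spec(input_dim, cfg$layer_widths,
                    output_activation = "softmax",
                    dropout = c(rep(cfg$dropout, k - 1L), 0)))
}

#' Train the utility classifier on (real) labeled data
#'
#' Minimizes the two-class cross-entropy with Adam on minibatches; the run
#' is reproducible given `cfg$seed`. Training data must be standardized
#' (the same scaler is then applied to every evaluation set) and contain
#' both classes.
#'
#' @param train a scaled [fog_matrix()] with both labels present.
#' @param cfg a [classifier_config()].
#' @param input_dim feature dimension.
#' @return an object of class `"fog_classifier"`: the trained network, the
#'   config, and a per-epoch cross-entropy `history`.
#' @export
fog_classifier <- function(train, cfg = classifier_config(), input_dim = ncol(train$X)) {
  stopifnot(inherits(train, "fog_matrix"), inherits(cfg, "classifier_config"))
  if (!train$scaled) stop("classifier training expects standardized features")
  if (length(unique(train$y)) < 2L)
    stop("training set must contain both classes")
  X <- train$X
  n <- nrow(X)
  m <- min(cfg$batch_size, n)
  # targets one-hot: column 1 = freeze (label 0), column 2 = no-freeze (label 1)
  Tm <- cbind(1 - train$y, train$y)
  with_seed(cfg$seed, {
    net <- build_classifier(cfg, input_dim)
    opt <- adam_new(net)
    steps <- n %/% m
    loss <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      el <- 0
      for (s in seq_len(steps)) {
        idx <- perm[((s - 1L) * m + 1L):(s * m)]
        cache <- mlp_forward_cache(net, X[idx, , drop = FALSE], training = TRUE)
        p <- pmax(cache$out, 1e-12)
        t <- Tm[idx, , drop = FALSE]
        el <- el - mean(rowSums(t * log(p)))
        grads <- mlp_backprop(net, cache, (cache$out - t) / m)
        st <- adam_step(net, grads, opt, cfg$learning_rate)
        net <- st$net; opt <- st$opt
      }
      loss[epoch] <- el / steps
      if (!is.finite(loss[epoch]))
        stop(sprintf("non-finite cross-entropy at epoch %d", epoch))
    }
    structure(list(net = net, cfg = cfg,
                   history = data.frame(epoch = seq_len(cfg$epochs),
                                        loss = loss)),
              class = "fog_classifier")
  })
}

#' Predict labels or class probabilities
#'
#' @param object a trained [fog_classifier()].
#' @param newdata a [fog_matrix()] or numeric matrix, scaled consistently
#'   with training.
#' @param type `"class"` for hard labels in `{0, 1}` (argmax), `"prob"` for
#'   the softmax matrix.
#' @param ... ignored.
#' @return integer labels or a probability matrix with columns
#'   `freeze`/`no_freeze`.
#' @export
predict.fog_classifier <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "fog_matrix")) newdata$X else as.matrix(newdata)
  p <- mlp_forward(object$net, X)
  colnames(p) <- c("freeze", "no_freeze")
  if (type == "prob") return(p)
  as.integer(p[, 2L] > p[, 1L])
}

#' @export
print.fog_classifier <- function(x, ...) {
  s <- x$net$spec
  cat(sprintf("Utility classifier: %d -> %s (softmax), %s parameters\n",
              s$input_dim, paste(s$layer_widths, collapse = " -> "),
              format(count_parameters(x$net), big.mark = ",")))
  cat(sprintf("  trained %d epochs, final cross-entropy %.4f\n",
              nrow(x$history), x$history$loss[nrow(x$history)]))
  invisible(x)
}

#' Classification accuracy on a labeled evaluation set
#'
#' @param clf a trained [fog_classifier()].
#' @param data a non-empty [fog_matrix()], scaled consistently with
#'   training.
#' @return fraction of correct argmax predictions in `[0, 1]`.
#' @export
evaluate_accuracy <- function(clf, data) {
  stopifnot(inherits(clf, "fog_classifier"), inherits(data, "fog_matrix"))
  if (nrow(data$X) == 0L) stop("empty evaluation set")
  mean(predict(clf, data) == data$y)
}

#' Pool an original evaluation set with generated samples
#'
#' Row-binds the two labeled matrices and shuffles the rows with a seed;
#' label multisets are conserved.
#'
#' @param original_eval,generated [fog_matrix()]s with the same feature
#'   schema and scaling state.
#' @param seed integer seed for the shuffle.
#' @return a [fog_matrix()] with `nrow(original_eval) + nrow(generated)`
#'   rows.
#' @export
build_mixed_eval <- function(original_eval, generated, seed = 1L) {
  stopifnot(inherits(original_eval, "fog_matrix"), inherits(generated, "fog_matrix"))
  if (ncol(original_eval$X) != ncol(generated$X))
    stop("schema mismatch: differing feature counts")
  if (original_eval$scaled != generated$scaled)
    stop("schema mismatch: differing scaling state")
  X <- rbind(original_eval$X, generated$X)
  y <- c(original_eval$y, generated$y)
  idx <- with_seed(seed, sample.int(nrow(X)))
  fog_matrix(X[idx, , drop = FALSE], y[idx],
             original_eval$scaled, original_eval$scaler_state)
}

#' Train-on-real, test-on-synthetic utility evaluation
#'
#' The three-scenario protocol: a classifier trained on real data is scored
#' on (i) the held-out real evaluation set, (ii) the generated set, and
#' (iii) their shuffled union. Close accuracies indicate that the synthetic
#' data carry the same predictive structure as the real data. Per-class
#' recalls are reported as supplementary fields because freeze is the
#' minority class and a headline accuracy can mask it.
#'
#' @param clf a trained [fog_classifier()].
#' @param original_eval held-out real data, scaled as in training.
#' @param generated synthetic data, scaled the same way.
#' @param seed seed for the mixing shuffle.
#' @return an object of class `"utility_report"` with the three accuracies,
#'   the set sizes, and per-class recalls on the original evaluation set.
#' @export
utility_evaluation <- function(clf, original_eval, generated, seed = 1L) {
  if (nrow(original_eval$X) == 0L || nrow(generated$X) == 0L)
    stop("evaluation sets must be non-empty")
  mixed <- build_mixed_eval(original_eval, generated, seed)
  pred_orig <- predict(clf, original_eval)
  recall <- function(cls) {
    sel <- original_eval$y == cls
    if (!any(sel)) return(NA_real_)
    mean(pred_orig[sel] == cls)
  }
  structure(list(
    accuracy_original = mean(pred_orig == original_eval$y),
    accuracy_generated = evaluate_accuracy(clf, generated),
    accuracy_mixed = evaluate_accuracy(clf, mixed),
    n_original = nrow(original_eval$X),
    n_generated = nrow(generated$X),
    n_mixed = nrow(mixed$X),
    recall_freeze = recall(0L),
    recall_no_freeze = recall(1L)),
    class = "utility_report")
}

#' @export
print.utility_report <- function(x, ...) {
  cat("Utility evaluation (classifier trained on real data)\n")
  cat(sprintf("  original  eval set: accuracy %6.2f%%  (n = %d)\n",
              100 * x$accuracy_original, x$n_original))
  cat(sprintf("  generated eval set: accuracy %6.2f%%  (n = %d)\n",
              100 * x$accuracy_generated, x$n_generated))
  cat(sprintf("  mixed     eval set: accuracy %6.2f%%  (n = %d)\n",
              100 * x$accuracy_mixed, x$n_mixed))
  cat(sprintf("  per-class recall (original): freeze %.3f, no-freeze %.3f\n",
              x$recall_freeze, x$recall_no_freeze))
  invisible(x)
}
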