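#' Noise-input specification for the generator
#'
#' The generator maps latent noise vectors `z ~ N(0, I)` of this dimension
#' to data space. The default dimension 8 is fixed by the published
#' architecture arithmetic: the first generator layer has 13,824 parameters
#' = (8 + 1) * 1536.
#'
#' @param dimension latent dimension (>= 1), default 8.
#' @return an object of class `"noise_spec"`.
#' @export
noise_spec <- function(dimension = 8L) {
  dimension <- as.integer(dimension)
  if (length(dimension) != 1L || is.na(dimension) || dimension < 1L)
    stop("noise 'dimension' must be a single integer >= 1")
  structure(list(dimension = dimension, distribution = "standard normal"),
            class = "noise_spec")
}

#' Adversarial training configuration
#'
#' Defaults follow the reference training recipe: 500 epochs, minibatch size
#' 50, Adam with learning rate 0.001 for the discriminator and 0.01 for the
#' generator. `generator_loss` selects between the non-saturating generator
#' objective (maximize `log D(G(z))`, the default for its healthier early
#' gradients) and the literal minimization of `log(1 - D(G(z)))`; both have
#' the same fixed point.
#'
#' @param epochs number of full passes over the training rows.
#' @param batch_size minibatch size `m`.
#' @param lr_discriminator,lr_generator Adam learning rates.
#' @param seed integer seed; a run is fully reproducible given the seed.
#' @param generator_loss `"non_saturating"` or `"literal"`.
#' @param adam_beta1 first-moment decay of both Adam optimizers; 0.5 is the
#'   conventional choice for adversarial training (high momentum makes the
#'   two-player oscillation worse).
#' @return an object of class `"gan_config"`.
#' @export
gan_config <- function(epochs = 500L, batch_size = 50L,
                       lr_discriminator = 0.001, lr_generator = 0.01,
                       seed = 1L,
                       generator_loss = c("non_saturating", "literal"),
                       adam_beta1 = 0.5) {
  generator_loss <- match.arg(generator_loss)
  if (epochs < 1L || batch_size < 1L) stop("'epochs' and 'batch_size' must be >= 1")
  if (lr_discriminator <= 0 || lr_generator <= 0) stop("learning rates must be positive")
  if (adam_beta1 < 0 || adam_beta1 >= 1) stop("'adam_beta1' must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_discriminator = lr_discriminator, lr_generator = lr_generator,
                 seed = as.integer(seed), generator_loss = generator_loss,
                 adam_beta1 = adam_beta1),
            class = "gan_config")
}

#' Reference network architectures
#'
#' The published layer layout: an 8-dimensional noise input feeding a
#' generator with hidden widths 1536, 1278, 1024, 512, 384, 256, 128, 64,
#' 32, 16 and a linear 9-unit output (4,152,071 parameters); a discriminator
#' with the same ten hidden widths, 20% dropout after every dense layer, and
#' a 1-unit logistic head on a 9-feature input; and a classifier with widths
#' 64, 32, 16, 8 and a 2-unit softmax head (3,402 parameters). The printed
#' discriminator table re-lists the generator's widths on an 8-dimensional
#' input ending in a 9-unit layer; that layout cannot produce the scalar
#' real-vs-fake probability the adversarial value function requires, so it
#' is exposed here only as `discriminator_table_widths` for arithmetic
#' checks, while the functional discriminator uses `discriminator_widths`.
#'
#' @return a list with elements `noise_dim`, `generator_widths`,
#'   `discriminator_widths`, `discriminator_table_widths` and
#'   `classifier_widths`.
#' @export
foggan_architecture <- function() {
  hidden <- c(1536L, 1278L, 1024L, 512L, 384L, 256L, 128L, 64L, 32L, 16L)
  list(noise_dim = 8L,
       generator_widths = c(hidden, 9L),
       discriminator_widths = c(hidden, 1L),
       discriminator_table_widths = c(hidden, 9L),
       classifier_widths = c(64L, 32L, 16L, 8L, 2L))
}

#' Build an (untrained) generator network
#'
#' Fully connected: noise input, rectifier hidden layers, linear 9-unit
#' output matching the preprocessed feature dimension. With the default
#' widths the network has 4,152,071 trainable parameters.
#'
#' @param noise a [noise_spec()].
#' @param layer_widths dense widths ending in the output width; defaults to
#'   the reference layout. Reduced widths give a cheaper generator for
#'   fixture-scale training.
#' @return a `"fog_network"` with freshly initialized parameters.
#' @export
build_generator <- function(noise = noise_spec(),
                            layer_widths = foggan_architecture()$generator_widths) {
  stopifnot(inherits(noise, "noise_spec"))
  mlp_init(mlp_spec(noise$dimension, layer_widths,
                    output_activation = "linear"))
}

#' Build an (untrained) discriminator network
#'
#' Rectifier dense layers with dropout after each of them, then a 1-unit
#' logistic head returning the probability that a sample is real; outputs
#' lie strictly in (0, 1).
#'
#' @param input_dim feature dimension of the data (9 for the gait channels).
#' @param hidden_widths dense hidden widths; defaults to the reference
#'   layout.
#' @param dropout dropout rate after every hidden layer, default 0.2.
#' @return a `"fog_network"` with freshly initialized parameters.
#' @export
build_discriminator <- function(input_dim = 9L,
                                hidden_widths = foggan_architecture()$discriminator_widths[-11L],
                                dropout = 0.2) {
  input_dim <- as.integer(input_dim)
  if (length(input_dim) != 1L || is.na(input_dim) || input_dim < 1L)
    stop("'input_dim' must be a single integer >= 1")
  mlp_init(mlp_spec(input_dim, c(hidden_widths, 1L),
                    output_activation = "sigmoid",
                    dropout = c(rep(dropout, length(hidden_widths)), 0)))
}

# Elementwise sum of two gradient sets.
.add_grads <- function(a, b) {
  list(W = Map(`+`, a$W, b$W), b = Map(`+`, a$b, b$b))
}

#' Train one generator/discriminator pair adversarially
#'
#' Alternating minibatch updates of the two-player value function
#' `V(D, G) = E_x[log D(x)] + E_z[log(1 - D(G(z)))]`: each step first
#' ascends the discriminator objective
#' `(1/m) sum_i [log D(x_i) + log(1 - D(G(z_i)))]` on `m` real and `m`
#' generated samples, then updates the generator — descending
#' `(1/m) sum_i log(1 - D(G(z_i)))` in `"literal"` mode, or ascending
#' `(1/m) sum_i log D(G(z_i))` in the default non-saturating mode. Both
#' networks use Adam. Epoch-mean losses are recorded as
#' `loss_d = -(1/m) sum [log D(x) + log(1 - D(G(z)))]` and the
#' corresponding generator objective.
#'
#' @param train a scaled [fog_matrix()] or a plain numeric matrix of
#'   standardized features; labels, if present, are ignored (per-class
#'   conditioning is handled by [foggan()]).
#' @param cfg a [gan_config()].
#' @param noise a [noise_spec()].
#' @param generator_widths,discriminator_widths optional reduced layer
#'   widths; defaults are the reference architecture sized to the feature
#'   dimension.
#' @param dropout discriminator dropout rate.
#' @return a list of class `"gan_fit"` with elements `G`, `D` (trained
#'   `"fog_network"`s) and `history` (data frame with per-epoch `loss_g`,
#'   `loss_d`).
#' @export
train_foggan <- function(train, cfg = gan_config(), noise = noise_spec(),
                         generator_widths = NULL, discriminator_widths = NULL,
                         dropout = 0.2) {
  X <- if (inherits(train, "fog_matrix")) train$X else as.matrix(train)
  if (inherits(train, "fog_matrix") && !train$scaled)
    stop("GAN training expects standardized features; apply the scaler first")
  n <- nrow(X)
  if (n == 0L) stop("empty training set")
  stopifnot(inherits(cfg, "gan_config"), inherits(noise, "noise_spec"))
  if (cfg$batch_size > n) stop("'batch_size' exceeds the number of training rows")
  p <- ncol(X)
  if (is.null(generator_widths)) generator_widths <- c(foggan_architecture()$generator_widths[-11L], p)
  if (is.null(discriminator_widths)) discriminator_widths <- foggan_architecture()$discriminator_widths[-11L]
  if (generator_widths[length(generator_widths)] != p)
    stop("generator output width must equal the feature dimension")
  zdim <- noise$dimension
  m <- cfg$batch_size
  non_sat <- cfg$generator_loss == "non_saturating"

  with_seed(cfg$seed, {
    G <- build_generator(noise, generator_widths)
    D <- build_discriminator(p, discriminator_widths, dropout = dropout)
    optG <- adam_new(G)
    optD <- adam_new(D)
    steps <- n %/% m
    loss_g <- loss_d <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      eg <- ed <- 0
      for (s in seq_len(steps)) {
        idx <- perm[((s - 1L) * m + 1L):(s * m)]
        xr <- X[idx, , drop = FALSE]

        # -- discriminator ascent on m real + m generated samples
        z <- matrix(stats::rnorm(m * zdim), m, zdim)
        fake <- mlp_forward(G, z)
        cr <- mlp_forward_cache(D, xr, training = TRUE)
        cf <- mlp_forward_cache(D, fake, training = TRUE)
        pr <- cr$out
        pf <- cf$out
        grads <- .add_grads(mlp_backprop(D, cr, (pr - 1) / m),
                            mlp_backprop(D, cf, pf / m))
        st <- adam_step(D, grads, optD, cfg$lr_discriminator,
                        beta1 = cfg$adam_beta1)
        D <- st$net; optD <- st$opt
        ed <- ed - (mean(log(pr)) + mean(log(1 - pf)))

        # -- generator step through the (frozen) discriminator
        z <- matrix(stats::rnorm(m * zdim), m, zdim)
        cg <- mlp_forward_cache(G, z)
        cd <- mlp_forward_cache(D, cg$out, training = TRUE)
        pg <- cd$out
        delta_out <- if (non_sat) (pg - 1) / m else -pg / m
        dinput <- mlp_backprop(D, cd, delta_out, input_grad = TRUE)$input
        gg <- mlp_backprop(G, cg, dinput)
        st <- adam_step(G, gg, optG, cfg$lr_generator,
                        beta1 = cfg$adam_beta1)
        G <- st$net; optG <- st$opt
        eg <- eg + if (non_sat) -mean(log(pg)) else mean(log(1 - pg))
      }
      loss_g[epoch] <- eg / steps
      loss_d[epoch] <- ed / steps
      if (!is.finite(loss_g[epoch]) || !is.finite(loss_d[epoch]))
        stop(sprintf("non-finite adversarial loss at epoch %d", epoch))
    }
    structure(list(G = G, D = D,
                   history = data.frame(epoch = seq_len(cfg$epochs),
                                        loss_g = loss_g, loss_d = loss_d)),
              class = "gan_fit")
  })
}

#' Fit per-class GANs to labeled accelerometer data
#'
#' The central fitting function: standardizes the features (fitting the
#' scaler on the supplied data unless it is already scaled), then trains one
#' generator/discriminator pair per label class. Training one unconditional
#' GAN per class is what lets generated samples carry labels — the 9-unit
#' generator output has no label channel, so conditioning is by construction.
#' The returned object samples labeled synthetic data in original units via
#' [simulate()][simulate.foggan()] or [sample_synthetic()].
#'
#' @param data a [fog_matrix()] (typically the training split). If unscaled,
#'   a standardizing scaler is fit on it; if already scaled, its own scaler
#'   state is reused.
#' @param cfg a [gan_config()]; per-class runs get seeds derived from
#'   `cfg$seed`.
#' @param noise a [noise_spec()].
#' @param generator_widths,discriminator_widths optional reduced widths
#'   passed to [train_foggan()]; the defaults are the full reference
#'   architecture.
#' @param dropout discriminator dropout rate.
#' @return an object of class `"foggan"`: per-class `fits` (each a
#'   `"gan_fit"`), the `scaler`, the training `class_mix` (label
#'   prevalences, the default mix of generated data), `cfg` and `noise`.
#' @examples
#' \donttest{
#' dat <- preprocess(make_fixture_dataset(2, 0.2, 4000, seed = 1))
#' fit <- foggan(dat, gan_config(epochs = 3, seed = 1),
#'               generator_widths = c(32, 16, 9),
#'               discriminator_widths = c(32, 16))
#' synth <- simulate(fit, nsim = 500, seed = 2)
#' }
#' @export
foggan <- function(data, cfg = gan_config(), noise = noise_spec(),
                   generator_widths = NULL, discriminator_widths = NULL,
                   dropout = 0.2) {
  stopifnot(inherits(data, "fog_matrix"))
  if (!data$scaled) {
    scaler <- fit_scaler(data)
    data <- apply_scaler(data, scaler)
  } else {
    scaler <- data$scaler_state
  }
  classes <- sort(unique(data$y))
  if (length(classes) == 0L) stop("no training rows")
  fits <- list()
  mix <- numeric(0)
  for (cl in classes) {
    rows <- data$y == cl
    cl_cfg <- cfg
    cl_cfg$seed <- derive_seed(cfg$seed, cl + 1L)
    fits[[as.character(cl)]] <- train_foggan(
      data$X[rows, , drop = FALSE], cl_cfg, noise,
      generator_widths = generator_widths,
      discriminator_widths = discriminator_widths,
      dropout = dropout)
    mix[as.character(cl)] <- mean(rows)
  }
  structure(list(fits = fits, scaler = scaler, class_mix = mix,
                 cfg = cfg, noise = noise,
                 n_train = nrow(data$X)),
            class = "foggan")
}

#' Sample labeled synthetic data from fitted per-class generators
#'
#' Draws latent noise, pushes it through each class's trained generator, and
#' inverts the standardization so the returned features are in original
#' units (milli-g). Label counts follow `class_mix` by largest-remainder
#' rounding so they sum exactly to `n_total`.
#'
#' @param object a fitted [foggan()] model.
#' @param n_total number of rows to generate.
#' @param class_mix named proportions per class (names are label values),
#'   summing to 1; defaults to the training prevalences.
#' @param seed integer seed.
#' @return a [fog_matrix()] in original units with generated labels.
#' @export
sample_synthetic <- function(object, n_total, class_mix = object$class_mix,
                             seed = 1L) {
  stopifnot(inherits(object, "foggan"))
  n_total <- as.integer(n_total)
  if (n_total < 1L) stop("'n_total' must be >= 1")
  if (is.null(names(class_mix))) names(class_mix) <- names(object$fits)
  if (abs(sum(class_mix) - 1) > 1e-8) stop("'class_mix' must sum to 1")
  missing_cl <- setdiff(names(class_mix)[class_mix > 0], names(object$fits))
  if (length(missing_cl))
    stop("no trained generator for class ", paste(missing_cl, collapse = ", "))
  # largest-remainder apportionment of n_total across classes
  raw <- n_total * class_mix
  counts <- floor(raw)
  short <- n_total - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1L
  }
  zdim <- object$noise$dimension
  with_seed(seed, {
    parts_X <- list(); parts_y <- list()
    for (cl in names(class_mix)) {
      k <- counts[[cl]]
      if (k == 0) next
      z <- matrix(stats::rnorm(k * zdim), k, zdim)
      parts_X[[cl]] <- mlp_forward(object$fits[[cl]]$G, z)
      parts_y[[cl]] <- rep(as.integer(cl), k)
    }
    scaled <- fog_matrix(do.call(rbind, parts_X),
                         unlist(parts_y, use.names = FALSE),
                         scaled = TRUE, scaler_state = object$scaler)
    invert_scaler(scaled)
  })
}

#' Simulate method for fitted FoGGAN models
#'
#' @param object a fitted [foggan()] model.
#' @param nsim number of synthetic rows to draw.
#' @param seed integer seed.
#' @param class_mix optional label proportions; defaults to the training
#'   prevalences.
#' @param ... ignored.
#' @return a [fog_matrix()], as from [sample_synthetic()].
#' @export
simulate.foggan <- function(object, nsim = 1L, seed = 1L,
                            class_mix = object$class_mix, ...) {
  sample_synthetic(object, nsim, class_mix = class_mix, seed = seed)
}

#' @export
print.foggan <- function(x, ...) {
  cat("Per-class adversarial generative model (FoGGAN)\n")
  cat(sprintf("  classes: %s (training mix %s)\n",
              paste(names(x$fits), collapse = ", "),
              paste(sprintf("%s=%.3f", names(x$class_mix), x$class_mix),
                    collapse = ", ")))
  g <- x$fits[[1L]]$G$spec
  cat(sprintf("  generator: %d -> %s; discriminator head: logistic\n",
              g$input_dim, paste(g$layer_widths, collapse = " -> ")))
  cat(sprintf("  trained %d epochs on %d rows (batch %d, lr D %.4g / G %.4g)\n",
              x$cfg$epochs, x$n_train, x$cfg$batch_size,
              x$cfg$lr_discriminator, x$cfg$lr_generator))
  invisible(x)
}

#' @export
summary.foggan <- function(object, ...) {
  print(object)
  for (cl in names(object$fits)) {
    h <- object$fits[[cl]]$history
    cat(sprintf("  class %s: final loss_g %.4f, loss_d %.4f (%d epochs)\n",
                cl, h$loss_g[nrow(h)], h$loss_d[nrow(h)], nrow(h)))
    cat(sprintf("    generator parameters: %s; discriminator parameters: %s\n",
                format(count_parameters(object$fits[[cl]]$G), big.mark = ","),
                format(count_parameters(object$fits[[cl]]$D), big.mark = ",")))
  }
  invisible(object)
}

#' Plot adversarial training histories
#'
#' One panel per class: generator and discriminator epoch-mean losses.
#'
#' @param x a fitted [foggan()] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.foggan <- function(x, ...) {
  k <- length(x$fits)
  old <- graphics::par(mfrow = c(1, k))
  on.exit(graphics::par(old))
  for (cl in names(x$fits)) {
    h <- x$fits[[cl]]$history
    graphics::matplot(h$epoch, cbind(h$loss_g, h$loss_d), type = "l",
                      lty = 1, col = c("firebrick", "steelblue"),
                      xlab = "epoch", ylab = "loss",
                      main = paste("class", cl), ...)
    graphics::legend("topright", c("generator", "discriminator"),
                     lty = 1, col = c("firebrick", "steelblue"), bty = "n")
  }
  invisible(x)
}

#' Save / load a fitted FoGGAN model as a JSON checkpoint
#'
#' A single-file container holding every network's spec and parameter
#' arrays, the scaler, the class mix and the training configuration;
#' [load_foggan()] restores an object that samples identically.
#'
#' @param object a fitted [foggan()] model.
#' @param path checkpoint file path (JSON).
#' @return `path` (saver, invisibly) or the restored `"foggan"` (loader).
#' @export
save_foggan <- function(object, path) {
  stopifnot(inherits(object, "foggan"))
  ser_net <- function(net) list(
    spec = unclass(net$spec),
    W = lapply(net$W, function(w) list(dim = dim(w), data = as.numeric(w))),
    b = net$b)
  payload <- list(
    class_mix = as.list(object$class_mix),
    scaler = unclass(object$scaler),
    cfg = unclass(object$cfg),
    noise = unclass(object$noise),
    n_train = object$n_train,
    fits = lapply(object$fits, function(f) list(
      G = ser_net(f$G), D = ser_net(f$D), history = f$history)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_foggan
#' @export
load_foggan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  de_net <- function(x) {
    spec <- mlp_spec(x$spec$input_dim, unlist(x$spec$layer_widths),
                     x$spec$hidden_activation, x$spec$output_activation,
                     unlist(x$spec$dropout))
    W <- lapply(x$W, function(w) {
      d <- unlist(w$dim)
      matrix(unlist(w$data), d[1L], d[2L])
    })
    b <- lapply(x$b, function(v) as.numeric(unlist(v)))
    structure(list(spec = spec, W = W, b = b), class = "fog_network")
  }
  fits <- lapply(p$fits, function(f)
    structure(list(G = de_net(f$G), D = de_net(f$D),
                   history = do.call(rbind, lapply(f$history, as.data.frame))),
              class = "gan_fit"))
  scaler <- structure(list(center = as.numeric(unlist(p$scaler$center)),
                           scale = as.numeric(unlist(p$scaler$scale))),
                      class = "fog_scaler")
  cfg <- gan_config(p$cfg$epochs, p$cfg$batch_size, p$cfg$lr_discriminator,
                    p$cfg$lr_generator, p$cfg$seed, p$cfg$generator_loss,
                    p$cfg$adam_beta1)
  structure(list(fits = fits, scaler = scaler,
                 class_mix = unlist(p$class_mix),
                 cfg = cfg, noise = noise_spec(p$noise$dimension),
                 n_train = p$n_train),
            class = "foggan")
}
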