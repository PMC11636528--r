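#' Build the sparse per-modality network specification
#'
#' Each input variable of each modality block is connected to its own
#' `fan_out` dedicated nodes in the first hidden layer; all first-layer
#' nodes belonging to block b feed block b's single second-layer node; the
#' second-layer nodes (one per block) feed one common output node. There
#' are no connections across blocks before the output layer, so the unequal
#' numbers of features per modality cannot bias one modality against
#' another, and each second-layer activation directly summarizes one
#' modality's contribution. Every node uses the logistic activation.
#'
#' @param layout either a named integer vector (block name -> input count)
#'   or the `layout` data.frame of a [assemble_feature_set()] result.
#' @param fan_out first-layer nodes dedicated to each input (default 10).
#' @return a `network_spec`: list with `blocks`, `widths`, `n_inputs`,
#'   `n_h1`, `n_h2`, `fan_out`, and the structural index maps
#'   `input_of_h1`, `block_of_h1`, `block_of_input` (1-based).
#' @export
build_network <- function(layout, fan_out = 10L) {
  if (is.data.frame(layout)) {
    widths <- stats::setNames(layout$width, layout$block)
  } else {
    widths <- layout
  }
  if (length(widths) < 1) stop("layout must contain at least one block")
  if (any(widths < 1)) stop("every block needs at least one input")
  widths <- vapply(widths, as.integer, integer(1))
  n_inputs <- sum(widths)
  b <- length(widths)
  block_of_input <- rep.int(seq_len(b), widths)
  input_of_h1 <- rep(seq_len(n_inputs), each = fan_out)
  block_of_h1 <- block_of_input[input_of_h1]
  structure(list(blocks = names(widths), widths = widths,
                 n_inputs = n_inputs, n_h1 = n_inputs * fan_out,
                 n_h2 = b, fan_out = as.integer(fan_out),
                 input_of_h1 = input_of_h1, block_of_h1 = block_of_h1,
                 block_of_input = block_of_input),
            class = "network_spec")
}

#' Training hyperparameters
#'
#' Defaults follow the analysis design: 10 000 mini-batch steps of batch
#' size 10 at learning rate 1e-4 with ADAM (decay 0.9/0.999, stabilizer
#' 1e-8), binary cross-entropy loss on a logistic output. One "iteration"
#' is one mini-batch step, drawn uniformly without replacement.
#'
#' @param iterations number of ADAM steps.
#' @param batch_size mini-batch size (must not exceed the training set).
#' @param learning_rate ADAM step size.
#' @param beta1,beta2 ADAM decay parameters.
#' @param adam_eps ADAM stabilizer.
#' @param seed optional integer; if `NULL`, training consumes the current
#'   RNG stream (so an enclosing seed still makes it reproducible).
#' @return a `train_config`.
#' @export
train_config <- function(iterations = 10000L, batch_size = 10L,
                         learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, seed = NULL) {
  stopifnot(iterations >= 1, batch_size >= 1, learning_rate > 0,
            beta1 > 0, beta2 > 0, adam_eps > 0)
  structure(list(iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1,
                 beta2 = beta2, adam_eps = adam_eps, seed = seed),
            class = "train_config")
}

# scaled uniform init per connection group; biases start at zero
init_weights <- function(spec) {
  l1 <- sqrt(6 / (1 + spec$fan_out))
  l2 <- sqrt(6 / (spec$fan_out * spec$widths + 1))[spec$block_of_h1]
  l3 <- sqrt(6 / (spec$n_h2 + 1))
  list(w1 = stats::runif(spec$n_h1, -l1, l1),
       b1 = numeric(spec$n_h1),
       w2 = stats::runif(spec$n_h1, -l2, l2),
       b2 = numeric(spec$n_h2),
       w3 = stats::runif(spec$n_h2, -l3, l3),
       b3 = 0)
}

#' Train the sparse network
#'
#' Runs `cfg$iterations` ADAM steps of binary cross-entropy on mini-batches
#' drawn uniformly without replacement at every step. Only the structurally
#' present connections are stored and optimized; absent connections cannot
#' acquire weight. Deterministic for a given seed.
#'
#' @param spec a `network_spec` from [build_network()].
#' @param x feature matrix (subjects x inputs), column count matching the
#'   spec.
#' @param y binary label vector (0/1).
#' @param cfg a [train_config()].
#' @return `network_weights`: the weight vectors plus the spec and config.
#' @export
train_network <- function(spec, x, y, cfg = train_config()) {
  stopifnot(inherits(spec, "network_spec"), inherits(cfg, "train_config"))
  x <- as.matrix(x)
  if (ncol(x) != spec$n_inputs)
    stop(sprintf("feature width %d does not match spec (%d inputs)",
                 ncol(x), spec$n_inputs))
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  if (length(y) != nrow(x)) stop("labels length must match rows of x")
  run <- function() {
    w0 <- init_weights(spec)
    fit <- .nn_train_cpp(x, as.numeric(y), spec$input_of_h1 - 1L,
                         spec$block_of_h1 - 1L, spec$n_h2, w0$w1, w0$b1,
                         w0$w2, w0$b2, w0$w3, w0$b3, cfg$iterations,
                         cfg$batch_size, cfg$learning_rate, cfg$beta1,
                         cfg$beta2, cfg$adam_eps)
    fit
  }
  w <- if (is.null(cfg$seed)) run() else withr::with_seed(cfg$seed, run())
  structure(c(w, list(spec = spec, cfg = cfg)), class = "network_weights")
}

# activations of every layer; x may be a vector (one subject) or a matrix
nn_forward <- function(weights, x) {
  spec <- weights$spec
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != spec$n_inputs) stop("feature width does not match network")
  .nn_forward_cpp(as.matrix(x), spec$input_of_h1 - 1L,
                  spec$block_of_h1 - 1L, spec$n_h2, weights$w1, weights$b1,
                  weights$w2, weights$b2, weights$w3, weights$b3)
}

nn_loss <- function(weights, x, y) {
  spec <- weights$spec
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  .nn_loss_cpp(as.matrix(x), as.numeric(y), spec$input_of_h1 - 1L,
               spec$block_of_h1 - 1L, spec$n_h2, weights$w1, weights$b1,
               weights$w2, weights$b2, weights$w3, weights$b3)
}

nn_gradients <- function(weights, x, y) {
  spec <- weights$spec
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  .nn_grad_cpp(as.matrix(x), as.numeric(y), spec$input_of_h1 - 1L,
               spec$block_of_h1 - 1L, spec$n_h2, weights$w1, weights$b1,
               weights$w2, weights$b2, weights$w3, weights$b3)
}

#' Predict classes and scores from a trained network
#'
#' The score is the output-node activation; the class is 1 when the score
#' is at least 0.5.
#'
#' @param weights `network_weights` from [train_network()].
#' @param x feature vector or matrix.
#' @return data.frame with `score` and `class`.
#' @export
predict_network <- function(weights, x) {
  fw <- nn_forward(weights, x)
  data.frame(score = fw$a3, class = as.integer(fw$a3 >= 0.5))
}

#' Linear support-vector-machine baseline
#'
#' Soft-margin linear SVM with regularization constant 1, the conventional
#' default for a binary baseline. Features are used as-is (no internal
#' rescaling), matching how the network consumes them.
#'
#' @param x feature matrix.
#' @param y binary labels (0/1).
#' @return an `svm_model` wrapping the fitted [e1071::svm()] object.
#' @export
train_svm_baseline <- function(x, y) {
  if (!all(y %in% c(0, 1))) stop("labels must be binary 0/1")
  fit <- e1071::svm(as.matrix(x), factor(y, levels = c(0, 1)),
                    kernel = "linear", cost = 1, scale = FALSE)
  structure(list(fit = fit), class = "svm_model")
}

#' @rdname train_svm_baseline
#' @param model an `svm_model`.
#' @export
predict_svm <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.integer(as.character(predict(model$fit, as.matrix(x))))
}
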