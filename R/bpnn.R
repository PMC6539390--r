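# Back-propagation neural network regressor: one sigmoid hidden layer and a
# linear output node, trained by gradient descent with momentum on the
# squared-error loss.  This is the quantitative model mapping color
# components to optical density.

#' Training control parameters for [bpnn()]
#'
#' Defaults are the study settings: 10 hidden neurons, learning rate and
#' momentum 0.1, initial weights uniform on \[-0.3, 0.3\], permitted training
#' error 0.01 (on the scaled mean squared error `E = mean(0.5 e^2)`), and at
#' most 1000 training epochs.
#'
#' @param n_hidden number of hidden-layer neurons.
#' @param learning_rate gradient-descent step size.
#' @param momentum classical momentum factor.
#' @param init_weight_scale weights are initialized uniformly on
#'   `[-init_weight_scale, init_weight_scale]`; thresholds start at zero.
#' @param error_goal training stops once the epoch error `E` (mean of
#'   `0.5 e^2` over samples, computed on the min--max scaled target) reaches
#'   this.
#' @param max_epochs maximum number of training epochs.
#' @param update `"online"` (parameters updated after every sample, in data
#'   order) or `"batch"` (one full-data gradient step per epoch).
#' @return a list of class `bpnn_control`.
#' @export
bpnn_control <- function(n_hidden = 10, learning_rate = 0.1, momentum = 0.1,
                         init_weight_scale = 0.3, error_goal = 0.01,
                         max_epochs = 1000, update = c("online", "batch")) {
  if (learning_rate < 0) stop("'learning_rate' must be >= 0")
  if (max_epochs < 1) stop("'max_epochs' must be >= 1")
  if (n_hidden < 1) stop("'n_hidden' must be >= 1")
  structure(list(n_hidden = as.integer(n_hidden),
                 learning_rate = learning_rate, momentum = momentum,
                 init_weight_scale = init_weight_scale,
                 error_goal = error_goal, max_epochs = as.integer(max_epochs),
                 update = match.arg(update)),
            class = "bpnn_control")
}

# Initialize weights uniformly on [-s, s]; thresholds zero.
bpnn_init <- function(n_inputs, control, seed = NULL) {
  s <- control$init_weight_scale
  q <- control$n_hidden
  with_seed(seed, {
    list(W1 = matrix(runif(n_inputs * q, -s, s), n_inputs, q),
         theta = numeric(q),
         W2 = runif(q, -s, s),
         b = 0)
  })
}

# Forward pass in scaled space: H = sigmoid(X W1 - theta), O = H W2 - b.
bpnn_forward <- function(net, X) {
  H <- 1 / (1 + exp(-sweep(X %*% net$W1, 2L, net$theta)))
  drop(H %*% net$W2) - net$b
}

# Loss E = mean(0.5 * (O - y)^2) and its analytic gradient; the reference
# for the compiled training updates and for finite-difference checks.
bpnn_error <- function(net, X, y) {
  mean(0.5 * (bpnn_forward(net, X) - y)^2)
}

bpnn_gradient <- function(net, X, y) {
  N <- nrow(X)
  H <- 1 / (1 + exp(-sweep(X %*% net$W1, 2L, net$theta)))
  O <- drop(H %*% net$W2) - net$b
  dO <- (O - y) / N
  dH <- (dO %*% t(net$W2)) * H * (1 - H)
  list(W1 = crossprod(X, dH),
       theta = -colSums(dH),
       W2 = drop(crossprod(H, dO)),
       b = -sum(dO))
}

scale_minmax <- function(x, lo, rng) {
  sweep(sweep(x, 2L, lo), 2L, rng, "/")
}

#' Fit a back-propagation neural network regressor
#'
#' Trains a single-hidden-layer feed-forward network (sigmoid hidden
#' activation, linear output) by error back-propagation with momentum.
#' Inputs and the target are min--max scaled to \[0, 1\] using training-set
#' ranges (the sigmoid layer saturates on raw gray levels and raw OD spans
#' about four decades); predictions are returned on the original scale.
#'
#' @param x numeric matrix of predictors (samples x features), or a formula.
#' @param ... further arguments passed to methods.
#' @return an object of class `bpnn` with components `net` (weights and
#'   thresholds), `scaling`, `trace` (per-epoch error `E`), `epochs_run`,
#'   `converged`, `fitted.values`, `residuals`, `control`, `seed`.
#' @seealso [bpnn_control()], [predict.bpnn()]
#' @export
#' @examples
#' d <- generate_dataset(n_batches = 2, seed = 1)
#' X <- feature_matrix(d)[, c(9, 24)]
#' fit <- bpnn(X, d$od_measured, seed = 1,
#'             control = bpnn_control(max_epochs = 200))
#' fit
bpnn <- function(x, ...) UseMethod("bpnn")

#' @rdname bpnn
#' @param y numeric response vector (OD units).
#' @param control a [bpnn_control()] object.
#' @param seed integer seed for weight initialization (fit is deterministic
#'   given seed, data and control).
#' @export
bpnn.default <- function(x, y, control = bpnn_control(), seed = NULL, ...) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("'x' and 'y' must be finite")
  x_lo <- apply(x, 2L, min)
  x_rng <- apply(x, 2L, max) - x_lo
  x_rng[x_rng == 0] <- 1
  y_lo <- min(y)
  y_rng <- max(y) - y_lo
  if (y_rng == 0) stop("'y' is constant; nothing to fit")
  Xs <- scale_minmax(x, x_lo, x_rng)
  ys <- (y - y_lo) / y_rng
  net0 <- bpnn_init(ncol(x), control, seed = seed)
  res <- .bpnn_train_cpp(Xs, ys, net0$W1, net0$theta, net0$W2, net0$b,
                         control$learning_rate, control$momentum,
                         control$error_goal, control$max_epochs,
                         control$update == "online")
  if (res$diverged)
    stop(sprintf("training diverged (non-finite error) at epoch %d",
                 res$epochs_run))
  net <- list(W1 = res$W1, theta = res$theta, W2 = res$W2, b = res$b)
  fitted <- as.vector(bpnn_forward(net, Xs)) * y_rng + y_lo
  structure(list(net = net,
                 scaling = list(x_lo = x_lo, x_rng = x_rng,
                                y_lo = y_lo, y_rng = y_rng),
                 trace = res$trace, epochs_run = res$epochs_run,
                 converged = res$converged,
                 fitted.values = fitted, residuals = y - fitted, y = y,
                 feature_names = colnames(x), control = control, seed = seed,
                 call = match.call()),
            class = "bpnn")
}

#' @rdname bpnn
#' @param formula model formula, e.g. `od_measured ~ .`.
#' @param data data.frame holding the variables in the formula.
#' @export
bpnn.formula <- function(formula, data, control = bpnn_control(),
                         seed = NULL, ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  x <- stats::model.matrix(attr(mf, "terms"), mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  fit <- bpnn.default(x, y, control = control, seed = seed)
  fit$terms <- attr(mf, "terms")
  fit$call <- match.call()
  fit
}

#' Predict optical density from a fitted BPNN
#'
#' @param object a [bpnn()] fit.
#' @param newdata matrix or data.frame of predictors; omitted returns fitted
#'   values.
#' @param ... unused.
#' @return numeric vector of predictions in OD units.
#' @export
predict.bpnn <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (!is.null(object$terms) && is.data.frame(newdata)) {
    tt <- stats::delete.response(object$terms)
    x <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  } else {
    x <- as.matrix(newdata)
  }
  if (ncol(x) != nrow(object$net$W1))
    stop(sprintf("newdata has %d feature(s); the network expects %d",
                 ncol(x), nrow(object$net$W1)))
  Xs <- scale_minmax(x, object$scaling$x_lo, object$scaling$x_rng)
  as.vector(bpnn_forward(object$net, Xs)) * object$scaling$y_rng +
    object$scaling$y_lo
}

#' @export
print.bpnn <- function(x, ...) {
  n_in <- nrow(x$net$W1)
  cat(sprintf("Back-propagation network: %d-%d-1 (sigmoid hidden, linear output)\n",
              n_in, length(x$net$theta)))
  cat(sprintf("Trained %d epoch(s); final error E = %.5g (%s)\n",
              x$epochs_run, utils::tail(x$trace, 1L),
              if (x$converged) "converged" else "goal not reached"))
  invisible(x)
}

#' @export
summary.bpnn <- function(object, ...) {
  r <- object$residuals
  out <- list(
    architecture = c(inputs = nrow(object$net$W1),
                     hidden = length(object$net$theta), outputs = 1L),
    epochs_run = object$epochs_run, converged = object$converged,
    final_error = utils::tail(object$trace, 1L),
    train_r2 = r2(object$y, object$fitted.values),
    train_rmse = rmse(object$y, object$fitted.values))
  class(out) <- "summary.bpnn"
  out
}

#' @export
print.summary.bpnn <- function(x, ...) {
  cat(sprintf("BPNN %d-%d-1; %d epoch(s), %s\n", x$architecture[1L],
              x$architecture[2L], x$epochs_run,
              if (x$converged) "converged" else "not converged"))
  cat(sprintf("Training R2 = %.4f, RMSE = %.4f, final E = %.5g\n",
              x$train_r2, x$train_rmse, x$final_error))
  invisible(x)
}

#' @export
coef.bpnn <- function(object, ...) {
  list(input_hidden_weights = object$net$W1,
       hidden_thresholds = object$net$theta,
       hidden_output_weights = object$net$W2,
       output_threshold = object$net$b)
}

#' @export
residuals.bpnn <- function(object, ...) object$residuals

#' @export
fitted.bpnn <- function(object, ...) object$fitted.values

#' Plot the training error trace of a BPNN fit
#'
#' @param x a [bpnn()] fit.
#' @param ... passed to [plot()].
#' @export
plot.bpnn <- function(x, ...) {
  plot(seq_along(x$trace), x$trace, type = "l", log = "y",
       xlab = "epoch", ylab = "training error E", ...)
  abline(h = x$control$error_goal, lty = 2)
  invisible(x)
}

#' Serialize a fitted BPNN to JSON
#'
#' Writes weights, thresholds, scaling parameters and control settings so a
#' model can be reloaded and applied elsewhere.
#'
#' @param object a [bpnn()] fit.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_bpnn <- function(object, path) {
  jsonlite::write_json(
    list(W1 = object$net$W1, theta = object$net$theta, W2 = object$net$W2,
         b = object$net$b, scaling = object$scaling,
         feature_names = object$feature_names,
         control = unclass(object$control), seed = object$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized BPNN model
#'
#' @param path JSON file written by [write_bpnn()].
#' @return a `bpnn` object usable with [predict.bpnn()].
#' @export
read_bpnn <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(net = list(W1 = as.matrix(j$W1), theta = j$theta,
                            W2 = j$W2, b = j$b),
                 scaling = j$scaling, feature_names = j$feature_names,
                 trace = numeric(0), epochs_run = NA_integer_,
                 converged = NA, control = do.call(bpnn_control, j$control),
                 seed = j$seed),
            class = "bpnn")
}
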