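#' MLP training configuration
#'
#' Fixed training regime of the pipeline: learning rate 0.001, momentum 0.90
#' (used by the sgd solver only), and at most 200 training iterations. The
#' architecture fields come from a decoded chromosome: activation function,
#' solver, and the two hidden-layer sizes.
#'
#' @param activation One of `"identity"`, `"logistic"`, `"tanh"`, `"relu"`.
#' @param solver One of `"lbfgs"`, `"sgd"`, `"adam"`.
#' @param h1,h2 Hidden layer sizes (1..50 in the chromosome search space;
#'   any positive integer accepted here).
#' @param learning_rate Step size for sgd/adam. Default 0.001.
#' @param momentum Momentum of the sgd solver. Default 0.90.
#' @param max_iterations Iteration cap. Default 200.
#' @param alpha L2 penalty on the weights. Default 1e-4.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `mlp_train_config`.
#' @export
mlp_train_config <- function(activation = "relu", solver = "adam",
                             h1 = 10L, h2 = 10L,
                             learning_rate = 0.001, momentum = 0.90,
                             max_iterations = 200L, alpha = 1e-4, seed = 1L) {
  activation <- match.arg(activation, activation_names())
  solver <- match.arg(solver, solver_names())
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            max_iterations >= 1, h1 >= 1, h2 >= 1, alpha >= 0)
  structure(list(activation = activation, solver = solver,
                 h1 = as.integer(h1), h2 = as.integer(h2),
                 learning_rate = learning_rate, momentum = momentum,
                 max_iterations = as.integer(max_iterations),
                 alpha = alpha, seed = as.integer(seed)),
            class = "mlp_train_config")
}

#' @rdname mlp_train_config
#' @param genotype An [mlp_genotype()] whose decoded architecture fields
#'   should be combined with the fixed training regime.
#' @param ... Overrides passed to `mlp_train_config()`.
#' @export
mlp_config_from_genotype <- function(genotype, ...) {
  d <- decode_genotype(genotype)
  mlp_train_config(activation = d$activation, solver = d$solver,
                   h1 = d$h1, h2 = d$h2, ...)
}

act_fun <- function(name) {
  switch(name,
         identity = list(f = function(z) z,
                         dfa = function(a) array(1, dim = dim(a))),
         logistic = list(f = function(z) 1 / (1 + exp(-z)),
                         dfa = function(a) a * (1 - a)),
         tanh = list(f = tanh,
                     dfa = function(a) 1 - a^2),
         relu = list(f = function(z) pmax(z, 0),
                     dfa = function(a) (a > 0) * 1))
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_init_params <- function(d, h1, h2, seed) {
  glorot <- function(n_in, n_out) {
    lim <- sqrt(6 / (n_in + n_out))
    matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
  }
  with_seed(derive_seed(seed, "mlp_init"), {
    list(W1 = glorot(d, h1), b1 = numeric(h1),
         W2 = glorot(h1, h2), b2 = numeric(h2),
         W3 = glorot(h2, 1L), b3 = numeric(1L))
  })
}

mlp_flatten <- function(p) {
  c(p$W1, p$b1, p$W2, p$b2, p$W3, p$b3)
}

mlp_unflatten <- function(theta, d, h1, h2) {
  i <- 0L
  take <- function(n) {
    out <- theta[i + seq_len(n)]
    i <<- i + n
    out
  }
  list(W1 = matrix(take(d * h1), d, h1), b1 = take(h1),
       W2 = matrix(take(h1 * h2), h1, h2), b2 = take(h2),
       W3 = matrix(take(h2), h2, 1L), b3 = take(1L))
}

mlp_forward <- function(params, X, act) {
  A1 <- act$f(sweep(X %*% params$W1, 2L, params$b1, "+"))
  A2 <- act$f(sweep(A1 %*% params$W2, 2L, params$b2, "+"))
  p <- sigmoid(drop(A2 %*% params$W3) + params$b3)
  list(A1 = A1, A2 = A2, p = p)
}

# binary cross-entropy + L2 on weights; gradient by backpropagation
mlp_loss_grad <- function(params, X, y, act, alpha, want_grad = TRUE) {
  n <- nrow(X)
  fwd <- mlp_forward(params, X, act)
  p <- pmin(pmax(fwd$p, 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p)) +
    alpha / (2 * n) * (sum(params$W1^2) + sum(params$W2^2) + sum(params$W3^2))
  if (!want_grad) return(list(loss = loss))
  delta3 <- matrix((p - y) / n, ncol = 1L)                     # n x 1
  gW3 <- t(fwd$A2) %*% delta3 + alpha / n * params$W3
  gb3 <- sum(delta3)
  delta2 <- (delta3 %*% t(params$W3)) * act$dfa(fwd$A2)        # n x h2
  gW2 <- t(fwd$A1) %*% delta2 + alpha / n * params$W2
  gb2 <- colSums(delta2)
  delta1 <- (delta2 %*% t(params$W2)) * act$dfa(fwd$A1)        # n x h1
  gW1 <- t(X) %*% delta1 + alpha / n * params$W1
  gb1 <- colSums(delta1)
  list(loss = loss,
       grad = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                   W3 = gW3, b3 = gb3))
}

#' Train a two-hidden-layer perceptron
#'
#' Feedforward binary classifier with hidden layers of sizes `(h1, h2)`, the
#' configured hidden activation, a sigmoid output unit, and binary
#' cross-entropy loss with a small L2 weight penalty. Training is full-batch
#' and capped at `max_iterations`:
#' \describe{
#'   \item{lbfgs}{limited-memory quasi-Newton via [stats::optim()] with the
#'     analytic backpropagation gradient;}
#'   \item{sgd}{gradient descent with classical momentum (the configured
#'     momentum applies only to this solver);}
#'   \item{adam}{adaptive-moment estimation with the standard
#'     (0.9, 0.999, 1e-8) settings.}
#' }
#' Weight initialisation and hence the full fit are deterministic given
#' `config$seed`.
#'
#' @param config An [mlp_train_config()].
#' @param X Numeric predictor matrix without missing values.
#' @param y Binary 0/1 vector; both classes must be present.
#' @return An object of class `trained_mlp` with a [predict][predict.trained_mlp]
#'   method; carries `input_dim`, `iterations` run, a `converged` flag, and
#'   the final `loss`.
#' @export
train_mlp <- function(config, X, y) {
  stopifnot(inherits(config, "mlp_train_config"))
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.integer(y)
  if (nrow(X) != length(y)) stop("X and y lengths differ")
  if (anyNA(X) || any(!is.finite(X))) stop("X must be finite with no missing values")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("train_mlp requires both classes present")

  act <- act_fun(config$activation)
  d <- ncol(X)
  params <- mlp_init_params(d, config$h1, config$h2, config$seed)
  iters <- config$max_iterations
  converged <- FALSE

  if (config$solver == "lbfgs") {
    fn <- function(theta) {
      mlp_loss_grad(mlp_unflatten(theta, d, config$h1, config$h2),
                    X, y, act, config$alpha, want_grad = FALSE)$loss
    }
    gr <- function(theta) {
      mlp_flatten(mlp_loss_grad(mlp_unflatten(theta, d, config$h1, config$h2),
                                X, y, act, config$alpha)$grad)
    }
    fit <- stats::optim(mlp_flatten(params), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = config$max_iterations))
    params <- mlp_unflatten(fit$par, d, config$h1, config$h2)
    final_loss <- fit$value
    iters <- fit$counts[["function"]]
    converged <- fit$convergence == 0L
  } else {
    lr <- config$learning_rate
    state <- NULL
    step <- if (config$solver == "sgd") {
      mom <- config$momentum
      state <- lapply(params, function(w) w * 0)
      function(params, grad, t) {
        state <<- Map(function(v, g) mom * v - lr * g, state, grad)
        Map(`+`, params, state)
      }
    } else { # adam
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      state <- list(m = lapply(params, function(w) w * 0),
                    v = lapply(params, function(w) w * 0))
      function(params, grad, t) {
        state$m <<- Map(function(m, g) b1 * m + (1 - b1) * g, state$m, grad)
        state$v <<- Map(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grad)
        Map(function(w, m, v) {
          mhat <- m / (1 - b1^t)
          vhat <- v / (1 - b2^t)
          w - lr * mhat / (sqrt(vhat) + eps)
        }, params, state$m, state$v)
      }
    }
    final_loss <- NA_real_
    for (t in seq_len(config$max_iterations)) {
      lg <- mlp_loss_grad(params, X, y, act, config$alpha)
      if (!is.finite(lg$loss)) stop("training diverged: non-finite loss at iteration ", t)
      params <- step(params, lg$grad, t)
      final_loss <- lg$loss
    }
  }
  if (!is.finite(final_loss)) stop("training diverged: non-finite final loss")

  structure(list(params = params, config = config, input_dim = d,
                 iterations = iters, converged = converged,
                 loss = final_loss),
            class = "trained_mlp")
}

#' Predict from a trained perceptron
#'
#' @param object A `trained_mlp`.
#' @param newdata Numeric matrix with `input_dim` columns.
#' @param type `"class"` (0/1 labels at the 0.5 probability threshold) or
#'   `"prob"` (positive-class probabilities).
#' @param ... Unused.
#' @return Integer labels or numeric probabilities, one per row.
#' @export
predict.trained_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$input_dim) {
    stop(sprintf("newdata has %d columns; model expects %d",
                 ncol(newdata), object$input_dim))
  }
  p <- mlp_forward(object$params, newdata, act_fun(object$config$activation))$p
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
print.trained_mlp <- function(x, ...) {
  cat(sprintf("trained_mlp: %d inputs -> (%d, %d) hidden [%s] -> 1; solver %s, loss %.4f\n",
              x$input_dim, x$config$h1, x$config$h2, x$config$activation,
              x$config$solver, x$loss))
  invisible(x)
}

#' Cross-validated fitness of an MLP chromosome
#'
#' The GA's objective: decode the chromosome, train the resulting MLP on
#' each training split of a (stratified) k-fold partition under the fixed
#' training regime, and return the mean held-out classification accuracy as
#' a percentage. Deterministic given the fold seed.
#'
#' @param genotype An [mlp_genotype()].
#' @param X Numeric predictor matrix.
#' @param y Binary 0/1 vector.
#' @param cv A [cv_config()].
#' @param mlp_overrides Named list of overrides for [mlp_train_config()]
#'   (e.g. `max_iterations` for a fast mode).
#' @return Mean CV accuracy in \[0, 100\].
#' @export
fitness_of <- function(genotype, X, y, cv = cv_config(), mlp_overrides = list()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  folds <- stratified_folds(y, cv$k, seed = cv$seed, stratified = cv$stratified)
  accs <- vapply(seq_len(cv$k), function(f) {
    tr <- folds != f
    cfg <- do.call(mlp_config_from_genotype,
                   c(list(genotype = genotype,
                          seed = derive_seed(cv$seed, paste0("fold", f))),
                     mlp_overrides))
    fit <- train_mlp(cfg, X[tr, , drop = FALSE], y[tr])
    pred <- predict(fit, X[!tr, , drop = FALSE])
    mean(pred == y[!tr])
  }, numeric(1))
  mean(accs) * 100
}
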