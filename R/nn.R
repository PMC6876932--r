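#' Network architecture genome
#'
#' The hyperparameter chromosome searched by the genetic optimizer: the
#' number of hidden layers and the neuron count of each. Weights are not
#' part of the genome; they are fitted by [train_network()].
#'
#' @param hidden Integer vector of neurons per hidden layer, e.g.
#'   `c(6, 7)` for two hidden layers of 6 and 7 units.
#' @param max_layers,max_neurons Admissible bounds.
#' @return Object of class `architecture_genome`.
#' @export
architecture_genome <- function(hidden, max_layers = 8L,
                                max_neurons = 1024L) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1L || length(hidden) > max_layers) {
    stop("number of hidden layers must lie in 1..", max_layers)
  }
  if (any(is.na(hidden)) || any(hidden < 1L) || any(hidden > max_neurons)) {
    stop("neurons per layer must lie in 1..", max_neurons)
  }
  structure(list(n_hidden_layers = length(hidden),
                 neurons_per_layer = hidden),
            class = "architecture_genome")
}

#' @export
format.architecture_genome <- function(x, ...) {
  paste0("L=", x$n_hidden_layers, " [",
         paste(x$neurons_per_layer, collapse = "-"), "]")
}

#' @export
print.architecture_genome <- function(x, ...) {
  cat("Architecture genome:", format(x), "\n")
  invisible(x)
}

# layer sizes including input (d) and the single logistic output unit
.layer_sizes <- function(genome, d) c(d, genome$neurons_per_layer, 1L)

# flatten/unflatten weights <-> parameter vector for the optimizer
.unflatten <- function(par, sizes) {
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  off <- 0L
  for (l in seq_along(W)) {
    nin <- sizes[l]; nout <- sizes[l + 1L]
    W[[l]] <- matrix(par[off + seq_len(nin * nout)], nin, nout)
    off <- off + nin * nout
    b[[l]] <- par[off + seq_len(nout)]
    off <- off + nout
  }
  list(W = W, b = b)
}

.n_params <- function(sizes) {
  sum(sizes[-length(sizes)] * sizes[-1L] + sizes[-1L])
}

# forward pass: rectified-linear hidden units, logistic output
.forward <- function(wb, X) {
  A <- list(X)
  L <- length(wb$W)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% wb$W[[l]], 2L, wb$b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else stats::plogis(Z)
  }
  A
}

# mean cross-entropy + L2 weight penalty, with analytic gradient
.loss_grad <- function(par, sizes, X, y01, l2) {
  wb <- .unflatten(par, sizes)
  A <- .forward(wb, X)
  L <- length(wb$W)
  n <- nrow(X)
  p <- pmin(pmax(A[[L + 1L]][, 1L], 1e-12), 1 - 1e-12)
  ce <- -mean(y01 * log(p) + (1 - y01) * log(1 - p))
  pen <- 0.5 * l2 * sum(vapply(wb$W, function(w) sum(w^2), 0))

  gW <- vector("list", L)
  gb <- vector("list", L)
  delta <- matrix((p - y01) / n, ncol = 1L)        # dCE/dZ_out
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta) + l2 * wb$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(wb$W[[l]])) * (A[[l]] > 0)
    }
  }
  grad <- numeric(length(par))
  off <- 0L
  for (l in seq_len(L)) {
    grad[off + seq_along(gW[[l]])] <- gW[[l]]
    off <- off + length(gW[[l]])
    grad[off + seq_along(gb[[l]])] <- gb[[l]]
    off <- off + length(gb[[l]])
  }
  list(value = ce + pen, ce = ce, grad = grad)
}

.init_params <- function(sizes, seed) {
  withr::with_seed(seed, {
    par <- numeric(.n_params(sizes))
    off <- 0L
    for (l in seq_len(length(sizes) - 1L)) {
      nin <- sizes[l]; nout <- sizes[l + 1L]
      lim <- sqrt(6 / (nin + nout))                # fan-scaled uniform
      par[off + seq_len(nin * nout)] <- stats::runif(nin * nout, -lim, lim)
      off <- off + nin * nout + nout               # biases stay zero
    }
    par
  })
}

#' Train the feed-forward classifier
#'
#' Fits the network defined by an [architecture_genome()] by minimizing
#' the mean cross-entropy between predicted probabilities and the
#' binary labels, plus a small L2 weight penalty (default `1e-4`) that
#' stabilizes training on the tiny per-fold datasets of
#' leave-one-subject-out validation. Two optimizers are available: a
#' quasi-Newton route (limited-memory BFGS with inverse-Hessian
#' updates, via [stats::optim()]) and a full-batch adaptive-moment
#' (Adam) loop. Both track the best-seen iterate, so the returned loss
#' never exceeds the loss at initialization and never increases with a
#' larger iteration budget. Training is fully deterministic given
#' `(seed, genome, optimizer, data)`.
#'
#' @param X Numeric feature matrix (`n x d`).
#' @param y Binary labels: `"PD"`/`"healthy"`, or a 0/1 / logical
#'   vector (1/`TRUE` = positive class PD).
#' @param genome An [architecture_genome()], or an integer vector of
#'   hidden-layer sizes.
#' @param optimizer `"quasi_newton"` (default) or `"adaptive_moment"`.
#' @param seed Integer seed for weight initialization.
#' @param maxit Iteration budget (default 500).
#' @param l2 L2 penalty coefficient.
#' @param tol Loss-change convergence tolerance (default `1e-6`).
#' @param learning_rate Adam step size.
#' @return Object of class `trained_network` with elements `genome`,
#'   `weights`, `optimizer`, `seed`, `final_loss` (best penalized
#'   objective), `cross_entropy` (data term at the best iterate) and
#'   `initial_loss`.
#' @examples
#' net <- train_network(matrix(c(-2, -1.8, 2, 2.2)), c(0, 0, 1, 1),
#'                      architecture_genome(2), seed = 1)
#' predict(net, matrix(c(-2, 2)))
#' @export
train_network <- function(X, y, genome,
                          optimizer = c("quasi_newton", "adaptive_moment"),
                          seed = 1L, maxit = 500L, l2 = 1e-4,
                          tol = 1e-6, learning_rate = 0.05) {
  optimizer <- match.arg(optimizer)
  if (!inherits(genome, "architecture_genome")) {
    genome <- architecture_genome(genome)
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(X))) stop("X must be finite")
  y01 <- .as_binary(y)
  if (length(y01) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(unique(y01)) < 2L) {
    stop("both classes must be present in the training labels")
  }
  sizes <- .layer_sizes(genome, ncol(X))
  par0 <- .init_params(sizes, seed)

  best <- new.env(parent = emptyenv())
  init <- .loss_grad(par0, sizes, X, y01, l2)
  best$par <- par0
  best$value <- init$value
  best$ce <- init$ce
  track <- function(par, res) {
    if (res$value < best$value) {
      best$par <- par
      best$value <- res$value
      best$ce <- res$ce
    }
  }

  if (optimizer == "quasi_newton") {
    fn <- function(par) {
      res <- .loss_grad(par, sizes, X, y01, l2)
      track(par, res)
      res$value
    }
    gr <- function(par) .loss_grad(par, sizes, X, y01, l2)$grad
    suppressWarnings(stats::optim(
      par0, fn, gr, method = "L-BFGS-B",
      control = list(maxit = maxit, factr = tol / .Machine$double.eps,
                     pgtol = 0)))
  } else {
    m <- numeric(length(par0)); v <- numeric(length(par0))
    par <- par0
    prev <- init$value
    for (t in seq_len(maxit)) {
      res <- .loss_grad(par, sizes, X, y01, l2)
      track(par, res)
      if (t > 1L && abs(prev - res$value) < tol) break
      prev <- res$value
      m <- 0.9 * m + 0.1 * res$grad
      v <- 0.999 * v + 0.001 * res$grad^2
      mhat <- m / (1 - 0.9^t)
      vhat <- v / (1 - 0.999^t)
      par <- par - learning_rate * mhat / (sqrt(vhat) + 1e-8)
    }
    res <- .loss_grad(par, sizes, X, y01, l2)
    track(par, res)
  }

  structure(list(
    genome = genome,
    weights = .unflatten(best$par, sizes),
    par = best$par,
    sizes = sizes,
    optimizer = optimizer,
    seed = as.integer(seed),
    final_loss = best$value,
    cross_entropy = best$ce,
    initial_loss = init$value
  ), class = "trained_network")
}

# map labels to 0/1 with PD (or 1/TRUE) as the positive class
.as_binary <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- setdiff(unique(y), c("PD", "healthy"))
    if (length(bad) > 0L) {
      stop("labels must be PD/healthy, got: ", paste(bad, collapse = ", "))
    }
    as.numeric(y == "PD")
  } else {
    y <- as.numeric(y)
    if (any(!y %in% c(0, 1))) stop("numeric labels must be 0/1")
    y
  }
}

#' Predict with a trained network
#'
#' Returns PD probabilities in (0, 1), or hard labels thresholded at
#' 0.5 with exact ties classified PD (the sensitivity-favoring
#' convention used throughout the package).
#'
#' @param object A `trained_network`.
#' @param newdata Feature matrix with the training dimensionality.
#' @param type `"prob"` (default) or `"label"`.
#' @param ... Unused.
#' @return Numeric probability vector, or character labels.
#' @export
predict.trained_network <- function(object, newdata, type = c("prob", "label"),
                                    ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$sizes[1L]) {
    stop("newdata has ", ncol(X), " columns; network expects ",
         object$sizes[1L])
  }
  A <- .forward(object$weights, X)
  p <- pmin(pmax(A[[length(A)]][, 1L], 1e-12), 1 - 1e-12)
  if (type == "prob") p else ifelse(p >= 0.5, "PD", "healthy")
}

#' @export
print.trained_network <- function(x, ...) {
  cat("Trained feed-forward network", format(x$genome), "\n")
  cat(sprintf("  optimizer: %s, seed %d, final loss %.6g (cross-entropy %.6g)\n",
              x$optimizer, x$seed, x$final_loss, x$cross_entropy))
  invisible(x)
}

#' Serialize / restore a trained network as JSON
#'
#' @param net A `trained_network`.
#' @param path File path.
#' @return `network_to_json()` returns `path` invisibly;
#'   `network_from_json()` a `trained_network`.
#' @export
network_to_json <- function(net, path) {
  jsonlite::write_json(
    list(hidden = net$genome$neurons_per_layer, sizes = net$sizes,
         par = net$par, optimizer = net$optimizer, seed = net$seed,
         final_loss = net$final_loss, cross_entropy = net$cross_entropy,
         initial_loss = net$initial_loss),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname network_to_json
#' @export
network_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sizes <- as.integer(x$sizes)
  structure(list(
    genome = architecture_genome(as.integer(x$hidden)),
    weights = .unflatten(as.numeric(x$par), sizes),
    par = as.numeric(x$par),
    sizes = sizes,
    optimizer = x$optimizer,
    seed = as.integer(x$seed),
    final_loss = as.numeric(x$final_loss),
    cross_entropy = as.numeric(x$cross_entropy),
    initial_loss = as.numeric(x$initial_loss)
  ), class = "trained_network")
}
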