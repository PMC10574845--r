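# Fully-connected feed-forward regression network trained with the Nadam
# optimizer (Nesterov-accelerated Adam) on mean squared error. All layers,
# including the output, use ReLU activations, so predictions are
# non-negative - appropriate for pressures in mmHg.

#' Neural-network configuration
#'
#' The reference architecture has nine hidden layers of
#' 1024/1024/1024/512/512/512/128/64/64 units, ReLU activations
#' throughout, Nadam optimization, batch size 4096, 150 epochs and a 0.2
#' validation split. A desk-scale profile (`scale = "small"`) with layers
#' 64/32 and 20 epochs is provided for testing and examples.
#'
#' @param hidden Integer vector of hidden-layer sizes.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs (no early stopping).
#' @param validation_split Fraction of rows (taken from the end) held out
#'   for the per-epoch validation loss.
#' @param learning_rate Nadam step size.
#' @param scale `"paper"` for the reference architecture, `"small"` for
#'   the desk-scale profile; explicit arguments override either.
#' @return Object of class `nn_config`.
#' @export
nn_config <- function(hidden = NULL, batch_size = NULL, epochs = NULL,
                      validation_split = 0.2, learning_rate = NULL,
                      scale = c("paper", "small")) {
  scale <- match.arg(scale)
  def <- if (scale == "paper") {
    list(hidden = c(1024, 1024, 1024, 512, 512, 512, 128, 64, 64),
         batch_size = 4096, epochs = 150, lr = 2e-3)
  } else {
    list(hidden = c(64, 32), batch_size = 256, epochs = 20, lr = 1e-2)
  }
  if (is.null(learning_rate)) learning_rate <- def$lr
  structure(list(hidden = if (is.null(hidden)) def$hidden else hidden,
                 batch_size = if (is.null(batch_size)) def$batch_size else batch_size,
                 epochs = if (is.null(epochs)) def$epochs else epochs,
                 validation_split = validation_split,
                 learning_rate = learning_rate),
            class = "nn_config")
}

.relu <- function(x) pmax(x, 0)

.nn_init <- function(sizes, y_mean) {
  L <- length(sizes) - 1
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  # bias the output at the target mean so the output ReLU starts active
  b[[L]] <- rep(y_mean, sizes[L + 1])
  list(W = W, b = b)
}

.nn_forward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (l in seq_len(L)) {
    z <- sweep(acts[[l]] %*% net$W[[l]], 2, net$b[[l]], "+")
    acts[[l + 1]] <- .relu(z)
  }
  acts
}

# One Nadam update (Dozat 2016), returning the updated state.
.nadam_step <- function(state, grads, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-7) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    m_hat <- state$m[[nm]] / (1 - beta1^(t + 1))
    v_hat <- state$v[[nm]] / (1 - beta2^t)
    upd <- (beta1 * m_hat + (1 - beta1) * g / (1 - beta1^t)) /
      (sqrt(v_hat) + eps)
    state$par[[nm]] <- state$par[[nm]] - lr * upd
  }
  state
}

# Train the network; X normalized features (matrix), y numeric target.
.nn_train <- function(X, y, config, seed) {
  .with_seed(seed, function() {
    n <- nrow(X)
    n_val <- round(config$validation_split * n)
    idx_val <- if (n_val > 0) (n - n_val + 1):n else integer(0)
    idx_tr <- setdiff(seq_len(n), idx_val)
    Xt <- X[idx_tr, , drop = FALSE]
    yt <- y[idx_tr]
    sizes <- c(ncol(X), config$hidden, 1)
    net <- .nn_init(sizes, mean(yt))
    L <- length(net$W)
    par <- c(stats::setNames(net$W, paste0("W", seq_len(L))),
             stats::setNames(net$b, paste0("b", seq_len(L))))
    state <- list(par = par,
                  m = lapply(par, function(p) p * 0),
                  v = lapply(par, function(p) p * 0))
    t_step <- 0
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_loss = numeric(0))
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(yt))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      for (bt in batches) {
        net_now <- list(W = state$par[paste0("W", seq_len(L))],
                        b = state$par[paste0("b", seq_len(L))])
        acts <- .nn_forward(net_now, Xt[bt, , drop = FALSE])
        pred <- acts[[L + 1]][, 1]
        m_b <- length(bt)
        delta <- matrix(2 * (pred - yt[bt]) / m_b, ncol = 1)
        delta <- delta * (acts[[L + 1]] > 0)      # output ReLU gradient
        grads <- list()
        for (l in L:1) {
          grads[[paste0("W", l)]] <- t(acts[[l]]) %*% delta
          grads[[paste0("b", l)]] <- colSums(delta)
          if (l > 1) {
            delta <- (delta %*% t(net_now$W[[l]])) * (acts[[l]] > 0)
          }
        }
        t_step <- t_step + 1
        state <- .nadam_step(state, grads, config$learning_rate, t_step)
      }
      net_now <- list(W = state$par[paste0("W", seq_len(L))],
                      b = state$par[paste0("b", seq_len(L))])
      tr_pred <- .nn_forward(net_now, Xt)[[L + 1]][, 1]
      loss <- mean((tr_pred - yt)^2)
      val_loss <- if (n_val > 0) {
        vp <- .nn_forward(net_now, X[idx_val, , drop = FALSE])[[L + 1]][, 1]
        mean((vp - y[idx_val])^2)
      } else NA_real_
      history <- rbind(history, data.frame(epoch = epoch, loss = loss,
                                           val_loss = val_loss))
    }
    list(net = list(W = state$par[paste0("W", seq_len(L))],
                    b = state$par[paste0("b", seq_len(L))]),
         history = history, n_validation = length(idx_val))
  })
}

.nn_predict <- function(net, X) {
  acts <- .nn_forward(net, X)
  acts[[length(acts)]][, 1]
}
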