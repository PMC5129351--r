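#' Hidden-layer size rule
#'
#' The conventional single-hidden-layer sizing rule
#' \code{a = (attribs + classes) / 2}, floored, with a minimum of one unit.
#'
#' @param attribs number of input attributes.
#' @param classes number of classes.
#' @return Positive integer hidden-unit count.
#' @examples
#' hidden_units(8, 2)  # 5
#' @export
hidden_units <- function(attribs, classes) {
  if (attribs < 1 || classes < 1) stop("attribs and classes must be >= 1")
  max(1L, as.integer(floor((attribs + classes) / 2)))
}

#' Control parameters for the MLP baseline
#'
#' Defaults mirror the conventional desktop data-mining settings the
#' baseline emulates: learning rate 0.3, momentum 0.2, up to 500 training
#' epochs, early stopping after 20 epochs without validation improvement
#' on a 20\% validation split.
#'
#' @param hidden hidden units; NULL means the [hidden_units()] rule.
#' @param epochs maximum training epochs (default 500).
#' @param patience consecutive non-improving validation epochs tolerated
#'   before stopping (default 20; must be <= epochs when epochs > 0).
#' @param lr learning rate for online gradient descent.
#' @param momentum momentum coefficient.
#' @param val_frac fraction of training rows held out for validation-based
#'   early stopping, in (0, 1).
#' @param seed optional integer seed (weight init, validation split,
#'   per-epoch shuffling).
#' @return List of class \code{"mlp_control"}.
#' @export
mlp_control <- function(hidden = NULL, epochs = 500, patience = 20,
                        lr = 0.3, momentum = 0.2, val_frac = 0.2,
                        seed = NULL) {
  if (epochs > 0 && patience > epochs) stop("patience must be <= epochs")
  if (val_frac <= 0 || val_frac >= 1) stop("val_frac must lie in (0, 1)")
  if (lr <= 0 || momentum < 0) stop("lr must be > 0 and momentum >= 0")
  structure(list(hidden = hidden, epochs = epochs, patience = patience,
                 lr = lr, momentum = momentum, val_frac = val_frac,
                 seed = seed),
            class = "mlp_control")
}

.sigmoid <- function(z) 1 / (1 + exp(-pmin(pmax(z, -500), 500)))

# forward pass for one standardized input vector; returns hidden activations
# and output probability of class 1
.mlp_forward <- function(w, x) {
  hz <- drop(w$W1 %*% x) + w$b1
  h <- .sigmoid(hz)
  o <- .sigmoid(sum(w$W2 * h) + w$b2)
  list(h = h, o = o)
}

#' Fit the single-hidden-layer perceptron baseline
#'
#' One hidden layer of sigmoid units and a sigmoid output, trained by
#' online (per-pattern) backpropagation with momentum on z-scored
#' descriptors. A random validation split drives early stopping: training
#' halts once the validation error has failed to improve for
#' \code{patience} consecutive epochs, and the best-validation weights are
#' restored. With \code{epochs = 0} the model falls back to the
#' majority-class prior. Fully reproducible given \code{control$seed}.
#'
#' @param formula model formula with a binary 0/1 response, e.g.
#'   \code{label ~ .}.
#' @param data data frame with the response and numeric descriptors.
#' @param control an [mlp_control()].
#' @return Object of class \code{"gep_mlp"} with weights, standardization
#'   constants, schema, training trace and call.
#' @seealso [predict.gep_mlp()], [margins()]
#' @export
mlp <- function(formula, data, control = mlp_control()) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  if (length(unique(y)) < 2) stop("both classes must be represented")
  X <- as.matrix(mf[-1])
  if (!is.numeric(X)) stop("all descriptors must be numeric")
  mu <- colMeans(X); sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  n <- nrow(Z); p <- ncol(Z)
  H <- if (is.null(control$hidden)) hidden_units(p, 2L) else control$hidden
  if (!is.null(control$seed)) set.seed(control$seed)

  prior <- mean(y)
  w <- list(W1 = matrix(0, H, p), b1 = rep(0, H),
            W2 = rep(0, H), b2 = stats::qlogis(min(max(prior, 1e-6), 1 - 1e-6)))
  trace <- data.frame(epoch = integer(0), train_mse = numeric(0),
                      val_mse = numeric(0))
  stopped_at <- 0L
  if (control$epochs > 0) {
    n_val <- max(1L, round(control$val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (length(unique(y[tr_idx])) < 2) {
      # degenerate split; fall back to training on everything and
      # validating on the same rows
      tr_idx <- seq_len(n); val_idx <- seq_len(n)
    }
    w <- list(W1 = matrix(stats::runif(H * p, -0.5, 0.5), H, p),
              b1 = stats::runif(H, -0.5, 0.5),
              W2 = stats::runif(H, -0.5, 0.5),
              b2 = stats::runif(1, -0.5, 0.5))
    v <- list(W1 = w$W1 * 0, b1 = w$b1 * 0, W2 = w$W2 * 0, b2 = 0)
    mse <- function(idx) {
      pr <- .mlp_probs(w, Z[idx, , drop = FALSE])
      mean((pr - y[idx])^2)
    }
    best_val <- Inf; best_w <- w; bad <- 0L
    for (epoch in seq_len(control$epochs)) {
      for (i in sample(tr_idx)) {
        x <- Z[i, ]
        fw <- .mlp_forward(w, x)
        # squared-error deltas through the sigmoids
        d_o <- (fw$o - y[i]) * fw$o * (1 - fw$o)
        d_h <- d_o * w$W2 * fw$h * (1 - fw$h)
        v$W2 <- control$momentum * v$W2 - control$lr * d_o * fw$h
        v$b2 <- control$momentum * v$b2 - control$lr * d_o
        v$W1 <- control$momentum * v$W1 - control$lr * outer(d_h, x)
        v$b1 <- control$momentum * v$b1 - control$lr * d_h
        w$W2 <- w$W2 + v$W2; w$b2 <- w$b2 + v$b2
        w$W1 <- w$W1 + v$W1; w$b1 <- w$b1 + v$b1
      }
      tm <- mse(tr_idx); vm <- mse(val_idx)
      trace <- rbind(trace, data.frame(epoch = epoch, train_mse = tm,
                                       val_mse = vm))
      if (vm < best_val - 1e-12) {
        best_val <- vm; best_w <- w; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= control$patience) break
      }
    }
    stopped_at <- nrow(trace)
    w <- best_w
  }
  structure(
    list(weights = w, center = mu, scale = sdv, schema = colnames(X),
         hidden = H, control = control, trace = trace,
         epochs_run = stopped_at, prior = prior, terms = stats::terms(mf),
         call = cl),
    class = "gep_mlp")
}

.mlp_probs <- function(w, Z) {
  Hz <- Z %*% t(w$W1)
  Hs <- .sigmoid(sweep(Hz, 2, w$b1, "+"))
  drop(.sigmoid(Hs %*% w$W2 + w$b2))
}

#' Predict from the MLP baseline
#'
#' @param object a fitted [mlp()] model.
#' @param newdata data frame with the model's descriptor columns.
#' @param type \code{"prob"} for a two-column probability matrix (columns
#'   \code{"0"} and \code{"1"}, rows summing to 1) or \code{"class"} for
#'   0/1 labels (1 iff p(1) > 0.5).
#' @param ... unused.
#' @export
predict.gep_mlp <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  miss <- setdiff(object$schema, names(newdata))
  if (length(miss))
    stop("newdata is missing descriptor column(s): ",
         paste(miss, collapse = ", "))
  X <- as.matrix(newdata[object$schema])
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  p1 <- .mlp_probs(object$weights, Z)
  if (type == "prob")
    cbind("0" = 1 - p1, "1" = p1)
  else
    as.integer(p1 > 0.5)
}

#' @export
print.gep_mlp <- function(x, ...) {
  cat("Single-hidden-layer perceptron baseline\n")
  cat(sprintf("  architecture: %d -> %d sigmoid -> 1 sigmoid\n",
              length(x$schema), x$hidden))
  cat(sprintf("  training:     %d epochs run (budget %d, patience %d)\n",
              x$epochs_run, x$control$epochs, x$control$patience))
  invisible(x)
}

#' @export
summary.gep_mlp <- function(object, ...) {
  print(object)
  if (nrow(object$trace)) {
    tr <- object$trace
    cat(sprintf("  final train MSE %.4f, best validation MSE %.4f\n",
                tr$train_mse[nrow(tr)], min(tr$val_mse)))
  }
  invisible(object)
}

#' Per-compound classification margins
#'
#' Margin = probability of the actual class minus the maximum probability
#' of any wrong class (for a binary model, \code{2 p(actual) - 1}). Values
#' near 1 indicate confident correct predictions; negative values mark
#' misclassified compounds.
#'
#' @param object a fitted [mlp()] model.
#' @param data labelled descriptor data frame.
#' @param label_col label column name.
#' @return Data frame with columns \code{index} and \code{margin}.
#' @export
margins <- function(object, data, label_col = "label") {
  y <- data[[label_col]]
  if (is.null(y)) stop("label column '", label_col, "' not found")
  pr <- predict(object, data, type = "prob")
  p_actual <- ifelse(y == 1, pr[, "1"], pr[, "0"])
  p_wrong <- ifelse(y == 1, pr[, "0"], pr[, "1"])
  data.frame(index = seq_along(y),
             margin = margin_score(p_actual, p_wrong))
}

#' Plot MLP margins compound by compound
#'
#' @param x a fitted [mlp()] model.
#' @param data labelled descriptor data frame.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gep_mlp <- function(x, data, ...) {
  m <- margins(x, data)
  graphics::plot(m$margin, m$index, xlim = c(-1, 1),
                 xlab = "margin", ylab = "compound",
                 main = "Classification margins", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
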