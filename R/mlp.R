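## Single-hidden-layer perceptron trained with Adam on raw (standardized)
## window values: 128 sigmoid hidden units, 2-unit softmax output,
## cross-entropy loss. Written in base R matrix algebra; the Adam update and
## the backward pass are derived by hand and gradient-checked in the test
## suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_init <- function(d, hidden, seed) {
  with_seed(seed, list(
    W1 = matrix(stats::rnorm(d * hidden, 0, sqrt(2 / (d + hidden))), d, hidden),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(hidden * 2, 0, sqrt(2 / (hidden + 2))), hidden, 2),
    b2 = numeric(2)))
}

mlp_forward <- function(par, x) {
  h <- sigmoid(sweep(x %*% par$W1, 2, par$b1, `+`))
  p <- softmax_rows(sweep(h %*% par$W2, 2, par$b2, `+`))
  list(h = h, p = p)
}

## Mean cross-entropy gradient; y is a 0/1 vector.
mlp_backward <- function(par, x, y, fw) {
  n <- nrow(x)
  t2 <- cbind(1 - y, y)                      # one-hot targets
  dz2 <- (fw$p - t2) / n
  dW2 <- crossprod(fw$h, dz2)
  db2 <- colSums(dz2)
  dh <- dz2 %*% t(par$W2)
  dz1 <- dh * fw$h * (1 - fw$h)
  list(W1 = crossprod(x, dz1), b1 = colSums(dz1), W2 = dW2, b2 = db2)
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(par)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grad[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, state = st)
}

mlp_train <- function(x, y, lr, batch, epochs, hidden, seed) {
  par <- mlp_init(ncol(x), hidden, child_seed(seed, 1))
  st <- adam_state(par)
  n <- nrow(x)
  with_seed(child_seed(seed, 2), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (i0 in seq(1, n, by = batch)) {
        i <- ord[i0:min(i0 + batch - 1L, n)]
        fw <- mlp_forward(par, x[i, , drop = FALSE])
        gr <- mlp_backward(par, x[i, , drop = FALSE], y[i], fw)
        up <- adam_step(par, gr, st, lr)
        par <- up$par; st <- up$state
      }
    }
  })
  par
}

## Best (window threshold, person threshold, person accuracy) for a vector of
## validation scores: enumerates window thresholds in {0.01..0.99}; the
## person threshold for each is chosen by the grid rule.
best_thresholds <- function(scores, person_id, group) {
  taus <- threshold_grid_candidates()
  ids <- unique(person_id)
  truth <- as.integer(group[match(ids, person_id)] == "treatment")
  ## ratios[i, j]: positive-window ratio of person i at window threshold j
  pos <- outer(scores, taus, `>=`)
  ratios <- rowsum(pos + 0, person_id)[ids, , drop = FALSE] /
    as.vector(table(person_id)[ids])
  best <- NULL
  for (j in seq_along(taus)) {
    t_p <- rr_threshold_grid(ratios[, j], truth)
    acc <- mean(as.integer(ratios[, j] > t_p) == truth)
    better <- is.null(best) || acc > best$acc ||
      (acc == best$acc && abs(taus[j] - 0.5) < abs(best$tau - 0.5))
    if (better) best <- list(tau = taus[j], t_person = t_p, acc = acc)
  }
  best
}

fit_mlp <- function(train, validation, spec, seed) {
  lr_grid <- spec$lr_grid %||% c(1e-3, 1e-4, 1e-5)
  batch_grid <- spec$batch_grid %||% c(256L, 512L, 1024L)
  epochs <- spec$epochs %||% 100L
  hidden <- spec$hidden %||% 128L

  mu <- colMeans(train$values)
  sdv <- apply(train$values, 2, stats::sd)
  sdv[sdv == 0] <- 1
  std <- function(m) sweep(sweep(m, 2, mu, `-`), 2, sdv, `/`)
  xtr <- std(train$values)
  xval <- std(validation$values)

  best <- NULL
  cell <- 0L
  for (lr in lr_grid) for (batch in batch_grid) {
    cell <- cell + 1L
    par <- mlp_train(xtr, train$label, lr, batch, epochs, hidden,
                     child_seed(seed, cell))
    scores <- mlp_forward(par, xval)$p[, 2]
    th <- best_thresholds(scores, validation$person_id, validation$group)
    if (is.null(best) || th$acc > best$acc)
      best <- list(par = par, lr = lr, batch = batch, tau = th$tau,
                   t_person = th$t_person, acc = th$acc)
  }

  fit <- list(par = best$par, mu = mu, sd = sdv,
              window_threshold = best$tau,
              person_threshold = best$t_person,
              person_rule = "grid",
              meta = list(learning_rate = best$lr, batch_size = best$batch,
                          window_threshold = best$tau, hidden = hidden,
                          epochs = epochs))
  class(fit) <- c("rr_mlp", "rr_classifier")
  fit$w <- train$w
  fit
}

#' @export
predict_windows.rr_mlp <- function(object, windows, type) {
  x <- sweep(sweep(windows$values, 2, object$mu, `-`), 2, object$sd, `/`)
  p <- mlp_forward(object$par, x)$p[, 2]
  if (type == "label") as.integer(p >= object$window_threshold) else p
}
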