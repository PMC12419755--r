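## GRU + FCN hybrid for univariate window classification, implemented in
## base R matrix algebra with hand-derived backpropagation (gradient-checked
## in the test suite).
##
## Two independent paths over a standardized window of length T:
##   * GRU path: 1-2 GRU layers (uni- or bidirectional), final hidden state,
##     inverted dropout;
##   * FCN path: three 1-D convolution blocks (128/256/128 kernels, sizes
##     7/5/3, "same" padding), each followed by batch normalization and
##     ReLU, then global average pooling over time.
## The two path outputs are concatenated into a fully connected softmax
## layer; training uses Adam with cross-entropy loss, a maximum of 30
## epochs, early stopping on validation loss (patience 10) and a
## learning-rate scheduler dividing the rate by 10 after 5 stagnant epochs.
##
## Internal tensor layout: a (B x T x C) activation is stored as a
## (B*T) x C matrix whose row (t - 1) * B + b holds position t of series b;
## time shifts are then whole-block row shifts, which keeps im2col cheap.

#' Default GRU+FCN training configuration
#'
#' Default configurations depend on the window length: for `w = 60`,
#' learning rate 1e-4, batch size 128, hidden state 100, single
#' unidirectional GRU layer with dropout 0.8; for `w = 300`, learning rate
#' 1e-3, batch size 64, hidden state 200 (other settings shared).
#'
#' @param w Window length.
#' @return Named list of configuration values (can be passed as the `spec`
#'   of [rr_classifier()] with entries overridden).
#' @export
rr_grufcn_config <- function(w) {
  cfg <- list(lr = 1e-4, batch = 128L, hidden = 100L, layers = 1L,
              bidirectional = FALSE, dropout = 0.8, epochs = 30L,
              patience_es = 10L, patience_lr = 5L,
              conv_channels = c(128L, 256L, 128L), kernels = c(7L, 5L, 3L))
  if (w >= 300) {
    cfg$lr <- 1e-3; cfg$batch <- 64L; cfg$hidden <- 200L
  }
  cfg
}

## ---- (B*T) x C block helpers -------------------------------------------

## Shift a (B*T) x C activation by `d` time steps (rows move by d*B), zero
## padding the vacated block.
shift_time <- function(a, d, B, T) {
  out <- matrix(0, nrow(a), ncol(a))
  if (d == 0) return(a)
  if (d > 0 && d < T) {
    out[seq_len((T - d) * B), ] <- a[(d * B + 1):(T * B), , drop = FALSE]
  } else if (d < 0 && -d < T) {
    out[((-d) * B + 1):(T * B), ] <- a[seq_len((T + d) * B), , drop = FALSE]
  }
  out
}

## im2col for "same"-padded 1-D convolution: columns are k blocks of C.
im2col <- function(a, k, B, T) {
  pl <- (k - 1L) %/% 2L
  do.call(cbind, lapply(seq_len(k) - 1L - pl, function(d)
    shift_time(a, d, B, T)))
}

## Scatter-add the im2col gradient back onto the input activation.
im2col_backward <- function(dcols, k, C, B, T) {
  pl <- (k - 1L) %/% 2L
  da <- matrix(0, B * T, C)
  for (j in seq_len(k)) {
    d <- j - 1L - pl
    block <- dcols[, ((j - 1L) * C + 1L):(j * C), drop = FALSE]
    da <- da + shift_time(block, -d, B, T)
  }
  da
}

## ---- batch normalization ------------------------------------------------

bn_forward <- function(x, gamma, beta, run, training, momentum = 0.1,
                       eps = 1e-5) {
  if (training) {
    mu <- colMeans(x)
    va <- colMeans(sweep(x, 2, mu, `-`)^2)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * va
  } else {
    mu <- run$mean; va <- run$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(x, 2, mu, `-`), 2, inv, `*`)
  out <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma),
       run = run)
}

bn_backward <- function(dout, cache) {
  n <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  dxhat <- sweep(dout, 2, cache$gamma, `*`)
  dx <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dout), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), n, ncol(dout),
                              byrow = TRUE),
              2, cache$inv, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

## ---- GRU layer ----------------------------------------------------------

gru_param_names <- c("Wir", "Wiz", "Win", "Whr", "Whz", "Whn",
                     "bir", "biz", "bin", "bhr", "bhz", "bhn")

gru_init <- function(din, H) {
  s <- 1 / sqrt(H)
  p <- list()
  for (nm in c("Wir", "Wiz", "Win"))
    p[[nm]] <- matrix(stats::runif(din * H, -s, s), din, H)
  for (nm in c("Whr", "Whz", "Whn"))
    p[[nm]] <- matrix(stats::runif(H * H, -s, s), H, H)
  for (nm in c("bir", "biz", "bin", "bhr", "bhz", "bhn"))
    p[[nm]] <- stats::runif(H, -s, s)
  p
}

## x_seq: list of T matrices (B x din). Returns full hidden sequence.
gru_layer_forward <- function(p, x_seq, H) {
  B <- nrow(x_seq[[1]])
  h <- matrix(0, B, H)
  T <- length(x_seq)
  h_seq <- vector("list", T)
  cache <- vector("list", T)
  for (t in seq_len(T)) {
    x <- x_seq[[t]]
    r <- sigmoid(sweep(x %*% p$Wir + h %*% p$Whr, 2, p$bir + p$bhr, `+`))
    z <- sigmoid(sweep(x %*% p$Wiz + h %*% p$Whz, 2, p$biz + p$bhz, `+`))
    hn_lin <- sweep(h %*% p$Whn, 2, p$bhn, `+`)
    n <- tanh(sweep(x %*% p$Win, 2, p$bin, `+`) + r * hn_lin)
    h_new <- (1 - z) * n + z * h
    cache[[t]] <- list(x = x, h_prev = h, r = r, z = z, n = n,
                       hn_lin = hn_lin)
    h <- h_new
    h_seq[[t]] <- h
  }
  list(h_seq = h_seq, cache = cache)
}

## dh_seq: list of T gradients (B x H), possibly mostly zero. Returns
## parameter gradients and dx_seq.
gru_layer_backward <- function(p, cache, dh_seq) {
  T <- length(cache)
  grads <- lapply(p, function(m) m * 0)
  dx_seq <- vector("list", T)
  dh <- dh_seq[[T]] * 0
  for (t in rev(seq_len(T))) {
    ca <- cache[[t]]
    dh <- dh + dh_seq[[t]]
    dz <- dh * (ca$h_prev - ca$n) * ca$z * (1 - ca$z)
    dn <- dh * (1 - ca$z) * (1 - ca$n^2)
    dh_prev <- dh * ca$z
    dr <- dn * ca$hn_lin * ca$r * (1 - ca$r)
    dhn_lin <- dn * ca$r
    grads$Win <- grads$Win + crossprod(ca$x, dn)
    grads$bin <- grads$bin + colSums(dn)
    grads$Whn <- grads$Whn + crossprod(ca$h_prev, dhn_lin)
    grads$bhn <- grads$bhn + colSums(dhn_lin)
    dh_prev <- dh_prev + dhn_lin %*% t(p$Whn)
    grads$Wir <- grads$Wir + crossprod(ca$x, dr)
    grads$bir <- grads$bir + colSums(dr)
    grads$bhr <- grads$bhr + colSums(dr)
    grads$Whr <- grads$Whr + crossprod(ca$h_prev, dr)
    dh_prev <- dh_prev + dr %*% t(p$Whr)
    grads$Wiz <- grads$Wiz + crossprod(ca$x, dz)
    grads$biz <- grads$biz + colSums(dz)
    grads$bhz <- grads$bhz + colSums(dz)
    grads$Whz <- grads$Whz + crossprod(ca$h_prev, dz)
    dh_prev <- dh_prev + dz %*% t(p$Whz)
    dx_seq[[t]] <- dr %*% t(p$Wir) + dz %*% t(p$Wiz) + dn %*% t(p$Win)
    dh <- dh_prev
  }
  list(grads = grads, dx_seq = dx_seq)
}

## ---- full network -------------------------------------------------------

grufcn_init <- function(T, cfg, seed) {
  with_seed(seed, {
    par <- list()
    dirs <- if (cfg$bidirectional) c("fw", "bw") else "fw"
    din <- 1L
    for (l in seq_len(cfg$layers)) {
      for (d in dirs) {
        gp <- gru_init(din, cfg$hidden)
        for (nm in names(gp)) par[[paste0("gru", l, d, "_", nm)]] <- gp[[nm]]
      }
      din <- cfg$hidden * length(dirs)
    }
    cin <- 1L
    for (i in 1:3) {
      k <- cfg$kernels[i]; cout <- cfg$conv_channels[i]
      fan <- k * cin + cout
      par[[paste0("conv", i, "_W")]] <-
        matrix(stats::rnorm(k * cin * cout, 0, sqrt(2 / fan)), k * cin, cout)
      par[[paste0("conv", i, "_b")]] <- numeric(cout)
      par[[paste0("bn", i, "_gamma")]] <- rep(1, cout)
      par[[paste0("bn", i, "_beta")]] <- numeric(cout)
      cin <- cout
    }
    gdim <- cfg$hidden * length(dirs)
    zdim <- gdim + cfg$conv_channels[3]
    par$out_W <- matrix(stats::rnorm(zdim * 2, 0, sqrt(2 / (zdim + 2))),
                        zdim, 2)
    par$out_b <- numeric(2)
    par
  })
}

grufcn_run_init <- function(cfg) {
  run <- list()
  for (i in 1:3)
    run[[paste0("bn", i)]] <- list(mean = numeric(cfg$conv_channels[i]),
                                   var = rep(1, cfg$conv_channels[i]))
  run
}

## Forward pass. x: B x T standardized windows. Returns probabilities plus
## caches for the backward pass; `run` carries BN running statistics.
grufcn_forward <- function(par, run, x, cfg, training = FALSE,
                           drop_mask = NULL) {
  B <- nrow(x); T <- ncol(x)
  dirs <- if (cfg$bidirectional) c("fw", "bw") else "fw"

  ## GRU path
  x_seq <- lapply(seq_len(T), function(t) x[, t, drop = FALSE])
  layer_in <- x_seq
  gru_caches <- list()
  for (l in seq_len(cfg$layers)) {
    outs <- list()
    for (d in dirs) {
      p <- par[paste0("gru", l, d, "_", gru_param_names)]
      names(p) <- gru_param_names
      seq_in <- if (d == "fw") layer_in else rev(layer_in)
      fw <- gru_layer_forward(p, seq_in, cfg$hidden)
      gru_caches[[paste0(l, d)]] <- fw$cache
      outs[[d]] <- if (d == "fw") fw$h_seq else rev(fw$h_seq)
    }
    layer_in <- lapply(seq_len(T), function(t)
      do.call(cbind, lapply(dirs, function(d) outs[[d]][[t]])))
  }
  ## final state: forward direction at t = T, backward direction at t = 1
  g <- do.call(cbind, lapply(dirs, function(d) {
    t_final <- if (d == "fw") T else 1L
    cols <- if (d == "fw") seq_len(cfg$hidden)
            else cfg$hidden + seq_len(cfg$hidden)
    if (length(dirs) == 1) layer_in[[t_final]]
    else layer_in[[t_final]][, cols, drop = FALSE]
  }))
  if (training && cfg$dropout > 0) {
    if (is.null(drop_mask))
      drop_mask <- matrix(stats::rbinom(length(g), 1, 1 - cfg$dropout) /
                            (1 - cfg$dropout), nrow(g), ncol(g))
    g_drop <- g * drop_mask
  } else {
    drop_mask <- NULL
    g_drop <- g
  }

  ## FCN path
  a <- matrix(as.vector(x), B * T, 1)   # (t-1)*B + b layout: as.vector of B x T
  conv_caches <- list()
  cin <- 1L
  for (i in 1:3) {
    k <- cfg$kernels[i]
    cols <- im2col(a, k, B, T)
    lin <- sweep(cols %*% par[[paste0("conv", i, "_W")]], 2,
                 par[[paste0("conv", i, "_b")]], `+`)
    bn <- bn_forward(lin, par[[paste0("bn", i, "_gamma")]],
                     par[[paste0("bn", i, "_beta")]],
                     run[[paste0("bn", i)]], training)
    run[[paste0("bn", i)]] <- bn$run
    relu <- pmax(bn$out, 0)
    conv_caches[[i]] <- list(cols = cols, bn = bn$cache, pre_relu = bn$out,
                             cin = cin, k = k)
    a <- relu
    cin <- cfg$conv_channels[i]
  }
  ## global average pooling over time
  f <- matrix(0, B, ncol(a))
  for (t in seq_len(T)) f <- f + a[((t - 1) * B + 1):(t * B), , drop = FALSE]
  f <- f / T

  z <- cbind(g_drop, f)
  logits <- sweep(z %*% par$out_W, 2, par$out_b, `+`)
  p <- softmax_rows(logits)
  list(p = p, run = run,
       cache = list(B = B, T = T, dirs = dirs, g = g, g_drop = g_drop,
                    drop_mask = drop_mask, f = f, z = z,
                    gru_caches = gru_caches, conv_caches = conv_caches,
                    last_relu = a))
}

grufcn_backward <- function(par, fw, y, cfg) {
  ca <- fw$cache
  B <- ca$B; T <- ca$T
  n <- B
  t2 <- cbind(1 - y, y)
  dlogits <- (fw$p - t2) / n
  grads <- list()
  grads$out_W <- crossprod(ca$z, dlogits)
  grads$out_b <- colSums(dlogits)
  dz <- dlogits %*% t(par$out_W)
  gdim <- ncol(ca$g)
  dg_drop <- dz[, seq_len(gdim), drop = FALSE]
  df <- dz[, (gdim + 1):ncol(dz), drop = FALSE]
  dg <- if (!is.null(ca$drop_mask)) dg_drop * ca$drop_mask else dg_drop

  ## FCN backward
  da <- matrix(0, B * T, ncol(df))
  for (t in seq_len(T)) da[((t - 1) * B + 1):(t * B), ] <- df / T
  for (i in 3:1) {
    cc <- ca$conv_caches[[i]]
    da <- da * (cc$pre_relu > 0)
    bb <- bn_backward(da, cc$bn)
    grads[[paste0("bn", i, "_gamma")]] <- bb$dgamma
    grads[[paste0("bn", i, "_beta")]] <- bb$dbeta
    dlin <- bb$dx
    grads[[paste0("conv", i, "_W")]] <- crossprod(cc$cols, dlin)
    grads[[paste0("conv", i, "_b")]] <- colSums(dlin)
    dcols <- dlin %*% t(par[[paste0("conv", i, "_W")]])
    da <- im2col_backward(dcols, cc$k, cc$cin, B, T)
  }
  dx_fcn <- matrix(da, B, T)

  ## GRU backward (top layer receives dg at its final state only)
  dirs <- ca$dirs
  H <- cfg$hidden
  dlayer_out <- lapply(seq_len(T), function(t)
    matrix(0, B, H * length(dirs)))
  for (di in seq_along(dirs)) {
    d <- dirs[di]
    t_final <- if (d == "fw") T else 1L
    cols <- (di - 1) * H + seq_len(H)
    dlayer_out[[t_final]][, cols] <-
      dlayer_out[[t_final]][, cols] + dg[, cols, drop = FALSE]
  }
  dx_gru <- NULL
  for (l in rev(seq_len(cfg$layers))) {
    din <- if (l == 1) 1L else H * length(dirs)
    dx_accum <- lapply(seq_len(T), function(t) matrix(0, B, din))
    for (di in seq_along(dirs)) {
      d <- dirs[di]
      cols <- (di - 1) * H + seq_len(H)
      dh_seq <- lapply(dlayer_out, function(m) m[, cols, drop = FALSE])
      if (d == "bw") dh_seq <- rev(dh_seq)
      p <- par[paste0("gru", l, d, "_", gru_param_names)]
      names(p) <- gru_param_names
      bw <- gru_layer_backward(p, ca$gru_caches[[paste0(l, d)]], dh_seq)
      for (nm in gru_param_names)
        grads[[paste0("gru", l, d, "_", nm)]] <- bw$grads[[nm]]
      dxs <- if (d == "bw") rev(bw$dx_seq) else bw$dx_seq
      for (t in seq_len(T)) dx_accum[[t]] <- dx_accum[[t]] + dxs[[t]]
    }
    dlayer_out <- dx_accum
  }
  dx_gru <- do.call(cbind, lapply(dlayer_out, function(m) m))

  list(grads = grads, dx = dx_gru + dx_fcn)
}

grufcn_loss <- function(p, y, eps = 1e-12) {
  -mean(log(pmax(ifelse(y == 1, p[, 2], p[, 1]), eps)))
}

grufcn_predict_scores <- function(fit, x, chunk = 512L) {
  out <- numeric(nrow(x))
  for (i0 in seq(1, nrow(x), by = chunk)) {
    i <- i0:min(i0 + chunk - 1L, nrow(x))
    fw <- grufcn_forward(fit$par, fit$run, x[i, , drop = FALSE], fit$cfg,
                         training = FALSE)
    out[i] <- fw$p[, 2]
  }
  out
}

grufcn_train <- function(xtr, ytr, xval, yval, cfg, seed) {
  T <- ncol(xtr)
  par <- grufcn_init(T, cfg, child_seed(seed, 1))
  run <- grufcn_run_init(cfg)
  st <- adam_state(par)
  lr <- cfg$lr
  best <- list(loss = Inf, par = par, run = run)
  es_wait <- 0L; lr_wait <- 0L
  n <- nrow(xtr)
  with_seed(child_seed(seed, 2), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      for (i0 in seq(1, n, by = cfg$batch)) {
        i <- ord[i0:min(i0 + cfg$batch - 1L, n)]
        fw <- grufcn_forward(par, run, xtr[i, , drop = FALSE], cfg,
                             training = TRUE)
        run <- fw$run
        bw <- grufcn_backward(par, fw, ytr[i], cfg)
        up <- adam_step(par, bw$grads, st, lr)
        par <- up$par; st <- up$state
      }
      vp <- numeric(nrow(xval))
      for (j0 in seq(1, nrow(xval), by = 1024L)) {
        j <- j0:min(j0 + 1023L, nrow(xval))
        vp[j] <- grufcn_forward(par, run, xval[j, , drop = FALSE], cfg,
                                training = FALSE)$p[, 2]
      }
      vloss <- -mean(log(pmax(ifelse(yval == 1, vp, 1 - vp), 1e-12)))
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, par = par, run = run)
        es_wait <- 0L; lr_wait <- 0L
      } else {
        es_wait <- es_wait + 1L
        lr_wait <- lr_wait + 1L
        if (lr_wait >= cfg$patience_lr) {
          lr <- lr / 10
          lr_wait <- 0L
          rr_log("epoch ", ep, ": reducing learning rate to ", lr)
        }
        if (es_wait >= cfg$patience_es) break
      }
    }
  })
  best
}

fit_grufcn <- function(train, validation, spec, seed) {
  cfg <- utils::modifyList(rr_grufcn_config(train$w), spec)
  if (train$w < max(cfg$kernels))
    stop2("window length smaller than the largest convolution kernel")
  mu <- mean(train$values)
  sdv <- stats::sd(train$values)
  if (sdv == 0) sdv <- 1
  xtr <- (train$values - mu) / sdv
  xval <- (validation$values - mu) / sdv

  tr <- grufcn_train(xtr, train$label, xval, validation$label, cfg, seed)

  fit <- list(par = tr$par, run = tr$run, cfg = cfg, mu = mu, sd = sdv,
              window_threshold = 0.5,
              person_rule = "grid",
              meta = list(lr = cfg$lr, batch = cfg$batch,
                          hidden = cfg$hidden, layers = cfg$layers,
                          bidirectional = cfg$bidirectional,
                          dropout = cfg$dropout, val_loss = tr$loss))
  class(fit) <- c("rr_gru_fcn", "rr_classifier")
  fit$w <- train$w
  labels <- as.integer(grufcn_predict_scores(fit, xval) >= 0.5)
  fit$person_threshold <- grid_threshold_from_labels(labels, validation)
  fit
}

#' @export
predict_windows.rr_gru_fcn <- function(object, windows, type) {
  x <- (windows$values - object$mu) / object$sd
  p <- grufcn_predict_scores(object, x)
  if (type == "label") as.integer(p >= object$window_threshold) else p
}
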