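#' Training configuration for the graph models
#'
#' Defaults follow the reference configuration of the method: full-batch Adam
#' with learning rate 0.01 and weight decay 5e-4, 300 epochs with early
#' stopping after 40 non-improving validation epochs, dropout 0.5, hidden
#' sizes 16 and 8, auxiliary-loss coefficients beta = 5e-10 (disparity) and
#' theta = 0.001 (consistency), seed 21.
#'
#' @param lr learning rate.
#' @param weight_decay L2 weight decay added to every gradient.
#' @param epochs maximal number of full-batch epochs.
#' @param patience early-stopping rounds on internal-validation loss.
#' @param dropout dropout rate applied to each layer input during training.
#' @param nhid1 first hidden layer width.
#' @param nhid2 embedding width.
#' @param att_hidden attention transform width (h'); defaults to nhid2.
#' @param beta coefficient of the disparity (dependence) loss.
#' @param theta coefficient of the consistency loss.
#' @param loss_reduction "mean" (default; stabilizes the learning rate across
#'   cohort sizes) or "sum" for the plain summed cross-entropy.
#' @param class_weights logical; inverse-frequency class weighting of the
#'   cross-entropy (default off).
#' @param seed integer seed for initialization and dropout streams.
#' @return list of class \code{train_config}.
#' @export
train_config <- function(lr = 0.01, weight_decay = 5e-4, epochs = 300,
                         patience = 40, dropout = 0.5, nhid1 = 16, nhid2 = 8,
                         att_hidden = nhid2, beta = 5e-10, theta = 0.001,
                         loss_reduction = c("mean", "sum"),
                         class_weights = FALSE, seed = 21) {
  stopifnot(lr >= 0, weight_decay >= 0, epochs >= 1, patience >= 1,
            dropout >= 0, dropout < 1, nhid1 >= 1, nhid2 >= 1,
            att_hidden >= 1, beta >= 0, theta >= 0)
  structure(list(lr = lr, weight_decay = weight_decay,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 dropout = dropout, nhid1 = as.integer(nhid1),
                 nhid2 = as.integer(nhid2), att_hidden = as.integer(att_hidden),
                 beta = beta, theta = theta,
                 loss_reduction = match.arg(loss_reduction),
                 class_weights = isTRUE(class_weights),
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- parameter containers ----------------------------------------------

init_amgcn_params <- function(D, config) {
  h1 <- config$nhid1; h2 <- config$nhid2; hp <- config$att_hidden
  list(
    Wp1 = init_weight(D, h1), Wp2 = init_weight(h1, h2),
    Wf1 = init_weight(D, h1), Wf2 = init_weight(h1, h2),
    Wc1 = init_weight(D, h1), Wc2 = init_weight(h1, h2),
    Wap = init_weight(hp, h2), bap = rep(0, hp),
    Waf = init_weight(hp, h2), baf = rep(0, hp),
    Wac = init_weight(hp, h2), bac = rep(0, hp),
    q = init_weight(hp, 1)[, 1],
    Wcls = init_weight(h2, 2), bcls = rep(0, 2)
  )
}

init_single_params <- function(D, config) {
  list(W1 = init_weight(D, config$nhid1),
       W2 = init_weight(config$nhid1, config$nhid2),
       Wcls = init_weight(config$nhid2, 2), bcls = rep(0, 2))
}

zero_like <- function(params) lapply(params, function(p) p * 0)

# ---- one two-layer ReLU propagation with cached intermediates -----------

prop_forward <- function(P, X, W1, W2, dropout, training) {
  drop_mask <- function(M) {
    if (training && dropout > 0) {
      matrix(stats::runif(length(M)) >= dropout, nrow(M), ncol(M)) / (1 - dropout)
    } else NULL
  }
  M0 <- drop_mask(X)
  X0 <- if (is.null(M0)) X else X * M0
  U1 <- P %*% X0
  A1 <- U1 %*% W1
  H1 <- relu(A1)
  M1 <- drop_mask(H1)
  H1d <- if (is.null(M1)) H1 else H1 * M1
  U2 <- P %*% H1d
  A2 <- U2 %*% W2
  Z <- relu(A2)
  list(Z = Z, U1 = U1, A1 = A1, M1 = M1, U2 = U2, A2 = A2, P = P, W2 = W2)
}

prop_backward <- function(cache, dZ) {
  G2 <- dZ * (cache$A2 > 0)
  dW2 <- crossprod(cache$U2, G2)
  dH1d <- (cache$P %*% G2) %*% t(cache$W2)
  dH1 <- if (is.null(cache$M1)) dH1d else dH1d * cache$M1
  G1 <- dH1 * (cache$A1 > 0)
  dW1 <- crossprod(cache$U1, G1)
  list(dW1 = dW1, dW2 = dW2)
}

#' Multi-channel embedding forward pass
#'
#' Runs the three channels of the model: the topology channel (population
#' graph, its own weights), the feature channel (KNN graph, its own weights)
#' and the common channel, whose single weight set is propagated through both
#' graphs; the common embedding is the average of those two shared-weight
#' propagations.
#'
#' @param Ahat_p,Ahat_f normalized adjacencies of the population and KNN
#'   graphs.
#' @param X node feature matrix.
#' @param params parameter list with \code{Wp1,Wp2,Wf1,Wf2,Wc1,Wc2}.
#' @param dropout,training dropout settings (off by default).
#' @return list with embeddings \code{Zp}, \code{Zf}, \code{Zc} and the two
#'   shared-weight propagations \code{Zcp}, \code{Zcf}.
#' @export
channel_forward <- function(Ahat_p, Ahat_f, X, params,
                            dropout = 0, training = FALSE) {
  cp <- prop_forward(Ahat_p, X, params$Wp1, params$Wp2, dropout, training)
  cf <- prop_forward(Ahat_f, X, params$Wf1, params$Wf2, dropout, training)
  ccp <- prop_forward(Ahat_p, X, params$Wc1, params$Wc2, dropout, training)
  ccf <- prop_forward(Ahat_f, X, params$Wc1, params$Wc2, dropout, training)
  list(Zp = cp$Z, Zf = cf$Z, Zc = (ccp$Z + ccf$Z) / 2,
       Zcp = ccp$Z, Zcf = ccf$Z,
       caches = list(p = cp, f = cf, cp = ccp, cf = ccf))
}

#' Attention fusion of channel embeddings
#'
#' Per node i and channel c, an attention score
#' \eqn{\omega_c^i = q^\top \tanh(W_c z_c^i + b_c)} is computed with a
#' channel-specific transform and a shared attention vector q; the three
#' scores are normalized per node by softmax into weights on the 2-simplex,
#' and the fused embedding is the per-node convex combination
#' \eqn{z_a^i = a_p^i z_p^i + a_f^i z_f^i + a_c^i z_c^i}.
#'
#' @param Zp,Zf,Zc channel embeddings (N x h).
#' @param att list with \code{Wap,bap,Waf,baf,Wac,bac,q}.
#' @return list with \code{weights} (N x 3 matrix, columns p/f/c, rows sum to
#'   1) and fused \code{Za}.
#' @export
attention_fuse <- function(Zp, Zf, Zc, att) {
  score <- function(Z, W, b) {
    T <- tanh(Z %*% t(W) + matrix(b, nrow(Z), length(b), byrow = TRUE))
    as.numeric(T %*% att$q)
  }
  omega <- cbind(p = score(Zp, att$Wap, att$bap),
                 f = score(Zf, att$Waf, att$baf),
                 c = score(Zc, att$Wac, att$bac))
  a <- softmax_rows(omega)
  Za <- a[, 1] * Zp + a[, 2] * Zf + a[, 3] * Zc
  list(weights = a, Za = Za)
}

#' Linear classifier with softmax output
#'
#' \eqn{\hat{Y} = \mathrm{softmax}(Z_a W + b)} per node; with two classes the
#' second column is the death probability.
#'
#' @param Za fused embeddings (N x h).
#' @param W classifier weights (h x 2).
#' @param b bias (length 2).
#' @return N x 2 matrix of class probabilities.
#' @export
classify <- function(Za, W, b) {
  softmax_rows(Za %*% W + matrix(b, nrow(Za), length(b), byrow = TRUE))
}

#' Cross-entropy node-classification loss
#'
#' \eqn{-\sum_{l \in \mathrm{mask}} \log \hat{Y}_{l, y_l}}, optionally
#' divided by the number of masked nodes ("mean", the default) and optionally
#' with inverse-frequency class weights. Probabilities are clamped at 1e-12.
#'
#' @param Yhat N x 2 probability matrix.
#' @param y 0/1 label vector.
#' @param mask integer indices of the nodes entering the loss.
#' @param reduction "mean" or "sum".
#' @param class_weights optional length-2 weight vector (class 0, class 1).
#' @return nonnegative scalar.
#' @export
task_loss <- function(Yhat, y, mask, reduction = c("mean", "sum"),
                      class_weights = NULL) {
  reduction <- match.arg(reduction)
  p <- pmax(Yhat[cbind(mask, y[mask] + 1L)], 1e-12)
  w <- if (is.null(class_weights)) rep(1, length(mask)) else class_weights[y[mask] + 1L]
  tot <- -sum(w * log(p))
  if (reduction == "mean") tot / sum(w) else tot
}

# ---- auxiliary losses ----------------------------------------------------

row_normalize_centered <- function(E) {
  C <- sweep(E, 2L, colMeans(E))
  r <- sqrt(rowSums(C^2))
  r0 <- pmax(r, 1e-12)
  list(N = C / r0, C = C, r = r0)
}

consistency_loss <- function(E1, E2) {
  n1 <- row_normalize_centered(E1)
  n2 <- row_normalize_centered(E2)
  S1 <- tcrossprod(n1$N)
  S2 <- tcrossprod(n2$N)
  mean((S1 - S2)^2)
}

double_center <- function(K) {
  rm <- rowMeans(K)
  K - rm - rep(rm, each = nrow(K)) + mean(K)
}

hsic <- function(E1, E2) {
  K1 <- tcrossprod(E1)
  K2 <- tcrossprod(E2)
  sum(double_center(K1) * K2)
}

#' Auxiliary consistency and disparity losses
#'
#' The consistency term (coefficient \code{theta}) encourages the two
#' shared-weight propagations to induce similar normalized node-similarity
#' matrices: embeddings are column-centered and row-normalized, and the mean
#' squared difference of their Gram matrices is penalized. The disparity term
#' (coefficient \code{beta}) is an empirical dependence measure
#' (Hilbert-Schmidt independence criterion with linear kernels) between each
#' channel-specific embedding and the shared-weight embedding on the same
#' graph, discouraging redundant channels. A zero coefficient disables the
#' corresponding term exactly.
#'
#' @param Zcp,Zcf shared-weight propagations through the population / KNN
#'   graph.
#' @param Zp,Zf channel-specific embeddings.
#' @param beta,theta nonnegative coefficients.
#' @return list with \code{consistency}, \code{disparity} (both unscaled) and
#'   the scaled \code{total}.
#' @export
auxiliary_losses <- function(Zcp, Zcf, Zp, Zf, beta = 5e-10, theta = 0.001) {
  cons <- if (theta > 0) consistency_loss(Zcp, Zcf) else 0
  disp <- if (beta > 0) hsic(Zp, Zcp) + hsic(Zf, Zcf) else 0
  list(consistency = cons, disparity = disp,
       total = theta * cons + beta * disp)
}

# gradient of mean((S1 - S2)^2) w.r.t. the two raw embeddings
consistency_grads <- function(E1, E2) {
  n1 <- row_normalize_centered(E1)
  n2 <- row_normalize_centered(E2)
  S1 <- tcrossprod(n1$N)
  S2 <- tcrossprod(n2$N)
  G <- 2 * (S1 - S2) / length(S1)
  back <- function(nrm, sign) {
    dN <- sign * 2 * (G %*% nrm$N)
    dC <- (dN - nrm$N * rowSums(nrm$N * dN)) / nrm$r
    dC - rep(colMeans(dC), each = nrow(dC))
  }
  list(dE1 = back(n1, 1), dE2 = back(n2, -1))
}

# gradient of tr(R K1 R K2) w.r.t. both embeddings
hsic_grads <- function(E1, E2) {
  K1 <- tcrossprod(E1)
  K2 <- tcrossprod(E2)
  list(dE1 = 2 * double_center(K2) %*% E1,
       dE2 = 2 * double_center(K1) %*% E2)
}

# ---- full AM-GCN loss + gradients ---------------------------------------

amgcn_forward <- function(params, X, Pp, Pf, dropout = 0, training = FALSE) {
  ch <- channel_forward(Pp, Pf, X, params, dropout, training)
  att <- list(Wap = params$Wap, bap = params$bap, Waf = params$Waf,
              baf = params$baf, Wac = params$Wac, bac = params$bac,
              q = params$q)
  tanh_cache <- function(Z, W, b) tanh(Z %*% t(W) + matrix(b, nrow(Z), length(b), byrow = TRUE))
  Tp <- tanh_cache(ch$Zp, params$Wap, params$bap)
  Tf <- tanh_cache(ch$Zf, params$Waf, params$baf)
  Tc <- tanh_cache(ch$Zc, params$Wac, params$bac)
  omega <- cbind(Tp %*% params$q, Tf %*% params$q, Tc %*% params$q)
  a <- softmax_rows(omega)
  Za <- a[, 1] * ch$Zp + a[, 2] * ch$Zf + a[, 3] * ch$Zc
  logits <- Za %*% params$Wcls +
    matrix(params$bcls, nrow(Za), 2, byrow = TRUE)
  Yhat <- softmax_rows(logits)
  list(ch = ch, Tp = Tp, Tf = Tf, Tc = Tc, a = a, Za = Za, Yhat = Yhat)
}

amgcn_loss_and_grads <- function(params, X, Pp, Pf, y, mask, config,
                                 training = FALSE, want_grads = TRUE) {
  fw <- amgcn_forward(params, X, Pp, Pf, config$dropout, training)
  cw <- NULL
  if (config$class_weights) {
    n1 <- sum(y[mask] == 1); n0 <- length(mask) - n1
    cw <- length(mask) / (2 * c(max(n0, 1), max(n1, 1)))
  }
  lt <- task_loss(fw$Yhat, y, mask, config$loss_reduction, cw)
  aux <- auxiliary_losses(fw$ch$Zcp, fw$ch$Zcf, fw$ch$Zp, fw$ch$Zf,
                          config$beta, config$theta)
  loss <- lt + aux$total
  if (!is.finite(loss)) stop("non-finite loss", call. = FALSE)
  if (!want_grads) return(list(loss = loss, task = lt, aux = aux, fw = fw))

  N <- nrow(X)
  ch <- fw$ch
  # classifier backward
  dlogits <- matrix(0, N, 2)
  onehot <- cbind(1 - y, y)
  w <- if (is.null(cw)) rep(1, length(mask)) else cw[y[mask] + 1L]
  denom <- if (config$loss_reduction == "mean") sum(w) else 1
  dlogits[mask, ] <- (fw$Yhat[mask, , drop = FALSE] -
                        onehot[mask, , drop = FALSE]) * (w / denom)
  dWcls <- crossprod(fw$Za, dlogits)
  dbcls <- colSums(dlogits)
  dZa <- dlogits %*% t(params$Wcls)

  # attention backward
  a <- fw$a
  dZp <- a[, 1] * dZa
  dZf <- a[, 2] * dZa
  dZc <- a[, 3] * dZa
  da <- cbind(rowSums(dZa * ch$Zp), rowSums(dZa * ch$Zf), rowSums(dZa * ch$Zc))
  domega <- a * (da - rowSums(a * da))
  att_back <- function(T, dom, Z, W) {
    dT <- dom %o% params$q          # N x hp
    dpre <- dT * (1 - T^2)
    list(dW = crossprod(dpre, Z), db = colSums(dpre), dZ = dpre %*% W)
  }
  bp <- att_back(fw$Tp, domega[, 1], ch$Zp, params$Wap)
  bf <- att_back(fw$Tf, domega[, 2], ch$Zf, params$Waf)
  bc <- att_back(fw$Tc, domega[, 3], ch$Zc, params$Wac)
  dq <- crossprod(fw$Tp, domega[, 1]) + crossprod(fw$Tf, domega[, 2]) +
    crossprod(fw$Tc, domega[, 3])
  dZp <- dZp + bp$dZ
  dZf <- dZf + bf$dZ
  dZc <- dZc + bc$dZ
  dZcp <- dZc / 2
  dZcf <- dZc / 2

  # auxiliary losses backward
  if (config$theta > 0) {
    cg <- consistency_grads(ch$Zcp, ch$Zcf)
    dZcp <- dZcp + config$theta * cg$dE1
    dZcf <- dZcf + config$theta * cg$dE2
  }
  if (config$beta > 0) {
    hg1 <- hsic_grads(ch$Zp, ch$Zcp)
    hg2 <- hsic_grads(ch$Zf, ch$Zcf)
    dZp <- dZp + config$beta * hg1$dE1
    dZcp <- dZcp + config$beta * hg1$dE2
    dZf <- dZf + config$beta * hg2$dE1
    dZcf <- dZcf + config$beta * hg2$dE2
  }

  gp <- prop_backward(ch$caches$p, dZp)
  gf <- prop_backward(ch$caches$f, dZf)
  gcp <- prop_backward(ch$caches$cp, dZcp)
  gcf <- prop_backward(ch$caches$cf, dZcf)

  grads <- list(
    Wp1 = gp$dW1, Wp2 = gp$dW2, Wf1 = gf$dW1, Wf2 = gf$dW2,
    Wc1 = gcp$dW1 + gcf$dW1, Wc2 = gcp$dW2 + gcf$dW2,
    Wap = bp$dW, bap = bp$db, Waf = bf$dW, baf = bf$db,
    Wac = bc$dW, bac = bc$db, q = as.numeric(dq),
    Wcls = dWcls, bcls = dbcls
  )
  list(loss = loss, task = lt, aux = aux, fw = fw, grads = grads)
}

# ---- single-channel (plain two-layer GCN + classifier) ------------------

single_loss_and_grads <- function(params, X, P, y, mask, config,
                                  training = FALSE, want_grads = TRUE) {
  cache <- prop_forward(P, X, params$W1, params$W2, config$dropout, training)
  Z <- cache$Z
  logits <- Z %*% params$Wcls + matrix(params$bcls, nrow(Z), 2, byrow = TRUE)
  Yhat <- softmax_rows(logits)
  cw <- NULL
  if (config$class_weights) {
    n1 <- sum(y[mask] == 1); n0 <- length(mask) - n1
    cw <- length(mask) / (2 * c(max(n0, 1), max(n1, 1)))
  }
  loss <- task_loss(Yhat, y, mask, config$loss_reduction, cw)
  if (!is.finite(loss)) stop("non-finite loss", call. = FALSE)
  if (!want_grads) return(list(loss = loss, Yhat = Yhat))
  N <- nrow(X)
  dlogits <- matrix(0, N, 2)
  onehot <- cbind(1 - y, y)
  w <- if (is.null(cw)) rep(1, length(mask)) else cw[y[mask] + 1L]
  denom <- if (config$loss_reduction == "mean") sum(w) else 1
  dlogits[mask, ] <- (Yhat[mask, , drop = FALSE] -
                        onehot[mask, , drop = FALSE]) * (w / denom)
  dWcls <- crossprod(Z, dlogits)
  dbcls <- colSums(dlogits)
  dZ <- dlogits %*% t(params$Wcls)
  g <- prop_backward(cache, dZ)
  list(loss = loss, Yhat = Yhat,
       grads = list(W1 = g$dW1, W2 = g$dW2, Wcls = dWcls, bcls = dbcls))
}

# ---- Adam + generic training loop ---------------------------------------

adam_step <- function(params, grads, state, config) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]] + config$weight_decay * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mh <- state$m[[nm]] / (1 - b1^state$t)
    vh <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - config$lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

train_loop <- function(params, grad_fn, val_fn, config) {
  state <- list(t = 0L, m = zero_like(params), v = zero_like(params))
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  history <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    res <- tryCatch(grad_fn(params),
                    error = function(e) stop(sprintf(
                      "training diverged at epoch %d: %s", epoch,
                      conditionMessage(e)), call. = FALSE))
    upd <- adam_step(params, res$grads, state, config)
    params <- upd$params; state <- upd$state
    vl <- val_fn(params)
    history[[epoch]] <- c(epoch = epoch, train_loss = res$loss, val_loss = vl)
    if (vl < best$loss - 1e-12) {
      best <- list(loss = vl, params = params, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  history <- as.data.frame(do.call(rbind, history[!vapply(history, is.null, logical(1))]))
  list(params = best$params, best_epoch = best$epoch, history = history)
}

#' Train the adaptive multi-channel GCN
#'
#' Full-batch gradient training of all channel, attention and classifier
#' parameters on the cross-entropy task loss plus consistency/disparity
#' auxiliary losses, with Adam, weight decay, dropout, and early stopping on
#' the internal-validation task loss (best-validation parameters returned).
#' Deterministic for a fixed config seed.
#'
#' @param X normalized N x D feature matrix.
#' @param graph_p,graph_f population / KNN \code{patient_graph}s (or raw
#'   adjacency matrices).
#' @param y 0/1 label vector (1 = death).
#' @param masks split as from [split_masks()] (uses \code{train_fit} for
#'   gradients and \code{val} for early stopping; falls back to \code{train}
#'   when no validation subset exists).
#' @param config a [train_config()].
#' @return object of class \code{amgcn_fit} with elements \code{params},
#'   \code{history} (per-epoch train/validation loss), \code{best_epoch},
#'   \code{config}.
#' @export
train_amgcn <- function(X, graph_p, graph_f, y, masks, config = train_config()) {
  Pp <- normalize_adjacency(graph_p)
  Pf <- normalize_adjacency(graph_f)
  fit_mask <- masks$train_fit %||% masks$train
  val_mask <- if (length(masks$val %||% integer(0)) > 0) masks$val else fit_mask
  if (length(unique(y[fit_mask])) < 2) {
    stop("training nodes must include both classes", call. = FALSE)
  }
  set.seed(derive_seed(config$seed, "amgcn-train"))
  params <- init_amgcn_params(ncol(X), config)
  grad_fn <- function(p) amgcn_loss_and_grads(p, X, Pp, Pf, y, fit_mask,
                                              config, training = TRUE)
  val_fn <- function(p) amgcn_loss_and_grads(p, X, Pp, Pf, y, val_mask,
                                             config, training = FALSE,
                                             want_grads = FALSE)$task
  out <- train_loop(params, grad_fn, val_fn, config)
  structure(list(params = out$params, history = out$history,
                 best_epoch = out$best_epoch, config = config,
                 model = "amgcn"),
            class = "amgcn_fit")
}

#' Predict death probabilities with a trained AM-GCN
#'
#' Evaluation-mode forward pass (dropout off), hence deterministic. With
#' \code{pin_channel} the per-node attention weights are overridden by a
#' one-hot vector on the named channel, which reduces the model to a plain
#' single-graph GCN with the same weights (the single-channel ablations).
#'
#' @param object an \code{amgcn_fit}.
#' @param X,graph_p,graph_f data the model was trained on (or new conforming
#'   data).
#' @param pin_channel "none" (default), "p", "f" or "c".
#' @param ... unused.
#' @return N x 2 matrix of class probabilities; column 2 is the death
#'   probability.
#' @export
predict.amgcn_fit <- function(object, X, graph_p, graph_f,
                              pin_channel = c("none", "p", "f", "c"), ...) {
  pin_channel <- match.arg(pin_channel)
  Pp <- normalize_adjacency(graph_p)
  Pf <- normalize_adjacency(graph_f)
  fw <- amgcn_forward(object$params, X, Pp, Pf, dropout = 0, training = FALSE)
  if (pin_channel != "none") {
    Z <- switch(pin_channel, p = fw$ch$Zp, f = fw$ch$Zf, c = fw$ch$Zc)
    return(classify(Z, object$params$Wcls, object$params$bcls))
  }
  fw$Yhat
}

#' Train a single-channel GCN (the p-GCN / K-GCN ablations)
#'
#' A plain two-layer ReLU GCN embedding on one graph followed by a linear
#' softmax classifier, trained with cross-entropy only — the topology-only
#' (population graph) and feature-only (KNN graph) ablations of the
#' multi-channel model.
#'
#' @inheritParams train_amgcn
#' @param graph a single \code{patient_graph} (or adjacency matrix).
#' @return object of class \code{gcn_fit}.
#' @export
train_gcn <- function(X, graph, y, masks, config = train_config()) {
  P <- normalize_adjacency(graph)
  fit_mask <- masks$train_fit %||% masks$train
  val_mask <- if (length(masks$val %||% integer(0)) > 0) masks$val else fit_mask
  if (length(unique(y[fit_mask])) < 2) {
    stop("training nodes must include both classes", call. = FALSE)
  }
  set.seed(derive_seed(config$seed, "gcn-train"))
  params <- init_single_params(ncol(X), config)
  grad_fn <- function(p) single_loss_and_grads(p, X, P, y, fit_mask, config,
                                               training = TRUE)
  val_fn <- function(p) single_loss_and_grads(p, X, P, y, val_mask, config,
                                              training = FALSE,
                                              want_grads = FALSE)$loss
  out <- train_loop(params, grad_fn, val_fn, config)
  structure(list(params = out$params, history = out$history,
                 best_epoch = out$best_epoch, config = config,
                 model = "single"),
            class = "gcn_fit")
}

#' @rdname train_gcn
#' @param object a \code{gcn_fit}.
#' @param ... unused.
#' @export
predict.gcn_fit <- function(object, X, graph, ...) {
  P <- normalize_adjacency(graph)
  cache <- prop_forward(P, X, object$params$W1, object$params$W2, 0, FALSE)
  classify(cache$Z, object$params$Wcls, object$params$bcls)
}
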