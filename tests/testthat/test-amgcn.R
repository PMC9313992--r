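test_that("channel forward: symmetric weights give equal channels, composition matches gcn_core", {
  ti <- tiny_instance()
  p <- ti$params
  # same graph + same weights in all channels -> identical embeddings
  p_eq <- p
  p_eq$Wf1 <- p_eq$Wc1 <- p_eq$Wp1
  p_eq$Wf2 <- p_eq$Wc2 <- p_eq$Wp2
  ch <- channel_forward(ti$Pp, ti$Pp, ti$X, p_eq)
  expect_equal(ch$Zp, ch$Zf, tolerance = 1e-12)
  expect_equal(ch$Zp, ch$Zc, tolerance = 1e-12)
  # zero common weights -> zero common embedding
  p0 <- p; p0$Wc1 <- p0$Wc1 * 0
  ch0 <- channel_forward(ti$Pp, ti$Pf, ti$X, p0)
  expect_equal(ch0$Zc, matrix(0, nrow(ti$X), ncol(p$Wp2)), ignore_attr = TRUE)
  # common channel is the average of two independent gcn_core propagations
  ch <- channel_forward(ti$Pp, ti$Pf, ti$X, p)
  two_relu <- function(P, W1, W2) {
    gcn_layer(P, gcn_layer(P, ti$X, W1, activation = "relu"), W2,
              activation = "relu")
  }
  expect_equal(ch$Zcp, two_relu(ti$Pp, p$Wc1, p$Wc2), tolerance = 1e-12)
  expect_equal(ch$Zcf, two_relu(ti$Pf, p$Wc1, p$Wc2), tolerance = 1e-12)
  expect_equal(ch$Zc, (ch$Zcp + ch$Zcf) / 2, tolerance = 1e-12)
  expect_equal(ch$Zp, two_relu(ti$Pp, p$Wp1, p$Wp2), tolerance = 1e-12)
})

test_that("attention weights live on the simplex and fuse convexly", {
  ti <- tiny_instance()
  ch <- channel_forward(ti$Pp, ti$Pf, ti$X, ti$params)
  att <- ti$params[c("Wap", "bap", "Waf", "baf", "Wac", "bac", "q")]
  fu <- attention_fuse(ch$Zp, ch$Zf, ch$Zc, att)
  expect_equal(rowSums(fu$weights), rep(1, nrow(ti$X)), tolerance = 1e-9)
  expect_true(all(fu$weights > 0 & fu$weights < 1))
  # q = 0 -> identical scores -> uniform weights
  att0 <- att; att0$q <- att0$q * 0
  fu0 <- attention_fuse(ch$Zp, ch$Zf, ch$Zc, att0)
  expect_equal(fu0$weights, matrix(1 / 3, nrow(ti$X), 3), ignore_attr = TRUE)
  # equal embeddings -> fusion returns them unchanged whatever the weights
  fu_eq <- attention_fuse(ch$Zp, ch$Zp, ch$Zp, att)
  expect_equal(fu_eq$Za, ch$Zp, tolerance = 1e-12)
})

test_that("attention on a single node matches a hand-evaluated tanh/softmax chain", {
  z <- matrix(c(0.5, -1), 1, 2)
  att <- list(Wap = matrix(c(1, 0, 0.5, -0.5), 2, 2),
              bap = c(0.1, -0.2),
              Waf = matrix(c(-1, 0.3, 0, 1), 2, 2), baf = c(0, 0),
              Wac = matrix(0, 2, 2), bac = c(0, 0),
              q = c(2, -1))
  sc <- function(W, b, zz) sum(att$q * tanh(W %*% t(zz) + b))
  w <- exp(c(sc(att$Wap, att$bap, z), sc(att$Waf, att$baf, z + 1),
             sc(att$Wac, att$bac, z - 1)))
  w <- w / sum(w)
  fu <- attention_fuse(z, z + 1, z - 1, att)
  expect_equal(as.numeric(fu$weights), w, tolerance = 1e-12)
  expect_equal(as.numeric(fu$Za),
               w[1] * z + w[2] * (z + 1) + w[3] * (z - 1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("classifier softmax rows sum to one; binary closed form holds", {
  set.seed(30)
  Za <- matrix(rnorm(20), 10, 2)
  expect_equal(classify(Za, matrix(0, 2, 2), c(0, 0)),
               matrix(0.5, 10, 2), ignore_attr = TRUE)
  W <- matrix(rnorm(4), 2, 2); b <- rnorm(2)
  P <- classify(Za, W, b)
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-9)
  logits <- Za %*% W + matrix(b, 10, 2, byrow = TRUE)
  expect_equal(P[, 2], 1 / (1 + exp(-(logits[, 2] - logits[, 1]))),
               tolerance = 1e-12)
})

test_that("cross-entropy loss: perfect, uniform and hand-computed cases", {
  Y <- c(0L, 1L, 0L)
  perfect <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(task_loss(perfect, Y, 1:3, "sum"), 3 * -log(1 - 1e-12),
               tolerance = 1e-9)
  uniform <- matrix(0.5, 3, 2)
  expect_equal(task_loss(uniform, Y, 1:3, "sum"), 3 * log(2), tolerance = 1e-12)
  expect_equal(task_loss(uniform, Y, 1:3, "mean"), log(2), tolerance = 1e-12)
  probs <- rbind(c(0.7, 0.3), c(0.2, 0.8), c(0.9, 0.1))
  expect_equal(task_loss(probs, Y, 1:3, "sum"),
               -(log(0.7) + log(0.8) + log(0.9)), tolerance = 1e-12)
  # restricting the mask restricts the sum
  expect_equal(task_loss(probs, Y, 2L, "sum"), -log(0.8), tolerance = 1e-12)
})

test_that("auxiliary losses vanish when disabled or when embeddings agree", {
  set.seed(31)
  E1 <- matrix(rnorm(12), 6, 2)
  E2 <- matrix(rnorm(12), 6, 2)
  expect_equal(auxiliary_losses(E1, E1, E1, E2, beta = 0.1, theta = 1)$consistency, 0)
  off <- auxiliary_losses(E1, E2, E1, E2, beta = 0, theta = 0)
  expect_equal(off$total, 0)
  on <- auxiliary_losses(E1, E2, E1, E2, beta = 2, theta = 3)
  expect_equal(on$total, 3 * on$consistency + 2 * on$disparity, tolerance = 1e-12)
  # independent re-evaluation of both formulas
  normed <- function(E) {
    C <- sweep(E, 2, colMeans(E))
    C / sqrt(rowSums(C^2))
  }
  S1 <- tcrossprod(normed(E1)); S2 <- tcrossprod(normed(E2))
  expect_equal(on$consistency, mean((S1 - S2)^2), tolerance = 1e-12)
  n <- nrow(E1)
  R <- diag(n) - matrix(1 / n, n, n)
  hsic_ref <- function(A, B) {
    sum(diag(R %*% tcrossprod(A) %*% R %*% tcrossprod(B)))
  }
  expect_equal(on$disparity, hsic_ref(E1, E1) + hsic_ref(E2, E2),
               tolerance = 1e-9)
})

test_that("analytic gradients match central differences on a tiny instance", {
  ti <- tiny_instance()
  res <- chdgcn:::amgcn_loss_and_grads(ti$params, ti$X, ti$Pp, ti$Pf, ti$y,
                                       ti$mask, ti$cfg)
  loss_at <- function(params) {
    chdgcn:::amgcn_loss_and_grads(params, ti$X, ti$Pp, ti$Pf, ti$y, ti$mask,
                                  ti$cfg, want_grads = FALSE)$loss
  }
  set.seed(99)
  h <- 1e-6
  checked <- 0
  for (rep in 1:10) {
    nm <- sample(names(ti$params), 1)
    idx <- sample(length(ti$params[[nm]]), 1)
    pp <- ti$params; pp[[nm]][idx] <- pp[[nm]][idx] + h
    pm <- ti$params; pm[[nm]][idx] <- pm[[nm]][idx] - h
    num <- (loss_at(pp) - loss_at(pm)) / (2 * h)
    ana <- res$grads[[nm]][idx]
    denom <- max(1e-6, abs(num) + abs(ana))
    expect_lt(abs(num - ana) / denom, 1e-4)
    checked <- checked + 1
  }
  expect_equal(checked, 10)
})

test_that("training is deterministic, zero learning rate freezes parameters", {
  set.seed(40)
  spec <- tiny_spec(n = 60, seed = 13)
  coh <- generate_cohort(spec)
  prep <- preprocess_cohort(coh, chd_schema(spec))
  gp <- population_adjacency(prep$X, prep$raw,
                             phenotype_measures(schema = prep$schema))
  gf <- knn_adjacency(cosine_similarity_matrix(prep$X), 4)
  masks <- split_masks(nrow(prep$X), 0.6, 2)
  cfg <- train_config(epochs = 15, patience = 5, seed = 3)
  f1 <- train_amgcn(prep$X, gp, gf, prep$labels, masks, cfg)
  f2 <- train_amgcn(prep$X, gp, gf, prep$labels, masks, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
  p1 <- predict(f1, prep$X, gp, gf)
  expect_identical(p1, predict(f1, prep$X, gp, gf))
  expect_equal(unname(rowSums(p1)), rep(1, nrow(p1)), tolerance = 1e-9)

  cfg0 <- train_config(epochs = 5, patience = 3, lr = 0,
                       weight_decay = 0, seed = 3)
  set.seed(derive_val <- chdgcn:::derive_seed(3, "amgcn-train"))
  init <- chdgcn:::init_amgcn_params(ncol(prep$X), cfg0)
  f0 <- train_amgcn(prep$X, gp, gf, prep$labels, masks, cfg0)
  expect_equal(f0$params, init, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a linearly separable toy with informative graphs is fit to training accuracy 1", {
  set.seed(41)
  n <- 20
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(rnorm(n, mean = ifelse(y == 1, 2, -2), sd = 0.4),
             matrix(rnorm(n * 2), n, 3 - 1))
  A <- outer(y, y, "==") * 1; diag(A) <- 0    # communities = classes
  masks <- list(train = 1:n, train_fit = 1:n, val = integer(0), test = integer(0))
  cfg <- train_config(epochs = 300, patience = 300, dropout = 0, seed = 5)
  fit <- train_amgcn(zscore(X), A, A, y, masks, cfg)
  prob <- predict(fit, zscore(X), A, A)
  expect_equal(as.integer(prob[, 2] >= 0.5), y)
})

test_that("pinned attention reproduces the single-channel ablation forward exactly", {
  ti <- tiny_instance(seed = 9, N = 8, D = 5)
  cfg <- ti$cfg
  fit <- structure(list(params = ti$params, config = cfg, model = "amgcn"),
                   class = "amgcn_fit")
  prob_p <- predict(fit, ti$X, ti$Ap, ti$Af, pin_channel = "p")
  # ablation: plain two-layer ReLU GCN on the population graph + classifier
  sfit <- structure(list(params = list(W1 = ti$params$Wp1, W2 = ti$params$Wp2,
                                       Wcls = ti$params$Wcls,
                                       bcls = ti$params$bcls),
                         config = cfg, model = "single"),
                    class = "gcn_fit")
  expect_equal(prob_p, predict(sfit, ti$X, ti$Ap), tolerance = 1e-12)
  prob_f <- predict(fit, ti$X, ti$Ap, ti$Af, pin_channel = "f")
  sfit$params$W1 <- ti$params$Wf1; sfit$params$W2 <- ti$params$Wf2
  expect_equal(prob_f, predict(sfit, ti$X, ti$Af), tolerance = 1e-12)
})

test_that("single-channel training errors without both classes and diverging loss is reported", {
  set.seed(42)
  X <- matrix(rnorm(40), 10, 4)
  A <- random_adjacency(10)
  masks <- list(train = 1:6, train_fit = 1:6, val = 7:8, test = 9:10)
  y_one <- rep(0L, 10)
  expect_error(train_gcn(X, A, y_one, masks), "both classes")
  y <- rep_len(c(0L, 1L), 10)
  fit <- train_gcn(X, A, y, masks, train_config(epochs = 10, patience = 5))
  expect_s3_class(fit, "gcn_fit")
  expect_true(all(is.finite(fit$history$train_loss)))
})
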