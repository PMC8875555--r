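# The seven classifier backends behind the screening models. Each
# algorithm is wrapped as fit_classifier()/predict_classifier() returning a
# positive-class probability, with hyperparameter defaults pinned in
# default_hyperparameters() so runs are reproducible. Bernoulli naive
# Bayes is implemented in closed form, the natural likelihood for binary
# fingerprint bits.

ALGORITHMS <- c("KNN", "NB", "Logit", "DT", "RF", "MLP", "XGBoost")
# simplicity order used for tie-breaking in model selection (fewer
# effective parameters first)
SIMPLICITY_ORDER <- c("NB", "Logit", "KNN", "DT", "RF", "XGBoost", "MLP")

#' Pinned hyperparameter defaults per algorithm
#'
#' @return named list of named lists; these are the resolved values written
#'   into every model manifest.
#' @export
default_hyperparameters <- function() {
  list(
    KNN = list(k = 5L),
    NB = list(laplace = 1),
    Logit = list(alpha = 0, lambda_n = 1),   # ridge penalty lambda = lambda_n / n
    DT = list(cp = 0.01, minsplit = 20L),
    RF = list(ntree = 100L),
    MLP = list(size = 16L, decay = 1e-4, maxit = 200L, lr = 0.01),
    XGBoost = list(nrounds = 100L, eta = 0.3, max_depth = 6L)
  )
}

#' Model specification
#'
#' @param algorithm one of `KNN`, `NB`, `Logit`, `DT`, `RF`, `MLP`,
#'   `XGBoost`.
#' @param fingerprint_kind one of `ECFP4`, `ECFP6`, `MACCS`.
#' @param hyperparameters named list overriding the pinned defaults.
#' @param seed integer seed for the stochastic fitters.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(algorithm, fingerprint_kind = "ECFP4",
                       hyperparameters = NULL, seed = 1L) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  fingerprint_kind <- match.arg(fingerprint_kind, names(FP_LENGTH))
  hp <- utils::modifyList(default_hyperparameters()[[algorithm]],
                          as.list(hyperparameters))
  structure(list(algorithm = algorithm, fingerprint_kind = fingerprint_kind,
                 hyperparameters = hp, seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit a classifier on a labelled bit matrix
#'
#' @param x numeric 0/1 matrix (rows = molecules).
#' @param y labels (0/1).
#' @param spec a [model_spec()].
#' @return fitted handle of class `"ds_classifier"`.
#' @export
fit_classifier <- function(x, y, spec) {
  stopifnot(nrow(x) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("both classes required for training")
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  model <- switch(spec$algorithm,
    KNN = list(train = x, cl = y, k = hp$k),
    NB = bernoulli_nb_fit(x, y, alpha = hp$laplace),
    Logit = {
      lam <- hp$lambda_n / nrow(x)
      # warm-started path down to the target penalty; a lone small lambda
      # leaves the coordinate descent unconverged
      path <- exp(seq(log(100 * lam), log(lam), length.out = 30L))
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = hp$alpha,
                            lambda = path, standardize = FALSE)
      list(fit = fit, lambda = lam)
    },
    DT = {
      df <- as.data.frame(x)
      df$.y <- factor(y, levels = c(0, 1))
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minsplit = hp$minsplit))
    },
    RF = randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                    ntree = hp$ntree),
    MLP = mlp_fit(x, y, size = hp$size, decay = hp$decay,
                  epochs = hp$maxit, lr = hp$lr),
    XGBoost = xgboost::xgboost(x, factor(y, levels = c(0, 1)),
                               objective = "binary:logistic",
                               nrounds = hp$nrounds,
                               learning_rate = hp$eta,
                               max_depth = hp$max_depth,
                               nthreads = 1L, verbosity = 0L,
                               seed = spec$seed %% 2147483647)
  )
  structure(list(spec = spec, model = model), class = "ds_classifier")
}

# Closed-form Bernoulli naive Bayes with Laplace smoothing.
bernoulli_nb_fit <- function(x, y, alpha = 1) {
  pos <- y == 1
  n_pos <- sum(pos); n_neg <- sum(!pos)
  p1 <- (colSums(x[pos, , drop = FALSE]) + alpha) / (n_pos + 2 * alpha)
  p0 <- (colSums(x[!pos, , drop = FALSE]) + alpha) / (n_neg + 2 * alpha)
  list(log_p1 = log(p1), log_q1 = log1p(-p1),
       log_p0 = log(p0), log_q0 = log1p(-p0),
       log_prior1 = log(n_pos / (n_pos + n_neg)),
       log_prior0 = log(n_neg / (n_pos + n_neg)))
}

# Single-hidden-layer perceptron (tanh hidden, logistic output) trained
# full-batch with Adam on the cross-entropy plus an L2 penalty. Written
# with dense matrix ops so the cost per epoch is linear in the weight
# count; quasi-Newton MLP fitters are quadratic in it and intractable at
# 1024 inputs.
mlp_fit <- function(x, y, size = 16L, decay = 1e-4, epochs = 200L,
                    lr = 0.01) {
  n <- nrow(x); p <- ncol(x)
  W1 <- matrix(stats::rnorm(p * size, 0, 1 / sqrt(p)), p, size)
  b1 <- numeric(size)
  W2 <- matrix(stats::rnorm(size, 0, 1 / sqrt(size)), size, 1)
  b2 <- 0
  pars <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  m1 <- v1 <- lapply(pars, function(p_) p_ * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  for (t in seq_len(epochs)) {
    h <- tanh(sweep(x %*% pars$W1, 2L, pars$b1, "+"))
    z <- as.numeric(h %*% pars$W2) + pars$b2
    prob <- 1 / (1 + exp(-z))
    d_z <- (prob - y) / n
    grads <- list(
      W1 = crossprod(x, (d_z %*% t(pars$W2)) * (1 - h^2)) + decay * pars$W1,
      b1 = colSums((d_z %*% t(pars$W2)) * (1 - h^2)),
      W2 = crossprod(h, d_z) + decay * pars$W2,
      b2 = sum(d_z)
    )
    for (nm in names(pars)) {
      m1[[nm]] <- beta1 * m1[[nm]] + (1 - beta1) * grads[[nm]]
      v1[[nm]] <- beta2 * v1[[nm]] + (1 - beta2) * grads[[nm]]^2
      mhat <- m1[[nm]] / (1 - beta1^t)
      vhat <- v1[[nm]] / (1 - beta2^t)
      pars[[nm]] <- pars[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  pars
}

mlp_predict <- function(pars, x) {
  h <- tanh(sweep(x %*% pars$W1, 2L, pars$b1, "+"))
  z <- as.numeric(h %*% pars$W2) + pars$b2
  1 / (1 + exp(-z))
}

bernoulli_nb_predict <- function(m, x) {
  s1 <- m$log_prior1 + x %*% m$log_p1 + (1 - x) %*% m$log_q1
  s0 <- m$log_prior0 + x %*% m$log_p0 + (1 - x) %*% m$log_q0
  as.numeric(1 / (1 + exp(s0 - s1)))
}

#' Positive-class probability from a fitted classifier
#'
#' For the instance-based KNN the vote fraction among the k neighbours is
#' returned; all other backends expose a genuine probability output.
#'
#' @param handle a `"ds_classifier"`.
#' @param x matrix of fingerprints to score.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict_classifier <- function(handle, x) {
  spec <- handle$spec
  m <- handle$model
  switch(spec$algorithm,
    KNN = {
      set.seed(spec$seed)   # distance-tie resolution is randomized
      pred <- class::knn(m$train, x, factor(m$cl, levels = c(0, 1)),
                         k = m$k, prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "1", pwin, 1 - pwin)
    },
    NB = bernoulli_nb_predict(m, x),
    Logit = as.numeric(stats::predict(m$fit, x, type = "response",
                                      s = m$lambda)),
    DT = {
      p <- stats::predict(m, as.data.frame(x), type = "prob")
      as.numeric(p[, "1"])
    },
    RF = as.numeric(stats::predict(m, x, type = "prob")[, "1"]),
    MLP = mlp_predict(m, x),
    XGBoost = as.numeric(stats::predict(m, x))
  )
}
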