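# Unified fit-and-predict interface over the classifier panel.
#
# Hyperparameters follow common library defaults: Gaussian naive Bayes without
# tuning, RBF-kernel SVM with default cost, 5-nearest-neighbour voting,
# unregularized logistic regression, and a fully grown decision tree.

CLASSIFIER_IDS <- c("NBAYES", "SVM", "KNN", "LR", "DT")

#' Train a classifier and predict labels
#'
#' Thin dispatcher used by the fitness function, the cross-validation scorer
#' and the final model stage. `classifier` is one of `"NBAYES"` (Gaussian
#' naive Bayes), `"SVM"` (RBF kernel, `e1071`), `"KNN"` (5 neighbours,
#' `class`), `"LR"` (logistic regression) or `"DT"` (decision tree, `rpart`).
#'
#' @param classifier Classifier identifier.
#' @param train_x,test_x Numeric matrices (rows = samples).
#' @param train_y Factor with levels `NEG`/`POS`.
#' @return Factor of predicted labels for `test_x`, levels `NEG`/`POS`.
#' @export
predict_labels <- function(classifier, train_x, train_y, test_x) {
  classifier <- match.arg(toupper(classifier), CLASSIFIER_IDS)
  if (!is.matrix(train_x)) train_x <- as.matrix(train_x)
  if (!is.matrix(test_x)) test_x <- as.matrix(test_x)
  pred <- switch(classifier,
    NBAYES = {
      fit <- nb_train(train_x, train_y)
      nb_predict(fit, test_x)
    },
    SVM = {
      fit <- e1071::svm(x = train_x, y = train_y, kernel = "radial", scale = FALSE)
      stats::predict(fit, test_x)
    },
    KNN = class::knn(train = train_x, test = test_x, cl = train_y,
                     k = min(5L, nrow(train_x))),
    LR = lr_predict(train_x, train_y, test_x),
    DT = dt_predict(train_x, train_y, test_x)
  )
  factor(as.character(pred), levels = c("NEG", "POS"))
}

# ---- Gaussian naive Bayes ---------------------------------------------------
# Implemented in-package because the wrapper fitness evaluates it ~10^5-10^6
# times per analysis; the additive structure over features lets run_si()
# precompute per-feature log-density margins once per run (see fitness.R).
# A small absolute variance floor guards constant features.

NB_VAR_EPS <- 1e-9

nb_train <- function(x, y) {
  pos <- y == "POS"
  xp <- x[pos, , drop = FALSE]
  xn <- x[!pos, , drop = FALSE]
  stats_for <- function(m) {
    mu <- colMeans(m)
    v <- colSums(m * m) / nrow(m) - mu * mu
    v <- pmax(v * nrow(m) / (nrow(m) - 1), 0) + NB_VAR_EPS
    list(mu = mu, var = v)
  }
  list(pos = stats_for(xp), neg = stats_for(xn),
       log_prior_diff = log(nrow(xp)) - log(nrow(xn)))
}

# Per-sample, per-feature log-density difference (POS minus NEG).
nb_margin_matrix <- function(fit, newx) {
  ll <- function(s) {
    mu <- matrix(s$mu, nrow(newx), ncol(newx), byrow = TRUE)
    sg <- matrix(s$var, nrow(newx), ncol(newx), byrow = TRUE)
    -0.5 * (log(2 * pi * sg) + (newx - mu)^2 / sg)
  }
  ll(fit$pos) - ll(fit$neg)
}

nb_predict <- function(fit, newx) {
  margin <- rowSums(nb_margin_matrix(fit, newx)) + fit$log_prior_diff
  factor(ifelse(margin > 0, "POS", "NEG"), levels = c("NEG", "POS"))
}

# ---- logistic regression ----------------------------------------------------
# Unregularized fit; aliased/rank-deficient coefficients are zeroed, which is
# the usual pragmatic treatment when p approaches n.

lr_predict <- function(train_x, train_y, test_x) {
  y01 <- as.integer(train_y == "POS")
  fit <- suppressWarnings(stats::glm.fit(cbind(1, train_x), y01,
                                         family = stats::binomial()))
  b <- fit$coefficients
  b[is.na(b)] <- 0
  eta <- drop(cbind(1, test_x) %*% b)
  factor(ifelse(eta > 0, "POS", "NEG"), levels = c("NEG", "POS"))
}

# ---- decision tree ----------------------------------------------------------

dt_predict <- function(train_x, train_y, test_x) {
  colnames(train_x) <- paste0("f", seq_len(ncol(train_x)))
  colnames(test_x) <- colnames(train_x)
  df <- data.frame(.y = train_y, train_x)
  fit <- rpart::rpart(.y ~ ., data = df, method = "class",
                      control = rpart::rpart.control(minsplit = 2, minbucket = 1,
                                                     cp = 0, xval = 0,
                                                     maxcompete = 0, maxsurrogate = 0))
  stats::predict(fit, data.frame(test_x), type = "class")
}
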