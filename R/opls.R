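#' Fit a single-response PLS1 regression by NIPALS
#'
#' Classical NIPALS partial least squares for one response.  Per component:
#' \eqn{w = X'y/\|X'y\|}, \eqn{t = Xw}, \eqn{p = X't/(t't)},
#' \eqn{q = y't/(t't)}, then X is deflated by \eqn{tp'}.  Predictions are
#' \eqn{\hat y = \sum_a t_a q_a + \bar y}.
#'
#' @param X numeric matrix, observations in rows, variables in columns.
#' @param y numeric response vector.
#' @param ncomp number of predictive components.
#' @param center,scale centre columns (always recommended) and scale them
#'   to unit variance (UV scaling, the default to match upstream
#'   standardization).  y is always centred, never scaled.
#' @return an object of class `opls` (PLS1 is the zero-orthogonal-component
#'   base case) with scores `T`, loadings `P`, weights `W`, y-loadings `Q`,
#'   diagnostics `R2X`, `R2Y`, fitted values and residuals.
#' @export
pls1 <- function(X, y, ncomp = 1, center = TRUE, scale = TRUE) {
  pre <- opls_prepare(X, y, center, scale)
  Xs <- pre$Xs; yc <- pre$yc
  n <- nrow(Xs); p_var <- ncol(Xs)
  if (ncomp > min(n - 1L, p_var))
    stop("ncomp exceeds the rank bound min(n - 1, p)")
  ssx_tot <- sum(Xs^2)
  W <- P <- matrix(0, p_var, ncomp,
                   dimnames = list(colnames(Xs), NULL))
  Tm <- matrix(0, n, ncomp)
  Q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    comp <- nipals_component(Xs, yc)
    W[, a] <- comp$w; Tm[, a] <- comp$t; P[, a] <- comp$p; Q[a] <- comp$q
    Xs <- Xs - tcrossprod(comp$t, comp$p)
  }
  finish_opls(pre, W, Tm, P, Q,
              Wo = NULL, To = NULL, Po = NULL,
              ssx_tot = ssx_tot, method = "pls1")
}

#' Fit an orthogonal projections to latent structures (OPLS) model
#'
#' Splits the predictor variation into a part correlated with the response
#' and parts orthogonal to it.  Per orthogonal component (Trygg-Wold
#' O-PLS): from the current NIPALS weight/loading pair \eqn{(w, p)},
#' \eqn{w_o = p - (w'p)w} (normalised), \eqn{t_o = Xw_o},
#' \eqn{p_o = X't_o/(t_o't_o)}, and X is deflated by \eqn{t_o p_o'}.  After
#' `n_orth` rounds a single predictive component is fitted on the filtered
#' X.  With `n_orth = 0` the model is identical to a 1-component PLS1.
#' When a requested orthogonal component has no variation left the fit
#' stops early with a warning and fewer components.
#'
#' @inheritParams pls1
#' @param n_orth number of orthogonal components (>= 0, default 1).
#' @return an object of class `opls`; orthogonal weights/scores/loadings
#'   are in `Wo`, `To`, `Po`.
#' @export
opls <- function(X, y, n_orth = 1, center = TRUE, scale = TRUE) {
  if (n_orth < 0) stop("n_orth must be >= 0")
  pre <- opls_prepare(X, y, center, scale)
  Xs <- pre$Xs; yc <- pre$yc
  n <- nrow(Xs); p_var <- ncol(Xs)
  if (1L + n_orth > min(n - 1L, p_var))
    stop("n_orth too large for the data dimensions")
  ssx_tot <- sum(Xs^2)
  Wo <- Po <- matrix(0, p_var, 0)
  To <- matrix(0, n, 0)
  for (a in seq_len(n_orth)) {
    comp <- nipals_component(Xs, yc)
    w_o <- comp$p - sum(comp$w * comp$p) * comp$w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) {
      warning(sprintf(
        "no orthogonal variation left after %d component(s); stopping early",
        a - 1L))
      break
    }
    w_o <- w_o / nrm
    t_o <- as.numeric(Xs %*% w_o)
    p_o <- as.numeric(crossprod(Xs, t_o)) / sum(t_o^2)
    Wo <- cbind(Wo, w_o); To <- cbind(To, t_o); Po <- cbind(Po, p_o)
    Xs <- Xs - tcrossprod(t_o, p_o)
  }
  comp <- nipals_component(Xs, yc)
  W <- matrix(comp$w, p_var, 1, dimnames = list(colnames(pre$Xs), NULL))
  Tm <- matrix(comp$t, n, 1)
  P <- matrix(comp$p, p_var, 1)
  finish_opls(pre, W, Tm, P, comp$q, Wo = Wo, To = To, Po = Po,
              ssx_tot = ssx_tot, method = "opls")
}

# centring/scaling bookkeeping shared by pls1/opls
opls_prepare <- function(X, y, center, scale) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y dimensions do not match")
  if (nrow(X) < 2L) stop("at least 2 observations are required")
  if (stats::sd(y) == 0) stop("zero-variance response")
  x_mean <- if (center) colMeans(X) else rep(0, ncol(X))
  x_sd <- if (scale) apply(X, 2L, stats::sd) else rep(1, ncol(X))
  x_sd[x_sd == 0] <- 1
  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  y_mean <- mean(y)
  list(Xs = Xs, yc = y - y_mean, y = y,
       x_mean = x_mean, x_sd = x_sd, y_mean = y_mean)
}

# one NIPALS PLS1 component on the current (deflated) X
nipals_component <- function(Xs, yc) {
  w <- as.numeric(crossprod(Xs, yc))
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps)
    stop("X carries no covariance with y; component undefined")
  w <- w / nw
  t <- as.numeric(Xs %*% w)
  tt <- sum(t^2)
  p <- as.numeric(crossprod(Xs, t)) / tt
  q <- sum(yc * t) / tt
  list(w = w, t = t, p = p, q = q)
}

finish_opls <- function(pre, W, Tm, P, Q, Wo, To, Po, ssx_tot, method) {
  yhat <- as.numeric(Tm %*% Q) + pre$y_mean
  ss_res <- sum((pre$y - yhat)^2)
  ss_tot <- sum((pre$y - pre$y_mean)^2)
  r2x_pred <- colSums(Tm^2) * colSums(P^2) / ssx_tot
  r2x_orth <- if (!is.null(To) && ncol(To))
    colSums(To^2) * colSums(Po^2) / ssx_tot else numeric()
  structure(list(method = method,
                 W = W, T = Tm, P = P, Q = Q,
                 Wo = Wo, To = To, Po = Po,
                 x_mean = pre$x_mean, x_sd = pre$x_sd,
                 y_mean = pre$y_mean, y = pre$y,
                 fitted = yhat, residuals = pre$y - yhat,
                 R2X = sum(r2x_pred) + sum(r2x_orth),
                 R2X_pred = r2x_pred, R2X_orth = r2x_orth,
                 R2Y = 1 - ss_res / ss_tot,
                 n = length(pre$y), p = nrow(W),
                 n_comp = ncol(W),
                 n_orth = if (is.null(To)) 0L else ncol(To)),
            class = "opls")
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("<opls> %s model: %d predictive + %d orthogonal component(s)\n",
              x$method, x$n_comp, x$n_orth))
  cat(sprintf("n = %d observations, p = %d variables\n", x$n, x$p))
  cat(sprintf("R2X = %.4f, R2Y = %.4f\n", x$R2X, x$R2Y))
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  out <- list(method = object$method, n = object$n, p = object$p,
              n_comp = object$n_comp, n_orth = object$n_orth,
              R2X = object$R2X, R2Y = object$R2Y,
              R2X_pred = object$R2X_pred, R2X_orth = object$R2X_orth,
              vip_top = utils::head(sort(vip(object), decreasing = TRUE),
                                    10L))
  class(out) <- "summary.opls"
  out
}

#' @export
print.summary.opls <- function(x, ...) {
  cat(sprintf("%s model: %d predictive + %d orthogonal component(s)\n",
              toupper(x$method), x$n_comp, x$n_orth))
  cat(sprintf("n = %d, p = %d\nR2X = %.4f (pred %s; orth %s)\nR2Y = %.4f\n",
              x$n, x$p, x$R2X,
              paste(sprintf("%.3f", x$R2X_pred), collapse = " "),
              if (length(x$R2X_orth))
                paste(sprintf("%.3f", x$R2X_orth), collapse = " ")
              else "-",
              x$R2Y))
  cat("top VIP:\n"); print(round(x$vip_top, 3))
  invisible(x)
}

#' @export
fitted.opls <- function(object, ...) object$fitted

#' @export
residuals.opls <- function(object, ...) object$residuals

#' Regression coefficients of a PLS/OPLS model
#'
#' Collapses the latent-variable model to a linear predictor on the
#' original variable scale: \eqn{\hat y = b_0 + x'b}.  For OPLS the
#' coefficients describe the predictive part applied after orthogonal
#' filtering of new observations.
#'
#' @param object an [opls()] / [pls1()] fit.
#' @param ... unused.
#' @return named coefficient vector, first element `(Intercept)`.
#' @export
coef.opls <- function(object, ...) {
  # b in scaled space: W (P'W)^-1 Q
  b_scaled <- object$W %*% solve(crossprod(object$P, object$W),
                                 matrix(object$Q, ncol = 1L))
  b <- as.numeric(b_scaled) / object$x_sd
  intercept <- object$y_mean - sum(b * object$x_mean)
  stats::setNames(c(intercept, b), c("(Intercept)", rownames(object$W)))
}

#' Predict from a PLS/OPLS model
#'
#' New observations are centred/scaled with the training vectors, stripped
#' of each fitted orthogonal component in order, and projected on the
#' predictive component(s).
#'
#' @param object an [opls()] / [pls1()] fit.
#' @param newdata matrix of new observations (training data when omitted).
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.opls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  Xn <- as.matrix(newdata)
  if (ncol(Xn) != object$p) stop("newdata has the wrong number of variables")
  Xs <- sweep(sweep(Xn, 2L, object$x_mean), 2L, object$x_sd, "/")
  if (object$n_orth > 0L)
    for (a in seq_len(object$n_orth)) {
      t_o <- as.numeric(Xs %*% object$Wo[, a])
      Xs <- Xs - tcrossprod(t_o, object$Po[, a])
    }
  Tn <- Xs %*% object$W %*% solve(crossprod(object$P, object$W))
  as.numeric(Tn %*% object$Q) + object$y_mean
}

#' Score plot of an OPLS model
#'
#' Predictive score against the first orthogonal score (or against the
#' observation index when no orthogonal component exists), coloured by the
#' response.
#'
#' @param x an [opls()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.opls <- function(x, ...) {
  t1 <- x$T[, 1L]
  if (x$n_orth > 0L) {
    graphics::plot(t1, x$To[, 1L], xlab = "t[1] (predictive)",
                   ylab = "t_o[1] (orthogonal)", ...)
  } else {
    graphics::plot(seq_along(t1), t1, xlab = "observation",
                   ylab = "t[1] (predictive)", ...)
  }
  invisible(x)
}

#' Variable importance in projection
#'
#' \deqn{VIP_j = \sqrt{p \,\frac{\sum_a SSY_a (w_{aj}/\|w_a\|)^2}
#'       {\sum_a SSY_a}}, \qquad SSY_a = q_a^2\, t_a't_a.}
#' The mean of the squared VIP over variables is 1 by construction.
#' `mode = "predictive"` (default) sums predictive components only;
#' `mode = "total"` additionally folds in the orthogonal components,
#' weighted by the X variation they explain (total-VIP flavour).
#'
#' @param model a fitted [opls()] / [pls1()] model.
#' @param mode `"predictive"` or `"total"`.
#' @return named per-variable VIP vector.
#' @export
vip <- function(model, mode = c("predictive", "total")) {
  mode <- match.arg(mode)
  if (!inherits(model, "opls")) stop("a fitted opls/pls1 model is required")
  p_var <- model$p
  ssy <- model$Q^2 * colSums(model$T^2)
  num <- as.numeric(model$W^2 %*% ssy)   # columns of W are unit norm
  den <- sum(ssy)
  if (mode == "total" && model$n_orth > 0L) {
    ssx_o <- colSums(model$To^2) * colSums(model$Po^2)
    num <- num + as.numeric(model$Wo^2 %*% ssx_o)
    den <- den + sum(ssx_o)
  }
  stats::setNames(sqrt(p_var * num / den), rownames(model$W))
}

#' Cross-validated predictive power Q2
#'
#' \eqn{Q^2 = 1 - PRESS/SS_{tot}} with PRESS accumulated from k-fold
#' deleted predictions of the chosen model.  Folds are assigned round-robin
#' on observation order ("venetian blinds"); set `shuffle = TRUE` for a
#' seeded random assignment.  `folds` larger than n is reduced to n
#' (leave-one-out) with a warning.
#'
#' @inheritParams pls1
#' @param folds number of cross-validation segments (default 7).
#' @param n_orth orthogonal components of the refitted models (default 1;
#'   ignored when `method = "pls1"`).
#' @param ncomp predictive components for `method = "pls1"`.
#' @param method `"opls"` (default) or `"pls1"`.
#' @param shuffle randomise the fold assignment.
#' @param seed RNG seed used when `shuffle = TRUE`.
#' @return Q2 (scalar, <= 1; negative values mean worse than the mean).
#' @export
cross_validate_q2 <- function(X, y, folds = 7, n_orth = 1, ncomp = 1,
                              method = c("opls", "pls1"),
                              center = TRUE, scale = TRUE,
                              shuffle = FALSE, seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n < 3L) stop("at least 3 observations are required")
  if (folds < 2L) stop("at least 2 folds are required")
  if (folds > n) {
    warning("folds > n; reduced to leave-one-out")
    folds <- n
  }
  assign <- rep_len(seq_len(folds), n)
  if (shuffle) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                        envir = globalenv()))
      set.seed(seed)
    }
    assign <- sample(assign)
  }
  press <- 0
  for (f in seq_len(folds)) {
    test <- assign == f
    fit <- if (method == "opls")
      opls(X[!test, , drop = FALSE], y[!test], n_orth = n_orth,
           center = center, scale = scale)
    else
      pls1(X[!test, , drop = FALSE], y[!test], ncomp = ncomp,
           center = center, scale = scale)
    pred <- predict(fit, X[test, , drop = FALSE])
    press <- press + sum((y[test] - pred)^2)
  }
  1 - press / sum((y - mean(y))^2)
}

#' Response permutation test of an OPLS model
#'
#' The response is permuted `n_perm` times with a recorded seed; R2Y and
#' cross-validated Q2 are refitted for each permutation.  A sound model has
#' an original Q2 clearly above the permuted distribution.
#'
#' @inheritParams cross_validate_q2
#' @param n_perm number of permutations (default 200).
#' @param seed RNG seed (recorded in the report; default 0).
#' @return an object of class `permutation_report`: original `r2y`/`q2`,
#'   permuted distributions, their quantiles, and `n_exceed`, the count of
#'   permuted Q2 >= the original Q2.
#' @export
permutation_test <- function(X, y, n_perm = 200, seed = 0, n_orth = 1,
                             folds = 7, center = TRUE, scale = TRUE) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  X <- as.matrix(X); y <- as.numeric(y)
  fit <- opls(X, y, n_orth = n_orth, center = center, scale = scale)
  q2 <- suppressWarnings(
    cross_validate_q2(X, y, folds = folds, n_orth = n_orth,
                      center = center, scale = scale))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  r2y_perm <- q2_perm <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    yp <- sample(y)
    r2y_perm[i] <- suppressWarnings(
      opls(X, yp, n_orth = n_orth, center = center, scale = scale)$R2Y)
    q2_perm[i] <- suppressWarnings(
      cross_validate_q2(X, yp, folds = folds, n_orth = n_orth,
                        center = center, scale = scale))
  }
  structure(list(n_perm = n_perm, seed = seed,
                 r2y = fit$R2Y, q2 = q2,
                 r2y_perm = r2y_perm, q2_perm = q2_perm,
                 q2_quantiles = stats::quantile(q2_perm,
                                                c(.05, .25, .5, .75, .95)),
                 n_exceed = sum(q2_perm >= q2)),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat(sprintf("<permutation_report> %d permutations (seed %d)\n",
              x$n_perm, x$seed))
  cat(sprintf("original R2Y = %.4f, Q2 = %.4f\n", x$r2y, x$q2))
  cat(sprintf("permuted Q2 median = %.4f; %d/%d permutations reach Q2 >= original\n",
              stats::median(x$q2_perm), x$n_exceed, x$n_perm))
  invisible(x)
}

#' OPLS discriminant analysis
#'
#' Binary classes are coded as a +/-1 dummy response and passed to
#' [opls()].  With more than two classes a one-vs-all model is fitted per
#' class.
#'
#' @inheritParams opls
#' @param labels class label per observation (>= 2 classes).
#' @return for two classes, an `opls` fit carrying `classes` and `labels`
#'   (class `oplsda`); for more, a named list of one-vs-all `oplsda` fits
#'   (class `oplsda_multi`).
#' @export
oplsda <- function(X, labels, n_orth = 1, center = TRUE, scale = TRUE) {
  labels <- as.factor(labels)
  classes <- levels(droplevels(labels))
  if (length(classes) < 2L) stop("at least 2 classes are required")
  if (length(classes) == 2L) {
    y <- ifelse(labels == classes[2L], 1, -1)
    fit <- opls(X, y, n_orth = n_orth, center = center, scale = scale)
    fit$classes <- classes
    fit$labels <- labels
    class(fit) <- c("oplsda", "opls")
    return(fit)
  }
  fits <- lapply(classes, function(cl)
    oplsda(X, factor(ifelse(labels == cl, cl, "rest"),
                     levels = c("rest", cl)),
           n_orth = n_orth, center = center, scale = scale))
  names(fits) <- classes
  structure(fits, class = "oplsda_multi")
}

#' Principal component analysis by NIPALS
#'
#' Column-centred (optionally UV-scaled) NIPALS PCA with per-component
#' explained-variation fractions.
#'
#' @inheritParams pls1
#' @param n_comp number of components, at most `min(n - 1, p)`.
#' @param tol,max_iter NIPALS convergence controls.
#' @return an object of class `nipals_pca` with `scores`, `loadings`,
#'   `R2X` (per component) and the centring/scaling vectors.
#' @export
pca_nipals <- function(X, n_comp = 2, center = TRUE, scale = FALSE,
                       tol = 1e-12, max_iter = 1000) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  if (n_comp > min(n - 1L, p))
    stop("n_comp exceeds min(n - 1, p)")
  x_mean <- if (center) colMeans(X) else rep(0, p)
  x_sd <- if (scale) pmax(apply(X, 2L, stats::sd), .Machine$double.eps)
          else rep(1, p)
  Xs <- sweep(sweep(X, 2L, x_mean), 2L, x_sd, "/")
  ss_tot <- sum(Xs^2)
  scores <- matrix(0, n, n_comp)
  loadings <- matrix(0, p, n_comp, dimnames = list(colnames(X), NULL))
  r2x <- numeric(n_comp)
  for (a in seq_len(n_comp)) {
    t <- Xs[, which.max(apply(Xs, 2L, stats::var))]
    for (i in seq_len(max_iter)) {
      p_vec <- as.numeric(crossprod(Xs, t)) / sum(t^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- as.numeric(Xs %*% p_vec)
      if (sqrt(sum((t_new - t)^2)) < tol * sqrt(sum(t_new^2))) {
        t <- t_new; break
      }
      t <- t_new
    }
    scores[, a] <- t
    loadings[, a] <- p_vec
    r2x[a] <- sum(t^2) / ss_tot
    Xs <- Xs - tcrossprod(t, p_vec)
  }
  structure(list(scores = scores, loadings = loadings, R2X = r2x,
                 x_mean = x_mean, x_sd = x_sd, n = n, p = p),
            class = "nipals_pca")
}

#' @export
print.nipals_pca <- function(x, ...) {
  cat(sprintf("<nipals_pca> %d component(s), n = %d, p = %d\n",
              length(x$R2X), x$n, x$p))
  cat("R2X:", paste(sprintf("%.4f", x$R2X), collapse = " "), "\n")
  invisible(x)
}
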