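#' Standard-ML baseline adapter
#'
#' Thin wrapper around established implementations, used only for comparison
#' runs (they are not part of the Ising-method contract):
#' * `"logistic"` — unconstrained (multinomial) logistic regression via
#'   `stats::glm` for K = 2; for K > 2 via `glmnet` with `lambda = 0`.
#' * `"lasso"`, `"ridge"` — penalized logistic/multinomial regression via
#'   `glmnet`, lambda selected by internal cross-validation.
#'
#' @param dataset training `labeled_dataset`.
#' @param method one of `"logistic"`, `"lasso"`, `"ridge"`.
#' @param seed integer seed (used by glmnet's CV fold assignment).
#' @return A `baseline_model` with a `predict` method (`type = "class"` or
#'   `"prob"`).
#' @export
fit_baseline <- function(dataset, method = c("logistic", "lasso", "ridge"),
                         seed = 1L) {
  method <- match.arg(method)
  X <- dataset$features
  y <- dataset$labels
  K <- dataset$n_classes
  if (method == "logistic" && K == 2L) {
    df <- data.frame(y = as.integer(y == 2L), X)
    fitted <- suppressWarnings(stats::glm(y ~ ., data = df,
                                          family = stats::binomial()))
    obj <- list(method = method, fit = fitted, K = K)
  } else {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("glmnet is required for this baseline", call. = FALSE)
    }
    alpha <- if (method == "lasso") 1 else 0
    fam <- if (K == 2L) "binomial" else "multinomial"
    fitted <- with_seed(seed, {
      if (method == "logistic") {
        glmnet::glmnet(X, factor(y), family = fam, alpha = 0, lambda = 0)
      } else {
        glmnet::cv.glmnet(X, factor(y), family = fam, alpha = alpha,
                          nfolds = 5L)
      }
    })
    obj <- list(method = method, fit = fitted, K = K)
  }
  structure(obj, class = "baseline_model")
}

#' @export
predict.baseline_model <- function(object, newdata,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  K <- object$K
  if (inherits(object$fit, "glm")) {
    p2 <- stats::predict(object$fit,
                         newdata = data.frame(newdata), type = "response")
    P <- cbind(1 - p2, p2)
  } else {
    s <- if (inherits(object$fit, "cv.glmnet")) "lambda.min" else NULL
    pr <- stats::predict(object$fit, newx = as.matrix(newdata),
                         type = "response", s = s)
    P <- if (K == 2L) cbind(1 - pr[, 1L], pr[, 1L]) else pr[, , 1L]
  }
  colnames(P) <- NULL
  if (type == "prob") P else apply(P, 1L, which.max)
}
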