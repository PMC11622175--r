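#' Fit a linear max-margin classifier (C-SVC)
#'
#' Solves the binary C-SVC dual on the linear Gram matrix with a compact SMO
#' solver. With the small sample counts produced by super-trial averaging the
#' dual has only tens of variables, so fitting is dominated by one BLAS
#' `tcrossprod()` call; this is what makes sliding-window decoding over
#' hundreds of time points tractable.
#'
#' @param x numeric matrix, samples x features.
#' @param y vector with exactly two unique values; the first level (sorted, or
#'   factor level order) is scored as the positive class.
#' @param cost soft-margin cost parameter C.
#' @param tol KKT violation tolerance of the dual solver.
#' @return object of class `linsvm` with elements `w` (feature weights),
#'   `rho` (bias), `levels` (class levels; decision values are positive for
#'   the first level).
#' @examples
#' x <- rbind(matrix(rnorm(40, 2), 10), matrix(rnorm(40, -2), 10))
#' y <- rep(c("a", "b"), each = 10)
#' fit <- linsvm(x, y)
#' table(predict(fit, x), y)
#' @export
linsvm <- function(x, y, cost = 1, tol = 1e-4) {
  x <- as.matrix(x)
  lev <- if (is.factor(y)) levels(droplevels(y)) else sort(unique(y))
  if (length(lev) != 2L) {
    stop("linsvm() is a binary classifier; got ", length(lev), " classes")
  }
  ypm <- ifelse(as.character(y) == lev[1L], 1, -1)
  K <- tcrossprod(x)
  fit <- .smo_svc(K, ypm, C = cost, tol = tol)
  w <- crossprod(x, fit$alpha * ypm)
  structure(
    list(w = drop(w), rho = fit$rho, levels = lev, cost = cost),
    class = "linsvm"
  )
}

#' @rdname linsvm
#' @param object fitted `linsvm` object.
#' @param newdata numeric matrix of samples to score.
#' @param type `"class"` for hard labels, `"decision"` for signed decision
#'   values (positive for the first class level).
#' @param ... unused.
#' @export
predict.linsvm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  scores <- drop(as.matrix(newdata) %*% object$w) - object$rho
  if (type == "decision") {
    return(scores)
  }
  factor(ifelse(scores >= 0, object$levels[1L], object$levels[2L]),
         levels = object$levels)
}

#' Area under the ROC curve from decision scores
#'
#' Rank-based (Mann-Whitney) AUC. Ties in scores contribute 1/2.
#'
#' @param scores numeric decision values, larger for the positive class.
#' @param y labels; `positive` names the positive class.
#' @param positive the positive class label (default: first factor level or
#'   first sorted unique value).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, y, positive = NULL) {
  y <- as.character(y)
  if (is.null(positive)) {
    positive <- if (is.factor(y)) levels(y)[1L] else sort(unique(y))[1L]
  }
  pos <- y == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("auc_score() needs both classes present")
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
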