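#' Fit an extreme learning machine classifier
#'
#' Single-hidden-layer network with a fixed random hidden layer and
#' closed-form output weights: hidden activations
#' `H = act(X W' + b)` with input weights drawn uniformly on [-1, 1]
#' and biases on [0, 1], and output weights `beta = pinv(H) T` for
#' one-hot targets `T`, the minimum-norm least-squares solution via
#' the SVD-based pseudoinverse.
#'
#' @param features Feature tibble from [extract_features()] or a
#'   numeric matrix (observations x features).
#' @param labels Character or factor labels (quadrants).
#' @param n_hidden Hidden neurons `L` (default 9000).
#' @param activation_kind Hidden activation (`"sigmoid"`).
#' @param seed Integer seed for the random hidden layer.
#' @return An object of class `elm_model`.
#' @export
elm_fit <- function(features, labels, n_hidden = 9000,
                    activation_kind = c("sigmoid", "tanh", "relu"),
                    seed = 1) {
  activation_kind <- match.arg(activation_kind)
  X <- feature_matrix(features)
  if (!all(is.finite(X))) stop("non-finite feature values")
  labels <- factor(labels, levels = QUADRANTS)
  stopifnot(nrow(X) >= nlevels(labels), !anyNA(labels))
  if (!all(QUADRANTS %in% labels)) stop("all four classes must be present")
  d <- ncol(X)
  set.seed(seed)
  W <- matrix(runif(n_hidden * d, -1, 1), n_hidden, d)
  b <- runif(n_hidden, 0, 1)
  H <- activation(X %*% t(W) + rep(b, each = nrow(X)), activation_kind)
  Tmat <- matrix(0, nrow(X), nlevels(labels))
  Tmat[cbind(seq_len(nrow(X)), as.integer(labels))] <- 1
  beta <- pinv_solve(H, Tmat)
  structure(list(input_weights = W, hidden_biases = b,
                 output_weights = beta,
                 activation_kind = activation_kind,
                 classes = QUADRANTS, n_hidden = n_hidden, d = d,
                 seed = seed),
            class = "elm_model")
}

# minimum-norm least-squares via economical SVD with standard cutoff
pinv_solve <- function(H, Tmat) {
  sv <- svd(H)
  tol <- max(dim(H)) * max(sv$d) * .Machine$double.eps
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*%
    ((1 / sv$d[pos]) * (t(sv$u[, pos, drop = FALSE]) %*% Tmat))
}

#' @export
print.elm_model <- function(x, ...) {
  cat("<elm_model>", x$n_hidden, "hidden neurons,", x$d,
      "input features,", length(x$classes), "classes\n")
  invisible(x)
}

#' Predict with an extreme learning machine
#'
#' Computes hidden activations for the new inputs and the class scores
#' `H beta`; the predicted label is the arg-max with lowest-index
#' tie-break.
#'
#' @param model An `elm_model`.
#' @param features Feature tibble or matrix with the training
#'   dimensionality.
#' @return A list with `labels` (character) and `scores`
#'   (observations x classes matrix).
#' @export
elm_predict <- function(model, features) {
  X <- feature_matrix(features)
  if (ncol(X) != model$d) {
    stop("feature dimension ", ncol(X), " does not match model (",
         model$d, ")")
  }
  H <- activation(X %*% t(model$input_weights) +
                    rep(model$hidden_biases, each = nrow(X)),
                  model$activation_kind)
  scores <- H %*% model$output_weights
  colnames(scores) <- model$classes
  list(labels = model$classes[max.col(scores, ties.method = "first")],
       scores = scores)
}

#' Stratified internal train/validation split
#'
#' Splits observations per class at the given ratio (validation
#' accuracy of the ELM is reported alongside the fit; no tuning loop
#' uses it).
#'
#' @param n Number of observations, or a vector of labels (preferred:
#'   enables stratification).
#' @param labels Class labels, length `n`.
#' @param ratio Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `validation`.
#' @export
internal_split <- function(labels, ratio = 0.8, seed = 1) {
  n <- length(labels)
  stopifnot(n >= 5)
  set.seed(seed)
  for (attempt in 1:2) {
    train <- sort(unlist(lapply(unique(labels), function(cl) {
      idx <- which(labels == cl)
      sample(idx, round(length(idx) * ratio))
    })))
    validation <- setdiff(seq_len(n), train)
    ok <- setequal(unique(labels[train]), unique(labels)) &&
      setequal(unique(labels[validation]), unique(labels))
    if (ok) {
      return(list(train = train, validation = validation))
    }
  }
  stop("a class is absent from one side of the split")
}
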