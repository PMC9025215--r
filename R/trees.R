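#' Predict per-cell suitability from a fitted model
#'
#' Generic for every suitability learner in the package; all methods
#' return finite values in [0, 1].
#' @param model a fitted model object
#' @param x predictor matrix (columns must match the training columns)
#' @return numeric vector of suitabilities in [0, 1]
#' @export
predict_suitability <- function(model, x) UseMethod("predict_suitability")

align_columns <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$vars)) {
    missing <- setdiff(model$vars, colnames(x))
    if (length(missing)) stop("missing predictor columns: ",
                              paste(missing, collapse = ", "))
    x <- x[, model$vars, drop = FALSE]
  }
  x
}

#' Random-forest style bagged trees
#'
#' Probability forest: fully grown (depth-limited) CART regression trees
#' on the 0/1 response, each fitted to a bootstrap resample with
#' \code{mtry} features tried per split; the prediction is the tree mean.
#'
#' @param x predictor matrix
#' @param y 0/1 response (1 = presence, 0 = background)
#' @param num_trees number of trees (default 200)
#' @param mtry features tried per split (default floor(sqrt(p)))
#' @param min_node minimum node size (default 5)
#' @param max_depth maximum depth (default 20)
#' @return object of class \code{sdm_rf}
#' @export
fit_rf <- function(x, y, num_trees = 200, mtry = NULL, min_node = 5,
                   max_depth = 20) {
  x <- as.matrix(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  n <- nrow(x)
  trees <- vector("list", num_trees)
  for (t in seq_len(num_trees)) {
    rows <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- cpp_grow_tree(x, as.numeric(y), rows, as.integer(mtry),
                                as.integer(min_node), as.integer(max_depth))
  }
  structure(list(algorithm = "RF", trees = trees, vars = colnames(x),
                 mtry = mtry, min_node = min_node, max_depth = max_depth,
                 num_trees = num_trees),
            class = c("sdm_rf", "sdm_model"))
}

#' @export
predict_suitability.sdm_rf <- function(model, x) {
  x <- align_columns(model, x)
  p <- rowMeans(vapply(model$trees, function(tr) cpp_tree_predict(tr, x),
                       numeric(nrow(x))))
  pmin(1, pmax(0, p))
}

#' Boosted regression trees (logistic gradient boosting)
#'
#' Stochastic gradient boosting of shallow CART trees on the Bernoulli
#' deviance: each iteration fits a tree to the current gradient
#' (y - p) on a random \code{bag_frac} subsample and takes a per-leaf
#' Newton step, damped by the learning rate.
#'
#' @param x predictor matrix
#' @param y 0/1 response
#' @param n_trees boosting iterations (default 300)
#' @param learning_rate shrinkage (default 0.05)
#' @param depth tree depth (default 3)
#' @param bag_frac subsample fraction per iteration (default 0.75)
#' @param min_node minimum node size (default 10)
#' @return object of class \code{sdm_brt}
#' @export
fit_brt <- function(x, y, n_trees = 300, learning_rate = 0.05, depth = 3,
                    bag_frac = 0.75, min_node = 10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- nrow(x)
  pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  f0 <- log(pbar / (1 - pbar))
  fhat <- rep(f0, n)
  trees <- vector("list", n_trees)
  nbag <- max(2L, round(bag_frac * n))
  for (t in seq_len(n_trees)) {
    p <- 1 / (1 + exp(-fhat))
    r <- y - p
    rows <- sample.int(n, nbag)
    tree <- cpp_grow_tree(x, r, rows, ncol(x), as.integer(min_node),
                          as.integer(depth))
    # Newton step per leaf on the bagged rows
    leaf <- cpp_tree_leaf(tree, x)
    num <- tapply(r[rows], leaf[rows], sum)
    den <- tapply((p * (1 - p))[rows], leaf[rows], sum)
    gamma <- num / pmax(den, 1e-6)
    gamma <- pmax(pmin(gamma, 4), -4)
    vals <- tree$value
    vals[] <- 0
    vals[as.integer(names(gamma))] <- gamma
    tree$value <- vals
    trees[[t]] <- tree
    fhat <- fhat + learning_rate * vals[leaf]
  }
  structure(list(algorithm = "BRT", trees = trees, f0 = f0,
                 learning_rate = learning_rate, vars = colnames(x),
                 n_trees = n_trees, depth = depth),
            class = c("sdm_brt", "sdm_model"))
}

#' @export
predict_suitability.sdm_brt <- function(model, x) {
  x <- align_columns(model, x)
  f <- rep(model$f0, nrow(x))
  for (tree in model$trees)
    f <- f + model$learning_rate * cpp_tree_predict(tree, x)
  1 / (1 + exp(-f))
}

#' Bootstrap-bagged wrapper exposing per-cell prediction uncertainty
#'
#' Stand-in for a posterior-sampling tree ensemble: refits the supplied
#' learner on bootstrap resamples and exposes the across-replicate
#' standard deviation of predictions as per-cell uncertainty, preserving
#' the uncertainty-mask semantics without a Bayesian dependency. Any
#' fitting function returning a \code{predict_suitability}-capable model
#' can be plugged in.
#'
#' @param x predictor matrix
#' @param y 0/1 response
#' @param fit_fun base learner, function(x, y) -> model (default
#'   \code{fit_rf} with light settings)
#' @param n_boot bootstrap replicates (default 25)
#' @return object of class \code{sdm_bagged}
#' @export
fit_bagged <- function(x, y, fit_fun = function(x, y)
                         fit_rf(x, y, num_trees = 60), n_boot = 25) {
  x <- as.matrix(x)
  n <- nrow(x)
  members <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(n, n, replace = TRUE)
    # ensure both classes survive the resample
    if (length(unique(y[rows])) < 2)
      rows <- c(rows[-1], which(y != y[rows[1]])[1])
    members[[b]] <- fit_fun(x[rows, , drop = FALSE], y[rows])
  }
  structure(list(algorithm = "BAGGED", members = members,
                 vars = colnames(x)),
            class = c("sdm_bagged", "sdm_model"))
}

bagged_prediction_matrix <- function(model, x) {
  x <- align_columns(model, x)
  vapply(model$members, function(m) predict_suitability(m, x),
         numeric(nrow(x)))
}

#' @export
predict_suitability.sdm_bagged <- function(model, x) {
  rowMeans(bagged_prediction_matrix(model, x))
}

#' Per-cell prediction uncertainty of a bagged model
#' @param model an \code{sdm_bagged} model
#' @param x predictor matrix
#' @return per-row standard deviation across bootstrap members
#' @export
predict_uncertainty <- function(model, x) {
  if (!inherits(model, "sdm_bagged"))
    stop("model does not expose per-cell uncertainty")
  apply(bagged_prediction_matrix(model, x), 1, stats::sd)
}
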