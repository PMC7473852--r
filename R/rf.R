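#' Fit a classification random forest
#'
#' Bagged CART with Gini splits and a random feature subset of size `mtry`
#' at every node, trees grown to purity — the standard defaults of
#' classification random forests. Implemented in compiled code inside this
#' package; deterministic under [set.seed()] / the `seed` argument.
#'
#' @param x numeric matrix or data.frame of predictors.
#' @param y factor (or character) of class labels.
#' @param ntree number of trees.
#' @param mtry features tried per node; default `floor(sqrt(p))`.
#' @param seed integer seed.
#' @return object of class `mt_forest` (trees, class levels, feature
#'   names, settings).
#' @export
rf_fit <- function(x, y, ntree = 500L, mtry = NULL, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least two classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  forest <- with_seed(seed, rf_fit_cpp(x, as.integer(y) - 1L, nlevels(y),
                                       as.integer(ntree), as.integer(mtry)))
  structure(list(forest = forest, classes = levels(y),
                 features = colnames(x), ntree = as.integer(ntree),
                 mtry = as.integer(mtry), seed = as.integer(seed),
                 implementation = paste0("mangrovetyper CART forest ",
                                         as.character(utils::packageVersion("mangrovetyper")))),
            class = "mt_forest")
}

#' Predict classes and vote fractions from a fitted forest
#'
#' @param object an `mt_forest`.
#' @param newdata matrix or data.frame holding (at least) the training
#'   feature columns; a column mismatch is an error.
#' @param tie_break class priority used when vote counts tie exactly;
#'   default the model's class order.
#' @param ... unused.
#' @return data.frame with `class` and one `vote_<class>` fraction column
#'   per class.
#' @export
predict.mt_forest <- function(object, newdata, tie_break = object$classes,
                              ...) {
  newdata <- as.data.frame(newdata)
  if (!all(object$features %in% colnames(newdata)))
    stop("covariate columns mismatch training: missing ",
         paste(setdiff(object$features, colnames(newdata)), collapse = ", "))
  x <- as.matrix(newdata[, object$features, drop = FALSE])
  storage.mode(x) <- "double"
  if (nrow(x) == 0L) {
    out <- data.frame(class = character(0))
    for (cl in object$classes) out[[paste0("vote_", cl)]] <- numeric(0)
    return(out)
  }
  votes <- rf_votes_cpp(object$forest, x, length(object$classes))
  colnames(votes) <- object$classes
  ord <- match(tie_break, object$classes)
  pick <- max.col(votes[, ord, drop = FALSE], ties.method = "first")
  out <- data.frame(class = tie_break[pick], stringsAsFactors = FALSE)
  frac <- votes / object$ntree
  for (cl in object$classes) out[[paste0("vote_", cl)]] <- frac[, cl]
  out
}
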