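# Classifier plug-in registry.
#
# Every classifier is a pair of functions
#   train(X, y)        X: samples x features numeric matrix, y: integer 0/1
#   predict(model, X)  -> integer 0/1 predictions
# keyed by name.  The five defaults mirror the classical panel used for
# transcriptome work -- SVM, KNN, DTree, NBayes, LR -- and are implemented
# in compiled code with fixed, documented hyperparameters (see the methods
# vignette).  They are deterministic: no internal randomness, ties broken
# by index.

.rifs_registry <- new.env(parent = emptyenv())

.BUILTIN_CLASSIFIERS <- c("SVM", "KNN", "DTree", "NBayes", "LR")

.register_builtins <- function() {
  for (nm in .BUILTIN_CLASSIFIERS) {
    local({
      name <- nm
      assign(name, list(
        train = function(X, y) {
          structure(list(name = name, X = as.matrix(X), y = as.integer(y)),
                    class = "rifs_builtin_model")
        },
        predict = function(model, X) {
          .builtin_predict_cpp(model$name, model$X, model$y, as.matrix(X))
        },
        builtin = TRUE
      ), envir = .rifs_registry)
    })
  }
}

#' Names of the built-in classifiers
#'
#' @return `c("SVM", "KNN", "DTree", "NBayes", "LR")`: an RBF
#'   least-squares SVM, 5-nearest-neighbours, a CART decision tree grown to
#'   purity, Gaussian naive Bayes, and ridge-stabilised logistic regression.
#' @export
default_classifiers <- function() .BUILTIN_CLASSIFIERS

#' Register a classifier plug-in
#'
#' Additional classifiers participate in every evaluation (and in `mAcc`)
#' exactly like the built-ins.  Implementations must be deterministic, or
#' seed themselves from their inputs, for runs to be reproducible.
#'
#' @param name classifier name (overwrites an existing entry).
#' @param train `function(X, y)` returning an opaque model; `X` is a
#'   samples-by-features numeric matrix, `y` an integer 0/1 vector
#'   (1 = positive class).
#' @param predict `function(model, X)` returning integer 0/1 predictions.
#' @return Invisibly, `name`.
#' @export
register_classifier <- function(name, train, predict) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(train), is.function(predict))
  assign(name, list(train = train, predict = predict, builtin = FALSE),
         envir = .rifs_registry)
  invisible(name)
}

#' Look up a registered classifier
#' @param name classifier name.
#' @return list with elements `train`, `predict`, `builtin`.
#' @export
get_classifier <- function(name) {
  if (!exists(name, envir = .rifs_registry, inherits = FALSE))
    rifs_stop("rifs_classifier_error", paste("unknown classifier:", name))
  get(name, envir = .rifs_registry, inherits = FALSE)
}

.all_builtin <- function(names) {
  all(vapply(names, function(nm) isTRUE(get_classifier(nm)$builtin),
             logical(1)))
}
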