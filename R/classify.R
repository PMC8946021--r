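# Beat-class assignment for the pathology-specific reconstruction branch and
# for qualitative evaluation of reconstructed beats: alpha-max (largest
# mega-dictionary coefficient), k-nearest-neighbour (on compressed
# measurements or reconstructed patterns), and a 10-hidden-unit multilayer
# perceptron.

#' Alpha-max classification
#'
#' The beat is assigned the class of the mega-dictionary atom carrying the
#' largest absolute basis-pursuit coefficient. Ties break to the lowest atom
#' index; an all-zero coefficient vector is unclassifiable and returns
#' `NA_integer_`.
#'
#' @param code a `sparse_code` solved against `mega`.
#' @param mega the mega [cs_dictionary] (class-labelled atoms).
#' @return integer class label, or `NA_integer_` when unclassifiable.
#' @export
classify_alpha_max <- function(code, mega) {
  stopifnot(inherits(code, "sparse_code"), inherits(mega, "cs_dictionary"))
  if (!identical(code$dict_id, dict_id(mega)))
    stop_cs("sparse code was not solved against this dictionary",
            class = "cardiocs_bad_input")
  a <- abs(code$alpha)
  if (all(a == 0)) return(NA_integer_)
  as.integer(mega$meta$class_label[which.max(a)])
}

#' Fit a k-nearest-neighbour beat classifier
#'
#' Trains on the mega-dictionary atoms: in `"compressed"` mode every atom is
#' projected through the sensing matrix (so queries are raw measurement
#' vectors `y`); in `"reconstructed"` mode the atoms are used as-is (so
#' queries are 301-sample patterns, typically reconstructed ones). The model
#' is bound to the sensing matrix it was trained under; classifying
#' measurements taken under a different matrix is an error. The Euclidean
#' metric is used; prediction ties break to the smallest class id.
#'
#' @param mega class-labelled [cs_dictionary].
#' @param phi `projection_matrix` (required in compressed mode).
#' @param k neighbour count, default 1.
#' @param mode `"compressed"` or `"reconstructed"`.
#' @param unnormalize train on atoms rescaled back to their original
#'   amplitudes (recommended: queries are on the original amplitude scale).
#' @return object of class `knn_model`.
#' @export
knn_fit <- function(mega, phi = NULL, k = 1L, mode = c("compressed", "reconstructed"),
                    unnormalize = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(mega, "cs_dictionary"))
  labels <- mega$meta$class_label
  if (anyNA(labels)) stop_cs("mega dictionary atoms must be class-labelled",
                             class = "cardiocs_bad_input")
  atoms <- mega$atoms
  if (unnormalize && mega$normalized) atoms <- sweep(atoms, 2, mega$norms, "*")
  if (mode == "compressed") {
    stopifnot(inherits(phi, "projection_matrix"))
    if (phi$n != nrow(atoms))
      stop_cs("sensing N = %d != atom length %d", phi$n, nrow(atoms),
              class = "cardiocs_bad_input")
    train <- t(phi$phi %*% atoms)
    pid <- phi_id(phi)
  } else {
    train <- t(atoms)
    pid <- NULL
  }
  structure(list(train = train, labels = as.integer(labels), k = as.integer(k),
                 mode = mode, phi_id = pid),
            class = "knn_model")
}

#' Predict with a fitted KNN beat classifier
#'
#' @param model a `knn_model`.
#' @param y in compressed mode, a `cs_measurements` object (its `phi_id`
#'   must match the model's) or a bare measurement vector; in reconstructed
#'   mode, a length-301 pattern vector or [cardiac_pattern()].
#' @return integer class label (majority among the k nearest training
#'   atoms; ties to the smallest class id).
#' @export
knn_predict <- function(model, y) {
  stopifnot(inherits(model, "knn_model"))
  if (inherits(y, "cs_measurements")) {
    if (model$mode != "compressed")
      stop_cs("model was trained on reconstructed patterns, not measurements",
              class = "cardiocs_bad_input")
    if (!identical(y$phi_id, model$phi_id))
      stop_cs("measurements acquired under a different sensing matrix than the model",
              class = "cardiocs_bad_input")
    y <- y$y
  }
  if (inherits(y, "cardiac_pattern")) y <- y$x
  y <- as.numeric(y)
  if (length(y) != ncol(model$train))
    stop_cs("query length %d != training dimension %d", length(y),
            ncol(model$train), class = "cardiocs_bad_input")
  d2 <- rowSums(sweep(model$train, 2, y)^2)
  k <- min(model$k, length(d2))
  nn <- order(d2)[seq_len(k)]
  votes <- table(model$labels[nn])
  winners <- as.integer(names(votes)[votes == max(votes)])
  min(winners)
}

#' Fit a multilayer-perceptron beat classifier
#'
#' A single hidden layer of 10 units (softmax output), trained on feature
#' vectors such as compressed mega-dictionary atoms. Initialization is
#' seeded, so refitting with the same seed reproduces the model exactly.
#'
#' @param train_x numeric matrix, one row per training vector.
#' @param labels integer class labels (>= 2 distinct values).
#' @param hidden_units hidden-layer width, default 10.
#' @param seed initialization seed.
#' @param maxit training iteration cap (default 500).
#' @param phi_id optional sensing-matrix binding carried to prediction time.
#' @return object of class `mlp_model` wrapping the fitted network.
#' @export
mlp_fit <- function(train_x, labels, hidden_units = 10L, seed = 0L,
                    maxit = 500L, phi_id = NULL) {
  train_x <- as.matrix(train_x)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stop_cs("need at least 2 classes, got %d", length(classes),
            class = "cardiocs_bad_input")
  yfac <- factor(labels, levels = classes)
  fit <- with_seed(seed, {
    if (length(classes) == 2L)
      nnet::nnet(train_x, as.numeric(yfac) - 1, size = hidden_units,
                 maxit = maxit, trace = FALSE, decay = 1e-4)
    else
      nnet::nnet(train_x, nnet::class.ind(yfac), size = hidden_units,
                 softmax = TRUE, maxit = maxit, trace = FALSE, decay = 1e-4)
  })
  if (fit$convergence != 0)
    warning("mlp_fit: optimizer hit the iteration cap before converging")
  structure(list(fit = fit, classes = classes, hidden_units = as.integer(hidden_units),
                 phi_id = phi_id, binary = length(classes) == 2L),
            class = "mlp_model")
}

#' @rdname mlp_fit
#' @param model a fitted `mlp_model`.
#' @param x query vector or matrix (rows = queries).
#' @return integer class label(s) (argmax of the network output).
#' @export
mlp_predict <- function(model, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  p <- stats::predict(model$fit, x)
  if (model$binary) {
    model$classes[1L + as.integer(p[, 1] > 0.5)]
  } else {
    model$classes[apply(p, 1, which.max)]
  }
}

#' Collapse 8-class labels to normal/abnormal
#'
#' For evaluations where only the two-class distinction matters.
#'
#' @param labels integer class labels.
#' @param normal_class the class id regarded as normal (default 1).
#' @return integer vector: 1 = normal, 2 = abnormal.
#' @export
collapse_binary <- function(labels, normal_class = 1L) {
  ifelse(as.integer(labels) == as.integer(normal_class), 1L, 2L)
}

#' Confusion matrix with fixed class order
#'
#' @param truth,predicted integer label vectors (NA predictions allowed and
#'   counted in an `unclassified` column).
#' @param classes class ids defining row/column order; default union.
#' @return integer matrix, rows = truth, columns = predictions.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  classes <- classes %||% sort(unique(c(truth, predicted[!is.na(predicted)])))
  m <- matrix(0L, length(classes), length(classes) + 1L,
              dimnames = list(truth = classes,
                              predicted = c(classes, "unclassified")))
  for (i in seq_along(truth)) {
    r <- match(truth[i], classes)
    c0 <- if (is.na(predicted[i])) length(classes) + 1L else match(predicted[i], classes)
    m[r, c0] <- m[r, c0] + 1L
  }
  if (all(m[, ncol(m)] == 0L)) m <- m[, -ncol(m), drop = FALSE]
  m
}
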