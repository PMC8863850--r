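#' The 10 tissue-type labels
#'
#' Labels recognised by the tissue-type classifier (classifier #1): cancer
#' plus 9 non-cancer classes.
#'
#' @return character vector of length 10.
#' @export
tissue_class_labels <- function() {
  c("cancer", "non_tumoral_mucosa", "hyperplastic_mucosa", "adenoma",
    "lymphoid_tissue", "smooth_muscle", "vessels", "fat", "nerve",
    "background")
}

#' Training configuration for the reference tile classifiers
#'
#' The reference model is a single-hidden-layer neural network trained with
#' minibatch stochastic gradient descent on downscaled tiles — small enough
#' to train on one CPU in minutes. It fills the classifier contract; a
#' heavyweight convolutional backbone can be substituted behind the same
#' interface.
#'
#' @param learning_rate SGD step size.
#' @param n_iterations training epochs (full passes over the data).
#' @param batch_size minibatch size.
#' @param seed RNG seed governing init, data order and the train split.
#' @param input_px tiles are block-averaged to `input_px` x `input_px`
#'   before entering the network (default 24).
#' @param hidden_units hidden-layer width.
#' @param weight_decay L2 penalty.
#' @param momentum SGD momentum.
#' @param lr_decay multiplicative learning-rate decay per epoch; the
#'   returned weights are those with the lowest training loss seen, so a
#'   late bounce out of a good optimum cannot degrade the fit.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.02, n_iterations = 120L,
                         batch_size = 32L, seed = 1L, input_px = 24L,
                         hidden_units = 32L, weight_decay = 1e-4,
                         momentum = 0.9, lr_decay = 0.98) {
  stopifnot(learning_rate > 0, n_iterations >= 1, batch_size >= 1,
            input_px >= 4, hidden_units >= 1)
  structure(as.list(environment()), class = "train_config")
}

## Featurize one gray tile: block-average to input_px, then take the sorted
## pixel values (the gray-level distribution as order statistics — invariant
## to where texture elements sit) plus horizontal/vertical gradient energy.
tile_features <- function(im, input_px) {
  ds <- downscale_gray(as_gray8(im), input_px) / 255
  c(sort(as.vector(ds)),
    mean(abs(diff(ds))),      # vertical gradient energy
    mean(abs(t(diff(t(ds))))) # horizontal gradient energy
  )
}

## Stack tiles into a standardized feature matrix.
tile_feature_matrix <- function(images, input_px, center = NULL, scale = NULL) {
  X <- t(vapply(images, tile_features, numeric(input_px^2 + 2L),
                input_px = input_px))
  if (is.null(center)) {
    center <- colMeans(X)
    ## floor the scale so near-constant features cannot explode after
    ## standardization (pixel values live on [0, 1])
    scale <- pmax(apply(X, 2L, sd), 0.01)
  }
  X <- sweep(sweep(X, 2L, center), 2L, scale, `/`)
  attr(X, "center") <- center
  attr(X, "scale") <- scale
  X
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1L, max)
  E <- exp(S)
  E / rowSums(E)
}

mlp_forward <- function(net, X) {
  H <- tanh(sweep(X %*% net$W1, 2L, net$b1, `+`))
  softmax_rows(sweep(H %*% net$W2, 2L, net$b2, `+`))
}

## Minibatch-SGD training of a 1-hidden-layer softmax network.
## Returns the fitted weights plus per-epoch cross-entropy loss and accuracy.
mlp_train <- function(X, y, config) {
  classes <- levels(y)
  k <- length(classes)
  n <- nrow(X); d <- ncol(X); h <- config$hidden_units
  set.seed(config$seed)
  net <- list(W1 = matrix(rnorm(d * h, sd = sqrt(1 / d)), d, h),
              b1 = numeric(h),
              W2 = matrix(rnorm(h * k, sd = sqrt(1 / h)), h, k),
              b2 = numeric(k))
  vel <- lapply(net, function(p) p * 0)
  Y <- diag(k)[as.integer(y), , drop = FALSE]
  lr <- config$learning_rate; mom <- config$momentum; wd <- config$weight_decay
  history <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())
  best <- list(loss = Inf, net = net)
  for (epoch in seq_len(config$n_iterations)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[idx, , drop = FALSE]; Yb <- Y[idx, , drop = FALSE]
      A <- sweep(Xb %*% net$W1, 2L, net$b1, `+`)
      H <- tanh(A)
      P <- softmax_rows(sweep(H %*% net$W2, 2L, net$b2, `+`))
      dS <- (P - Yb) / nrow(Xb)
      g <- list(W1 = NULL, b1 = NULL, W2 = t(H) %*% dS + wd * net$W2,
                b2 = colSums(dS))
      dA <- (dS %*% t(net$W2)) * (1 - H^2)
      g$W1 <- t(Xb) %*% dA + wd * net$W1
      g$b1 <- colSums(dA)
      for (p in names(net)) {
        vel[[p]] <- mom * vel[[p]] - lr * g[[p]]
        net[[p]] <- net[[p]] + vel[[p]]
      }
    }
    P <- mlp_forward(net, X)
    loss <- -mean(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-12)))
    acc <- mean(max.col(P) == as.integer(y))
    history <- rbind(history, data.frame(epoch = epoch, loss = loss, accuracy = acc))
    if (loss < best$loss) best <- list(loss = loss, net = net)
    lr <- lr * (config$lr_decay %||% 1)
  }
  list(net = best$net, classes = classes, history = history)
}

#' Train the tissue-type tile classifier (classifier #1)
#'
#' Fits the reference network to labeled texture tiles. Every label must be
#' one of [tissue_class_labels()] and at least two classes must be present.
#' Cross-entropy loss and training accuracy are logged per epoch.
#'
#' @param tiles list with `images` (gray matrices) and `labels` (parallel
#'   character vector), e.g. from [generate_tissue_tiles()].
#' @param config a [train_config()].
#' @return a `tissue_classifier` with elements `net`, `classes`,
#'   `history`, `input_px`, `tile_px`, `center`, `scale`.
#' @export
train_tissue_classifier <- function(tiles, config = train_config()) {
  labels <- tiles$labels
  unknown <- setdiff(unique(labels), tissue_class_labels())
  if (length(unknown)) stop_tf("unknown tissue labels: %s", paste(unknown, collapse = ", "))
  if (length(unique(labels)) < 2L) {
    stop_tf("degenerate training set: only one class present")
  }
  X <- tile_feature_matrix(tiles$images, config$input_px)
  y <- factor(labels, levels = intersect(tissue_class_labels(), unique(labels)))
  fit <- mlp_train(X, y, config)
  structure(list(net = fit$net, classes = fit$classes, history = fit$history,
                 input_px = config$input_px,
                 tile_px = nrow(tiles$images[[1L]]),
                 center = attr(X, "center"), scale = attr(X, "scale"),
                 config = config),
            class = "tissue_classifier")
}

#' Train the LNM tile classifier (classifier #2) on weak labels
#'
#' Trains only on tiles whose cancer-class probability strictly exceeds
#' `cancer_prob_cutoff` (default 0.8), each tile weakly labeled with its
#' case's LNM status. Outputs a model that maps a tile to its metastatic
#' probability `p_met`.
#'
#' @param images list of gray tile matrices.
#' @param p_cancer numeric vector of per-tile cancer-class probabilities.
#' @param case_id character vector of per-tile case ids.
#' @param case_labels data.frame with `case_id` and `lnm_label`
#'   ("negative"/"positive").
#' @param cancer_prob_cutoff strict lower cutoff on `p_cancer`.
#' @param config a [train_config()].
#' @return an `lnm_tile_classifier`.
#' @export
train_lnm_tile_classifier <- function(images, p_cancer, case_id, case_labels,
                                      cancer_prob_cutoff = 0.8,
                                      config = train_config()) {
  keep <- which(p_cancer > cancer_prob_cutoff)
  if (length(keep) == 0L) {
    stop_tf("empty training set: no tile has p_cancer > %.3g", cancer_prob_cutoff)
  }
  lab <- case_labels$lnm_label[match(case_id[keep], case_labels$case_id)]
  if (anyNA(lab)) stop_tf("tiles reference case ids absent from case_labels")
  if (length(unique(lab)) < 2L) {
    stop_tf("both LNM classes must be present after the cancer-probability cutoff")
  }
  X <- tile_feature_matrix(images[keep], config$input_px)
  y <- factor(lab, levels = c("negative", "positive"))
  fit <- mlp_train(X, y, config)
  structure(list(net = fit$net, classes = fit$classes, history = fit$history,
                 input_px = config$input_px,
                 tile_px = nrow(images[[keep[1L]]]),
                 center = attr(X, "center"), scale = attr(X, "scale"),
                 cancer_prob_cutoff = cancer_prob_cutoff, config = config),
            class = "lnm_tile_classifier")
}

#' Classify tiles with a trained model
#'
#' Pure at inference: the same tile always yields the same probabilities,
#' and batch composition does not change outputs. Tiles whose resolution
#' differs from the training tiles are resized (block average) with a
#' warning.
#'
#' @param model a `tissue_classifier` or `lnm_tile_classifier`.
#' @param images list of gray tile matrices (may be empty).
#' @return for a tissue model, a data.frame with one probability column per
#'   class (`p_<class>`), `predicted_label` and `p_cancer`; for an LNM
#'   model, a data.frame with `p_met` and `p_nonmet`.
#' @export
classify_tiles <- function(model, images) {
  stopifnot(inherits(model, c("tissue_classifier", "lnm_tile_classifier")))
  if (length(images) == 0L) {
    return(if (inherits(model, "tissue_classifier")) {
      out <- as.data.frame(matrix(numeric(), 0L, length(model$classes) + 1L))
      names(out) <- c(paste0("p_", model$classes), "p_cancer")
      out$predicted_label <- character()
      out
    } else data.frame(p_met = numeric(), p_nonmet = numeric()))
  }
  px <- vapply(images, nrow, 0L)
  if (any(px != model$tile_px)) {
    warning(sprintf("tile resolution differs from training (%d px); resizing",
                    model$tile_px))
  }
  X <- tile_feature_matrix(images, model$input_px,
                           center = model$center, scale = model$scale)
  P <- mlp_forward(model$net, X)
  colnames(P) <- model$classes
  if (inherits(model, "tissue_classifier")) {
    out <- as.data.frame(P)
    names(out) <- paste0("p_", model$classes)
    out$predicted_label <- model$classes[max.col(P, ties.method = "first")]
    out$p_cancer <- if ("cancer" %in% model$classes) P[, "cancer"] else 0
    out
  } else {
    data.frame(p_met = P[, "positive"], p_nonmet = P[, "negative"])
  }
}

#' Flag cases with no detected cancer tile
#'
#' Cases in which the tissue classifier detects no cancer-class tile cannot
#' be scored and are excluded from the case-level model (mirroring the
#' clinical pipeline's exclusion step); they are flagged, not failed.
#'
#' @param tile_records data.frame with `case_id` and `predicted_label`
#'   (or `p_cancer` plus a cutoff when labels are unavailable).
#' @param case_ids all case ids under consideration.
#' @return character vector of excluded case ids.
#' @export
excluded_cases <- function(tile_records, case_ids) {
  has_cancer <- if ("predicted_label" %in% names(tile_records)) {
    unique(tile_records$case_id[tile_records$predicted_label == "cancer"])
  } else {
    unique(tile_records$case_id)
  }
  setdiff(case_ids, has_cancer)
}

#' Save / load a trained tile classifier
#'
#' The model weights are serialized as a versioned binary with a JSON
#' sidecar describing classes, input size and training config.
#'
#' @param model a trained classifier.
#' @param path output path for the binary (sidecar gets `.json` appended).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format_version = 1L, class = class(model)[1L],
               model = unclass(model)), path)
  side <- list(format_version = 1L, class = class(model)[1L],
               classes = model$classes, input_px = model$input_px,
               tile_px = model$tile_px,
               config = unclass(model$config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (is.null(x$format_version)) stop_tf("not a tileforest model file")
  structure(x$model, class = x$class)
}
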