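# Training: softmax cross-entropy with minibatch first-order optimizers.
# The fitting surface follows the classic modelling idiom: fabnet() returns
# a classed object with print/summary/coef/predict/plot methods.

#' Training configuration
#'
#' Defaults follow the tuned protocol: 100 epochs, learning rate 1e-3,
#' batch size 16 (64 is the class-folder-style default), Adam, categorical
#' cross-entropy on the softmax head, no data augmentation, no early
#' stopping.
#'
#' @param epochs number of passes over the training set.
#' @param learning_rate optimizer step size.
#' @param batch_size minibatch size.
#' @param optimizer one of adam, adadelta, adamax, sgd, rmsprop, nadam.
#' @param seed integer seed covering weight initialization and shuffling.
#' @param loss only \code{"categorical-cross-entropy"}.
#' @param task binary or multiclass (informational; the head width rules).
#' @return An object of class \code{"train_config"}.
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-3,
                         batch_size = 16L,
                         optimizer = c("adam", "adadelta", "adamax", "sgd",
                                       "rmsprop", "nadam"),
                         seed = 1L, loss = "categorical-cross-entropy",
                         task = c("binary", "multiclass")) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss, "categorical-cross-entropy")
  task <- match.arg(task)
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 optimizer = optimizer, seed = as.integer(seed),
                 loss = loss, task = task),
            class = "train_config")
}

# One optimizer step; st holds slot lists (m, v, u, t) keyed like params.
.opt_step <- function(params, grads, st, cfg) {
  lr <- cfg$learning_rate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; rho <- 0.95
  st$t <- st$t + 1L
  t <- st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    p <- params[[nm]]
    switch(cfg$optimizer,
      sgd = { p <- p - lr * g },
      adam = {
        st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
        st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
        p <- p - lr * (st$m[[nm]] / (1 - b1^t)) /
          (sqrt(st$v[[nm]] / (1 - b2^t)) + eps)
      },
      nadam = {
        st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
        st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
        mhat <- st$m[[nm]] / (1 - b1^t)
        vhat <- st$v[[nm]] / (1 - b2^t)
        p <- p - lr * (b1 * mhat + (1 - b1) * g / (1 - b1^t)) /
          (sqrt(vhat) + eps)
      },
      adamax = {
        st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
        st$u[[nm]] <- pmax(b2 * st$u[[nm]], abs(g))
        p <- p - (lr / (1 - b1^t)) * st$m[[nm]] / (st$u[[nm]] + eps)
      },
      rmsprop = {
        st$v[[nm]] <- 0.9 * st$v[[nm]] + 0.1 * g^2
        p <- p - lr * g / (sqrt(st$v[[nm]]) + eps)
      },
      adadelta = {
        st$v[[nm]] <- rho * st$v[[nm]] + (1 - rho) * g^2
        dx <- -sqrt(st$u[[nm]] + eps) / sqrt(st$v[[nm]] + eps) * g
        st$u[[nm]] <- rho * st$u[[nm]] + (1 - rho) * dx^2
        p <- p + lr * dx
      })
    params[[nm]] <- p
  }
  list(params = params, st = st)
}

.opt_init <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, u = zeros, t = 0L)
}

# Load a patch manifest into an (H, W, C, N) array scaled to [0, 1].
.load_patch_array <- function(manifest, input_shape) {
  n <- nrow(manifest)
  x <- array(0, c(input_shape[1], input_shape[2], input_shape[3], n))
  for (i in seq_len(n)) {
    img <- read_image(manifest$path[i])
    d <- dim(img)
    if (d[1] != input_shape[1] || d[2] != input_shape[2])
      img <- resize_bilinear(img, input_shape[1], input_shape[2])
    x[, , , i] <- img / 255
  }
  x
}

#' Fit a feature-agglomeration network
#'
#' The fitting function of the package. Accepts either a patch manifest
#' (data frame with \code{path} and \code{class_label} columns, as produced
#' by \code{\link{extract_cohort_patches}}) or a raw pixel array plus
#' labels. Trains with minibatch softmax cross-entropy for
#' \code{config$epochs} epochs; weight initialization, shuffling and batch
#' normalization are all governed by \code{config$seed}, so two runs with
#' identical inputs are identical.
#'
#' @param x patch manifest data frame, or array (height, width, channels, n).
#' @param y class labels (factor/character/integer); ignored when \code{x}
#'   is a manifest (the \code{class_label} column is used).
#' @param spec a \code{\link{fabnet_spec}}; defaults to a reduced
#'   single-pair variant sized to the input. Use
#'   \code{\link{default_fabnet_spec}} for the full network.
#' @param config a \code{\link{train_config}}.
#' @param split optional \code{\link{make_patient_split}} plan; when given,
#'   the manifest is audited and restricted to training-side patients so no
#'   test patient can leak into fitting.
#' @return An object of class \code{"fabnet"}: the trained model, the
#'   per-epoch \code{history} (loss, accuracy), the class levels, the
#'   config, and the provenance audit.
#' @export
fabnet <- function(x, y = NULL, spec = NULL, config = train_config(),
                   split = NULL) {
  stopifnot(inherits(config, "train_config"))
  audit <- NULL
  if (is.data.frame(x)) {
    manifest <- x
    if (!nrow(manifest)) stop("data error: empty training manifest")
    if (!is.null(split)) {
      stopifnot(inherits(split, "split_plan"))
      leaked <- intersect(unique(manifest$patient_id), split$test_patients)
      manifest <- split_side(manifest, split, "train")
      if (!nrow(manifest))
        stop("data error: no training-side patches after the split audit")
      audit <- list(excluded_test_patients = split$test_patients,
                    dropped_rows = length(leaked))
    }
    y <- manifest$class_label
    if (is.null(spec)) {
      first <- read_image(manifest$path[1])
      spec <- tiny_fabnet_spec(head_classes = length(unique(y)),
                               input_size = dim(first)[1])
    }
    xarr <- .load_patch_array(manifest, spec$input_shape)
  } else {
    if (is.null(y)) stop("y is required when x is a pixel array")
    if (length(dim(x)) != 4) stop("x must be a (H, W, C, N) array")
    if (is.null(spec))
      spec <- tiny_fabnet_spec(head_classes = length(unique(y)),
                               input_size = dim(x)[1])
    xarr <- x
    manifest <- NULL
  }
  validate_fabnet_spec(spec)
  classes <- if (is.factor(y)) levels(y) else sort(unique(as.character(y)))
  yi <- match(as.character(y), classes)
  if (anyNA(yi)) stop("label error: labels outside the class set")
  if (length(classes) != spec$head_classes)
    stop("label error: ", length(classes), " classes in the data but the ",
         "spec head has ", spec$head_classes, " units")
  n <- length(yi)

  model <- build_model(spec, seed = config$seed)
  st <- .opt_init(model$params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric())
  .with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        xb <- xarr[, , , idx, drop = FALSE]
        yb <- yi[idx]
        fw <- .forward_full(model, xb, training = TRUE, keep_cache = TRUE)
        model$state <- fw$state
        bw <- .backward_full(model, fw, yb)
        up <- .opt_step(model$params, bw$grads, st, config)
        model$params <- up$params
        st <- up$st
        ep_loss <- ep_loss + bw$loss * length(idx)
        pred <- max.col(fw$probs, ties.method = "first")
        ep_correct <- ep_correct + sum(pred == yb)
      }
      history[ep, ] <- list(ep, ep_loss / n, ep_correct / n)
    }
  })
  structure(list(model = model, history = history, classes = classes,
                 config = config, spec = spec, n_train = n, audit = audit),
            class = "fabnet")
}

#' @export
print.fabnet <- function(x, ...) {
  cat("Fitted feature-agglomeration network\n")
  cat("  classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  trainable parameters:",
      format(count_trainable_parameters(x$model), big.mark = ","), "\n")
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  %d epochs on %d patches; final loss %.4f, accuracy %.3f\n",
              nrow(x$history), x$n_train, last$loss, last$accuracy))
  invisible(x)
}

#' @export
summary.fabnet <- function(object, ...) {
  print(object)
  cat("\nArchitecture:\n")
  print(object$spec)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.fabnet <- function(object, ...) object$model$params

#' @export
plot.fabnet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$history$epoch, x$history$loss, type = "b", xlab = "epoch",
       ylab = "cross-entropy loss", main = "Training loss", ...)
  plot(x$history$epoch, x$history$accuracy, type = "b", xlab = "epoch",
       ylab = "accuracy", ylim = c(0, 1), main = "Training accuracy", ...)
  invisible(x)
}

#' Predict from a fitted network
#'
#' @param object a fitted \code{"fabnet"}.
#' @param newdata patch manifest data frame or (H, W, C, N) pixel array.
#' @param type \code{"prob"} for the probability matrix, \code{"class"} for
#'   hard labels, \code{"records"} for a prediction-record data frame with
#'   provenance (requires a manifest).
#' @param ... unused.
#' @return See \code{type}.
#' @export
predict.fabnet <- function(object, newdata,
                           type = c("prob", "class", "records"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    xarr <- .load_patch_array(newdata, object$spec$input_shape)
  } else {
    if (type == "records")
      stop("type = 'records' needs a manifest with provenance columns")
    xarr <- newdata
    if (length(dim(xarr)) == 3) dim(xarr) <- c(dim(xarr), 1L)
  }
  probs <- model_predict_probs(object$model, xarr)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  pred <- object$classes[max.col(probs, ties.method = "first")]
  if (type == "class") return(pred)
  prediction_records(
    patch_id = newdata$patch_id,
    image_id = newdata$source_image_id,
    patient_id = newdata$patient_id,
    true_label = newdata$class_label,
    probs = probs)
}

#' Per-patch probability records for a manifest
#'
#' One record per manifest row with the probability vector and full
#' patient/image lineage; probabilities sum to 1 per record.
#'
#' @param fit a fitted \code{"fabnet"}.
#' @param manifest patch manifest.
#' @return Prediction-record data frame (see
#'   \code{\link{prediction_records}}).
#' @export
predict_patches <- function(fit, manifest) {
  stopifnot(inherits(fit, "fabnet"))
  predict(fit, manifest, type = "records")
}
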