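#' Convolution block specification
#'
#' A block is the network's repeating unit: the input is sent through a 5x5
#' and a 3x3 convolution in parallel (stride 1, zero padding preserving the
#' spatial size, ReLU on each branch), the two activation maps are
#' concatenated along the channel axis, and a 1x1 convolution compresses the
#' concatenation to \code{reduce_width} channels, followed by batch
#' normalization and ReLU.
#'
#' @param index 1-based position of the block in the network.
#' @param filters_parallel number of kernels in each parallel convolution
#'   (the 5x5 and 3x3 branches use the same count).
#' @param reduce_width output channels of the 1x1 bottleneck convolution.
#'   Must not exceed \code{2 * filters_parallel}, the concatenation width.
#' @param use_batch_norm apply batch normalization after the 1x1 convolution.
#' @param activation activation function; only \code{"relu"} is supported.
#' @return An object of class \code{"conv_block_spec"}.
#' @export
conv_block_spec <- function(index, filters_parallel, reduce_width,
                            use_batch_norm = TRUE, activation = "relu") {
  stopifnot(is.numeric(index), index >= 1,
            is.numeric(filters_parallel), filters_parallel >= 1,
            is.numeric(reduce_width), reduce_width >= 1)
  activation <- match.arg(activation, "relu")
  if (reduce_width > 2 * filters_parallel)
    stop("reduce_width (", reduce_width, ") cannot exceed the concatenation ",
         "width 2 * filters_parallel (", 2 * filters_parallel, ")")
  structure(list(index = as.integer(index),
                 filters_parallel = as.integer(filters_parallel),
                 reduce_width = as.integer(reduce_width),
                 use_batch_norm = isTRUE(use_batch_norm),
                 activation = activation),
            class = "conv_block_spec")
}

#' Network architecture specification
#'
#' Declarative description of a feature-agglomeration network: an even number
#' of convolution blocks fused in consecutive pairs. Within a pair the first
#' block feeds the second; their outputs are concatenated and average-pooled
#' (2x2, stride 2), and the pooled map is both the next pair's input and that
#' stage's tap. All stage taps are average-pooled down to the final spatial
#' size, concatenated (the stage fusion), global-average pooled, and fed to a
#' dense softmax head.
#'
#' @param blocks list of \code{\link{conv_block_spec}} objects, length even.
#' @param head_classes number of output classes (>= 2).
#' @param input_shape integer vector (height, width, channels).
#' @return An object of class \code{"fabnet_spec"} with fields \code{blocks},
#'   \code{pairs}, \code{pool}, \code{stage_taps}, \code{head_classes},
#'   \code{input_shape}.
#' @export
fabnet_spec <- function(blocks, head_classes = 2L,
                        input_shape = c(224L, 224L, 3L)) {
  if (!is.list(blocks) || !length(blocks) ||
      !all(vapply(blocks, inherits, logical(1), "conv_block_spec")))
    stop("blocks must be a non-empty list of conv_block_spec objects")
  if (length(blocks) %% 2 != 0)
    stop("number of blocks must be even (blocks are fused in pairs)")
  if (!is.numeric(head_classes) || head_classes < 2)
    stop("head_classes must be at least 2")
  idx <- vapply(blocks, `[[`, integer(1), "index")
  if (!identical(idx, seq_along(blocks)))
    stop("block indices must be 1..n in order")
  n_pairs <- length(blocks) %/% 2L
  pairs <- lapply(seq_len(n_pairs), function(p) c(2L * p - 1L, 2L * p))
  spec <- structure(list(
    blocks = blocks,
    pairs = pairs,
    pool = list(type = "average", window = 2L, stride = 2L),
    stage_taps = paste0("C", seq_len(n_pairs)),
    head_classes = as.integer(head_classes),
    input_shape = as.integer(input_shape)
  ), class = "fabnet_spec")
  validate_fabnet_spec(spec)
  spec
}

#' @export
print.fabnet_spec <- function(x, ...) {
  f <- vapply(x$blocks, `[[`, integer(1), "filters_parallel")
  r <- vapply(x$blocks, `[[`, integer(1), "reduce_width")
  cat("Feature-agglomeration network spec\n")
  cat("  blocks:          ", length(x$blocks), " (", length(x$pairs),
      " fused pairs)\n", sep = "")
  cat("  parallel filters:", paste(f, collapse = " "), "\n")
  cat("  1x1 widths:      ", paste(r, collapse = " "), "\n")
  cat("  input:           ", paste(x$input_shape, collapse = "x"), "\n")
  cat("  head classes:    ", x$head_classes, "\n")
  cat("  conv layers:     ", count_conv_layers(x),
      " | trainable params: ", format(spec_parameter_count(x), big.mark = ","),
      "\n", sep = "")
  invisible(x)
}

validate_fabnet_spec <- function(spec) {
  stopifnot(inherits(spec, "fabnet_spec"))
  n <- length(spec$blocks)
  used <- unlist(spec$pairs)
  if (!setequal(used, seq_len(n)) || anyDuplicated(used))
    stop("every block index must appear in exactly one pair")
  if (!all(vapply(spec$pairs, function(p) p[2] == p[1] + 1L, logical(1))))
    stop("pairs must fuse consecutive blocks")
  if (length(spec$stage_taps) != length(spec$pairs))
    stop("number of stage taps must equal number of pairs")
  if (length(spec$input_shape) != 3 || any(spec$input_shape <= 0))
    stop("input_shape must be positive (height, width, channels)")
  invisible(spec)
}

#' The default 10-block network
#'
#' Canonical configuration: parallel filter counts
#' (16, 32, 32, 64, 64, 128, 128, 256, 256, 512) for blocks B1..B10, so the
#' five pairs follow an (f, 2f) progression; 1x1 bottleneck widths
#' \code{min(filters_parallel, reduce_cap)} with \code{reduce_cap = 32};
#' five stage taps C1..C5; 224x224x3 input.
#'
#' @param head_classes number of output classes (2 for benign/malignant,
#'   8 for the breast subtypes, 9 for the colorectal tissue classes).
#' @param reduce_cap cap on the 1x1 bottleneck width per block.
#' @return A \code{\link{fabnet_spec}}.
#' @export
default_fabnet_spec <- function(head_classes = 2L, reduce_cap = 32L) {
  if (!is.numeric(head_classes) || length(head_classes) != 1 ||
      head_classes < 2)
    stop("head_classes must be a single integer >= 2")
  filters <- c(16L, 32L, 32L, 64L, 64L, 128L, 128L, 256L, 256L, 512L)
  blocks <- lapply(seq_along(filters), function(i)
    conv_block_spec(i, filters[i], min(filters[i], as.integer(reduce_cap))))
  fabnet_spec(blocks, head_classes = head_classes)
}

#' A reduced variant for CPU-scale experiments
#'
#' Same topology as the full network but with fewer pairs, narrower filters
#' and a smaller input, suitable for training on synthetic cohorts without a
#' GPU. Pair p uses parallel filters (base * 2^(p-1), base * 2^p).
#'
#' @param head_classes number of output classes.
#' @param n_pairs number of fused block pairs (n_blocks = 2 * n_pairs).
#' @param base_filters parallel filter count of the first block.
#' @param reduce_cap cap on the 1x1 bottleneck width.
#' @param input_size spatial input size (square); must be divisible by
#'   \code{2^n_pairs}.
#' @return A \code{\link{fabnet_spec}}.
#' @export
tiny_fabnet_spec <- function(head_classes = 2L, n_pairs = 1L,
                             base_filters = 8L, reduce_cap = 8L,
                             input_size = 32L) {
  filters <- as.integer(unlist(lapply(seq_len(n_pairs), function(p)
    c(base_filters * 2^(p - 1), base_filters * 2^p))))
  blocks <- lapply(seq_along(filters), function(i)
    conv_block_spec(i, filters[i], min(filters[i], as.integer(reduce_cap))))
  fabnet_spec(blocks, head_classes = head_classes,
              input_shape = c(as.integer(input_size),
                              as.integer(input_size), 3L))
}

#' Count convolution layers
#'
#' Each block contributes three convolution layers (the 5x5 branch, the 3x3
#' branch, and the 1x1 bottleneck); pooling and dense layers are excluded.
#' The default 10-block network has 30.
#'
#' @param spec a \code{\link{fabnet_spec}}.
#' @return Integer layer count.
#' @export
count_conv_layers <- function(spec) {
  validate_fabnet_spec(spec)
  3L * length(spec$blocks)
}

# Channel widths entering each block, the pair-fusion widths, and the stage
# fusion width, derived purely from the spec. Used by both the closed-form
# parameter count and the shape tracer; kept independent of the built model.
spec_channel_plan <- function(spec) {
  n_pairs <- length(spec$pairs)
  in_ch <- integer(length(spec$blocks))
  pair_ch <- integer(n_pairs)
  prev <- spec$input_shape[3]
  for (p in seq_len(n_pairs)) {
    a <- spec$pairs[[p]][1]; b <- spec$pairs[[p]][2]
    in_ch[a] <- prev
    in_ch[b] <- spec$blocks[[a]]$reduce_width
    pair_ch[p] <- spec$blocks[[a]]$reduce_width + spec$blocks[[b]]$reduce_width
    prev <- pair_ch[p]
  }
  list(in_ch = in_ch, pair_ch = pair_ch, fusion_ch = sum(pair_ch))
}

#' Closed-form trainable parameter count
#'
#' Sums, per block, the 5x5 and 3x3 convolution weights and biases, the 1x1
#' bottleneck weights and biases, and the batch-norm scale and shift, plus
#' the dense softmax head, directly from the specification without building
#' the model. Serves as the independent oracle against
#' \code{\link{count_trainable_parameters}} on a built model.
#'
#' @param spec a \code{\link{fabnet_spec}}.
#' @return Total number of trainable scalars.
#' @export
spec_parameter_count <- function(spec) {
  validate_fabnet_spec(spec)
  plan <- spec_channel_plan(spec)
  total <- 0
  for (i in seq_along(spec$blocks)) {
    b <- spec$blocks[[i]]
    cin <- plan$in_ch[i]; f <- b$filters_parallel; r <- b$reduce_width
    total <- total +
      (25 * cin * f + f) +            # 5x5 conv + bias
      (9 * cin * f + f) +             # 3x3 conv + bias
      (2 * f * r + r) +               # 1x1 conv on the concat + bias
      if (b$use_batch_norm) 2 * r else 0
  }
  total + plan$fusion_ch * spec$head_classes + spec$head_classes
}

#' Trace feature-map shapes through the network
#'
#' Deterministic shape bookkeeping for every block output, pair fusion,
#' pooled pair output, stage bridge, the stage fusion, the global-average
#' pooled vector and the head, without building the model.
#'
#' @param spec a \code{\link{fabnet_spec}}.
#' @param input_shape (height, width, channels); defaults to the spec's.
#' @return Named list of integer \code{c(height, width, channels)} vectors in
#'   forward order.
#' @export
infer_feature_shapes <- function(spec, input_shape = spec$input_shape) {
  validate_fabnet_spec(spec)
  input_shape <- as.integer(input_shape)
  n_pairs <- length(spec$pairs)
  if (any(input_shape[1:2] %% 2^n_pairs != 0))
    stop("input spatial size ", input_shape[1], "x", input_shape[2],
         " is not divisible by 2^", n_pairs, " (one pooling per pair)")
  plan <- spec_channel_plan(spec)
  shapes <- list()
  h <- input_shape[1]; w <- input_shape[2]
  for (p in seq_len(n_pairs)) {
    a <- spec$pairs[[p]][1]; b <- spec$pairs[[p]][2]
    shapes[[paste0("B", a)]] <- c(h, w, spec$blocks[[a]]$reduce_width)
    shapes[[paste0("B", b)]] <- c(h, w, spec$blocks[[b]]$reduce_width)
    shapes[[paste0("pair", p, "_concat")]] <- c(h, w, plan$pair_ch[p])
    h <- h %/% 2L; w <- w %/% 2L
    shapes[[paste0("pair", p, "_pool")]] <- c(h, w, plan$pair_ch[p])
  }
  for (p in seq_len(n_pairs))
    shapes[[spec$stage_taps[p]]] <- c(h, w, plan$pair_ch[p])
  shapes[["stage_fusion"]] <- c(h, w, plan$fusion_ch)
  shapes[["gap"]] <- c(1L, 1L, plan$fusion_ch)
  shapes[["head"]] <- c(1L, 1L, spec$head_classes)
  lapply(shapes, as.integer)
}

#' Serialize an architecture spec
#'
#' Writes the spec as a JSON or YAML document (chosen by file extension)
#' with keys \code{blocks}, \code{pairs}, \code{pool}, \code{stage_taps},
#' \code{head_classes}, \code{input_shape}.
#'
#' @param spec a \code{\link{fabnet_spec}}.
#' @param path output file ending in \code{.json}, \code{.yaml} or
#'   \code{.yml}.
#' @return \code{path}, invisibly.
#' @export
write_architecture_spec <- function(spec, path) {
  validate_fabnet_spec(spec)
  doc <- list(
    blocks = lapply(spec$blocks, function(b)
      list(index = b$index, filters_parallel = b$filters_parallel,
           reduce_width = b$reduce_width, use_batch_norm = b$use_batch_norm,
           activation = b$activation)),
    pairs = spec$pairs,
    pool = spec$pool,
    stage_taps = as.list(spec$stage_taps),
    head_classes = spec$head_classes,
    input_shape = spec$input_shape
  )
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(doc, path)
  } else stop("unsupported spec format: .", ext)
  invisible(path)
}

#' @rdname write_architecture_spec
#' @export
read_architecture_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
         else if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else stop("unsupported spec format: .", ext)
  blocks <- lapply(doc$blocks, function(b)
    conv_block_spec(b$index, b$filters_parallel, b$reduce_width,
                    isTRUE(b$use_batch_norm), b$activation))
  fabnet_spec(blocks, head_classes = doc$head_classes,
              input_shape = unlist(doc$input_shape))
}
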