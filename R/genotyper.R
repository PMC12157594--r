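#' Genotyper model configuration
#'
#' A deliberately small convolutional classifier: three 3x3 convolution
#' blocks (16/32/64 filters, stride-2 downsampling, ReLU) over the
#' (2*height, width, 6) tensor, one dense ReLU layer with dropout, and a
#' softmax over the three genotype classes. Sized to train in minutes on
#' one CPU. Class weighting is inverse-frequency by default because
#' reference (false-candidate) examples are usually the minority or
#' majority class depending on the scenario; every stochastic element
#' (initialization, shuffling, dropout) derives from `seed`.
#'
#' @param conv_filters Filters per conv block.
#' @param kernel,stride Convolution kernel size and stride.
#' @param dense Width of the dense hidden layer.
#' @param dropout Dropout rate on the dense layer during training.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without holdout-loss
#'   improvement) when holdout examples exist.
#' @param seed Integer seed for all model randomness.
#' @param class_weighting `"inverse"` (inverse class frequency) or
#'   `"none"`.
#' @return A `model_config` list.
#' @export
model_config <- function(conv_filters = c(16L, 32L, 64L), kernel = 3L,
                         stride = 2L, dense = 64L, dropout = 0.2,
                         learning_rate = 1e-3, batch_size = 32L,
                         epochs = 10L, patience = 3L, seed = 1L,
                         class_weighting = c("inverse", "none")) {
  stopifnot(all(conv_filters >= 1L), kernel >= 1L, stride >= 1L,
            dense >= 1L, dropout >= 0, dropout < 1, learning_rate > 0,
            batch_size >= 1L, epochs >= 1L, patience >= 1L)
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), stride = as.integer(stride),
                 dense = as.integer(dense), dropout = dropout,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed),
                 class_weighting = match.arg(class_weighting)),
            class = "model_config")
}

arch_list <- function(config) {
  list(filters = config$conv_filters, kernel = config$kernel,
       stride = config$stride, pad = 1L, dense = config$dense)
}

example_dims <- function(examples) {
  c(2L * examples$height, examples$width, length(examples$channels))
}

class_weights_from_labels <- function(labels, weighting) {
  w <- rep(1, 3)
  if (weighting == "inverse") {
    tab <- tabulate(labels + 1L, nbins = 3L)
    present <- tab > 0L
    w[present] <- sum(tab) / (sum(present) * tab[present])
  }
  w
}

#' Train the genotype classifier
#'
#' Examples on `holdout_contigs` are excluded from gradient updates and
#' used for per-epoch holdout loss/accuracy and early stopping — the
#' held-out-chromosome convention. The returned model carries the
#' training log and the tensor/channel descriptor it was trained on.
#'
#' @param examples A labelled `pg_examples` object.
#' @param config A [model_config].
#' @param holdout_contigs Contigs reserved for validation (may be empty).
#' @return A `pg_genotyper`: list with `weights`, `arch`, `dims`,
#'   `channels`, `log`, `best_epoch`, `config`.
#' @export
train_genotyper <- function(examples, config = model_config(),
                            holdout_contigs = NULL) {
  labels <- examples$meta$label
  if (anyNA(labels)) stop("examples must be labelled before training")
  ho <- examples$meta$contig %in% holdout_contigs
  if (all(ho)) stop("holdout contigs cover every example; nothing to train on")
  train_labels <- labels[!ho]
  if (length(unique(train_labels)) < 2L) {
    stop("training set contains a single genotype class; cannot train")
  }
  dims <- example_dims(examples)
  cw <- class_weights_from_labels(train_labels, config$class_weighting)
  opt <- list(lr = config$learning_rate, batch_size = config$batch_size,
              epochs = config$epochs, patience = config$patience,
              dropout = config$dropout, seed = as.double(config$seed),
              class_weights = cw)
  res <- cpp_cnn_train(examples$tensors, as.integer(labels),
                       which(!ho), which(ho), arch_list(config), opt, dims)
  structure(list(weights = res$weights, arch = arch_list(config),
                 dims = dims, channels = examples$channels,
                 log = as.data.table(res$log), best_epoch = res$best_epoch,
                 config = config),
            class = "pg_genotyper")
}

#' @export
print.pg_genotyper <- function(x, ...) {
  cat("<pg_genotyper> input (", paste(x$dims, collapse = ", "),
      "), conv ", paste(x$arch$filters, collapse = "/"),
      ", dense ", x$arch$dense, ", best epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Predict genotype probabilities
#'
#' @param model A `pg_genotyper`.
#' @param examples A `pg_examples` object with the same tensor shape and
#'   channel descriptor the model was trained on.
#' @return Matrix with columns `p_ref`, `p_het`, `p_hom`; one row per
#'   example, each row summing to 1.
#' @export
predict_genotypes <- function(model, examples) {
  dims <- example_dims(examples)
  if (!identical(as.integer(dims), as.integer(model$dims))) {
    stop("tensor shape mismatch: model expects (",
         paste(model$dims, collapse = ", "), "), examples are (",
         paste(dims, collapse = ", "), ")")
  }
  if (!identical(examples$channels, model$channels)) {
    stop("channel descriptor mismatch between model and examples")
  }
  p <- cpp_cnn_predict(model$weights, examples$tensors, model$arch,
                       as.integer(dims))
  colnames(p) <- c("p_ref", "p_het", "p_hom")
  p
}

#' Save a model checkpoint
#'
#' A JSON header (architecture, dims, channels, shapes) followed by the
#' weights as float32, gzip-compressed. Reloading reproduces predictions
#' bitwise because weights are stored at their native precision.
#'
#' @param model A `pg_genotyper`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  shapes <- lapply(model$weights, function(w) as.integer(dim(w)))
  header <- jsonlite::toJSON(list(
    package = "pangecall", format = 1L,
    arch = model$arch, dims = model$dims, channels = model$channels,
    best_epoch = model$best_epoch,
    weight_names = names(model$weights), weight_shapes = shapes),
    auto_unbox = TRUE, digits = NA)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  hraw <- charToRaw(as.character(header))
  writeBin(length(hraw), con, size = 4L)
  writeBin(hraw, con)
  for (w in model$weights) writeBin(as.numeric(w), con, size = 4L)
  invisible(path)
}

#' Load a model checkpoint written by [save_checkpoint]
#' @param path Checkpoint path.
#' @return A `pg_genotyper`.
#' @export
load_checkpoint <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hlen <- readBin(con, "integer", 1L, size = 4L)
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", hlen)),
                               simplifyVector = TRUE)
  if (!identical(header$package, "pangecall")) {
    stop("not a pangecall checkpoint: ", path)
  }
  weights <- vector("list", length(header$weight_names))
  names(weights) <- header$weight_names
  for (i in seq_along(weights)) {
    shp <- as.integer(header$weight_shapes[[i]])
    w <- readBin(con, "numeric", prod(shp), size = 4L)
    dim(w) <- shp
    weights[[i]] <- w
  }
  arch <- header$arch
  arch$filters <- as.integer(arch$filters)
  structure(list(weights = weights, arch = arch,
                 dims = as.integer(header$dims),
                 channels = as.character(header$channels),
                 log = NULL, best_epoch = header$best_epoch, config = NULL),
            class = "pg_genotyper")
}
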