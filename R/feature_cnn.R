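# Feature-extraction CNNs: specification, training, scoring, and the
# fold-level feature matrix P consumed by the forest.

#' Specification of one feature-extraction CNN
#'
#' Defaults follow the reference configuration: two 3 x 3 stride-2
#' convolutions with 32 and 64 filters, ReLU activations, one dense layer
#' of 128 units, a single linear output unit trained with hinge loss and
#' an L2 weight penalty of 0.001, batch size 256, 10 epochs.
#'
#' @param input_shape integer pair; images must be preprocessed to this
#'   shape before training/scoring.
#' @param n_conv_layers number of convolution layers.
#' @param filters integer vector of filter counts, one per conv layer.
#' @param kernel_size integer pair (square kernels only).
#' @param stride convolution stride.
#' @param activation hidden activation; only `"relu"` is implemented.
#' @param n_dense_layers number of dense hidden layers (only 1 supported).
#' @param dense_units units in the dense hidden layer.
#' @param loss training loss; only `"hinge"` is implemented.
#' @param l2_coefficient L2 penalty coefficient on weight matrices.
#' @param batch_size mini-batch size.
#' @param optimizer `"adagrad"`, `"rmsprop"` or `"adam"`.
#' @param epochs training epochs.
#' @param learning_rate step size; `NULL` uses the optimizer's standard
#'   default (Adagrad 0.01, RMSProp 0.001, Adam 0.001).
#' @param select_best_epoch keep the weights from the epoch with minimum
#'   validation loss (when a validation subset is supplied) instead of the
#'   final weights.
#' @return a `cnn_spec` list.
#' @export
cnn_spec <- function(input_shape = c(100L, 100L), n_conv_layers = 2L,
                     filters = c(32L, 64L), kernel_size = c(3L, 3L),
                     stride = 2L, activation = "relu", n_dense_layers = 1L,
                     dense_units = 128L, loss = "hinge",
                     l2_coefficient = 0.001, batch_size = 256L,
                     optimizer = "adam", epochs = 10L,
                     learning_rate = NULL, select_best_epoch = TRUE) {
  spec <- list(input_shape = as.integer(input_shape),
               n_conv_layers = as.integer(n_conv_layers),
               filters = as.integer(filters),
               kernel_size = as.integer(kernel_size),
               stride = as.integer(stride),
               activation = tolower(activation),
               n_dense_layers = as.integer(n_dense_layers),
               dense_units = as.integer(dense_units),
               loss = tolower(loss),
               l2_coefficient = l2_coefficient,
               batch_size = as.integer(batch_size),
               optimizer = tolower(optimizer),
               epochs = as.integer(epochs),
               learning_rate = learning_rate,
               select_best_epoch = isTRUE(select_best_epoch))
  if (length(spec$filters) != spec$n_conv_layers)
    stop("filters must have one entry per convolution layer")
  if (any(c(spec$filters, spec$dense_units, spec$epochs, spec$batch_size,
            spec$stride, spec$kernel_size, spec$input_shape) < 1L))
    stop("all cnn_spec size fields must be positive")
  if (spec$kernel_size[1] != spec$kernel_size[2])
    stop("only square kernels are supported")
  if (spec$activation != "relu") stop("only ReLU activation is implemented")
  if (spec$loss != "hinge") stop("only hinge loss is implemented")
  if (spec$n_dense_layers != 1L)
    stop("exactly one dense hidden layer is supported")
  if (!spec$optimizer %in% c("adagrad", "rmsprop", "adam"))
    stop("optimizer must be one of adagrad, rmsprop, adam")
  structure(spec, class = "cnn_spec")
}

# Build the layer plans for a spec (validates that the input is large
# enough for the conv stack).
cnn_build_plans <- function(spec) {
  H <- spec$input_shape[1]; W <- spec$input_shape[2]; Cin <- 1L
  plans <- vector("list", spec$n_conv_layers)
  for (i in seq_len(spec$n_conv_layers)) {
    plans[[i]] <- conv_plan(H, W, Cin, spec$filters[i],
                            k = spec$kernel_size[1], s = spec$stride)
    H <- plans[[i]]$Ho; W <- plans[[i]]$Wo; Cin <- spec$filters[i]
  }
  plans
}

# Stack dataset images (already at spec shape) into a (H*W) x B matrix.
dataset_matrix <- function(dataset, ids, input_shape) {
  idx <- match(ids, dataset$sample_id)
  if (anyNA(idx)) stop("sample id(s) not present in dataset")
  npix <- prod(input_shape)
  X <- matrix(0, npix, length(idx))
  for (j in seq_along(idx)) {
    img <- dataset$images[[idx[j]]]
    if (!identical(dim(img), as.integer(input_shape)))
      stop(sprintf("image %s has shape %dx%d, expected %dx%d (preprocess first)",
                   ids[j], nrow(img), ncol(img),
                   input_shape[1], input_shape[2]))
    X[, j] <- img
  }
  X
}

#' Partition a training fold into n disjoint, class-stratified subsets
#'
#' Subsets are pairwise disjoint, cover the fold exactly, have sizes
#' differing by at most one, and each preserves the fold's class ratio
#' within rounding.
#'
#' @param sample_ids character vector of fold sample ids.
#' @param labels 0/1 labels aligned with `sample_ids`.
#' @param n number of subsets (>= 2, <= fold size).
#' @param rng_seed integer seed for the shuffles.
#' @return list of `n` character vectors of sample ids.
#' @export
partition_subsets <- function(sample_ids, labels, n, rng_seed = 1L) {
  if (n < 2L) stop("n must be at least 2")
  if (n > length(sample_ids)) stop("n exceeds the fold size")
  if (length(labels) != length(sample_ids))
    stop("labels must align with sample_ids")
  with_seed(rng_seed, {
    subsets <- rep(list(character(0)), n)
    totals <- integer(n)
    for (cls in c(0L, 1L)) {
      ids <- sample(sample_ids[labels == cls])
      m <- length(ids)
      sizes <- rep(m %/% n, n)
      extra <- m %% n
      if (extra > 0L) {
        # give remainders to the currently smallest subsets (ties random)
        ord <- order(totals, stats::runif(n))
        sizes[ord[seq_len(extra)]] <- sizes[ord[seq_len(extra)]] + 1L
      }
      stop_at <- cumsum(sizes)
      start <- c(1L, utils::head(stop_at, -1L) + 1L)
      for (i in seq_len(n)) {
        if (sizes[i] > 0L)
          subsets[[i]] <- c(subsets[[i]], ids[start[i]:stop_at[i]])
      }
      totals <- totals + sizes
    }
    subsets
  })
}

#' Train one feature-extraction CNN
#'
#' Trains with seeded mini-batch SGD using the spec's optimizer and hinge
#' loss on targets \eqn{\pm 1}.  When a validation subset is given and
#' `spec$select_best_epoch` is `TRUE`, the returned weights are those of
#' the epoch with the lowest validation loss.
#'
#' @param train_ids,val_ids disjoint character vectors of sample ids;
#'   `val_ids = NULL` trains without validation (no epoch selection).
#' @param dataset a `cohort_dataset` whose images already have the spec's
#'   input shape.
#' @param spec a [cnn_spec()].
#' @param rng_seed seed controlling initialisation and batch order.
#' @return a `feature_extractor` with elements `spec`, `params`,
#'   `training_log` (one row per epoch: epoch, train_loss, val_loss),
#'   `best_epoch` and `initial_loss` (train/val loss at initialisation).
#' @export
train_cnn <- function(train_ids, val_ids, dataset, spec, rng_seed = 1L) {
  if (!length(train_ids)) stop("empty training set")
  if (!is.null(val_ids) && length(intersect(train_ids, val_ids)))
    stop("train and validation subsets must be disjoint")
  ytr <- dataset$label[match(train_ids, dataset$sample_id)]
  if (anyNA(ytr)) stop("training sample id(s) not in dataset")
  if (length(unique(ytr)) < 2L)
    stop("training set must contain both classes (hinge targets undefined)")
  plans <- cnn_build_plans(spec)
  flat <- plans[[length(plans)]]$npix_out
  Xtr <- dataset_matrix(dataset, train_ids, spec$input_shape)
  ytr <- ifelse(ytr == 1L, 1, -1)
  has_val <- !is.null(val_ids) && length(val_ids) > 0L
  if (has_val) {
    Xval <- dataset_matrix(dataset, val_ids, spec$input_shape)
    yval <- ifelse(dataset$label[match(val_ids, dataset$sample_id)] == 1L,
                   1, -1)
  }
  net <- list(plans = plans, l2 = spec$l2_coefficient)
  log_df <- data.frame(epoch = seq_len(spec$epochs),
                       train_loss = NA_real_, val_loss = NA_real_)
  best <- list(loss = Inf, epoch = 0L, params = NULL)
  with_seed(rng_seed, {
    net$params <- cnn_init_params(plans, spec$dense_units, flat)
    opt <- make_optimizer(spec$optimizer, spec$learning_rate)
    initial <- c(train = cnn_loss(net, cnn_forward(net, Xtr), ytr),
                 val = if (has_val)
                   cnn_loss(net, cnn_forward(net, Xval), yval) else NA_real_)
    ntr <- ncol(Xtr)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(ntr)
      starts <- seq(1L, ntr, by = spec$batch_size)
      for (st in starts) {
        sel <- ord[st:min(st + spec$batch_size - 1L, ntr)]
        fwd <- cnn_forward(net, Xtr[, sel, drop = FALSE], keep = TRUE)
        g <- cnn_gradients(net, fwd, ytr[sel])
        opt$step(net$params, g)   # in-place update of the weight buffers
      }
      log_df$train_loss[ep] <- cnn_loss(net, cnn_forward(net, Xtr), ytr)
      if (has_val) {
        log_df$val_loss[ep] <- cnn_loss(net, cnn_forward(net, Xval), yval)
        if (log_df$val_loss[ep] < best$loss) {
          # deep copy: the optimizer mutates the live buffers in place
          best <- list(loss = log_df$val_loss[ep], epoch = ep,
                       params = lapply(net$params, function(x) x + 0))
        }
      }
    }
    if (has_val && spec$select_best_epoch && !is.null(best$params)) {
      net$params <- best$params
    } else {
      best$epoch <- spec$epochs
    }
    structure(list(spec = spec, params = net$params, plans = plans,
                   l2 = spec$l2_coefficient,
                   training_log = log_df, best_epoch = best$epoch,
                   initial_loss = initial, rng_seed = rng_seed),
              class = "feature_extractor")
  })
}

#' Score one preprocessed image with a trained extractor
#'
#' The score is the raw margin of the linear output unit: larger values
#' indicate the positive class.  Deterministic for fixed weights.
#'
#' @param extractor a `feature_extractor`.
#' @param image numeric matrix matching the extractor's input shape.
#' @return a single real score.
#' @export
cnn_score <- function(extractor, image) {
  shp <- extractor$spec$input_shape
  if (!identical(dim(image), as.integer(shp)))
    stop(sprintf("image shape %s does not match extractor input %s",
                 paste(dim(image), collapse = "x"),
                 paste(shp, collapse = "x")))
  net <- list(plans = extractor$plans, params = extractor$params,
              l2 = extractor$l2)
  cnn_forward(net, matrix(as.numeric(image), ncol = 1L))
}

# Batched scoring used for test-set evaluation (same math as cnn_score,
# many columns at once).
cnn_score_batch <- function(extractor, X) {
  net <- list(plans = extractor$plans, params = extractor$params,
              l2 = extractor$l2)
  cnn_forward(net, X)
}

#' Save / load a trained extractor
#'
#' One directory per CNN: `spec.json` (the [cnn_spec()] plus training
#' metadata, human-readable) and `weights.rds` (the parameter arrays).
#'
#' @param extractor a `feature_extractor`.
#' @param dir target directory (created if needed).
#' @return `dir` (save) or the restored `feature_extractor` (load).
#' @export
save_extractor <- function(extractor, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(spec = unclass(extractor$spec),
               best_epoch = extractor$best_epoch,
               rng_seed = extractor$rng_seed,
               training_log = extractor$training_log)
  jsonlite::write_json(meta, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, dataframe = "columns")
  saveRDS(extractor$params, file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_extractor
#' @export
load_extractor <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  sp <- meta$spec
  spec <- cnn_spec(sp$input_shape, sp$n_conv_layers, sp$filters,
                   sp$kernel_size, sp$stride, sp$activation,
                   sp$n_dense_layers, sp$dense_units, sp$loss,
                   sp$l2_coefficient, sp$batch_size, sp$optimizer,
                   sp$epochs, sp$learning_rate, sp$select_best_epoch)
  structure(list(spec = spec, params = readRDS(file.path(dir, "weights.rds")),
                 plans = cnn_build_plans(spec), l2 = spec$l2_coefficient,
                 training_log = as.data.frame(meta$training_log),
                 best_epoch = meta$best_epoch,
                 initial_loss = NULL, rng_seed = meta$rng_seed),
            class = "feature_extractor")
}

#' Build the fold feature matrix P
#'
#' Row i, column j holds extractor j's score for fold sample i — including
#' the samples that served as extractor j's validation subset.  Each entry
#' is produced by the same single-image inference as [cnn_score()], so the
#' matrix is exactly reproducible entry by entry.
#'
#' @param extractors non-empty list of `feature_extractor`s sharing one
#'   input shape.
#' @param fold_ids character vector of training-fold sample ids.
#' @param dataset a `cohort_dataset` at the extractors' input shape.
#' @return numeric matrix `length(fold_ids)` x `length(extractors)` with
#'   `fold_ids` as rownames and extractor indices as colnames.
#' @export
build_feature_matrix <- function(extractors, fold_ids, dataset) {
  if (!length(extractors)) stop("empty extractor list")
  shp <- extractors[[1]]$spec$input_shape
  for (e in extractors)
    if (!identical(e$spec$input_shape, shp))
      stop("all extractors must share one input shape")
  X <- dataset_matrix(dataset, fold_ids, shp)
  P <- matrix(NA_real_, length(fold_ids), length(extractors),
              dimnames = list(fold_ids, sprintf("cnn%02d",
                                                seq_along(extractors))))
  for (j in seq_along(extractors))
    for (i in seq_along(fold_ids))
      P[i, j] <- cnn_score_batch(extractors[[j]], X[, i, drop = FALSE])
  P
}
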