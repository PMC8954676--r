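# The 3D convolutional affinity model.
#
# The default architecture follows the published layer sequence: five
# convolutions of 32x3^3, 64x3^3, 64x3^3, 64x3^3, 64x2^3 filters, then a
# 256-unit ReLU dense layer and a linear scalar output (predicted pK).
# Strides and pooling are not published; the default inserts 2^3 max-pools
# after the second and fourth convolutions so the flattened size stays
# tractable, and the layer list is fully configurable so other readings are
# expressible. Higher score = stronger predicted binding (pK scale).

#' Layer constructors
#'
#' Building blocks for [build_model()]: a stride-1 valid 3D convolution, a
#' max-pool, a flatten marker and a dense layer.
#'
#' @param filters,units Output channels / units.
#' @param kernel Kernel edge length (2 or 3).
#' @param stride Convolution stride.
#' @param activation `"relu"` or `"linear"`.
#' @param size Pool edge length.
#' @return A layer specification list.
#' @name layers
NULL

#' @rdname layers
#' @export
conv3d_layer <- function(filters, kernel = 3L, stride = 1L, activation = "relu") {
  stopifnot(kernel %in% c(2L, 3L), filters > 0, stride >= 1)
  list(kind = "conv3d", filters = as.integer(filters), kernel = as.integer(kernel),
       stride = as.integer(stride), activation = match.arg(activation, c("relu", "linear")))
}

#' @rdname layers
#' @export
maxpool_layer <- function(size = 2L) list(kind = "maxpool", size = as.integer(size))

#' @rdname layers
#' @export
flatten_layer <- function() list(kind = "flatten")

#' @rdname layers
#' @export
dense_layer <- function(units, activation = "relu") {
  stopifnot(units > 0)
  list(kind = "dense", units = as.integer(units),
       activation = match.arg(activation, c("relu", "linear")))
}

#' Default scoring architecture
#'
#' The published five-conv sequence (32x3^3, 64x3^3, 64x3^3, 64x3^3,
#' 64x2^3) with 2^3 max-pools after convolutions 2 and 4, a 256-unit ReLU
#' dense layer and a linear scalar head.
#'
#' @return List of layer specifications.
#' @export
default_architecture <- function() {
  list(conv3d_layer(32, 3), conv3d_layer(64, 3), maxpool_layer(2),
       conv3d_layer(64, 3), conv3d_layer(64, 3), maxpool_layer(2),
       conv3d_layer(64, 2), flatten_layer(),
       dense_layer(256, "relu"), dense_layer(1, "linear"))
}

#' Build a scoring model
#'
#' Validates the layer shape chain against the grid spec and initializes
#' parameters (He scheme for ReLU layers, scaled-normal for the linear head;
#' zero biases), deterministically from `rng_seed`.
#'
#' @param layers Layer list (default [default_architecture()]).
#' @param spec A [grid_spec()] describing the input.
#' @param rng_seed Integer seed for initialization.
#' @return Object of class `voxnet` with fields `layers`, `params`,
#'   `input_spec`, `shapes`, `history`.
#' @export
build_model <- function(layers = default_architecture(), spec = grid_spec(),
                        rng_seed = 1L) {
  Cin <- spec$scheme$n_channels
  shapes <- cnn_shapes_cpp(layers, Cin, spec$n)  # errors name the bad layer
  params <- with_seed(rng_seed, {
    C <- Cin; d <- spec$n; flat_dim <- NA
    lapply(layers, function(ly) {
      if (ly$kind == "conv3d") {
        fan_in <- C * ly$kernel^3
        W <- matrix(rnorm(ly$filters * fan_in,
                          sd = if (ly$activation == "relu") sqrt(2 / fan_in)
                               else sqrt(1 / fan_in)),
                    nrow = ly$filters)
        p <- list(W = W, b = numeric(ly$filters))
        C <<- ly$filters; d <<- (d - ly$kernel) %/% ly$stride + 1L
        p
      } else if (ly$kind == "maxpool") {
        d <<- d %/% ly$size
        list()
      } else if (ly$kind == "flatten") {
        flat_dim <<- C * d^3
        list()
      } else {
        fan_in <- if (is.na(flat_dim)) C * d^3 else flat_dim
        W <- matrix(rnorm(ly$units * fan_in,
                          sd = if (ly$activation == "relu") sqrt(2 / fan_in)
                               else sqrt(1 / fan_in)),
                    nrow = ly$units)
        flat_dim <<- ly$units
        list(W = W, b = numeric(ly$units))
      }
    })
  })
  if (utils::tail(shapes$out_dim, 1) != 1L)
    vs_stop("model output must be a single scalar; final layer emits %d values",
            utils::tail(shapes$out_dim, 1))
  structure(list(layers = layers, params = params, input_spec = spec,
                 shapes = shapes, history = NULL),
            class = "voxnet")
}

#' @export
print.voxnet <- function(x, ...) {
  desc <- vapply(x$layers, function(ly) switch(ly$kind,
    conv3d = sprintf("conv %dx%d^3/%s", ly$filters, ly$kernel, ly$activation),
    maxpool = sprintf("maxpool %d^3", ly$size),
    flatten = "flatten",
    dense = sprintf("dense %d/%s", ly$units, ly$activation)), "")
  np <- sum(vapply(x$params, function(p)
    if (length(p)) length(p$W) + length(p$b) else 0L, 0))
  cat(sprintf("<voxnet: %d-channel %d^3 input | %s | %s parameters%s>\n",
              x$input_spec$scheme$n_channels, x$input_spec$n,
              paste(desc, collapse = " -> "), format(np, big.mark = ","),
              if (!is.null(x$history)) sprintf(" | trained %d epochs (final MSE %.4g)",
                                               length(x$history),
                                               utils::tail(x$history, 1)) else ""))
  invisible(x)
}

#' @export
summary.voxnet <- function(object, ...) {
  s <- data.frame(
    layer = vapply(object$layers, function(l) l$kind, ""),
    in_dim = object$shapes$in_dim, out_dim = object$shapes$out_dim,
    n_params = vapply(object$params, function(p)
      if (length(p)) length(p$W) + length(p$b) else 0L, 0L))
  cat("Voxel-grid convolutional scoring model\n")
  print(s, row.names = FALSE)
  if (!is.null(object$history))
    cat(sprintf("Training: %d epochs, final training MSE %.6f\n",
                length(object$history), utils::tail(object$history, 1)))
  invisible(s)
}

#' @export
coef.voxnet <- function(object, ...) object$params

# Per-compound pose-stream seed, derived from the molecule's content
# (elements + coordinates), so structurally identical compounds share a
# pose stream and results never depend on library order or labeling.
compound_pose_seed <- function(rng_seed, mol) {
  content <- c(match(mol$atoms, names(.ELEMENT_MASS), nomatch = 99L),
               if (!is.null(mol$coords)) as.integer(round(mol$coords * 1e4)))
  derive_seed(rng_seed, paste0("pose:", hash_ints(content)))
}

# Grids (list of voxel_grid) -> input matrix (d x B).
grids_to_matrix <- function(grids, spec) {
  d <- spec$scheme$n_channels * spec$n^3
  X <- matrix(0, d, length(grids))
  for (i in seq_along(grids)) {
    g <- grids[[i]]
    if (!identical(dim(g$values), c(spec$scheme$n_channels, spec$n, spec$n, spec$n)))
      vs_stop("grid %d does not match the model's input spec", i)
    X[, i] <- as.vector(g$values)
  }
  X
}

#' Score a single pose grid
#'
#' @param model A [build_model()] result.
#' @param grid A `voxel_grid` matching the model's input spec.
#' @return Scalar pose score (pK units).
#' @export
predict_pose <- function(model, grid) {
  X <- grids_to_matrix(list(grid), model$input_spec)
  as.numeric(cnn_forward_cpp(model$layers, model$params, X,
                             model$input_spec$scheme$n_channels,
                             model$input_spec$n))
}

#' Predict pose scores for a batch of grids
#'
#' @param object A `voxnet` model.
#' @param grids List of `voxel_grid` objects (or a prebuilt input matrix).
#' @param ... Unused.
#' @return Numeric vector of pose scores.
#' @export
predict.voxnet <- function(object, grids, ...) {
  X <- if (is.matrix(grids)) grids else grids_to_matrix(grids, object$input_spec)
  as.numeric(cnn_forward_cpp(object$layers, object$params, X,
                             object$input_spec$scheme$n_channels,
                             object$input_spec$n))
}

#' Boltzmann-weighted ensemble score
#'
#' Combines an ensemble of pose scores into one compound score:
#' `S = sum(s_i * exp(beta * s_i)) / sum(exp(beta * s_i))`, computed with a
#' max-shift so large scores cannot overflow. `beta = 0` gives the
#' arithmetic mean; large `beta` approaches the maximum. The result is
#' bounded by the min and max of the inputs and shifts by `d` when all
#' inputs shift by `d`; note it is not monotone in every single input
#' (raising a far-below-average score can lower the weighted mean, since
#' `dS/ds_i = w_i (1 + beta (s_i - S))`).
#'
#' @param scores Numeric vector of pose scores (length >= 1).
#' @param beta Boltzmann inverse temperature in 1/pK units (>= 0).
#' @return Scalar ensemble score.
#' @examples
#' ensemble_score(c(1, 3), beta = 0)   # 2
#' ensemble_score(c(1, 3), beta = 50)  # ~3
#' @export
ensemble_score <- function(scores, beta = 1.0) {
  if (!length(scores)) vs_stop("ensemble_score needs at least one pose score")
  stopifnot(is.finite(beta), beta >= 0)
  w <- beta * scores
  w <- exp(w - max(w))
  sum(scores * w) / sum(w)
}

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate ADAM step size (default 1e-3).
#' @param epochs Training epochs.
#' @param rng_seed Seed for shuffling.
#' @param weight_decay Decoupled L2 weight decay applied to weight matrices
#'   (not biases) each step; 0 disables it.
#' @param param_averaging Exponential-moving-average decay for Polyak-style
#'   parameter averaging (e.g. 0.99); the averaged parameters become the
#'   fitted model. 0 disables it. Averaging damps the step-to-step noise
#'   of the optimization trajectory without changing the loss.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, learning_rate = 1e-3,
                         epochs = 10L, rng_seed = 1L, weight_decay = 0,
                         param_averaging = 0) {
  stopifnot(batch_size >= 1, epochs >= 0, learning_rate >= 0,
            weight_decay >= 0, param_averaging >= 0, param_averaging < 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 rng_seed = as.integer(rng_seed),
                 weight_decay = weight_decay,
                 param_averaging = param_averaging),
            class = "train_config")
}

#' Train a scoring model
#'
#' Mini-batch ADAM on the mean-squared error between predicted and labeled
#' pK. Reproducible: shuffling comes from `config$rng_seed`, initialization
#' from [build_model()]'s seed. The per-epoch training MSE history is not
#' guaranteed monotone.
#'
#' @param model A `voxnet` from [build_model()].
#' @param grids List of `voxel_grid` objects (or an input matrix).
#' @param labels Numeric pK labels, one per grid.
#' @param config A [train_config()].
#' @return The trained `voxnet`; `$history` holds per-epoch training MSE.
#' @export
train_model <- function(model, grids, labels, config = train_config()) {
  X <- if (is.matrix(grids)) grids else grids_to_matrix(grids, model$input_spec)
  if (length(labels) != ncol(X)) vs_stop("one label per training grid required")
  if (!all(is.finite(labels))) vs_stop("labels must be finite")
  if (ncol(X) == 0L) vs_stop("empty training set")
  orders <- with_seed(config$rng_seed, {
    t(vapply(seq_len(max(config$epochs, 1L)),
             function(e) sample.int(ncol(X)), integer(ncol(X))))
  })
  if (config$epochs == 0L) {
    model$history <- numeric(0)
    return(model)
  }
  res <- cnn_train_cpp(model$layers, model$params, X, labels,
                       model$input_spec$scheme$n_channels, model$input_spec$n,
                       config$epochs, config$batch_size, config$learning_rate,
                       orders, weight_decay = config$weight_decay %||% 0,
                       avg_decay = config$param_averaging %||% 0)
  fitted <- if ((config$param_averaging %||% 0) > 0) res$avg_params
            else res$params
  # arma vectors come back as n x 1 matrices; restore plain numeric biases
  model$params <- lapply(fitted, function(p)
    if (length(p)) list(W = p$W, b = as.numeric(p$b)) else p)
  model$history <- c(model$history, as.numeric(res$history))
  model
}

#' Save / load a model checkpoint
#'
#' Self-describing archive: layer specs, parameter tensors, input spec and
#' training history.
#'
#' @param model A `voxnet`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored `voxnet` (load).
#' @export
save_model <- function(model, path) {
  saveRDS(list(format = "voxnet-checkpoint-1", layers = model$layers,
               params = model$params,
               input = list(n = model$input_spec$n,
                            spacing = model$input_spec$spacing,
                            groups = model$input_spec$scheme$groups),
               history = model$history), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "voxnet-checkpoint-1"))
    vs_stop("not a voxnet checkpoint: %s", path)
  spec <- grid_spec(obj$input$n, obj$input$spacing, channel_scheme(obj$input$groups))
  m <- build_model(obj$layers, spec, rng_seed = 0L)
  m$params <- obj$params
  m$history <- obj$history
  m
}

#' Screen a compound library against a site
#'
#' For every compound: sample clash-free poses, rasterize each pose,
#' score with the model, and combine pose scores by Boltzmann averaging.
#' Compounds are ranked by descending score with lexicographic id
#' tie-breaks; compounds with no placeable pose are ranked last and
#' flagged, not dropped. Per-compound RNG streams are derived from the
#' compound id, so results do not depend on library order.
#'
#' @param model A trained `voxnet`.
#' @param lib Named list of [mol_graph()] objects with 3D coordinates.
#' @param s A [vox_structure()].
#' @param site A [flood_site()] result.
#' @param n_poses Poses per compound.
#' @param t_max,clash_factor Pose-sampling parameters ([sample_poses()]).
#' @param beta Ensemble inverse temperature ([ensemble_score()]).
#' @param rng_seed Master seed.
#' @return data.frame: `rank`, `compound_id`, `score`, `n_poses_accepted`,
#'   `flags`.
#' @export
screen_library <- function(model, lib, s, site, n_poses = 16L, t_max = 4.0,
                           clash_factor = 0.75, beta = 1.0, rng_seed = 1L) {
  ids <- vapply(lib, function(m) m$id, "")
  spec <- model$input_spec
  rows <- lapply(seq_along(lib), function(i) {
    mol <- lib[[i]]
    seed_i <- compound_pose_seed(rng_seed, mol)
    poses <- withCallingHandlers(
      tryCatch(sample_poses(s, mol, site, n_poses = n_poses, t_max = t_max,
                            clash_factor = clash_factor, rng_seed = seed_i),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(poses))
      return(data.frame(compound_id = mol$id, score = NA_real_,
                        n_poses_accepted = 0L, flags = "no_placeable_pose"))
    grids <- lapply(poses, function(p) rasterize_complex(s, mol, p, site, spec))
    sc <- predict.voxnet(model, grids)
    data.frame(compound_id = mol$id, score = ensemble_score(sc, beta),
               n_poses_accepted = length(poses),
               flags = if (length(poses) < n_poses) "partial_poses" else "")
  })
  out <- do.call(rbind, rows)
  ord <- order(is.na(out$score), -ifelse(is.na(out$score), -Inf, out$score),
               out$compound_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("rank", "compound_id", "score", "n_poses_accepted", "flags")]
}

#' Write screen results as CSV
#'
#' Fixed-format numeric output so identical runs produce byte-identical
#' files.
#'
#' @param ranked [screen_library()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(ranked, path) {
  out <- ranked
  out$score <- fmt_num(out$score)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
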