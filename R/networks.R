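#' Training configuration for turn-side networks
#'
#' Bundles the optimisation hyperparameters used by [train_network()]. The
#' defaults depend on the model kind: the attention network uses minibatches
#' of 500 samples and a learning rate annealed from 1e-4 to 1e-5, the
#' interaction network minibatches of 200 and 5e-5 to 1e-5, and the
#' focal-only baseline follows the attention settings. The learning rate
#' decays exponentially per epoch from `lr_start` to `lr_end` over
#' `max_epochs`. Training stops early when the validation loss has not
#' reached a new minimum for `patience` epochs *and* has risen at least
#' `rise` (fraction) above that minimum.
#'
#' @param model_kind one of `"attention"`, `"interaction"`, `"focal"`.
#' @param batch_size minibatch size; default depends on `model_kind`.
#' @param lr_start,lr_end learning-rate schedule endpoints.
#' @param max_epochs maximum number of epochs (default 100).
#' @param anneal_epochs number of epochs over which the learning rate is
#'   annealed from `lr_start` to `lr_end` (default: `max_epochs`). Keeping
#'   this at 100 while capping `max_epochs` lower reproduces the reference
#'   schedule's early-epoch learning rates in a shorter run.
#' @param patience early-stopping patience in epochs (default 10).
#' @param rise relative validation-loss rise that, together with exhausted
#'   patience, triggers early stopping (default 0.25).
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return a list of class `"train_config"`.
#' @export
train_config <- function(model_kind = c("attention", "interaction", "focal"),
                         batch_size = NULL, lr_start = NULL, lr_end = 1e-5,
                         max_epochs = 100L, anneal_epochs = max_epochs,
                         patience = 10L, rise = 0.25, seed = 1L) {
  model_kind <- match.arg(model_kind)
  if (is.null(batch_size))
    batch_size <- if (model_kind == "interaction") 200L else 500L
  if (is.null(lr_start))
    lr_start <- if (model_kind == "interaction") 5e-5 else 1e-4
  stopifnot(batch_size >= 1, lr_start > 0, lr_end > 0, lr_end <= lr_start,
            max_epochs >= 1, anneal_epochs >= 1, patience >= 1, rise >= 0)
  structure(list(model_kind = model_kind, batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_end = lr_end,
                 max_epochs = as.integer(max_epochs),
                 anneal_epochs = as.integer(anneal_epochs),
                 patience = as.integer(patience), rise = rise,
                 seed = as.integer(seed)),
            class = "train_config")
}

# fan-in-scaled Gaussian init (He for ReLU stacks); uses the current R RNG
init_mlp <- function(sizes) {
  lapply(seq_len(length(sizes) - 1L), function(l) {
    fan_in <- sizes[l]
    sd <- sqrt(2 / fan_in)
    list(W = matrix(stats::rnorm(fan_in * sizes[l + 1L], sd = sd),
                    fan_in, sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

#' Build an untrained turn-side model
#'
#' Constructs the parameter containers for one of the three model kinds,
#' matched to the feature layout of a [build_dataset()] result.
#'
#' * `"interaction"`: a pair-embedding MLP (3 hidden layers of 128 units,
#'   128-unit linear readout) whose per-neighbour outputs are summed,
#'   rectified and passed through an aggregator MLP (one 128-unit hidden
#'   layer, 1-unit readout). The whole map is antisymmetrized under
#'   body-axis reflection.
#' * `"attention"`: a pair-logit MLP (same stack, 1-unit readout,
#'   antisymmetrized per neighbour) combined with a positive weighting MLP
#'   acting on a reflection-invariant input subset; the weights are
#'   softmax-normalized so they are positive and sum to one.
#' * `"focal"`: an MLP on the asocial variables only, antisymmetrized.
#'
#' @param kind model kind.
#' @param dataset a `turn_dataset`; supplies input dimensions, feature
#'   metadata and standardization statistics.
#' @param seed integer seed for parameter initialization.
#' @param hidden hidden-layer width (default 128).
#' @return a list of class `"fish_model"`.
#' @export
build_model <- function(kind = c("attention", "interaction", "focal"),
                        dataset, seed = 1L, hidden = 128L) {
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "turn_dataset"))
  d_pair <- ncol(dataset$x_pair)
  d_w <- ncol(dataset$x_w)
  d_alpha <- length(dataset$vars$alpha)
  old <- .Random.seed_save()
  set.seed(seed)
  params <- switch(kind,
    attention = list(pi = init_mlp(c(d_pair, hidden, hidden, hidden, 1L)),
                     w = init_mlp(c(d_w, hidden, hidden, hidden, 1L))),
    interaction = list(pi = init_mlp(c(d_pair, hidden, hidden, hidden, hidden)),
                       gamma = init_mlp(c(hidden, hidden, 1L))),
    focal = list(mlp = init_mlp(c(d_alpha, hidden, hidden, hidden, 1L))))
  .Random.seed_restore(old)
  structure(list(kind = kind, params = params, n = dataset$n,
                 vars = dataset$vars, odd_pair = dataset$odd_pair,
                 odd_alpha = dataset$odd_alpha, stats = dataset$stats,
                 seed = as.integer(seed), hidden = as.integer(hidden)),
            class = "fish_model")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    rm(".Random.seed", envir = globalenv())
  invisible(NULL)
}

check_dataset_match <- function(model, dataset) {
  if (!identical(model$vars, dataset$vars))
    stop("dataset variable subset does not match the model's manifest",
         call. = FALSE)
  if (model$kind != "focal" && model$n != dataset$n)
    stop("dataset neighbour count does not match the model", call. = FALSE)
}

# row indices into the pair matrices for a set of sample indices
pair_rows <- function(idx, n) {
  rep((idx - 1L) * n, each = n) + seq_len(n)
}

#' Logistic link from logit to probability
#'
#' @param z numeric logit(s), log-odds of a right turn.
#' @return probability in (0, 1).
#' @export
logit_to_probability <- function(z) 1 / (1 + exp(-z))

#' Mean cross-entropy of turn-side predictions
#'
#' The loss is the mean negative log of the probability assigned to the
#' realized side: `p` for right turns, `1 - p` for left turns.
#' Probabilities are clamped to `[1e-12, 1 - 1e-12]` before the log.
#'
#' @param p predicted probabilities of a right turn.
#' @param labels 0/1 vector, 1 = right.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(p, labels) {
  stopifnot(length(p) == length(labels), length(p) >= 1)
  p_star <- ifelse(labels == 1, p, 1 - p)
  p_star <- pmin(pmax(p_star, 1e-12), 1 - 1e-12)
  -mean(log(p_star))
}

#' Attention-network logit with per-neighbour weights
#'
#' Evaluates the attention network on samples of a dataset, returning the
#' logit together with the per-neighbour pair logits and the normalized
#' attention weights (positive, summing to one within each sample).
#'
#' @param model a trained or untrained attention `fish_model`.
#' @param dataset a `turn_dataset` built with the model's variable subset.
#' @param idx sample indices to evaluate (default all).
#' @return list with `z` (length m), `pi` and `log_w` and `omega`
#'   (n x m matrices).
#' @export
attention_logit <- function(model, dataset, idx = NULL) {
  stopifnot(model$kind == "attention")
  check_dataset_match(model, dataset)
  if (is.null(idx)) idx <- seq_len(dataset$m)
  rows <- pair_rows(idx, dataset$n)
  out <- cpp_attn_forward(dataset$x_pair[rows, , drop = FALSE],
                          dataset$x_w[rows, , drop = FALSE],
                          model$odd_pair, dataset$n,
                          model$params$pi, model$params$w)
  out$z <- as.vector(out$z)
  out
}

#' Interaction-network logit
#'
#' @inheritParams attention_logit
#' @return numeric vector of logits.
#' @export
interaction_logit <- function(model, dataset, idx = NULL) {
  stopifnot(model$kind == "interaction")
  check_dataset_match(model, dataset)
  if (is.null(idx)) idx <- seq_len(dataset$m)
  rows <- pair_rows(idx, dataset$n)
  cpp_inter_forward(dataset$x_pair[rows, , drop = FALSE], model$odd_pair,
                    dataset$n, model$params$pi, model$params$gamma)
}

#' Model logit for any model kind
#'
#' @inheritParams attention_logit
#' @param chunk evaluate in chunks of this many samples to bound memory.
#' @return numeric vector of logits, one per sample in `idx`.
#' @export
predict_logit <- function(model, dataset, idx = NULL, chunk = 4096L) {
  if (is.null(idx)) idx <- seq_len(dataset$m)
  out <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = chunk)) {
    sel <- idx[start:min(start + chunk - 1L, length(idx))]
    out[start:(start + length(sel) - 1L)] <- switch(model$kind,
      attention = attention_logit(model, dataset, sel)$z,
      interaction = interaction_logit(model, dataset, sel),
      focal = cpp_focal_forward(dataset$x_alpha[sel, , drop = FALSE],
                                model$odd_alpha, model$params$mlp))
  }
  out
}

# one gradient evaluation on a batch of sample indices
batch_grad <- function(model, dataset, idx) {
  y <- dataset$label[idx]
  if (model$kind == "focal") {
    g <- cpp_focal_grad(dataset$x_alpha[idx, , drop = FALSE], model$odd_alpha,
                        y, model$params$mlp)
    return(list(loss = g$loss, grads = list(mlp = g$g)))
  }
  rows <- pair_rows(idx, dataset$n)
  xp <- dataset$x_pair[rows, , drop = FALSE]
  if (model$kind == "attention") {
    g <- cpp_attn_grad(xp, dataset$x_w[rows, , drop = FALSE], model$odd_pair,
                       dataset$n, y, model$params$pi, model$params$w)
    list(loss = g$loss, grads = list(pi = g$g_pi, w = g$g_w))
  } else {
    g <- cpp_inter_grad(xp, model$odd_pair, dataset$n, y, model$params$pi,
                        model$params$gamma)
    list(loss = g$loss, grads = list(pi = g$g_pi, gamma = g$g_gamma))
  }
}

adam_state <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

adam_update <- function(params, grads, state, lr, step,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  for (mod in names(params)) {
    for (l in seq_along(params[[mod]])) {
      for (p in c("W", "b")) {
        g <- grads[[mod]][[l]][[p]]
        if (p == "b") g <- as.vector(g)
        state$m[[mod]][[l]][[p]] <- beta1 * state$m[[mod]][[l]][[p]] + (1 - beta1) * g
        state$v[[mod]][[l]][[p]] <- beta2 * state$v[[mod]][[l]][[p]] + (1 - beta2) * g^2
        mhat <- state$m[[mod]][[l]][[p]] / bc1
        vhat <- state$v[[mod]][[l]][[p]] / bc2
        params[[mod]][[l]][[p]] <- params[[mod]][[l]][[p]] -
          lr * mhat / (sqrt(vhat) + eps)
      }
    }
  }
  list(params = params, state = state)
}

# early-stopping rule: stop once the validation loss has not improved for
# `patience` epochs and the current loss sits at least `rise` above the
# minimum (relative), or when max_epochs is exhausted (handled by caller)
should_stop <- function(val_history, patience, rise) {
  best <- which.min(val_history)
  since <- length(val_history) - best
  since >= patience &&
    val_history[length(val_history)] >= (1 + rise) * min(val_history)
}

#' Train a turn-side model
#'
#' Minimises the cross-entropy of the predicted turning side with Adam,
#' following the learning-rate schedule and early-stopping rule in the
#' [train_config()]. The parameters at the epoch of minimum validation loss
#' are returned. The run is deterministic given `config$seed`.
#'
#' @param model an untrained `fish_model` from [build_model()].
#' @param dataset a `turn_dataset` with non-empty train and validation
#'   splits.
#' @param config a [train_config()]; its `model_kind` must match the model.
#' @param verbose print per-epoch losses.
#' @return the trained model, with a `history` element (data frame of
#'   per-epoch train/validation losses and learning rates) and
#'   `best_epoch`.
#' @export
train_network <- function(model, dataset, config = train_config(model$kind),
                          verbose = FALSE) {
  stopifnot(inherits(model, "fish_model"), inherits(config, "train_config"))
  if (config$model_kind != model$kind)
    stop("config model_kind does not match the model", call. = FALSE)
  check_dataset_match(model, dataset)
  idx_train <- which(dataset$split == "train")
  idx_val <- which(dataset$split == "validation")
  if (!length(idx_train) || !length(idx_val))
    stop("dataset must contain train and validation samples", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  params <- model$params
  state <- list(m = adam_state(params), v = adam_state(params))
  decay <- if (config$anneal_epochs > 1)
    (config$lr_end / config$lr_start)^(1 / (config$anneal_epochs - 1)) else 1
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  best <- list(loss = Inf, params = params, epoch = 0L)
  step <- 0L

  val_loss_of <- function(p) {
    model_tmp <- model
    model_tmp$params <- p
    z <- predict_logit(model_tmp, dataset, idx_val)
    cross_entropy_loss(logit_to_probability(z), dataset$label[idx_val])
  }

  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$lr_start * decay^(epoch - 1)
    perm <- sample(idx_train)
    losses <- numeric(0)
    for (start in seq(1L, length(perm), by = config$batch_size)) {
      sel <- perm[start:min(start + config$batch_size - 1L, length(perm))]
      g <- batch_grad(list(kind = model$kind, params = params,
                           odd_pair = model$odd_pair,
                           odd_alpha = model$odd_alpha), dataset, sel)
      if (!is.finite(g$loss))
        stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch),
             call. = FALSE)
      step <- step + 1L
      upd <- adam_update(params, g$grads, state, lr, step)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, g$loss)
    }
    vl <- val_loss_of(params)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_loss = vl, lr = lr))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = epoch)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2e",
                      epoch, mean(losses), vl, lr))
    if (should_stop(history$val_loss, config$patience, config$rise)) break
  }
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model$config <- config
  model
}

#' Turn-side accuracy on a dataset split, filtered by turning angle
#'
#' The predicted side is right when the logit is non-negative. Accuracy is
#' the fraction of correct side predictions among samples whose turning
#' angle lies in the closed `angle_range` (degrees); `c(0, 180)` keeps all
#' samples.
#'
#' @param model a trained `fish_model`.
#' @param dataset a `turn_dataset`.
#' @param angle_range closed interval of turning angles in degrees.
#' @param split which split to evaluate (`"test"`, `"validation"`,
#'   `"train"`, or `"all"`).
#' @return accuracy in `[0, 1]`.
#' @export
evaluate_accuracy <- function(model, dataset, angle_range = c(0, 180),
                              split = "test") {
  stopifnot(length(angle_range) == 2, angle_range[1] <= angle_range[2])
  idx <- if (identical(split, "all")) seq_len(dataset$m)
         else which(dataset$split == split)
  keep <- idx[dataset$turn_angle[idx] >= angle_range[1] &
              dataset$turn_angle[idx] <= angle_range[2]]
  if (!length(keep))
    stop("no samples with turning angle in the requested range", call. = FALSE)
  z <- predict_logit(model, dataset, keep)
  pred <- as.integer(z >= 0)
  mean(pred == dataset$label[keep])
}

#' Save and load trained models
#'
#' Checkpoints carry the full parameter set together with the variable
#' manifest and standardization statistics, so a reloaded model refuses to
#' evaluate on datasets built with a different variable subset.
#'
#' @param model a `fish_model`.
#' @param path file path (conventionally `.rds`).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "fish_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "fish_model"))
    stop("file does not contain a fish_model checkpoint", call. = FALSE)
  model
}

#' @export
print.fish_model <- function(x, ...) {
  cat(sprintf("<fish_model: %s>\n", x$kind))
  cat(sprintf("  neighbours: %s, hidden width: %d\n",
              if (x$kind == "focal") "-" else x$n, x$hidden))
  cat(sprintf("  pair vars: %s\n", paste(c(x$vars$alpha, x$vars$social),
                                         collapse = ", ")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, best val loss %.4f at epoch %d\n",
                nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}
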