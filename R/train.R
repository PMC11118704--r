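#' Training configuration
#'
#' Defaults follow the pretraining recipe: Adam at a starting learning rate
#' of 2e-5 with a warmup ratio of 0.1, mini-batch size 10, 13 epochs.
#' Gradients are clipped at global norm 1.0 for small-batch stability.
#'
#' @param batch_size mini-batch size (default 10).
#' @param learning_rate peak learning rate (default 2e-5).
#' @param warmup_ratio fraction of total steps spent in linear warmup
#'   (default 0.1); the rate then decays linearly to 0.
#' @param epochs training epochs (default 13).
#' @param seed RNG seed controlling shuffling, corruption and dropout.
#' @param policy a `masking_policy`.
#' @param r_smooth soft-label smoothing mass (default 0.1).
#' @param clip_norm global gradient-norm clip (default 1.0).
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 10L, learning_rate = 2e-5,
                         warmup_ratio = 0.1, epochs = 13L, seed = 1L,
                         policy = masking_policy(), r_smooth = 0.1,
                         clip_norm = 1.0) {
  if (batch_size <= 0 || learning_rate <= 0 || epochs <= 0)
    stop("batch_size, learning_rate and epochs must be positive")
  if (warmup_ratio < 0 || warmup_ratio > 1)
    stop("warmup_ratio must lie in [0, 1]")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 warmup_ratio = warmup_ratio, epochs = as.integer(epochs),
                 seed = as.integer(seed), policy = policy,
                 r_smooth = r_smooth, clip_norm = clip_norm),
            class = "train_config")
}

#' Learning-rate schedule: linear warmup, linear decay
#'
#' `lr(0) = 0`, rises linearly to the configured peak at step
#' `ceiling(warmup_ratio * total)`, then decays linearly to 0 at the final
#' step.
#'
#' @param step integer step (1-based).
#' @param total total number of steps.
#' @param peak peak learning rate.
#' @param warmup_ratio warmup fraction.
#' @return learning rate at `step`.
#' @export
lr_schedule <- function(step, total, peak, warmup_ratio = 0.1) {
  w <- max(1L, ceiling(warmup_ratio * total))
  decay <- if (total == w) rep(0, length(step))
           else peak * pmax(0, (total - step) / (total - w))
  ifelse(step <= w, peak * step / w, decay)
}

adam_state <- function(params) {
  list(m = init_zero_grads(params), v = init_zero_grads(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip_norm = 1.0) {
  if (is.finite(clip_norm) && clip_norm > 0) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (gn > clip_norm) grads <- lapply(grads, function(g) g * clip_norm / gn)
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Pretrain the encoder with the masked multi-task objective
#'
#' Runs masked-language-model pretraining: each epoch reshuffles the corpus
#' and draws a fresh corruption of every cell (gene slots masked at
#' `policy$r_geno`, phenotype slots at `policy$r_pheno`), then minimizes the
#' masked soft-label cross-entropy with Adam under a linear warmup/decay
#' schedule. Fully reproducible from `train_config$seed`.
#'
#' @param corpus a `tokenized_cells` object (>= `batch_size` cells).
#' @param cfg a `model_config` consistent with the corpus vocabulary.
#' @param tc a `train_config`.
#' @param params optional warm-start parameters (default fresh
#'   [init_params()] from `tc$seed`).
#' @param max_steps optional cap on total optimizer steps (useful for short
#'   runs and overfitting checks); default unlimited.
#' @param verbose print per-epoch mean loss.
#' @return list with `params` (trained weights), `epoch_loss` (per-epoch
#'   mean), `step_loss` (per-step), `config`, `train_config`.
#' @export
pretrain <- function(corpus, cfg, tc = train_config(), params = NULL,
                     max_steps = Inf, verbose = FALSE) {
  stopifnot(inherits(corpus, "tokenized_cells"),
            inherits(cfg, "model_config"), inherits(tc, "train_config"))
  n <- nrow(corpus$tokens)
  if (n < tc$batch_size) stop("corpus smaller than one batch")
  if (is.null(params)) params <- init_params(cfg, seed = tc$seed)
  set.seed(tc$seed)
  steps_per_epoch <- floor(n / tc$batch_size)
  total <- min(tc$epochs * steps_per_epoch, max_steps)
  state <- adam_state(params)
  step <- 0L
  epoch_loss <- numeric(0)
  step_loss <- numeric(0)
  for (ep in seq_len(tc$epochs)) {
    if (step >= total) break
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b in seq_len(steps_per_epoch)) {
      if (step >= total) break
      idx <- ord[((b - 1L) * tc$batch_size + 1L):(b * tc$batch_size)]
      batch <- corrupt(subset_tokenized(corpus, idx), tc$policy)
      lg <- loss_and_grads(params, cfg, batch, tc$r_smooth, train = TRUE)
      if (!is.finite(lg$loss))
        stop("divergence: non-finite loss at step ", step + 1L)
      step <- step + 1L
      lr <- lr_schedule(step, total, tc$learning_rate, tc$warmup_ratio)
      upd <- adam_step(params, lg$grads, state, lr,
                       clip_norm = tc$clip_norm)
      params <- upd$params
      state <- upd$state
      losses <- c(losses, lg$loss)
    }
    epoch_loss <- c(epoch_loss, mean(losses))
    step_loss <- c(step_loss, losses)
    if (verbose)
      message(sprintf("epoch %d/%d  mean loss %.4f", ep, tc$epochs,
                      mean(losses)))
  }
  list(params = params, epoch_loss = epoch_loss, step_loss = step_loss,
       config = cfg, train_config = tc)
}

# macro precision/recall/F1 from a square confusion matrix (rows = truth)
macro_prf <- function(conf) {
  tp <- diag(conf)
  fp <- colSums(conf) - tp
  fn <- rowSums(conf) - tp
  support <- rowSums(conf)
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  rec <- ifelse(support > 0, tp / (tp + fn), NA_real_)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), NA_real_)
  present <- support > 0
  list(precision = mean(prec[present], na.rm = TRUE),
       recall = mean(rec[present], na.rm = TRUE),
       f1 = mean(f1[present], na.rm = TRUE),
       per_class = data.frame(class = rownames(conf), precision = prec,
                              recall = rec, f1 = f1, support = support))
}

#' Masked-recovery evaluation
#'
#' Corrupts a held-out corpus once (seeded), predicts the argmax token over
#' each masked slot's legal set, and reports macro-averaged precision,
#' recall and F1 per phenotype field and for the gene bins, plus a
#' micro-averaged `"all"` row over every masked slot, with one confusion
#' matrix per field (rows = truth, columns = prediction). A field with no
#' masked instances is reported as `NA` and flagged.
#'
#' @param params trained parameters.
#' @param cfg the `model_config`.
#' @param heldout a `tokenized_cells` corpus disjoint from training.
#' @param policy a `masking_policy`.
#' @param seed corruption seed.
#' @param batch_size forward batch size (memory knob only).
#' @return an `eval_report`: list with `metrics` (data.frame: field,
#'   precision, recall, f1, n_masked), `confusion` (named list of matrices),
#'   `undefined_fields`.
#' @export
evaluate_masked <- function(params, cfg, heldout, policy = masking_policy(),
                            seed = 1L, batch_size = 64L) {
  stopifnot(inherits(heldout, "tokenized_cells"))
  set.seed(seed)
  corr <- corrupt(heldout, policy)
  pred <- predict_masked_tokens(params, cfg, corr, batch_size)
  vocab <- heldout$vocab
  cls <- slot_classes(corr$F, corr$T, vocab)
  n <- nrow(corr$tokens)
  flat_cls <- cls[rep(seq_len(ncol(corr$tokens)), each = n)]
  masked_flat <- as.vector(corr$masked)
  truth <- as.vector(corr$labels)[masked_flat]
  phat <- pred[masked_flat]
  mcls <- flat_cls[masked_flat]
  groups <- c(names(vocab$phenotype_tokens), "gene")
  metrics <- list(); confusion <- list(); undefined <- character(0)
  for (gname in groups) {
    legal <- vocab$legal_sets[[if (gname == "gene") "gene" else gname]]
    lab <- vocab$labels[legal]
    sel <- mcls == gname
    if (!any(sel)) {
      undefined <- c(undefined, gname)
      metrics[[gname]] <- data.frame(field = gname, precision = NA_real_,
                                     recall = NA_real_, f1 = NA_real_,
                                     n_masked = 0L)
      next
    }
    conf <- table(factor(truth[sel], levels = legal, labels = lab),
                  factor(phat[sel], levels = legal, labels = lab))
    conf <- unclass(conf)
    confusion[[gname]] <- conf
    m <- macro_prf(conf)
    metrics[[gname]] <- data.frame(field = gname, precision = m$precision,
                                   recall = m$recall, f1 = m$f1,
                                   n_masked = sum(sel))
  }
  acc <- mean(phat == truth)  # micro: every slot has one truth, one pred
  metrics[["all"]] <- data.frame(field = "all", precision = acc,
                                 recall = acc, f1 = acc,
                                 n_masked = length(truth))
  structure(list(metrics = do.call(rbind, metrics),
                 confusion = confusion, undefined_fields = undefined),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("masked-recovery evaluation\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

# argmax token prediction for all slots; returns flat vector of ids
predict_masked_tokens <- function(params, cfg, corr, batch_size = 64L) {
  n <- nrow(corr$tokens)
  vocab <- corr$vocab
  pred <- integer(n * ncol(corr$tokens))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    sub <- corr
    sub$tokens <- corr$tokens[idx, , drop = FALSE]
    sub$pad <- corr$pad[idx, , drop = FALSE]
    ms <- forward_logits(sub, params, cfg)
    am <- max.col(ms$scores, ties.method = "first")
    # back to (cell, slot) positions in the full flat vector
    m <- length(idx)
    for (s in seq_len(ncol(corr$tokens)))
      pred[(s - 1L) * n + idx] <- am[(s - 1L) * m + seq_len(m)]
  }
  pred
}

#' Annotate a phenotype by mask filling
#'
#' Replaces the given field's slot by MASK in every cell, runs the encoder,
#' and returns the softmax over the field's categories together with the
#' argmax category — phenotype annotation as masked-token recovery.
#'
#' @param params trained parameters.
#' @param cfg the `model_config`.
#' @param cells a `tokenized_cells` object.
#' @param field phenotype field name.
#' @param batch_size forward batch size.
#' @return list with `category` (character vector, one per cell) and
#'   `probabilities` (cells x categories matrix).
#' @export
annotate_phenotype <- function(params, cfg, cells, field,
                               batch_size = 64L) {
  stopifnot(inherits(cells, "tokenized_cells"))
  vocab <- cells$vocab
  slot <- match(field, names(vocab$phenotype_tokens))
  if (is.na(slot)) stop("schema error: unknown field '", field, "'")
  legal <- vocab$legal_sets[[field]]
  cats <- names(vocab$phenotype_tokens[[field]])
  n <- nrow(cells$tokens)
  probs <- matrix(NA_real_, n, length(legal),
                  dimnames = list(cells$cell_ids, cats))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    sub <- subset_tokenized(cells, idx)
    sub$tokens[, slot] <- vocab$mask
    ms <- forward_logits(sub, params, cfg)
    m <- length(idx)
    rows <- (slot - 1L) * m + seq_len(m)
    z <- ms$scores[rows, legal, drop = FALSE]
    z <- z - apply(z, 1L, max)
    p <- exp(z)
    probs[idx, ] <- p / rowSums(p)
  }
  list(category = cats[max.col(probs, ties.method = "first")],
       probabilities = probs)
}
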