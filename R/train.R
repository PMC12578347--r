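# Training loop (Adam), five-fold cross-validation, ablation and
# loss-comparison harnesses.

#' Training configuration
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Sequences per gradient step.
#' @param learning_rate Adam step size.
#' @param loss Loss name: `"mfdl"`, `"bce"`, `"focal"`, `"mlfdl"`,
#'   `"ldam_margin"` or `"asymmetric"`.
#' @param mfdl A [mfdl_config()] (exponents, clips, margins, weights).
#' @param model A [model_config()]; its `n_classes` and `seed` are aligned
#'   with the run.
#' @param threshold Classification probability threshold.
#' @param folds Cross-validation folds (>= 2).
#' @param clip_norm Global gradient-norm ceiling (Inf disables clipping).
#' @param seed Master seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @export
train_config <- function(epochs = 10L, batch_size = 64L, learning_rate = 1e-3,
                         loss = "mfdl", mfdl = mfdl_config(),
                         model = model_config(), threshold = 0.5,
                         folds = 5L, clip_norm = 5, seed = 1L,
                         verbose = FALSE) {
  if (epochs < 1L) stop("config error: epochs must be >= 1")
  if (batch_size < 1L) stop("config error: batch_size must be >= 1")
  if (folds < 2L) stop("config error: folds must be >= 2")
  if (threshold <= 0 || threshold >= 1)
    stop("config error: threshold must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, loss = loss, mfdl = mfdl,
                 model = model, threshold = threshold, folds = as.integer(folds),
                 clip_norm = clip_norm, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pf_train_config")
}

adam_init <- function(params) {
  lapply(params, function(p) list(m = p$value * 0, v = p$value * 0))
}

# scale all gradients so their global L2 norm does not exceed max_norm
clip_gradients <- function(params, max_norm) {
  if (!is.finite(max_norm)) return(invisible())
  tot <- 0
  for (p in params) if (!is.null(p$grad)) tot <- tot + sum(p$grad^2)
  nrm <- sqrt(tot)
  if (nrm > max_norm) {
    fac <- max_norm / nrm
    for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * fac
  }
  invisible()
}

adam_step <- function(params, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.null(p$grad)) next
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * p$grad
    st$v <- beta2 * st$v + (1 - beta2) * p$grad^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
    state[[nm]] <- st
  }
  state
}

#' Evaluate a model on labeled records
#'
#' @param model A `pf_model`.
#' @param records `pf_records` data.frame.
#' @param labels A [label_space()].
#' @param threshold Probability threshold.
#' @return List with the `pf_metric_report`, the probability matrix and the
#'   binary prediction matrix.
#' @export
evaluate_model <- function(model, records, labels, threshold = 0.5) {
  probs <- predict_proba(model, records)
  colnames(probs) <- labels$names
  pred <- (probs > threshold) * 1L
  Y <- label_matrix(records, labels)
  list(report = metric_report(Y, pred, probs), probs = probs, pred = pred)
}

#' Train a model
#'
#' Optimizes every trainable parameter (embeddings, attention, graph
#' attention, fuzzifier centers/widths, projections, gates, recurrent,
#' convolutional, FFN and classifier weights) with Adam against the
#' configured loss. Deterministic for a fixed config and seed.
#'
#' @param train_records,valid_records `pf_records` data.frames
#'   (`valid_records` may be NULL).
#' @param config A [train_config()].
#' @param labels A [label_space()].
#' @return List with the trained `model` and a `report` (per-epoch loss
#'   curve, final held-out `pf_metric_report`, class stats, config, seed).
#' @export
train_model <- function(train_records, valid_records, config, labels) {
  if (!nrow(train_records)) stop("no training records")
  mcfg <- config$model
  mcfg$n_classes <- labels$size
  mcfg$seed <- config$seed
  Y <- label_matrix(train_records, labels)
  stats <- compute_class_stats(Y, config$mfdl)
  model <- build_model(mcfg)
  # start the classifier at the per-class prior log-odds so that initial
  # probabilities match the label frequencies; dice-type losses have
  # vanishing positive-side gradients near p = 0, and a cold start from
  # near-zero probabilities can otherwise trap training in an
  # all-negative state
  prior <- pmin(pmax(colMeans(Y), 1e-3), 1 - 1e-3)
  model$params$cls_b2$value <- matrix(stats::qlogis(prior), 1L)
  tk <- tokenize_batch(train_records, max_len = mcfg$max_len)
  n <- nrow(tk$tokens)
  # length-bucketed batches, padded to the longest member; buckets are
  # re-drawn every epoch (random order among equal lengths) and visited in
  # random order, so batch composition varies while padding stays small
  lens <- rowSums(tk$mask)
  make_buckets <- function() {
    ord <- order(lens, stats::runif(n))
    groups <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    lapply(groups, function(idx) {
      Lb <- max(lens[idx])
      list(idx = idx,
           batch = make_batch(tk$tokens[idx, seq_len(Lb), drop = FALSE],
                              tk$mask[idx, seq_len(Lb), drop = FALSE], model))
    })
  }
  opt <- adam_init(model$params)
  curve <- numeric(config$epochs)
  step <- 0L
  lcfg <- config$mfdl
  lcfg$reduction <- "mean"
  local_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      prepared <- make_buckets()
      losses <- numeric(length(prepared))
      for (k in sample.int(length(prepared))) {
        pb <- prepared[[k]]
        logits <- forward_batch(model, pb$batch, training = TRUE)
        loss <- loss_graph(config$loss, logits, Y[pb$idx, , drop = FALSE],
                           stats, lcfg)
        lv <- as.numeric(loss$value)
        if (!is.finite(lv))
          stop("divergence: non-finite loss at epoch ", ep,
               " (try a lower learning rate)")
        pf_backward(loss)
        clip_gradients(model$params, config$clip_norm)
        step <- step + 1L
        opt <- adam_step(model$params, opt, config$learning_rate, step)
        losses[k] <- lv
      }
      curve[ep] <- mean(losses)
      if (config$verbose)
        message(sprintf("epoch %d/%d loss %.4f", ep, config$epochs, curve[ep]))
    }
  })
  report <- list(loss_curve = curve, class_stats = stats, config = config,
                 seed = config$seed)
  if (!is.null(valid_records) && nrow(valid_records)) {
    ev <- evaluate_model(model, valid_records, labels, config$threshold)
    report$metrics <- ev$report
  }
  list(model = model, report = report)
}

#' Seeded k-fold cross-validation
#'
#' @param records `pf_records` data.frame.
#' @param config A [train_config()] (uses `config$folds`).
#' @param labels A [label_space()].
#' @return List with per-fold `pf_metric_report`s, the fold assignment, and
#'   a `summary` data.frame of mean, sd and `mean±sd` strings per metric.
#' @export
cross_validate <- function(records, config, labels) {
  n <- nrow(records)
  if (config$folds > n) stop("config error: more folds than records")
  fold_of <- local_seed(config$seed, sample(rep(seq_len(config$folds),
                                               length.out = n)))
  reports <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    fit <- train_model(records[fold_of != f, , drop = FALSE],
                       records[fold_of == f, , drop = FALSE], config, labels)
    reports[[f]] <- fit$report$metrics
  }
  list(fold_reports = reports, fold_of = fold_of,
       summary = summarize_folds(reports))
}

#' Mean +/- sd summary of fold metrics
#'
#' @param reports List of `pf_metric_report`s.
#' @return data.frame with columns metric, mean, sd and the formatted
#'   `mean±sd` string used in results tables.
#' @export
summarize_folds <- function(reports) {
  keys <- c("precision", "coverage", "accuracy", "absolute_true",
            "absolute_false", "f1", "mcc")
  vals <- sapply(keys, function(k) vapply(reports, `[[`, numeric(1), k))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1L,
                                         dimnames = list(NULL, keys))
  data.frame(metric = keys,
             mean = colMeans(vals),
             sd = apply(vals, 2L, stats::sd),
             formatted = sprintf("%.3f±%.3f", colMeans(vals),
                                 apply(vals, 2L, stats::sd)),
             row.names = NULL)
}

#' Ablation harness
#'
#' One run per target with only that element disabled: module targets remove
#' the component (gate fusion is replaced by plain summation of aligned
#' streams), stream targets zero the stream in every batch. All other
#' hyperparameters are held fixed. An empty target list yields the baseline
#' run only.
#'
#' @param records `pf_records` data.frame (split 80/20 internally with the
#'   config seed).
#' @param config A [train_config()].
#' @param labels A [label_space()].
#' @param targets Character vector of module and/or stream names.
#' @return data.frame of metrics, one row per run (first row `baseline`).
#' @export
run_ablation <- function(records, config, labels, targets = character(0)) {
  bad <- setdiff(targets, c(MODULE_NAMES, STREAM_NAMES))
  if (length(bad)) stop("config error: unknown target(s) ", paste(bad, collapse = ","))
  sp <- split_dataset(records, 0.8, config$seed)
  one_run <- function(target) {
    cfg <- config
    if (!is.na(target)) {
      if (target %in% MODULE_NAMES) {
        cfg$model$ablate_modules <- union(cfg$model$ablate_modules, target)
      } else {
        cfg$model$ablate_streams <- union(cfg$model$ablate_streams, target)
      }
    }
    fit <- train_model(sp$train, sp$test, cfg, labels)
    m <- fit$report$metrics
    data.frame(target = if (is.na(target)) "baseline" else target,
               precision = m$precision, coverage = m$coverage,
               accuracy = m$accuracy, absolute_true = m$absolute_true,
               absolute_false = m$absolute_false, f1 = m$f1, mcc = m$mcc)
  }
  do.call(rbind, lapply(c(NA_character_, targets), one_run))
}

#' Per-class coverage (recall)
#'
#' @param true_matrix,pred_matrix Binary matrices.
#' @return Per-class recall vector (`NA` for classes without positives).
#' @export
per_class_coverage <- function(true_matrix, pred_matrix) {
  npos <- colSums(true_matrix == 1)
  hit <- colSums(true_matrix == 1 & pred_matrix == 1)
  ifelse(npos > 0, hit / npos, NA_real_)
}

#' Loss-comparison harness
#'
#' Trains the same architecture under each loss variant on a fixed 80/20
#' split and reports the seven metrics plus minority-class coverage (the
#' class with the fewest training positives).
#'
#' @param records `pf_records` data.frame.
#' @param config A [train_config()].
#' @param labels A [label_space()].
#' @param variants Loss names to compare.
#' @return data.frame, one row per variant.
#' @export
compare_losses <- function(records, config, labels,
                           variants = c("mfdl", "bce", "focal", "mlfdl",
                                        "ldam_margin", "asymmetric")) {
  sp <- split_dataset(records, 0.8, config$seed)
  Ytr <- label_matrix(sp$train, labels)
  minority <- which.min(ifelse(colSums(Ytr) > 0, colSums(Ytr), Inf))
  do.call(rbind, lapply(variants, function(v) {
    cfg <- config
    cfg$loss <- v
    fit <- train_model(sp$train, sp$test, cfg, labels)
    ev <- evaluate_model(fit$model, sp$test, labels, cfg$threshold)
    cov <- per_class_coverage(label_matrix(sp$test, labels), ev$pred)
    m <- ev$report
    data.frame(loss = v, precision = m$precision, coverage = m$coverage,
               accuracy = m$accuracy, absolute_true = m$absolute_true,
               absolute_false = m$absolute_false, f1 = m$f1, mcc = m$mcc,
               minority_coverage = cov[minority])
  }))
}
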