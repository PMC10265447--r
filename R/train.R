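# Seeded multitask training: Adam with (decoupled by default) weight decay,
# minibatches interleaved across relations each epoch, class-balanced BCE for
# binary relations, MSE for regressions.

#' Training configuration
#'
#' Defaults follow the reference setup: Adam with learning rate 0.001 and
#' weight decay 0.001. The epoch schedule (full pass per relation per epoch,
#' minibatch-interleaved, optional per-relation cap for dense self-relations)
#' and the epoch count with plateau early stopping are this package's
#' choices.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay Weight penalty rate.
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed; initialization and batching are bit-reproducible
#'   under it on a single thread.
#' @param per_relation_cap Optional maximum number of cells sampled per
#'   relation per epoch (uniformly, without replacement within the epoch);
#'   keeps the cost of dense similarity self-relations linear in the main
#'   relation size.
#' @param patience Early-stopping patience: training stops after this many
#'   epochs without global-training-loss improvement of at least `min_delta`.
#'   `Inf` disables early stopping.
#' @param min_delta Minimum improvement counted by the plateau rule.
#' @param decoupled Apply weight decay decoupled from the adaptive step
#'   (default); `FALSE` adds the classical L2 term `weight_decay * theta` to
#'   the gradient instead, which makes Adam's stationary points coincide with
#'   minima of `loss + (weight_decay / 2) * ||theta||^2`.
#' @param balance_direction Direction of the binary class-balance weight,
#'   see [bce_pos_weight()].
#' @param frozen Character vector of relation names excluded from training
#'   (no batches drawn); relations with zero training cells must be listed
#'   here.
#' @return A list of class `er_train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.001,
                         epochs = 200L, batch_size = 2048L, seed = 1L,
                         per_relation_cap = NULL, patience = 20L,
                         min_delta = 1e-4, decoupled = TRUE,
                         balance_direction = "neg_over_pos",
                         frozen = character(0)) {
  stopifnot(learning_rate > 0, weight_decay >= 0, epochs >= 0, batch_size >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed), per_relation_cap = per_relation_cap,
                 patience = patience, min_delta = min_delta,
                 decoupled = isTRUE(decoupled),
                 balance_direction = balance_direction, frozen = frozen),
            class = "er_train_config")
}

adam_step <- function(model, gacc, st, config, t) {
  P <- model$params
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  lr <- config$learning_rate
  wd <- config$weight_decay
  c1 <- 1 - b1^t
  c2 <- 1 - b2^t
  for (key in model$param_names) {
    th <- P[[key]]
    g <- gacc[[key]]
    if (is.null(g)) {
      if (is.null(st$m[[key]])) {
        if (wd > 0 && config$decoupled) P[[key]] <- th - lr * wd * th
        if (wd > 0 && !config$decoupled) g <- wd * th else next
      } else g <- 0
    }
    if (!config$decoupled && wd > 0) g <- g + wd * th
    m <- st$m[[key]]
    v <- st$v[[key]]
    if (is.null(m)) {
      m <- 0
      v <- 0
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    st$m[[key]] <- m
    st$v[[key]] <- v
    th <- th - lr * (m / c1) / (sqrt(v / c2) + eps)
    if (config$decoupled && wd > 0) th <- th - lr * wd * th
    P[[key]] <- th
  }
  invisible(NULL)
}

#' Fit an ER model by seeded multitask optimization
#'
#' Initializes a model for `graph` and optimizes all parameters jointly on
#' the given training cells. Each epoch draws a full pass (or up to
#' `per_relation_cap` cells) over every relation's training cells, split into
#' minibatches and interleaved across relations in random order; every
#' minibatch is one optimizer step on the weighted relation loss.
#'
#' @param graph An [er_graph()].
#' @param train Named list (by relation) of integer indices into that
#'   relation's `cells` rows to train on; relations not listed train on all
#'   their cells. A relation with no training cells must appear in
#'   `config$frozen`.
#' @param config A [train_config()].
#' @return A fitted `er_model` with elements `history` (per-epoch global and
#'   per-relation training losses) and `train_idx`.
#' @export
fit <- function(graph, train = NULL, config = train_config()) {
  stopifnot(inherits(graph, "er_graph"), inherits(config, "er_train_config"))
  rels <- graph$relations
  if (!length(rels)) stop("graph has no relations")
  train_idx <- lapply(rels, function(r) seq_len(nrow(r$cells)))
  if (!is.null(train)) {
    for (nm in names(train)) {
      if (!nm %in% names(rels)) stop(sprintf("unknown relation '%s'", nm))
      idx <- as.integer(train[[nm]])
      if (length(idx) && (min(idx) < 1L || max(idx) > nrow(rels[[nm]]$cells)))
        stop(sprintf("relation '%s': training index out of range", nm))
      train_idx[[nm]] <- idx
    }
  }
  active <- setdiff(names(rels), config$frozen)
  main <- main_relation(graph)
  if (main %in% active && length(train_idx[[main]]) == 0L)
    stop("empty main relation")
  for (nm in active)
    if (length(train_idx[[nm]]) == 0L)
      stop(sprintf("relation '%s' has no training cells and is not frozen", nm))

  model <- init_er_model(graph, seed = config$seed)
  cell_row <- lapply(rels, function(r) r$cells$row)
  cell_col <- lapply(rels, function(r) r$cells$col)
  cell_val <- lapply(rels, function(r) r$cells$value)
  pos_w <- lapply(names(rels), function(nm) {
    r <- rels[[nm]]
    if (r$loss != "bce_balanced") return(1)
    bce_pos_weight(r$cells$value[train_idx[[nm]]], config$balance_direction)
  })
  names(pos_w) <- names(rels)

  hist_global <- numeric(0)
  hist_rel <- list()
  if (config$epochs > 0L) {
    st <- new.env(parent = emptyenv())
    st$m <- list()
    st$v <- list()
    t <- 0L
    with_seed(config$seed + 1L, {
      best <- Inf
      bad <- 0L
      for (ep in seq_len(config$epochs)) {
        tasks <- list()
        for (nm in active) {
          idx <- train_idx[[nm]]
          n <- length(idx)
          take <- if (!is.null(config$per_relation_cap))
            min(n, config$per_relation_cap) else n
          perm <- idx[sample.int(n, take)]
          nb <- ceiling(take / config$batch_size)
          grp <- rep(seq_len(nb), each = config$batch_size, length.out = take)
          for (b in split(perm, grp))
            tasks[[length(tasks) + 1L]] <- list(rel = nm, idx = b)
        }
        tasks <- tasks[sample.int(length(tasks))]
        ep_loss <- structure(numeric(length(rels)), names = names(rels))
        ep_n <- structure(numeric(length(rels)), names = names(rels))
        for (task in tasks) {
          rel <- rels[[task$rel]]
          rr <- cell_row[[task$rel]][task$idx]
          cv <- cell_col[[task$rel]][task$idx]
          vv <- cell_val[[task$rel]][task$idx]
          fw <- relation_forward(model, rel, rr, cv, cache = TRUE)
          lg <- relation_loss_grad(rel, fw$score, vv, pos_w[[task$rel]])
          if (!is.finite(lg$loss))
            stop(sprintf("non-finite loss in relation '%s' at epoch %d",
                         task$rel, ep))
          gacc <- g_new()
          relation_backward(model, rel, fw, rel$weight * lg$dscore, gacc)
          t <- t + 1L
          adam_step(model, gacc, st, config, t)
          ep_loss[task$rel] <- ep_loss[task$rel] + lg$loss * length(task$idx)
          ep_n[task$rel] <- ep_n[task$rel] + length(task$idx)
        }
        rl <- ifelse(ep_n > 0, ep_loss / pmax(ep_n, 1), NA_real_)
        gl <- sum(vapply(names(rels), function(nm)
          if (ep_n[nm] > 0) rels[[nm]]$weight * rl[nm] else 0, numeric(1)))
        hist_global <- c(hist_global, gl)
        hist_rel[[length(hist_rel) + 1L]] <- rl
        if (gl < best - config$min_delta) {
          best <- gl
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad >= config$patience) break
        }
      }
    })
  }
  hist <- if (length(hist_global)) {
    cbind(data.frame(epoch = seq_along(hist_global), global = hist_global),
          as.data.frame(do.call(rbind, hist_rel)))
  } else {
    data.frame(epoch = integer(0), global = numeric(0))
  }
  for (nm in names(rels)) {
    cc <- rels[[nm]]$cells[train_idx[[nm]], ]
    sn <- rels[[nm]]$src
    dn <- rels[[nm]]$dst
    model$trained[[sn]][unique(cc$row)] <- TRUE
    model$trained[[dn]][unique(cc$col)] <- TRUE
  }
  model$history <- hist
  model$train_idx <- train_idx
  model$pos_weight <- pos_w
  model$config <- config
  model
}

#' Predict scores for arbitrary pairs of a relation
#'
#' Scores any `(row, col)` pairs, including cells never observed. Pairs
#' involving an entity instance that appeared in no training cell keep their
#' (random-initialization) score but are flagged `untrained`.
#'
#' @param object A fitted `er_model`.
#' @param relation Relation name.
#' @param pairs `data.frame` (or 2-column matrix) of 1-based `row`, `col`
#'   indices.
#' @param ... Unused.
#' @return `data.frame(row, col, score, prob, untrained)`; `prob` is
#'   `plogis(score)` for binary tasks, `NA` otherwise.
#' @export
predict.er_model <- function(object, relation, pairs, ...) {
  rel <- object$graph$relations[[relation]]
  if (is.null(rel)) stop(sprintf("unknown relation '%s'", relation))
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 2L) stop("pairs must have two columns (row, col)")
  names(pairs)[1:2] <- c("row", "col")
  sc <- relation_score(object, relation, pairs$row, pairs$col)
  untrained <- !(object$trained[[rel$src]][pairs$row] &
                 object$trained[[rel$dst]][pairs$col])
  data.frame(row = pairs$row, col = pairs$col, score = sc,
             prob = if (rel$task == "binary") plogis(sc) else NA_real_,
             untrained = untrained)
}

#' Evaluate a fitted model on held-out cells
#'
#' Computes the task metrics on test cells of a relation: AUC, AUPRC,
#' precision and recall for binary tasks; MSE and concordance index for
#' regressions. Any overlap between the test cells and the cells the model
#' was trained on is a hard error (leakage guard).
#'
#' @param model A fitted `er_model`.
#' @param relation Relation name.
#' @param test Integer indices into the relation's `cells` rows, or a
#'   `data.frame(row, col, value)` of labeled cells.
#' @param threshold Probability threshold for precision/recall.
#' @return A one-row `data.frame` of metrics.
#' @export
evaluate <- function(model, relation, test, threshold = 0.5) {
  stopifnot(inherits(model, "er_model"))
  rel <- model$graph$relations[[relation]]
  if (is.null(rel)) stop(sprintf("unknown relation '%s'", relation))
  cells <- if (is.data.frame(test)) test else rel$cells[as.integer(test), ]
  tr <- rel$cells[model$train_idx[[relation]], ]
  if (any(paste(cells$row, cells$col) %in% paste(tr$row, tr$col)))
    stop(sprintf("relation '%s': test cells overlap training cells (leakage)",
                 relation))
  pr <- predict(model, relation, cells[c("row", "col")])
  if (rel$task == "binary") {
    pc <- precision_recall(pr$prob, cells$value, threshold = threshold)
    data.frame(auc = roc_auc(pr$prob, cells$value),
               auprc = pr_auc(pr$prob, cells$value),
               precision = pc[["precision"]], recall = pc[["recall"]],
               n = nrow(cells))
  } else {
    data.frame(mse = mse(pr$score, cells$value),
               ci = concordance_index(cells$value, pr$score),
               n = nrow(cells))
  }
}
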