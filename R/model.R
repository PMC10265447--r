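# Model state and forward contracts.
#
# Parameters live in a flat environment keyed by dotted paths
# ("e.<entity>.emb", "e.<entity>.f1.W", "s.<entity>.We", "r.<rel>.A", ...),
# which gives reference semantics during training and a deterministic
# ordering for the optimizer and for serialization.

entity_param_keys <- function(ent) {
  keys <- list(emb = sprintf("e.%s.emb", ent$name))
  keys$layers <- lapply(seq_len(ent$depth), function(l)
    c(W = sprintf("e.%s.f%d.W", ent$name, l),
      b = sprintf("e.%s.f%d.b", ent$name, l)))
  keys
}

side_param_keys <- function(entity) {
  c(We = sprintf("s.%s.We", entity), Wx = sprintf("s.%s.Wx", entity))
}

relation_param_keys <- function(rel) {
  if (rel$module$mode == "dot") return(list())
  keys <- list(bil = c(A = sprintf("r.%s.A", rel$name),
                       c = sprintf("r.%s.c", rel$name)))
  hk <- lapply(seq_len(rel$module$head_depth), function(l)
    c(W = sprintf("r.%s.h%d.W", rel$name, l),
      b = sprintf("r.%s.h%d.b", rel$name, l)))
  pure_bilinear <- rel$module$head_depth == 0L && rel$module$hidden == 1L
  if (!pure_bilinear)
    hk <- c(hk, list(c(W = sprintf("r.%s.out.W", rel$name),
                       b = sprintf("r.%s.out.b", rel$name))))
  keys$head <- hk
  keys$pure_bilinear <- pure_bilinear
  keys
}

#' Initialize a model for an ER graph
#'
#' Allocates embedding tables, entity-module weights, side-information mixers
#' and relation modules with seeded fan-in-scaled Gaussian initialization.
#' Two models initialized from the same graph and seed are identical.
#'
#' @param graph An [er_graph()] with at least one relation.
#' @param seed Integer seed for the initialization stream.
#' @return An object of class `er_model`.
#' @export
init_er_model <- function(graph, seed = 1L) {
  stopifnot(inherits(graph, "er_graph"))
  if (!length(graph$relations)) stop("graph has no relations")
  P <- new.env(parent = emptyenv())
  order <- character(0)
  put <- function(key, val) {
    P[[key]] <- val
    order <<- c(order, key)
  }
  with_seed(seed, {
    for (ent in graph$entities) {
      put(sprintf("e.%s.emb", ent$name),
          matrix(rnorm(ent$n * ent$emb_dim, sd = 1 / sqrt(ent$emb_dim)),
                 ent$n, ent$emb_dim))
      din <- ent$emb_dim
      for (l in seq_len(ent$depth)) {
        put(sprintf("e.%s.f%d.W", ent$name, l),
            matrix(rnorm(din * ent$width, sd = 1 / sqrt(din)), din, ent$width))
        put(sprintf("e.%s.f%d.b", ent$name, l), numeric(ent$width))
        din <- ent$width
      }
    }
    for (si in graph$side_info) {
      ent <- graph$entities[[si$entity]]
      w <- if (ent$depth > 0L) ent$width else ent$emb_dim
      put(sprintf("s.%s.We", si$entity),
          matrix(rnorm(ent$emb_dim * w, sd = 1 / sqrt(ent$emb_dim)),
                 ent$emb_dim, w))
      put(sprintf("s.%s.Wx", si$entity),
          matrix(rnorm(si$d * w, sd = 1 / sqrt(si$d)), si$d, w))
    }
    for (rel in graph$relations) {
      if (rel$module$mode == "dot") next
      wu <- latent_width(graph, rel$src)
      wv <- latent_width(graph, rel$dst)
      H <- rel$module$hidden
      put(sprintf("r.%s.A", rel$name),
          matrix(rnorm(wu * H * wv, sd = (wu * wv)^-0.5), wu, H * wv))
      put(sprintf("r.%s.c", rel$name), numeric(H))
      din <- H
      for (l in seq_len(rel$module$head_depth)) {
        put(sprintf("r.%s.h%d.W", rel$name, l),
            matrix(rnorm(din * rel$module$head_width, sd = 1 / sqrt(din)),
                   din, rel$module$head_width))
        put(sprintf("r.%s.h%d.b", rel$name, l), numeric(rel$module$head_width))
        din <- rel$module$head_width
      }
      if (!(rel$module$head_depth == 0L && H == 1L)) {
        put(sprintf("r.%s.out.W", rel$name),
            matrix(rnorm(din, sd = 1 / sqrt(din)), din, 1L))
        put(sprintf("r.%s.out.b", rel$name), 0)
      }
    }
  })
  structure(list(graph = graph, params = P, param_names = order,
                 seed = seed,
                 trained = lapply(graph$entities, function(e) logical(e$n)),
                 history = NULL),
            class = "er_model")
}

latent_width <- function(graph, entity) {
  ent <- graph$entities[[entity]]
  if (ent$depth > 0L) ent$width else ent$emb_dim
}

# forward through an entity module (+ side-information mixing); optionally
# caches intermediates for the backward pass
entity_forward <- function(model, entity, idx, activation = "tanh",
                           cache = FALSE) {
  graph <- model$graph
  ent <- graph$entities[[entity]]
  P <- model$params
  keys <- entity_param_keys(ent)
  x0 <- P[[keys$emb]][idx, , drop = FALSE]
  ff <- ff_forward(x0, P, keys$layers, activation, norm = TRUE, cache = cache)
  out <- ff$out
  si <- graph$side_info[[entity]]
  sic <- NULL
  if (!is.null(si)) {
    sk <- side_param_keys(entity)
    Ew <- x0 %*% P[[sk[["We"]]]]
    Xs <- si$features[idx, , drop = FALSE]
    Xw <- as.matrix(Xs %*% P[[sk[["Wx"]]]])
    out <- out + Ew * Xw
    if (cache) sic <- list(Ew = Ew, Xw = Xw, Xs = Xs)
  }
  list(out = out, x0 = x0, idx = idx, ff = ff, sic = sic, keys = keys)
}

# backward for entity_forward; accumulates parameter grads into gacc,
# including the (rowsum-aggregated) embedding gradient
entity_backward <- function(model, entity, fw, dout, activation, gacc) {
  P <- model$params
  keys <- fw$keys
  dx0 <- ff_backward(dout, P, keys$layers, fw$ff$caches, activation, gacc)
  if (is.null(dim(dx0))) dx0 <- matrix(dx0, nrow = length(fw$idx))
  if (!is.null(fw$sic)) {
    sk <- side_param_keys(entity)
    dEw <- dout * fw$sic$Xw
    dXw <- dout * fw$sic$Ew
    g_add(gacc, sk[["We"]], crossprod(fw$x0, dEw))
    g_add(gacc, sk[["Wx"]], as.matrix(Matrix::crossprod(fw$sic$Xs, dXw)))
    dx0 <- dx0 + tcrossprod(dEw, P[[sk[["We"]]]])
  }
  agg <- rowsum(dx0, fw$idx)
  rows <- as.integer(rownames(agg))
  ekey <- keys$emb
  cur <- gacc[[ekey]]
  if (is.null(cur)) cur <- matrix(0, nrow(P[[ekey]]), ncol(P[[ekey]]))
  cur[rows, ] <- cur[rows, , drop = FALSE] + agg
  gacc[[ekey]] <- cur
  invisible(NULL)
}

# forward for a batch of (row, col) pairs of one relation; entity modules
# run once per unique instance, only the pairing stage is per cell
relation_forward <- function(model, rel, rows, cols, cache = FALSE) {
  act <- rel$module$activation
  ur <- unique(rows)
  iu <- match(rows, ur)
  uc <- unique(cols)
  iv <- match(cols, uc)
  fu <- entity_forward(model, rel$src, ur, act, cache = cache)
  fv <- entity_forward(model, rel$dst, uc, act, cache = cache)
  if (rel$module$mode == "dot") {
    score <- as.vector(pair_dot_cpp(t(fu$out), t(fv$out), iu, iv))
    return(list(score = score, fu = fu, fv = fv, iu = iu, iv = iv,
                bil = NULL, head = NULL))
  }
  rk <- relation_param_keys(rel)
  P <- model$params
  bil <- bil_forward(fu$out, fv$out, iu, iv, P[[rk$bil[["A"]]]],
                     P[[rk$bil[["c"]]]], cache = cache)
  if (rk$pure_bilinear) {
    return(list(score = bil$out[, 1L], fu = fu, fv = fv, iu = iu, iv = iv,
                bil = bil, head = NULL, rk = rk))
  }
  hf <- ff_forward(bil$out, P, rk$head, act, norm = rel$module$norm,
                   linear_last = TRUE, cache = cache)
  list(score = hf$out[, 1L], fu = fu, fv = fv, iu = iu, iv = iv,
       bil = bil, head = hf, rk = rk)
}

# backward from dscore (vector) through the relation module and both
# entities; latent gradients are aggregated per unique instance
relation_backward <- function(model, rel, fw, dscore, gacc) {
  act <- rel$module$activation
  if (rel$module$mode == "dot") {
    du <- rowsum_ordered(dscore * fw$fv$out[fw$iv, , drop = FALSE], fw$iu,
                         nrow(fw$fu$out))
    dv <- rowsum_ordered(dscore * fw$fu$out[fw$iu, , drop = FALSE], fw$iv,
                         nrow(fw$fv$out))
  } else {
    P <- model$params
    rk <- fw$rk
    if (is.null(fw$head)) {
      dbil <- matrix(dscore, ncol = 1L)
    } else {
      dbil <- ff_backward(matrix(dscore, ncol = 1L), P, rk$head,
                          fw$head$caches, act, gacc)
    }
    bb <- bil_backward(dbil, P[[rk$bil[["A"]]]], fw$bil$cache, rk$bil, gacc)
    du <- bb$du
    dv <- bb$dv
  }
  entity_backward(model, rel$src, fw$fu, du, act, gacc)
  entity_backward(model, rel$dst, fw$fv, dv, act, gacc)
  invisible(NULL)
}

#' Latent representation of entity instances
#'
#' Returns `f(e[indices])`, the entity-module output for the selected
#' instances, with side information mixed in when attached. Deterministic
#' given the model parameters.
#'
#' @param model An [init_er_model()] or fitted model.
#' @param entity Entity name.
#' @param indices 1-based instance indices.
#' @return A `length(indices) x width` matrix.
#' @export
entity_latent <- function(model, entity, indices) {
  stopifnot(inherits(model, "er_model"))
  ent <- model$graph$entities[[entity]]
  if (is.null(ent)) stop(sprintf("unknown entity '%s'", entity))
  indices <- as.integer(indices)
  if (length(indices) && (min(indices) < 1L || max(indices) > ent$n))
    stop("index out of range")
  entity_forward(model, entity, indices, activation = "tanh")$out
}

#' Raw scores for entity pairs under a relation
#'
#' One raw score per `(row, col)` pair. For binary tasks the predicted
#' probability is `plogis(score)`; for regression the score is the predicted
#' value.
#'
#' @param model An `er_model`.
#' @param relation Relation name.
#' @param rows,cols Equal-length 1-based index vectors into the source and
#'   destination entities.
#' @return Numeric vector of scores, in input order.
#' @export
relation_score <- function(model, relation, rows, cols) {
  stopifnot(inherits(model, "er_model"))
  rel <- model$graph$relations[[relation]]
  if (is.null(rel)) stop(sprintf("unknown relation '%s'", relation))
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  if (length(rows) != length(cols)) stop("rows and cols must have equal length")
  ns <- model$graph$entities[[rel$src]]$n
  nd <- model$graph$entities[[rel$dst]]$n
  if (length(rows) && (min(rows) < 1L || max(rows) > ns ||
                       min(cols) < 1L || max(cols) > nd))
    stop("index out of range")
  relation_forward(model, rel, rows, cols)$score
}

#' Weighted multitask loss over per-relation batches
#'
#' Computes `sum_ij omega_ij * L_ij` where each `L_ij` is the relation's loss
#' evaluated on its batch of observed cells. Cells not observed in the
#' relation are rejected.
#'
#' @param model An `er_model`.
#' @param batches Named list (by relation name) of `data.frame(row, col,
#'   value)` batches, each a subset of that relation's observed cells.
#' @return Scalar loss.
#' @export
global_loss <- function(model, batches) {
  stopifnot(inherits(model, "er_model"))
  total <- 0
  for (nm in names(batches)) {
    rel <- model$graph$relations[[nm]]
    if (is.null(rel)) stop(sprintf("unknown relation '%s'", nm))
    b <- batches[[nm]]
    obs <- paste(rel$cells$row, rel$cells$col)
    if (!all(paste(b$row, b$col) %in% obs))
      stop(sprintf("relation '%s': batch references unobserved cells", nm))
    sc <- relation_score(model, nm, b$row, b$col)
    lf <- relation_loss_value(rel, sc, b$value,
                              pos_weight = bce_pos_weight(rel$cells$value))
    total <- total + rel$weight * lf
  }
  total
}

relation_loss_value <- function(rel, scores, values, pos_weight = 1) {
  if (rel$loss == "bce_balanced")
    balanced_bce(scores, values, pos_weight = pos_weight)
  else mean((scores - values)^2)
}
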