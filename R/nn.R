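# Low-level neural primitives: feed-forward stacks with pre-activation layer
# normalization, and the stacked bilinear pairing stage. Forward passes cache
# exactly what the hand-derived backward passes need; everything is plain
# matrix algebra so the whole step is BLAS-bound.

LN_EPS <- 1e-5

# add a bias row-vector to every row of a matrix (column-major recycling)
add_bias <- function(z, b) z + rep(b, each = nrow(z))

ln_forward <- function(z) {
  m <- rowMeans(z)
  v <- rowMeans(z * z) - m * m
  inv <- 1 / sqrt(pmax(v, 0) + LN_EPS)
  list(zn = (z - m) * inv, inv = inv)
}

# dzn: gradient w.r.t. normalized output; zn, inv from the forward cache
ln_backward <- function(dzn, zn, inv) {
  inv * (dzn - rowMeans(dzn) - zn * rowMeans(dzn * zn))
}

act_forward <- function(z, activation) {
  if (activation == "tanh") tanh(z) else z
}

act_backward <- function(dout, a, activation) {
  if (activation == "tanh") dout * (1 - a * a) else dout
}

# keys: list of c(W = "...", b = "...") per layer, resolved in env `P`.
# Layer: z = x W + b; layer norm (pre-activation, skipped on width-1 layers);
# activation. `linear_last` turns off norm+activation on the final layer
# (used for the raw-score output layer of relation heads).
ff_forward <- function(x, P, keys, activation, norm, linear_last = FALSE,
                       cache = FALSE) {
  L <- length(keys)
  caches <- if (cache) vector("list", L) else NULL
  for (l in seq_len(L)) {
    W <- P[[keys[[l]][["W"]]]]
    last_linear <- linear_last && l == L
    use_norm <- norm && !last_linear && ncol(W) > 1L
    tanh_act <- !last_linear && activation == "tanh"
    r <- layer_fwd_cpp(x, W, P[[keys[[l]][["b"]]]], use_norm, tanh_act)
    if (cache) caches[[l]] <- list(x = x, zn = r$zn, a = r$a, inv = r$inv,
                                   use_norm = use_norm, tanh_act = tanh_act)
    x <- r$a
  }
  list(out = x, caches = caches)
}

ff_backward <- function(dout, P, keys, caches, activation, gacc) {
  for (l in rev(seq_along(keys))) {
    cc <- caches[[l]]
    r <- layer_bwd_cpp(dout, cc$x, cc$a, cc$zn,
                       if (cc$use_norm) cc$inv else numeric(0),
                       P[[keys[[l]][["W"]]]], cc$use_norm, cc$tanh_act)
    g_add(gacc, keys[[l]][["W"]], r$dW)
    g_add(gacc, keys[[l]][["b"]], r$db)
    dout <- r$dx
  }
  dout
}

# Stacked bilinear stage over unique instances:
# h[b, k] = u[iu[b], ] %*% A_k %*% v[iv[b], ] + c[k].
# A is stored wu x (H * wv) with column (j - 1) * H + k holding A_k[, j]
# (H-interleaved layout). The fused kernels live in src/bilinear.cpp.
bil_forward <- function(Uu, Vu, iu, iv, A, cvec, cache = FALSE) {
  UAuT <- t(Uu %*% A)
  VuT <- t(Vu)
  hT <- pair_bil_fwd_cpp(UAuT, VuT, iu, iv, cvec)
  res <- list(out = t(hT))
  if (cache) res$cache <- list(Uu = Uu, UAuT = UAuT, VuT = VuT,
                               iu = iu, iv = iv)
  res
}

# returns per-unique-instance latent gradients dUu (nu x wu), dVu (nv x wv)
bil_backward <- function(dh, A, cc, keys, gacc) {
  r <- pair_bil_bwd_cpp(t(dh), cc$UAuT, cc$VuT, cc$iu, cc$iv)
  dUAu <- t(r$dUAuT)
  g_add(gacc, keys[["A"]], crossprod(cc$Uu, dUAu))
  g_add(gacc, keys[["c"]], r$dc)
  list(du = tcrossprod(dUAu, A), dv = t(r$dVuT))
}

# aggregate rows of x by group index g into an n-row matrix (group i -> row i)
rowsum_ordered <- function(x, g, n) {
  agg <- rowsum(x, g)
  out <- matrix(0, n, ncol(x))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

# gradient accumulator helpers (environment-backed, reference semantics)
g_new <- function() new.env(parent = emptyenv())

g_add <- function(gacc, key, val) {
  val <- as.matrix(val)
  cur <- gacc[[key]]
  gacc[[key]] <- if (is.null(cur)) val else cur + val
  invisible(NULL)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
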