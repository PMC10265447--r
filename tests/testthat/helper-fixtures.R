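# Shared fixtures, built in code.

# a small fully-specified binary DTI graph
tiny_graph <- function(n_drugs = 8, n_proteins = 6, n_cells = 20, seed = 1) {
  cells <- withr_seed(seed, {
    all <- expand.grid(row = seq_len(n_drugs), col = seq_len(n_proteins))
    all <- all[sample(nrow(all), n_cells), ]
    all$value <- rbinom(n_cells, 1, 0.5)
    all
  })
  g <- er_graph()
  g <- add_entity(g, "drug", n_drugs, embedding_dim = 6, module_width = 4,
                  module_depth = 2)
  g <- add_entity(g, "protein", n_proteins, embedding_dim = 5,
                  module_width = 4, module_depth = 2)
  add_relation(g, "dti", "drug", "protein", cells, task = "binary",
               module = list(hidden = 4, head_width = 4))
}

# seed helper that restores the RNG state (tests should not leak state)
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# brute-force O(n^2) ROC AUC: concordant positive-negative score pairs,
# half credit for ties
bruteforce_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# brute-force concordance index over pairs with distinct truths
bruteforce_ci <- function(true, pred) {
  num <- 0
  z <- 0
  n <- length(true)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (true[i] == true[j]) next
    hi <- if (true[i] > true[j]) i else j
    lo <- if (true[i] > true[j]) j else i
    d <- pred[hi] - pred[lo]
    num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
    z <- z + 1
  }
  num / z
}

# exhaustive threshold enumeration of the precision-recall step area
bruteforce_prauc <- function(scores, labels) {
  ths <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prev_rec <- 0
  area <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / npos
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# brute-force per-pair Tanimoto on a list of 0-based on-bit sets
bruteforce_tanimoto <- function(bitsets) {
  n <- length(bitsets)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    u <- length(union(bitsets[[i]], bitsets[[j]]))
    S[i, j] <- if (u == 0) 0 else
      length(intersect(bitsets[[i]], bitsets[[j]])) / u
  }
  S
}
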