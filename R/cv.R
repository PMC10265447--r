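# The five cross-validation fold schemes for interaction matrices, and the
# entity-polarization leakage diagnostic.
#
# Schemes (per observed cell of a drug x protein relation):
#   random        cells partitioned uniformly into k folds
#   no_strat      random partition repaired so every entity in a test fold
#                 also occurs in that fold's training cells
#   protein_strat proteins partitioned; a fold's test cells are the cells of
#                 its protein group (test proteins unseen in training)
#   drug_strat    same with drugs
#   pair_strat    drugs and proteins partitioned independently; fold f tests
#                 cells with BOTH endpoints in group f, trains on cells with
#                 NEITHER, and discards cells with exactly one held-out
#                 endpoint (unusable for that fold)

FOLD_SCHEMES <- c("random", "no_strat", "protein_strat", "drug_strat",
                  "pair_strat")

#' Build a cross-validation fold plan
#'
#' @param cells `data.frame(row, col, ...)` of observed cells (`row` = drug
#'   index, `col` = protein index).
#' @param scheme One of `"random"`, `"no_strat"`, `"protein_strat"`,
#'   `"drug_strat"`, `"pair_strat"`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; entity groupings are uniform random.
#' @return An object of class `fold_plan`. Use [train_cells()] /
#'   [test_cells()] / [discarded_cells()] to obtain per-fold cell indices.
#' @export
make_folds <- function(cells, scheme = FOLD_SCHEMES, k = 5L, seed = 1L) {
  scheme <- match.arg(scheme)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  n <- nrow(cells)
  if (n < k) stop("fewer cells than folds")
  plan <- list(scheme = scheme, k = k, seed = seed, n = n,
               row = cells$row, col = cells$col)
  with_seed(seed, {
    if (scheme %in% c("random", "no_strat")) {
      fold <- sample(rep_len(seq_len(k), n))
      if (scheme == "no_strat") fold <- repair_no_strat(cells, fold, k)
      plan$fold <- fold
    } else if (scheme %in% c("protein_strat", "drug_strat")) {
      ent <- if (scheme == "drug_strat") cells$row else cells$col
      ids <- unique(ent)
      if (length(ids) < k)
        stop(sprintf("%s: fewer than k distinct entities", scheme))
      grp <- structure(sample(rep_len(seq_len(k), length(ids))), names = ids)
      plan$entity_group <- grp
      plan$fold <- unname(grp[as.character(ent)])
    } else {
      dr <- unique(cells$row)
      pr <- unique(cells$col)
      if (length(dr) < k || length(pr) < k)
        stop("pair_strat: fewer than k distinct drugs or proteins")
      plan$drug_group <- structure(sample(rep_len(seq_len(k), length(dr))),
                                   names = dr)
      plan$protein_group <- structure(sample(rep_len(seq_len(k), length(pr))),
                                      names = pr)
    }
  })
  structure(plan, class = "fold_plan")
}

# move cells of entities concentrated in a single fold so that every test
# entity also appears in training; requires entities with >= 2 cells
repair_no_strat <- function(cells, fold, k) {
  for (iter in 1:100) {
    bad <- FALSE
    for (side in c("row", "col")) {
      ent <- cells[[side]]
      for (id in unique(ent)) {
        w <- which(ent == id)
        if (length(w) < 2L) next  # singleton entity: unrepairable, reported
        if (length(unique(fold[w])) == 1L) {
          bad <- TRUE
          fold[w[1]] <- fold[w[1]] %% k + 1L
        }
      }
    }
    if (!bad) return(fold)
  }
  fold
}

cell_status <- function(plan, f) {
  if (plan$scheme == "pair_strat") {
    dg <- unname(plan$drug_group[as.character(plan$row)])
    pg <- unname(plan$protein_group[as.character(plan$col)])
    ifelse(dg == f & pg == f, "test",
           ifelse(dg != f & pg != f, "train", "discarded"))
  } else {
    ifelse(plan$fold == f, "test", "train")
  }
}

#' @rdname make_folds
#' @param plan A `fold_plan`.
#' @param f Fold number in `1..k`.
#' @return Integer indices into the `cells` the plan was built on.
#' @export
train_cells <- function(plan, f) which(cell_status(plan, f) == "train")

#' @rdname make_folds
#' @export
test_cells <- function(plan, f) which(cell_status(plan, f) == "test")

#' @rdname make_folds
#' @export
discarded_cells <- function(plan, f) which(cell_status(plan, f) == "discarded")

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %s, k=%d, %d cells, seed=%d\n", x$scheme, x$k, x$n,
              x$seed))
  for (f in seq_len(x$k)) {
    st <- cell_status(x, f)
    cat(sprintf("  fold %d: train=%d test=%d discarded=%d\n", f,
                sum(st == "train"), sum(st == "test"), sum(st == "discarded")))
  }
  invisible(x)
}

#' Entity polarization of a binary interaction table
#'
#' The fraction of entities whose observed interactions carry only one label
#' (only positives or only negatives), among entities with at least one
#' observed cell -- the leakage diagnostic explaining why entity-stratified
#' cross-validation can look easy: a model can learn whether an entity is
#' "generally active" from the non-stratified side.
#'
#' @param cells `data.frame(row, col, value)` with binary values.
#' @return List with `drug`, `protein` and `overall` polarization fractions
#'   (`overall` pools both entity classes).
#' @export
polarization_report <- function(cells) {
  if (!all(cells$value %in% c(0, 1)))
    stop("polarization is defined for binary relations only")
  homog <- function(ent) {
    both <- tapply(cells$value, ent, function(v) min(v) == max(v))
    c(sum(both), length(both))
  }
  d <- homog(cells$row)
  p <- homog(cells$col)
  list(drug = d[1] / d[2], protein = p[1] / p[2],
       overall = (d[1] + p[1]) / (d[2] + p[2]))
}

#' Verify a fold plan against its cells
#'
#' Report-only diagnostic: asserts per-fold train/test cell disjointness,
#' full test coverage for `random`/`no_strat`, scheme-specific entity
#' disjointness, the `no_strat` contract (every test entity occurs in that
#' fold's training cells) and the pair-stratification discard accounting
#' (every discarded cell has exactly one held-out endpoint).
#'
#' @param plan A [make_folds()] plan.
#' @param cells The cells the plan was built on.
#' @param status Optional explicit per-(cell, fold) status table as returned
#'   by [read_fold_plan()]; when given, the serialized assignment is verified
#'   instead of the plan's own (so externally stored or edited splits can be
#'   audited).
#' @return Character vector of violations; empty means the plan is valid.
#' @export
verify_folds <- function(plan, cells, status = NULL) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  if (nrow(cells) != plan$n) say("cell count mismatch: %d vs %d", nrow(cells), plan$n)
  status_of <- function(f) {
    if (is.null(status)) return(cell_status(plan, f))
    sf <- status[status$fold == f, ]
    sf$status[order(sf$cell)]
  }
  test_seen <- integer(0)
  for (f in seq_len(plan$k)) {
    st <- status_of(f)
    tr <- which(st == "train")
    te <- which(st == "test")
    if (length(intersect(tr, te))) say("fold %d: train/test cells overlap", f)
    test_seen <- c(test_seen, te)
    if (plan$scheme == "drug_strat" &&
        length(bad <- intersect(cells$row[tr], cells$row[te])))
      say("fold %d: drug %s in both train and test", f, bad[1])
    if (plan$scheme == "protein_strat" &&
        length(bad <- intersect(cells$col[tr], cells$col[te])))
      say("fold %d: protein %s in both train and test", f, bad[1])
    if (plan$scheme == "pair_strat") {
      if (length(bad <- intersect(cells$row[tr], cells$row[te])))
        say("fold %d: drug %s in both train and test", f, bad[1])
      if (length(bad <- intersect(cells$col[tr], cells$col[te])))
        say("fold %d: protein %s in both train and test", f, bad[1])
      dg <- unname(plan$drug_group[as.character(cells$row)])
      pg <- unname(plan$protein_group[as.character(cells$col)])
      disc <- which(st == "discarded")
      one_out <- xor(dg[disc] == f, pg[disc] == f)
      if (!all(one_out))
        say("fold %d: %d discarded cells without exactly one held-out endpoint",
            f, sum(!one_out))
      if (length(tr) + length(te) + length(disc) != plan$n)
        say("fold %d: cells unaccounted for", f)
    }
    if (plan$scheme == "no_strat") {
      if (length(bad <- setdiff(cells$row[te], cells$row[tr])))
        say("fold %d: test drug %s absent from training", f, bad[1])
      if (length(bad <- setdiff(cells$col[te], cells$col[tr])))
        say("fold %d: test protein %s absent from training", f, bad[1])
    }
  }
  if (plan$scheme %in% c("random", "no_strat", "protein_strat", "drug_strat")) {
    if (length(test_seen) != plan$n || anyDuplicated(test_seen))
      say("test folds do not cover all cells exactly once")
  }
  v
}

#' Serialize / read a fold plan as TSV
#'
#' One row per (cell, fold) with the cell's status, enabling external
#' reproduction of exact splits.
#'
#' @param plan A [make_folds()] plan.
#' @param path Output file.
#' @return `write_fold_plan` invisibly returns `path`; `read_fold_plan`
#'   returns a `data.frame(cell, fold, status)`.
#' @export
write_fold_plan <- function(plan, path) {
  rows <- do.call(rbind, lapply(seq_len(plan$k), function(f)
    data.frame(cell = seq_len(plan$n), fold = f, status = cell_status(plan, f))))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
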