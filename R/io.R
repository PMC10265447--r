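# TSV interchange formats. Ids are opaque strings mapped to dense 1-based
# indices in first-appearance order; registries persist the mapping so
# splits stay valid across runs.

#' Read a drug-protein interaction table
#'
#' Three tab-separated columns (no header): drug id, protein id, value
#' (binary label or real-valued affinity). Ids are assigned dense indices in
#' first-appearance order.
#'
#' @param path Input TSV.
#' @return List with `cells` (`data.frame(row, col, value)`), `drug_ids` and
#'   `protein_ids` registries.
#' @export
read_interactions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sprintf("%s: malformed line %d (expected 3 tab-separated fields)",
                 path, bad[1]))
  drug <- vapply(parts, `[[`, "", 1L)
  prot <- vapply(parts, `[[`, "", 2L)
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  if (anyNA(val))
    stop(sprintf("%s: non-numeric value on line %d", path, which(is.na(val))[1]))
  dup <- duplicated(paste(drug, prot))
  if (any(dup))
    stop(sprintf("%s: duplicate pair (%s, %s)", path, drug[which(dup)[1]],
                 prot[which(dup)[1]]))
  drug_ids <- unique(drug)
  protein_ids <- unique(prot)
  list(cells = data.frame(row = match(drug, drug_ids),
                          col = match(prot, protein_ids),
                          value = val),
       drug_ids = drug_ids, protein_ids = protein_ids)
}

#' Write an interaction table
#'
#' @param tab `data.frame(drug, protein, value)` with ids as strings.
#' @param path Output TSV.
#' @export
write_interactions <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a dense similarity matrix
#'
#' Square TSV with id header row and id first column. The matrix is
#' reordered to match `ids` when given; an id missing from the file is an
#' error; values outside `[0, 1]` are kept with a warning.
#'
#' @param path Input TSV.
#' @param ids Optional entity registry fixing the output order.
#' @return Dense numeric matrix with id dimnames.
#' @export
read_similarity <- function(path, ids = NULL) {
  tab <- read.delim(path, row.names = 1L, check.names = FALSE)
  M <- as.matrix(tab)
  if (nrow(M) != ncol(M))
    stop(sprintf("%s: similarity matrix must be square (got %d x %d)",
                 path, nrow(M), ncol(M)))
  if (!identical(sort(rownames(M)), sort(colnames(M))))
    stop(sprintf("%s: row and column ids differ", path))
  M <- M[, rownames(M), drop = FALSE]
  if (!is.null(ids)) {
    missing <- setdiff(ids, rownames(M))
    if (length(missing))
      stop(sprintf("%s: entities missing from similarity matrix: %s", path,
                   paste(head(missing, 5), collapse = ", ")))
    M <- M[ids, ids, drop = FALSE]
  }
  if (any(M < 0) || any(M > 1))
    warning(sprintf("%s: similarity values outside [0, 1] kept as-is", path))
  M
}

#' Write a dense similarity matrix
#'
#' @param M Square matrix with id dimnames.
#' @param path Output TSV.
#' @export
write_similarity <- function(M, path) {
  write.table(as.data.frame(M), path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a two-column annotation table
#'
#' `entity_id<TAB>term`, no header.
#'
#' @param path Input TSV.
#' @return Named list mapping entity id -> character vector of terms.
#' @export
read_annotations <- function(path) {
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  split(as.character(tab[[2]]),
        factor(as.character(tab[[1]]), levels = unique(as.character(tab[[1]]))))
}

#' Export a training history as TSV
#'
#' @param model A fitted `er_model`.
#' @param path Output TSV (one row per epoch: global and per-relation loss).
#' @export
write_history <- function(model, path) {
  write.table(model$history, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model to a plain-text archive
#'
#' Writes all parameters, the graph structure, the training configuration
#' and seed into one JSON file from which [read_er_model()] rebuilds an
#' identical model.
#'
#' @param model An `er_model`.
#' @param path Output `.json` file.
#' @export
write_er_model <- function(model, path) {
  stopifnot(inherits(model, "er_model"))
  graph <- model$graph
  side <- lapply(graph$side_info, function(si) {
    list(entity = si$entity, features = as.matrix(si$features))
  })
  obj <- list(
    seed = model$seed,
    param_names = model$param_names,
    params = lapply(structure(model$param_names, names = model$param_names),
                    function(k) model$params[[k]]),
    trained = model$trained,
    config = unclass(model$config),
    graph = list(
      entities = lapply(graph$entities, function(e)
        e[c("name", "n", "emb_dim", "width", "depth", "ids")]),
      relations = lapply(graph$relations, function(r)
        list(name = r$name, src = r$src, dst = r$dst, task = r$task,
             loss = r$loss, weight = r$weight, main = r$main,
             module = r$module, cells = r$cells)),
      side_info = side
    )
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_er_model
#' @param path Archive written by [write_er_model()].
#' @return A reconstructed `er_model`.
#' @export
read_er_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- er_graph()
  for (e in obj$graph$entities)
    g <- add_entity(g, e$name, e$n, e$emb_dim, e$width, e$depth,
                    ids = if (length(e$ids)) e$ids else NULL)
  for (r in obj$graph$relations)
    g <- add_relation(g, r$name, r$src, r$dst, as.data.frame(r$cells),
                      task = r$task, loss = r$loss, weight = r$weight,
                      main = r$main, module = as.list(r$module))
  for (si in obj$graph$side_info)
    g <- add_side_info(g, si$entity, si$features)
  model <- init_er_model(g, seed = obj$seed)
  for (k in obj$param_names) {
    ref <- model$params[[k]]
    val <- obj$params[[k]]
    model$params[[k]] <- if (is.matrix(ref)) matrix(val, nrow(ref)) else
      as.numeric(val)
  }
  model$trained <- lapply(obj$trained, as.logical)
  if (!is.null(obj$config)) {
    cfg <- obj$config
    cfg$per_relation_cap <- cfg$per_relation_cap %||% NULL
    model$config <- structure(cfg, class = "er_train_config")
  }
  model
}
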