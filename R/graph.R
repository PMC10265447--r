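# Entity-relation graph data model.
#
# An er_graph is a plain list holding entities (each a trainable embedding
# table description), relations (sparsely observed matrices between two
# entities, each a prediction task with its own loss and weight) and optional
# per-entity side information (feature matrices mixed into the latent
# representation rather than modelled as relations).

#' Create an empty entity-relation graph
#'
#' An ER graph collects *entities* (classes of objects such as drugs,
#' proteins or protein domains, each represented by a trainable embedding
#' table) and *relations* (sparsely observed matrices between two entities).
#' All relations registered on a graph are factorized jointly by one
#' multitask model: entities shared between relations share a single
#' embedding table and entity module, which is the mechanism by which
#' auxiliary relations inform the main task.
#'
#' @return An object of class `er_graph`.
#' @seealso [add_entity()], [add_relation()], [add_side_info()], [fit()]
#' @export
#' @examples
#' g <- er_graph()
#' g <- add_entity(g, "drug", n_instances = 10, embedding_dim = 20)
er_graph <- function() {
  structure(list(entities = list(), relations = list(), side_info = list()),
            class = "er_graph")
}

#' Register an entity on an ER graph
#'
#' @param graph An [er_graph()].
#' @param name Entity name (unique within the graph).
#' @param n_instances Number of instances (rows of the embedding table).
#' @param embedding_dim Embedding dimensionality. Defaults follow the model's
#'   reference architecture: 30 for proteins, 20 for drugs, 10 for domains
#'   (see [entity_defaults()]).
#' @param module_width Output width of the entity module (latent dimension);
#'   10 for drugs, 20 for proteins in the reference architecture.
#' @param module_depth Number of feed-forward layers in the entity module.
#' @param ids Optional character vector of instance identifiers
#'   (length `n_instances`); maps external ids to row indices.
#' @return The modified graph.
#' @export
add_entity <- function(graph, name, n_instances, embedding_dim = 20,
                       module_width = 10, module_depth = 3, ids = NULL) {
  stopifnot(inherits(graph, "er_graph"))
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("entity name must be a non-empty string")
  if (name %in% names(graph$entities))
    stop(sprintf("entity '%s' is already registered", name))
  if (n_instances < 1 || embedding_dim < 1 || module_width < 1 || module_depth < 0)
    stop("entity sizes must be positive (module_depth may be 0)")
  if (!is.null(ids)) {
    ids <- as.character(ids)
    if (length(ids) != n_instances) stop("ids must have length n_instances")
    if (anyDuplicated(ids)) stop("entity ids must be unique")
  }
  graph$entities[[name]] <- list(
    name = name,
    n = as.integer(n_instances),
    emb_dim = as.integer(embedding_dim),
    width = as.integer(module_width),
    depth = as.integer(module_depth),
    ids = ids
  )
  graph
}

#' Reference architecture defaults for an entity role
#'
#' Embedding dimensions 30/20/10 and entity-module widths 20/10 for
#' proteins/drugs (domains get width 10) mirror the reference model.
#'
#' @param role One of `"drug"`, `"protein"`, `"domain"`.
#' @return A list with `embedding_dim`, `module_width`, `module_depth`.
#' @export
entity_defaults <- function(role = c("drug", "protein", "domain")) {
  role <- match.arg(role)
  switch(role,
    drug    = list(embedding_dim = 20L, module_width = 10L, module_depth = 3L),
    protein = list(embedding_dim = 30L, module_width = 20L, module_depth = 3L),
    domain  = list(embedding_dim = 10L, module_width = 10L, module_depth = 3L)
  )
}

# validate a cell data.frame against its endpoint entities
validate_cells <- function(cells, src_ent, dst_ent, task, relation_name = "?") {
  if (!is.data.frame(cells) || !all(c("row", "col", "value") %in% names(cells)))
    stop("cells must be a data.frame with columns row, col, value")
  cells <- data.frame(row = as.integer(cells$row), col = as.integer(cells$col),
                      value = as.numeric(cells$value))
  if (nrow(cells)) {
    if (anyNA(cells)) stop("cells contain NA")
    if (min(cells$row) < 1L || max(cells$row) > src_ent$n)
      stop(sprintf("relation '%s': row index out of range [1, %d]",
                   relation_name, src_ent$n))
    if (min(cells$col) < 1L || max(cells$col) > dst_ent$n)
      stop(sprintf("relation '%s': col index out of range [1, %d]",
                   relation_name, dst_ent$n))
    if (anyDuplicated(cells[c("row", "col")]))
      stop(sprintf("relation '%s': duplicate (row, col) cells", relation_name))
    if (task == "binary" && !all(cells$value %in% c(0, 1)))
      stop(sprintf("relation '%s': binary task requires values in {0, 1}",
                   relation_name))
  }
  cells
}

#' Register a relation (observed matrix) on an ER graph
#'
#' A relation is a sparsely observed matrix between a source and a
#' destination entity, reconstructed by a relation module (bilinear stage
#' followed by a small feed-forward head) and trained with its own loss,
#' weighted by `weight` in the global multitask objective. A *self-relation*
#' (`src == dst`, e.g. drug-drug similarity) shares the single embedding
#' table of its entity.
#'
#' @param graph An [er_graph()].
#' @param name Relation name (unique).
#' @param src,dst Names of registered entities (rows resp. columns).
#' @param cells `data.frame(row, col, value)` of observed cells
#'   (1-based indices). Binary tasks require values in `{0, 1}`.
#' @param task `"binary"` or `"regression"`.
#' @param loss One of `"bce_balanced"` (class-balanced binary cross-entropy)
#'   or `"mse"`; defaults to the task's canonical loss.
#' @param weight Non-negative task weight `omega` in the global objective
#'   (uniform 1 by default).
#' @param main Mark this relation as the main prediction task. The first
#'   relation added is the main task unless overridden.
#' @param module Optional list overriding relation-module hyperparameters:
#'   `hidden` (bilinear output width, default 10), `head_depth` (default 2),
#'   `head_width` (default 10), `activation` (`"tanh"` or `"identity"`),
#'   `norm` (layer normalization, default `TRUE`), `mode` (`"bilinear"` or
#'   `"dot"`; `"dot"` scores by the plain inner product of the two latents,
#'   the linear matrix-factorization limit).
#' @return The modified graph.
#' @export
add_relation <- function(graph, name, src, dst, cells,
                         task = c("binary", "regression"), loss = NULL,
                         weight = 1, main = NA, module = list()) {
  stopifnot(inherits(graph, "er_graph"))
  task <- match.arg(task)
  if (name %in% names(graph$relations))
    stop(sprintf("relation '%s' is already registered", name))
  for (e in c(src, dst))
    if (!e %in% names(graph$entities))
      stop(sprintf("entity '%s' is not registered", e))
  if (is.null(loss)) loss <- if (task == "binary") "bce_balanced" else "mse"
  loss <- match.arg(loss, c("bce_balanced", "mse"))
  if (task == "binary" && loss == "mse")
    stop("binary tasks use the bce_balanced loss")
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0)
    stop("weight must be a single non-negative number")
  cells <- validate_cells(cells, graph$entities[[src]], graph$entities[[dst]],
                          task, name)
  mod <- modifyList(list(hidden = 10L, head_depth = 2L, head_width = 10L,
                         activation = "tanh", norm = TRUE, mode = "bilinear"),
                    module)
  if (is.na(main)) main <- length(graph$relations) == 0L
  graph$relations[[name]] <- list(
    name = name, src = src, dst = dst, task = task, loss = loss,
    weight = weight, cells = cells, main = isTRUE(main), module = mod
  )
  graph
}

#' Attach side information to an entity
#'
#' Side information is a per-instance feature matrix (dense, or sparse for
#' e.g. 30000-bit fingerprints) mixed into the entity's latent representation
#' through a factored bilinear combination of the embedding and the feature
#' vector, rather than modelled as a relation. Sparse features are never
#' densified in the forward pass.
#'
#' @param graph An [er_graph()].
#' @param entity Name of a registered entity.
#' @param features Matrix (or `Matrix::sparseMatrix`) with
#'   `n_instances` rows, row order matching the entity's index.
#' @return The modified graph.
#' @export
add_side_info <- function(graph, entity, features) {
  stopifnot(inherits(graph, "er_graph"))
  if (!entity %in% names(graph$entities))
    stop(sprintf("entity '%s' is not registered", entity))
  ent <- graph$entities[[entity]]
  if (nrow(features) != ent$n)
    stop(sprintf("features must have %d rows (one per instance)", ent$n))
  if (inherits(features, "sparseMatrix"))
    features <- methods::as(features, "CsparseMatrix")
  graph$side_info[[entity]] <- list(entity = entity, features = features,
                                    d = ncol(features))
  graph
}

#' @export
print.er_graph <- function(x, ...) {
  cat("er_graph:", length(x$entities), "entities,",
      length(x$relations), "relations\n")
  for (e in x$entities)
    cat(sprintf("  entity %-10s n=%d emb=%d width=%d depth=%d%s\n", e$name,
                e$n, e$emb_dim, e$width, e$depth,
                if (e$name %in% names(x$side_info))
                  sprintf(" +side[%d]", x$side_info[[e$name]]$d) else ""))
  for (r in x$relations)
    cat(sprintf("  relation %-12s %s x %s  %s/%s  cells=%d  w=%g%s\n", r$name,
                r$src, r$dst, r$task, r$loss, nrow(r$cells), r$weight,
                if (r$main) "  [main]" else ""))
  invisible(x)
}

main_relation <- function(graph) {
  for (r in graph$relations) if (r$main) return(r$name)
  if (length(graph$relations)) names(graph$relations)[1L] else
    stop("graph has no relations")
}

#' Build a DTI graph with the reference architecture
#'
#' Convenience constructor for the common graphs: the single-relation
#' baseline (G1, main DTI task only) and its extensions with similarity
#' self-relations and annotation data. Uses the reference entity sizes
#' ([entity_defaults()]).
#'
#' @param cells `data.frame(row, col, value)` of observed DTI cells
#'   (drug x protein).
#' @param n_drugs,n_proteins Entity sizes.
#' @param task `"binary"` or `"regression"`.
#' @param drug_similarity,protein_similarity Optional dense similarity
#'   matrices added as MSE-regression self-relations.
#' @param annotations Optional binary protein x term incidence matrix added
#'   as a binary protein-domain relation.
#' @param annotations_as_side Attach `annotations` as sparse side
#'   information on the protein entity instead of as a relation.
#' @return An [er_graph()].
#' @export
dti_graph <- function(cells, n_drugs, n_proteins,
                      task = c("binary", "regression"),
                      drug_similarity = NULL, protein_similarity = NULL,
                      annotations = NULL, annotations_as_side = FALSE) {
  task <- match.arg(task)
  dense_cells <- function(S)
    data.frame(row = rep(seq_len(nrow(S)), ncol(S)),
               col = rep(seq_len(ncol(S)), each = nrow(S)),
               value = as.vector(S))
  dd <- entity_defaults("drug")
  pd <- entity_defaults("protein")
  g <- er_graph()
  g <- add_entity(g, "drug", n_drugs, dd$embedding_dim, dd$module_width,
                  dd$module_depth)
  g <- add_entity(g, "protein", n_proteins, pd$embedding_dim,
                  pd$module_width, pd$module_depth)
  g <- add_relation(g, "dti", "drug", "protein", cells, task = task,
                    main = TRUE)
  if (!is.null(drug_similarity))
    g <- add_relation(g, "drug_sim", "drug", "drug",
                      dense_cells(drug_similarity), task = "regression")
  if (!is.null(protein_similarity))
    g <- add_relation(g, "protein_sim", "protein", "protein",
                      dense_cells(protein_similarity), task = "regression")
  if (!is.null(annotations)) {
    if (annotations_as_side) {
      g <- add_side_info(g, "protein", Matrix::Matrix(annotations,
                                                      sparse = TRUE))
    } else {
      td <- entity_defaults("domain")
      g <- add_entity(g, "domain", ncol(annotations), td$embedding_dim,
                      td$module_width, td$module_depth)
      g <- add_relation(g, "pfam", "protein", "domain",
                        dense_cells(annotations), task = "binary")
    }
  }
  g
}
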