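# Builders for the auxiliary relations and side information: fingerprint
# Tanimoto similarity, row-normalised alignment-score similarity, domain
# incidence, sparse fingerprint side information, log-space affinity
# transform and negative sampling.

#' Construct a fingerprint set
#'
#' @param ids Character vector of instance ids (ordered as the entity index).
#' @param bits List (per id) of 0-based on-bit indices, or a sparse/dense
#'   binary matrix with `length(ids)` rows.
#' @param n_bits Fingerprint length; 1028 is the similarity default, 30000
#'   the sparse side-information default.
#' @param radius Circular-fingerprint radius recorded as provenance.
#' @return Object of class `fingerprint_set` with a sparse logical `bits`
#'   matrix (`n x n_bits`).
#' @export
fingerprint_set <- function(ids, bits, n_bits = 1028L, radius = 2L) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate fingerprint ids")
  if (is.list(bits)) {
    if (length(bits) != length(ids)) stop("one bit vector per id required")
    ii <- rep(seq_along(bits), lengths(bits))
    jj <- unlist(bits, use.names = FALSE)
    if (length(jj) && (min(jj) < 0 || max(jj) >= n_bits))
      stop(sprintf("bit index out of range [0, %d)", n_bits))
    M <- Matrix::sparseMatrix(i = ii, j = jj + 1L, x = 1,
                              dims = c(length(ids), n_bits))
  } else {
    M <- methods::as(methods::as(Matrix::Matrix(bits, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    if (nrow(M) != length(ids)) stop("one row per id required")
    n_bits <- ncol(M)
  }
  structure(list(ids = ids, bits = M, n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "fingerprint_set")
}

#' Pairwise Tanimoto (Jaccard) similarity of binary fingerprints
#'
#' `S[i, j] = |bits_i & bits_j| / |bits_i | bits_j|`; symmetric, 1 on the
#' diagonal for non-empty fingerprints. A pair of two empty fingerprints is
#' defined as 0 (no shared chemistry evidence).
#'
#' @param fps A [fingerprint_set()].
#' @return Dense `n x n` similarity matrix in `[0, 1]` with id dimnames.
#' @export
tanimoto_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  B <- fps$bits
  inter <- as.matrix(Matrix::tcrossprod(B))
  sz <- Matrix::rowSums(B)
  un <- outer(sz, sz, "+") - inter
  S <- ifelse(un > 0, inter / pmax(un, 1e-300), 0)
  dimnames(S) <- list(fps$ids, fps$ids)
  S
}

#' Row-normalize a non-negative matrix
#'
#' Divides every row with a positive sum by that sum (the convention used
#' for alignment bit-score similarity matrices); all-zero rows are left
#' unchanged. Idempotent.
#'
#' @param M Non-negative numeric matrix.
#' @return Matrix whose row sums are 0 or 1.
#' @export
row_normalize <- function(M) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("matrix entries must be non-negative")
  rs <- rowSums(M)
  pos <- rs > 0
  M[pos, ] <- M[pos, , drop = FALSE] / rs[pos]
  M
}

#' Binary incidence matrix from entity -> term annotations
#'
#' Builds the binary entity x term matrix (e.g. protein x Pfam domain):
#' rows follow `ids`, columns the sorted vocabulary of all annotated terms.
#'
#' @param annotations Named list mapping entity id -> character vector of
#'   terms, or a two-column `data.frame(id, term)`.
#' @param ids Character vector of registered entity ids fixing the row
#'   order; annotation ids outside it are an error.
#' @return Binary matrix with dimnames `(ids, vocabulary)`.
#' @export
incidence_matrix <- function(annotations, ids) {
  ids <- as.character(ids)
  if (is.data.frame(annotations)) {
    annotations <- split(as.character(annotations[[2]]),
                         factor(as.character(annotations[[1]]),
                                levels = unique(as.character(annotations[[1]]))))
  }
  unknown <- setdiff(names(annotations), ids)
  if (length(unknown))
    stop(sprintf("annotated ids not in the entity registry: %s",
                 paste(head(unknown, 5), collapse = ", ")))
  vocab <- sort(unique(unlist(annotations, use.names = FALSE)))
  M <- matrix(0, length(ids), length(vocab), dimnames = list(ids, vocab))
  for (id in names(annotations))
    M[id, unique(annotations[[id]])] <- 1
  M
}

#' Load fingerprints from an on-bit index file or SMILES
#'
#' Two sources are supported: (a) a sparse on-bit file, one record per line,
#' `id<TAB>comma-separated 0-based on-bit indices`; (b) a two-column TSV
#' `id<TAB>smiles`, hashed into extended-connectivity circular fingerprints
#' (radius 2 via OpenBabel's ECFP4 through the ChemmineOB package) and
#' folded to `n_bits` by index modulo. Unparsable SMILES are skipped with a
#' warning.
#'
#' @param path Input file.
#' @param format `"bits"` or `"smiles"`.
#' @param n_bits Fingerprint length (1028 default).
#' @param radius Circular-fingerprint radius (2; SMILES path).
#' @return A [fingerprint_set()].
#' @export
load_fingerprints <- function(path, format = c("bits", "smiles"),
                              n_bits = 1028L, radius = 2L) {
  format <- match.arg(format)
  if (format == "bits") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 1L)
    if (length(bad)) stop(sprintf("malformed fingerprint line %d", bad[1]))
    ids <- vapply(parts, `[[`, "", 1L)
    bits <- lapply(parts, function(p) {
      if (length(p) < 2L || !nzchar(trimws(p[[2]]))) return(integer(0))
      as.integer(strsplit(trimws(p[[2]]), ",", fixed = TRUE)[[1]])
    })
    return(fingerprint_set(ids, bits, n_bits = n_bits, radius = radius))
  }
  if (!requireNamespace("ChemmineOB", quietly = TRUE))
    stop("the SMILES path requires the ChemmineOB package")
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  smis <- as.character(tab[[2]])
  fpname <- sprintf("ECFP%d", 2L * radius)
  bits <- vector("list", length(ids))
  keep <- logical(length(ids))
  for (i in seq_along(ids)) {
    raw <- try(suppressWarnings(ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smis[i], identity), fpname)),
      silent = TRUE)
    row <- if (is.matrix(raw) && nrow(raw) >= 1L) raw[1, ] else raw
    if (inherits(raw, "try-error") || !is.numeric(row) || !length(row) ||
        sum(row) == 0) {
      warning(sprintf("skipping unparsable SMILES for id '%s'", ids[i]))
      next
    }
    on <- which(row != 0) - 1L
    bits[[i]] <- sort(unique(on %% n_bits))
    keep[i] <- TRUE
  }
  fingerprint_set(ids[keep], bits[keep], n_bits = n_bits, radius = radius)
}

#' Write a fingerprint set as a sparse on-bit file
#'
#' @param fps A [fingerprint_set()].
#' @param path Output file (`id<TAB>comma-separated 0-based indices`).
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(inherits(fps, "fingerprint_set"))
  B <- methods::as(fps$bits, "TsparseMatrix")
  per <- split(B@j, factor(B@i, levels = seq_along(fps$ids) - 1L))
  lines <- vapply(seq_along(fps$ids), function(i)
    paste0(fps$ids[i], "\t", paste(sort(per[[i]]), collapse = ",")), "")
  writeLines(lines, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-space transform of binding affinities
#'
#' Dissociation constants in nM are mapped to pKd:
#' `pKd = -log10(Kd / 1e9)` (so Kd = 1 nM gives 9). Pre-combined bioactivity
#' scores (aggregated Ki/Kd/IC50 indices) pass through unchanged.
#'
#' @param kd Positive affinities.
#' @param kind `"kd_nM"` or `"score"`.
#' @return Regression target values.
#' @export
transform_affinity <- function(kd, kind = c("kd_nM", "score")) {
  kind <- match.arg(kind)
  if (kind == "score") return(as.numeric(kd))
  if (any(kd <= 0)) stop("Kd values must be positive")
  -log10(kd / 1e9)
}

#' Sample putative negative drug-protein pairs
#'
#' Uniformly samples `(drug, protein)` pairs not present in the positives,
#' without replacement (the random-pairing construction of putative
#' negatives).
#'
#' @param positives `data.frame(row, col)` of positive pairs (1-based).
#' @param n_drugs,n_proteins Entity sizes.
#' @param ratio Negatives per positive (default 1).
#' @param seed Integer seed.
#' @return `data.frame(row, col)` of negatives, disjoint from positives.
#' @export
sample_negatives <- function(positives, n_drugs, n_proteins, ratio = 1,
                             seed = 1L) {
  if (ratio <= 0) stop("ratio must be positive")
  pos_key <- (positives$row - 1) * n_proteins + positives$col
  total <- as.double(n_drugs) * n_proteins
  m <- round(ratio * nrow(positives))
  if (m > total - length(unique(pos_key)))
    stop("requested more negatives than available non-positive pairs")
  with_seed(seed, {
    found <- numeric(0)
    while (length(found) < m) {
      cand <- ceiling(runif(2L * (m - length(found))) * total)
      cand <- setdiff(unique(cand), c(pos_key, found))
      found <- c(found, cand)
    }
    found <- found[seq_len(m)]
  })
  data.frame(row = as.integer((found - 1) %/% n_proteins + 1),
             col = as.integer((found - 1) %% n_proteins + 1))
}
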