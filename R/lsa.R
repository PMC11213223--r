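# Latent semantic analysis of claims codes: log-transformed counts,
# truncated SVD, cosine similarity, and agglomerative clustering on
# angular distance.

#' Build a reduced-rank latent code space
#'
#' Per-pregnancy code counts are transformed with `log(1 + count)` and
#' decomposed by truncated singular value decomposition; the `k` dimensions
#' with the largest singular values are retained (capped at the matrix
#' rank).  Code vectors are the right singular vectors scaled by their
#' singular values, so codes that co-occur across pregnancies receive nearby
#' vectors.  The matrix is not centred before decomposition (the classical
#' latent-semantic-analysis convention); set `center = TRUE` for a
#' PCA-style variant.
#'
#' @param counts Count matrix (pregnancies x codes; base or `Matrix` sparse)
#'   with code column names, or a [derive_panel()] panel (its count matrix is
#'   used) - preferably over all mapped codes, not only the top-k screen set.
#' @param k Retained rank (default 500).
#' @param log_transform Apply `log(1 + x)` first (default `TRUE`).
#' @param center Column-centre before SVD (default `FALSE`).
#' @return Object of class `latent_space`: `k`, `d` (singular values,
#'   non-increasing), `vectors` (codes x k), `codes`.
#' @export
build_latent_space <- function(counts, k = 500L, log_transform = TRUE,
                               center = FALSE) {
  if (inherits(counts, "covariate_panel")) counts <- counts$counts
  if (k < 1L) stop_config("k", "must be >= 1")
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop_config("counts", "must have at least 2 rows and 2 columns")
  }
  X <- as.matrix(counts)
  if (log_transform) X <- log1p(X)
  if (center) X <- scale(X, center = TRUE, scale = FALSE)
  k <- min(k, nrow(X), ncol(X))
  dec <- svd(X, nu = 0L, nv = k)
  d <- dec$d[seq_len(k)]
  vectors <- dec$v * rep(d, each = nrow(dec$v))
  rownames(vectors) <- colnames(counts)
  structure(list(k = k, d = d, vectors = vectors,
                 codes = colnames(counts),
                 log_transform = log_transform, center = center),
            class = "latent_space")
}

#' @export
print.latent_space <- function(x, ...) {
  cat(sprintf("Latent code space: %d codes embedded in %d dimensions\n",
              length(x$codes), x$k))
  cat("  leading singular values:",
      paste(format(head(x$d, 5), digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' Pairwise cosine similarity of code vectors
#'
#' `cos(u, v) = <u, v> / (|u| |v|)`; the derived angular distance is
#' `arccos(cos) / pi`, normalized to `[0, 1]`.  Codes with zero-norm vectors
#' have undefined similarity: they are flagged and excluded.
#'
#' @param space A [build_latent_space()] result.
#' @param codes Codes to compare (subset of the embedded codes; default all).
#' @return Object of class `code_similarity`: `codes`, `cosine`, `distance`,
#'   `zero_norm` (the excluded codes).
#' @export
code_cosines <- function(space, codes = space$codes) {
  stopifnot(inherits(space, "latent_space"))
  missing <- setdiff(codes, space$codes)
  if (length(missing)) {
    stop_config("codes", paste("not embedded:", paste(missing, collapse = ", ")))
  }
  V <- space$vectors[codes, , drop = FALSE]
  nrm <- sqrt(rowSums(V^2))
  zero <- codes[nrm == 0]
  keep <- nrm > 0
  V <- V[keep, , drop = FALSE] / nrm[keep]
  cosine <- tcrossprod(V)
  cosine <- pmin(pmax(cosine, -1), 1)
  diag(cosine) <- 1
  distance <- acos(cosine) / pi
  diag(distance) <- 0
  structure(list(codes = codes[keep], cosine = cosine, distance = distance,
                 zero_norm = zero), class = "code_similarity")
}

#' Cluster codes by angular distance
#'
#' Agglomerative hierarchical clustering (average linkage by default) of the
#' angular-distance matrix; flat groups are cut at the supplied height and
#' reported in a grouping table (code terms per group, group size).
#'
#' @param sim A [code_cosines()] result.
#' @param cut Cut height on the normalized angular-distance scale `[0, 1]`.
#' @param linkage `"average"`, `"single"`, or `"complete"`.
#' @return Object of class `code_clustering`: `tree` (hclust), `labels`
#'   (named cluster ids), `groups` (data frame: group, code_terms, size).
#' @export
cluster_codes <- function(sim, cut, linkage = c("average", "single", "complete")) {
  stopifnot(inherits(sim, "code_similarity"))
  linkage <- match.arg(linkage)
  if (!is.numeric(cut) || length(cut) != 1L || cut < 0 || cut > 1) {
    stop_config("cut", "must lie in [0, 1]")
  }
  if (length(sim$codes) < 2L) {
    labels <- stats::setNames(seq_along(sim$codes), sim$codes)
    groups <- data.frame(group = unname(labels), code_terms = sim$codes,
                         size = 1L, stringsAsFactors = FALSE)
    return(structure(list(tree = NULL, labels = labels, groups = groups,
                          cut = cut, linkage = linkage),
                     class = "code_clustering"))
  }
  tree <- hclust(as.dist(sim$distance), method = linkage)
  labels <- cutree(tree, h = cut)
  terms <- tapply(names(labels), labels, paste, collapse = "; ")
  groups <- data.frame(group = as.integer(names(terms)),
                       code_terms = as.character(terms),
                       size = as.integer(table(labels)[names(terms)]),
                       stringsAsFactors = FALSE)
  groups <- groups[order(-groups$size, groups$group), , drop = FALSE]
  rownames(groups) <- NULL
  structure(list(tree = tree, labels = labels, groups = groups,
                 cut = cut, linkage = linkage), class = "code_clustering")
}

#' @export
print.code_clustering <- function(x, ...) {
  cat(sprintf("Code clustering (%s linkage, cut %.2f): %d groups over %d codes\n",
              x$linkage, x$cut, nrow(x$groups), length(x$labels)))
  print(head(x$groups, 10), row.names = FALSE)
  invisible(x)
}
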