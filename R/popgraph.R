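#' Phenotype edge specification
#'
#' Declares which phenotype columns enter the population-graph adjacency
#' and how each is compared: categorical phenotypes match by Kronecker
#' delta (1 iff equal), numeric phenotypes by a unit step on the absolute
#' difference (1 iff `|a - b| < theta`, strictly; ties at exactly `theta`
#' score 0).
#'
#' @param ... named per-phenotype entries, each a list with `kind`
#'   (`"categorical"` or `"numeric"`) and, for numeric kinds, `theta > 0`
#' @return an object of class `edge_spec`
#' @examples
#' edge_spec(age = list(kind = "numeric", theta = 2),
#'           gender = list(kind = "categorical"))
#' @export
edge_spec <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && is.null(names(entries)) && is.list(entries[[1]]) &&
      !is.null(names(entries[[1]])) && is.list(entries[[1]][[1]])) {
    entries <- entries[[1]]  # allow edge_spec(list(age = ..., ...))
  }
  if (length(entries) == 0L || is.null(names(entries)) || any(names(entries) == "")) {
    abort_fmt("edge_spec needs at least one named phenotype entry")
  }
  for (nm in names(entries)) {
    e <- entries[[nm]]
    if (!is.list(e) || is.null(e$kind) ||
        !e$kind %in% c("categorical", "numeric")) {
      abort_fmt("phenotype '%s': kind must be 'categorical' or 'numeric'", nm)
    }
    if (e$kind == "numeric") {
      if (is.null(e$theta)) e$theta <- 2
      if (!is.numeric(e$theta) || e$theta <= 0) {
        abort_fmt("phenotype '%s': theta must be > 0", nm)
      }
      entries[[nm]] <- e
    }
  }
  structure(entries, class = "edge_spec")
}

#' Default phenotype edge specification
#'
#' Age and APOE epsilon-4 count as numeric phenotypes with threshold 2,
#' gender as categorical -- the three phenotypes used to weight subject
#' similarity in the population graph.
#'
#' @return an [edge_spec()]
#' @export
default_edge_spec <- function() {
  edge_spec(age = list(kind = "numeric", theta = 2),
            gender = list(kind = "categorical"),
            apoe4_count = list(kind = "numeric", theta = 2))
}

#' Pairwise phenotype similarity
#'
#' The scalar similarity entering each adjacency term: Kronecker delta
#' for categorical phenotypes, unit step `1[|a - b| < theta]` for
#' numeric ones. Vectorized over `a` and `b`.
#'
#' @param a,b phenotype values of the same kind
#' @param kind `"categorical"` or `"numeric"`
#' @param theta strict threshold for numeric phenotypes (default 2)
#' @return 0/1 integer vector
#' @examples
#' phenotype_similarity(70, 71.5, "numeric", theta = 2) # 1
#' phenotype_similarity(70, 73,   "numeric", theta = 2) # 0
#' phenotype_similarity("F", "F", "categorical")        # 1
#' @export
phenotype_similarity <- function(a, b, kind = c("categorical", "numeric"),
                                 theta = 2) {
  kind <- match.arg(kind)
  if (kind == "numeric") {
    if (!is.numeric(a) || !is.numeric(b)) {
      abort_fmt("numeric similarity needs numeric values on both sides")
    }
    as.integer(abs(a - b) < theta)
  } else {
    as.integer(as.character(a) == as.character(b))
  }
}

#' Build the phenotype-similarity adjacency matrix
#'
#' `W[m, n]` counts the phenotypes on which subjects `m` and `n` agree
#' under the edge specification, so entries are integers in `[0, P]`
#' where `P` is the number of phenotypes. The diagonal is set to 0 (no
#' self-edges; propagation operators add their own self-loops).
#'
#' @param phenotypes data.frame with one row per subject and the columns
#'   named in `spec` (a `subject` id column is used for dimnames if present)
#' @param spec an [edge_spec()]
#' @return symmetric integer matrix N x N
#' @export
build_adjacency <- function(phenotypes, spec = default_edge_spec()) {
  stopifnot(inherits(spec, "edge_spec"), is.data.frame(phenotypes))
  n <- nrow(phenotypes)
  if (n < 2L) abort_fmt("need at least 2 subjects to build a graph")
  missing_cols <- setdiff(names(spec), names(phenotypes))
  if (length(missing_cols)) {
    abort_fmt("phenotype table lacks columns: %s",
              paste(missing_cols, collapse = ", "))
  }
  ids <- if ("subject" %in% names(phenotypes)) {
    as.character(phenotypes$subject)
  } else {
    rownames(phenotypes)
  }
  W <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (nm in names(spec)) {
    v <- phenotypes[[nm]]
    if (anyNA(v)) {
      abort_fmt("phenotype '%s' missing for subjects: %s", nm,
                paste(ids[is.na(v)], collapse = ", "))
    }
    if (spec[[nm]]$kind == "numeric") {
      v <- as.numeric(v)
      W <- W + (abs(outer(v, v, "-")) < spec[[nm]]$theta)
    } else {
      v <- as.character(v)
      W <- W + outer(v, v, "==")
    }
  }
  diag(W) <- 0L
  storage.mode(W) <- "integer"
  W
}

#' Population graph for semi-supervised classification
#'
#' Bundles the node feature matrix (one subject per row), the symmetric
#' phenotype-similarity adjacency, per-node labels (NA for unlabeled
#' nodes) and disjoint train/test masks. Rows of `X`, `W` and the label
#' vector must refer to the same subject ordering.
#'
#' @param X numeric feature matrix N x M
#' @param W symmetric nonnegative adjacency N x N
#' @param labels factor of length N (NA = unlabeled)
#' @param train_mask,test_mask disjoint logical masks of length N
#' @param phenotypes optional phenotype data.frame kept for provenance
#' @return an object of class `population_graph`
#' @export
population_graph <- function(X, W, labels, train_mask, test_mask,
                             phenotypes = NULL) {
  X <- as.matrix(X)
  W <- as.matrix(W)
  n <- nrow(X)
  if (nrow(W) != n || ncol(W) != n) abort_fmt("W must be %d x %d", n, n)
  if (!isSymmetric(unname(W), tol = 0)) abort_fmt("W must be exactly symmetric")
  if (any(W < 0)) abort_fmt("W must be nonnegative")
  labels <- as.factor(labels)
  if (length(labels) != n) abort_fmt("labels must have length %d", n)
  train_mask <- as.logical(train_mask); test_mask <- as.logical(test_mask)
  if (length(train_mask) != n || length(test_mask) != n) {
    abort_fmt("masks must have length %d", n)
  }
  if (any(train_mask & test_mask)) abort_fmt("train and test masks overlap")
  structure(
    list(X = X, W = W, labels = labels, train_mask = train_mask,
         test_mask = test_mask, phenotypes = phenotypes),
    class = "population_graph"
  )
}

#' @export
print.population_graph <- function(x, ...) {
  cat(sprintf("<population_graph> %d nodes, %d features, %d train / %d test\n",
              nrow(x$X), ncol(x$X), sum(x$train_mask), sum(x$test_mask)))
  invisible(x)
}

#' Symmetric normalized graph Laplacian
#'
#' `L = I - D^{-1/2} W D^{-1/2}` with `D` the degree matrix. For an
#' isolated node (zero degree) the 0/0 limit is resolved to a Laplacian
#' row equal to the identity row, so `L` is always symmetric with
#' eigenvalues in `[0, 2]`.
#'
#' @param W symmetric nonnegative adjacency
#' @return dense symmetric matrix L
#' @examples
#' normalized_laplacian(matrix(c(0, 1, 1, 0), 2)) # [[1,-1],[-1,1]]
#' @export
normalized_laplacian <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) abort_fmt("adjacency must be nonnegative")
  if (!isSymmetric(unname(W))) abort_fmt("adjacency must be symmetric")
  d <- rowSums(W)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  L <- -dinv * sweep(W, 2L, dinv, "*")
  diag(L) <- 1
  (L + t(L)) / 2
}

#' First-order renormalized propagation operator
#'
#' The self-looped, degree-normalized operator
#' `S = D~^{-1/2} (W + I) D~^{-1/2}`, with `D~` the degree matrix of
#' `W + I`, used as the single-hop realization of spectral graph
#' convolution in each network layer. Symmetric with spectral radius
#' at most 1; for an edgeless graph `S = I`.
#'
#' @param W symmetric nonnegative adjacency
#' @return dense symmetric matrix S
#' @examples
#' renormalized_propagation(matrix(c(0, 1, 1, 0), 2)) # all entries 0.5
#' @export
renormalized_propagation <- function(W) {
  W <- as.matrix(W)
  if (any(W < 0)) abort_fmt("adjacency must be nonnegative")
  if (!isSymmetric(unname(W))) abort_fmt("adjacency must be symmetric")
  Wt <- W + diag(nrow(W))
  dinv <- 1 / sqrt(rowSums(Wt))
  S <- dinv * sweep(Wt, 2L, dinv, "*")
  (S + t(S)) / 2
}
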