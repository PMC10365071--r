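#' Vertex-wise cortical thickness dataset
#'
#' A `thickness_dataset` stores per-subject, per-ROI vertex-wise cortical
#' thickness with a shared vertex correspondence across subjects: row
#' `i`, column `v` of `values` is subject `i`'s thickness (mm) at
#' registered vertex `v`, and `vertex_roi[v]` names the ROI that vertex
#' belongs to. All subjects share the same `(ROI, vertex count)`
#' structure by construction.
#'
#' @param values numeric matrix, subjects in rows (rownames are subject
#'   ids), registered vertices in columns
#' @param vertex_roi character or factor of length `ncol(values)` giving
#'   the ROI of each vertex column; vertices of one ROI must be contiguous
#' @param roi_names optional character vector fixing ROI order; defaults
#'   to order of first appearance in `vertex_roi`
#' @return an object of class `thickness_dataset` with fields `values`,
#'   `vertex_roi` (factor) and `roi_names`
#' @export
thickness_dataset <- function(values, vertex_roi, roi_names = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) abort_fmt("thickness values must be numeric")
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("subj%03d", seq_len(nrow(values)))
  }
  if (length(vertex_roi) != ncol(values)) {
    abort_fmt("vertex_roi has length %d but values has %d vertex columns",
              length(vertex_roi), ncol(values))
  }
  if (is.null(roi_names)) roi_names <- unique(as.character(vertex_roi))
  vertex_roi <- factor(as.character(vertex_roi), levels = roi_names)
  if (anyNA(vertex_roi)) abort_fmt("vertex_roi contains ROIs absent from roi_names")
  if (!all(is.finite(values))) abort_fmt("thickness values must be finite")
  structure(
    list(values = values, vertex_roi = vertex_roi, roi_names = roi_names),
    class = "thickness_dataset"
  )
}

#' @export
print.thickness_dataset <- function(x, ...) {
  cat(sprintf("<thickness_dataset> %d subjects, %d ROIs, %d vertices\n",
              nrow(x$values), length(x$roi_names), ncol(x$values)))
  invisible(x)
}

#' @export
dim.thickness_dataset <- function(x) dim(x$values)

#' Subject identifiers of a thickness dataset
#' @param x a `thickness_dataset`
#' @return character vector of subject ids
#' @export
subjects <- function(x) UseMethod("subjects")

#' @export
subjects.thickness_dataset <- function(x) rownames(x$values)

#' Per-ROI vertex counts
#' @param x a `thickness_dataset` or `atrophy_pattern`
#' @return named integer vector, one entry per ROI
#' @export
roi_vertex_counts <- function(x) {
  tab <- table(x$vertex_roi)
  stats::setNames(as.integer(tab), names(tab))
}

#' Subset a thickness dataset by subject
#'
#' @param x a `thickness_dataset`
#' @param ids character subject ids or logical/integer row index
#' @return a `thickness_dataset` restricted to those subjects
#' @export
subset_subjects <- function(x, ids) {
  stopifnot(inherits(x, "thickness_dataset"))
  values <- x$values[ids, , drop = FALSE]
  thickness_dataset(values, x$vertex_roi, x$roi_names)
}

# shared structure check for pattern/dataset pairs
check_same_structure <- function(a, b, what = "inputs") {
  if (length(a$vertex_roi) != length(b$vertex_roi) ||
      !identical(as.character(a$vertex_roi), as.character(b$vertex_roi))) {
    mism <- union(
      setdiff(unique(as.character(a$vertex_roi)), unique(as.character(b$vertex_roi))),
      setdiff(unique(as.character(b$vertex_roi)), unique(as.character(a$vertex_roi)))
    )
    if (length(mism) == 0) mism <- "(vertex counts differ)"
    abort_fmt("%s do not share vertex structure; mismatched ROIs: %s",
              what, paste(mism, collapse = ", "))
  }
  invisible(TRUE)
}

#' Vertex-wise atrophy pattern
#'
#' A z-score per registered vertex quantifying cortical thinning relative
#' to a cognitively unimpaired reference: negative z means thinner than
#' reference. `kind` records whether the pattern describes a group
#' (two-sample contrast) or an individual (one subject against the
#' reference), and `df` the degrees of freedom used in the t-to-z mapping.
#'
#' @param z numeric vector of z-scores, one per vertex
#' @param vertex_roi ROI of each vertex (as in [thickness_dataset()])
#' @param kind `"group"` or `"individual"`
#' @param df degrees of freedom of the originating t statistics
#' @param roi_names optional ROI order
#' @return an object of class `atrophy_pattern`
#' @export
atrophy_pattern <- function(z, vertex_roi, kind = c("group", "individual"),
                            df = NA_real_, roi_names = NULL) {
  kind <- match.arg(kind)
  if (length(z) != length(vertex_roi)) {
    abort_fmt("z has length %d but vertex_roi has length %d",
              length(z), length(vertex_roi))
  }
  if (!all(is.finite(z))) abort_fmt("atrophy z-scores must be finite")
  if (is.null(roi_names)) roi_names <- unique(as.character(vertex_roi))
  vertex_roi <- factor(as.character(vertex_roi), levels = roi_names)
  structure(
    list(z = as.numeric(z), vertex_roi = vertex_roi, kind = kind,
         df = df, roi_names = roi_names),
    class = "atrophy_pattern"
  )
}

#' @export
print.atrophy_pattern <- function(x, ...) {
  cat(sprintf("<atrophy_pattern:%s> %d ROIs, %d vertices, df = %s\n",
              x$kind, length(x$roi_names), length(x$z), format(x$df)))
  invisible(x)
}
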