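#' Remove age and gender effects from vertex-wise thickness
#'
#' Fits, per vertex, an ordinary-least-squares model of thickness on age
#' and gender (and, when the covariate table carries more than one
#' diagnostic group, group indicators so that group differences are kept
#' out of the nuisance estimates and are not regressed away). The
#' returned values subtract only the age and gender terms, evaluated
#' relative to the fitting sample's means, so the output is thickness
#' with covariate effects removed at the sample mean.
#'
#' @param thickness a [thickness_dataset()]
#' @param covariates data.frame with one row per subject of `thickness`
#'   (matched by `subject` column or by order) holding `age` (numeric),
#'   `gender` (two-level factor) and optionally `group`
#' @param fit_subjects optional subject ids on which the model is fitted
#'   (e.g. a CU reference); coefficients are then applied to all
#'   subjects. Default: fit on all subjects
#' @return a [thickness_dataset()] of adjusted values, same structure
#' @export
adjust_glm <- function(thickness, covariates, fit_subjects = NULL) {
  stopifnot(inherits(thickness, "thickness_dataset"), is.data.frame(covariates))
  ids <- subjects(thickness)
  if ("subject" %in% names(covariates)) {
    if (!all(ids %in% covariates$subject)) {
      abort_fmt("covariates missing for subjects: %s",
                paste(setdiff(ids, covariates$subject), collapse = ", "))
    }
    covariates <- covariates[match(ids, covariates$subject), , drop = FALSE]
  } else if (nrow(covariates) != length(ids)) {
    abort_fmt("covariates must have one row per subject")
  }
  if (anyNA(covariates$age) || anyNA(covariates$gender)) {
    abort_fmt("covariates contain missing age or gender values")
  }
  fit_idx <- if (is.null(fit_subjects)) seq_along(ids) else match(fit_subjects, ids)
  if (anyNA(fit_idx)) abort_fmt("fit_subjects not all present in the dataset")
  if (length(fit_idx) < 3L) abort_fmt("need at least 3 subjects to fit the model")

  age <- as.numeric(covariates$age)
  gender <- factor(covariates$gender)
  if (nlevels(droplevels(gender[fit_idx])) < 2L) {
    abort_fmt("degenerate design: only one gender level in the fitting sample")
  }
  age_c <- age - mean(age[fit_idx])
  gender_ind <- as.numeric(gender == levels(gender)[2L])
  gender_c <- gender_ind - mean(gender_ind[fit_idx])

  D <- cbind(intercept = 1, age = age_c[fit_idx], gender = gender_c[fit_idx])
  if (!is.null(covariates$group)) {
    grp <- droplevels(factor(covariates$group)[fit_idx])
    if (nlevels(grp) > 1L) {
      G <- stats::model.matrix(~grp)[, -1L, drop = FALSE]
      D <- cbind(D, scale(G, scale = FALSE))
    }
  }
  if (qr(D)$rank < ncol(D)) {
    abort_fmt("degenerate design: covariate columns are collinear")
  }
  beta <- qr.coef(qr(D), thickness$values[fit_idx, , drop = FALSE])
  adjusted <- thickness$values -
    outer(age_c, beta["age", ]) - outer(gender_c, beta["gender", ])
  thickness_dataset(adjusted, thickness$vertex_roi, thickness$roi_names)
}

#' Map t statistics to z-scores
#'
#' The quantile transform `z = qnorm(pt(t, df))`: the z-score with the
#' same cumulative probability under the standard normal as `t` has
#' under a Student-t with `df` degrees of freedom. Strictly increasing
#' in `t`, sign-preserving, and evaluated on the log scale of the
#' nearer tail so extreme t values map to finite, accurate z.
#'
#' @param t numeric vector of t statistics
#' @param df degrees of freedom (scalar or vector, >= 1)
#' @return numeric vector of z-scores
#' @examples
#' t_to_z(0, 10)        # 0
#' t_to_z(2, 100)       # slightly above 1.97
#' @export
t_to_z <- function(t, df) {
  if (any(df < 1)) abort_fmt("degrees of freedom must be >= 1")
  if (!all(is.finite(t))) abort_fmt("t statistics must be finite")
  z <- numeric(length(t))
  neg <- t <= 0
  # work in the lower tail of |t| for precision, then mirror
  z[neg] <- stats::qnorm(stats::pt(t[neg], if (length(df) > 1) df[neg] else df,
                                   log.p = TRUE), log.p = TRUE)
  z[!neg] <- -stats::qnorm(stats::pt(-t[!neg], if (length(df) > 1) df[!neg] else df,
                                     log.p = TRUE), log.p = TRUE)
  z
}

#' Group atrophy pattern (disease group vs. reference group)
#'
#' Computes, vertex by vertex, the pooled-variance two-sample t
#' statistic for the mean thickness difference (disease minus
#' reference) and maps it through [t_to_z()]. Negative z marks vertices
#' where the disease group is thinner, so the pattern encodes the
#' group-level atrophy topography.
#'
#' @param ad GLM-adjusted [thickness_dataset()] of the disease group
#'   (>= 2 subjects)
#' @param cu GLM-adjusted [thickness_dataset()] of the reference group
#'   (>= 2 subjects), structurally identical to `ad`
#' @return an [atrophy_pattern()] with `kind = "group"` and
#'   `df = n_ad + n_cu - 2`
#' @export
group_atrophy_pattern <- function(ad, cu) {
  stopifnot(inherits(ad, "thickness_dataset"), inherits(cu, "thickness_dataset"))
  check_same_structure(ad, cu, "group datasets")
  n1 <- nrow(ad$values); n2 <- nrow(cu$values)
  if (n1 < 2L || n2 < 2L) abort_fmt("each group needs at least 2 subjects")
  m1 <- colMeans(ad$values); m2 <- colMeans(cu$values)
  v1 <- apply(ad$values, 2L, stats::var)
  v2 <- apply(cu$values, 2L, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  bad <- which(sp2 <= 0)
  if (length(bad)) {
    abort_fmt("zero pooled variance at vertex %d (ROI %s)",
              bad[1], as.character(ad$vertex_roi[bad[1]]))
  }
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  atrophy_pattern(t_to_z(tt, df), ad$vertex_roi, kind = "group",
                  df = df, roi_names = ad$roi_names)
}

#' Individual atrophy pattern (one subject vs. reference group)
#'
#' Scores one subject's thickness against the reference-group mean,
#' vertex by vertex: `t = (x - mean_ref) / (sd_ref * sqrt(1 + 1/n_ref))`
#' -- the prediction-interval standardization that treats the subject as
#' a new draw from the reference population -- mapped through
#' [t_to_z()] with `df = n_ref - 1`.
#'
#' @param subject numeric vector of the subject's vertex thickness, in
#'   the reference dataset's vertex order (or a one-subject
#'   [thickness_dataset()])
#' @param cu_reference GLM-adjusted [thickness_dataset()] of the
#'   reference group (>= 2 subjects)
#' @return an [atrophy_pattern()] with `kind = "individual"`
#' @export
individual_atrophy_pattern <- function(subject, cu_reference) {
  stopifnot(inherits(cu_reference, "thickness_dataset"))
  if (inherits(subject, "thickness_dataset")) {
    check_same_structure(subject, cu_reference, "subject and reference")
    if (nrow(subject$values) != 1L) {
      abort_fmt("`subject` must contain exactly one subject")
    }
    subject <- drop(subject$values)
  }
  if (length(subject) != ncol(cu_reference$values)) {
    abort_fmt("subject has %d vertices but reference has %d",
              length(subject), ncol(cu_reference$values))
  }
  Z <- individual_z_matrix(matrix(subject, nrow = 1L), cu_reference)
  atrophy_pattern(drop(Z), cu_reference$vertex_roi, kind = "individual",
                  df = nrow(cu_reference$values) - 1L,
                  roi_names = cu_reference$roi_names)
}

# vectorized individual z-scores for a matrix of subjects (rows)
individual_z_matrix <- function(values, cu_reference) {
  n_ref <- nrow(cu_reference$values)
  if (n_ref < 2L) abort_fmt("reference group needs at least 2 subjects")
  m <- colMeans(cu_reference$values)
  s <- apply(cu_reference$values, 2L, stats::sd)
  bad <- which(s <= 0)
  if (length(bad)) {
    abort_fmt("zero reference variance at vertex %d (ROI %s)",
              bad[1], as.character(cu_reference$vertex_roi[bad[1]]))
  }
  tt <- sweep(sweep(values, 2L, m), 2L, s * sqrt(1 + 1 / n_ref), "/")
  Z <- matrix(t_to_z(as.numeric(tt), n_ref - 1L), nrow(values), ncol(values))
  rownames(Z) <- rownames(values)
  Z
}

#' Per-ROI neurodegeneration biomarker from two atrophy patterns
#'
#' For each ROI `k` with vertices `i = 1..m_k`, the biomarker is the
#' inner product of the individual and group atrophy z-scores over the
#' ROI, divided by the fixed scale constant 100:
#' `UNB_k = sum_i(Z_individual_ki * Z_group_ki) / 100`.
#' Concordant atrophy (both z negative at the same vertices) contributes
#' positively, so larger values mean the individual's atrophy topography
#' is closer to the disease group's.
#'
#' @param individual an [atrophy_pattern()] with `kind = "individual"`
#' @param group an [atrophy_pattern()] with `kind = "group"`, same
#'   vertex structure
#' @return named numeric vector, one score per ROI
#' @examples
#' ind <- atrophy_pattern(c(1, 2), c("r1", "r1"), "individual", df = 9)
#' grp <- atrophy_pattern(c(2, 3), c("r1", "r1"), "group", df = 20)
#' compute_unb(ind, grp)  # (1*2 + 2*3)/100 = 0.08
#' @export
compute_unb <- function(individual, group) {
  stopifnot(inherits(individual, "atrophy_pattern"),
            inherits(group, "atrophy_pattern"))
  if (individual$kind != "individual" || group$kind != "group") {
    abort_fmt("expected an individual pattern and a group pattern")
  }
  check_same_structure(individual, group, "atrophy patterns")
  unb <- rowsum(individual$z * group$z, individual$vertex_roi) / 100
  stats::setNames(drop(unb), levels(individual$vertex_roi))
}

#' Biomarker matrix for a whole dataset
#'
#' Convenience wrapper computing the per-ROI biomarker for every subject
#' of a dataset against a reference group and a group atrophy pattern.
#' Equivalent to looping [individual_atrophy_pattern()] +
#' [compute_unb()] over subjects.
#'
#' @param thickness GLM-adjusted [thickness_dataset()] of test subjects
#' @param group_pattern [atrophy_pattern()] with `kind = "group"`
#' @param cu_reference GLM-adjusted reference [thickness_dataset()]
#' @return numeric matrix, subjects x ROIs
#' @export
unb_matrix <- function(thickness, group_pattern, cu_reference) {
  stopifnot(inherits(thickness, "thickness_dataset"))
  check_same_structure(thickness, cu_reference, "test and reference datasets")
  check_same_structure(thickness, group_pattern, "dataset and group pattern")
  Z <- individual_z_matrix(thickness$values, cu_reference)
  U <- t(rowsum(t(Z * rep(group_pattern$z, each = nrow(Z))),
                thickness$vertex_roi)) / 100
  dimnames(U) <- list(subjects(thickness), thickness$roi_names)
  U
}

#' End-to-end biomarker pipeline on a cohort
#'
#' Runs the full biomarker stage on a (synthetic or loaded) cohort:
#' covariate adjustment on the pooled AD+CU sample with group retained
#' for the group pattern; covariate adjustment fitted on the CU
#' reference alone for the individual patterns; then the per-ROI
#' biomarker for every subject. In atlas mode the dataset's ROI names
#' must be exactly the 34 left-hemisphere Desikan-Killiany regions.
#'
#' @param thickness [thickness_dataset()] for all subjects
#' @param phenotypes data.frame with `subject`, `age`, `gender`
#' @param labels named factor of diagnoses (levels including AD and CU)
#' @param ad_ids,cu_ids subject ids of the pattern-defining AD group and
#'   the CU reference; default: all subjects labeled AD / CU
#' @param atlas if TRUE, validate ROI names against [dk_lh_atlas()]
#' @return list with `unb` (subjects x ROIs matrix), `group_pattern`,
#'   and the adjusted datasets
#' @export
unb_pipeline <- function(thickness, phenotypes, labels,
                         ad_ids = NULL, cu_ids = NULL, atlas = FALSE) {
  ids <- subjects(thickness)
  labels <- labels[ids]
  if (is.null(ad_ids)) ad_ids <- ids[!is.na(labels) & labels == "AD"]
  if (is.null(cu_ids)) cu_ids <- ids[!is.na(labels) & labels == "CU"]
  if (atlas) {
    unknown <- setdiff(thickness$roi_names, dk_lh_atlas())
    if (length(unknown)) {
      abort_fmt("ROIs not in the left-hemisphere Desikan-Killiany atlas: %s",
                paste(unknown, collapse = ", "))
    }
    if (length(thickness$roi_names) != 34L) {
      abort_fmt("atlas mode requires all 34 left-hemisphere ROIs; got %d",
                length(thickness$roi_names))
    }
  }

  # group path: pooled AD+CU adjustment with group as a retained covariate
  pool_ids <- c(ad_ids, cu_ids)
  pool <- subset_subjects(thickness, pool_ids)
  cov_pool <- phenotypes[match(pool_ids, phenotypes$subject), , drop = FALSE]
  cov_pool$group <- factor(ifelse(pool_ids %in% ad_ids, "AD", "CU"))
  pool_adj <- adjust_glm(pool, cov_pool)
  grp <- group_atrophy_pattern(subset_subjects(pool_adj, ad_ids),
                               subset_subjects(pool_adj, cu_ids))

  # individual path: adjustment fitted on the CU reference only
  cov_all <- phenotypes[match(ids, phenotypes$subject), , drop = FALSE]
  cov_all$group <- NULL
  all_adj <- adjust_glm(thickness, cov_all, fit_subjects = cu_ids)
  cu_adj <- subset_subjects(all_adj, cu_ids)
  unb <- unb_matrix(all_adj, grp, cu_adj)
  list(unb = unb, group_pattern = grp,
       adjusted = all_adj, cu_reference = cu_adj)
}
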