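#' Configuration for a synthetic cortical-thickness cohort
#'
#' Describes a three-group (AD / MCI / CU) cohort of vertex-wise cortical
#' thickness with planted group atrophy on a subset of "affected" ROIs,
#' linear age and gender covariate effects, subject-level heterogeneity,
#' measurement noise, and a 24-month follow-up with group-specific
#' additional thinning on the affected ROIs.
#'
#' Defaults are chosen to resemble FreeSurfer-scale cortical thickness:
#' a ~2.5 mm baseline, mild age-related thinning, sub-millimetre group
#' effects and measurement noise of a tenth of a millimetre or so.
#'
#' @param n_ad,n_mci,n_cu subjects per diagnostic group (each >= 1)
#' @param n_rois number of ROIs; 34 uses the left-hemisphere
#'   Desikan-Killiany names from [dk_lh_atlas()]
#' @param vertices_per_roi single count or one count per ROI
#' @param atrophy_effect_ad,atrophy_effect_mci mean thickness decrement
#'   (mm) applied to affected-ROI vertices for AD and MCI subjects
#' @param age_slope thinning per year of age (mm/year, typically negative)
#' @param gender_offset additive thickness offset (mm) for male subjects
#' @param noise_sd vertex-level measurement noise SD (mm), > 0
#' @param subject_sd SD (mm) of a per-subject global thickness offset
#' @param longitudinal_decline named vector `c(AD=, MCI=, CU=)` of
#'   additional affected-ROI thinning (mm) accrued over 24 months
#' @param decline_sd between-subject SD (mm) of the 24-month decline:
#'   each subject's decline is `longitudinal_decline[group] +
#'   N(0, decline_sd)` shared across affected vertices, so longitudinal
#'   change rates vary across subjects as they do in real cohorts
#' @param affected_roi_fraction fraction of ROIs carrying the group
#'   effect, in \[0, 1\]
#' @param baseline_mean grand-mean cortical thickness (mm)
#' @param seed integer seed; identical config + seed gives a
#'   bit-identical cohort
#' @return an object of class `cohort_config`
#' @export
cohort_config <- function(n_ad = 40, n_mci = 40, n_cu = 40,
                          n_rois = 34, vertices_per_roi = 100,
                          atrophy_effect_ad = 0.3,
                          atrophy_effect_mci = 0.15,
                          age_slope = -0.005, gender_offset = 0.05,
                          noise_sd = 0.25, subject_sd = 0.05,
                          longitudinal_decline = c(AD = 0.12, MCI = 0.06, CU = 0.02),
                          decline_sd = 0.08,
                          affected_roi_fraction = 0.3,
                          baseline_mean = 2.5, seed = 1L) {
  for (nm in c("n_ad", "n_mci", "n_cu", "n_rois")) {
    if (!is_count(get(nm))) abort_fmt("`%s` must be a positive integer", nm)
  }
  if (!(length(vertices_per_roi) %in% c(1L, n_rois)) ||
      !all(vapply(vertices_per_roi, is_count, logical(1)))) {
    abort_fmt("`vertices_per_roi` must be one count or one count per ROI")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) {
    abort_fmt("`noise_sd` must be > 0")
  }
  if (affected_roi_fraction < 0 || affected_roi_fraction > 1) {
    abort_fmt("`affected_roi_fraction` must lie in [0, 1]")
  }
  if (!all(c("AD", "MCI", "CU") %in% names(longitudinal_decline))) {
    abort_fmt("`longitudinal_decline` needs named entries AD, MCI, CU")
  }
  structure(
    list(n_ad = as.integer(n_ad), n_mci = as.integer(n_mci),
         n_cu = as.integer(n_cu), n_rois = as.integer(n_rois),
         vertices_per_roi = as.integer(vertices_per_roi),
         atrophy_effect_ad = atrophy_effect_ad,
         atrophy_effect_mci = atrophy_effect_mci,
         age_slope = age_slope, gender_offset = gender_offset,
         noise_sd = noise_sd, subject_sd = subject_sd,
         longitudinal_decline = longitudinal_decline[c("AD", "MCI", "CU")],
         decline_sd = decline_sd,
         affected_roi_fraction = affected_roi_fraction,
         baseline_mean = baseline_mean, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates baseline and 24-month vertex-wise thickness for AD, MCI and
#' CU groups plus a phenotype table (age, gender, APOE epsilon-4 allele
#' count) and amyloid status. Thickness at a vertex is
#' `vertex mean + age_slope * (age - mean age) + gender_offset * 1[male]
#' - group effect on affected ROIs + subject offset + noise`; the
#' follow-up additionally subtracts the group's `longitudinal_decline`
#' on affected ROIs and redraws the measurement noise. With positive
#' effects the expected total atrophy orders AD > MCI > CU.
#'
#' @param config a [cohort_config()]
#' @return an object of class `synthetic_cohort`: a list with
#'   `thickness` and `thickness_followup` ([thickness_dataset()]s sharing
#'   vertex correspondence), `phenotypes` (data.frame: subject, age,
#'   gender, apoe4_count), `labels` (named factor AD/MCI/CU),
#'   `amyloid_status` (named character "+"/"-"), `affected_rois`
#'   (integer ROI indices) and the `config`
#' @examples
#' coh <- generate_cohort(cohort_config(n_ad = 5, n_mci = 5, n_cu = 5,
#'                                      n_rois = 4, vertices_per_roi = 10))
#' dim(coh$thickness)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n_rois <- config$n_rois
    vpr <- config$vertices_per_roi
    if (length(vpr) == 1L) vpr <- rep(vpr, n_rois)
    roi_names <- if (n_rois == 34L) dk_lh_atlas() else sprintf("roi%02d", seq_len(n_rois))
    vertex_roi <- rep(roi_names, times = vpr)
    v_total <- sum(vpr)

    n <- c(AD = config$n_ad, MCI = config$n_mci, CU = config$n_cu)
    n_total <- sum(n)
    group <- factor(rep(names(n), times = n), levels = c("AD", "MCI", "CU"))
    ids <- sprintf("%s%03d", tolower(as.character(group)),
                   unlist(lapply(n, seq_len), use.names = FALSE))

    n_aff <- ceiling(config$affected_roi_fraction * n_rois)
    affected_rois <- if (n_aff > 0) sort(sample.int(n_rois, n_aff)) else integer(0)
    affected_vertex <- as.integer(vertex_roi %in% roi_names[affected_rois])

    age_mu <- c(AD = 75, MCI = 73, CU = 72)
    age <- pmin(pmax(stats::rnorm(n_total, age_mu[as.character(group)], 6), 55), 90)
    gender <- factor(sample(c("F", "M"), n_total, replace = TRUE),
                     levels = c("F", "M"))
    apoe_probs <- list(AD = c(0.35, 0.45, 0.20), MCI = c(0.45, 0.40, 0.15),
                       CU = c(0.70, 0.25, 0.05))
    apoe4 <- vapply(as.character(group), function(g) {
      sample(0:2, 1L, prob = apoe_probs[[g]])
    }, integer(1))
    amyloid <- ifelse(group == "AD", "+",
                      ifelse(group == "MCI",
                             ifelse(stats::runif(n_total) < 0.9, "+", "-"),
                             ifelse(stats::runif(n_total) < 0.4, "+", "-")))

    vertex_mean <- config$baseline_mean + stats::rnorm(v_total, 0, 0.15)
    subj_offset <- stats::rnorm(n_total, 0, config$subject_sd)
    group_effect <- c(AD = config$atrophy_effect_ad,
                      MCI = config$atrophy_effect_mci, CU = 0)

    # deterministic mean structure shared by both visits
    base_mu <- matrix(vertex_mean, n_total, v_total, byrow = TRUE) +
      (config$age_slope * (age - mean(age)) + subj_offset +
         config$gender_offset * (gender == "M")) -
      outer(group_effect[as.character(group)], affected_vertex)

    baseline <- base_mu + matrix(stats::rnorm(n_total * v_total, 0, config$noise_sd),
                                 n_total, v_total)
    decline <- config$longitudinal_decline[as.character(group)] +
      stats::rnorm(n_total, 0, config$decline_sd)
    followup <- base_mu - outer(unname(decline), affected_vertex) +
      matrix(stats::rnorm(n_total * v_total, 0, config$noise_sd),
             n_total, v_total)
    rownames(baseline) <- rownames(followup) <- ids

    structure(
      list(
        thickness = thickness_dataset(baseline, vertex_roi, roi_names),
        thickness_followup = thickness_dataset(followup, vertex_roi, roi_names),
        phenotypes = data.frame(subject = ids, age = age, gender = gender,
                                apoe4_count = apoe4, stringsAsFactors = FALSE),
        labels = stats::setNames(group, ids),
        amyloid_status = stats::setNames(amyloid, ids),
        affected_rois = affected_rois,
        config = config
      ),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d AD / %d MCI / %d CU; %d ROIs (%d affected)\n",
              x$config$n_ad, x$config$n_mci, x$config$n_cu,
              x$config$n_rois, length(x$affected_rois)))
  invisible(x)
}

#' Two-class population graph with planted feature separation
#'
#' A sanity fixture for the semi-supervised classifier: node features are
#' drawn from two Gaussians whose means differ by `separation / sqrt(M)`
#' per coordinate (so the overall Mahalanobis separation between class
#' means is `separation` standard deviations), and phenotypes are drawn
#' so that within-class phenotype similarity exceeds between-class
#' similarity on average. The phenotype assortativity scales with the
#' same `separation` knob (clamped to `[0, 5]` and mapped to `[0, 1]`):
#' at `separation = 0` the fixture is an exact null -- features carry no
#' class signal and the phenotype graph is class-independent -- while at
#' `separation = 5` age bands no longer overlap between classes and the
#' epsilon-4 count is class-deterministic. Labels use levels
#' `c("AD", "CU")` and masks are a stratified train/test split.
#'
#' @param n_per_class nodes per class (>= 2)
#' @param separation between-class mean distance in noise-SD units
#' @param seed integer seed
#' @param n_features feature dimension M
#' @param train_fraction fraction of each class placed in the train mask
#' @param edge_spec phenotype [edge_spec()] used for the adjacency
#' @return a [population_graph()]
#' @export
planted_feature_graph <- function(n_per_class, separation, seed,
                                  n_features = 10L, train_fraction = 0.9,
                                  edge_spec = default_edge_spec()) {
  if (!is_count(n_per_class, min = 2L)) {
    abort_fmt("`n_per_class` must be an integer >= 2")
  }
  with_seed(seed, {
    n <- 2L * n_per_class
    cls <- factor(rep(c("AD", "CU"), each = n_per_class),
                  levels = c("AD", "CU"))
    delta <- separation / sqrt(n_features)
    mu <- ifelse(cls == "AD", +delta / 2, -delta / 2)
    X <- matrix(stats::rnorm(n * n_features), n, n_features) + mu
    rownames(X) <- sprintf("node%03d", seq_len(n))

    # phenotype assortativity rises with the same separation knob
    assort <- min(max(separation, 0), 5) / 5
    age <- stats::runif(n, 60, 64) + ifelse(cls == "AD", 16 * assort, 0)
    p_male <- ifelse(cls == "AD", 0.5 + 0.2 * assort, 0.5 - 0.2 * assort)
    gender <- factor(ifelse(stats::runif(n) < p_male, "M", "F"),
                     levels = c("F", "M"))
    base_apoe <- c(0.5, 0.3, 0.2)
    apoe4 <- vapply(seq_len(n), function(i) {
      target <- if (cls[i] == "AD") c(0, 0, 1) else c(1, 0, 0)
      sample(0:2, 1L, prob = (1 - assort) * base_apoe + assort * target)
    }, integer(1))
    phen <- data.frame(subject = rownames(X), age = age, gender = gender,
                       apoe4_count = apoe4, stringsAsFactors = FALSE)

    test_idx <- unlist(lapply(split(seq_len(n), cls), function(ix) {
      sample(ix, max(1L, round((1 - train_fraction) * length(ix))))
    }), use.names = FALSE)
    test_mask <- seq_len(n) %in% test_idx

    W <- build_adjacency(phen, edge_spec)
    population_graph(X = X, W = W, labels = stats::setNames(cls, rownames(X)),
                     train_mask = !test_mask, test_mask = test_mask,
                     phenotypes = phen)
  })
}
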