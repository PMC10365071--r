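# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (explicit loops, direct formulas) so they
# stay independent of the vectorized implementation paths they check.

# random thickness dataset with no group structure
random_thickness <- function(n_subj, rois, vpr, seed, mean_mm = 2.5, sd_mm = 0.2) {
  withr_seed(seed)
  vertex_roi <- rep(rois, each = vpr)
  values <- matrix(stats::rnorm(n_subj * length(vertex_roi), mean_mm, sd_mm),
                   n_subj, length(vertex_roi))
  rownames(values) <- sprintf("s%03d", seq_len(n_subj))
  thickness_dataset(values, vertex_roi, rois)
}

# set.seed that does not leak into package internals (tests may call freely)
withr_seed <- function(seed) set.seed(seed)

# Eq-by-eq double-loop UNB oracle
naive_unb <- function(z_ind, z_grp, vertex_roi) {
  rois <- unique(as.character(vertex_roi))
  out <- numeric(length(rois))
  names(out) <- rois
  for (k in seq_along(rois)) {
    idx <- which(as.character(vertex_roi) == rois[k])
    acc <- 0
    for (i in idx) acc <- acc + z_ind[i] * z_grp[i]
    out[k] <- acc / 100
  }
  out
}

# O(N^2 P) pairwise adjacency oracle
naive_adjacency <- function(phen, spec) {
  n <- nrow(phen)
  W <- matrix(0L, n, n)
  for (m in seq_len(n)) for (q in seq_len(n)) {
    if (m == q) next
    s <- 0L
    for (nm in names(spec)) {
      e <- spec[[nm]]
      a <- phen[[nm]][m]; b <- phen[[nm]][q]
      s <- s + if (e$kind == "numeric") {
        as.integer(abs(as.numeric(a) - as.numeric(b)) < e$theta)
      } else {
        as.integer(as.character(a) == as.character(b))
      }
    }
    W[m, q] <- s
  }
  W
}

# explicit-loop GCN layer oracle
naive_gcn_layer <- function(S, H, Theta, relu = TRUE) {
  n <- nrow(S); d <- ncol(Theta)
  out <- matrix(0, n, d)
  for (i in seq_len(n)) for (j in seq_len(d)) {
    acc <- 0
    for (a in seq_len(ncol(S))) for (b in seq_len(nrow(Theta))) {
      acc <- acc + S[i, a] * H[a, b] * Theta[b, j]
    }
    out[i, j] <- if (relu) max(acc, 0) else acc
  }
  out
}

# all-pairs concordance AUC oracle
naive_auc <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  acc <- 0
  for (a in sp) for (b in sn) {
    acc <- acc + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  acc / (length(sp) * length(sn))
}

# quadrature-based t CDF (independent of stats::pt)
quad_pt <- function(t, df) {
  dens <- function(x) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  if (t <= 0) {
    stats::integrate(dens, -Inf, t, rel.tol = 1e-12)$value
  } else {
    1 - stats::integrate(dens, t, Inf, rel.tol = 1e-12)$value
  }
}

# small phenotype table for graph tests
random_phenotypes <- function(n, seed) {
  withr_seed(seed)
  data.frame(
    subject = sprintf("p%03d", seq_len(n)),
    age = stats::runif(n, 55, 90),
    gender = factor(sample(c("F", "M"), n, TRUE), levels = c("F", "M")),
    apoe4_count = sample(0:2, n, TRUE),
    stringsAsFactors = FALSE
  )
}

# longitudinal UNB totals (baseline, follow-up) for a generated cohort
cohort_unb_totals <- function(coh) {
  p <- unb_pipeline(coh$thickness, coh$phenotypes, coh$labels,
                    atlas = coh$config$n_rois == 34L)
  fu <- unb_matrix(
    adjust_glm(coh$thickness_followup, coh$phenotypes,
               fit_subjects = subjects(p$cu_reference)),
    p$group_pattern, p$cu_reference)
  list(baseline = rowSums(p$unb), followup = rowSums(fu),
       labels = coh$labels, unb = p$unb, pipe = p)
}
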