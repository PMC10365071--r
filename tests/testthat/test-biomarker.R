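test_that("t_to_z is sign-preserving, monotone, and matches quadrature", {
  expect_identical(t_to_z(0, 5), 0)
  expect_identical(t_to_z(0, 1000), 0)

  tt <- seq(-6, 6, length.out = 41)
  z <- t_to_z(tt, 12)
  expect_true(all(diff(z) > 0))
  expect_identical(sign(z), sign(tt))
  # antisymmetry
  expect_equal(t_to_z(-tt, 12), -z, tolerance = 1e-12)

  # independent quadrature oracle for the t CDF
  for (t0 in c(-3.5, -1, 0.5, 2, 4)) {
    expect_equal(t_to_z(t0, 100), stats::qnorm(quad_pt(t0, 100)),
                 tolerance = 1e-8)
  }
  # extreme t stays finite and ordered
  zext <- t_to_z(c(20, 40), 50)
  expect_true(all(is.finite(zext)) && zext[1] < zext[2])
  expect_error(t_to_z(1, 0.5), "degrees of freedom")
})

test_that("adjust_glm removes age/gender effects and nothing else", {
  set.seed(21)
  n <- 30; v <- 40
  age <- runif(n, 60, 85)
  gender <- factor(sample(c("F", "M"), n, TRUE), levels = c("F", "M"))
  slope <- 0.02; goff <- 0.3
  base <- matrix(rnorm(n * v, 2.5, 0.1), n, v)
  vals <- base + slope * (age - mean(age)) + goff * (gender == "M")
  rownames(vals) <- sprintf("s%02d", 1:n)
  td <- thickness_dataset(vals, rep(c("a", "b"), each = v / 2))
  cov <- data.frame(subject = rownames(vals), age = age, gender = gender)

  adj <- adjust_glm(td, cov)
  # residual orthogonality: regressing adjusted values on age gives slope ~ 0
  slopes <- apply(adj$values, 2, function(y) coef(lm(y ~ age + gender))["age"])
  expect_lt(max(abs(slopes)), 1e-10)

  # zero-effect covariates: adjusted ~ raw within 3 SEs (per-vertex OLS oracle)
  vals0 <- base
  rownames(vals0) <- rownames(vals)
  td0 <- thickness_dataset(vals0, rep(c("a", "b"), each = v / 2))
  adj0 <- adjust_glm(td0, cov)
  age_c <- age - mean(age)
  gender_c <- (gender == "M") - mean(gender == "M")
  for (j in c(1, 20, 40)) {
    co <- summary(lm(vals0[, j] ~ age_c + gender_c))$coefficients
    bound <- 3 * (co["age_c", "Std. Error"] * max(abs(age_c)) +
                    co["gender_c", "Std. Error"] * max(abs(gender_c)))
    expect_lt(max(abs(adj0$values[, j] - vals0[, j])), bound)
  }

  # constant input is returned unchanged
  tdc <- thickness_dataset(matrix(2.5, n, 4,
                                  dimnames = list(rownames(vals), NULL)),
                           rep("a", 4))
  expect_equal(adjust_glm(tdc, cov)$values, tdc$values, tolerance = 1e-12)

  # degenerate design: single gender
  cov_bad <- cov; cov_bad$gender <- factor(rep("F", n), levels = c("F", "M"))
  expect_error(adjust_glm(td, cov_bad), "degenerate")
})

test_that("group atrophy pattern has the documented sign and symmetry", {
  rois <- c("r1", "r2", "r3")
  ad <- random_thickness(10, rois, 20, seed = 1)
  cu <- random_thickness(12, rois, 20, seed = 2)

  # identical groups give z ~ 0... use self-vs-self with jitter-free check via antisymmetry
  p1 <- group_atrophy_pattern(ad, cu)
  p2 <- group_atrophy_pattern(cu, ad)
  expect_equal(p1$z, -p2$z, tolerance = 1e-10)
  expect_identical(p1$kind, "group")
  expect_identical(p1$df, 10 + 12 - 2)

  # null case: two samples from the same distribution, z near standard normal
  expect_lt(abs(mean(p1$z)), 0.2)

  # direct per-vertex t oracle
  v <- 7
  tt <- stats::t.test(ad$values[, v], cu$values[, v], var.equal = TRUE)$statistic
  expect_equal(p1$z[v], t_to_z(unname(tt), 20), tolerance = 1e-10)

  # planted effect: affected ROIs carry more negative z than unaffected
  coh <- generate_cohort(cohort_config(n_ad = 25, n_cu = 25, n_mci = 1,
                                       n_rois = 6, vertices_per_roi = 30,
                                       atrophy_effect_ad = 0.5, noise_sd = 0.1,
                                       affected_roi_fraction = 0.5, seed = 9))
  adg <- subset_subjects(coh$thickness, names(coh$labels)[coh$labels == "AD"])
  cug <- subset_subjects(coh$thickness, names(coh$labels)[coh$labels == "CU"])
  gp <- group_atrophy_pattern(adg, cug)
  aff <- as.character(gp$vertex_roi) %in% coh$thickness$roi_names[coh$affected_rois]
  expect_lt(mean(gp$z[aff]), mean(gp$z[!aff]))
  expect_lt(mean(gp$z[aff]), -3)

  # zero pooled variance errors with the vertex named
  cvals <- matrix(2.5, 4, 3, dimnames = list(sprintf("c%d", 1:4), NULL))
  cd <- thickness_dataset(cvals, c("x", "x", "x"))
  expect_error(group_atrophy_pattern(cd, cd), "vertex 1")
})

test_that("individual atrophy pattern standardizes against the reference", {
  rois <- c("r1", "r2")
  cu <- random_thickness(25, rois, 30, seed = 5)
  m <- colMeans(cu$values)

  # subject equal to the reference mean: z = 0 everywhere
  p0 <- individual_atrophy_pattern(m, cu)
  expect_true(all(abs(p0$z) < 1e-12))
  expect_identical(p0$kind, "individual")
  expect_identical(p0$df, 24L)

  # strong one-vertex deviation: strongly negative z there only
  s <- apply(cu$values, 2, sd)
  x <- m; x[10] <- m[10] - 10 * s[10]
  p1 <- individual_atrophy_pattern(x, cu)
  expect_lt(p1$z[10], -5)
  expect_true(all(abs(p1$z[-10]) < 1e-12))

  # null distribution: z for a fresh CU-like draw is ~ standard normal
  big_cu <- random_thickness(40, "r", 10000, seed = 6)
  withr_seed(7)
  draw <- colMeans(big_cu$values) +
    rnorm(10000, 0, sd = apply(big_cu$values, 2, sd) * sqrt(1 + 1 / 40))
  pz <- individual_atrophy_pattern(draw, big_cu)
  ks <- suppressWarnings(stats::ks.test(pz$z, "pnorm"))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("compute_unb matches Eq-style direct evaluation and the loop oracle", {
  # one-ROI worked example
  ind <- atrophy_pattern(c(1, 2), c("r1", "r1"), "individual", df = 9)
  grp <- atrophy_pattern(c(2, 3), c("r1", "r1"), "group", df = 20)
  expect_equal(unname(compute_unb(ind, grp)), 0.08, tolerance = 1e-15)

  # zero individual pattern
  ind0 <- atrophy_pattern(c(0, 0), c("r1", "r1"), "individual", df = 9)
  expect_identical(unname(compute_unb(ind0, grp)), 0)

  # 34 x 100 random patterns against the double-loop oracle
  withr_seed(13)
  vroi <- rep(dk_lh_atlas(), each = 100)
  zi <- rnorm(3400); zg <- rnorm(3400)
  u <- compute_unb(atrophy_pattern(zi, vroi, "individual", df = 10),
                   atrophy_pattern(zg, vroi, "group", df = 50))
  o <- naive_unb(zi, zg, vroi)
  expect_equal(u[names(o)], o, tolerance = 1e-12)

  # bilinearity in the individual pattern
  u3 <- compute_unb(atrophy_pattern(3 * zi, vroi, "individual", df = 10),
                    atrophy_pattern(zg, vroi, "group", df = 50))
  expect_equal(u3, 3 * u, tolerance = 1e-12)

  # kind and structure guards
  expect_error(compute_unb(grp, grp), "individual pattern")
  ind_bad <- atrophy_pattern(c(1, 2), c("r2", "r2"), "individual", df = 9)
  expect_error(compute_unb(ind_bad, grp), "mismatched ROIs")
})

test_that("unb_matrix equals the per-subject loop and orders groups", {
  coh <- generate_cohort(cohort_config(n_ad = 10, n_mci = 10, n_cu = 12,
                                       n_rois = 5, vertices_per_roi = 20,
                                       seed = 17))
  p <- unb_pipeline(coh$thickness, coh$phenotypes, coh$labels)
  expect_identical(dim(p$unb), c(32L, 5L))

  # row-by-row agreement with individual_atrophy_pattern + compute_unb
  for (id in subjects(coh$thickness)[c(1, 15, 32)]) {
    ip <- individual_atrophy_pattern(drop(p$adjusted$values[id, ]),
                                     p$cu_reference)
    expect_equal(p$unb[id, ], compute_unb(ip, p$group_pattern),
                 tolerance = 1e-12)
  }
})

test_that("mean total UNB orders AD > MCI > CU across seeds", {
  ok <- 0L
  for (s in 1:20) {
    coh <- generate_cohort(cohort_config(n_ad = 12, n_mci = 12, n_cu = 14,
                                         n_rois = 8, vertices_per_roi = 30,
                                         seed = 100 + s))
    p <- unb_pipeline(coh$thickness, coh$phenotypes, coh$labels)
    tot <- tapply(rowSums(p$unb), coh$labels, mean)
    ok <- ok + (tot["AD"] > tot["MCI"] && tot["MCI"] > tot["CU"])
  }
  expect_gte(ok, 19L)
})
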