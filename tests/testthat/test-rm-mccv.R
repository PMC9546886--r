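test_that("within-subject transform centres each pair into sign-opposed rows", {
  fx <- paired_from_diffs(c(1, 2, 3), n_features = 4)
  ml <- within_subject_transform(fx$table, fx$design)
  x <- feature_values(ml$table)
  pre <- x[ml$design$timepoint == "pre", ]
  post <- x[ml$design$timepoint == "post", ]
  expect_equal(post, -pre, ignore_attr = TRUE)
  # per-subject column sums vanish
  sums <- rowsum(x, ml$design$subject)
  expect_lt(max(abs(sums)), 1e-9)
  # idempotent
  twice <- within_subject_transform(ml$table, ml$design)
  expect_equal(feature_values(twice$table), x)
})

test_that("incomplete subjects are dropped with a warning", {
  fx <- paired_from_diffs(c(1, 2, 3))
  short <- fx$table[-1, ]
  expect_warning(ml <- within_subject_transform(short, fx$design[-1, ]), "s01")
  expect_false("s01" %in% ml$design$subject)
  solo <- fx$table[1, ]
  expect_error(suppressWarnings(within_subject_transform(solo, fx$design[1, ])),
               "both timepoints")
})

test_that("covariate adjustment produces residuals orthogonal to the covariates", {
  set.seed(1)
  n <- 30
  z <- tibble::tibble(sample = paste0("s", 1:n), a = rnorm(n), b = rnorm(n))
  vals <- matrix(rnorm(n * 5), n, 5, dimnames = list(z$sample, paste0("f", 1:5)))
  vals[, 1] <- 3 * z$a - 2          # exact linear function of a covariate
  ft <- as_feature_table(vals)
  adj <- covariate_adjust(ft, z)
  res <- feature_values(adj)
  expect_lt(max(abs(res[, 1])), 1e-9)
  expect_lt(max(abs(crossprod(cbind(z$a, z$b), res))), 1e-8)
  # intercept-only: plain column centring
  cen <- covariate_adjust(ft, matrix(numeric(0), n, 0))
  expect_equal(feature_values(cen), sweep(vals, 2, colMeans(vals)), tolerance = 1e-10)
  zz <- dplyr::mutate(z, c = a + b)
  expect_error(covariate_adjust(ft, zz), "collinear")
})

test_that("the engine is bit-reproducible and splits by subject", {
  sim <- generate_paired_matrix(10, 40, 4, effect_size = 2, seed = 20)
  lg <- log_transform(median_fold_change_normalise(sim$table)$normalised)
  f1 <- run_rm_mccv_plsda(lg, sim$design, n_models = 60, n_boot = 5, seed = 77)
  f2 <- run_rm_mccv_plsda(lg, sim$design, n_models = 60, n_boot = 5, seed = 77)
  expect_identical(f1$features, f2$features)
  expect_identical(f1$samples, f2$samples)
  # pre and post samples of a subject are always held out together
  inc <- tapply(f1$samples$inclusions, f1$samples$subject, function(v) length(unique(v)))
  expect_true(all(inc == 1))
  expect_true(all(f1$samples$inclusions <= 60))
  expect_error(run_rm_mccv_plsda(lg, sim$design, test_fraction = 1.2), "test_fraction")
})

test_that("planted positive effects push post-sample scores above pre", {
  sim <- generate_paired_matrix(15, 60, 6, effect_size = 2, seed = 21)
  lg <- log_transform(median_fold_change_normalise(sim$table)$normalised)
  fit <- run_rm_mccv_plsda(lg, sim$design, n_models = 100, n_boot = 5, seed = 3)
  tp <- fit$samples
  expect_gt(mean(tp$tpred_mean[tp$timepoint == "post"]),
            mean(tp$tpred_mean[tp$timepoint == "pre"]))
  aff <- sim$truth$affected_features
  expect_true(all(fit$features$beta[aff] > 0))
})

test_that("power is monotone in the planted effect size", {
  recovered <- sapply(c(0.5, 1, 2), function(es) {
    mean(vapply(1:10, function(s) {
      sim <- generate_paired_matrix(20, 100, 5, effect_size = es, seed = 1000 * es + s)
      lg <- log_transform(median_fold_change_normalise(sim$table)$normalised)
      fit <- run_rm_mccv_plsda(lg, sim$design, n_models = 100, n_boot = 5, seed = s)
      mean(fit$features$q[sim$truth$affected_features] <= 0.01)
    }, numeric(1)))
  })
  expect_true(all(diff(recovered) >= 0))
  expect_gt(recovered[3], recovered[1])
})

test_that("the scaled-down engine agrees with the full engine on strong effects", {
  sim <- generate_paired_matrix(20, 100, 8, effect_size = 2, seed = 31)
  lg <- log_transform(median_fold_change_normalise(sim$table)$normalised)
  small <- run_rm_mccv_plsda(lg, sim$design, n_models = 200, n_boot = 10, seed = 5)
  full <- run_rm_mccv_plsda(lg, sim$design, n_models = 1000, n_boot = 25, seed = 6)
  s1 <- small$features$feature[small$features$q <= 0.01]
  s2 <- full$features$feature[full$features$q <= 0.01]
  jaccard <- length(intersect(s1, s2)) / length(union(s1, s2))
  expect_gte(jaccard, 0.9)
})

test_that("manhattan scores follow the signed log-q rule", {
  feats <- tibble::tibble(feature = c("a", "b", "c"),
                          beta = c(2, -0.5, 1),
                          q = c(0.01, 0.001, 1))
  man <- manhattan_table(feats, q_threshold = 0.01)
  expect_equal(man$score, c(2, -3, 0))
  expect_equal(man$cut[1], 2)
  expect_identical(man$significant, c(TRUE, TRUE, FALSE))
  feats$q[1] <- 0
  expect_warning(man0 <- manhattan_table(feats, q_threshold = 0.01), "clamped")
  expect_true(is.finite(man0$score[1]) && man0$score[1] > 300)
  feats$q[1] <- 2
  expect_error(manhattan_table(feats), "\\[0, 1\\]")
})

test_that("T_pred densities integrate to one and separate distinct groups", {
  mk <- function(pre, post) {
    structure(list(samples = tibble::tibble(
      sample = paste0("s", seq_along(c(pre, post))),
      subject = paste0("p", c(seq_along(pre), seq_along(post))),
      timepoint = rep(c("pre", "post"), c(length(pre), length(post))),
      tpred_mean = c(pre, post), tpred_var = 0.1,
      inclusions = 10L)), class = "rm_mccv")
  }
  set.seed(4)
  far <- mk(rnorm(30, -4, 0.5), rnorm(30, 4, 0.5))
  dens <- tpred_density(far)
  areas <- tapply(seq_len(nrow(dens)), dens$group, function(i) {
    sum(diff(dens$t[i]) * (head(dens$density[i], -1) + tail(dens$density[i], -1)) / 2)
  })
  expect_true(all(abs(areas - 1) < 1e-3))
  wide <- tidyr::pivot_wider(dens, names_from = "group", values_from = "density")
  overlap <- sum(diff(wide$t) * (head(pmin(wide$pre, wide$post), -1) +
                                   tail(pmin(wide$pre, wide$post), -1)) / 2)
  expect_lt(overlap, 0.05)

  same_vals <- rnorm(30)
  same <- mk(same_vals, same_vals)
  dsame <- tidyr::pivot_wider(tpred_density(same), names_from = "group",
                              values_from = "density")
  expect_equal(dsame$pre, dsame$post, tolerance = 1e-12)
  expect_error(tpred_density(mk(c(1, 1, 1), c(2, 2.5, 3))), "zero-variance")
})

test_that("Benjamini-Hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(0.037), 0.037)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.9)), c(0.04, 0.04, 0.04, 0.9))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")

  bh_brute <- function(p) {   # independent implementation straight from the definition
    m <- length(p)
    ord <- order(p)
    q_sorted <- vapply(seq_len(m), function(i) {
      min(vapply(i:m, function(j) p[ord][j] * m / j, numeric(1)), 1)
    }, numeric(1))
    q <- numeric(m); q[ord] <- q_sorted; q
  }
  for (s in 1:5) {
    set.seed(s)
    p <- runif(sample(5:1000, 1))^2
    expect_equal(benjamini_hochberg(p), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("manhattan autoplot builds a ggplot", {
  sim <- generate_paired_matrix(8, 20, 2, effect_size = 2, seed = 41)
  lg <- log_transform(sim$table)
  fit <- run_rm_mccv_plsda(lg, sim$design, n_models = 30, n_boot = 3, seed = 2)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
  expect_s3_class(plot_tpred_density(fit), "ggplot")
})
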