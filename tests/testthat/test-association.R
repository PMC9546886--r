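test_that("paired signed-rank p-values match exhaustive sign-flip enumeration", {
  fx <- paired_from_diffs(c(1, 2, 3, 4, 5), n_features = 1)
  res <- univariate_tests(fx$table, fx$design, paired = TRUE)
  # oracle: enumerate all 2^5 sign assignments of the ranked differences
  d <- c(1, 2, 3, 4, 5)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 5))
  w_all <- as.matrix(signs) %*% r
  p_oracle <- min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
  expect_equal(res$p, p_oracle)
  expect_equal(res$direction, 1)

  null_fx <- paired_from_diffs(rep(0, 5), n_features = 2)
  null_res <- univariate_tests(null_fx$table, null_fx$design, paired = TRUE)
  expect_true(all(null_res$p == 1))
  expect_true(all(null_res$tied))
})

test_that("Mann-Whitney on fully separated toy groups gives exact p = 0.1", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1, dimnames = list(paste0("s", 1:6), "f1"))
  design <- tibble::tibble(sample = paste0("s", 1:6),
                           class = rep(c("ctrl", "t2d"), each = 3))
  res <- univariate_tests(as_feature_table(vals), design, paired = FALSE)
  # oracle: all choose(6,3) = 20 label splits; the observed split is the extreme
  expect_equal(res$p, 0.1)
  expect_equal(res$direction, 1)  # t2d median above ctrl
})

test_that("spearman edges recover exact small-sample p-values and flag constants", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.0)
  y <- c(2.1, 3.0, 2.5, 6.1, 3.9)
  vals <- matrix(x, 5, 1, dimnames = list(paste0("s", 1:5), "f1"))
  targets <- tibble::tibble(sample = paste0("s", 1:5), bmi = y)
  res <- spearman_matrix(as_feature_table(vals), targets)
  # oracle: exhaustive permutation distribution of |rho| over all 5! orders
  rho_obs <- cor(x, y, method = "spearman")
  perms <- combinat_perms <- do.call(rbind, lapply(
    asplit(as.matrix(expand.grid(rep(list(1:5), 5))), 1),
    function(p) if (length(unique(p)) == 5) p else NULL))
  rho_all <- apply(perms, 1, function(p) cor(x, y[p], method = "spearman"))
  p_oracle <- mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
  expect_equal(res$p, p_oracle, tolerance = 1e-9)

  # monotone invariance and sign
  n <- 30; set.seed(2); v <- rnorm(n)
  vals2 <- matrix(v, n, 1, dimnames = list(paste0("s", 1:n), "f1"))
  t2 <- tibble::tibble(sample = paste0("s", 1:n), cube = v^3, neg = -v, flat = 1)
  res2 <- spearman_matrix(as_feature_table(vals2), t2)
  expect_equal(res2$rho[res2$target == "cube"], 1)
  expect_equal(res2$rho[res2$target == "neg"], -1)
  expect_identical(res2$flag[res2$target == "flat"], "constant")
  expect_true(is.na(res2$rho[res2$target == "flat"]))
})

test_that("partial spearman removes a shared monotone confounder", {
  expect_equal(partial_spearman(1:10, (1:10)^2)$rho, 1)
  set.seed(3)
  z <- rnorm(200)
  x <- exp(z) + rnorm(200, sd = 0.1)
  y <- z^3 + rnorm(200, sd = 0.1)
  raw <- partial_spearman(x, y)$rho
  ctl <- partial_spearman(x, y, z = data.frame(z = z))$rho
  expect_gt(abs(raw), 0.8)
  expect_lt(abs(ctl), 0.15)

  # single-covariate recursion formula on rank correlations
  set.seed(4)
  n <- 500
  z2 <- rnorm(n); x2 <- 0.6 * z2 + rnorm(n); y2 <- -0.4 * z2 + rnorm(n)
  sp <- function(a, b) cor(a, b, method = "spearman")
  rxy <- sp(x2, y2); rxz <- sp(x2, z2); ryz <- sp(y2, z2)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(partial_spearman(x2, y2, data.frame(z = z2))$rho, oracle,
               tolerance = 0.02)
  expect_error(partial_spearman(x2, y2, cbind(z2, z2)), "rank deficient")
})

test_that("network building keeps only significant edges and counts degrees", {
  edges <- tibble::tibble(
    feature = c("f1", "f1", "f2", "f3"),
    target = c("bmi", "hba1c", "bmi", "bmi"),
    rho = c(0.9, -0.5, 0.2, 0.4),
    q = c(0.001, 0.5, 0.002, 0.05)
  )
  net <- build_network(edges, q_threshold = 0.01)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$edges$sign, c(1, 1))
  # degree recount oracle
  for (nd in net$nodes$node) {
    expect_equal(net$nodes$degree[net$nodes$node == nd],
                 sum(net$edges$feature == nd) + sum(net$edges$target == nd))
  }
  empty <- build_network(dplyr::mutate(edges, q = 0.9))
  expect_equal(nrow(empty$edges), 0)
  expect_true(all(empty$nodes$degree == 0))
})

test_that("planted covariate links surface as the strongest recovered edges", {
  sim <- generate_paired_matrix(100, 15, 0, seed = 50)
  des <- generate_covariate_structure(
    sim$table, sim$design,
    links = data.frame(feature = "feat003", covariate = "bmi", rho = 0.99),
    seed = 51
  )
  res <- spearman_matrix(log_transform(sim$table), des[c("sample", "bmi", "hba1c")])
  net <- build_network(res, q_threshold = 0.01)
  top <- res[which.max(abs(res$rho)), ]
  expect_identical(top$feature, "feat003")
  expect_identical(top$target, "bmi")
  expect_true(any(net$edges$feature == "feat003" & net$edges$target == "bmi" &
                    net$edges$sign == 1))
})

test_that("correlation clustering is deterministic and separates planted blocks", {
  block <- function(n, r) { m <- matrix(r, n, n); diag(m) <- 1; m }
  rho <- rbind(cbind(block(3, 0.9), matrix(0, 3, 3)),
               cbind(matrix(0, 3, 3), block(3, 0.85)))
  dimnames(rho) <- list(c("a1", "a2", "a3", "b1", "b2", "b3"),
                        c("a1", "a2", "a3", "b1", "b2", "b3"))
  cl <- cluster_correlations(rho)
  grp <- substr(cl$order, 1, 1)
  expect_equal(length(rle(grp)$values), 2)   # blocks contiguous in leaf order

  # identical rows merge first at height zero
  rho2 <- rho; rho2["a2", ] <- rho2["a1", ]; rho2[, "a2"] <- rho2[, "a1"]
  cl2 <- cluster_correlations(rho2)
  expect_equal(min(cl2$hclust$height), 0)

  # permuting the input rows does not change the leaf sequence
  perm <- c(4, 2, 6, 1, 3, 5)
  cl3 <- cluster_correlations(rho[perm, perm])
  expect_identical(cl3$order, cl$order)
  expect_error(cluster_correlations(matrix(1:4, 2)), "symmetric")
})

test_that("association sets apply the strict q threshold and rebuild by rule", {
  tabs <- list(
    surgery = tibble::tibble(id = c("m1", "m2", "m3"), q = c(0.01, 0.05, 0.2),
                             direction = c(1, -1, 1)),
    bmi = tibble::tibble(id = c("m1", "m4"), q = c(0.04, 0.001), direction = c(1, 1))
  )
  sets <- build_association_sets(tabs, alpha = 0.05)
  # q exactly at alpha (m2, q = 0.05) is excluded by the strict rule
  expect_setequal(sets$members$id[sets$members$context == "surgery"], "m1")
  expect_setequal(sets$members$id[sets$members$context == "bmi"], c("m1", "m4"))
  set.seed(6)
  rnd <- lapply(1:3, function(i) tibble::tibble(id = paste0("m", 1:40),
                                                q = runif(40), direction = 1))
  names(rnd) <- c("a", "b", "c")
  got <- build_association_sets(rnd, alpha = 0.3)
  for (ctx in names(rnd)) {
    expect_setequal(got$members$id[got$members$context == ctx],
                    rnd[[ctx]]$id[rnd[[ctx]]$q < 0.3])
  }
  expect_error(build_association_sets(list(a = tibble::tibble(id = "x"))), "q")
})

test_that("overlap regions and pairwise commonality match exhaustive accounting", {
  sets <- list(A = c("x", "y", "z"), B = c("y", "z", "w"), C = "q")
  rep_ <- overlap_report(sets)
  expect_equal(sum(rep_$regions$count), rep_$union_size)
  ab <- rep_$pairs[rep_$pairs$context_a == "A" & rep_$pairs$context_b == "B", ]
  expect_equal(ab$commonality, 100 * 2 / 4)
  expect_equal(ab$share_of_a, 100 * 2 / 3)

  set.seed(7)
  rnd <- lapply(1:3, function(i) sample(paste0("e", 1:20), sample(5:20, 1)))
  names(rnd) <- c("s1", "s2", "s3")
  rr <- overlap_report(rnd)
  # brute force every element's membership pattern
  uni <- unique(unlist(rnd))
  pat <- vapply(uni, function(e) {
    paste(names(rnd)[vapply(rnd, function(s) e %in% s, logical(1))], collapse = "&")
  }, character(1))
  want <- table(pat)
  for (k in rr$regions$pattern) {
    expect_equal(rr$regions$count[rr$regions$pattern == k], unname(want[[k]]))
  }
  expect_equal(sum(rr$regions$count), length(uni))
  # identical sets: one region, 100% commonality
  same <- overlap_report(list(A = c("a", "b"), B = c("a", "b")))
  expect_equal(nrow(same$regions), 1)
  expect_equal(same$pairs$commonality, 100)
})

test_that("balanced error rate hits its anchor points", {
  truth <- rep(c(0, 1), 50)
  expect_equal(balanced_error_rate(truth, truth)$ber, 0)
  expect_equal(balanced_error_rate(truth, 1 - truth)$ber, 1)
  cs <- balanced_error_rate(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_equal(cs$fpr, 0.5)
  expect_equal(cs$fnr, 0.5)
  expect_equal(cs$ber, 0.5 * (cs$fpr + cs$fnr))
  expect_error(balanced_error_rate(rep(1, 4), c(1, 0, 1, 0)), "both classes")
  expect_error(balanced_error_rate(c(1, 0), c(1, 0, 1)), "equal length")
})

test_that("BH keeps the realised false-discovery proportion at its level under the null", {
  set.seed(8)
  fdp <- vapply(1:200, function(i) {
    p <- runif(100)
    mean(benjamini_hochberg(p) <= 0.05) # every rejection is false under the null
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 3 * sd(fdp) / sqrt(200))
})
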