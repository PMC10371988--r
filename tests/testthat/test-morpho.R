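# TPS I/O, unbending, GPA, sliding, Procrustes ANOVA

test_that("TPS write/read round-trips and reports malformed records", {
  tmp <- withr::local_tempfile(fileext = ".tps")
  cfgs <- gen_landmarks(shape_scenario(n_per_group = 2, seed = 6))
  write_tps(cfgs, tmp)
  back <- read_tps(tmp)
  expect_length(back, 4)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$coords, cfgs[[i]]$coords, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_identical(back[[i]]$specimen_id, cfgs[[i]]$specimen_id)
  }

  writeLines(c("LM=3", "0 0", "1 0", "0 1", "ID=tri"), tmp)
  one <- read_tps(tmp)
  expect_length(one, 1)
  expect_equal(one[[1]]$coords, rbind(c(0, 0), c(1, 0), c(0, 1)))

  writeLines(c("LM=3", "0 0", "1 0", "ID=tri"), tmp)    # truncated
  expect_error(read_tps(tmp), "record 1")
  writeLines(c("LM=2", "0 0", "1 0", "SCALE=0.5", "ID=a"), tmp)
  expect_equal(read_tps(tmp)[[1]]$scale, 0.5)
})

test_that("unbend is the identity on an already-straight axis", {
  straight <- rbind(cbind(seq(0, 1, length.out = 6), 0.2), c(0.5, 0.6))
  ub <- unbend(straight, 1:6)
  expect_lt(max(abs(align_residual(ub, straight))), 1e-9)
})

test_that("unbend inverts a known quadratic bend to within 2% of centroid size", {
  set.seed(12)
  mid <- cbind(seq(0, 1, length.out = 8), 0)
  off <- cbind(runif(8), runif(8, -0.15, 0.15))
  cfg <- rbind(mid, off)
  bent <- cfg
  x0 <- mean(bent[, 1])
  bent[, 2] <- bent[, 2] + 0.15 * (bent[, 1] - x0)^2
  ub <- unbend(bent, 1:8)
  resid <- sqrt(sum(align_residual(ub, cfg)^2))
  expect_lt(resid / centroid_size(cfg), 0.02)
  # the straightened axis landmarks are collinear
  expect_lt(stats::sd(ub[1:8, 2]), 1e-6 * centroid_size(cfg))
})

test_that("unbend rejects degenerate axes", {
  cfg <- rbind(c(0, 0), c(1, 1), c(2, 0))
  expect_error(unbend(cfg, 1:2), "at least 3")
  vert <- rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 1))
  expect_error(unbend(vert, 1:3), "degenerate")
})

test_that("gpa aligns transformed copies of one shape to < 1e-9", {
  base <- tadpole_template()
  set.seed(3)
  copies <- lapply(1:6, function(i) {
    s <- runif(1, 0.5, 3)
    th <- runif(1, 0, 2 * pi)
    sweep(s * base %*% rot2(th), 2, runif(2, -5, 5), "+")
  })
  fit <- gpa(copies)
  expect_true(fit$converged)
  for (i in 2:6)
    expect_lt(sqrt(sum((fit$aligned[i, , ] - fit$aligned[1, , ])^2)), 1e-9)
  # unit centroid sizes after alignment
  for (i in 1:6)
    expect_lt(abs(sqrt(sum(fit$aligned[i, , ]^2)) - 1), 1e-12)
  # mean shape is the average of aligned configurations
  expect_equal(fit$mean_shape, apply(fit$aligned, c(2, 3), mean),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("gpa shape relationships are invariant to arbitrary pre-transforms", {
  cfgs <- gen_landmarks(shape_scenario(n_per_group = 3, seed = 9))
  mats <- lapply(cfgs, `[[`, "coords")
  set.seed(8)
  pre <- lapply(mats, function(m)
    sweep(runif(1, 0.2, 4) * m %*% rot2(runif(1, 0, 2 * pi)),
          2, runif(2, -10, 10), "+"))
  f1 <- gpa(mats); f2 <- gpa(pre)
  d <- function(f) as.matrix(dist(matrix(f$aligned, dim(f$aligned)[1])))
  expect_equal(d(f1), d(f2), tolerance = 1e-9)
})

test_that("optimal rotation matches a brute-force angle search", {
  A <- rbind(c(0, 0), c(1, 0), c(0.4, 0.9))
  B <- rbind(c(0.1, -0.05), c(0.95, 0.3), c(0.05, 1))
  A <- sweep(A, 2, colMeans(A)); A <- A / sqrt(sum(A^2))
  B <- sweep(B, 2, colMeans(B)); B <- B / sqrt(sum(B^2))
  R <- chromatrack:::optimal_rotation(A, B)
  ours <- sum((A %*% R - B)^2)
  brute <- align_residual(A, B, angles = seq(0, 2 * pi, by = 0.001))
  expect_lt(abs(ours - brute), 1e-5)
  expect_lte(ours, brute + 1e-12)
  expect_equal(det(R), 1, tolerance = 1e-12)
})

test_that("sliding never increases the criterion within an iteration", {
  for (crit in c("bending_energy", "procrustes_distance")) {
    cfgs <- gen_landmarks(shape_scenario(seed = 13))
    fit <- gpa(cfgs, slide = TRUE, criterion = crit)
    expect_true(fit$converged)
    tr <- fit$criterion_trace
    expect_true(all(tr[, "after"] <= tr[, "before"] + 1e-12))
  }
})

test_that("procrustes_anova decomposes sums of squares and saturates", {
  cfgs <- gen_landmarks(shape_scenario(seed = 17))
  groups <- vapply(cfgs, `[[`, "", "group")
  fit <- gpa(cfgs)
  an <- procrustes_anova(fit, groups, n_perm = 499, seed = 3)
  expect_equal(unname(an$ss["between"] + an$ss["within"]),
               unname(an$ss["total"]), tolerance = 1e-9)
  expect_equal(unname(an$df), c(1L, 8L))
  expect_gte(an$p, 1 / 500)

  # label order does not change F; seed reproduces p
  an2 <- procrustes_anova(fit, factor(groups, levels = c("light", "dark")),
                          n_perm = 499, seed = 3)
  expect_equal(an2$F, an$F)
  expect_equal(an2$p, an$p)

  # large shape displacement (subset of landmarks, so not removable by
  # superimposition), small noise: minimum attainable p
  delta <- matrix(0, 22, 2); delta[1:5, 1] <- 0.1; delta[6:10, 2] <- -0.08
  big <- gen_landmarks(shape_scenario(group_effect = delta,
                                      landmark_noise_sd = 0.002, seed = 2))
  fit_big <- gpa(big)
  grp_big <- vapply(big, `[[`, "", "group")
  an_big <- procrustes_anova(fit_big, grp_big, n_perm = 199, seed = 1)
  # saturation: the only permutations reaching F_obs are those that
  # reproduce the observed group partition (for equal group sizes, either
  # orientation); p is the minimum attainable given those duplicates
  perms <- withr::with_seed(1L, replicate(199, sample.int(10),
                                          simplify = FALSE))
  dark <- which(grp_big == "dark")
  dup <- vapply(perms, function(pm)
    setequal(pm[dark], dark) || setequal(pm[dark], which(grp_big == "light")),
    logical(1))
  expect_equal(an_big$p, (1 + sum(dup)) / 200)
  expect_lte(an_big$p, 0.05)

  # duplicated groups with zero noise: F = 0
  sc0 <- shape_scenario(landmark_noise_sd = 0,
                        group_effect = matrix(0, 22, 2), n_per_group = 3,
                        seed = 1)
  same <- gen_landmarks(sc0)
  # configs are all identical; perturb deterministically so GPA is defined
  for (i in seq_along(same))
    same[[i]]$coords <- same[[i]]$coords +
      0.01 * sin(i %% 3 + seq_len(44))      # same within matched pairs
  same[[4]]$coords <- same[[1]]$coords
  same[[5]]$coords <- same[[2]]$coords
  same[[6]]$coords <- same[[3]]$coords
  fit0 <- gpa(same)
  an0 <- procrustes_anova(fit0, c("a", "a", "a", "b", "b", "b"),
                          n_perm = 99, seed = 1)
  expect_equal(unname(an0$ss["between"]), 0, tolerance = 1e-12)
  expect_equal(an0$F, 0, tolerance = 1e-9)

  expect_error(procrustes_anova(fit, c("a", rep("b", 9))), "2 specimens")
})

test_that("shape_pca separates displaced groups along PC1", {
  cfgs <- gen_landmarks(shape_scenario(seed = 23))
  groups <- vapply(cfgs, `[[`, "", "group")
  pca <- shape_pca(gpa(cfgs, slide = TRUE))
  expect_equal(sum(pca$variance_explained), 1)
  pc1 <- pca$scores[, 1]
  expect_true(all(range(pc1[groups == "dark"]) < min(pc1[groups == "light"])) ||
                all(range(pc1[groups == "dark"]) > max(pc1[groups == "light"])))
})
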