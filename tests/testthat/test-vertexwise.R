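test_that("vertexwise OLS matches the normal-equations oracle", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(20:40, 1); k <- sample(3:6, 1)
    X <- cbind(intercept = 1,
               matrix(rnorm(n * (k - 1)), n,
                      dimnames = list(NULL, paste0("x", 1:(k - 1)))))
    Y <- matrix(rnorm(n * 5), n, 5)
    fit <- fit_vertexwise(Y, list(X = X, focal = "x1"))
    for (v in 1:5) {
      want <- ols_oracle(X, Y[, v])
      expect_equal(unname(fit$beta[v]), want$b[["x1"]], tolerance = 1e-10)
      expect_equal(unname(fit$se[v]), want$se[["x1"]], tolerance = 1e-10)
      expect_equal(unname(fit$t[v]), want$t[["x1"]], tolerance = 1e-10)
      expect_equal(unname(fit$p[v]), want$p[["x1"]], tolerance = 1e-10)
    }
    expect_equal(fit$df, n - k)
  }
})

test_that("a noiseless orthogonal predictor gives beta = 2 with zero SE", {
  set.seed(3)
  n <- 30
  wmh <- rnorm(n)
  other <- rnorm(n)
  other <- residuals(lm(other ~ wmh))      # orthogonalize
  X <- cbind(intercept = 1, wmh = wmh - mean(wmh), other = other)
  Y <- matrix(2 * X[, "wmh"], n, 3)
  fit <- fit_vertexwise(Y, list(X = X, focal = "wmh"))
  expect_equal(unname(fit$beta), rep(2, 3), tolerance = 1e-12)
  expect_equal(unname(fit$se), rep(0, 3))
})

test_that("rank-deficient designs fail naming the collinear columns", {
  X <- cbind(intercept = 1, a = 1:20, dup = 1:20)
  expect_error(fit_vertexwise(matrix(rnorm(40), 20), list(X = X, focal = "a")),
               "dup")
})

test_that("under the global null, vertexwise p values are calibrated", {
  set.seed(99)
  n <- 40; reps <- 120; V <- 25
  X <- cbind(intercept = 1, wmh = rnorm(n), age = rnorm(n))
  pvals <- replicate(reps, {
    fit <- fit_vertexwise(matrix(rnorm(n * V), n), list(X = X, focal = "wmh"))
    fit$p
  })
  frac <- mean(pvals < 0.01)
  se <- sqrt(0.01 * 0.99 / (reps * V))
  expect_lt(abs(frac - 0.01), 4 * se)
  expect_gt(ks.test(as.vector(pvals), "punif")$p.value, 1e-4)
})

test_that("cluster finding matches brute force on the path-mesh example", {
  mesh <- path_mesh(5)
  df <- 1000
  cfg <- cluster_config(cft = 2 * pt(-2, df), iterations = 100)   # crit = 2
  tmap <- c(3, 3, 0, 3, 0)
  cl <- find_clusters(tmap, mesh, cfg, df)
  expect_equal(cl$critical_t, 2)
  expect_equal(length(cl$members), 2)
  expect_equal(cl$members[[1]], c(1L, 2L))
  expect_equal(cl$members[[2]], 4L)
  expect_equal(cl$table$n_vertices, c(2L, 1L))
  # all-zero map: nothing
  expect_equal(nrow(find_clusters(rep(0, 5), mesh, cfg, df)$table), 0)
  # adjacent opposite signs never merge
  mesh2 <- path_mesh(2)
  cl2 <- find_clusters(c(3, -3), mesh2, cfg, df)
  expect_equal(nrow(cl2$table), 2)
  expect_setequal(cl2$table$sign, c(1, -1))
})

test_that("cluster finding equals brute-force components on random maps", {
  set.seed(6)
  df <- 50
  cfg <- cluster_config(cft = 0.1, iterations = 100)
  for (mesh in list(icosphere(1), path_mesh(30))) {
    crit <- qt(1 - 0.05, df)
    for (i in 1:10) {
      tmap <- rnorm(n_vertices(mesh), 0, 2)
      cl <- find_clusters(tmap, mesh, cfg, df)
      crit <- cl$critical_t
      for (s in c(1, -1)) {
        got <- lapply(cl$members[cl$table$sign == s], sort)
        want <- bfs_components(which(s * tmap > crit), mesh$edges)
        key <- function(l) sort(vapply(l, function(x) paste(x, collapse = ","), ""))
        expect_equal(key(got), key(want))
      }
      expect_true(all(abs(tmap[unlist(cl$members)]) > crit))
      expect_equal(anyDuplicated(unlist(cl$members)), 0)
    }
  }
})

test_that("Monte Carlo p values are seeded, floored and method-agnostic in form", {
  set.seed(20)
  mesh <- icosphere(1)
  n <- 40
  tab_x <- rnorm(n)
  X <- cbind(intercept = 1, wmh = tab_x, age = rnorm(n))
  # strong planted effect on a 6-vertex patch
  patch <- mesh_ball(mesh, 5, 1)
  Y <- matrix(rnorm(n * 42, 0, 0.3), n)
  Y[, patch] <- Y[, patch] + 2 * tab_x
  fit <- fit_vertexwise(Y, list(X = X, focal = "wmh"))
  cfg <- cluster_config(iterations = 999, seed = 42)
  cl <- monte_carlo_cluster_p(find_clusters(fit$t, mesh, cfg, fit$df),
                              fit, mesh, cfg)
  big <- which.max(cl$table$n_vertices)
  # p follows the (1 + x)/(N + 1) estimator against the stored null maxima
  obs <- cl$table$n_vertices[big]
  expect_equal(cl$table$p[big],
               (1 + sum(cl$null_max_extent >= obs)) / 1000)
  expect_gt(min(cl$table$p), 0)
  cl_again <- monte_carlo_cluster_p(find_clusters(fit$t, mesh, cfg, fit$df),
                                    fit, mesh, cfg)
  expect_identical(cl$table$p, cl_again$table$p)
  # unsmoothed synthetic-noise null: a 6-vertex cluster beats every null
  # maximum, so p lands exactly on the 1/(N + 1) floor
  cfg0 <- cluster_config(iterations = 999, seed = 11, method = "smooth-noise",
                         smooth_iters = 0)
  cl0 <- monte_carlo_cluster_p(find_clusters(fit$t, mesh, cfg0, fit$df),
                               fit, mesh, cfg0)
  expect_equal(cl0$table$p[which.max(cl0$table$n_vertices)], 1 / 1000)
  # smooth-noise variant: deterministic, valid probabilities
  cfg2 <- cluster_config(iterations = 150, seed = 7, method = "smooth-noise")
  cl2 <- monte_carlo_cluster_p(find_clusters(fit$t, mesh, cfg2, fit$df),
                               fit, mesh, cfg2)
  expect_true(all(cl2$table$p > 0 & cl2$table$p <= 1))
  cl2b <- monte_carlo_cluster_p(find_clusters(fit$t, mesh, cfg2, fit$df),
                                fit, mesh, cfg2)
  expect_identical(cl2$table$p, cl2b$table$p)
  expect_error(cluster_config(iterations = 50), "100")
})

test_that("cluster-mean SPC extraction is an unweighted vertex mean", {
  mesh <- path_mesh(4)
  spc <- rbind(c(-2, -4, 1, 5), c(0, 0, 0, 0), c(3, 3, 3, 3))
  cl <- list(members = list(c(1L, 2L)), table = data.frame(cluster = 1))
  expect_equal(extract_cluster_mean_spc(spc, cl, 1), c(-3, 0, 3))
  expect_equal(extract_cluster_mean_spc(spc, cl, c(1L, 2L)), c(-3, 0, 3))
  expect_error(extract_cluster_mean_spc(spc, cl, 2), "no such cluster")
  expect_error(extract_cluster_mean_spc(spc, list(members = list(integer(0))), 1),
               "empty cluster")
})
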