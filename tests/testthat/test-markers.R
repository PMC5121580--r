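test_that("canonical analysis produces G-1 ordered roots", {
  sim <- make_separated_scores(8, 3, 4, sep = 6, seed = 1)
  cm <- canonical_analysis(sim$scores, sim$labels)
  expect_identical(ncol(cm$root_coefficients), 2L)   # 3 classes -> 2 roots
  expect_true(all(cm$eigenvalues >= 0))
  expect_true(all(diff(cm$eigenvalues) <= 1e-10))
  expect_identical(nrow(cm$root_scores), nrow(sim$scores))

  # deterministic signs: dominant coefficient positive
  for (r in 1:2) {
    j <- which.max(abs(cm$root_coefficients[, r]))
    expect_gt(cm$root_coefficients[j, r], 0)
  }
})

test_that("a two-class 1D problem yields one root along the centroid gap", {
  x <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  lab <- rep(c("a", "b"), each = 3)
  cm <- canonical_analysis(x, lab)
  expect_identical(ncol(cm$root_coefficients), 1L)
  mm <- tapply(cm$root_scores[, 1], lab, mean)
  expect_gt(abs(mm["b"] - mm["a"]), 0)
  # scores are a monotone map of x (collinear with the centroid difference)
  expect_true(all(diff(cm$root_scores[, 1]) > 0) ||
                all(diff(cm$root_scores[, 1]) < 0))
})

test_that("roots agree with a direct generalized-eigenproblem solve", {
  withr::with_seed(8, {
    for (rep in 1:5) {
      sim <- make_separated_scores(7, 3, 2, sep = runif(1, 2, 6),
                                   seed = sample.int(1e6, 1))
      X <- sim$scores; lab <- sim$labels
      cm <- canonical_analysis(X, lab)

      lv <- sort(unique(lab)); y <- match(lab, lv)
      cent <- rowsum(X, y) / as.integer(table(y))
      Xw <- X - cent[y, ]
      W <- crossprod(Xw)
      Cb <- sweep(cent, 2, colMeans(X))
      B <- crossprod(Cb * sqrt(as.integer(table(y))))
      ev <- eigen(solve(W) %*% B)
      vals <- sort(Re(ev$values), decreasing = TRUE)[1:2]
      expect_equal(cm$eigenvalues, vals, tolerance = 1e-8)

      # coefficient directions match the generalized eigenvectors up to scale
      for (r in 1:2) {
        v <- Re(ev$vectors[, order(Re(ev$values), decreasing = TRUE)[r]])
        a <- cm$root_coefficients[, r]
        cosang <- abs(sum(v * a)) / sqrt(sum(v^2) * sum(a^2))
        expect_equal(cosang, 1, tolerance = 1e-8)
      }
    }
  })
})

test_that("root 1 maximises the between/within variance ratio", {
  sim <- make_separated_scores(9, 3, 3, sep = 5, seed = 14)
  cm <- canonical_analysis(sim$scores, sim$labels)
  ratio <- function(direction) {
    z <- drop(sim$scores %*% direction)
    lv <- unique(sim$labels); y <- match(sim$labels, lv)
    mm <- as.numeric(tapply(z, y, mean))
    b <- sum(table(y) * (mm - mean(z))^2)
    w <- sum((z - mm[y])^2)
    b / w
  }
  r1 <- ratio(cm$root_coefficients[, 1])
  expect_equal(r1, cm$eigenvalues[1], tolerance = 1e-8)
  withr::with_seed(15, {
    for (i in 1:25) {
      d <- rnorm(3)
      expect_lte(ratio(d / sqrt(sum(d^2))), r1 + 1e-10)
    }
  })
})

test_that("variable weights are the loadings-coefficients product", {
  # identity loadings pass coefficients through unchanged
  A <- rbind(c(0.7030, -0.6584), c(0.7108, 0.6446))
  w <- variable_weights(diag(2), A)
  expect_equal(w$weight_root1, c(0.7030, 0.7108))
  expect_equal(w$weight_root2, c(-0.6584, 0.6446))

  # 3 variables x 2 components, multiplied by hand
  L <- rbind(c(1, 0), c(0, 2), c(1, 1))
  A2 <- rbind(c(0.5, -1), c(0.25, 0.5))
  wh <- variable_weights(L, A2, mz = c(93, 110, 185))
  expect_equal(wh$weight_root1, c(0.5, 0.5, 0.75))
  expect_equal(wh$weight_root2, c(-1, 1, -0.5))
  expect_equal(wh$mz, c(93, 110, 185))

  expect_equal(variable_weights(L, A2 * 0)$weight_root2, rep(0, 3))
  expect_error(variable_weights(L, rbind(1, 2, 3)), "match")

  # linearity in the coefficients argument
  B2 <- rbind(c(-0.2, 0.3), c(0.1, -0.4))
  expect_equal(variable_weights(L, A2 + B2)$weight_root1,
               variable_weights(L, A2)$weight_root1 +
                 variable_weights(L, B2)$weight_root1)
})

test_that("fixed thresholds flag weights per root", {
  w <- data.frame(mz = c(93, 110, 185, 300),
                  weight_root1 = c(0.12, -0.05, 0.3, 0.09),
                  weight_root2 = c(0.04, 0.06, -0.2, -0.04))
  class(w) <- c("marker_table", class(w))
  f <- significant_weights(w, "fixed")
  expect_identical(f$flag_root1, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(f$flag_root2, c(FALSE, TRUE, TRUE, FALSE))
  expect_error(significant_weights(w, "bogus"))
})

test_that("normal-probability mode stays quiet on a single normal population", {
  false_pos <- vapply(1:20, function(s) {
    withr::with_seed(1000 + s, w <- rnorm(200, sd = 0.05))
    tbl <- data.frame(mz = seq_along(w), weight_root1 = w)
    class(tbl) <- c("marker_table", class(tbl))
    mean(significant_weights(tbl, "normal_probability")$flag_root1)
  }, numeric(1))
  expect_lt(mean(false_pos), 0.01)

  # planted outliers far off the line are caught
  withr::with_seed(7, w <- c(rnorm(200, sd = 0.05), 1.5, -1.2))
  tbl <- data.frame(mz = seq_along(w), weight_root1 = w)
  class(tbl) <- c("marker_table", class(tbl))
  f <- significant_weights(tbl, "normal_probability")
  expect_true(all(f$flag_root1[201:202]))
})

test_that("root interpretation reports class means, signs and order", {
  scores <- matrix(c(-3, -2.5, -3.5, 3, 2.5, 3.5), ncol = 1)
  lab <- rep(c("neg", "pos"), each = 3)
  out <- interpret_roots(scores, lab)
  expect_length(out, 1L)
  expect_identical(out[[1]]$class, c("neg", "pos"))
  expect_identical(out[[1]]$sign, c("-", "+"))
  expect_warning(res <- interpret_roots(scores, rep("only", 6)), "classes")
  expect_length(res, 0L)
})

test_that("end to end, glycerol is isolated and its markers flagged", {
  al <- align_spectra(generate_dataset(parchment_only_config(), 77), 0.01)
  m <- range_scale_columns(range_scale_rows(al, 0, 1), 0, 1)
  pca <- fit_pca(m, 6)
  cm <- canonical_analysis(pca$training_scores, m$labels)
  root <- separating_root(cm, "parchment_glycerol")
  summ <- interpret_roots(cm)[[root]]
  gly <- summ$mean_score[summ$class == "parchment_glycerol"]
  others <- summ$mean_score[summ$class != "parchment_glycerol"]
  expect_true(all(sign(others) != sign(gly)) ||
                min(abs(gly - others)) > diff(range(others)))

  w <- significant_weights(
    variable_weights(pca$loadings, cm$root_coefficients, mz = al$mz))
  for (marker in c(93.049, 110.058, 185.063)) {
    j <- which.min(abs(w$mz - marker))
    expect_true(w[[paste0("flag_root", root)]][j])
  }
})
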