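test_that("pooled covariance and centroids match the hand formula", {
  # 1D: class A {0, 2}, class B {4, 6}: each class variance 2, pooled = 2
  scores <- matrix(c(0, 2, 4, 6), ncol = 1)
  m <- fit_lda(scores, c("A", "A", "B", "B"))
  expect_equal(unname(m$centroids[, 1]), c(1, 5))
  expect_equal(m$pooled_covariance[1, 1], 2)
  expect_equal(m$priors, c(0.5, 0.5))

  # equal priors over three classes
  s3 <- make_separated_scores(g = 3)
  m3 <- fit_lda(s3$scores, s3$labels)
  expect_equal(m3$priors, rep(1 / 3, 3))

  expect_error(fit_lda(scores, c("A", "A", "A", "A")), "2 classes")
  expect_error(fit_lda(scores, c("A", "A", "B", "C")), "2 samples")
})

test_that("discriminant scores reproduce closed-form evaluations", {
  # centroid sample, identity covariance, three equal priors:
  # D = 0 + ln|I| - 2 ln(1/3) = 2 ln 3
  m3 <- manual_lda_model(rbind(c(0, 0), c(4, 0), c(0, 4)), diag(2))
  D <- discriminant_scores(m3, c(0, 0))
  expect_equal(unname(D[1, 1]), 2 * log(3), tolerance = 1e-12)

  # two centroids at (0,0) and (2,0), equal priors
  m2 <- manual_lda_model(rbind(c(0, 0), c(2, 0)), diag(2))
  Dmid <- discriminant_scores(m2, c(1, 0))
  expect_equal(unname(Dmid[1, 1]), unname(Dmid[1, 2]))                    # symmetric tie
  expect_identical(classify(m2, c(1, 0)), "c1")           # tie -> first class

  Dq <- discriminant_scores(m2, c(0.5, 0))
  expect_equal(unname(Dq[1, 1]), 0.25 - 2 * log(0.5), tolerance = 1e-12)  # ~1.636
  expect_equal(unname(Dq[1, 2]), 2.25 - 2 * log(0.5), tolerance = 1e-12)  # ~3.636
  expect_identical(classify(m2, c(0.5, 0)), "c1")
})

test_that("unequal priors move the boundary toward the rarer class", {
  cen <- rbind(0, 2)
  scan <- matrix(seq(-1, 3, by = 0.01), ncol = 1)
  for (p1 in c(0.5, 0.8, 0.95)) {
    m <- manual_lda_model(cen, matrix(1), priors = c(p1, 1 - p1))
    pred <- classify(m, scan)
    # brute-force evaluation with an explicit inverse
    Dref <- brute_force_discriminant(scan, cen, matrix(1), c(p1, 1 - p1))
    ref <- c("c1", "c2")[max.col(-Dref, ties.method = "first")]
    expect_identical(pred, ref)
  }
  b <- function(p1) {
    m <- manual_lda_model(cen, matrix(1), priors = c(p1, 1 - p1))
    max(scan[classify(m, scan) == "c1"])
  }
  expect_gt(b(0.95), b(0.5))   # higher prior on c1 -> boundary shifts right
})

test_that("classification matches brute-force evaluation on random instances", {
  withr::with_seed(42, {
    for (rep in 1:8) {
      g <- sample(2:3, 1); k <- sample(1:3, 1)
      n_per <- sample(4:10, 1)
      sim <- make_separated_scores(n_per, g, k, sep = runif(1, 2, 8),
                                   seed = sample.int(1e6, 1))
      m <- fit_lda(sim$scores, sim$labels)
      Dref <- brute_force_discriminant(sim$scores, m$centroids,
                                       m$pooled_covariance, m$priors)
      expect_equal(unname(discriminant_scores(m, sim$scores)), Dref,
                   tolerance = 1e-8)
      expect_identical(classify(m, sim$scores),
                       m$class_labels[max.col(-Dref, ties.method = "first")])
      # equal priors + shared covariance = nearest-Mahalanobis assignment
      Sinv <- solve(m$pooled_covariance)
      maha <- t(apply(sim$scores, 1, function(x)
        apply(m$centroids, 1, function(cg) t(x - cg) %*% Sinv %*% (x - cg))))
      expect_identical(classify(m, sim$scores),
                       m$class_labels[max.col(-maha, ties.method = "first")])
    }
  })
})

test_that("adding a constant to every discriminant score changes nothing", {
  sim <- make_separated_scores(6, 3, 2, seed = 9)
  m <- fit_lda(sim$scores, sim$labels)
  D <- discriminant_scores(m, sim$scores)
  expect_identical(max.col(-D, ties.method = "first"),
                   max.col(-(D + 123.4), ties.method = "first"))
})

test_that("predictions agree with an independent reference implementation", {
  skip_if_not_installed("MASS")
  sim <- make_separated_scores(10, 3, 3, sep = 6, seed = 17)
  m <- fit_lda(sim$scores, sim$labels)
  ref <- MASS::lda(sim$scores, grouping = sim$labels,
                   prior = rep(1 / 3, 3))
  expect_identical(classify(m, sim$scores),
                   as.character(predict(ref, sim$scores)$class))
})

test_that("singular pooled covariance is repaired by the ridge", {
  # two perfectly collinear features
  base <- c(0, 1, 2, 10, 11, 12)
  scores <- cbind(base, 2 * base)
  m <- fit_lda(scores, rep(c("A", "B"), each = 3))
  expect_identical(classify(m, scores), rep(c("A", "B"), each = 3))
})

test_that("NER and per-class metrics follow their definitions", {
  expect_equal(ner_percent(c("a", "b"), c("a", "b")), 100)
  expect_equal(ner_percent(c("a", "b"), c("b", "a")), 0)
  truth14 <- rep(c("a", "b"), 7)
  pred14 <- truth14; pred14[c(1, 2)] <- c("b", "a")
  expect_equal(ner_percent(truth14, pred14), 100 * 12 / 14)  # 85.714...
  expect_error(ner_percent(character(0), character(0)), "empty")

  perfect <- class_metrics(c("a", "a", "b", "b"), c("a", "a", "b", "b"))
  expect_true(all(perfect$per_class$specificity == 100))
  expect_true(all(perfect$per_class$selectivity == 100))
  expect_equal(perfect$ner, 100)

  allA <- class_metrics(c("a", "a", "b", "b"), c("a", "a", "a", "a"))
  expect_equal(allA$per_class$specificity[allA$per_class$class == "a"], 0)
  # nothing assigned to b: vacuous precision
  expect_equal(allA$per_class$selectivity[allA$per_class$class == "b"], 100)
  expect_error(class_metrics(c("a", "b"), c("a", "z")), "unknown")
})
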