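test_that("stratified splitting follows the half-up rounding rule", {
  labels <- rep(c("u", "c", "g"), times = c(19, 28, 21))
  sp <- stratified_split(labels, 0.2, seed = 1)
  test_counts <- table(labels[sp$test])
  expect_identical(as.integer(test_counts[c("u", "c", "g")]), c(4L, 6L, 4L))
  expect_length(sp$test, 14L)
  # disjoint and exhaustive
  expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))

  expect_length(stratified_split(labels, 0, seed = 1)$test, 0L)

  lab2 <- rep(c("a", "b"), each = 10)
  t2 <- table(lab2[stratified_split(lab2, 0.2, 3)$test])
  expect_identical(as.integer(t2), c(2L, 2L))

  # same seed, same split; different seed differs
  expect_identical(stratified_split(labels, 0.2, 5),
                   stratified_split(labels, 0.2, 5))
  expect_false(identical(stratified_split(labels, 0.2, 5)$test,
                         stratified_split(labels, 0.2, 6)$test))

  expect_error(stratified_split(rep(c("a", "b"), c(2, 20)), 0.4, 1),
               "fewer than 2")
  expect_error(stratified_split(labels, 1, 1), "fraction")
})

test_that("bootstrap CV is exact on separated data and chance on shuffled", {
  sim <- make_separated_scores(10, 3, 2, sep = 12, seed = 2)
  expect_equal(bootstrap_cv_ner(sim$scores, sim$labels, 1:2,
                                n_iterations = 50, seed = 4), 100)
  # identical seeds reproduce the estimate exactly
  a <- bootstrap_cv_ner(sim$scores, sim$labels, 1, n_iterations = 30, seed = 7)
  b <- bootstrap_cv_ner(sim$scores, sim$labels, 1, n_iterations = 30, seed = 7)
  expect_identical(a, b)

  # labels shuffled independently of scores: NER ~ 1/3
  withr::with_seed(11, {
    noise <- matrix(rnorm(120 * 2), 120, 2)
    lab <- rep(c("a", "b", "c"), each = 40)
  })
  cv <- bootstrap_cv_ner(noise, lab, 1:2, n_iterations = 300, seed = 8)
  expect_gt(cv, 33.3 - 8)
  expect_lt(cv, 33.3 + 8)
})

test_that("forward selection stops and accumulates correctly", {
  # one candidate separates perfectly: model is that single component
  sim <- make_separated_scores(8, 2, 1, sep = 20, seed = 3)
  withr::with_seed(4, scores <- cbind(sim$scores, rnorm(16), rnorm(16)))
  fs <- forward_select(scores, sim$labels, candidate_pcs = 1:3,
                       n_iterations = 40, seed = 5)
  expect_identical(fs$selected, 1L)
  expect_length(fs$cv_path, 1L)
  expect_equal(fs$cv_path[1], 100)

  # neither margin separates, their sum does: both components get selected
  a <- seq(-2.5, 2.5, by = 0.5)
  xor_scores <- rbind(cbind(a, 1 - a), cbind(a, -1 - a))
  xor_labels <- rep(c("p", "q"), each = length(a))
  fs2 <- forward_select(xor_scores, xor_labels, candidate_pcs = 1:2,
                        n_iterations = 60, seed = 6)
  expect_setequal(fs2$selected, 1:2)
  expect_equal(fs2$cv_path[length(fs2$cv_path)], 100)

  # CV path is nondecreasing by construction of the stopping rule
  withr::with_seed(12, {
    messy <- matrix(rnorm(40 * 5), 40, 5)
    messy[, 2] <- messy[, 2] + rep(c(0, 1.2), each = 20)
    lab <- rep(c("a", "b"), each = 20)
  })
  fs3 <- forward_select(messy, lab, candidate_pcs = 1:5,
                        n_iterations = 40, seed = 7)
  expect_true(all(diff(fs3$cv_path) >= 0))
  expect_error(forward_select(messy, lab, integer(0)), "empty")
})

test_that("best-model choice minimises distance to the ideal NER point", {
  rec <- data.frame(repeat_index = 1:3, split_seed = 1:3, cv_seed = 1:3,
                    n_selected = 1, selected_pcs = I(list(1, 1, 1)),
                    ner_train = c(96, 100, 100), ner_cv = c(99, 98, 100),
                    ner_test = c(100, 100, 100))
  best <- pick_best_model(rec)
  expect_identical(best$repeat_index, 3L)
  expect_equal(best$distance_to_ideal, 0)

  # (100,98,100) at distance 2 beats (96,99,100) at sqrt(17) ~ 4.123
  two <- rec[1:2, ]
  best2 <- pick_best_model(two)
  expect_identical(best2$repeat_index, 2L)
  expect_equal(best2$distance_to_ideal, 2)
  expect_equal(sqrt(sum((100 - unlist(two[1, c("ner_train", "ner_cv",
                                               "ner_test")]))^2)),
               sqrt(17))

  single <- rec[1, ]
  expect_identical(pick_best_model(single)$repeat_index, 1L)
  expect_error(pick_best_model(rec[0, ]), "no validation")
})

test_that("repeated validation runs one full cycle and stays above chance", {
  al <- align_spectra(generate_dataset(parchment_only_config(), 21), 0.01)
  rec <- repeated_validation(al, n_repeats = 2, n_iterations = 30,
                             n_pcs = 10, seed = 13)
  expect_identical(nrow(rec), 2L)
  expect_true(all(rec$ner_train >= 100 / 3))
  expect_true(all(rec$ner_train >= 0 & rec$ner_train <= 100))
  expect_true(all(rec$ner_cv >= 0 & rec$ner_cv <= 100))
  expect_true(all(rec$n_selected >= 1))
  expect_true(all(unlist(rec$selected_pcs) <= 10))
  # reproducibility of the full protocol
  rec2 <- repeated_validation(al, n_repeats = 2, n_iterations = 30,
                              n_pcs = 10, seed = 13)
  expect_equal(as.data.frame(rec), as.data.frame(rec2))
})

test_that("models never see the test rows", {
  al <- align_spectra(generate_dataset(parchment_only_config(), 31), 0.01)
  rec <- repeated_validation(al, n_repeats = 1, n_iterations = 30,
                             n_pcs = 8, seed = 19)
  fit <- refit_record(al, rec[1, ], n_iterations = 30, n_pcs = 8)

  # corrupt the test rows in the raw matrix and refit
  al2 <- al
  al2$X[fit$split$test, ] <- al2$X[fit$split$test, ] * 5 + 100
  fit2 <- refit_record(al2, rec[1, ], n_iterations = 30, n_pcs = 8)

  expect_identical(fit2$selected, fit$selected)
  expect_equal(fit2$column_params, fit$column_params)
  expect_equal(fit2$pca$loadings, fit$pca$loadings)
  expect_equal(fit2$ner_train, fit$ner_train)
  expect_equal(fit2$ner_cv, fit$ner_cv)
})
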