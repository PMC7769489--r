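test_that("similarity identity, symmetry, range and the one-cell example", {
  set.seed(13)
  for (i in 1:20) {
    A <- random_esec(sample(1:6, 1))
    B <- random_esec(sample(1:6, 1))
    expect_equal(esec_similarity(A, A), 100)
    expect_equal(esec_similarity(A, B), esec_similarity(B, A))
    s <- esec_similarity(A, B)
    expect_gte(s, 0); expect_lte(s, 100)
  }
  # single-column matrices differing only in one pair's TNR slot:
  # d = 1/3 for that cell, D = 1/30, similarity 96.67
  a <- esec(matrix(base_column(), 30, 1))
  m <- esec_mat <- matrix(base_column(), 30, 1)
  m[1, 1] <- ifelse(m[1, 1] == "T", "N", "T")
  b <- esec(m)
  br <- esec_similarity(a, b, breakdown = TRUE)
  expect_equal(unname(br$d[1, 1]), 1 / 3)
  expect_equal(br$D, 1 / 30)
  expect_equal(br$similarity, (1 - 1 / 30) * 100)
  expect_equal(round(br$similarity, 2), 96.67)
  # matrices differing in every cell
  m2 <- matrix(c(rep("N", 10), rep("O", 10), rep("Q", 10)), 30, 1)
  m1 <- matrix(c(rep("T", 10), rep("To", 10), rep("HT", 10)), 30, 1)
  expect_equal(esec_similarity(esec(m1), esec(m2)), 0)
})

test_that("padding repeats the shorter matrix's last column", {
  long <- random_esec(5)
  short <- esec(long$mat[, 1:3])
  padded <- cbind(long$mat[, 1:3], long$mat[, 3], long$mat[, 3])
  manual <- mean((padded != long$mat)[1:10, ] +
                   (padded != long$mat)[11:20, ] +
                   (padded != long$mat)[21:30, ]) / 3
  expect_equal(esec_similarity(short, long), (1 - manual) * 100)
})

test_that("predictive power is the fraction of columns spared", {
  expect_equal(round(predictive_power(5, 13), 2), 61.54)
  expect_equal(predictive_power(10, 10), 0)
  expect_equal(predictive_power(1, 10), 90)
  expect_error(predictive_power(0, 10), "domain error")
  expect_error(predictive_power(11, 10), "domain error")
})

test_that("progressive classification matches the brute-force scan", {
  set.seed(23)
  for (rep in 1:12) {
    classes <- paste0("c", 1:3)
    training <- unlist(lapply(classes, function(cl)
      lapply(1:2, function(i) random_esec(sample(2:5, 1), label = cl))),
      recursive = FALSE)
    test <- random_esec(sample(2:5, 1), label = sample(classes, 1))
    got <- classify_progressive(test, training)
    want <- naive_classify(test, training)
    expect_identical(got$label, want$label)
    expect_equal(got$prediction_column, want$column)
  }
})

test_that("a test identical to one class is recognised at first divergence", {
  # three classes sharing two start columns, diverging from column 3
  base <- random_esec(5)$mat
  mk <- function(cl, sym) {
    m <- base
    m[1, 3:5] <- sym          # class-specific TNR from column 3 on
    m[11, 3:5] <- c("Ab", "Ab", "Ab")
    esec(m, action_label = cl)
  }
  training <- list(mk("x", "T"), mk("y", "N"), mk("z", "U"))
  test <- mk("y", "N")
  got <- classify_progressive(test, training)
  expect_identical(got$label, "y")
  expect_equal(got$prediction_column, 3L)
  expect_equal(got$predictive_power, predictive_power(3, 5))
})

test_that("single-class training predicts trivially at column 1", {
  tr <- list(random_esec(3, label = "only"))
  got <- classify_progressive(random_esec(4, label = "only"), tr)
  expect_identical(got$label, "only")
  expect_equal(got$prediction_column, 1L)
  expect_error(classify_progressive(random_esec(3), list()), "empty training")
})

test_that("the winning class stays argmax from the prediction column on", {
  set.seed(31)
  for (i in 1:10) {
    training <- unlist(lapply(c("a", "b"), function(cl)
      lapply(1:2, function(j) random_esec(4, label = cl))),
      recursive = FALSE)
    test <- random_esec(4, label = "a")
    got <- classify_progressive(test, training)
    sim <- got$class_similarity
    w <- match(got$label, colnames(sim))
    if (got$prediction_column < nrow(sim))
      for (j in seq(got$prediction_column, nrow(sim)))
        expect_true(sim[j, w] >= max(sim[j, -w]))
  }
})

test_that("indistinguishable classes split at chance", {
  # two classes built from one identical matrix: accuracy ~ 0.5 by tie-break
  m <- random_esec(3)
  ds <- c(lapply(1:4, function(i) esec(m$mat, action_label = "p")),
          lapply(1:4, function(i) esec(m$mat, action_label = "q")))
  ev <- evaluate_dataset(ds, split = 0.5, seed = 3)
  expect_equal(ev$overall$accuracy, 0.5)
  expect_true(all(ev$per_action$mean_pp == 0))
})

test_that("dataset evaluation is deterministic given the seed", {
  ds <- unlist(lapply(c("a", "b"), function(cl) {
    set.seed(match(cl, c("a", "b")))
    lapply(1:4, function(i) random_esec(4, label = cl))
  }), recursive = FALSE)
  e1 <- evaluate_dataset(ds, split = 0.5, seed = 11)
  e2 <- evaluate_dataset(ds, split = 0.5, seed = 11)
  expect_identical(e1$per_action, e2$per_action)
})
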