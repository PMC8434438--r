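# quick stream builder: person-present frames carry constant patches drawn
# from per-frame prototypes so the rounding recognizer can be driven by a
# plain probability function instead of a fitted model
stub_stream <- function(n, person = rep(TRUE, n), location = "bed",
                        distance = 0.7) {
  tibble::tibble(
    frame = seq_len(n),
    person = person,
    patch = lapply(seq_len(n), function(k)
      if (person[k]) matrix(2, 16, 16) else NULL),
    location = ifelse(person, location, NA_character_),
    floor_distance = ifelse(person, distance, NA_real_))
}

stub_config <- function(...) {
  pipeline_config(canvas = c(16, 16), hog_cell = 16, hog_bins = 9, ...)
}

const_model <- function(probs) {
  function(features) matrix(probs, nrow = 1, byrow = TRUE,
                            dimnames = list(NULL, names(probs)))
}

test_that("the classifier separates synthetic clusters deterministically", {
  set.seed(31)
  n <- 40; p <- 60
  x <- rbind(matrix(rnorm(n * p, 0, 0.3), n, p),
             matrix(rnorm(n * p, 2, 0.3), n, p))
  y <- rep(c(2L, 4L), each = n)
  model <- train_classifier(x, y, seed = 1)
  pr <- predict_proba(model, x)
  expect_equal(as.integer(colnames(pr)[max.col(pr)]), y)   # 0 training errors

  model2 <- train_classifier(x, y, seed = 1)
  probe <- matrix(rnorm(5 * p, 1, 1), 5, p)
  expect_equal(predict_proba(model, probe), predict_proba(model2, probe))

  expect_error(train_classifier(x, rep(2L, 2 * n)), "2 classes")
  expect_error(predict_proba(model, matrix(0, 1, p + 1)), "layout mismatch")
})

test_that("five well-separated classes are recognized on held-out data", {
  set.seed(32)
  p <- 200; per <- 30
  centers <- matrix(rnorm(5 * p, 0, 1), 5, p) * 3
  make <- function(m) t(vapply(seq_len(m), function(i) {
    k <- ((i - 1) %% 5) + 1
    centers[k, ] + rnorm(p, 0, 0.3)
  }, numeric(p)))
  x_tr <- make(5 * per); y_tr <- rep_len(1:5, 5 * per)
  x_te <- make(50); y_te <- rep_len(1:5, 50)
  model <- train_classifier(x_tr, y_tr, seed = 3)
  pr <- predict_proba(model, x_te)
  expect_gte(mean(as.integer(colnames(pr)[max.col(pr)]) == y_te), 0.95)
  expect_equal(unname(rowSums(pr)), rep(1, 50), tolerance = 1e-9)

  # a probe deep inside a cluster takes that class
  pr1 <- predict_proba(model, matrix(centers[3, ], 1))
  expect_equal(colnames(pr1)[which.max(pr1)], "3")

  # the midpoint of two symmetric clusters splits its probability
  set.seed(33)
  x2 <- rbind(matrix(rnorm(600, -1, 0.2), 30, 20),
              matrix(rnorm(600, 1, 0.2), 30, 20))
  m2 <- train_classifier(x2, rep(c(1L, 2L), each = 30), seed = 1)
  pm <- predict_proba(m2, matrix(0, 1, 20))
  expect_lt(abs(pm[1, 1] - pm[1, 2]), 0.1)
})

test_that("a confident stream closes its first round at the minimum length", {
  cfg <- stub_config()
  model <- const_model(c("1" = 0.01, "2" = 0.01, "3" = 0.02, "4" = 0.95,
                         "5" = 0.01))
  rounds <- rounding_recognize(stub_stream(20), model, cfg)
  expect_equal(rounds$start[1], 1)
  expect_equal(rounds$end[1], 5)                    # min length 5
  expect_equal(rounds$label[1], 4L)
  expect_gte(rounds$probability[1], cfg$th_prob)
})

test_that("an indecisive stream yields 30-frame undetermined rounds", {
  cfg <- stub_config()
  model <- const_model(c("1" = 0.2, "2" = 0.2, "3" = 0.2, "4" = 0.2,
                         "5" = 0.2))
  rounds <- rounding_recognize(stub_stream(65), model, cfg)
  expect_equal(rounds$end[1] - rounds$start[1] + 1, 30)  # max duration
  expect_true(is.na(rounds$label[1]))
  expect_true(is.na(rounds$raw_label[1]))
})

test_that("rounds tile the person-present portion without gaps or overlap", {
  cfg <- stub_config()
  set.seed(34)
  for (rep in 1:5) {
    probs <- c("2" = 0.5, "4" = 0.5)
    model <- function(f) {
      p <- runif(1)
      matrix(c(p, 1 - p), 1, dimnames = list(NULL, c("2", "4")))
    }
    person <- runif(60) < 0.8
    stream <- stub_stream(60, person = person)
    rounds <- rounding_recognize(stream, model, cfg)
    covered <- unlist(lapply(seq_len(nrow(rounds)), function(r)
      rounds$start[r]:rounds$end[r]))
    expect_false(any(duplicated(covered)))          # no overlap
    expect_setequal(covered, which(person))         # no gaps
  }
  expect_equal(nrow(rounding_recognize(stub_stream(0), const_model(c("2" = 1)),
                                       cfg)), 0)
})

test_that("height overrides and the bed sanity check follow the rule table", {
  expect_equal(apply_context_rules(4L, "bed", 1.2), 6L)     # assistance
  expect_equal(apply_context_rules(3L, "floor", 0.3), 7L)   # fall
  expect_equal(apply_context_rules(4L, "bed", 0.7), 4L)     # untouched
  expect_equal(apply_context_rules(2L, "other", 0.85), 2L)
  # low centroid off the floor is not a fall
  expect_equal(apply_context_rules(4L, "bed", 0.3), 4L)
  expect_true(is.na(suppressMessages(apply_context_rules(5L, "floor", 0.6))))
  expect_equal(suppressMessages(apply_context_rules(5L, "bed", 0.6)), 5L)
})

test_that("the block median filter emits one label per window", {
  expect_equal(median_filter_labels(c(5L, 5L, 4L, 5L, 5L)), 5L)
  expect_equal(median_filter_labels(rep(3L, 25)), rep(3L, 5))
  out <- median_filter_labels(rep(c(4L, 5L), 300), window = 5)
  expect_length(out, 120)
  expect_message(median_filter_labels(rep(1L, 7)), "partial block")
  # undetermined frames drop out of the block median
  expect_equal(median_filter_labels(c(2L, NA, NA, NA, 2L)), 2L)
  expect_true(is.na(median_filter_labels(rep(NA_integer_, 5))))
})

test_that("evaluation counts match a brute-force confusion oracle", {
  pred <- c(1L, 1L, 2L, NA, 3L, 3L, 2L, 1L, NA, 2L)
  truth <- c(1L, 2L, 2L, 2L, 3L, 1L, 2L, 1L, 3L, 3L)
  ev <- evaluate_labels(pred, truth)
  keep <- !is.na(pred)
  expect_equal(ev$n_evaluated, sum(keep))
  expect_equal(ev$n_undetermined, 2)
  expect_equal(ev$accuracy, mean(pred[keep] == truth[keep]))
  ref <- matrix(0L, 8, 8, dimnames = list(0:7, 0:7))
  for (k in which(keep)) ref[truth[k] + 1, pred[k] + 1] <-
      ref[truth[k] + 1, pred[k] + 1] + 1L
  expect_equal(unname(unclass(ev$confusion)), unname(ref))
  expect_equal(sum(ev$confusion), ev$n_evaluated)

  expect_equal(evaluate_labels(truth, truth)$accuracy, 1)
  nine <- c(rep(1L, 9), 2L)
  expect_equal(evaluate_labels(nine, rep(1L, 10))$accuracy, 0.9)
  expect_error(evaluate_labels(1L, c(1L, 2L)), "lengths differ")
})

test_that("tidy and glance methods expose tabular results", {
  ev <- evaluate_labels(c(1L, 2L, NA), c(1L, 2L, 3L))
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$n), 2)
  expect_equal(glance(ev)$accuracy, 1)
})
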