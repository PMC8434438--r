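#' Action label codes
#'
#' The eight actions are coded 0-7: 0 Outside the room, 1 Transition,
#' 2 Seated in wheelchair, 3 Standing, 4 Sitting on the bed, 5 Lying on
#' the bed, 6 Receiving assistance, 7 Falling.  Undetermined frames are
#' represented as `NA`.
#'
#' @return A named integer vector mapping label names to codes.
#' @export
action_labels <- function() {
  c("Outside the room" = 0L, "Transition" = 1L, "Seated in wheelchair" = 2L,
    "Standing" = 3L, "Sitting on the bed" = 4L, "Lying on the bed" = 5L,
    "Receiving assistance" = 6L, "Falling" = 7L)
}

#' Train the action classifier
#'
#' Fits a multi-class linear classifier (ridge-penalized multinomial
#' logistic regression with a tiny fixed penalty, giving linear decision
#' boundaries and calibrated class probabilities) on fused DMA/DMH
#' descriptors of short annotated action sequences.  The floor-distance
#' feature is deliberately excluded — it drives the height overrides, not
#' the classifier.
#'
#' @param features Numeric matrix, one row per training sequence (3168
#'   columns with the default layout), or a list of equal-length vectors.
#' @param labels Integer action codes (a subset of 1-5), one per row.
#' @param seed Integer seed (the fit itself is deterministic; the seed
#'   guards any future stochastic component).
#' @param lambda Ridge penalty.
#' @return An object of class `action_classifier`.
#' @export
train_classifier <- function(features, labels, seed = 1L, lambda = 1e-3) {
  if (is.list(features)) features <- do.call(rbind, features)
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least 2 classes to train")
  set.seed(as.integer(seed))
  fit <- glmnet::glmnet(features, factor(labels, levels = classes),
                        family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  structure(list(fit = fit, classes = classes, lambda = lambda,
                 p = ncol(features), seed = as.integer(seed)),
            class = "action_classifier")
}

#' @export
print.action_classifier <- function(x, ...) {
  cat(sprintf("<action_classifier> %d classes (%s), %d features\n",
              length(x$classes), paste(x$classes, collapse = ", "), x$p))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.action_classifier <- function(x, ...) {
  coefs <- stats::coef(x$fit, s = x$lambda)
  dplyr::bind_rows(lapply(names(coefs), function(cl) {
    m <- as.matrix(coefs[[cl]])
    tibble::tibble(class = as.integer(cl),
                   term = rownames(m),
                   estimate = m[, 1])
  }))
}

#' @exportS3Method generics::glance
glance.action_classifier <- function(x, ...) {
  tibble::tibble(n_classes = length(x$classes), n_features = x$p,
                 lambda = x$lambda)
}

#' Class probabilities for feature vectors
#'
#' @param model An [train_classifier()] model, or a plain function mapping
#'   a feature matrix to a matrix of class probabilities (useful for
#'   testing the rounding recognizer in isolation).
#' @param features Feature vector or matrix (rows = observations).
#' @return Matrix of probabilities, one row per observation, columns named
#'   by class code; rows sum to 1.
#' @export
predict_proba <- function(model, features) {
  if (is.function(model)) {
    p <- model(features)
    return(if (is.matrix(p)) p else matrix(p, nrow = 1,
                                           dimnames = list(NULL, names(p))))
  }
  stopifnot(inherits(model, "action_classifier"))
  if (!is.matrix(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != model$p)
    stop(sprintf("feature layout mismatch: %d columns, model expects %d",
                 ncol(features), model$p))
  pr <- predict(model$fit, features, s = model$lambda, type = "response")[, , 1]
  if (!is.matrix(pr)) pr <- matrix(pr, nrow = 1,
                                   dimnames = list(NULL, names(pr)))
  pr / rowSums(pr)
}

#' Height and location overrides
#'
#' After a recognition round closes, the classifier label is checked
#' against the person's centroid-to-floor distance and room location:
#' a centroid higher than `th_assist` means a (taller) nurse is merged with
#' the resident — "Receiving assistance"; a centroid lower than `th_fall`
#' while the blob is on the floor means "Falling".  As a sanity check,
#' "Lying on the bed" is demoted to undetermined when the blob is not on
#' the bed.
#'
#' @param label Integer classifier label (1-5).
#' @param location Blob location from [localize_blob()].
#' @param floor_distance Centroid-to-floor distance in metres.
#' @param th_assist,th_fall Height thresholds in metres.
#' @return Integer action code, or `NA` (undetermined).
#' @export
apply_context_rules <- function(label, location, floor_distance,
                                th_assist = 1.0, th_fall = 0.4) {
  if (is.na(label)) return(NA_integer_)
  if (!is.na(floor_distance)) {
    if (floor_distance > th_assist) return(6L)
    if (floor_distance < th_fall && identical(location, "floor")) return(7L)
  }
  if (label == 5L && !identical(location, "bed")) {
    message("lying label demoted: blob not located on the bed")
    return(NA_integer_)
  }
  as.integer(label)
}

#' Automatic rounding recognition of a continuous sequence
#'
#' Splits the person-present portion of a long sequence into short
#' recognition rounds, online: each round starts with freshly zeroed
#' DMA/DMH templates and grows frame by frame; from the minimum length on,
#' the fused descriptor is classified and the round closes with the top
#' label as soon as its probability reaches `th_prob`; a round that
#' reaches the maximum duration closes as undetermined.  Closed labels
#' pass through the height/location overrides.  Frames with no confirmed
#' person are labelled 0 (Outside the room); a round interrupted by losing
#' the person (or by the end of the stream) closes as undetermined.
#'
#' @param stream A tibble with one row per frame: `frame` (index), `person`
#'   (logical), `patch` (list of silhouette patches, `NULL` when absent),
#'   `location` (character), `floor_distance` (numeric).
#' @param model An [train_classifier()] model (or probability function, see
#'   [predict_proba()]).
#' @param config A [pipeline_config()].
#' @return A tibble of rounds: `start`, `end` (inclusive frame span),
#'   `raw_label` (classifier output), `label` (after overrides, `NA` =
#'   undetermined), `probability`.
#' @export
rounding_recognize <- function(stream, model, config = pipeline_config()) {
  rounds <- list()
  open <- NULL
  close_round <- function(open, end, raw, label, prob) {
    tibble::tibble(start = open$start, end = end,
                   raw_label = raw, label = label, probability = prob)
  }
  for (k in seq_len(nrow(stream))) {
    present <- isTRUE(stream$person[k]) && !is.null(stream$patch[[k]])
    if (!present) {
      if (!is.null(open)) {
        rounds <- c(rounds, list(close_round(open, stream$frame[k - 1],
                                             NA_integer_, NA_integer_, NA_real_)))
        open <- NULL
      }
      next
    }
    if (is.null(open)) {
      open <- list(start = stream$frame[k],
                   maps = action_maps(config$canvas[1], config$canvas[2],
                                      tau = config$tau, delta = config$delta),
                   prev_patch = NULL, len = 0L,
                   locations = character(0), distances = numeric(0))
    }
    patch <- stream$patch[[k]]
    open$maps <- update_dma(open$maps, patch)
    if (!is.null(open$prev_patch))
      open$maps <- update_dmh(open$maps, patch, open$prev_patch)
    open$prev_patch <- patch
    open$len <- open$len + 1L
    open$locations <- c(open$locations, stream$location[k])
    open$distances <- c(open$distances, stream$floor_distance[k])
    closed <- FALSE
    if (open$len >= config$min_round) {
      feat <- fuse_features(
        hog_descriptor(open$maps$dma, config$hog_cell, config$hog_bins),
        hog_descriptor(open$maps$dmh, config$hog_cell, config$hog_bins))
      pr <- predict_proba(model, feat)
      best <- which.max(pr[1, ])
      if (pr[1, best] >= config$th_prob) {
        raw <- as.integer(colnames(pr)[best])
        loc <- names(which.max(table(open$locations)))
        dist <- mean(open$distances, na.rm = TRUE)
        lab <- apply_context_rules(raw, loc, dist,
                                   th_assist = config$th_assist,
                                   th_fall = config$th_fall)
        rounds <- c(rounds, list(close_round(open, stream$frame[k],
                                             raw, lab, pr[1, best])))
        closed <- TRUE
      }
    }
    if (!closed && open$len >= config$max_round) {
      rounds <- c(rounds, list(close_round(open, stream$frame[k],
                                           NA_integer_, NA_integer_, NA_real_)))
      closed <- TRUE
    }
    if (closed) open <- NULL
  }
  if (!is.null(open)) {
    rounds <- c(rounds, list(close_round(open, stream$frame[nrow(stream)],
                                         NA_integer_, NA_integer_, NA_real_)))
  }
  if (length(rounds) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          raw_label = integer(), label = integer(),
                          probability = numeric()))
  }
  dplyr::bind_rows(rounds)
}

#' Expand rounds to per-frame labels
#'
#' Frames inside a round take the round's label (`NA` when the round closed
#' undetermined); frames outside any round are 0 (Outside the room).
#'
#' @param rounds Tibble from [rounding_recognize()].
#' @param n_frames Sequence length.
#' @return Integer vector of length `n_frames` with `NA` for undetermined
#'   frames.
#' @export
rounds_to_labels <- function(rounds, n_frames) {
  labels <- rep(0L, n_frames)
  for (r in seq_len(nrow(rounds))) {
    labels[rounds$start[r]:rounds$end[r]] <- rounds$label[r]
  }
  labels
}

#' Block median filter on a label sequence
#'
#' Labels are processed in consecutive non-overlapping blocks of `window`
#' frames; each block emits the median of its labels (lower median for
#' ties, `NA`-frames excluded), so a 600-frame sequence with the default
#' window yields 120 outputs.  A trailing partial block emits its median
#' with a message.
#'
#' @param labels Integer label vector (`NA` = undetermined).
#' @param window Odd block width.
#' @return Integer vector of `ceiling(length(labels) / window)` block
#'   medians.
#' @export
median_filter_labels <- function(labels, window = 5) {
  stopifnot(window %% 2 == 1, window >= 1)
  n <- length(labels)
  if (n %% window != 0)
    message(sprintf("trailing partial block of %d labels", n %% window))
  starts <- seq(1, n, by = window)
  vapply(starts, function(s) {
    block <- labels[s:min(s + window - 1, n)]
    block <- block[!is.na(block)]
    if (length(block) == 0) return(NA_integer_)
    sort(block)[ceiling(length(block) / 2)]
  }, integer(1))
}

#' Per-frame evaluation against ground truth
#'
#' Frame-wise accuracy and the 8x8 confusion matrix (rows = actual,
#' columns = predicted).  Undetermined predictions (`NA`) are excluded
#' from the accuracy denominator and from the confusion counts.
#'
#' @param predicted,truth Equal-length integer label vectors.
#' @return An object of class `action_evaluation`: list with `accuracy`,
#'   `confusion` (8x8 integer matrix), `n_evaluated`, `n_undetermined`.
#' @export
evaluate_labels <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth lengths differ")
  keep <- !is.na(predicted)
  lv <- 0:7
  confusion <- table(factor(truth[keep], lv), factor(predicted[keep], lv))
  structure(list(
    accuracy = if (any(keep)) mean(predicted[keep] == truth[keep]) else NA_real_,
    confusion = unclass(confusion),
    n_evaluated = sum(keep),
    n_undetermined = sum(!keep)),
    class = "action_evaluation")
}

#' @export
print.action_evaluation <- function(x, ...) {
  cat(sprintf("<action_evaluation> accuracy %.1f%% over %d frames (%d undetermined)\n",
              100 * x$accuracy, x$n_evaluated, x$n_undetermined))
  print(x$confusion)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.action_evaluation <- function(x, ...) {
  df <- as.data.frame(as.table(x$confusion))
  names(df) <- c("actual", "predicted", "n")
  tibble::as_tibble(df) |>
    dplyr::mutate(actual = as.integer(as.character(.data$actual)),
                  predicted = as.integer(as.character(.data$predicted)),
                  n = as.integer(.data$n))
}

#' @exportS3Method generics::glance
glance.action_evaluation <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_evaluated = x$n_evaluated,
                 n_undetermined = x$n_undetermined)
}
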