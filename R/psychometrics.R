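# Psychometric evaluation of categorical video ratings: recognition accuracy
# against the true category, confusion structure, chance-corrected
# inter-rater agreement (Fleiss' kappa), and a one-sample test of accuracy
# against the chance level with Cohen's d.

#' Construct a rating matrix
#'
#' Canonical long form: one row per (video, rater) pair. The default label
#' set is the three action categories Normal (kinematically natural,
#' goal-intact), How (kinematically unnatural, goal-intact) and What
#' (kinematically natural, goal-violating).
#'
#' @param data data frame with columns `video_id`, `rater_id`, `response` and
#'   optionally `truth`.
#' @param labels character vector of allowed category labels.
#' @return `data` with class `rating_matrix` and a `labels` attribute.
#' @export
rating_matrix <- function(data, labels = c("Normal", "How", "What")) {
  need <- c("video_id", "rater_id", "response")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("ratings need columns video_id, rater_id, response", call. = FALSE)
  if (nrow(data) == 0L) stop("ratings table is empty", call. = FALSE)
  bad <- setdiff(unique(as.character(data$response)), labels)
  if (length(bad) > 0)
    stop("response label(s) outside the label set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if ("truth" %in% names(data)) {
    bad <- setdiff(unique(as.character(data$truth)), labels)
    if (length(bad) > 0)
      stop("truth label(s) outside the label set: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(as.data.frame(data), labels = labels,
            class = c("rating_matrix", "data.frame"))
}

#' Read ratings from CSV
#'
#' @param path CSV with columns video_id, rater_id, response and optionally
#'   truth.
#' @param labels allowed category labels.
#' @return a [rating_matrix()].
#' @export
read_ratings <- function(path, labels = c("Normal", "How", "What")) {
  if (!file.exists(path)) stop("ratings file not found: ", path, call. = FALSE)
  rating_matrix(utils::read.csv(path, stringsAsFactors = FALSE), labels)
}

#' Write ratings to tidy long-format CSV
#'
#' One row per (video, rater): the layout any external stats package expects
#' for repeated-measures models.
#'
#' @param ratings a [rating_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(ratings, path) {
  utils::write.csv(as.data.frame(ratings), path, row.names = FALSE)
  invisible(path)
}

rating_truth <- function(ratings) {
  if (!"truth" %in% names(ratings))
    stop("this operation needs a 'truth' column in the ratings",
         call. = FALSE)
  invisible(ratings)
}

#' Per-rater recognition accuracy
#'
#' @param ratings a [rating_matrix()] with truth labels.
#' @return data frame `rater_id`, `n_items`, `n_correct`, `pct`
#'   (= 100 * n_correct / n_items).
#' @export
score_ratings <- function(ratings) {
  stopifnot(inherits(ratings, "rating_matrix"))
  rating_truth(ratings)
  correct <- as.character(ratings$response) == as.character(ratings$truth)
  n_items <- tapply(correct, ratings$rater_id, length)
  n_correct <- tapply(correct, ratings$rater_id, sum)
  out <- data.frame(rater_id = names(n_items),
                    n_items = as.integer(n_items),
                    n_correct = as.integer(n_correct),
                    stringsAsFactors = FALSE)
  out$pct <- accuracy_percentage(out$n_correct, out$n_items)
  rownames(out) <- NULL
  out
}

#' Convert a correct count to a percentage
#'
#' Also accepts fractional counts, e.g. a mean number of correctly classified
#' videos across raters.
#'
#' @param count (possibly fractional) number of correct classifications.
#' @param n_items number of items rated.
#' @return percentage, `100 * count / n_items`.
#' @export
accuracy_percentage <- function(count, n_items) {
  if (any(n_items < 1)) stop("n_items must be >= 1", call. = FALSE)
  100 * count / n_items
}

#' Confusion matrix of category classifications
#'
#' Rows are the true category, columns the assigned category, in label-set
#' order.
#'
#' @param ratings a [rating_matrix()] with truth labels.
#' @param per_item if TRUE, return a named list with one confusion matrix per
#'   video; the per-item matrices sum to the overall one.
#' @return k x k count matrix (or list of them).
#' @export
confusion_matrix <- function(ratings, per_item = FALSE) {
  stopifnot(inherits(ratings, "rating_matrix"))
  rating_truth(ratings)
  labels <- attr(ratings, "labels")
  tab <- function(df) {
    m <- table(factor(df$truth, levels = labels),
               factor(df$response, levels = labels))
    m <- unclass(m)
    names(dimnames(m)) <- c("truth", "assigned")
    m
  }
  if (!per_item) return(tab(ratings))
  lapply(split(as.data.frame(ratings), ratings$video_id), tab)
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Standard formulation for N items each rated by the same number n of
#' raters over k categories: with n_ij the number of raters assigning item i
#' to category j, per-item agreement is
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`, the category proportions are
#' `p_j = sum_i n_ij / (N n)`, and
#' `kappa = (Pbar - Pbar_e) / (1 - Pbar_e)` with `Pbar = mean(P_i)` and
#' `Pbar_e = sum_j p_j^2`. When all mass falls in one category
#' (`Pbar_e = 1`) kappa is undefined and the result is flagged rather than
#' an error, so batch runs survive degenerate simulated inputs.
#'
#' @param ratings a [rating_matrix()], or an items x categories count matrix.
#' @return list of class `kappa_result`: `kappa`, `per_item_agreement`,
#'   `category_proportions`, `mean_agreement`, `expected_agreement`,
#'   `n_items`, `n_raters`, `undefined`.
#' @export
fleiss_kappa <- function(ratings) {
  counts <- if (inherits(ratings, "rating_matrix")) {
    labels <- attr(ratings, "labels")
    unclass(table(factor(ratings$video_id),
                  factor(ratings$response, levels = labels)))
  } else if (is.matrix(ratings)) {
    ratings
  } else stop("expected a rating_matrix or a count matrix", call. = FALSE)
  n_per_item <- rowSums(counts)
  if (length(unique(n_per_item)) != 1L)
    stop("Fleiss' kappa needs the same number of ratings per item",
         call. = FALSE)
  n <- n_per_item[[1L]]
  if (n < 2) stop("Fleiss' kappa needs at least 2 raters", call. = FALSE)
  N <- nrow(counts)
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_j <- colSums(counts) / (N * n)
  Pbar <- mean(P_i)
  Pe <- sum(p_j^2)
  undefined <- (1 - Pe) <= .Machine$double.eps
  structure(
    list(kappa = if (undefined) NA_real_ else (Pbar - Pe) / (1 - Pe),
         per_item_agreement = unname(P_i),
         category_proportions = unname(p_j),
         mean_agreement = Pbar,
         expected_agreement = Pe,
         n_items = N, n_raters = as.integer(n),
         undefined = undefined),
    class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  if (x$undefined)
    cat("<kappa_result> undefined (all ratings in one category)\n")
  else
    cat(sprintf(
      "<kappa_result> kappa = %.3f (Pbar = %.3f, Pe = %.3f; %d items, %d raters)\n",
      x$kappa, x$mean_agreement, x$expected_agreement, x$n_items, x$n_raters))
  invisible(x)
}

#' Chance-level correct count
#'
#' Expected number of correct classifications under uniform guessing over k
#' categories.
#'
#' @param n_items number of items (>= 1).
#' @param k_categories number of categories (>= 2).
#' @return `n_items / k_categories`.
#' @export
chance_level <- function(n_items, k_categories) {
  if (n_items < 1) stop("n_items must be >= 1", call. = FALSE)
  if (k_categories < 2) stop("k_categories must be >= 2", call. = FALSE)
  n_items / k_categories
}

#' One-sample t test with Cohen's d
#'
#' Tests whether the mean of `values` differs from `mu0`, reporting the t
#' statistic, two-sided p, the 95% CI of the mean, and the one-sample effect
#' size `d = (mean - mu0) / SD`. A summary-statistics mode (`mean`, `sd`,
#' `n`) is provided so printed summaries can be checked without raw data;
#' both modes run through the same closed-form path. Zero variance gives a
#' flagged degenerate result rather than an error.
#'
#' @param values numeric vector of raw observations (length >= 2), or NULL
#'   when using summary mode.
#' @param mu0 reference value under the null.
#' @param mean,sd,n summary-statistics mode inputs (ignored when `values`
#'   is given).
#' @param conf_level confidence level of the CI; default 0.95.
#' @return list of class `chance_test`: `t`, `df`, `p`, `ci` (length 2),
#'   `d`, `mean`, `sd`, `n`, `mu0`, `degenerate`.
#' @export
one_sample_t <- function(values = NULL, mu0, mean = NULL, sd = NULL, n = NULL,
                         conf_level = 0.95) {
  if (!is.null(values)) {
    if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
    mean <- base::mean(values)
    sd <- stats::sd(values)
    n <- length(values)
  } else if (is.null(mean) || is.null(sd) || is.null(n)) {
    stop("supply either raw values or all of mean, sd, n", call. = FALSE)
  }
  df <- n - 1
  if (sd <= 0) {
    return(structure(
      list(t = NA_real_, df = df, p = NA_real_, ci = c(mean, mean),
           d = NA_real_, mean = mean, sd = sd, n = n, mu0 = mu0,
           degenerate = TRUE),
      class = "chance_test"))
  }
  se <- sd / sqrt(n)
  t <- (mean - mu0) / se
  crit <- stats::qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(t = t, df = df, p = 2 * stats::pt(-abs(t), df),
         ci = c(mean - crit * se, mean + crit * se),
         d = (mean - mu0) / sd,
         mean = mean, sd = sd, n = n, mu0 = mu0, degenerate = FALSE),
    class = "chance_test")
}

#' @export
print.chance_test <- function(x, ...) {
  if (x$degenerate) {
    cat("<chance_test> degenerate: zero variance\n")
  } else {
    cat(sprintf(
      "<chance_test> t(%g) = %.2f, p = %.3g, 95%% CI [%.2f, %.2f], d = %.2f\n",
      x$df, x$t, x$p, x$ci[1], x$ci[2], x$d))
  }
  invisible(x)
}

#' Convert a frame count to seconds
#'
#' E.g. a 3-frame jitter at 60 fps is 0.05 s.
#'
#' @param frames frame count (may be fractional, e.g. a mean).
#' @param fps frames per second (> 0).
#' @return seconds, `frames / fps`.
#' @export
frames_to_seconds <- function(frames, fps) {
  if (any(fps <= 0)) stop("fps must be > 0", call. = FALSE)
  frames / fps
}

#' Full psychometric report for a rating table
#'
#' Bundles per-rater accuracy, the accuracy summary, the overall confusion
#' matrix, Fleiss' kappa, and a one-sample t test of per-rater correct
#' counts against the chance level.
#'
#' @param ratings a [rating_matrix()] with truth labels.
#' @return list of class `psychometric_report`.
#' @export
evaluate_ratings <- function(ratings) {
  stopifnot(inherits(ratings, "rating_matrix"))
  rating_truth(ratings)
  acc <- score_ratings(ratings)
  n_items <- acc$n_items[[1L]]
  k <- length(attr(ratings, "labels"))
  chance <- chance_level(n_items, k)
  test <- if (nrow(acc) >= 2) one_sample_t(acc$n_correct, mu0 = chance)
          else NULL
  structure(
    list(accuracy = acc,
         summary = list(n_items = n_items, n_raters = nrow(acc),
                        mean_correct = mean(acc$n_correct),
                        sd_correct = stats::sd(acc$n_correct),
                        mean_pct = mean(acc$pct), sd_pct = stats::sd(acc$pct)),
         confusion = confusion_matrix(ratings),
         kappa = fleiss_kappa(ratings),
         chance = chance,
         chance_test = test),
    class = "psychometric_report")
}
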