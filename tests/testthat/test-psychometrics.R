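make_rm <- function(video_id, rater_id, response, truth = NULL,
                    labels = c("Normal", "How", "What")) {
  df <- data.frame(video_id = video_id, rater_id = rater_id,
                   response = response, stringsAsFactors = FALSE)
  if (!is.null(truth)) df$truth <- truth
  rating_matrix(df, labels = labels)
}

test_that("per-rater accuracy counts and percentages are consistent", {
  rm <- make_rm(rep(c("a", "b", "c"), 2),
                rep(c("r1", "r2"), each = 3),
                c("Normal", "How", "What", "Normal", "Normal", "What"),
                truth = rep(c("Normal", "How", "What"), 2))
  acc <- score_ratings(rm)
  expect_equal(acc$n_correct[acc$rater_id == "r1"], 3L)
  expect_equal(acc$pct[acc$rater_id == "r1"], 100)
  expect_equal(acc$n_correct[acc$rater_id == "r2"], 2L)
  expect_equal(acc$pct[acc$rater_id == "r2"], 200/3)
  # percentage x n_items / 100 recovers the count for every rater
  expect_equal(acc$pct * acc$n_items / 100, as.numeric(acc$n_correct))
  # a fractional mean count converts the same way: 119.63 of 135 -> 88.61%
  expect_equal(round(accuracy_percentage(119.63, 135), 2), 88.61)
  expect_error(score_ratings(make_rm("a", "r1", "Normal")), "truth")
  expect_error(rating_matrix(data.frame(video_id = "a", rater_id = "r",
                                        response = "Weird")), "label")
})

test_that("confusion matrices count (truth, assigned) pairs and conserve totals", {
  rm <- make_rm(rep("a", 2), c("r1", "r2"), c("Normal", "How"),
                truth = rep("Normal", 2))
  cm <- confusion_matrix(rm)
  expect_equal(unname(cm["Normal", ]), c(1, 1, 0))
  expect_equal(sum(cm), 2)
  # perfect raters give a diagonal matrix
  truth <- rep(c("Normal", "How", "What"), each = 2)
  perfect <- make_rm(rep(sprintf("v%d", 1:6), 2),
                     rep(c("r1", "r2"), each = 6),
                     rep(truth, 2), truth = rep(truth, 2))
  cmp <- confusion_matrix(perfect)
  expect_equal(unname(diag(cmp)), c(4, 4, 4))
  expect_equal(sum(cmp) - sum(diag(cmp)), 0)
  # per-item matrices sum to the overall matrix
  per <- confusion_matrix(perfect, per_item = TRUE)
  expect_equal(Reduce(`+`, per), cmp)
  expect_equal(sum(cmp), 12)  # items x raters
})

test_that("Fleiss' kappa matches hand-computed and boundary cases", {
  # unanimous raters on every item
  rm1 <- make_rm(rep(c("a", "b"), each = 3), rep(c("r1", "r2", "r3"), 2),
                 c(rep("Normal", 3), rep("What", 3)))
  expect_equal(fleiss_kappa(rm1)$kappa, 1)
  # 2 items x 3 raters, votes (A,A,B) and (B,B,B); by hand:
  # P1 = 1/3, P2 = 1, Pbar = 2/3, Pe = (1/3)^2 + (2/3)^2 = 5/9, kappa = 0.25
  rm2 <- make_rm(rep(c("a", "b"), each = 3), rep(c("r1", "r2", "r3"), 2),
                 c("Normal", "Normal", "How", "How", "How", "How"))
  k2 <- fleiss_kappa(rm2)
  expect_equal(k2$kappa, 0.25)
  expect_equal(k2$mean_agreement, 2/3)
  expect_equal(k2$expected_agreement, 5/9)
  expect_equal(k2$per_item_agreement, c(1/3, 1))
  expect_equal(sum(k2$category_proportions), 1)
  # count-matrix entry point agrees
  counts <- rbind(c(2, 1, 0), c(0, 3, 0))
  expect_equal(fleiss_kappa(counts)$kappa, 0.25)
  # all mass in one category: flagged undefined, not an error
  rm3 <- make_rm(rep(c("a", "b"), each = 2), rep(c("r1", "r2"), 2),
                 rep("Normal", 4))
  expect_true(fleiss_kappa(rm3)$undefined)
  expect_true(is.na(fleiss_kappa(rm3)$kappa))
  expect_error(fleiss_kappa(make_rm(c("a", "a", "b"), c("r1", "r2", "r1"),
                                    rep("Normal", 3))),
               "same number")
})

test_that("kappa is invariant under relabeling of the categories", {
  spec <- synthetic_rating_spec(n_items = 40, n_raters = 6, seed = 21)
  rm <- make_ratings(spec)
  k0 <- fleiss_kappa(rm)$kappa
  perm <- c(Normal = "What", How = "Normal", What = "How")
  rm2 <- rating_matrix(
    data.frame(video_id = rm$video_id, rater_id = rm$rater_id,
               response = unname(perm[as.character(rm$response)]),
               stringsAsFactors = FALSE))
  expect_equal(fleiss_kappa(rm2)$kappa, k0)
})

test_that("the chance level is items over categories", {
  expect_equal(chance_level(135, 3), 45)
  expect_equal(chance_level(10, 4), 2.5)
  expect_error(chance_level(10, 1), "k_categories")
  expect_error(chance_level(0, 3), "n_items")
})

test_that("one-sample t from raw values matches t.test and summary mode", {
  set.seed(5)
  x <- rnorm(51, mean = 119, sd = 10)
  mine <- one_sample_t(x, mu0 = 45)
  ref <- t.test(x, mu = 45)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$ci, unname(as.vector(ref$conf.int)), tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter))
  # raw mode and summary mode agree to 10 significant digits
  summ <- one_sample_t(mu0 = 45, mean = mean(x), sd = sd(x), n = length(x))
  expect_equal(summ$t, mine$t, tolerance = 1e-10)
  expect_equal(summ$ci, mine$ci, tolerance = 1e-10)
  expect_equal(summ$d, mine$d, tolerance = 1e-10)
  # hand-computed case: values 1..3 against 0 -> t = 2 / (1/sqrt(3))
  hand <- one_sample_t(c(1, 2, 3), mu0 = 0)
  expect_equal(hand$t, 2 * sqrt(3), tolerance = 1e-12)
  # mu0 at the sample mean: t = d = 0
  null <- one_sample_t(c(1, 2, 3), mu0 = 2)
  expect_equal(null$t, 0); expect_equal(null$d, 0)
  expect_true(mine$ci[1] < mean(x) && mean(x) < mine$ci[2])
  # zero variance flags a degenerate result
  flat <- one_sample_t(c(2, 2, 2), mu0 = 0)
  expect_true(flat$degenerate); expect_true(is.na(flat$t))
  expect_error(one_sample_t(1, mu0 = 0), "2 values")
})

test_that("frame counts convert to seconds by the frame rate", {
  expect_equal(frames_to_seconds(3, 60), 0.05)
  expect_equal(frames_to_seconds(0, 60), 0)
  expect_equal(frames_to_seconds(81, 60), 1.35)
  expect_error(frames_to_seconds(10, 0), "fps")
})

test_that("evaluate_ratings bundles accuracy, confusion, kappa and the chance test", {
  rm <- make_ratings(synthetic_rating_spec(n_items = 30, n_raters = 8,
                                           seed = 4))
  rep <- evaluate_ratings(rm)
  expect_equal(rep$summary$n_items, 30)
  expect_equal(rep$summary$n_raters, 8)
  expect_equal(rep$chance, 10)
  expect_equal(sum(rep$confusion), 240)
  expect_equal(rep$chance_test$mu0, 10)
  expect_s3_class(rep$kappa, "kappa_result")
  # round trip through CSV
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ratings.csv")
  write_ratings(rm, path)
  back <- read_ratings(path)
  expect_equal(as.data.frame(back), as.data.frame(rm))
})
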