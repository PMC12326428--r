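test_that("window features match closed-form values on crafted windows", {
  f <- extract_features(constant_window(0, 0, 1))
  expect_equal(unname(f[c("mean_x", "mean_y", "mean_z")]), c(0, 0, 1))
  expect_equal(unname(f[c("sd_x", "sd_y", "sd_z", "mad")]), rep(0, 4))
  expect_equal(unname(f[c("min_z", "max_z")]), c(1, 1))

  # alternating +/- a heave: SD via the direct two-pass formula
  a <- 0.3
  z <- rep(c(a, -a), length.out = 25)
  w <- constant_window(0, 0, 0)
  w$az <- z
  f2 <- extract_features(w)
  sd_oracle <- sqrt(sum((z - sum(z) / 25)^2) / 24)
  expect_equal(unname(f2["sd_z"]), sd_oracle)
  expect_equal(unname(f2["mean_z"]), a / 25)

  # features are stateless: shifting the window timestamps changes nothing
  w2 <- w
  w2$t <- w2$t + 1234
  expect_identical(extract_features(w), extract_features(w2))
  expect_error(extract_features(w[1:10, ]), "exactly 25")
})

test_that("accel_features matches extract_features window by window", {
  sch <- manual_schedule(c("flying", "non_flying"), c(3, 2))
  a <- synth_acceleration(sch, seed = 8)
  fw <- accel_features(a)
  expect_equal(nrow(fw$features), 5L)
  for (k in c(1, 3, 5)) {
    rows <- ((k - 1) * 25 + 1):(k * 25)
    expect_equal(fw$features[k, ], extract_features(a[rows, ]))
  }
})

test_that("CART finds separable splits and pure inputs give one leaf", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c("a", "a", "a", "b", "b", "b")
  tree <- train_tree(x, y, max_depth = 3)
  expect_equal(nrow(tree$nodes), 3L)              # one split, two leaves
  expect_equal(tree$nodes$threshold[1], 6.5)      # midpoint
  expect_equal(predict(tree, x), y)

  expect_warning(t2 <- train_tree(x, rep("a", 6)), "single-class")
  expect_equal(nrow(t2$nodes), 1L)
  expect_equal(predict(t2, x), rep("a", 6))
})

test_that("XOR needs depth 2; depth-1 accuracy equals the enumeration oracle", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)[rep(1:4, 2), ]
  y <- c("A", "B", "B", "A")[rep(1:4, 2)]
  oracle1 <- depth1_accuracy_oracle(x, y)
  t1 <- train_tree(x, y, max_depth = 1)
  expect_equal(mean(predict(t1, x) == y), oracle1)   # 0.5 for balanced XOR
  expect_equal(oracle1, 0.5)
  t2 <- train_tree(x, y, max_depth = 2)
  expect_equal(mean(predict(t2, x) == y), 1.0)
})

test_that("prediction uses the <=-goes-left convention at the threshold", {
  x <- matrix(c(1, 2, 3, 10, 11, 12), ncol = 1)
  y <- c("a", "a", "a", "b", "b", "b")
  tree <- train_tree(x, y)
  thr <- tree$nodes$threshold[1]
  expect_equal(predict(tree, matrix(thr, ncol = 1)), "a")
  expect_equal(predict(tree, matrix(thr + 1e-9, ncol = 1)), "b")
})

test_that("tie-breaking picks the lowest feature index and threshold", {
  # two identical perfectly separating features: feature 1 must win
  x <- cbind(f1 = c(0, 0, 1, 1), f2 = c(0, 0, 1, 1))
  y <- c("a", "a", "b", "b")
  tree <- train_tree(x, y)
  expect_equal(tree$nodes$feature[1], 1L)
})

test_that("classifier metrics match hand-computed and brute-force oracles", {
  # exact identity
  r0 <- classifier_report(c("flying", "non_flying"), c("flying", "non_flying"))
  expect_equal(unname(r0$macro), c(1, 1, 1))
  expect_false(r0$zero_division)

  # TP=91, FN=9, FP=1, TN=99 for the flying class
  pred <- c(rep("flying", 91), rep("non_flying", 9),
            rep("flying", 1), rep("non_flying", 99))
  truth <- c(rep("flying", 100), rep("non_flying", 100))
  r <- classifier_report(pred, truth)
  flying <- r$per_class[r$per_class$class == "flying", ]
  expect_equal(round(flying$precision, 3), 0.989)
  expect_equal(round(flying$recall, 3), 0.910)
  expect_equal(round(flying$f1, 3), 0.948)

  # swapping class roles swaps rows, macro unchanged
  swap <- function(x) ifelse(x == "flying", "non_flying", "flying")
  r_sw <- classifier_report(swap(pred), swap(truth))
  expect_equal(r_sw$macro, r$macro)
  expect_equal(r_sw$per_class$f1[r_sw$per_class$class == "non_flying"],
               r$per_class$f1[r$per_class$class == "flying"])

  # brute-force oracle on random labels (including zero-division paths)
  set.seed(301)
  p2 <- sample(c("flying", "non_flying"), 500, replace = TRUE, c(0.9, 0.1))
  t2 <- sample(c("flying", "non_flying"), 500, replace = TRUE)
  bf <- brute_force_report(p2, t2)
  r2 <- classifier_report(p2, t2)
  for (cl in names(bf))
    expect_equal(unlist(r2$per_class[r2$per_class$class == cl,
                                     c("precision", "recall", "f1")]),
                 bf[[cl]], ignore_attr = TRUE)
  expect_error(classifier_report(character(0), character(0)), "empty")
})

test_that("model text serialization round-trips exactly", {
  b <- synth_bundle(120, seed = 51, include_mask = FALSE,
                    mean_fly_bout = 30, mean_rest_bout = 30)
  model <- train_behaviour_classifier(b, max_depth = 3, min_leaf = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_tree(model, path)
  model2 <- read_tree(path)
  set.seed(77)
  probes <- matrix(rnorm(1000 * 13), ncol = 13,
                   dimnames = list(NULL, names(extract_features(constant_window()))))
  expect_identical(predict(model, probes), predict(model2, probes))
  expect_identical(model$nodes$threshold, model2$nodes$threshold)

  leaf <- suppressWarnings(train_tree(matrix(1:4, ncol = 1), rep("x", 4)))
  expect_equal(length(format_tree(leaf)), 3L + 1L)   # headers + 1 node line
})

test_that("a hand-written 3-node model file predicts by manual descent", {
  txt <- c("# flat_tree v1",
           "# classes: flying,non_flying",
           "id,feature,threshold,left,right,class",
           "1,2,0.25,2,3,NA",
           "2,NA,NA,NA,NA,non_flying",
           "3,NA,NA,NA,NA,flying")
  model <- read_tree(text = txt)
  probe_lo <- c(f1 = 9, f2 = 0.1)   # feature 2 <= 0.25 -> left
  probe_hi <- c(f1 = -9, f2 = 0.4)
  expect_equal(predict(model, probe_lo), "non_flying")
  expect_equal(predict(model, probe_hi), "flying")
  bad <- txt
  bad[5] <- "2,NA,NA,NA,non_flying"
  expect_error(read_tree(text = bad), "line 5")
})

test_that("training accuracy matches rpart on clean separable features", {
  skip_if_not_installed("rpart")
  b <- synth_bundle(300, seed = 61, include_mask = FALSE,
                    mean_fly_bout = 60, mean_rest_bout = 60)
  fw <- accel_features(b$accel)
  lab <- schedule_second_labels(b$schedule)[seq_along(fw$t_start)]
  ours <- train_tree(fw$features, lab, max_depth = 3, min_leaf = 5)
  acc_ours <- mean(predict(ours, fw$features) == lab)
  df <- data.frame(fw$features, lab = factor(lab))
  ref <- rpart::rpart(lab ~ ., df, method = "class",
                      control = rpart::rpart.control(maxdepth = 3,
                                                     minbucket = 5, cp = 0))
  acc_ref <- mean(predict(ref, df, type = "class") == lab)
  expect_equal(acc_ours, acc_ref)
  expect_gte(acc_ours, 0.98)
})
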