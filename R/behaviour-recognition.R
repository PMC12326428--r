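FEATURE_NAMES <- c("mean_x", "mean_y", "mean_z", "sd_x", "sd_y", "sd_z",
                   "min_x", "min_y", "min_z", "max_x", "max_y", "max_z",
                   "mad")

#' Per-second feature extraction from a 25 Hz acceleration stream
#'
#' Slices the stream into non-overlapping 1-s windows of exactly 25 samples
#' and computes, per window: per-axis mean, SD, min and max, plus the mean
#' absolute dynamic acceleration (`mad`) — the mean over axes and samples of
#' |sample − axis window mean|. These are the light-weight statistics an
#' on-board classifier can afford at 64 MHz.
#'
#' @param accel Data frame `t, ax, ay, az` at 25 Hz.
#' @param fs Sampling rate (25 Hz).
#' @return List with `t_start` (window start times) and `features`
#'   (numeric matrix, one row per window, one column per feature).
#' @export
accel_features <- function(accel, fs = 25) {
  n_win <- floor(nrow(accel) / fs)
  if (n_win < 1L) stop("need at least one full ", fs, "-sample window")
  used <- n_win * fs
  axm <- matrix(accel$ax[seq_len(used)], nrow = fs)
  aym <- matrix(accel$ay[seq_len(used)], nrow = fs)
  azm <- matrix(accel$az[seq_len(used)], nrow = fs)
  colsd <- function(m) {
    mu <- colMeans(m)
    sqrt(colSums((t(t(m) - mu))^2) / (fs - 1))
  }
  dyn <- function(m) colMeans(abs(t(t(m) - colMeans(m))))
  f <- cbind(colMeans(axm), colMeans(aym), colMeans(azm),
             colsd(axm), colsd(aym), colsd(azm),
             apply(axm, 2, min), apply(aym, 2, min), apply(azm, 2, min),
             apply(axm, 2, max), apply(aym, 2, max), apply(azm, 2, max),
             (dyn(axm) + dyn(aym) + dyn(azm)) / 3)
  colnames(f) <- FEATURE_NAMES
  list(t_start = accel$t[seq(1, used, by = fs)], features = f)
}

#' Feature vector for one 1-s acceleration window
#'
#' @param window Data frame (or matrix with columns ax, ay, az) of exactly
#'   25 samples.
#' @param fs Samples per window (25).
#' @return Named numeric vector of the 13 window features.
#' @export
extract_features <- function(window, fs = 25) {
  if (is.matrix(window)) window <- as.data.frame(window)
  if (nrow(window) != fs)
    stop("window must contain exactly ", fs, " samples, got ", nrow(window))
  if (is.null(window$t)) window$t <- (seq_len(fs) - 1) / fs
  accel_features(window, fs = fs)$features[1L, ]
}

# Gini impurity of class counts.
gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best split of rows `idx` by exhaustive feature x midpoint-threshold search.
# Returns NULL when no split leaves >= min_leaf on both sides. Ties are
# broken by lowest feature index then lowest threshold; splits are accepted
# even at zero impurity decrease (a node splits whenever it is impure and a
# valid split exists).
best_split <- function(x, y_int, n_class, idx, min_leaf) {
  best <- NULL
  n <- length(idx)
  for (j in seq_len(ncol(x))) {
    v <- x[idx, j]
    o <- order(v)
    vs <- v[o]
    ys <- y_int[idx][o]
    distinct <- which(diff(vs) > 0)         # split after position i
    if (!length(distinct)) next
    counts <- matrix(0L, nrow = n, ncol = n_class)
    counts[cbind(seq_len(n), ys)] <- 1L
    cum <- apply(counts, 2, cumsum)
    tot <- cum[n, ]
    for (i in distinct) {
      if (i < min_leaf || n - i < min_leaf) next
      left <- cum[i, ]
      right <- tot - left
      w <- (i * gini(left) + (n - i) * gini(right)) / n
      thr <- (vs[i] + vs[i + 1]) / 2
      if (is.null(best) || w < best$impurity - 1e-12) {
        best <- list(feature = j, threshold = thr, impurity = w,
                     left_idx = idx[o][seq_len(i)],
                     right_idx = idx[o][(i + 1):n])
      }
    }
  }
  best
}

#' Train a compact CART decision tree (Gini impurity)
#'
#' Flat-array CART emulating an on-board behaviour classifier: exhaustive
#' best-split search over feature x midpoint thresholds, Gini impurity,
#' deterministic tie-breaking (lowest feature index, then lowest threshold),
#' `<=` goes left. Nodes split whenever impure and a valid split exists,
#' subject to `max_depth` and `min_leaf`. Training is fully deterministic
#' given its inputs; `seed` is accepted for interface symmetry only.
#'
#' @param x Numeric feature matrix (rows = examples).
#' @param y Class labels (character/factor); leaf majorities break ties
#'   toward the lexicographically smallest class.
#' @param max_depth Maximum root-to-leaf depth (root = depth 0); default 3,
#'   a plausibility cap for a microcontroller target.
#' @param min_leaf Minimum examples per leaf.
#' @param seed Unused (training is deterministic); kept in the signature.
#' @return A `flat_tree`: list with `nodes` (data frame `id, feature,
#'   threshold, left, right, class`; `feature` is `NA` at leaves) and
#'   `classes`.
#' @export
train_tree <- function(x, y, max_depth = 3, min_leaf = 1, seed = NULL) {
  x <- as.matrix(x)
  y <- as.character(y)
  if (nrow(x) != length(y)) stop("x and y lengths differ")
  if (max_depth < 1) stop("`max_depth` must be >= 1")
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    warning("single-class input: degenerate single-leaf tree")
  } else if (min(table(y)) < 2L) {
    stop("need at least 2 examples per class")
  }
  y_int <- match(y, classes)
  n_class <- length(classes)

  nodes <- new.env()
  nodes$df <- list()
  add_node <- function() {
    id <- length(nodes$df) + 1L
    nodes$df[[id]] <- list(id = id, feature = NA_integer_,
                           threshold = NA_real_, left = NA_integer_,
                           right = NA_integer_, class = NA_character_)
    id
  }
  majority <- function(idx) {
    counts <- tabulate(y_int[idx], n_class)
    classes[which.max(counts)]   # first max -> lexicographically smallest
  }
  grow <- function(idx, depth) {
    id <- add_node()
    counts <- tabulate(y_int[idx], n_class)
    pure <- sum(counts > 0L) <= 1L
    sp <- NULL
    if (!pure && depth < max_depth && length(idx) >= 2L * min_leaf)
      sp <- best_split(x, y_int, n_class, idx, min_leaf)
    if (is.null(sp)) {
      nodes$df[[id]]$class <- majority(idx)
    } else {
      l <- grow(sp$left_idx, depth + 1L)
      r <- grow(sp$right_idx, depth + 1L)
      nodes$df[[id]]$feature <- sp$feature
      nodes$df[[id]]$threshold <- sp$threshold
      nodes$df[[id]]$left <- l
      nodes$df[[id]]$right <- r
    }
    id
  }
  grow(seq_along(y), 0L)
  df <- do.call(rbind, lapply(nodes$df, function(n)
    data.frame(n, stringsAsFactors = FALSE)))
  structure(list(nodes = df, classes = classes,
                 feature_names = colnames(x)), class = "flat_tree")
}

#' Predict classes with a flat decision tree
#'
#' Deterministic descent: a sample goes left when
#' `feature value <= threshold`.
#'
#' @param object A [train_tree()] model.
#' @param newdata Numeric matrix (or single named vector) of features whose
#'   columns match the training matrix.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.flat_tree <- function(object, newdata, ...) {
  nd <- object$nodes
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL, names(newdata)))
  newdata <- as.matrix(newdata)
  if (any(nd$feature > ncol(newdata), na.rm = TRUE))
    stop("invalid model: feature index exceeds feature count")
  node <- rep(1L, nrow(newdata))
  repeat {
    leaf <- is.na(nd$feature[node])
    if (all(leaf)) break
    i <- which(!leaf)
    k <- node[i]
    goleft <- newdata[cbind(i, nd$feature[k])] <= nd$threshold[k]
    node[i] <- ifelse(goleft, nd$left[k], nd$right[k])
  }
  nd$class[node]
}

#' Confusion matrix and precision/recall/F1 report
#'
#' Per-class precision TP/(TP+FP), recall TP/(TP+FN) and F1 (harmonic mean),
#' plus their unweighted macro averages. A zero denominator yields metric 0
#' and sets the `zero_division` flag.
#'
#' @param predicted,truth Equal-length label vectors.
#' @param classes Optional class ordering; default sorted union.
#' @return A `classifier_report`: list with `confusion` (classes x classes,
#'   rows = truth), `per_class` data frame, `macro` named vector and
#'   `zero_division` flag.
#' @export
classifier_report <- function(predicted, truth, classes = NULL) {
  if (length(predicted) == 0L) stop("empty input")
  if (length(predicted) != length(truth)) stop("label lengths differ")
  classes <- classes %||% sort(unique(c(predicted, truth)))
  cm <- table(truth = factor(truth, classes),
              predicted = factor(predicted, classes))
  cm <- matrix(as.integer(cm), nrow = length(classes),
               dimnames = list(truth = classes, predicted = classes))
  zero_div <- FALSE
  safe_div <- function(num, den) {
    if (den == 0) { zero_div <<- TRUE; return(0) }
    num / den
  }
  per <- lapply(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    p <- safe_div(tp, tp + fp)
    r <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * p * r, p + r)
    c(precision = p, recall = r, f1 = f1)
  })
  per <- data.frame(class = classes, do.call(rbind, per),
                    stringsAsFactors = FALSE)
  macro <- c(precision = mean(per$precision), recall = mean(per$recall),
             f1 = mean(per$f1))
  structure(list(confusion = cm, per_class = per, macro = macro,
                 zero_division = zero_div), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report>\n")
  print(x$confusion)
  print(x$per_class, row.names = FALSE, digits = 3)
  cat(sprintf("macro: precision %.3f  recall %.3f  F1 %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

#' Serialize / load a flat decision tree as plain text
#'
#' One line per node, comma-separated, fixed column order
#' `id,feature,threshold,left,right,class` after a format header; leaves
#' carry `NA` feature/threshold/children. Round-trips exactly.
#'
#' @param model A `flat_tree`.
#' @param path File path; `format_tree` returns the lines instead.
#' @return `read_tree` returns a `flat_tree`; writers return the path
#'   invisibly.
#' @export
write_tree <- function(model, path) {
  writeLines(format_tree(model), path)
  invisible(path)
}

#' @rdname write_tree
#' @export
format_tree <- function(model) {
  nd <- model$nodes
  c("# flat_tree v1",
    paste0("# classes: ", paste(model$classes, collapse = ",")),
    "id,feature,threshold,left,right,class",
    sprintf("%d,%s,%s,%s,%s,%s", nd$id,
            ifelse(is.na(nd$feature), "NA", nd$feature),
            ifelse(is.na(nd$threshold), "NA",
                   formatC(nd$threshold, digits = 17, format = "g")),
            ifelse(is.na(nd$left), "NA", nd$left),
            ifelse(is.na(nd$right), "NA", nd$right),
            ifelse(is.na(nd$class), "NA", nd$class)))
}

#' @rdname write_tree
#' @param text Character vector of lines (alternative to `path`).
#' @export
read_tree <- function(path, text = NULL) {
  lines <- text %||% readLines(path)
  if (length(lines) < 4L || lines[1] != "# flat_tree v1")
    stop("not a flat_tree v1 file")
  classes <- strsplit(sub("^# classes: ", "", lines[2]), ",")[[1]]
  if (lines[3] != "id,feature,threshold,left,right,class")
    stop("malformed header at line 3")
  rows <- lapply(seq_along(lines[-(1:3)]) + 3L, function(ln) {
    parts <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    if (length(parts) != 6L)
      stop("parse error at line ", ln, ": expected 6 fields, got ",
           length(parts))
    num <- suppressWarnings(as.numeric(parts[c(1:5)]))
    if (any(is.na(num) & parts[1:5] != "NA"))
      stop("parse error at line ", ln, ": non-numeric field")
    data.frame(id = as.integer(num[1]), feature = as.integer(num[2]),
               threshold = num[3], left = as.integer(num[4]),
               right = as.integer(num[5]),
               class = ifelse(parts[6] == "NA", NA_character_, parts[6]),
               stringsAsFactors = FALSE)
  })
  structure(list(nodes = do.call(rbind, rows), classes = classes,
                 feature_names = NULL), class = "flat_tree")
}

#' Train a behaviour classifier from a labelled sensor bundle
#'
#' Convenience wrapper: extracts per-second features from the bundle's
#' acceleration stream, labels them from the ground-truth schedule and
#' trains a [train_tree()] model.
#'
#' @param bundle A [synth_bundle()] result.
#' @param max_depth,min_leaf Passed to [train_tree()].
#' @return A `flat_tree`.
#' @export
train_behaviour_classifier <- function(bundle, max_depth = 3, min_leaf = 5) {
  fw <- accel_features(bundle$accel)
  labels <- schedule_second_labels(bundle$schedule)[seq_along(fw$t_start)]
  train_tree(fw$features, labels, max_depth = max_depth, min_leaf = min_leaf)
}
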