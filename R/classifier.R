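#' Random-forest classifier configuration
#'
#' Defaults follow the tuned analysis settings: 2500 trees, 20 candidate
#' features per split, 75/25 train/test split. `max_cat` is the maximum
#' category cardinality kept as a factor (larger categoricals would be
#' one-hot encoded upstream); per-offset base identities have 4 levels and
#' are kept categorical.
#'
#' @param n_trees number of trees (default 2500).
#' @param mtry candidate features per split (default 20; capped at the number
#'   of available features).
#' @param train_fraction training proportion of loci (default 0.75).
#' @param max_cat maximum factor cardinality kept categorical (default 4).
#' @param seed integer seed for the split and the forest.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(n_trees = 2500, mtry = 20, train_fraction = 0.75,
                              max_cat = 4, seed = 1) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                 train_fraction = train_fraction, max_cat = as.integer(max_cat),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# model frame from a feature table: label as factor, features only, complete
# rows; factors above max_cat cardinality are one-hot encoded
.feature_frame <- function(table, max_cat = 4) {
  meta <- c("gene_id", "chrom", "pos", "strand", "edge_flag")
  df <- table[, setdiff(names(table), meta), drop = FALSE]
  if (!"label" %in% names(df)) stop("feature table has no label column")
  df$label <- factor(df$label, levels = c("control", "real"))
  for (f in setdiff(names(df), "label")) {
    if (is.character(df[[f]])) df[[f]] <- factor(df[[f]])
    if (is.factor(df[[f]]) && nlevels(df[[f]]) > max_cat) {
      lv <- levels(df[[f]])
      for (l in lv) df[[paste0(f, "_", l)]] <- as.numeric(df[[f]] == l)
      df[[f]] <- NULL
    }
  }
  keep <- complete.cases(df)
  list(df = df[keep, , drop = FALSE],
       genes = table$gene_id[keep],
       dropped = sum(!keep))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic with
#' tie averaging, so it is invariant to any strictly monotone transform of
#' the scores.
#'
#' @param scores numeric predicted scores (higher = more positive).
#' @param labels logical or 0/1 vector of true classes.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n2 <- sum(!labels)
  if (n1 == 0 || n2 == 0) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# ROC curve points (FPR, TPR), from (0,0) to (1,1)
.roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(labels[ord]) / sum(labels)
  fpr <- cumsum(!labels[ord]) / sum(!labels)
  data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
}

# gene-level split: loci of one gene never straddle train/test
.gene_split <- function(genes, train_fraction, seed) {
  set.seed(seed)
  gs <- sample(unique(genes))
  sizes <- table(genes)[gs]
  ntrain_target <- train_fraction * length(genes)
  train_genes <- gs[cumsum(sizes) <= ntrain_target]
  if (!length(train_genes)) train_genes <- gs[1]
  genes %in% train_genes
}

#' Train and evaluate a pause classifier
#'
#' Fits a random forest (randomForest engine, out-of-bag bookkeeping enabled)
#' on a `train_fraction` split of loci, stratified at the gene level so loci
#' from one gene never straddle train and test, and evaluates the held-out
#' AUC by the rank statistic over predicted probabilities.
#'
#' @param table feature table from [assemble_features()].
#' @param config A [classifier_config()].
#' @return List of class `pause_classifier_eval`: `auc`, `roc` (data frame),
#'   `importance` (per-feature mean decrease in accuracy, OOB), `model`,
#'   `n_train`, `n_test`, `dropped` (incomplete rows removed).
#' @export
train_and_evaluate <- function(table, config = classifier_config()) {
  ff <- .feature_frame(table, config$max_cat)
  df <- ff$df
  if (nlevels(droplevels(df$label)) < 2) stop("feature table has a single class")
  in_train <- .gene_split(ff$genes, config$train_fraction, config$seed)
  train <- df[in_train, , drop = FALSE]
  test <- df[!in_train, , drop = FALSE]
  if (!nrow(test) || nlevels(droplevels(test$label)) < 2)
    stop("held-out split lacks both classes; provide more genes")
  set.seed(config$seed)
  fit <- randomForest::randomForest(
    label ~ ., data = train, ntree = config$n_trees,
    mtry = min(config$mtry, ncol(train) - 1L), importance = TRUE)
  prob <- predict(fit, newdata = test, type = "prob")[, "real"]
  auc <- auc_rank(prob, test$label == "real")
  structure(list(auc = auc,
                 roc = .roc_points(prob, test$label == "real"),
                 importance = permutation_importance(fit),
                 model = fit, n_train = nrow(train), n_test = nrow(test),
                 dropped = ff$dropped),
            class = "pause_classifier_eval")
}

#' @export
print.pause_classifier_eval <- function(x, ...) {
  cat(sprintf("<pause_classifier_eval> held-out AUC = %.3f (train %d, test %d loci)\n",
              x$auc, x$n_train, x$n_test))
  invisible(x)
}

#' Out-of-bag permutation feature importance
#'
#' Mean decrease in accuracy over out-of-bag predictions when a feature is
#' permuted after training but before prediction, averaged over trees
#' (unscaled).
#'
#' @param model a fitted `randomForest` with `importance = TRUE`.
#' @return Named numeric vector, one value per feature.
#' @export
permutation_importance <- function(model) {
  imp <- randomForest::importance(model, type = 1, scale = FALSE)
  setNames(imp[, 1], rownames(imp))
}

#' Cross-strain transfer-of-learning AUC matrix
#'
#' Off-diagonal cells: a forest trained on 100% of one strain's real and
#' control loci, tested on all loci of another strain. Diagonal cells: the
#' strain's own held-out AUC from its 75/25 split (the within-strain
#' convention).
#'
#' @param tables named list of feature tables, one per strain, with
#'   compatible feature columns.
#' @param config A [classifier_config()].
#' @return Numeric strain x strain matrix (rows = training strain).
#' @export
transfer_matrix <- function(tables, config = classifier_config()) {
  strains <- names(tables)
  cols <- lapply(tables, function(t) sort(names(t)))
  for (s in strains[-1]) {
    if (!identical(cols[[1]], cols[[s]])) {
      bad <- c(setdiff(cols[[1]], cols[[s]]), setdiff(cols[[s]], cols[[1]]))
      stop("feature-column mismatch between strains '", strains[1], "' and '",
           s, "': ", paste(bad, collapse = ", "))
    }
  }
  m <- matrix(NA_real_, length(strains), length(strains),
              dimnames = list(train = strains, test = strains))
  frames <- lapply(tables, .feature_frame, max_cat = config$max_cat)
  for (a in strains) {
    set.seed(config$seed)
    full <- randomForest::randomForest(
      label ~ ., data = frames[[a]]$df, ntree = config$n_trees,
      mtry = min(config$mtry, ncol(frames[[a]]$df) - 1L))
    for (b in strains) {
      if (a == b) {
        m[a, b] <- train_and_evaluate(tables[[a]], config)$auc
      } else {
        prob <- predict(full, newdata = frames[[b]]$df, type = "prob")[, "real"]
        m[a, b] <- auc_rank(prob, frames[[b]]$df$label == "real")
      }
    }
  }
  m
}
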