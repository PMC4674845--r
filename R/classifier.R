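# Site classification: labeled training sets from simulation truth or an
# annotation table, seeded stratified 10-fold cross-validated grid search
# over (C, gamma), and deterministic prediction.

#' Build a labeled training set of candidate sites
#'
#' In simulation mode (`truth` given) a candidate site is labeled 1 when it
#' lies within `slack` bp of a truth junction boundary of the same direction,
#' else 0; every candidate is kept. In annotation mode (`annotation` given)
#' positives are annotated sites with nonzero coverage around them (an
#' annotated site in a silent region is not expressed in the sample and must
#' not be treated as true); an equal number of negatives is then sampled,
#' seeded, from covered candidate sites not in the annotation.
#'
#' @param features Feature table from [compute_features()].
#' @param truth Truth junction table (`contig`, `donor_pos`, `acceptor_pos`)
#'   for simulation mode.
#' @param annotation Annotation table (`contig`, `pos`, `direction`) for
#'   annotation mode.
#' @param track Coverage track (annotation mode coverage check).
#' @param slack Positive-label matching slack in bp (default 10, the site
#'   merge distance).
#' @param l Coverage-check window in bp (default 25).
#' @param seed Seed for negative sampling (default 42).
#' @return `data.table` with the four normalized features and a `label`
#'   column in `{0, 1}`.
#' @export
build_training_set <- function(features, truth = NULL, annotation = NULL,
                               track = NULL, slack = 10L, l = 25L, seed = 42L) {
  if (is.null(truth) == is.null(annotation))
    stop("provide exactly one of `truth` (simulation) or `annotation`")
  fx <- copy(features)
  if (!is.null(truth)) {
    fx[, label := as.integer(site_is_true(contig, pos, direction, truth, slack))]
  } else {
    if (is.null(track)) stop("annotation mode needs the coverage track")
    ann <- as.data.table(annotation)
    cov_ok <- vapply(seq_len(nrow(fx)), function(i) {
      d <- track[[fx$contig[i]]]
      region_mean(d, fx$pos[i] - l, fx$pos[i] + l) > 0
    }, logical(1))
    annotated <- vapply(seq_len(nrow(fx)), function(i) {
      nrow(ann[contig == fx$contig[i] & direction == fx$direction[i] &
                 abs(pos - fx$pos[i]) <= slack]) > 0
    }, logical(1))
    pos_idx <- which(annotated & cov_ok)
    neg_pool <- which(!annotated & cov_ok)
    if (length(pos_idx) == 0L) stop("no positive examples")
    if (length(neg_pool) < length(pos_idx))
      stop("not enough covered non-annotated sites to balance the classes")
    set.seed(seed)
    neg_idx <- sort(sample(neg_pool, length(pos_idx)))
    fx <- fx[c(pos_idx, neg_idx)]
    fx[, label := rep(c(1L, 0L), c(length(pos_idx), length(neg_idx)))]
  }
  if (sum(fx$label == 1L) == 0L) stop("no positive examples")
  fx[]
}

# is each site within `slack` of a truth boundary of matching direction?
site_is_true <- function(contig, pos, direction, truth, slack) {
  tr_contig <- truth$contig
  tr_donor <- truth$donor_pos
  tr_acceptor <- truth$acceptor_pos
  vapply(seq_along(pos), function(i) {
    on_ct <- tr_contig == contig[i]
    b <- if (direction[i] == "DONOR") tr_donor[on_ct] else tr_acceptor[on_ct]
    length(b) > 0 && min(abs(b - pos[i])) <= slack
  }, logical(1))
}

feature_cols <- c("nf_clip", "nf_seg", "nf_disc", "nf_cov")

scale_fit <- function(X) {
  mn <- apply(X, 2, min); rg <- apply(X, 2, max) - mn
  rg[rg == 0] <- 1
  list(min = mn, range = rg)
}
scale_apply <- function(X, sc) sweep(sweep(X, 2, sc$min), 2, sc$range, "/")

#' Train the site classifier
#'
#' Features are scaled to `[0, 1]` per feature (scaling parameters are stored
#' in the model), then a grid search over `(C, gamma)` maximizes mean
#' stratified 10-fold cross-validation accuracy; the final model is refit on
#' all examples with the best hyperparameters. All randomness (fold
#' assignment) derives from `cfg$seed`.
#'
#' @param examples Labeled table from [build_training_set()].
#' @param cfg List of `C_grid` (default `2^seq(-3, 7, 2)`), `gamma_grid`
#'   (default `2^seq(-7, 3, 2)`), `folds` (10), `kernel` (`"rbf"`),
#'   `seed` (42).
#' @return An object of class `cj_model` with the fitted SVM, scaling,
#'   best hyperparameters and CV accuracy.
#' @export
train_model <- function(examples, cfg = list()) {
  C_grid <- cfg$C_grid %||% 2^seq(-3, 7, 2)
  gamma_grid <- cfg$gamma_grid %||% 2^seq(-7, 3, 2)
  folds <- cfg$folds %||% 10L
  kernel <- cfg$kernel %||% "rbf"
  seed <- cfg$seed %||% 42L
  if (folds < 2L) stop("folds must be >= 2")
  X <- as.matrix(examples[, feature_cols, with = FALSE])
  y <- examples$label
  if (length(unique(y)) < 2L) stop("both classes must be present")
  sc <- scale_fit(X)
  Xs <- scale_apply(X, sc)
  fold_id <- stratified_folds(y, folds, seed)
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in sort(unique(fold_id))) {
      tr <- fold_id != f; te <- !tr
      if (length(unique(y[tr])) < 2L) next
      fit <- svm_fit(Xs[tr, , drop = FALSE], y[tr],
                     C = grid$C[g], gamma = grid$gamma[g], kernel = kernel)
      correct <- correct + sum(predict(fit, Xs[te, , drop = FALSE]) == y[te])
    }
    acc[g] <- correct / length(y)
  }
  best <- which.max(acc)   # ties: first grid point (smallest C, then gamma)
  fit <- svm_fit(Xs, y, C = grid$C[best], gamma = grid$gamma[best],
                 kernel = kernel)
  structure(list(fit = fit, scaling = sc, kernel = kernel,
                 C = grid$C[best], gamma = grid$gamma[best],
                 cv_accuracy = acc[best], grid_accuracy = acc,
                 feature_cols = feature_cols, seed = seed),
            class = "cj_model")
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    id[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  id
}

#' @export
print.cj_model <- function(x, ...) {
  cat(sprintf("site classifier: %s SVM, C = %g, gamma = %g, CV accuracy = %.4f\n",
              x$kernel, x$C, x$gamma, x$cv_accuracy))
  invisible(x)
}

#' Classify candidate sites as true or false
#'
#' @param model A `cj_model`.
#' @param features Feature table from [compute_features()].
#' @return Logical vector (one per site), `TRUE` for predicted splice sites.
#' @export
predict_sites <- function(model, features) {
  X <- as.matrix(features[, model$feature_cols, with = FALSE])
  if (ncol(X) != length(model$feature_cols))
    stop("feature dimension mismatch")
  Xs <- scale_apply(X, model$scaling)
  predict(model$fit, Xs) == 1L
}

#' Save / load a trained model
#'
#' The model archive stores hyperparameters, feature scaling and support
#' vectors; a reloaded model yields bit-identical predictions.
#' @param model A `cj_model`.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Convert GTF exon rows to a splice-site annotation table
#'
#' Exon boundaries become donor sites (exon ends) and acceptor sites (exon
#' starts); first/last exon boundaries of single-exon features are still
#' emitted (callers may filter). Coordinates are converted from GTF's 1-based
#' closed convention to 0-based half-open boundaries.
#'
#' @param gtf_path Path to a GTF/GFF file.
#' @return Annotation `data.table`: `contig`, `pos`, `direction`.
#' @export
gtf_to_annotation <- function(gtf_path) {
  g <- fread(gtf_path, header = FALSE, sep = "\t",
             col.names = c("contig", "source", "feature", "start", "end",
                           "score", "strand", "frame", "attr"))
  e <- g[tolower(feature) == "exon"]
  rbindlist(list(
    e[, .(contig, pos = end, direction = "DONOR")],        # 1-based end == 0-based boundary
    e[, .(contig, pos = start - 1L, direction = "ACCEPTOR")]
  ))[order(contig, pos)]
}
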