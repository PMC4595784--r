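#' Viewpoint-generalization benchmark with a multi-class linear SVM
#'
#' Trains and tests a multi-class linear SVM on the feature matrices of the
#' original and extended models over repeated random splits of the video
#' database.  Splits are made at the sequence level — whole sequences are
#' held out, so test frames always come from viewpoints (sequences) never
#' seen in training — and are stratified by category so every category is
#' represented in every training set.  The regularization (cost) parameter
#' is chosen per split and per model by an inner cross-validation over
#' training sequences.
#'
#' @param features_by_model named list of numeric feature matrices (e.g.
#'   `original`, `extended`), row-aligned to the same frames.
#' @param labels category label per frame.
#' @param sequence_ids sequence identifier per frame (split unit).
#' @param n_splits number of random splits.
#' @param test_frac fraction of each category's sequences held out.
#' @param cost_grid candidate SVM cost values for the inner CV.
#' @param inner_folds folds of the inner CV (over training sequences).
#' @param seed integer RNG seed.
#' @return an object of class `svm_benchmark`: `per_split` (tibble of
#'   per-split accuracies and chosen costs), `summary` (per model: mean/sd
#'   accuracy in percent, chance level), `paired_p` (two-sided Wilcoxon
#'   signed-rank across splits comparing the first two models; 1 with
#'   `degenerate = TRUE` when accuracies are identical), and `splits` (the
#'   held-out sequences per split, for audit).
#' @export
svm_benchmark <- function(features_by_model, labels, sequence_ids,
                          n_splits = 15L, test_frac = 0.2,
                          cost_grid = 10^(-2:2), inner_folds = 3L,
                          seed = 1L) {
  stopifnot(is.list(features_by_model), length(features_by_model) >= 1L,
            !is.null(names(features_by_model)))
  labels <- as.character(labels)
  sequence_ids <- as.character(sequence_ids)
  n <- length(labels)
  for (m in features_by_model) {
    stopifnot(is.matrix(m), nrow(m) == n)
  }
  if (length(unique(labels)) < 2L) {
    stop("need at least 2 categories", call. = FALSE)
  }
  seq_info <- unique(data.frame(sequence_id = sequence_ids, label = labels,
                                stringsAsFactors = FALSE))
  if (anyDuplicated(seq_info$sequence_id)) {
    stop("a sequence maps to more than one label", call. = FALSE)
  }
  cats <- unique(seq_info$label)

  withr::with_seed(as.integer(seed), {
    splits <- lapply(seq_len(n_splits), function(k) {
      test_seqs <- unlist(lapply(cats, function(cl) {
        s <- seq_info$sequence_id[seq_info$label == cl]
        # a category with a single sequence stays in training: holding it
        # out would leave it unlearnable
        n_test <- min(max(1L, round(test_frac * length(s))), length(s) - 1L)
        if (n_test <= 0L) return(character(0))
        sample(s, n_test)
      }))
      if (length(test_seqs) == 0L) {
        stop("no category has enough sequences to hold one out", call. = FALSE)
      }
      inner_seed <- sample.int(.Machine$integer.max, 1L)
      list(test_seqs = test_seqs, inner_seed = inner_seed)
    })
  })

  rows <- list()
  for (k in seq_len(n_splits)) {
    test_idx <- sequence_ids %in% splits[[k]]$test_seqs
    for (mn in names(features_by_model)) {
      X <- features_by_model[[mn]]
      cost <- tune_cost(X[!test_idx, , drop = FALSE], labels[!test_idx],
                        sequence_ids[!test_idx], cost_grid, inner_folds,
                        splits[[k]]$inner_seed)
      fit <- e1071::svm(X[!test_idx, , drop = FALSE],
                        factor(labels[!test_idx]),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, X[test_idx, , drop = FALSE])
      acc <- 100 * mean(as.character(pred) == labels[test_idx])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        split = k, model = mn, cost = cost, accuracy = acc)
    }
  }
  per_split <- dplyr::bind_rows(rows)
  chance <- 100 / length(cats)
  summary <- per_split |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(mean_accuracy = mean(.data$accuracy),
                     sd_accuracy = stats::sd(.data$accuracy),
                     n_splits = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(chance_level = chance)

  paired_p <- NA_real_
  degenerate <- FALSE
  if (length(features_by_model) >= 2L) {
    mns <- names(features_by_model)[1:2]
    a <- per_split$accuracy[per_split$model == mns[1]]
    b <- per_split$accuracy[per_split$model == mns[2]]
    if (sum(a - b != 0) < 5L) {
      paired_p <- 1
      degenerate <- TRUE
    } else {
      paired_p <- wilcoxon_signed_rank(a, b)$p.value
    }
  }
  structure(list(per_split = per_split, summary = summary,
                 paired_p = paired_p, degenerate = degenerate,
                 chance_level = chance,
                 splits = lapply(splits, `[[`, "test_seqs")),
            class = "svm_benchmark")
}

# Inner cross-validation over training sequences: pick the cost with the
# highest held-out accuracy (smallest cost on ties).
tune_cost <- function(X, y, seqs, cost_grid, inner_folds, seed) {
  if (length(cost_grid) == 1L) return(cost_grid)
  us <- unique(seqs)
  withr::with_seed(as.integer(seed %% .Machine$integer.max), {
    fold_of <- stats::setNames(sample(rep_len(seq_len(inner_folds),
                                              length(us))), us)
  })
  acc <- vapply(cost_grid, function(cost) {
    correct <- 0L; total <- 0L
    for (f in seq_len(inner_folds)) {
      hold <- seqs %in% us[fold_of[us] == f]
      if (!any(hold) || !any(!hold)) next
      fit <- e1071::svm(X[!hold, , drop = FALSE], factor(y[!hold]),
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- stats::predict(fit, X[hold, , drop = FALSE])
      correct <- correct + sum(as.character(pred) == y[hold])
      total <- total + sum(hold)
    }
    if (total == 0L) 0 else correct / total
  }, numeric(1))
  cost_grid[which.max(acc)]
}

#' @export
print.svm_benchmark <- function(x, ...) {
  cat("<svm_benchmark>\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-10s %.1f +/- %.1f%% (n = %d splits, chance %.1f%%)\n",
                s$model, s$mean_accuracy, s$sd_accuracy, s$n_splits,
                s$chance_level))
  }
  if (!is.na(x$paired_p)) {
    cat(sprintf("  paired Wilcoxon p = %.3g%s\n", x$paired_p,
                if (x$degenerate) " [degenerate]" else ""))
  }
  invisible(x)
}

#' Randomize category labels at the sequence level
#'
#' Assigns every sequence an independent uniformly random label from the
#' observed categories (frames of one sequence keep a common label), for
#' chance-level controls.  Independent draws — rather than a permutation —
#' make each held-out sequence's label independent of the training set, so
#' chance accuracy is exactly binomial at 1/k.
#'
#' @param labels category label per frame.
#' @param sequence_ids sequence identifier per frame.
#' @param seed integer RNG seed.
#' @return character vector of randomized labels, frame-aligned.
#' @export
shuffle_sequence_labels <- function(labels, sequence_ids, seed = 1L) {
  labels <- as.character(labels)
  sequence_ids <- as.character(sequence_ids)
  us <- unique(sequence_ids)
  cats <- unique(labels)
  withr::with_seed(as.integer(seed), {
    shuffled <- sample(cats, length(us), replace = TRUE)
  })
  unname(stats::setNames(shuffled, us)[sequence_ids])
}
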