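#' Rank-based ROC curve and AUC
#'
#' AUC is computed with the rank (Mann-Whitney) statistic — the
#' probability that a random positive outranks a random negative, ties
#' credited one half. The ROC curve is a threshold sweep over the unique
#' scores (TPR = sensitivity, FPR = 1 - specificity).
#'
#' @param scores numeric vector of prediction scores.
#' @param is_positive logical mask, same length; at least one `TRUE` and
#'   one `FALSE`.
#' @return An object of class `roc_result`: fields `fpr`, `tpr` (each
#'   nondecreasing from 0 to 1), `auc`, `n_positive`, `n_negative`.
#' @export
roc_auc <- function(scores, is_positive) {
  stopifnot(is.numeric(scores), length(scores) == length(is_positive))
  is_positive <- as.logical(is_positive)
  if (any(is.na(scores)) || any(is.na(is_positive))) {
    stop("scores and labels must not contain missing values", call. = FALSE)
  }
  np <- sum(is_positive)
  nn <- sum(!is_positive)
  if (np == 0 || nn == 0) {
    stop("AUC is undefined without at least one positive and one negative",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[is_positive]) - np * (np + 1) / 2) / (np * nn)

  ord <- order(scores, decreasing = TRUE, method = "radix")
  s <- scores[ord]
  y <- is_positive[ord]
  tps <- cumsum(y)
  fps <- cumsum(!y)
  keep <- which(c(diff(s) != 0, TRUE))   # one point per unique threshold
  structure(
    list(fpr = c(0, fps[keep] / nn),
         tpr = c(0, tps[keep] / np),
         auc = auc,
         n_positive = np,
         n_negative = nn),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' Cross-validation plan
#'
#' @param scheme `"global_loocv"` or `"kfold"`.
#' @param folds number of folds (`>= 2`) for `"kfold"`.
#' @param repeats number of repeated random partitions (`>= 1`).
#' @param seed integer seed controlling fold assignment.
#' @return A list of class `cv_plan`.
#' @export
cv_plan <- function(scheme = c("kfold", "global_loocv"), folds = 5L,
                    repeats = 10L, seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "kfold") stopifnot(folds >= 2)
  stopifnot(repeats >= 1)
  structure(list(scheme = scheme, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "cv_plan")
}

#' Global leave-one-out cross-validation
#'
#' Each known association is zeroed in turn in a training copy and the
#' full pipeline is rerun from scratch on the training matrix (GIP
#' kernels, fusion and WKNKN densification are all recomputed, so no
#' information about the held-out pair leaks into training; precomputed
#' kernels are used as supplied). The held-out pair's score is pooled with
#' the scores of every pair unknown in the full matrix (the candidate
#' set) from the same runs, and a single global ROC/AUC is computed.
#'
#' @param A a binary [assoc_matrix()] with at least 2 known associations.
#' @param disease_kernels,mirna_kernels precomputed kernels (may be empty
#'   lists).
#' @param config a [pipeline_config()].
#' @param workers number of worker processes (`parallel::mclapply`);
#'   results are identical for any worker count.
#' @return A list: `roc` (a `roc_result`), `runs` (number of pipeline
#'   re-runs executed, one per known association), `held_out_scores`.
#' @export
global_loocv <- function(A, disease_kernels = list(), mirna_kernels = list(),
                         config = pipeline_config(), workers = 1L) {
  stopifnot(inherits(A, "assoc_matrix"))
  if (!all(A$values %in% c(0, 1))) {
    stop("LOOCV requires a binary association matrix", call. = FALSE)
  }
  pos <- which(A$values == 1, arr.ind = TRUE)
  if (nrow(pos) < 2) stop("need at least 2 known associations", call. = FALSE)
  cand_idx <- which(A$values == 0)

  run_one <- function(p) {
    i <- pos[p, 1]
    j <- pos[p, 2]
    train_vals <- A$values
    train_vals[i, j] <- 0
    Atr <- assoc_matrix(train_vals,
                        disease_labels = A$disease_labels,
                        mirna_labels = A$mirna_labels)
    stopifnot(Atr$values[i, j] == 0)         # leak audit
    F <- fuselp_predict(Atr, disease_kernels, mirna_kernels, config)
    list(held = F[i, j], cand = F[cand_idx])
  }
  results <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(pos)), run_one,
                       mc.cores = as.integer(workers))
  } else {
    lapply(seq_len(nrow(pos)), run_one)
  }
  held <- vapply(results, `[[`, 0, "held")
  cand <- unlist(lapply(results, `[[`, "cand"), use.names = FALSE)
  roc <- roc_auc(c(held, cand),
                 c(rep(TRUE, length(held)), rep(FALSE, length(cand))))
  list(roc = roc, runs = nrow(pos), held_out_scores = held)
}

#' Repeated k-fold cross-validation
#'
#' Per repeat, the known associations are partitioned uniformly at random
#' (seeded) into `plan$folds` groups. Per fold, the test positives are
#' zeroed in a training copy, the pipeline is rerun from scratch, and the
#' test positives' scores are pooled — within the repeat, across folds —
#' against the scores of all pairs unknown in the full matrix. One AUC is
#' reported per repeat; the summary is their mean and standard deviation.
#'
#' @param A a binary [assoc_matrix()].
#' @param disease_kernels,mirna_kernels precomputed kernels.
#' @param config a [pipeline_config()].
#' @param plan a [cv_plan()] (`folds` must not exceed the number of known
#'   associations).
#' @return A list: `auc` (per-repeat vector), `mean`, `sd`, `plan`.
#' @export
kfold_cv <- function(A, disease_kernels = list(), mirna_kernels = list(),
                     config = pipeline_config(),
                     plan = cv_plan(folds = 5L, repeats = 10L, seed = 1L)) {
  stopifnot(inherits(A, "assoc_matrix"), inherits(plan, "cv_plan"))
  if (!all(A$values %in% c(0, 1))) {
    stop("cross-validation requires a binary association matrix", call. = FALSE)
  }
  pos <- which(A$values == 1, arr.ind = TRUE)
  npos <- nrow(pos)
  if (plan$folds > npos) {
    stop("more folds than known associations", call. = FALSE)
  }
  cand_idx <- which(A$values == 0)
  # draw all fold assignments up front so the pipeline runs are RNG-free
  assignments <- withr::with_seed(plan$seed, {
    lapply(seq_len(plan$repeats), function(r) {
      sample(rep(seq_len(plan$folds), length.out = npos))
    })
  })
  aucs <- vapply(seq_len(plan$repeats), function(r) {
    fold_of <- assignments[[r]]
    held <- numeric(0)
    cand <- numeric(0)
    for (f in seq_len(plan$folds)) {
      test <- which(fold_of == f)
      train_vals <- A$values
      train_vals[pos[test, , drop = FALSE]] <- 0
      Atr <- assoc_matrix(train_vals,
                          disease_labels = A$disease_labels,
                          mirna_labels = A$mirna_labels)
      stopifnot(all(Atr$values[pos[test, , drop = FALSE]] == 0))  # leak audit
      F <- fuselp_predict(Atr, disease_kernels, mirna_kernels, config)
      held <- c(held, F[pos[test, , drop = FALSE]])
      cand <- c(cand, F[cand_idx])
    }
    roc_auc(c(held, cand),
            c(rep(TRUE, length(held)), rep(FALSE, length(cand))))$auc
  }, 0)
  list(auc = aucs, mean = mean(aucs),
       sd = if (length(aucs) > 1) stats::sd(aucs) else NA_real_,
       plan = plan)
}

#' Rank candidate miRNAs for one disease
#'
#' Returns the miRNAs with no known association to the given disease,
#' sorted by descending prediction score (ties by ascending miRNA label).
#'
#' @param F numeric score matrix with dimnames (as returned by
#'   [fuselp_predict()]).
#' @param A the [assoc_matrix()] the scores were computed from (its known
#'   associations are excluded from the candidate list).
#' @param disease_label disease identifier present in `A`.
#' @param top_n number of candidates to return (the full list when fewer
#'   are available).
#' @return A data frame with columns `mirna`, `score`.
#' @export
rank_candidates <- function(F, A, disease_label, top_n = 50L) {
  stopifnot(inherits(A, "assoc_matrix"))
  d <- match(disease_label, A$disease_labels)
  if (is.na(d)) {
    stop(sprintf("unknown disease label '%s'", disease_label), call. = FALSE)
  }
  if (!identical(dim(F), dim(A$values))) {
    stop("score matrix shape does not match the association matrix", call. = FALSE)
  }
  cand <- which(A$values[d, ] == 0)
  if (length(cand) == 0) {
    return(data.frame(mirna = character(0), score = numeric(0)))
  }
  s <- F[d, cand]
  lab <- A$mirna_labels[cand]
  ord <- order(-s, lab, method = "radix")
  take <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(mirna = lab[take], score = unname(s[take]),
             stringsAsFactors = FALSE)
}
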