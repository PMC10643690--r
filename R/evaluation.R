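#' Rank of the matched candidate for each query
#'
#' Candidates are ordered by descending cosine similarity to the query;
#' ties are broken by candidate index (earlier index wins), which makes the
#' ranking deterministic.
#'
#' @param queryEmb,candEmb [EmbeddingMatrix-class] objects (or unit-norm
#'   matrices with rownames as ids).
#' @param pairing data.frame with columns `query_id`, `candidate_id`
#'   mapping each query to its matched candidate; every `query_id` must
#'   appear in `queryEmb` and every `candidate_id` in `candEmb`.
#' @return integer vector of ranks (1 = matched candidate most similar),
#'   named by query id.
#' @export
rankMatched <- function(queryEmb, candEmb, pairing) {
  Q <- asUnitMatrix(queryEmb); C <- asUnitMatrix(candEmb)
  qids <- if (is(queryEmb, "EmbeddingMatrix")) embIds(queryEmb) else rownames(Q)
  cids <- if (is(candEmb, "EmbeddingMatrix")) embIds(candEmb) else rownames(C)
  stopifnot(all(c("query_id", "candidate_id") %in% names(pairing)))
  qi <- match(pairing$query_id, qids)
  ci <- match(pairing$candidate_id, cids)
  if (anyNA(qi)) stop("pairing query ids missing from query embeddings: ",
                      paste(head(pairing$query_id[is.na(qi)]), collapse = ", "))
  if (anyNA(ci)) stop("pairing candidate ids missing from candidates: ",
                      paste(head(pairing$candidate_id[is.na(ci)]), collapse = ", "))
  S <- tcrossprod(Q, C)
  ranks <- integer(nrow(pairing))
  for (r in seq_len(nrow(pairing))) {
    s <- S[qi[r], ]
    sm <- s[ci[r]]
    ranks[r] <- 1L + sum(s > sm) + sum(s == sm & seq_along(s) < ci[r])
  }
  names(ranks) <- pairing$query_id
  ranks
}

#' Top-k accuracy of a rank list, in percent
#'
#' @param ranks integer vector of matched-candidate ranks (>= 1).
#' @param k cutoff (>= 1).
#' @return `100 * mean(ranks <= k)`; monotone non-decreasing in k.
#' @examples
#' topkAccuracy(c(1, 3, 11), 10)  # 66.67
#' @export
topkAccuracy <- function(ranks, k) {
  if (any(k < 1)) stop("k must be >= 1")
  if (any(ranks < 1)) stop("ranks must be >= 1")
  100 * mean(ranks <= k)
}

#' Exact Clopper-Pearson binomial confidence interval, in percent
#'
#' Beta-quantile formulation of the exact interval: the lower bound is the
#' alpha/2 quantile of Beta(x, n - x + 1) and the upper bound the
#' 1 - alpha/2 quantile of Beta(x + 1, n - x), with the conventions
#' lower = 0 when x = 0 and upper = 100% when x = n. The interval always
#' contains the point estimate x/n.
#'
#' @param successes number of successes x (0 <= x <= n).
#' @param n number of trials (> 0).
#' @param level confidence level (default 0.95).
#' @return named numeric vector `c(lower, upper)` in percent.
#' @examples
#' clopperPearsonCI(1, 2115)  # c(0.0012, 0.263) approximately
#' @export
clopperPearsonCI <- function(successes, n, level = 0.95) {
  if (n < 1) stop("n must be >= 1")
  if (successes < 0 || successes > n) stop("successes must be in [0, n]")
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Cross-modal retrieval evaluation
#'
#' Evaluates both retrieval directions on matched embeddings:
#' `structure_retrieval` (each image queries the molecule candidates) and
#' `image_retrieval` (each molecule queries the image candidates). Reports
#' top-k accuracies in percent with exact 95% Clopper-Pearson intervals.
#' With `subsample` set (e.g. 99), each query instead faces its matched
#' candidate plus `subsample` sampled un-matched candidates — the
#' 1-vs-99 protocol at subsample = 99.
#'
#' @param imageEmb,structEmb [EmbeddingMatrix-class] objects.
#' @param pairing data.frame `image_id`, `molecule_id` (a bijection).
#' @param ks cutoffs (default 1, 5, 10).
#' @param subsample number of un-matched candidates per query, or NULL for
#'   the full candidate set.
#' @param seed seed for subsampling.
#' @param level confidence level for the intervals.
#' @return named list of two [RetrievalReport-class] objects:
#'   `structure_retrieval`, `image_retrieval`.
#' @export
retrievalEval <- function(imageEmb, structEmb, pairing, ks = c(1L, 5L, 10L),
                          subsample = NULL, seed = 1L, level = 0.95) {
  stopifnot(all(c("image_id", "molecule_id") %in% names(pairing)))
  if (anyDuplicated(pairing$image_id) || anyDuplicated(pairing$molecule_id))
    stop("pairing must be a bijection between image and molecule ids")
  if (nrow(pairing) < 2L) stop("need at least 2 candidates")
  mkReport <- function(queryEmb, candEmb, qid, cid, direction) {
    pr <- data.frame(query_id = qid, candidate_id = cid,
                     stringsAsFactors = FALSE)
    if (is.null(subsample)) {
      ranks <- rankMatched(queryEmb, candEmb, pr)
      nCand <- nrow(pr)
    } else {
      old <- globalRNGState(); on.exit(restoreRNGState(old), add = TRUE)
      set.seed(seed)
      C <- asUnitMatrix(candEmb)
      cids <- if (is(candEmb, "EmbeddingMatrix")) embIds(candEmb) else rownames(C)
      nCand <- subsample + 1L
      ranks <- integer(nrow(pr))
      Q <- asUnitMatrix(queryEmb)
      qids <- if (is(queryEmb, "EmbeddingMatrix")) embIds(queryEmb) else rownames(Q)
      for (r in seq_len(nrow(pr))) {
        mi <- match(pr$candidate_id[r], cids)
        pool <- setdiff(seq_along(cids), mi)
        sel <- c(mi, sample(pool, min(subsample, length(pool))))
        s <- drop(C[sel, , drop = FALSE] %*% Q[match(pr$query_id[r], qids), ])
        ranks[r] <- 1L + sum(s > s[1L]) # matched is sel[1]; earlier index wins
      }
      names(ranks) <- pr$query_id
    }
    ks <- ks[ks <= nCand]
    acc <- vapply(ks, function(k) topkAccuracy(ranks, k), numeric(1))
    ci <- t(vapply(ks, function(k)
      clopperPearsonCI(sum(ranks <= k), length(ranks), level), numeric(2)))
    new("RetrievalReport", direction = direction,
        nCandidates = as.integer(nCand), ranks = as.integer(ranks),
        metrics = data.frame(k = as.integer(ks), accuracy = acc,
                             ci_lower = ci[, 1], ci_upper = ci[, 2]))
  }
  list(structure_retrieval = mkReport(imageEmb, structEmb,
                                      pairing$image_id, pairing$molecule_id,
                                      "structure_retrieval"),
       image_retrieval = mkReport(structEmb, imageEmb,
                                  pairing$molecule_id, pairing$image_id,
                                  "image_retrieval"))
}

#' Build a zero-shot reference set with plate-effect filtering
#'
#' Randomly selects one reference image per class (molecule or
#' mechanism-of-action), then removes from the query pool the reference
#' images themselves and every image sharing both the molecule and the
#' plate with any reference image, so that classification cannot be driven
#' by plate effects. Classes left with no queries are dropped with a
#' warning.
#'
#' @param meta image metadata data.frame (`image_id`, `plate_id`,
#'   `molecule_id`, and `moa` when classifying by mechanism).
#' @param classKey `"molecule_id"` or `"moa"`.
#' @param seed seed for the reference draw.
#' @return list with `references` (data.frame `image_id`, `class`),
#'   `queries` (data.frame `image_id`, `class`), and `dropped` (classes
#'   removed for lack of queries).
#' @export
buildReferenceSet <- function(meta, classKey = c("molecule_id", "moa"),
                              seed = 1L) {
  classKey <- match.arg(classKey)
  stopifnot(all(c("image_id", "plate_id", "molecule_id") %in% names(meta)),
            classKey %in% names(meta))
  old <- globalRNGState(); on.exit(restoreRNGState(old), add = TRUE)
  set.seed(seed)
  cls <- as.character(meta[[classKey]])
  refIdx <- vapply(split(seq_len(nrow(meta)), cls), function(ix)
    if (length(ix) == 1L) ix else sample(ix, 1L), integer(1))
  refs <- data.frame(image_id = meta$image_id[refIdx],
                     class = names(refIdx), stringsAsFactors = FALSE)
  refKey <- paste(meta$molecule_id[refIdx], meta$plate_id[refIdx])
  exclude <- meta$image_id %in% refs$image_id |
    paste(meta$molecule_id, meta$plate_id) %in% refKey
  queries <- data.frame(image_id = meta$image_id[!exclude],
                        class = cls[!exclude], stringsAsFactors = FALSE)
  dropped <- setdiff(refs$class, unique(queries$class))
  if (length(dropped)) {
    warning("dropping classes with no remaining queries: ",
            paste(dropped, collapse = ", "))
    refs <- refs[!refs$class %in% dropped, , drop = FALSE]
    queries <- queries[queries$class %in%
                         refs$class, , drop = FALSE]
  }
  list(references = refs, queries = queries, dropped = dropped)
}

#' Zero-shot classification by similarity to one reference per class
#'
#' Computes cosine similarity of each query embedding to every reference
#' embedding and applies the softmax over references to obtain calibrated
#' per-class scores. Top-k hits are judged on the raw similarity order
#' (ties broken by reference index).
#'
#' @param queryEmb,refEmb [EmbeddingMatrix-class] objects.
#' @param refLabels class label per reference row.
#' @param queryLabels true class label per query row.
#' @param ks accuracy cutoffs.
#' @return list with `scores` (query x class softmax matrix), `ranks`
#'   (rank of the true class per query), and `metrics` (data.frame k,
#'   accuracy, ci_lower, ci_upper, in percent).
#' @export
zeroshotClassify <- function(queryEmb, refEmb, refLabels, queryLabels,
                             ks = c(1L, 5L, 10L)) {
  Q <- asUnitMatrix(queryEmb); R <- asUnitMatrix(refEmb)
  refLabels <- as.character(refLabels); queryLabels <- as.character(queryLabels)
  if (length(refLabels) != nrow(R))
    stop("refLabels misaligned with reference embeddings")
  if (length(queryLabels) != nrow(Q))
    stop("queryLabels misaligned with query embeddings")
  if (anyDuplicated(refLabels)) stop("one reference per class required")
  if (!all(queryLabels %in% refLabels))
    stop("query labels missing from reference classes")
  S <- tcrossprod(Q, R)
  E <- exp(S - apply(S, 1, max))
  scores <- E / rowSums(E)
  colnames(scores) <- refLabels
  ti <- match(queryLabels, refLabels)
  ranks <- vapply(seq_len(nrow(S)), function(i) {
    s <- S[i, ]
    1L + sum(s > s[ti[i]]) + sum(s == s[ti[i]] & seq_along(s) < ti[i])
  }, integer(1))
  ks <- ks[ks <= ncol(S)]
  acc <- vapply(ks, function(k) topkAccuracy(ranks, k), numeric(1))
  ci <- t(vapply(ks, function(k)
    clopperPearsonCI(sum(ranks <= k), length(ranks)), numeric(2)))
  list(scores = scores, ranks = ranks,
       metrics = data.frame(k = as.integer(ks), accuracy = acc,
                            ci_lower = ci[, 1], ci_upper = ci[, 2]))
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation with midrank tie handling:
#' `AUC = (sum of positive ranks - nPos (nPos + 1) / 2) / (nPos * nNeg)`.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
aucRank <- function(scores, labels) {
  labels <- as.integer(labels)
  nP <- sum(labels == 1L); nN <- sum(labels == 0L)
  if (nP == 0L || nN == 0L) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1L]) - nP * (nP + 1) / 2) / (nP * nN)
}

f1Score <- function(pred, labels) {
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Linear probing of frozen representations
#'
#' Fits one L2-regularized logistic regression per task on frozen features.
#' The regularization strength lambda is tuned per task on the validation
#' AUC over `lambdaGrid`, and test AUC and F1 (threshold 0.5 on the
#' predicted probability) are reported, together with counts of tasks
#' exceeding AUC 0.9 / 0.8 / 0.7. Tasks with a single class in any split
#' are skipped and recorded.
#'
#' @param features numeric matrix, rownames are sample ids.
#' @param labels sample x task matrix of 0/1/NA (NA = unobserved).
#' @param split data.frame from [makeSplit()] (`molecule_id`, `split`)
#'   where `molecule_id` matches feature rownames.
#' @param lambdaGrid L2 strengths to consider (default `10^(-6:6)`).
#' @return list with `results` (data.frame task, lambda, auc, f1,
#'   auc_gt_0.9/0.8/0.7), `summary` (counts and mean AUC), and `skipped`.
#' @export
linearProbe <- function(features, labels, split,
                        lambdaGrid = 10^seq(-6, 6)) {
  stopifnot(is.matrix(features), is.matrix(labels),
            !is.null(rownames(features)))
  ids <- rownames(features)
  spl <- setNames(as.character(split$split), split$molecule_id)[ids]
  if (anyNA(spl)) stop("feature rows missing from split assignment")
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)
  res <- list(); skipped <- character(0)
  for (t in seq_len(ncol(labels))) {
    task <- colnames(labels)[t] %||% sprintf("task_%03d", t)
    y <- labels[ids, t]
    obs <- !is.na(y)
    tr <- obs & spl == "train"; va <- obs & spl == "valid"
    te <- obs & spl == "test"
    if (!sum(te)) { skipped <- c(skipped, task); next }
    oneClass <- function(m) length(unique(y[m])) < 2L
    if (oneClass(tr) || oneClass(va) || oneClass(te)) {
      skipped <- c(skipped, task); next
    }
    fit <- glmnet::glmnet(features[tr, , drop = FALSE], y[tr],
                          family = "binomial", alpha = 0,
                          lambda = lambdaGrid, standardize = TRUE)
    pv <- predict(fit, features[va, , drop = FALSE], type = "response")
    vaAuc <- apply(pv, 2, aucRank, labels = y[va])
    best <- which.max(vaAuc)  # first (largest lambda) wins ties
    pt <- predict(fit, features[te, , drop = FALSE],
                  type = "response")[, best]
    auc <- aucRank(pt, y[te])
    res[[task]] <- data.frame(
      task = task, lambda = fit$lambda[best], auc = auc,
      f1 = f1Score(1L * (pt >= 0.5), y[te]),
      auc_gt_0.9 = auc > 0.9, auc_gt_0.8 = auc > 0.8, auc_gt_0.7 = auc > 0.7,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, res)
  summary <- if (is.null(results)) {
    data.frame(n_tasks = 0L, mean_auc = NA_real_, mean_f1 = NA_real_,
               n_auc_gt_0.9 = 0L, n_auc_gt_0.8 = 0L, n_auc_gt_0.7 = 0L)
  } else data.frame(
    n_tasks = nrow(results), mean_auc = mean(results$auc),
    mean_f1 = mean(results$f1),
    n_auc_gt_0.9 = sum(results$auc_gt_0.9),
    n_auc_gt_0.8 = sum(results$auc_gt_0.8),
    n_auc_gt_0.7 = sum(results$auc_gt_0.7))
  list(results = results, summary = summary, skipped = skipped)
}
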