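#' Pearson correlation pruning of collinear predictors
#'
#' Flags every pair of continuous predictors whose Pearson correlation
#' exceeds `threshold` in absolute value and, walking the flagged pairs in
#' decreasing `|r|`, drops the lower-priority member of any pair whose
#' members are both still present. The correlation matrix is computed once
#' on the input: nothing is recomputed after drops. Indicator (0/1)
#' predictors are exempt — correlation screening applies to the numerical
#' predictors only.
#'
#' @param X Data frame of predictor columns.
#' @param threshold Absolute correlation above which a pair is flagged
#'   (strict inequality; default 0.70).
#' @param priority Character vector ranking all non-indicator numeric
#'   predictors from most to least preferred (the member whose effect on
#'   SOC dynamics is better established is kept). Defaults to column
#'   order.
#' @return A list with `data` (the pruned predictor table) and `report`
#'   (correlation matrix, data frame of dropped pairs, surviving names).
#' @export
correlation_prune <- function(X, threshold = 0.70, priority = NULL) {
  stopifnot(is.data.frame(X))
  is_ind <- vapply(X, function(v) all(v %in% c(0, 1)), TRUE)
  num <- names(X)[!is_ind]
  if (length(num) < 2L) {
    return(list(data = X,
                report = list(correlation_matrix = NULL,
                              dropped_by_correlation =
                                data.frame(dropped = character(),
                                           kept = character(), r = numeric()),
                              kept = names(X))))
  }
  priority <- priority %||% num
  if (!all(num %in% priority)) {
    stop_invalid("priority must cover every numeric predictor; missing: ",
                 paste(setdiff(num, priority), collapse = ", "))
  }
  C <- cor(as.matrix(X[num]))
  pr <- match(num, priority)
  pairs <- which(upper.tri(C) & abs(C) > threshold, arr.ind = TRUE)
  dropped <- character()
  log <- list()
  if (nrow(pairs)) {
    ord <- order(-abs(C[pairs]), pairs[, 1L], pairs[, 2L])
    pairs <- pairs[ord, , drop = FALSE]
    for (row in seq_len(nrow(pairs))) {
      a <- num[pairs[row, 1L]]
      b <- num[pairs[row, 2L]]
      if (a %in% dropped || b %in% dropped) next
      drop <- if (pr[pairs[row, 1L]] <= pr[pairs[row, 2L]]) b else a
      keep <- setdiff(c(a, b), drop)
      dropped <- c(dropped, drop)
      log[[length(log) + 1L]] <-
        data.frame(dropped = drop, kept = keep, r = C[a, b])
    }
  }
  kept_cols <- setdiff(names(X), dropped)
  list(data = X[kept_cols],
       report = list(
         correlation_matrix = C,
         dropped_by_correlation = if (length(log)) do.call(rbind, log) else
           data.frame(dropped = character(), kept = character(), r = numeric()),
         kept = kept_cols))
}

#' Simple random train/test split
#'
#' Unstratified split with `n_train = floor(train_fraction * n)`; the two
#' partitions are disjoint and exhaustive and the membership is
#' deterministic given the seed.
#'
#' @param table Data frame of observations (at least 8 rows).
#' @param train_fraction Fraction assigned to training, in (0, 1);
#'   default 0.75.
#' @param seed Integer RNG seed.
#' @return A list with `train` and `test` data frames.
#' @export
train_test_split <- function(table, train_fraction = 0.75, seed = 1L) {
  n <- nrow(table)
  if (n < 8L) stop_invalid("need at least 8 rows to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_invalid("train_fraction must lie strictly between 0 and 1")
  }
  idx <- with_seed(seed, sort(sample(n, floor(train_fraction * n))))
  list(train = table[idx, , drop = FALSE],
       test = table[-idx, , drop = FALSE])
}

# Least-squares stats for one candidate subset via the QR factorization:
# coefficients, partial t p-values (predictors only), overall F p-value,
# R^2 and adjusted R^2.
subset_lm_stats <- function(Xs, z) {
  n <- length(z)
  q <- ncol(Xs)
  Xd <- cbind(`(Intercept)` = 1, Xs)
  qrx <- qr(Xd)
  if (qrx$rank < ncol(Xd)) return(NULL)
  beta <- qr.coef(qrx, z)
  res <- z - drop(Xd %*% beta)
  rss <- sum(res^2)
  df <- n - q - 1L
  tss <- sum((z - mean(z))^2)
  sigma2 <- rss / df
  xtxinv <- chol2inv(qr.R(qrx))
  se <- sqrt(diag(xtxinv) * sigma2)
  tval <- beta / se
  p_t <- 2 * pt(abs(tval[-1L]), df, lower.tail = FALSE)
  fstat <- ((tss - rss) / q) / sigma2
  p_f <- pf(fstat, q, df, lower.tail = FALSE)
  r2 <- 1 - rss / tss
  list(coef = beta, p_t = p_t, p_f = p_f, r2 = r2,
       adj_r2 = 1 - (rss / df) / (tss / (n - 1)))
}

#' Best-subset predictor selection under F-test significance
#'
#' Among candidate subsets of at most `max_subset_size` predictors, returns
#' the one maximizing adjusted R^2 subject to two constraints: the overall
#' regression F-test and every predictor's partial t-test are significant
#' at `alpha`. Ties are broken by smaller subset, then lexicographic
#' predictor order. When 15 or fewer predictors survive screening the
#' candidate set is exhaustive; with more, forward stepwise selection
#' proposes one candidate subset per size (logged via a message).
#' If no subset satisfies the constraints the null model is returned with
#' a warning.
#'
#' @param X Data frame or matrix of training predictors (columns must have
#'   nonzero variance).
#' @param z Transformed training response.
#' @param max_subset_size Largest subset considered; defaults to the
#'   number of predictors.
#' @param alpha Significance level for the F and partial t tests
#'   (default 0.05).
#' @return An object of class `subset_selection`: `predictors` (character,
#'   possibly empty), `r2`, `adj_r2`, `n_candidates`.
#' @export
best_subset_select <- function(X, z, max_subset_size = NULL, alpha = 0.05) {
  X <- as.data.frame(X)
  p <- ncol(X)
  if (any(vapply(X, function(v) var(v) == 0, TRUE))) {
    stop_invalid("predictor columns must have nonzero variance")
  }
  max_subset_size <- min(max_subset_size %||% p, p)
  Xm <- as.matrix(X)
  nm <- colnames(Xm)
  if (p <= 15L) {
    candidates <- unlist(lapply(seq_len(max_subset_size), function(k) {
      combn(nm, k, simplify = FALSE)
    }), recursive = FALSE)
  } else {
    message("more than 15 predictors survive screening; ",
            "falling back to forward stepwise candidates")
    candidates <- list()
    current <- character()
    for (k in seq_len(max_subset_size)) {
      remaining <- setdiff(nm, current)
      rss <- vapply(remaining, function(v) {
        Xd <- cbind(1, Xm[, c(current, v), drop = FALSE])
        sum(qr.resid(qr(Xd), z)^2)
      }, numeric(1L))
      current <- c(current, remaining[which.min(rss)])
      candidates[[k]] <- current
    }
  }
  best <- NULL
  for (s in candidates) {
    st <- subset_lm_stats(Xm[, s, drop = FALSE], z)
    if (is.null(st)) next
    if (st$p_f >= alpha || any(st$p_t >= alpha)) next
    if (is.null(best) ||
        st$adj_r2 > best$adj_r2 + 1e-12 ||
        (abs(st$adj_r2 - best$adj_r2) <= 1e-12 &&
         (length(s) < length(best$predictors) ||
          (length(s) == length(best$predictors) &&
           paste(sort(s), collapse = ",") <
             paste(sort(best$predictors), collapse = ","))))) {
      best <- list(predictors = s, r2 = st$r2, adj_r2 = st$adj_r2)
    }
  }
  if (is.null(best)) {
    warning("no subset satisfies the significance constraints; ",
            "returning the null model", call. = FALSE)
    best <- list(predictors = character(), r2 = 0, adj_r2 = 0)
  }
  structure(c(best, list(n_candidates = length(candidates), alpha = alpha)),
            class = "subset_selection")
}

#' @export
print.subset_selection <- function(x, ...) {
  if (length(x$predictors)) {
    cat(sprintf("selected %d predictor(s): %s\n  R2 = %.3f, adj R2 = %.3f (%d candidate subsets)\n",
                length(x$predictors), paste(x$predictors, collapse = ", "),
                x$r2, x$adj_r2, x$n_candidates))
  } else {
    cat("null model: no subset met the significance constraints\n")
  }
  invisible(x)
}

#' Linear-vs-rank association screen
#'
#' Diagnostic comparison of Pearson and Spearman correlation between each
#' predictor and the response; a large gap suggests a monotone but
#' non-linear relationship that a linear model will under-use. Purely
#' informational — no transformation is applied.
#'
#' @param X Data frame of predictors.
#' @param z Response vector.
#' @return Data frame with `predictor`, `pearson`, `spearman`, `gap`.
#' @export
linearity_screen <- function(X, z) {
  pe <- vapply(X, function(v) cor(v, z), numeric(1L))
  sp <- vapply(X, function(v) cor(v, z, method = "spearman"), numeric(1L))
  data.frame(predictor = names(X), pearson = pe, spearman = sp,
             gap = abs(sp) - abs(pe), row.names = NULL)
}
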