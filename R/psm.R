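#' Build a numeric design matrix from a covariate table
#'
#' Numeric and 0/1 columns pass through; character/factor columns are
#' expanded to indicator columns with the first level dropped as reference.
#' Missing values are a hard error: analyses are restricted to complete
#' cases, no imputation.
#'
#' @param covariates data.frame of covariates.
#' @return numeric matrix (no intercept column).
#' @export
design_matrix <- function(covariates) {
  stopifnot(is.data.frame(covariates))
  if (anyNA(covariates))
    stop("covariates contain missing values; complete cases are required ",
         "(no imputation)", call. = FALSE)
  covariates[] <- lapply(covariates, function(col) {
    if (is.character(col)) factor(col) else col
  })
  mm <- stats::model.matrix(~ ., data = covariates)
  mm[, setdiff(colnames(mm), "(Intercept)"), drop = FALSE]
}

#' Fit a logistic propensity model
#'
#' Maximum-likelihood logistic regression of treatment on covariates via
#' iteratively reweighted least squares (Fisher scoring). Rank-deficient
#' designs and (quasi-)perfect separation are explicit errors, not
#' silently diverged fits.
#'
#' @param covariates data.frame or numeric matrix of covariates (no
#'   missing values; categoricals expanded via [design_matrix()]).
#' @param treated logical (or 0/1) treatment indicator.
#' @param ids optional character ids stored on the model (default row
#'   numbers).
#' @param tolerance IRLS convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return object of class `propensity_model`: coefficients (with
#'   intercept), `fitted_scores` in (0,1), `logit_scores`, `converged`,
#'   `n_iterations`, `log_likelihood`, `treated`, `ids`.
#' @export
fit_propensity <- function(covariates, treated, ids = NULL,
                           tolerance = 1e-8, max_iter = 25L) {
  X <- if (is.matrix(covariates)) covariates else design_matrix(covariates)
  y <- as.integer(treated)
  stopifnot(length(y) == nrow(X), all(y %in% 0:1))
  if (anyNA(X)) stop("covariates contain missing values", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))

  Xd <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(Xd)
  if (qrd$rank < ncol(Xd)) {
    dropped <- colnames(Xd)[qrd$pivot[(qrd$rank + 1):ncol(Xd)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  fit <- suppressWarnings(stats::glm.fit(
    Xd, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = tolerance, maxit = max_iter)))
  mu <- fit$fitted.values

  # (quasi-)separation: fitted probabilities at the boundary mean some
  # coefficient diverged; name the offending covariates
  at_boundary <- mu < 1e-8 | mu > 1 - 1e-8
  if (any(at_boundary)) {
    sds <- apply(X, 2, stats::sd)
    sc <- abs(fit$coefficients[colnames(X)]) * ifelse(sds > 0, sds, 1)
    culprit <- names(sc)[sc >= 0.5 * max(sc)]
    stop("perfect or quasi-perfect separation detected; separating ",
         "covariate set: ", paste(culprit, collapse = ", "),
         call. = FALSE)
  }

  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  structure(list(
    coefficients = fit$coefficients,
    fitted_scores = as.numeric(mu),
    logit_scores = as.numeric(Xd %*% fit$coefficients),
    converged = fit$converged,
    n_iterations = fit$iter,
    log_likelihood = ll,
    treated = y == 1L,
    ids = ids
  ), class = "propensity_model")
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf(
    "<propensity_model: %d obs (%d treated), %d coefficients, logLik %.2f, %s in %d iter>\n",
    length(x$fitted_scores), sum(x$treated), length(x$coefficients),
    x$log_likelihood, if (x$converged) "converged" else "NOT converged",
    x$n_iterations))
  invisible(x)
}

#' Greedy 1:1 nearest-neighbor caliper matching
#'
#' Matches each treated unit, processed in descending propensity score
#' (ties broken by ascending id), to the unmatched control nearest in
#' logit-score distance, provided the distance does not exceed the caliper;
#' without replacement. The caliper is expressed in SD units of the logit
#' of the propensity score (the dominant convention), or on the raw
#' probability scale with `caliper_scale = "probability"`.
#'
#' @param model a [fit_propensity()] result.
#' @param caliper_sd caliper width (default 0.1).
#' @param caliper_scale `"logit_sd"` (caliper times the SD of all logit
#'   scores) or `"probability"` (absolute difference in scores).
#' @param covariates optional covariate data.frame aligned with the model;
#'   if supplied, balance tables before/after matching are attached.
#' @return object of class `match_result`: `pairs` (data.frame with
#'   treated/control ids, scores and logit distance), `unmatched_treated`,
#'   `unmatched_control`, `caliper`, `caliper_width` (the realized
#'   distance bound), `balance_before`, `balance_after` (NULL unless
#'   `covariates` given).
#' @export
match_caliper <- function(model, caliper_sd = 0.1,
                          caliper_scale = c("logit_sd", "probability"),
                          covariates = NULL) {
  stopifnot(inherits(model, "propensity_model"), caliper_sd > 0)
  caliper_scale <- match.arg(caliper_scale)
  tr <- which(model$treated)
  ct <- which(!model$treated)
  if (length(tr) == 0 || length(ct) == 0)
    stop("matching requires both a treated and a control group",
         call. = FALSE)

  dist_val <- if (caliper_scale == "logit_sd") model$logit_scores else
    model$fitted_scores
  width <- if (caliper_scale == "logit_sd")
    caliper_sd * stats::sd(model$logit_scores) else caliper_sd

  # process treated in descending propensity; ties by ascending id
  tr <- tr[order(-model$fitted_scores[tr], model$ids[tr])]
  avail <- rep(TRUE, length(dist_val))
  pairs <- vector("list", length(tr))
  unmatched_t <- character(0)
  for (k in seq_along(tr)) {
    i <- tr[k]
    cand <- ct[avail[ct]]
    if (length(cand) == 0) { unmatched_t <- c(unmatched_t, model$ids[i]); next }
    d <- abs(dist_val[cand] - dist_val[i])
    best <- cand[order(d, model$ids[cand])][1]
    if (min(d) <= width) {
      avail[best] <- FALSE
      pairs[[k]] <- data.frame(
        treated_id = model$ids[i], control_id = model$ids[best],
        score_t = model$fitted_scores[i],
        score_c = model$fitted_scores[best],
        distance = abs(dist_val[best] - dist_val[i]),
        stringsAsFactors = FALSE)
    } else {
      unmatched_t <- c(unmatched_t, model$ids[i])
    }
  }
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(treated_id = character(0),
                        control_id = character(0), score_t = numeric(0),
                        score_c = numeric(0), distance = numeric(0))

  res <- structure(list(
    pairs = pairs,
    caliper = caliper_sd,
    caliper_scale = caliper_scale,
    caliper_width = width,
    unmatched_treated = unmatched_t,
    unmatched_control = setdiff(model$ids[ct], pairs$control_id),
    balance_before = NULL,
    balance_after = NULL
  ), class = "match_result")

  if (!is.null(covariates)) {
    res$balance_before <- balance_table(covariates, model$treated)
    res$balance_after <- balance_table(covariates, model$treated,
                                       pairs = pairs, ids = model$ids)
  }
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result: %d pairs, caliper %.3g (%s, width %.4g), %d treated unmatched>\n",
    nrow(x$pairs), x$caliper, x$caliper_scale, x$caliper_width,
    length(x$unmatched_treated)))
  if (!is.null(x$balance_after))
    cat(sprintf("  max |SMD| before %.3f, after %.3f\n",
                attr(x$balance_before, "max_abs_smd"),
                attr(x$balance_after, "max_abs_smd")))
  invisible(x)
}

#' Standardized mean difference, continuous covariate
#'
#' `(mean_1 - mean_2) / sqrt((var_1 + var_2) / 2)` with n-1 sample
#' variances. Equal means give 0 even at zero pooled variance; unequal
#' means at zero pooled variance give signed infinity (flagged by a
#' warning).
#'
#' @param x_t,x_c value vectors for the two groups (each n >= 2).
#' @return signed SMD.
#' @export
smd_continuous <- function(x_t, x_c) {
  stopifnot(length(x_t) >= 2, length(x_c) >= 2)
  num <- mean(x_t) - mean(x_c)
  den <- sqrt((stats::var(x_t) + stats::var(x_c)) / 2)
  if (den == 0) {
    if (num == 0) return(0)
    warning("zero pooled variance with unequal means: SMD is infinite")
    return(sign(num) * Inf)
  }
  num / den
}

#' Standardized mean difference, binary covariate
#'
#' `(p_t - p_c) / sqrt((p_t (1 - p_t) + p_c (1 - p_c)) / 2)` on raw
#' (unrounded) proportions.
#'
#' @param p_t,p_c group proportions in \[0, 1\].
#' @return signed SMD; 0 when both proportions are degenerate and equal,
#'   signed infinity (with a warning) when degenerate and unequal.
#' @export
smd_binary <- function(p_t, p_c) {
  stopifnot(p_t >= 0, p_t <= 1, p_c >= 0, p_c <= 1)
  num <- p_t - p_c
  den <- sqrt((p_t * (1 - p_t) + p_c * (1 - p_c)) / 2)
  if (den == 0) {
    if (num == 0) return(0)
    warning("degenerate unequal proportions: SMD is infinite")
    return(sign(num) * Inf)
  }
  num / den
}

#' Covariate balance table
#'
#' Standardized mean differences per covariate between treated and control,
#' optionally restricted to a matched set. Numeric columns use the
#' continuous formula, 0/1 columns the binary-proportion formula, and
#' multi-level categoricals are expanded to per-level indicators (each
#' level reported, plus a variable-level row carrying the maximum absolute
#' level SMD). Sign convention: treated minus control.
#'
#' @param covariates covariate data.frame.
#' @param treated logical/0-1 treatment indicator aligned with rows.
#' @param pairs optional matched-pairs data.frame (`treated_id`,
#'   `control_id`) restricting the computation to matched units.
#' @param ids character ids aligning `covariates` rows with pair ids
#'   (required when `pairs` is given).
#' @return data.frame of class `balance_table` with columns `covariate`,
#'   `level`, `smd`, `abs_smd`; attribute `max_abs_smd` is the maximum
#'   absolute variable-level SMD.
#' @export
balance_table <- function(covariates, treated, pairs = NULL, ids = NULL) {
  stopifnot(is.data.frame(covariates),
            length(treated) == nrow(covariates))
  treated <- as.logical(treated)
  if (!is.null(pairs)) {
    if (is.null(ids)) stop("ids are required when pairs are supplied",
                           call. = FALSE)
    keep <- ids %in% c(pairs$treated_id, pairs$control_id)
    covariates <- covariates[keep, , drop = FALSE]
    treated <- treated[keep]
  }

  rows <- list()
  for (nm in names(covariates)) {
    col <- covariates[[nm]]
    if (is.character(col) || is.factor(col)) {
      col <- as.character(col)
      lv_smd <- vapply(sort(unique(col)), function(lv) {
        smd_binary(mean(col[treated] == lv), mean(col[!treated] == lv))
      }, numeric(1))
      for (lv in names(lv_smd))
        rows[[length(rows) + 1]] <- data.frame(
          covariate = nm, level = lv, smd = lv_smd[[lv]],
          stringsAsFactors = FALSE)
      vmax <- lv_smd[which.max(abs(lv_smd))]
      rows[[length(rows) + 1]] <- data.frame(
        covariate = nm, level = "<max>", smd = unname(vmax),
        stringsAsFactors = FALSE)
    } else {
      col <- as.numeric(col)
      s <- if (all(col %in% 0:1))
        smd_binary(mean(col[treated]), mean(col[!treated]))
      else smd_continuous(col[treated], col[!treated])
      rows[[length(rows) + 1]] <- data.frame(
        covariate = nm, level = "", smd = s, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$abs_smd <- abs(out$smd)
  class(out) <- c("balance_table", class(out))
  var_rows <- out$level %in% c("", "<max>")
  attr(out, "max_abs_smd") <- max(out$abs_smd[var_rows])
  out
}

#' Maximum absolute variable-level SMD of a balance table
#'
#' @param balance a [balance_table()].
#' @return scalar.
#' @export
max_abs_smd <- function(balance) {
  stopifnot(inherits(balance, "balance_table"))
  attr(balance, "max_abs_smd")
}

#' @export
print.balance_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df$smd <- round(df$smd, digits)
  df$abs_smd <- round(df$abs_smd, digits)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf("max |SMD| (variable level): %.3f\n",
              attr(x, "max_abs_smd")))
  invisible(x)
}

#' Love plot: covariate balance before vs after matching
#'
#' Dot chart of absolute standardized mean differences per covariate in
#' the unmatched and matched cohorts, with a reference line at the 0.2
#' balance criterion.
#'
#' @param before,after [balance_table()]s for the unmatched and matched
#'   cohorts.
#' @param threshold reference line (default 0.2).
#' @return invisibly, the plotted data.frame.
#' @export
love_plot <- function(before, after, threshold = 0.2) {
  b <- before[before$level %in% c("", "<max>"), ]
  a <- after[after$level %in% c("", "<max>"), ]
  m <- merge(b[, c("covariate", "abs_smd")],
             a[, c("covariate", "abs_smd")],
             by = "covariate", suffixes = c("_before", "_after"))
  m <- m[order(m$abs_smd_before), ]
  graphics::dotchart(m$abs_smd_before, labels = m$covariate,
                     xlim = c(0, max(m$abs_smd_before, threshold) * 1.05),
                     pch = 19, color = "firebrick",
                     xlab = "|standardized mean difference|")
  graphics::points(m$abs_smd_after, seq_len(nrow(m)), pch = 19,
                   col = "steelblue")
  graphics::abline(v = threshold, lty = 2)
  graphics::legend("bottomright", legend = c("unmatched", "matched"),
                   pch = 19, col = c("firebrick", "steelblue"),
                   bty = "n")
  invisible(m)
}
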