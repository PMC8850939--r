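#' Estimate propensity scores
#'
#' Fits a logistic regression of PEG-arm membership on the specified
#' covariates and returns the fitted probabilities. Covariates that are
#' constant across the cohort (e.g. gender in an all-female breast-cancer
#' sample) are dropped with a warning rather than breaking the fit; complete
#' or quasi-complete separation is reported as an error advising covariate
#' review.
#'
#' @param records cohort data.frame (see [generate_cohort()])
#' @param covariates character vector of column names; default mirrors the
#'   published matching set: age, insurance type, and the number of
#'   concomitant diseases (gender is constant here and so drops out)
#' @return numeric vector of propensity scores in `[0,1]`, named by
#'   `patient_id`, with the fitted model in the `"model"` attribute
#' @export
estimate_propensity <- function(records,
                                covariates = c("age", "insurance_type",
                                               "n_concomitant_diseases")) {
  if (!all(c("PEG", "RHG") %in% records$arm) ||
      sum(records$arm == "PEG") < 2L || sum(records$arm == "RHG") < 2L) {
    stop("need at least 2 patients per arm to fit a propensity model", call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    stop(sprintf("covariate(s) not present on the records: %s",
                 paste(missing_cov, collapse = ", ")), call. = FALSE)
  }
  constant <- covariates[vapply(covariates, function(v) {
    length(unique(records[[v]])) < 2L
  }, logical(1))]
  if (length(constant)) {
    warning(sprintf("dropping constant covariate(s): %s",
                    paste(constant, collapse = ", ")), call. = FALSE)
    covariates <- setdiff(covariates, constant)
  }
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f <- stats::as.formula(paste("I(arm == \"PEG\") ~", rhs))
  fit <- withCallingHandlers(
    stats::glm(f, data = records, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        stop(paste("perfect separation in the propensity model;",
                   "review the covariate list"), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  fitted_p <- as.numeric(stats::fitted(fit))
  if (any(fitted_p > 1 - 1e-8) || any(fitted_p < 1e-8)) {
    stop(paste("perfect separation in the propensity model;",
               "review the covariate list"), call. = FALSE)
  }
  scores <- stats::setNames(fitted_p, records$patient_id)
  attr(scores, "model") <- fit
  scores
}

#' Greedy 1:1 nearest-neighbour matching on the propensity score
#'
#' Matches each PEG (treated) patient to the nearest rhG (control) patient
#' by absolute propensity-score difference, without replacement. Treated
#' patients are processed in descending score order (hardest-to-match
#' first); distance ties go to the control with the lexicographically
#' smallest `patient_id`. An optional caliper on the logit of the score
#' discards pairs farther apart than the threshold; the conventional width
#' is `0.2 * sd(logit(score))`, exposed as [default_caliper()].
#'
#' @param records cohort data.frame
#' @param scores named score vector from [estimate_propensity()]
#' @param caliper maximum allowed `|logit(ps_peg) - logit(ps_rhg)|`, or
#'   `NULL` for no caliper
#' @return object of class `matched_cohort`: list with `pairs` (data.frame
#'   `peg_id, rhg_id, ps_peg, ps_rhg`), `n_matched_per_arm`, `mean_ps_peg`,
#'   `mean_ps_rhg`, and the caliper used
#' @export
match_1to1 <- function(records, scores, caliper = NULL) {
  if (!all(records$patient_id %in% names(scores))) {
    stop("scores are missing for some patients", call. = FALSE)
  }
  scores <- scores[records$patient_id]
  treated <- records$patient_id[records$arm == "PEG"]
  control <- records$patient_id[records$arm == "RHG"]
  s_t <- as.numeric(scores[treated])
  s_c <- as.numeric(scores[control])
  ## process hardest-to-match (highest-score) treated patients first
  ord <- order(-s_t, treated)
  available <- rep(TRUE, length(control))
  eps <- 1e-12
  pairs <- vector("list", length(treated))
  k <- 0L
  for (i in ord) {
    if (!any(available)) break
    d <- abs(s_c - s_t[i])
    d[!available] <- Inf
    best <- min(d)
    if (!is.finite(best)) break
    cand <- which(d <= best + eps)
    j <- cand[order(control[cand])][1L]
    if (!is.null(caliper)) {
      gap <- abs(logit(pmin(pmax(s_t[i], eps), 1 - eps)) -
                 logit(pmin(pmax(s_c[j], eps), 1 - eps)))
      if (gap > caliper) next
    }
    available[j] <- FALSE
    k <- k + 1L
    pairs[[k]] <- data.frame(peg_id = treated[i], rhg_id = control[j],
                             ps_peg = s_t[i], ps_rhg = s_c[j],
                             stringsAsFactors = FALSE)
  }
  if (k == 0L) {
    warning("no pairs within the caliper; returning an empty matched cohort",
            call. = FALSE)
    pairs_df <- data.frame(peg_id = character(0), rhg_id = character(0),
                           ps_peg = numeric(0), ps_rhg = numeric(0),
                           stringsAsFactors = FALSE)
  } else {
    pairs_df <- do.call(rbind, pairs[seq_len(k)])
    pairs_df <- pairs_df[order(pairs_df$peg_id), , drop = FALSE]
    rownames(pairs_df) <- NULL
  }
  out <- list(pairs = pairs_df,
              n_matched_per_arm = nrow(pairs_df),
              mean_ps_peg = if (k) mean(pairs_df$ps_peg) else NA_real_,
              mean_ps_rhg = if (k) mean(pairs_df$ps_rhg) else NA_real_,
              caliper = caliper)
  class(out) <- "matched_cohort"
  out
}

#' Conventional caliper width
#'
#' @param scores propensity scores
#' @param mult multiplier, default 0.2
#' @return `mult * sd(logit(scores))`
#' @export
default_caliper <- function(scores, mult = 0.2) {
  s <- pmin(pmax(as.numeric(scores), 1e-12), 1 - 1e-12)
  mult * stats::sd(logit(s))
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("1:1 matched cohort: %d pairs (caliper %s)\n",
              x$n_matched_per_arm,
              if (is.null(x$caliper)) "none" else format(x$caliper, digits = 4)))
  cat(sprintf("mean propensity score: PEG %.3f, rhG %.3f\n",
              x$mean_ps_peg, x$mean_ps_rhg))
  invisible(x)
}

smd_continuous <- function(x1, x2) {
  pooled <- sqrt((stats::var(x1) + stats::var(x2)) / 2)
  if (!is.finite(pooled) || pooled == 0) {
    if (isTRUE(all.equal(mean(x1), mean(x2)))) return(0)
    return(NA_real_)  # undefined: different means, zero pooled SD
  }
  (mean(x1) - mean(x2)) / pooled
}

#' Covariate balance before and after matching
#'
#' Standardized mean differences (continuous covariates: difference in
#' means over the pooled SD; binary covariates and category indicators:
#' raw proportion difference) between the PEG and rhG arms, before
#' matching and within the matched sample. A zero-pooled-SD covariate with
#' equal means is reported as 0; with unequal means it is flagged `NA`
#' (undefined).
#'
#' @param records full cohort data.frame
#' @param matched a [match_1to1()] result
#' @param covariates covariate columns to diagnose
#' @return data.frame `covariate, smd_before, smd_after` of class
#'   `balance_table`
#' @export
balance_table <- function(records, matched,
                          covariates = c("age", "insurance_type",
                                         "n_concomitant_diseases", "surgery")) {
  if (!inherits(matched, "matched_cohort") || matched$n_matched_per_arm == 0L) {
    stop("matched cohort is empty; nothing to diagnose", call. = FALSE)
  }
  expand <- function(d) {
    cols <- list()
    for (v in covariates) {
      x <- d[[v]]
      if (is.numeric(x)) {
        cols[[v]] <- x
      } else if (is.logical(x)) {
        cols[[v]] <- as.numeric(x)
      } else {
        for (lev in sort(unique(records[[v]]))) {
          cols[[paste0(v, "=", lev)]] <- as.numeric(x == lev)
        }
      }
    }
    as.data.frame(cols, check.names = FALSE)
  }
  one_pass <- function(d) {
    X <- expand(d)
    trt <- d$arm == "PEG"
    vapply(names(X), function(nm) {
      x1 <- X[[nm]][trt]; x2 <- X[[nm]][!trt]
      binary <- all(X[[nm]] %in% c(0, 1))
      if (binary) mean(x1) - mean(x2) else smd_continuous(x1, x2)
    }, numeric(1))
  }
  before <- one_pass(records)
  kept <- records[records$patient_id %in%
                    c(matched$pairs$peg_id, matched$pairs$rhg_id), , drop = FALSE]
  after <- one_pass(kept)
  out <- data.frame(covariate = names(before),
                    smd_before = as.numeric(before),
                    smd_after = as.numeric(after),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("balance_table", "data.frame")
  out
}

#' Write matched pairs and balance table to CSV
#'
#' @param matched a [match_1to1()] result
#' @param balance a [balance_table()] result
#' @param pairs_path,balance_path output paths
#' @return invisibly, the two paths
#' @export
write_matching_csv <- function(matched, balance, pairs_path, balance_path) {
  utils::write.csv(matched$pairs, pairs_path, row.names = FALSE)
  utils::write.csv(balance, balance_path, row.names = FALSE)
  invisible(c(pairs_path, balance_path))
}
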