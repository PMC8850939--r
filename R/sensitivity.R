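#' Distribution specification for probabilistic sensitivity analysis
#'
#' A beta or gamma distribution given either explicitly (`alpha`, `beta` =
#' shape/shape for beta, shape/rate for gamma) or by moments (`mean`,
#' `se`), solved by the method of moments; or a degenerate `"fixed"` spec.
#'
#' @param kind `"beta"`, `"gamma"` or `"fixed"`
#' @param mean,se moment parameterization
#' @param alpha,beta explicit parameterization (both > 0)
#' @param value the constant for `"fixed"` specs
#' @return object of class `dist_spec`
#' @examples
#' fit_distribution(dist_spec("beta", alpha = 289, beta = 881))$mean  # 0.2470
#' @export
dist_spec <- function(kind = c("beta", "gamma", "fixed"),
                      mean = NULL, se = NULL, alpha = NULL, beta = NULL,
                      value = NULL) {
  kind <- match.arg(kind)
  spec <- list(kind = kind, mean = mean, se = se, alpha = alpha, beta = beta,
               value = value)
  class(spec) <- "dist_spec"
  spec
}

#' Turn a distribution spec into a sampler
#'
#' Explicit specs use the given shape parameters; moment specs solve the
#' beta (`alpha = m*nu, beta = (1-m)*nu` with `nu = m(1-m)/s^2 - 1`) or
#' gamma (`shape = (m/s)^2, rate = m/s^2`) parameters from `(mean, se)`.
#' A moment-mode mean outside the distribution's support, or a beta SE too
#' large for the mean (`s^2 >= m(1-m)`), is an error.
#'
#' @param spec a [dist_spec()]
#' @return list with `sample(n)` (draws from the shared RNG stream, so
#'   reproducible under `set.seed`) and the analytic `mean`
#' @export
fit_distribution <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$kind == "fixed") {
    v <- spec$value %||% spec$mean
    if (is.null(v)) stop("fixed spec needs a 'value'", call. = FALSE)
    return(list(sample = function(n) rep(v, n), mean = v))
  }
  if (!is.null(spec$alpha) && !is.null(spec$beta)) {
    a <- spec$alpha; b <- spec$beta
    if (a <= 0 || b <= 0) stop("explicit shape parameters must be positive", call. = FALSE)
  } else {
    m <- spec$mean; s <- spec$se
    if (is.null(m) || is.null(s)) {
      stop("spec needs either (alpha, beta) or (mean, se)", call. = FALSE)
    }
    if (spec$kind == "beta") {
      if (m <= 0 || m >= 1) {
        stop(sprintf("beta moment mode needs a mean in (0,1), got %g", m), call. = FALSE)
      }
      if (s^2 >= m * (1 - m)) {
        stop("beta moment mode: se too large for the given mean", call. = FALSE)
      }
      nu <- m * (1 - m) / s^2 - 1
      a <- m * nu; b <- (1 - m) * nu
    } else {
      if (m <= 0) stop(sprintf("gamma moment mode needs a positive mean, got %g", m),
                       call. = FALSE)
      a <- (m / s)^2; b <- m / s^2   # shape, rate
    }
  }
  if (spec$kind == "beta") {
    list(sample = function(n) stats::rbeta(n, a, b), mean = a / (a + b))
  } else {
    list(sample = function(n) stats::rgamma(n, shape = a, rate = b), mean = a / b)
  }
}

#' Default PSA distribution set
#'
#' One [dist_spec()] per sampled parameter: published alpha/beta pairs
#' where the source reports them (RDI risks, survivor utilities), and
#' moment-matched distributions at SE = 15% of the current value elsewhere
#' (probabilities and utilities beta, costs and RR/OR/HR gamma) — the same
#' 15% spread the one-way analysis varies parameters by. Structural
#' quantities and discount rates stay fixed. Set `explicit = FALSE` to
#' force moment matching everywhere (every distribution then centred on
#' the current parameter value).
#'
#' @param params a [cea_parameters()] object
#' @param se_frac moment-mode SE as a fraction of the mean
#' @param explicit use published alpha/beta pairs where available
#' @return named list of `dist_spec` objects
#' @export
default_psa_specs <- function(params, se_frac = 0.15, explicit = TRUE) {
  reg <- param_registry()
  sampled <- reg[reg$psa %in% c("beta", "gamma"), , drop = FALSE]
  ## ratio measures are sampled as gamma around their point estimate
  specs <- lapply(seq_len(nrow(sampled)), function(i) {
    nm <- sampled$name[i]
    m <- params[[nm]]
    if (explicit && !is.na(sampled$alpha[i])) {
      dist_spec(sampled$psa[i], alpha = sampled$alpha[i], beta = sampled$beta[i])
    } else if (m == 0) {
      dist_spec("fixed", value = 0)
    } else {
      dist_spec(sampled$psa[i], mean = m, se = se_frac * m)
    }
  })
  stats::setNames(specs, sampled$name)
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte-Carlo resampling of the full two-model pipeline: for each draw,
#' every sampled parameter is drawn from its distribution (in fixed
#' alphabetical order, so the stream is reproducible given the seed), both
#' models are run for both arms, and the incremental cost and QALYs are
#' recorded. A draw whose parameter vector fails model validation is
#' recorded as `NA` and logged with its index.
#'
#' @param params base-case [cea_parameters()]
#' @param specs named list of [dist_spec()] (default [default_psa_specs()])
#' @param n_draws number of Monte-Carlo draws
#' @param seed integer seed
#' @param life_table life table for the survival model (default synthetic)
#' @return object of class `psa_cloud`: data.frame with columns `draw`,
#'   `dcost`, `dqaly_chemo`, `dqaly_post`, `dqaly_total`; the sampled
#'   parameter matrix, seed and specs ride along as attributes
#' @export
run_psa <- function(params, specs = default_psa_specs(params),
                    n_draws = 1000, seed = 1, life_table = NULL) {
  validate_parameters(params)
  if (n_draws < 1) stop("n_draws must be at least 1", call. = FALSE)
  if (is.null(life_table)) life_table <- make_life_table(entry_age = params$start_age)
  reg_names <- param_registry()$name
  bad <- setdiff(names(specs), reg_names)
  if (length(bad)) {
    stop(sprintf("specs given for unknown parameter(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  nm_order <- sort(names(specs))
  samplers <- lapply(specs[nm_order], fit_distribution)
  set.seed(as.integer(seed))
  draws <- matrix(NA_real_, n_draws, length(nm_order),
                  dimnames = list(NULL, nm_order))
  for (j in seq_along(nm_order)) draws[, j] <- samplers[[j]]$sample(n_draws)
  res <- matrix(NA_real_, n_draws, 4,
                dimnames = list(NULL, c("dcost", "dqaly_chemo", "dqaly_post",
                                        "dqaly_total")))
  failed <- integer(0)
  for (i in seq_len(n_draws)) {
    p_i <- params
    for (nm in nm_order) p_i[[nm]] <- draws[i, nm]
    ok <- tryCatch({
      validate_parameters(p_i)
      fit <- run_cea(p_i, life_table = life_table)
      res[i, ] <- c(fit$comparison$chemo$inc_cost,
                    fit$comparison$chemo$inc_qaly,
                    fit$comparison$post$inc_qaly,
                    fit$comparison$total$inc_qaly)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failed <- c(failed, i)
  }
  if (length(failed)) {
    warning(sprintf("%d PSA draw(s) failed model validation (indices: %s)",
                    length(failed),
                    paste(utils::head(failed, 10), collapse = ", ")),
            call. = FALSE)
  }
  cloud <- data.frame(draw = seq_len(n_draws), res)
  attr(cloud, "parameters") <- draws
  attr(cloud, "seed") <- as.integer(seed)
  attr(cloud, "specs") <- specs
  attr(cloud, "failed") <- failed
  class(cloud) <- c("psa_cloud", "data.frame")
  cloud
}

#' @export
print.psa_cloud <- function(x, ...) {
  cat(sprintf("PSA cloud: %d draws (seed %d, %d failed)\n",
              nrow(x), attr(x, "seed"), length(attr(x, "failed"))))
  cat(sprintf("mean dcost %.2f CNY; mean dQALY %.4f (chemo) / %.4f (total)\n",
              mean(x$dcost, na.rm = TRUE), mean(x$dqaly_chemo, na.rm = TRUE),
              mean(x$dqaly_total, na.rm = TRUE)))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value `lambda`, the fraction of PSA draws
#' with positive net monetary benefit `lambda * dQALY - dcost > 0`. At
#' `lambda = 0` this is the fraction of cost-saving draws.
#'
#' @param cloud a [run_psa()] cloud
#' @param wtp_grid non-negative WTP values, CNY/QALY
#' @param qaly which QALY horizon the draws are judged on
#' @return data.frame `wtp, probability` of class `ceac`
#' @export
ceac <- function(cloud, wtp_grid = seq(0, 2e5, by = 5000),
                 qaly = c("total", "chemo", "post")) {
  qaly <- match.arg(qaly)
  if (length(wtp_grid) == 0) stop("wtp_grid must be nonempty", call. = FALSE)
  if (any(wtp_grid < 0)) stop("WTP values must be non-negative", call. = FALSE)
  if (nrow(cloud) == 0) stop("PSA cloud is empty", call. = FALSE)
  dq <- cloud[[paste0("dqaly_", qaly)]]
  dc <- cloud$dcost
  keep <- !is.na(dq) & !is.na(dc)
  dq <- dq[keep]; dc <- dc[keep]
  prob <- vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
  out <- data.frame(wtp = wtp_grid, probability = prob)
  class(out) <- c("ceac", "data.frame")
  out
}

#' Export the cost-effectiveness plane
#'
#' One row per draw with its plane quadrant (x = incremental QALYs, y =
#' incremental cost): `NE` costlier and more effective, `SE` dominant
#' (cheaper, more effective), `NW` dominated, `SW` cheaper and less
#' effective.
#'
#' @inheritParams ceac
#' @param path optional CSV path
#' @return data.frame `draw, dqaly, dcost, quadrant`
#' @export
ce_plane_export <- function(cloud, qaly = c("total", "chemo", "post"),
                            path = NULL) {
  qaly <- match.arg(qaly)
  if (nrow(cloud) == 0) stop("PSA cloud is empty", call. = FALSE)
  dq <- cloud[[paste0("dqaly_", qaly)]]
  dc <- cloud$dcost
  quadrant <- paste0(ifelse(dc >= 0, "N", "S"), ifelse(dq >= 0, "E", "W"))
  quadrant[is.na(dq) | is.na(dc)] <- NA
  out <- data.frame(draw = cloud$draw, dqaly = dq, dcost = dc,
                    quadrant = quadrant, stringsAsFactors = FALSE)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' @export
plot.psa_cloud <- function(x, qaly = "total", wtp = NULL, ...) {
  pl <- ce_plane_export(x, qaly = qaly)
  graphics::plot(pl$dqaly, pl$dcost, pch = 16, cex = 0.5,
                 col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "incremental QALYs", ylab = "incremental cost (CNY)",
                 main = "Cost-effectiveness plane")
  graphics::abline(h = 0, v = 0, col = "grey60")
  if (!is.null(wtp)) graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(x)
}

#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$probability, type = "l", ylim = c(0, 1),
                 xlab = "willingness to pay (CNY/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability curve")
  invisible(x)
}

#' Default one-way sensitivity ranges
#'
#' Every sampled parameter varied by +/-15% of its base value
#' (probabilities and utilities capped at 1), the annual discount rate of
#' the survival model swept 3-7%, and the time horizon 25-45 years.
#'
#' @param params a [cea_parameters()] object
#' @param frac relative half-width of the default range
#' @return data.frame `parameter, low, high, source`
#' @export
default_dsa_ranges <- function(params, frac = 0.15) {
  reg <- param_registry()
  sampled <- reg[reg$psa %in% c("beta", "gamma"), , drop = FALSE]
  rows <- lapply(sampled$name, function(nm) {
    base <- params[[nm]]
    up <- base * (1 + frac)
    if (sampled$upper[match(nm, sampled$name)] == 1) up <- min(up, 1)
    data.frame(parameter = nm, low = base * (1 - frac), high = up,
               source = "pct15", stringsAsFactors = FALSE)
  })
  rows <- c(rows, list(
    data.frame(parameter = "discount_post", low = 0.03, high = 0.07,
               source = "discount_3_7", stringsAsFactors = FALSE),
    data.frame(parameter = "horizon_years", low = 25, high = 45,
               source = "horizon", stringsAsFactors = FALSE)
  ))
  do.call(rbind, rows)
}

#' One-way deterministic sensitivity analysis
#'
#' Reruns the full two-model pipeline at each parameter's low and high
#' value (all others at base) and records the chosen incremental outcome,
#' returning tornado entries sorted by descending swing
#' `|outcome_high - outcome_low|` (ties broken alphabetically).
#'
#' @param params base-case [cea_parameters()]
#' @param ranges data.frame `parameter, low, high` (default
#'   [default_dsa_ranges()]); each range must bracket the base value
#' @param outcome `"incremental_cost"` or `"incremental_qaly"`
#' @param horizon QALY horizon for `"incremental_qaly"`
#' @param life_table life table (default synthetic)
#' @return data.frame of class `tornado` with columns `parameter, low,
#'   high, outcome_low, outcome_high, swing` plus the base-case outcome in
#'   the `"base_outcome"` attribute
#' @export
one_way_dsa <- function(params, ranges = default_dsa_ranges(params),
                        outcome = c("incremental_cost", "incremental_qaly"),
                        horizon = c("total", "chemo", "post"),
                        life_table = NULL) {
  outcome <- match.arg(outcome)
  horizon <- match.arg(horizon)
  validate_parameters(params)
  if (is.null(life_table)) life_table <- make_life_table(entry_age = params$start_age)
  reg_names <- param_registry()$name
  unknown <- setdiff(ranges$parameter, reg_names)
  if (length(unknown)) {
    stop(sprintf("unknown DSA parameter(s): %s; valid names: %s",
                 paste(unknown, collapse = ", "),
                 paste(reg_names, collapse = ", ")), call. = FALSE)
  }
  extract <- function(fit) {
    if (outcome == "incremental_cost") fit$comparison$chemo$inc_cost
    else fit$comparison[[horizon]]$inc_qaly
  }
  base_val <- extract(run_cea(params, life_table = life_table))
  eval_at <- function(nm, value) {
    extract(run_cea(set_parameter(params, nm, value), life_table = life_table))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(ranges)), function(i) {
    nm <- ranges$parameter[i]
    lo <- ranges$low[i]; hi <- ranges$high[i]
    base <- params[[nm]]
    if (lo > base || hi < base) {
      stop(sprintf("range for '%s' [%g, %g] does not bracket the base value %g",
                   nm, lo, hi, base), call. = FALSE)
    }
    data.frame(parameter = nm, low = lo, high = hi,
               outcome_low = eval_at(nm, lo), outcome_high = eval_at(nm, hi),
               stringsAsFactors = FALSE)
  }))
  out$swing <- abs(out$outcome_high - out$outcome_low)
  out <- out[order(-out$swing, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "base_outcome") <- base_val
  attr(out, "outcome") <- outcome
  class(out) <- c("tornado", "data.frame")
  out
}

#' @export
plot.tornado <- function(x, n_top = 12, ...) {
  d <- utils::head(x, n_top)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_outcome")
  graphics::par(mar = c(4, 12, 3, 1))
  graphics::plot(NULL, xlim = range(c(d$outcome_low, d$outcome_high, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = attr(x, "outcome"), ylab = "",
                 main = "One-way sensitivity analysis")
  for (i in seq_len(nrow(d))) {
    graphics::segments(d$outcome_low[i], i, d$outcome_high[i], i, lwd = 8,
                       col = "steelblue")
  }
  graphics::abline(v = base, lty = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Write sensitivity-analysis tables to CSV
#'
#' @param tornado a [one_way_dsa()] result
#' @param ceac_table a [ceac()] result
#' @param tornado_path,ceac_path output paths
#' @return invisibly, the paths
#' @export
write_sensitivity_csv <- function(tornado, ceac_table, tornado_path, ceac_path) {
  utils::write.csv(tornado, tornado_path, row.names = FALSE)
  utils::write.csv(ceac_table, ceac_path, row.names = FALSE)
  invisible(c(tornado_path, ceac_path))
}
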