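#' Incremental cost-effectiveness comparison
#'
#' Computes incremental cost, incremental QALYs, the ICER (flagged
#' undefined when the QALY difference is zero; the intervention is labelled
#' dominant when it costs no more and yields strictly more QALYs, dominated
#' in the mirror case), and the net monetary benefit
#' `NMB = wtp * dQALY - dcost`.
#'
#' @param cost1,qaly1 intervention totals
#' @param cost0,qaly0 comparator totals
#' @param wtp willingness-to-pay, CNY/QALY
#' @param labels length-2 character vector naming the strategies
#' @return object of class `cea_result`
#' @examples
#' cea_compare(146091, 3.456, 146055, 3.352)  # ICER 346.15 CNY/QALY
#' @export
cea_compare <- function(cost1, qaly1, cost0, qaly0, wtp = 72371,
                        labels = c("intervention", "comparator")) {
  inc_cost <- cost1 - cost0
  inc_qaly <- qaly1 - qaly0
  icer_defined <- inc_qaly != 0
  icer <- if (icer_defined) inc_cost / inc_qaly else NA_real_
  status <- if (inc_cost <= 0 && inc_qaly > 0) "dominant"
  else if (inc_cost >= 0 && inc_qaly < 0) "dominated"
  else "trade-off"
  out <- list(labels = labels,
              cost1 = cost1, qaly1 = qaly1, cost0 = cost0, qaly0 = qaly0,
              inc_cost = inc_cost, inc_qaly = inc_qaly,
              icer = icer, icer_defined = icer_defined,
              status = status, wtp = wtp,
              nmb = wtp * inc_qaly - inc_cost)
  class(out) <- "cea_result"
  out
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("%s vs %s (WTP %.0f CNY/QALY)\n", x$labels[1], x$labels[2], x$wtp))
  cat(sprintf("  incremental cost:  %10.2f CNY\n", x$inc_cost))
  cat(sprintf("  incremental QALYs: %10.4f\n", x$inc_qaly))
  if (x$icer_defined) {
    cat(sprintf("  ICER: %.2f CNY/QALY (%s)\n", x$icer, x$status))
  } else {
    cat(sprintf("  ICER: undefined (zero QALY difference; %s)\n", x$status))
  }
  cat(sprintf("  NMB at WTP: %.2f CNY\n", x$nmb))
  invisible(x)
}

#' Run the full two-model cost-effectiveness analysis
#'
#' Runs the 12-week chemotherapy model and the 35-year post-chemotherapy
#' survival model for both G-CSF arms, links them through each arm's
#' course-level FN probability, and assembles the incremental comparisons
#' at the three horizons (chemotherapy-phase, post-chemotherapy, and
#' combined). The chemotherapy model carries all costs; the survival model
#' carries only QALYs.
#'
#' @param params a [cea_parameters()] object
#' @param life_table a life table (default: the package's synthetic
#'   [make_life_table()] anchored at the parameter set's entry age)
#' @param wtp willingness-to-pay, CNY/QALY (default: the parameter set's)
#' @return object of class `cea`, with `chemo` and `post` per-arm outcome
#'   pairs and `comparison` (list of `cea_result` at horizons `chemo`,
#'   `post`, `total`); supports `print`, `summary`, `plot`, and
#'   [simulate.cea()] for probabilistic sensitivity analysis
#' @examples
#' fit <- run_cea(cea_parameters())
#' fit
#' summary(fit)
#' @export
run_cea <- function(params = cea_parameters(), life_table = NULL, wtp = NULL) {
  validate_parameters(params)
  if (is.null(life_table)) {
    life_table <- make_life_table(entry_age = params$start_age)
  }
  wtp <- wtp %||% params$wtp
  chemo <- list(PEG = run_chemo_arm(params, "PEG"),
                RHG = run_chemo_arm(params, "RHG"))
  post <- list(
    PEG = run_postchemo_arm(params, life_table, chemo$PEG$p_fn_course),
    RHG = run_postchemo_arm(params, life_table, chemo$RHG$p_fn_course)
  )
  comparison <- list(
    chemo = cea_compare(chemo$PEG$total_cost, chemo$PEG$total_qalys,
                        chemo$RHG$total_cost, chemo$RHG$total_qalys,
                        wtp = wtp, labels = c("PEG-rhG-CSF", "rhG-CSF")),
    post = cea_compare(0, post$PEG$total_qalys, 0, post$RHG$total_qalys,
                       wtp = wtp, labels = c("PEG-rhG-CSF", "rhG-CSF")),
    total = cea_compare(chemo$PEG$total_cost,
                        chemo$PEG$total_qalys + post$PEG$total_qalys,
                        chemo$RHG$total_cost,
                        chemo$RHG$total_qalys + post$RHG$total_qalys,
                        wtp = wtp, labels = c("PEG-rhG-CSF", "rhG-CSF"))
  )
  out <- list(params = params, life_table = life_table, wtp = wtp,
              chemo = chemo, post = post, comparison = comparison)
  class(out) <- "cea"
  out
}

#' @export
print.cea <- function(x, ...) {
  cat("Two-model G-CSF cost-effectiveness analysis (2019 CNY)\n\n")
  tab <- data.frame(
    strategy = c("PEG-rhG-CSF", "rhG-CSF"),
    cost = c(x$chemo$PEG$total_cost, x$chemo$RHG$total_cost),
    qalys_chemo = c(x$chemo$PEG$total_qalys, x$chemo$RHG$total_qalys),
    qalys_post = c(x$post$PEG$total_qalys, x$post$RHG$total_qalys)
  )
  print(tab, row.names = FALSE, digits = 6)
  cc <- x$comparison
  cat(sprintf("\nincremental cost %.2f CNY; incremental QALYs %.4f (chemo) / %.4f (post) / %.4f (total)\n",
              cc$chemo$inc_cost, cc$chemo$inc_qaly, cc$post$inc_qaly,
              cc$total$inc_qaly))
  if (cc$total$icer_defined) {
    cat(sprintf("ICER (combined horizon): %.2f CNY/QALY [%s]\n",
                cc$total$icer, cc$total$status))
  }
  invisible(x)
}

#' @export
summary.cea <- function(object, ...) {
  x <- object
  s <- list(
    table = data.frame(
      strategy = c("PEG-rhG-CSF", "rhG-CSF"),
      cost = c(x$chemo$PEG$total_cost, x$chemo$RHG$total_cost),
      qalys_chemo = c(x$chemo$PEG$total_qalys, x$chemo$RHG$total_qalys),
      qalys_post = c(x$post$PEG$total_qalys, x$post$RHG$total_qalys),
      fn_per_1000 = c(x$chemo$PEG$fn_per_1000, x$chemo$RHG$fn_per_1000),
      inf_per_1000 = c(x$chemo$PEG$inf_per_1000, x$chemo$RHG$inf_per_1000),
      deaths_per_1000 = c(x$chemo$PEG$deaths_per_1000,
                          x$chemo$RHG$deaths_per_1000)
    ),
    comparison = x$comparison,
    wtp = x$wtp
  )
  class(s) <- "summary.cea"
  s
}

#' @export
print.summary.cea <- function(x, ...) {
  cat("Per-arm outcomes\n")
  print(x$table, row.names = FALSE, digits = 6)
  cat("\nIncremental comparisons\n")
  for (h in names(x$comparison)) {
    cc <- x$comparison[[h]]
    cat(sprintf("  %-6s dCost %9.2f  dQALY %8.4f  %s\n", h,
                cc$inc_cost, cc$inc_qaly,
                if (cc$icer_defined) sprintf("ICER %9.2f", cc$icer) else "ICER undefined"))
  }
  invisible(x)
}

#' Probabilistic sensitivity analysis of a fitted CEA
#'
#' `simulate()` on a [run_cea()] object dispatches to [run_psa()] with the
#' object's own parameters and life table.
#'
#' @param object a `cea` object
#' @param nsim number of Monte-Carlo draws
#' @param seed integer seed
#' @param ... passed to [run_psa()]
#' @return a [run_psa()] cloud
#' @export
simulate.cea <- function(object, nsim = 1000, seed = 1, ...) {
  run_psa(object$params, n_draws = nsim, seed = seed,
          life_table = object$life_table, ...)
}

#' Plot method for a fitted CEA
#'
#' `type = "trace"` draws the chemotherapy-model occupancy trace for both
#' arms; `type = "survival"` the post-chemotherapy survival curves.
#'
#' @param x a `cea` object
#' @param type `"trace"` or `"survival"`
#' @param ... ignored
#' @export
plot.cea <- function(x, type = c("trace", "survival"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    occ_peg <- x$chemo$PEG$trace$occupancy
    alive <- rowSums(occ_peg[, c("OnChemo", "FNa", "FNb", "InfA", "InfB",
                                 "Completed")])
    occ_rhg <- x$chemo$RHG$trace$occupancy
    alive_r <- rowSums(occ_rhg[, c("OnChemo", "FNa", "FNb", "InfA", "InfB",
                                   "Completed")])
    graphics::plot(0:(nrow(occ_peg) - 1), alive, type = "s", ylim = c(min(alive_r) - 0.005, 1),
                   xlab = "chemotherapy-model cycle", ylab = "fraction alive",
                   main = "Chemotherapy model: survival by arm")
    graphics::lines(0:(nrow(occ_rhg) - 1), alive_r, type = "s", lty = 2)
    graphics::legend("bottomleft", c("PEG-rhG-CSF", "rhG-CSF"), lty = 1:2, bty = "n")
  } else {
    tr_p <- x$post$PEG$trace
    tr_r <- x$post$RHG$trace
    if (is.null(tr_p)) stop("no post-chemotherapy trace (horizon 0)", call. = FALSE)
    alive_p <- 1 - tr_p$occupancy[, "Dead"]
    alive_r <- 1 - tr_r$occupancy[, "Dead"]
    graphics::plot(0:(length(alive_p) - 1), alive_p, type = "l",
                   xlab = "years since chemotherapy", ylab = "overall survival",
                   main = "Post-chemotherapy survival by arm")
    graphics::lines(0:(length(alive_r) - 1), alive_r, lty = 2)
    graphics::legend("bottomleft", c("PEG-rhG-CSF", "rhG-CSF"), lty = 1:2, bty = "n")
  }
  invisible(x)
}
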