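#' Highest posterior density interval
#'
#' The shortest contiguous interval of the sorted draws containing
#' `ceiling(prob * n)` draws. Ties between equally short windows are broken
#' toward the lower interval. Interval width is non-decreasing in `prob`.
#'
#' @param draws numeric vector of posterior draws (>= 2 unless all equal).
#' @param prob interval mass in (0, 1).
#' @return named numeric `c(lower, upper)`.
#' @export
hpdi <- function(draws, prob = 0.95) {
  if (length(draws) == 0) stop("empty draws")
  stopifnot(prob > 0, prob < 1)
  s <- sort(draws)
  n <- length(s)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = s[1], upper = s[n]))
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- which.min(widths)  # first minimum = lowest window
  c(lower = s[i], upper = s[i + m - 1])
}

#' Probability of direction
#'
#' Proportion of posterior draws in the predicted direction. Draws exactly
#' at zero are counted half toward each direction, so
#' `prob_direction(x, "positive") + prob_direction(x, "negative") = 1`
#' always holds.
#'
#' @param draws numeric vector of posterior draws (>= 1).
#' @param direction `"positive"` or `"negative"` — the hypothesised sign.
#' @return proportion in `[0, 1]`.
#' @export
prob_direction <- function(draws, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (length(draws) == 0) stop("empty draws")
  p <- (sum(draws > 0) + 0.5 * sum(draws == 0)) / length(draws)
  if (direction == "positive") p else 1 - p
}

#' Evidence classification for an effect
#'
#' Implements the inference rules used throughout: `"evidence"` when the
#' 95% HPDI excludes zero, `"weak"` when it overlaps zero but the
#' probability of direction exceeds 0.90, `"none"` otherwise.
#'
#' @param hpdi95 length-2 interval from [hpdi()].
#' @param pd probability of direction in the hypothesised direction.
#' @return one of `"evidence"`, `"weak"`, `"none"`.
#' @export
evidence_class <- function(hpdi95, pd) {
  if (hpdi95[1] > 0 || hpdi95[2] < 0) "evidence"
  else if (pd > 0.90) "weak"
  else "none"
}

#' Urban-vs-forest among-cluster variance contrast
#'
#' Compares the habitat-specific among-cluster variance draws at the
#' requested level: `"cluster_mean"` (among-cluster variance in mean trait
#' values, "parameter 1") or `"cluster_dispersion"` (among-cluster variance
#' in the log residual SD, "parameter 3"). Variances are computed per draw
#' as SD^2, preserving the nonlinearity; the difference draws are
#' urban - forest and pd is the proportion of difference draws matching the
#' predicted direction (ties split evenly).
#'
#' @param fit a [dhglm()] fit in categorical urbanisation mode.
#' @param level `"cluster_mean"` or `"cluster_dispersion"`.
#' @param direction predicted direction of the urban - forest difference
#'   (default `"positive"`: urban > forest).
#' @return object of class `variance_contrast`: per-draw urban and forest
#'   variances, difference and ratio draws, their summaries, `pd` and the
#'   evidence class.
#' @export
habitat_variance_contrast <- function(fit,
                                      level = c("cluster_mean",
                                                "cluster_dispersion"),
                                      direction = "positive") {
  level <- match.arg(level)
  if (!fit$design$hetero)
    stop("habitat-specific cluster variances are only fitted in ",
         "categorical urbanisation mode")
  sd_names <- if (level == "cluster_mean")
    c("sd_clust_m_forest", "sd_clust_m_urban") else
    c("sd_clust_d_forest", "sd_clust_d_urban")
  m <- dhglm_draws(fit, sd_names)
  var_forest <- m[, 1]^2
  var_urban <- m[, 2]^2
  diff <- var_urban - var_forest
  pd <- prob_direction(diff, direction)
  h95 <- hpdi(diff, 0.95)
  structure(list(
    level = level,
    var_urban = var_urban, var_forest = var_forest,
    diff = diff, ratio = var_urban / var_forest,
    estimate_urban = mean(var_urban), estimate_forest = mean(var_forest),
    estimate_diff = mean(diff), estimate_ratio = mean(var_urban) /
      mean(var_forest),
    hpdi95_diff = h95, hpdi50_diff = hpdi(diff, 0.5),
    pd = pd, direction = direction,
    evidence = evidence_class(h95, pd)),
    class = "variance_contrast")
}

#' @export
print.variance_contrast <- function(x, digits = 3, ...) {
  cat(sprintf("Among-cluster variance contrast (%s):\n", x$level))
  cat(sprintf("  urban %.3f vs forest %.3f (ratio of means %.2f)\n",
              x$estimate_urban, x$estimate_forest, x$estimate_ratio))
  cat(sprintf("  urban - forest: %.3f [%.3f, %.3f], pd(%s) = %.3f (%s)\n",
              x$estimate_diff, x$hpdi95_diff[1], x$hpdi95_diff[2],
              x$direction, x$pd, x$evidence))
  invisible(x)
}

#' Back-transform the dispersion-part urbanisation effect
#'
#' With a log link on the residual SD, an urbanisation coefficient `g`
#' multiplies the within-cluster residual SD by `exp(g)`, i.e. a
#' `100 * (exp(g) - 1)` percent change. Given the dispersion baseline
#' (forest log residual SD on the Z scale) and the trait's original-units
#' SD, the residual SDs are returned in original units.
#'
#' @param gamma_hab dispersion-part urban coefficient (scalar or draws).
#' @param baseline_log_sd dispersion-part forest baseline on the log scale
#'   (intercept plus any covariate contribution), same length or scalar.
#' @param trait_sd SD of the trait in original units (mm or days) used to
#'   undo the Z-transform (default 1 = stay on the model scale).
#' @return list with `pct_increase`, `sd_forest` and `sd_urban` (same
#'   length as the inputs).
#' @export
back_transform_dispersion <- function(gamma_hab, baseline_log_sd = 0,
                                      trait_sd = 1) {
  stopifnot(trait_sd > 0)
  list(pct_increase = 100 * (exp(gamma_hab) - 1),
       sd_forest = exp(baseline_log_sd) * trait_sd,
       sd_urban = exp(baseline_log_sd + gamma_hab) * trait_sd)
}

#' Posterior summary table for a DHGLM fit
#'
#' One row per fixed effect, random-effect SD and mean-dispersion
#' correlation in both model parts, with posterior mean and median, 95% and
#' 50% HPDIs, probability of direction (toward the sign of the posterior
#' median) and the evidence flags used in reporting: fixed effects and
#' correlations are flagged when the 95% HPDI excludes zero; random-effect
#' SDs when the 95% HPDI lies above 0.001. Random-effect rows additionally
#' carry the per-draw variance (SD^2) summaries.
#'
#' @param object a fitted [dhglm()] object.
#' @param ... unused.
#' @return a `summary.dhglm` object: a data frame of summary rows with the
#'   fit's convergence diagnostics attached.
#' @export
summary.dhglm <- function(object, ...) {
  m <- dhglm_draws(object)
  part_of <- function(p) {
    if (startsWith(p, "beta_") || p == "sd_year" || p == "sd_sys_m" ||
        p %in% c("sd_clust_m_forest", "sd_clust_m_urban", "sd_clust_m"))
      "mean" else "dispersion"
  }
  rows <- lapply(object$params, function(p) {
    x <- m[, p]
    h95 <- hpdi(x, 0.95); h50 <- hpdi(x, 0.5)
    med <- stats::median(x)
    pd <- prob_direction(x, if (med >= 0) "positive" else "negative")
    is_sd <- startsWith(p, "sd_")
    flag <- if (is_sd) h95[1] > 0.001 else (h95[1] > 0 || h95[2] < 0)
    ev <- if (is_sd) NA_character_ else evidence_class(h95, pd)
    vh <- if (is_sd) hpdi(x^2, 0.95) else c(NA_real_, NA_real_)
    data.frame(part = part_of(p), term = p,
               estimate = mean(x), median = med,
               hpdi95_lo = h95[1], hpdi95_hi = h95[2],
               hpdi50_lo = h50[1], hpdi50_hi = h50[2],
               pd = pd, flag = flag, evidence = ev,
               var_estimate = if (is_sd) mean(x^2) else NA_real_,
               var_hpdi95_lo = vh[1], var_hpdi95_hi = vh[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(match(out$part, c("mean", "dispersion"))), ]
  structure(list(table = out, diagnostics = object$diagnostics,
                 meta = object$design$meta, scale = object$design$scale),
            class = "summary.dhglm")
}

#' @export
print.summary.dhglm <- function(x, digits = 3, ...) {
  tab <- x$table
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  for (part in c("mean", "dispersion")) {
    sub <- tab[tab$part == part, ]
    if (!nrow(sub)) next
    cat(toupper(substring(part, 1, 1)), substring(part, 2), "part\n",
        sep = "")
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("  %-22s %s [%s, %s]%s\n", sub$term[i],
                  fmt(sub$estimate[i]), fmt(sub$hpdi95_lo[i]),
                  fmt(sub$hpdi95_hi[i]),
                  if (isTRUE(sub$flag[i])) " *" else ""))
    }
  }
  if (!is.null(x$diagnostics))
    cat(sprintf("Convergence: max split-Rhat %.3f, min ESS %.0f\n",
                max(x$diagnostics$table$rhat),
                min(x$diagnostics$table$ess)))
  invisible(x)
}

#' @export
plot.dhglm <- function(x, ...) {
  if (!x$design$hetero) {
    stop("plot.dhglm displays the habitat variance contrasts; ",
         "fit in categorical mode")
  }
  p1 <- habitat_variance_contrast(x, "cluster_mean")
  p3 <- habitat_variance_contrast(x, "cluster_dispersion")
  g <- dhglm_draws(x, grep("^gamma_(hab|isa)", x$params, value = TRUE)[1])
  items <- list(
    `forest var (mean)` = p1$var_forest,
    `urban var (mean)` = p1$var_urban,
    `urban effect (disp)` = as.numeric(g),
    `forest var (disp)` = p3$var_forest,
    `urban var (disp)` = p3$var_urban)
  est <- vapply(items, mean, numeric(1))
  h95 <- vapply(items, function(v) hpdi(v, 0.95), numeric(2))
  h50 <- vapply(items, function(v) hpdi(v, 0.5), numeric(2))
  k <- length(items)
  old <- graphics::par(mar = c(4, 11, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(est, seq_len(k), xlim = range(h95), ylim = c(0.5, k + 0.5),
                 yaxt = "n", ylab = "", xlab = "posterior value",
                 pch = 19, ...)
  graphics::axis(2, at = seq_len(k), labels = names(items), las = 1)
  graphics::segments(h95[1, ], seq_len(k), h95[2, ], seq_len(k), lwd = 1)
  graphics::segments(h50[1, ], seq_len(k), h50[2, ], seq_len(k), lwd = 3)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Export the summary rows in the flat file layout
#'
#' Flattens a [summary.dhglm()] into the column set written by
#' [write_summary_table()].
#'
#' @param s a `summary.dhglm` object.
#' @return data frame with one row per model term.
#' @export
summary_rows <- function(s) {
  stopifnot(inherits(s, "summary.dhglm"))
  s$table[, c("part", "term", "estimate", "median", "hpdi95_lo",
              "hpdi95_hi", "hpdi50_lo", "hpdi50_hi", "pd", "flag",
              "evidence", "var_estimate", "var_hpdi95_lo",
              "var_hpdi95_hi")]
}
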