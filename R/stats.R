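#' Fit the normal background-noise model from unedited controls
#'
#' Unedited control embryos carry a background of error-classified reads
#' (PCR/sequencing artifacts and somatic variation, typically a few percent
#' of reads). Their error fractions are modeled as normally distributed per
#' target site and analysis method; edited samples are later compared
#' against this distribution.
#'
#' @param control_summaries rbind-ed [summarize_embryo()] rows for at least
#'   two unedited control embryos from one target site and method.
#' @return an object of class `background_model`: list with `target`,
#'   `method`, `n_controls`, `mean` and `sd` (sample standard deviation,
#'   n - 1 denominator).
#' @export
fit_background <- function(control_summaries) {
  s <- control_summaries
  s <- s[!isTRUE(s$no_data) & !is.na(s$frac_error), , drop = FALSE]
  if (nrow(s) < 2L) stop("insufficient_controls: need >= 2 control embryos")
  if (length(unique(s$target[!is.na(s$target)])) > 1L)
    stop("control embryos from mixed target sites")
  if (length(unique(s$method)) > 1L)
    stop("control embryos analyzed with mixed methods")
  structure(list(target = s$target[1], method = s$method[1],
                 n_controls = nrow(s), mean = mean(s$frac_error),
                 sd = sd(s$frac_error)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("Background error model for target '", x$target, "' (method ",
      x$method, ")\n", sep = "")
  cat(sprintf("  %d controls: mean %.4f, sd %.4f\n", x$n_controls,
              x$mean, x$sd))
  invisible(x)
}

#' Call embryos positive for the precise edit
#'
#' A strict detection cutoff on the raw (unadjusted) precise-read
#' fraction: positive iff `frac_precise > cutoff`. An embryo at exactly
#' the cutoff is called unedited.
#'
#' @param summary an `embryo_summary` data.frame (one or more rows) or a
#'   numeric vector of precise fractions.
#' @param cutoff detection threshold (default 0.01, i.e. 1% of reads).
#' @return logical vector.
#' @export
call_precise <- function(summary, cutoff = 0.01) {
  frac <- if (is.data.frame(summary)) summary$frac_precise else summary
  frac > cutoff
}

#' One-sided z-test of excess errors against the background model
#'
#' Tests whether an embryo's error-read fraction exceeds the control
#' background: `z = (frac_error - mean) / sd`, upper-tail standard normal
#' p, significant iff `p < alpha / m_tests` (Bonferroni). A degenerate
#' background (sd = 0) is floored at `sd_floor` with a warning so that
#' small control groups remain testable.
#'
#' @param summary one or more `embryo_summary` rows.
#' @param model a [fit_background()] model for the same target and method.
#' @param alpha family-wise significance level (default 0.001).
#' @param m_tests Bonferroni family size; defaults to the number of
#'   embryos tested in this call.
#' @param sd_floor lower bound substituted for a zero model sd.
#' @return data.frame of class `editing_calls` with columns `embryo_id`,
#'   `frac_error`, `error_z`, `error_p`, `error_significant`, `m_tests`.
#' @export
test_errors <- function(summary, model, alpha = 0.001,
                        m_tests = nrow(summary), sd_floor = 1e-6) {
  stopifnot(inherits(model, "background_model"), m_tests >= 1L)
  check_background_match(summary, model)
  s <- model$sd
  if (s <= 0) {
    warning("background sd is zero; flooring at ", sd_floor)
    s <- sd_floor
  }
  z <- (summary$frac_error - model$mean) / s
  p <- pnorm(z, lower.tail = FALSE)
  out <- data.frame(embryo_id = summary$embryo_id,
                    frac_error = summary$frac_error,
                    error_z = z, error_p = p,
                    error_significant = p < alpha / m_tests,
                    m_tests = as.integer(m_tests),
                    stringsAsFactors = FALSE)
  class(out) <- c("editing_calls", "data.frame")
  out
}

#' Two-sample comparison of group values
#'
#' Two-sided two-sample t-test: pooled variance (Student) or
#' Welch-Satterthwaite degrees of freedom (Welch). When both groups are
#' essentially constant the test statistic is computed directly with each
#' group's standard deviation floored at `sd_floor` (with a warning)
#' rather than failing.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param variant `"student"` or `"welch"`.
#' @param sd_floor floor for degenerate (zero-variance) inputs.
#' @return list with `t`, `p` (two-sided), `df`, `mean_a`, `mean_b`.
#' @export
compare_groups <- function(a, b, variant = c("student", "welch"),
                           sd_floor = 1e-6) {
  variant <- match.arg(variant)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  pooled <- variant == "student"
  res <- tryCatch(t.test(a, b, var.equal = pooled),
                  error = function(e) NULL)
  if (is.null(res)) {
    warning("degenerate (constant) groups; flooring group sd at ", sd_floor)
    va <- max(stats::var(a), sd_floor^2)
    vb <- max(stats::var(b), sd_floor^2)
    na <- length(a); nb <- length(b)
    if (pooled) {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      se <- sqrt(sp2 * (1 / na + 1 / nb))
      df <- na + nb - 2
    } else {
      se <- sqrt(va / na + vb / nb)
      df <- (va / na + vb / nb)^2 /
        ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    }
    tt <- (mean(a) - mean(b)) / se
    return(list(t = tt, p = 2 * pt(-abs(tt), df), df = df,
                mean_a = mean(a), mean_b = mean(b)))
  }
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Correlation of predicted and observed editing efficiencies
#'
#' Pearson correlation between model-predicted efficiency scores and
#' observed (e.g. median per-group) precise-edit fractions, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))`, plus the
#' least-squares fit used for plotting.
#'
#' @param predicted numeric vector of predicted scores.
#' @param observed numeric vector of observed efficiencies, matched by
#'   edit.
#' @return list with `r`, `p`, `n`, `slope`, `intercept`.
#' @export
prediction_correlation <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(predicted) < 3L) stop("need at least 3 matched pairs")
  if (sd(predicted) == 0 || sd(observed) == 0)
    stop("zero variance in predicted or observed values")
  ct <- cor.test(predicted, observed, method = "pearson",
                 alternative = "two.sided")
  fit <- lm(observed ~ predicted)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(predicted),
       slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}
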