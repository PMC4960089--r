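# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
tidy.fst_null <- function(x, ...) {
  tibble(fst = x$values)
}

#' @export
glance.fst_null <- function(x, ...) {
  tibble(
    n = length(x$values), provenance = x$provenance,
    mean = mean(x$values), q95 = unname(quantile(x$values, 0.95))
  )
}

#' @export
print.fst_null <- function(x, ...) {
  cat("<fst_null> ", x$provenance, " null, ", length(x$values),
      " values (mean ", signif(mean(x$values), 3), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.ne_estimate <- function(x, ...) {
  x$grid
}

#' @export
glance.ne_estimate <- function(x, ...) {
  tibble(
    mle = x$mle, lower95 = x$lower95, upper95 = x$upper95,
    upper_unresolved = x$upper_unresolved, n_alleles = x$n_alleles
  )
}

#' @export
tidy.abc_posterior <- function(x, ...) {
  tibble(s = x$accepted_s)
}

#' @export
glance.abc_posterior <- function(x, ...) {
  tibble(
    median = x$median, ci_low = x$ci95[1], ci_high = x$ci95[2],
    n_accepted = x$n_accepted, n_sims_run = x$n_sims_run,
    acceptance_rate = x$acceptance_rate
  )
}

#' Plot an F_ST null distribution
#'
#' @param object An [fst_null][simulate_null()].
#' @param observed Optional observed theta to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fst_null <- function(object, observed = NULL, ...) {
  p <- ggplot(tidy(object), aes(x = .data$fst)) +
    geom_histogram(bins = 60, fill = "grey40") +
    labs(
      x = expression(F[ST]),
      y = "count",
      title = paste0(object$provenance, " null distribution")
    ) +
    theme_minimal()
  if (!is.null(observed)) {
    p <- p + geom_vline(xintercept = observed, colour = "firebrick",
                        linetype = 2)
  }
  p
}

#' Plot a relative log-likelihood curve for the effective size
#'
#' @param object An [ne_estimate][estimate_ne()].
#' @param ... Unused.
#' @return A ggplot with the profile curve, the -1.92 drop line and the MLE.
#' @export
autoplot.ne_estimate <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$ne, y = .data$rel_loglik)) +
    geom_line() +
    geom_hline(yintercept = -1.92, linetype = 2, colour = "grey50") +
    geom_vline(xintercept = object$mle, colour = "firebrick", linetype = 3) +
    scale_x_log10() +
    labs(x = "effective size Ne (diploid)",
         y = "relative log pseudo-likelihood") +
    theme_minimal()
}

#' Plot an ABC posterior for the selection coefficient
#'
#' @param object An [abc_posterior][abc_estimate_s()].
#' @param ... Unused.
#' @return A ggplot histogram of accepted draws with median and 95% interval.
#' @export
autoplot.abc_posterior <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$s)) +
    geom_histogram(bins = 40, fill = "grey40") +
    geom_vline(xintercept = object$median, colour = "firebrick") +
    geom_vline(xintercept = object$ci95, colour = "firebrick", linetype = 2) +
    xlim(0, 1) +
    labs(x = "selection coefficient s", y = "accepted draws") +
    theme_minimal()
}

#' @export
ggplot2::autoplot
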