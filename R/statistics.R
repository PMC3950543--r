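#' Normalized stress of every trace at chosen instants
#'
#' Internal workhorse shared by the summary table and the ANOVA: each
#' trace is normalized to its initial hold stress and linearly
#' interpolated (in log time) at the requested instants.
#'
#' @param dataset A `relaxation_dataset`.
#' @param instants Reporting times (s).
#' @return A tibble with one row per trace x instant: `donor_id`,
#'   `sample_id`, `strain_level`, `instant_s`, `ratio`.
#' @export
relaxation_at_instants <- function(dataset, instants = c(0.1, 6, 72, 240)) {
  traces <- dataset_traces(dataset, keep_meta = TRUE)
  rows <- lapply(traces, function(tr) {
    r <- .interp_ratio(normalize_trace(tr), instants)
    if (any(!is.finite(r))) {
      stop("an instant lies outside the support of trace ",
           attr(tr, "sample_id"), call. = FALSE)
    }
    tibble::tibble(donor_id = attr(tr, "donor_id"),
                   sample_id = attr(tr, "sample_id"),
                   strain_level = attr(tr, "strain_level"),
                   instant_s = instants, ratio = r)
  })
  do.call(rbind, rows)
}

#' Mean and SD of stress relaxation by strain level
#'
#' Reproduces the study's summary layout: for each imposed strain level,
#' the mean and sample standard deviation (n - 1 denominator) of the
#' normalized stress over samples, at the reporting instants of the
#' relaxation process.
#'
#' @param dataset A `relaxation_dataset`.
#' @param instants Reporting times (s), default 0.1, 6, 72 and 240 s.
#' @param donors Optional donor subset.
#' @return A tibble of class `relaxation_summary`: `strain_level`,
#'   `instant_s`, `mean`, `sd`, `n`.
#' @export
summarize_relaxation <- function(dataset, instants = c(0.1, 6, 72, 240),
                                 donors = NULL) {
  at <- relaxation_at_instants(dataset, instants)
  if (!is.null(donors)) at <- at[at$donor_id %in% donors, ]
  key <- interaction(at$strain_level, at$instant_s, drop = TRUE)
  agg <- lapply(split(at, key), function(g) {
    tibble::tibble(strain_level = g$strain_level[1],
                   instant_s = g$instant_s[1],
                   mean = mean(g$ratio),
                   sd = stats::sd(g$ratio),
                   n = nrow(g))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$strain_level, out$instant_s), ]
  rownames(out) <- NULL
  class(out) <- c("relaxation_summary", class(out))
  out
}

#' Format a relaxation summary as a wide "mean (SD)" table
#'
#' @param summary A `relaxation_summary` from [summarize_relaxation()].
#' @param digits Decimal places.
#' @return A data.frame with one row per strain level and one column per
#'   instant, cells formatted "mean (SD)".
#' @export
format_summary_table <- function(summary, digits = 2) {
  fmt <- function(m, s) sprintf("%.*f (%.*f)", digits, m, digits, s)
  levels_ <- sort(unique(summary$strain_level))
  instants <- sort(unique(summary$instant_s))
  out <- data.frame(strain = sprintf("%g%%", 100 * levels_))
  for (t in instants) {
    col <- vapply(levels_, function(l) {
      row <- summary[summary$strain_level == l & summary$instant_s == t, ]
      fmt(row$mean, row$sd)
    }, character(1))
    out[[sprintf("t = %g s", t)]] <- col
  }
  out
}

#' One-way ANOVA F statistic from group sums of squares
#'
#' Classical fixed-effects decomposition computed from first principles:
#' between-group sum of squares over its degrees of freedom divided by the
#' within-group mean square, with the p-value from the F distribution.
#'
#' @param groups A list of numeric vectors (one per group), each with at
#'   least 2 observations; at least 2 groups.
#' @return An object of class `anova_result`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `significant` (at the 0.05 level).
#' @export
oneway_f <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  ns <- lengths(groups)
  if (any(ns < 2)) stop("every group needs at least 2 observations",
                        call. = FALSE)
  all_y <- unlist(groups, use.names = FALSE)
  grand <- mean(all_y)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum(vapply(seq_along(groups), function(i) {
    sum((groups[[i]] - means[i])^2)
  }, numeric(1)))
  df_b <- length(groups) - 1L
  df_w <- sum(ns) - length(groups)
  if (ss_within == 0) {
    f <- if (ss_between == 0) 0 else Inf
  } else {
    f <- (ss_between / df_b) / (ss_within / df_w)
  }
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(f_stat = f, df_between = df_b, df_within = df_w,
                 p_value = p, significant = is.finite(p) && p < 0.05),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$f_stat, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Compare stress relaxation across strain levels by one-way ANOVA
#'
#' Tests whether the normalized stress at a given instant of the hold
#' differs between the imposed strain levels — the strain-invariance check
#' underpinning the quasi-linear viscoelasticity assumption. Donors are
#' pooled by default.
#'
#' @param dataset A `relaxation_dataset`.
#' @param instant Time (s) into the hold at which to compare.
#' @param donors Optional donor subset.
#' @return An `anova_result`.
#' @export
anova_by_strain <- function(dataset, instant, donors = NULL) {
  stopifnot(length(instant) == 1)
  at <- relaxation_at_instants(dataset, instant)
  if (!is.null(donors)) at <- at[at$donor_id %in% donors, ]
  groups <- split(at$ratio, at$strain_level)
  oneway_f(groups)
}
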