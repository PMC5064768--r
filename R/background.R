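# Background model of demethylation. The genome does not demethylate
# uniformly; to find regions deviating from the global trend we bin probes
# by their starting methylation (equal-occupancy bins) and keep, within
# each bin, the empirical distribution of the methylation change
# (end - start) as the expectation. Modelling the change rather than the
# raw end level removes the residual start-methylation trend inside a bin:
# an exact genome-wide shift then has zero scale in every bin. Probes
# significantly above the trend are demethylation-resistant ("escapees"),
# probes below are hyper-demethylated.

#' Fit a background model of demethylation
#'
#' @param mm long methylation matrix from [quantify_probes()]
#' @param start_sample,end_sample sample labels of the start and end points
#'   of the transition being modelled
#' @param n_bins number of equal-occupancy bins on start methylation
#' @param min_bin_n minimum probes per bin; bins are reduced (with a
#'   message) when fewer than `n_bins * min_bin_n` usable probes remain
#' @return an object of class `germ_background`: probe table (with the
#'   per-probe methylation change `delta`), per-bin empirical
#'   distributions of the change with median and MAD, and the fit
#'   parameters
#' @export
fit_background <- function(mm, start_sample, end_sample, n_bins = 20,
                           min_bin_n = 50) {
  wide <- mm %>%
    filter(sample %in% c(start_sample, end_sample)) %>%
    meth_matrix_wide()
  if (!all(c(start_sample, end_sample) %in% names(wide))) {
    abort("start_sample/end_sample not found in methylation matrix")
  }
  probes <- tibble(
    probe_id = wide$probe_id,
    start_fraction = wide[[start_sample]],
    end_fraction = wide[[end_sample]]
  ) %>%
    filter(!is.na(start_fraction), !is.na(end_fraction))
  n <- nrow(probes)
  if (n < 2 * min_bin_n) {
    abort(paste0("too few usable probes (", n, ") for at least 2 bins of ",
                 min_bin_n))
  }
  if (n < n_bins * min_bin_n) {
    n_bins <- max(2L, n %/% min_bin_n)
    inform(paste0("fit_background: reducing to ", n_bins, " bins for ", n,
                  " probes"))
  }
  breaks <- unique(quantile(probes$start_fraction,
                            probs = seq(0, 1, length.out = n_bins + 1),
                            type = 7, names = FALSE))
  if (length(breaks) < 2) {
    # all start values identical: a single bin holding everything
    inform("fit_background: start values identical; collapsing to one bin")
    probes$bin <- 1L
  } else {
    probes$bin <- as.integer(cut(probes$start_fraction, breaks = breaks,
                                 include.lowest = TRUE))
    if (length(breaks) - 1 < n_bins) {
      inform(paste0("fit_background: tied start values collapsed bins to ",
                    length(breaks) - 1))
    }
    # merge undersized bins (quantile ties) into their left neighbour
    repeat {
      sizes <- table(factor(probes$bin, levels = sort(unique(probes$bin))))
      small <- names(sizes)[sizes < min_bin_n]
      if (length(small) == 0 || length(sizes) <= 1) break
      b <- as.integer(small[1])
      lv <- sort(unique(probes$bin))
      target <- if (b == min(lv)) lv[lv > b][1] else max(lv[lv < b])
      probes$bin[probes$bin == b] <- target
    }
    probes$bin <- match(probes$bin, sort(unique(probes$bin)))
  }
  probes$delta <- probes$end_fraction - probes$start_fraction
  bins <- probes %>%
    group_by(bin) %>%
    summarise(
      n = n(),
      start_lo = min(start_fraction), start_hi = max(start_fraction),
      location = median(delta), scale = mad(delta),
      values = list(sort(delta)),
      .groups = "drop"
    )
  structure(
    list(probes = probes, bins = bins,
         params = list(start_sample = start_sample, end_sample = end_sample,
                       n_bins = max(probes$bin), min_bin_n = min_bin_n)),
    class = "germ_background"
  )
}

#' @export
print.germ_background <- function(x, ...) {
  cat("Background model of demethylation\n")
  cat("  transition:", x$params$start_sample, "->", x$params$end_sample, "\n")
  cat("  probes:", nrow(x$probes), " bins:", nrow(x$bins), "\n")
  invisible(x)
}

#' Call outlier probes against a background model
#'
#' Scores each probe's methylation change (end - start) against the
#' empirical distribution of changes in its start-methylation bin.
#' `method = "empirical"` uses the add-one-smoothed two-sided empirical
#' tail probability `p = min(1, 2 min(#\{v <= x\}, #\{v >= x\}) / (n + 1))`
#' over the bin's `n` members; it is distribution-free and exactly
#' calibrated, but its attainable p floor is `2/(n+1)`. `method = "zscore"`
#' uses a robust normal approximation from the bin median and MAD; it is
#' resistant to contamination of the bin by true outliers and yields
#' continuous p-values suitable for Benjamini-Hochberg correction, which
#' is the recommended configuration for escapee discovery.
#'
#' @param model a `germ_background` object
#' @param alpha significance threshold (default 0.05)
#' @param correction `"none"` (raw p, default) or `"bh"`
#'   (Benjamini-Hochberg before thresholding)
#' @param method `"empirical"` (default) or `"zscore"`
#' @return tibble of class `germ_outliers` (`probe_id`, `start_fraction`,
#'   `end_fraction`, `bin`, `p`, `p_adj`, `class` in higher/lower/ns)
#' @export
call_outliers <- function(model, alpha = 0.05,
                          correction = c("none", "bh"),
                          method = c("empirical", "zscore")) {
  stopifnot(inherits(model, "germ_background"))
  correction <- match.arg(correction)
  method <- match.arg(method)
  probes <- model$probes
  bins <- model$bins
  if (any(!probes$bin %in% bins$bin)) abort("probe outside all bins")
  p <- numeric(nrow(probes))
  loc <- numeric(nrow(probes))
  for (i in seq_len(nrow(bins))) {
    sel <- probes$bin == bins$bin[i]
    x <- probes$delta[sel]
    v <- bins$values[[i]]
    n <- length(v)
    loc[sel] <- bins$location[i]
    if (method == "empirical") {
      lo <- findInterval(x, v)                    # #{v <= x}
      hi <- n - findInterval(x, v, left.open = TRUE)  # #{v >= x}
      p[sel] <- pmin(1, 2 * pmin(lo, hi) / (n + 1))
    } else {
      s <- bins$scale[i]
      if (s <= 0) {
        p[sel] <- ifelse(x == bins$location[i], 1, .Machine$double.xmin)
      } else {
        z <- (x - bins$location[i]) / s
        p[sel] <- 2 * pnorm(-abs(z))
      }
    }
  }
  p_adj <- if (correction == "bh") p.adjust(p, method = "BH") else p
  out <- probes %>%
    mutate(
      p = p, p_adj = p_adj,
      class = case_when(
        p_adj < alpha & delta > loc ~ "higher",
        p_adj < alpha & delta < loc ~ "lower",
        TRUE ~ "ns"
      )
    )
  attr(out, "alpha") <- alpha
  attr(out, "correction") <- correction
  attr(out, "method") <- method
  class(out) <- c("germ_outliers", class(out))
  out
}

#' @export
tidy.germ_background <- function(x, ...) {
  x$bins %>% select(bin, n, start_lo, start_hi, location, scale)
}

#' @export
glance.germ_background <- function(x, ...) {
  tibble(
    n_probes = nrow(x$probes), n_bins = nrow(x$bins),
    start_sample = x$params$start_sample, end_sample = x$params$end_sample,
    mean_start = mean(x$probes$start_fraction),
    mean_end = mean(x$probes$end_fraction)
  )
}

#' Plot a background model with outlier calls
#'
#' Start vs end methylation scatter; if `calls` is supplied, probes are
#' coloured by their outlier class (resistant probes red, hyper-demethylated
#' blue), mirroring the standard scatter-band view of non-uniform
#' demethylation.
#'
#' @param object a `germ_background` object
#' @param calls optional `germ_outliers` tibble from [call_outliers()]
#' @param ... ignored
#' @return a ggplot object
#' @export
autoplot.germ_background <- function(object, calls = NULL, ...) {
  d <- if (is.null(calls)) {
    object$probes %>% mutate(class = "ns")
  } else {
    as_tibble(calls)
  }
  ggplot(d, aes(x = start_fraction, y = end_fraction, colour = class)) +
    geom_point(size = 0.4, alpha = 0.6) +
    scale_colour_manual(values = c(higher = "#d7301f", lower = "#0570b0",
                                   ns = "grey60")) +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = object$params$start_sample, y = object$params$end_sample) +
    theme_minimal()
}
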