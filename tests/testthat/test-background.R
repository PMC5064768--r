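# Background model of demethylation and outlier calling.

# synthetic start/end fractions as a long methylation matrix
bg_mm <- function(start, end) {
  n <- length(start)
  bind_rows(
    tibble(probe_id = paste0("p", seq_len(n)), sample = "start",
           meth_fraction = start, total_calls = 100L, covered_cpgs = 50L),
    tibble(probe_id = paste0("p", seq_len(n)), sample = "end",
           meth_fraction = end, total_calls = 100L, covered_cpgs = 50L)
  )
}

test_that("an exact uniform shift yields no outliers", {
  withr::with_seed(1, start <- runif(500, 0.4, 0.9))
  m <- fit_background(bg_mm(start, start - 0.3), "start", "end",
                      n_bins = 5, min_bin_n = 50)
  out <- call_outliers(m)
  expect_true(all(out$class == "ns"))
  expect_true(all(tidy(m)$scale >= 0))
})

test_that("identical start values collapse to a single bin", {
  withr::with_seed(2, end <- runif(200))
  expect_message(
    m <- fit_background(bg_mm(rep(0.6, 200), end), "start", "end",
                        n_bins = 5, min_bin_n = 20),
    "collaps")
  expect_equal(nrow(m$bins), 1L)
})

test_that("too few probes for two bins errors", {
  expect_error(
    fit_background(bg_mm(runif(30), runif(30)), "start", "end",
                   n_bins = 5, min_bin_n = 50),
    "too few")
})

test_that("bin medians match an independent sort-based oracle", {
  withr::with_seed(3, {
    start <- runif(2000, 0.2, 0.9)
    end <- pmax(0, start - 0.3 + rnorm(2000, sd = 0.05))
  })
  m <- fit_background(bg_mm(start, end), "start", "end",
                      n_bins = 10, min_bin_n = 50)
  med_oracle <- vapply(sort(unique(m$probes$bin)), function(b) {
    v <- sort(m$probes$delta[m$probes$bin == b])
    k <- length(v)
    if (k %% 2 == 1) v[(k + 1) / 2] else mean(v[k / 2 + 0:1])
  }, numeric(1))
  expect_equal(m$bins$location, med_oracle)
})

test_that("a probe at its bin median is never significant", {
  withr::with_seed(4, {
    start <- runif(400, 0.4, 0.6)
    end <- runif(400, 0.1, 0.5)
  })
  m <- fit_background(bg_mm(start, end), "start", "end",
                      n_bins = 2, min_bin_n = 100)
  out <- call_outliers(m)
  at_median <- out$delta == m$bins$location[out$bin]
  expect_true(all(out$class[at_median] == "ns"))
})

test_that("raising an end fraction never lowers its high-side standing", {
  withr::with_seed(5, {
    start <- runif(300, 0.4, 0.9)
    end <- start - 0.3 + rnorm(300, sd = 0.05)
  })
  for (method in c("empirical", "zscore")) {
    m <- fit_background(bg_mm(start, end), "start", "end",
                        n_bins = 3, min_bin_n = 50)
    out <- call_outliers(m, method = method)
    # bump one probe's end value upward within its bin and refit scoring
    i <- which(out$class == "higher")[1]
    if (is.na(i)) i <- which.max(out$end_fraction - m$bins$location[out$bin])
    end2 <- end
    end2[i] <- min(1, end2[i] + 0.2)
    m2 <- fit_background(bg_mm(start, end2), "start", "end",
                         n_bins = 3, min_bin_n = 50)
    out2 <- call_outliers(m2, method = method)
    expect_false(out2$class[i] == "lower")
    if (out$class[i] == "higher") expect_equal(out2$class[i], "higher")
  }
})

test_that("empirical p-values are calibrated under the null", {
  flagged <- 0; total <- 0
  for (s in 1:3) {
    withr::with_seed(100 + s, {
      start <- runif(2000, 0.35, 0.9)
      end <- start - 0.25 + rnorm(2000, sd = 0.06)
    })
    m <- fit_background(bg_mm(start, end), "start", "end",
                        n_bins = 10, min_bin_n = 50)
    out <- call_outliers(m, alpha = 0.05)
    flagged <- flagged + sum(out$class != "ns")
    total <- total + nrow(out)
  }
  ci <- 0.05 + c(-1, 1) * 2.576 * sqrt(0.05 * 0.95 / total)
  expect_gt(flagged / total, ci[1])
  expect_lt(flagged / total, ci[2])
})

test_that("robust z with BH recovers planted escapees", {
  withr::with_seed(77, {
    n <- 2000
    start <- runif(n, 0.4, 0.9)
    end <- start - 0.3 + rnorm(n, sd = 0.05)
    planted <- sample.int(n, n * 0.05)
    end[planted] <- end[planted] + 0.35
  })
  m <- fit_background(bg_mm(start, end), "start", "end",
                      n_bins = 10, min_bin_n = 50)
  out <- call_outliers(m, method = "zscore", correction = "bh")
  is_planted <- seq_len(n) %in% planted
  called_high <- out$class == "higher"
  sens <- sum(called_high & is_planted) / sum(is_planted)
  fdp <- sum(called_high & !is_planted) / max(1, sum(called_high))
  expect_gte(sens, 0.9)
  expect_lte(fdp, 0.1)
})
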