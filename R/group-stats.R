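#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the D'Agostino skewness Z and the Anscombe-Glynn kurtosis Z into
#' `K2 = Z1^2 + Z2^2`, referred to a chi-squared distribution with 2 df.
#' Requires n >= 8 (the kurtosis transform is undefined below that).
#'
#' @param x numeric sample.
#' @return List with `statistic` (K2), `p_value`, `z_skew`, `z_kurt`, `n`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) abort("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  if (m2 == 0) abort("sample is constant: normality test undefined")

  # skewness component (D'Agostino 1970)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis component (Anscombe & Glynn 1983)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(statistic = k2, p_value = pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2, n = n)
}

#' Significance star labels
#'
#' `ns` / `*` / `**` / `***` / `****` by strict inequality at 0.05, 0.01,
#' 0.001 and 0.0001.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return Character vector of labels.
#' @export
star_labels <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p must lie in [0, 1]")
  }
  dplyr::case_when(p < 0.0001 ~ "****", p < 0.001 ~ "***",
                   p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "ns")
}

#' Normality-gated two-group comparison
#'
#' Reproduces the study's test-selection rule. With `distributional = TRUE`
#' the two-sample Kolmogorov-Smirnov test is used. With `paired = TRUE` a
#' paired t test is used (a normality caveat is recorded in `notes` when
#' either sample fails the gate). Otherwise: if both groups have n >= 8 and
#' pass the D'Agostino-Pearson normality test at alpha = 0.05, an unpaired
#' two-tailed t test is run, upgraded to the Welch correction when an F test
#' of variance equality rejects at alpha = 0.05; groups that are small
#' (n < 8) or non-normal are compared with the two-tailed Mann-Whitney U test
#' (exact p for min(n) <= 8 without ties, normal approximation with tie
#' correction otherwise).
#'
#' @param a,b numeric samples.
#' @param paired force a paired t test (equal lengths required).
#' @param distributional compare full distributions with the two-sample KS
#'   test.
#' @param alpha gate level for the normality and variance-equality tests.
#' @param labels length-2 character group labels.
#' @return A `bq_comparison` object; see [tidy.bq_comparison()].
#' @export
compare_groups <- function(a, b, paired = FALSE, distributional = FALSE,
                           alpha = 0.05, labels = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("need n >= 2 per group")
  if (paired && length(a) != length(b)) {
    abort("paired comparison requires equal-length samples")
  }
  notes <- character()

  norm_p <- c(NA_real_, NA_real_)
  normal <- c(FALSE, FALSE)
  for (i in 1:2) {
    x <- if (i == 1) a else b
    if (length(x) >= 8 && sd(x) > 0) {
      norm_p[i] <- dagostino_pearson_test(x)$p_value
      normal[i] <- norm_p[i] > alpha
    } else if (length(x) < 8) {
      notes <- c(notes, sprintf(
        "group %s has n < 8: treated as non-normal", labels[i]))
    }
  }

  if (distributional) {
    ht <- suppressWarnings(ks.test(a, b))
    test <- "ks_2samp"
  } else if (paired) {
    if (!all(normal)) {
      notes <- c(notes, "paired t test forced despite failed normality gate")
    }
    ht <- t.test(a, b, paired = TRUE)
    test <- "paired_t"
  } else if (all(normal)) {
    var_p <- var.test(a, b)$p.value
    welch <- var_p < alpha
    ht <- t.test(a, b, var.equal = !welch)
    test <- if (welch) "welch_t" else "student_t"
  } else {
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- min(length(a), length(b)) <= 8 && !ties
    ht <- suppressWarnings(wilcox.test(a, b, exact = exact, correct = !exact))
    test <- "mann_whitney"
  }

  structure(list(
    labels = labels, n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)), sem = c(sem(a), sem(b)),
    normality_p = norm_p, test_used = test,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    stars = star_labels(ht$p.value), notes = notes),
    class = "bq_comparison")
}

#' @export
print.bq_comparison <- function(x, ...) {
  cat(sprintf("<bq_comparison> %s vs %s: %s, stat = %.4g, p = %.4g (%s)\n",
              x$labels[1], x$labels[2], x$test_used, x$statistic,
              x$p_value, x$stars))
  if (length(x$notes)) cat(paste0("  note: ", x$notes, "\n"))
  invisible(x)
}

#' @rdname compare_groups
#' @param x a `bq_comparison`.
#' @param ... unused.
#' @export
tidy.bq_comparison <- function(x, ...) {
  tibble(test = x$test_used, statistic = x$statistic, p_value = x$p_value,
         stars = x$stars,
         n_a = x$n[1], n_b = x$n[2],
         mean_a = x$mean[1], mean_b = x$mean[2],
         sem_a = x$sem[1], sem_b = x$sem[2],
         normality_p_a = x$normality_p[1], normality_p_b = x$normality_p[2],
         notes = paste(x$notes, collapse = "; "))
}

#' @rdname compare_groups
#' @export
glance.bq_comparison <- function(x, ...) {
  tibble(test = x$test_used, p_value = x$p_value, stars = x$stars)
}

#' Animal-level summary of nested measurements
#'
#' Means per animal, then mean +/- SEM across animal means, reported
#' alongside the pooled per-observation summary.
#'
#' @param values numeric measurements.
#' @param animal_ids animal identifier per measurement.
#' @return List with `per_animal` (tibble) and `summary` (one-row tibble with
#'   pooled and animal-level mean/SEM); SEM is `NA` with a note for a single
#'   animal.
#' @export
per_animal_summary <- function(values, animal_ids) {
  if (length(values) != length(animal_ids) || anyNA(animal_ids)) {
    abort("every value needs an animal id")
  }
  per_animal <- tibble(animal = animal_ids, value = values) |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(),
                     .groups = "drop")
  note <- if (nrow(per_animal) < 2) "single animal: SEM undefined" else
    NA_character_
  summary <- tibble(
    n_obs = length(values), pooled_mean = mean(values),
    pooled_sem = sem(values),
    n_animals = nrow(per_animal),
    animal_mean = mean(per_animal$mean),
    animal_sem = sem(per_animal$mean),
    note = note)
  list(per_animal = per_animal, summary = summary)
}
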