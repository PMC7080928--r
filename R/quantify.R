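# Group statistics over per-nucleus foci counts: summaries with the animal
# as the experimental unit, zero-foci fractions, count histograms, one-way
# ANOVA and Tukey HSD.

#' Tidy per-nucleus foci count table
#'
#' @param animal_id,group,tissue,cell_class,nucleus_id,n_foci vectors of
#'   equal length (recycled where length 1)
#' @param groups declared set of valid group labels
#' @return a tibble of class `foci_count_table`
#' @export
foci_count_table <- function(animal_id, group, tissue, cell_class,
                             nucleus_id, n_foci,
                             groups = c("control", "4h", "25h")) {
  tb <- tibble::tibble(animal_id = animal_id, group = group, tissue = tissue,
                       cell_class = cell_class,
                       nucleus_id = as.integer(nucleus_id),
                       n_foci = as.integer(n_foci))
  if (any(!tb$group %in% groups))
    stop("group values outside the declared set: ",
         paste(setdiff(unique(tb$group), groups), collapse = ", "))
  if (any(tb$n_foci < 0)) stop("n_foci must be non-negative")
  key <- paste(tb$animal_id, tb$tissue, tb$nucleus_id)
  if (anyDuplicated(key)) stop("(animal, tissue, nucleus_id) must be unique")
  class(tb) <- c("foci_count_table", class(tb))
  tb
}

#' Group summaries of foci per nucleus
#'
#' With `unit = "animal"` (default, matching a design where the animal is
#' the experimental unit) the per-animal means are computed first and the
#' group mean and SD are taken over animal means; the SD is flagged
#' undefined (`NA` with `sd_defined = FALSE`) for single-animal groups.
#' `unit = "nucleus"` pools all nuclei.
#'
#' @param table a [foci_count_table()]
#' @param unit `"animal"` or `"nucleus"`
#' @return tibble with one row per group x cell_class: n_animals, n_nuclei,
#'   mean_foci, sd_foci, sd_defined, and (animal unit) a list column of
#'   per-animal means
#' @export
summarize_groups <- function(table, unit = c("animal", "nucleus")) {
  unit <- match.arg(unit)
  stopifnot(nrow(table) > 0)
  if (unit == "animal") {
    per_animal <- table |>
      dplyr::group_by(group, cell_class, animal_id) |>
      dplyr::summarize(animal_mean = mean(n_foci), n_nuclei = dplyr::n(),
                       .groups = "drop")
    per_animal |>
      dplyr::group_by(group, cell_class) |>
      dplyr::summarize(n_animals = dplyr::n(),
                       n_nuclei = sum(n_nuclei),
                       mean_foci = mean(animal_mean),
                       sd_foci = ifelse(dplyr::n() > 1,
                                        stats::sd(animal_mean), NA_real_),
                       sd_defined = dplyr::n() > 1,
                       animal_means = list(animal_mean),
                       .groups = "drop")
  } else {
    table |>
      dplyr::group_by(group, cell_class) |>
      dplyr::summarize(n_animals = dplyr::n_distinct(animal_id),
                       n_nuclei = dplyr::n(),
                       mean_foci = mean(n_foci),
                       sd_foci = stats::sd(n_foci),
                       sd_defined = dplyr::n() > 1,
                       .groups = "drop")
  }
}

#' Fraction of nuclei without any focus
#'
#' @param table a [foci_count_table()]
#' @return tibble per group x cell_class: n_nuclei, zero_fraction
#' @export
zero_foci_fraction <- function(table) {
  stopifnot(nrow(table) > 0)
  table |>
    dplyr::group_by(group, cell_class) |>
    dplyr::summarize(n_nuclei = dplyr::n(),
                     zero_fraction = mean(n_foci == 0), .groups = "drop")
}

#' Histogram of foci counts per nucleus
#'
#' Fractions of analyzed nuclei containing each observed focus count, per
#' group x cell_class stratum; fractions sum to 1 within each stratum.
#'
#' @param table a [foci_count_table()]
#' @return tibble: group, cell_class, n_foci, fraction
#' @export
count_histogram <- function(table) {
  stopifnot(nrow(table) > 0)
  table |>
    dplyr::group_by(group, cell_class) |>
    dplyr::count(n_foci, name = "n_nuclei") |>
    dplyr::mutate(fraction = n_nuclei / sum(n_nuclei)) |>
    dplyr::ungroup() |>
    dplyr::select(group, cell_class, n_foci, fraction)
}

#' One-way ANOVA
#'
#' Classic fixed-effects one-way analysis of variance over k groups, fitted
#' via [stats::lm()]. When the within-group variance is zero with a nonzero
#' between-group variance, F is reported as infinite with p = 0 and the
#' result is flagged degenerate.
#'
#' @param groups list of k >= 2 numeric vectors (each non-empty)
#' @return object of class `anova_result`: F, df_between, df_within, p,
#'   degenerate flag
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, integer(1)) >= 1))
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_len(k), times = vapply(groups, length, integer(1))))
  n <- length(values)
  if (n - k < 1) stop("need N - k >= 1 residual degrees of freedom")
  # suppress the "essentially perfect fit" warning for the degenerate
  # zero-within-variance case, which is flagged explicitly below
  tab <- suppressWarnings(stats::anova(stats::lm(values ~ fac)))
  ssb <- tab$`Sum Sq`[1]; ssw <- tab$`Sum Sq`[2]
  dfb <- tab$Df[1]; dfw <- tab$Df[2]
  msb <- ssb / dfb; msw <- ssw / dfw
  degenerate <- msw <= .Machine$double.eps * max(1, msb)
  f <- if (degenerate && msb > 0) Inf else if (degenerate) 0 else msb / msw
  p <- if (is.infinite(f)) 0 else stats::pf(f, dfb, dfw, lower.tail = FALSE)
  structure(list(F = f, df_between = dfb, df_within = dfw, p = p,
                 degenerate = degenerate, ms_within = msw,
                 means = vapply(groups, mean, numeric(1)),
                 n = vapply(groups, length, integer(1))),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$degenerate) " (degenerate: zero within-group variance)" else ""))
  invisible(x)
}

#' Tukey HSD post hoc test
#'
#' All pairwise comparisons after a one-way ANOVA using the studentized
#' range distribution; unbalanced designs use the Tukey-Kramer standard
#' error `sqrt(MS_within * (1/n_i + 1/n_j) / 2)`.
#'
#' @param groups list of k >= 2 numeric vectors
#' @return tibble of class `tukey_result`: group_i, group_j, diff (mean_j -
#'   mean_i), q (studentized range statistic), p_adj
#' @export
tukey_hsd <- function(groups) {
  a <- one_way_anova(groups)
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    d <- a$means[j] - a$means[i]
    se <- sqrt(a$ms_within * (1 / a$n[i] + 1 / a$n[j]) / 2)
    q <- if (se > 0) abs(d) / se else if (d == 0) 0 else Inf
    p <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = a$df_within, lower.tail = FALSE)
    tibble::tibble(group_i = i, group_j = j, diff = d, q = q, p_adj = p)
  })
  res <- dplyr::bind_rows(out)
  class(res) <- c("tukey_result", class(res))
  res
}
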