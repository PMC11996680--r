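# Hierarchical (superplot) aggregation of per-track or per-microtubule
# values through the replicate hierarchy condition > experiment > movie >
# microtubule, and directionality proportion summaries.

#' Aggregate values through the replicate hierarchy
#'
#' Superplot-style aggregation: values measured per microtubule (or per
#' track) are mapped through the manifest and summarized at the requested
#' level. Experiment-level values are the means of the microtubule values
#' within each experiment; movie level likewise. The pooled distribution is
#' summarized with the median, quartiles and 10th/90th percentiles — the
#' quantities drawn in a superplot box.
#'
#' @param values Data frame with a `context_id` column and the value column.
#' @param manifest Validated manifest mapping contexts to movies,
#'   experiments and conditions.
#' @param value_col Name of the numeric column to aggregate.
#' @param level `"mt"`, `"movie"` or `"experiment"`.
#' @return Object of class `superplot_summary`: list with `condition`-split
#'   components `values` (per-unit values at the requested level),
#'   `experiment_means`, `pooled` (median, q1, q3, p10, p90) and counts.
#' @export
aggregate_values <- function(values, manifest, value_col,
                             level = c("mt", "movie", "experiment")) {
  level <- match.arg(level)
  manifest <- validate_manifest(manifest)
  if (!value_col %in% names(values))
    stop("no column '", value_col, "' in values")
  idx <- match(as.character(values$context_id), manifest$context_id)
  if (anyNA(idx)) {
    orphan <- unique(as.character(values$context_id)[is.na(idx)])
    stop("value rows reference context(s) absent from the manifest: ",
         paste(orphan, collapse = ", "))
  }
  df <- data.frame(
    condition = manifest$condition[idx],
    experiment_id = manifest$experiment_id[idx],
    movie_id = manifest$movie_id[idx],
    context_id = as.character(values$context_id),
    value = values[[value_col]]
  )
  per_cond <- lapply(split(df, df$condition), function(d) {
    unit <- switch(level,
      mt = d$value,
      movie = tapply(d$value, d$movie_id, mean),
      experiment = tapply(d$value, d$experiment_id, mean))
    unit <- as.numeric(unit)
    exp_means <- tapply(d$value, d$experiment_id, mean)
    qs <- stats::quantile(unit, c(0.10, 0.25, 0.50, 0.75, 0.90),
                          names = FALSE, type = 7)
    list(values = unit,
         experiment_means = as.numeric(exp_means),
         experiment_ids = names(exp_means),
         pooled = list(median = qs[3], q1 = qs[2], q3 = qs[4],
                       p10 = qs[1], p90 = qs[5]),
         n = length(unit),
         n_mt = length(unique(d$context_id)),
         n_movies = length(unique(d$movie_id)),
         n_experiments = length(unique(d$experiment_id)))
  })
  structure(list(level = level, value_col = value_col, conditions = per_cond),
            class = "superplot_summary")
}

#' @export
print.superplot_summary <- function(x, ...) {
  cat("Superplot summary of '", x$value_col, "' at level '", x$level, "'\n",
      sep = "")
  for (nm in names(x$conditions)) {
    c_ <- x$conditions[[nm]]
    cat(sprintf(
      "  %s: n = %d (%d mt / %d movies / %d experiments), median = %.4g [q1 %.4g, q3 %.4g]\n",
      nm, c_$n, c_$n_mt, c_$n_movies, c_$n_experiments,
      c_$pooled$median, c_$pooled$q1, c_$pooled$q3))
  }
  invisible(x)
}

#' Flatten a superplot summary to a data frame
#'
#' @param summary A `superplot_summary`.
#' @return Data frame with one row per condition (pooled quantiles, counts).
#' @export
superplot_table <- function(summary) {
  rows <- lapply(names(summary$conditions), function(nm) {
    c_ <- summary$conditions[[nm]]
    data.frame(condition = nm, level = summary$level,
               n = c_$n, n_mt = c_$n_mt, n_movies = c_$n_movies,
               n_experiments = c_$n_experiments,
               median = c_$pooled$median, q1 = c_$pooled$q1,
               q3 = c_$pooled$q3, p10 = c_$pooled$p10, p90 = c_$pooled$p90,
               mean_of_experiment_means = mean(c_$experiment_means))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

CLASS_LEVELS <- c("static", "plus", "minus", "bidirectional")

#' Directionality proportions, pooled and per experiment
#'
#' Pooled per-class counts and fractions across all tracks, and the mean ±
#' sample s.d. of the per-experiment class fractions — the two conventions
#' for reporting directionality: pooled fractions describe the track
#' population, per-experiment means ± s.d. describe replicate-to-replicate
#' spread. Both are reported and labeled; they differ whenever experiments
#' contribute unequal track numbers.
#'
#' @param classifications Data frame from [classify_tracks()] (needs
#'   `track_id`, `context_id`, `label`).
#' @param manifest Manifest mapping contexts to experiments.
#' @return List: `pooled` (data frame class/count/fraction), `total_tracks`,
#'   `per_experiment` (class fractions per experiment), `experiment_summary`
#'   (mean and sd of fractions per class), `n_experiments`.
#' @export
directionality_proportions <- function(classifications, manifest) {
  manifest <- validate_manifest(manifest)
  idx <- match(as.character(classifications$context_id), manifest$context_id)
  if (anyNA(idx)) {
    orphan <- unique(as.character(classifications$context_id)[is.na(idx)])
    stop("classification rows reference context(s) absent from the manifest: ",
         paste(orphan, collapse = ", "))
  }
  lab <- factor(classifications$label, levels = CLASS_LEVELS)
  if (anyNA(lab)) stop("unknown class label(s)")
  total <- length(lab)
  counts <- table(lab)
  pooled <- data.frame(class = CLASS_LEVELS,
                       count = as.integer(counts),
                       fraction = as.numeric(counts) / total)
  expid <- manifest$experiment_id[idx]
  per_exp <- do.call(rbind, lapply(split(seq_along(lab), expid), function(ii) {
    tab <- table(lab[ii])
    data.frame(experiment_id = expid[ii[1]], class = CLASS_LEVELS,
               count = as.integer(tab),
               fraction = as.numeric(tab) / length(ii))
  }))
  rownames(per_exp) <- NULL
  summ <- do.call(rbind, lapply(CLASS_LEVELS, function(cl) {
    fr <- per_exp$fraction[per_exp$class == cl]
    data.frame(class = cl, mean_fraction = mean(fr),
               sd_fraction = if (length(fr) > 1) stats::sd(fr) else 0)
  }))
  list(pooled = pooled, total_tracks = total, per_experiment = per_exp,
       experiment_summary = summ,
       n_experiments = length(unique(expid)))
}
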