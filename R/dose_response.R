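#' Percent change from baseline
#'
#' The plate assay's dose-response readout: `100 * (post - pre) / pre` per
#' well. Undefined or zero pre-compound values yield `NA` (the well is
#' excluded, never counted as zero change).
#'
#' @param post,pre Numeric vectors (post- and pre-compound values).
#' @return Percent change(s).
#' @examples
#' percent_change(250, 200)   # +25
#' percent_change(200, 200)   # 0
#' @export
percent_change <- function(post, pre) {
  out <- 100 * (post - pre) / pre
  out[!is.finite(pre) | pre == 0] <- NA_real_
  out
}

#' Default evaluation parameters for dose-response tables
#' @return Character vector of well-summary column names.
#' @export
dose_response_parameters <- function() {
  c("beat_rate", "amplitude_mean", "v_up_mean", "v_down_mean",
    "pwd20cF", "pwd30cF", "pwd40cF", "pwd50cF", "pwd70cF", "pwd80cF",
    "pwd90cF", "pwd30_80")
}

#' Build a percent-change dose-response table
#'
#' For every (drug, group, concentration, parameter) condition, computes the
#' per-well percent change from the pre-compound baseline and aggregates it
#' as mean, SD and contributing well count. Wells labeled `arrest` in the
#' post phase are excluded from parameter means (their parameters are
#' undefined) but remain in incidence denominators; wells with an undefined
#' pre-phase value are excluded with a message.
#'
#' @param pre_summaries,post_summaries Data.frames of per-well summaries
#'   (one row per well, as from [as.data.frame.well_summary()]), keyed by
#'   `well_id`.
#' @param plate_map Data.frame with `well`, `group`, `drug`,
#'   `concentration_uM` (post-phase rows used if a `phase` column exists).
#' @param parameters Summary columns to tabulate.
#' @param event_calls Optional data.frame (`well_id`, `label`) of post-phase
#'   event calls; arrest wells are dropped from the means.
#' @return Data.frame of class `dose_response` with columns `drug`, `group`,
#'   `concentration_uM`, `parameter`, `mean_pct`, `sd_pct`, `n`; the
#'   per-well percent changes are attached as attribute `"per_well"`.
#' @export
build_dose_response <- function(pre_summaries, post_summaries, plate_map,
                                parameters = dose_response_parameters(),
                                event_calls = NULL) {
  pm <- plate_map
  if ("phase" %in% names(pm)) pm <- pm[pm$phase == "post", , drop = FALSE]
  pm <- unique(pm[, c("well", "group", "drug", "concentration_uM")])

  post <- post_summaries
  if (!is.null(event_calls)) {
    arrested <- event_calls$well_id[event_calls$label == "arrest"]
    post <- post[!post$well_id %in% arrested, , drop = FALSE]
  }
  m <- merge(post, pre_summaries, by = "well_id",
             suffixes = c("_post", "_pre"))
  dropped <- setdiff(post$well_id, m$well_id)
  if (length(dropped)) {
    message("wells without a pre-phase summary excluded: ",
            paste(dropped, collapse = ", "))
  }
  per_well <- data.frame(well_id = m$well_id, stringsAsFactors = FALSE)
  for (p in parameters) {
    pre_col <- paste0(p, "_pre")
    post_col <- paste0(p, "_post")
    if (!pre_col %in% names(m)) {
      stop("parameter '", p, "' not present in the summaries", call. = FALSE)
    }
    per_well[[p]] <- percent_change(m[[post_col]], m[[pre_col]])
  }
  per_well <- merge(per_well, pm, by.x = "well_id", by.y = "well")

  key <- interaction(per_well$drug, per_well$group,
                     per_well$concentration_uM, drop = TRUE)
  rows <- list()
  for (g in split(per_well, key)) {
    for (p in parameters) {
      v <- g[[p]]
      v <- v[is.finite(v)]
      rows[[length(rows) + 1L]] <- data.frame(
        drug = g$drug[1], group = g$group[1],
        concentration_uM = g$concentration_uM[1], parameter = p,
        mean_pct = if (length(v)) mean(v) else NA_real_,
        sd_pct = if (length(v) >= 2) stats::sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    drug = character(0), group = character(0),
    concentration_uM = numeric(0), parameter = character(0),
    mean_pct = numeric(0), sd_pct = numeric(0), n = integer(0)
  )
  out <- out[order(out$drug, out$group, out$concentration_uM, out$parameter), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "per_well") <- per_well
  class(out) <- c("dose_response", "data.frame")
  out
}

#' Compare two independent groups
#'
#' The assay's two-sample comparison: Shapiro-Wilk normality check on each
#' sample, an F-ratio test of variance homogeneity at alpha = 0.05, then
#' Student's t-test when variances are homogeneous and Welch's t-test
#' otherwise (two-sided).
#'
#' @param a,b Numeric samples (each n >= 3 required).
#' @param alpha_var Significance level of the variance-homogeneity gate.
#' @return An object of class `stat_result`: `test` (`"student_t"` or
#'   `"welch_t"`), `shapiro_p`, `variance_p`, `statistic`, `p`, `sig05`,
#'   `sig01`. With n < 3 in either sample, `test = "not_evaluable"` and the
#'   numeric fields are `NA`.
#' @export
compare_groups <- function(a, b, alpha_var = 0.05) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 3 || length(b) < 3) {
    return(structure(list(test = "not_evaluable",
                          shapiro_p = c(a = NA_real_, b = NA_real_),
                          variance_p = NA_real_, statistic = NA_real_,
                          p = NA_real_, sig05 = NA, sig01 = NA),
                     class = "stat_result"))
  }
  shap <- function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  sp <- c(a = shap(a), b = shap(b))
  vp <- if (stats::sd(a) == 0 && stats::sd(b) == 0) 1 else
    tryCatch(stats::var.test(a, b)$p.value, error = function(e) NA_real_)
  equal_var <- is.finite(vp) && vp >= alpha_var
  tt <- stats::t.test(a, b, var.equal = equal_var)
  structure(
    list(test = if (equal_var) "student_t" else "welch_t",
         shapiro_p = sp, variance_p = vp,
         statistic = unname(tt$statistic), p = tt$p.value,
         sig05 = tt$p.value < 0.05, sig01 = tt$p.value < 0.01),
    class = "stat_result"
  )
}

#' Compare three or more groups (one-way ANOVA + Tukey HSD)
#'
#' One-way analysis of variance across the groups followed by Tukey's
#' honestly-significant-difference test for all pairwise comparisons.
#'
#' @param groups Named list of numeric samples (>= 3 groups, each n >= 3).
#' @return An object of class `stat_result`: `test = "anova_tukey"`,
#'   `statistic` (F), `p`, `sig05`, `sig01`, `shapiro_p` per group and
#'   `tukey` (data.frame: `comparison`, `diff`, `p_adj`, `sig05`).
#' @export
compare_multi <- function(groups) {
  if (!is.list(groups) || length(groups) < 3) {
    stop("compare_multi() needs at least 3 groups; ",
         "use compare_groups() for two-sample comparisons", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(x) x[is.finite(x)])
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop("each group needs n >= 3", call. = FALSE)
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  Fv <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(
    comparison = rownames(tk), diff = tk[, "diff"], p_adj = tk[, "p adj"],
    sig05 = tk[, "p adj"] < 0.05, row.names = NULL,
    stringsAsFactors = FALSE
  )
  shap <- vapply(groups, function(x) {
    if (stats::sd(x) == 0) NA_real_ else stats::shapiro.test(x)$p.value
  }, numeric(1))
  structure(
    list(test = "anova_tukey", shapiro_p = shap, variance_p = NA_real_,
         statistic = Fv, p = p, sig05 = p < 0.05, sig01 = p < 0.01,
         tukey = tukey),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat("Statistical comparison:", x$test, "\n")
  if (x$test == "not_evaluable") {
    cat("  insufficient sample size (n < 3)\n")
    return(invisible(x))
  }
  cat(sprintf("  statistic = %.4g, p = %.4g%s\n", x$statistic, x$p,
              if (isTRUE(x$sig01)) " (**)" else if (isTRUE(x$sig05)) " (*)" else ""))
  if (!is.null(x$tukey)) {
    cat("  Tukey HSD:\n")
    for (i in seq_len(nrow(x$tukey))) {
      cat(sprintf("    %s: diff %.3g, p_adj %.4g\n", x$tukey$comparison[i],
                  x$tukey$diff[i], x$tukey$p_adj[i]))
    }
  }
  invisible(x)
}
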